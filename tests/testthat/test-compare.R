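test_that("Spearman correlation handles identity, reversal and ties", {
  x <- stats::setNames(runif(100), paste0("p", 1:100))
  expect_equal(spearman_reliability(x, x)$rho, 1)
  y <- stats::setNames(rev(sort(x))[rank(x)], names(x))
  # reverse-ordered values: perfect negative rank correlation
  expect_equal(spearman_reliability(x, y)$rho, -1)

  a <- stats::setNames(c(0.1, 0.2, 0.2, 0.5, 0.7, 0.9), paste0("p", 1:6))
  b <- stats::setNames(c(0.3, 0.1, 0.6, 0.4, 0.8, 0.9), paste0("p", 1:6))
  res <- spearman_reliability(a, b)
  expect_equal(res$rho, oracle_spearman(a, b), tolerance = 1e-12)
  expect_equal(res$n_shared, 6L)

  # only shared, non-missing probes are used
  a2 <- c(a, pX = 0.5)
  b2 <- b
  b2["p1"] <- NA
  expect_equal(spearman_reliability(a2, b2)$n_shared, 5L)
  expect_error(spearman_reliability(a[1:2], b[1:2]), "at least 3")
  expect_error(spearman_reliability(unname(a), b), "named")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(21)
  x <- stats::setNames(runif(50), paste0("p", 1:50))
  y <- stats::setNames(runif(50), paste0("p", 1:50))
  base <- spearman_reliability(x, y)$rho
  expect_equal(spearman_reliability(exp(3 * x), y)$rho, base, tolerance = 1e-12)
  expect_equal(spearman_reliability(x, y^3 + 2)$rho, base, tolerance = 1e-12)
})

test_that("cross-tabulation counts, row percentages and concordance", {
  ids <- paste0("p", 1:5)
  a <- stats::setNames(c("Poor", "Fair", "Good", "Good", "Excellent"), ids)
  b <- stats::setNames(c("Poor", "Fair", "Fair", "Good", "Good"), ids)
  ct <- crosstab_classes(a, b)
  expect_equal(ct$concordance, 60.00)
  expect_equal(ct$n_total, 5L)
  expect_equal(unname(ct$counts["Good", c("Fair", "Good")]), c(1L, 1L))
  expect_equal(unname(ct$row_pct["Good", c("Fair", "Good")]), c(50.0, 50.0))

  # identical classifications: diagonal table, 100% concordance
  ct2 <- crosstab_classes(a, a)
  expect_equal(ct2$concordance, 100.00)
  expect_equal(sum(ct2$counts) - sum(diag(ct2$counts)), 0L)

  # relabeling probes consistently leaves the concordance unchanged
  perm <- sample(5)
  a3 <- stats::setNames(unname(a)[perm], paste0("q", 1:5))
  b3 <- stats::setNames(unname(b)[perm], paste0("q", 1:5))
  expect_equal(crosstab_classes(a3, b3)$concordance, ct$concordance)

  # Undefined probes excluded and counted
  a4 <- c(a, p6 = "Undefined")
  b4 <- c(b, p6 = "Poor")
  ct4 <- crosstab_classes(a4, b4)
  expect_equal(ct4$n_total, 5L)
  expect_equal(ct4$n_undefined, 1L)

  expect_error(crosstab_classes(a, stats::setNames(b, paste0("x", 1:5))),
               "no shared probes")
  expect_output(print(ct), "Concordance: 60.00%")
})

test_that("rank-sum contrast: exact enumeration and approximation agree", {
  tab <- data.frame(probe_id = paste0("p", 1:6), micc = c(1, 2, 3, 4, 5, 6),
                    icc = c(1, 2, 3, 4, 5, 6))
  flag <- stats::setNames(c(rep(TRUE, 3), rep(FALSE, 3)), tab$probe_id)
  res <- compare_groups(tab, flag, stat = "micc")
  # all 20 assignments of 3 ranks; only the two extremes are as extreme
  expect_equal(res$p_value, 0.1)
  expect_equal(res$median_in, 2)
  expect_equal(res$median_out, 5)
  expect_equal(res$method, "exact enumeration")

  # symmetric toy with identical groups: every assignment equally extreme
  tab2 <- data.frame(probe_id = paste0("p", 1:8),
                     micc = rep(c(0.1, 0.2, 0.3, 0.4), 2),
                     icc = rep(c(0.1, 0.2, 0.3, 0.4), 2))
  flag2 <- stats::setNames(rep(c(TRUE, FALSE), each = 4), tab2$probe_id)
  res2 <- compare_groups(tab2, flag2)
  expect_equal(res2$median_in - res2$median_out, 0)
  expect_equal(res2$p_value, 1)

  expect_error(compare_groups(tab, stats::setNames(rep(TRUE, 6), tab$probe_id)),
               "non-empty")
})

test_that("exact and normal-approximation p-values agree for n >= 8", {
  set.seed(33)
  for (i in 1:10) {
    x <- runif(8)
    y <- runif(9) + runif(1, -0.3, 0.3)
    tab <- data.frame(probe_id = paste0("p", 1:17), micc = c(x, y),
                      icc = c(x, y))
    flag <- stats::setNames(c(rep(TRUE, 8), rep(FALSE, 9)), tab$probe_id)
    p_exact <- compare_groups(tab, flag)$p_value
    p_norm <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(p_exact - p_norm), 0.05)
  }
})

test_that("stratified summaries reproduce enumerable medians", {
  tab <- data.frame(probe_id = paste0("p", 1:6),
                    icc = c(0.9, 0.8, 0.5, 0.4, 0.7, 0.6),
                    micc = c(0.7, 0.6, 0.3, 0.2, 0.5, 0.4),
                    mean_beta = c(0.05, 0.15, 0.55, 0.95, 0.5, 1.0))
  ann <- data.frame(probe_id = tab$probe_id,
                    probe_type = c("I", "I", "II", "II", "II", "I"))
  by_type <- stratified_summary(tab, ann, stratum = "probe_type")
  expect_equal(by_type$n, c(3L, 3L))
  expect_equal(by_type$median_micc[by_type$stratum == "I"],
               median(c(0.7, 0.6, 0.4)))
  expect_equal(by_type$median_icc[by_type$stratum == "II"],
               median(c(0.5, 0.4, 0.7)))

  # single stratum reproduces the global summary
  ann1 <- data.frame(probe_id = tab$probe_id, all = "all")
  glob <- stratified_summary(tab, ann1, stratum = "all")
  expect_equal(glob$n, 6L)
  expect_equal(glob$median_icc, median(tab$icc))

  # default mean-beta bins, closed at the top
  bybin <- stratified_summary(tab)
  expect_equal(sum(bybin$n), 6L)
  expect_equal(bybin$n[bybin$stratum == "[0.9,1]"], 2L)
  expect_equal(bybin$n[bybin$stratum == "[0.5,0.6)"], 2L)
  expect_error(stratified_summary(tab, ann, stratum = "nope"),
               "unknown stratum")
})

test_that("mid-range probe means with larger signal variance rank highest", {
  mus <- c(0.05, 0.5, 0.95)
  tr <- synthetic_truth(60, n_subjects = 100,
                        mu = rep(mus, each = 20),
                        sigma_b2 = rep(c(0.002, 0.02, 0.002), each = 20),
                        sigma_w2 = 0.002, seed = 44)
  sim <- suppressWarnings(simulate_duplicates(tr))
  fit <- probe_reliability(sim$beta, sim$sample_sheet)
  s <- stratified_summary(fit, bins = c(0, 0.2, 0.8, 1))
  mid <- s$median_icc[s$stratum == "[0.2,0.8)"]
  expect_gt(mid, s$median_icc[s$stratum == "[0,0.2)"])
  expect_gt(mid, s$median_icc[s$stratum == "[0.8,1]"])
})

test_that("binomial variance of a methylation proportion", {
  expect_equal(binomial_variance(0.5, 1), 0.25)
  expect_equal(binomial_variance(0, 10), 0)
  expect_equal(binomial_variance(1, 10), 0)
  expect_equal(binomial_variance(0.2, 10), 0.016)
  expect_error(binomial_variance(1.2, 10), "0, 1")
  expect_error(binomial_variance(0.5, 0), ">= 1")
  # maximised at p = 0.5 over a grid
  grid <- seq(0, 1, by = 0.01)
  expect_equal(grid[which.max(binomial_variance(grid, 5))], 0.5)
})
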