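#' Generating parameters for synthetic duplicate beta values
#'
#' Describes, per probe, the additive Gaussian model used by
#' [simulate_duplicates()]: a probe mean `mu`, between-subject variance
#' `sigma_b2`, within-subject (technical) variance `sigma_w2`, and an
#' optional plate shift added to replicate 2 only. The implied large-sample
#' intraclass correlation is `sigma_b2 / (sigma_b2 + sigma_w2)`.
#'
#' Defaults emulate a duplicate study of the common EPIC-array design:
#' 69 subjects measured twice, probe means spread over the unit interval
#' away from the boundaries, and variance components typical of a variable
#' CpG (between-subject SD 0.1, technical SD 0.05), giving a true ICC of
#' 0.8 with negligible boundary clipping.
#'
#' @param n_probes Number of probes to simulate.
#' @param n_subjects Number of subjects (duplicate pairs); default 69.
#' @param mu Probe mean beta value(s) in (0, 1); recycled to `n_probes`.
#'   Default spreads means evenly over \[0.1, 0.9\].
#' @param sigma_b2 Between-subject variance(s), >= 0; recycled.
#' @param sigma_w2 Within-subject variance(s), >= 0; recycled.
#' @param plate_shift Additive offset applied to replicate 2; recycled.
#' @param seed Integer seed making the simulation reproducible.
#' @return Object of class `"synthetic_truth"`: a list with `probes`
#'   (data frame of per-probe parameters including `true_icc`),
#'   `n_subjects` and `seed`.
#' @export
synthetic_truth <- function(n_probes, n_subjects = 69L,
                            mu = seq(0.1, 0.9, length.out = n_probes),
                            sigma_b2 = 0.01, sigma_w2 = 0.0025,
                            plate_shift = 0, seed = 1L) {
  stopifnot(n_probes >= 1L, n_subjects >= 2L)
  mu <- rep_len(mu, n_probes)
  sigma_b2 <- rep_len(sigma_b2, n_probes)
  sigma_w2 <- rep_len(sigma_w2, n_probes)
  plate_shift <- rep_len(plate_shift, n_probes)
  if (any(mu <= 0 | mu >= 1)) stop("'mu' must lie strictly inside (0, 1)")
  if (any(sigma_b2 < 0) || any(sigma_w2 < 0)) stop("variances must be >= 0")
  tot <- sigma_b2 + sigma_w2
  true_icc <- ifelse(tot > 0, sigma_b2 / tot, NA_real_)
  probes <- data.frame(
    probe_id = sprintf("probe_%04d", seq_len(n_probes)),
    mu = mu, sigma_b2 = sigma_b2, sigma_w2 = sigma_w2,
    plate_shift = plate_shift, true_icc = true_icc,
    stringsAsFactors = FALSE)
  structure(list(probes = probes, n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic duplicate-study truth: %d probes x %d subjects (seed %d)\n",
              nrow(x$probes), x$n_subjects, x$seed))
  cat(sprintf("  true ICC range: %.3f - %.3f\n",
              min(x$probes$true_icc), max(x$probes$true_icc)))
  invisible(x)
}

#' Simulate duplicate beta values with known variance components
#'
#' Generates, for each probe p and subject i, paired measurements
#' `y_pij = clip(mu_p + b_pi + shift_p * 1[j = 2] + e_pij, eps, 1 - eps)`
#' with `b_pi ~ N(0, sigma_b2)`, `e_pij ~ N(0, sigma_w2)` and
#' `eps = 1e-6`. Clipping keeps values on the beta scale; when a probe has
#' more than 50% of its values clipped a warning is issued, because the
#' nominal variance components no longer hold near the boundaries.
#'
#' The generation is bit-reproducible under the truth's seed. The returned
#' sample sheet places replicate 1 on plate "P1" and replicate 2 on plate
#' "P2", matching the cross-plate duplicate design.
#'
#' @param truth A [synthetic_truth()] object.
#' @return List with `beta` (probes x samples matrix), `sample_sheet`
#'   (data frame: `sample_id`, `subject_id`, `replicate`, `plate`) and
#'   `truth` (the input, for downstream parameter-recovery checks).
#' @examples
#' sim <- simulate_duplicates(synthetic_truth(3, n_subjects = 10, seed = 42))
#' dim(sim$beta)
#' @export
simulate_duplicates <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  p <- nrow(truth$probes)
  n <- truth$n_subjects
  eps <- 1e-6
  out <- .with_seed(truth$seed, {
    b <- matrix(stats::rnorm(p * n), p, n) * sqrt(truth$probes$sigma_b2)
    e1 <- matrix(stats::rnorm(p * n), p, n) * sqrt(truth$probes$sigma_w2)
    e2 <- matrix(stats::rnorm(p * n), p, n) * sqrt(truth$probes$sigma_w2)
    y1 <- truth$probes$mu + b + e1
    y2 <- truth$probes$mu + b + truth$probes$plate_shift + e2
    list(y1 = y1, y2 = y2)
  })
  clipped <- (out$y1 < eps | out$y1 > 1 - eps) +
    (out$y2 < eps | out$y2 > 1 - eps)
  frac_clipped <- rowSums(clipped) / (2 * n)
  if (any(frac_clipped > 0.5))
    warning(sprintf("%d probe(s) have > 50%% of values clipped to [%g, %g]; generated variance components no longer hold",
                    sum(frac_clipped > 0.5), eps, 1 - eps))
  y1 <- pmin(pmax(out$y1, eps), 1 - eps)
  y2 <- pmin(pmax(out$y2, eps), 1 - eps)

  subj <- sprintf("subj_%04d", seq_len(n))
  s1 <- paste0(subj, "_r1")
  s2 <- paste0(subj, "_r2")
  beta <- cbind(y1, y2)
  rownames(beta) <- truth$probes$probe_id
  colnames(beta) <- c(s1, s2)
  sheet <- data.frame(sample_id = c(s1, s2),
                      subject_id = rep(subj, 2),
                      replicate = rep(1:2, each = n),
                      plate = rep(c("P1", "P2"), each = n),
                      stringsAsFactors = FALSE)
  list(beta = beta, sample_sheet = sheet, truth = truth)
}

#' Large-sample expectation of HoLA under pure technical noise
#'
#' When duplicates differ only by independent within-subject noise with
#' variance `sigma_w2`, the paired difference has variance `2 * sigma_w2`,
#' so the half-width of the limits of agreement converges to
#' `z * sqrt(2 * sigma_w2)`.
#'
#' @param sigma_w2 Within-subject variance, >= 0.
#' @param z Limits-of-agreement multiplier (default 1.96).
#' @return The expected HoLA.
#' @examples
#' expected_hola(0.01)  # ~0.277
#' @export
expected_hola <- function(sigma_w2, z = 1.96) {
  if (any(sigma_w2 < 0)) stop("'sigma_w2' must be >= 0")
  z * sqrt(2 * sigma_w2)
}
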