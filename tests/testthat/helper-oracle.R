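# Brute-force oracles, coded independently of the package internals.

# Mean squares by explicit element-wise loops over the two-way layout;
# SSE accumulated directly from the residuals, not by subtraction.
oracle_mean_squares <- function(v) {
  n <- nrow(v)
  k <- ncol(v)
  g <- mean(v)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(v[i, ]) - g)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(v[, j]) - g)^2
  sse <- 0
  for (i in seq_len(n))
    for (j in seq_len(k))
      sse <- sse + (v[i, j] - mean(v[i, ]) - mean(v[, j]) + g)^2
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

oracle_icc_a1 <- function(v) {
  ms <- oracle_mean_squares(v)
  denom <- ms$msr + (ms$k - 1) * ms$mse + (ms$k / ms$n) * (ms$msc - ms$mse)
  if (abs(denom) < 1e-30) return(NA_real_)
  (ms$msr - ms$mse) / denom
}

# ICC(A,1) through stats::aov, a second independent route to the mean squares.
aov_icc_a1 <- function(v) {
  n <- nrow(v)
  df <- data.frame(y = c(v), subjf = factor(rep(seq_len(n), 2)),
                   repf = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subjf + repf, df))[[1]][["Mean Sq"]]
  (ms[1] - ms[3]) / (ms[1] + ms[3] + (2 / n) * (ms[2] - ms[3]))
}

# Spearman via explicit rank-then-Pearson.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

random_duplicate_set <- function(n = sample(2:10, 1)) {
  matrix(runif(2 * n), n, 2)
}

toy_sample_sheet <- function(n_subjects = 3, plates = NULL) {
  subj <- paste0("S", seq_len(n_subjects))
  data.frame(sample_id = c(paste0(subj, "_a"), paste0(subj, "_b")),
             subject_id = rep(subj, 2),
             replicate = rep(1:2, each = n_subjects),
             plate = if (is.null(plates)) rep(c("P1", "P2"), each = n_subjects)
                     else plates,
             stringsAsFactors = FALSE)
}

extdata <- function(f) system.file("extdata", f, package = "methrel")
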