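#' Two-way ANOVA mean squares for one probe's duplicate measurements
#'
#' Decomposes an n x 2 matrix of paired measurements (rows = subjects,
#' columns = replicates) into the mean squares of the two-way crossed
#' design without interaction: subjects (rows), replicates (columns) and
#' residual. These are the building blocks of the single-measure,
#' absolute-agreement, two-way random-effects intraclass correlation.
#'
#' @param values Numeric n x 2 matrix; one row per subject, one column per
#'   technical replicate. Rows containing a missing value are dropped.
#' @return A list of class `"anova_summary"` with components `msr`, `msc`,
#'   `mse` (mean squares for subjects, replicates and residual), `n`
#'   (complete pairs used) and `k` (replicates, always 2 here).
#' @examples
#' anova_mean_squares(cbind(c(0.1, 0.4, 0.9), c(0.2, 0.5, 0.7)))
#' @export
anova_mean_squares <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) != 2L)
    stop("'values' must have exactly 2 columns (replicates)")
  values <- values[stats::complete.cases(values), , drop = FALSE]
  if (!all(is.finite(values)))
    stop("non-finite values in duplicate measurements")
  n <- nrow(values)
  if (n < 2L)
    stop("insufficient pairs: need at least 2 complete pairs, got ", n)
  k <- 2L
  grand <- mean(values)
  row_means <- rowMeans(values)
  col_means <- colMeans(values)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((values - grand)^2)
  sse <- max(0, sst - ssr - ssc)
  out <- list(msr = ssr / (n - 1L),
              msc = ssc / (k - 1L),
              mse = sse / ((n - 1L) * (k - 1L)),
              n = n, k = k)
  class(out) <- "anova_summary"
  out
}

#' Single-measure absolute-agreement ICC from ANOVA mean squares
#'
#' Computes ICC(A,1), the intraclass correlation for a single measurement
#' under the two-way random-effects, absolute-agreement model:
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' Population target is \eqn{\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)} where
#' \eqn{\sigma_b^2} is between-subject and \eqn{\sigma_w^2} within-subject
#' variance. Negative estimates are retained, not clamped.
#'
#' @param a An `"anova_summary"` as returned by [anova_mean_squares()].
#' @return The ICC estimate, or `NA` when all measurements are identical
#'   (the denominator is zero and the ratio is undefined).
#' @export
icc_a1 <- function(a) {
  stopifnot(inherits(a, "anova_summary"))
  denom <- a$msr + (a$k - 1) * a$mse + (a$k / a$n) * (a$msc - a$mse)
  if (denom <= .Machine$double.eps^2) return(NA_real_)
  (a$msr - a$mse) / denom
}

#' Method-of-moments variance components from ANOVA mean squares
#'
#' Between-subject variance is `max(0, (MSR - MSE)/k)` (truncated at zero);
#' within-subject variance is the residual mean square.
#'
#' @inheritParams icc_a1
#' @return List with `sigma_b2` (between-subject) and `sigma_w2`
#'   (within-subject) variance estimates.
#' @export
variance_components <- function(a) {
  stopifnot(inherits(a, "anova_summary"))
  list(sigma_b2 = max(0, (a$msr - a$mse) / a$k),
       sigma_w2 = a$mse)
}

#' Bland-Altman limits of agreement for duplicate measurements
#'
#' Takes per-pair differences d = replicate 1 - replicate 2 and returns
#' the 95% limits of agreement `mean(d) +/- z * sd(d)` together with the
#' standard deviation of the differences and the half-width of the limits
#' (HoLA = z * sd(d)). The sample standard deviation (n - 1 denominator)
#' is used.
#'
#' @inheritParams anova_mean_squares
#' @param z Normal-quantile multiplier for the limits; 1.96 gives the
#'   conventional 95% interval.
#' @return List with `lower`, `upper`, `mean_diff`, `sigma_d`, `hola`
#'   and `n` (complete pairs used).
#' @examples
#' limits_of_agreement(cbind(c(0.1, 0.4, 0.9), c(0.2, 0.4, 0.7)))
#' @export
limits_of_agreement <- function(values, z = 1.96) {
  values <- as.matrix(values)
  if (ncol(values) != 2L)
    stop("'values' must have exactly 2 columns (replicates)")
  if (!is.numeric(z) || length(z) != 1L || z < 0)
    stop("'z' must be a single non-negative number")
  values <- values[stats::complete.cases(values), , drop = FALSE]
  n <- nrow(values)
  if (n < 2L)
    stop("insufficient pairs: need at least 2 complete pairs, got ", n)
  d <- values[, 1L] - values[, 2L]
  m <- mean(d)
  sigma_d <- stats::sd(d)
  hola <- z * sigma_d
  list(lower = m - hola, upper = m + hola, mean_diff = m,
       sigma_d = sigma_d, hola = hola, n = n)
}

#' Modified ICC: ICC penalised by the half-width of the limits of agreement
#'
#' `micc = icc - hola`. A probe can reach a high ICC purely through large
#' between-subject variance even when its duplicates disagree substantially;
#' subtracting HoLA penalises that absolute disagreement.
#'
#' @param icc ICC estimate(s); `NA` propagates.
#' @param hola Half-width(s) of the 95% limits of agreement; must be >= 0.
#' @return `icc - hola`, vectorised.
#' @examples
#' modified_icc(0.8099, 0.2521)
#' @export
modified_icc <- function(icc, hola) {
  if (any(!is.na(hola) & hola < 0))
    stop("'hola' must be non-negative")
  icc - hola
}

#' Reliability classification scheme
#'
#' Ordered cutpoints and labels mapping a reliability statistic (ICC or
#' mICC) to a class. The default reproduces the conventional bands
#' Poor (< 0.4), Fair (0.4-0.6), Good (0.6-0.75), Excellent (> 0.75),
#' with the boundary convention Fair: 0.4 <= v < 0.6, Good:
#' 0.6 <= v <= 0.75, Excellent: v > 0.75. `boundary_rule` records, for
#' each cutpoint, whether a value equal to the cutpoint falls in the band
#' above (`"up"`) or below (`"down"`) it, so the convention is auditable.
#'
#' @param cutpoints Strictly increasing numeric vector of band boundaries.
#' @param labels Character vector of band labels, one more than cutpoints,
#'   ordered from lowest to highest band.
#' @param boundary_rule Character vector, one entry per cutpoint, each
#'   `"up"` or `"down"`.
#' @return An object of class `"classification_scheme"`.
#' @export
classification_scheme <- function(cutpoints = c(0.4, 0.6, 0.75),
                                  labels = c("Poor", "Fair", "Good", "Excellent"),
                                  boundary_rule = c("up", "up", "down")) {
  if (any(diff(cutpoints) <= 0))
    stop("'cutpoints' must be strictly increasing")
  if (length(labels) != length(cutpoints) + 1L)
    stop("need exactly one more label than cutpoints")
  boundary_rule <- rep_len(boundary_rule, length(cutpoints))
  if (!all(boundary_rule %in% c("up", "down")))
    stop("'boundary_rule' entries must be \"up\" or \"down\"")
  structure(list(cutpoints = as.numeric(cutpoints),
                 labels = as.character(labels),
                 boundary_rule = boundary_rule),
            class = "classification_scheme")
}

#' @export
print.classification_scheme <- function(x, ...) {
  lo <- c(-Inf, x$cutpoints)
  hi <- c(x$cutpoints, Inf)
  lbr <- c("(", ifelse(x$boundary_rule == "up", "[", "("))
  rbr <- c(ifelse(x$boundary_rule == "up", ")", "]"), ")")
  cat("Reliability classification scheme:\n")
  for (i in seq_along(x$labels))
    cat(sprintf("  %-10s %s%s, %s%s\n", x$labels[i],
                lbr[i], format(lo[i]), format(hi[i]), rbr[i]))
  invisible(x)
}

#' Classify reliability values into ordered bands
#'
#' Maps each value to its class label under a [classification_scheme()].
#' Missing values are labelled `"Undefined"` (degenerate probes with no
#' variation have no defensible ICC and are reported as such).
#'
#' @param value Numeric vector of reliability statistics.
#' @param scheme A [classification_scheme()].
#' @return Character vector of labels, same length as `value`.
#' @examples
#' classify(c(0.8099, 0.5579, -0.2, NA))
#' @export
classify <- function(value, scheme = classification_scheme()) {
  stopifnot(inherits(scheme, "classification_scheme"))
  idx <- vapply(value, function(v) {
    if (is.na(v)) return(NA_integer_)
    below <- sum((v > scheme$cutpoints) |
                   (v == scheme$cutpoints & scheme$boundary_rule == "up"))
    below + 1L
  }, integer(1))
  out <- scheme$labels[idx]
  out[is.na(idx)] <- "Undefined"
  out
}
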