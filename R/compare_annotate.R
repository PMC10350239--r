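#' Spearman correlation between two per-probe reliability vectors
#'
#' Intersects the two vectors on probe ID, drops missing values, and
#' computes the Spearman rank correlation (average ranks for ties). Used
#' to compare ICC estimates between studies or platforms.
#'
#' @param x,y Named numeric vectors keyed by probe ID.
#' @return List with `rho` and `n_shared` (probes used).
#' @export
spearman_reliability <- function(x, y) {
  if (is.null(names(x)) || is.null(names(y)))
    stop("'x' and 'y' must be named by probe ID")
  shared <- intersect(names(x), names(y))
  xs <- x[shared]
  ys <- y[shared]
  ok <- !is.na(xs) & !is.na(ys)
  if (sum(ok) < 3L)
    stop("need at least 3 shared probes with non-missing values, got ", sum(ok))
  list(rho = stats::cor(xs[ok], ys[ok], method = "spearman"),
       n_shared = sum(ok))
}

# Assemble a reliability_crosstab object from a count matrix.
.crosstab_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("empty cross-tabulation")
  row_tot <- rowSums(counts)
  row_pct <- 100 * counts / ifelse(row_tot > 0, row_tot, NA)
  concordance <- 100 * sum(diag(counts)) / total
  structure(list(counts = counts,
                 row_pct = round(row_pct, 1),
                 concordance = round(concordance, 2),
                 n_total = total),
            class = "reliability_crosstab")
}

#' Cross-tabulate two probe classifications
#'
#' Builds the label x label contingency table of two classifications over
#' their shared probes, with row percentages (one decimal) and the overall
#' concordance, the percentage of probes classified identically
#' (diagonal / total, two decimals). Probes labelled `"Undefined"` in
#' either input are excluded from the table and counted separately.
#'
#' @param a,b Named character vectors of class labels keyed by probe ID,
#'   or a pre-computed count matrix passed as `a` (with `b` missing) when
#'   only published counts are available.
#' @param scheme [classification_scheme()] supplying the label order.
#' @return Object of class `"reliability_crosstab"`: `counts`, `row_pct`,
#'   `concordance` (percent), `n_total`, and for label input
#'   `n_undefined`.
#' @examples
#' ct <- crosstab_classes(
#'   c(p1 = "Poor", p2 = "Fair", p3 = "Good"),
#'   c(p1 = "Poor", p2 = "Fair", p3 = "Fair"))
#' ct$concordance
#' @export
crosstab_classes <- function(a, b, scheme = classification_scheme()) {
  if (missing(b)) {
    if (!is.matrix(a)) stop("single-argument form requires a count matrix")
    return(.crosstab_from_counts(a))
  }
  if (is.null(names(a)) || is.null(names(b)))
    stop("'a' and 'b' must be named by probe ID")
  shared <- intersect(names(a), names(b))
  if (!length(shared)) stop("no shared probes between the two classifications")
  av <- a[shared]
  bv <- b[shared]
  undef <- is.na(av) | is.na(bv) | av == "Undefined" | bv == "Undefined"
  av <- av[!undef]
  bv <- bv[!undef]
  if (!length(av)) stop("no shared probes with defined classes")
  bad <- setdiff(unique(c(av, bv)), scheme$labels)
  if (length(bad))
    stop("labels not in scheme: ", paste(bad, collapse = ", "))
  counts <- table(factor(av, levels = scheme$labels),
                  factor(bv, levels = scheme$labels))
  out <- .crosstab_from_counts(unclass(counts))
  out$n_undefined <- sum(undef)
  out
}

#' @export
print.reliability_crosstab <- function(x, ...) {
  cat("Classification cross-tabulation (rows = first input)\n")
  disp <- matrix(sprintf("%d (%.1f%%)", x$counts, x$row_pct),
                 nrow(x$counts), dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  cat(sprintf("Concordance: %.2f%% of %d probes", x$concordance, x$n_total))
  if (!is.null(x$n_undefined) && x$n_undefined > 0)
    cat(sprintf(" (%d undefined probes excluded)", x$n_undefined))
  cat("\n")
  invisible(x)
}

# Exact two-sided rank-sum p-value by enumeration of all assignments of
# the pooled (average) ranks to group 1, valid with ties.
.ranksum_exact_p <- function(x, y) {
  r <- rank(c(x, y))
  m <- length(x)
  w_obs <- sum(r[seq_len(m)])
  mu <- m * mean(r)
  combos <- utils::combn(length(r), m)
  w_all <- colSums(matrix(r[combos], nrow = m))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

#' Compare reliability between two probe groups
#'
#' Contrasts a reliability statistic (ICC or mICC) between probes with and
#' without a boolean flag (e.g. influenced by an mQTL, inside a DMR) using
#' group medians and a two-sided Wilcoxon rank-sum test. With both groups
#' of size <= 10 the p-value is computed by exact enumeration of all
#' assignments (valid under ties); otherwise the normal approximation with
#' tie correction is used.
#'
#' @param rel A [probe_reliability()] fit or its `table` data frame.
#' @param flag Logical vector named by probe ID (or unnamed, matched by
#'   position to the table rows) marking group membership.
#' @param stat `"icc"` or `"micc"`.
#' @return List with `median_in`, `median_out`, `p_value`, `n_in`,
#'   `n_out`, `method`.
#' @export
compare_groups <- function(rel, flag, stat = c("micc", "icc")) {
  stat <- match.arg(stat)
  tab <- if (inherits(rel, "probe_reliability")) rel$table else rel
  v <- tab[[stat]]
  names(v) <- tab$probe_id
  if (!is.null(names(flag))) {
    flag <- flag[match(tab$probe_id, names(flag))]
  } else if (length(flag) != nrow(tab)) {
    stop("'flag' must be named by probe ID or match the table length")
  }
  ok <- !is.na(v) & !is.na(flag)
  x <- v[ok & flag]                     # flagged group
  y <- v[ok & !flag]
  if (!length(x) || !length(y))
    stop("both groups must be non-empty after dropping missing values")
  exact <- length(x) <= 10L && length(y) <= 10L
  p <- if (exact) .ranksum_exact_p(x, y)
       else suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = TRUE)$p.value)
  list(median_in = stats::median(x), median_out = stats::median(y),
       p_value = p, n_in = length(x), n_out = length(y),
       method = if (exact) "exact enumeration" else "normal approximation")
}

#' Stratified reliability summaries
#'
#' Summarises ICC and mICC by a stratum: either a column of a probe
#' annotation table (e.g. `probe_type`, `island_relation`, `tss_group`)
#' or bins of the per-probe mean beta value (`stratum = "mean_beta"`,
#' default bins \[0,0.1), \[0.1,0.2), ..., \[0.9,1\]).
#'
#' @inheritParams compare_groups
#' @param annotation Optional data frame with a `probe_id` column plus
#'   stratum columns; merged onto the reliability table.
#' @param stratum Name of the stratifying field, or `"mean_beta"` for
#'   beta-value bins.
#' @param bins Numeric vector of bin edges for `stratum = "mean_beta"`.
#' @return Data frame with one row per stratum: `stratum`, `n`,
#'   `mean_icc`, `median_icc`, `mean_micc`, `median_micc`.
#' @export
stratified_summary <- function(rel, annotation = NULL, stratum = "mean_beta",
                               bins = seq(0, 1, by = 0.1)) {
  tab <- if (inherits(rel, "probe_reliability")) rel$table else rel
  if (identical(stratum, "mean_beta")) {
    labs <- paste0("[", utils::head(bins, -1), ",", utils::tail(bins, -1),
                   c(rep(")", length(bins) - 2L), "]"))
    # right = FALSE + include.lowest closes the top bin at the upper edge
    grp <- cut(tab$mean_beta, breaks = bins, labels = labs,
               right = FALSE, include.lowest = TRUE)
  } else {
    if (is.null(annotation)) stop("'annotation' required for stratum ", stratum)
    if (!stratum %in% names(annotation))
      stop("unknown stratum field: ", stratum)
    grp <- annotation[[stratum]][match(tab$probe_id, annotation$probe_id)]
  }
  keep <- !is.na(grp)
  stats_by <- function(v) {
    v <- split(v, grp[keep])
    data.frame(mean = vapply(v, function(z) mean(z, na.rm = TRUE), numeric(1)),
               median = vapply(v, function(z) stats::median(z, na.rm = TRUE),
                               numeric(1)))
  }
  icc_s <- stats_by(tab$icc[keep])
  micc_s <- stats_by(tab$micc[keep])
  data.frame(stratum = rownames(icc_s),
             n = as.integer(table(grp[keep])),
             mean_icc = icc_s$mean, median_icc = icc_s$median,
             mean_micc = micc_s$mean, median_micc = micc_s$median,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Binomial variance of a methylation proportion
#'
#' For a cell population of size `n_cells` in which each cell is
#' methylated with probability `p`, the sampling variance of the observed
#' methylation proportion is `p * (1 - p) / n_cells`. This mean-variance
#' relationship explains why probes with extreme average beta values have
#' small variances and hence tend to show poor reliability.
#'
#' @param p Methylation probability in \[0, 1\].
#' @param n_cells Number of cells contributing signal, >= 1.
#' @return The variance `p * (1 - p) / n_cells`, vectorised.
#' @export
binomial_variance <- function(p, n_cells) {
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]")
  if (any(n_cells < 1)) stop("'n_cells' must be >= 1")
  p * (1 - p) / n_cells
}
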