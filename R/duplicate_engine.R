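#' Build a subject -> (replicate 1, replicate 2) pair map from a sample sheet
#'
#' The sample sheet must contain columns `sample_id`, `subject_id` and
#' `replicate` (values 1 and 2), plus an optional `plate` column. Subjects
#' with anything other than exactly two listed replicates are excluded with
#' a warning (or an error in strict mode). When `require_cross_plate` is
#' set, subjects whose two replicates sit on the same methylation plate are
#' also excluded: plate effects inflate apparent within-subject variance,
#' and a reliability estimate from same-plate duplicates would not reflect
#' them.
#'
#' @param sample_sheet Data frame with the columns above.
#' @param require_cross_plate Drop subjects whose replicates share a plate.
#' @param strict Error instead of warn on subjects with != 2 replicates.
#' @return Data frame of class `"pair_map"` with one row per retained
#'   subject: `subject_id`, `sample_1`, `sample_2`, `plate_1`, `plate_2`.
#' @export
build_pair_map <- function(sample_sheet, require_cross_plate = FALSE,
                           strict = FALSE) {
  required <- c("sample_id", "subject_id", "replicate")
  missing_cols <- setdiff(required, names(sample_sheet))
  if (length(missing_cols))
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(sample_sheet$sample_id))
    stop("duplicate sample IDs in sample sheet")
  has_plate <- "plate" %in% names(sample_sheet)
  if (require_cross_plate && !has_plate)
    stop("require_cross_plate = TRUE but sample sheet has no 'plate' column")

  split_idx <- split(seq_len(nrow(sample_sheet)),
                     as.character(sample_sheet$subject_id))
  bad <- names(split_idx)[vapply(split_idx, length, integer(1)) != 2L]
  if (length(bad)) {
    msg <- sprintf("excluded %d subject(s) without exactly 2 replicates: %s",
                   length(bad), paste(utils::head(bad, 5), collapse = ", "))
    if (strict) stop(msg) else warning(msg)
    split_idx <- split_idx[setdiff(names(split_idx), bad)]
  }
  if (!length(split_idx)) stop("no subjects with 2 replicates remain")

  rows <- lapply(names(split_idx), function(subj) {
    idx <- split_idx[[subj]]
    sub <- sample_sheet[idx, ]
    # order by replicate label; ties keep sheet order
    sub <- sub[order(as.integer(sub$replicate)), ]
    data.frame(subject_id = subj,
               sample_1 = as.character(sub$sample_id[1]),
               sample_2 = as.character(sub$sample_id[2]),
               plate_1 = if (has_plate) as.character(sub$plate[1]) else NA_character_,
               plate_2 = if (has_plate) as.character(sub$plate[2]) else NA_character_,
               stringsAsFactors = FALSE)
  })
  pm <- do.call(rbind, rows)
  if (require_cross_plate) {
    same <- !is.na(pm$plate_1) & !is.na(pm$plate_2) & pm$plate_1 == pm$plate_2
    if (any(same)) {
      message(sprintf("excluded %d subject(s) with both replicates on one plate: %s",
                      sum(same), paste(utils::head(pm$subject_id[same], 5),
                                       collapse = ", ")))
      pm <- pm[!same, , drop = FALSE]
    }
    if (!nrow(pm)) stop("no cross-plate duplicate pairs remain")
  }
  rownames(pm) <- NULL
  class(pm) <- c("pair_map", "data.frame")
  pm
}

#' Drop probes with too many missing values
#'
#' Removes probes whose fraction of missing entries strictly exceeds
#' `max_missing_frac` (default 0.05, i.e. missing in more than 5% of
#' samples).
#'
#' @param beta Numeric probes x samples matrix with probe IDs as row names.
#' @param max_missing_frac Maximum tolerated missing fraction, in \[0, 1\].
#' @return The filtered matrix, with attribute `"n_removed"` recording how
#'   many probes were dropped.
#' @export
filter_probes_by_missingness <- function(beta, max_missing_frac = 0.05) {
  if (!is.numeric(max_missing_frac) || max_missing_frac < 0 || max_missing_frac > 1)
    stop("'max_missing_frac' must be in [0, 1]")
  frac <- rowMeans(is.na(beta))
  keep <- frac <= max_missing_frac
  if (!any(keep)) warning("all probes removed by missingness filter")
  out <- beta[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

# Extract the two replicate sub-matrices (probes x subjects) for a pair map.
.replicate_matrices <- function(beta, pairs) {
  missing_samples <- setdiff(c(pairs$sample_1, pairs$sample_2), colnames(beta))
  if (length(missing_samples))
    stop("sample(s) in pair map absent from beta matrix: ",
         paste(utils::head(missing_samples, 5), collapse = ", "))
  list(y1 = beta[, pairs$sample_1, drop = FALSE],
       y2 = beta[, pairs$sample_2, drop = FALSE])
}

# Vectorised per-probe reliability statistics for the k = 2 design.
# Closed forms of the two-way ANOVA decomposition applied row-wise;
# equivalence with anova_mean_squares()/icc_a1() per probe is asserted in
# the test suite.
.scan_stats <- function(y1, y2, z) {
  ok <- !is.na(y1) & !is.na(y2)
  n <- rowSums(ok)
  y1[!ok] <- NA
  y2[!ok] <- NA
  s1 <- rowSums(y1, na.rm = TRUE)
  s2 <- rowSums(y2, na.rm = TRUE)
  grand <- (s1 + s2) / (2 * n)
  c1 <- s1 / n
  c2 <- s2 / n
  m <- (y1 + y2) / 2                       # subject means
  ssr <- 2 * rowSums((m - grand)^2, na.rm = TRUE)
  ssc <- n * ((c1 - grand)^2 + (c2 - grand)^2)
  sst <- rowSums((y1 - grand)^2, na.rm = TRUE) +
    rowSums((y2 - grand)^2, na.rm = TRUE)
  sse <- pmax(0, sst - ssr - ssc)
  msr <- ssr / (n - 1)
  msc <- ssc                               # k - 1 = 1
  mse <- sse / (n - 1)
  denom <- msr + mse + (2 / n) * (msc - mse)
  icc <- ifelse(denom > .Machine$double.eps^2, (msr - mse) / denom, NA_real_)
  d <- y1 - y2
  dbar <- rowSums(d, na.rm = TRUE) / n
  sigma_d <- sqrt(rowSums((d - dbar)^2, na.rm = TRUE) / (n - 1))
  hola <- z * sigma_d
  list(n_pairs = n, icc = icc,
       sigma_b2 = pmax(0, (msr - mse) / 2), sigma_w2 = mse,
       sigma_d = sigma_d, hola = hola, micc = icc - hola)
}

#' Per-probe mean and duplicate-aware standard deviation of beta values
#'
#' The mean uses all paired samples (both replicates). The standard
#' deviation is computed after selecting, for each subject, one of the two
#' duplicates uniformly at random; including both would understate
#' biological spread by double-counting subjects. The selection is
#' deterministic under `seed`.
#'
#' @inheritParams filter_probes_by_missingness
#' @param pairs A [build_pair_map()] result.
#' @param seed Integer seed controlling which replicate is picked per
#'   subject.
#' @return Data frame with `probe_id`, `mean_beta`, `sd_beta`.
#' @export
probe_mean_sd <- function(beta, pairs, seed = 1L) {
  mats <- .replicate_matrices(beta, pairs)
  mean_beta <- rowMeans(cbind(mats$y1, mats$y2), na.rm = TRUE)
  pick <- .with_seed(seed, stats::rbinom(nrow(pairs), 1L, 0.5))
  chosen <- ifelse(matrix(pick == 1L, nrow(beta), nrow(pairs), byrow = TRUE),
                   mats$y2, mats$y1)
  sd_beta <- apply(chosen, 1L, stats::sd, na.rm = TRUE)
  data.frame(probe_id = rownames(beta), mean_beta = mean_beta,
             sd_beta = sd_beta, row.names = NULL, stringsAsFactors = FALSE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Estimate per-probe reliability from duplicate methylation measurements
#'
#' The main fitting function. Given a probes x samples beta-value matrix
#' and a sample sheet describing technical duplicates, it filters probes by
#' missingness, assembles each probe's subject x replicate matrix
#' (dropping incomplete pairs), and computes per probe: the two-way
#' random-effects absolute-agreement single-measure ICC, between- and
#' within-subject variance components, the standard deviation of paired
#' differences, the half-width of the 95% limits of agreement
#' (HoLA = z * sigma_d), the modified ICC (mICC = ICC - HoLA), reliability
#' classes for both statistics, and the mean/SD of beta values.
#'
#' Probes with fewer than `min_pairs` complete pairs, or with no variation
#' at all, get missing statistics and class `"Undefined"`.
#'
#' @param beta Numeric probes x samples matrix (row names = probe IDs,
#'   column names = sample IDs), or the list returned by
#'   [read_beta_matrix()].
#' @param sample_sheet Data frame with columns `sample_id`, `subject_id`,
#'   `replicate` and optionally `plate`; alternatively a ready-made
#'   [build_pair_map()] object.
#' @param scheme [classification_scheme()] used for both ICC and mICC.
#' @param z Multiplier for the limits of agreement (default 1.96, the 95%
#'   normal quantile).
#' @param max_missing_frac Missingness filter threshold (default 0.05).
#' @param min_pairs Minimum complete pairs per probe (default 3).
#' @param require_cross_plate Only keep subjects whose duplicates sit on
#'   different plates.
#' @param seed Seed for the random replicate selection behind `sd_beta`.
#' @return An object of class `"probe_reliability"`: a list with `table`
#'   (the per-probe reliability data frame), `scheme`, `pairs`, and the
#'   configuration used. Supports `print`, `summary`, `coef`, `plot` and
#'   `as.data.frame`.
#' @examples
#' truth <- synthetic_truth(n_probes = 5, n_subjects = 30, seed = 7)
#' sim <- simulate_duplicates(truth)
#' fit <- probe_reliability(sim$beta, sim$sample_sheet)
#' summary(fit)
#' @export
probe_reliability <- function(beta, sample_sheet,
                              scheme = classification_scheme(),
                              z = 1.96,
                              max_missing_frac = 0.05,
                              min_pairs = 3L,
                              require_cross_plate = FALSE,
                              seed = 1L) {
  if (is.list(beta) && !is.matrix(beta) && !is.null(beta$values))
    beta <- beta$values
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("'beta' needs probe IDs as row names and sample IDs as column names")
  pairs <- if (inherits(sample_sheet, "pair_map")) sample_sheet
           else build_pair_map(sample_sheet, require_cross_plate = require_cross_plate)

  n_before <- nrow(beta)
  beta <- filter_probes_by_missingness(beta, max_missing_frac)
  n_filtered <- attr(beta, "n_removed")
  if (!nrow(beta)) stop("no probes left after missingness filtering")

  mats <- .replicate_matrices(beta, pairs)
  st <- .scan_stats(mats$y1, mats$y2, z)
  low <- st$n_pairs < min_pairs
  for (f in c("icc", "sigma_b2", "sigma_w2", "sigma_d", "hola", "micc"))
    st[[f]][low] <- NA_real_

  ms <- probe_mean_sd(beta, pairs, seed = seed)
  tab <- data.frame(probe_id = rownames(beta),
                    n_pairs = as.integer(st$n_pairs),
                    icc = st$icc,
                    sigma_b2 = st$sigma_b2,
                    sigma_w2 = st$sigma_w2,
                    sd_diff = st$sigma_d,
                    hola = st$hola,
                    micc = st$micc,
                    class_icc = classify(st$icc, scheme),
                    class_micc = classify(st$micc, scheme),
                    mean_beta = ms$mean_beta,
                    sd_beta = ms$sd_beta,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, scheme = scheme, pairs = pairs,
                 config = list(z = z, max_missing_frac = max_missing_frac,
                               min_pairs = as.integer(min_pairs),
                               require_cross_plate = require_cross_plate,
                               seed = as.integer(seed)),
                 n_probes_in = n_before, n_probes_filtered = n_filtered),
            class = "probe_reliability")
}

#' @export
print.probe_reliability <- function(x, ...) {
  cat("Probe reliability from duplicate measurements\n")
  cat(sprintf("  probes: %d analysed (%d read, %d removed by >%.0f%% missingness)\n",
              nrow(x$table), x$n_probes_in, x$n_probes_filtered,
              100 * x$config$max_missing_frac))
  cat(sprintf("  subjects (duplicate pairs): %d\n", nrow(x$pairs)))
  cat(sprintf("  z multiplier: %g; min pairs per probe: %d; seed: %d\n",
              x$config$z, x$config$min_pairs, x$config$seed))
  ok <- !is.na(x$table$icc)
  if (any(ok))
    cat(sprintf("  ICC:  mean %.3f, median %.3f;  mICC: mean %.3f, median %.3f\n",
                mean(x$table$icc[ok]), stats::median(x$table$icc[ok]),
                mean(x$table$micc[ok]), stats::median(x$table$micc[ok])))
  invisible(x)
}

#' @export
summary.probe_reliability <- function(object, ...) {
  tab <- object$table
  ok <- !is.na(tab$icc)
  out <- list(
    n_probes = nrow(tab),
    n_undefined = sum(!ok),
    icc = if (any(ok)) summary(tab$icc[ok]) else NULL,
    micc = if (any(ok)) summary(tab$micc[ok]) else NULL,
    class_icc = table(factor(tab$class_icc,
                             levels = c(object$scheme$labels, "Undefined"))),
    class_micc = table(factor(tab$class_micc,
                              levels = c(object$scheme$labels, "Undefined"))))
  class(out) <- "summary.probe_reliability"
  out
}

#' @export
print.summary.probe_reliability <- function(x, ...) {
  cat(sprintf("Reliability summary over %d probes (%d undefined)\n",
              x$n_probes, x$n_undefined))
  if (!is.null(x$icc)) {
    cat("ICC:\n"); print(x$icc)
    cat("mICC:\n"); print(x$micc)
  }
  cat("Classes by ICC:\n"); print(x$class_icc)
  cat("Classes by mICC:\n"); print(x$class_micc)
  invisible(x)
}

#' @export
coef.probe_reliability <- function(object, ...) {
  m <- as.matrix(object$table[, c("icc", "micc")])
  rownames(m) <- object$table$probe_id
  m
}

#' @export
as.data.frame.probe_reliability <- function(x, ...) x$table

#' @export
plot.probe_reliability <- function(x, which = c("icc", "micc"), breaks = 40, ...) {
  which <- match.arg(which)
  v <- x$table[[which]]
  v <- v[!is.na(v)]
  graphics::hist(v, breaks = breaks,
                 main = sprintf("Distribution of %s over %d probes",
                                toupper(which), length(v)),
                 xlab = toupper(which), ...)
  graphics::abline(v = x$scheme$cutpoints, lty = 2, col = "grey40")
  invisible(x)
}
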