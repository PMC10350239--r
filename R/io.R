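#' Read a probes x samples beta-value matrix
#'
#' Expects a TSV (or CSV) file with probe IDs in the first column and a
#' header row of sample IDs. Empty cells, `"NA"` and `"NaN"` parse as
#' missing. In beta mode (the default) values outside \[0, 1\] are
#' rejected with a message naming the offending probe and sample; disable
#' the range check for M-values or other unbounded scales.
#'
#' @param path Path to the file.
#' @param sep Field separator; `"\t"` by default, use `","` for CSV.
#' @param range_check Reject values outside \[0, 1\].
#' @return Numeric matrix with probe IDs as row names and sample IDs as
#'   column names.
#' @export
read_beta_matrix <- function(path, sep = "\t", range_check = TRUE) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", "NaN", ""),
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stop("beta matrix needs a probe-ID column plus samples")
  probe_ids <- as.character(df[[1L]])
  if (anyDuplicated(probe_ids))
    stop("duplicate probe IDs: ",
         paste(utils::head(unique(probe_ids[duplicated(probe_ids)]), 5),
               collapse = ", "))
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(utils::head(unique(sample_ids[duplicated(sample_ids)]), 5),
               collapse = ", "))
  non_num <- !vapply(df[-1L], is.numeric, logical(1))
  if (any(non_num))
    stop("non-numeric values in sample column(s): ",
         paste(utils::head(sample_ids[non_num], 5), collapse = ", "))
  m <- as.matrix(df[-1L])
  rownames(m) <- probe_ids
  if (range_check) {
    bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("value %g out of [0, 1] at probe '%s', sample '%s' (use range_check = FALSE for M-values)",
                   m[bad[1L, 1L], bad[1L, 2L]],
                   probe_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  m
}

#' Write a probes x samples beta-value matrix as TSV
#'
#' Inverse of [read_beta_matrix()]: probe IDs in the first column
#' (`probe_id`), sample IDs as the header, missing values as `"NA"`.
#'
#' @param beta Numeric matrix with probe and sample IDs as dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a duplicate-sample sheet
#'
#' CSV with required columns `sample_id`, `subject_id`, `replicate`
#' (1 or 2) and an optional `plate` column.
#'
#' @param path Path to the CSV file.
#' @return Data frame with character IDs and integer replicate labels.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", "NaN", ""))
  required <- c("sample_id", "subject_id", "replicate")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  df$replicate <- as.integer(df$replicate)
  df
}

#' Read a probe annotation table
#'
#' CSV with a required `probe_id` column and any of: `chr`, `pos`
#' (1-based), `probe_type` (`"I"`/`"II"`), `island_relation`, `tss_group`,
#' `gene`, plus arbitrary boolean flag columns (values TRUE/FALSE or 0/1).
#'
#' @param path Path to the CSV file.
#' @return Data frame keyed by `probe_id`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", "NaN", ""))
  if (!"probe_id" %in% names(df)) stop("annotation lacks 'probe_id' column")
  if (anyDuplicated(df$probe_id)) stop("duplicate probe IDs in annotation")
  if ("probe_type" %in% names(df)) {
    bad <- !is.na(df$probe_type) & !df$probe_type %in% c("I", "II")
    if (any(bad)) stop("probe_type must be \"I\" or \"II\"")
  }
  df
}

.reliability_columns <- c("probe_id", "n_pairs", "icc", "sigma_b2",
                          "sigma_w2", "sd_diff", "hola", "micc",
                          "class_icc", "class_micc", "mean_beta", "sd_beta")

#' Write a per-probe reliability table
#'
#' TSV with the fixed column order `probe_id, n_pairs, icc, sigma_b2,
#' sigma_w2, sd_diff, hola, micc, class_icc, class_micc, mean_beta,
#' sd_beta`. Floating-point columns are written with 6 significant digits;
#' missing values as `"NA"`. The file round-trips losslessly at that
#' precision via [read_reliability_table()].
#'
#' @param rel A [probe_reliability()] fit or its `table` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reliability_table <- function(rel, path) {
  tab <- if (inherits(rel, "probe_reliability")) rel$table else rel
  miss <- setdiff(.reliability_columns, names(tab))
  if (length(miss))
    stop("reliability table lacks column(s): ", paste(miss, collapse = ", "))
  tab <- tab[, .reliability_columns]
  for (col in c("icc", "sigma_b2", "sigma_w2", "sd_diff", "hola", "micc",
                "mean_beta", "sd_beta"))
    tab[[col]] <- signif(tab[[col]], 6)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a per-probe reliability table written by [write_reliability_table()]
#'
#' @param path Path to the TSV file.
#' @return Data frame with the fixed reliability-table columns.
#' @export
read_reliability_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", "NaN", ""),
                          colClasses = c(probe_id = "character"))
  miss <- setdiff(.reliability_columns, names(df))
  if (length(miss))
    stop("not a reliability table; missing column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Run configuration with the package defaults
#'
#' Bundles the tunable constants of a reliability run: the
#' limits-of-agreement multiplier `z` (1.96 for the 95% interval), the
#' classification cutpoints and labels, the missingness filter threshold,
#' the minimum complete pairs per probe, the replicate-selection seed, the
#' cross-plate requirement, and the mean-beta bin edges for stratified
#' summaries. Serialises to a flat `key: value` text file.
#'
#' @param z Limits-of-agreement multiplier.
#' @param cutpoints,labels,boundary_rule Passed to
#'   [classification_scheme()].
#' @param max_missing_frac Missingness filter threshold.
#' @param min_pairs Minimum complete pairs per probe.
#' @param seed Seed for the replicate selection behind `sd_beta`.
#' @param require_cross_plate Only keep cross-plate duplicate pairs.
#' @param beta_bins Bin edges for mean-beta stratification.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(z = 1.96,
                       cutpoints = c(0.4, 0.6, 0.75),
                       labels = c("Poor", "Fair", "Good", "Excellent"),
                       boundary_rule = c("up", "up", "down"),
                       max_missing_frac = 0.05,
                       min_pairs = 3L,
                       seed = 1L,
                       require_cross_plate = FALSE,
                       beta_bins = seq(0, 1, by = 0.1)) {
  scheme <- classification_scheme(cutpoints, labels, boundary_rule)
  structure(list(z = z, cutpoints = scheme$cutpoints,
                 labels = scheme$labels,
                 boundary_rule = scheme$boundary_rule,
                 max_missing_frac = max_missing_frac,
                 min_pairs = as.integer(min_pairs),
                 seed = as.integer(seed),
                 require_cross_plate = isTRUE(require_cross_plate),
                 beta_bins = beta_bins),
            class = "run_config")
}

#' Write a run configuration to a flat key-value file
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  fmt <- function(v) paste(vapply(v, format, character(1), digits = 15),
                           collapse = ",")
  lines <- vapply(names(config),
                  function(k) paste0(k, ": ", fmt(config[[k]])), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration from a flat key-value file
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path Path to the config file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  if (any(vapply(kv, length, integer(1)) != 3L))
    stop("malformed config line(s)")
  keys <- trimws(vapply(kv, `[`, character(1), 2L))
  vals <- vapply(kv, `[`, character(1), 3L)
  defaults <- run_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- list()
  for (i in seq_along(keys)) {
    v <- strsplit(vals[i], ",")[[1]]
    args[[keys[i]]] <- switch(keys[i],
      labels = , boundary_rule = trimws(v),
      require_cross_plate = as.logical(trimws(v)),
      min_pairs = , seed = as.integer(trimws(v)),
      as.numeric(trimws(v)))
  }
  # cutpoints key in file maps to the constructor argument of the same name
  do.call(run_config, args)
}
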