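#' Confusion rates of presence calls against truth labels
#'
#' TPR is the fraction of truly present genomes called present, TNR the
#' fraction of truly absent genomes called absent, and balanced accuracy
#' their mean. A rate whose class is empty is `NA`, and balanced accuracy is
#' `NA` with it.
#'
#' @param calls A calls tibble with `genome_id` and logical `present`.
#' @param truth Truth labels: a data frame with `genome_id` and a logical
#'   (or 0/1) `present` column, or a named logical vector.
#' @return A one-row tibble: `tpr`, `tnr`, `balanced_accuracy`, `tp`, `fn`,
#'   `tn`, `fp`.
#' @export
confusion_rates <- function(calls, truth) {
  truth <- truth_vector(truth)
  missing <- setdiff(calls$genome_id, names(truth))
  if (length(missing) > 0) {
    abort(paste0(
      "genomes without a truth label: ",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  lab <- truth[calls$genome_id]
  tp <- sum(lab & calls$present)
  fn <- sum(lab & !calls$present)
  tn <- sum(!lab & !calls$present)
  fp <- sum(!lab & calls$present)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  tibble(
    tpr = tpr, tnr = tnr, balanced_accuracy = (tpr + tnr) / 2,
    tp = tp, fn = fn, tn = tn, fp = fp
  )
}

truth_vector <- function(truth) {
  if (is.data.frame(truth)) {
    setNames(as.logical(truth$present), truth$genome_id)
  } else {
    as.logical(truth) |> setNames(names(truth))
  }
}

#' Coverage bin boundaries
#'
#' Presence-call accuracy varies with coverage, so evaluation groups
#' observations into geometric coverage bins. Bin `i` spans the half-open
#' interval `(0.00004 * 2^i, 0.00004 * 2^(i + 1)]`; `index_origin` shifts
#' the labelling (with `index_origin = 1`, bin `x` spans
#' `(0.00004 * 2^(x-1), 0.00004 * 2^x]`) without moving the boundaries.
#'
#' @param i Bin indices (non-negative integers).
#' @param index_origin Index label offset, 0 by default.
#' @return A tibble with `i`, `low`, `up`.
#' @export
coverage_bins <- function(i, index_origin = 0) {
  tibble(
    i = i,
    low = 0.00004 * 2^(i - index_origin),
    up = 0.00004 * 2^(i - index_origin + 1)
  )
}

#' Coverage-binned TPR/TNR
#'
#' Assigns each (coverage, call, truth) observation to its coverage bin and
#' computes the TPR over truth-present observations and the TNR over
#' truth-absent observations of each bin. A genome observed at several
#' coverages (e.g. across downsampled alignments) contributes one
#' observation per coverage.
#'
#' @param observations A tibble with numeric `coverage` (> 0), logical
#'   `present` (the call) and logical `truth`.
#' @param i_max Largest bin index to keep; observations above the last bin
#'   are dropped with a warning.
#' @param index_origin See [coverage_bins()].
#' @return A tibble with one row per non-empty bin: `i`, `low`, `up`, `n`,
#'   `n_present`, `n_absent`, `tpr`, `tnr`.
#' @export
binned_rates <- function(observations, i_max = 21, index_origin = 0) {
  if (any(observations$coverage <= 0)) {
    abort("binned rates need strictly positive coverages.")
  }
  # bin i contains coverage c iff 0.00004*2^i < c <= 0.00004*2^(i+1)
  idx <- ceiling(log2(observations$coverage / 0.00004)) - 1 + index_origin
  idx[idx < index_origin] <- index_origin - 1 # below the first bin
  in_range <- idx >= index_origin & idx <= i_max
  if (any(!in_range)) {
    warn(paste0(
      sum(!in_range), " observation(s) fall outside bins ",
      index_origin, "..", i_max, " and are dropped."
    ))
  }
  obs <- observations[in_range, , drop = FALSE]
  obs$i <- idx[in_range]
  obs |>
    group_by(.data$i) |>
    summarise(
      n = n(),
      n_present = sum(.data$truth),
      n_absent = sum(!.data$truth),
      tpr = if (sum(.data$truth) > 0) {
        sum(.data$truth & .data$present) / sum(.data$truth)
      } else NA_real_,
      tnr = if (sum(!.data$truth) > 0) {
        sum(!.data$truth & !.data$present) / sum(!.data$truth)
      } else NA_real_,
      .groups = "drop"
    ) |>
    left_join(coverage_bins(0:i_max + index_origin, index_origin), by = "i") |>
    select("i", "low", "up", "n", "n_present", "n_absent", "tpr", "tnr")
}

#' Read truth labels from a two-column TSV
#'
#' @param path TSV with columns `genome_id` and `present` (0/1); a header
#'   line is optional.
#' @return A tibble with `genome_id` (character) and `present` (logical).
#' @export
read_truth <- function(path) {
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  has_header <- grepl("genome", first, ignore.case = TRUE)
  readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else c("genome_id", "present"),
    col_types = "cd", skip = 0, progress = FALSE
  ) |>
    mutate(present = .data$present != 0)
}

#' Write truth labels
#'
#' @param truth A tibble with `genome_id` and logical `present`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(
    mutate(truth, present = as.integer(.data$present)),
    path, progress = FALSE
  )
  invisible(path)
}
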