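#' Classifier configuration
#'
#' Thresholds of the presence decision rule. The defaults are the protocol
#' the benchmarks settled on: a genome is present when it has at least
#' `min_reads` mapped reads and BER above `ber_threshold`; below
#' `coverage_switch` average coverage, FUG above `fug_threshold` is
#' additionally required, because at low coverage BER alone cannot tell
#' genome-wide placements from a covered island, while at high coverage the
#' integer rounding of the expected distance makes FUG unreliable.
#'
#' Presets: `"default"` is the recommended protocol (BER > 0.8, FUG > 0.5,
#' 80-read limit, coverage switch 0.1); `"cami"` raises the coverage switch
#' to 1 (the rule used on the community benchmark where FUG covered all
#' genomes below coverage 1); `"optimal"` lowers the BER threshold to 0.77,
#' a tuned alternative operating point.
#'
#' @param ber_threshold BER above which a genome can be called present.
#' @param fug_threshold FUG above which the gap criterion holds.
#' @param min_reads Detection limit: genomes with fewer mapped reads are
#'   absent regardless of metrics.
#' @param coverage_switch Average coverage above which FUG is not consulted.
#' @param fug_aggregation `"mean"` compares the mean FUG of the defined
#'   mate groups against the threshold; `"all"` requires every defined
#'   group to pass.
#' @param preset Optional named preset applied before explicit arguments.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(ber_threshold = 0.8, fug_threshold = 0.5,
                              min_reads = 80, coverage_switch = 0.1,
                              fug_aggregation = c("mean", "all"),
                              preset = NULL) {
  fug_aggregation <- match.arg(fug_aggregation)
  cfg <- list(
    ber_threshold = ber_threshold, fug_threshold = fug_threshold,
    min_reads = min_reads, coverage_switch = coverage_switch,
    fug_aggregation = fug_aggregation
  )
  if (!is.null(preset)) {
    cfg <- switch(preset,
      default = cfg,
      cami = utils::modifyList(cfg, list(coverage_switch = 1)),
      optimal = utils::modifyList(cfg, list(ber_threshold = 0.77)),
      abort(paste0("unknown preset: ", preset))
    )
  }
  stopifnot(
    cfg$ber_threshold > 0, cfg$ber_threshold <= 1,
    cfg$fug_threshold > 0, cfg$fug_threshold <= 1,
    cfg$min_reads >= 1, cfg$coverage_switch >= 0
  )
  structure(cfg, class = "classifier_config")
}

#' Call presence per genome from evenness and gap metrics
#'
#' Applies the decision rule to a joined metrics table. The rule, per
#' genome: absent when the mapped-read count is below the detection limit
#' (reason `no_reads` at zero, `below_detection_limit` otherwise);
#' otherwise, above the coverage switch, present iff BER clears its
#' threshold (`present_ber_only` / `low_ber`); at or below the switch,
#' present iff BER clears its threshold and the FUG criterion holds
#' (`present_ber_fug` / `low_ber` / `low_fug`). A genome whose FUG is
#' undefined in the low-coverage regime is absent with reason `low_fug`:
#' the gap evidence the regime requires is missing.
#'
#' @param metrics A tibble with at least `genome_id`, `n_reads`, `coverage`,
#'   `ber`, and the FUG columns of [genome_gap_metrics()] — i.e. the join
#'   of [genome_evenness()] and [genome_gap_metrics()].
#' @param config A [classifier_config()].
#' @return The input with `present` (logical) and `reason` columns added.
#' @export
call_presence <- function(metrics, config = classifier_config()) {
  fug_crit <- if (config$fug_aggregation == "mean") {
    !is.na(metrics$fug_mean) & metrics$fug_mean > config$fug_threshold
  } else {
    groups <- cbind(metrics$fug_first, metrics$fug_second,
                    metrics$fug_unpaired)
    apply(groups, 1, function(v) {
      any(!is.na(v)) && all(v[!is.na(v)] > config$fug_threshold)
    })
  }
  metrics |>
    mutate(
      .fug_ok = fug_crit,
      .ber_ok = !is.na(.data$ber) & .data$ber > config$ber_threshold,
      reason = dplyr::case_when(
        .data$n_reads == 0 ~ "no_reads",
        .data$n_reads < config$min_reads ~ "below_detection_limit",
        !.data$.ber_ok ~ "low_ber",
        .data$coverage > config$coverage_switch ~ "present_ber_only",
        .data$.fug_ok ~ "present_ber_fug",
        .default = "low_fug"
      ),
      present = .data$reason %in% c("present_ber_only", "present_ber_fug")
    ) |>
    select(!c(".fug_ok", ".ber_ok"))
}

#' Normalized read count (Rcn)
#'
#' An abundance proxy normalized for genome length and sequencing depth:
#' `Nr * 1e9 / (Gl * Rtot)`, where `Nr` is the number of reads mapped on
#' the genome, `Gl` its length, and `Rtot` the total reads in the sample.
#' The 1e9 factor only rescales for readability. Rcn is linear in `Nr` and
#' invariant under proportional changes of `Nr` and `Rtot`.
#'
#' @param n_reads Reads mapped on the genome.
#' @param genome_length Genome length (bp), > 0.
#' @param total_reads Total reads in the sample, > 0.
#' @return The normalized read count.
#' @examples
#' rcn(10, 1e6, 1e7) # 1
#' @export
rcn <- function(n_reads, genome_length, total_reads) {
  if (any(total_reads <= 0)) {
    abort("total read count must be > 0.")
  }
  if (any(genome_length <= 0)) {
    abort("genome length must be > 0.")
  }
  n_reads * 1e9 / (genome_length * total_reads)
}

report_columns <- c(
  "genome", "length", "n_reads", "coverage", "breadth", "expected_breadth",
  "ber", "fug_first", "fug_second", "fug_unpaired", "fug_mean", "rcn",
  "present", "reason"
)

#' Write a presence report
#'
#' Writes one TSV row per genome in lexicographic genome order with a fixed
#' column set, `NA` for undefined metrics, floats at 6 significant digits,
#' and `present` as 0/1. A companion `<path>.present.tsv` restricted to the
#' present genomes is written alongside.
#'
#' @param calls A calls tibble from [call_presence()] (with `rcn`, as
#'   produced by [screen_presence()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(calls, path) {
  tbl <- calls |>
    mutate(
      genome = .data$genome_id, length = .data$genome_length,
      present = as.integer(.data$present)
    ) |>
    arrange(.data$genome)
  for (col in setdiff(report_columns, names(tbl))) tbl[[col]] <- NA_real_
  tbl <- select(tbl, all_of(report_columns)) |>
    mutate(across(
      c("coverage", "breadth", "expected_breadth", "ber", "fug_first",
        "fug_second", "fug_unpaired", "fug_mean", "rcn"),
      ~ signif(.x, 6)
    ))
  readr::write_tsv(tbl, path, na = "NA", progress = FALSE)
  readr::write_tsv(
    filter(tbl, .data$present == 1L),
    paste0(sub("\\.tsv$", "", path), ".present.tsv"),
    na = "NA", progress = FALSE
  )
  invisible(path)
}

#' Read a presence report back into a calls tibble
#'
#' @param path A TSV written by [write_report()].
#' @return A tibble in the same shape [call_presence()] produces.
#' @export
read_report <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      genome = "c", reason = "c", n_reads = "i", present = "i",
      .default = "d"
    ),
    progress = FALSE
  ) |>
    mutate(
      genome_id = .data$genome, genome_length = .data$length,
      present = .data$present == 1L
    ) |>
    select(!c("genome", "length"))
}
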