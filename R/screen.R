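#' Screen a metagenomic alignment for present genomes
#'
#' The main pipeline: reads the placements of a coordinate-sorted SAM/BAM,
#' computes per-genome evenness (coverage, breadth, expected breadth, BER)
#' and gap (FUG per mate group) metrics, applies the presence decision
#' rule, and attaches the normalized read count (Rcn). Accepts either an
#' alignment path plus catalog, or a placement tibble directly (useful with
#' simulated placements).
#'
#' @param alignment Path to a sorted SAM/BAM file, or a placement tibble as
#'   returned by [read_placements()] / [sample_placements()].
#' @param catalog A `genome_catalog` ([load_genome_catalog()]), or a path
#'   that [load_genome_catalog()] accepts.
#' @param config A [classifier_config()].
#' @param total_reads Total reads in the sample for Rcn; defaults to the
#'   number of mapped placements.
#' @param ... Passed to [read_placements()] when `alignment` is a path.
#' @return An object of class `presence_screen`: a list with `calls` (the
#'   per-genome tibble), `config`, and `total_reads`. Use [tidy()] for the
#'   calls, [glance()] for a one-row summary, [autoplot()] for the BER-FUG
#'   plane, [write_report()] on the calls to export.
#' @examples
#' spec <- simulation_spec(
#'   tibble::tibble(
#'     genome_id = c("gA", "gB"),
#'     contigs = list(5e4, 5e4),
#'     pattern = c("uniform", "region_restricted"),
#'     coverage = c(0.5, 0.5)
#'   ),
#'   seed = 7
#' )
#' scr <- screen_presence(sample_placements(spec), spec_catalog(spec))
#' tidy(scr)
#' @export
screen_presence <- function(alignment, catalog,
                            config = classifier_config(),
                            total_reads = NULL, ...) {
  if (is.character(catalog)) {
    catalog <- load_genome_catalog(catalog)
  }
  placements <- if (is.character(alignment)) {
    read_placements(alignment, catalog, ...)
  } else {
    alignment
  }
  total_reads <- total_reads %||% nrow(placements)
  evenness <- genome_evenness(placements, catalog)
  gaps <- genome_gap_metrics(placements, catalog)
  calls <- evenness |>
    left_join(gaps, by = "genome_id") |>
    call_presence(config) |>
    mutate(
      rcn = if (.env$total_reads > 0) {
        rcn(.data$n_reads, .data$genome_length, .env$total_reads)
      } else NA_real_
    ) |>
    arrange(.data$genome_id)
  structure(
    list(calls = calls, config = config, total_reads = total_reads),
    class = "presence_screen"
  )
}

#' @export
print.presence_screen <- function(x, ...) {
  cat(
    "Presence screen: ", nrow(x$calls), " genomes, ",
    sum(x$calls$present), " called present (BER > ",
    x$config$ber_threshold, ", FUG > ", x$config$fug_threshold,
    " below coverage ", x$config$coverage_switch,
    ", detection limit ", x$config$min_reads, " reads)\n",
    sep = ""
  )
  print(x$calls, ...)
  invisible(x)
}

#' Per-genome calls of a presence screen
#'
#' @param x A `presence_screen`.
#' @param ... Unused.
#' @return The per-genome calls tibble.
#' @method tidy presence_screen
#' @export
tidy.presence_screen <- function(x, ...) {
  x$calls
}

#' One-row summary of a presence screen
#'
#' @param x A `presence_screen`.
#' @param ... Unused.
#' @return A tibble with genome counts, mapped-read totals, and the
#'   thresholds used.
#' @method glance presence_screen
#' @export
glance.presence_screen <- function(x, ...) {
  tibble(
    n_genomes = nrow(x$calls),
    n_present = sum(x$calls$present),
    n_below_limit = sum(x$calls$reason %in%
                          c("no_reads", "below_detection_limit")),
    total_reads = x$total_reads,
    mapped_reads = sum(x$calls$n_reads),
    ber_threshold = x$config$ber_threshold,
    fug_threshold = x$config$fug_threshold,
    min_reads = x$config$min_reads,
    coverage_switch = x$config$coverage_switch
  )
}

#' BER-FUG plane of a presence screen
#'
#' Scatterplot of mean FUG against BER for every genome above the detection
#' limit, with the decision thresholds drawn as dashed lines — the standard
#' view of how present and absent genomes separate.
#'
#' @param object A `presence_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot presence_screen
#' @export
autoplot.presence_screen <- function(object, ...) {
  calls <- filter(
    object$calls,
    !.data$reason %in% c("no_reads", "below_detection_limit")
  )
  ggplot2::ggplot(
    calls,
    ggplot2::aes(x = .data$ber, y = .data$fug_mean, colour = .data$present)
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(
      xintercept = object$config$ber_threshold, linetype = "dashed"
    ) +
    ggplot2::geom_hline(
      yintercept = object$config$fug_threshold, linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "BER (observed / expected breadth)",
      y = "FUG (mean over mate groups)",
      colour = "called present"
    ) +
    ggplot2::theme_minimal()
}

#' Per-base depth distribution of one genome
#'
#' Histogram of the per-base sequencing depth of a genome, the diagnostic
#' that separates even coverage (a single Poisson-like mode) from the
#' tailed or bimodal profiles produced by mismapped reads.
#'
#' @param placements A placement tibble.
#' @param catalog A `genome_catalog`.
#' @param genome_id The genome to profile.
#' @return A ggplot object.
#' @export
plot_depth_distribution <- function(placements, catalog, genome_id) {
  depth <- genome_depths(placements, catalog, genome_id)
  ggplot2::ggplot(
    tibble(depth = depth),
    ggplot2::aes(x = .data$depth)
  ) +
    ggplot2::geom_histogram(binwidth = 1, boundary = -0.5) +
    ggplot2::labs(
      x = "per-base depth", y = "positions",
      title = genome_id
    ) +
    ggplot2::theme_minimal()
}

#' Per-base depth vector of one genome
#'
#' @inheritParams plot_depth_distribution
#' @return An integer vector of per-base depths over the genome's contig
#'   concatenation.
#' @export
genome_depths <- function(placements, catalog, genome_id) {
  entry <- filter(as_tibble(catalog), .data$genome_id == .env$genome_id)
  if (nrow(entry) == 0) {
    abort(paste0("genome not in catalog: ", genome_id))
  }
  on_genome <- filter(placements, .data$contig_id %in% entry$contig_id)
  unlist(map(seq_len(nrow(entry)), function(i) {
    on_contig <- on_genome[on_genome$contig_id == entry$contig_id[i], ,
                           drop = FALSE]
    depth_profile(on_contig$start, on_contig$read_length, entry$length[i])
  }), use.names = FALSE)
}
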