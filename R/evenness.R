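#' Per-base depth profile of one contig
#'
#' Builds the depth profile with a difference array: +1 at each read start,
#' -1 just past each read end, then a prefix sum. Reads overhanging the
#' contig end are clamped to it (real mappers produce such records at contig
#' boundaries), so the sum of the profile equals the sum of the clamped read
#' spans.
#'
#' @param starts 0-based read start positions on the contig.
#' @param read_lengths Read lengths (bp), recycled against `starts`.
#' @param contig_length Contig length (bp).
#' @return An integer vector of length `contig_length` with the depth at
#'   each position.
#' @examples
#' depth_profile(c(2, 2), 3, 10)
#' @export
depth_profile <- function(starts, read_lengths, contig_length) {
  if (length(starts) == 0) {
    return(integer(contig_length))
  }
  n <- length(starts)
  read_lengths <- rep_len(read_lengths, n)
  if (any(starts < 0) || any(starts >= contig_length)) {
    abort("read starts must lie in [0, contig_length).")
  }
  if (any(read_lengths < 1)) {
    abort("read lengths must be >= 1.")
  }
  ends <- pmin(starts + read_lengths, contig_length)
  inc <- tabulate(starts + 1L, nbins = contig_length)
  dec <- tabulate(ends + 1L, nbins = contig_length)
  cumsum(inc - dec)
}

#' Average coverage and observed breadth of a genome
#'
#' Coverage is the mean per-base depth over all positions of all contigs;
#' breadth is one minus the fraction of zero-depth positions. Both are
#' computed from the depth profiles themselves, so they stay consistent with
#' end-clamping of overhanging reads.
#'
#' @param placements Placements on a single genome: a data frame with
#'   `contig_id`, `start`, `read_length`.
#' @param catalog_entry Rows of the catalog for that genome (`contig_id`,
#'   `length`).
#' @return A list with `coverage` and `breadth`.
#' @export
coverage_and_breadth <- function(placements, catalog_entry) {
  gl <- sum(catalog_entry$length)
  total <- 0
  zeros <- 0
  for (i in seq_len(nrow(catalog_entry))) {
    cid <- catalog_entry$contig_id[i]
    clen <- catalog_entry$length[i]
    on_contig <- placements[placements$contig_id == cid, , drop = FALSE]
    depth <- depth_profile(on_contig$start, on_contig$read_length, clen)
    total <- total + sum(as.numeric(depth))
    zeros <- zeros + sum(depth == 0L)
  }
  list(coverage = total / gl, breadth = 1 - zeros / gl)
}

#' Expected breadth at a given average coverage
#'
#' The fraction of a genome expected to be covered by at least one read
#' under random fragmentation, `1 - exp(-0.883 * coverage)`. The 0.883
#' constant is an empirical correction of the ideal Poisson exponent
#' (derived by Olm and colleagues from resampled synthetic reads) and is
#' kept fixed.
#'
#' @param coverage Mean per-base depth, >= 0.
#' @return Expected breadth in `[0, 1)`.
#' @examples
#' expected_breadth(1) # ~0.5865
#' @export
expected_breadth <- function(coverage) {
  if (any(coverage < 0)) {
    abort("coverage must be non-negative.")
  }
  1 - exp(-0.883 * coverage)
}

#' Breadth to expected-breadth ratio (BER)
#'
#' The ratio of observed to expected breadth. Reads spread genome-wide give
#' a ratio near 1; reads confined to a fraction of the genome depress the
#' observed breadth and the ratio with it. Values above 1 are legal (the
#' 0.883-corrected expectation can undershoot the observed breadth).
#'
#' @param breadth Observed breadth in `[0, 1]`.
#' @param exp_breadth Expected breadth, > 0.
#' @return `breadth / exp_breadth`.
#' @export
ber <- function(breadth, exp_breadth) {
  if (any(exp_breadth <= 0)) {
    abort("expected breadth must be > 0 (the genome has no reads).")
  }
  breadth / exp_breadth
}

#' Evenness metrics for every genome of a catalog
#'
#' Computes, per genome, the average coverage, observed breadth, expected
#' breadth, and BER from a placement table. Genomes with no mapped reads get
#' zero coverage and breadth and `NA` metrics.
#'
#' @param placements A placement tibble ([read_placements()] or
#'   [sample_placements()]).
#' @param catalog A `genome_catalog`.
#' @return A tibble with one row per genome: `genome_id`, `genome_length`,
#'   `n_reads`, `mean_read_length`, `coverage`, `breadth`,
#'   `expected_breadth`, `ber`.
#' @export
genome_evenness <- function(placements, catalog) {
  per_genome <- collect_genome_placements(placements, catalog)
  cat_tbl <- as_tibble(catalog)
  rows <- pmap(
    list(per_genome$genome_id, per_genome$placements),
    function(gid, pl) {
      entry <- cat_tbl[cat_tbl$genome_id == gid, , drop = FALSE]
      cb <- coverage_and_breadth(pl, entry)
      tibble(coverage = cb$coverage, breadth = cb$breadth)
    }
  ) |>
    list_rbind()
  per_genome |>
    select(!"placements") |>
    dplyr::bind_cols(rows) |>
    mutate(
      expected_breadth = if_else(
        .data$n_reads > 0, expected_breadth(.data$coverage), NA_real_
      ),
      ber = if_else(
        .data$n_reads > 0, .data$breadth / .data$expected_breadth, NA_real_
      )
    )
}
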