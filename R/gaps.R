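#' Add sentinel reads to a mate-group position array
#'
#' Two artificial read positions are added to each mate-group array before
#' gap statistics are computed: one at the start of the genome's contig
#' concatenation (position 0) and one at the end minus the mean read length
#' (`Gl - round(Rl)`). Without them, reads confined to a single interior
#' region can look perfectly even; the sentinels force the flanking gaps to
#' appear in the distance distribution. Duplicated positions are kept — a
#' stacked read is a zero distance, not a tie to break.
#'
#' @param positions Sorted read start positions in concatenated coordinates,
#'   each in `[0, Gl)`.
#' @param genome_length Total genome length `Gl` (bp).
#' @param mean_read_length Mean read length of the genome's mapped reads (bp).
#' @return The sorted positions with the two sentinels included.
#' @export
add_sentinels <- function(positions, genome_length, mean_read_length) {
  tail_pos <- genome_length - round(mean_read_length)
  if (tail_pos < 0) {
    abort("genome shorter than the mean read length; cannot place sentinels.")
  }
  sort(c(0, positions, tail_pos))
}

#' Expected distance between consecutive reads
#'
#' Under a homogeneous Poisson placement the inter-read distance is
#' exponential with rate `n / Gl`; the expected distance is rounded to the
#' nearest integer (round-half-to-even, base R's convention) because
#' genomic positions are discrete.
#'
#' @param n_positions Number of positions in the mate-group array,
#'   sentinels included; must be >= 2.
#' @param genome_length Genome length `Gl` (bp).
#' @return The integer expected distance `Delta`.
#' @export
expected_distance <- function(n_positions, genome_length) {
  if (n_positions < 2) {
    abort("expected distance needs at least 2 positions.")
  }
  round(genome_length / n_positions)
}

#' Fraction of unexpected gaps (FUG) of one position array
#'
#' Distances between consecutive read start positions are compared with the
#' expected distance `Delta`. Each distance exceeding `Delta` contributes
#' its excess, weighted by its frequency in the distance distribution, to a
#' penalty; FUG is `(Delta - penalty) / Delta`. It equals 1 exactly when no
#' gap exceeds `Delta`, approximates `1 - exp(-1) ~ 0.632` for uniformly
#' random positions, and drops well below 0.5 when reads cluster in a small
#' fraction of the genome (it may go negative for extreme clustering).
#'
#' @param positions Sorted position array, sentinels already included
#'   ([add_sentinels()]); length >= 2.
#' @param genome_length Genome length `Gl` (bp).
#' @return The FUG value (a real number <= 1).
#' @examples
#' fug(c(0, 10, 11, 12, 90), 100) # 0.275
#' @export
fug <- function(positions, genome_length) {
  n <- length(positions)
  if (n < 2) {
    abort("FUG needs at least 2 positions (including sentinels).")
  }
  delta <- expected_distance(n, genome_length)
  d <- diff(positions)
  penalty <- sum(pmax(d - delta, 0)) / length(d)
  (delta - penalty) / delta
}

#' Distance histogram of a position array
#'
#' Tabulates the distances between consecutive positions as frequencies
#' `p_d = N_d / (n - 1)`. Mostly of diagnostic interest; [fug()] consumes
#' the distances directly.
#'
#' @inheritParams fug
#' @return A tibble with `distance`, `count`, and `p` (frequencies summing
#'   to 1).
#' @export
distance_histogram <- function(positions, genome_length) {
  if (length(positions) < 2) {
    abort("a distance histogram needs at least 2 positions.")
  }
  d <- diff(sort(positions))
  tab <- table(d)
  tibble(
    distance = as.numeric(names(tab)),
    count = as.integer(tab),
    p = as.integer(tab) / length(d)
  )
}

#' Gap metrics for every genome of a catalog
#'
#' Computes FUG per genome and mate group. For paired data the first-mate
#' and second-mate arrays are scored independently, each with its own
#' sentinels and expected distance, so that the fixed insert size between
#' mates does not contaminate the gap distribution; unpaired reads form a
#' single group. Groups with fewer than `min_group_size` real (non-sentinel)
#' reads yield `NA`: the gap distribution of one or zero reads carries no
#' information. `fug_mean` averages the defined groups.
#'
#' @inheritParams genome_evenness
#' @param min_group_size Minimum non-sentinel reads a mate group needs for
#'   its FUG to be defined.
#' @return A tibble with one row per genome: `genome_id`, `fug_first`,
#'   `fug_second`, `fug_unpaired`, `fug_mean` (all `NA` when no group is
#'   defined).
#' @export
genome_gap_metrics <- function(placements, catalog, min_group_size = 2) {
  per_genome <- collect_genome_placements(placements, catalog)
  rows <- pmap(
    list(per_genome$genome_id, per_genome$genome_length,
         per_genome$mean_read_length, per_genome$placements),
    function(gid, gl, rl, pl) {
      groups <- c("first", "second", "unpaired")
      vals <- map_dbl(groups, function(g) {
        pos <- sort(pl$concat_pos[pl$mate_group == g])
        group_fug(pos, gl, rl, min_group_size)
      })
      names(vals) <- paste0("fug_", groups)
      defined <- vals[!is.na(vals)]
      tibble(
        genome_id = gid,
        fug_first = vals[["fug_first"]],
        fug_second = vals[["fug_second"]],
        fug_unpaired = vals[["fug_unpaired"]],
        fug_mean = if (length(defined) > 0) mean(defined) else NA_real_
      )
    }
  )
  list_rbind(rows)
}

group_fug <- function(positions, genome_length, mean_read_length,
                      min_group_size) {
  if (length(positions) < min_group_size) {
    return(NA_real_)
  }
  fug(add_sentinels(positions, genome_length, mean_read_length),
      genome_length)
}
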