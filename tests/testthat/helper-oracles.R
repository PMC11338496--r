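# Independent oracles and small fixture builders used across the suite.

# naive per-position overlap count: the reference for the difference-array
# depth computation
naive_depth <- function(starts, read_lengths, contig_length) {
  read_lengths <- rep_len(read_lengths, length(starts))
  depth <- integer(contig_length)
  for (i in seq_along(starts)) {
    span <- seq(starts[i] + 1, min(starts[i] + read_lengths[i], contig_length))
    depth[span] <- depth[span] + 1L
  }
  depth
}

# FUG recomputed literally from the distance histogram definition:
# (Delta - sum_{d >= Delta} p_d (d - Delta)) / Delta
fug_via_histogram <- function(positions, genome_length) {
  d <- diff(sort(positions))
  delta <- round(genome_length / length(positions))
  tab <- table(d)
  dv <- as.numeric(names(tab))
  p <- as.numeric(tab) / length(d)
  over <- dv >= delta
  (delta - sum(p[over] * (dv[over] - delta))) / delta
}

# one-contig-per-genome catalog from named lengths
toy_catalog <- function(lengths) {
  genome_catalog(tibble::tibble(
    contig_id = paste0(names(lengths), "_c1"),
    genome_id = names(lengths),
    length = as.numeric(lengths)
  ))
}

toy_placements <- function(contig_id, start, read_length = 150,
                           mate_group = "unpaired") {
  tibble::tibble(
    contig_id = contig_id, start = start,
    read_length = read_length, mate_group = mate_group
  )
}

# a small mixed community: uniform genomes are truly present,
# region-restricted ones absent
mixed_community_spec <- function(seed, genome_length = 2e5) {
  simulation_spec(
    tibble::tibble(
      genome_id = c("pres_hi", "pres_lo", "pres_mid", "abs_hi", "abs_lo"),
      contigs = list(genome_length, genome_length, c(genome_length / 2,
                                                     genome_length / 2),
                     genome_length, genome_length),
      pattern = c("uniform", "uniform", "uniform",
                  "region_restricted", "region_restricted"),
      coverage = c(0.5, 0.08, 0.2, 0.5, 0.1),
      covered_fraction = c(1, 1, 1, 0.1, 0.08),
      n_regions = c(1, 1, 1, 2, 1)
    ),
    seed = seed
  )
}
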