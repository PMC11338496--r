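#' Build a simulation specification
#'
#' Describes a synthetic community: one row per genome with its contig
#' lengths and a read-placement pattern. Reads are *placed*, not sequenced —
#' no base errors and no mapper in the loop — because the presence metrics
#' consume mapping positions only; this isolates them from aligner
#' behaviour.
#'
#' Patterns:
#' * `"uniform"` — starts i.i.d. uniform over the genome, the homogeneous
#'   Poisson placement of randomly fragmented DNA from a genome that is
#'   really in the sample;
#' * `"region_restricted"` — starts confined to `n_regions` disjoint random
#'   intervals totalling `covered_fraction` of the genome, the signature of
#'   reads mismapped onto a genome that is absent;
#' * `"bimodal"` — a uniform layer at `coverage` plus a region-restricted
#'   spike at `spike_coverage` on `spike_fraction` of the genome, the
#'   tailed/bimodal depth profile of a present genome receiving mismapped
#'   reads from an abundant relative.
#'
#' @param genomes A data frame with columns `genome_id`, `contigs` (list
#'   column of contig length vectors, or a single numeric length),
#'   `pattern`, `coverage`, and optionally `covered_fraction` (default 0.1),
#'   `n_regions` (default 1), `spike_coverage`, `spike_fraction`, and
#'   `truth_present`. Missing truth defaults to `TRUE` for `uniform` and
#'   `bimodal`, `FALSE` for `region_restricted`.
#' @param read_length Read length in bp.
#' @param paired Generate read pairs (`TRUE`) or single-end reads.
#' @param insert_mean,insert_sd Insert-size model for paired reads (bp);
#'   the default 270 bp mean matches common short-read library preparations.
#' @param seed Integer master seed. Each genome draws from its own stream,
#'   derived by a stable hash of `(seed, genome_id)`, so results do not
#'   depend on genome order.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(genomes, read_length = 150, paired = TRUE,
                            insert_mean = 270, insert_sd = 30, seed = 1) {
  genomes <- as_tibble(genomes)
  stopifnot(all(c("genome_id", "contigs", "pattern", "coverage") %in%
                  names(genomes)))
  if (!is.list(genomes$contigs)) genomes$contigs <- as.list(genomes$contigs)
  if (any(unlist(genomes$contigs) <= 0)) abort("contig lengths must be > 0.")
  if (any(genomes$coverage < 0)) abort("coverages must be >= 0.")
  defaults <- list(
    covered_fraction = 0.1, n_regions = 1,
    spike_coverage = NA_real_, spike_fraction = NA_real_
  )
  for (col in names(defaults)) {
    if (!col %in% names(genomes)) genomes[[col]] <- defaults[[col]]
  }
  bad_frac <- !is.na(genomes$covered_fraction) &
    (genomes$covered_fraction <= 0 | genomes$covered_fraction > 1)
  if (any(bad_frac)) abort("covered_fraction must lie in (0, 1].")
  if (!"truth_present" %in% names(genomes)) {
    genomes$truth_present <- genomes$pattern != "region_restricted"
  }
  structure(
    list(
      genomes = genomes, read_length = read_length, paired = paired,
      insert_mean = insert_mean, insert_sd = insert_sd,
      seed = as.integer(seed)
    ),
    class = "simulation_spec"
  )
}

# deterministic 31-adic hash of (seed, id), kept below 2^31
genome_seed <- function(seed, genome_id) {
  h <- seed %% 2147483647
  for (code in utf8ToInt(genome_id)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Generate the genome sequences of a simulation
#'
#' Writes one FASTA file per genome (random A/C/G/T of the requested contig
#' lengths, seeded and deterministic) and returns the matching catalog.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return The `genome_catalog` of the written genomes.
#' @export
make_genomes <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(nrow(spec$genomes))) {
    gid <- spec$genomes$genome_id[k]
    lens <- spec$genomes$contigs[[k]]
    seqs <- withr::with_seed(genome_seed(spec$seed, gid), {
      map(lens, ~ paste(
        sample(c("A", "C", "G", "T"), .x, replace = TRUE),
        collapse = ""
      ))
    })
    names(seqs) <- paste0(gid, "_c", seq_along(lens))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(unlist(seqs)),
      file.path(dir, paste0(gid, ".fasta"))
    )
  }
  spec_catalog(spec)
}

#' Catalog implied by a simulation spec
#'
#' @param spec A [simulation_spec()].
#' @return The `genome_catalog` the spec describes (contigs named
#'   `<genome_id>_c<k>`), without touching the file system.
#' @export
spec_catalog <- function(spec) {
  rows <- pmap(
    list(spec$genomes$genome_id, spec$genomes$contigs),
    function(gid, lens) {
      tibble(
        contig_id = paste0(gid, "_c", seq_along(lens)),
        genome_id = gid, length = as.numeric(lens)
      )
    }
  )
  genome_catalog(list_rbind(rows))
}

#' Sample read placements for every genome of a simulation
#'
#' Draws read start positions per genome according to its pattern, at
#' `round(coverage * Gl / read_length)` reads (pairs count two reads).
#' Paired reads get a forward mate placed uniformly and a partner offset by
#' an insert drawn from the normal insert model, truncated to stay on the
#' genome. Positions are sampled in concatenated genome coordinates and
#' mapped back to contigs.
#'
#' @param spec A [simulation_spec()].
#' @param catalog Optional catalog; defaults to [spec_catalog()].
#' @return A placement tibble: `contig_id`, `start`, `read_length`,
#'   `mate_group`, `read_id`, `genome_id`.
#' @export
sample_placements <- function(spec, catalog = spec_catalog(spec)) {
  rows <- map(seq_len(nrow(spec$genomes)), function(k) {
    g <- spec$genomes[k, ]
    gl <- sum(g$contigs[[1]])
    withr::with_seed(
      genome_seed(spec$seed, g$genome_id),
      sample_genome_placements(g, gl, spec)
    )
  })
  pl <- list_rbind(rows)
  if (nrow(pl) == 0) {
    return(mutate(empty_placements(), read_id = character())[
      c("contig_id", "start", "read_length", "mate_group", "read_id")
    ])
  }
  # map concatenated positions back onto contigs
  cat_tbl <- as_tibble(catalog)
  per <- pl |>
    group_by(.data$genome_id) |>
    dplyr::group_modify(function(d, key) {
      contigs <- cat_tbl[cat_tbl$genome_id == key$genome_id, , drop = FALSE]
      idx <- findInterval(d$concat_pos, contigs$offset)
      d$contig_id <- contigs$contig_id[idx]
      d$start <- d$concat_pos - contigs$offset[idx]
      d
    }) |>
    ungroup()
  select(per, "contig_id", "start", "read_length", "mate_group", "read_id",
         "genome_id")
}

sample_genome_placements <- function(g, gl, spec) {
  rl <- spec$read_length
  layers <- if (g$pattern == "bimodal") {
    if (is.na(g$spike_coverage) || is.na(g$spike_fraction)) {
      abort("bimodal pattern needs spike_coverage and spike_fraction.")
    }
    list(
      list(coverage = g$coverage, fraction = 1, n_regions = 1),
      list(coverage = g$spike_coverage, fraction = g$spike_fraction,
           n_regions = g$n_regions)
    )
  } else if (g$pattern == "region_restricted") {
    list(list(coverage = g$coverage, fraction = g$covered_fraction,
              n_regions = g$n_regions))
  } else if (g$pattern == "uniform") {
    list(list(coverage = g$coverage, fraction = 1, n_regions = 1))
  } else {
    abort(paste0("unknown placement pattern: ", g$pattern))
  }
  out <- list()
  layer_tag <- 0
  for (ly in layers) {
    layer_tag <- layer_tag + 1
    n_reads <- round(ly$coverage * gl / rl)
    if (n_reads < 1) {
      if (ly$coverage > 0) {
        warn(paste0(
          "genome ", g$genome_id, ": requested coverage yields 0 reads."
        ))
      }
      next
    }
    regions <- if (ly$fraction >= 1) {
      tibble(start = 0, len = gl)
    } else {
      draw_regions(gl, ly$fraction, ly$n_regions)
    }
    if (spec$paired) {
      n_pairs <- max(round(n_reads / 2), 1)
      first <- region_uniform(n_pairs, regions, rl)
      insert <- pmax(round(rnorm(n_pairs, spec$insert_mean, spec$insert_sd)),
                     rl)
      second <- pmin(pmax(first + insert - rl, 0), gl - rl)
      ids <- paste0(g$genome_id, "_L", layer_tag, "_p", seq_len(n_pairs))
      out[[length(out) + 1]] <- tibble(
        genome_id = g$genome_id,
        concat_pos = c(first, second),
        read_length = rl,
        mate_group = rep(c("first", "second"), each = n_pairs),
        read_id = c(ids, ids)
      )
    } else {
      out[[length(out) + 1]] <- tibble(
        genome_id = g$genome_id,
        concat_pos = region_uniform(n_reads, regions, rl),
        read_length = rl,
        mate_group = "unpaired",
        read_id = paste0(g$genome_id, "_L", layer_tag, "_r",
                         seq_len(n_reads))
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(
      genome_id = character(), concat_pos = numeric(),
      read_length = numeric(), mate_group = character(),
      read_id = character()
    ))
  }
  list_rbind(out)
}

# n_regions disjoint intervals with total length fraction * gl, placed by
# distributing the leftover length into random gaps
draw_regions <- function(gl, fraction, n_regions) {
  total <- fraction * gl
  len_each <- total / n_regions
  slack <- gl - total
  gaps <- diff(c(0, sort(runif(n_regions)), 1)) * slack
  starts <- cumsum(gaps[seq_len(n_regions)]) +
    (seq_len(n_regions) - 1) * len_each
  tibble(start = floor(starts), len = floor(len_each))
}

# uniform starts over a union of intervals, keeping a read-length margin
region_uniform <- function(n, regions, read_length) {
  avail <- pmax(regions$len - read_length, 1)
  cum <- cumsum(avail)
  u <- runif(n, 0, cum[length(cum)])
  idx <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(regions))
  floor(regions$start[idx] + (u - c(0, cum)[idx]))
}

#' Subsample placements, keeping mates together
#'
#' Keeps each read pair (or unpaired read) independently with probability
#' `fraction`; the two mates of a pair are kept or dropped together, as the
#' original sampling unit is the fragment. Mirrors downsampling a BAM file
#' by fraction.
#'
#' @param placements A placement tibble carrying a `read_id` column (as
#'   produced by [sample_placements()]); rows sharing a `read_id` are mates.
#' @param fraction Keep probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The subsampled placements.
#' @export
subsample_placements <- function(placements, fraction, seed = 1) {
  if (fraction < 0 || fraction > 1) {
    abort("subsampling fraction must lie in [0, 1].")
  }
  units <- unique(placements$read_id)
  keep <- withr::with_seed(
    as.integer(seed),
    units[runif(length(units)) < fraction]
  )
  filter(placements, .data$read_id %in% keep)
}

#' Write placements as a coordinate-sorted SAM file
#'
#' Produces a valid SAM: a header with one sequence line per catalog contig
#' (declared `SO:coordinate`), and one record per placement with 1-based
#' POS, pair flags from the mate group, a placeholder `<len>M` CIGAR, and
#' dummy sequence/quality. Records are coordinate-sorted.
#'
#' @param placements A placement tibble (`contig_id`, `start`,
#'   `read_length`, `mate_group`, optionally `read_id`).
#' @param catalog The `genome_catalog` the placements refer to.
#' @param path Output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(placements, catalog, path) {
  cat_tbl <- as_tibble(catalog)
  if (!all(placements$contig_id %in% cat_tbl$contig_id)) {
    abort("placements reference contigs absent from the catalog.")
  }
  lens <- setNames(cat_tbl$length, cat_tbl$contig_id)
  if (any(placements$start < 0) ||
      any(placements$start >= lens[placements$contig_id])) {
    abort("placement start positions fall outside their contig.")
  }
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", cat_tbl$contig_id, as.integer(cat_tbl$length))
  )
  pl <- placements
  if (!"read_id" %in% names(pl)) {
    pl$read_id <- paste0("read", seq_len(nrow(pl)))
  }
  flag <- c(first = 65L, second = 129L, unpaired = 0L)[pl$mate_group]
  pl <- pl |>
    mutate(
      flag = flag,
      rname_order = match(.data$contig_id, cat_tbl$contig_id),
      pos = as.integer(.data$start + 1)
    ) |>
    arrange(.data$rname_order, .data$pos)
  records <- sprintf(
    "%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
    pl$read_id, pl$flag, pl$contig_id, pl$pos,
    as.integer(pl$read_length),
    strrep("A", pl$read_length), strrep("I", pl$read_length)
  )
  writeLines(c(header, records), path)
  invisible(path)
}

#' Materialise a full synthetic scenario on disk
#'
#' Writes the genome FASTA files, the sorted SAM alignment, and a
#' truth-label TSV for a simulation spec — everything needed to exercise
#' the complete pipeline end to end.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory.
#' @param genomes Also write the FASTA files (default `TRUE`; the SAM and
#'   truth table alone are enough for metric tests).
#' @return A list with `catalog`, `placements`, and the `sam`, `truth`,
#'   and `genome_dir` paths.
#' @export
simulate_scenario <- function(spec, dir, genomes = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome_dir <- file.path(dir, "genomes")
  catalog <- if (genomes) {
    make_genomes(spec, genome_dir)
  } else {
    spec_catalog(spec)
  }
  placements <- sample_placements(spec, catalog)
  sam <- file.path(dir, "alignment.sam")
  write_alignment(placements, catalog, sam)
  truth_path <- file.path(dir, "truth.tsv")
  write_truth(
    tibble(
      genome_id = spec$genomes$genome_id,
      present = spec$genomes$truth_present
    ),
    truth_path
  )
  list(
    catalog = catalog, placements = placements, sam = sam,
    truth = truth_path, genome_dir = if (genomes) genome_dir else NULL
  )
}
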