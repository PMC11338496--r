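#' Read mapped placements from a coordinate-sorted SAM/BAM file
#'
#' Streams every mapped alignment record out of a sorted SAM or BAM file and
#' returns its placement: contig, 0-based leftmost start, read length, and
#' mate group. This is deliberately permissive — mapping quality, CIGAR
#' operations, and multimapping status are not filtered on, because the
#' evenness metrics downstream are defined on raw mapping positions.
#'
#' Mate groups come from the SAM pair flags: first-in-pair records form the
#' `first` group, second-in-pair the `second` group, unpaired reads the
#' `unpaired` group. The two mate groups of paired data are later treated as
#' independent point processes so that insert-size correlation between mates
#' does not distort the gap statistics.
#'
#' @param path A coordinate-sorted SAM or BAM file. SAM input is converted
#'   in a temporary directory via [Rsamtools::asBam()].
#' @param catalog A `genome_catalog`; records on contigs absent from it are
#'   skipped with a warning (or are fatal under `strict = TRUE`).
#' @param strict If `TRUE`, a record on a contig missing from the catalog
#'   is an error instead of a warning.
#' @param primary_only If `TRUE`, secondary and supplementary alignments are
#'   dropped. The default keeps them, consistent with ignoring multimapper
#'   status.
#' @param default_read_length Read length to assume when a record carries
#'   neither a sequence nor a query width the parser can derive; a
#'   defensive fallback, since htslib reconstructs the query width from the
#'   alignment for sequence-less records.
#' @return A tibble with one row per mapped record: `contig_id`, `start`
#'   (0-based), `read_length`, `mate_group` (`"first"`, `"second"` or
#'   `"unpaired"`).
#' @export
read_placements <- function(path, catalog, strict = FALSE,
                            primary_only = FALSE,
                            default_read_length = 150) {
  if (!file.exists(path)) {
    abort(paste0("alignment file does not exist: ", path))
  }
  bam <- as_bam_path(path)
  header <- Rsamtools::scanBamHeader(bam)[[1]]
  check_coordinate_sorted(header, path)

  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  if (primary_only) {
    flags <- Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE
    )
  }
  param <- Rsamtools::ScanBamParam(
    flag = flags, what = c("rname", "pos", "qwidth", "flag")
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]

  pl <- tibble(
    contig_id = as.character(rec$rname),
    start = as.numeric(rec$pos) - 1,
    read_length = as.numeric(rec$qwidth),
    mate_group = mate_group_from_flag(rec$flag)
  )
  pl$read_length[is.na(pl$read_length)] <- default_read_length

  unknown <- setdiff(unique(pl$contig_id), catalog$contig_id)
  if (length(unknown) > 0) {
    msg <- paste0(
      length(unknown), " contig(s) in the alignment are absent from the ",
      "catalog (e.g. ", paste(head(unknown, 3), collapse = ", "), ")"
    )
    if (strict) abort(paste0(msg, "; strict mode is on."))
    warn(paste0(msg, "; their records are skipped."))
    pl <- filter(pl, !.data$contig_id %in% unknown)
  }
  pl
}

as_bam_path <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    return(path)
  }
  dest <- tempfile(fileext = ".bam")
  Rsamtools::asBam(path, sub("\\.bam$", "", dest), indexDestination = FALSE)
}

check_coordinate_sorted <- function(header, path) {
  hd <- header$text[["@HD"]]
  so <- if (is.null(hd)) character() else grep("^SO:", hd, value = TRUE)
  if (length(so) == 0 || so[1] != "SO:coordinate") {
    abort(paste0(
      "alignment file is not declared coordinate-sorted (@HD SO tag): ", path
    ))
  }
  invisible(TRUE)
}

mate_group_from_flag <- function(flag) {
  paired <- bitwAnd(flag, 1L) != 0L
  second <- bitwAnd(flag, 128L) != 0L
  dplyr::case_when(
    !paired ~ "unpaired",
    second ~ "second",
    .default = "first"
  )
}

#' Annotate placements with genome membership and concatenated coordinates
#'
#' Joins placements to the catalog, adding the owning genome and the
#' position of each read start in its genome's contig concatenation
#' (`concat_pos = contig offset + start`). All gap statistics are computed
#' on these concatenated coordinates.
#'
#' @param placements A placement tibble from [read_placements()] or
#'   [sample_placements()].
#' @param catalog A `genome_catalog`.
#' @return The placements with `genome_id`, `genome_length`, and
#'   `concat_pos` columns, sorted by genome and concatenated position.
#' @export
annotate_placements <- function(placements, catalog) {
  placements |>
    select(dplyr::any_of(
      c("contig_id", "start", "read_length", "mate_group", "read_id")
    )) |>
    left_join(
      select(as_tibble(catalog), "contig_id", "genome_id", "offset",
             "genome_length"),
      by = "contig_id"
    ) |>
    mutate(concat_pos = .data$offset + .data$start) |>
    arrange(.data$genome_id, .data$concat_pos)
}

#' Collect placements per genome
#'
#' Groups annotated placements by genome, carrying the total mapped read
#' count, the mean read length, and a nested tibble of the genome's
#' placements (sorted concatenated positions split by mate group downstream).
#' Genomes of the catalog with no mapped reads appear with `n_reads = 0` and
#' an empty nest, so downstream callers can report them as absent.
#'
#' @inheritParams annotate_placements
#' @return A tibble with one row per catalog genome: `genome_id`,
#'   `genome_length`, `n_reads`, `mean_read_length` (`NA` when no reads),
#'   and `placements` (list column of per-genome placement tibbles).
#' @export
collect_genome_placements <- function(placements, catalog) {
  ann <- annotate_placements(placements, catalog)
  nested <- ann |>
    tidyr::nest(placements = !c("genome_id", "genome_length")) |>
    mutate(
      n_reads = map_int(.data$placements, nrow),
      mean_read_length = map_dbl(
        .data$placements, ~ mean(.x$read_length)
      )
    )
  genome_lengths(catalog) |>
    select("genome_id", "genome_length") |>
    left_join(nested, by = c("genome_id", "genome_length")) |>
    mutate(
      n_reads = if_else(is.na(.data$n_reads), 0L, .data$n_reads),
      placements = map(.data$placements, ~ .x %||% empty_placements())
    ) |>
    select("genome_id", "genome_length", "n_reads", "mean_read_length",
           "placements")
}

empty_placements <- function() {
  tibble(
    contig_id = character(), start = numeric(), read_length = numeric(),
    mate_group = character(), offset = numeric(), concat_pos = numeric()
  )
}
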