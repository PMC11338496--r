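#' Load a genome catalog
#'
#' A genome catalog records which contig belongs to which genome, the contig
#' lengths, and the offset of each contig within an arbitrary concatenation
#' of its genome's contigs. All per-genome statistics (coverage, breadth,
#' gap distances) are computed in these concatenated coordinates, so the
#' catalog is the coordinate system every other function works in.
#'
#' Two input layouts are accepted:
#'
#' * a **directory of FASTA files**, one file per genome: the genome id is
#'   the file name without extension, the contigs are the FASTA records in
#'   file order;
#' * a **two-column TSV** mapping `contig_id` to `genome_id` (no header,
#'   line order preserved), in which case contig lengths must be supplied
#'   separately via `lengths` — either a named numeric vector or a
#'   `.fai`-style file whose first two columns are contig name and length.
#'
#' @param path Directory of FASTA files, or a contig-to-genome map TSV.
#' @param lengths Contig lengths when `path` is a map TSV: a named numeric
#'   vector, or the path to a tab-separated file whose first two columns
#'   are contig id and length (a `samtools faidx` index works as is).
#' @return A tibble with class `genome_catalog` and one row per contig:
#'   `contig_id`, `genome_id`, `length`, `offset` (0-based start of the
#'   contig in its genome's concatenation), `genome_length`. Contig ids are
#'   unique across the whole catalog.
#' @examples
#' dir <- tempfile("genomes")
#' dir.create(dir)
#' Biostrings::writeXStringSet(
#'   Biostrings::DNAStringSet(c(c1 = "ACGTACGT", c2 = "ACGT")),
#'   file.path(dir, "gA.fasta")
#' )
#' load_genome_catalog(dir)
#' @export
load_genome_catalog <- function(path, lengths = NULL) {
  if (length(path) != 1 || !is.character(path)) {
    abort("`path` must be a single directory or file path.")
  }
  if (dir.exists(path)) {
    catalog <- catalog_from_fasta_dir(path)
  } else if (file.exists(path)) {
    catalog <- catalog_from_map(path, lengths)
  } else {
    abort(paste0("genome catalog path does not exist: ", path))
  }
  validate_catalog(catalog)
}

catalog_from_fasta_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fna|fasta)$", full.names = TRUE)
  if (length(files) == 0) {
    abort(paste0("no FASTA files (*.fa, *.fna, *.fasta) found in ", dir))
  }
  rows <- map(files, function(f) {
    seqs <- Biostrings::readDNAStringSet(f)
    if (length(seqs) == 0) {
      abort(paste0("empty genome FASTA: ", f))
    }
    tibble(
      contig_id = sub("\\s.*$", "", names(seqs)),
      genome_id = sub("\\.(fa|fna|fasta)$", "", basename(f)),
      length = as.numeric(Biostrings::width(seqs))
    )
  })
  list_rbind(rows)
}

catalog_from_map <- function(map_path, lengths) {
  if (is.null(lengths)) {
    abort("a contig map TSV needs `lengths` (named vector or .fai-style file).")
  }
  map_tbl <- readr::read_tsv(
    map_path,
    col_names = c("contig_id", "genome_id"),
    col_types = "cc", progress = FALSE
  )
  if (is.character(lengths)) {
    fai <- readr::read_tsv(
      lengths,
      col_names = FALSE, col_types = readr::cols(.default = "c"),
      progress = FALSE
    )
    lengths <- setNames(as.numeric(fai[[2]]), fai[[1]])
  }
  missing <- setdiff(map_tbl$contig_id, names(lengths))
  if (length(missing) > 0) {
    abort(paste0(
      "contigs in the map have no length entry: ",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  mutate(map_tbl, length = as.numeric(lengths[.data$contig_id]))
}

validate_catalog <- function(catalog) {
  if (anyDuplicated(catalog$contig_id)) {
    dup <- catalog$contig_id[duplicated(catalog$contig_id)]
    abort(paste0(
      "duplicate contig ids across the catalog: ",
      paste(unique(head(dup, 5)), collapse = ", ")
    ))
  }
  if (any(catalog$length < 1)) {
    abort("all contig lengths must be >= 1.")
  }
  catalog <- catalog |>
    group_by(.data$genome_id) |>
    mutate(
      offset = cumsum(.data$length) - .data$length,
      genome_length = sum(.data$length)
    ) |>
    ungroup()
  structure(catalog, class = c("genome_catalog", class(catalog)))
}

#' Per-genome lengths of a catalog
#'
#' @param catalog A `genome_catalog` from [load_genome_catalog()].
#' @return A tibble with one row per genome: `genome_id`, `genome_length`,
#'   `n_contigs`.
#' @export
genome_lengths <- function(catalog) {
  catalog |>
    group_by(.data$genome_id) |>
    summarise(
      genome_length = first(.data$genome_length),
      n_contigs = n(),
      .groups = "drop"
    )
}

#' Build a catalog from in-memory contig records
#'
#' Convenience constructor used by the simulator and in tests; takes the
#' contig table directly instead of reading files.
#'
#' @param contigs A data frame with columns `contig_id`, `genome_id`,
#'   `length`.
#' @return A `genome_catalog` tibble (see [load_genome_catalog()]).
#' @export
genome_catalog <- function(contigs) {
  need <- c("contig_id", "genome_id", "length")
  if (!all(need %in% names(contigs))) {
    abort("`contigs` needs columns contig_id, genome_id, length.")
  }
  validate_catalog(as_tibble(contigs)[need])
}
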