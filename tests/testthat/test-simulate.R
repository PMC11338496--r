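two_genome_spec <- function(seed, pattern = c("uniform", "uniform"),
                            coverage = c(0.5, 0.2), paired = TRUE) {
  simulation_spec(
    tibble::tibble(
      genome_id = c("gA", "gB"), contigs = list(c(2e4, 3e4), 4e4),
      pattern = pattern, coverage = coverage,
      covered_fraction = c(0.1, 0.1)
    ),
    paired = paired, seed = seed
  )
}

test_that("identical spec and seed reproduce byte-identical output", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_scenario(two_genome_spec(31), d1)
  s2 <- simulate_scenario(two_genome_spec(31), d2)
  expect_identical(readLines(s1$sam), readLines(s2$sam))
  expect_identical(
    readLines(file.path(d1, "genomes", "gA.fasta")),
    readLines(file.path(d2, "genomes", "gA.fasta"))
  )
  # a different seed moves the reads but keeps the geometry
  s3 <- simulate_scenario(two_genome_spec(32), withr::local_tempdir())
  expect_false(identical(readLines(s1$sam), readLines(s3$sam)))
  expect_equal(
    as.data.frame(s1$catalog)[c("contig_id", "length")],
    as.data.frame(s3$catalog)[c("contig_id", "length")]
  )
})

test_that("genome sequences have the requested lengths and order", {
  dir <- withr::local_tempdir()
  catalog <- make_genomes(two_genome_spec(8), dir)
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "gA.fasta"))
  expect_equal(names(seqs), c("gA_c1", "gA_c2"))
  expect_equal(Biostrings::width(seqs), c(2e4, 3e4))
  # catalog read back from the written files matches the implied one
  expect_equal(
    as.data.frame(load_genome_catalog(dir)),
    as.data.frame(catalog)
  )
})

test_that("read counts follow round(C * Gl / Rl), pairs balanced", {
  # single-end: C = 1, Gl = 1500, Rl = 150 -> exactly 10 reads
  spec <- simulation_spec(
    tibble::tibble(genome_id = "g", contigs = list(1500),
                   pattern = "uniform", coverage = 1),
    paired = FALSE, seed = 4
  )
  pl <- sample_placements(spec)
  expect_equal(nrow(pl), 10)
  expect_equal(unique(pl$mate_group), "unpaired")
  # paired: equal first/second group sizes
  spec_pe <- two_genome_spec(21)
  pl_pe <- sample_placements(spec_pe)
  counts <- table(pl_pe$genome_id, pl_pe$mate_group)
  expect_equal(counts[, "first"], counts[, "second"])
  # a coverage too low for a single read warns and yields none
  spec0 <- simulation_spec(
    tibble::tibble(genome_id = "g", contigs = list(1000),
                   pattern = "uniform", coverage = 1e-4),
    paired = FALSE, seed = 4
  )
  expect_warning(pl0 <- sample_placements(spec0), "0 reads")
  expect_equal(nrow(pl0), 0)
})

test_that("region-restricted placements stay within a bounded footprint", {
  spec <- simulation_spec(
    tibble::tibble(
      genome_id = "g", contigs = list(1e5), pattern = "region_restricted",
      coverage = 2, covered_fraction = 0.1, n_regions = 2
    ),
    paired = FALSE, seed = 17
  )
  catalog <- spec_catalog(spec)
  pl <- sample_placements(spec, catalog)
  ev <- genome_evenness(pl, catalog)
  # everything lands inside ~10% of the genome (+ read-length spill)
  expect_lte(ev$breadth, 0.1 + 2 * 150 / 1e5)
  expect_gt(ev$coverage, 1.8)
})

test_that("empirical coverage matches the request for dense placements", {
  # C * Gl / Rl >= 1000 reads
  spec <- simulation_spec(
    tibble::tibble(genome_id = "g", contigs = list(2e5),
                   pattern = "uniform", coverage = 1),
    paired = FALSE, seed = 6
  )
  catalog <- spec_catalog(spec)
  ev <- genome_evenness(sample_placements(spec, catalog), catalog)
  expect_lt(abs(ev$coverage - 1) / 1, 0.05)
})

test_that("bimodal placements show two depth modes and depressed metrics", {
  gl <- 1e5
  base <- tibble::tibble(
    genome_id = "g", contigs = list(gl), pattern = "bimodal",
    coverage = 1, spike_coverage = 19, spike_fraction = 0.05,
    n_regions = 1
  )
  spec_bi <- simulation_spec(base, paired = FALSE, seed = 12)
  catalog <- spec_catalog(spec_bi)
  pl_bi <- sample_placements(spec_bi, catalog)
  total_reads <- nrow(pl_bi)
  # uniform counterpart with the same total read budget
  spec_u <- simulation_spec(
    tibble::tibble(genome_id = "g", contigs = list(gl),
                   pattern = "uniform",
                   coverage = total_reads * 150 / gl),
    paired = FALSE, seed = 12
  )
  pl_u <- sample_placements(spec_u, catalog)
  expect_equal(nrow(pl_u), total_reads, tolerance = 0.01)

  depth_bi <- genome_depths(pl_bi, catalog, "g")
  # the spike region is far deeper than the base layer: bulk of positions
  # near depth ~1, a heavy secondary mass at high depth
  expect_gt(mean(depth_bi >= 10), 0.03)
  expect_gt(mean(depth_bi <= 3), 0.8)
  ev_bi <- genome_evenness(pl_bi, catalog)
  ev_u <- genome_evenness(pl_u, catalog)
  gm_bi <- genome_gap_metrics(pl_bi, catalog)
  gm_u <- genome_gap_metrics(pl_u, catalog)
  expect_lt(ev_bi$ber, ev_u$ber)
  expect_lt(gm_bi$fug_mean, gm_u$fug_mean)
})

test_that("subsampling is binomial per fragment and keeps mates together", {
  spec <- simulation_spec(
    tibble::tibble(genome_id = "g", contigs = list(3e6),
                   pattern = "uniform", coverage = 1),
    paired = TRUE, seed = 3
  )
  pl <- sample_placements(spec)
  n_pairs <- length(unique(pl$read_id))
  expect_identical(subsample_placements(pl, 1, seed = 1), pl)
  expect_equal(nrow(subsample_placements(pl, 0, seed = 1)), 0)
  kept <- subsample_placements(pl, 0.5, seed = 2)
  # mates kept or dropped together
  expect_true(all(table(kept$read_id) == 2))
  # kept fragment count within 3 binomial SDs of the expectation
  sd3 <- 3 * sqrt(n_pairs * 0.5 * 0.5)
  expect_lt(abs(length(unique(kept$read_id)) - 0.5 * n_pairs), sd3)
  expect_error(subsample_placements(pl, 1.2), "fraction")
})

test_that("scenario directories carry alignment, genomes, and truth", {
  dir <- withr::local_tempdir()
  spec <- two_genome_spec(44, pattern = c("uniform", "region_restricted"))
  sc <- simulate_scenario(spec, dir)
  expect_true(file.exists(sc$sam))
  expect_true(file.exists(sc$truth))
  expect_setequal(
    list.files(sc$genome_dir), c("gA.fasta", "gB.fasta")
  )
  truth <- read_truth(sc$truth)
  expect_equal(truth$present[truth$genome_id == "gA"], TRUE)
  expect_equal(truth$present[truth$genome_id == "gB"], FALSE)
  # off-contig placements are rejected by the SAM writer
  expect_error(
    write_alignment(
      toy_placements("gA_c1", 2.5e4), sc$catalog,
      file.path(dir, "bad.sam")
    ),
    "outside"
  )
})
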