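metric_row <- function(n_reads, coverage, ber, fug_mean = NA_real_,
                       fug_first = NA_real_, fug_second = NA_real_,
                       genome_id = "g") {
  tibble::tibble(
    genome_id = genome_id, genome_length = 1e6, n_reads = n_reads,
    coverage = coverage, ber = ber, fug_first = fug_first,
    fug_second = fug_second, fug_unpaired = NA_real_, fug_mean = fug_mean
  )
}

test_that("the decision rule follows the published protocol", {
  cfg <- classifier_config()
  # below the 80-read detection limit, metrics are irrelevant
  r <- call_presence(metric_row(79, 0.05, 0.99, fug_mean = 0.63), cfg)
  expect_false(r$present)
  expect_equal(r$reason, "below_detection_limit")
  expect_equal(call_presence(metric_row(0, 0, NA), cfg)$reason, "no_reads")
  # above the coverage switch, BER decides alone
  r <- call_presence(metric_row(10000, 0.5, 0.9, fug_mean = 0.1), cfg)
  expect_true(r$present)
  expect_equal(r$reason, "present_ber_only")
  # below the switch, both metrics are required
  r <- call_presence(metric_row(200, 0.05, 0.9, fug_mean = 0.3), cfg)
  expect_false(r$present)
  expect_equal(r$reason, "low_fug")
  r <- call_presence(metric_row(200, 0.05, 0.9, fug_mean = 0.63), cfg)
  expect_true(r$present)
  expect_equal(r$reason, "present_ber_fug")
  r <- call_presence(metric_row(200, 0.05, 0.5, fug_mean = 0.63), cfg)
  expect_equal(r$reason, "low_ber")
  # low coverage with no defined FUG group: the required evidence is missing
  r <- call_presence(metric_row(200, 0.05, 0.9), cfg)
  expect_false(r$present)
  expect_equal(r$reason, "low_fug")
})

test_that("fug aggregation modes differ on split groups", {
  m <- metric_row(200, 0.05, 0.9, fug_mean = 0.55,
                  fug_first = 0.7, fug_second = 0.4)
  expect_true(call_presence(m, classifier_config())$present)
  expect_false(
    call_presence(m, classifier_config(fug_aggregation = "all"))$present
  )
})

test_that("presets reproduce the published operating points", {
  expect_equal(classifier_config(preset = "cami")$coverage_switch, 1)
  expect_equal(classifier_config(preset = "optimal")$ber_threshold, 0.77)
  expect_equal(classifier_config()$min_reads, 80)
  expect_error(classifier_config(preset = "nope"), "preset")
  # the cami preset consults FUG for a coverage-0.5 genome
  m <- metric_row(10000, 0.5, 0.9, fug_mean = 0.1)
  expect_true(call_presence(m, classifier_config())$present)
  expect_false(
    call_presence(m, classifier_config(preset = "cami"))$present
  )
})

test_that("raising thresholds never converts absent to present", {
  withr::with_seed(202, {
    base <- classifier_config()
    for (rep in 1:50) {
      m <- metric_row(
        n_reads = sample(c(0, 50, 100, 5000), 1),
        coverage = runif(1, 0, 0.5),
        ber = runif(1, 0, 1.3),
        fug_mean = runif(1, -0.2, 1)
      )
      tighter <- classifier_config(
        ber_threshold = min(base$ber_threshold + runif(1, 0, 0.19), 1),
        fug_threshold = min(base$fug_threshold + runif(1, 0, 0.49), 1)
      )
      was <- call_presence(m, base)$present
      now <- call_presence(m, tighter)$present
      expect_false(!was && now)
    }
  })
})

test_that("rcn matches its definition and scaling laws", {
  expect_equal(rcn(10, 1e6, 1e7), 10 * 1e9 / (1e6 * 1e7))
  expect_equal(rcn(0, 1e6, 1e7), 0)
  expect_equal(rcn(10, 1e6, 2e7), rcn(10, 1e6, 1e7) / 2) # doubling Rtot halves it
  expect_equal(rcn(20, 1e6, 2e7), rcn(10, 1e6, 1e7)) # joint doubling
  expect_error(rcn(10, 1e6, 0), "total read")
  expect_error(rcn(10, 0, 1e7), "genome length")
})

test_that("reports round-trip and list present genomes separately", {
  spec <- simulation_spec(
    tibble::tibble(
      genome_id = c("gB", "gA"), contigs = list(5e4, 5e4),
      pattern = c("uniform", "region_restricted"), coverage = c(0.5, 0.3)
    ),
    seed = 9
  )
  scr <- screen_presence(sample_placements(spec), spec_catalog(spec))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(tidy(scr), path)
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(tbl$genome, sort(tbl$genome)) # lexicographic order
  back <- read_report(path)
  expect_equal(back$genome_id, c("gA", "gB"))
  expect_equal(back$present, c(FALSE, TRUE))
  expect_equal(back$ber, signif(tidy(scr)$ber, 6))
  # second write of the parsed calls is byte-identical (stable serialization)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_report(back, path2)
  expect_identical(readLines(path2), readLines(path))
  present_only <- readr::read_tsv(
    paste0(sub("\\.tsv$", "", path), ".present.tsv"),
    show_col_types = FALSE
  )
  expect_equal(present_only$genome, "gB")
})

test_that("an empty call set writes a header-only report", {
  path <- withr::local_tempfile(fileext = ".tsv")
  empty <- call_presence(metric_row(1, 0.1, 0.5)[0, ], classifier_config())
  write_report(dplyr::mutate(empty, rcn = numeric(0)), path)
  lines <- readLines(path)
  expect_length(lines, 1)
  expect_match(lines, "^genome\t")
})

test_that("zero-read genomes appear in the report with NA metrics", {
  catalog <- toy_catalog(c(gA = 1000))
  scr <- screen_presence(toy_placements(character(), numeric()), catalog,
                         total_reads = 100)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(tidy(scr), path)
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(tbl$present, 0)
  expect_true(is.na(tbl$ber))
  expect_equal(tbl$reason, "no_reads")
})
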