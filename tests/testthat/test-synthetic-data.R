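two_species_spec <- function(...) {
  fx <- fixture_library("two_species")
  defaults <- list(codebook = fx$codebook,
                   params = ligation_params(1, 0, 4, 2),
                   molecules_per_region = 1500L, read_error = 0,
                   species_of_region = fx$species_of_region, seed = 7L)
  args <- utils::modifyList(defaults, list(...))
  do.call(experiment_spec, args)
}

test_that("equal specs generate byte-identical experiments", {
  a <- generate_experiment(two_species_spec(molecules_per_region = 300L))
  b <- generate_experiment(two_species_spec(molecules_per_region = 300L))
  expect_identical(a$r1, b$r1)
  expect_identical(a$r2, b$r2)
  expect_identical(a$truth, b$truth)
  expect_identical(a$traces, b$traces)
  # with d = 1, c = 0 Read 1 is deterministic, but the tag draw is seeded
  c <- generate_experiment(two_species_spec(molecules_per_region = 300L, seed = 8L))
  expect_false(identical(a$r2, c$r2))
})

test_that("perfect barcoding demultiplexes every read to its region", {
  exp <- generate_experiment(two_species_spec())
  res <- demux_reads(exp$r1, exp$r2, codebook = exp$codebook)
  expect_true(all(res$reason == "assigned"))
  expect_equal(res$region, exp$truth$region)
})

test_that("shared-tag fraction shows up as foreign composition near h", {
  exp <- generate_experiment(two_species_spec(molecules_per_region = 4000L))
  res <- demux_reads(exp$r1, exp$r2, codebook = exp$codebook)
  res$species <- classify_species(res$tag, exp$pools)
  tab <- tabulate_demux(res, truth = exp$truth)
  h <- exp$spec$h
  sd3 <- 3 * sqrt(h * (1 - h) / 4000)
  expect_lt(abs(tab$composition["top", "B"] - h), sd3 + 0.005)
  expect_lt(abs(tab$composition["bottom", "A"] - h), sd3 + 0.005)
  # truth bookkeeping agrees: homolog tags are exactly the foreign ones
  expect_equal(mean(exp$truth$tag_origin == "homolog"),
               unname((tab$composition["top", "B"] + tab$composition["bottom", "A"]) / 2),
               tolerance = 1e-12)
})

test_that("species pools share exactly the configured fraction", {
  pools <- make_species_pools(pool_size = 500, tag_bp = 60, h = 0.047, seed = 3)
  expect_equal(pools$n_shared, round(0.047 * 500))
  expect_equal(sum(classify_species(pools$pool_A, pools) == "B"), pools$n_shared)
  expect_equal(sum(classify_species(pools$pool_B, pools) == "A"), pools$n_shared)
  expect_true(all(nchar(pools$pool_A) == 60))
  none <- make_species_pools(100, 40, 0, seed = 3)
  expect_equal(none$n_shared, 0)
  expect_true(all(classify_species(none$pool_A, none) == "A"))
})

test_that("simulated traces reflect the molecule length distribution", {
  spec <- two_species_spec(params = ligation_params(0.845, 0.025, 4, 2),
                           molecules_per_region = 5000L)
  exp <- generate_experiment(spec)
  fit <- fit_multi_gaussian(exp$traces$top, R = 2)
  got <- fractions_from_fit(fit)
  pmf <- length_distribution(spec$params)
  # compare 1- and 2-letter species among lengths >= 1 (the fit ignores the
  # barcode-free peak at base_bp)
  visible <- pmf[c("1", "2", "3")] / sum(pmf[as.character(1:8)])
  expect_lt(abs(got[[2]] - visible[["2"]]), 0.03)
  expect_lt(abs(got[[1]] - visible[["1"]]), 0.03)
})

test_that("sequencing errors degrade demultiplexing gracefully", {
  exp <- generate_experiment(two_species_spec(read_error = 0.01,
                                              molecules_per_region = 1000L))
  res <- demux_reads(exp$r1, exp$r2, codebook = exp$codebook)
  tab <- tabulate_demux(res, truth = exp$truth)
  # 1% per-base errors: most reads survive the 2-mismatch letter tolerance
  expect_gt(tab$assigned_fraction, 0.9)
  expect_lt(tab$assigned_fraction, 1)
  # but assigned reads stay correct (exact policy detects, never misassigns
  # to the distance-2 codeword)
  expect_equal(tab$misassignment_rate, 0)
})

test_that("experiments round-trip through files with provenance", {
  dir <- withr::local_tempdir()
  exp <- generate_experiment(two_species_spec(molecules_per_region = 200L),
                             dir = dir)
  expect_setequal(
    list.files(dir),
    c("R1.fastq.gz", "R2.fastq.gz", "truth.tsv", "trace_top.csv",
      "trace_bottom.csv", "provenance.json"))
  r1 <- read_fastq(file.path(dir, "R1.fastq.gz"))
  expect_identical(unname(r1), unname(exp$r1))
  expect_identical(names(r1), names(exp$r1))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$seed, 7L)
  expect_equal(prov$h, 0.047)
  expect_equal(prov$codewords$top, "L1L3")
  res <- demux_reads(file.path(dir, "R1.fastq.gz"),
                     file.path(dir, "R2.fastq.gz"), codebook = exp$codebook)
  expect_true(all(res$reason == "assigned"))
})

test_that("fixtures are deterministic and match their documented designs", {
  fx <- fixture_library("four_region_2x2")
  expect_equal(names(fx$codebook$assignment), c("I", "II", "III", "IV"))
  expect_equal(fx$codebook$assignment$III, c(2L, 1L))
  expect_identical(fixture_library("four_region_2x2"), fx)
  tr <- fixture_library("trace_2x2")
  expect_equal(sum(tr$fractions), 1)
  expect_equal(tr$observed, c("2" = 0.692, "3" = 0.035))
  sc <- fixture_library("single_cell_4x3")
  expect_equal(length(sc$codebook$assignment), 64L)
  expect_equal(sc$codebook$m, 4L)
  ts <- fixture_library("two_species")
  expect_equal(min_hamming_distance(ts$codebook), 2L)
})

test_that("experiment specs are validated", {
  fx <- fixture_library("two_species")
  expect_error(experiment_spec(fx$codebook, ligation_params(1, 0, 2, 2)),
               "match the codebook")
  expect_error(two_species_spec(h = 1.5), "probability")
  expect_error(two_species_spec(read1_bp = 30L), "too short")
  expect_error(
    two_species_spec(species_of_region = c(top = "A", bottom = "C")),
    "two pools")
})
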