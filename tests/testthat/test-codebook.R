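test_that("build_codebook enumerates all m^n codewords in lexicographic order", {
  cb <- build_codebook(2, 2)
  expect_equal(format_codeword(cb$codewords), c("L1L1", "L1L2", "L2L1", "L2L2"))
  expect_equal(nrow(build_codebook(4, 5)$codewords), 1024L)
  cb1 <- build_codebook(1, 3)
  expect_equal(format_codeword(cb1$codewords), "L1L1L1")
  for (m in 1:5) for (n in 1:6) {
    expect_equal(nrow(build_codebook(m, n, letters = letter_alphabet(m))$codewords),
                 m^n)
  }
  expect_error(build_codebook(0, 2), "positive integer")
  expect_error(build_codebook(2, -1), "positive integer")
})

test_that("repeat-code expansion duplicates digits in place", {
  expect_equal(expand_repeat_code(c(1, 2), 2), c(1L, 1L, 2L, 2L))
  expect_equal(expand_repeat_code(c(1, 2), 1), c(1L, 2L))
  expect_equal(expand_repeat_code(3, 3), c(3L, 3L, 3L))
  cb <- assign_regions(build_codebook(2, 2), c("a", "b", "c", "d"))
  ex <- expand_repeat_codebook(cb, 2)
  expect_equal(ex$n, 4L)
  expect_equal(ex$assignment$b, c(1L, 1L, 2L, 2L))
  expect_equal(attr(ex, "repeat_r"), 2L)
})

test_that("efficiency arithmetic matches enumeration and round-trips", {
  expect_equal(effective_letter_efficiency(0.9, 2), 0.99)
  expect_equal(effective_letter_efficiency(0.7, 1), 0.7)
  expect_equal(effective_letter_efficiency(0.5, 3), 0.875)
  # brute force over {success, fail}^r
  for (r in 1:4) for (p in c(0.2, 0.5, 0.9)) {
    outcomes <- expand.grid(rep(list(0:1), r))
    prob <- apply(outcomes, 1L, function(x) prod(ifelse(x == 1, p, 1 - p)))
    expect_equal(effective_letter_efficiency(p, r),
                 sum(prob[rowSums(outcomes) >= 1]), tolerance = 1e-12)
  }
  expect_equal(full_length_fraction(0.9, 5), 0.9^5)
  expect_equal(full_length_fraction(1, 7), 1)
  expect_equal(full_length_fraction(0.9, 10), 0.3487, tolerance = 1e-4)
  expect_equal(per_round_efficiency_from_fraction(1, 4), 1)
  expect_equal(per_round_efficiency_from_fraction(0.811, 4), 0.949, tolerance = 5e-4)
  expect_equal(per_round_efficiency_from_fraction(0.6209, 5), 0.909, tolerance = 5e-4)
  set.seed(42)
  for (i in 1:20) {
    p <- runif(1); n <- sample(1:10, 1)
    expect_equal(per_round_efficiency_from_fraction(full_length_fraction(p, n), n),
                 p, tolerance = 1e-12)
  }
  expect_error(effective_letter_efficiency(1.2, 2), "probability")
  expect_error(full_length_fraction(-0.1, 2), "probability")
})

test_that("splint pool covers all ordered pairs with exact junction complementarity", {
  letters <- letter_alphabet(4)
  pool <- generate_splint_pool(letters)
  expect_equal(nrow(pool), 16L)
  expect_setequal(pool$name,
                  paste0("splint", rep(1:4, each = 4), rep(1:4, 4)))
  expect_true(all(nchar(pool$sequence) == 15L))
  for (i in seq_len(nrow(pool))) {
    inc <- letters$sequence[pool$incoming_id[i]]
    pri <- letters$sequence[pool$prior_id[i]]
    junction <- paste0(substr(inc, nchar(inc) - 4, nchar(inc)),
                       substr(pri, 1, 10))
    expect_equal(pool$sequence[i], revcomp_chr(junction))
  }
  one <- generate_splint_pool(letter_alphabet(1))
  expect_equal(one$name, "splint11")
  # incoming L1 onto prior L2 is splint12
  expect_equal(pool$name[pool$incoming_id == 1 & pool$prior_id == 2], "splint12")
  short <- letter_alphabet(2)
  short$sequence <- substr(short$sequence, 1, 14)
  expect_error(generate_splint_pool(short), "15")
})

test_that("minimum Hamming distance reflects error-detection capability", {
  expect_equal(min_hamming_distance(build_codebook(3, 3)), 1L)
  expect_equal(min_hamming_distance(list(c(1, 3), c(2, 4))), 2L)
  # repeat expansion of distinct codewords at least doubles distance (brute force)
  cb <- build_codebook(2, 2)
  expanded <- t(apply(cb$codewords, 1, rep, each = 2))
  pairs <- combn(nrow(expanded), 2)
  brute <- min(apply(pairs, 2, function(ij) {
    sum(expanded[ij[1], ] != expanded[ij[2], ])
  }))
  expect_equal(min_hamming_distance(expand_repeat_codebook(cb, 2)$codewords), brute)
  expect_gte(brute, 2L)
  expect_error(min_hamming_distance(list(c(1, 2))), "at least 2")
})

test_that("codeword serialization round-trips in all three dialects", {
  expect_equal(format_codeword(c(1, 2, 4)), "L1L2L4")
  expect_equal(parse_codeword("L1L2L4"), c(1L, 2L, 4L))
  expect_equal(parse_codeword("124"), c(1L, 2L, 4L))
  expect_equal(parse_codeword("10.1.4"), c(10L, 1L, 4L))
  expect_equal(compact_codeword(c(1, 2, 4)), "124")
  expect_equal(compact_codeword(c(10, 1)), "10.1")
  expect_error(parse_codeword("L0"), "parse")
})

test_that("codebooks round-trip through YAML and reject bad assignments", {
  cb <- assign_regions(build_codebook(2, 2), c("I", "II", "III", "IV"))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_codebook(cb, path)
  back <- read_codebook(path)
  expect_equal(back$assignment, cb$assignment)
  expect_equal(back$letters$sequence, cb$letters$sequence)
  expect_error(assign_regions(build_codebook(2, 2), list(a = "L1L1", b = "L1L1")),
               "injective")
  expect_error(assign_regions(build_codebook(2, 2), list(a = "L1L3")), "1..m")
  expect_error(assign_regions(build_codebook(2, 2), list(a = "L1L1L1")), "length")
})

test_that("letter validation flags design-guideline violations as warnings only", {
  low_gc <- c("ATATATATATATATATATAT", "TACGCGCGCGCGCGCGCGAT")
  expect_warning(letter_alphabet(2, sequences = low_gc), "GC content")
  gc_end <- c("CACGCGCGCGCGCGCGCGAG", "TGCATGCATGCATGCATGCA")
  expect_warning(letter_alphabet(2, sequences = gc_end), "terminus")
  expect_error(letter_alphabet(2, sequences = c("ACGTN" , "ACGTA")), "15")
  expect_error(
    letter_alphabet(2, sequences = c("TACGCGCGCGCGCGCGCGAT", "TACGCGCGCGCGCGCGCGAT")),
    "distinct")
})
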