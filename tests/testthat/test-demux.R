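test_that("a clean read decodes to its codeword and region (worked fixture)", {
  fx <- fixture_library("two_species")
  cb <- fx$codebook
  layout <- read_layout(test_handle, n = 2)
  # region "bottom" is L2L4; Read 1 carries the letters in reverse ligation
  # order: L4's sequence first, then L2's
  read <- make_read1(test_handle, cb$letters, cb$assignment$bottom)
  expect_equal(substr(read, nchar(test_handle) + 1,
                      nchar(test_handle) + 20),
               cb$letters$sequence[4])
  parsed <- parse_barcode(read, layout, cb$letters)
  expect_equal(parsed$reason, "ok")
  expect_equal(parsed$digits[1, ], c(2L, 4L))
  asg <- assign_region(parsed$digits[1, ], cb, policy = "exact")
  expect_equal(asg$region, "bottom")
  expect_equal(asg$reason, "assigned")
})

test_that("every single-substitution variant of a letter still decodes", {
  fx <- fixture_library("two_species")
  cb <- fx$codebook
  layout <- read_layout(test_handle, n = 2)
  base_read <- make_read1(test_handle, cb$letters, cb$assignment$bottom)
  # mutate each position of the first letter window (L4's sequence)
  offset <- nchar(test_handle)
  variants <- character(0)
  for (pos in 1:20) {
    for (b in setdiff(c("A", "C", "G", "T"),
                      substr(base_read, offset + pos, offset + pos))) {
      v <- base_read
      substr(v, offset + pos, offset + pos) <- b
      variants <- c(variants, v)
    }
  }
  parsed <- parse_barcode(variants, layout, cb$letters, max_mm_per_letter = 2)
  expect_true(all(parsed$reason == "ok"))
  expect_true(all(parsed$digits[, 1] == 2L & parsed$digits[, 2] == 4L))
})

test_that("unusable reads are rejected with the right reason", {
  fx <- fixture_library("two_species")
  cb <- fx$codebook
  layout <- read_layout(test_handle, n = 2)
  allA <- strrep("A", 150)
  parsed <- parse_barcode(allA, layout, cb$letters)
  expect_equal(parsed$reason, "no-handle")
  short <- substr(make_read1(test_handle, cb$letters, c(2, 4)), 1, 40)
  expect_equal(parse_barcode(short, layout, cb$letters)$reason, "length-anomaly")
  # scramble one letter window beyond tolerance
  bad <- make_read1(test_handle, cb$letters, c(2, 4))
  substr(bad, nchar(test_handle) + 1, nchar(test_handle) + 20) <- strrep("A", 20)
  expect_equal(parse_barcode(bad, layout, cb$letters)$reason, "letter-mismatch")
})

test_that("alphabet separation is validated before decoding", {
  close_letters <- letter_alphabet(2, sequences = c(
    "TAGCAGCATGCATGCATGCT",
    "TAGCAGCATGCATGCAAGCT"  # Hamming distance 1
  ))
  layout <- read_layout(test_handle, n = 1)
  expect_error(
    parse_barcode(strrep("A", 60), layout, close_letters, max_mm_per_letter = 2),
    "separation")
})

test_that("exact policy detects errors; nearest-unique never breaks ties", {
  fx <- fixture_library("two_species")
  cb <- fx$codebook  # {top = L1L3, bottom = L2L4}, min distance 2
  # L2L3 is Hamming-1 from both codewords: brute-force check, then policies
  d23 <- c(2L, 3L)
  dists <- vapply(cb$assignment, function(cw) sum(cw != d23), 0L)
  expect_equal(unname(dists), c(1L, 1L))
  expect_equal(assign_region(d23, cb, policy = "exact")$reason, "no-match")
  nu <- assign_region(d23, cb, policy = "nearest-unique")
  expect_equal(nu$reason, "ambiguous")
  # a codeword at distance 1 from exactly one entry is accepted
  expect_equal(assign_region(c(1L, 4L), cb, policy = "nearest-unique")$reason,
               "ambiguous")  # L1L4 is distance 1 from both L1L3 and L2L4
  one <- assign_regions(build_codebook(4, 2), list(only = "L1L3"))
  expect_equal(assign_region(c(1L, 4L), one, policy = "nearest-unique")$region,
               "only")
})

test_that("repeat-collapse decodes a digit from any surviving repeat", {
  base <- assign_regions(build_codebook(2, 2), list(a = "L1L2", b = "L2L1"))
  # enumerate every single-repeat corruption (NA) of the expanded codeword
  expanded <- expand_repeat_code(base$assignment$a, 2)  # 1 1 2 2
  for (pos in 1:4) {
    corrupted <- expanded
    corrupted[pos] <- NA_integer_
    res <- assign_region(corrupted, base, policy = "repeat-collapse", r = 2)
    expect_equal(res$region, "a")
  }
  # conflicting surviving repeats are ambiguous
  conflict <- c(1L, 2L, 2L, 2L)
  expect_equal(assign_region(conflict, base, policy = "repeat-collapse",
                             r = 2)$reason, "ambiguous")
  # a fully lost digit cannot match
  lost <- c(NA_integer_, NA_integer_, 2L, 2L)
  expect_equal(assign_region(lost, base, policy = "repeat-collapse",
                             r = 2)$reason, "no-match")
})

test_that("error-free reads are always assigned to their generating region", {
  set.seed(13)
  for (i in 1:10) {
    m <- sample(2:4, 1); n <- sample(2:3, 1)
    cb <- build_codebook(m, n)
    k <- sample(2:min(6, m^n), 1)
    rows <- sample(nrow(cb$codewords), k)
    cb <- assign_regions(cb, setNames(
      lapply(rows, function(r) unname(cb$codewords[r, ])),
      paste0("reg", seq_len(k))))
    layout <- read_layout(test_handle, n = n)
    truth <- sample(names(cb$assignment), 50, replace = TRUE)
    reads <- vapply(truth, function(rg) {
      make_read1(test_handle, cb$letters, cb$assignment[[rg]])
    }, "")
    res <- demux_reads(reads, codebook = cb, layout = layout)
    expect_equal(res$region, unname(truth))
    expect_true(all(res$reason == "assigned"))
  }
})

test_that("raising the per-letter mismatch tolerance never loses reads", {
  fx <- fixture_library("two_species")
  cb <- fx$codebook
  layout <- read_layout(test_handle, n = 2)
  set.seed(23)
  clean <- vapply(rep(c("top", "bottom"), 50), function(rg) {
    make_read1(test_handle, cb$letters, cb$assignment[[rg]])
  }, "")
  # sprinkle 0-4 substitutions per read
  noisy <- vapply(clean, function(rd) {
    nmut <- sample(0:4, 1)
    for (p in sample(nchar(rd), nmut)) {
      substr(rd, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    rd
  }, "", USE.NAMES = FALSE)
  counts <- vapply(0:4, function(mm) {
    parsed <- parse_barcode(noisy, layout, cb$letters, max_mm_per_letter = mm)
    sum(!is.na(assign_region(parsed$digits, cb, policy = "exact")$region))
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("tabulation is consistent and safe on empty input", {
  res <- data.frame(read_id = c("r1", "r2", "r3"),
                    region = c("a", "a", NA),
                    reason = c("assigned", "assigned", "no-handle"),
                    species = c("A", "A", NA))
  truth <- data.frame(region = c("a", "b", "a"), species = c("A", "A", "A"))
  tab <- tabulate_demux(res, truth)
  expect_equal(tab$per_region$reads, 2L)
  expect_equal(tab$rejects$reads, 1L)
  expect_equal(tab$misassignment_rate, 0.5)
  expect_equal(sum(tab$per_region$reads) + sum(tab$rejects$reads), nrow(res))
  none <- data.frame(read_id = "r", region = NA_character_, reason = "no-handle")
  tab0 <- tabulate_demux(none)
  expect_equal(nrow(tab0$per_region), 0L)
  expect_equal(tab0$assigned_fraction, 0)
})
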