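# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: brute-force enumeration and hand-rolled string
# ops only.

# Barcode-length pmf by exhaustive enumeration of all 2^(n_L * R) reaction
# outcome vectors. One reaction per letter per round; the reaction matching
# the target digit succeeds with prob d, every other with prob c.
pmf_bruteforce <- function(d, c, n_L, R, target = rep(1L, R)) {
  cols <- n_L * R
  col_letter <- rep(seq_len(n_L), times = R)
  col_round <- rep(seq_len(R), each = n_L)
  p <- ifelse(col_letter == target[col_round], d, c)
  outcomes <- as.matrix(expand.grid(rep(list(0:1), cols)))
  probs <- apply(outcomes, 1L, function(x) prod(ifelse(x == 1, p, 1 - p)))
  lens <- rowSums(outcomes)
  vapply(0:cols, function(N) sum(probs[lens == N]), 0)
}

# reverse complement without Biostrings
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

hamming_str <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# assemble a Read 1 string the way the sequencer sees it: handle, then the
# ligated letters in REVERSE ligation order, T-padded
make_read1 <- function(handle, letters, digits, pad_to = 150L) {
  body <- paste(rev(letters$sequence[digits]), collapse = "")
  substr(paste0(handle, body, strrep("T", pad_to)), 1L, pad_to)
}

test_handle <- "CAGACGTGTGCTCTTCCGATCT"
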