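# Combinatorial codebooks: m letters over n rounds encode m^n regions.

#' Enumerate a combinatorial codebook
#'
#' With an alphabet of `m` letters and `n` ligation rounds, every region can
#' be assigned one of the `m^n` codewords (ordered digit strings of letter
#' ids, digit 1 = earliest ligation round). Codewords are enumerated in
#' lexicographic digit order (`L1L1, L1L2, ..., L2L1, ...`), so output is
#' deterministic.
#'
#' @param m Alphabet size, `m >= 1`.
#' @param n Number of ligation rounds, `n >= 1`.
#' @param letters Optional `letter_alphabet` of exactly `m` letters; a
#'   deterministic synthetic alphabet is generated when omitted.
#' @return A `codebook` object: a list with `m`, `n`, `letters`, `codewords`
#'   (an `m^n` by `n` integer matrix of letter ids, one codeword per row) and
#'   an (initially empty) `assignment` of region ids to codewords.
#' @examples
#' cb <- build_codebook(2, 2)
#' format_codeword(cb$codewords)  # "L1L1" "L1L2" "L2L1" "L2L2"
#' @export
build_codebook <- function(m, n, letters = NULL) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m) ||
      !is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`m` and `n` must be positive integers")
  }
  m <- as.integer(m); n <- as.integer(n)
  if (is.null(letters)) letters <- letter_alphabet(m)
  if (nrow(letters) != m) stop("`letters` must contain exactly m = ", m, " letters")
  # lexicographic: first digit varies slowest
  grid <- do.call(expand.grid, rev(replicate(n, seq_len(m), simplify = FALSE)))
  codewords <- as.matrix(grid[, rev(seq_len(n)), drop = FALSE])
  dimnames(codewords) <- list(NULL, paste0("round", seq_len(n)))
  storage.mode(codewords) <- "integer"
  structure(
    list(m = m, n = n, letters = letters, codewords = codewords,
         assignment = list()),
    class = "codebook"
  )
}

#' @export
print.codebook <- function(x, ...) {
  cat("Codebook: m =", x$m, "letters, n =", x$n, "rounds,",
      nrow(x$codewords), "codewords,", length(x$assignment),
      "regions assigned\n")
  if (length(x$assignment)) {
    shown <- head(names(x$assignment), 8L)
    for (r in shown) {
      cat("  ", r, " -> ", format_codeword(x$assignment[[r]]), "\n", sep = "")
    }
    if (length(x$assignment) > 8L) cat("  ...\n")
  }
  invisible(x)
}

#' Assign regions to codewords
#'
#' @param codebook A `codebook`.
#' @param regions Character vector of region ids, or a named list/character
#'   vector mapping region id to a codeword (an integer digit vector or a
#'   string accepted by [parse_codeword()]). When `regions` is a bare
#'   character vector of ids, codewords are taken from the codebook in
#'   enumeration order.
#' @return The codebook with its `assignment` filled in. Distinct regions may
#'   not share a codeword (the mapping must be injective).
#' @examples
#' cb <- assign_regions(build_codebook(2, 2), c("I", "II", "III", "IV"))
#' format_codeword(cb$assignment$II)  # "L1L2"
#' @export
assign_regions <- function(codebook, regions) {
  stopifnot(inherits(codebook, "codebook"))
  if (is.null(names(regions))) {
    ids <- as.character(regions)
    if (length(ids) > nrow(codebook$codewords)) {
      stop("more regions than codewords (", nrow(codebook$codewords), ")")
    }
    cw <- lapply(seq_along(ids), function(i) unname(codebook$codewords[i, ]))
    names(cw) <- ids
  } else {
    cw <- lapply(regions, function(x) {
      if (is.character(x)) parse_codeword(x) else unname(as.integer(x))
    })
  }
  if (anyDuplicated(names(cw))) stop("region ids must be unique")
  for (r in names(cw)) {
    d <- cw[[r]]
    if (length(d) != codebook$n) {
      stop("codeword for region '", r, "' has length ", length(d),
           ", expected n = ", codebook$n)
    }
    if (any(d < 1L | d > codebook$m)) {
      stop("codeword for region '", r, "' uses letter ids outside 1..m")
    }
  }
  keys <- vapply(cw, paste, "", collapse = ".")
  if (anyDuplicated(keys)) stop("assignment must be injective: regions ",
                                paste(names(cw)[duplicated(keys) | duplicated(keys, fromLast = TRUE)],
                                      collapse = ", "),
                                " share a codeword")
  codebook$assignment <- cw
  codebook
}

#' Format and parse codewords
#'
#' `format_codeword()` renders digit vectors in the `"L1L2L4"` dialect;
#' `compact_codeword()` renders the digits-only form used in files (`"124"`,
#' or dot-separated like `"10.1.4"` when the alphabet has more than 9
#' letters). `parse_codeword()` accepts all three forms.
#'
#' @param digits An integer vector of letter ids, or a matrix (one codeword
#'   per row).
#' @return A character vector (one element per codeword), or for
#'   `parse_codeword()` an integer digit vector.
#' @examples
#' format_codeword(c(1, 2, 4))   # "L1L2L4"
#' parse_codeword("L1L2L4")      # 1 2 4
#' parse_codeword("124")         # 1 2 4
#' @export
format_codeword <- function(digits) {
  if (is.matrix(digits)) {
    return(apply(digits, 1L, function(d) paste0("L", d, collapse = "")))
  }
  paste0("L", digits, collapse = "")
}

#' @rdname format_codeword
#' @export
compact_codeword <- function(digits) {
  fmt <- function(d) {
    if (any(d > 9L)) paste(d, collapse = ".") else paste(d, collapse = "")
  }
  if (is.matrix(digits)) return(apply(digits, 1L, fmt))
  fmt(as.integer(digits))
}

#' @rdname format_codeword
#' @param x A codeword string in `"L1L2L4"`, `"124"`, or `"1.2.4"` form.
#' @export
parse_codeword <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl("^L", x)) {
    d <- as.integer(strsplit(sub("^L", "", x), "L", fixed = TRUE)[[1]])
  } else if (grepl(".", x, fixed = TRUE)) {
    d <- as.integer(strsplit(x, ".", fixed = TRUE)[[1]])
  } else {
    d <- as.integer(strsplit(x, "")[[1]])
  }
  if (anyNA(d) || any(d < 1L)) stop("cannot parse codeword '", x, "'")
  d
}

#' Expand a codeword or codebook into a repeat code
#'
#' In an r-repeat code each digit is ligated `r` times in succession, so a
#' codeword of length `n` becomes one of length `n * r`. The decoding rule is
#' fixed: a digit is recovered if at least one of its `r` repeats survives;
#' repeated digits raise the effective per-letter efficiency from `p` to
#' `1 - (1 - p)^r` (see [effective_letter_efficiency()]).
#'
#' @param codeword An integer digit vector.
#' @param r Number of repeats per digit, `r >= 1`.
#' @return For `expand_repeat_code()`, the expanded digit vector. For
#'   `expand_repeat_codebook()`, a new codebook with `n * r` rounds, expanded
#'   codewords and assignment, and attribute `repeat_r = r`.
#' @examples
#' expand_repeat_code(c(1, 2), 2)  # 1 1 2 2
#' @export
expand_repeat_code <- function(codeword, r) {
  if (!is.numeric(r) || length(r) != 1L || r < 1 || r != round(r)) {
    stop("`r` must be a positive integer")
  }
  rep(as.integer(codeword), each = as.integer(r))
}

#' @rdname expand_repeat_code
#' @param codebook A `codebook`.
#' @export
expand_repeat_codebook <- function(codebook, r) {
  stopifnot(inherits(codebook, "codebook"))
  cw <- t(apply(codebook$codewords, 1L, expand_repeat_code, r = r))
  dimnames(cw) <- list(NULL, paste0("round", seq_len(ncol(cw))))
  out <- codebook
  out$n <- codebook$n * as.integer(r)
  out$codewords <- cw
  out$assignment <- lapply(codebook$assignment, expand_repeat_code, r = r)
  attr(out, "repeat_r") <- as.integer(r)
  out
}

#' Barcoding efficiency arithmetic
#'
#' `full_length_fraction(p, n)` is the fraction `p^n` of molecules expected
#' to carry a complete n-letter barcode when each ligation round succeeds
#' independently with probability `p`;
#' `per_round_efficiency_from_fraction(f, n)` inverts it (`f^(1/n)`), which
#' is how per-round efficiency is estimated from an observed full-length
#' fraction. `effective_letter_efficiency(p, r)` is the probability
#' `1 - (1 - p)^r` that at least one of `r` repeats of a digit is ligated.
#'
#' @param p Per-round (or per-repeat) success probability in `[0, 1]`.
#' @param n Number of rounds, `n >= 1`.
#' @param f Observed full-length fraction in `[0, 1]`.
#' @param r Number of repeats, `r >= 1`.
#' @return A probability.
#' @examples
#' full_length_fraction(0.9, 5)            # ~0.59: why ~5 rounds is practical
#' per_round_efficiency_from_fraction(0.811, 4)
#' effective_letter_efficiency(0.9, 2)     # 0.99
#' @export
full_length_fraction <- function(p, n) {
  check_prob(p, "p"); check_posint(n, "n")
  p^n
}

#' @rdname full_length_fraction
#' @export
per_round_efficiency_from_fraction <- function(f, n) {
  check_prob(f, "f"); check_posint(n, "n")
  f^(1 / n)
}

#' @rdname full_length_fraction
#' @export
effective_letter_efficiency <- function(p, r) {
  check_prob(p, "p"); check_posint(r, "r")
  1 - (1 - p)^r
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop("`", name, "` must be a probability in [0, 1]")
  }
  invisible(x)
}

check_posint <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    stop("`", name, "` must be a positive integer")
  }
  invisible(x)
}

#' Minimum pairwise Hamming distance of a codeword set
#'
#' The error-detection capability of a codebook: any fewer than
#' `min_hamming_distance` letter errors is guaranteed detectable, and a
#' distance of `2e + 1` permits correction of `e` errors. For a complete
#' `m^n` codebook the distance is 1; repeat-code expansion of distinct
#' codewords at least doubles it.
#'
#' @param x A `codebook` (its assigned codewords are used when an assignment
#'   exists, otherwise all enumerated codewords), an integer matrix with one
#'   codeword per row, or a list of digit vectors.
#' @return The minimum pairwise Hamming distance (integer).
#' @export
min_hamming_distance <- function(x) {
  if (inherits(x, "codebook")) {
    x <- if (length(x$assignment)) do.call(rbind, x$assignment) else x$codewords
  }
  if (is.list(x)) x <- do.call(rbind, lapply(x, as.integer))
  if (!is.matrix(x) || nrow(x) < 2L) stop("need at least 2 codewords")
  best <- ncol(x)
  for (i in seq_len(nrow(x) - 1L)) {
    d <- rowSums(x[(i + 1L):nrow(x), , drop = FALSE] !=
                   matrix(x[i, ], nrow(x) - i, ncol(x), byrow = TRUE))
    best <- min(best, d)
    if (best == 0L) stop("codewords are not pairwise distinct")
    if (best == 1L) break
  }
  as.integer(best)
}

#' Read and write codebook files
#'
#' Codebooks round-trip through a small YAML document: alphabet size, round
#' count, letter sequences, and the region assignment in compact digit form.
#'
#' @param codebook A `codebook`.
#' @param path File path (YAML).
#' @return `write_codebook()` returns `path` invisibly; `read_codebook()`
#'   returns a `codebook`.
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "codebook"))
  doc <- list(
    m = codebook$m,
    n = codebook$n,
    letters = lapply(seq_len(nrow(codebook$letters)), function(i) {
      l <- codebook$letters[i, ]
      out <- list(id = l$id, sequence = l$sequence)
      if (!is.na(l$detect_tag)) out$detect_tag <- l$detect_tag
      out
    }),
    assignment = lapply(codebook$assignment, compact_codeword)
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  doc <- yaml::read_yaml(path)
  letters <- letter_alphabet(
    m = doc$m,
    sequences = vapply(doc$letters, `[[`, "", "sequence"),
    detect_tag = vapply(doc$letters, function(l) {
      if (is.null(l$detect_tag)) NA_character_ else l$detect_tag
    }, "")
  )
  cb <- build_codebook(doc$m, doc$n, letters = letters)
  if (length(doc$assignment)) {
    cb <- assign_regions(cb, lapply(doc$assignment, as.character))
  }
  cb
}
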