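# Letter alphabets and splint pools.
#
# A "letter" is a short oligonucleotide (20 nt by default) ligated onto the
# growing barcode; a splint is the 15-nt oligo that templates the ligation of
# one letter onto another by hybridizing across the junction.

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Reverse complement of DNA character strings
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

hamming_chr <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Construct a letter alphabet
#'
#' Builds the alphabet data frame used throughout the package. If `sequences`
#' is omitted, a deterministic synthetic alphabet is generated: sequences of
#' length `letter_bp` with A/T termini, at least 40% GC content, and large
#' pairwise Hamming separation so that error-tolerant demultiplexing is safe.
#' Letter ids are 1-based (`L1`, `L2`, ...) and id order is the order letters
#' are offered within a ligation round.
#'
#' @param m Alphabet size (number of distinct letters), `m >= 1`.
#' @param sequences Optional character vector of `m` nucleotide sequences
#'   (A/C/G/T), all the same length (>= 15 nt).
#' @param letter_bp Letter length in nucleotides for synthetic alphabets
#'   (default 20).
#' @param detect_tag Optional character vector of FISH-readable subsequences,
#'   recycled to length `m`; stored but not used by the sequence machinery.
#' @param seed Integer seed for synthetic sequence generation; the default
#'   gives a fixed, reproducible alphabet for each `m`.
#' @return A data frame of class `letter_alphabet` with columns `id`
#'   (integer), `sequence`, and `detect_tag`.
#' @examples
#' letters4 <- letter_alphabet(4)
#' nchar(letters4$sequence)
#' @export
letter_alphabet <- function(m, sequences = NULL, letter_bp = 20L,
                            detect_tag = NA_character_, seed = 71L) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop("`m` must be a positive integer")
  }
  m <- as.integer(m)
  if (is.null(sequences)) {
    sequences <- with_seed(seed + m, synth_letter_sequences(m, letter_bp))
  }
  out <- data.frame(
    id = seq_len(m),
    sequence = toupper(as.character(sequences)),
    detect_tag = rep_len(detect_tag, m),
    stringsAsFactors = FALSE
  )
  class(out) <- c("letter_alphabet", "data.frame")
  validate_letters(out)
  out
}

# rejection-sample sequences with A/T ends, >= 40% GC, pairwise Hamming >= 8
synth_letter_sequences <- function(m, letter_bp) {
  if (letter_bp < 15) stop("letter_bp must be >= 15")
  seqs <- character(0)
  while (length(seqs) < m) {
    mid <- sample(c("A", "C", "G", "T"), letter_bp - 2L, replace = TRUE)
    cand <- paste0(
      sample(c("A", "T"), 1L),
      paste(mid, collapse = ""),
      sample(c("A", "T"), 1L)
    )
    gc <- sum(strsplit(cand, "")[[1]] %in% c("G", "C")) / letter_bp
    if (gc < 0.4) next
    if (length(seqs) && any(vapply(seqs, hamming_chr, 0L, cand) < 8L)) next
    seqs <- c(seqs, cand)
  }
  seqs
}

#' Validate a letter alphabet
#'
#' Structural invariants (uniform length >= 15 nt, A/C/G/T only, pairwise
#' distinct sequences) are errors. The wet-lab design guidelines — at least
#' 40% GC content and no G or C at the sequence termini, which favour
#' efficient ligation — are reported as warnings only, so arbitrary test
#' alphabets remain usable.
#'
#' @param letters A `letter_alphabet` data frame.
#' @param min_separation If not `NULL`, additionally require this minimum
#'   pairwise Hamming distance between letters (used by the demultiplexer).
#' @return `letters`, invisibly.
#' @export
validate_letters <- function(letters, min_separation = NULL) {
  seqs <- letters$sequence
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) stop("letter sequences must all have the same length")
  if (widths[1] < 15L) stop("letter sequences must be at least 15 nt")
  if (anyDuplicated(seqs)) stop("letter sequences must be pairwise distinct")
  if (any(grepl("[^ACGT]", seqs))) stop("letter sequences may contain only A, C, G, T")
  gc <- vapply(strsplit(seqs, ""), function(s) mean(s %in% c("G", "C")), 0)
  if (any(gc < 0.4)) {
    warning("letter(s) ", paste(letters$id[gc < 0.4], collapse = ", "),
            " have < 40% GC content")
  }
  ends <- substr(seqs, 1L, 1L) %in% c("G", "C") |
    substr(seqs, widths, widths) %in% c("G", "C")
  if (any(ends)) {
    warning("letter(s) ", paste(letters$id[ends], collapse = ", "),
            " have G or C at a terminus")
  }
  if (!is.null(min_separation) && nrow(letters) > 1L) {
    pairs <- combn(seq_along(seqs), 2L)
    d <- apply(pairs, 2L, function(ij) hamming_chr(seqs[ij[1]], seqs[ij[2]]))
    if (min(d) < min_separation) {
      stop("letter alphabet violates minimum pairwise Hamming separation of ",
           min_separation, " (observed ", min(d), ")")
    }
  }
  invisible(letters)
}

#' Generate the splint pool for an alphabet
#'
#' One splint per ordered (incoming, prior) letter pair, `m^2` in total, so
#' that any letter can be ligated onto any previously added letter. Each
#' splint is the 15-nt reverse complement of the junction it templates: the 5
#' bases at the 3' end of the incoming letter followed by the 10 bases at the
#' 5' end of the prior letter. Names follow the `splint{incoming}{prior}`
#' convention, e.g. ligating L1 onto a barcode ending in L2 uses `splint12`.
#'
#' @param letters A `letter_alphabet` data frame (sequences >= 15 nt).
#' @return A data frame with columns `name`, `incoming_id`, `prior_id`,
#'   `sequence`.
#' @examples
#' sp <- generate_splint_pool(letter_alphabet(4))
#' nrow(sp)  # 16
#' @export
generate_splint_pool <- function(letters) {
  seqs <- letters$sequence
  w <- nchar(seqs[1])
  if (w < 15L) stop("letters too short for splint design (need >= 15 nt)")
  grid <- expand.grid(prior_id = letters$id, incoming_id = letters$id)
  # order: incoming-major to match splint11, splint12, ... splint{m}{m}
  grid <- grid[order(grid$incoming_id, grid$prior_id), , drop = FALSE]
  junction <- paste0(
    substr(seqs[grid$incoming_id], w - 4L, w),  # 3'-terminal 5-mer, incoming
    substr(seqs[grid$prior_id], 1L, 10L)        # 5'-terminal 10-mer, prior
  )
  data.frame(
    name = paste0("splint", grid$incoming_id, grid$prior_id),
    incoming_id = grid$incoming_id,
    prior_id = grid$prior_id,
    sequence = revcomp(junction),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Export letters or splints as FASTA
#'
#' Writes one record per row; record ids are `L{id}` for letter alphabets and
#' the splint `name` for splint pools.
#'
#' @param x A `letter_alphabet` or splint-pool data frame.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
export_fasta <- function(x, path) {
  ids <- if (!is.null(x$name)) x$name else paste0("L", x$id)
  set <- Biostrings::DNAStringSet(setNames(x$sequence, ids))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
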