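# Demultiplexing: decode the concatenated barcode letters in Read 1 and
# assign each read to its spatial region.
#
# Read-order convention (the single most error-prone point of the format):
# the barcode grows at the cDNA 5' end and every new letter is ligated 5' of
# the previous one, so after the 5' handle Read 1 presents the letters in
# REVERSE ligation order — the last-ligated letter comes first. Decoded
# codewords are reported in ligation-round order.

#' Describe the structure of Read 1
#'
#' @param handle Fixed 5' handle sequence (sequencing/PCR tag) preceding the
#'   barcode slot; must be non-empty.
#' @param n Number of letters in the barcode slot (for an r-repeat code this
#'   is `n_base * r`).
#' @param letter_bp Letter width in nt (default 20).
#' @param anchor Optional fixed sequence expected 3' of the barcode slot
#'   (e.g. a poly-T stub); informational only.
#' @return A `read_layout` list.
#' @export
read_layout <- function(handle, n, letter_bp = 20L, anchor = NULL) {
  if (!nzchar(handle)) stop("`handle` must be non-empty")
  check_posint(n, "n"); check_posint(letter_bp, "letter_bp")
  structure(list(handle = toupper(handle), n = as.integer(n),
                 letter_bp = as.integer(letter_bp), anchor = anchor),
            class = "read_layout")
}

# character matrix (reads x positions) from fixed-width substrings
char_matrix <- function(x, from, width) {
  seg <- substr(x, from, from + width - 1L)
  matrix(unlist(strsplit(seg, ""), use.names = FALSE), nrow = length(x),
         ncol = width, byrow = TRUE)
}

#' Decode barcode letters from Read 1 sequences
#'
#' Locates the 5' handle (exact or at most one mismatch, at the read start),
#' then decodes each fixed-width letter window against the alphabet by
#' minimum Hamming distance. A letter is accepted iff its distance is at
#' most `max_mm_per_letter` and the best match is unique; otherwise that
#' digit is `NA`. The decoded codeword is returned in ligation-round order,
#' i.e. the windows are reversed (see the read-order convention above).
#'
#' The alphabet is validated on entry to be pairwise Hamming-separated by
#' more than `2 * max_mm_per_letter`, which guarantees decoding is
#' unambiguous for up to `max_mm_per_letter` substitutions per letter.
#'
#' @param read1 Character vector of Read 1 sequences.
#' @param layout A [read_layout()].
#' @param letters A `letter_alphabet`.
#' @param max_mm_per_letter Maximum substitutions tolerated per letter
#'   (default 2).
#' @return A list: `digits` (integer matrix, one row per read, `layout$n`
#'   columns, round order, `NA` for undecodable letters) and `reason`
#'   (character: `"ok"`, `"no-handle"`, `"length-anomaly"`,
#'   `"letter-mismatch"`, `"ambiguous"`).
#' @export
parse_barcode <- function(read1, layout, letters, max_mm_per_letter = 2L) {
  stopifnot(inherits(layout, "read_layout"))
  if (nchar(letters$sequence[1]) != layout$letter_bp) {
    stop("alphabet letter length does not match layout letter_bp")
  }
  validate_letters(letters, min_separation = 2L * max_mm_per_letter + 1L)
  read1 <- toupper(read1)
  nreads <- length(read1)
  hw <- nchar(layout$handle)
  need <- hw + layout$n * layout$letter_bp
  reason <- rep("ok", nreads)
  digits <- matrix(NA_integer_, nreads, layout$n)
  too_short <- nchar(read1) < need
  reason[too_short] <- "length-anomaly"

  ok <- !too_short
  if (any(ok)) {
    hmat <- char_matrix(read1[ok], 1L, hw)
    hmm <- rowSums(hmat != matrix(strsplit(layout$handle, "")[[1]],
                                  sum(ok), hw, byrow = TRUE))
    no_handle <- hmm > 1L
    reason[ok][no_handle] <- "no-handle"
    ok[ok] <- !no_handle
  }
  if (any(ok)) {
    idx <- which(ok)
    lchars <- strsplit(letters$sequence, "")
    mismatch_fail <- rep(FALSE, length(idx))
    ambiguous <- rep(FALSE, length(idx))
    for (slot in seq_len(layout$n)) {
      from <- hw + (slot - 1L) * layout$letter_bp + 1L
      wmat <- char_matrix(read1[idx], from, layout$letter_bp)
      dist <- vapply(lchars, function(lc) {
        rowSums(wmat != matrix(lc, length(idx), layout$letter_bp, byrow = TRUE))
      }, numeric(length(idx)))
      dist <- matrix(dist, nrow = length(idx))
      dmin <- dist[cbind(seq_len(length(idx)), max.col(-dist, ties.method = "first"))]
      best <- max.col(-dist, ties.method = "first")
      tie <- rowSums(dist == dmin) > 1L
      pass <- dmin <= max_mm_per_letter & !tie
      # slot `slot` counts from the handle = reverse ligation order
      round_pos <- layout$n - slot + 1L
      digits[idx[pass], round_pos] <- best[pass]
      ambiguous <- ambiguous | (tie & dmin <= max_mm_per_letter)
      mismatch_fail <- mismatch_fail | (!pass & !tie)
    }
    reason[idx[ambiguous]] <- "ambiguous"
    reason[idx[!ambiguous & mismatch_fail]] <- "letter-mismatch"
  }
  list(digits = digits, reason = reason)
}

#' Assign a decoded codeword to a region
#'
#' Policies:
#' * `"exact"`: the decoded codeword (no missing digits) must equal an
#'   assigned codeword; anything else is rejected, which is what gives
#'   multi-letter-distinct codebooks their error-detection capability.
#' * `"nearest-unique"`: accept iff exactly one assigned codeword lies
#'   within Hamming distance 1 (missing digits count as mismatches); a tie
#'   is rejected as `"ambiguous"`.
#' * `"repeat-collapse"`: for an r-repeat code, collapse each run of `r`
#'   repeats to a single digit — recovered if at least one repeat decoded
#'   and all decoded repeats agree — then require an exact match in the
#'   base codebook.
#'
#' @param digits Integer digit vector (round order; `NA` = undecoded
#'   letter), or a matrix with one read per row.
#' @param codebook An assigned `codebook`. For `"repeat-collapse"` pass the
#'   BASE codebook (codeword length `n`) and the repeat count `r`.
#' @param policy Assignment policy (see above).
#' @param r Repeat count for `"repeat-collapse"` (default 1).
#' @return For a vector input, a list `region` (id or `NA`) and `reason`
#'   (`"assigned"`, `"no-match"`, `"ambiguous"`); for a matrix, vectors of
#'   the same.
#' @export
assign_region <- function(digits, codebook,
                          policy = c("exact", "nearest-unique", "repeat-collapse"),
                          r = 1L) {
  policy <- match.arg(policy)
  stopifnot(inherits(codebook, "codebook"))
  if (!length(codebook$assignment)) stop("codebook has no region assignment")
  single <- !is.matrix(digits)
  if (single) digits <- matrix(as.integer(digits), 1L)
  cw <- do.call(rbind, codebook$assignment)
  regions <- names(codebook$assignment)

  if (policy == "repeat-collapse") {
    check_posint(r, "r")
    if (ncol(digits) != codebook$n * r) {
      stop("digit width ", ncol(digits), " does not equal n * r = ", codebook$n * r)
    }
    collapsed <- matrix(NA_integer_, nrow(digits), codebook$n)
    bad <- rep(FALSE, nrow(digits))
    for (pos in seq_len(codebook$n)) {
      reps <- digits[, (pos - 1L) * r + seq_len(r), drop = FALSE]
      for (i in seq_len(nrow(digits))) {
        seen <- unique(reps[i, !is.na(reps[i, ])])
        if (length(seen) == 1L) collapsed[i, pos] <- seen
        else if (length(seen) > 1L) bad[i] <- TRUE
      }
    }
    res <- assign_region(collapsed, codebook, policy = "exact")
    res$reason[bad] <- "ambiguous"
    res$region[bad] <- NA_character_
    if (single) return(list(region = res$region[1], reason = res$reason[1]))
    return(res)
  }

  if (ncol(digits) != codebook$n) {
    stop("digit width ", ncol(digits), " does not equal codebook n = ", codebook$n)
  }
  region <- rep(NA_character_, nrow(digits))
  reason <- rep("no-match", nrow(digits))
  if (policy == "exact") {
    keys <- apply(digits, 1L, paste, collapse = ".")
    keys[apply(digits, 1L, anyNA)] <- NA_character_
    cwkeys <- apply(cw, 1L, paste, collapse = ".")
    hit <- match(keys, cwkeys)
    region[!is.na(hit)] <- regions[hit[!is.na(hit)]]
    reason[!is.na(hit)] <- "assigned"
  } else {  # nearest-unique
    for (i in seq_len(nrow(digits))) {
      d <- rowSums(cw != matrix(digits[i, ], nrow(cw), ncol(cw), byrow = TRUE) |
                     is.na(matrix(digits[i, ], nrow(cw), ncol(cw), byrow = TRUE)))
      within <- which(d <= 1L)
      if (length(within) == 1L) {
        region[i] <- regions[within]; reason[i] <- "assigned"
      } else if (length(within) > 1L) {
        reason[i] <- "ambiguous"
      }
    }
  }
  if (single) list(region = region[1], reason = reason[1])
  else list(region = region, reason = reason)
}

#' Demultiplex paired-end reads by their Read 1 barcodes
#'
#' Full pipeline: parse Read 1 barcodes ([parse_barcode()]), assign regions
#' ([assign_region()]), and return per-read calls. Inputs may be FASTQ paths
#' (gzip-transparent) or plain character vectors of sequences.
#'
#' @param r1 Read 1 sequences: character vector or FASTQ path.
#' @param r2 Optional Read 2 (transcript side): character vector or FASTQ
#'   path; carried through as `tag` for downstream species tabulation.
#' @param codebook An assigned `codebook`.
#' @param layout A [read_layout()]; defaults to a layout matching the
#'   codebook (`n` letters of the alphabet's width) with handle
#'   `"CAGACGTGTGCTCTTCCGATCT"`.
#' @param policy,r Passed to [assign_region()].
#' @param max_mm_per_letter Passed to [parse_barcode()].
#' @return A data frame with one row per read: `read_id`, `codeword`
#'   (formatted, `NA` unless fully decoded), `region`, `reason`
#'   (`"assigned"` or the rejection reason), and `tag` when `r2` is given.
#' @export
demux_reads <- function(r1, r2 = NULL, codebook, layout = NULL,
                        policy = "exact", r = 1L, max_mm_per_letter = 2L) {
  seqs1 <- if (length(r1) == 1L && file.exists(r1)) read_fastq(r1) else
    setNames(as.character(r1), paste0("read", seq_along(r1)))
  if (is.null(layout)) {
    layout <- read_layout(handle = "CAGACGTGTGCTCTTCCGATCT", n = codebook$n,
                          letter_bp = nchar(codebook$letters$sequence[1]))
  }
  parsed <- parse_barcode(unname(seqs1), layout, codebook$letters,
                          max_mm_per_letter = max_mm_per_letter)
  asg <- assign_region(parsed$digits, codebook, policy = policy, r = r)
  reason <- ifelse(parsed$reason != "ok", parsed$reason, asg$reason)
  region <- asg$region
  region[parsed$reason != "ok"] <- NA_character_
  full <- !apply(parsed$digits, 1L, anyNA)
  codeword <- rep(NA_character_, length(seqs1))
  if (any(full)) {
    codeword[full] <- apply(parsed$digits[full, , drop = FALSE], 1L,
                            function(d) paste0("L", d, collapse = ""))
  }
  out <- data.frame(read_id = names(seqs1), codeword = codeword,
                    region = region, reason = reason,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(r2)) {
    seqs2 <- if (length(r2) == 1L && file.exists(r2)) read_fastq(r2) else
      as.character(r2)
    if (length(seqs2) != nrow(out)) stop("Read 1 and Read 2 counts differ")
    out$tag <- unname(seqs2)
  }
  out
}

#' Tabulate demultiplexing results
#'
#' @param results Per-read data frame from [demux_reads()] (columns
#'   `region`, `reason`; optionally `species` added by the caller).
#' @param truth Optional ground-truth data frame aligned row-by-row with
#'   `results`, with columns `region` and optionally `species`.
#' @return A list: `per_region` (assigned read counts), `rejects` (counts
#'   by rejection reason), `assigned_fraction`; with truth, additionally
#'   `misassignment_rate` (fraction of assigned reads whose called region
#'   differs from the generating region) and, when `results$species` is
#'   present, `composition` (per called region, fraction of each called
#'   species). Empty inputs yield empty tables, never division by zero.
#' @export
tabulate_demux <- function(results, truth = NULL) {
  assigned <- !is.na(results$region)
  count_table <- function(x, name) {
    tab <- table(x)
    out <- data.frame(key = names(tab), reads = as.integer(tab),
                      stringsAsFactors = FALSE, row.names = NULL)
    names(out)[1] <- name
    out
  }
  per_region <- count_table(results$region[assigned], "region")
  rejects <- count_table(results$reason[!assigned], "reason")
  out <- list(
    per_region = per_region,
    rejects = rejects,
    assigned_fraction = if (nrow(results)) mean(assigned) else NA_real_
  )
  if (!is.null(truth)) {
    if (nrow(truth) != nrow(results)) stop("truth and results row counts differ")
    if (any(assigned)) {
      out$misassignment_rate <-
        mean(results$region[assigned] != truth$region[assigned])
    } else {
      out$misassignment_rate <- NA_real_
    }
  }
  if (!is.null(results$species) && any(assigned)) {
    tab <- table(region = results$region[assigned],
                 species = results$species[assigned])
    out$composition <- prop.table(tab, margin = 1L)
  }
  out
}
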