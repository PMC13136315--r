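# Illumination scheduling: turn a region->codeword assignment into the
# ordered list of patterned-light ligation steps. All regions that receive
# the same letter in the same round are illuminated simultaneously, which is
# what makes m^n barcodes reachable in at most m*n steps.

#' Define regions, optionally with mask geometry
#'
#' Regions are abstract ids; geometry (an axis-aligned rectangle or a circle
#' in pixel units) is only needed when rendering illumination masks.
#' Coordinates use image convention: origin at the top-left, x rightward,
#' y downward, pixel centers at integer coordinates starting at 1. For
#' rectangles `(x, y)` is the top-left pixel and `w`, `h` the extent in
#' pixels; for circles `(x, y)` is the center and `w` the diameter (`h` is
#' ignored).
#'
#' @param id Character vector of unique region ids.
#' @param shape `"rect"`, `"circle"`, or `NA` for geometry-free regions
#'   (recycled).
#' @param x,y,w,h Numeric geometry parameters (recycled); `NA` when absent.
#' @return A data frame of class `region_table`.
#' @export
region_table <- function(id, shape = NA_character_, x = NA_real_,
                         y = NA_real_, w = NA_real_, h = NA_real_) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("region ids must be unique")
  out <- data.frame(id = id, shape = rep_len(shape, length(id)),
                    x = rep_len(x, length(id)), y = rep_len(y, length(id)),
                    w = rep_len(w, length(id)), h = rep_len(h, length(id)),
                    stringsAsFactors = FALSE)
  bad <- !is.na(out$shape) &
    ((out$shape == "rect" & (out$w <= 0 | out$h <= 0)) |
       (out$shape == "circle" & out$w <= 0))
  if (any(bad)) stop("degenerate geometry (non-positive extent) for region(s): ",
                     paste(out$id[bad], collapse = ", "))
  class(out) <- c("region_table", "data.frame")
  out
}

#' Build the illumination/ligation schedule for an assigned codebook
#'
#' For each round `r` and each letter `l` (ascending letter id, so output is
#' deterministic), emits one step illuminating exactly the regions whose
#' codeword has digit `l` in position `r`. Letters unused in a round produce
#' no step, so the total is at most `m * n` steps, with equality for a
#' complete codebook.
#'
#' @param codebook A `codebook` with a non-empty region assignment.
#' @param regions Optional character vector restricting (and ordering) which
#'   assigned regions to schedule; defaults to all assigned regions.
#' @return An `illumination_schedule`: a data frame with columns
#'   `step_index`, `round`, `letter_id` and list-column `regions`, plus
#'   attributes `m` and `n`.
#' @examples
#' cb <- assign_regions(build_codebook(2, 2), c("I", "II", "III", "IV"))
#' sched <- build_schedule(cb)
#' sched$regions[[1]]  # regions lit together in round 1 under L1
#' @export
build_schedule <- function(codebook, regions = NULL) {
  stopifnot(inherits(codebook, "codebook"))
  if (!length(codebook$assignment)) stop("codebook has no region assignment")
  ids <- if (is.null(regions)) names(codebook$assignment) else as.character(regions)
  missing <- setdiff(ids, names(codebook$assignment))
  if (length(missing)) stop("unassigned region(s): ", paste(missing, collapse = ", "))
  digits <- do.call(rbind, codebook$assignment[ids])
  steps <- vector("list", codebook$n * codebook$m)
  k <- 0L
  for (r in seq_len(codebook$n)) {
    col <- digits[, r]
    for (l in seq_len(codebook$m)) {
      lit <- ids[col == l]
      if (!length(lit)) next
      k <- k + 1L
      steps[[k]] <- list(round = r, letter_id = l, regions = lit)
    }
  }
  steps <- steps[seq_len(k)]
  out <- data.frame(
    step_index = seq_len(k),
    round = vapply(steps, `[[`, 0L, "round"),
    letter_id = vapply(steps, `[[`, 0L, "letter_id")
  )
  out$regions <- lapply(steps, `[[`, "regions")
  attr(out, "m") <- codebook$m
  attr(out, "n") <- codebook$n
  class(out) <- c("illumination_schedule", "data.frame")
  out
}

#' Reconstruct the region assignment encoded by a schedule
#'
#' Round-trip validator: reassembles each region's codeword from the steps it
#' appears in. Every (region, round) pair must appear in exactly one step;
#' a missing or duplicated pair is an error, since such a schedule cannot
#' have been produced by a consistent assignment.
#'
#' @param schedule An `illumination_schedule`.
#' @return A named list mapping region id to its integer digit vector;
#'   `reconstruct_assignment(build_schedule(cb))` equals `cb$assignment`.
#' @export
reconstruct_assignment <- function(schedule) {
  n <- attr(schedule, "n")
  if (!nrow(schedule)) return(setNames(list(), character(0)))
  lens <- lengths(schedule$regions)
  region <- unlist(schedule$regions, use.names = FALSE)
  round <- rep(schedule$round, lens)
  letter <- rep(schedule$letter_id, lens)
  key <- paste(region, round)
  dup <- duplicated(key)
  if (any(dup)) {
    stop("inconsistent schedule: region/round pair(s) appear in multiple steps: ",
         paste(unique(key[dup]), collapse = "; "))
  }
  ids <- unique(region)
  digits <- matrix(NA_integer_, length(ids), n, dimnames = list(ids, NULL))
  digits[cbind(match(region, ids), round)] <- letter
  if (anyNA(digits)) {
    miss <- which(is.na(digits), arr.ind = TRUE)
    stop("inconsistent schedule: missing round(s) for region(s): ",
         paste(unique(ids[miss[, 1]]), collapse = ", "))
  }
  setNames(lapply(seq_along(ids), function(i) unname(digits[i, ])), ids)
}

#' Render binary illumination masks for each schedule step
#'
#' Produces one binary image per ligation step; a pixel is 1 iff its center
#' lies inside any region illuminated in that step. Masks can be written as
#' portable graymap (PGM) files named `step{idx}_round{r}_L{l}.pgm`, the
#' exchange format a light-patterning device script can consume.
#'
#' @param schedule An `illumination_schedule`.
#' @param regions A `region_table` giving geometry for every scheduled
#'   region.
#' @param width,height Canvas size in pixels.
#' @param dir Optional output directory for PGM files (created if needed).
#' @param format `"P2"` (ASCII) or `"P5"` (binary) PGM.
#' @return Invisibly, a named list of 0/1 integer matrices (rows = y), named
#'   like the PGM files.
#' @export
render_masks <- function(schedule, regions, width, height, dir = NULL,
                         format = c("P2", "P5")) {
  format <- match.arg(format)
  stopifnot(inherits(schedule, "illumination_schedule"))
  needed <- unique(unlist(schedule$regions, use.names = FALSE))
  geo <- regions[match(needed, regions$id), , drop = FALSE]
  if (anyNA(geo$shape)) {
    stop("no geometry for region(s): ", paste(needed[is.na(geo$shape)], collapse = ", "))
  }
  xmin <- ifelse(geo$shape == "circle", geo$x - geo$w / 2, geo$x)
  xmax <- ifelse(geo$shape == "circle", geo$x + geo$w / 2, geo$x + geo$w - 1)
  ymin <- ifelse(geo$shape == "circle", geo$y - geo$w / 2, geo$y)
  ymax <- ifelse(geo$shape == "circle", geo$y + geo$w / 2, geo$y + geo$h - 1)
  oob <- xmin < 1 | ymin < 1 | xmax > width | ymax > height
  if (any(oob)) stop("geometry outside canvas for region(s): ",
                     paste(geo$id[oob], collapse = ", "))
  px <- matrix(rep(seq_len(width), each = height), height, width)
  py <- matrix(rep(seq_len(height), times = width), height, width)
  region_mask <- function(g) {
    if (g$shape == "rect") {
      px >= g$x & px <= g$x + g$w - 1 & py >= g$y & py <= g$y + g$h - 1
    } else {
      (px - g$x)^2 + (py - g$y)^2 <= (g$w / 2)^2
    }
  }
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- vector("list", nrow(schedule))
  names(out) <- sprintf("step%d_round%d_L%d", schedule$step_index,
                        schedule$round, schedule$letter_id)
  for (i in seq_len(nrow(schedule))) {
    acc <- matrix(FALSE, height, width)
    for (rid in schedule$regions[[i]]) {
      acc <- acc | region_mask(geo[geo$id == rid, , drop = FALSE])
    }
    m <- matrix(as.integer(acc), height, width)
    out[[i]] <- m
    if (!is.null(dir)) {
      write_pgm(m, file.path(dir, paste0(names(out)[i], ".pgm")), format)
    }
  }
  invisible(out)
}

# Minimal PGM writer (maxval 1); P2 is ASCII, P5 binary.
write_pgm <- function(mat, path, format = "P2") {
  header <- sprintf("%s\n%d %d\n1\n", format, ncol(mat), nrow(mat))
  if (format == "P2") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sub("\n$", "", header), con)
    write(t(mat), file = con, ncolumns = ncol(mat))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(header, con, eos = NULL)
    writeBin(as.raw(t(mat)), con)
  }
  invisible(path)
}

#' Read and write schedule files
#'
#' CSV with columns `step_index`, `round`, `letter_id`, `region_ids`
#' (semicolon-joined).
#'
#' @param schedule An `illumination_schedule`.
#' @param path File path (CSV).
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns an `illumination_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  df <- data.frame(
    step_index = schedule$step_index,
    round = schedule$round,
    letter_id = schedule$letter_id,
    region_ids = vapply(schedule$regions, paste, "", collapse = ";")
  )
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_schedule
#' @param m,n Alphabet size and round count to attach; inferred from the
#'   file contents when omitted.
#' @export
read_schedule <- function(path, m = NULL, n = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- df[, c("step_index", "round", "letter_id")]
  out$regions <- strsplit(df$region_ids, ";", fixed = TRUE)
  attr(out, "m") <- if (is.null(m)) max(df$letter_id) else m
  attr(out, "n") <- if (is.null(n)) max(df$round) else n
  class(out) <- c("illumination_schedule", "data.frame")
  out
}
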