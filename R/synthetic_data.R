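# End-to-end synthetic experiments: molecules, traces, and paired FASTQ
# with ground truth, emulating a two-species mixed-culture validation run.
#
# "Species" here are synthetic transcript-tag pools, not genomes: each
# region draws Read 2 tags from its species' pool, and a configurable
# fraction h of each pool is shared verbatim with the other species. Shared
# tags classify to the other species under exact lookup, which makes h a
# direct stand-in for the cross-species mapping rate caused by
# transcriptome homology, without any alignment.

#' Specify a synthetic barcoding-and-sequencing experiment
#'
#' @param codebook An assigned `codebook`.
#' @param params A [ligation_params()]; `n_L` must equal the codebook's
#'   alphabet size and `R` its round count.
#' @param molecules_per_region Reads (molecules) generated per region
#'   (default 10000).
#' @param read_error Per-base substitution rate applied to both reads
#'   (default 0.001); indels are not modeled, consistent with the
#'   fixed-window demultiplexer.
#' @param h Shared ("homologous") fraction of each species' tag pool,
#'   in `[0, 1]` (default 0.047).
#' @param pool_size Tags per species pool (default 500).
#' @param tag_bp Tag length in nt (default 60).
#' @param read1_bp Fixed Read 1 length; barcoded inserts are padded with T
#'   and truncated to this (default 150).
#' @param handle Fixed 5' handle on Read 1 (default a sequencing-adapter
#'   stub).
#' @param species_of_region Named character vector mapping region id to
#'   `"A"` or `"B"`; defaults to alternating assignment over the codebook's
#'   regions.
#' @param seed Master seed; all randomness in [generate_experiment()]
#'   derives from it.
#' @return An `experiment_spec` list.
#' @export
experiment_spec <- function(codebook, params,
                            molecules_per_region = 10000L,
                            read_error = 0.001, h = 0.047,
                            pool_size = 500L, tag_bp = 60L,
                            read1_bp = 150L,
                            handle = "CAGACGTGTGCTCTTCCGATCT",
                            species_of_region = NULL, seed = 1L) {
  stopifnot(inherits(codebook, "codebook"), inherits(params, "ligation_params"))
  if (!length(codebook$assignment)) stop("codebook has no region assignment")
  if (params$n_L != codebook$m || params$R != codebook$n) {
    stop("ligation params (n_L, R) must match the codebook (m, n)")
  }
  check_prob(h, "h"); check_prob(read_error, "read_error")
  regions <- names(codebook$assignment)
  if (is.null(species_of_region)) {
    species_of_region <- setNames(rep(c("A", "B"), length.out = length(regions)),
                                  regions)
  }
  if (!all(regions %in% names(species_of_region))) {
    stop("species_of_region must cover every assigned region")
  }
  if (!all(species_of_region %in% c("A", "B"))) {
    stop("species labels must be 'A' or 'B' (two pools)")
  }
  need <- nchar(handle) + codebook$n * nchar(codebook$letters$sequence[1])
  if (read1_bp < need) stop("read1_bp too short for handle + barcode slot (need ",
                            need, ")")
  structure(
    list(codebook = codebook, params = params,
         molecules_per_region = as.integer(molecules_per_region),
         read_error = read_error, h = h, pool_size = as.integer(pool_size),
         tag_bp = as.integer(tag_bp), read1_bp = as.integer(read1_bp),
         handle = handle, species_of_region = species_of_region,
         seed = as.integer(seed)),
    class = "experiment_spec"
  )
}

#' Build the two species tag pools
#'
#' Each species has `pool_size` transcript tags; a fraction `h` of each
#' pool's slots is replaced verbatim by tags native to the other species,
#' so a read drawn uniformly from its region's pool carries a
#' foreign-classifying tag with probability `h` exactly (up to rounding).
#'
#' @param pool_size Tags per pool.
#' @param tag_bp Tag length in nt.
#' @param h Shared fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `pool_A`, `pool_B` (character vectors of tags) and
#'   `native` (named character vector mapping every native tag to `"A"` or
#'   `"B"`), plus `n_shared`.
#' @export
make_species_pools <- function(pool_size, tag_bp, h, seed) {
  with_seed(seed, {
    random_tags <- function(k) {
      vapply(seq_len(k), function(i) {
        paste(sample(c("A", "C", "G", "T"), tag_bp, replace = TRUE),
              collapse = "")
      }, "")
    }
    repeat {
      natives <- random_tags(2L * pool_size)
      if (!anyDuplicated(natives)) break
    }
    nat_A <- natives[seq_len(pool_size)]
    nat_B <- natives[pool_size + seq_len(pool_size)]
    n_sh <- round(h * pool_size)
    pool_A <- nat_A
    pool_B <- nat_B
    if (n_sh > 0) {
      pool_A[sample(pool_size, n_sh)] <- sample(nat_B, n_sh)
      pool_B[sample(pool_size, n_sh)] <- sample(nat_A, n_sh)
    }
    list(pool_A = pool_A, pool_B = pool_B,
         native = setNames(rep(c("A", "B"), each = pool_size), natives),
         n_shared = n_sh)
  })
}

#' Classify transcript tags by exact pool lookup
#'
#' @param tags Character vector of Read 2 tags.
#' @param pools Output of [make_species_pools()].
#' @return Character vector: `"A"`, `"B"`, or `NA` for tags native to
#'   neither pool (e.g. carrying sequencing errors).
#' @export
classify_species <- function(tags, pools) {
  unname(pools$native[tags])
}

# iid per-base substitutions on fixed-width sequences
add_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  w <- nchar(seqs[1])
  mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                nrow = length(seqs), ncol = w, byrow = TRUE)
  hit <- which(matrix(runif(length(mat)) < rate, nrow(mat), ncol(mat)))
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    old <- mat[hit]
    mat[hit] <- vapply(old, function(b) sample(setdiff(bases, b), 1L), "")
  }
  apply(mat, 1L, paste, collapse = "")
}

#' Generate a complete synthetic experiment
#'
#' For each assigned region, draws molecules from the on/off-target
#' ligation process ([simulate_molecules()]), assembles Read 1 from each
#' molecule's actual (possibly erroneous) barcode — handle first, letters in
#' reverse ligation order, T-padded to a fixed read length — and draws
#' Read 2 as a transcript tag from the region's species pool. Per-region
#' electropherogram traces are synthesized from the empirical molecule
#' length histogram (not the closed form), so trace-fitting tests exercise
#' the full stochastic path. All randomness derives from `spec$seed`; equal
#' specs give identical output.
#'
#' @param spec An [experiment_spec()].
#' @param dir Optional output directory; when given, writes `R1.fastq.gz`,
#'   `R2.fastq.gz`, `truth.tsv`, one `trace_<region>.csv` per region, and
#'   `provenance.json` (parameters and seeds).
#' @return A list: `r1`, `r2` (named character vectors of reads), `truth`
#'   (data frame: `read_id`, `region`, `codeword`, `barcode`, `species`,
#'   `tag_origin`), `traces` (named list of `trace` objects), `pools`,
#'   `codebook`, and `spec`.
#' @export
generate_experiment <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "experiment_spec"))
  cb <- spec$codebook
  regions <- names(cb$assignment)
  letter_seqs <- cb$letters$sequence
  pools <- make_species_pools(spec$pool_size, spec$tag_bp, spec$h,
                              seed = spec$seed)
  r1 <- character(0); r2 <- character(0)
  truth <- vector("list", length(regions))
  traces <- vector("list", length(regions))
  names(traces) <- regions
  for (i in seq_along(regions)) {
    reg <- regions[i]
    sim <- simulate_molecules(spec$params, cb$assignment[[reg]],
                              spec$molecules_per_region,
                              seed = spec$seed + 1000L * i)
    inserts <- vapply(sim$digits, function(d) {
      paste(rev(letter_seqs[d]), collapse = "")
    }, "")
    reads1 <- substr(paste0(spec$handle, inserts,
                            strrep("T", spec$read1_bp)), 1L, spec$read1_bp)
    pool <- if (spec$species_of_region[[reg]] == "A") pools$pool_A else pools$pool_B
    tags <- with_seed(spec$seed + 1000L * i + 1L, {
      pool[sample(length(pool), spec$molecules_per_region, replace = TRUE)]
    })
    reads2 <- tags
    if (spec$read_error > 0) {
      reads1 <- with_seed(spec$seed + 1000L * i + 2L,
                          add_substitutions(reads1, spec$read_error))
      reads2 <- with_seed(spec$seed + 1000L * i + 3L,
                          add_substitutions(reads2, spec$read_error))
    }
    ids <- sprintf("%s_m%06d", reg, sim$molecule_id)
    r1 <- c(r1, setNames(reads1, ids))
    r2 <- c(r2, setNames(reads2, ids))
    tag_species <- classify_species(tags, pools)  # pre-error origin
    truth[[i]] <- data.frame(
      read_id = ids,
      region = reg,
      codeword = format_codeword(cb$assignment[[reg]]),
      barcode = sim$barcode,
      species = spec$species_of_region[[reg]],
      tag_origin = ifelse(tag_species == spec$species_of_region[[reg]],
                          "native", "homolog"),
      stringsAsFactors = FALSE
    )
    hist <- length_histogram(sim)
    traces[[i]] <- synth_trace(hist, sigma = 6, noise_sd = 0)
  }
  truth <- do.call(rbind, truth)
  out <- list(r1 = r1, r2 = r2, truth = truth, traces = traces,
              pools = pools, codebook = cb, spec = spec)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fastq(r1, file.path(dir, "R1.fastq.gz"))
    write_fastq(r2, file.path(dir, "R2.fastq.gz"))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    for (reg in regions) {
      write_trace(traces[[reg]], file.path(dir, paste0("trace_", reg, ".csv")))
    }
    prov <- list(
      seed = spec$seed,
      params = unclass(spec$params),
      molecules_per_region = spec$molecules_per_region,
      read_error = spec$read_error, h = spec$h,
      pool_size = spec$pool_size, tag_bp = spec$tag_bp,
      read1_bp = spec$read1_bp, handle = spec$handle,
      regions = regions,
      codewords = as.list(vapply(cb$assignment, format_codeword, ""))
    )
    jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Canned deterministic fixtures
#'
#' Small named fixtures used throughout the documentation and tests;
#' repeated calls return identical objects.
#'
#' * `"four_region_2x2"`: the worked four-region example — 2 letters, 2
#'   rounds, regions I--IV assigned `L1L1, L1L2, L2L1, L2L2`.
#' * `"trace_2x2"`: the two-letter/two-round trace case — printed length
#'   proportions (27.3% / 69.2% / 3.5% for 1/2/3 letters), the observed
#'   fractions used for `(d, c)` inversion, and the published estimates.
#' * `"single_cell_4x3"`: the 64-cell case — 4 letters, 3 rounds, 64
#'   regions (`cell01..cell64`), observed 3- and 4-letter fractions and the
#'   published `(d, c)`.
#' * `"two_species"`: the mixed-species design — two regions with
#'   two-digit-distinct codewords (`top = L1L3`, `bottom = L2L4`, minimum
#'   Hamming distance 2) and shared-tag fraction 0.047.
#'
#' @param name Fixture name.
#' @return A list; contents depend on the fixture (see above). Codebook
#'   fixtures contain `codebook`; parameter fixtures additionally contain
#'   `observed`, `d`, `c`, `n_L`, `R`.
#' @export
fixture_library <- function(name = c("four_region_2x2", "trace_2x2",
                                     "single_cell_4x3", "two_species")) {
  name <- match.arg(name)
  switch(
    name,
    four_region_2x2 = {
      cb <- assign_regions(build_codebook(2, 2), c("I", "II", "III", "IV"))
      list(codebook = cb,
           groups = list(list(round = 1, letter = 1, regions = c("I", "II")),
                         list(round = 1, letter = 2, regions = c("III", "IV")),
                         list(round = 2, letter = 1, regions = c("I", "III")),
                         list(round = 2, letter = 2, regions = c("II", "IV"))))
    },
    trace_2x2 = list(
      fractions = c("1" = 0.273, "2" = 0.692, "3" = 0.035),
      observed = c("2" = 0.692, "3" = 0.035),
      d = 0.845, c = 0.025, n_L = 2L, R = 2L
    ),
    single_cell_4x3 = {
      cb <- assign_regions(build_codebook(4, 3), sprintf("cell%02d", 1:64))
      list(codebook = cb,
           observed = c("3" = 0.583, "4" = 0.074),
           d = 0.854, c = 0.014, n_L = 4L, R = 3L)
    },
    two_species = {
      cb <- assign_regions(build_codebook(4, 2),
                           list(top = "L1L3", bottom = "L2L4"))
      list(codebook = cb,
           species_of_region = c(top = "A", bottom = "B"),
           h = 0.047)
    }
  )
}
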