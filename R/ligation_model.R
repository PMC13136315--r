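# Stochastic model of light-directed barcode construction.
#
# Each of the R rounds consists of n_L letter-addition reactions, one per
# letter, each under its own illumination pattern. In the reaction targeting
# a region, the letter is added with on-target probability d; in each of the
# other n_L - 1 reactions a stray letter is added with off-target
# probability c. Rounds and reactions are independent, so the barcode length
# L (letters actually ligated) is the sum of Binomial(R, d) on-target and
# Binomial((n_L - 1) R, c) off-target additions.

#' Ligation process parameters
#'
#' @param d Per-round on-target letter-addition probability.
#' @param c Per-reaction off-target letter-addition probability.
#' @param n_L Number of distinct letters offered per round, `n_L >= 1`.
#' @param R Number of ligation rounds, `R >= 1`.
#' @return A validated `ligation_params` list.
#' @examples
#' ligation_params(d = 0.845, c = 0.025, n_L = 2, R = 2)
#' @export
ligation_params <- function(d, c, n_L, R) {
  check_prob(d, "d"); check_prob(c, "c")
  check_posint(n_L, "n_L"); check_posint(R, "R")
  structure(list(d = d, c = c, n_L = as.integer(n_L), R = as.integer(R)),
            class = "ligation_params")
}

#' @export
print.ligation_params <- function(x, ...) {
  cat(sprintf("Ligation model: d = %.4g, c = %.4g, n_L = %d, R = %d\n",
              x$d, x$c, x$n_L, x$R))
  invisible(x)
}

#' Closed-form barcode-length distribution
#'
#' Probability that a molecule ends up with a barcode of `N` letters:
#' \deqn{P(L=N)=\sum_{k=\max(0,\,N-(n_L-1)R)}^{\min(R,\,N)}
#'   \binom{R}{k} d^k (1-d)^{R-k}
#'   \binom{(n_L-1)R}{N-k} c^{N-k} (1-c)^{(n_L-1)R-(N-k)}}
#' where `k` counts on-target additions. This is the convolution of
#' `Binomial(R, d)` and `Binomial((n_L - 1) R, c)` evaluated at `N`; the sum
#' limits reflect that at most `R` letters can arrive on target and at most
#' `(n_L - 1) R` off target. `N` outside `0..n_L * R` has probability 0.
#'
#' @param N Barcode length(s) in letters (vectorized).
#' @param params A [ligation_params()] object.
#' @return Probabilities, one per element of `N`.
#' @examples
#' p <- ligation_params(0.845, 0.025, n_L = 2, R = 2)
#' length_pmf(2, p)  # ~0.692
#' length_pmf(3, p)  # ~0.035
#' @export
length_pmf <- function(N, params) {
  stopifnot(inherits(params, "ligation_params"))
  M_off <- (params$n_L - 1L) * params$R
  vapply(N, function(nn) {
    if (nn < 0 || nn > params$n_L * params$R || nn != round(nn)) return(0)
    k <- seq(max(0L, nn - M_off), min(params$R, nn))
    sum(dbinom(k, params$R, params$d) * dbinom(nn - k, M_off, params$c))
  }, 0)
}

#' @rdname length_pmf
#' @return `length_distribution()` returns the full pmf as a named numeric
#'   vector over the support `0..n_L * R`.
#' @export
length_distribution <- function(params) {
  support <- 0:(params$n_L * params$R)
  setNames(length_pmf(support, params), support)
}

#' Estimate on- and off-target probabilities from observed length fractions
#'
#' Inverts the closed-form length distribution: finds `(d, c)` in the unit
#' square minimizing the sum of squared deviations between [length_pmf()]
#' and the observed fractions at the fitted lengths. With two observed
#' fractions and two unknowns the fit is typically exact (residual ~ 0);
#' this is how per-round on-target and per-reaction off-target rates are
#' estimated from electropherogram-derived barcode-length proportions. When
#' only an upper bound is known for a length (e.g. an undetectable
#' overlength peak), the bound is fitted as an equality, yielding a
#' conservative `c`.
#'
#' Optimization is bounded L-BFGS-B from a 5x5 grid of starting points; the
#' best local optimum wins, ties broken by lower residual then lower `c`.
#'
#' @param observed Named numeric vector of observed fractions; names are
#'   barcode lengths in letters. At least two distinct lengths are required
#'   (two unknowns).
#' @param n_L,R Letters per round and number of rounds.
#' @param lengths_to_fit Optional subset of lengths to fit (default all of
#'   `names(observed)`).
#' @return A `dc_fit` list: `d`, `c`, `residual` (sum of squares),
#'   `converged` (logical), and `fitted` (model fractions at the fitted
#'   lengths).
#' @examples
#' estimate_dc(c("2" = 0.692, "3" = 0.035), n_L = 2, R = 2)
#' @export
estimate_dc <- function(observed, n_L, R, lengths_to_fit = NULL) {
  if (is.null(names(observed))) stop("`observed` must be named by barcode length")
  if (!is.null(lengths_to_fit)) {
    observed <- observed[as.character(lengths_to_fit)]
    if (anyNA(observed)) stop("`lengths_to_fit` not all present in `observed`")
  }
  lens <- as.integer(names(observed))
  if (anyNA(lens)) stop("names of `observed` must be integer lengths")
  if (length(unique(lens)) < 2L) {
    stop("underdetermined: need fractions at >= 2 distinct lengths to estimate (d, c)")
  }
  if (any(observed < 0 | observed > 1)) stop("observed fractions must lie in [0, 1]")
  check_posint(n_L, "n_L"); check_posint(R, "R")
  obs <- as.numeric(observed)
  obj <- function(par) {
    # clamp: L-BFGS-B's finite-difference gradient may step just outside
    par <- pmin(pmax(par, 0), 1)
    p <- ligation_params(par[1], par[2], n_L, R)
    sum((length_pmf(lens, p) - obs)^2)
  }
  # c starts spaced toward small values: off-target rates are typically
  # a few percent, and the true basin can be narrow in that corner
  starts <- expand.grid(d = seq(0.1, 0.9, length.out = 5),
                        c = c(0.01, 0.05, 0.1, 0.3, 0.6))
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
          lower = c(0, 0), upper = c(1, 1),
          control = list(factr = 10, pgtol = 1e-14, maxit = 500,
                         ndeps = c(1e-7, 1e-7)))
  })
  resid <- vapply(fits, `[[`, 0, "value")
  cs <- vapply(fits, function(f) f$par[2], 0)
  # residuals within numerical noise of the minimum are ties (for n_L = 2
  # the convolution is symmetric in d and c, so a mirror optimum always
  # exists); prefer the physically expected low off-target rate
  tied <- which(resid <= min(resid) + 1e-10)
  best <- fits[[tied[which.min(cs[tied])]]]
  params <- ligation_params(best$par[1], best$par[2], n_L, R)
  out <- list(
    d = best$par[1], c = best$par[2],
    residual = best$value,
    converged = best$convergence == 0L,
    fitted = setNames(length_pmf(lens, params), lens),
    n_L = as.integer(n_L), R = as.integer(R)
  )
  class(out) <- "dc_fit"
  if (!out$converged) warning("estimate_dc did not converge; treat estimates with caution")
  out
}

#' @export
print.dc_fit <- function(x, ...) {
  cat(sprintf("d = %.4f (%.1f%%), c = %.4f (%.1f%%)  [n_L = %d, R = %d]\n",
              x$d, 100 * x$d, x$c, 100 * x$c, x$n_L, x$R))
  cat(sprintf("residual = %.3g, converged = %s\n", x$residual, x$converged))
  invisible(x)
}

#' Simulate barcode construction molecule by molecule
#'
#' Draws per-molecule outcomes of the on/off-target ligation process for a
#' region targeted with codeword `target`. Within each round the `n_L`
#' reactions run in schedule order (ascending letter id); the reaction whose
#' letter matches the round's target digit succeeds with probability `d`,
#' each other reaction appends its stray letter with probability `c`. In the
#' default independent-rounds mode a failure never blocks later additions,
#' matching the closed-form [length_pmf()]. The optional `blocking` mode
#' instead terminates a molecule's extension after its first failed
#' on-target reaction (no exposed 5' phosphate); it does NOT follow the
#' closed form and is excluded from its oracle.
#'
#' @param params A [ligation_params()] object.
#' @param target Integer codeword of length `R` (letter ids in `1..n_L`).
#' @param n_molecules Number of molecules to draw, `>= 1`.
#' @param seed Integer seed; recorded in the output.
#' @param blocking Use the blocking extension mode (default `FALSE`).
#' @return A data frame with one row per molecule: `molecule_id`, `barcode`
#'   (string, ligation order), `length`, `k_on`, `k_off`, and a list-column
#'   `digits` of the ligated letter ids. Attribute `seed` records the seed.
#' @examples
#' p <- ligation_params(0.9, 0.02, n_L = 2, R = 2)
#' sim <- simulate_molecules(p, target = c(1, 2), n_molecules = 1000, seed = 1)
#' mean(sim$length == 2)
#' @export
simulate_molecules <- function(params, target, n_molecules, seed,
                               blocking = FALSE) {
  stopifnot(inherits(params, "ligation_params"))
  target <- as.integer(target)
  if (length(target) != params$R) stop("`target` must have length R = ", params$R)
  if (any(target < 1L | target > params$n_L)) stop("`target` digits must lie in 1..n_L")
  check_posint(n_molecules, "n_molecules")
  n <- as.integer(n_molecules)
  cols <- params$n_L * params$R
  col_letter <- rep(seq_len(params$n_L), times = params$R)
  col_round <- rep(seq_len(params$R), each = params$n_L)
  on_col <- col_letter == target[col_round]
  p_col <- ifelse(on_col, params$d, params$c)
  added <- with_seed(seed, {
    u <- matrix(runif(n * cols), n, cols)
    add <- sweep(u, 2L, p_col, `<`)
    if (blocking) {
      alive <- rep(TRUE, n)
      for (r in seq_len(params$R)) {
        jj <- which(col_round == r)
        add[, jj] <- add[, jj] & alive
        alive <- alive & add[, jj[which(on_col[jj])]]
      }
    }
    add
  })
  k_on <- as.integer(rowSums(added[, on_col, drop = FALSE]))
  len <- as.integer(rowSums(added))
  w <- which(added, arr.ind = TRUE)
  ord <- order(w[, 1L], w[, 2L])
  digits <- split(col_letter[w[ord, 2L]],
                  factor(w[ord, 1L], levels = seq_len(n)))
  digits <- lapply(digits, as.integer)
  barcode <- vapply(digits, function(d) {
    if (length(d)) paste0("L", d, collapse = "") else ""
  }, "")
  out <- data.frame(
    molecule_id = seq_len(n),
    barcode = unname(barcode),
    length = len,
    k_on = k_on,
    k_off = len - k_on,
    stringsAsFactors = FALSE
  )
  out$digits <- unname(digits)
  attr(out, "seed") <- seed
  attr(out, "params") <- params
  attr(out, "target") <- target
  out
}

#' Empirical barcode-length histogram
#'
#' @param outcomes A data frame from [simulate_molecules()] (its `length`
#'   column is used) or a numeric vector of barcode lengths.
#' @return A named numeric vector of fractions over the observed lengths,
#'   summing to 1.
#' @export
length_histogram <- function(outcomes) {
  lens <- if (is.data.frame(outcomes)) outcomes$length else outcomes
  if (!length(lens)) stop("no outcomes to tabulate")
  tab <- table(factor(lens, levels = sort(unique(lens))))
  setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Write simulated molecule outcomes to CSV
#'
#' Columns: `molecule_id`, `barcode_string`, `length`, `k_on`, `k_off`.
#'
#' @param outcomes Data frame from [simulate_molecules()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  df <- data.frame(
    molecule_id = outcomes$molecule_id,
    barcode_string = outcomes$barcode,
    length = outcomes$length,
    k_on = outcomes$k_on,
    k_off = outcomes$k_off
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
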