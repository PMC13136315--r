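# Electropherogram synthesis and constrained multi-Gaussian fitting.
#
# Capillary-electrophoresis traces of the extracted barcoded material show
# one peak per barcode length, spaced one letter (20 bp by default) apart.
# Fitting a sum of Gaussians recovers the relative abundance of each length
# species, including an upper bound on an overlength (off-target) species
# whose peak may be invisible by eye.

#' Synthesize an electropherogram trace
#'
#' Builds a length-vs-intensity trace as a sum of Gaussian peaks, one per
#' barcode-length species, each centered at `base_bp + letters * letter_bp`
#' with common width `sigma` and amplitude proportional to the species
#' fraction (equal widths make peak area proportional to amplitude).
#' Optional iid Gaussian noise is added relative to the maximum intensity;
#' intensities are clipped at 0.
#'
#' @param fractions Named numeric vector: names are barcode lengths in
#'   letters, values their fractions (must sum to 1).
#' @param base_bp Length in bp of the barcode-free construct (primer plus
#'   handles); default 100.
#' @param letter_bp Letter length in bp (default 20).
#' @param sigma Peak standard deviation in bp (default 6).
#' @param noise_sd Noise standard deviation as a fraction of the maximum
#'   noiseless intensity (default 0).
#' @param grid Numeric vector of bp positions; default covers all peaks
#'   with 5-sigma margins at 1-bp steps.
#' @param seed Seed for the noise draw (required when `noise_sd > 0`).
#' @return A `trace` data frame with columns `length_bp`, `intensity`.
#' @examples
#' tr <- synth_trace(c("1" = 0.273, "2" = 0.692, "3" = 0.035))
#' @export
synth_trace <- function(fractions, base_bp = 100, letter_bp = 20, sigma = 6,
                        noise_sd = 0, grid = NULL, seed = NULL) {
  if (is.null(names(fractions))) stop("`fractions` must be named by barcode length")
  lens <- as.numeric(names(fractions))
  if (abs(sum(fractions) - 1) > 1e-8) stop("`fractions` must sum to 1")
  if (sigma <= 0) stop("`sigma` must be positive")
  mu <- base_bp + lens * letter_bp
  if (is.null(grid)) {
    grid <- seq(floor(min(mu) - 5 * sigma), ceiling(max(mu) + 5 * sigma), by = 1)
  }
  if (length(grid) < 10L) stop("trace grid must have >= 10 points")
  intensity <- rowSums(vapply(seq_along(mu), function(k) {
    fractions[k] * exp(-(grid - mu[k])^2 / (2 * sigma^2))
  }, numeric(length(grid))))
  if (noise_sd > 0) {
    if (is.null(seed)) stop("`seed` is required when noise_sd > 0")
    noise <- with_seed(seed, rnorm(length(grid), 0, noise_sd * max(intensity)))
    intensity <- pmax(intensity + noise, 0)
  }
  new_trace(grid, intensity)
}

new_trace <- function(length_bp, intensity) {
  if (length(length_bp) != length(intensity)) stop("trace arrays differ in length")
  if (is.unsorted(length_bp, strictly = TRUE)) stop("trace positions must be strictly increasing")
  if (any(intensity < 0)) stop("trace intensities must be non-negative")
  structure(data.frame(length_bp = length_bp, intensity = intensity),
            class = c("trace", "data.frame"))
}

#' Read and write electropherogram traces
#'
#' Two-column CSV (`length_bp`, `intensity`) with a header row, matching the
#' common electropherogram CSV export convention.
#'
#' @param trace A `trace` data frame.
#' @param path CSV path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   a `trace`.
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  if (ncol(df) < 2L) stop("trace CSV must have two columns (length_bp, intensity)")
  new_trace(as.numeric(df[[1]]), as.numeric(df[[2]]))
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  write.csv(data.frame(length_bp = trace$length_bp, intensity = trace$intensity),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit a trace as a sum of Gaussian peaks
#'
#' Nonlinear least squares fit of
#' \deqn{f(l) = \sum_{k=1}^{K} A_k \exp\!\big(-(l-\mu_k)^2 / (2\sigma_k^2)\big)}
#' with `K = R + 1` components: one per expected barcode length `1..R` plus
#' one overlength component for a single off-target addition. In the
#' constrained mode (the default) the overlength component is tied to the
#' last expected one — `mu[R+1] = mu[R] + letter_bp` and
#' `sigma[R+1] = sigma[R]` — because an off-target addition lengthens the
#' product by exactly one letter and the size spread on the instrument is
#' species-independent; this pins the fit when the overlength peak is too
#' small to locate on its own. The unconstrained mode frees all `3K`
#' parameters.
#'
#' Initialization is deterministic: means at `base_bp + k * letter_bp`,
#' common width from the full-width-at-half-maximum of the tallest peak,
#' amplitudes from the trace intensity at each initial mean. Amplitudes are
#' bounded below by 0 and widths by a small positive floor.
#'
#' @param trace A `trace` data frame.
#' @param R Number of ligation rounds (expected maximum on-target length).
#' @param constrained Tie the overlength component as described (default
#'   `TRUE`).
#' @param base_bp,letter_bp Peak-position model (defaults 100 and 20 bp).
#' @param baseline Include a constant background offset (default `FALSE`).
#' @return A `peak_model` list: vectors `A`, `mu`, `sigma` (length `K`),
#'   `baseline`, `residual` (sum of squared residuals), `converged`,
#'   `constrained`, `R`, `letter_bp`.
#' @examples
#' tr <- synth_trace(c("1" = 0.3, "2" = 0.7))
#' fit <- fit_multi_gaussian(tr, R = 2)
#' fractions_from_fit(fit)
#' @export
fit_multi_gaussian <- function(trace, R, constrained = TRUE, base_bp = 100,
                               letter_bp = 20, baseline = FALSE) {
  check_posint(R, "R")
  l <- trace$length_bp; y <- trace$intensity
  K <- R + 1L
  mu0 <- base_bp + seq_len(K) * letter_bp
  if (min(mu0) < min(l) || max(mu0[seq_len(R)]) > max(l)) {
    stop("trace does not cover the expected peak positions")
  }
  # width from FWHM of the tallest point: fwhm = 2*sqrt(2*log(2))*sigma
  peak <- which.max(y)
  half <- y[peak] / 2
  left <- suppressWarnings(max(which(y[seq_len(peak)] <= half)))
  right_idx <- which(y[peak:length(y)] <= half)
  right <- if (length(right_idx)) peak - 1L + min(right_idx) else length(y)
  fwhm <- if (is.finite(left)) l[right] - l[left] else 4 * letter_bp / 5
  sigma0 <- max(fwhm / (2 * sqrt(2 * log(2))), 1)
  A0 <- pmax(approx(l, y, xout = mu0, rule = 2)$y, 1e-6 * max(y))

  model_y <- function(A, mu, sigma, b) {
    out <- rep(b, length(l))
    for (k in seq_len(K)) out <- out + A[k] * exp(-(l - mu[k])^2 / (2 * sigma[k]^2))
    out
  }
  unpack <- function(par) {
    if (constrained) {
      A <- par[seq_len(K)]
      mu <- par[K + seq_len(R)]
      sigma <- par[K + R + seq_len(R)]
      mu <- c(mu, mu[R] + letter_bp)
      sigma <- c(sigma, sigma[R])
    } else {
      A <- par[seq_len(K)]
      mu <- par[K + seq_len(K)]
      sigma <- par[2L * K + seq_len(K)]
    }
    b <- if (baseline) par[length(par)] else 0
    list(A = A, mu = mu, sigma = sigma, b = b)
  }
  resid_fn <- function(par) {
    p <- unpack(par)
    y - model_y(p$A, p$mu, p$sigma, p$b)
  }
  nmu <- if (constrained) R else K
  par0 <- c(A0, mu0[seq_len(nmu)], rep(sigma0, nmu), if (baseline) 0)
  lower <- c(rep(0, K), rep(min(l), nmu), rep(0.5, nmu), if (baseline) 0)
  upper <- c(rep(Inf, K), rep(max(l), nmu), rep(diff(range(l)), nmu),
             if (baseline) max(y))
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  p <- unpack(fit$par)
  converged <- fit$info %in% 1:4
  if (!converged) warning("multi-Gaussian fit did not converge (info = ", fit$info, ")")
  if (any(p$A < 0)) {
    warning("negative fitted amplitude(s) clipped at 0")
    p$A <- pmax(p$A, 0)
  }
  structure(
    list(A = unname(p$A), mu = unname(p$mu), sigma = unname(p$sigma),
         baseline = p$b, residual = sum(resid_fn(fit$par)^2),
         converged = converged, constrained = constrained, R = R,
         letter_bp = letter_bp),
    class = "peak_model"
  )
}

#' @export
print.peak_model <- function(x, ...) {
  cat(sprintf("Multi-Gaussian fit (%s), %d components, residual %.3g\n",
              if (x$constrained) "constrained" else "unconstrained",
              length(x$A), x$residual))
  print(data.frame(component = seq_along(x$A), A = x$A, mu = x$mu,
                   sigma = x$sigma))
  invisible(x)
}

#' Barcode-length fractions from a fitted peak model
#'
#' Converts fitted components into normalized species fractions. By default
#' a component's weight is its integrated area, `A_k * sigma_k` (the
#' `sqrt(2*pi)` factor cancels in the normalization), because species
#' abundance is proportional to integrated signal; `mode = "amplitude"`
#' normalizes peak heights instead, as when reading peak intensities off an
#' instrument plot. Under the constrained fit the two conventions coincide
#' for the tied overlength component.
#'
#' @param model A `peak_model`.
#' @param mode `"area"` (default) or `"amplitude"`.
#' @return Named numeric vector of fractions (names = barcode length in
#'   letters, component `k` = `k`-letter species), summing to 1.
#' @export
fractions_from_fit <- function(model, mode = c("area", "amplitude")) {
  mode <- match.arg(mode)
  w <- if (mode == "area") model$A * model$sigma else model$A
  if (sum(w) <= 0) stop("all fitted amplitudes are zero; no fractions defined")
  setNames(w / sum(w), seq_along(w))
}
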