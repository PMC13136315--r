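---
title: "Light-directed combinatorial barcoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Light-directed combinatorial barcoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photobarcode)
```

## The barcoding scheme

Spatially resolved sequencing experiments need a way to stamp each molecule
with a barcode that records where in the sample it sat. In the light-directed
scheme this package models, barcodes are built in situ by iterative ligation
of short oligonucleotide **letters** (20 nt by default), gated by
photocleavable linkers: only regions illuminated with patterned UV light
expose the 5' phosphate needed for the next ligation. With an alphabet of
`m` letters and `n` ligation rounds, `m^n` distinct codewords are available,
and because every region receiving the same letter in the same round can be
illuminated simultaneously, the whole codebook is written in at most
`m * n` ligation steps. The canonical four-region example (`m = 2`,
`n = 2`) assigns `L1L1, L1L2, L2L1, L2L2` to regions I--IV and needs four
steps: `{I,II}` then `{III,IV}` in round 1, `{I,III}` then `{II,IV}` in
round 2.

```{r}
cb <- assign_regions(build_codebook(2, 2), c("I", "II", "III", "IV"))
build_schedule(cb)$regions
```

Within a round, steps are emitted in ascending letter id. The ordering of
letter steps within a round carries no information (each region appears in
exactly one step per round), so a fixed ascending order was chosen purely to
make outputs deterministic and diffable. Letters unused in a round produce
no step: emitting an empty illumination would waste a wet-lab step, so the
`m * n` step count is exact only for complete codebooks.

## The on/off-target ligation model

Each round consists of `n_L` letter-addition reactions, one per letter,
each under its own illumination pattern. For a given region, the reaction
carrying its intended letter succeeds with per-round **on-target
probability** `d`; each of the other `n_L - 1` reactions may still add its
stray letter with per-reaction **off-target probability** `c` (stray light,
scattering, light-independent cleavage). Assuming all reactions are
independent — a failed ligation does not block later rounds — the barcode
length `L` is the sum of a `Binomial(R, d)` on-target count and a
`Binomial((n_L - 1) R, c)` off-target count, giving the closed form
implemented by `length_pmf()`:

$$P(L=N)=\sum_{k=\max(0,\,N-(n_L-1)R)}^{\min(R,\,N)}
\binom{R}{k} d^k (1-d)^{R-k}
\binom{(n_L-1)R}{N-k} c^{N-k} (1-c)^{(n_L-1)R-(N-k)}.$$

Two modeling choices deserve comment.

* **One `c` for all reactions.** The prose description of the chemistry is
  written for two reactions per round, but the formula generalizes to `n_L`
  reactions per round with a single shared off-target rate; we follow the
  formula. Whether the first and later reactions of a round should have
  different off-target rates is unknowable from length data alone, and a
  single scalar keeps the model identifiable from two observed fractions.
* **Independent rounds.** `simulate_molecules()` matches this assumption
  and is validated against an exhaustive enumeration oracle. A `blocking`
  mode, in which a molecule stops extending after its first failed
  on-target reaction (no 5' phosphate exposed), is provided for
  sensitivity analysis; it deliberately does *not* follow the closed form
  and is excluded from the oracle tests.

At `c = 0` and `n_L = 1` the model collapses to the familiar full-length
arithmetic `P(L = R) = d^R` (`full_length_fraction()`), which is why with
~90% per-round efficiency about 60% of molecules carry a full 5-letter
barcode, and why an r-repeat code — each digit ligated `r` times, decoded
from any surviving repeat — lifts the effective per-letter efficiency to
`1 - (1 - p)^r` (`effective_letter_efficiency()`). The at-least-one-repeat
decoding rule is fixed; majority vote is not implemented because with
`r = 2` it cannot break ties and for small `r` it discards valid
information.

### Estimating `d` and `c`

`estimate_dc()` inverts the closed form on observed barcode-length
fractions by bounded least squares over the unit square. Numerical notes:

* **Multi-start.** The objective can have a spurious shallow basin in the
  interior and a narrow true basin near small `c`. A 5x5 grid of L-BFGS-B
  starts is used, with the `c` starts spaced toward small values
  (0.01--0.6) because physically plausible off-target rates are a few
  percent.
* **Ties.** For `n_L = 2` the convolution is symmetric in `d` and `c`, so
  every optimum has an exact mirror image. Fits whose residuals agree to
  within 1e-10 are treated as tied and the tie is broken toward the lower
  `c`, i.e. the physically expected branch.
* **Bounds as equalities.** When an experiment reports only an upper bound
  for an overlength fraction (an undetectable peak), the bound is fitted as
  if it were the observed value; the resulting `c` is then itself an upper
  bound. This mirrors how such fractions are produced by the constrained
  trace fit below.
* With two fractions and two unknowns the fit is exact (residual at
  numerical zero); `converged` and `residual` are always reported, and
  non-convergence warns rather than failing silently.

## Electropherogram fitting

Capillary-electrophoresis traces of the extracted material show one peak
per barcode length, spaced `letter_bp` (default 20 bp, the letter length)
apart. `fit_multi_gaussian()` fits
$f(l) = \sum_{k=1}^{R+1} A_k e^{-(l-\mu_k)^2/2\sigma_k^2}$
with one component per expected length `1..R` plus one overlength
component for a single off-target addition. In the constrained mode the
overlength component is tied to its neighbour, $\mu_{R+1} = \mu_R +$
`letter_bp` and $\sigma_{R+1} = \sigma_R$: an off-target addition lengthens
the product by exactly one letter, and the instrumental size spread is
species-independent. The constraint is what makes a bounded estimate of an
*invisible* peak meaningful. The unconstrained mode (all `3(R+1)` free
parameters) is appropriate when the overlength peak is visible.

Fits are deterministic: means initialize at `base_bp + k * letter_bp`,
the common width from the FWHM of the tallest peak, amplitudes from the
trace intensity at each initial mean; optimization is
Levenberg--Marquardt (`minpack.lm::nls.lm`) with amplitudes bounded at 0
and widths at 0.5 bp. A constant-baseline term is available but off by
default: the synthetic fixtures are baseline-free, and whether real fits
should include one is instrument-dependent, so it is a flag rather than a
default.

`fractions_from_fit()` converts components to species fractions by
integrated area, `A_k σ_k` (the $\sqrt{2\pi}$ cancels), because species
abundance is proportional to integrated signal; "normalized peak
intensity" conventions that use amplitudes are preserved under
`mode = "amplitude"`. Under the σ-tying constraint the two conventions
coincide for the overlength component.

```{r}
tr <- synth_trace(c("1" = 0.273, "2" = 0.692, "3" = 0.035),
                  noise_sd = 0.02, seed = 1)
round(fractions_from_fit(fit_multi_gaussian(tr, R = 2)), 3)
```

## Demultiplexing conventions

`parse_barcode()` decodes Read 1 as: fixed 5' handle (exact or one
mismatch), then `n` fixed-width letter windows decoded by minimum Hamming
distance, accepting a letter only if the distance is at most
`max_mm_per_letter` (default 2) and the best match is unique. Because each
new letter is ligated 5' of the previous one, **Read 1 carries the letters
in reverse ligation order**; decoded codewords are reported in round
order. This convention is the easiest place to go wrong and is pinned by a
worked fixture in the tests.

Indels are not handled: letters are 20 nt, windows are fixed-width, and
the synthetic read model is substitution-only. The default tolerance of 2
mismatches per letter is safe because alphabets are validated at load time
to be pairwise separated by more than `2 * max_mm_per_letter`.

`assign_region()` offers three policies: `exact` (any decoding error is
detected, the point of assigning codewords that differ in more than one
digit), `nearest-unique` (accept a unique codeword within Hamming distance
1, never breaking ties), and `repeat-collapse` (decode each digit from any
surviving repeat, then exact match).

## What the synthetic data does and does not emulate

`generate_experiment()` produces, from one master seed, everything the
analysis consumes: per-region molecules from the ligation model, Read 1
assembled from each molecule's *actual* (possibly erroneous) barcode,
Read 2 transcript tags, per-region traces, and ground truth. Design
choices:

* **Species are tag pools, not genomes.** Each of two "species" is a pool
  of 500 random 60-mers; a fraction `h` (default 0.047) of each pool's
  slots is replaced verbatim by tags native to the other species. Under
  exact lookup those shared tags classify to the other species, so `h`
  directly plays the role of the cross-species mapping rate caused by
  transcriptome homology. This makes the mixed-species baseline testable
  without genomes or aligners, but it does not model alignment ambiguity,
  intronic reads, or expression-level weighting.
* **Traces come from the empirical length histogram**, not the closed
  form, so trace-fit tests exercise the full stochastic path rather than
  comparing the model with itself.
* **Sequencing errors** are iid per-base substitutions (default 0.1%),
  with constant quality strings; no indels, no quality profiles, no PCR
  bias. Passing tests therefore demonstrate correctness of the decoding
  logic under substitution noise, not robustness to real instrument error
  profiles.

Problem sizes in the test suite were chosen to make sampling error
negligible relative to the tolerances being asserted: 2x10^5 molecules for
total-variation comparison with the closed form (TV < 0.01), 10^5 for
parameter recovery (within 0.02), 10^4 reads per region for the
mixed-species composition (3-sigma binomial), and 100 noise seeds for the
trace round trip.

## Known limitations

* Off-target addition is a single scalar `c`; the distance dependence of
  off-target illumination is not modeled, nor is letter competition when
  multiple letters are present in one reaction (the mechanism suspected of
  reducing observed barcode diversity below `m^n` in pooled-splint runs).
* The trace fitter models exactly one overlength component; two or more
  consecutive off-target additions on one molecule are outside the model
  class (their probability is second-order in `c`).
* Codebook construction is plain enumeration; no attempt is made at
  error-correcting code design beyond repeat codes, and letter/splint
  sequences are not screened thermodynamically or against genomes.
* Masks are binary and 2-D; grayscale patterns and 3-D illumination are
  out of scope.
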