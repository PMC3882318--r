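---
title: "Multi-isotope natural abundance correction: model, numerics and design"
author: "NAcorrectR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-isotope natural abundance correction: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NAcorrectR)
```

## The problem

Ultra-high resolution FT-MS instruments resolve the isotopologues of an
identified metabolite into separate peaks, indexed by how many heavy atoms
of each element they carry. In a stable isotope-resolved metabolomics
(SIRM) experiment the experimenter feeds a tracer (13C-glucose,
13C/15N-glutamine, ...) and reads labeling patterns off these peaks. But
heavy isotopes also occur naturally — about 1.1% of all carbon is 13C — so
every observed isotopologue intensity mixes tracer-derived labeling with
natural-abundance (NA) contamination from less-labeled isotopologues.
Quantitative work (isotopologue fractions, flux estimation) requires
removing that contribution first, and with two or three simultaneous
tracers the contamination couples across label dimensions.

`NAcorrectR` performs this correction for 1-3 tracer isotopes at once,
on single in-memory arrays (`correctNA()`) or on whole peak-table
collections (`correctCollection()`, `exec/nacorrect`).

## The model

Fix a molecule with formula-derived atom counts $N_e$ per tracer element
$e$ (e.g. $N_C = 17$, $N_N = 3$ for UDP-GlcNAc, C17H27N3O17P2), and let
$p_e$ be the natural-abundance fraction of the heavy isotope. Index
isotopologues by tuples $x = (x_1, \dots, x_n)$ of heavy-atom counts,
$0 \le x_e \le N_e$. If $I_{corrected}(i)$ denotes the tracer-only (clean)
intensity, the observed intensity is

$$ I_{data}(x) \;=\; \sum_{i \le x} I_{corrected}(i)\, K(x, i), \qquad
   K(x, i) \;=\; \prod_e P_e\!\left(N_e - i_e,\; x_e - i_e\right), $$

where $P(n, k) = \binom{n}{k} p^k (1-p)^{n-k}$ is the binomial probability
that $k$ of $n$ unlabeled atoms are heavy by natural abundance, and the sum
runs over all tuples dominated componentwise by $x$ (the "ultimate" index
set; `iterateUpto()`). The diagonal term

$$ K(x, x) \;=\; \prod_e (1-p_e)^{N_e - x_e} \;=\; \prod_e S_e(x_e) $$

is the *survival* fraction: the share of a corrected isotopologue's
intensity that stays at its own peak. The $P$ and $S$ factors are
precomputed into lookup tables (`buildPTable()`, `buildSTable()`). They
depend only on the tracer isotope and the element's atom count — not on
the molecule — so one table pair serves every molecule (and every
replicate or time point) sharing that count; `getOrBuildTables()` caches
them keyed by (label, abundance, count). Caching changes run time only:
cached and fresh tables are bit-identical, which the test suite asserts at
collection scale.

Because the index space extends to $N_e$ in every dimension, the forward
map conserves total intensity; `addNA()` implements it directly.

## Inversion: clamped sweep plus iterative refinement

The kernel is lower triangular with respect to the componentwise partial
order, so the exact inverse is a single ascending sweep
(`solvePass()`):

$$ I_{corr}(x) = \frac{I_{data}(x) - \sum_{i < x} I_{corr}(i) K(x,i)}
                      {K(x,x)}, $$

visiting indices in ascending lexicographic order (a topological order for
dominance) and using already-updated entries. Real data are noisy, and
noise can drive entries negative; negative isotopologue intensities are
unphysical, so each entry is clamped at zero as it is computed. Clamping
makes the sweep inexact, which motivates the refinement loop of
`correctNA()`:

1. start from the clamped sweep of the data;
2. re-contaminate the current estimate ($I_{datacalc}$ = `addNA()` of the
   estimate) and measure the error $e = \sum_x |I_{data} - I_{datacalc}|$;
3. if $e$ did not strictly decrease (or the iteration cap was hit), return
   the best iterate seen; otherwise add an *unclamped* sweep of the
   residual to the estimate, clamp the combined estimate at zero, and
   repeat.

Design choices here, made where several alternatives would be defensible:

* **Error metric** — the sum of absolute residuals: scale-covariant,
  robust, and free of tuning constants. Convergence is judged on strict
  decrease, so no absolute tolerance is needed; the returned iterate is
  the arg-min over all visited ones.
* **Clamp placement** — inside the initial sweep and on the combined
  estimate each cycle, but *not* on the residual increment. Clamping the
  increment would forbid downward corrections of overshoot; clamping the
  combined estimate keeps iterates feasible while the noise-free case
  stays exact after a single cycle.
* **Iteration cap** — 100 cycles by default. Observed real datasets
  converge in on the order of ten cycles; the cap is a safety net, not a
  tuning parameter, and the strict-decrease rule normally stops the loop
  much earlier.
* **Missing peaks** — unobserved isotopologues enter the dense array as
  zeros, and the array always spans $0..N_e$ per dimension even when
  observations stop earlier. A truncated array would leak intensity out of
  the index space and break conservation.
* **Units** — intensities are processed unnormalized; normalization is the
  caller's choice, and correction commutes with positive scaling.

On one-dimensional data all loops collapse to plain integer ranges and a
specialized fast path is used; it produces bit-identical results to the
generic n-dimensional path (asserted in the tests).

## Natural-abundance constants

Defaults: $p(^{13}C) = 0.01109$, $p(^{15}N) = 0.0037$, $p(^{2}H) =
0.00015$ (dimensionless fractions). These are the constants under which
the package's reference validation values were produced; they are close
to, but not identical with, IUPAC representative values (e.g. 0.0107 for
13C), and measured abundances genuinely vary by source material. They are
therefore configuration, not constants: every entry point accepts
overrides (`abundances =` argument, `abundances:` config key), and the
table cache keys on the abundance so overridden and default tables never
mix. Isotopes beyond the built-in three can be declared with
`isotopeSpec()` (element inferred from labels like `"18O"`), subject to
one assumption: each tracer element has a single relevant heavy isotope
(elements such as Se with several abundant heavy isotopes are out of
scope, as is correction for tracer enrichment below 100%).

## Binomial numerics

$P(n, k)$ mixes a potentially astronomical binomial coefficient with
powers that underflow; at $n = 500$, $p = 0.00015$ the coefficient reaches
$10^{149}$ while $p^k$ alone underflows double precision for $k \gtrsim
280$. The production evaluation (`"org"`) therefore interleaves one
coefficient factor $(n-k+j)/j$ with one $p$ and one $(1-p)$ factor per
loop step, appending leftover $(1-p)$ powers, so intermediates stay near
the final magnitude. Four numerically independent implementations guard
it: exact arbitrary-precision integer factorials (`"choose"`), an exact
arbitrary-precision multiplicative coefficient (`"comb"`), a log-gamma
evaluation (`"comb2"`), and a base-10 logarithmic variant of the
interleaving (`"logReal"`). The two exact-integer routes use a small
base-$2^{32}$ big-integer implemented in the package's C++ layer (R ships
no arbitrary-precision integer type) and agree with each other exactly;
the acceptance suite sweeps all five methods over every $0 \le k \le n
\le 500$ at deuterium abundance and checks the maximum pairwise absolute
difference (measured at $5.6 \times 10^{-14}$, dominated by the log-gamma
route as expected — `lgamma` near 2600 carries a few $10^{-13}$ of
absolute log error, i.e. a few $10^{-14}$ absolute on values of order
$10^{-1}$).

P tables are built with `"org"`; the alternatives exist to *cross-check*
it, and `pTermMatrix()` exposes them for benchmarking.

## Quality control

Three row-level checks annotate (never alter) the data: heavy-label counts
above the formula's atom bound (`count_exceeds_formula`), repeated
label-count tuples within one dataset (`duplicate_isotopologue`; the first
row in file order wins and enters the array), and unparseable rows
(`malformed_row`; echoed to the output, excluded from the array). Flagged
rows receive no corrected value.

Optionally, the re-contaminated reconstruction is scanned for peaks
predicted at or above a threshold — a percentage of the minimum, maximum
or average observed peak intensity, per dataset or per collection — but
absent from the input (`predicted_not_observed`). Statistics use observed
nonzero intensities only, since densification zeros are artifacts, not
peaks. Many such rows across a collection usually mean upstream peak
identification was too strict. The boundary is inclusive (`>=`), and
observed peaks are never re-added.

## The synthetic generator

`makeCollectionFile()` emulates the structure of a real peak collection:
random small-molecule formulas over C/H/N/O/P, sparse clean isotopologue
distributions (default 0.3 nonzero fraction, log-normal intensities with
`sdlog = 1.5` — long-tailed, like real peak intensities), forward NA
contamination, total intensities spanning $10^4$-$10^7$ (typical FT-MS
arbitrary units), and optional injected duplicates and overflow counts for
exercising quality control. Everything is a pure function of the seed,
down to the file bytes.

What it deliberately does *not* emulate: m/z values and mass accuracy,
detector noise, peak-overlap at finite resolution, tracer impurity, and
correlated replicate structure. Passing the round-trip suites on this
generator therefore demonstrates the *algebraic* correctness of the
correction (exact inversion, conservation, clamping behavior, cache and
scheduling transparency) — not robustness to measurement noise beyond the
clamped refinement's design, nor anything about misidentified peaks.

Two fixed fixtures, `simulatedCarbonVector()` and
`simulatedNitrogenVector()`, reproduce the reference 9-carbon and
6-nitrogen validation distributions; their outer product
(`outerDataset()`) is the standard construction of a two-tracer validation
dataset from single-tracer ones, valid because the kernel factorizes over
dimensions.

## Validation and problem sizes

The test suite validates, among others: the published single-label
UDP-GlcNAc correction (12 corrected values reproduced within 0.02,
including an exact clamp to zero); the forward-contaminated simulated
rows at 4 printed decimals; the two-tracer outer-product round trip
(maximum elementwise error below $10^{-16}$ on unit-normalized data);
agreement of the iterative correction with a brute-force dense triangular
solve built independently from `choose()` (within $10^{-9}$ relative on
shapes up to $N = 12$ in 1-D and $(4,5)$ in 2-D, where nothing clamps);
and seeded recovery of random clean arrays after contamination (within
$10^{-8}$ relative, up to three dimensions with per-dimension maxima up to
9). Collection-scale properties (cache transparency, order independence,
QC flags) run on generated files of 4-10 molecules; these sizes exercise
every code path while keeping the suite fast, and nothing in the algorithm
is size-dependent beyond run time, which grows with the square of the
per-molecule cell count.

## Known limitations

* At most three simultaneous tracers, one heavy isotope per element.
* No handling of resolution-limited peak overlap, ionization isotope
  effects, or tracer enrichment below 100%.
* Peak identification is strictly upstream: rows arrive with formulas and
  label counts already assigned.
* The clamped refinement returns the best feasible iterate under the
  absolute-residual metric; with heavily corrupted inputs (large negative
  implied intensities) the result is the closest nonnegative explanation,
  not a noise model.
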