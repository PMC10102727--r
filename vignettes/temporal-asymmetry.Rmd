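---
title: "Measuring the arrow of time in parcellated brain signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the arrow of time in parcellated brain signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainrev)
```

## The model and its assumptions

A stationary stochastic process satisfies detailed balance exactly when its
finite-dimensional distributions are invariant under time reversal. `brainrev`
quantifies departures from that symmetry without fitting a generative model:
it compares the lag-`T` dependence structure of the observed multivariate
signal with that of its time-reversed copy.

For regions `i, j` of an `N x L` series, the forward and reversal
functional-shift (FS) matrices hold the Gaussian mutual information
`-1/2 log(1 - r^2)` of the lag-`T` Pearson correlations of the original and
flipped signals. Their elementwise squared difference is the reversibility
matrix, and its mean over all `N^2` entries is the global irreversibility
`I`. For a process in detailed balance the two FS matrices estimate the same
quantity and `I` shrinks to zero as `L` grows; directed temporal dependence
(region `i` driving region `j` at lag `T`) inflates the forward entry
relative to the reversed one and `I` stays bounded away from zero.

The statistic is model-free but not assumption-free. It sees only
second-order, lag-`T` structure: a process that is irreversible purely in its
higher moments, or only at other lags, is invisible to it. The mutual
information transform assumes the Gaussian correlation–MI relation, which for
fMRI BOLD (approximately Gaussian after preprocessing) is a monotone
re-weighting that emphasizes strong correlations.

There is also a pairwise variant, `pairwise_irreversibility()`, which is the
absolute difference of the *signed* forward and reversed correlations
(no MI transform) — the two coexist deliberately: the scalar variant is the
pedagogical two-signal statistic, the matrix path is what the pipeline
aggregates.

## Estimator choice and an exact symmetry

The lag-`T` correlation is estimated on the `L - T` overlapping pairs
`(x(t), y(t + T))`. Two normalizations are offered:

* `estimator = "segment_normalized"` (default): means and standard deviations
  are computed on the two overlapping segments — the ordinary sample Pearson
  correlation of the lagged pairs.
* `estimator = "full_window"`: means and standard deviations from the whole
  window. It differs by edge terms of order `1/L`.

Under the segment-normalized estimator an algebraic identity holds: reversing
both series and shifting enumerates exactly the same pairs with the roles of
the two series exchanged, so `FS_reversal` equals the transpose of
`FS_forward` *exactly*, and the reversibility matrix is symmetric with a zero
diagonal. The package still always computes the reversal from the explicitly
flipped signal — the identity is used as a test oracle (it must hold to
1e-10), not as a shortcut, and under `full_window` it holds only
approximately. A consequence worth stating: with the default estimator the
information content of the whole matrix is carried by the asymmetry of
`FS_forward` alone.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `shift` (`T`) | 1 | timepoints | autocorrelation of ~2 s-TR BOLD has decayed sufficiently at one sample; larger `T` probes slower timescales |
| `window_length` (`W`) | 90 | timepoints | long enough for a stable `N x N` correlation estimate, short enough to resolve non-stationarity |
| `overlap` | 85 | timepoints | dense 5-point stride gives 21 windows at `L = 195`, 17 at `L = 175` |
| `alpha` | 0.01 | — | binarization threshold for network significance triangles |
| `exclude_diagonal` | `FALSE` | — | the norm is defined over all `N^2` elements; the diagonal is ~0 either way |
| `include_final_window` | `FALSE` | — | see below |

**Window-count convention.** `make_windows()` counts
`n = floor((L - W) / step)` windows, *not* the conventional `+ 1`: the final
admissible window is dropped. This is forced jointly by the two reference
counts (195 → 21 and 175 → 17 at `W = 90`, step 5), which are inconsistent
with the `+ 1` convention. `include_final_window = TRUE` restores it.

**Deviation reversibility** uses the sample (n−1) standard deviation across
windows; the choice of denominator is a convention the source analysis does
not pin down.

**Degenerate inputs.** A zero-variance segment makes the correlation
undefined; the default policy is an error naming the offending region,
switchable to "return 0 with a warning" (`zero_variance_policy = "zero"`).
`r^2` is clipped at `1 - 1e-12` before the log, so perfectly correlated pairs
give ~13.8 nats instead of infinity.

## The synthetic cohort: what it emulates, what it does not

No patient data ship with the package; the generator provides a cohort with
the *statistical structure* the analysis is designed to detect. Each subject
is a lag-1 vector autoregression `x(t) = g(t) W x(t-1) + eps(t)`. This family
is chosen because it brackets the construct exactly: with symmetric coupling
(`kappa = 0`) the stationary Gaussian process satisfies detailed balance and
is reversible, while directed coupling (`kappa -> 1`) breaks it. `W` is drawn
by blending a random matrix with its symmetrization
(`asymmetric_coupling()`), rescaled to spectral radius `coupling_scale`.

Defaults (chosen once; the group sizes, lengths and kappa grading reproduce
the study design being emulated):

* groups CNT/MCS/UWS with n = 13/31/24, lengths 195/175/175 timepoints,
  `kappa` = 0.8/0.4/0.1;
* 100 regions, `coupling_scale = 0.5` (comfortably stationary, realistic
  moderate lag-1 dependence), unit innovation noise — Pearson-based
  statistics are scale-free, so the noise scale is a pure convention;
* `nonstationarity` = 0.6/0.3/0.15: a sinusoidal envelope `g(t)` on the
  coupling, one full period per series, of that relative amplitude. It
  produces window-to-window fluctuation of `I` (what deviation reversibility
  measures) while each 90-point window stays approximately stationary. The
  grading mirrors the qualitative finding that non-stationarity of the
  asymmetry also decreases with the level of consciousness. Stationarity at
  the envelope peak requires `coupling_scale * (1 + nonstationarity) < 1`,
  which is enforced.
* burn-in of `10 * n_regions` samples removes initial-condition transients
  cheaply.

Per-subject seeds are a stated polynomial hash of `(base_seed, group label,
subject index)` so cohorts are reproducible independent of iteration order.

What the generator does **not** emulate: haemodynamics (no HRF convolution),
empirical structural connectivity, spatial autocorrelation of parcels,
scanner noise, motion artefacts, or between-subject anatomical variability. A
green ordering-recovery test therefore establishes that the pipeline detects
graded coupling asymmetry at realistic n, L and N under Gaussian VAR
dynamics — not that it would recover the clinical effect sizes, which depend
on data this package does not have.

## Statistics

Group comparisons are two-sided Mann–Whitney rank-sum tests: exact null
distribution when both groups have ≤ 8 subjects and no ties, otherwise a
normal approximation with midranks, tie-corrected variance and continuity
correction. FDR correction is Benjamini–Hochberg step-up.

The source analysis never states its FDR families, so the package computes
the two readings its printed outputs support and labels both: at the global
level the family is the 3 pairwise tests of one measure; at the network level
both the 7 within-network tests (`p_fdr_within`, matching per-network summary
listings) and all 28 network pairs (`p_fdr_all`, used for the triangular
significance matrices) are reported. The binarization threshold defaults to
`alpha = 0.01` (the text's value; the corresponding figure caption says
0.001 — the discrepancy is documented, and `alpha` is a flag). Outliers are
never removed for statistics.

## Numerical choices and degenerate cases

* Correlations are clamped to `[-1, 1]` against one-ulp excursions from the
  BLAS `tcrossprod` path before the MI transform.
* `bh_adjust` enforces `adjusted >= raw` exactly (the step-up product can
  undershoot by one ulp at `k = m`).
* A 1-region series has `I = 0` by construction (only the zero diagonal).
* Windows are computed on raw series; Pearson correlation inside each window
  is invariant to per-region affine rescaling, so no global z-scoring is
  applied.

## Known limitations

* Sensitivity is limited to lag-`T` second-order structure at a single `T`.
* The two acquisition-length conventions (195 vs 175 timepoints) yield 21 vs
  17 windows; subjects are compared on per-window summaries, not matched
  window counts.
* The network decomposition uses blocks of the full-series FS matrices
  (equivalently, the statistic on node subsets — each FS entry depends only
  on its own row pair); parcels outside the seven cortical networks are out
  of scope.
* The synthetic null is the package's choice of generative family; the
  analysis it emulates defines none.
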