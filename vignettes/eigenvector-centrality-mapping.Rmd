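---
title: "Eigenvector centrality mapping: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigenvector centrality mapping: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Resting-state functional imaging produces, for each voxel $i$ inside a mask
of $n$ voxels, a time series $x_i(t)$ of length $T$. ecmap summarizes the
network structure of these data without an activation model: it forms a
symmetric, non-negative *similarity matrix* $A$ over all voxel pairs and
assigns each voxel a centrality score.

**Eigenvector centrality (EC).** The score of voxel $i$ is the $i$-th entry
of the unit-norm eigenvector belonging to the largest eigenvalue of $A$:
$A x = \lambda_1 x$. A voxel scores high when it is strongly similar to
voxels that are themselves central — the same recursion behind PageRank.
For this to be well defined, $A$ must be non-negative and irreducible: the
Perron–Frobenius theorem then guarantees a unique largest eigenvalue with a
strictly positive eigenvector. This is why similarity metrics are
constrained to $[0,1]$; symmetric matrices with negative entries can have
tied largest eigenvalues and no unique first eigenvector.

**Degree centrality** is the off-diagonal row sum $d_i = \sum_{j \ne i}
a_{ij}$. Degree and EC react differently to global effects: multiplying
every similarity by $s$ scales degree by $s$ but leaves the eigenvector
unchanged. A global rise in correlations (e.g. physiological) therefore
inflates degree maps everywhere while EC maps highlight only relative
reorganization. This scale dichotomy is asserted exactly in the test suite.

**Betweenness centrality** is the normalized shortest-path load
$c_b(v) = \frac{1}{(n-1)(n-2)/2} \sum_{s \ne v \ne t} \sigma_{st}(v) /
\sigma_{st}$, computed with Brandes' accumulation (BFS for unit edges,
Dijkstra for weighted ones). It requires thresholding the similarities into
a graph and is computationally infeasible at voxel scale, so node counts
above 5,000 are refused without `force = TRUE`.

## Similarity metrics

**Scaled correlation.** Pearson correlation $r_{ij}$ mapped through
$r \mapsto (r+1)/2$, the unique increasing affine map from $[-1,1]$ onto
$[0,1]$. An `absolute` mode ($|r|$) is provided for the view that strong
anti-correlation is strong coupling. The scaled form admits an exact
factorization $A = (ZZ^\top + \mathbf{1}\mathbf{1}^\top)/2$ with
$z_i = (x_i - \bar x_i)/\lVert x_i - \bar x_i \rVert$, so $Ax$ costs
$O(nT)$ and whole-mask EC never materializes the $n \times n$ matrix (a
52,000-voxel mask would otherwise need ~20 GB in double precision).

**Spectral coherence.** For zero-mean series, the lag-window estimate of
the cross-spectral density at angular frequency $\omega = 2\pi f\,TR$
(radians per sample) is
$f_{xy}(\omega) = \sum_{k=-M}^{M} w_{|k|}\, c_{xy}(k)\, e^{i\omega k}$,
with $c_{xy}(k)$ the sample cross-covariance and $w_k$ a Tukey
($\tfrac12(1+\cos \pi k/M)$) or Parzen window. Its real part is the
cospectrum $c(\omega)$, its imaginary part the quadrature spectrum
$q(\omega)$, and the similarity is the magnitude-squared coherence
$C_{xy}(\omega) = (c^2 + q^2)/(f_{xx} f_{yy}) \in [0,1]$. Phase coherence
is $\varphi = \operatorname{atan2}(q, c)$; with the $e^{+i\omega k}$ sign
convention used here, a series that lags another by $\tau$ samples has
phase $+\omega\tau$. Coherence-based EC is frequency-resolved: planting
signals in disjoint bands moves centrality between voxel groups as the
evaluation frequency changes, and the acceptance suite verifies this on
ground-truth data.

Numerical notes:

* The squared form is used because it is the standard magnitude-squared
  coherence and is guaranteed into $[0,1]$ by Cauchy–Schwarz; values are
  clipped against rounding.
* The Tukey lag window is *not* positive semidefinite: near a strong
  narrowband signal the off-band auto-spectral estimate can be non-positive,
  which ecmap treats as a hard error rather than silently producing a
  coherence outside $[0,1]$.
* The default lag count is $M = \operatorname{round}(2\sqrt T)$ clamped to
  $[T/10, T/3]$, the classical rule of thumb; it is configurable
  (`--lags`).
* The full coherence matrix is assembled from one $n \times n$ lag matrix
  per lag $k \le M$ via BLAS, mathematically identical to the per-pair
  estimator (tested to $10^{-12}$).

## Power iteration

EC is computed by power iteration with the deterministic uniform start
$\mathbf{1}/\sqrt n$ — strictly positive, hence never orthogonal to the
Perron vector, so no RNG is involved. Convergence is declared when the
max-norm change of the normalized iterate falls below `tol` (default
$10^{-9}$, `max_iter` 1000); the eigenvalue is the Rayleigh quotient at
convergence. Irreducibility (every row has a non-zero off-diagonal entry)
is checked before iterating. The diagonal of $A$ is kept as computed:
$A + cI$ has the same eigenvectors, so the choice is provably immaterial,
and the tests assert it.

## Group statistics

Per-subject EC maps are not Gaussian across voxels, so before parametric
tests each map is **Gaussianized**: values are ranked (ties averaged), rank
$r$ is mapped through $\Phi^{-1}((r-0.5)/n)$, and the result is rescaled to
the input's mean and standard deviation. The transform is strictly rank
preserving and idempotent up to that rescaling.

Conditions are compared with a voxel-wise **paired t-map** on differences
($\mathrm{df} = $ subjects $- 1$), converted to z-scores by the probability
integral transform, and thresholded at $z = 2.33$. Suprathreshold
**clusters** (26-connectivity by default; 6 and 18 available because
volumetric conventions differ between packages) are tested against a
**Monte-Carlo null**: Gaussian white noise on the grid, smoothed with a
Gaussian kernel of stated FWHM, restandardized inside the mask,
thresholded, and the maximum cluster size and maximum cluster peak
recorded per iteration. A cluster is significant at level $\alpha$ if its
size exceeds the $(1-\alpha/2)$ null quantile of max sizes **or** its peak
exceeds the $(1-\alpha/2)$ null quantile of max peaks — a Bonferroni split
that operationalizes the qualitative trade-off that a large cluster with a
moderate peak, or a small cluster with a very high peak, can both be
significant. A joint (size, peak) exceedance rule would be a reasonable
alternative; the marginal-OR rule is simpler to report and is the one
whose calibration is tested. Positive and negative tails are corrected
independently, each at $\alpha$, matching the dual-direction (red/blue)
reporting convention, so the familywise rate over both tails is bounded by
$2\alpha$.

**Choosing the null's smoothness.** The Monte-Carlo cluster method takes
the spatial smoothness of the statistic maps as an input; with real data
the preprocessing kernel (e.g. FWHM 8 mm) is the usual choice, and ecmap
keeps the FWHM strictly user-supplied (residual-based estimation is out of
scope). Cluster extent under the null is governed by the correlation area —
the integral of the spatial autocorrelation function — so when the ACF is
known or measurable, the equivalent Gaussian FWHM should be matched on
correlation area rather than on the lag-1 autocorrelation alone. The
acceptance tests do exactly this for the synthetic world: the synthetic EC
difference maps have intrinsic module-block correlation (ACF ≈ 0.31, 0.25,
0.20, 0.21 at voxel lags 1–4), and an unsmoothed null is demonstrably
anti-conservative there, while the area-matched null (≈ 5.8 mm at 3 mm
voxels) calibrates the familywise false-positive rate into the expected
band. With real data whose ACF is unknown, the supplied FWHM inherits this
caveat: non-Gaussian long-range correlation makes any single Gaussian FWHM
an approximation.

## The synthetic world

`synth_config()` defaults state the emulated regime once: a 12×12×8 grid of
3 mm voxels with a centered 10×10×5 block mask (500 voxels), T = 180
volumes at TR = 2.3 s (≈ 7 min of scanning), 4 spatially contiguous modules
of equal size, 5% hub voxels, unit-variance band-limited latents in
0.01–0.1 Hz, and signal amplitude = noise SD = 1 (SNR 1). Each module has
one latent Gaussian signal built by boxcar band-masking white noise in the
frequency domain (exactly reproducible per seed); module voxels carry
their module's latent, hub voxels the mean of all latents, both plus white
noise. Hubs therefore correlate moderately with *every* module while module
voxels correlate strongly only within their own — the configuration in
which eigenvector centrality, which weights neighbors by their own
centrality, favors hubs. `two_condition_cohort()` adds a paired condition
in which the coupling of a chosen voxel set is multiplied by
$1 + \text{effect\_size}$.

What a green test does establish: the estimators implement their
definitions (verified against independent dense-eigendecomposition,
brute-force-path, and windowed-sum oracles), the factored and dense paths
agree, hubs and band-specific modules are recovered from data with known
ground truth, and the cluster correction is calibrated on this world. What
it does not establish: behavior under hemodynamic response variation,
physiological (cardiac/respiratory) noise, motion artifacts, registration
error, or non-stationary coupling — none of which the generator emulates —
nor any neuroscientific claim about real resting-state data.

## Degenerate inputs and tie-breaking

* Voxels with zero-variance or non-finite series are removed from the mask
  at load time with a warning; correlation is undefined for them.
* A reducible similarity matrix (a row with no non-zero off-diagonal) is a
  precondition error naming the offending rows.
* Zero-variance paired differences produce a 0 statistic and a warning
  rather than NaN.
* Equal shortest-path lengths in weighted betweenness are merged within an
  absolute tolerance of $10^{-12}$.
* Monte-Carlo quantiles use the type-1 (inverse-ECDF) definition and a
  strictly-greater rule, the conservative choice for discrete size
  distributions; `apply_cluster_correction()` refuses nulls too small to
  resolve the requested quantile.
* The volume floor in `filter_report()` is strictly greater-than, matching
  a "regions larger than x mm³" reporting convention.

## Known limitations

* Betweenness is exact but quadratic-to-cubic; it exists for small ROI
  analyses and validation, not whole-brain maps.
* Dense coherence matrices are materialized ($8n^2$ bytes); the factored
  matrix-free path exists only for scaled correlation, whose algebraic
  structure makes it possible.
* The NIfTI-1 reader covers the single-file variant and the five scalar
  types common in practice; two-file pairs, extensions, and exotic dtypes
  are rejected loudly.
* Spaces (MNI, Talairach, …) are treated as opaque metadata carried in the
  affine; no registration or conversion is attempted.
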