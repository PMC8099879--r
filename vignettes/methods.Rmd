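---
title: "Models and methods in smlmtc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in smlmtc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlmtc)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the choices made where
the design was genuinely open. Every number shown here is computed by the
code below or by the test suite; nothing is quoted from elsewhere.

## 1. The sCMOS localization model

A raw frame is modelled per pixel as

$$\mathrm{ADU} = \mathrm{offset} + \mathrm{gain}\cdot
\mathrm{Poisson}(\mu) + \mathcal N(0, \sigma_r),$$

where $\mu$ is the expected photoelectron count: a uniform background plus
each emitter's photon flux integrated over the pixel under a 2D Gaussian
PSF. Offset, gain and read-noise variance are per-pixel calibration maps —
the defining feature of sCMOS sensors, whose pixels are *not*
interchangeable.

`localize_stack()` detects candidates on a band-passed frame (raw minus an
inverse-variance-weighted box filter of width 4× the PSF FWHM; threshold 4×
the robust noise sd — a default chosen where the source method states none, config-exposed) and fits each
7×7 window by maximum likelihood. The Poisson-shot ⊛ Gaussian-read
likelihood is handled with the standard variance-offset formulation: data
and model are shifted by $v_i = \sigma_{r,i}^2/g_i^2$ photoelectrons and
treated as Poisson, which matches the exact convolution to excellent
accuracy at realistic read noise (≲ 2 e⁻) and makes the Fisher information,
hence the Cramér–Rao lower bound (CRLB), analytic. Free parameters are
position, photon count and background; the PSF sd is fixed from the
configured FWHM because it is a property of the instrument, not of one
emitter. Windows whose deviance against the saturated model exceeds the
0.9999 χ² quantile are dropped as crowded or misfit — a deliberate
single-emitter-plus-rejection reduction of multi-emitter fitting, sufficient
at desk scale and stated as such.

The acceptance suite verifies estimator efficiency: over 500 replicates of a
5000-photon emitter, the empirical RMSE sits within a few percent of the
mean CRLB (the test allows 15%).

**Blink merging.** Chains of localizations in consecutive frames within
2.5× the localization precision of the running merged position collapse to
one record at the inverse-CRLB-variance-weighted mean; the merged variance
is $1/\sum_i 1/\mathrm{var}_i$, photons are summed, and the chain length is
kept as `multiplicity`. The gate compares each candidate against the
*running weighted mean* using the *candidate's own* precision — the source
method does not say whose precision gates the chain, and this choice makes
the gate progressively harder to fool as a chain accumulates evidence.
Merging is a single greedy forward pass; its idempotence is a property test
on realistic simulated blinking, not a theorem for adversarial inputs.

**Precision QC.** The per-localization precision distribution is fitted by
a maximum-likelihood skew-normal (density
$\tfrac{2}{\omega}\phi(z)\Phi(\alpha z)$); the fit is reported for quality
control only — the source does not state any downstream use, so none is
implemented.

## 2. Channel registration

Chromatic aberration is corrected by mapping each channel onto the
reference channel with a least-squares second-degree polynomial over the
monomials $\{1, x, y, x^2, xy, y^2\}$, fitted to fiducial bead
localizations. Beads are paired by mutual nearest neighbour within 500 nm
(beads are sparse by design; ambiguous pairs are dropped), coordinates are
centred and scaled before the solve for conditioning, and coefficients are
reported back in nm units. A planted noiseless quadratic warp on 50 beads is
recovered with < 0.1 nm residual; the quadratic residual is never worse than
the nested affine fit.

## 3. Pair correlation and the two-Gaussian focus model

`auto_correlation()` uses the *un-centred* normalization
$g(r) = \langle\rho\rho\rangle/\langle\rho\rangle^2$, whose CSR baseline is
1. The printed definition with centred fluctuations ($\delta\rho$) has
baseline 0, yet the focus model carries an explicit "+1"; the un-centred
estimator is the one consistent with that fit model, and this choice is the
package's resolution of that ambiguity. Edge handling: reference points are
restricted to the ROI eroded by `r_max`, so annulus areas need no boundary
correction; densities come from the full ROI. Fit weights are
$1/\sqrt{\mathrm{pairs}+1}$ and the first bin (self-pair and merge
artefacts) is excluded.

The model

$$g(r) = \frac{1}{4\pi\sigma^2\langle\rho\rangle}
e^{-r^2/4\sigma^2} + A\,e^{-r^2/4(\sigma^2+r_\mathrm{app}^2)} + 1$$

fixes $\langle\rho\rangle$ to the observed count/area — otherwise the first
term's amplitude is degenerate with $A$. The first term is the
autocorrelation of repeated localizations of one molecule (residual
blinking); the second is the autocorrelation of a Gaussian focus of sd
$r_\mathrm{app}$ blurred by the precision $\sigma$. The molecular content
$\langle N\rangle = 2\pi\langle\rho\rangle A r_\mathrm{app}^2$ holds as an
exact identity for every returned fit.

**Content convention.** For foci with Poisson-distributed molecule number
$\lambda$ and residual blinking multiplicity $m$, the pair-count algebra
gives $\langle N\rangle = \lambda\bar m/2$: the method reports half the mean
localization count per focus. `generate_clustered_field()` therefore takes
its `content` argument *in the measured convention* and plants
$2\cdot\mathrm{content}/(1+\mu_\mathrm{blink})$ molecules per focus. Its
default $\mu_\mathrm{blink} = 0.62$ solves $E[m(m-1)] = E[m]$ for
$m = 1 + \mathrm{Poisson}(\mu)$, which makes the planted self-pair
statistics exactly consistent with the model's single-molecule term — so
the fitted $\sigma$ is meaningful rather than a misfit artefact.

```{r ac-demo}
f <- generate_clustered_field(n_clusters = 150, content = 20, r_app = 50,
                              precision = 10, seed = 5)
fit_ac_model(auto_correlation(f, 10, 500), field_density(f))
```

## 4. Triple correlation

The TC statistic averages the product of channel-2 and channel-3 density
fluctuations at two displacements from every channel-1 coordinate,
normalized by the three global densities. Density fluctuations at a
displacement are estimated by sector-annulus counting with exact bin-area
normalization ($\mathrm{area} = \tfrac{r_\mathrm{out}^2 -
r_\mathrm{in}^2}{2}\,\Delta\theta$, $\Delta\theta = 2\pi/n_\theta$) — a
direct coordinate-visiting estimator with no kernel bandwidth to choose.
Defaults: `r_max` 300 nm (the replisome length scale), `bin_width` 20 nm
(about twice the localization precision), `n_theta` 18 (20° sectors).

**The r₃ transform.** Because triplets are randomly oriented, the angular
average collapses $f(r_1, r_2, \Delta\theta)$ onto triangle geometries via
$r_3^2 = r_1^2 + r_2^2 + 2 r_1 r_2\cos\Delta\theta$. The law of cosines for
the third side carries a minus sign; the plus-sign form is equivalent under
the convention that $\Delta\theta$ is the *supplement* of the angle between
the two displacement vectors, and that is how the collapse is implemented —
`tc_r3(100, 100, 120°) = 100` (an equilateral triangle) and
`tc_r3(100, 100, 0) = 200` (collinear), while planted equilateral triplets
peak at (100, 100, 100) on the collapsed grid, as they must.

**Significance.** Nulls resample channel 3 — the probe species — as CSR at
matched density, preserving the channel-1/2 structure; this is the minimal
exchangeable null (the original calibration procedure is not public, so the
package defines its own and says so). Each cell gets a z-score against the
null mean and sd. Because the search spans on the order of 10³ grid cells, a
per-cell threshold alone would produce several false cells per scene;
`find_tc_triplets()` therefore also requires a candidate's amplitude to
clear the Gumbel quantile fitted (by moments) to the nulls' scene-wide
maxima at tail probability $\Phi(-z_\mathrm{threshold})$ — the
extreme-value calibration appropriate for a whole-grid maximum. A normal
mean + 3sd gate was considered and rejected: maxima are Gumbel, not normal,
distributed, and the normal gate measurably under-controls the per-scene
false-positive rate. With the Gumbel gate, ≤ 5% (measured ~0–1%) of pure-CSR
scenes yield any significant triplet, while planted peaks sit several-fold
above the gate.

Cells must additionally be backed by at least `min_support = 3` observed
triple coincidences (echoing the DBSCAN minimum-point convention): a
*recurrent* pattern is one seen repeatedly, and in sparse scenes a single
chance coincidence can otherwise produce an arbitrarily large normalized
amplitude in a small-area cell.

One triplet is reported per connected above-threshold region — the
amplitude peak among the region's local maxima, ties broken by larger z and
then smaller $r_1+r_2+r_3$.

**Conditional density.** $C_3 = \langle\delta\rho_1\delta\rho_2\delta\rho_3
\rangle / \langle\delta\rho_1\delta\rho_2\rangle$ at the triplet's cells
estimates the local density of the third species at its vertex given a
correlated pair. Uniform channel-3 background cancels by construction
(δρ subtracts the mean), and doubling channel-3 site occupancy doubles
$C_3$ — both verified by simulation. The denominator must be positive
(there is no conditional density without pair support); otherwise the call
errors.

**Oracle.** `brute_force_triplets()` counts point triplets matching a
geometry within a tolerance in $O(N_1 N_2 N_3)$ via masked matrix products.
The acceptance suite checks two-way concordance between TC-significant
cells and brute-force excess over a CSR Monte-Carlo expectation, as a
concordance rate: both are finite-sample statistics, and the raw count is
deliberately sensitive to *second-order* (pair-driven) structure that the
third-order statistic is designed to ignore.

**Frequency.** The per-scene frequency of a significant pattern is its
brute-force instance count (tolerance one grid bin) divided by a
co-analyzed reference-pattern count. The normalizer is a caller-supplied
choice because the quantity is only meaningful relative to a stated
reference population.

## 5. DBSCAN colocalization

Foci are DBSCAN clusters with eps 15 nm and at least 3 points — printed
constants, not tunables. "Edge-to-edge" NND is the minimum distance between
the convex-hull boundary points of two clusters (the source does not define
the edge; the hull is the natural convex proxy, and 1–2-point clusters fall
back to the points themselves), zero for overlapping hulls; ≤ 5 nm defines
a colocalized pair, and the fraction divides colocalized pairs by the
queried species' cluster count. The Monte-Carlo baseline rigidly translates
and rotates every cluster of the second species to uniform positions inside
the ROI (rejection-sampled; the source is silent on boundary handling) and
recomputes the fraction; only one channel is randomized, keeping the other
conditioned as observed. Pair pruning uses a centroid-distance lower bound,
so results are exact but scale to Monte-Carlo use.

## 6. Two-state smFRET analysis

Efficiency is $E = a/(a+d)$ clipped to [0, 1]; frames with total intensity
below 10% of the trajectory median are masked as dark/bleached (a default
chosen where the source method is silent — the generator does not simulate
bleaching, so this guard rarely triggers on synthetic data).

The pooled histogram (50 bins on [0, 1]) is fitted with two independent
Gaussian curves; the unfolded fraction is the low-E component's area share.
When the two components collapse onto one mode (means closer than the mean
of their sds, or one area vanishing), the mass is attributed to the side of
the efficiency range its pooled mean falls on and the result is flagged —
component areas, not a hard cut, are used whenever the components are
distinct.

Idealization replaces a variational-Bayes HMM with a plain two-state
Gaussian-emission HMM trained by Baum–Welch across all trajectories
(initialized from the pooled histogram's modes) with Viterbi paths —
simpler, deterministic given the initialization, and sufficient for
two-state data; non-convergence falls back to midpoint thresholding with a
flag. Dwell times exclude each trajectory's first and last dwell (censored
by the observation window); rates are exponential maximum-likelihood
estimates $k = 1/\bar\tau$ with standard error $k/\sqrt{n}$ from the
information matrix. Sampling at 30 ms makes dwells geometric rather than
exponential; at the rates studied ($k\,\Delta t \approx 0.03$) the induced
bias is ~3%, well inside the 15% recovery tolerance, so no discretization
correction is applied.

```{r fret-demo}
sim <- simulate_fret_trajectories(fret_sim_spec(n_traj = 50, seed = 11))
fit_fret_histogram(sim)
fit_rates(idealize_two_state(sim), 0.03)
```

## 7. The synthetic-data generators

The generators define the study conditions used throughout the tests:

* **Frames**: per-pixel offset 100 ± 2 ADU, gain 2.0 ± 0.05 ADU/e⁻,
  read noise 1.5 e⁻ — typical sCMOS values, config-exposed.
* **Scenes**: a 6 × 6 µm² ROI; planted triplets are placed uniformly with
  uniform orientation in the ROI eroded by the triangle circumradius, so
  ground truth is exact for oracle tests (no boundary-straddling patterns).
  Molecules per site are Poisson (no multiplicity model is given by the
  source; Poisson matches the label-stochasticity assumption implicit in
  correlation analysis); defaults (8 per site, 80% detection, 15 nm site
  scatter, 10 nm localization error, 20 µm⁻² background) are field-typical
  placeholders for sensitivity scans, not estimates of any particular cell.
* **FRET**: 800 frames at 30 ms; folded/unfolded efficiencies 0.70/0.25;
  per-channel Gaussian intensity noise (default sd 7% of the 1000
  photons/frame total, ≈ 0.055 sd in efficiency units by the delta method).

What they do *not* emulate — and what passing tests therefore cannot show —
includes: detector drift, astigmatic/3D PSFs, full blinking photophysics
(only per-frame detection thinning and, for clustered fields, a geometric
relocalization multiplicity), chromatic PSF differences, photobleaching in
FRET trajectories, and any biology (cell-to-cell variability, chromatin
context, real replisome composition). Parameter-recovery results bound
estimator behaviour under the stated noise models only.

## 8. Numerical choices and problem sizes

* Optimizers: L-BFGS-B with analytic gradients for emitter MLE (tolerance
  1e-4 relative, ≤ 100 iterations); Levenberg–Marquardt (minpack.lm) for
  curve fits; EM to 1e-8 relative log-likelihood.
* Degenerate inputs: constant precision vectors, single-state FRET series,
  flat correlation profiles, and zero-variance t-test groups all return
  flagged results or informative errors rather than spurious fits.
* Test problem sizes (the package's own choice of desk scale): ≤ 300
  points/channel for oracle-concordance scenes; 20 CSR replicate scenes for
  type-I control; 150 clusters for focus-model recovery; 500 replicate
  frames for the CRLB check; 200 × 800-frame trajectories for the FRET
  round trip.

## 9. Known limitations

* Multi-emitter windows are rejected, not fitted; dense raw data loses
  recall (documented crowding flag).
* The TC estimator's per-cell null sd from 20 resamples is noisy in sparse
  scenes; the support filter and the Gumbel gate guard reported triplets,
  but per-cell z values for unreported cells should be read with that in
  mind.
* Edge-to-edge distances use hull vertices; for very elongated clusters a
  segment-to-segment distance would be slightly tighter.
* The exponential dwell fit ignores frame discretization (~3% at the
  default rates) and missed sub-frame excursions; both matter only when
  $k\,\Delta t$ approaches 1.
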