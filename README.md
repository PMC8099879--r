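# smlmtc

Quantitative analysis of multi-colour single-molecule localization
microscopy (SMLM) point patterns and two-state single-molecule FRET
trajectories, built for studies of replication-fork-associated DNA
structures (e.g. G-quadruplexes forming at replisomes) but applicable to any
three-species nuclear point pattern.

## Who it is for

Researchers who have (a) raw sCMOS camera stacks or localization tables for
up to three colour channels of one nucleus, and/or (b) donor/acceptor smFRET
intensity trajectories, and want the statistics that connect them: where
molecules sit relative to each other, whether three species recur in a fixed
geometry, and how fast a tagged structure folds and unfolds. A seeded
synthetic-data generator reproduces the statistical structure of all these
inputs with known ground truth, so every estimator in the package is
testable by parameter recovery.

## What it computes

**Localization.** Raw frames are box-filtered (4x the PSF FWHM, each pixel
weighted by its inverse pre-calibrated variance), candidates are local
maxima of the band-passed frame, and each 7x7 window is fit by maximum
likelihood under the per-pixel sCMOS noise model (Poisson shot noise plus
Gaussian read noise). Precision comes from the Cramér–Rao lower bound
(CRLB); localizations in consecutive frames within 2.5x their precision
merge into one record at the inverse-variance-weighted mean. Channels are
registered onto a reference channel with a bead-calibrated second-degree
polynomial warp.

**Pair correlation.** The auto-correlation of one channel,
g(r) = ⟨ρ(R)ρ(R+r)⟩/⟨ρ⟩² (baseline 1), is fitted with the two-Gaussian
focus model

    g(r) = exp(-r²/4σ²) / (4πσ²⟨ρ⟩) + A·exp(-r²/(4(σ² + r_app²))) + 1

whose parameters are the localization precision σ, the clustering amplitude
A and the apparent focus radius r_app; the average molecular content per
focus is ⟨N⟩ = 2π⟨ρ⟩A·r_app². The cross-channel analogue c(r) with a
randomized baseline tests pairwise colocalization.

**Triple correlation (TC).** The third-order statistic

    f(r₁, r₂) = ⟨δρ₁(R) δρ₂(R+r₁) δρ₃(R+r₂)⟩_R / (⟨ρ₁⟩⟨ρ₂⟩⟨ρ₃⟩)

is computed by visiting every channel-1 coordinate, estimating the density
fluctuations of channels 2 and 3 in displaced sector-annulus bins, averaging
over orientation, and collapsing onto a symmetric (r₁, r₂, r₃) grid of
triangle geometries via r₃² = r₁² + r₂² + 2r₁r₂cosΔθ. Significant recurrent
triplets are local maxima whose per-cell z-score against channel-3-resampled
CSR nulls passes a threshold and whose amplitude clears an extreme-value
(Gumbel) calibration of the nulls' scene-wide maxima. The conditional local
density C₃ = ⟨δρ₁δρ₂δρ₃⟩/⟨δρ₁δρ₂⟩ reports how much of the third species sits
at a triplet vertex given a correlated pair. An O(N³) brute-force triplet
counter serves as the independent oracle.

**Cluster colocalization.** DBSCAN foci (eps 15 nm, minimum 3 points),
edge-to-edge nearest-neighbour distances between convex cluster boundaries,
the ≤ 5 nm colocalization rule, and a Monte-Carlo baseline that rigidly
repositions and reorients clusters inside the ROI.

**smFRET kinetics.** Frame efficiency E = a/(a+d); pooled histograms
decomposed into two Gaussian components (unfolded fraction from component
areas); two-state hidden-Markov idealization (Baum–Welch + Viterbi); and
fold/unfold rates from maximum-likelihood exponential fits to censored dwell
times.

## Worked example

```r
library(smlmtc)

# a three-channel nuclear scene with 50 planted equilateral (100 nm) triplets
sc <- generate_triplet_scene(scene_spec(n_triplets = 50, seed = 2))
m  <- compute_tc_map(sc$fields[[1]], sc$fields[[2]], sc$fields[[3]])
nl <- tc_null_maps(sc$fields[[1]], sc$fields[[2]], sc$fields[[3]],
                   n_rand = 20, seed = 3)
find_tc_triplets(m, nl)
#>   r1_nm r2_nm r3_nm        f        z support
#> 1    90   110   110 44.70966 36.93088     231

# focus-model recovery on a clustered field (truth: r_app 50 nm, <N> 20)
f <- generate_clustered_field(n_clusters = 150, content = 20, r_app = 50,
                              precision = 10, seed = 5)
fit_ac_model(auto_correlation(f, 10, 500), field_density(f))
#> <ac_fit> sigma = 10.9 nm, A = 7.34, r_app = 51.4 nm, <N> = 20.1 (rho = 165 /um^2)

# smFRET round trip at 800 frames / 30 ms, k_unfold = k_fold = 1 /s
sim <- simulate_fret_trajectories(fret_sim_spec(n_traj = 200, seed = 11))
fit_fret_histogram(sim)
#> <fret_histogram_fit> folded E = 0.699 (sd 0.053), unfolded E = 0.251 (sd 0.055),
#>   unfolded fraction = 0.496
fit_rates(idealize_two_state(sim), 0.03)
#> <rate_fit> k_unfold = 1.02 +/- 0.022 s^-1 (n=2223), k_fold = 1.02 +/- 0.022 s^-1 (n=2229)
```

The detected triplet grid cell (90, 110, 110) is within one 20-nm bin of the
planted (100, 100, 100) geometry; the focus fit recovers radius and content
within a few percent; the FRET chain returns the planted state efficiencies
and switching rates.

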