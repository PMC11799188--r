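# tcgrad

Low-dimensional axes ("gradients") of thalamocortical connectivity, with
spatially autocorrelated null models.

The human thalamus is classically subdivided into discrete nuclei, but many
of its connectional and microstructural properties vary continuously across
nuclear borders. `tcgrad` characterizes that continuous organization from
seed-voxel-by-cortical-parcel connectivity matrices: it derives thalamic
gradients by diffusion map embedding of a normalized-angle affinity,
relates them to intrathalamic scalar maps (quantitative T1 as a myelin
proxy; a core–matrix cell-type proxy) with variogram-matched surrogate
tests, projects them back onto the cortex, and decodes the resulting
patterns against thalamic nuclei and functional communities. A synthetic
thalamus generator with planted two-axis ground truth makes the whole
pipeline testable without MRI data. The intended users are neuroimaging
researchers working with voxel-to-parcel connectomes, and methodologists
who need a calibrated spatial-autocorrelation-aware correlation test for
volumetric maps.

## The model

Given a thalamocortical matrix `X` (seeds × parcels; streamline counts,
Fisher-z functional connectivity, or across-subject qT1 covariance), the
gradient decomposition is:

1. column-max normalization (counts): `X[, j] <- X[, j] / max(X[, j])`;
2. row-wise percentile threshold (75th structural / 90th functional),
   linear-interpolation percentiles, ties kept;
3. normalized-angle affinity `W_ij = 1 − acos(cos_sim(X_i·, X_j·)) / π`;
4. diffusion map embedding: `W′_ij = W_ij / (d_i^α d_j^α)` with `d = W 1`
   and `α = 0.5`, Markov operator `P = D′⁻¹ W′`, eigenvectors `ψ_k`
   (trivial stationary pair discarded), loadings `ψ_k · λ_k/(1 − λ_k)`,
   explained variance `λ_k / Σ_{m≤K} λ_m`.

Gradient–map associations use `r = Pearson(G, map)` with
`p_SA = (1 + #{|r_null| ≥ |r_obs|}) / (1 + N)` computed against `N`
surrogate maps that preserve the gradient's variogram (Gaussian-kernel
smoothed value permutations, bandwidth/scale/nugget fitted to the
empirical variogram, values rank-mapped onto the original multiset).

## Worked example

Simulate a thalamus with two planted axes, derive structural-connectivity
gradients, test the association with the (also simulated) qT1 map, and
decode the cortical projection of the principal gradient:

```r
library(tcgrad)

cfg  <- synth_config(rng_seed = 0)
geom <- make_geometry(cfg)

sc_norm <- normalize_columns_max(simulate_sc_counts(geom))
grad <- align_sign(connectivity_gradients(sc_norm, threshold_pct = 75),
                   reference = geom$u1)
grad
#> <gradient_set> 600 seeds x 10 components (alpha=0.5)
#>   explained variance: 27.6% 19.8% 16.7% 11.4% 7.5% 5.4% 4.2% 2.7% 2.5% 2.2%

cor(grad$loadings[, 1], geom$u1)   # recovery of the planted principal axis
#> [1] 0.9450193

qt1 <- simulate_qt1(geom)
d   <- pairwise_distances(geom$seeds)
sa_corrected_correlation(grad$loadings[, 1], qt1, d, n_surr = 10000, seed = 7)
#> <sa_test> r = -0.695, p_SA = 0.0443 (10000 variogram-matched surrogates)

decode_by_communities(project_gradient(grad$loadings[, 1], sc_norm),
                      geom$parcels)
#> <group_summary> 7 groups ordered ascending by mean
#>      Limbic         DMN         FPN         VAN         DAN Somatomotor
#> -0.83806507 -0.81937180 -0.54861828  0.01796892  0.57020448  0.84204788
#>      Visual
#>  0.88958093
```

Reading the output: the first two components carry 27.6% and 19.8% of the
retained eigenvalue mass; the principal gradient recovers the planted
medial-to-lateral axis at r = 0.95; the group qT1 map falls along that
axis (r = −0.695, i.e. myelin rises along it), and the association
survives correction for spatial autocorrelation (p_SA = 0.044); projected
onto the cortex, the gradient orders the functional communities from
limbic/default-mode (medial apex) to somatomotor/visual (lateral apex).

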