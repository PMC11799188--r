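#' Configuration for the synthetic thalamus generator
#'
#' Defines the conditions every simulated dataset shares.  Defaults emulate
#' the desk-scale analogue of a single-hemisphere thalamocortical study:
#' `n_seeds = 600` seed voxels (same order of magnitude as a ~1000-voxel
#' thalamic mask), `n_parcels = 100` ipsilateral cortical parcels,
#' `n_subjects = 50`, `n_timepoints = 700` resting-state volumes, 2 mm
#' voxels.  `intensity_scale` is the expected streamline count for a seed
#' sitting exactly on a parcel's anchor (500, the order of counts surviving
#' from a few thousand samples per voxel); `kernel_width` (1.0 latent SD) is
#' the connectivity bandwidth in the latent plane, a few times the anchor
#' grid spacing, so each seed connects strongly to a contiguous
#' neighborhood of parcels while profiles still differentiate clearly
#' across the thalamus.  `axis2_scale` compresses the second axis inside
#' the connectivity kernel (0.6), making the planted principal axis
#' genuinely principal: the two leading eigenvalues separate, the
#' components are identifiable rather than an arbitrary rotation of the
#' latent plane, and the explained-variance spectrum is unequal as in real
#' thalamocortical data.  `noise_sd` is the dimensionless
#' noise-to-signal ratio of every generated map/stack (1.0 gives planted
#' map-axis correlations near 0.7, matching the magnitude of reported
#' empirical associations); `sa_smoothing_mm` (6 mm) is the spatial range of
#' the autocorrelated noise fields.  `coupling_qt1` is negative so qT1
#' decreases (myelin increases) along the principal axis; `coupling_cm`
#' plants the core-matrix proxy on the secondary axis.
#'
#' @param n_seeds,n_parcels,n_subjects,n_timepoints Counts (all `>= 2`;
#'   `n_timepoints >= 50`).
#' @param intensity_scale Expected streamline count at zero latent distance
#'   (`> 0`).
#' @param kernel_width Latent-space connectivity bandwidth (`> 0`).
#' @param axis2_scale Relative weight of the second latent axis in the
#'   connectivity kernel, in `(0, 1]`.
#' @param noise_sd Noise-to-signal ratio of scalar maps, time series and
#'   subject stacks (0 = noiseless).
#' @param sa_smoothing_mm Gaussian smoothing range (mm) of the spatially
#'   autocorrelated noise fields.
#' @param coupling_qt1 Slope (ms per latent SD) of qT1 on the first axis;
#'   negative by default.
#' @param coupling_cm Slope of the core-matrix proxy on the second axis.
#' @param baseline_qt1 Mean thalamic qT1 (ms).
#' @param subject_effect_sd Between-subject qT1 factor scale (ms).
#' @param ar_coef AR(1) coefficient of parcel time series (fixed mild
#'   autocorrelation).
#' @param voxel_size Voxel edge (mm).
#' @param hemisphere Hemisphere label.
#' @param rng_seed Integer seed; every generator is a pure function of
#'   (config, rng_seed).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_seeds = 600, n_parcels = 100,
                         intensity_scale = 500, kernel_width = 1,
                         axis2_scale = 0.6, noise_sd = 1, sa_smoothing_mm = 6,
                         n_subjects = 50, n_timepoints = 700,
                         coupling_qt1 = -40, coupling_cm = 0.8,
                         baseline_qt1 = 1500, subject_effect_sd = 30,
                         ar_coef = 0.3, voxel_size = 2,
                         hemisphere = "L", rng_seed = 0L) {
  counts <- c(n_seeds = n_seeds, n_parcels = n_parcels,
              n_subjects = n_subjects, n_timepoints = n_timepoints)
  if (any(counts < 2)) stop("all counts must be >= 2", call. = FALSE)
  if (kernel_width <= 0) stop("kernel_width must be > 0", call. = FALSE)
  if (axis2_scale <= 0 || axis2_scale > 1)
    stop("axis2_scale must lie in (0, 1]", call. = FALSE)
  if (intensity_scale <= 0) stop("intensity_scale must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_seeds = as.integer(n_seeds),
                 n_parcels = as.integer(n_parcels),
                 intensity_scale = intensity_scale,
                 kernel_width = kernel_width, axis2_scale = axis2_scale,
                 noise_sd = noise_sd,
                 sa_smoothing_mm = sa_smoothing_mm,
                 n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints),
                 coupling_qt1 = coupling_qt1, coupling_cm = coupling_cm,
                 baseline_qt1 = baseline_qt1,
                 subject_effect_sd = subject_effect_sd,
                 ar_coef = ar_coef, voxel_size = voxel_size,
                 hemisphere = hemisphere, rng_seed = as.integer(rng_seed)),
            class = "synth_config")
}

# Smooth unit-variance Gaussian random field over seed coordinates: white
# noise convolved with a row-normalized Gaussian kernel of range h (mm).
# Row normalization keeps the field's local roughness uniform across the
# structure (no boundary amplitude artifacts), i.e. as stationary as the
# irregular support allows.
smooth_field <- function(coords, h) {
  n <- nrow(coords)
  z <- stats::rnorm(n)
  if (h <= 0) return(as.numeric(scale(z)))
  d2 <- as.matrix(stats::dist(coords))^2
  K <- exp(-d2 / (2 * h^2))
  f <- as.numeric((K / rowSums(K)) %*% z)
  as.numeric(scale(f))
}

#' Generate the latent thalamus geometry
#'
#' Places `n_seeds` voxels on a regular grid clipped to an ellipsoid (axis
#' ratios 1 : 0.55 : 0.45, scaled so the ellipsoid volume matches the voxel
#' count), then plants two latent axes: `u1` is the standardized projection
#' on the longest ellipsoid axis plus a small smooth perturbation, giving
#' the "medial-to-lateral" axis a geometric meaning; `u2` is the analogous
#' standardized projection on the second ellipsoid axis (plus its own
#' smooth perturbation), orthogonalized against `u1` (so `cor(u1, u2) = 0`
#' by construction).  Tying both axes to the seed cloud's geometry gives
#' the diffusion operator well-separated low-frequency modes along each
#' axis, so the planted axes are recoverable and stable across thresholds.
#' Parcel anchors tile the `(u1, u2)`
#' plane on a jittered grid, and the seven canonical functional communities
#' are assigned in bands along the anchors' `u1` position, ordered from
#' limbic/transmodal to somatomotor/sensory.
#'
#' @param cfg A [synth_config()]; `n_seeds < 8` is an error.
#' @return A `latent_geometry`: `seeds` ([seed_space()]), `u1`, `u2`
#'   (standardized, `|cor| <= 0.1`), `anchors` (`n_parcels x 2`), `parcels`
#'   ([parcel_space()] with communities), and the generating `cfg`.
#' @export
make_geometry <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_seeds < 8) stop("n_seeds must be at least 8", call. = FALSE)
  v <- cfg$voxel_size
  ratios <- c(1, 0.55, 0.45)
  a <- (cfg$n_seeds * v^3 / (4 / 3 * pi * prod(ratios)))^(1 / 3)
  semi <- a * ratios
  grids <- lapply(semi, function(s) {
    m <- ceiling(1.25 * s / v)
    (seq(-m, m)) * v
  })
  # enumerate with the last axis fastest to match the seed-ordering convention
  vox <- as.matrix(expand.grid(k = seq_along(grids[[3]]),
                               j = seq_along(grids[[2]]),
                               i = seq_along(grids[[1]])))[, 3:1]
  xyz <- cbind(grids[[1]][vox[, 1]], grids[[2]][vox[, 2]], grids[[3]][vox[, 3]])
  r2 <- rowSums(sweep(xyz, 2L, semi, "/")^2)
  sel <- order(r2)[seq_len(cfg$n_seeds)]   # ellipsoid clip, exact count
  sel <- sel[order(sel)]                   # restore linear-index order
  dims <- lengths(grids)
  affine <- rbind(cbind(diag(v, 3), c(grids[[1]][1], grids[[2]][1], grids[[3]][1])),
                  c(0, 0, 0, 1))
  seeds <- seed_space(vox[sel, , drop = FALSE], dims, affine, voxel_size = v,
                      hemisphere = cfg$hemisphere)
  with_seed(substream_seed(cfg$rng_seed, 11L), {
    x <- seeds$coords[, 1L]
    pert <- smooth_field(seeds$coords, cfg$sa_smoothing_mm)
    u1 <- as.numeric(scale(as.numeric(scale(x)) + 0.2 * pert))
    y <- seeds$coords[, 2L]
    pert2 <- smooth_field(seeds$coords, cfg$sa_smoothing_mm)
    g <- as.numeric(scale(as.numeric(scale(y)) + 0.2 * pert2))
    res <- stats::lm.fit(cbind(1, u1), g)$residuals
    u2 <- as.numeric(scale(res))
    # jittered anchor grid tiling the occupied latent plane
    p <- cfg$n_parcels
    g_side <- ceiling(sqrt(p))
    ax <- seq(-1.7, 1.7, length.out = g_side)
    grid <- as.matrix(expand.grid(u1 = ax, u2 = ax))
    pick <- round(seq(1, nrow(grid), length.out = p))
    anchors <- grid[pick, , drop = FALSE] +
      matrix(stats::runif(2 * p, -0.12, 0.12), ncol = 2)
    communities <- c("Limbic", "DMN", "FPN", "VAN", "DAN", "Somatomotor",
                     "Visual")
    band <- cut(rank(anchors[, 1L], ties.method = "first"),
                breaks = 7, labels = FALSE)
    parcels <- parcel_space(sprintf("P%03d", seq_len(p)),
                            community = communities[band])
    structure(list(seeds = seeds, u1 = u1, u2 = u2, anchors = anchors,
                   parcels = parcels, cfg = cfg),
              class = "latent_geometry")
  })
}

#' @export
print.latent_geometry <- function(x, ...) {
  cat(sprintf("<latent_geometry> %d seeds, %d parcels, |cor(u1,u2)| = %.2g\n",
              x$seeds$n_seeds, x$parcels$n_parcels,
              abs(stats::cor(x$u1, x$u2))))
  invisible(x)
}

# Expected streamline count: Gaussian kernel in the latent plane between
# each seed's (u1, u2) position and each parcel anchor; the second axis is
# compressed by axis2_scale so the first axis dominates the profiles.
sc_rates <- function(geom) {
  cfg <- geom$cfg
  s2 <- cfg$axis2_scale %||% 1
  d2 <- outer(geom$u1, geom$anchors[, 1L], "-")^2 +
    s2^2 * outer(geom$u2, geom$anchors[, 2L], "-")^2
  cfg$intensity_scale * exp(-d2 / (2 * cfg$kernel_width^2))
}

#' Simulate thalamocortical streamline counts
#'
#' Rates are `lambda_ij = intensity_scale * exp(-d_ij^2 / (2 kernel_width^2))`
#' with `d_ij` the latent-plane distance from seed `i` to parcel anchor `j`;
#' counts are Poisson draws around the rates (the simplest generative match
#' to tractography count data), or the rates themselves in deterministic
#' mode (for exact tests).
#'
#' @param geom A `latent_geometry` from [make_geometry()].
#' @param cfg The generating [synth_config()] (defaults to the one stored in
#'   `geom`).
#' @param deterministic If `TRUE`, return the expected counts instead of
#'   sampling.
#' @return A [conn_matrix()] with modality `sc_counts`.
#' @export
simulate_sc_counts <- function(geom, cfg = geom$cfg, deterministic = FALSE) {
  lam <- sc_rates(geom)
  vals <- if (deterministic) lam else
    with_seed(substream_seed(cfg$rng_seed, 23L),
              matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam)))
  conn_matrix(vals, "sc_counts", seed_ids = geom$seeds$seed_ids,
              parcel_ids = geom$parcels$parcel_ids,
              hemisphere = cfg$hemisphere)
}

# map = baseline + coupling * axis + |coupling| * noise_sd * smooth noise.
# The noise field is orthogonalized against both latent axes (then
# re-standardized) so the planted couplings are exact: a 6 mm smooth field
# over a ~17 mm structure has few effective degrees of freedom and would
# otherwise itself load appreciably on the axes, blurring the ground truth.
planted_map <- function(geom, cfg, axis, coupling, baseline, stream) {
  with_seed(substream_seed(cfg$rng_seed, stream), {
    noise <- if (cfg$noise_sd > 0) {
      f <- smooth_field(geom$seeds$coords, cfg$sa_smoothing_mm)
      f <- stats::lm.fit(cbind(1, geom$u1, geom$u2), f)$residuals
      abs(coupling) * cfg$noise_sd * as.numeric(scale(f))
    } else 0
    stats::setNames(baseline + coupling * axis + noise,
                    as.character(geom$seeds$seed_ids))
  })
}

#' Random spatially autocorrelated seed map
#'
#' A unit-variance Gaussian random field over the seed coordinates (white
#' noise convolved with a Gaussian kernel), used as an independent smooth
#' null map, e.g. for calibrating the surrogate-based correlation test.
#'
#' @param seeds A [seed_space()] (or coordinate matrix).
#' @param range_mm Gaussian smoothing range in mm.
#' @param seed Integer RNG seed.
#' @return Numeric vector, one value per seed (mean 0, sd 1).
#' @export
random_smooth_map <- function(seeds, range_mm = 6, seed = 1L) {
  coords <- if (inherits(seeds, "seed_space")) seeds$coords else as.matrix(seeds)
  with_seed(seed, smooth_field(coords, range_mm))
}

#' Simulate the intrathalamic qT1 map
#'
#' `qT1_i = baseline_qt1 + coupling_qt1 * u1_i + noise`, with spatially
#' autocorrelated noise of relative scale `noise_sd`.  The default negative
#' coupling makes qT1 fall (myelin rise) along the principal axis.
#'
#' @inheritParams simulate_sc_counts
#' @return Named numeric scalar seed map (ms).
#' @export
simulate_qt1 <- function(geom, cfg = geom$cfg) {
  planted_map(geom, cfg, geom$u1, cfg$coupling_qt1, cfg$baseline_qt1, 31L)
}

#' Simulate the core-matrix cell-type proxy map
#'
#' A dimensionless map planted on the *second* latent axis:
#' `cm_i = coupling_cm * u2_i + noise`.  Because `u2` is orthogonal to `u1`
#' by construction, the map is uncorrelated with the principal axis.
#'
#' @inheritParams simulate_sc_counts
#' @return Named numeric scalar seed map (dimensionless).
#' @export
simulate_corematrix <- function(geom, cfg = geom$cfg) {
  planted_map(geom, cfg, geom$u2, cfg$coupling_cm, 0, 37L)
}

# voxel series = weighted parcel series + white noise of relative scale
mix_voxel_ts <- function(weights, parcel_ts, noise_sd) {
  sig <- weights %*% parcel_ts
  if (noise_sd > 0) {
    sdsig <- sqrt(rowSums(weights^2))   # marginal signal sd (unit-var parcels)
    sig <- sig + noise_sd * sdsig *
      matrix(stats::rnorm(length(sig)), nrow(sig), ncol(sig))
  }
  sig
}

#' Simulate thalamic voxel and cortical parcel time series
#'
#' Parcel signals are independent unit-variance AR(1) series (coefficient
#' `ar_coef`); each voxel series is the connectivity-weighted sum of parcel
#' signals (`w_ij = lambda_ij` normalized per seed) plus white noise scaled
#' by `noise_sd` relative to the voxel's signal sd.  The voxel-parcel
#' correlation structure therefore inherits the planted axes.
#'
#' @inheritParams simulate_sc_counts
#' @param n_timepoints Series length (defaults to `cfg$n_timepoints`; must
#'   be `>= 50`).
#' @return List with `voxel_ts` (`n_seeds x T`) and `parcel_ts`
#'   (`n_parcels x T`).
#' @export
simulate_timeseries <- function(geom, cfg = geom$cfg,
                                n_timepoints = cfg$n_timepoints) {
  if (n_timepoints < 50) stop("n_timepoints must be >= 50", call. = FALSE)
  with_seed(substream_seed(cfg$rng_seed, 41L), {
    p <- geom$parcels$n_parcels
    phi <- cfg$ar_coef
    innov_sd <- sqrt(1 - phi^2)      # unit marginal variance
    E <- matrix(stats::rnorm(p * n_timepoints, sd = innov_sd), p, n_timepoints)
    S <- E
    S[, 1L] <- stats::rnorm(p)       # stationary start
    for (t in 2:n_timepoints) S[, t] <- phi * S[, t - 1L] + E[, t]
    lam <- sc_rates(geom)
    W <- lam / rowSums(lam)
    voxel_ts <- mix_voxel_ts(W, S, cfg$noise_sd)
    rownames(voxel_ts) <- as.character(geom$seeds$seed_ids)
    rownames(S) <- geom$parcels$parcel_ids
    list(voxel_ts = voxel_ts, parcel_ts = S)
  })
}

#' Simulate a multi-subject qT1 stack
#'
#' Each subject `s` carries one standard-normal factor `h_sj` per cortical
#' parcel (its idiosyncratic maturational state).  A parcel's qT1 is
#' `nu_j + subject_effect_sd * h_sj + noise`; a thalamic voxel inherits the
#' parcel factors in proportion to its connectivity,
#' `mu_i + subject_effect_sd * sum_j L_ij h_sj + noise`, where `L` is the
#' connectivity rate matrix scaled to unit mean transmitted variance.
#' Connected thalamocortical pairs therefore covary across subjects, with
#' covariance proportional to connectivity strength.  Noise sd is
#' `noise_sd` times the subject-effect scale.
#'
#' When explicit `beta` / `gamma` loading vectors are supplied, the model
#' collapses to its single-shared-factor limit (`f_s` standard normal,
#' voxel value `mu_i + beta_i * f_s + noise`, parcel value
#' `nu_j + gamma_j * f_s + noise`), useful for exact checks and nulls
#' (e.g. `beta_i = 0` for a decoupled voxel).
#'
#' @inheritParams simulate_sc_counts
#' @param n_subjects Number of subjects (defaults to `cfg$n_subjects`;
#'   `< 3` is an error, covariance would be degenerate).
#' @param beta,gamma Optional explicit loading vectors selecting the
#'   single-shared-factor limit of the model.
#' @return A `subject_stack`: `voxel_values` (`subjects x n_seeds`),
#'   `parcel_values` (`subjects x n_parcels`), `n_subjects`.
#' @export
simulate_subject_qt1_stack <- function(geom, cfg = geom$cfg,
                                       n_subjects = cfg$n_subjects,
                                       beta = NULL, gamma = NULL) {
  if (n_subjects < 3) stop("n_subjects must be >= 3", call. = FALSE)
  with_seed(substream_seed(cfg$rng_seed, 53L), {
    lam <- sc_rates(geom)
    n <- nrow(lam); p <- ncol(lam)
    se <- cfg$subject_effect_sd
    mu <- cfg$baseline_qt1 + cfg$coupling_qt1 * geom$u1
    nu <- cfg$baseline_qt1 + cfg$coupling_qt1 * geom$anchors[, 1L]
    if (is.null(beta) && is.null(gamma)) {
      rel <- lam / cfg$intensity_scale
      L <- rel / sqrt(mean(rowSums(rel^2)))   # unit mean transmitted variance
      H <- matrix(stats::rnorm(n_subjects * p), n_subjects, p)
      sig_v <- se * (H %*% t(L))
      sig_p <- se * H
    } else {
      beta <- beta %||% (se * rowSums(lam) / mean(rowSums(lam)))
      gamma <- gamma %||% (se * colSums(lam) / mean(colSums(lam)))
      f <- stats::rnorm(n_subjects)
      sig_v <- outer(f, beta)
      sig_p <- outer(f, gamma)
    }
    voxel_values <- sig_v +
      matrix(mu, n_subjects, n, byrow = TRUE) +
      matrix(stats::rnorm(n_subjects * n, sd = cfg$noise_sd * se),
             n_subjects, n)
    parcel_values <- sig_p +
      matrix(nu, n_subjects, p, byrow = TRUE) +
      matrix(stats::rnorm(n_subjects * p, sd = cfg$noise_sd * se),
             n_subjects, p)
    colnames(voxel_values) <- as.character(geom$seeds$seed_ids)
    colnames(parcel_values) <- geom$parcels$parcel_ids
    structure(list(voxel_values = voxel_values,
                   parcel_values = parcel_values,
                   n_subjects = as.integer(n_subjects)),
              class = "subject_stack")
  })
}

#' Simulate a complete synthetic dataset
#'
#' Runs every generator under one configuration: geometry (with ground-truth
#' axes), streamline counts, qT1 and core-matrix maps, voxel/parcel time
#' series, and the multi-subject qT1 stack.
#'
#' @param cfg A [synth_config()].
#' @return Named list with elements `geometry`, `sc_counts`, `qt1`,
#'   `corematrix`, `timeseries`, `stack`.
#' @export
simulate_dataset <- function(cfg = synth_config()) {
  geom <- make_geometry(cfg)
  list(geometry = geom,
       sc_counts = simulate_sc_counts(geom, cfg),
       qt1 = simulate_qt1(geom, cfg),
       corematrix = simulate_corematrix(geom, cfg),
       timeseries = simulate_timeseries(geom, cfg),
       stack = simulate_subject_qt1_stack(geom, cfg))
}
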