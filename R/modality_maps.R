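#' Thalamocortical functional connectivity matrix
#'
#' Pearson-correlates each thalamic voxel time series with each cortical
#' parcel time series.  Zero-variance series make the affected entries
#' absent (`NA`) with a warning rather than propagating `NaN`.
#'
#' @param voxel_ts `n_seeds x T` matrix of voxel time series.
#' @param parcel_ts `n_parcels x T` matrix of parcel time series (same `T`,
#'   `T >= 3`).
#' @return A [conn_matrix()] with modality `fc_r`, values in `[-1, 1]`.
#' @export
fc_matrix <- function(voxel_ts, parcel_ts) {
  voxel_ts <- as.matrix(voxel_ts); parcel_ts <- as.matrix(parcel_ts)
  if (ncol(voxel_ts) != ncol(parcel_ts))
    stop("voxel and parcel series must share the number of timepoints",
         call. = FALSE)
  if (ncol(voxel_ts) < 3) stop("need at least 3 timepoints", call. = FALSE)
  sdv <- apply(voxel_ts, 1L, stats::sd)
  sdp <- apply(parcel_ts, 1L, stats::sd)
  if (any(sdv == 0) || any(sdp == 0))
    warning(sprintf("%d zero-variance series; affected entries set absent",
                    sum(sdv == 0) + sum(sdp == 0)))
  r <- suppressWarnings(stats::cor(t(voxel_ts), t(parcel_ts)))
  r[sdv == 0, ] <- NA_real_
  r[, sdp == 0] <- NA_real_
  r <- clamp(r, -1, 1)
  conn_matrix(r, "fc_r", seed_ids = rownames(voxel_ts),
              parcel_ids = rownames(parcel_ts))
}

#' Fisher r-to-z transform of a correlation matrix
#'
#' Element-wise `z = atanh(r)`, after clamping `|r|` to `1 - 1e-7` so exactly
#' collinear series do not produce infinities.  Applied to functional
#' connectivity rows before group averaging and thresholding.  (This is the
#' r-to-z variance-stabilizing transform, not row standardization; see
#' [row_zscore()] for the alternative.)
#'
#' @param m A [conn_matrix()] with modality `fc_r` (values in `[-1, 1]`).
#' @return A [conn_matrix()] with modality `fc_z`; strictly monotone in `r`.
#' @export
fisher_z <- function(m) {
  v <- as_values(m)
  if (any(abs(v) > 1 + 1e-12, na.rm = TRUE))
    stop("fisher_z input must lie in [-1, 1]", call. = FALSE)
  z <- atanh(clamp(v, -(1 - 1e-7), 1 - 1e-7))
  conn_matrix(z, "fc_z", seed_ids = rownames(v), parcel_ids = colnames(v),
              hemisphere = if (inherits(m, "conn_matrix")) m$hemisphere else NULL)
}

#' Row-wise z-scoring of a connectivity matrix
#'
#' Sensitivity alternative to [fisher_z()]: standardizes each row to mean 0,
#' sd 1.
#'
#' @param m A [conn_matrix()] or matrix.
#' @return Matrix of the same shape.
#' @export
row_zscore <- function(m) {
  v <- as_values(m)
  t(apply(v, 1L, function(r) (r - mean(r, na.rm = TRUE)) /
            stats::sd(r, na.rm = TRUE)))
}

#' Group-level qT1 map
#'
#' Voxel-wise arithmetic mean of qT1 across subjects, skipping absent
#' entries; a voxel absent in every subject stays absent.
#'
#' @param stack A `subject_stack` (see [simulate_subject_qt1_stack()]), or
#'   any `subjects x n_seeds` matrix as `voxel_values`.
#' @return Named numeric scalar seed map (ms).
#' @export
group_qt1 <- function(stack) {
  v <- if (inherits(stack, "subject_stack")) stack$voxel_values else as.matrix(stack)
  n_present <- colSums(!is.na(v))
  tc_log("group_qt1: %d voxels, subject counts %d-%d", ncol(v),
         min(n_present), max(n_present))
  out <- colMeans(v, na.rm = TRUE)
  out[n_present == 0] <- NA_real_
  out
}

#' Thalamocortical structural covariance
#'
#' Pearson-correlates, across subjects, each thalamic voxel's qT1 with each
#' cortical parcel's qT1 — the covariance analogue of a connectivity matrix,
#' a proxy for shared maturational/genetic effects.  Fewer than 3 subjects
#' is an error (any two points give `|r| = 1`); zero across-subject variance
#' makes the affected entries absent with a warning.
#'
#' @param stack A `subject_stack` with `n_subjects >= 3`.
#' @return A [conn_matrix()] with modality `scov_r`, values in `[-1, 1]`.
#' @export
structural_covariance <- function(stack) {
  stopifnot(inherits(stack, "subject_stack"))
  if (stack$n_subjects < 3)
    stop("correlation across subjects degenerate: n_subjects < 3", call. = FALSE)
  vv <- stack$voxel_values; pv <- stack$parcel_values
  sdv <- apply(vv, 2L, stats::sd)
  sdp <- apply(pv, 2L, stats::sd)
  if (any(sdv == 0) || any(sdp == 0))
    warning(sprintf("%d zero-variance qT1 series; affected entries set absent",
                    sum(sdv == 0) + sum(sdp == 0)))
  r <- suppressWarnings(stats::cor(vv, pv))
  r[sdv == 0, ] <- NA_real_
  r[, sdp == 0] <- NA_real_
  r <- clamp(r, -1, 1)
  conn_matrix(r, "scov_r", seed_ids = colnames(vv), parcel_ids = colnames(pv))
}
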