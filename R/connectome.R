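#' Average connectivity matrices across subjects
#'
#' Element-wise arithmetic mean of per-subject seed-by-parcel matrices, the
#' group-level matrix used for gradient decomposition.  All inputs must share
#' shape and modality; the modality is preserved.
#'
#' @param matrices A list of [conn_matrix()] objects (or plain matrices, in
#'   which case a modality must be inferable from the first element).
#' @return A [conn_matrix()] of the same modality.
#' @export
group_average <- function(matrices) {
  if (!length(matrices)) stop("empty list of matrices", call. = FALSE)
  first <- matrices[[1L]]
  if (!inherits(first, "conn_matrix"))
    stop("elements must be conn_matrix objects", call. = FALSE)
  mod <- first$modality
  dims <- dim(first$values)
  acc <- array(0, dims)
  for (m in matrices) {
    if (!inherits(m, "conn_matrix") || m$modality != mod)
      stop("all matrices must share one modality", call. = FALSE)
    if (!all(dim(m$values) == dims))
      stop("matrix shape mismatch in group average", call. = FALSE)
    acc <- acc + m$values
  }
  conn_matrix(acc / length(matrices), mod,
              seed_ids = rownames(first$values),
              parcel_ids = colnames(first$values),
              hemisphere = first$hemisphere)
}

#' Column-wise maximum normalization of streamline counts
#'
#' Divides every value of each column by that column's maximum, so each
#' parcel's strongest connection becomes 1.  All-zero columns are left at
#' zero (with a warning) rather than producing a division error.
#'
#' @param m A [conn_matrix()] with modality `sc_counts` (non-negative).
#' @return A [conn_matrix()] with modality `sc_norm`; post-condition: every
#'   column maximum is 0 or exactly 1.
#' @export
normalize_columns_max <- function(m) {
  v <- as_values(m)
  if (any(v < 0, na.rm = TRUE))
    stop("column-max normalization requires non-negative input", call. = FALSE)
  if (inherits(m, "conn_matrix") && m$modality != "sc_counts")
    stop("column-max normalization applies to sc_counts matrices", call. = FALSE)
  cmax <- apply(v, 2L, max, na.rm = TRUE)
  zero <- cmax == 0
  if (any(zero)) {
    warning(sprintf("%d all-zero column(s) left unnormalized", sum(zero)))
    cmax[zero] <- 1
  }
  out <- sweep(v, 2L, cmax, "/")
  conn_matrix(out, "sc_norm", seed_ids = rownames(v), parcel_ids = colnames(v),
              hemisphere = if (inherits(m, "conn_matrix")) m$hemisphere else NULL)
}

#' Percentile thresholding of a connectivity matrix
#'
#' Sets entries strictly below the `pct`-th percentile to zero, keeping
#' entries equal to the threshold (keep-on-tie).  The percentile is computed
#' with linear interpolation between order statistics.  With `scope = "row"`
#' (the default, each seed keeping its top connections) the threshold is
#' per-row; with `scope = "global"` one threshold applies to the whole
#' matrix.
#'
#' @param m A [conn_matrix()] or numeric matrix.
#' @param pct Percentile in `[0, 100)`; `pct = 0` leaves the matrix
#'   unchanged.
#' @param scope `"row"` or `"global"`.
#' @return Same type as `m`, thresholded; the operation is idempotent at a
#'   fixed `pct` and scope.
#' @export
threshold_percentile <- function(m, pct, scope = c("row", "global")) {
  scope <- match.arg(scope)
  if (pct < 0 || pct >= 100) stop("pct must lie in [0, 100)", call. = FALSE)
  v <- as_values(m)
  if (scope == "global") {
    thr <- stats::quantile(v, pct / 100, na.rm = TRUE, names = FALSE)
    v[v < thr] <- 0
  } else {
    thr <- apply(v, 1L, stats::quantile, probs = pct / 100, na.rm = TRUE,
                 names = FALSE)
    v[sweep(v, 1L, thr, "<")] <- 0
  }
  if (inherits(m, "conn_matrix")) {
    m$values <- v
    m
  } else v
}
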