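#' Normalized-angle affinity kernel
#'
#' Converts connectivity profiles (one row per seed) into a non-negative
#' similarity matrix: `a_ij = 1 - acos(cos_sim(row_i, row_j)) / pi`, which
#' maps cosine similarity into `[0, 1]` (identical profiles give 1,
#' orthogonal 0.5, antiparallel 0).  Cosine similarities are clamped to
#' `[-1, 1]` before `acos` to absorb floating-point overshoot.  The kernel
#' is scale-free: multiplying rows by positive constants leaves it
#' unchanged.
#'
#' @param profiles Numeric matrix (or [conn_matrix()]) of row profiles; rows
#'   may be sparse but not entirely absent.
#' @param on_zero How to treat zero-norm rows (typically produced by
#'   over-aggressive thresholding): `"error"` (default) names the offending
#'   seeds; `"permissive"` assigns those rows/columns the orthogonality
#'   value 0.5.
#' @return A symmetric `n x n` matrix in `[0, 1]` with unit diagonal for all
#'   rows with nonzero profiles.
#' @export
normalized_angle_affinity <- function(profiles, on_zero = c("error", "permissive")) {
  on_zero <- match.arg(on_zero)
  p <- as_values(profiles)
  if (anyNA(p)) stop("profiles contain absent values", call. = FALSE)
  nrm <- sqrt(rowSums(p^2))
  zero <- nrm == 0
  if (any(zero)) {
    if (on_zero == "error")
      stop(sprintf("zero-norm profile for seed(s): %s",
                   paste(utils::head(which(zero), 10L), collapse = ", ")),
           call. = FALSE)
    nrm[zero] <- 1
  }
  u <- p / nrm
  cs <- clamp(tcrossprod(u), -1, 1)
  # snap float dust so exactly (anti)parallel profiles give exactly 1 / 0
  cs[cs > 1 - 1e-12] <- 1
  cs[cs < -1 + 1e-12] <- -1
  a <- 1 - acos(cs) / pi
  if (any(zero)) {
    a[zero, ] <- 0.5
    a[, zero] <- 0.5
  }
  diag(a)[!zero] <- 1
  (a + t(a)) / 2
}

# Connected components of the graph with edges where w > 0 (simple BFS).
graph_components <- function(w) {
  n <- nrow(w)
  comp <- integer(n)
  cur <- 0L
  adj <- w > 0
  diag(adj) <- FALSE
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nxt <- which(matrixStats_any_col(adj, frontier) & comp == 0L)
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}

# column-wise "any" over selected rows without extra dependencies
matrixStats_any_col <- function(adj, rows) {
  if (length(rows) == 1L) adj[rows, ] else colSums(adj[rows, , drop = FALSE]) > 0
}

#' Diffusion map embedding of an affinity matrix
#'
#' Computes the spectral embedding of the degree-normalized Markov operator
#' built from a symmetric non-negative affinity `W`.  With `d` the row sums
#' of `W`, the anisotropic normalization forms `W'_ij = W_ij / (d_i^alpha *
#' d_j^alpha)`; with `d'` the row sums of `W'`, the Markov operator is
#' `P = diag(d')^-1 W'`.  `alpha = 0` recovers the classical random-walk
#' Laplacian; `alpha = 0.5` (the default used throughout) approximates
#' Fokker-Planck scaling, preserving large-scale relations and damping the
#' influence of sampling density.  Eigenvectors are obtained from the
#' symmetric conjugate `D'^{1/2} P D'^{-1/2}` for numerical stability and
#' back-transformed; the trivial stationary eigenpair (eigenvalue 1,
#' constant eigenvector) is discarded.
#'
#' Loadings follow the diffusion-time-0 convention: component `k` is
#' `psi_k * lambda_k / (1 - lambda_k)`; for `diffusion_time = t > 0` the
#' scale is `lambda_k^t` instead.  Explained variance is each retained
#' eigenvalue as a fraction of the retained eigenvalue sum.
#'
#' @param W Symmetric non-negative affinity matrix whose positive entries
#'   form a single connected graph (a disconnected graph is an error that
#'   reports the component sizes, not a silently patched input).
#' @param alpha Degree-normalization exponent in `[0, 1]`.
#' @param n_components Number of non-trivial components to retain.
#' @param diffusion_time Non-negative diffusion time; 0 selects the
#'   `lambda / (1 - lambda)` scaling.
#' @return A `gradient_set`: `loadings` (`n x k`, columns `G1..Gk`),
#'   `eigenvalues` (retained, descending, in `(0, 1)`),
#'   `explained_variance` (fractions summing to 1 over the retained set),
#'   `alpha`, `diffusion_time`.
#' @export
diffusion_map_embed <- function(W, alpha = 0.5, n_components = 10,
                                diffusion_time = 0) {
  W <- as_values(W)
  n <- nrow(W)
  if (n != ncol(W)) stop("affinity matrix must be square", call. = FALSE)
  if (any(W < 0)) stop("affinity matrix must be non-negative", call. = FALSE)
  if (max(abs(W - t(W))) > 1e-10)
    stop("affinity matrix must be symmetric", call. = FALSE)
  if (n < n_components + 1L)
    stop(sprintf("need at least n_components + 1 = %d rows, got %d",
                 n_components + 1L, n), call. = FALSE)
  comp <- graph_components(W)
  if (max(comp) > 1L)
    stop(sprintf("affinity graph is disconnected (component sizes: %s)",
                 paste(tabulate(comp), collapse = ", ")), call. = FALSE)
  W <- (W + t(W)) / 2
  d <- rowSums(W)
  da <- d^alpha
  Wp <- W / outer(da, da)
  dp <- rowSums(Wp)
  inv_sqrt <- 1 / sqrt(dp)
  S <- Wp * outer(inv_sqrt, inv_sqrt)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lam <- clamp(e$values, -1, 1)
  V <- e$vectors
  # back-transform and normalize so the trivial eigenvector is constant 1
  v1 <- V[, 1L]
  if (sum(v1) < 0) v1 <- -v1
  psi <- (V * inv_sqrt) / (v1 * inv_sqrt)
  keep <- seq(2L, n_components + 1L)
  lam_k <- lam[keep]
  if (any(lam_k <= 0))
    stop("retained spectrum contains non-positive eigenvalues; reduce n_components",
         call. = FALSE)
  if (any(lam_k >= 1 - 1e-12))
    stop("repeated unit eigenvalue: affinity graph is effectively disconnected",
         call. = FALSE)
  scale_k <- if (diffusion_time == 0) lam_k / (1 - lam_k) else lam_k^diffusion_time
  loadings <- sweep(psi[, keep, drop = FALSE], 2L, scale_k, "*")
  colnames(loadings) <- paste0("G", seq_len(n_components))
  rownames(loadings) <- rownames(W)
  structure(list(loadings = loadings, eigenvalues = lam_k,
                 explained_variance = explained_variance(lam_k),
                 alpha = alpha, diffusion_time = diffusion_time),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("<gradient_set> %d seeds x %d components (alpha=%.2g)\n",
              nrow(x$loadings), ncol(x$loadings), x$alpha))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = " "), "\n")
  invisible(x)
}

#' Explained variance fractions of an eigenvalue spectrum
#'
#' Each retained eigenvalue as a fraction of the retained eigenvalue sum; the
#' denominator is the retained (non-trivial) spectrum, not the full one.
#'
#' @param eigenvalues Positive, non-increasing eigenvalues.
#' @return Fractions, non-increasing, summing to 1.
#' @export
explained_variance <- function(eigenvalues) {
  if (any(eigenvalues <= 0))
    stop("eigenvalues must be positive", call. = FALSE)
  if (any(diff(eigenvalues) > 1e-12))
    stop("eigenvalues must be non-increasing", call. = FALSE)
  eigenvalues / sum(eigenvalues)
}

#' Deterministic sign alignment of gradient components
#'
#' Eigenvector signs are arbitrary; this fixes them reproducibly.  With a
#' reference map, each component is flipped so its correlation with the
#' reference is non-negative; without one, so that its largest-magnitude
#' entry is positive.  Idempotent: aligning an already aligned (or
#' wholesale-negated) gradient set gives the same output.
#'
#' @param g A `gradient_set` (from [diffusion_map_embed()]) or a loadings
#'   matrix.
#' @param reference Optional scalar seed map of matching length.
#' @return Same type as `g`, with aligned signs.
#' @export
align_sign <- function(g, reference = NULL) {
  loadings <- if (inherits(g, "gradient_set")) g$loadings else as.matrix(g)
  if (!is.null(reference) && length(reference) != nrow(loadings))
    stop("reference length does not match loadings", call. = FALSE)
  for (k in seq_len(ncol(loadings))) {
    v <- loadings[, k]
    if (stats::sd(v) == 0) {
      warning(sprintf("component %d has zero variance; left unchanged", k))
      next
    }
    flip <- if (is.null(reference)) {
      v[which.max(abs(v))] < 0
    } else {
      isTRUE(stats::cor(v, reference, use = "pairwise.complete.obs") < 0)
    }
    if (flip) loadings[, k] <- -v
  }
  if (inherits(g, "gradient_set")) {
    g$loadings <- loadings
    g
  } else loadings
}

#' Gradients from a connectivity matrix in one call
#'
#' Convenience wrapper running the thresholding, affinity kernel, and
#' diffusion map embedding in the order used throughout: percentile
#' threshold (per row by default), normalized-angle affinity, embedding.
#'
#' @param m A [conn_matrix()] or numeric seed-by-parcel matrix (already
#'   normalized for `sc`; Fisher z for `fc`).
#' @param threshold_pct Percentile threshold (75 for structural, 90 for
#'   functional connectivity).
#' @param scope Threshold scope, see [threshold_percentile()].
#' @param alpha,n_components,diffusion_time Passed to
#'   [diffusion_map_embed()].
#' @param on_zero Passed to [normalized_angle_affinity()].
#' @return A `gradient_set`.
#' @export
connectivity_gradients <- function(m, threshold_pct = 75,
                                   scope = c("row", "global"), alpha = 0.5,
                                   n_components = 10, diffusion_time = 0,
                                   on_zero = "error") {
  scope <- match.arg(scope)
  thr <- threshold_percentile(m, threshold_pct, scope = scope)
  aff <- normalized_angle_affinity(thr, on_zero = on_zero)
  diffusion_map_embed(aff, alpha = alpha, n_components = n_components,
                      diffusion_time = diffusion_time)
}
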