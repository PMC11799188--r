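#' Project a thalamic gradient onto the cortex
#'
#' Correlates a gradient (or any scalar seed map) with each column of a
#' thalamocortical matrix, yielding one Pearson r per cortical parcel — the
#' cortical echo of the thalamic axis.  Negative parcels relate to the
#' gradient's negative apex, positive parcels to the positive apex.
#'
#' @param g Scalar seed map (length = number of matrix rows); zero variance
#'   is an error.
#' @param m A [conn_matrix()] or seed-by-parcel matrix of any modality.
#' @return Named numeric vector, one r in `[-1, 1]` per parcel; absent only
#'   where a column had zero variance (warned).
#' @export
project_gradient <- function(g, m) {
  v <- as_values(m)
  g <- as.numeric(g)
  if (length(g) != nrow(v))
    stop("gradient length does not match matrix rows", call. = FALSE)
  ok <- is.finite(g)
  if (stats::sd(g[ok]) == 0) stop("zero-variance gradient", call. = FALSE)
  sdc <- apply(v, 2L, stats::sd, na.rm = TRUE)
  if (any(sdc == 0, na.rm = TRUE))
    warning(sprintf("%d zero-variance column(s) set absent", sum(sdc == 0)))
  r <- suppressWarnings(
    as.numeric(stats::cor(g, v, use = "pairwise.complete.obs")))
  r[sdc == 0] <- NA_real_
  stats::setNames(r, colnames(v))
}

#' Decode a cortical map by functional communities
#'
#' Averages parcel values within each functional community and orders the
#' communities ascending by mean (ties broken lexicographically by label).
#' Communities whose values are all absent are flagged and excluded from the
#' ordering.
#'
#' @param values Named numeric vector, one value per parcel (e.g. from
#'   [project_gradient()]).
#' @param parcels A [parcel_space()] with community labels (or a character
#'   vector of labels, one per parcel).
#' @return A `group_summary`: `labels` (ordered ascending by statistic),
#'   `statistic` (per-group means, same order), `groups` (named list of the
#'   per-group value vectors), `stat_name = "mean"`.
#' @export
decode_by_communities <- function(values, parcels) {
  labels <- if (inherits(parcels, "parcel_space")) parcels$community
            else as.character(parcels)
  if (is.null(labels)) stop("community labels are required", call. = FALSE)
  group_summary(values, labels, stat = "mean")
}

#' Decode a thalamic map by nuclei
#'
#' Summarizes gradient loadings per thalamic nucleus by median (with
#' quartiles for raincloud-style export) and orders the nuclei ascending by
#' median.  Unlabeled seeds are excluded with a logged count.
#'
#' @param g Scalar seed map of gradient loadings.
#' @param nucleus_labels Per-seed nucleus labels (`NA` = unlabeled).
#' @return A `group_summary` with `stat_name = "median"` and a `quartiles`
#'   matrix (rows = nuclei in the same order, columns q25/q50/q75).
#' @export
decode_by_nuclei <- function(g, nucleus_labels) {
  labels <- as.character(nucleus_labels)
  drop <- is.na(labels)
  if (any(drop)) {
    tc_log("decode_by_nuclei: %d unlabeled seeds excluded", sum(drop))
    g <- g[!drop]; labels <- labels[!drop]
  }
  out <- group_summary(g, labels, stat = "median")
  out$quartiles <- t(vapply(out$groups, stats::quantile,
                            numeric(3L), probs = c(0.25, 0.5, 0.75),
                            na.rm = TRUE, names = FALSE))
  colnames(out$quartiles) <- c("q25", "q50", "q75")
  out
}

group_summary <- function(values, labels, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (length(values) != length(labels))
    stop("values and labels must have the same length", call. = FALSE)
  groups <- split(as.numeric(values), labels)
  fun <- if (stat == "mean") function(v) mean(v, na.rm = TRUE)
         else function(v) stats::median(v, na.rm = TRUE)
  s <- vapply(groups, fun, numeric(1L))
  empty <- vapply(groups, function(v) all(is.na(v)), logical(1L))
  if (any(empty)) {
    warning(sprintf("group(s) with all values absent excluded: %s",
                    paste(names(groups)[empty], collapse = ", ")))
    groups <- groups[!empty]; s <- s[!empty]
  }
  ord <- order(s, names(s))   # ascending; lexicographic tie-break
  structure(list(labels = names(s)[ord], statistic = unname(s[ord]),
                 groups = groups[ord], stat_name = stat),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %d groups ordered ascending by %s\n",
              length(x$labels), x$stat_name))
  print(stats::setNames(x$statistic, x$labels))
  invisible(x)
}

#' Seed table in gradient space
#'
#' One row per seed with its position in the 2-D space framed by two
#' gradients plus any overlay columns (scalar maps or labels), for external
#' plotting or export.
#'
#' @param g1,g2 Scalar seed maps (same length).
#' @param overlays Named list of per-seed vectors (scalars or labels).
#' @param seed_ids Optional seed identifiers.
#' @return A `data.frame` with columns `seed_id`, `g1`, `g2`, then the
#'   overlays in their given order; no seed is dropped.
#' @export
gradient_space_table <- function(g1, g2, overlays = list(), seed_ids = NULL) {
  if (length(g1) != length(g2))
    stop("g1 and g2 must have the same length", call. = FALSE)
  bad <- vapply(overlays, function(o) length(o) != length(g1), logical(1L))
  if (any(bad)) stop("overlay length mismatch", call. = FALSE)
  df <- data.frame(seed_id = seed_ids %||% names(g1) %||% seq_along(g1),
                   g1 = as.numeric(g1), g2 = as.numeric(g2))
  for (nm in names(overlays)) df[[nm]] <- overlays[[nm]]
  df
}

#' Consistency of individual maps with a group map
#'
#' Pearson r between each individual-level map and the group-level map, the
#' per-subject consistency measure.
#'
#' @param individual_maps List of scalar seed maps (all the same length).
#' @param group_map The group-level scalar seed map.
#' @return Numeric vector of per-individual r values; `NA` (with a warning)
#'   where an individual map has zero variance.
#' @export
map_consistency <- function(individual_maps, group_map) {
  vapply(individual_maps, function(m) {
    if (length(m) != length(group_map))
      stop("map length mismatch", call. = FALSE)
    r <- tryCatch(pearson_pairwise(as.numeric(m), as.numeric(group_map)),
                  error = function(e) {
                    warning(conditionMessage(e))
                    NA_real_
                  })
    r
  }, numeric(1L))
}

#' Match gradient components to target axes
#'
#' Greedy one-to-one assignment of gradient components to reference axes by
#' descending absolute correlation, used when checking planted-axis
#' recovery (eigenvector order can swap when eigenvalues are close).
#'
#' @param g A `gradient_set` or loadings matrix.
#' @param targets Matrix or list of reference axes (columns).
#' @param n_candidates How many leading components may be matched.
#' @return Data frame with one row per target: `target`, `component`, `r`.
#' @export
match_components <- function(g, targets, n_candidates = NULL) {
  loadings <- if (inherits(g, "gradient_set")) g$loadings else as.matrix(g)
  targets <- as.matrix(if (is.list(targets)) do.call(cbind, targets) else targets)
  n_candidates <- min(n_candidates %||% ncol(loadings), ncol(loadings))
  cand <- seq_len(n_candidates)
  cmat <- abs(stats::cor(loadings[, cand, drop = FALSE], targets,
                         use = "pairwise.complete.obs"))
  res <- data.frame(target = integer(0), component = integer(0), r = numeric(0))
  for (step in seq_len(ncol(targets))) {
    best <- which(cmat == max(cmat, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    comp <- cand[best[1L]]
    tgt <- best[2L]
    r_signed <- stats::cor(loadings[, comp], targets[, tgt],
                           use = "pairwise.complete.obs")
    res <- rbind(res, data.frame(target = tgt, component = comp, r = r_signed))
    cmat[best[1L], ] <- NA
    cmat[, best[2L]] <- NA
  }
  res[order(res$target), , drop = FALSE]
}
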