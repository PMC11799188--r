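MODALITIES <- c("sc_counts", "sc_norm", "fc_r", "fc_z", "scov_r")

#' Connectivity matrices
#'
#' A `conn_matrix` is a seed-by-parcel real matrix tagged by modality:
#' `sc_counts` (streamline counts, non-negative), `sc_norm` (column-max
#' normalized structural connectivity), `fc_r` / `fc_z` (functional
#' connectivity, Pearson r and Fisher z), or `scov_r` (across-subject
#' structural covariance).  Row names are seed ids, column names parcel ids.
#'
#' @param values Numeric matrix, seeds in rows, parcels in columns.
#' @param modality One of `r paste0('\x60', MODALITIES, '\x60', collapse = ", ")`.
#' @param seed_ids,parcel_ids Optional dimension identifiers; default to
#'   existing dimnames or 1..n.
#' @param hemisphere Optional hemisphere tag carried into file metadata.
#' @return An object of class `conn_matrix`.
#' @export
conn_matrix <- function(values, modality, seed_ids = NULL, parcel_ids = NULL,
                        hemisphere = NULL) {
  modality <- match.arg(modality, MODALITIES)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (modality == "sc_counts" && any(values < 0, na.rm = TRUE))
    stop("sc_counts must be non-negative", call. = FALSE)
  if (modality %in% c("fc_r", "scov_r") &&
      any(abs(values) > 1 + 1e-12, na.rm = TRUE))
    stop(sprintf("%s values must lie in [-1, 1]", modality), call. = FALSE)
  seed_ids <- seed_ids %||% rownames(values) %||% seq_len(nrow(values))
  parcel_ids <- parcel_ids %||% colnames(values) %||% seq_len(ncol(values))
  if (length(seed_ids) != nrow(values) || length(parcel_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  dimnames(values) <- list(as.character(seed_ids), as.character(parcel_ids))
  structure(list(values = values, modality = modality,
                 hemisphere = hemisphere),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %d seeds x %d parcels, modality %s\n",
              nrow(x$values), ncol(x$values), x$modality))
  invisible(x)
}

#' @export
dim.conn_matrix <- function(x) dim(x$values)

as_values <- function(m) if (inherits(m, "conn_matrix")) m$values else as.matrix(m)

#' Write / read a connectivity matrix as TSV
#'
#' The on-disk format is a single metadata comment line
#' (`# modality=... hemisphere=...`), a header row of parcel ids, a first
#' column of seed ids, and tab-separated numeric cells.  Reading re-sorts
#' rows into ascending seed-id order (or a supplied seed space's order), so
#' files with permuted rows load identically.
#'
#' @param m A [conn_matrix()].
#' @param path TSV path.
#' @param expected_shape Optional `c(n_seeds, n_parcels)`; a mismatch is an
#'   error.
#' @param seeds,parcels Optional [seed_space()] / [parcel_space()] whose
#'   orderings the rows / columns are aligned to.
#' @return `path` (write) or a [conn_matrix()] (read).
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "conn_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# modality=%s hemisphere=%s", m$modality,
                     m$hemisphere %||% "NA"), con)
  df <- data.frame(seed_id = rownames(m$values),
                   format(as.data.frame(m$values), digits = 17,
                          scientific = FALSE, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, expected_shape = NULL, seeds = NULL,
                        parcels = NULL) {
  lines <- readLines(path)
  meta_lines <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 2L || !grepl("^seed_id\\t", body[1L]))
    stop("malformed matrix TSV: missing 'seed_id' header row", call. = FALSE)
  kv <- if (length(meta_lines)) parse_meta(meta_lines) else character()
  modality <- kv[["modality"]] %||% "sc_counts"
  hemisphere <- kv[["hemisphere"]] %||% NULL
  if (identical(hemisphere, "NA")) hemisphere <- NULL
  df <- utils::read.delim(text = body, check.names = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric cell in matrix TSV", call. = FALSE)
  rownames(vals) <- as.character(df[[1L]])
  # align rows to seed order, columns to parcel order
  row_order <- if (!is.null(seeds)) as.character(seeds$seed_ids)
               else rownames(vals)[order(suppressWarnings(as.numeric(rownames(vals))),
                                         rownames(vals))]
  col_order <- if (!is.null(parcels)) parcels$parcel_ids else colnames(vals)
  if (!setequal(row_order, rownames(vals)) || !setequal(col_order, colnames(vals)))
    stop("matrix TSV ids do not match the requested seed/parcel spaces",
         call. = FALSE)
  vals <- vals[row_order, col_order, drop = FALSE]
  if (!is.null(expected_shape) && !all(dim(vals) == expected_shape))
    stop(sprintf("matrix shape %dx%d does not match expected %dx%d",
                 nrow(vals), ncol(vals), expected_shape[1L], expected_shape[2L]),
         call. = FALSE)
  conn_matrix(vals, modality, hemisphere = hemisphere)
}

#' Read a scalar seed map
#'
#' A scalar seed map is one value per seed in seed-space order (a qT1 value,
#' a core-matrix proxy value, or a gradient loading), as a named numeric
#' vector (names = seed ids).  Missing values are `NA`, never silently zero.
#'
#' @param x Either a NIfTI volume path (values are sampled at the seed
#'   voxels) or a two-column TSV (`seed_id`, `value`).
#' @param seeds A [seed_space()] defining the ordering.
#' @return Named numeric vector of length `seeds$n_seeds`.
#' @export
read_scalar_map <- function(x, seeds) {
  stopifnot(inherits(seeds, "seed_space"))
  if (grepl("\\.nii(\\.gz)?$", x)) {
    arr <- as.array(RNifti::readNifti(x))
    if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L) arr <- arr[, , , 1L]
    if (!all(dim(arr) == seeds$dim))
      stop("scalar volume extent does not match the seed space", call. = FALSE)
    vals <- arr[seeds$vox_idx]
  } else {
    df <- utils::read.delim(x, comment.char = "#", check.names = FALSE)
    idx <- match(seeds$seed_ids, df$seed_id)
    if (anyNA(idx))
      stop("scalar TSV is missing values for some seeds", call. = FALSE)
    vals <- as.numeric(df$value[idx])
  }
  if (anyNA(vals))
    warning(sprintf("%d seed(s) have absent scalar values", sum(is.na(vals))))
  stats::setNames(as.numeric(vals), as.character(seeds$seed_ids))
}

#' Write a scalar seed map as TSV
#' @param values Named numeric vector (names = seed ids).
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_scalar_map <- function(values, path) {
  df <- data.frame(seed_id = names(values) %||% seq_along(values),
                   value = format(as.numeric(values), digits = 17,
                                  scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the analysis parameters: the percentile thresholds applied to the
#' structural (default 75) and functional (default 90) connectivity matrices
#' before the affinity kernel, the diffusion-map anisotropic-normalization
#' exponent `alpha` (default 0.5, preserving large-scale relations), the
#' number of retained gradient components (default 10), the surrogate-map
#' count for spatial-autocorrelation-corrected tests (default 1000), and the
#' RNG seed.
#'
#' @param threshold_percentile_sc,threshold_percentile_fc Percentiles in
#'   `[0, 100)`.
#' @param alpha Degree-normalization exponent in `[0, 1]`.
#' @param n_components Retained components, `>= 1`.
#' @param n_surrogates Surrogate maps per SA-corrected test.
#' @param rng_seed Integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold_percentile_sc = 75,
                            threshold_percentile_fc = 90,
                            alpha = 0.5, n_components = 10,
                            n_surrogates = 1000, rng_seed = 1L) {
  for (p in c(threshold_percentile_sc, threshold_percentile_fc))
    if (p < 0 || p >= 100) stop("percentiles must lie in [0, 100)", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (n_components < 1) stop("n_components must be >= 1", call. = FALSE)
  structure(list(threshold_percentile_sc = threshold_percentile_sc,
                 threshold_percentile_fc = threshold_percentile_fc,
                 alpha = alpha, n_components = as.integer(n_components),
                 n_surrogates = as.integer(n_surrogates),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#' @param path JSON path.
#' @param config A [pipeline_config()].
#' @return A [pipeline_config()] (read) or `path` (write).
#' @export
read_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
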