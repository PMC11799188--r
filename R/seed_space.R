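#' Seed spaces: the ordered set of thalamic seed voxels
#'
#' A `seed_space` records every voxel of a binary thalamic mask together with
#' its voxel indices, physical (mm) coordinates, and a stable ordering.  All
#' connectivity matrices and scalar maps downstream are row-aligned to this
#' ordering.
#'
#' The ordering convention is: ascending linear index over the mask array as
#' stored, with the *last* axis fastest (for a `(n1, n2, n3)` array, voxel
#' `(i, j, k)` has linear index `((i-1) * n2 + (j-1)) * n3 + k`).  This is a
#' pure function of the mask volume, independent of the affine, so re-reading
#' the same file always yields the same ordering.
#'
#' @param vox_idx Integer matrix `n x 3` of 1-based voxel indices.
#' @param dim Integer vector of length 3, array dimensions.
#' @param affine 4x4 voxel-to-world affine (0-based voxel indices map to mm).
#' @param voxel_size Voxel edge length in mm.
#' @param hemisphere `"L"` or `"R"`.
#' @param seed_ids Optional strictly increasing integer identifiers; defaults
#'   to the linear indices of the voxels (guaranteeing order stability).
#' @return An object of class `seed_space` with fields `n_seeds`, `coords`
#'   (n x 3 mm), `vox_idx`, `seed_ids`, `dim`, `affine`, `voxel_size`,
#'   `hemisphere`.
#' @export
seed_space <- function(vox_idx, dim, affine, voxel_size = 1,
                       hemisphere = c("L", "R"), seed_ids = NULL) {
  hemisphere <- match.arg(hemisphere)
  vox_idx <- matrix(as.integer(vox_idx), ncol = 3L)
  if (nrow(vox_idx) < 2L) stop("a seed space needs at least 2 seeds", call. = FALSE)
  dim <- as.integer(dim)
  affine <- matrix(as.numeric(affine), 4L, 4L)
  lin <- linear_index(vox_idx, dim)
  if (anyDuplicated(lin)) stop("duplicate seed voxels", call. = FALSE)
  ord <- order(lin)
  vox_idx <- vox_idx[ord, , drop = FALSE]
  lin <- lin[ord]
  if (is.null(seed_ids)) {
    seed_ids <- lin
  } else {
    seed_ids <- as.integer(seed_ids)[ord]
    if (any(diff(seed_ids) <= 0))
      stop("seed_ids must be strictly increasing in mask order", call. = FALSE)
  }
  coords <- voxel_to_world(vox_idx, affine)
  if (anyDuplicated(coords)) stop("seed coordinates are not unique", call. = FALSE)
  structure(
    list(n_seeds = nrow(vox_idx), coords = coords, vox_idx = vox_idx,
         seed_ids = seed_ids, dim = dim, affine = affine,
         voxel_size = voxel_size, hemisphere = hemisphere),
    class = "seed_space")
}

# Linear index with the last axis fastest (1-based result).
linear_index <- function(vox_idx, dim) {
  ((vox_idx[, 1L] - 1L) * dim[2L] + (vox_idx[, 2L] - 1L)) * dim[3L] + vox_idx[, 3L]
}

voxel_to_world <- function(vox_idx, affine) {
  hom <- cbind(vox_idx - 1L, 1)          # NIfTI affines act on 0-based indices
  xyz <- hom %*% t(affine)
  unname(xyz[, 1:3, drop = FALSE])
}

#' @export
print.seed_space <- function(x, ...) {
  cat(sprintf("<seed_space> %d seeds, hemisphere %s, voxel %.3g mm\n",
              x$n_seeds, x$hemisphere, x$voxel_size))
  invisible(x)
}

#' Read a seed space from a binary NIfTI mask
#'
#' One seed per nonzero voxel; coordinates are affine-transformed voxel
#' centers; ordering follows the fixed linear-index convention described in
#' [seed_space()].
#'
#' @param path Path to a 3-D NIfTI volume containing only values 0 and 1.
#' @param hemisphere Hemisphere label for the mask.
#' @return A [seed_space()].
#' @export
read_seed_space <- function(path, hemisphere = c("L", "R")) {
  hemisphere <- match.arg(hemisphere)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L) stop("mask volume must be 3-D", call. = FALSE)
  vals <- unique(as.vector(arr))
  if (!all(vals %in% c(0, 1)))
    stop("mask volume is not binary (values other than 0/1 found)", call. = FALSE)
  if (sum(arr) == 0) stop("mask volume is empty", call. = FALSE)
  vox_idx <- which(arr != 0, arr.ind = TRUE)
  pd <- RNifti::pixdim(img)
  seed_space(vox_idx, dim(arr), as_affine(img), voxel_size = mean(pd[1:3]),
             hemisphere = hemisphere)
}

as_affine <- function(img) {
  xf <- RNifti::xform(img)
  matrix(as.numeric(xf), 4L, 4L)
}

#' Write a seed space as a binary NIfTI mask
#'
#' @param seeds A [seed_space()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_seed_mask <- function(seeds, path) {
  arr <- array(0, dim = seeds$dim)
  arr[seeds$vox_idx] <- 1
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, sqrt(colSums(seeds$affine[1:3, 1:3]^2)))
  img <- RNifti::`sform<-`(img, structure(seeds$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(seeds$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a seed space as TSV
#'
#' The TSV carries seed ids, voxel indices, and mm coordinates, plus metadata
#' comment lines (`# key=value`) holding the array dimensions, affine, voxel
#' size and hemisphere, so a round trip reproduces the seed space exactly.
#'
#' @param seeds A [seed_space()].
#' @param path Output TSV path.
#' @return `path` (write) or a [seed_space()] (read).
#' @export
write_seed_space <- function(seeds, path) {
  meta <- c(
    sprintf("# hemisphere=%s voxel_size=%.17g dim=%s", seeds$hemisphere,
            seeds$voxel_size, paste(seeds$dim, collapse = ",")),
    sprintf("# affine=%s", paste(sprintf("%.17g", as.vector(seeds$affine)),
                                 collapse = ",")),
    "# ordering=ascending linear index, last axis fastest")
  df <- data.frame(seed_id = seeds$seed_ids,
                   i = seeds$vox_idx[, 1L], j = seeds$vox_idx[, 2L],
                   k = seeds$vox_idx[, 3L],
                   x = seeds$coords[, 1L], y = seeds$coords[, 2L],
                   z = seeds$coords[, 3L])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seed_space
#' @export
read_seed_space_tsv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  kv <- parse_meta(meta)
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          check.names = FALSE)
  dim <- as.integer(strsplit(kv[["dim"]], ",")[[1L]])
  affine <- matrix(as.numeric(strsplit(kv[["affine"]], ",")[[1L]]), 4L, 4L)
  seed_space(as.matrix(df[, c("i", "j", "k")]), dim, affine,
             voxel_size = as.numeric(kv[["voxel_size"]]),
             hemisphere = kv[["hemisphere"]], seed_ids = df$seed_id)
}

parse_meta <- function(meta_lines) {
  toks <- unlist(strsplit(sub("^#\\s*", "", meta_lines), "\\s+"))
  toks <- toks[grepl("=", toks, fixed = TRUE)]
  kv <- strsplit(toks, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(p) paste(p[-1L], collapse = "="), ""),
                  vapply(kv, `[[`, "", 1L))
}

#' Parcel spaces: the ordered cortical target parcels
#'
#' @param parcel_ids Unique parcel labels (coerced to character).
#' @param community Optional per-parcel functional community labels
#'   (canonically Visual, Somatomotor, DAN, VAN, Limbic, FPN, DMN); when
#'   present they must cover all parcels.
#' @return An object of class `parcel_space`.
#' @export
parcel_space <- function(parcel_ids, community = NULL) {
  parcel_ids <- as.character(parcel_ids)
  if (anyDuplicated(parcel_ids)) stop("parcel_ids must be unique", call. = FALSE)
  if (!is.null(community)) {
    community <- as.character(community)
    if (length(community) != length(parcel_ids) || anyNA(community))
      stop("community labels, when present, must cover all parcels", call. = FALSE)
  }
  structure(list(n_parcels = length(parcel_ids), parcel_ids = parcel_ids,
                 community = community),
            class = "parcel_space")
}

#' @export
print.parcel_space <- function(x, ...) {
  cat(sprintf("<parcel_space> %d parcels%s\n", x$n_parcels,
              if (is.null(x$community)) "" else
                sprintf(", %d communities", length(unique(x$community)))))
  invisible(x)
}

#' Write / read a parcel table (parcel_id -> community) as TSV
#' @param parcels A [parcel_space()].
#' @param path TSV path.
#' @return `path` (write) or a [parcel_space()] (read).
#' @export
write_parcel_space <- function(parcels, path) {
  df <- data.frame(parcel_id = parcels$parcel_ids)
  if (!is.null(parcels$community)) df$community <- parcels$community
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parcel_space
#' @export
read_parcel_space <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  parcel_space(df$parcel_id, community = df$community)
}
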