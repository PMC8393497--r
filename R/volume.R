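#' @importFrom stats rnorm runif sd var qnorm pnorm pt setNames
#' @importFrom utils read.csv write.csv
NULL

VALID_UNITS <- c("ms", "mm2_per_s", "activity", "ratio", "probability", "count")

#' Construct a voxel volume
#'
#' A `voxel_volume` bundles a 3-D scalar array with the 4x4 affine that maps
#' 0-based voxel indices (i, j, k, 1) to world coordinates in millimetres, and
#' an explicit units tag. The units tag travels with the data so that
#' quantities measured in different units (relaxation times in ms, diffusion
#' in mm^2/s, tracer activity, ratios, probabilities) can never be mixed
#' silently.
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 numeric matrix, voxel-index (0-based) to world-mm
#'   transform. Must be invertible.
#' @param units one of `"ms"`, `"mm2_per_s"`, `"activity"`, `"ratio"`,
#'   `"probability"`, `"count"`.
#' @return An object of class `voxel_volume` with elements `data`, `affine`,
#'   `units`.
#' @export
voxel_volume <- function(data, affine = diag(4), units) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_relaxo("non-3-D", "volume data must be a 3-D array, got ",
                paste(dim(data), collapse = "x"))
  if (any(dim(data) < 1L))
    stop_relaxo("non-3-D", "all three dimensions must be >= 1")
  affine <- as_affine(affine)
  units <- match.arg(units, VALID_UNITS)
  structure(list(data = data, affine = affine, units = units),
            class = "voxel_volume")
}

#' Construct a binary mask volume
#'
#' @param data 3-D logical (or 0/1 numeric) array.
#' @param affine as in [voxel_volume()].
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(data, affine = diag(4)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_relaxo("non-3-D", "mask data must be a 3-D array")
  if (is.numeric(data)) {
    bad <- !(data %in% c(0, 1))
    if (any(bad))
      stop_relaxo("non-binary-mask", sum(bad), " voxels are neither 0 nor 1")
    data <- array(data != 0, dim = dim(data))
  }
  if (!is.logical(data)) stop_relaxo("non-binary-mask", "mask must be logical or 0/1")
  structure(list(data = data, affine = as_affine(affine)),
            class = "mask_volume")
}

as_affine <- function(affine) {
  affine <- unclass(affine)
  attributes(affine) <- attributes(affine)["dim"]
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop_relaxo("bad-affine", "affine must be a 4x4 matrix")
  d <- det(affine)
  if (!is.finite(d) || abs(d) < .Machine$double.eps * 64)
    stop_relaxo("singular-affine", "affine is singular (det = ", d, ")")
  storage.mode(affine) <- "double"
  affine
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(dim(x$data), collapse = " x "),
      " [", x$units, "]\n", sep = "")
  sp <- voxel_spacing(x)
  cat("  spacing (mm): ", paste(signif(sp, 4), collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat("<mask_volume> ", paste(dim(x$data), collapse = " x "),
      ", ", sum(x$data), " voxels set\n", sep = "")
  invisible(x)
}

#' Voxel spacing along each axis in mm
#' @param volume a `voxel_volume` or `mask_volume`.
#' @return numeric length-3 vector of voxel edge lengths in mm.
#' @export
voxel_spacing <- function(volume) {
  A <- volume$affine[1:3, 1:3]
  sqrt(colSums(A^2))
}

#' Typed error helper: all package errors carry class `relaxo_error` plus a
#' condition-specific subclass so callers and tests can discriminate failure
#' modes.
#' @noRd
stop_relaxo <- function(subclass, ...) {
  stop(structure(
    class = c(paste0("relaxo_", gsub("-", "_", subclass)), "relaxo_error",
              "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!all(dim(a$data) == dim(b$data)))
    stop_relaxo("shape-mismatch", what, " differ in shape: ",
                paste(dim(a$data), collapse = "x"), " vs ",
                paste(dim(b$data), collapse = "x"))
  if (max(abs(a$affine - b$affine)) > 1e-6)
    stop_relaxo("affine-mismatch", what, " differ in affine")
  invisible(TRUE)
}

check_units <- function(volume, expected) {
  if (!identical(volume$units, expected))
    stop_relaxo("units-mismatch", "expected units '", expected,
                "' but volume is tagged '", volume$units, "'")
  invisible(TRUE)
}

#' Read a volume from a NIfTI-1 file
#'
#' The affine is taken from the file's sform/qform and maps 0-based voxel
#' indices to world mm. The units tag is never guessed from the file: pass it
#' explicitly, or let it be read from the JSON sidecar `<path>.json` written
#' by [write_volume()].
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param units units tag (see [voxel_volume()]); if `NULL`, the sidecar is
#'   consulted and its absence is an error.
#' @return A `voxel_volume`.
#' @export
read_volume <- function(path, units = NULL) {
  if (!file.exists(path))
    stop_relaxo("missing-file", "no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop_relaxo("non-3-D", "expected a 3-D image, got ", length(d),
                " dimensions in ", path)
  if (is.null(units)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop_relaxo("unknown-units",
                  "units not given and no sidecar found at ", sidecar)
    units <- jsonlite::read_json(sidecar)$units
  }
  aff <- RNifti::xform(img)
  voxel_volume(array(as.numeric(img), dim = d), aff, units)
}

#' Write a volume to a NIfTI-1 file
#'
#' Writes the data with the affine stored as the sform (code 2) and a JSON
#' sidecar `<path>.json` carrying the units tag.
#'
#' @param volume a `voxel_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  img <- RNifti::asNifti(volume$data)
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(units = volume$units), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a binary mask from a NIfTI-1 file
#' @param path path to a NIfTI file with 0/1 voxels.
#' @return A `mask_volume`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    stop_relaxo("missing-file", "no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop_relaxo("non-3-D", "expected a 3-D mask, got ", length(d), " dims")
  mask_volume(array(as.numeric(img), dim = d), RNifti::xform(img))
}

#' Write a binary mask to a NIfTI-1 file
#' @param mask a `mask_volume`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_volume"))
  img <- RNifti::asNifti(array(as.integer(mask$data), dim = dim(mask$data)))
  img <- RNifti::`sform<-`(img, structure(mask$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert world coordinates (mm) to continuous 0-based voxel indices
#'
#' Applies the inverse affine with no rounding or clamping. Coordinates that
#' land outside the grid are returned as-is with the `out_of_bounds` attribute
#' set, so callers can decide how to treat them.
#'
#' @param world_xyz numeric length-3 world coordinate in mm, or an n x 3
#'   matrix of coordinates.
#' @param volume a `voxel_volume` or `mask_volume` supplying the affine and
#'   grid extent.
#' @return Continuous 0-based index vector (or n x 3 matrix), with a logical
#'   attribute `out_of_bounds` (per row).
#' @export
world_to_voxel <- function(world_xyz, volume) {
  aff <- volume$affine
  inv <- solve(aff)
  single <- is.null(dim(world_xyz))
  W <- if (single) matrix(world_xyz, nrow = 1) else as.matrix(world_xyz)
  if (ncol(W) != 3L) stop_relaxo("bad-coordinate", "world coordinates must have 3 components")
  if (!all(is.finite(W))) stop_relaxo("bad-coordinate", "non-finite world coordinate")
  idx <- t(inv %*% rbind(t(W), 1))[, 1:3, drop = FALSE]
  d <- dim(volume$data)
  oob <- idx[, 1] < -0.5 | idx[, 1] > d[1] - 0.5 |
         idx[, 2] < -0.5 | idx[, 2] > d[2] - 0.5 |
         idx[, 3] < -0.5 | idx[, 3] > d[3] - 0.5
  if (single) {
    out <- as.numeric(idx[1, ])
    attr(out, "out_of_bounds") <- oob[1]
  } else {
    out <- idx
    attr(out, "out_of_bounds") <- oob
  }
  out
}

#' Convert 0-based voxel indices to world coordinates (mm)
#' @param index numeric length-3 0-based voxel index, or n x 3 matrix.
#' @param volume volume supplying the affine.
#' @return world coordinate(s) in mm.
#' @export
voxel_to_world <- function(index, volume) {
  single <- is.null(dim(index))
  V <- if (single) matrix(index, nrow = 1) else as.matrix(index)
  W <- t(volume$affine %*% rbind(t(V), 1))[, 1:3, drop = FALSE]
  if (single) as.numeric(W[1, ]) else W
}
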