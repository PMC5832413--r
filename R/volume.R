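# Minimal volume container: a 3D array with a 4x4 affine mapping 0-based voxel
# indices to world mm. The pre-installed R stack has no NIfTI reader, so
# volumes are serialized as a plain-text voxel table plus a JSON header (see
# read_volume_tsv / write_volume_tsv).

#' Construct a volume
#'
#' @param data 3D numeric or logical array
#' @param affine 4x4 matrix mapping homogeneous 0-based voxel indices
#'   (i, j, k, 1) to world mm; default 2 mm isotropic, origin at voxel (0,0,0)
#' @return the array with class `volume` and an `affine` attribute
#' @export
volume <- function(data, affine = NULL) {
  if (length(dim(data)) != 3) stop("volume data must be a 3D array")
  if (is.null(affine)) affine <- diag(c(2, 2, 2, 1))
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be 4x4")
  structure(data, class = c("volume", class(data)), affine = affine)
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("volume: %s, %s values\n", paste(dim(x), collapse = " x "),
              typeof(x)))
  invisible(x)
}

#' Affine of a volume
#' @param x a `volume`
#' @return 4x4 matrix
#' @export
vol_affine <- function(x) attr(x, "affine")

#' World coordinates of voxels
#'
#' @param idx n x 3 matrix of 1-based array indices (as from [which()] with
#'   `arr.ind = TRUE`)
#' @param affine 4x4 affine
#' @return n x 3 matrix of world mm coordinates
#' @export
voxel_to_world <- function(idx, affine) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  h <- cbind(idx - 1, 1)          # 0-based internally
  out <- h %*% t(affine)
  out[, 1:3, drop = FALSE]
}
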