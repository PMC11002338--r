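#' Gradient table for a single-shell DWI acquisition
#'
#' Bundles b-values with unit gradient directions and validates the
#' combination: every direction paired with a nonzero b-value must have unit
#' Euclidean norm (to 1e-4), at least one b = 0 entry must be present, and at
#' least six non-collinear diffusion-weighted directions are required for a
#' tensor fit. b-values below `b0_threshold` count as b = 0, since scanners
#' commonly emit small nonzero nominal values.
#'
#' @param bvals Numeric vector of b-values (s/mm^2), all non-negative.
#' @param bvecs Direction cosines, either a 3 x q matrix (FSL row dialect) or
#'   q x 3; the layout is detected from the shape.
#' @param b0_threshold b-values strictly below this count as b = 0 (s/mm^2).
#' @return An object of class `gradient_table` with elements `bvals`
#'   (length q), `bvecs` (q x 3), and `b0_threshold`.
#' @export
gradient_table <- function(bvals, bvecs, b0_threshold = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- unname(as.matrix(bvecs))
  if (nrow(bvecs) == 3L && ncol(bvecs) != 3L) bvecs <- t(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) == 3L && length(bvals) == 3L) {
    # ambiguous 3x3: assume FSL 3-row layout
    bvecs <- t(bvecs)
  }
  if (ncol(bvecs) != 3L) abort("`bvecs` must be 3 x q or q x 3")
  if (nrow(bvecs) != length(bvals)) {
    abort(sprintf("gradient count mismatch: %d b-values but %d directions",
                  length(bvals), nrow(bvecs)))
  }
  if (any(!is.finite(bvals)) || any(bvals < 0)) abort("b-values must be finite and >= 0")
  dwi <- bvals >= b0_threshold
  if (!any(!dwi)) abort("gradient table needs at least one b = 0 entry")
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- dwi & abs(nrm - 1) > 1e-4
  if (any(bad)) {
    abort(sprintf("%d diffusion-weighted bvecs are not unit norm (worst |norm-1| = %.2e)",
                  sum(bad), max(abs(nrm[bad] - 1))))
  }
  g <- bvecs[dwi, , drop = FALSE]
  # non-collinearity: the quadratic-form design spanned by the directions
  # must have full rank 6 for the six unique tensor elements
  q6 <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
              2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  if (nrow(g) < 6L || qr(q6)$rank < 6L) {
    abort("at least 6 non-collinear diffusion-weighted directions are required")
  }
  structure(list(bvals = bvals, bvecs = bvecs, b0_threshold = b0_threshold),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  nb0 <- sum(x$bvals < x$b0_threshold)
  cat(sprintf("<gradient_table> %d volumes: %d b0, %d diffusion-weighted (b = %s)\n",
              length(x$bvals), nb0, length(x$bvals) - nb0,
              paste(unique(round(x$bvals[x$bvals >= x$b0_threshold])), collapse = ", ")))
  invisible(x)
}

is_b0 <- function(gtab) gtab$bvals < gtab$b0_threshold

#' 4-D diffusion-weighted volume
#'
#' @param signal 4-D non-negative array (x, y, z, q).
#' @param affine 4 x 4 voxel-to-world matrix (mm, RAS+, 0-based voxel indices).
#' @param gtab A [gradient_table()]; its length must match the 4th dimension.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(signal, affine, gtab) {
  if (length(dim(signal)) != 4L) abort("`signal` must be a 4-D array")
  if (dim(signal)[4] != length(gtab$bvals)) {
    abort(sprintf("volume/gradient mismatch: image has %d volumes but gradient table has %d entries",
                  dim(signal)[4], length(gtab$bvals)))
  }
  affine <- check_affine(affine)
  if (any(signal < 0, na.rm = TRUE)) abort("`signal` must be non-negative")
  structure(list(signal = signal, affine = affine, gtab = gtab),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dwi_volume> %d x %d x %d grid, %d volumes, voxel %.3g mm\n",
              d[1], d[2], d[3], d[4], abs(x$affine[1, 1])))
  invisible(x)
}

check_affine <- function(affine) {
  affine <- matrix(as.numeric(affine), nrow(as.matrix(affine)))
  if (!all(dim(affine) == c(4L, 4L))) abort("affine must be 4 x 4")
  if (abs(det(affine)) < .Machine$double.eps) abort("affine is singular")
  affine
}

#' Binary volume mask
#'
#' @param data 3-D array with values in \{0, 1\} (logical accepted).
#' @param affine 4 x 4 voxel-to-world matrix.
#' @return An object of class `volume_mask`; `data` is stored as logical.
#' @export
volume_mask <- function(data, affine) {
  if (length(dim(data)) != 3L) abort("mask must be a 3-D array")
  v <- as.vector(data)
  if (!all(v %in% c(0, 1, TRUE, FALSE))) abort("mask values must be 0/1")
  structure(list(data = array(as.logical(data), dim(data)), affine = check_affine(affine)),
            class = "volume_mask")
}

as_mask_array <- function(mask, shape) {
  if (is.null(mask)) return(array(TRUE, shape))
  m <- if (inherits(mask, "volume_mask")) mask$data else mask
  if (!identical(dim(m), as.integer(shape))) {
    abort(sprintf("mask grid %s does not match volume grid %s",
                  paste(dim(m), collapse = "x"), paste(shape, collapse = "x")))
  }
  array(as.logical(m), shape)
}

#' Read a DWI series from NIfTI plus FSL bval/bvec files
#'
#' @param image_path Path to a 4-D NIfTI image (.nii or .nii.gz).
#' @param bval_path Whitespace-delimited b-value file (one row).
#' @param bvec_path Whitespace-delimited bvec file, 3 rows x q columns
#'   (a transposed q x 3 layout is detected and accepted).
#' @param b0_threshold Passed to [gradient_table()].
#' @return A [dwi_volume()].
#' @export
read_dwi <- function(image_path, bval_path, bvec_path, b0_threshold = 50) {
  img <- RNifti::readNifti(image_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) abort("DWI image must be 4-D")
  bvals <- scan(bval_path, quiet = TRUE)
  bvec_rows <- utils::read.table(bvec_path)
  gtab <- gradient_table(bvals, as.matrix(bvec_rows), b0_threshold = b0_threshold)
  if (length(gtab$bvals) != dim(arr)[4]) {
    abort(sprintf("image has %d volumes but gradient files list %d entries",
                  dim(arr)[4], length(gtab$bvals)))
  }
  dwi_volume(arr, affine = unclass(RNifti::xform(img)), gtab = gtab)
}

#' Write a DWI series as NIfTI plus FSL bval/bvec files
#'
#' @param vol A [dwi_volume()].
#' @param image_path,bval_path,bvec_path Output paths.
#' @return Invisibly, a named character vector of the three paths written.
#' @export
write_dwi <- function(vol, image_path, bval_path, bvec_path) {
  if (!inherits(vol, "dwi_volume")) abort("`vol` must be a dwi_volume")
  write_nifti_map(vol$signal, vol$affine, image_path)
  writeLines(paste(format(vol$gtab$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  bv <- t(vol$gtab$bvecs)  # 3 rows x q columns, FSL dialect
  writeLines(apply(bv, 1, function(r) paste(format(r, digits = 15), collapse = " ")),
             bvec_path)
  invisible(c(image = image_path, bval = bval_path, bvec = bvec_path))
}

#' Write a 3-D or 4-D array as NIfTI with a given affine
#'
#' @param map Numeric array.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param path Output path (.nii or .nii.gz).
#' @return Invisibly, `path`.
#' @export
write_nifti_map <- function(map, affine, path) {
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  nd <- length(dim(map))
  img <- RNifti::asNifti(map)
  img <- RNifti::`pixdim<-`(img, c(vox, rep(1, max(0, nd - 3))))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-D NIfTI map
#'
#' @param path Path to a NIfTI file.
#' @return List with `data` (array) and `affine`.
#' @export
read_nifti_map <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), affine = unclass(RNifti::xform(img)))
}

# World-mm coordinates of every voxel center, 0-based indices. Returns an
# n x 3 matrix in grid (column-major) order.
voxel_world_coords <- function(shape, affine) {
  idx <- as.matrix(expand.grid(x = seq_len(shape[1]) - 1L,
                               y = seq_len(shape[2]) - 1L,
                               z = seq_len(shape[3]) - 1L))
  sweep(idx %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], `+`)
}

#' Resample a 3-D map under a world-space affine transform
#'
#' Applies a user-supplied affine (e.g., an externally estimated
#' registration) by pulling values from the source grid onto a target grid.
#' The transform maps source world coordinates to target world coordinates;
#' estimation of such transforms is outside the scope of this package.
#'
#' @param map 3-D numeric array.
#' @param affine Source voxel-to-world matrix.
#' @param transform 4 x 4 world-to-world transform (must be invertible).
#' @param target_shape Integer length-3 grid shape (defaults to `dim(map)`).
#' @param target_affine Target voxel-to-world matrix (defaults to `affine`).
#' @param interp `"trilinear"` for continuous maps, `"nearest"` for masks
#'   and label images.
#' @param fill Value used outside the source grid.
#' @return 3-D array on the target grid.
#' @export
resample_affine <- function(map, affine, transform = diag(4),
                            target_shape = dim(map), target_affine = affine,
                            interp = c("trilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  affine <- check_affine(affine)
  transform <- as.matrix(transform)
  if (!all(dim(transform) == c(4L, 4L)) || abs(det(transform)) < .Machine$double.eps) {
    abort("`transform` must be an invertible 4 x 4 matrix")
  }
  target_affine <- check_affine(target_affine)
  # target voxel -> target world -> source world -> source voxel
  M <- solve(affine) %*% solve(transform) %*% target_affine
  idx <- as.matrix(expand.grid(x = seq_len(target_shape[1]) - 1L,
                               y = seq_len(target_shape[2]) - 1L,
                               z = seq_len(target_shape[3]) - 1L))
  src <- sweep(idx %*% t(M[1:3, 1:3]), 2, M[1:3, 4], `+`)
  d <- dim(map)
  gather <- function(i, j, k) {
    ok <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 & k >= 0 & k <= d[3] - 1
    out <- rep(fill, length(i))
    lin <- 1L + i[ok] + d[1] * (j[ok] + d[2] * k[ok])
    out[ok] <- map[lin]
    out
  }
  if (interp == "nearest") {
    vals <- gather(round(src[, 1]), round(src[, 2]), round(src[, 3]))
  } else {
    i0 <- floor(src[, 1]); j0 <- floor(src[, 2]); k0 <- floor(src[, 3])
    fx <- src[, 1] - i0; fy <- src[, 2] - j0; fz <- src[, 3] - k0
    vals <- gather(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
      gather(i0 + 1, j0, k0) * fx * (1 - fy) * (1 - fz) +
      gather(i0, j0 + 1, k0) * (1 - fx) * fy * (1 - fz) +
      gather(i0, j0, k0 + 1) * (1 - fx) * (1 - fy) * fz +
      gather(i0 + 1, j0 + 1, k0) * fx * fy * (1 - fz) +
      gather(i0 + 1, j0, k0 + 1) * fx * (1 - fy) * fz +
      gather(i0, j0 + 1, k0 + 1) * (1 - fx) * fy * fz +
      gather(i0 + 1, j0 + 1, k0 + 1) * fx * fy * fz
  }
  array(vals, target_shape)
}
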