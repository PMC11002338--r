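# Log-linear design matrix for the single-tensor model:
# ln S_q = ln s0 - b_q g_q^T D g_q, with D packed as
# (dxx, dyy, dzz, dxy, dxz, dyz).
tensor_design <- function(gtab) {
  g <- gtab$bvecs
  b <- gtab$bvals
  cbind(1, -b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                      2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                      2 * g[, 2] * g[, 3]))
}

# q x 6 matrix such that Xb %*% d6 = b_q g^T D g per volume
bquad_design <- function(gtab) {
  g <- gtab$bvecs
  gtab$bvals * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                     2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                     2 * g[, 2] * g[, 3])
}

# Average multiple b0 volumes into a single leading volume; standard
# practice before tensor fitting.
collapse_b0 <- function(dwi) {
  b0 <- is_b0(dwi$gtab)
  if (sum(b0) <= 1L) return(dwi)
  d <- dim(dwi$signal)
  sig <- matrix(dwi$signal, prod(d[1:3]), d[4])
  b0mean <- rowMeans(sig[, b0, drop = FALSE])
  keep <- which(!b0)
  out <- cbind(b0mean, sig[, keep, drop = FALSE])
  gtab <- gradient_table(c(0, dwi$gtab$bvals[keep]),
                         rbind(c(0, 0, 0), dwi$gtab$bvecs[keep, , drop = FALSE]),
                         b0_threshold = dwi$gtab$b0_threshold)
  dwi_volume(array(out, c(d[1:3], ncol(out))), dwi$affine, gtab)
}

# Floor non-positive signals at (smallest positive observed value) x 1e-3
# so the log-linear fit is defined; matches common dtifit-style practice.
floor_signal <- function(sig) {
  pos <- sig[sig > 0]
  floorv <- if (length(pos)) min(pos) * 1e-3 else 1e-12
  sig[sig <= 0] <- floorv
  sig
}

#' Fit the single diffusion tensor model
#'
#' Per-voxel (weighted) least-squares solution of the log-linearized tensor
#' model, the same estimator as FSL's `dtifit`. WLS weights are the squared
#' predicted signals from an initial OLS pass, correcting the
#' heteroscedasticity introduced by the log transform of Rician-distributed
#' magnitudes. Negative eigenvalues are clamped to zero (never reordered by
#' magnitude) and the affected voxels flagged as degenerate.
#'
#' @param dwi A [dwi_volume()] with at least 6 directions plus b0.
#' @param mask Optional [volume_mask()] or logical array restricting the fit.
#' @param method `"wls"` (default) or `"ols"`.
#' @return An object of class `tensor_maps`: 4-D `tensor` array
#'   (x, y, z, 6; order dxx, dyy, dzz, dxy, dxz, dyz), eigenvalue array
#'   `evals` (x, y, z, 3; descending), maps `fa`, `md`, `dxx`, `dyy`, `dzz`,
#'   `s0`, logical `degenerate` flag, plus `mask` and `affine`.
#' @export
fit_tensor <- function(dwi, mask = NULL, method = c("wls", "ols")) {
  method <- match.arg(method)
  if (!inherits(dwi, "dwi_volume")) abort("`dwi` must be a dwi_volume")
  dwi <- collapse_b0(dwi)
  shape <- dim(dwi$signal)[1:3]
  m <- as_mask_array(mask, shape)
  if (!any(m)) abort("mask is empty")
  if (length(dwi$gtab$bvals) < 7L) abort("need at least 7 volumes (6 directions + b0)")
  X <- tensor_design(dwi$gtab)
  cn <- kappa(crossprod(X), exact = TRUE)
  if (!is.finite(cn) || cn > 1e12) {
    abort(sprintf("rank-deficient gradient design (condition number %.3g)", cn))
  }
  sig <- matrix(dwi$signal, prod(shape), dim(dwi$signal)[4])[m, , drop = FALSE]
  logS <- log(floor_signal(t(sig)))              # q x nvox
  B <- cpp_wls_fit(X, logS, reweight = if (method == "wls") 1L else 0L)
  ec <- cpp_eig_clamp(B[2:7, , drop = FALSE], 0, Inf)
  mk_map <- function(values) {
    out <- array(NA_real_, shape)
    out[m] <- values
    out
  }
  tensor <- array(NA_real_, c(shape, 6L))
  evals <- array(NA_real_, c(shape, 3L))
  for (k in 1:6) tensor[, , , k][m] <- ec$tensor[k, ]
  for (k in 1:3) evals[, , , k][m] <- ec$evals[k, ]
  fa <- mk_map(fa_from_eigenvalues(ec$evals[1, ], ec$evals[2, ], ec$evals[3, ]))
  structure(list(
    tensor = tensor, evals = evals, fa = fa,
    md = mk_map(colMeans(ec$evals)),
    dxx = mk_map(ec$tensor[1, ]), dyy = mk_map(ec$tensor[2, ]),
    dzz = mk_map(ec$tensor[3, ]),
    s0 = mk_map(exp(B[1, ])),
    degenerate = mk_map(ec$flag) > 0,
    mask = m, affine = dwi$affine, method = method
  ), class = "tensor_maps")
}

#' @export
print.tensor_maps <- function(x, ...) {
  cat(sprintf("<tensor_maps> %s grid, %d voxels fitted (%s), median FA %.3f\n",
              paste(dim(x$fa), collapse = " x "), sum(x$mask), x$method,
              stats::median(x$fa[x$mask], na.rm = TRUE)))
  invisible(x)
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' \deqn{FA = \sqrt{1/2}\,
#'   \frac{\sqrt{(\lambda_1-\lambda_2)^2 + (\lambda_2-\lambda_3)^2 +
#'   (\lambda_1-\lambda_3)^2}}{\sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}}}
#' Vectorized; voxels with all-zero eigenvalues get FA = 0 (carried in the
#' `"zero_flag"` attribute).
#'
#' @param l1,l2,l3 Eigenvalue vectors, all >= 0.
#' @return FA values in \[0, 1\], with attribute `zero_flag`.
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  if (any(c(l1, l2, l3) < 0, na.rm = TRUE)) abort("eigenvalues must be >= 0")
  ss <- l1^2 + l2^2 + l3^2
  zero <- ss == 0
  num <- sqrt((l1 - l2)^2 + (l2 - l3)^2 + (l1 - l3)^2)
  fa <- ifelse(zero, 0, sqrt(0.5) * num / sqrt(pmax(ss, .Machine$double.xmin)))
  fa <- pmin(pmax(fa, 0), 1)
  attr(fa, "zero_flag") <- zero
  fa
}

#' Axis diffusivities from a fitted tensor field
#'
#' The three diagonal tensor elements in image/atlas axes (not the
#' eigenframe): the quantities entering the ALPS ratio.
#'
#' @param x A `tensor_maps` object or a 4-D tensor array
#'   (x, y, z, 6; order dxx, dyy, dzz, dxy, dxz, dyz).
#' @return Named list of three 3-D maps `dxx`, `dyy`, `dzz` (mm^2/s).
#' @export
axis_diffusivities <- function(x) {
  t6 <- if (inherits(x, "tensor_maps")) x$tensor else x
  if (length(dim(t6)) != 4L || dim(t6)[4] != 6L) {
    abort("expected a tensor field with 6 elements per voxel")
  }
  list(dxx = t6[, , , 1], dyy = t6[, , , 2], dzz = t6[, , , 3])
}
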