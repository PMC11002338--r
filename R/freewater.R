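#' Configuration of the bi-tensor free-water fit
#'
#' Single-shell bi-tensor estimation is ill-posed without constraints; all
#' stabilizing choices live here. Tissue eigenvalues are confined to
#' `lambda_bounds` to keep the tissue compartment separated from free water,
#' the fraction map is regularized by Gaussian spatial smoothing, and voxels
#' whose profile objective is nearly flat in f (the single-shell ridge) are
#' flagged rather than masked.
#'
#' @param d_w Free-water diffusivity (mm^2/s); body-temperature literature
#'   value 3.0e-3.
#' @param lambda_bounds Tissue eigenvalue bounds (mm^2/s).
#' @param sigma Gaussian smoothing sigma for the f map, in voxels
#'   (0 disables the spatial regularizer).
#' @param max_iter Maximum alternating iterations of the smoothing loop.
#' @param tol Convergence tolerance on the maximum per-voxel change in f.
#' @param f_bounds Bounds for the estimated fraction.
#' @param md_tissue_ref Reference tissue mean diffusivity used by the
#'   initializer (mm^2/s).
#' @param flat_tol Curvature threshold (per unit f^2, normalized signal
#'   units) below which a voxel is flagged as lying on a flat ridge.
#' @return An object of class `fw_config`.
#' @export
fw_config <- function(d_w = 3.0e-3, lambda_bounds = c(0.1e-3, 2.5e-3),
                      sigma = 1.0, max_iter = 50, tol = 1e-4,
                      f_bounds = c(0, 1), md_tissue_ref = 0.6e-3,
                      flat_tol = 1e-6) {
  if (lambda_bounds[1] >= lambda_bounds[2] || f_bounds[1] >= f_bounds[2]) {
    abort("bounds must be ordered")
  }
  if (tol <= 0) abort("`tol` must be > 0")
  structure(list(d_w = d_w, lambda_bounds = lambda_bounds, sigma = sigma,
                 max_iter = max_iter, tol = tol, f_bounds = f_bounds,
                 md_tissue_ref = md_tissue_ref, flat_tol = flat_tol),
            class = "fw_config")
}

#' Initial free-water fraction from mean diffusivity
#'
#' Linear interpolation of the single-tensor MD between a reference tissue
#' MD and the free-water diffusivity, clipped to \[0.05, 0.95\]:
#' `f_init = clip((MD - MD_ref) / (d_w - MD_ref), 0.05, 0.95)`. Monotone
#' non-decreasing in MD.
#'
#' @param md Mean diffusivity map or vector (mm^2/s).
#' @param cfg A [fw_config()].
#' @return f values, same shape as `md`.
#' @export
init_fw <- function(md, cfg = fw_config()) {
  raw <- (md - cfg$md_tissue_ref) / (cfg$d_w - cfg$md_tissue_ref)
  pmin(pmax(raw, 0.05), 0.95)
}

# Separable Gaussian smoothing of a 3-D map restricted to a mask
# (normalized convolution, so edge voxels are not biased toward zero).
gaussian_smooth_masked <- function(map, mask, sigma) {
  if (sigma <= 0) return(map)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_axis <- function(a, axis) {
    out <- array(0, dim(a))
    for (off in seq(-r, r)) {
      w <- k[off + r + 1]
      idx_src <- pmin(pmax(seq_len(dim(a)[axis]) + off, 1L), dim(a)[axis])
      out <- out + w * switch(axis,
                              a[idx_src, , , drop = FALSE],
                              a[, idx_src, , drop = FALSE],
                              a[, , idx_src, drop = FALSE])
    }
    out
  }
  num <- map
  num[!mask] <- 0
  den <- array(as.numeric(mask), dim(map))
  for (ax in 1:3) {
    num <- conv_axis(num, ax)
    den <- conv_axis(den, ax)
  }
  out <- map
  out[mask] <- num[mask] / pmax(den[mask], .Machine$double.eps)
  out
}

#' Fit the bi-tensor free-water model
#'
#' Per voxel the model \eqn{S_q/s_0 = (1-f) e^{-b_q g^T D g} + f e^{-b_q
#' d_w}} is fitted by variable projection: for a candidate fraction f the
#' water compartment is subtracted, the tissue tensor refit by weighted
#' least squares with eigenvalue clamping, and f chosen by bounded 1-D
#' (golden-section) minimization of the resulting profile objective. When
#' `cfg$sigma > 0` the fit is spatially regularized by local likelihood
#' pooling: the profile objective is evaluated on a grid of candidate
#' fractions, Gaussian-smoothed across voxels within the mask, and each
#' voxel takes the parabolically refined argmin of its pooled objective —
#' neighboring voxels thereby share evidence along the single-shell ridge
#' without any iterative scheme that could drift. Voxels with a nearly flat
#' profile (near-isotropic tissue, the documented single-shell ridge) keep
#' their estimate and are flagged in `ridge_flag`.
#'
#' @param dwi A [dwi_volume()] (single shell plus b0).
#' @param mask Optional [volume_mask()] or logical array; must be nonempty.
#' @param cfg A [fw_config()].
#' @return An object of class `fw_result`: `f` map in \[0, 1\], corrected
#'   tissue `tensor_maps`, logical `ridge_flag` and `converged` maps, the
#'   profile `curvature` map the flag is derived from, `iterations`, and
#'   the config used.
#' @export
fit_fw <- function(dwi, mask = NULL, cfg = fw_config()) {
  if (!inherits(dwi, "dwi_volume")) abort("`dwi` must be a dwi_volume")
  dwi <- collapse_b0(dwi)
  shape <- dim(dwi$signal)[1:3]
  m <- as_mask_array(mask, shape)
  if (!any(m)) abort("mask is empty")
  gtab <- dwi$gtab
  X <- tensor_design(gtab)
  Xb <- bquad_design(gtab)
  sig <- t(matrix(dwi$signal, prod(shape), dim(dwi$signal)[4])[m, , drop = FALSE])
  sig <- floor_signal(sig)                       # q x nvox
  b0row <- which(is_b0(gtab))
  s0 <- colMeans(sig[b0row, , drop = FALSE])
  if (cfg$sigma <= 0) {
    fit <- cpp_fw_profile(sig, X, Xb, s0, gtab$bvals, cfg$d_w,
                          cfg$f_bounds[1], cfg$f_bounds[2],
                          cfg$lambda_bounds[1], cfg$lambda_bounds[2], cfg$tol)
    fvec <- fit$f
    D6 <- fit$tensor
    curv <- fit$curvature
    iterations <- 1L
  } else {
    fhi <- min(cfg$f_bounds[2], 0.99)
    fgrid <- seq(cfg$f_bounds[1], fhi, length.out = 41L)
    Jgrid <- cpp_fw_objective_grid(sig, X, Xb, s0, gtab$bvals, cfg$d_w,
                                   fgrid, cfg$lambda_bounds[1], cfg$lambda_bounds[2])
    # pool evidence spatially: smooth each candidate's objective map
    for (i in seq_along(fgrid)) {
      jm <- array(0, shape)
      jm[m] <- Jgrid[i, ]
      Jgrid[i, ] <- gaussian_smooth_masked(jm, m, cfg$sigma)[m]
    }
    h <- fgrid[2] - fgrid[1]
    best <- max.col(-t(Jgrid), ties.method = "first")
    # parabolic refinement through the argmin and its grid neighbors
    fvec <- vapply(seq_along(best), function(v) {
      i <- best[v]
      if (i == 1L || i == length(fgrid)) return(fgrid[i])
      y0 <- Jgrid[i - 1L, v]; y1 <- Jgrid[i, v]; y2 <- Jgrid[i + 1L, v]
      den <- y0 - 2 * y1 + y2
      if (den <= 0) return(fgrid[i])
      fgrid[i] + h * 0.5 * (y0 - y2) / den
    }, numeric(1))
    fvec <- pmin(pmax(fvec, cfg$f_bounds[1]), fhi)
    D6 <- cpp_fw_tensor_at_f(sig, X, s0, gtab$bvals, cfg$d_w, fvec,
                             cfg$lambda_bounds[1], cfg$lambda_bounds[2])$tensor
    ib <- pmin(pmax(best, 2L), length(fgrid) - 1L)
    curv <- vapply(seq_along(best), function(v) {
      (Jgrid[ib[v] - 1L, v] + Jgrid[ib[v] + 1L, v] - 2 * Jgrid[ib[v], v]) / h^2
    }, numeric(1))
    iterations <- 1L
  }
  ridge <- curv < cfg$flat_tol
  converged <- rep(TRUE, length(fvec))
  mk_map <- function(values, default = NA_real_) {
    out <- array(default, shape)
    out[m] <- values
    out
  }
  ecf <- cpp_eig_clamp(D6, cfg$lambda_bounds[1], cfg$lambda_bounds[2])
  tensor <- array(NA_real_, c(shape, 6L))
  evals <- array(NA_real_, c(shape, 3L))
  for (k in 1:6) tensor[, , , k][m] <- ecf$tensor[k, ]
  for (k in 1:3) evals[, , , k][m] <- ecf$evals[k, ]
  tissue <- structure(list(
    tensor = tensor, evals = evals,
    fa = mk_map(fa_from_eigenvalues(ecf$evals[1, ], ecf$evals[2, ], ecf$evals[3, ])),
    md = mk_map(colMeans(ecf$evals)),
    dxx = mk_map(ecf$tensor[1, ]), dyy = mk_map(ecf$tensor[2, ]),
    dzz = mk_map(ecf$tensor[3, ]),
    s0 = mk_map(s0), degenerate = mk_map(0) > 0,
    mask = m, affine = dwi$affine, method = "fw-corrected wls"
  ), class = "tensor_maps")
  structure(list(
    f = mk_map(fvec), tissue = tissue,
    ridge_flag = mk_map(as.numeric(ridge), default = 0) > 0,
    curvature = mk_map(curv),
    converged = mk_map(as.numeric(converged), default = 0) > 0,
    iterations = iterations, mask = m, affine = dwi$affine, config = cfg
  ), class = "fw_result")
}

#' @export
print.fw_result <- function(x, ...) {
  cat(sprintf("<fw_result> %d voxels, median f = %.3f, %d ridge-flagged, %d iterations\n",
              sum(x$mask), stats::median(x$f[x$mask]), sum(x$ridge_flag), x$iterations))
  invisible(x)
}

# Exact 1-D squared Euclidean distance transform (Felzenszwalb & Huttenlocher
# lower-envelope algorithm) of a sampled function f.
edt_1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1)
  k <- 1L
  v[1] <- 1L
  z[1] <- -Inf
  z[2] <- Inf
  for (q in 2:n) {
    repeat {
      vk <- v[k]
      s <- ((f[q] + q^2) - (f[vk] + vk^2)) / (2 * q - 2 * vk)
      if (s <= z[k]) {
        k <- k - 1L
      } else {
        k <- k + 1L
        v[k] <- q
        z[k] <- s
        z[k + 1] <- Inf
        break
      }
    }
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# Exact squared Euclidean distance (in voxels) from each TRUE voxel to the
# nearest FALSE voxel inside the grid; voxels beyond the grid edge are not
# treated as background. Regions with no background anywhere get Inf.
distance_transform <- function(mask) {
  d <- dim(mask)
  f <- array(ifelse(mask, 1e18, 0), d)   # large finite stand-in for Inf
  for (j in seq_len(d[2])) for (k in seq_len(d[3])) f[, j, k] <- edt_1d(f[, j, k])
  for (i in seq_len(d[1])) for (k in seq_len(d[3])) f[i, , k] <- edt_1d(f[i, , k])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) f[i, j, ] <- edt_1d(f[i, j, ])
  f[f >= 1e17] <- Inf
  f
}

#' White matter skeleton from an FA map
#'
#' A deterministic, simplified skeletonization standing in for the full
#' TBSS projection pipeline: voxels with FA above `fa_threshold` are kept
#' and thinned to the plateau local maxima of the exact Euclidean distance
#' transform over the 6-neighborhood — the medial surface of the
#' suprathreshold set. Idempotent: skeletonizing a skeleton returns it
#' unchanged.
#'
#' @param fa FA map (3-D array) or a `tensor_maps` object.
#' @param mask Optional additional mask.
#' @param fa_threshold FA threshold (TBSS convention 0.2).
#' @param affine Affine for the returned mask (taken from `fa` if it is a
#'   `tensor_maps`).
#' @return A [volume_mask()] of the skeleton.
#' @export
wm_skeleton <- function(fa, mask = NULL, fa_threshold = 0.2, affine = NULL) {
  if (inherits(fa, "tensor_maps")) {
    affine <- affine %||% fa$affine
    fa <- fa$fa
  }
  affine <- affine %||% diag(4)
  m <- as_mask_array(mask, dim(fa))
  sel <- !is.na(fa) & fa > fa_threshold & m
  if (!any(sel)) abort(sprintf("no voxels exceed the FA threshold %.3g", fa_threshold))
  dt <- distance_transform(sel)
  d <- dim(sel)
  keep <- array(FALSE, d)
  idx <- which(sel, arr.ind = TRUE)
  vals <- dt[sel]
  ge_neighbor <- rep(TRUE, nrow(idx))
  for (ax in 1:3) {
    for (off in c(-1L, 1L)) {
      nb <- idx
      nb[, ax] <- nb[, ax] + off
      ok <- nb[, ax] >= 1L & nb[, ax] <= d[ax]
      nlin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L) + d[1] * d[2] * (nb[ok, 3] - 1L)
      inmask <- sel[nlin]
      cmp <- rep(TRUE, nrow(idx))
      cmp[ok][inmask] <- vals[ok][inmask] >= dt[nlin][inmask]
      ge_neighbor <- ge_neighbor & cmp
    }
  }
  keep[sel] <- ge_neighbor
  volume_mask(keep, affine)
}

#' Mean free-water index over the white matter skeleton
#'
#' Arithmetic mean of the free-water fraction over skeleton voxels, with
#' lesion voxels excluded before averaging.
#'
#' @param f Free-water fraction map (3-D array) or an `fw_result`.
#' @param skeleton A [volume_mask()] (or logical array) of skeleton voxels.
#' @param lesion_mask Optional [volume_mask()] of voxels to exclude.
#' @return List with `fw_index`, `n_used`, `n_excluded`.
#' @export
mean_fw_on_skeleton <- function(f, skeleton, lesion_mask = NULL) {
  if (inherits(f, "fw_result")) f <- f$f
  sk <- as_mask_array(skeleton, dim(f))
  les <- if (is.null(lesion_mask)) array(FALSE, dim(f)) else as_mask_array(lesion_mask, dim(f))
  use <- sk & !les
  if (!any(use)) abort("no usable skeleton voxels after lesion exclusion")
  list(fw_index = mean(f[use]), n_used = sum(use), n_excluded = sum(sk & les))
}
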