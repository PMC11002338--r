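#' Evenly spread diffusion gradient directions
#'
#' Generates `n` unit directions by electrostatic repulsion of antipodal
#' point pairs on the sphere, the standard construction for single-shell
#' DWI sampling schemes. Deterministic for a fixed `seed`.
#'
#' @param n Number of directions.
#' @param seed Integer seed for the random initialization.
#' @param iterations Repulsion iterations.
#' @return n x 3 matrix of unit vectors.
#' @export
dwi_directions <- function(n = 32, seed = 42, iterations = 200) {
  g <- with_local_seed(seed, {
    m <- matrix(rnorm(3 * n), n, 3)
    m / sqrt(rowSums(m^2))
  })
  step <- 0.05
  for (it in seq_len(iterations)) {
    force_mat <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d <- sweep(rbind(g, -g), 2, g[i, ], `-`)   # vectors from g_i to all +/- points
      r2 <- rowSums(d^2)
      keep <- r2 > 1e-12
      force_mat[i, ] <- -colSums(d[keep, , drop = FALSE] / r2[keep]^1.5)
    }
    g <- g + step * force_mat / n
    g <- g / sqrt(rowSums(g^2))
    step <- step * 0.97
  }
  g
}

#' Simulate the bi-tensor DWI signal for one voxel
#'
#' Two-compartment signal model: an anisotropic tissue tensor plus an
#' isotropic free-water compartment with fixed diffusivity `d_w`,
#' \deqn{S_q = s_0 [(1-f) e^{-b_q g_q^T D g_q} + f e^{-b_q d_w}].}
#' At b = 0 the signal equals `s0` for any `f`.
#'
#' @param tensor 3 x 3 symmetric positive semi-definite tissue tensor
#'   (mm^2/s).
#' @param f Free-water fraction in \[0, 1\].
#' @param gtab A [gradient_table()].
#' @param s0 Non-diffusion-weighted signal level (> 0).
#' @param d_w Free-water diffusivity (mm^2/s); 3.0e-3 is the
#'   body-temperature literature value.
#' @return Numeric signal vector, one entry per gradient table row.
#' @export
simulate_signal <- function(tensor, f, gtab, s0 = 1000, d_w = 3.0e-3) {
  tensor <- as.matrix(tensor)
  if (!isTRUE(all.equal(tensor, t(tensor), tolerance = 1e-10))) {
    abort("`tensor` must be symmetric")
  }
  ev <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(abs(ev), 1e-30)) abort("`tensor` must be positive semi-definite")
  if (f < 0 || f > 1) abort("`f` must be in [0, 1]")
  stopifnot_scalar(s0, "s0")
  quad <- rowSums((gtab$bvecs %*% tensor) * gtab$bvecs)
  as.vector(s0 * ((1 - f) * exp(-gtab$bvals * quad) + f * exp(-gtab$bvals * d_w)))
}

#' Add measurement noise to a DWI signal
#'
#' Rician noise is the magnitude-MRI model: \eqn{\sqrt{(S+\epsilon_1)^2 +
#' \epsilon_2^2}} with independent Gaussian components of standard deviation
#' `s0 / snr`. A plain Gaussian model is offered for analytic tests.
#'
#' @param signal Numeric vector or array of noise-free signal.
#' @param snr Signal-to-noise ratio relative to `s0`.
#' @param s0 Reference signal level defining the noise scale.
#' @param model `"rician"`, `"gaussian"`, or `"none"`.
#' @param seed Optional integer seed; the global RNG state is preserved.
#' @return Noisy signal, same shape as `signal`.
#' @export
add_noise <- function(signal, snr, s0 = 1000, model = c("rician", "gaussian", "none"),
                      seed = NULL) {
  model <- match.arg(model)
  if (model == "none") return(signal)
  if (!is.numeric(snr) || snr <= 0) abort("`snr` must be > 0")
  sigma <- s0 / snr
  with_local_seed(seed, {
    if (model == "rician") {
      e1 <- rnorm(length(signal), 0, sigma)
      e2 <- rnorm(length(signal), 0, sigma)
      out <- sqrt((signal + e1)^2 + e2^2)
    } else {
      out <- signal + rnorm(length(signal), 0, sigma)
    }
    if (!is.null(dim(signal))) dim(out) <- dim(signal)
    out
  })
}

default_regions <- function() {
  list(
    background = list(evals = c(0.8e-3, 0.8e-3, 0.8e-3), f = 0.05),
    # projection fibers: principal axis z (superior-inferior slab)
    projection = list(evals = c(1.2e-3, 0.6e-3, 1.7e-3), f = 0.10),
    # association fibers: principal axis y (anterior-posterior slab)
    association = list(evals = c(1.2e-3, 1.7e-3, 0.6e-3), f = 0.10),
    csf = list(evals = c(3.0e-3, 3.0e-3, 3.0e-3), f = 1.0)
  )
}

#' Specification of a two-slab DWI phantom
#'
#' Describes a synthetic brain-like volume with a projection-fiber slab
#' (principal diffusion axis along image z), an association-fiber slab
#' (principal axis along y), isotropic background tissue, an optional CSF
#' border, and optional spherical lesions. Region diffusion tensors are
#' diagonal in image axes with the given eigenvalues, so the analytic ALPS
#' index implied by the slab diffusivities is known exactly.
#'
#' @param shape Grid shape in voxels.
#' @param voxel_mm Isotropic voxel size (mm).
#' @param regions Named list with entries `background`, `projection`,
#'   `association` (and optionally `csf`), each a list with `evals`
#'   (length-3 diagonal tensor, mm^2/s, in (0, 4e-3]) and `f` (true
#'   free-water fraction in \[0, 1\]).
#' @param lesions List of lesions, each `list(center_mm =, radius_mm =,
#'   diffusivity =, f =)`; lesion tensors are isotropic.
#' @param csf_border Include a CSF rim of this many voxels at the z faces
#'   (0 = none).
#' @param s0 Baseline signal level.
#' @param snr Signal-to-noise ratio for [add_noise()].
#' @param noise `"rician"`, `"gaussian"`, or `"none"`.
#' @param n_directions Number of diffusion-weighted directions.
#' @param bvalue Shell b-value (s/mm^2).
#' @param seed Integer seed controlling the noise realization.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(40, 40, 20), voxel_mm = 2,
                         regions = default_regions(), lesions = list(),
                         csf_border = 0, s0 = 1000, snr = 30,
                         noise = c("rician", "gaussian", "none"),
                         n_directions = 32, bvalue = 1000, seed = 1L) {
  noise <- match.arg(noise)
  for (rn in c("background", "projection", "association")) {
    if (is.null(regions[[rn]])) abort(sprintf("regions must include '%s'", rn))
  }
  for (rn in names(regions)) {
    r <- regions[[rn]]
    if (any(r$evals <= 0) || any(r$evals > 4e-3)) {
      abort(sprintf("region '%s' eigenvalues must lie in (0, 4e-3] mm^2/s", rn))
    }
    if (r$f < 0 || r$f > 1) abort(sprintf("region '%s' f must be in [0, 1]", rn))
  }
  for (ls in lesions) {
    if (is.null(ls$radius_mm) || ls$radius_mm <= 0) abort("lesion radius must be > 0")
  }
  structure(list(shape = as.integer(shape), voxel_mm = voxel_mm,
                 regions = regions, lesions = lesions, csf_border = csf_border,
                 s0 = s0, snr = snr, noise = noise,
                 n_directions = n_directions, bvalue = bvalue,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_affine <- function(shape, voxel_mm) {
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- -voxel_mm * (shape - 1) / 2   # world origin at grid center
  aff
}

phantom_gtab <- function(spec) {
  dirs <- dwi_directions(spec$n_directions)
  gradient_table(c(0, rep(spec$bvalue, spec$n_directions)),
                 rbind(c(0, 0, 0), dirs))
}

# Voxel index ranges (1-based) of the two fiber slabs.
slab_ranges <- function(shape) {
  ny <- shape[2]; nz <- shape[3]
  zr <- seq(max(1L, round(0.20 * nz)), round(0.80 * nz))
  list(projection = list(y = seq(max(1L, round(0.10 * ny)), round(0.40 * ny)), z = zr),
       association = list(y = seq(round(0.55 * ny), round(0.85 * ny)), z = zr))
}

#' Build a synthetic DWI phantom with known ground truth
#'
#' Assembles the voxelwise bi-tensor signal via [simulate_signal()] (one
#' evaluation per region, since region tensors are constant), overrides
#' lesion spheres, then applies [add_noise()]. The returned ground truth
#' includes the label map, true tensor and free-water fields, the lesion
#' mask, the analytic ALPS index implied by the slab diffusivities, and an
#' ALPS ROI specification placed inside the slabs.
#'
#' @param spec A [phantom_spec()].
#' @return List with `dwi` (a [dwi_volume()]) and `truth` (list with
#'   `labels`, `tensor6`, `f`, `lesion_mask`, `alps_analytic`,
#'   `region_diffusivities`, `roi_spec`, `affine`).
#' @export
build_phantom <- function(spec) {
  shape <- spec$shape
  affine <- phantom_affine(shape, spec$voxel_mm)
  gtab <- phantom_gtab(spec)
  labels <- array("background", shape)
  sr <- slab_ranges(shape)
  labels[, sr$projection$y, sr$projection$z] <- "projection"
  labels[, sr$association$y, sr$association$z] <- "association"
  if (spec$csf_border > 0 && !is.null(spec$regions$csf)) {
    k <- seq_len(spec$csf_border)
    labels[, , k] <- "csf"
    labels[, , shape[3] + 1L - k] <- "csf"
  }
  lesion_mask <- array(FALSE, shape)
  lesion_id <- array(0L, shape)
  if (length(spec$lesions) > 0) {
    world <- voxel_world_coords(shape, affine)
    for (i in seq_along(spec$lesions)) {
      ls <- spec$lesions[[i]]
      d2 <- colSums((t(world) - ls$center_mm)^2)
      inside <- d2 <= ls$radius_mm^2
      if (!any(inside)) {
        warn(sprintf("lesion %d lies fully outside the grid; skipped", i))
        next
      }
      lesion_mask[inside] <- TRUE
      lesion_id[inside] <- i
    }
  }
  nvox <- prod(shape)
  f_field <- array(0, shape)
  tensor6 <- array(0, c(shape, 6L))
  sigmat <- matrix(0, nvox, length(gtab$bvals))
  fill_region <- function(sel, evals, f) {
    D <- diag(evals)
    sig <- simulate_signal(D, f, gtab, s0 = spec$s0)
    sigmat[sel, ] <<- matrix(sig, sum(sel), length(sig), byrow = TRUE)
    f_field[sel] <<- f
    for (k in 1:3) {
      t6 <- tensor6[, , , k]
      t6[sel] <- evals[k]
      tensor6[, , , k] <<- t6
    }
  }
  for (rn in unique(as.vector(labels))) {
    r <- spec$regions[[rn]]
    fill_region(as.vector(labels == rn) & !as.vector(lesion_mask), r$evals, r$f)
  }
  for (i in seq_along(spec$lesions)) {
    sel <- as.vector(lesion_id == i)
    if (any(sel)) {
      ls <- spec$lesions[[i]]
      fill_region(sel, rep(ls$diffusivity, 3), ls$f)
    }
  }
  signal <- array(sigmat, c(shape, length(gtab$bvals)))
  if (spec$noise != "none") {
    signal <- add_noise(signal, snr = spec$snr, s0 = spec$s0,
                        model = spec$noise, seed = spec$seed)
  }
  rd <- list(dxx_proj = spec$regions$projection$evals[1],
             dxx_assoc = spec$regions$association$evals[1],
             dyy_proj = spec$regions$projection$evals[2],
             dzz_assoc = spec$regions$association$evals[3])
  truth <- list(
    labels = labels, tensor6 = tensor6, f = f_field,
    lesion_mask = volume_mask(lesion_mask, affine),
    region_diffusivities = rd,
    alps_analytic = alps_from_means(rd$dxx_proj, rd$dxx_assoc, rd$dyy_proj, rd$dzz_assoc),
    roi_spec = phantom_roi_spec(spec),
    affine = affine
  )
  list(dwi = dwi_volume(signal, affine, gtab), truth = truth)
}

#' Default ALPS ROI placement for a phantom
#'
#' Sphere centers at +/- x inside each fiber slab, on the phantom's world
#' grid.
#'
#' @param spec A [phantom_spec()].
#' @param diameter_mm ROI sphere diameter (mm).
#' @return An [alps_roi_spec()].
#' @export
phantom_roi_spec <- function(spec, diameter_mm = 5) {
  shape <- spec$shape
  affine <- phantom_affine(shape, spec$voxel_mm)
  sr <- slab_ranges(shape)
  ctr <- function(yr, zr, xfrac) {
    v <- c(round(xfrac * (shape[1] - 1)), round(mean(yr)) - 1, round(mean(zr)) - 1)
    as.vector(affine[1:3, 1:3] %*% v + affine[1:3, 4])
  }
  alps_roi_spec(
    proj_left = ctr(sr$projection$y, sr$projection$z, 0.70),
    proj_right = ctr(sr$projection$y, sr$projection$z, 0.30),
    assoc_left = ctr(sr$association$y, sr$association$z, 0.70),
    assoc_right = ctr(sr$association$y, sr$association$z, 0.30),
    diameter_mm = diameter_mm
  )
}

#' Specification of a simulated patient cohort
#'
#' Group sizes, per-group age and disability (EDSS) distributions, and
#' generative linear coefficients for the two imaging outcomes. Defaults
#' reproduce the clinical structure of a two-group neuroinflammatory cohort:
#' 42 MS and 21 NMOSD patients, MS age 33.97 +/- 7.52 vs NMOSD
#' 47.23 +/- 11.18 years, MS EDSS 1.48 +/- 1.65 vs NMOSD 2.95 +/- 2.79. The
#' group effects default to zero — the null scenario — and are exposed as
#' parameters.
#'
#' @param n_ms,n_nmosd Group sizes (>= 2).
#' @param age_mean,age_sd Length-2 vectors (MS, NMOSD), years.
#' @param edss_mean,edss_sd Length-2 vectors (MS, NMOSD); draws are clamped
#'   to the EDSS range \[0, 10\].
#' @param fw Generative coefficients for the skeleton-mean free-water
#'   fraction: `intercept`, `delta` (NMOSD minus MS at equal covariates),
#'   `beta_age` (per year), `beta_edss` (per point), `sd` (residual).
#' @param alps Same structure for the mean ALPS index.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ms = 42, n_nmosd = 21,
                        age_mean = c(33.97, 47.23), age_sd = c(7.52, 11.18),
                        edss_mean = c(1.48, 2.95), edss_sd = c(1.65, 2.79),
                        fw = list(intercept = 0.20, delta = 0, beta_age = 5e-4,
                                  beta_edss = 2e-3, sd = 0.02),
                        alps = list(intercept = 1.60, delta = 0, beta_age = -5e-3,
                                    beta_edss = -0.02, sd = 0.10),
                        seed = 1L) {
  if (n_ms < 2 || n_nmosd < 2) abort("group sizes must be >= 2")
  for (cf in list(fw, alps)) {
    if (is.null(cf$sd) || cf$sd < 0) abort("residual sd must be >= 0")
  }
  structure(list(n_ms = n_ms, n_nmosd = n_nmosd, age_mean = age_mean,
                 age_sd = age_sd, edss_mean = edss_mean, edss_sd = edss_sd,
                 fw = fw, alps = alps, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort covariate-outcome table
#'
#' Draws per-subject group, age, and EDSS from the cohort specification and
#' generates the two outcomes from additive linear models
#' `outcome = intercept + delta * group + beta_age * age + beta_edss * EDSS
#' + Normal(0, sd)` with group coded MS = 0, NMOSD = 1. When
#' `phantoms = TRUE` each row additionally carries a [phantom_spec()] whose
#' slab diffusivities and free-water fractions are back-solved so the
#' image-level pipeline targets the tabled outcome values.
#'
#' @param spec A [cohort_spec()].
#' @param phantoms Attach a `phantom` list-column of per-subject
#'   [phantom_spec()] objects.
#' @param phantom_args Named list of arguments forwarded to [phantom_spec()]
#'   (e.g., `shape`, `snr`) for the per-subject phantoms.
#' @return A tibble with columns `subject`, `group` (factor MS/NMOSD),
#'   `group_code` (0/1), `age`, `edss`, `fw`, `alps`, and optionally
#'   `phantom`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), phantoms = FALSE,
                            phantom_args = list()) {
  n <- spec$n_ms + spec$n_nmosd
  gi <- c(rep(1L, spec$n_ms), rep(2L, spec$n_nmosd))  # 1 = MS, 2 = NMOSD
  tab <- with_local_seed(spec$seed, {
    age <- rnorm(n, spec$age_mean[gi], spec$age_sd[gi])
    edss <- pmin(pmax(rnorm(n, spec$edss_mean[gi], spec$edss_sd[gi]), 0), 10)
    gcode <- gi - 1L
    outc <- function(cf) {
      cf$intercept + cf$delta * gcode + cf$beta_age * age + cf$beta_edss * edss +
        rnorm(n, 0, cf$sd)
    }
    tibble::tibble(
      subject = sprintf("sub-%03d", seq_len(n)),
      group = factor(c("MS", "NMOSD")[gi], levels = c("MS", "NMOSD")),
      group_code = gcode,
      age = age, edss = edss,
      fw = pmin(pmax(outc(spec$fw), 0.01), 0.9),
      alps = pmax(outc(spec$alps), 0.55)
    )
  })
  if (phantoms) {
    tab$phantom <- purrr::pmap(list(tab$fw, tab$alps, seq_len(n)),
                               function(fw_i, alps_i, i) {
      args <- c(list(regions = backsolve_regions(fw_i, alps_i),
                     seed = derive_seed(spec$seed, i)),
                phantom_args)
      do.call(phantom_spec, args)
    })
  }
  tab
}

# Single-tensor effective diffusivity of a two-compartment voxel along an
# axis with tissue eigenvalue lam: what a plain DTI fit reads off.
effective_diffusivity <- function(lam, f, b = 1000, d_w = 3.0e-3) {
  -log((1 - f) * exp(-b * lam) + f * exp(-b * d_w)) / b
}

# Inverse: tissue eigenvalue whose effective diffusivity equals target.
tissue_lambda_for <- function(target_eff, f, b = 1000, d_w = 3.0e-3) {
  arg <- (exp(-b * target_eff) - f * exp(-b * d_w)) / (1 - f)
  if (arg <= 0) abort("target effective diffusivity unreachable at this f")
  -log(arg) / b
}

# Slab region layout whose *measured* (single-tensor) ALPS index targets
# `alps_target` in the presence of the free-water fraction `fw_target`:
# the transverse tissue eigenvalue is fixed at a corona-radiata-like
# 0.5e-3 mm^2/s and the perivascular-axis eigenvalue solved so that the
# ratio of water-contaminated effective diffusivities equals the target.
backsolve_regions <- function(fw_target, alps_target, b = 1000, d_w = 3.0e-3) {
  regions <- default_regions()
  f <- min(max(fw_target, 0), 0.7)
  a <- min(max(alps_target, 0.7), 2.5)
  perp <- 0.5e-3
  perp_eff <- effective_diffusivity(perp, f, b, d_w)
  dxx <- tissue_lambda_for(a * perp_eff, f, b, d_w)
  dxx <- min(max(dxx, 0.15e-3), 2.4e-3)
  regions$projection$evals <- c(dxx, perp, 1.7e-3)
  regions$association$evals <- c(dxx, 1.7e-3, perp)
  regions$projection$f <- f
  regions$association$f <- f
  regions
}
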