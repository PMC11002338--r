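#' ALPS region-of-interest specification
#'
#' Four labeled 5 mm spheres: bilateral projection-fiber (superior corona
#' radiata) and association-fiber (superior longitudinal fasciculus) ROIs at
#' the level of the lateral-ventricle body. Centers are world-mm coordinates
#' under the RAS+ convention (left/right by the sign of world x). The
#' shipped defaults are approximate template-space placements documented as
#' placeholders; supply atlas-derived centers for real data.
#'
#' @param proj_left,proj_right,assoc_left,assoc_right Length-3 world-mm
#'   centers.
#' @param diameter_mm Sphere diameter (mm), default 5.
#' @return An object of class `alps_roi_spec`: a tibble with columns `roi`,
#'   `fiber`, `side`, `center` (list of length-3 vectors), `diameter_mm`.
#' @export
alps_roi_spec <- function(proj_left = c(26, -16, 26),
                          proj_right = c(-26, -16, 26),
                          assoc_left = c(38, -18, 26),
                          assoc_right = c(-38, -18, 26),
                          diameter_mm = 5) {
  if (diameter_mm <= 0) abort("`diameter_mm` must be > 0")
  centers <- list(proj_left = proj_left, proj_right = proj_right,
                  assoc_left = assoc_left, assoc_right = assoc_right)
  for (nm in names(centers)) {
    if (length(centers[[nm]]) != 3L || any(!is.finite(centers[[nm]]))) {
      abort(sprintf("`%s` must be a finite length-3 world-mm coordinate", nm))
    }
  }
  if (identical(proj_left, proj_right) || identical(assoc_left, assoc_right)) {
    abort("left/right ROI centers must be distinct")
  }
  out <- tibble::tibble(
    roi = names(centers),
    fiber = rep(c("projection", "association"), each = 2),
    side = rep(c("left", "right"), 2),
    center = unname(centers),
    diameter_mm = diameter_mm
  )
  class(out) <- c("alps_roi_spec", class(out))
  out
}

#' Spherical ROI mask on a voxel grid
#'
#' A voxel is included iff its world-space center lies within
#' `diameter_mm / 2` of `center_mm` (voxel-center rule, no partial-volume
#' weighting).
#'
#' @param center_mm Length-3 world-mm center.
#' @param diameter_mm Sphere diameter (mm).
#' @param shape Grid shape (voxels).
#' @param affine Voxel-to-world matrix.
#' @return A [volume_mask()].
#' @export
sphere_mask <- function(center_mm, diameter_mm, shape, affine) {
  if (diameter_mm <= 0) abort("`diameter_mm` must be > 0")
  world <- voxel_world_coords(shape, affine)
  d2 <- colSums((t(world) - center_mm)^2)
  inside <- d2 <= (diameter_mm / 2)^2
  if (!any(inside)) abort("sphere does not intersect the grid")
  volume_mask(array(inside, shape), affine)
}

#' Mean of a map over an ROI with lesion exclusion
#'
#' @param map 3-D numeric array.
#' @param roi [volume_mask()] or logical array selecting the ROI.
#' @param lesion_mask Optional [volume_mask()] of excluded voxels.
#' @param label ROI name used in error messages.
#' @return List with `mean`, `n_used`, `n_excluded`.
#' @export
roi_mean <- function(map, roi, lesion_mask = NULL, label = "roi") {
  r <- as_mask_array(roi, dim(map))
  les <- if (is.null(lesion_mask)) array(FALSE, dim(map)) else as_mask_array(lesion_mask, dim(map))
  use <- r & !les
  if (!any(use)) abort(sprintf("all voxels of ROI '%s' are lesion-excluded", label))
  list(mean = mean(map[use]), n_used = sum(use), n_excluded = sum(r & les))
}

#' ALPS index from the four ROI mean diffusivities
#'
#' \deqn{ALPS = \frac{\mathrm{mean}(D_{xx,proj}, D_{xx,assoc})}
#'                   {\mathrm{mean}(D_{yy,proj}, D_{zz,assoc})}}
#'
#' @param dxx_proj,dxx_assoc,dyy_proj,dzz_assoc Mean diffusivities
#'   (mm^2/s), all > 0.
#' @return The ALPS index (unitless).
#' @export
alps_from_means <- function(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc) {
  vals <- c(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all four mean diffusivities must be finite and > 0")
  }
  mean(c(dxx_proj, dxx_assoc)) / mean(c(dyy_proj, dzz_assoc))
}

#' Compute the DTI-ALPS index from fitted tensor maps
#'
#' For each hemisphere, extracts the lesion-excluded mean x-axis diffusivity
#' in the projection and association ROIs and the y- (projection) and z-axis
#' (association) diffusivities, forms the per-side ALPS ratio, and averages
#' the two sides into the mean ALPS index. Diffusivity maps are assumed
#' already registered to the ROI space.
#'
#' @param tmaps A `tensor_maps` object (from [fit_tensor()] or the corrected
#'   tissue fit of [fit_fw()]).
#' @param rois An [alps_roi_spec()].
#' @param lesion_mask Optional [volume_mask()] of lesion voxels to exclude.
#' @return An object of class `alps_result`: `alps_left`, `alps_right`,
#'   `alps_mean`, and a tibble `rois` of per-ROI mean diffusivities and
#'   voxel counts.
#' @export
compute_alps <- function(tmaps, rois = alps_roi_spec(), lesion_mask = NULL) {
  if (!inherits(tmaps, "tensor_maps")) abort("`tmaps` must be a tensor_maps object")
  shape <- dim(tmaps$fa)
  ad <- axis_diffusivities(tmaps)
  per_roi <- purrr::pmap(rois, function(roi, fiber, side, center, diameter_mm) {
    sm <- sphere_mask(center, diameter_mm, shape, tmaps$affine)
    pick <- function(map, axis) {
      rm <- roi_mean(map, sm, lesion_mask, label = roi)
      tibble::tibble(roi = roi, fiber = fiber, side = side, axis = axis,
                     mean_diffusivity = rm$mean, n_used = rm$n_used,
                     n_excluded = rm$n_excluded)
    }
    if (fiber == "projection") {
      dplyr::bind_rows(pick(ad$dxx, "x"), pick(ad$dyy, "y"))
    } else {
      dplyr::bind_rows(pick(ad$dxx, "x"), pick(ad$dzz, "z"))
    }
  })
  roitab <- dplyr::bind_rows(per_roi)
  side_index <- function(s) {
    g <- function(fb, ax) {
      roitab$mean_diffusivity[roitab$side == s & roitab$fiber == fb & roitab$axis == ax]
    }
    alps_from_means(g("projection", "x"), g("association", "x"),
                    g("projection", "y"), g("association", "z"))
  }
  left <- side_index("left")
  right <- side_index("right")
  structure(list(alps_left = left, alps_right = right,
                 alps_mean = (left + right) / 2, rois = roitab),
            class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf("<alps_result> left %.4f, right %.4f, mean %.4f\n",
              x$alps_left, x$alps_right, x$alps_mean))
  invisible(x)
}
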