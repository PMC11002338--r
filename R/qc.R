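#' Temporal signal-to-noise ratio screening of a DWI series
#'
#' Per voxel, the mean over the selected volumes divided by the sample
#' (n - 1) standard deviation over volumes; the summary tSNR is the mean of
#' the per-voxel values over the mask. Constant-series voxels (sd = 0) are
#' excluded from the summary and counted. A subject passes when the summary
#' exceeds the cutoff; 6.47 is the published screening threshold for poor
#' DWI data.
#'
#' @param dwi A [dwi_volume()].
#' @param mask Optional [volume_mask()] or logical array.
#' @param volumes Which volumes enter the temporal statistics: the
#'   diffusion-weighted `"shell"` (default — with a single b0 the shell is
#'   the only subset across which temporal variation is meaningful),
#'   `"b0"`, or `"all"`.
#' @param cutoff Pass/fail threshold on the summary tSNR.
#' @return An object of class `qc_report`: `tsnr_map`, `summary`, `cutoff`,
#'   `pass`, `volumes`, `n_voxels`, `n_constant`.
#' @export
tsnr <- function(dwi, mask = NULL, volumes = c("shell", "b0", "all"),
                 cutoff = 6.47) {
  volumes <- match.arg(volumes)
  if (!inherits(dwi, "dwi_volume")) abort("`dwi` must be a dwi_volume")
  shape <- dim(dwi$signal)[1:3]
  m <- as_mask_array(mask, shape)
  b0 <- is_b0(dwi$gtab)
  sel <- switch(volumes, shell = !b0, b0 = b0, all = rep(TRUE, length(b0)))
  if (sum(sel) < 3L) abort("need at least 3 volumes in the selected subset")
  sig <- matrix(dwi$signal, prod(shape), dim(dwi$signal)[4])[m, sel, drop = FALSE]
  mu <- rowMeans(sig)
  sdv <- sqrt(pmax(rowSums((sig - mu)^2), 0) / (ncol(sig) - 1))
  ok <- sdv > 0
  if (!any(ok)) abort("degenerate series: all voxels have zero temporal variance")
  vals <- rep(NA_real_, length(mu))
  vals[ok] <- mu[ok] / sdv[ok]
  tsnr_map <- array(NA_real_, shape)
  tsnr_map[m] <- vals
  summary_tsnr <- mean(vals[ok])
  structure(list(tsnr_map = tsnr_map, summary = summary_tsnr, cutoff = cutoff,
                 pass = summary_tsnr > cutoff, volumes = volumes,
                 n_voxels = sum(ok), n_constant = sum(!ok)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> tSNR %.2f over %d voxels (%s volumes), cutoff %.2f: %s\n",
              x$summary, x$n_voxels, x$volumes, x$cutoff,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
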