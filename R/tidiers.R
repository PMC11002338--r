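#' Tidy a Bayesian model-averaged ANCOVA
#'
#' @param x A `bayes_ancova` object.
#' @param ... Unused.
#' @return Tibble with one row per model: `model`, `prior_prob`, `bf10`,
#'   `log_bf10`, `posterior_prob`, `bf_m`, `R2`.
#' @method tidy bayes_ancova
#' @export
tidy.bayes_ancova <- function(x, ...) {
  dplyr::select(x$models, "model", "prior_prob", "bf10", "log_bf10",
                "posterior_prob", "bf_m", "R2")
}

#' One-row summary of a Bayesian model-averaged ANCOVA
#'
#' @param x A `bayes_ancova` object.
#' @param ... Unused.
#' @return One-row tibble: `dv`, `n`, `n_dropped`, `null_posterior_prob`,
#'   `null_bf_m`, `best_model`, and the group inclusion BF (variant "all").
#' @method glance bayes_ancova
#' @export
glance.bayes_ancova <- function(x, ...) {
  nullrow <- x$models[x$models$model == "null", ]
  tibble::tibble(
    dv = x$dv, n = x$n, n_dropped = x$n_dropped,
    null_posterior_prob = nullrow$posterior_prob,
    null_bf_m = nullrow$bf_m,
    best_model = x$models$model[which.max(x$models$posterior_prob)],
    group_inclusion_bf = x$inclusion$inclusion_bf[
      x$inclusion$predictor == x$factor_var & x$inclusion$variant == "all"]
  )
}

#' Plot posterior model probabilities of a Bayesian ANCOVA
#'
#' @param object A `bayes_ancova` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bayes_ancova
#' @export
autoplot.bayes_ancova <- function(object, ...) {
  d <- dplyr::mutate(object$models,
                     model = stats::reorder(.data$model, .data$posterior_prob))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$posterior_prob, y = .data$model)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = unique(d$prior_prob), linetype = "dashed") +
    ggplot2::labs(x = "Posterior model probability", y = NULL,
                  title = sprintf("Model comparison (dv = %s)", object$dv),
                  subtitle = "dashed line: uniform prior probability") +
    ggplot2::theme_minimal()
}

#' Tidy an ALPS result
#'
#' @param x An `alps_result` object.
#' @param ... Unused.
#' @return Tibble of per-ROI mean diffusivities and counts.
#' @method tidy alps_result
#' @export
tidy.alps_result <- function(x, ...) x$rois

#' One-row summary of an ALPS result
#'
#' @param x An `alps_result` object.
#' @param ... Unused.
#' @return One-row tibble: `alps_left`, `alps_right`, `alps_mean`.
#' @method glance alps_result
#' @export
glance.alps_result <- function(x, ...) {
  tibble::tibble(alps_left = x$alps_left, alps_right = x$alps_right,
                 alps_mean = x$alps_mean)
}

#' Tidy the per-subject table of a pipeline result
#'
#' @param x A `pipeline_result` object.
#' @param ... Unused.
#' @return The per-subject tibble.
#' @method tidy pipeline_result
#' @export
tidy.pipeline_result <- function(x, ...) x$subjects

#' Plot an axial slice of a 3-D map
#'
#' @param map 3-D array (or `fw_result` / `tensor_maps`, in which case the
#'   f or FA map is shown).
#' @param z Slice index (default: middle slice).
#' @param title Plot title.
#' @return A ggplot.
#' @export
plot_slice <- function(map, z = NULL, title = NULL) {
  if (inherits(map, "fw_result")) { title <- title %||% "free-water fraction"; map <- map$f }
  if (inherits(map, "tensor_maps")) { title <- title %||% "FA"; map <- map$fa }
  z <- z %||% ceiling(dim(map)[3] / 2)
  d <- expand.grid(x = seq_len(dim(map)[1]), y = seq_len(dim(map)[2]))
  d$value <- as.vector(map[, , z])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title %||% sprintf("slice z = %d", z)) +
    ggplot2::theme_void()
}

#' Raincloud-style group comparison of a cohort outcome
#'
#' @param data Cohort tibble with a `group` column.
#' @param outcome Column name to plot (e.g., `"fw"` or `"alps"`).
#' @return A ggplot.
#' @export
plot_group_comparison <- function(data, outcome) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$group, y = .data[[outcome]],
                                     fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.4, colour = NA) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA, alpha = 0.8) +
    ggplot2::geom_jitter(width = 0.08, size = 1, alpha = 0.6) +
    ggplot2::labs(y = outcome, x = NULL) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
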