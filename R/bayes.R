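#' Enumerate the additive model space over a set of predictors
#'
#' All 2^p additive subsets of the predictors, including the null
#' (intercept-only) model, with a uniform prior probability 1/2^p per model.
#' With the three predictors age, EDSS, and group this yields 8 models and a
#' null-model prior probability of 0.125.
#'
#' @param predictors Named character vector mapping predictor names to kinds:
#'   `"continuous"` or `"factor"` (e.g.,
#'   `c(age = "continuous", group = "factor")`).
#' @return An object of class `model_space`: a tibble with columns `model`
#'   (label), `terms` (list of character vectors), `prior_prob`, and the
#'   predictor kinds as attribute `kinds`.
#' @export
enumerate_models <- function(predictors) {
  if (length(predictors) < 1L) abort("need at least one predictor")
  nms <- names(predictors)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms)) {
    abort("predictors must have unique names")
  }
  if (!all(predictors %in% c("continuous", "factor"))) {
    abort("predictor kinds must be 'continuous' or 'factor'")
  }
  p <- length(nms)
  subsets <- purrr::map(seq_len(2^p) - 1L, function(bits) {
    nms[bitwAnd(bits, 2^(seq_len(p) - 1L)) > 0L]
  })
  out <- tibble::tibble(
    model = purrr::map_chr(subsets, ~ if (length(.x)) paste(.x, collapse = " + ") else "null"),
    terms = subsets,
    prior_prob = rep(1 / 2^p, 2^p)
  )
  attr(out, "kinds") <- predictors
  class(out) <- c("model_space", class(out))
  out
}

#' Centered design matrix for one candidate model
#'
#' Conventions of common Bayesian ANOVA implementations: the response is
#' left on its raw scale (the intercept is always included and integrated
#' out by centering), continuous covariates are mean-centered and scaled by
#' their sample standard deviation, and a 2-level factor is coded
#' sum-to-zero as -1/2, +1/2 (then centered, which for unbalanced groups
#' shifts the column without changing the model fit).
#'
#' @param data Data frame with the modeled columns.
#' @param dv Name of the response column.
#' @param terms Character vector of predictor names (possibly empty = null
#'   model).
#' @param kinds Named character vector of predictor kinds (see
#'   [enumerate_models()]).
#' @return List with `y` (centered response), `X` (n x k centered design,
#'   k = 0 for the null model), `n`, `k`.
#' @export
design_matrix <- function(data, dv, terms, kinds) {
  y <- data[[dv]]
  if (is.null(y)) abort(sprintf("response column '%s' not found", dv))
  n <- length(y)
  cols <- lapply(terms, function(tm) {
    v <- data[[tm]]
    if (is.null(v)) abort(sprintf("predictor column '%s' not found", tm))
    if (kinds[[tm]] == "factor") {
      f <- as.factor(v)
      if (nlevels(f) != 2L) abort(sprintf("factor '%s' must have exactly 2 levels", tm))
      x <- ifelse(f == levels(f)[1], -0.5, 0.5)
    } else {
      x <- as.numeric(v)
      s <- sd(x)
      if (s == 0) abort(sprintf("covariate '%s' has zero variance", tm))
      x <- (x - mean(x)) / s
    }
    x - mean(x)
  })
  X <- if (length(cols)) do.call(cbind, cols) else matrix(numeric(0), n, 0)
  colnames(X) <- terms
  list(y = y - mean(y), X = X, n = n, k = ncol(X))
}

log_invgamma_density <- function(g, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(g) - scale / g
}

# log of the JZS Bayes factor integrand on the log-g axis (Jacobian included)
jzs_log_integrand <- function(t, n, k, R2, b) {
  g <- exp(t)
  (n - 1 - k) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - R2)) +
    log_invgamma_density(g, 0.5, b) + t
}

#' JZS Bayes factor of one model against the null
#'
#' Zellner-Siow mixture-of-g-priors Bayes factor for an additive linear
#' model on the centered design,
#' \deqn{BF_{10} = \int_0^\infty (1+g)^{(n-1-k)/2}
#'   \left[1 + g(1-R^2_M)\right]^{-(n-1)/2} \pi(g)\, dg,}
#' with \eqn{\pi(g)} the inverse-gamma(1/2, n r^2/2) density (the
#' unit-information Cauchy prior on standardized effects). A single g is
#' shared across the model's terms with effective \eqn{r^2} equal to the
#' mean of the included terms' squared scales. Computed in log space by
#' adaptive quadrature on the log-g axis after locating the integrand peak,
#' so Bayes factors up to e±700 are representable.
#'
#' @param data Data frame of complete cases.
#' @param dv Response column name.
#' @param terms Character vector of included predictors (empty = null model,
#'   BF = 1 exactly).
#' @param kinds Named character vector of predictor kinds.
#' @param r_scales Prior Cauchy scales by kind; defaults are the
#'   conventional fixed-effect scale 1/2 and covariate scale sqrt(2)/4.
#' @param rel_tol Quadrature relative tolerance.
#' @return List with `bf10`, `log_bf10`, `R2`, `k`, `n`, `r_eff2`.
#' @export
model_bf10 <- function(data, dv, terms, kinds,
                       r_scales = c(factor = 0.5, continuous = sqrt(2) / 4),
                       rel_tol = 1e-10) {
  dm <- design_matrix(data, dv, terms, kinds)
  if (dm$k == 0L) {
    return(list(bf10 = 1, log_bf10 = 0, R2 = 0, k = 0L, n = dm$n, r_eff2 = NA_real_))
  }
  if (dm$n <= dm$k + 2L) abort("need n > k + 2 observations")
  fit <- lm.fit(dm$X, dm$y)
  R2 <- 1 - sum(fit$residuals^2) / sum(dm$y^2)
  if (R2 >= 1) abort("saturated model: R^2 >= 1")
  r_eff2 <- mean(r_scales[kinds[terms]]^2)
  b <- dm$n * r_eff2 / 2
  peak <- optimize(jzs_log_integrand, c(-50, 50), maximum = TRUE,
                   n = dm$n, k = dm$k, R2 = R2, b = b)
  M <- peak$objective
  quad <- tryCatch(
    integrate(function(t) exp(jzs_log_integrand(t, dm$n, dm$k, R2, b) - M),
              -60, 60, rel.tol = rel_tol, subdivisions = 500L),
    error = function(e) abort(sprintf("quadrature failed: %s", conditionMessage(e)))
  )
  if (quad$message != "OK") {
    abort(sprintf("quadrature did not converge: %s", quad$message))
  }
  log_bf <- M + log(quad$value)
  list(bf10 = exp(log_bf), log_bf10 = log_bf, R2 = R2, k = dm$k, n = dm$n,
       r_eff2 = r_eff2)
}

#' Posterior model probabilities from Bayes factors
#'
#' `P(M | D) = P(M) BF10(M) / sum_M' P(M') BF10(M')`, computed in log space.
#'
#' @param space A `model_space` from [enumerate_models()].
#' @param log_bf10 Numeric vector of log Bayes factors, one per model, with
#'   the null model's entry equal to 0.
#' @return Numeric vector of posterior probabilities (sums to 1).
#' @export
posterior_model_probs <- function(space, log_bf10) {
  if (length(log_bf10) != nrow(space)) abort("one Bayes factor per model required")
  if (any(!is.finite(log_bf10))) abort("non-finite Bayes factor")
  lw <- log(space$prior_prob) + log_bf10
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Change from prior to posterior model odds
#'
#' `BF_M = [P(M|D) / (1 - P(M|D))] / [P(M) / (1 - P(M))]`.
#'
#' @param prior_prob,posterior_prob Model probabilities in (0, 1).
#' @return The BF_M value.
#' @export
bf_m <- function(prior_prob, posterior_prob) {
  if (any(posterior_prob <= 0 | posterior_prob >= 1)) {
    abort("degenerate posterior probability (0 or 1)")
  }
  (posterior_prob / (1 - posterior_prob)) / (prior_prob / (1 - prior_prob))
}

#' Inclusion Bayes factor for one predictor
#'
#' Change from prior to posterior inclusion odds of the models containing
#' the predictor. Variant `"all"` uses all models; variant `"matched"`
#' restricts to pairs of models differing only by the predictor (in an
#' additive space, each model not containing the predictor pairs with the
#' model adding it).
#'
#' @param space A `model_space`.
#' @param posteriors Posterior model probabilities (from
#'   [posterior_model_probs()]).
#' @param predictor Predictor name.
#' @param variant `"all"` or `"matched"`.
#' @return The inclusion Bayes factor.
#' @export
inclusion_bf <- function(space, posteriors, predictor,
                         variant = c("all", "matched")) {
  variant <- match.arg(variant)
  has <- purrr::map_lgl(space$terms, ~ predictor %in% .x)
  if (!any(has) || all(has)) abort(sprintf("predictor '%s' not in the model space", predictor))
  keep <- rep(TRUE, nrow(space))
  if (variant == "matched") {
    key <- purrr::map_chr(space$terms, ~ paste(sort(setdiff(.x, predictor)), collapse = "+"))
    # a model participates if its with/without partner exists in the space
    keep <- purrr::map_lgl(seq_len(nrow(space)), function(i) {
      sum(key == key[i]) == 2L
    })
  }
  post_in <- sum(posteriors[keep & has]); post_out <- sum(posteriors[keep & !has])
  pri_in <- sum(space$prior_prob[keep & has]); pri_out <- sum(space$prior_prob[keep & !has])
  if (post_out == 0 || pri_out == 0) abort("empty exclusion set")
  (post_in / post_out) / (pri_in / pri_out)
}

#' Bayesian model-averaged ANCOVA
#'
#' Enumerates all additive models over the covariates and the group factor,
#' computes each model's JZS Bayes factor against the null
#' ([model_bf10()]), converts to posterior model probabilities, and reports
#' BF_M per model and inclusion Bayes factors (both variants) per
#' predictor. Rows with missing values in the modeled columns are dropped
#' listwise and counted. Deterministic given the data and configuration.
#'
#' @param data Data frame / tibble with the dv, covariate, and factor
#'   columns (e.g., the output of [simulate_cohort()]).
#' @param dv Response column name (e.g., `"fw"` or `"alps"`).
#' @param covariates Character vector of continuous covariate columns.
#' @param factor_var Name of the 2-level grouping factor column.
#' @param r_scales Prior Cauchy scales, named `factor` and `continuous`.
#' @return An object of class `bayes_ancova` with elements `models` (tibble:
#'   model, terms, prior_prob, bf10, log_bf10, posterior_prob, bf_m, R2),
#'   `inclusion` (tibble: predictor, variant, inclusion_bf), `dv`, `n`,
#'   `n_dropped`, `r_scales`.
#' @export
run_bayes_ancova <- function(data, dv, covariates = c("age", "edss"),
                             factor_var = "group",
                             r_scales = c(factor = 0.5, continuous = sqrt(2) / 4)) {
  cols <- c(dv, covariates, factor_var)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(sprintf("columns not found: %s", paste(missing_cols, collapse = ", ")))
  }
  cc <- stats::complete.cases(data[, cols, drop = FALSE])
  n_dropped <- sum(!cc)
  data <- data[cc, , drop = FALSE]
  kinds <- c(setNames(rep("continuous", length(covariates)), covariates),
             setNames("factor", factor_var))
  space <- enumerate_models(kinds)
  fits <- purrr::map(space$terms, ~ model_bf10(data, dv, .x, kinds, r_scales = r_scales))
  log_bf <- purrr::map_dbl(fits, "log_bf10")
  post <- posterior_model_probs(space, log_bf)
  models <- dplyr::mutate(
    tibble::as_tibble(space),
    bf10 = exp(log_bf), log_bf10 = log_bf, posterior_prob = post,
    bf_m = bf_m(.data$prior_prob, post),
    R2 = purrr::map_dbl(fits, "R2")
  )
  preds <- names(kinds)
  inclusion <- tidyr::expand_grid(predictor = preds, variant = c("all", "matched"))
  inclusion$inclusion_bf <- purrr::map2_dbl(
    inclusion$predictor, inclusion$variant,
    ~ inclusion_bf(space, post, .x, variant = .y)
  )
  structure(list(models = models, inclusion = inclusion, dv = dv, n = nrow(data),
                 n_dropped = n_dropped, r_scales = r_scales,
                 covariates = covariates, factor_var = factor_var),
            class = "bayes_ancova")
}

#' @export
print.bayes_ancova <- function(x, ...) {
  cat(sprintf("Bayesian model-averaged ANCOVA  (dv = %s, n = %d%s)\n\n", x$dv, x$n,
              if (x$n_dropped) sprintf(", %d rows dropped", x$n_dropped) else ""))
  m <- dplyr::arrange(x$models, dplyr::desc(.data$posterior_prob))
  cat(sprintf("%-24s %10s %10s %10s %10s\n", "Model", "P(M)", "BF10", "P(M|D)", "BF_M"))
  for (i in seq_len(nrow(m))) {
    cat(sprintf("%-24s %10.3f %10.4g %10.3f %10.4g\n", m$model[i], m$prior_prob[i],
                m$bf10[i], m$posterior_prob[i], m$bf_m[i]))
  }
  cat("\nInclusion Bayes factors (across all models / matched models):\n")
  inc <- tidyr::pivot_wider(x$inclusion, names_from = "variant",
                            values_from = "inclusion_bf")
  for (i in seq_len(nrow(inc))) {
    cat(sprintf("  %-8s %10.4g %10.4g\n", inc$predictor[i], inc$all[i], inc$matched[i]))
  }
  invisible(x)
}
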