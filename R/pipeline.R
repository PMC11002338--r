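#' End-to-end pipeline configuration
#'
#' Exactly one of `cohort` (a simulation specification) or `subjects` (a
#' tibble of file paths for real data: columns `subject`, `group`, `age`,
#'  `edss`, `dwi`, `bval`, `bvec`, and optionally `lesion`) must be given.
#'
#' @param cohort A [cohort_spec()] for simulated input.
#' @param subjects Tibble of per-subject input paths and covariates; if it
#'   carries a `phantom` list-column of [phantom_spec()] objects (e.g., from
#'   `simulate_cohort(..., phantoms = TRUE)`, possibly edited per subject),
#'   phantoms are built in place of reading files.
#' @param fw A [fw_config()].
#' @param rois An [alps_roi_spec()], or `NULL` to use each phantom's own ROI
#'   placement (simulated input only).
#' @param qc_cutoff tSNR pass/fail threshold.
#' @param qc_exclude Drop QC-failing subjects from the group inference.
#' @param fa_threshold Skeleton FA threshold.
#' @param covariates,factor_var Columns entering the Bayesian ANCOVAs.
#' @param r_scales Prior scales for [run_bayes_ancova()].
#' @param seed Master seed; all per-subject randomness derives from it.
#' @param phantom_args Arguments forwarded to [phantom_spec()] for
#'   simulated subjects.
#' @param out_dir Optional output directory for the cohort CSV and result
#'   JSON.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, subjects = NULL, fw = fw_config(),
                            rois = NULL, qc_cutoff = 6.47, qc_exclude = TRUE,
                            fa_threshold = 0.2,
                            covariates = c("age", "edss"), factor_var = "group",
                            r_scales = c(factor = 0.5, continuous = sqrt(2) / 4),
                            seed = 1L, phantom_args = list(), out_dir = NULL) {
  if (is.null(cohort) == is.null(subjects)) {
    abort("provide exactly one of `cohort` or `subjects`")
  }
  structure(list(cohort = cohort, subjects = subjects, fw = fw, rois = rois,
                 qc_cutoff = qc_cutoff, qc_exclude = qc_exclude,
                 fa_threshold = fa_threshold, covariates = covariates,
                 factor_var = factor_var, r_scales = r_scales,
                 seed = as.integer(seed), phantom_args = phantom_args,
                 out_dir = out_dir),
            class = "pipeline_config")
}

process_subject <- function(dwi, lesion_mask, cfg) {
  qc <- tsnr(dwi, cutoff = cfg$qc_cutoff)
  tmaps <- fit_tensor(dwi)
  fwres <- fit_fw(dwi, cfg = cfg$fw)
  skel <- wm_skeleton(tmaps, fa_threshold = cfg$fa_threshold)
  fwsum <- mean_fw_on_skeleton(fwres, skel, lesion_mask)
  list(qc = qc, tmaps = tmaps, fw = fwres, skeleton = skel, fw_summary = fwsum)
}

#' Run the full glymphatic-DWI pipeline
#'
#' Per subject: tSNR QC, single-tensor fit, bi-tensor free-water fit,
#' skeleton-mean FW index, and the DTI-ALPS index with lesion exclusion;
#' then two Bayesian model-averaged ANCOVAs (dv = fw and dv = alps) with
#' age and EDSS as covariates and group as the fixed factor. Subjects
#' failing QC are flagged and, by default, excluded from the inference with
#' a logged count. Fully deterministic given the master seed.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print per-subject progress to stderr.
#' @return An object of class `pipeline_result`: `subjects` (per-subject
#'   tibble), `ancova_fw` and `ancova_alps` ([run_bayes_ancova()] results),
#'   `n_qc_failed`, `seed`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config")
  if (!is.null(config$cohort)) {
    tab <- simulate_cohort(config$cohort, phantoms = TRUE,
                           phantom_args = config$phantom_args)
    tab <- dplyr::rename(tab, fw_target = "fw", alps_target = "alps")
  } else {
    tab <- tibble::as_tibble(config$subjects)
  }
  simulated <- "phantom" %in% names(tab)
  rows <- purrr::map(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    res <- tryCatch({
      if (simulated) {
        ph <- build_phantom(row$phantom[[1]])
        dwi <- ph$dwi
        lesion <- ph$truth$lesion_mask
        rois <- config$rois %||% ph$truth$roi_spec
      } else {
        dwi <- read_dwi(row$dwi, row$bval, row$bvec)
        lesion <- if (!is.null(row$lesion) && !is.na(row$lesion)) {
          lm <- read_nifti_map(row$lesion)
          volume_mask(lm$data != 0, lm$affine)
        } else NULL
        rois <- config$rois %||% alps_roi_spec()
      }
      sub <- process_subject(dwi, lesion, config)
      alps_res <- compute_alps(sub$tmaps, rois, lesion)
      tibble::tibble(
        tsnr = sub$qc$summary, qc_pass = sub$qc$pass,
        fw = sub$fw_summary$fw_index,
        fw_n_used = sub$fw_summary$n_used, fw_n_excluded = sub$fw_summary$n_excluded,
        alps = alps_res$alps_mean, alps_left = alps_res$alps_left,
        alps_right = alps_res$alps_right,
        error = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(tsnr = NA_real_, qc_pass = FALSE, fw = NA_real_,
                     fw_n_used = NA_integer_, fw_n_excluded = NA_integer_,
                     alps = NA_real_, alps_left = NA_real_, alps_right = NA_real_,
                     error = conditionMessage(e))
    })
    if (verbose) {
      message(sprintf("[%d/%d] %s: tSNR %.2f, fw %.3f, alps %.3f%s",
                      i, nrow(tab), row$subject, res$tsnr, res$fw, res$alps,
                      if (!is.na(res$error)) paste0(" ERROR: ", res$error) else ""))
    }
    res
  })
  subjects <- dplyr::bind_cols(
    dplyr::select(tab, dplyr::any_of(c("subject", "group", "group_code", "age", "edss",
                                       "fw_target", "alps_target"))),
    dplyr::bind_rows(rows)
  )
  usable <- subjects[!is.na(subjects$fw) & !is.na(subjects$alps), , drop = FALSE]
  if (config$qc_exclude) usable <- usable[usable$qc_pass, , drop = FALSE]
  n_qc_failed <- sum(!subjects$qc_pass, na.rm = TRUE)
  counts <- table(usable[[config$factor_var]])
  if (length(counts) < 2L || any(counts < 3L)) {
    abort("fewer than 3 usable subjects per group after QC exclusion")
  }
  anc_fw <- run_bayes_ancova(usable, "fw", covariates = config$covariates,
                             factor_var = config$factor_var, r_scales = config$r_scales)
  anc_alps <- run_bayes_ancova(usable, "alps", covariates = config$covariates,
                               factor_var = config$factor_var, r_scales = config$r_scales)
  out <- structure(list(subjects = subjects, ancova_fw = anc_fw,
                        ancova_alps = anc_alps, n_qc_failed = n_qc_failed,
                        seed = config$seed),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(out, config$out_dir)
  out
}

#' Serialize a pipeline result to CSV + JSON
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "cohort_results.csv")
  subj <- dplyr::select(result$subjects, -dplyr::any_of("phantom"))
  utils::write.csv(subj, csv, row.names = FALSE)
  js <- file.path(out_dir, "bayes_results.json")
  payload <- list(
    seed = result$seed,
    n_qc_failed = result$n_qc_failed,
    ancova = lapply(list(fw = result$ancova_fw, alps = result$ancova_alps), function(a) {
      list(dv = a$dv, n = a$n, n_dropped = a$n_dropped,
           r_scales = as.list(a$r_scales),
           models = dplyr::mutate(a$models, terms = purrr::map_chr(
             a$models$terms, ~ paste(.x, collapse = "+"))),
           inclusion = a$inclusion)
    })
  )
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv, json = js))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects (%d QC failures), seed %d\n",
              nrow(x$subjects), x$n_qc_failed, x$seed))
  for (a in list(x$ancova_fw, x$ancova_alps)) {
    gi <- a$inclusion$inclusion_bf[a$inclusion$predictor == a$factor_var &
                                     a$inclusion$variant == "all"]
    cat(sprintf("  dv %-5s: group inclusion BF = %.4g, null P(M|D) = %.3f\n",
                a$dv, gi, a$models$posterior_prob[a$models$model == "null"]))
  }
  invisible(x)
}
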