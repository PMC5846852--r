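# Pipeline orchestration: cohort -> forward curves -> tri-linear fits ->
# group comparison -> experimental-vs-computational concordance ->
# bone-rigidity sensitivity study.

trilinear_metrics <- c("eym_initial", "eym_transition", "eym_linear",
                       "ts1", "ts2")

#' Concordance report between two paired fit tables
#'
#' For each tri-linear metric: R^2 of the least-squares regression of `y` on
#' `x`, Lin's concordance correlation coefficient, and the two-sided variance
#' F-test p-value between the paired series.
#'
#' @param fits_x,fits_y Fit tables as returned by [fit_cohort()], matched by
#'   `specimen_id`.
#' @param metrics Metric columns to compare (default the five tri-linear
#'   quantities).
#' @return A tibble with one row per metric: `metric`, `r_squared`, `ccc`,
#'   `f_test_p`, `n_pairs`.
#' @export
concordance_report <- function(fits_x, fits_y, metrics = trilinear_metrics) {
  stopifnot(is.data.frame(fits_x), is.data.frame(fits_y))
  m <- dplyr::inner_join(fits_x, fits_y, by = "specimen_id",
                         suffix = c("_x", "_y"))
  purrr::map_dfr(metrics, function(k) {
    x <- m[[paste0(k, "_x")]]
    y <- m[[paste0(k, "_y")]]
    identical_pair <- isTRUE(all.equal(x, y, tolerance = 0))
    tibble::tibble(
      metric = k,
      r_squared = if (identical_pair) 1 else regression_r2(x, y),
      ccc = if (identical_pair) 1 else lin_ccc(x, y),
      f_test_p = variance_f_test(x, y)$p_value,
      n_pairs = length(x)
    )
  })
}

#' Run the bone-rigidity sensitivity study
#'
#' Re-solves the noise-free forward model for every specimen under the
#' `homogeneous_average` (both vertebrae set to the cohort-average-greyscale
#' modulus) and `near_rigid` (PMMA modulus) bone variants, refits the
#' tri-linear model, and reports Lin's CCC between the heterogeneous
#' baseline and each variant for every tri-linear metric.
#'
#' @param cohort An `fsu_cohort`.
#' @param fits_het Optional precomputed baseline fit table
#'   (from `fit_cohort(cohort, "computational")`); computed if `NULL`.
#' @param protocol A [load_protocol()]; defaults to the cohort's own.
#' @param modes Sensitivity modes to run.
#' @return A tibble: `metric`, `mode`, `ccc`, `r_squared`, `n_pairs`.
#' @export
run_sensitivity <- function(cohort, fits_het = NULL, protocol = NULL,
                            modes = c("homogeneous_average", "near_rigid")) {
  stopifnot(inherits(cohort, "fsu_cohort"))
  config <- attr(cohort, "config")
  if (is.null(protocol)) {
    protocol <- if (!is.null(config)) config$protocol else load_protocol()
  }
  if (is.null(fits_het)) fits_het <- fit_cohort(cohort, "computational")
  gs_mean <- mean(purrr::map_dbl(cohort$specimen, function(s)
    mean(c(s$vertebra_sup$mean_greyscale, s$vertebra_inf$mean_greyscale))))
  purrr::map_dfr(modes, function(mode) {
    variant <- cohort
    variant$specimen <- purrr::map(cohort$specimen, sensitivity_variant,
                                   mode = mode,
                                   cohort_mean_greyscale = gs_mean)
    variant$curve <- purrr::map(variant$specimen, specimen_response,
                                protocol = protocol)
    fits_v <- fit_cohort(variant, "computational")
    rep <- concordance_report(fits_het, fits_v)
    tibble::tibble(metric = rep$metric, mode = mode, ccc = rep$ccc,
                   r_squared = rep$r_squared, n_pairs = rep$n_pairs)
  })
}

#' Run the full in-silico study
#'
#' Generates the cohort, fits the tri-linear model to both arms (noise-free
#' forward model playing the computational role; noisy curves the
#' experimental role), compares groups per metric with normality-gated
#' omnibus tests, computes the experimental-vs-computational concordance
#' report, the per-specimen bone strain contributions for the CON group, and
#' (optionally) the bone-rigidity sensitivity study. Deterministic under the
#' configuration seed.
#'
#' @param config A [cohort_config()].
#' @param alpha Significance level for the statistics layer.
#' @param sensitivity Run the bone-rigidity sensitivity study (default
#'   `TRUE`).
#' @param posthoc_adjust Post hoc p-value adjustment, `"none"` or `"holm"`.
#' @return An object of class `fsu_report`: `fits` (both arms, long),
#'   `group_comparison` (tidy omnibus table per metric and arm),
#'   `posthoc` (pairwise t-test table, when applicable), `concordance`,
#'   `bone_contribution`, `sensitivity` (or `NULL`), `provenance`.
#' @export
run_full <- function(config = cohort_config(), alpha = 0.05,
                     sensitivity = TRUE,
                     posthoc_adjust = c("none", "holm")) {
  posthoc_adjust <- match.arg(posthoc_adjust)
  cohort <- generate_cohort(config)
  fits_comp <- fit_cohort(cohort, "computational")
  fits_exp <- fit_cohort(cohort, "experimental")
  fits <- dplyr::bind_rows(
    dplyr::mutate(fits_comp, arm = "computational", .before = 1),
    dplyr::mutate(fits_exp, arm = "experimental", .before = 1)
  )

  comparisons <- purrr::map(
    rlang::set_names(c("computational", "experimental")),
    function(arm_k) {
      tab <- if (arm_k == "computational") fits_comp else fits_exp
      purrr::map(rlang::set_names(trilinear_metrics), function(k)
        compare_groups(tab, k, "group", alpha = alpha,
                       posthoc_adjust = posthoc_adjust))
    })
  group_comparison <- purrr::map_dfr(names(comparisons), function(arm_k)
    dplyr::mutate(purrr::map_dfr(comparisons[[arm_k]], tidy),
                  arm = arm_k, .before = 1))
  posthoc <- purrr::map_dfr(names(comparisons), function(arm_k)
    purrr::map_dfr(comparisons[[arm_k]], function(cmp) {
      if (is.null(cmp$posthoc)) return(NULL)
      dplyr::mutate(cmp$posthoc, arm = arm_k, metric = cmp$metric,
                    .before = 1)
    }))

  concordance <- concordance_report(fits_exp, fits_comp)

  con <- cohort[cohort$group == "CON", ]
  bone_contribution <- tibble::tibble(
    specimen_id = con$id,
    contribution_pct = 100 * purrr::map_dbl(con$specimen,
                                            bone_strain_contribution,
                                            protocol = config$protocol)
  )

  sens <- if (sensitivity) {
    run_sensitivity(cohort, fits_het = fits_comp, protocol = config$protocol)
  }

  structure(
    list(fits = fits, group_comparison = group_comparison,
         posthoc = if (nrow(posthoc) > 0) posthoc else NULL,
         concordance = concordance,
         bone_contribution = bone_contribution,
         sensitivity = sens,
         cohort = cohort,
         provenance = list(seed = config$seed,
                           config_hash = rlang::hash(config),
                           package_version =
                             as.character(utils::packageVersion("fsuaxial")),
                           r_version = R.version.string)),
    class = "fsu_report"
  )
}

#' @export
print.fsu_report <- function(x, ...) {
  cat("In-silico bone-disc-bone compression study (seed ",
      x$provenance$seed, ")\n", sep = "")
  cat("Group comparison (omnibus):\n")
  print(as.data.frame(x$group_comparison), row.names = FALSE, digits = 4)
  cat("\nExperimental vs computational concordance:\n")
  print(as.data.frame(x$concordance), row.names = FALSE, digits = 4)
  cat("\nBone contribution to apparent strain (CON group, % at peak load):\n")
  print(as.data.frame(x$bone_contribution), row.names = FALSE, digits = 3)
  if (!is.null(x$sensitivity)) {
    cat("\nBone-rigidity sensitivity (CCC vs heterogeneous baseline):\n")
    print(as.data.frame(x$sensitivity), row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write a study report to a directory
#'
#' Writes the fit table, group comparison, concordance, bone contribution
#' and sensitivity tables as CSV plus a single `report.json`.
#'
#' @param report An `fsu_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "fsu_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(fits = report$fits,
               group_comparison = report$group_comparison,
               posthoc = report$posthoc,
               concordance = report$concordance,
               bone_contribution = report$bone_contribution,
               sensitivity = report$sensitivity)
  tabs <- tabs[!purrr::map_lgl(tabs, is.null)]
  purrr::iwalk(tabs, function(tab, nm)
    readr::write_csv(tab, file.path(dir, paste0(nm, ".csv"))))
  jsonlite::write_json(c(tabs, list(provenance = report$provenance)),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
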