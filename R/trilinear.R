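#' Normalize a force-displacement curve to effective stress / engineering strain
#'
#' `stress = force / area` (MPa for N and mm^2) and
#' `strain = displacement / height` (dimensionless), using specimen-specific
#' disc cross-sectional area and disc height.
#'
#' @param curve An [fd_curve()] (or any data frame with `displacement_mm`
#'   and `force_N` columns).
#' @param area Disc cross-sectional area, mm^2 (> 0).
#' @param height Disc height, mm (> 0).
#' @return A tibble of class `stress_strain` with columns `strain`, `stress`.
#' @export
#' @examples
#' normalize_curve(fd_curve(c(0, 1.2), c(10, 2100)), area = 700, height = 8)
normalize_curve <- function(curve, area, height) {
  stopifnot(is.data.frame(curve),
            all(c("displacement_mm", "force_N") %in% names(curve)))
  if (!is.finite(area) || area <= 0 || !is.finite(height) || height <= 0) {
    rlang::abort("area and height must be positive",
                 class = "fsuaxial_error_domain")
  }
  structure(tibble::tibble(strain = curve$displacement_mm / height,
                           stress = curve$force_N / area),
            class = c("stress_strain", "tbl_df", "tbl", "data.frame"))
}

#' Parameters of the continuous tri-linear stress/strain model
#'
#' @param eym_initial,eym_transition,eym_linear Effective Young's moduli of
#'   the three segments, MPa.
#' @param ts1,ts2 Transition strains (0 < ts1 < ts2).
#' @param intercept Stress at zero strain, MPa (default 0).
#' @return An object of class `trilinear_params`.
#' @export
trilinear_params <- function(eym_initial, eym_transition, eym_linear,
                             ts1, ts2, intercept = 0) {
  stopifnot(is.finite(c(eym_initial, eym_transition, eym_linear, intercept)),
            ts1 > 0, ts2 > ts1)
  structure(list(eym_initial = eym_initial, eym_transition = eym_transition,
                 eym_linear = eym_linear, ts1 = ts1, ts2 = ts2,
                 intercept = intercept),
            class = "trilinear_params")
}

#' Evaluate the continuous tri-linear model
#'
#' \deqn{\sigma(\varepsilon) = \sigma_0 + E_1 \min(\varepsilon, \varepsilon_1)
#'  + E_2\,\mathrm{clamp}(\varepsilon - \varepsilon_1, 0,
#'   \varepsilon_2 - \varepsilon_1)
#'  + E_3 \max(\varepsilon - \varepsilon_2, 0)}
#' Continuous everywhere with piecewise slopes exactly
#' (`eym_initial`, `eym_transition`, `eym_linear`).
#'
#' @param strain Strain value(s).
#' @param params A [trilinear_params()] object.
#' @return Stress, MPa.
#' @export
trilinear_model <- function(strain, params) {
  stopifnot(inherits(params, "trilinear_params"))
  params$intercept +
    params$eym_initial * pmin(strain, params$ts1) +
    params$eym_transition * pmin(pmax(strain - params$ts1, 0),
                                 params$ts2 - params$ts1) +
    params$eym_linear * pmax(strain - params$ts2, 0)
}

# Basis matrix of the tri-linear model at breakpoints (e1, e2).
trilinear_basis <- function(strain, e1, e2, free_intercept = FALSE) {
  X <- cbind(pmin(strain, e1),
             pmin(pmax(strain - e1, 0), e2 - e1),
             pmax(strain - e2, 0))
  if (free_intercept) X <- cbind(1, X)
  X
}

# RSS and slopes for fixed breakpoints (inner exact linear least squares).
trilinear_profile <- function(strain, stress, e1, e2, free_intercept = FALSE) {
  X <- trilinear_basis(strain, e1, e2, free_intercept)
  fit <- stats::lm.fit(X, stress)
  list(coef = unname(fit$coefficients), rss = sum(fit$residuals^2),
       fitted = as.numeric(stress - fit$residuals))
}

# Smooth bounded transform of the 2-D breakpoint coordinates:
# s = 0.02 + 0.96 * plogis(u) in (0.02, 0.98);
# e1 = smax * s1, e2 = e1 + (smax - e1) * s2, guaranteeing order.
breakpoints_from_u <- function(u, smax) {
  s <- 0.02 + 0.96 * stats::plogis(u)
  e1 <- smax * s[1]
  c(e1, e1 + (smax - e1) * s[2])
}

u_from_breakpoints <- function(e1, e2, smax) {
  s1 <- clip(e1 / smax, 0.021, 0.979)
  s2 <- clip((e2 - e1) / (smax - e1), 0.021, 0.979)
  stats::qlogis((c(s1, s2) - 0.02) / 0.96)
}

#' Fit the continuous tri-linear model to a stress/strain curve
#'
#' Minimizes \eqn{\sum_i (\sigma_i - \sigma(\varepsilon_i))^2} over the five
#' parameters (three segment moduli, two ordered interior transition
#' strains). The breakpoints are optimized by Nelder-Mead in a smooth bounded
#' transform that guarantees `0 < ts1 < ts2 < max(strain)`; for any candidate
#' breakpoint pair the slopes are profiled out by exact linear least squares.
#' Multiple deterministic starts (breakpoints at fixed strain-quantile pairs)
#' guard against local minima. If any two fitted slopes differ by less than
#' 1% relative the fit is flagged `degenerate` (breakpoints unidentifiable)
#' and the breakpoints are reported at the 33rd/66th strain percentiles with
#' slopes re-solved there.
#'
#' @param curve A `stress_strain` tibble (see [normalize_curve()]), >= 8
#'   points spanning a nonzero strain range.
#' @param free_intercept Estimate a free intercept (default `FALSE`: curves
#'   are re-zeroed at the preload so the fit is anchored at the origin).
#' @param n_starts Number of deterministic multi-starts (default 5).
#' @param reltol,maxit Nelder-Mead convergence controls.
#' @return An object of class `trilinear_fit`: fields `params`
#'   ([trilinear_params()]), `nrmse_pct` (RMSE as % of the stress range),
#'   `pearson_r`, `converged`, `degenerate`, `n_points`, `rss`, `data`,
#'   `fitted`. Has [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
fit_trilinear <- function(curve, free_intercept = FALSE, n_starts = 5,
                          reltol = 1e-14, maxit = 4000) {
  stopifnot(is.data.frame(curve), all(c("strain", "stress") %in% names(curve)))
  strain <- curve$strain
  stress <- curve$stress
  n <- length(strain)
  if (n < 8) {
    rlang::abort("tri-linear fit needs at least 8 points",
                 class = "fsuaxial_error_fit")
  }
  smax <- max(strain)
  if (!(smax > min(strain)) || smax <= 0) {
    rlang::abort("strain range must be nonzero",
                 class = "fsuaxial_error_fit")
  }

  obj <- function(u) {
    e <- breakpoints_from_u(u, smax)
    trilinear_profile(strain, stress, e[1], e[2], free_intercept)$rss
  }

  # deterministic quantile-pair starts; first is the 33/66 initialization
  start_q <- list(c(1 / 3, 2 / 3), c(0.2, 0.5), c(0.5, 0.8),
                  c(0.25, 0.75), c(0.15, 0.4))
  start_q <- start_q[seq_len(min(n_starts, length(start_q)))]
  best <- NULL
  for (q in start_q) {
    e0 <- stats::quantile(strain, q, names = FALSE)
    u0 <- u_from_breakpoints(e0[1], e0[2], smax)
    res <- stats::optim(u0, obj, method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = maxit))
    if (is.null(best) || res$value < best$value) best <- res
  }

  e <- breakpoints_from_u(best$par, smax)
  prof <- trilinear_profile(strain, stress, e[1], e[2], free_intercept)
  coef <- prof$coef
  intercept <- if (free_intercept) coef[1] else 0
  slopes <- if (free_intercept) coef[-1] else coef

  # degeneracy: any two slopes within 1% relative => breakpoints
  # unidentifiable; report them at the initialization quantiles
  rel <- function(a, b) abs(a - b) / max(abs(a), abs(b), .Machine$double.eps)
  degenerate <- rel(slopes[1], slopes[2]) < 0.01 ||
    rel(slopes[2], slopes[3]) < 0.01 || rel(slopes[1], slopes[3]) < 0.01
  if (degenerate) {
    e <- stats::quantile(strain, c(1 / 3, 2 / 3), names = FALSE)
    prof <- trilinear_profile(strain, stress, e[1], e[2], free_intercept)
    coef <- prof$coef
    intercept <- if (free_intercept) coef[1] else 0
    slopes <- if (free_intercept) coef[-1] else coef
  }

  gof <- goodness_of_fit(curve, prof$fitted)
  structure(
    list(params = trilinear_params(slopes[1], slopes[2], slopes[3],
                                   e[1], e[2], intercept),
         nrmse_pct = gof$nrmse_pct, pearson_r = gof$pearson_r,
         converged = best$convergence == 0, degenerate = degenerate,
         n_points = n, rss = prof$rss,
         data = tibble::as_tibble(curve[c("strain", "stress")]),
         fitted = prof$fitted),
    class = "trilinear_fit"
  )
}

#' Goodness of fit of a fitted stress curve
#'
#' Normalized RMSE (as a percentage of the observed stress range) and the
#' product-moment (Pearson) correlation between data and fitted values. With
#' constant data the correlation is undefined and reported as `NA` (with a
#' warning), never silently 0.
#'
#' @param curve A `stress_strain` tibble (columns `strain`, `stress`).
#' @param fitted Fitted stress values, same length as the data.
#' @return A list with `nrmse_pct` and `pearson_r`.
#' @export
goodness_of_fit <- function(curve, fitted) {
  stopifnot(is.data.frame(curve), "stress" %in% names(curve))
  stress <- curve$stress
  if (length(stress) != length(fitted) || length(stress) < 2) {
    rlang::abort("data and fitted values must have equal length >= 2",
                 class = "fsuaxial_error_fit")
  }
  rmse <- sqrt(mean((stress - fitted)^2))
  rng <- diff(range(stress))
  nrmse <- if (rng > 0) 100 * rmse / rng else NA_real_
  r <- if (stats::sd(stress) == 0 || stats::sd(fitted) == 0) {
    rlang::warn("correlation undefined for constant data; reporting NA")
    NA_real_
  } else {
    stats::cor(stress, fitted)
  }
  list(nrmse_pct = nrmse, pearson_r = r)
}

#' @export
print.trilinear_fit <- function(x, ...) {
  p <- x$params
  cat("Continuous tri-linear stress/strain fit (", x$n_points, " points)\n",
      sep = "")
  cat(sprintf("  EYM (MPa): initial %.4g, transition %.4g, linear %.4g\n",
              p$eym_initial, p$eym_transition, p$eym_linear))
  cat(sprintf("  transition strains: %.4g, %.4g\n", p$ts1, p$ts2))
  cat(sprintf("  NRMSE %.3g%% of stress range, Pearson r %.5f%s\n",
              x$nrmse_pct, x$pearson_r,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Tidy a tri-linear fit
#'
#' @param x A `trilinear_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate` (three moduli, two
#'   transition strains, intercept).
#' @export
tidy.trilinear_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("eym_initial", "eym_transition", "eym_linear",
             "ts1", "ts2", "intercept"),
    estimate = c(p$eym_initial, p$eym_transition, p$eym_linear,
                 p$ts1, p$ts2, p$intercept)
  )
}

#' Glance at a tri-linear fit
#'
#' @param x A `trilinear_fit`.
#' @param ... Unused.
#' @return A one-row tibble with goodness-of-fit summaries.
#' @export
glance.trilinear_fit <- function(x, ...) {
  tibble::tibble(nrmse_pct = x$nrmse_pct, pearson_r = x$pearson_r,
                 rss = x$rss, converged = x$converged,
                 degenerate = x$degenerate, n_points = x$n_points)
}

#' Plot a tri-linear fit over its data
#'
#' @param object A `trilinear_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trilinear_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  p <- object$params
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strain)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$stress), size = 0.8,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::geom_vline(xintercept = c(p$ts1, p$ts2), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "engineering strain", y = "effective stress (MPa)",
                  title = "Continuous tri-linear fit")
}

#' Fit the tri-linear model to every specimen of a cohort
#'
#' Normalizes each curve by its specimen's disc cross-sectional area and disc
#' height, fits the continuous tri-linear model, and returns one row per
#' specimen.
#'
#' @param cohort An `fsu_cohort` (see [generate_cohort()]).
#' @param arm `"computational"` (noise-free forward-model curves) or
#'   `"experimental"` (noisy arm).
#' @param ... Passed to [fit_trilinear()].
#' @return A tibble with columns `specimen_id`, `group`, `eym_initial`,
#'   `eym_transition`, `eym_linear`, `ts1`, `ts2`, `nrmse_pct`, `pearson_r`,
#'   `degenerate`.
#' @export
fit_cohort <- function(cohort, arm = c("computational", "experimental"), ...) {
  stopifnot(inherits(cohort, "fsu_cohort"))
  arm <- match.arg(arm)
  col <- if (arm == "computational") "curve" else "curve_noisy"
  rows <- purrr::pmap(list(cohort$id, as.character(cohort$group),
                           cohort$specimen, cohort[[col]]),
                      function(id, grp, spec, cv, ...) {
    ss <- normalize_curve(cv, spec$geometry$disc_area,
                          spec$geometry$disc_height)
    ft <- fit_trilinear(ss, ...)
    p <- ft$params
    tibble::tibble(specimen_id = id, group = grp,
                   eym_initial = p$eym_initial,
                   eym_transition = p$eym_transition,
                   eym_linear = p$eym_linear,
                   ts1 = p$ts1, ts2 = p$ts2,
                   nrmse_pct = ft$nrmse_pct, pearson_r = ft$pearson_r,
                   degenerate = ft$degenerate)
  })
  out <- dplyr::bind_rows(rows)
  out$group <- factor(out$group, levels = fsu_groups)
  out
}

#' Batch-fit externally supplied curve files
#'
#' Reads force-displacement CSVs (dialect `displacement_mm, force_N`) and a
#' geometry table, normalizes and fits each curve.
#'
#' @param curve_files Named character vector of CSV paths; names are
#'   specimen ids (defaults to file base names).
#' @param geometry A data frame with columns `specimen_id`, `area_mm2`,
#'   `height_mm`.
#' @param ... Passed to [fit_trilinear()].
#' @return The same results table as [fit_cohort()] (without `group`).
#' @export
fit_curve_files <- function(curve_files, geometry, ...) {
  stopifnot(is.data.frame(geometry),
            all(c("specimen_id", "area_mm2", "height_mm") %in% names(geometry)))
  ids <- names(curve_files)
  if (is.null(ids)) ids <- sub("\\.[^.]*$", "", basename(curve_files))
  rows <- purrr::map2(curve_files, ids, function(path, id) {
    g <- geometry[geometry$specimen_id == id, ]
    if (nrow(g) != 1) {
      rlang::abort(paste0("no unique geometry row for specimen ", id),
                   class = "fsuaxial_error_parse")
    }
    ss <- normalize_curve(read_curve_csv(path), g$area_mm2, g$height_mm)
    ft <- fit_trilinear(ss, ...)
    p <- ft$params
    tibble::tibble(specimen_id = id,
                   eym_initial = p$eym_initial,
                   eym_transition = p$eym_transition,
                   eym_linear = p$eym_linear,
                   ts1 = p$ts1, ts2 = p$ts2,
                   nrmse_pct = ft$nrmse_pct, pearson_r = ft$pearson_r,
                   degenerate = ft$degenerate)
  })
  dplyr::bind_rows(rows)
}
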