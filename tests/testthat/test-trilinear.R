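test_that("normalization is the stated arithmetic and scales correctly", {
  cv <- fd_curve(c(0, 0.6, 1.2), c(10, 1000, 2100))
  ss <- normalize_curve(cv, area = 700, height = 8)
  expect_equal(ss$stress[3], 3, tolerance = 1e-12)
  expect_equal(ss$strain[3], 0.15, tolerance = 1e-12)
  expect_equal(ss$strain[1], 0)
  # doubling the area halves every stress and leaves strain unchanged
  ss2 <- normalize_curve(cv, area = 1400, height = 8)
  expect_equal(ss2$stress, ss$stress / 2)
  expect_equal(ss2$strain, ss$strain)
  expect_error(normalize_curve(cv, area = 0, height = 8),
               class = "fsuaxial_error_domain")
  expect_error(normalize_curve(cv, area = 700, height = -1),
               class = "fsuaxial_error_domain")
})

test_that("the tri-linear model is continuous with the stated piecewise form", {
  p <- trilinear_params(1, 4, 10, 0.03, 0.07)
  expect_equal(trilinear_model(0, p), 0)
  # hand evaluation at 0.10: 1*0.03 + 4*0.04 + 10*0.03
  expect_equal(trilinear_model(0.10, p), 0.49, tolerance = 1e-12)
  # continuity across both breakpoints
  h <- 1e-12
  expect_equal(trilinear_model(p$ts1 - h, p), trilinear_model(p$ts1 + h, p),
               tolerance = 1e-8)
  expect_equal(trilinear_model(p$ts2 - h, p), trilinear_model(p$ts2 + h, p),
               tolerance = 1e-8)
  # segment slopes are exactly the three moduli
  slope <- function(a, b) (trilinear_model(b, p) - trilinear_model(a, p)) / (b - a)
  expect_equal(slope(0, 0.03), 1)
  expect_equal(slope(0.03, 0.07), 4)
  expect_equal(slope(0.07, 0.2), 10)
  # free intercept shifts the whole curve
  p2 <- trilinear_params(1, 4, 10, 0.03, 0.07, intercept = 0.5)
  expect_equal(trilinear_model(0, p2), 0.5)
})

test_that("noise-free generative data are recovered to high accuracy", {
  truth <- trilinear_params(1, 4, 10, 0.03, 0.07)
  ft <- fit_trilinear(trilinear_data(truth, n = 120))
  est <- ft$params
  for (k in c("eym_initial", "eym_transition", "eym_linear", "ts1", "ts2")) {
    expect_equal(est[[k]], truth[[k]], tolerance = 1e-4)
  }
  expect_false(ft$degenerate)
  expect_true(ft$converged)
  expect_lt(ft$nrmse_pct, 1e-4)
  expect_equal(ft$pearson_r, 1, tolerance = 1e-9)
})

test_that("random tri-linear parameter sets are recovered noise-free", {
  withr::with_seed(21, {
    for (r in 1:25) {
      truth <- trilinear_params(
        eym_initial = runif(1, 0.5, 3),
        eym_transition = runif(1, 4, 8),
        eym_linear = runif(1, 10, 25),
        ts1 = runif(1, 0.04, 0.12),
        ts2 = runif(1, 0.16, 0.28))
      ft <- fit_trilinear(trilinear_data(truth, n = 150))
      est <- ft$params
      for (k in c("eym_initial", "eym_transition", "eym_linear", "ts1", "ts2")) {
        expect_equal(est[[k]], truth[[k]], tolerance = 1e-3)
      }
    }
  })
})

test_that("straight-line data trigger the degeneracy rule", {
  strain <- seq(0.001, 0.2, length.out = 60)
  ss <- tibble::tibble(strain = strain, stress = 5 * strain)
  ft <- fit_trilinear(ss)
  expect_true(ft$degenerate)
  expect_equal(ft$params$eym_initial, 5, tolerance = 1e-6)
  expect_equal(ft$params$eym_transition, 5, tolerance = 1e-6)
  expect_equal(ft$params$eym_linear, 5, tolerance = 1e-6)
  # breakpoints reported at the initialization quantiles
  expect_equal(ft$params$ts1, unname(quantile(strain, 1 / 3)), tolerance = 1e-9)
  expect_equal(ft$params$ts2, unname(quantile(strain, 2 / 3)), tolerance = 1e-9)
})

test_that("proportional noise leaves slopes recoverable and nrmse near the noise level", {
  truth <- trilinear_params(1.5, 5, 15, 0.05, 0.12)
  for (seed in 1:8) {
    ft <- fit_trilinear(trilinear_data(truth, n = 400, noise_sd = 0.02,
                                       seed = seed))
    est <- ft$params
    expect_equal(est$eym_initial, truth$eym_initial, tolerance = 0.05)
    expect_equal(est$eym_transition, truth$eym_transition, tolerance = 0.05)
    expect_equal(est$eym_linear, truth$eym_linear, tolerance = 0.05)
    # 2% proportional noise on stresses up to ~sigma_max: nrmse (% of range)
    # stays the same order as the noise level
    expect_gt(ft$nrmse_pct, 0.3)
    expect_lt(ft$nrmse_pct, 4)
    expect_gt(ft$pearson_r, 0.995)
  }
})

test_that("the optimizer is never beaten by the brute-force breakpoint grid", {
  withr::with_seed(31, {
    for (r in 1:10) {
      truth <- trilinear_params(
        eym_initial = runif(1, 0.5, 3), eym_transition = runif(1, 4, 8),
        eym_linear = runif(1, 10, 25),
        ts1 = runif(1, 0.05, 0.1), ts2 = runif(1, 0.15, 0.25))
      ss <- trilinear_data(truth, n = 40, noise_sd = 0.03, seed = 1000 + r)
      ft <- fit_trilinear(ss)
      oracle <- trilinear_grid_oracle(ss$strain, ss$stress)
      expect_lte(ft$rss, oracle + 1e-9)
    }
  })
})

test_that("rescaling stress rescales the moduli and fixes the transition strains", {
  truth <- trilinear_params(1, 4, 10, 0.05, 0.12)
  ss <- trilinear_data(truth, n = 150, noise_sd = 0.02, seed = 77)
  f1 <- fit_trilinear(ss)
  ss2 <- ss
  ss2$stress <- ss2$stress * 7
  f2 <- fit_trilinear(ss2)
  expect_equal(f2$params$eym_initial, 7 * f1$params$eym_initial, tolerance = 1e-6)
  expect_equal(f2$params$eym_linear, 7 * f1$params$eym_linear, tolerance = 1e-6)
  expect_equal(f2$params$ts1, f1$params$ts1, tolerance = 1e-6)
  expect_equal(f2$params$ts2, f1$params$ts2, tolerance = 1e-6)
  expect_equal(f2$nrmse_pct, f1$nrmse_pct, tolerance = 1e-6)
})

test_that("fitted segment values are non-decreasing on monotone data", {
  s <- specimen("m")
  ss <- normalize_curve(specimen_response(s, load_protocol(n_points = 40)),
                        s$geometry$disc_area, s$geometry$disc_height)
  ft <- fit_trilinear(ss)
  vals <- trilinear_model(c(0, ft$params$ts1, ft$params$ts2, max(ss$strain)),
                          ft$params)
  expect_true(all(diff(vals) >= 0))
})

test_that("goodness of fit follows the stated formulas", {
  ss <- tibble::tibble(strain = 1:5 / 10, stress = c(1, 2, 4, 7, 11))
  g <- goodness_of_fit(ss, ss$stress)
  expect_equal(g$nrmse_pct, 0)
  expect_equal(g$pearson_r, 1)
  # constant offset: nrmse = 100 c / range, r stays 1
  g2 <- goodness_of_fit(ss, ss$stress + 0.5)
  expect_equal(g2$nrmse_pct, 100 * 0.5 / 10)
  expect_equal(g2$pearson_r, 1)
  # small worked vector against the direct formulas
  fitted <- c(1.2, 1.9, 4.4, 6.8, 11.1)
  g3 <- goodness_of_fit(ss, fitted)
  expect_equal(g3$nrmse_pct,
               100 * sqrt(mean((ss$stress - fitted)^2)) / diff(range(ss$stress)))
  expect_equal(g3$pearson_r, cor(ss$stress, fitted))
  # constant data: undefined correlation is reported, not silently zero
  const <- tibble::tibble(strain = 1:4 / 10, stress = rep(2, 4))
  expect_warning(g4 <- goodness_of_fit(const, rep(2, 4)))
  expect_true(is.na(g4$pearson_r))
  expect_error(goodness_of_fit(ss, 1:3), class = "fsuaxial_error_fit")
})

test_that("fit preconditions are enforced", {
  expect_error(fit_trilinear(tibble::tibble(strain = 1:5 / 10, stress = 1:5)),
               class = "fsuaxial_error_fit")
  expect_error(
    fit_trilinear(tibble::tibble(strain = rep(0, 10), stress = rep(1, 10))),
    class = "fsuaxial_error_fit")
})

test_that("tidy, glance and autoplot expose the fit in broom/ggplot idiom", {
  truth <- trilinear_params(1, 4, 10, 0.03, 0.07)
  ft <- fit_trilinear(trilinear_data(truth, n = 80))
  td <- tidy(ft)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$estimate[td$term == "eym_linear"], 10, tolerance = 1e-4)
  gl <- glance(ft)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("nrmse_pct", "pearson_r", "degenerate") %in% names(gl)))
  expect_s3_class(autoplot(ft), "ggplot")
})
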