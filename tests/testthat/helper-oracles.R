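# Independent oracles and shared fixtures, built in code.

# Random admissible deformation states around the reference configuration.
random_states <- function(n, seed = 42, spread = 0.12) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      lam <- exp(stats::runif(3, -spread, spread))
      deformation_state(lam[1], lam[2], lam[3])
    })
  })
}

# Central finite-difference principal Cauchy stresses from an energy
# function W(lambda_vec) -> scalar (independent of the analytic path).
fd_cauchy <- function(W_fun, lam, h = 1e-6) {
  J <- prod(lam)
  dW <- vapply(1:3, function(i) {
    lp <- lam; lm <- lam
    lp[i] <- lp[i] + h
    lm[i] <- lm[i] - h
    (W_fun(lp) - W_fun(lm)) / (2 * h)
  }, numeric(1))
  lam * dW / J
}

# Energy-minimization oracle for the disc axial force: at fixed axial
# stretch, minimize the annulus energy density over the (shared) lateral
# stretch, add the nucleus uniaxial Mooney-Rivlin energy, and differentiate
# the total potential with respect to the axial displacement numerically.
disc_force_energy_oracle <- function(spec, axial_stretch, h = 1e-6) {
  ann <- fsuaxial:::effective_annulus(spec)
  geo <- spec$geometry
  ann_W <- function(lz) {
    opt <- stats::optimize(function(lat)
      energy_holzapfel(deformation_state(lat, lat, lz), ann),
      interval = lz^(-1 / 2) * c(0.9, 1.1), tol = 1e-12)
    opt$objective
  }
  mr_W <- function(lz) {
    if (is.null(spec$nucleus)) return(0)
    lam <- c(lz^(-1 / 2), lz^(-1 / 2), lz)
    I1 <- sum(lam^2)
    I2 <- sum((lam * lam[c(2, 3, 1)])^2)
    spec$nucleus$c10 * (I1 - 3) + spec$nucleus$c01 * (I2 - 3)
  }
  # Pi(lz) = V_ann * W_ann + V_nuc * W_nuc; F = -dPi/d(h0 * lz)
  Pi <- function(lz) {
    geo$annulus_area * geo$disc_height * ann_W(lz) +
      geo$nucleus_area * geo$disc_height * mr_W(lz)
  }
  -(Pi(axial_stretch + h) - Pi(axial_stretch - h)) / (2 * h * geo$disc_height)
}

# Brute-force breakpoint-grid oracle for the tri-linear fit: try all ordered
# pairs of interior candidate breakpoints, solve the slopes by OLS, return
# the best RSS found.
trilinear_grid_oracle <- function(strain, stress, n_grid = 40) {
  cand <- seq(min(strain) + 0.02 * diff(range(strain)),
              max(strain) - 0.02 * diff(range(strain)),
              length.out = n_grid)
  best <- Inf
  for (i in seq_len(n_grid - 1)) {
    for (j in (i + 1):n_grid) {
      X <- cbind(pmin(strain, cand[i]),
                 pmin(pmax(strain - cand[i], 0), cand[j] - cand[i]),
                 pmax(strain - cand[j], 0))
      rss <- sum(stats::lm.fit(X, stress)$residuals^2)
      if (rss < best) best <- rss
    }
  }
  best
}

# Synthetic stress/strain data from known tri-linear parameters.
trilinear_data <- function(params, n = 200, smax = NULL, noise_sd = 0,
                           seed = NULL) {
  if (is.null(smax)) smax <- 1.4 * params$ts2
  strain <- seq(smax / n, smax, length.out = n)
  stress <- trilinear_model(strain, params)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    stress <- stress * (1 + stats::rnorm(n, 0, noise_sd))
  }
  structure(tibble::tibble(strain = strain, stress = stress),
            class = c("stress_strain", "tbl_df", "tbl", "data.frame"))
}

# Default cohort, generated once per test run and cached (used by several
# acceptance checks).
default_cohort_cached <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$cohort)) cache$cohort <- generate_cohort(cohort_config())
    cache$cohort
  }
})

default_fits_cached <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$fits)) {
      cache$fits <- fit_cohort(default_cohort_cached(), "computational")
    }
    cache$fits
  }
})
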