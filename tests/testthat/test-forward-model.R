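test_that("disc carries no force in the reference state and loses force on nucleotomy", {
  s <- specimen("a")
  expect_equal(disc_force(s, 1), 0)
  nr <- apply_group(s, "NR")
  for (lz in c(0.95, 0.85, 0.75)) {
    expect_lt(disc_force(nr, lz), disc_force(s, lz))
    expect_gt(disc_force(s, lz), 0)
  }
  expect_error(disc_force(s, 1.2), class = "fsuaxial_error_kinematics")
})

test_that("disc force agrees with the energy-minimization oracle", {
  withr::with_seed(99, {
    for (k in 1:20) {
      grp <- sample(c("CON", "NR", "PEP"), 1)
      base <- specimen(
        paste0("o", k),
        geometry = specimen_geometry(disc_diameter = runif(1, 25, 35),
                                     disc_height = runif(1, 6, 10)),
        annulus = holzapfel_params(c10 = 0.32 * runif(1, 0.7, 1.3)),
        nucleus = mooney_rivlin_params(c10 = 0.07 * runif(1, 0.7, 1.3))
      )
      s <- apply_group(base, grp, collapse_factor = runif(1, 0.4, 0.9))
      lz <- runif(1, 0.72, 0.95)
      expect_equal(disc_force(s, lz), disc_force_energy_oracle(s, lz),
                   tolerance = 1e-4)
    }
  })
})

test_that("a 15 mm, 409 MPa, 700 mm^2 bone segment deflects 0.110 mm at 2.1 kN", {
  d <- sqrt(4 * 700 / pi)
  gmap <- greyscale_map()
  gs409 <- (409 - gmap$intercept) / gmap$slope
  s <- specimen("b",
                geometry = specimen_geometry(disc_diameter = d,
                                             bone_length_sup = 15,
                                             bone_length_inf = 15),
                vertebra_sup = vertebra_props(gs409, 15),
                vertebra_inf = vertebra_props(gs409, 15))
  comp <- fsuaxial:::component_displacements(s, 2100)
  # hand arithmetic: 2100 * 15 / (409 * 700) per segment
  expect_equal(comp$bone / 2, 2100 * 15 / (409 * 700), tolerance = 1e-10)
})

test_that("total displacement is the exact sum of component displacements", {
  s <- specimen("c", endcap = list(material = linear_elastic_params(),
                                   length = 5))
  for (f in c(10, 500, 2100)) {
    comp <- fsuaxial:::component_displacements(s, f)
    expect_equal(comp$total, comp$disc + comp$bone + comp$endcap,
                 tolerance = 1e-9)
    expect_gt(comp$endcap, 0)
  }
})

test_that("specimen curves are monotone, preload-zeroed and end at max load", {
  s <- specimen("d")
  pr <- load_protocol(n_points = 30)
  cv <- specimen_response(s, pr)
  expect_s3_class(cv, "fd_curve")
  expect_equal(nrow(cv), 30)
  expect_equal(cv$displacement_mm[1], 0)
  expect_equal(cv$force_N[1], pr$preload)
  expect_equal(cv$force_N[nrow(cv)], pr$max_force)
  expect_true(all(diff(cv$displacement_mm) > 0))
  expect_true(all(diff(cv$force_N) > 0))
})

test_that("doubling the bone lengths doubles the bone displacement at every force", {
  s1 <- specimen("e")
  g <- s1$geometry
  s2 <- specimen("e2",
                 geometry = specimen_geometry(
                   disc_diameter = g$disc_diameter, disc_height = g$disc_height,
                   bone_length_sup = 2 * g$bone_length_sup,
                   bone_length_inf = 2 * g$bone_length_inf),
                 vertebra_sup = vertebra_props(113, 2 * g$bone_length_sup),
                 vertebra_inf = vertebra_props(113, 2 * g$bone_length_inf))
  for (f in c(100, 1000, 2100)) {
    c1 <- fsuaxial:::component_displacements(s1, f)
    c2 <- fsuaxial:::component_displacements(s2, f)
    expect_equal(c2$bone, 2 * c1$bone, tolerance = 1e-12)
    expect_equal(c2$disc, c1$disc, tolerance = 1e-12)
  }
})

test_that("rigid-bone limit: bone share vanishes, curve approaches disc-only", {
  s <- specimen("f")
  rigid <- sensitivity_variant(s, "near_rigid", rigid_modulus = 1e5)
  expect_lt(bone_strain_contribution(rigid), 0.005)
  # curve converges to the disc-only displacement at every force level
  pr <- load_protocol(n_points = 15)
  cv <- specimen_response(rigid, pr)
  disc_only <- vapply(cv$force_N, function(f)
    fsuaxial:::component_displacements(s, f)$disc, numeric(1))
  expect_equal(cv$displacement_mm, disc_only - disc_only[1], tolerance = 1e-3)
})

test_that("equal-compliance construction gives exactly half the strain to bone", {
  s <- specimen("g")
  pr <- load_protocol()
  disc_disp <- fsuaxial:::component_displacements(s, pr$max_force)$disc
  # choose the bone modulus so the two bone segments deflect as much as the disc
  A <- s$geometry$disc_area
  L <- s$geometry$bone_length_sup + s$geometry$bone_length_inf
  E_eq <- pr$max_force * L / (A * disc_disp)
  s$vertebra_sup$effective_modulus <- E_eq
  s$vertebra_inf$effective_modulus <- E_eq
  expect_equal(bone_strain_contribution(s, pr), 0.5, tolerance = 1e-9)
})

test_that("group modifications follow the study design", {
  base <- specimen("h")
  expect_identical(apply_group(base, "CON"), base)
  nr <- apply_group(base, "NR", collapse_factor = 0.7)
  expect_null(nr$nucleus)
  expect_equal(nr$annulus_collapse_factor, 0.7)
  bp <- apply_group(base, "BP", plug_modulus_factor = 1.2)
  expect_equal(bp$vertebra_sup$effective_modulus,
               1.2 * base$vertebra_sup$effective_modulus)
  # PEP with hydrogel equal to the native nucleus responds exactly like BP
  # at plug factor 1
  pep <- apply_group(base, "PEP", hydrogel = base$nucleus)
  bp1 <- apply_group(base, "BP", plug_modulus_factor = 1)
  pr <- load_protocol(n_points = 12)
  expect_equal(specimen_response(pep, pr)$displacement_mm,
               specimen_response(bp1, pr)$displacement_mm, tolerance = 1e-12)
  expect_error(apply_group(nr, "CON"), class = "fsuaxial_error_specimen")
  expect_error(specimen("x", group = "NR"), class = "fsuaxial_error_specimen")
  expect_error(specimen("x", group = "CON", nucleus = NULL),
               class = "fsuaxial_error_specimen")
})

test_that("sensitivity variants set the prescribed bone moduli and stiffen the specimen", {
  s <- specimen("i")
  expect_identical(sensitivity_variant(s, "heterogeneous"), s)
  nr <- sensitivity_variant(s, "near_rigid")
  expect_equal(nr$vertebra_sup$effective_modulus, 1500)
  expect_equal(nr$vertebra_inf$effective_modulus, 1500)
  hom <- sensitivity_variant(s, "homogeneous_average",
                             cohort_mean_greyscale = 113)
  expect_equal(hom$vertebra_sup$effective_modulus,
               greyscale_to_modulus(113, s$vertebra_sup$map))
  # already-uniform bone: homogeneous average at own greyscale changes nothing
  hom_self <- sensitivity_variant(s, "homogeneous_average",
                                  cohort_mean_greyscale = s$vertebra_sup$mean_greyscale)
  expect_equal(hom_self$vertebra_sup$effective_modulus,
               s$vertebra_sup$effective_modulus)
  # stiffness ordering: near-rigid specimen displaces less at every force
  pr <- load_protocol(n_points = 12)
  cv_het <- specimen_response(s, pr)
  cv_rig <- specimen_response(nr, pr)
  expect_true(all(cv_rig$displacement_mm[-1] < cv_het$displacement_mm[-1]))
  expect_lt(bone_strain_contribution(nr, pr), bone_strain_contribution(s, pr))
  expect_error(sensitivity_variant(s, "homogeneous_average"),
               class = "fsuaxial_error_specimen")
})
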