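test_that("linear displacement fields record the closed-form Jacobian", {
  sp <- phantom_spec(field_family = list(family = "linear", A = diag(3) * 0.1))
  f <- make_displacement_field(sp)
  # det(1.1 I) = 1.331, so the recorded ventilation is 0.331 everywhere
  expect_equal(unique(as.vector(f$analytic_vjac)), 1.1^3 - 1, tolerance = 1e-12)
  # u(x) = 0.1 (x - x0): linear in position with slope 0.1
  co <- voxel_coords(f)
  expect_equal(f$ux, 0.1 * (co$x - mean(range(co$x))), tolerance = 1e-12)
})

test_that("degenerate field families give the zero field", {
  sp0 <- phantom_spec(field_family = list(family = "linear", A = matrix(0, 3, 3)))
  f0 <- make_displacement_field(sp0)
  expect_true(all(f0$ux == 0) && all(f0$uy == 0) && all(f0$uz == 0))
  sps <- phantom_spec(field_family = list(family = "sinusoidal",
                                          amplitude = c(0, 0, 0),
                                          freq = c(2, 1, 3)))
  fs <- make_displacement_field(sps)
  expect_true(all(fs$ux == 0) && all(fs$uy == 0) && all(fs$uz == 0))
})

test_that("non-invertible linear coefficients are rejected, naming the determinant", {
  sp <- phantom_spec(field_family = list(family = "linear", A = diag(3) * -1.5))
  expect_error(make_displacement_field(sp), "det\\(I \\+ A\\)")
})

test_that("radial fields match their closed-form Jacobian at fine spacing", {
  # central-difference truncation ~ 1.8 a h^2 / s^2: below 1e-3 at h = 1 mm
  # for amplitude 0.08 and width 15 mm
  sp <- phantom_spec(grid_shape = c(24, 24, 24), spacing_mm = c(1, 1, 1),
                     field_family = list(family = "radial",
                                         center_norm = c(0.5, 0.5, 0.5),
                                         amplitude = 0.08, width_mm = 15))
  f <- make_displacement_field(sp)
  jv <- jacobian_ventilation(f, full_mask(c(24, 24, 24)))$ventilation
  interior <- 2:23
  err <- abs(jv$values - f$analytic_vjac)[interior, interior, interior]
  expect_lt(max(err), 1e-3)
})

test_that("CT pair construction encodes the target ventilation exactly", {
  d <- c(28, 28, 32)
  sp <- phantom_spec(field_family = list(family = "linear", A = matrix(0, 3, 3)),
                     seed = 9)
  lung <- make_lung_mask(sp)
  f <- make_displacement_field(sp)
  # zero field: registered inhale equals the inhale image
  target <- grid_volume(array(0.5, d), sp$spacing_mm, kind = "ventilation")
  pair <- make_ct_pair(sp, f, target, lung)
  expect_equal(pair$registered_inhale$values, pair$inhale$values)
  inm <- lung$values == 1
  # worked rule: HU_ex = HU_in_reg + V (HU_in_reg + 1000); e.g. -900 -> -850
  expect_equal(pair$exhale$values[inm],
               pair$registered_inhale$values[inm] +
                 0.5 * (pair$registered_inhale$values[inm] + 1000),
               tolerance = 1e-12)
  # zero target: exhale equals registered inhale inside the lung
  pair0 <- make_ct_pair(sp, f, grid_volume(array(0, d), sp$spacing_mm,
                                           kind = "ventilation"), lung)
  expect_equal(pair0$exhale$values[inm], pair0$registered_inhale$values[inm])
  # outside the lungs: constant soft tissue
  expect_true(all(pair$exhale$values[!inm] == 40))
  # unphysical target is rejected
  expect_error(make_ct_pair(sp, f, grid_volume(array(-1.2, d), sp$spacing_mm,
                                               kind = "ventilation"), lung),
               "unphysical")
})

test_that("HU metric recovers the phantom's target ventilation (round trip)", {
  p <- make_phantom_patient(phantom_spec(seed = 17))
  reg <- resample_inhale(p$inhale, p$field)
  hv <- hu_ventilation(p$exhale, reg$volume, p$lung_mask)
  idx <- which(hv$mask$values == 1)
  err <- abs(hv$ventilation$values[idx] - p$target_ventilation$values[idx])
  expect_gt(mean(err < 1e-6), 0.99)
})

test_that("phantom dose is the prescription in the GITV with Gaussian falloff", {
  sp <- phantom_spec(seed = 2)
  lung <- make_lung_mask(sp)
  gitv <- make_gitv_mask(sp, lung)
  dose <- make_dose(sp, gitv, lung)
  expect_true(all(dose$values[gitv$values == 1] == 60))
  expect_true(all(dose$values >= 0))
  # every voxel outside the GITV follows the closed-form falloff
  ctr <- rpvent:::tumor_center_mm(sp, lung)
  co <- rpvent:::spec_coords(sp)
  r <- sqrt((co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2)
  dist <- pmax(r - sp$tumor_radius_mm, 0)
  expected <- 60 * exp(-0.5 * (dist / sp$falloff_sigma_mm)^2)
  out <- gitv$values == 0
  expect_equal(dose$values[out], expected[out], tolerance = 1e-12)
  # falloff width -> 0: no dose outside the target
  sp0 <- sp; sp0$falloff_sigma_mm <- 0
  d0 <- make_dose(sp0, gitv, lung)
  expect_true(all(d0$values[out & dist > 0] == 0))
  # empty GITV is rejected
  empty <- grid_volume(array(0, sp$grid_shape), sp$spacing_mm, kind = "mask")
  expect_error(make_dose(sp, empty, lung), "empty")
})

test_that("tumors outside the lung bounding box are rejected", {
  sp <- phantom_spec(tumor_center = c(0.99, 0.99, 0.99), tumor_radius_mm = 30)
  expect_error(make_gitv_mask(sp), "bounding box")
})

test_that("cohort generation is deterministic for a fixed seed", {
  c1 <- make_cohort(cohort_spec(4, seed = 123))
  c2 <- make_cohort(cohort_spec(4, seed = 123))
  expect_identical(c1$table$features, c2$table$features)
  expect_identical(c1$table$label, c2$table$label)
  c3 <- make_cohort(cohort_spec(4, seed = 124))
  expect_false(identical(c1$table$features, c3$table$features))
})

test_that("null label model gives the logit-target intercept and ~25% incidence", {
  co <- cached("cohort_null40",
               make_cohort(cohort_spec(40, label_model = list(
                 coefficients = c(fV20 = 0), intercept = NULL), seed = 31)))
  expect_equal(co$intercept, qlogis(0.247), tolerance = 1e-6)
  expect_lt(abs(co$achieved_incidence - 0.247), 0.15)  # n = 40, binomial noise
})

test_that("a strong fV20 coefficient makes fV20 itself predictive", {
  co <- small_cohort()  # default label model: 2 SD units on fV20
  expect_gt(auc(co$table$features$fV20, co$table$label), 0.5)
})

test_that("a two-patient cohort still yields one case of each class", {
  co <- make_cohort(cohort_spec(2, seed = 55))
  expect_setequal(co$table$label, c(0, 1))
})

test_that("cohort incidence with auto-calibrated intercept tracks the target", {
  co <- big_cohort()  # n = 100
  expect_lt(abs(co$achieved_incidence - 0.247), 0.05)
})
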