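#' Phantom patient specification
#'
#' Parametric description of one synthetic patient: grid geometry, two
#' ellipsoidal lung fields, a spherical tumor (GITV), a displacement-field
#' family with analytically known Jacobian where possible, a prescription,
#' and a knob controlling how much the high-function region overlaps the
#' high-dose region.
#'
#' Defaults describe a desk-scale thorax: a 28 x 28 x 32 grid at 7 mm
#' spacing (~19 x 19 x 22 cm), ~2 L of lung, a 20 mm radius tumor, 60 Gy in
#' 30 fractions, and per-lung radial expansion fields giving specific
#' ventilation in the physiological 0.1-0.5 range.
#'
#' @param grid_shape integer triple, >= 8 voxels per axis.
#' @param spacing_mm positive spacing triple, mm.
#' @param lung_geometry list with `left` and `right`, each
#'   `list(center_norm, semiaxes_mm)` of an ellipsoid (centers normalized to
#'   the volume extent).
#' @param tumor_center normalized triple in \[0,1\]^3, interpreted within the
#'   lung bounding box.
#' @param tumor_radius_mm positive tumor radius.
#' @param field_family list describing the displacement field; see
#'   [make_displacement_field()].
#' @param prescription `list(total_dose_Gy, n_fractions)`.
#' @param falloff_sigma_mm Gaussian dose falloff width beyond the GITV
#'   surface, mm.
#' @param function_dose_overlap real in \[-1, 1\]: positive values add
#'   expansion (high function) centred on the tumor, negative values a
#'   contraction (function defect) there.
#' @param include_exclusion add a central-airway exclusion cylinder.
#' @param seed integer RNG seed for the per-patient draws.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(28L, 28L, 32L),
                         spacing_mm = c(7, 7, 7),
                         lung_geometry = default_lung_geometry(),
                         tumor_center = c(0.30, 0.50, 0.35),
                         tumor_radius_mm = 20,
                         field_family = default_field_family(),
                         prescription = list(total_dose_Gy = 60, n_fractions = 30L),
                         falloff_sigma_mm = 20,
                         function_dose_overlap = 0.3,
                         include_exclusion = TRUE,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("'grid_shape' must be three integers >= 8")
  if (any(spacing_mm <= 0)) stop("'spacing_mm' must be positive")
  if (any(tumor_center < 0) || any(tumor_center > 1))
    stop("'tumor_center' must lie in [0,1]^3")
  if (tumor_radius_mm <= 0) stop("'tumor_radius_mm' must be positive")
  if (abs(function_dose_overlap) > 1)
    stop("'function_dose_overlap' must lie in [-1, 1]")
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 lung_geometry = lung_geometry, tumor_center = tumor_center,
                 tumor_radius_mm = tumor_radius_mm, field_family = field_family,
                 prescription = prescription, falloff_sigma_mm = falloff_sigma_mm,
                 function_dose_overlap = function_dose_overlap,
                 include_exclusion = include_exclusion,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_lung_geometry <- function() {
  list(left = list(center_norm = c(0.30, 0.52, 0.48), semiaxes_mm = c(45, 65, 85)),
       right = list(center_norm = c(0.70, 0.52, 0.48), semiaxes_mm = c(48, 68, 90)))
}

#' @rdname phantom_spec
#' @export
default_field_family <- function() {
  list(family = "composite", components = list(
    list(family = "radial", center_norm = c(0.30, 0.52, 0.48),
         amplitude = 0.09, width_mm = 70),
    list(family = "radial", center_norm = c(0.70, 0.52, 0.48),
         amplitude = 0.09, width_mm = 70)))
}

extent_mm <- function(spec) (spec$grid_shape - 1) * spec$spacing_mm

spec_coords <- function(spec) {
  voxel_coords(structure(list(
    values = array(0, spec$grid_shape),
    spacing_mm = spec$spacing_mm, origin_mm = c(0, 0, 0)), class = "grid_volume"))
}

ellipsoid_mask <- function(co, center_mm, semi) {
  ((co$x - center_mm[1]) / semi[1])^2 +
    ((co$y - center_mm[2]) / semi[2])^2 +
    ((co$z - center_mm[3]) / semi[3])^2 <= 1
}

#' Lung, tumor and exclusion masks of a phantom
#'
#' @param spec a [phantom_spec()].
#' @return `make_lung_mask`: binary `grid_volume` of the two ellipsoidal
#'   lungs. `make_gitv_mask`: spherical GITV mask; errors if the tumor is
#'   not fully inside the lung bounding box. `make_exclusion_mask`: central
#'   airway cylinder, or `NULL` if the spec disables it.
#' @export
make_lung_mask <- function(spec) {
  co <- spec_coords(spec)
  L <- extent_mm(spec)
  inm <- array(FALSE, spec$grid_shape)
  for (side in spec$lung_geometry)
    inm <- inm | ellipsoid_mask(co, side$center_norm * L, side$semiaxes_mm)
  grid_volume(array(as.numeric(inm), spec$grid_shape), spec$spacing_mm, kind = "mask")
}

tumor_center_mm <- function(spec, lung_mask) {
  li <- which(lung_mask$values == 1, arr.ind = TRUE)
  lo <- (apply(li, 2, min) - 1) * spec$spacing_mm
  hi <- (apply(li, 2, max) - 1) * spec$spacing_mm
  lo + spec$tumor_center * (hi - lo)
}

#' @rdname make_lung_mask
#' @param lung_mask lung mask of the same spec (computed if missing).
#' @export
make_gitv_mask <- function(spec, lung_mask = make_lung_mask(spec)) {
  ctr <- tumor_center_mm(spec, lung_mask)
  li <- which(lung_mask$values == 1, arr.ind = TRUE)
  lo <- (apply(li, 2, min) - 1) * spec$spacing_mm
  hi <- (apply(li, 2, max) - 1) * spec$spacing_mm
  if (any(ctr - spec$tumor_radius_mm < lo - 1e-9) ||
      any(ctr + spec$tumor_radius_mm > hi + 1e-9))
    stop("tumor is not fully inside the lung bounding box")
  co <- spec_coords(spec)
  r2 <- (co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2
  inm <- r2 <= spec$tumor_radius_mm^2
  if (!any(inm)) stop("GITV mask is empty at this grid resolution")
  grid_volume(array(as.numeric(inm), spec$grid_shape), spec$spacing_mm, kind = "mask")
}

#' @rdname make_lung_mask
#' @export
make_exclusion_mask <- function(spec) {
  if (!isTRUE(spec$include_exclusion)) return(NULL)
  co <- spec_coords(spec)
  L <- extent_mm(spec)
  # central-airway stand-in: a vertical cylinder on the midline, upper thorax
  inm <- (co$x - 0.5 * L[1])^2 + (co$y - 0.5 * L[2])^2 <= 14^2 &
    co$z <= 0.55 * L[3]
  grid_volume(array(as.numeric(inm), spec$grid_shape), spec$spacing_mm, kind = "mask")
}

# one displacement-field component on precomputed coordinates; returns
# list(ux, uy, uz, analytic_vjac or NULL)
field_component <- function(fam, co, L) {
  switch(fam$family,
    linear = {
      A <- fam$A
      if (!is.matrix(A) || !identical(dim(A), c(3L, 3L)) || any(!is.finite(A)))
        stop("linear family needs a finite 3x3 coefficient matrix A")
      dt <- det(diag(3) + A)
      if (dt <= 0)
        stop(sprintf("linear field is not invertible: det(I + A) = %.6g <= 0", dt))
      tr <- if (is.null(fam$t)) c(0, 0, 0) else fam$t
      c0 <- 0.5 * L
      dx <- co$x - c0[1]; dy <- co$y - c0[2]; dz <- co$z - c0[3]
      list(ux = A[1, 1] * dx + A[1, 2] * dy + A[1, 3] * dz + tr[1],
           uy = A[2, 1] * dx + A[2, 2] * dy + A[2, 3] * dz + tr[2],
           uz = A[3, 1] * dx + A[3, 2] * dy + A[3, 3] * dz + tr[3],
           analytic_vjac = array(dt - 1, dim(co$x)))
    },
    radial = {
      ctr <- fam$center_norm * L
      dx <- co$x - ctr[1]; dy <- co$y - ctr[2]; dz <- co$z - ctr[3]
      r2 <- dx^2 + dy^2 + dz^2
      s2 <- fam$width_mm^2
      g <- fam$amplitude * exp(-r2 / (2 * s2))
      # det of x -> c + (1 + g(r)) (x - c) is (1+g)^2 (1 + g + r g'); here
      # r g' = -(r^2/s^2) g
      dt <- (1 + g)^2 * (1 + g - (r2 / s2) * g)
      list(ux = g * dx, uy = g * dy, uz = g * dz, analytic_vjac = dt - 1)
    },
    sinusoidal = {
      a <- fam$amplitude; k <- fam$freq
      ph <- if (is.null(fam$phase)) c(0, 0, 0) else fam$phase
      if (length(a) != 3L || length(k) != 3L) stop("sinusoidal family needs length-3 amplitude and freq")
      args <- list(2 * pi * k[1] * co$x / L[1] + ph[1],
                   2 * pi * k[2] * co$y / L[2] + ph[2],
                   2 * pi * k[3] * co$z / L[3] + ph[3])
      dii <- lapply(1:3, function(i) a[i] * cos(args[[i]]) * 2 * pi * k[i] / L[i])
      list(ux = a[1] * sin(args[[1]]), uy = a[2] * sin(args[[2]]),
           uz = a[3] * sin(args[[3]]),
           analytic_vjac = (1 + dii[[1]]) * (1 + dii[[2]]) * (1 + dii[[3]]) - 1)
    },
    stop(sprintf("unknown field family '%s'", fam$family))
  )
}

#' Build the phantom displacement field
#'
#' Supported families: `linear` (`u = A (x - x0) + t`, constant Jacobian
#' `det(I+A) - 1`, rejected unless `det(I+A) > 0`), `radial` (Gaussian-bump
#' radial expansion with closed-form Jacobian), `sinusoidal` (separable sine
#' wiggle, closed-form diagonal Jacobian; used to exercise finite-difference
#' truncation error), and `composite` (a sum of components; no closed form
#' is recorded because the Jacobian of a sum is not a product).
#'
#' @param spec a [phantom_spec()] whose `field_family` names the family and
#'   its coefficients.
#' @return `disp_field` with `analytic_vjac` filled in for the closed-form
#'   families.
#' @export
make_displacement_field <- function(spec) {
  co <- spec_coords(spec)
  L <- extent_mm(spec)
  fam <- spec$field_family
  if (identical(fam$family, "composite")) {
    ux <- uy <- uz <- array(0, spec$grid_shape)
    for (cmp in fam$components) {
      f <- field_component(cmp, co, L)
      ux <- ux + f$ux; uy <- uy + f$uy; uz <- uz + f$uz
    }
    analytic <- NULL
  } else {
    f <- field_component(fam, co, L)
    ux <- f$ux; uy <- f$uy; uz <- f$uz
    analytic <- f$analytic_vjac
  }
  disp_field(ux, uy, uz, spec$spacing_mm, analytic_vjac = analytic)
}

#' Construct a consistent inhale/exhale CT pair
#'
#' Builds a smooth synthetic peak-inhale image, resamples it through the
#' displacement field onto the exhale grid, and constructs the exhale image
#' so that the HU ventilation metric recovers `target_ventilation` exactly:
#' `HU_ex = HU_in_reg + V * (HU_in_reg + 1000)` inside the lung mask, with
#' constant soft tissue (+40 HU) outside. The construction inverts the HU
#' metric rather than simulating density change, so the generator owns an
#' exact ground truth.
#'
#' @param spec a [phantom_spec()].
#' @param field `disp_field` from [make_displacement_field()].
#' @param target_ventilation `grid_volume` of kind `"ventilation"`; the
#'   specific volume change the pair must encode inside the lung mask.
#' @param lung_mask optional precomputed lung mask.
#' @return list with `inhale`, `exhale`, `registered_inhale` (grid_volumes)
#'   and `valid` (resampling validity mask).
#' @export
make_ct_pair <- function(spec, field, target_ventilation,
                         lung_mask = make_lung_mask(spec)) {
  co <- spec_coords(spec)
  L <- extent_mm(spec)
  set.seed(spec$seed)
  ph <- runif(3, 0, 2 * pi)
  # smooth parenchyma texture; bounded within -940..-820 HU so the near-air
  # denominator guard (|HU + 1000| >= 50) never fires on phantom tissue
  inh_vals <- -880 +
    35 * sin(2 * pi * 1.3 * co$x / L[1] + ph[1]) *
         sin(2 * pi * 1.1 * co$y / L[2] + ph[2]) +
    25 * sin(2 * pi * 0.9 * co$z / L[3] + ph[3])
  inhale <- grid_volume(inh_vals, spec$spacing_mm, kind = "HU")
  reg <- resample_inhale(inhale, field)
  inm <- lung_mask$values == 1
  v <- target_ventilation$values
  if (any(inm & !is.finite(v)))
    stop("target ventilation must be finite inside the lung mask")
  if (any(reg$volume$values[inm] <= -1000))
    stop("registered inhale HU must exceed -1000 inside the lung mask")
  ex_in <- reg$volume$values[inm] + v[inm] * (reg$volume$values[inm] + 1000)
  if (any(ex_in <= -1000) || any(ex_in >= 200))
    stop("unphysical phantom: target ventilation pushes exhale HU outside (-1000, 200)")
  ex <- array(40, spec$grid_shape)  # constant soft tissue outside the lungs
  ex[inm] <- ex_in
  list(inhale = inhale,
       exhale = grid_volume(ex, spec$spacing_mm, kind = "HU"),
       registered_inhale = reg$volume,
       valid = reg$valid)
}

#' Analytic dose grid of a phantom
#'
#' Prescription dose inside the GITV, Gaussian falloff with distance beyond
#' the GITV surface outside: `D = total * exp(-0.5 dist^2 / sigma^2)`. A
#' stand-in for treatment-planning dose, not beam transport.
#'
#' @param spec a [phantom_spec()].
#' @param gitv_mask GITV mask (must be nonempty).
#' @param lung_mask optional precomputed lung mask (tumor geometry reference).
#' @return `grid_volume` of kind `"dose_Gy"` (physical dose).
#' @export
make_dose <- function(spec, gitv_mask, lung_mask = make_lung_mask(spec)) {
  assert_mask(gitv_mask)
  if (!any(gitv_mask$values == 1)) stop("GITV mask is empty")
  total <- spec$prescription$total_dose_Gy
  if (total <= 0 || spec$prescription$n_fractions < 1)
    stop("prescription must have positive dose and >= 1 fraction")
  ctr <- tumor_center_mm(spec, lung_mask)
  co <- spec_coords(spec)
  r <- sqrt((co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2)
  dist <- pmax(r - spec$tumor_radius_mm, 0)
  s <- spec$falloff_sigma_mm
  D <- if (s > 0) total * exp(-0.5 * (dist / s)^2) else total * (dist == 0)
  D[gitv_mask$values == 1] <- total
  grid_volume(D, spec$spacing_mm, kind = "dose_Gy")
}

#' Assemble one self-consistent phantom patient
#'
#' Generates masks, displacement field, the target ventilation (the field's
#' own Jacobian ventilation, so both metrics agree by construction), the
#' CT pair, dose grid, fractionation scheme and clinical scalars.
#'
#' @param spec a [phantom_spec()].
#' @param age,brinkman_index clinical scalars; drawn from seeded defaults
#'   (age uniform 50-85 y, Brinkman index uniform 0-1500) when `NULL`.
#' @return a patient bundle (list) consumable by [patient_features()]; the
#'   stored `target_ventilation` is the ground truth for round-trip tests.
#' @export
make_phantom_patient <- function(spec, age = NULL, brinkman_index = NULL) {
  lung <- make_lung_mask(spec)
  gitv <- make_gitv_mask(spec, lung)
  excl <- make_exclusion_mask(spec)
  field <- make_displacement_field(spec)
  allm <- grid_volume(array(1, spec$grid_shape), spec$spacing_mm, kind = "mask")
  target <- jacobian_ventilation(field, allm)$ventilation
  pair <- make_ct_pair(spec, field, target, lung)
  dose <- make_dose(spec, gitv, lung)
  set.seed(spec$seed + 7L)
  if (is.null(age)) age <- round(runif(1, 50, 85), 1)
  if (is.null(brinkman_index)) brinkman_index <- round(runif(1, 0, 1500))
  scheme <- suppressWarnings(fractionation_scheme(
    spec$prescription$total_dose_Gy, spec$prescription$n_fractions))
  list(spec = spec, lung_mask = lung, gitv_mask = gitv, exclusion_mask = excl,
       field = field, target_ventilation = target,
       inhale = pair$inhale, exhale = pair$exhale,
       registered_inhale = pair$registered_inhale, resample_valid = pair$valid,
       dose = dose, scheme = scheme,
       age = age, brinkman_index = brinkman_index)
}
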