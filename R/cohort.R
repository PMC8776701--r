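#' Cohort specification
#'
#' Parametric description of a synthetic patient cohort: how many patients,
#' the per-patient randomization ranges, and the logistic label model that
#' generates the radiation-pneumonitis (grade >= 2) endpoint from the
#' computed features.
#'
#' The label model applies its coefficients to cohort-z-scored features, so
#' coefficients are effects per standard deviation. When `intercept` is
#' `NULL` it is auto-calibrated so the expected incidence equals
#' `incidence_target` (default 0.247, matching the reference cohort's
#' 21/85). The default demonstration model loads on fV20 with a strong
#' effect (2 per SD).
#'
#' @param n_patients integer >= 2.
#' @param label_model `list(coefficients = named numeric, intercept = NULL or
#'   numeric)`; names must be computed feature names.
#' @param incidence_target target RP incidence in (0, 1).
#' @param seed master seed for the cohort.
#' @param ranges per-patient randomization ranges; see
#'   [default_cohort_ranges()].
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        label_model = list(coefficients = c(fV20 = 2),
                                           intercept = NULL),
                        incidence_target = 0.247,
                        seed = 1L,
                        ranges = default_cohort_ranges()) {
  if (n_patients < 2) stop("'n_patients' must be >= 2")
  if (incidence_target <= 0 || incidence_target >= 1)
    stop("'incidence_target' must lie in (0, 1)")
  if (is.null(names(label_model$coefficients)) &&
      length(label_model$coefficients) > 0 &&
      any(label_model$coefficients != 0))
    stop("label model coefficients must be named after computed features")
  structure(list(n_patients = as.integer(n_patients), label_model = label_model,
                 incidence_target = incidence_target, seed = as.integer(seed),
                 ranges = ranges),
            class = "cohort_spec")
}

#' Default per-patient randomization ranges
#'
#' Tumor position uniform over the central lung bounding box, tumor radius
#' 12-25 mm, per-lung radial expansion amplitudes 0.05-0.13 (specific
#' ventilation up to ~0.5), function-dose overlap -0.2 to 0.8, prescription
#' drawn from the four reference fractionation schemes at their printed
#' cohort proportions, age 50-85 y, Brinkman index 0-1500.
#'
#' @return list of ranges consumed by [make_cohort()].
#' @export
default_cohort_ranges <- function() {
  list(tumor_center = list(lo = c(0.2, 0.2, 0.2), hi = c(0.8, 0.8, 0.8)),
       tumor_radius_mm = c(12, 25),
       lung_amplitude = c(0.05, 0.13),
       lung_width_mm = c(55, 85),
       overlap = c(-0.2, 0.8),
       tumor_field_amplitude = 0.10,
       tumor_field_width_mm = 45,
       sin_amplitude_mm = c(0, 1.5),
       age = c(50, 85),
       brinkman = c(0, 1500),
       prescriptions = data.frame(total_dose_Gy = c(60, 66, 69, 72),
                                  n_fractions = c(30L, 33L, 23L, 24L),
                                  prob = c(56, 19, 6, 4) / 85))
}

derive_seed <- function(seed, i, salt = 0) {
  as.integer((abs(as.numeric(seed)) * 1009 + i * 97 + salt) %% 2147483647)
}

random_phantom_spec <- function(cspec, i) {
  s <- derive_seed(cspec$seed, i)
  set.seed(s)
  rg <- cspec$ranges
  geo <- default_lung_geometry()
  overlap <- runif(1, rg$overlap[1], rg$overlap[2])
  tumor_center <- runif(3, rg$tumor_center$lo, rg$tumor_center$hi)
  comps <- list(
    list(family = "radial", center_norm = geo$left$center_norm,
         amplitude = runif(1, rg$lung_amplitude[1], rg$lung_amplitude[2]),
         width_mm = runif(1, rg$lung_width_mm[1], rg$lung_width_mm[2])),
    list(family = "radial", center_norm = geo$right$center_norm,
         amplitude = runif(1, rg$lung_amplitude[1], rg$lung_amplitude[2]),
         width_mm = runif(1, rg$lung_width_mm[1], rg$lung_width_mm[2])),
    list(family = "sinusoidal",
         amplitude = runif(3, rg$sin_amplitude_mm[1], rg$sin_amplitude_mm[2]),
         freq = sample(1:3, 3, replace = TRUE), phase = runif(3, 0, 2 * pi)))
  presc <- rg$prescriptions[sample.int(nrow(rg$prescriptions), 1,
                                       prob = rg$prescriptions$prob), ]
  spec <- phantom_spec(
    tumor_center = tumor_center,
    tumor_radius_mm = runif(1, rg$tumor_radius_mm[1], rg$tumor_radius_mm[2]),
    field_family = list(family = "composite", components = comps),
    prescription = list(total_dose_Gy = presc$total_dose_Gy,
                        n_fractions = presc$n_fractions),
    function_dose_overlap = overlap,
    seed = s)
  # the overlap knob becomes a tumor-centred radial component: extra
  # expansion (high function) near the tumor when positive, a defect when
  # negative; where the patient's dose is concentrated
  lung <- make_lung_mask(spec)
  ctr_norm <- tumor_center_mm(spec, lung) / extent_mm(spec)
  spec$field_family$components <- c(spec$field_family$components, list(
    list(family = "radial", center_norm = ctr_norm,
         amplitude = overlap * rg$tumor_field_amplitude,
         width_mm = rg$tumor_field_width_mm)))
  spec
}

calibrate_intercept <- function(eta, target) {
  f <- function(b) mean(plogis(eta + b)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0)
    stop(sprintf("incidence calibration failed: achievable range [%.3f, %.3f] excludes target %.3f",
                 mean(plogis(eta + lo)), mean(plogis(eta + hi)), target))
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate a synthetic patient cohort with RP labels
#'
#' Draws `n_patients` phantoms from the cohort's randomization ranges,
#' computes their feature vectors with the chosen ventilation metric, and
#' generates binary RP labels from the logistic label model on the
#' cohort-z-scored features. Deterministic for a fixed seed.
#'
#' If the Bernoulli draw leaves a class empty (possible at small n), the
#' patient with the most extreme event probability is deterministically
#' flipped to the missing class so the cohort remains usable for stratified
#' modeling; the flip count is recorded.
#'
#' @param cspec a [cohort_spec()].
#' @param metric ventilation metric used for the DFH features of the label
#'   model, `"hu"` or `"jacobian"`.
#' @param keep_volumes keep the full per-patient volume bundles (memory
#'   heavy); if `FALSE` only specs and features are returned.
#' @param feature_metrics metrics for which feature tables are built
#'   (defaults to `metric`; labels are shared across metrics since the
#'   patients are the same).
#' @return list with `table` (a [feature_table()] for `metric`), `tables`
#'   (one per requested metric), `patients` (bundles or specs),
#'   `achieved_incidence`, `intercept`, `n_flipped`.
#' @export
make_cohort <- function(cspec, metric = c("hu", "jacobian"),
                        keep_volumes = FALSE, feature_metrics = NULL) {
  metric <- match.arg(metric)
  if (is.null(feature_metrics)) feature_metrics <- metric
  feature_metrics <- union(metric, feature_metrics)
  n <- cspec$n_patients
  patients <- vector("list", n)
  fmats <- rep(list(NULL), length(feature_metrics))
  names(fmats) <- feature_metrics
  for (i in seq_len(n)) {
    p <- tryCatch({
      spec <- random_phantom_spec(cspec, i)
      make_phantom_patient(spec)
    }, error = function(e)
      stop(sprintf("phantom generation failed for patient %d: %s",
                   i, conditionMessage(e))))
    for (m in feature_metrics)
      fmats[[m]] <- rbind(fmats[[m]], patient_features(p, m))
    patients[[i]] <- if (keep_volumes) p else list(spec = p$spec, age = p$age,
                                                   brinkman_index = p$brinkman_index)
  }
  fmats <- lapply(fmats, function(m) {
    m <- as.data.frame(m); rownames(m) <- NULL; m
  })
  feats <- fmats[[metric]]
  beta <- cspec$label_model$coefficients
  unknown <- setdiff(names(beta), names(feats))
  if (length(unknown))
    stop(sprintf("label model references unknown features: %s",
                 paste(unknown, collapse = ", ")))
  eta <- rep(0, n)
  for (nm in names(beta)) {
    x <- feats[[nm]]
    s <- sqrt(mean((x - mean(x))^2))
    z <- if (s > 0) (x - mean(x)) / s else rep(0, n)
    eta <- eta + beta[[nm]] * z
  }
  b <- cspec$label_model$intercept
  if (is.null(b)) b <- calibrate_intercept(eta, cspec$incidence_target)
  p_event <- plogis(eta + b)
  set.seed(derive_seed(cspec$seed, 0, salt = 13))
  y <- rbinom(n, 1, p_event)
  n_flipped <- 0L
  if (all(y == 0)) { y[which.max(p_event)] <- 1L; n_flipped <- 1L }
  if (all(y == 1)) { y[which.min(p_event)] <- 0L; n_flipped <- 1L }
  ids <- sprintf("P%03d", seq_len(n))
  tables <- lapply(fmats, feature_table, label = y, patient_id = ids)
  list(table = tables[[metric]], tables = tables,
       patients = patients,
       achieved_incidence = mean(y),
       intercept = b,
       n_flipped = n_flipped)
}
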