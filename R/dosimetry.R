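#' Fractionation scheme
#'
#' Total prescribed dose, number of fractions, and the linear-quadratic
#' tissue parameter alpha/beta used for the EQD2 correction (3 Gy for lung
#' late toxicity). Fraction sizes outside the 1.8-3.0 Gy/fraction regime
#' that the feature definitions assume trigger a warning, not an error.
#'
#' @param total_dose_Gy positive total prescription, Gy.
#' @param n_fractions positive integer fraction count.
#' @param alpha_beta_Gy positive alpha/beta ratio, Gy (default 3).
#' @return object of class `fractionation_scheme`.
#' @export
fractionation_scheme <- function(total_dose_Gy, n_fractions, alpha_beta_Gy = 3) {
  if (!is.numeric(total_dose_Gy) || total_dose_Gy <= 0)
    stop("'total_dose_Gy' must be positive")
  if (n_fractions < 1 || n_fractions != round(n_fractions))
    stop("'n_fractions' must be a positive integer")
  if (alpha_beta_Gy <= 0) stop("'alpha_beta_Gy' must be positive")
  d <- total_dose_Gy / n_fractions
  if (d < 1.8 || d > 3.0)
    warning(sprintf("fraction size %.2f Gy is outside the 1.8-3.0 Gy regime", d))
  structure(list(total_dose_Gy = total_dose_Gy,
                 n_fractions = as.integer(n_fractions),
                 alpha_beta_Gy = alpha_beta_Gy),
            class = "fractionation_scheme")
}

#' Convert physical dose to EQD2
#'
#' Voxelwise equivalent dose in 2 Gy fractions under the linear-quadratic
#' model: `EQD2 = D * (d + alpha/beta) / (2 + alpha/beta)` with the per-voxel
#' fraction dose `d = D / n_fractions`. The conversion is the identity
#' exactly where `d = 2` Gy/fraction and maps zero to zero.
#'
#' @param dose `grid_volume` of kind `"dose_Gy"`, physical dose.
#' @param scheme a [fractionation_scheme()].
#' @return `grid_volume` of kind `"dose_Gy"`, EQD2.
#' @export
eqd2_convert <- function(dose, scheme) {
  if (!inherits(dose, "grid_volume") || dose$kind != "dose_Gy")
    stop("'dose' must be a grid_volume of kind 'dose_Gy'")
  if (!inherits(scheme, "fractionation_scheme"))
    stop("'scheme' must be a fractionation_scheme")
  D <- dose$values
  neg <- which(!is.na(D) & D < 0)
  if (length(neg)) {
    bad <- arrayInd(neg[1], dim(D))
    stop(sprintf("negative dose %.3f Gy at voxel (%d, %d, %d)",
                 D[neg[1]], bad[1], bad[2], bad[3]))
  }
  ab <- scheme$alpha_beta_Gy
  d <- D / scheme$n_fractions
  grid_volume(D * (d + ab) / (2 + ab), dose$spacing_mm, dose$origin_mm, "dose_Gy")
}

dvh_thresholds_Gy <- c(5, 10, 20, 30, 40, 50)

#' Dose-volume histogram features
#'
#' Mean lung dose and Vx of the healthy-lung evaluation mask: Vx is the
#' percentage of in-mask voxels receiving dose strictly exceeding x Gy, for
#' x in 5, 10, 20, 30, 40, 50.
#'
#' @param dose_eqd2 EQD2 dose `grid_volume`.
#' @param eval_mask binary evaluation mask (lungs minus GITV minus exclusions).
#' @return named numeric vector `MLD, V5, V10, V20, V30, V40, V50`
#'   (MLD in Gy, Vx in percent).
#' @export
dvh_features <- function(dose_eqd2, eval_mask) {
  assert_mask(eval_mask)
  assert_same_grid(dose_eqd2, eval_mask)
  d <- dose_eqd2$values[mask_which(eval_mask)]
  if (!length(d)) stop("evaluation mask is empty")
  if (any(is.na(d))) stop("NA dose inside the evaluation mask")
  out <- c(MLD = mean(d),
           vapply(dvh_thresholds_Gy, function(x) 100 * mean(d > x), 0))
  names(out)[-1] <- paste0("V", dvh_thresholds_Gy)
  out
}

#' Dose-function histogram features
#'
#' Function-weighted analogues of the DVH features, using the percentile
#' ventilation map as the voxel weight: `fVx = 100 * sum(f_v over voxels
#' with dose > x) / sum(f_v)` and `fMLD = sum(f_v * D_v) / sum(f_v)` over
#' the evaluation mask. With a uniform function map these reduce exactly to
#' Vx and MLD.
#'
#' @param dose_eqd2 EQD2 dose `grid_volume`.
#' @param fmap percentile function map (`grid_volume` of kind `"percentile"`).
#' @param eval_mask binary evaluation mask.
#' @return named numeric vector `fMLD, fV5, ..., fV50`.
#' @export
dfh_features <- function(dose_eqd2, fmap, eval_mask) {
  assert_mask(eval_mask)
  assert_same_grid(dose_eqd2, eval_mask)
  assert_same_grid(fmap, eval_mask)
  idx <- mask_which(eval_mask)
  d <- dose_eqd2$values[idx]
  f <- fmap$values[idx]
  if (any(is.na(d)) || any(is.na(f))) stop("NA dose or function inside the evaluation mask")
  W <- sum(f)
  if (W <= 0) stop("total function weight is zero over the evaluation mask")
  out <- c(fMLD = sum(f * d) / W,
           vapply(dvh_thresholds_Gy, function(x) 100 * sum(f[d > x]) / W, 0))
  names(out)[-1] <- paste0("fV", dvh_thresholds_Gy)
  out
}

#' Normalized GITV position within the lung
#'
#' The tumor centroid expressed as a fraction of the lung bounding box along
#' the three anatomical axes, clipped to \[0, 1\]. Orientation convention:
#' 0 corresponds to the superior, anterior and left extremes respectively
#' (array index 1 on each axis).
#'
#' @param gitv,lung binary masks on one grid.
#' @return named numeric vector `gitv_pos_ul, gitv_pos_ap, gitv_pos_lr`.
#' @export
gitv_position <- function(gitv, lung) {
  assert_mask(gitv); assert_mask(lung)
  assert_same_grid(gitv, lung)
  gi <- which(gitv$values == 1, arr.ind = TRUE)
  li <- which(lung$values == 1, arr.ind = TRUE)
  if (!nrow(gi)) stop("GITV mask is empty")
  if (!nrow(li)) stop("lung mask is empty")
  # axis order in feature space: upper-lower = z, anterior-posterior = y,
  # left-right = x
  ax <- c(3L, 2L, 1L)
  pos <- vapply(ax, function(a) {
    lo <- min(li[, a]); hi <- max(li[, a])
    if (hi == lo) stop(sprintf("lung bounding box degenerate along axis %d", a))
    min(max((mean(gi[, a]) - lo) / (hi - lo), 0), 1)
  }, 0)
  names(pos) <- c("gitv_pos_ul", "gitv_pos_ap", "gitv_pos_lr")
  pos
}

#' GITV volume in cubic centimetres
#'
#' @param gitv binary mask.
#' @return volume in cc (voxel count times voxel volume).
#' @export
gitv_volume <- function(gitv) {
  assert_mask(gitv)
  sum(gitv$values == 1, na.rm = TRUE) * prod(gitv$spacing_mm) / 1000
}

#' Full feature vector of one patient
#'
#' Runs the per-patient feature pipeline: registered-inhale resampling, the
#' chosen ventilation metric, percentile conversion over the evaluation mask
#' (lungs minus GITV minus exclusions), EQD2 conversion, and DVH/DFH/clinical
#' geometry extraction.
#'
#' @param patient a phantom patient bundle from [make_phantom_patient()], or
#'   any list with elements `inhale`, `exhale`, `field`, `dose`, `lung_mask`,
#'   `gitv_mask`, optional `exclusion_mask`, `scheme`, and clinical scalars
#'   `age`, `brinkman_index`.
#' @param metric `"hu"` or `"jacobian"` ventilation metric.
#' @return named numeric feature vector (clinical, DVH, DFH components).
#' @export
patient_features <- function(patient, metric = c("hu", "jacobian")) {
  metric <- match.arg(metric)
  eval_mask <- apply_exclusion(patient$lung_mask, patient$exclusion_mask,
                               patient$gitv_mask)
  if (metric == "hu") {
    reg <- resample_inhale(patient$inhale, patient$field)
    hv <- hu_ventilation(patient$exhale, reg$volume, eval_mask)
    vent <- hv$ventilation; vmask <- hv$mask
  } else {
    jv <- jacobian_ventilation(patient$field, eval_mask)
    vent <- jv$ventilation; vmask <- jv$mask
  }
  fmap <- percentile_normalize(vent, vmask)
  deqd2 <- eqd2_convert(patient$dose, patient$scheme)
  c(age = patient$age, brinkman_index = patient$brinkman_index,
    gitv_position(patient$gitv_mask, patient$lung_mask),
    gitv_volume_cc = gitv_volume(patient$gitv_mask),
    dvh_features(deqd2, eval_mask),
    dfh_features(deqd2, fmap, vmask))
}
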