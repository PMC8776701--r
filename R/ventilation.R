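#' @useDynLib rpvent, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats plogis runif rnorm rbinom median quantile sd uniroot wilcox.test cor qnorm
#' @importFrom utils write.csv read.csv head
"_PACKAGE"

# vectorized trilinear interpolation at continuous 1-based indices.
# points outside the array take `pad` and are flagged invalid.
trilinear_sample <- function(arr, xi, yi, zi, pad) {
  d <- dim(arr)
  valid <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
  xi <- pmin(pmax(xi, 1), d[1]); yi <- pmin(pmax(yi, 1), d[2]); zi <- pmin(pmax(zi, 1), d[3])
  i0 <- pmin(floor(xi), d[1] - 1L); j0 <- pmin(floor(yi), d[2] - 1L); k0 <- pmin(floor(zi), d[3] - 1L)
  fx <- xi - i0; fy <- yi - j0; fz <- zi - k0
  n1 <- d[1]; n12 <- d[1] * d[2]
  base <- i0 + (j0 - 1) * n1 + (k0 - 1) * n12
  v000 <- arr[base];             v100 <- arr[base + 1]
  v010 <- arr[base + n1];        v110 <- arr[base + n1 + 1]
  v001 <- arr[base + n12];       v101 <- arr[base + n12 + 1]
  v011 <- arr[base + n1 + n12];  v111 <- arr[base + n1 + n12 + 1]
  out <- (1 - fz) * ((1 - fy) * ((1 - fx) * v000 + fx * v100) +
                       fy * ((1 - fx) * v010 + fx * v110)) +
    fz * ((1 - fy) * ((1 - fx) * v001 + fx * v101) +
            fy * ((1 - fx) * v011 + fx * v111))
  out[!valid] <- pad
  list(values = out, valid = valid)
}

#' Resample the inhale image through a displacement field
#'
#' Pulls the inhale (moving) image onto the exhale (fixed) grid by trilinear
#' interpolation at `x + u(x)`, producing the registered inhale image that
#' the HU ventilation metric consumes. Sample points that fall outside the
#' inhale volume take the air padding value -1000 HU and are flagged in the
#' validity mask.
#'
#' @param inhale `grid_volume` of kind `"HU"` (the moving image).
#' @param field `disp_field` on the exhale grid, millimetres.
#' @param pad padding intensity for out-of-volume samples (default -1000 HU).
#' @return list with `volume` (registered inhale, a `grid_volume`) and
#'   `valid` (a mask `grid_volume`, 1 where the sample point was inside).
#' @export
resample_inhale <- function(inhale, field, pad = -1000) {
  if (!inherits(inhale, "grid_volume")) stop("'inhale' must be a grid_volume")
  if (!inherits(field, "disp_field")) stop("'field' must be a disp_field")
  assert_same_grid(inhale, field, "inhale image and displacement field")
  co <- voxel_coords(field)
  sp <- inhale$spacing_mm; o <- inhale$origin_mm
  xi <- (co$x + field$ux - o[1]) / sp[1] + 1
  yi <- (co$y + field$uy - o[2]) / sp[2] + 1
  zi <- (co$z + field$uz - o[3]) / sp[3] + 1
  s <- trilinear_sample(inhale$values, xi, yi, zi, pad)
  d <- dim(inhale$values)
  list(volume = grid_volume(array(s$values, d), sp, o, "HU"),
       valid = grid_volume(array(as.numeric(s$valid), d), sp, o, "mask"))
}

#' HU ventilation metric
#'
#' Voxelwise specific volume change from the density difference between the
#' exhale image and the registered inhale image, under the model that lung
#' CT intensity is a linear mixture of air (-1000 HU) and tissue (0 HU):
#' `V = (HU_ex - HU_in_reg) / (HU_in_reg + 1000)`.
#'
#' Voxels whose registered-inhale denominator `HU_in_reg + 1000` is smaller
#' in magnitude than `denom_guard_hu` are near-pure air where the ratio blows
#' up; they are set to the excluded sentinel (`NA`) and dropped from the
#' returned evaluation mask, as are all out-of-mask voxels.
#'
#' @param exhale,registered_inhale `grid_volume`s of kind `"HU"` on one grid.
#' @param mask binary lung evaluation mask.
#' @param denom_guard_hu exclusion threshold on `|HU_in_reg + 1000|`, HU.
#' @return list with `ventilation` (`grid_volume`, NA outside the valid set)
#'   and `mask` (the evaluation mask after guard exclusions).
#' @export
hu_ventilation <- function(exhale, registered_inhale, mask, denom_guard_hu = 50) {
  for (v in list(exhale, registered_inhale))
    if (!inherits(v, "grid_volume") || v$kind != "HU")
      stop("exhale and registered_inhale must be grid_volumes of kind 'HU'")
  assert_same_grid(exhale, registered_inhale)
  assert_same_grid(exhale, mask)
  assert_mask(mask)
  denom <- registered_inhale$values + 1000
  keep <- !is.na(mask$values) & mask$values == 1 & abs(denom) >= denom_guard_hu
  vent <- array(NA_real_, dim(exhale$values))
  vent[keep] <- (exhale$values[keep] - registered_inhale$values[keep]) / denom[keep]
  out_mask <- array(0, dim(exhale$values)); out_mask[keep] <- 1
  list(ventilation = grid_volume(vent, exhale$spacing_mm, exhale$origin_mm, "ventilation"),
       mask = grid_volume(out_mask, exhale$spacing_mm, exhale$origin_mm, "mask"))
}

# spacing-aware derivative along one axis: central differences in the
# interior (exact on affine fields), one-sided on the faces.
diff_axis <- function(arr, ax, h) {
  p <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, p)
  n <- dim(a)[1]
  if (n < 2L) stop("gradient needs >= 2 voxels per axis")
  g <- a
  if (n > 2L)
    g[2:(n - 1), , ] <- (a[3:n, , ] - a[1:(n - 2), , ]) / (2 * h)
  g[1, , ] <- (a[2, , ] - a[1, , ]) / h
  g[n, , ] <- (a[n, , ] - a[n - 1, , ]) / h
  aperm(g, order(p))
}

grad3 <- function(arr, spacing_mm)
  lapply(1:3, function(ax) diff_axis(arr, ax, spacing_mm[ax]))

#' Jacobian ventilation metric
#'
#' Voxelwise specific volume change computed directly from the displacement
#' field as `det(I + grad u) - 1`. Partial derivatives are estimated by
#' central finite differences scaled by the voxel spacing (one-sided on the
#' volume faces); central differences are exact for affine fields, which the
#' phantom's linear family exploits as an oracle.
#'
#' @param field `disp_field` in millimetres.
#' @param mask binary evaluation mask on the same grid.
#' @return list with `ventilation` (`grid_volume`, NA outside the mask) and
#'   `mask` (the evaluation mask, unchanged).
#' @export
jacobian_ventilation <- function(field, mask) {
  if (!inherits(field, "disp_field")) stop("'field' must be a disp_field")
  assert_same_grid(field, mask, "field and mask")
  assert_mask(mask)
  sp <- field$spacing_mm
  gx <- grad3(field$ux, sp); gy <- grad3(field$uy, sp); gz <- grad3(field$uz, sp)
  a11 <- 1 + gx[[1]]; a12 <- gx[[2]]; a13 <- gx[[3]]
  a21 <- gy[[1]]; a22 <- 1 + gy[[2]]; a23 <- gy[[3]]
  a31 <- gz[[1]]; a32 <- gz[[2]]; a33 <- 1 + gz[[3]]
  det <- a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  if (any(!is.finite(det))) {
    bad <- which(!is.finite(det), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite Jacobian derivative at voxel (%d, %d, %d)",
                 bad[1], bad[2], bad[3]))
  }
  vent <- array(NA_real_, dim(det))
  inm <- mask$values == 1 & !is.na(mask$values)
  vent[inm] <- det[inm] - 1
  list(ventilation = grid_volume(vent, sp, field$origin_mm, "ventilation"),
       mask = mask)
}

#' Percentile function map
#'
#' Converts a ventilation image to a per-patient percentile map over the
#' valid in-mask voxels: each voxel receives `100 * rank / N`, ties taking
#' the mean rank of their tie group, so values lie in (0, 100] and are
#' uniform up to ties. Out-of-mask and excluded voxels are 0, so the map can
#' be used directly as a nonnegative weight image.
#'
#' @param vent ventilation `grid_volume` (NA marks excluded voxels).
#' @param mask binary evaluation mask.
#' @return `grid_volume` of kind `"percentile"`.
#' @export
percentile_normalize <- function(vent, mask) {
  if (!inherits(vent, "grid_volume")) stop("'vent' must be a grid_volume")
  assert_same_grid(vent, mask)
  assert_mask(mask)
  keep <- mask$values == 1 & !is.na(mask$values) & !is.na(vent$values)
  n <- sum(keep)
  if (n == 0) stop("no valid in-mask ventilation voxels to rank")
  r <- rank(vent$values[keep], ties.method = "average")
  out <- array(0, dim(vent$values))
  out[keep] <- 100 * r / n
  grid_volume(out, vent$spacing_mm, vent$origin_mm, "percentile")
}

#' Healthy-lung evaluation mask
#'
#' The voxel set over which dose-volume and dose-function features are
#' computed: lung minus the gross internal tumor volume (GITV) minus any
#' exclusion mask (trimmed central airways and great vessels).
#'
#' @param mask binary lung mask.
#' @param exclusion,gitv optional binary masks on the same grid; `NULL`
#'   means empty.
#' @return binary `grid_volume`.
#' @export
apply_exclusion <- function(mask, exclusion = NULL, gitv = NULL) {
  assert_mask(mask)
  keep <- mask$values == 1
  for (m in list(exclusion, gitv)) {
    if (is.null(m)) next
    assert_mask(m)
    assert_same_grid(mask, m)
    keep <- keep & !(m$values == 1)
  }
  if (!any(keep)) stop("evaluation mask is empty after exclusions")
  grid_volume(array(as.numeric(keep), dim(mask$values)),
              mask$spacing_mm, mask$origin_mm, "mask")
}
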