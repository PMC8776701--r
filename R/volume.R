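#' Gridded 3D volume
#'
#' Container for a scalar field sampled on a regular 3D grid: CT intensity
#' (HU), dose (Gy), ventilation, percentile function, or a binary mask.
#' Array dimensions follow the anatomical convention used throughout the
#' package: dim 1 runs left (index 1) to right, dim 2 anterior (1) to
#' posterior, dim 3 superior (1) to inferior.
#'
#' Excluded voxels (outside the evaluation mask, or dropped by a guard such
#' as the near-air denominator rule) carry the sentinel `NA_real_`.
#'
#' @param values 3D numeric array.
#' @param spacing_mm positive numeric length-3 voxel spacing in millimetres.
#' @param origin_mm numeric length-3 position of voxel (1,1,1) in millimetres.
#' @param kind one of `"HU"`, `"dose_Gy"`, `"ventilation"`, `"percentile"`,
#'   `"mask"`.
#' @return An object of class `grid_volume`.
#' @export
grid_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                        kind = c("HU", "dose_Gy", "ventilation", "percentile", "mask")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("'spacing_mm' must be three positive numbers")
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("'origin_mm' must be three finite numbers")
  if (kind == "mask") {
    v <- values[!is.na(values)]
    if (length(v) && !all(v %in% c(0, 1)))
      stop("mask volumes may contain only 0 and 1")
    storage.mode(values) <- "double"
  }
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin_mm = origin_mm, kind = kind),
            class = "grid_volume")
}

#' @export
print.grid_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid_volume %s> %d x %d x %d voxels, spacing %s mm\n",
              x$kind, d[1], d[2], d[3],
              paste(format(x$spacing_mm), collapse = " x ")))
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  range [%g, %g], %d NA voxels\n",
                min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' Displacement field on the exhale grid
#'
#' A voxelwise vector field, in millimetres, defined on the exhale (fixed)
#' grid. Each voxel's vector points to the corresponding location in the
#' inhale (moving) image, so that `inhale(x + u(x))` is the inhale intensity
#' that matches exhale voxel `x`. This direction convention is the only one
#' consistent with the HU ventilation metric and is asserted here.
#'
#' @param ux,uy,uz 3D numeric arrays of identical dimension, components in mm.
#' @param spacing_mm,origin_mm grid geometry, as in [grid_volume()].
#' @param analytic_vjac optional 3D array with the closed-form Jacobian
#'   ventilation `det(I + grad u) - 1` of the field, for oracle testing.
#' @return An object of class `disp_field`.
#' @export
disp_field <- function(ux, uy, uz, spacing_mm, origin_mm = c(0, 0, 0),
                       analytic_vjac = NULL) {
  d <- dim(ux)
  if (is.null(d) || length(d) != 3L)
    stop("components must be 3D arrays")
  if (!identical(d, dim(uy)) || !identical(d, dim(uz)))
    stop("displacement components must share one grid")
  if (any(!is.finite(ux)) || any(!is.finite(uy)) || any(!is.finite(uz)))
    stop("displacement field must be finite everywhere")
  structure(list(ux = ux, uy = uy, uz = uz,
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm),
                 analytic_vjac = analytic_vjac),
            class = "disp_field")
}

#' @export
print.disp_field <- function(x, ...) {
  d <- dim(x$ux)
  mag <- sqrt(x$ux^2 + x$uy^2 + x$uz^2)
  cat(sprintf("<disp_field> %d x %d x %d voxels, |u| max %.2f mm%s\n",
              d[1], d[2], d[3], max(mag),
              if (!is.null(x$analytic_vjac)) ", analytic Jacobian recorded" else ""))
  invisible(x)
}

grid_dims <- function(x) dim(if (inherits(x, "disp_field")) x$ux else x$values)

# shared-grid precondition for all voxelwise operations
assert_same_grid <- function(a, b, what = "volumes") {
  da <- grid_dims(a); db <- grid_dims(b)
  if (!identical(da, db))
    stop(sprintf("%s are on different grids: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  if (any(abs(a$spacing_mm - b$spacing_mm) > 1e-9))
    stop(sprintf("%s have different spacings: (%s) mm vs (%s) mm", what,
                 paste(format(a$spacing_mm), collapse = ", "),
                 paste(format(b$spacing_mm), collapse = ", ")))
  invisible(TRUE)
}

assert_mask <- function(m) {
  if (!inherits(m, "grid_volume") || m$kind != "mask")
    stop("expected a grid_volume of kind 'mask'")
  v <- m$values[!is.na(m$values)]
  if (!all(v %in% c(0, 1))) stop("mask is not binary")
  invisible(TRUE)
}

mask_which <- function(m) which(!is.na(m$values) & m$values == 1)

#' Voxel centre coordinates in millimetres
#'
#' @param vol a `grid_volume` or `disp_field`.
#' @return list of three arrays (`x`, `y`, `z`), each the mm coordinate of
#'   every voxel along that axis.
#' @export
voxel_coords <- function(vol) {
  d <- grid_dims(vol)
  sp <- vol$spacing_mm; o <- vol$origin_mm
  ax <- lapply(1:3, function(i) o[i] + (seq_len(d[i]) - 1) * sp[i])
  list(x = array(rep(ax[[1]], times = d[2] * d[3]), d),
       y = array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d),
       z = array(rep(ax[[3]], each = d[1] * d[2]), d))
}
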