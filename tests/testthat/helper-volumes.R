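# small-volume builders shared across test files

mk_vol <- function(values, dim3 = NULL, spacing = c(1, 1, 1), kind = "HU") {
  if (!is.null(dim3)) values <- array(values, dim3)
  grid_volume(values, spacing, kind = kind)
}

mk_mask <- function(values, dim3 = NULL, spacing = c(1, 1, 1)) {
  if (!is.null(dim3)) values <- array(values, dim3)
  grid_volume(values, spacing, kind = "mask")
}

full_mask <- function(dim3, spacing = c(1, 1, 1))
  mk_mask(array(1, dim3), spacing = spacing)

zero_field <- function(dim3, spacing = c(1, 1, 1))
  disp_field(array(0, dim3), array(0, dim3), array(0, dim3), spacing)

# random invertible linear field coefficients (det(I + A) > 0)
random_linear_A <- function() {
  repeat {
    A <- matrix(runif(9, -0.15, 0.15), 3, 3)
    if (det(diag(3) + A) > 0.05) return(A)
  }
}
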