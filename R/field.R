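# Dense 2D displacement fields and their algebra.
#
# A displacement field lives on the fixed grid: for fixed-grid pixel (r, c)
# the warped image samples the moving image at (r + dy[r,c], c + dx[r,c]).
# Fields are finite everywhere (they are defined on the whole grid even where
# the images carry the NA sentinel).

#' Construct a dense displacement field
#'
#' @param dy,dx matrices of row/column displacements (pixels), same shape.
#' @param pixel_size pixel size in micrometres (metadata only).
#' @return object of class `displacement_field`.
#' @export
displacement_field <- function(dy, dx, pixel_size = 50) {
  stopifnot(is.matrix(dy), is.matrix(dx), all(dim(dy) == dim(dx)))
  if (!all(is.finite(dy)) || !all(is.finite(dx)))
    stop("displacement field must be finite everywhere")
  structure(list(dy = dy, dx = dx, pixel_size = pixel_size),
            class = "displacement_field")
}

#' Identity displacement field (all-zero vectors)
#'
#' @param shape integer vector `c(nrow, ncol)`.
#' @inheritParams displacement_field
#' @export
identity_field <- function(shape, pixel_size = 50) {
  z <- matrix(0, shape[1], shape[2])
  displacement_field(z, z, pixel_size = pixel_size)
}

field_magnitude <- function(field) sqrt(field$dy^2 + field$dx^2)

#' Warp an image through a displacement field
#'
#' Linear interpolation is meant for metric channels; nearest for label maps
#' (it cannot fabricate new labels).  Samples that fall outside the grid take
#' the NA sentinel.
#'
#' @param field a [displacement_field()].
#' @param image matrix with the same shape as the field.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return warped matrix.
#' @export
apply_field <- function(field, image, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(field, "displacement_field"), is.matrix(image),
            all(dim(image) == dim(field$dy)))
  nr <- nrow(image); nc <- ncol(image)
  rr <- matrix(seq_len(nr), nr, nc) + field$dy
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) + field$dx
  v <- if (interpolation == "linear") bilinear_sample(image, as.vector(rr), as.vector(cc))
       else nearest_sample(image, as.vector(rr), as.vector(cc))
  matrix(v, nr, nc)
}

# Sample a field's components at fractional coordinates, clamping coordinates
# to the grid so the result stays finite (fields extend by continuation).
field_sample <- function(field, y, x) {
  nr <- nrow(field$dy); nc <- ncol(field$dy)
  y <- pmin(pmax(y, 1), nr); x <- pmin(pmax(x, 1), nc)
  list(dy = bilinear_sample(field$dy, y, x, min_weight = 0),
       dx = bilinear_sample(field$dx, y, x, min_weight = 0))
}

#' Compose two displacement fields
#'
#' `apply_field(compose_fields(outer, inner), img)` is equivalent (up to
#' interpolation) to `apply_field(outer, apply_field(inner, img))`; this is
#' the transform concatenation used when chaining slice-to-slice
#' registrations.
#'
#' @param outer,inner displacement fields on the same grid; `outer` is the
#'   transform applied second.
#' @return composed `displacement_field`.
#' @export
compose_fields <- function(outer, inner) {
  stopifnot(inherits(outer, "displacement_field"),
            inherits(inner, "displacement_field"))
  if (!all(dim(outer$dy) == dim(inner$dy))) stop("field grids do not match")
  nr <- nrow(outer$dy); nc <- ncol(outer$dy)
  rr <- matrix(seq_len(nr), nr, nc) + outer$dy
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) + outer$dx
  s <- field_sample(inner, as.vector(rr), as.vector(cc))
  displacement_field(outer$dy + matrix(s$dy, nr, nc),
                     outer$dx + matrix(s$dx, nr, nc),
                     pixel_size = outer$pixel_size)
}

# ---- cubic B-spline free-form deformation ---------------------------------

# Cubic B-spline blending weights for fractional offset u in [0,1).
bspline_weights <- function(u) {
  cbind((1 - u)^3 / 6,
        (3 * u^3 - 6 * u^2 + 4) / 6,
        (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
        u^3 / 6)
}

# Basis matrix mapping a 1D row of control coefficients to dense pixel values.
# n pixels, control knots every `spacing` pixels; returns n x ncp.
bspline_basis_matrix <- function(n, spacing) {
  t <- (seq_len(n) - 1) / spacing
  i <- floor(t)
  u <- t - i
  ncp <- max(i) + 4L
  W <- bspline_weights(u)
  B <- matrix(0, n, ncp)
  for (k in 0:3) B[cbind(seq_len(n), i + k + 1L)] <- W[, k + 1L]
  B
}

# Dense displacement field from control-point displacement matrices (tensor
# product of 1D bases): field = Br %*% C %*% t(Bc).
ffd_field <- function(cy, cx, shape, spacing, pixel_size = 50) {
  Br <- bspline_basis_matrix(shape[1], spacing)
  Bc <- bspline_basis_matrix(shape[2], spacing)
  displacement_field(Br %*% cy %*% t(Bc), Br %*% cx %*% t(Bc),
                     pixel_size = pixel_size)
}

ffd_control_shape <- function(shape, spacing) {
  c(floor((shape[1] - 1) / spacing) + 4L, floor((shape[2] - 1) / spacing) + 4L)
}
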