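# 2D registration engine: affine (moments initialization + simplex refinement
# of SSD) and B-spline free-form deformation optimized by gradient descent
# with backtracking line search, coarse-to-fine in control spacing.  The
# contract downstream stages rely on: the masked SSD never increases across
# accepted iterations, and the field is smooth (roughness penalty on control
# displacements).

#' Registration configuration
#'
#' @param metric similarity metric; only `"ssd"` (sum of squared
#'   differences over the union of masks) is implemented.
#' @param spacing B-spline control-grid spacing in pixels at the finest
#'   level (>= 2).
#' @param levels multiresolution levels (>= 1); level `l` uses spacing
#'   `spacing * 2^(l-1)`, coarse to fine.
#' @param smooth_weight weight of the squared-difference roughness penalty on
#'   control displacements.
#' @param max_iter maximum gradient iterations per level.
#' @param tol convergence: stop when the relative SSD improvement falls
#'   below `tol`.
#' @param affine_init run an affine stage before the nonrigid stage in
#'   [build_template()]-style mask registration.
#' @param chain_direction `"toward_reference"` registers slice s+1 (moving)
#'   onto slice s (fixed) when composing outward from the reference;
#'   `"away_from_reference"` selects the inverse convention.
#' @return object of class `registration_config`.
#' @export
registration_config <- function(metric = "ssd", spacing = 8L, levels = 3L,
                                smooth_weight = 0.01, max_iter = 200L,
                                tol = 1e-4, affine_init = TRUE,
                                chain_direction = c("toward_reference",
                                                    "away_from_reference")) {
  stopifnot(identical(metric, "ssd"), spacing >= 2, levels >= 1,
            smooth_weight >= 0, max_iter >= 1, tol > 0)
  structure(list(metric = metric, spacing = as.integer(spacing),
                 levels = as.integer(levels), smooth_weight = smooth_weight,
                 max_iter = as.integer(max_iter), tol = tol,
                 affine_init = affine_init,
                 chain_direction = match.arg(chain_direction)),
            class = "registration_config")
}

# Mean squared difference over pixels where either image is defined
# (union-of-masks support); NA treated as 0-background there.
masked_ssd <- function(fixed, warped) {
  support <- !is.na(fixed) | !is.na(warped)
  if (!any(support)) return(0)
  f <- fixed; f[is.na(f)] <- 0
  w <- warped; w[is.na(w)] <- 0
  sum((f[support] - w[support])^2) / sum(support)
}

# image centroid and second moments of |img| (NA -> 0)
img_moments <- function(img) {
  img[is.na(img)] <- 0
  w <- abs(img)
  s <- sum(w)
  if (s == 0) stop("empty mask: image has no nonzero pixels")
  r <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  c_ <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  mr <- sum(w * r) / s; mc <- sum(w * c_) / s
  vr <- sum(w * (r - mr)^2) / s; vc <- sum(w * (c_ - mc)^2) / s
  list(center = c(mr, mc), var = c(vr, vc), mass = s)
}

# Warp moving through an affine: sample moving at A (p - c0) + c0 + t,
# p = fixed-grid coordinates, c0 = grid center.
affine_warp_coords <- function(par, shape) {
  nr <- shape[1]; nc <- shape[2]
  c0 <- c((nr + 1) / 2, (nc + 1) / 2)
  r <- matrix(seq_len(nr), nr, nc) - c0[1]
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - c0[2]
  A <- par$A; t <- par$t
  list(y = A[1, 1] * r + A[1, 2] * cc + c0[1] + t[1],
       x = A[2, 1] * r + A[2, 2] * cc + c0[2] + t[2])
}

#' Apply affine parameters to an image
#'
#' @param par affine parameters as returned by [estimate_affine()].
#' @param image matrix.
#' @param interpolation `"linear"` or `"nearest"`.
#' @export
apply_affine <- function(par, image, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  co <- affine_warp_coords(par, dim(image))
  v <- if (interpolation == "linear")
    bilinear_sample(image, as.vector(co$y), as.vector(co$x))
  else nearest_sample(image, as.vector(co$y), as.vector(co$x))
  matrix(v, nrow(image), ncol(image))
}

#' Convert affine parameters to a dense displacement field
#'
#' @inheritParams apply_affine
#' @param shape grid shape `c(rows, cols)`.
#' @export
affine_to_field <- function(par, shape, pixel_size = 50) {
  co <- affine_warp_coords(par, shape)
  nr <- shape[1]; nc <- shape[2]
  displacement_field(co$y - matrix(seq_len(nr), nr, nc),
                     co$x - matrix(seq_len(nc), nr, nc, byrow = TRUE),
                     pixel_size = pixel_size)
}

identity_affine <- function() list(A = diag(2), t = c(0, 0))

#' Estimate a 2D affine transform between two images
#'
#' Centroid/second-moment initialization (translation + axis-aligned scale)
#' followed by Nelder-Mead refinement of the six parameters on the masked
#' SSD.  Returns the identity if no candidate improves on it, so applying
#' the result never increases the SSD relative to identity.
#'
#' @param fixed,moving matrices on the same grid (NA = background).
#' @return list with `A` (2x2), `t` (row/col translation), `ssd`.
#' @export
estimate_affine <- function(fixed, moving) {
  stopifnot(all(dim(fixed) == dim(moving)))
  mf <- img_moments(fixed); mm <- img_moments(moving)
  s <- sqrt(mm$var / pmax(mf$var, .Machine$double.eps))
  init <- c(s[1], 0, 0, s[2], mm$center - mf$center * s)
  # translation init must account for scaling about the grid center
  c0 <- c((nrow(fixed) + 1) / 2, (ncol(fixed) + 1) / 2)
  init[5:6] <- mm$center - (c0 + s * (mf$center - c0))
  obj <- function(p) {
    par <- list(A = matrix(p[1:4], 2, 2, byrow = TRUE), t = p[5:6])
    masked_ssd(fixed, apply_affine(par, moving))
  }
  ssd_id <- masked_ssd(fixed, moving)
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-8))
  fit2 <- stats::optim(c(1, 0, 0, 1, 0, 0), obj, method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-8))
  best <- if (fit$value <= fit2$value) fit else fit2
  if (best$value <= ssd_id) {
    p <- best$par
    list(A = matrix(p[1:4], 2, 2, byrow = TRUE), t = p[5:6], ssd = best$value)
  } else {
    c(identity_affine(), list(ssd = ssd_id))
  }
}

# gradient images by central differences (NA -> 0 first)
image_gradients <- function(img) {
  img[is.na(img)] <- 0
  nr <- nrow(img); nc <- ncol(img)
  gy <- img; gx <- img
  gy[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  gy[c(1, nr), ] <- 0
  gx[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
  gx[, c(1, nc)] <- 0
  list(gy = gy, gx = gx)
}

# roughness penalty and gradient: sum of squared first differences of the
# control displacement matrices along both axes
roughness <- function(C) {
  dr <- diff(C); dc <- t(diff(t(C)))
  sum(dr^2) + sum(dc^2)
}
roughness_grad <- function(C) {
  g <- matrix(0, nrow(C), ncol(C))
  dr <- diff(C)
  g[-nrow(C), ] <- g[-nrow(C), ] - 2 * dr
  g[-1, ] <- g[-1, ] + 2 * dr
  dc <- t(diff(t(C)))
  g[, -ncol(C)] <- g[, -ncol(C)] - 2 * dc
  g[, -1] <- g[, -1] + 2 * dc
  g
}

# One FFD optimization stage at a given control spacing.  Returns the control
# matrices; objective (masked SSD + smooth_weight * roughness) is monotone
# non-increasing by backtracking.
ffd_optimize <- function(fixed, moving, spacing, cfg) {
  shape <- dim(fixed)
  Br <- bspline_basis_matrix(shape[1], spacing)
  Bc <- bspline_basis_matrix(shape[2], spacing)
  cs <- c(ncol(Br), ncol(Bc))
  cy <- matrix(0, cs[1], cs[2]); cx <- matrix(0, cs[1], cs[2])
  grad <- image_gradients(moving)
  nr <- shape[1]; nc <- shape[2]
  rgrid <- matrix(seq_len(nr), nr, nc)
  cgrid <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # roughness is averaged per control point so the data and smoothness terms
  # stay on comparable scales across grid sizes
  lambda <- cfg$smooth_weight / prod(cs)

  energy <- function(cy, cx) {
    yy <- rgrid + Br %*% cy %*% t(Bc)
    xx <- cgrid + Br %*% cx %*% t(Bc)
    warped <- matrix(bilinear_sample(moving, as.vector(yy), as.vector(xx)), nr, nc)
    list(e = masked_ssd(fixed, warped) + lambda * (roughness(cy) + roughness(cx)),
         warped = warped, yy = yy, xx = xx)
  }
  cur <- energy(cy, cx)
  low_improve <- 0L
  for (it in seq_len(cfg$max_iter)) {
    # residual on the union support, NA -> 0
    f0 <- fixed; f0[is.na(f0)] <- 0
    w0 <- cur$warped; w0[is.na(w0)] <- 0
    support <- !is.na(fixed) | !is.na(cur$warped)
    res <- (w0 - f0) * support
    npix <- max(sum(support), 1)
    gy_s <- matrix(bilinear_sample(grad$gy, as.vector(cur$yy), as.vector(cur$xx),
                                   min_weight = 0), nr, nc)
    gx_s <- matrix(bilinear_sample(grad$gx, as.vector(cur$yy), as.vector(cur$xx),
                                   min_weight = 0), nr, nc)
    gy_s[is.na(gy_s)] <- 0; gx_s[is.na(gx_s)] <- 0
    gcy <- crossprod(Br, (2 * res * gy_s / npix)) %*% Bc + lambda * roughness_grad(cy)
    gcx <- crossprod(Br, (2 * res * gx_s / npix)) %*% Bc + lambda * roughness_grad(cx)
    gmax <- max(abs(gcy), abs(gcx))
    if (gmax == 0) break
    step <- 1 / gmax                        # first trial moves <= 1 px
    improved <- FALSE
    for (bt in 1:40) {
      cand <- energy(cy - step * gcy, cx - step * gcx)
      if (cand$e < cur$e) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) break
    cy <- cy - step * gcy; cx <- cx - step * gcx
    rel <- (cur$e - cand$e) / max(cur$e, .Machine$double.eps)
    cur <- cand
    low_improve <- if (rel < cfg$tol) low_improve + 1L else 0L
    if (low_improve >= 3L) break
  }
  list(cy = cy, cx = cx, energy = cur$e)
}

#' Estimate a nonrigid (B-spline FFD) displacement field
#'
#' Coarse-to-fine free-form deformation: each level optimizes an incremental
#' field on the currently warped moving image (control spacing halving from
#' `spacing * 2^(levels-1)` down to `spacing`), and increments are folded in
#' by field composition.  The masked SSD never increases across accepted
#' iterations.
#'
#' @param fixed,moving images on the same grid (NA = background).
#' @param cfg a [registration_config()].
#' @return a [displacement_field()] mapping fixed-grid coordinates into the
#'   moving image.
#' @export
estimate_nonrigid <- function(fixed, moving, cfg = registration_config()) {
  stopifnot(all(dim(fixed) == dim(moving)), inherits(cfg, "registration_config"))
  if (any(!is.finite(fixed[!is.na(fixed)])) || any(!is.finite(moving[!is.na(moving)])))
    stop("non-finite pixels inside mask")
  shape <- dim(fixed)
  total <- identity_field(shape)
  for (l in rev(seq_len(cfg$levels))) {
    spacing <- cfg$spacing * 2^(l - 1)
    if (spacing >= max(shape)) next
    moving_l <- apply_field(total, moving, "linear")
    fit <- ffd_optimize(fixed, moving_l, spacing, cfg)
    delta <- ffd_field(fit$cy, fit$cx, shape, spacing)
    # accept the level only if it helped the raw similarity
    cand <- compose_fields(delta, total)
    if (masked_ssd(fixed, apply_field(cand, moving, "linear")) <=
        masked_ssd(fixed, apply_field(total, moving, "linear")) + 1e-12)
      total <- cand
  }
  total
}

#' Step-by-step registration chain across an ordered slice stack
#'
#' Adjacent slices are registered pairwise (only neighbouring indices are
#' ever registered to each other) and the pairwise fields are concatenated
#' outward from the reference slice, so the stored field for slice `s` maps
#' it all the way into the reference slice's space.  The reference slice
#' stores the identity.
#'
#' @param slices list of images (typically the axon-density channel).
#' @param ref_index index of the reference slice (the region mid-slice in
#'   region-wise aggregation).
#' @param cfg a [registration_config()].
#' @return object of class `registration_chain`: `ref_index`, `fields` (one
#'   composed [displacement_field()] per slice).
#' @export
stepwise_chain <- function(slices, ref_index, cfg = registration_config()) {
  n <- length(slices)
  if (n == 0) stop("empty slice stack")
  stopifnot(ref_index >= 1, ref_index <= n)
  shape <- dim(slices[[1]])
  fields <- vector("list", n)
  fields[[ref_index]] <- identity_field(shape)
  toward <- cfg$chain_direction == "toward_reference"
  if (ref_index < n) {
    for (s in (ref_index + 1):n) {
      pair <- if (toward) estimate_nonrigid(slices[[s - 1]], slices[[s]], cfg)
              else estimate_nonrigid(slices[[s]], slices[[s - 1]], cfg)
      fields[[s]] <- compose_fields(fields[[s - 1]], pair)
    }
  }
  if (ref_index > 1) {
    for (s in (ref_index - 1):1) {
      pair <- if (toward) estimate_nonrigid(slices[[s + 1]], slices[[s]], cfg)
              else estimate_nonrigid(slices[[s]], slices[[s + 1]], cfg)
      fields[[s]] <- compose_fields(fields[[s + 1]], pair)
    }
  }
  structure(list(ref_index = ref_index, fields = fields),
            class = "registration_chain")
}
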