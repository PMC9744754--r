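#' @keywords internal
"_PACKAGE"

# Shared low-level helpers: image interpolation, mirroring, truncated-normal
# sampling.  Images are plain R matrices, row = dorsoventral axis (row 1 =
# dorsal-most), column = left-right axis; pixels outside the tissue carry NA
# (the sentinel -- 0 is a legal metric value and never marks background).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mirror an image about its left-right midline
#'
#' @param x matrix (or logical matrix).
#' @return `x` with columns reversed.
#' @export
mirror_lr <- function(x) {
  stopifnot(is.matrix(x))
  x[, ncol(x):1, drop = FALSE]
}

# Vectorized bilinear sampling with NA-aware weight renormalization.  y/x are
# fractional 1-based row/col coordinates.  Neighbors that are NA (or off-grid)
# drop out and the remaining weights are renormalized; if less than half of
# the total weight is defined the sample is NA.  This avoids eroding the
# tissue mask by one pixel at every resampling step.
bilinear_sample <- function(img, y, x, min_weight = 0.5) {
  nr <- nrow(img); nc <- ncol(img)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0;   fx <- x - x0
  val <- numeric(length(y)); wsum <- numeric(length(y))
  for (k in 1:4) {
    dy <- c(0L, 1L, 0L, 1L)[k]; dx <- c(0L, 0L, 1L, 1L)[k]
    yy <- y0 + dy; xx <- x0 + dx
    w <- (if (dy == 0) 1 - fy else fy) * (if (dx == 0) 1 - fx else fx)
    ok <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc & w > 0
    idx <- (xx[ok] - 1L) * nr + yy[ok]
    v <- img[idx]
    def <- !is.na(v)
    okk <- which(ok)[def]
    val[okk] <- val[okk] + w[okk] * v[def]
    wsum[okk] <- wsum[okk] + w[okk]
  }
  out <- ifelse(wsum >= min_weight, val / pmax(wsum, .Machine$double.eps), NA_real_)
  out
}

# Nearest-neighbour sampling; off-grid -> NA.  Ties at .5 round to the larger
# index (base round half-to-even avoided for determinism).
nearest_sample <- function(img, y, x) {
  nr <- nrow(img); nc <- ncol(img)
  yy <- floor(y + 0.5); xx <- floor(x + 0.5)
  ok <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
  out <- rep(NA_real_, length(y))
  idx <- (xx[ok] - 1L) * nr + yy[ok]
  out[ok] <- img[idx]
  out
}

# Block-mean downsampling by an integer factor, NA-aware.
block_downsample <- function(img, f = 2L) {
  nr <- floor(nrow(img) / f) * f
  nc <- floor(ncol(img) / f) * f
  img <- img[seq_len(nr), seq_len(nc), drop = FALSE]
  a <- array(img, dim = c(f, nr / f, f, nc / f))
  apply(a, c(2, 4), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
}

# Truncated-normal draws by inverse-CDF; degenerate sd = 0 returns the mean
# (clamped into the bounds).  Deterministic given the RNG state.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (length(mean) == 1) mean <- rep(mean, n)
  if (length(sd) == 1) sd <- rep(sd, n)
  out <- pmin(pmax(mean, lower), upper)
  pos <- sd > 0
  if (any(pos)) {
    pl <- stats::pnorm(lower, mean[pos], sd[pos])
    pu <- stats::pnorm(upper, mean[pos], sd[pos])
    u <- stats::runif(sum(pos), pl, pu)
    out[pos] <- stats::qnorm(u, mean[pos], sd[pos])
  }
  pmin(pmax(out, lower), upper)
}

# Stable hash of an R object for provenance manifests (md5 of its canonical
# JSON serialization).
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), f)
  unname(tools::md5sum(f))
}

# Connected components of a logical mask under 4-neighbourhood; returns an
# integer matrix (0 outside mask) and the component count.
mask_components <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(list(labels = matrix(0L, nrow(mask), ncol(mask)), n = 0L))
  g <- build_connectivity(mask, scheme = "axial4")
  comp <- g$component_id
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[idx] <- comp
  list(labels = lab, n = as.integer(g$n_components))
}
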