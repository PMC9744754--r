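# MetricStack: the aligned multi-channel morphometric maps for one axial
# slice.  Channel order is fixed (clustering consumes channels positionally):
# axon_density, axon_diameter, axon_volume_fraction, g_ratio,
# myelin_thickness.  Pixels outside the white matter carry NA.

#' Construct a metric stack
#'
#' @param metrics named list of matrices in the canonical channel order (any
#'   order is accepted and reordered; all five must be present).
#' @param mask logical white-matter mask, same grid.
#' @param pixel_size pixel size in micrometres.
#' @param level spinal level label (or region name for aggregated stacks).
#' @return object of class `metric_stack`.
#' @export
metric_stack <- function(metrics, mask = NULL, pixel_size = 50, level = NA_character_) {
  stopifnot(is.list(metrics), setequal(names(metrics), METRIC_NAMES))
  metrics <- metrics[METRIC_NAMES]
  d <- dim(metrics[[1]])
  for (m in metrics) stopifnot(is.matrix(m), all(dim(m) == d))
  if (is.null(mask)) mask <- Reduce(`&`, lapply(metrics, function(m) !is.na(m)))
  stopifnot(is.logical(mask), all(dim(mask) == d))
  for (m in metrics) {
    if (any(!is.finite(m[mask])))
      stop("metric channels must be finite inside the mask")
  }
  structure(list(metrics = metrics, mask = mask, pixel_size = pixel_size,
                 level = level),
            class = "metric_stack")
}

#' @export
print.metric_stack <- function(x, ...) {
  cat("<metric_stack>", x$level, "-", nrow(x$mask), "x", ncol(x$mask), "px,",
      sum(x$mask), "masked pixels,", length(x$metrics), "channels\n")
  invisible(x)
}

#' White-matter mask from a metric stack
#'
#' The mask is the set of pixels where every channel is defined (non-NA);
#' optionally restricted to the largest 4-connected component to drop
#' stray specks.
#'
#' @param stack a [metric_stack()].
#' @param largest_component keep only the largest connected component.
#' @return logical matrix.
#' @export
make_wm_mask <- function(stack, largest_component = FALSE) {
  stopifnot(inherits(stack, "metric_stack"))
  mask <- Reduce(`&`, lapply(stack$metrics, function(m) !is.na(m)))
  if (!any(mask)) stop("empty white-matter mask")
  if (largest_component) {
    cc <- mask_components(mask)
    if (cc$n > 1L) {
      sizes <- tabulate(cc$labels[cc$labels > 0L])
      mask <- cc$labels == which.max(sizes)
    }
  }
  mask
}

#' Impose right-left symmetry on an image
#'
#' Returns the average of the image and its left-right mirror.  NA pixels are
#' ignored in the average, so the output is defined on the union of the mask
#' and its mirror and is exactly mirror-symmetric.  Idempotent.
#'
#' @param image matrix (logical masks are symmetrized by union).
#' @return symmetric matrix of the same shape.
#' @export
symmetrize <- function(image) {
  stopifnot(is.matrix(image))
  m <- mirror_lr(image)
  if (is.logical(image)) return(image | m)
  out <- matrix(NA_real_, nrow(image), ncol(image))
  both <- !is.na(image) & !is.na(m)
  out[both] <- (image[both] + m[both]) / 2
  only_a <- !is.na(image) & is.na(m)
  out[only_a] <- image[only_a]
  only_b <- is.na(image) & !is.na(m)
  out[only_b] <- m[only_b]
  out
}
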