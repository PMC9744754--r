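# Across-subject template construction and region-wise aggregation.
#
# Subjects at a level are co-registered (affine then nonrigid, both driven by
# the white-matter masks) to a provisional common space -- the first
# subject's slice -- then metrics are resampled, averaged pixelwise over the
# subjects that define each pixel, and right-left symmetry is imposed.
# Region-wise aggregation chains slice-to-slice registrations on the
# axon-density channel to the region mid-slice, applies the composed fields
# to all metric channels and to one-hot tract channels, and averages along
# the superior-inferior axis; warped one-hot tract channels become partial
# volumes in [0, 1].

#' Build the across-subject morphometric template for one level
#'
#' @param cohort result of [generate_cohort()] (or any list with `samples`
#'   of `subject_sample` objects).
#' @param level level label to assemble.
#' @param cfg a [registration_config()].
#' @return a [metric_stack()] in the common space, mirror-symmetric.
#' @export
build_template <- function(cohort, level, cfg = registration_config()) {
  samples <- Filter(function(s) identical(s$level, level), cohort$samples)
  if (!length(samples)) stop("no subjects at level ", level)
  ref <- samples[[1]]
  ref_mask_img <- ref$stack$mask * 1
  warped <- vector("list", length(samples))
  warped[[1]] <- ref$stack$metrics
  if (length(samples) > 1) {
    for (j in 2:length(samples)) {
      mov <- samples[[j]]
      mov_mask_img <- mov$stack$mask * 1
      field <- if (cfg$affine_init) {
        aff <- estimate_affine(ref_mask_img, mov_mask_img)
        aff_field <- affine_to_field(aff[c("A", "t")], dim(ref_mask_img))
        warped_mask <- apply_field(aff_field, mov_mask_img, "linear")
        nr <- estimate_nonrigid(ref_mask_img, warped_mask, cfg)
        compose_fields(nr, aff_field)
      } else {
        estimate_nonrigid(ref_mask_img, mov_mask_img, cfg)
      }
      warped[[j]] <- lapply(mov$stack$metrics, function(m)
        apply_field(field, m, "linear"))
    }
  }
  averaged <- stats::setNames(lapply(METRIC_NAMES, function(metric) {
    imgs <- lapply(warped, `[[`, metric)
    acc <- matrix(0, nrow(ref_mask_img), ncol(ref_mask_img))
    cnt <- matrix(0L, nrow(ref_mask_img), ncol(ref_mask_img))
    for (im in imgs) {
      def <- !is.na(im)
      acc[def] <- acc[def] + im[def]
      cnt <- cnt + def
    }
    out <- matrix(NA_real_, nrow(acc), ncol(acc))
    out[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
    symmetrize(out)
  }), METRIC_NAMES)
  mask <- Reduce(`&`, lapply(averaged, function(m) !is.na(m)))
  metric_stack(averaged, mask = mask, pixel_size = ref$stack$pixel_size,
               level = level)
}

# one-hot channels of a label atlas (0/1 per tract), NA outside the grid? --
# background stays 0 so linear resampling yields partial volumes.
one_hot_labels <- function(atlas) {
  lapply(atlas$tract_ids, function(t) (atlas$labels == t) * 1)
}

#' Aggregate template slices within a spinal region
#'
#' Runs [stepwise_chain()] on the axon-density slices with the region
#' mid-slice (lower median for even counts) as reference, applies each
#' composed field to all five metric channels (linear) and to the one-hot
#' tract channels of the per-slice reference atlases (linear, yielding
#' partial volumes), and averages along the superior-inferior axis.
#'
#' @param stacks ordered list of [metric_stack()]s belonging to one region.
#' @param atlases matching ordered list of `label_atlas` objects (optional;
#'   `NULL` skips the soft atlas).
#' @param region region name (metadata).
#' @param cfg a [registration_config()].
#' @return list with `stack` (aggregated [metric_stack()]), `soft` (a
#'   `soft_atlas`: 3D array `pixels x tracts` of partial volumes in [0, 1]),
#'   `chain` (the [stepwise_chain()] result) and `ref_index`.
#' @export
aggregate_region <- function(stacks, atlases = NULL, region = NA_character_,
                             cfg = registration_config()) {
  if (!length(stacks)) stop("region with zero slices: ", region)
  if (!is.null(atlases)) stopifnot(length(atlases) == length(stacks))
  n <- length(stacks)
  ref_index <- (n + 1L) %/% 2L         # lower median
  density <- lapply(stacks, function(s) s$metrics$axon_density)
  chain <- if (n > 1) stepwise_chain(density, ref_index, cfg)
           else structure(list(ref_index = 1L,
                               fields = list(identity_field(dim(density[[1]])))),
                          class = "registration_chain")
  avg_metric <- function(extract, interpolation = "linear") {
    acc <- NULL; cnt <- NULL
    for (s in seq_len(n)) {
      im <- apply_field(chain$fields[[s]], extract(s), interpolation)
      if (is.null(acc)) {
        acc <- matrix(0, nrow(im), ncol(im))
        cnt <- matrix(0L, nrow(im), ncol(im))
      }
      def <- !is.na(im)
      acc[def] <- acc[def] + im[def]
      cnt <- cnt + def
    }
    out <- matrix(NA_real_, nrow(acc), ncol(acc))
    out[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
    out
  }
  metrics <- stats::setNames(lapply(METRIC_NAMES, function(metric)
    avg_metric(function(s) stacks[[s]]$metrics[[metric]])), METRIC_NAMES)
  mask <- Reduce(`&`, lapply(metrics, function(m) !is.na(m)))
  stack <- metric_stack(metrics, mask = mask,
                        pixel_size = stacks[[1]]$pixel_size, level = region)
  soft <- NULL
  if (!is.null(atlases)) {
    tract_names <- atlases[[1]]$tract_names
    pv <- array(0, dim = c(dim(mask), length(tract_names)),
                dimnames = list(NULL, NULL, tract_names))
    for (ti in seq_along(tract_names)) {
      ch <- avg_metric(function(s) one_hot_labels(atlases[[s]])[[ti]])
      ch[is.na(ch)] <- 0
      pv[, , ti] <- pmin(pmax(ch, 0), 1)    # clip interpolation overshoot
    }
    soft <- structure(list(pv = pv, tract_names = tract_names,
                           pixel_size = stacks[[1]]$pixel_size,
                           region = region),
                      class = "soft_atlas")
  }
  list(stack = stack, soft = soft, chain = chain, ref_index = ref_index)
}
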