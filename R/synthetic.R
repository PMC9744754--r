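# Synthetic subject generation: draw per-pixel morphometrics from per-tract
# truncated normals, then warp labels and metrics with a smooth random
# deformation.  This emulates the 50 um downsampled metric maps that axon
# segmentation produces -- not the raw electron microscopy, individual axons,
# or segmentation failure modes.

# Smooth random displacement: iid N(0, amplitude) on a coarse control grid,
# upsampled through the cubic B-spline tensor basis.  The control-point
# amplitude bounds the displacement gradient (|grad u| <~ 2*amplitude /
# spacing), keeping small-amplitude fields invertible.
random_smooth_field <- function(shape, amplitude, spacing = 12, pixel_size = 50) {
  if (amplitude <= 0) return(identity_field(shape, pixel_size))
  cs <- ffd_control_shape(shape, spacing)
  cy <- matrix(stats::rnorm(prod(cs), 0, amplitude), cs[1], cs[2])
  cx <- matrix(stats::rnorm(prod(cs), 0, amplitude), cs[1], cs[2])
  ffd_field(cy, cx, shape, spacing, pixel_size)
}

#' Generate one synthetic subject slice
#'
#' Each pixel of tract `t` draws every metric from a truncated normal with
#' the tract's configured mean and `sd * noise_scale` (truncated at 0, and at
#' 1 for fractions and the g-ratio).  A smooth random deformation of the
#' requested amplitude then warps the label map (nearest neighbour) and the
#' metric channels (linear) together, emulating inter-subject anatomical
#' variability.  The same seed reproduces the sample bit-for-bit.
#'
#' @param atlas a `label_atlas` (see [build_reference_atlas()]).
#' @param signatures signature data.frame (see [default_signatures()]); every
#'   label present in the atlas must have a row.
#' @param noise_scale multiplier on the signature standard deviations
#'   (`0` = noise-free, `1` = the configured pixelwise spread).
#' @param deform_amplitude displacement amplitude in pixels (`0` = none).
#' @param seed integer seed.
#' @return object of class `subject_sample`: `stack` ([metric_stack()]),
#'   `truth` (warped `label_atlas`), `field`, `seed`, parameters.
#' @export
sample_subject <- function(atlas, signatures, noise_scale = 1,
                           deform_amplitude = 1.5, seed = 1L) {
  stopifnot(inherits(atlas, "label_atlas"), noise_scale >= 0,
            deform_amplitude >= 0)
  present <- sort(unique(atlas$labels[atlas$labels > 0L]))
  if (!all(present %in% signatures$tract_id))
    stop("missing signature for label(s): ",
         paste(setdiff(present, signatures$tract_id), collapse = ", "))
  set.seed(as.integer(seed))
  lab <- atlas$labels
  nr <- nrow(lab); nc <- ncol(lab)
  metrics <- stats::setNames(vector("list", length(METRIC_NAMES)), METRIC_NAMES)
  for (metric in METRIC_NAMES) {
    img <- matrix(NA_real_, nr, nc)
    b <- metric_bounds(metric)
    for (t in present) {
      row <- signatures[signatures$tract_id == t, ]
      idx <- which(lab == t)
      img[idx] <- rtruncnorm(length(idx), row[[paste0(metric, "_mean")]],
                             row[[paste0(metric, "_sd")]] * noise_scale,
                             b[1], b[2])
    }
    metrics[[metric]] <- img
  }
  field <- random_smooth_field(c(nr, nc), deform_amplitude,
                               pixel_size = atlas$pixel_size)
  if (deform_amplitude > 0) {
    metrics <- lapply(metrics, function(m) apply_field(field, m, "linear"))
    wl <- apply_field(field, lab + 0, "nearest")
    wl[is.na(wl)] <- 0
    lab <- matrix(as.integer(wl), nr, nc)
    # keep channels and labels on one support
    joint <- lab > 0L & Reduce(`&`, lapply(metrics, function(m) !is.na(m)))
    lab[!joint] <- 0L
    metrics <- lapply(metrics, function(m) { m[!joint] <- NA_real_; m })
  }
  truth <- atlas
  truth$labels <- lab
  truth$mask <- lab > 0L
  stack <- metric_stack(metrics, mask = truth$mask,
                        pixel_size = atlas$pixel_size, level = atlas$level)
  structure(list(stack = stack, truth = truth, field = field,
                 seed = as.integer(seed), noise_scale = noise_scale,
                 deform_amplitude = deform_amplitude,
                 subject = NA_integer_, level = atlas$level),
            class = "subject_sample")
}

#' Generate a cohort of synthetic subjects across spinal levels
#'
#' Emulates the study design: `n_subjects` animals, one slice per level of
#' the scheme (31 levels C1--S4 by default), with per-level smooth shape
#' modulation from the atlas spec and independent per-sample noise and
#' deformation.  All per-sample seeds are drawn once from the master seed and
#' recorded in the manifest.
#'
#' @param spec a [toy_atlas_spec()].
#' @param signatures see [default_signatures()].
#' @param n_subjects number of subjects (>= 1).
#' @param scheme a [level_scheme()] (possibly restricted via `levels`).
#' @param levels optional character subset of level labels.
#' @param noise_scale,deform_amplitude passed to [sample_subject()].
#' @param seed master seed; everything downstream derives from it.
#' @return list with `samples` (named `subject<j>_<level>`), `atlases`
#'   (per-level reference atlases) and `manifest` (parameters + seed table).
#' @export
generate_cohort <- function(spec, signatures, n_subjects = 5L,
                            scheme = level_scheme(), levels = NULL,
                            noise_scale = 1, deform_amplitude = 1.5,
                            seed = 1L) {
  stopifnot(n_subjects >= 1)
  lvls <- levels %||% scheme$levels
  stopifnot(all(lvls %in% scheme$levels))
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_subjects * length(lvls))
  atlases <- lapply(lvls, function(l) build_reference_atlas(spec, l))
  names(atlases) <- lvls
  samples <- vector("list", n_subjects * length(lvls))
  nm <- character(length(samples))
  k <- 0L
  seed_table <- data.frame(subject = integer(), level = character(),
                           seed = integer())
  for (j in seq_len(n_subjects)) {
    for (l in lvls) {
      k <- k + 1L
      s <- sample_subject(atlases[[l]], signatures, noise_scale,
                          deform_amplitude, seed = seeds[k])
      s$subject <- j
      samples[[k]] <- s
      nm[k] <- sprintf("subject%d_%s", j, l)
      seed_table <- rbind(seed_table,
                          data.frame(subject = j, level = l, seed = seeds[k]))
    }
  }
  names(samples) <- nm
  manifest <- list(n_subjects = n_subjects, levels = lvls,
                   noise_scale = noise_scale,
                   deform_amplitude = deform_amplitude,
                   master_seed = as.integer(seed), seeds = seed_table,
                   grid = spec$shape, pixel_size = spec$pixel_size,
                   merge_lfvf = spec$merge_lfvf,
                   signature_hash = config_hash(signatures))
  list(samples = samples, atlases = atlases, manifest = manifest)
}
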