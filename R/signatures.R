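# Per-tract morphometric signatures.
#
# Means anchor on the template statistics reported for rat spinal white
# matter: axon density from 78,000 axons/mm^2 in the fasciculus gracilis up
# to 168,800 axons/mm^2 in the dorsal corticospinal tract; mean axon diameter
# 1.1 um in the dCST and 1.35 um in the ascending dorsal column; myelin
# thickness between 0.35 and 0.5 um; derived myelin volume fraction between
# 15 and 30%; g-ratio approximately flat at 0.7 across tracts.  Values not
# individually reported are interpolations within those ranges (they are
# configuration, not measurements).  Standard deviations are sized so that
# per-tract pixel distributions overlap substantially -- except the dCST,
# whose density is well separated -- mirroring published per-tract violin
# distributions at C1.

METRIC_NAMES <- c("axon_density", "axon_diameter", "axon_volume_fraction",
                  "g_ratio", "myelin_thickness")

# avf means are chosen so that the derived myelin volume fraction
# avf * (1/g^2 - 1) spans exactly 15--30% across tracts (min at LSp, max at
# dCST); see myelin_vf().
signature_table <- function() {
  mvf <- c(FG = 0.20, PSdc = 0.19, FC = 0.24, dCST = 0.30, LatC = 0.22,
           LSp = 0.15, RST = 0.21, LF = 0.26, VF = 0.25)
  g <- c(FG = 0.70, PSdc = 0.70, FC = 0.70, dCST = 0.70, LatC = 0.70,
         LSp = 0.70, RST = 0.71, LF = 0.70, VF = 0.69)
  data.frame(
    tract_id = seq_along(TRACT_NAMES),
    tract = TRACT_NAMES,
    axon_density_mean = c(78000, 95000, 110000, 168800, 100000, 90000,
                          105000, 85000, 88000),
    axon_density_sd = c(18000, 20000, 22000, 30000, 20000, 18000,
                        20000, 17000, 18000),
    axon_diameter_mean = c(1.35, 1.35, 1.35, 1.10, 1.20, 1.25, 1.25, 1.30, 1.30),
    axon_diameter_sd = rep(0.22, 9),
    axon_volume_fraction_mean = unname(mvf * g^2 / (1 - g^2)),
    axon_volume_fraction_sd = rep(0.05, 9),
    g_ratio_mean = unname(g),
    g_ratio_sd = rep(0.04, 9),
    myelin_thickness_mean = c(0.42, 0.40, 0.45, 0.35, 0.44, 0.46, 0.43, 0.50, 0.48),
    myelin_thickness_sd = rep(0.08, 9),
    stringsAsFactors = FALSE
  )
}

#' Default per-tract morphometric signatures
#'
#' @param merge_lfvf collapse LF and VF into a single ventrolateral signature
#'   (unweighted mean of the two), matching the 8-tract atlas convention.
#' @return data.frame with one row per tract and `<metric>_mean` /
#'   `<metric>_sd` columns for the five morphometrics.
#' @export
default_signatures <- function(merge_lfvf = FALSE) {
  sig <- signature_table()
  if (merge_lfvf) {
    lfvf <- sig[sig$tract %in% c("LF", "VF"), ]
    merged <- lfvf[1, ]
    num <- vapply(lfvf, is.numeric, logical(1))
    merged[num] <- colMeans(lfvf[num])
    merged$tract_id <- 8L
    merged$tract <- "LFVF"
    sig <- rbind(sig[1:7, ], merged)
  }
  validate_signatures(sig)
  rownames(sig) <- sig$tract
  sig
}

validate_signatures <- function(sig) {
  means <- paste0(METRIC_NAMES, "_mean")
  sds <- paste0(METRIC_NAMES, "_sd")
  stopifnot(all(c("tract_id", "tract", means, sds) %in% names(sig)))
  if (any(as.matrix(sig[means]) <= 0)) stop("signature means must be strictly positive")
  if (any(as.matrix(sig[sds]) < 0)) stop("signature standard deviations must be >= 0")
  if (any(sig$g_ratio_mean <= 0 | sig$g_ratio_mean >= 1))
    stop("g-ratio means must lie in (0, 1)")
  if (any(sig$axon_volume_fraction_mean >= 1))
    stop("volume-fraction means must lie in (0, 1)")
  invisible(sig)
}

# Per-metric truncation bounds for the noise model: all metrics are
# non-negative; fractions and the g-ratio are additionally bounded by 1.
metric_bounds <- function(metric) {
  if (metric %in% c("axon_volume_fraction", "g_ratio")) c(0, 1) else c(0, Inf)
}

#' Derived myelin volume fraction map
#'
#' For circular fiber cross-sections the myelin area fraction follows from
#' the axon volume fraction and the g-ratio: `mvf = avf * (1/g^2 - 1)`
#' (outer-to-inner area ratio `1/g^2`).  Returned in percent.
#'
#' @param stack a [metric_stack()].
#' @return matrix in percent, NA outside the mask.
#' @export
myelin_vf <- function(stack) {
  stopifnot(inherits(stack, "metric_stack"))
  100 * stack$metrics$axon_volume_fraction * (1 / stack$metrics$g_ratio^2 - 1)
}
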