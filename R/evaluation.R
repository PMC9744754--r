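# Matching parcellations to reference tracts by overlap, coloring them the
# way the tract-vs-cluster hemisection figures are colored (cluster inherits
# the hue of its best-matching tract; clusters sharing a tract are separated
# by intensity in [0.2, 1] scaled with the amount of overlap), and
# quantitative recovery scores against synthetic ground truth.

#' Cluster-by-tract overlap matrix
#'
#' Against a discrete atlas, entry (c, t) counts pixels with cluster `c` and
#' tract `t`; against a soft atlas it sums tract-`t` partial volume over the
#' pixels of cluster `c`.
#'
#' @param parc a `parcellation` (see [ward_cluster()]).
#' @param atlas a `label_atlas` or `soft_atlas` on the same grid.
#' @return numeric matrix, rows = clusters, columns = tracts, with class
#'   `overlap_matrix`.
#' @export
overlap_matrix <- function(parc, atlas) {
  stopifnot(inherits(parc, "parcellation"))
  lab <- parc$labels
  if (inherits(atlas, "label_atlas")) {
    if (!all(dim(lab) == dim(atlas$labels))) stop("grid mismatch")
    both <- !is.na(lab) & atlas$labels > 0L
    cl <- factor(lab[both], levels = sort(unique(lab[!is.na(lab)])))
    tr <- factor(atlas$labels[both], levels = atlas$tract_ids)
    M <- as.matrix(table(cl, tr))
    dimnames(M) <- list(cluster = levels(cl), tract = atlas$tract_names)
  } else if (inherits(atlas, "soft_atlas")) {
    if (!all(dim(lab) == dim(atlas$pv)[1:2])) stop("grid mismatch")
    clusters <- sort(unique(lab[!is.na(lab)]))
    M <- matrix(0, length(clusters), length(atlas$tract_names),
                dimnames = list(cluster = clusters, tract = atlas$tract_names))
    for (i in seq_along(clusters)) {
      inc <- !is.na(lab) & lab == clusters[i]
      for (t in seq_along(atlas$tract_names))
        M[i, t] <- sum(atlas$pv[, , t][inc])
    }
  } else stop("atlas must be a label_atlas or soft_atlas")
  structure(M * 1, class = c("overlap_matrix", "matrix"))
}

#' Match clusters to tracts and assign colors
#'
#' Each cluster inherits the hue of its maximal-overlap tract.  When several
#' clusters share a tract, their intensities are spread over [0.2, 1]
#' linearly in the overlap fraction relative to the best of those clusters:
#' `intensity = 0.2 + 0.8 * frac / max(frac)` where `frac` is the fraction
#' of the tract covered by the cluster.  Ties are deterministic: equal
#' fractions rank by cluster size (larger brighter), then by cluster id.
#'
#' @param om an [overlap_matrix()].
#' @param palette named vector of hex colors per tract (default
#'   [default_tract_palette()] for the matrix's tract names).
#' @return data.frame with one row per cluster: `cluster`, `tract`,
#'   `overlap_fraction`, `intensity` (in [0.2, 1]), `color` (hex).
#' @export
match_and_color <- function(om, palette = NULL) {
  M <- unclass(om)
  if (!nrow(M) || all(M == 0)) stop("all-zero overlap matrix")
  tract_names <- colnames(M)
  palette <- palette %||% default_tract_palette(tract_names)
  stopifnot(all(tract_names %in% names(palette)))
  tract_size <- colSums(M)
  cluster_size <- rowSums(M)
  best <- apply(M, 1, which.max)          # first max -> lowest tract id on ties
  frac <- M[cbind(seq_len(nrow(M)), best)] / pmax(tract_size[best], .Machine$double.eps)
  intensity <- rep(1, nrow(M))
  for (t in unique(best)) {
    members <- which(best == t)
    f <- frac[members]
    i <- 0.2 + 0.8 * f / max(f)
    # deterministic tie policy: equal fractions -> larger cluster brighter
    ord <- order(-f, -cluster_size[members], members)
    ranked <- members[ord]
    i_sorted <- sort(i, decreasing = TRUE)
    intensity[ranked] <- i_sorted
  }
  hsvs <- grDevices::rgb2hsv(grDevices::col2rgb(palette[tract_names[best]]))
  cols <- grDevices::hsv(hsvs[1, ], hsvs[2, ], hsvs[3, ] * intensity)
  data.frame(cluster = as.integer(rownames(M)),
             tract = tract_names[best],
             overlap_fraction = unname(frac),
             intensity = intensity,
             color = cols,
             stringsAsFactors = FALSE)
}

#' Default tract palette
#'
#' Hues follow the usual figure convention for these tracts (cuneate
#' fasciculus red, dorsal corticospinal tract cyan, postsynaptic dorsal
#' column green, ...).
#'
#' @param tract_names tract names to color.
#' @return named character vector of hex colors.
#' @export
default_tract_palette <- function(tract_names = TRACT_NAMES) {
  base <- c(FG = "#404040", PSdc = "#2CA02C", FC = "#D62728", dCST = "#17BECF",
            LatC = "#FF7F0E", LSp = "#E8D500", RST = "#9467BD", LF = "#1F77B4",
            VF = "#3B5FC0", LFVF = "#1F77B4")
  missing <- setdiff(tract_names, names(base))
  if (length(missing)) {
    extra <- grDevices::rainbow(length(missing))
    names(extra) <- missing
    base <- c(base, extra)
  }
  base[tract_names]
}

#' Adjusted Rand Index between a parcellation and ground-truth labels
#'
#' Chance-corrected agreement over the pixels covered by both the
#' parcellation mask and the atlas labels; 1 = identical partitions (up to
#' relabeling), approximately 0 for independent labelings.
#'
#' @param parc a `parcellation`.
#' @param truth a `label_atlas`.
#' @return numeric in [-1, 1].
#' @export
ari <- function(parc, truth) {
  stopifnot(inherits(parc, "parcellation"), inherits(truth, "label_atlas"))
  both <- !is.na(parc$labels) & truth$labels > 0L
  if (!any(both)) stop("empty shared mask")
  mclust::adjustedRandIndex(parc$labels[both], truth$labels[both])
}

#' Per-tract recall of the best-matching cluster
#'
#' For each tract, the fraction of its mass captured by the single cluster
#' that overlaps it most.
#'
#' @param om an [overlap_matrix()].
#' @return named numeric vector over tracts.
#' @export
tract_recall <- function(om) {
  M <- unclass(om)
  out <- apply(M, 2, max) / pmax(colSums(M), .Machine$double.eps)
  stats::setNames(as.numeric(out), colnames(M))
}

#' Render a cluster-vs-atlas hemisection image
#'
#' Left half of the written image shows the parcellation in its matched
#' colors; the right half shows the reference atlas at full intensity with
#' the same palette; background is white.  Output is deterministic
#' (byte-identical across calls).
#'
#' @param parc a `parcellation`.
#' @param atlas a `label_atlas` on the same grid.
#' @param colors a [match_and_color()] assignment for `parc`.
#' @param path output PNG path.
#' @param upscale integer pixel replication factor.
#' @return `path`, invisibly.
#' @export
render_hemisection <- function(parc, atlas, colors, path, upscale = 4L) {
  stopifnot(inherits(parc, "parcellation"), inherits(atlas, "label_atlas"),
            all(dim(parc$labels) == dim(atlas$labels)))
  nr <- nrow(parc$labels); nc <- ncol(parc$labels)
  mid <- (nc + 1) / 2
  palette <- default_tract_palette(atlas$tract_names)
  img <- array(1, dim = c(nr, nc, 3))
  colvec <- colors$color[match(as.vector(parc$labels), colors$cluster)]
  colvec[is.na(colvec)] <- "#FFFFFF"
  cluster_col <- grDevices::col2rgb(colvec) / 255
  tract_col <- grDevices::col2rgb(palette[atlas$tract_names])[, atlas$labels + (atlas$labels == 0)] / 255
  for (ch in 1:3) {
    cl <- matrix(cluster_col[ch, ], nr, nc)
    tr <- matrix(tract_col[ch, ], nr, nc)
    plane <- img[, , ch]
    left <- col(plane) <= mid & !is.na(parc$labels)
    right <- col(plane) > mid & atlas$labels > 0L
    plane[left] <- cl[left]
    plane[right] <- tr[right]
    img[, , ch] <- plane
  }
  if (upscale > 1) {
    idx_r <- rep(seq_len(nr), each = upscale)
    idx_c <- rep(seq_len(nc), each = upscale)
    img <- img[idx_r, idx_c, , drop = FALSE]
  }
  png::writePNG(img, path)
  invisible(path)
}
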