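# Toy spinal-cord reference atlas.
#
# A parametric stand-in for a digitized rat tract atlas: a cord outline
# (ellipse), a gray-matter "butterfly", and nine white-matter tract regions
# placed to mimic the usual rat topology -- dorsal column (fasciculus
# gracilis FG medially, postsynaptic dorsal column PSdc, fasciculus cuneatus
# FC laterally), dorsal corticospinal tract dCST at the base of the dorsal
# column, lateral cervical nucleus LatC / lateral spinal nucleus LSp on the
# dorsolateral surface, rubrospinal tract RST deep to them, and the lateral
# and ventral funiculi LF / VF.  All geometry is computed from |x| so the
# atlas is exactly mirror-symmetric about the midline column.

TRACT_NAMES <- c("FG", "PSdc", "FC", "dCST", "LatC", "LSp", "RST", "LF", "VF")

#' Spinal level scheme (C1--S4)
#'
#' 31 axial levels in 4 regions: cervical C1--C8, thoracic T1--T13, lumbar
#' L1--L6, sacral S1--S4.
#'
#' @return list with `levels` (ordered labels), `region` (named factor of
#'   region per level) and `regions`.
#' @export
level_scheme <- function() {
  levels <- c(paste0("C", 1:8), paste0("T", 1:13), paste0("L", 1:6), paste0("S", 1:4))
  region <- rep(c("cervical", "thoracic", "lumbar", "sacral"), c(8L, 13L, 6L, 4L))
  names(region) <- levels
  list(levels = levels, region = region,
       regions = c("cervical", "thoracic", "lumbar", "sacral"))
}

# Smooth per-level scale factor of the cord cross-section: larger at the
# cervical and lumbar enlargements, smallest at S4.  Spline through anchor
# levels; deterministic.
level_scale <- function(level, scheme = level_scheme()) {
  i <- match(level, scheme$levels)
  if (any(is.na(i))) stop("unknown level label: ", paste(level[is.na(i)], collapse = ", "))
  anchors_x <- c(1, 6, 9, 15, 21, 25, 28, 31)
  anchors_y <- c(1.00, 1.05, 0.92, 0.82, 0.85, 0.95, 0.80, 0.62)
  stats::spline(anchors_x, anchors_y, xout = i, method = "natural")$y
}

#' Parametric toy atlas specification
#'
#' Geometry is expressed in fractions of the cord semi-axes so one spec
#' serves all levels; per-level modulation smoothly rescales the outline and
#' wobbles the dorsal-column width.
#'
#' @param shape grid shape in pixels, `c(rows, cols)`.
#' @param pixel_size pixel size in micrometres (the maps emulate 50 um
#'   morphometry grids).
#' @param rx,ry cord semi-axes as fractions of the half-grid.
#' @param merge_lfvf merge the lateral and ventral funiculi into a single
#'   ventrolateral label (the 8-tract reference convention)?
#' @param symmetric impose exact right-left mirror symmetry.
#' @param modulation amplitude of the smooth per-level wobble of internal
#'   boundaries (fraction, 0 disables).
#' @return object of class `toy_atlas_spec`.
#' @export
toy_atlas_spec <- function(shape = c(64L, 64L), pixel_size = 50, rx = 0.84,
                           ry = 0.72, merge_lfvf = FALSE, symmetric = TRUE,
                           modulation = 0.05) {
  stopifnot(length(shape) == 2, all(shape >= 24), rx > 0, ry > 0,
            modulation >= 0)
  structure(list(shape = as.integer(shape), pixel_size = pixel_size,
                 rx = rx, ry = ry, merge_lfvf = merge_lfvf,
                 symmetric = symmetric, modulation = modulation,
                 # gray-matter butterfly (fractions of the cord semi-axes)
                 gm = list(central = c(x = 0.00, y = 0.05, a = 0.30, b = 0.20),
                           ventral = c(x = 0.30, y = 0.38, a = 0.22, b = 0.30),
                           dorsal  = c(x = 0.26, y = -0.35, a = 0.13, b = 0.38)),
                 # tract partition parameters (see build_reference_atlas)
                 tracts = list(y_dc = -0.10, y_dcst = -0.45, x_dcst = 0.22,
                               x_fg = 0.13, x_ps = 0.26, x_dc = 0.40,
                               phi_latc = 52, phi_lsp = 84, phi_rst_in = 28,
                               phi_vf = 118, rho_rim = 0.70)),
            class = "toy_atlas_spec")
}

in_ellipse <- function(x, y, cx, cy, a, b) ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1

#' Build the toy reference atlas for one spinal level
#'
#' @param spec a [toy_atlas_spec()].
#' @param level level label from [level_scheme()].
#' @return object of class `label_atlas`: integer label matrix (`0` =
#'   background / gray matter), `tract_ids`, `tract_names`, white-matter
#'   `mask`, plus grid metadata.
#' @export
build_reference_atlas <- function(spec, level) {
  stopifnot(inherits(spec, "toy_atlas_spec"))
  scheme <- level_scheme()
  li <- match(level, scheme$levels)
  if (is.na(li)) stop("unknown level label: ", level)
  sc <- level_scale(level)
  nr <- spec$shape[1]; nc <- spec$shape[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  rx <- spec$rx * (nc - 1) / 2 * sc
  ry <- spec$ry * (nr - 1) / 2 * sc
  if (rx > (nc - 1) / 2 || ry > (nr - 1) / 2)
    stop("tract geometry leaves the grid: cord outline exceeds the image")

  # smooth per-level wobble of internal boundaries
  wob <- spec$modulation * sin(2 * pi * li / 31)
  tp <- spec$tracts
  x_dc <- tp$x_dc * (1 + wob)
  y_dcst <- tp$y_dcst * (1 + 0.5 * wob)

  # coordinate grids; y < 0 is dorsal (row 1), x in columns, |x| for symmetry
  y <- (matrix(seq_len(nr), nr, nc) - cy) / ry
  x <- (matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx) / rx
  ax <- if (spec$symmetric) abs(x) else x

  cord <- x^2 + y^2 <= 1
  gm <- spec$gm
  gray <- in_ellipse(ax, y, gm$central["x"], gm$central["y"], gm$central["a"], gm$central["b"]) |
          in_ellipse(ax, y, gm$ventral["x"], gm$ventral["y"], gm$ventral["a"], gm$ventral["b"]) |
          in_ellipse(ax, y, gm$dorsal["x"],  gm$dorsal["y"],  gm$dorsal["a"],  gm$dorsal["b"])
  wm <- cord & !gray

  lab <- matrix(0L, nr, nc)
  id <- stats::setNames(seq_along(TRACT_NAMES), TRACT_NAMES)

  dc <- wm & y <= tp$y_dc & ax <= x_dc
  dcst <- dc & y > y_dcst & ax <= tp$x_dcst
  dc_asc <- dc & y <= y_dcst
  lab[dcst] <- id["dCST"]
  lab[dc_asc & ax <= tp$x_fg] <- id["FG"]
  lab[dc_asc & ax > tp$x_fg & ax <= tp$x_ps] <- id["PSdc"]
  lab[dc_asc & ax > tp$x_ps] <- id["FC"]

  rest <- wm & lab == 0L
  phi <- atan2(ax, -y) * 180 / pi       # 0 = dorsal midline, 180 = ventral
  rho <- sqrt(x^2 + y^2)
  vf <- rest & phi >= tp$phi_vf
  latc <- rest & !vf & phi < tp$phi_latc & rho >= tp$rho_rim
  lsp <- rest & !vf & phi >= tp$phi_latc & phi < tp$phi_lsp & rho >= tp$rho_rim
  rst <- rest & !vf & !latc & !lsp & phi >= tp$phi_rst_in & phi < tp$phi_lsp &
         rho < tp$rho_rim
  lab[vf] <- id["VF"]; lab[latc] <- id["LatC"]; lab[lsp] <- id["LSp"]
  lab[rst] <- id["RST"]
  lab[rest & lab == 0L] <- id["LF"]

  tract_names <- TRACT_NAMES
  if (spec$merge_lfvf) {
    lab[lab == id["VF"]] <- id["LF"]
    tract_names <- c(TRACT_NAMES[1:7], "LFVF")
    lab[lab == id["LF"]] <- 8L
  }
  present <- sort(unique(lab[lab > 0L]))
  if (!identical(present, seq_along(tract_names)))
    stop("tract geometry degenerate at level ", level, ": missing tract(s) ",
         paste(tract_names[setdiff(seq_along(tract_names), present)], collapse = ", "))
  if (spec$symmetric && !identical(lab, mirror_lr(lab)))
    stop("internal error: symmetric atlas is not mirror-symmetric")

  structure(list(labels = lab, tract_ids = seq_along(tract_names),
                 tract_names = tract_names, mask = lab > 0L,
                 pixel_size = spec$pixel_size, level = level,
                 region = unname(scheme$region[level])),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat("<label_atlas> level", x$level, sprintf("(%s),", x$region),
      nrow(x$labels), "x", ncol(x$labels), "px,",
      length(x$tract_names), "tracts,", sum(x$mask), "white-matter pixels\n")
  invisible(x)
}

#' Keep only one hemicord of a mask
#'
#' Restricts a mask (or labeled image) to columns strictly on one side of the
#' midline.  Useful for recovery experiments: on a hemisection every tract of
#' the symmetric toy atlas is a single connected region.
#'
#' @param x logical or integer matrix.
#' @param side `"left"` or `"right"` (image columns below/above the midline).
#' @return matrix of the same shape with the other side set to FALSE / 0 / NA.
#' @export
hemisection_mask <- function(x, side = c("left", "right")) {
  side <- match.arg(side)
  nc <- ncol(x)
  mid <- (nc + 1) / 2
  drop_cols <- if (side == "left") which(seq_len(nc) > mid) else which(seq_len(nc) < mid)
  if (is.logical(x)) x[, drop_cols] <- FALSE
  else if (is.integer(x)) x[, drop_cols] <- 0L
  else x[, drop_cols] <- NA_real_
  x
}
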