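# Shared fixtures and independent oracles for the test suite.

# Smooth multi-blob test image for registration tests.
blob_image <- function(nr = 48, nc = 48) {
  r <- matrix(seq_len(nr), nr, nc)
  c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  exp(-((r - nr * 0.42)^2 + (c_ - nc * 0.5)^2) / 60) +
    0.8 * exp(-((r - nr * 0.67)^2 + (c_ - nc * 0.37)^2) / 40) +
    0.6 * exp(-((r - nr * 0.58)^2 + (c_ - nc * 0.71)^2) / 80)
}

constant_field <- function(shape, dy, dx) {
  displacement_field(matrix(dy, shape[1], shape[2]),
                     matrix(dx, shape[1], shape[2]))
}

# Metric stack with all five channels equal to `base` (plus optional named
# overrides); convenient for clustering tests driven by one pattern.
stack_from_matrix <- function(base, overrides = list(), level = "C1") {
  metrics <- stats::setNames(rep(list(base), 5),
                             c("axon_density", "axon_diameter",
                               "axon_volume_fraction", "g_ratio",
                               "myelin_thickness"))
  # keep fraction-valued channels in a legal range
  metrics$axon_volume_fraction <- base / max(base, na.rm = TRUE) * 0.5
  metrics$g_ratio <- base * 0 + 0.7
  for (nm in names(overrides)) metrics[[nm]] <- overrides[[nm]]
  metric_stack(metrics, level = level)
}

# Independent brute-force Ward oracle: at every step recompute ALL pairwise
# Ward costs  n_i n_j / (n_i + n_j) ||mu_i - mu_j||^2  from scratch over the
# current clusters, restrict to pairs allowed by the (optional) adjacency,
# merge the cheapest (lexicographically smallest pair on ties).  O(n^3);
# for <= 15-point instances only.
brute_force_ward <- function(X, k, edges = NULL) {
  n <- nrow(X)
  clusters <- as.list(seq_len(n))
  adj <- NULL
  if (!is.null(edges)) {
    adj <- matrix(FALSE, n, n)
    adj[edges] <- TRUE
    adj[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  while (length(clusters) > k) {
    m <- length(clusters)
    best <- NULL; best_cost <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (!is.null(adj) &&
            !any(adj[clusters[[i]], clusters[[j]], drop = FALSE])) next
        ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
        mui <- colMeans(X[clusters[[i]], , drop = FALSE])
        muj <- colMeans(X[clusters[[j]], , drop = FALSE])
        cost <- ni * nj / (ni + nj) * sum((mui - muj)^2)
        if (cost < best_cost - 1e-12) { best <- c(i, j); best_cost <- cost }
      }
    }
    if (is.null(best)) break
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}

# agreement of two labelings up to relabeling
same_partition <- function(a, b) {
  mclust::adjustedRandIndex(a, b) == 1
}

# full connectivity graph over a fake 1 x n mask (for oracle-equivalence
# tests that need an unconstrained graph in the constrained engine)
full_graph <- function(n) {
  mask <- matrix(TRUE, 1, n)
  g <- build_connectivity(mask, "axial4")
  pairs <- t(utils::combn(n, 2))
  g$edges <- cbind(a = pairs[, 1], b = pairs[, 2])
  g
}

# default small fixtures
tiny_spec <- function(shape = c(48L, 48L), ...) toy_atlas_spec(shape = shape, ...)

hemisection_stack <- function(sample, side = "left") {
  hm <- hemisection_mask(sample$stack$mask, side)
  metrics <- lapply(sample$stack$metrics, function(m) { m[!hm] <- NA_real_; m })
  metric_stack(metrics, mask = hm, pixel_size = sample$stack$pixel_size,
               level = sample$stack$level)
}

hemisection_truth <- function(sample, side = "left") {
  truth <- sample$truth
  truth$labels <- hemisection_mask(truth$labels, side)
  truth$mask <- truth$labels > 0L
  truth
}
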