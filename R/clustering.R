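# Connectivity-constrained agglomerative clustering, Ward linkage, Euclidean
# affinity -- written from scratch.  Pixels are graph nodes; only clusters
# sharing at least one graph edge may merge, which keeps every parcel
# spatially connected under the axial neighbourhood schemes.  The merge cost
# is the Ward increment
#     delta(i, j) = n_i n_j / (n_i + n_j) * ||mu_i - mu_j||^2
# computed from maintained cluster centroids and sizes (algebraically the
# same quantity the Lance-Williams Ward recurrence propagates).  Candidate
# merges live in a lazily-deleted queue: edges referencing absorbed clusters
# are discarded when popped.  Ties on cost break to the lexicographically
# smallest (id_a, id_b) pair, so results are bit-reproducible.

#' Min-max normalize metric channels into a feature table
#'
#' Each channel is scaled to [0, 1] over the masked pixels only.  A constant
#' channel maps to all zeros with a warning.  Row order is the column-major
#' order of the masked pixels and is shared with [build_connectivity()].
#'
#' @param stack a [metric_stack()].
#' @param metrics optional character subset of channels (default: all five).
#' @return object of class `feature_table`: `features` (pixels x metrics,
#'   in [0, 1]), `rows`, `cols` (pixel coordinates), `metrics`.
#' @export
normalize_metrics <- function(stack, metrics = NULL) {
  stopifnot(inherits(stack, "metric_stack"))
  metrics <- metrics %||% METRIC_NAMES
  stopifnot(all(metrics %in% METRIC_NAMES))
  mask <- stack$mask
  if (!any(mask)) stop("empty mask")
  idx <- which(mask)
  X <- vapply(metrics, function(m) stack$metrics[[m]][idx], numeric(length(idx)))
  X <- matrix(X, nrow = length(idx), dimnames = list(NULL, metrics))
  for (j in seq_len(ncol(X))) {
    rng <- range(X[, j])
    if (diff(rng) == 0) {
      warning("metric '", metrics[j], "' is constant inside the mask; ",
              "normalized to all zeros")
      X[, j] <- 0
    } else {
      X[, j] <- (X[, j] - rng[1]) / diff(rng)
    }
  }
  coords <- arrayInd(idx, dim(mask))
  structure(list(features = X, rows = coords[, 1], cols = coords[, 2],
                 metrics = metrics, mask = mask),
            class = "feature_table")
}

#' Pixel adjacency graph over a mask
#'
#' Edges connect in-mask neighbour pairs under the chosen axial scheme
#' (4- or 8-neighbourhood); no self loops, each undirected edge stored once.
#' Node order is the column-major order of the masked pixels.
#'
#' @param mask logical matrix.
#' @param scheme `"axial4"` or `"axial8"`.
#' @return object of class `connectivity_graph`: `edges` (2-column integer
#'   matrix of node indices, a < b), `n` nodes, `n_components`,
#'   `component_id`.
#' @export
build_connectivity <- function(mask, scheme = c("axial4", "axial8")) {
  scheme <- match.arg(scheme)
  stopifnot(is.logical(mask))
  idx <- which(mask)
  if (!length(idx)) stop("empty mask")
  nr <- nrow(mask); nc <- ncol(mask)
  node <- matrix(0L, nr, nc)
  node[idx] <- seq_along(idx)
  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (scheme == "axial8") offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  ea <- integer(0); eb <- integer(0)
  coords <- arrayInd(idx, c(nr, nc))
  for (off in offsets) {
    rr <- coords[, 1] + off[1]; cc <- coords[, 2] + off[2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    ok[ok] <- mask[cbind(rr[ok], cc[ok])]
    a <- node[idx[ok]]
    b <- node[cbind(rr[ok], cc[ok])]
    ea <- c(ea, pmin(a, b)); eb <- c(eb, pmax(a, b))
  }
  g <- igraph::graph_from_edgelist(cbind(ea, eb), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  structure(list(edges = cbind(a = ea, b = eb), n = length(idx),
                 scheme = scheme, n_components = as.integer(comp$no),
                 component_id = comp$membership),
            class = "connectivity_graph")
}

# Greedy constrained Ward agglomeration over one connected set of nodes.
# X: features for these nodes; edges: 2-col matrix in local node indices.
# Returns local labels (1..k) and the merge record.
ward_agglomerate <- function(X, edges, k) {
  n <- nrow(X)
  if (k >= n) {
    return(list(labels = seq_len(n),
                merges = data.frame(a = integer(0), b = integer(0),
                                    cost = numeric(0), size = integer(0))))
  }
  max_id <- 2L * n
  cent <- matrix(NA_real_, max_id, ncol(X))
  cent[seq_len(n), ] <- X
  sz <- integer(max_id); sz[seq_len(n)] <- 1L
  alive <- logical(max_id); alive[seq_len(n)] <- TRUE
  nbrs <- vector("list", max_id)

  ward_cost <- function(i, j) {
    d <- cent[i, ] - cent[j, ]
    (sz[i] * sz[j]) / (sz[i] + sz[j]) * sum(d * d)
  }

  # initial candidate queue from the graph edges
  ea <- pmin(edges[, 1], edges[, 2]); eb <- pmax(edges[, 1], edges[, 2])
  key <- unique((ea - 1) * n + eb)            # dedupe parallel edges
  ea <- ((key - 1) %/% n) + 1; eb <- ((key - 1) %% n) + 1
  for (i in seq_len(n)) nbrs[[i]] <- integer(0)
  for (e in seq_along(ea)) {
    nbrs[[ea[e]]] <- c(nbrs[[ea[e]]], eb[e])
    nbrs[[eb[e]]] <- c(nbrs[[eb[e]]], ea[e])
  }
  qa <- as.integer(ea); qb <- as.integer(eb)
  d <- cent[qa, , drop = FALSE] - cent[qb, , drop = FALSE]
  qcost <- (sz[qa] * sz[qb]) / (sz[qa] + sz[qb]) * rowSums(d * d)

  merges <- data.frame(a = integer(n - k), b = integer(n - k),
                       cost = numeric(n - k), size = integer(n - k))
  next_id <- n
  for (m in seq_len(n - k)) {
    # pop the cheapest valid candidate (lazy deletion; lexicographic ties)
    repeat {
      if (!length(qcost) || all(is.infinite(qcost)))
        stop("graph exhausted before reaching the requested cluster count")
      minc <- min(qcost)
      cand <- which(qcost == minc)
      valid <- alive[qa[cand]] & alive[qb[cand]]
      qcost[cand[!valid]] <- Inf
      if (!any(valid)) next
      cand <- cand[valid]
      pick <- cand[order(qa[cand], qb[cand])[1]]
      break
    }
    i <- qa[pick]; j <- qb[pick]
    qcost[pick] <- Inf
    next_id <- next_id + 1L
    cent[next_id, ] <- (sz[i] * cent[i, ] + sz[j] * cent[j, ]) / (sz[i] + sz[j])
    sz[next_id] <- sz[i] + sz[j]
    alive[c(i, j)] <- FALSE
    alive[next_id] <- TRUE
    merges$a[m] <- i; merges$b[m] <- j
    merges$cost[m] <- minc; merges$size[m] <- sz[next_id]
    un <- unique(c(nbrs[[i]], nbrs[[j]]))
    un <- un[alive[un] & un != next_id]
    nbrs[[next_id]] <- un
    nbrs[[i]] <- integer(0); nbrs[[j]] <- integer(0)
    if (length(un)) {
      for (u in un) nbrs[[u]] <- c(nbrs[[u]], next_id)
      dd <- cent[un, , drop = FALSE] -
            matrix(cent[next_id, ], length(un), ncol(X), byrow = TRUE)
      costs <- (sz[un] * sz[next_id]) / (sz[un] + sz[next_id]) * rowSums(dd * dd)
      qa <- c(qa, pmin(un, next_id)); qb <- c(qb, pmax(un, next_id))
      qcost <- c(qcost, costs)
    }
  }
  # resolve final labels by walking the merge records
  parent <- seq_len(max_id)
  for (m in seq_len(n - k)) parent[c(merges$a[m], merges$b[m])] <- n + m
  find_root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  roots <- vapply(seq_len(n), find_root, integer(1))
  list(labels = as.integer(factor(roots, levels = sort(unique(roots)))),
       merges = merges)
}

# Apportion k clusters across components proportionally to pixel counts,
# largest remainder, at least one per component.
apportion_clusters <- function(sizes, k) {
  m <- length(sizes)
  k <- max(k, m)
  quota <- sizes / sum(sizes) * k
  base <- pmax(1L, floor(quota))
  while (sum(base) > k) {                 # the >=1 floor can overshoot
    over <- which(base > 1)
    i <- over[which.min((quota - base)[over])]
    base[i] <- base[i] - 1L
  }
  rem <- k - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  base <- pmin(base, sizes)               # cannot exceed component pixel count
  while (sum(base) < k) {                 # redistribute if capped
    room <- which(base < sizes)
    if (!length(room)) break
    i <- room[which.max(sizes[room] - base[room])]
    base[i] <- base[i] + 1L
  }
  as.integer(base)
}

#' Connectivity-constrained Ward clustering
#'
#' Greedy agglomeration under the pixel adjacency constraint.  On a connected
#' graph it stops at exactly `n_clusters`; a disconnected mask is clustered
#' component-by-component with `n_clusters` apportioned by component pixel
#' share (at least one each), so the effective count is
#' `max(n_clusters, n_components)`.
#'
#' @param features a [normalize_metrics()] feature table (or a bare numeric
#'   matrix).
#' @param graph a [build_connectivity()] graph over the same pixels.
#' @param n_clusters requested number of clusters (>= 1, <= pixel count).
#' @return list of class `ward_result` with `parcellation` (a `parcellation`
#'   when a mask is available, else integer labels), `labels`, `dendrogram`
#'   (merge records: `a`, `b`, `cost`, `size`, `component`) and `n_clusters`.
#' @export
ward_cluster <- function(features, graph, n_clusters) {
  X <- if (inherits(features, "feature_table")) features$features else features
  stopifnot(is.matrix(X), inherits(graph, "connectivity_graph"))
  n <- nrow(X)
  if (n == 0) stop("empty feature table")
  if (graph$n != n) stop("graph and feature table cover different pixel sets")
  if (n_clusters < 1 || n_clusters > n)
    stop("n_clusters must be in [1, number of pixels]")
  comp <- graph$component_id
  ncomp <- graph$n_components
  labels <- integer(n)
  merges_all <- NULL
  if (ncomp == 1L) {
    res <- ward_agglomerate(X, graph$edges, n_clusters)
    labels <- res$labels
    merges_all <- cbind(res$merges,
                        component = rep(1L, nrow(res$merges)))
  } else {
    sizes <- tabulate(comp, ncomp)
    kc <- apportion_clusters(sizes, n_clusters)
    offset <- 0L
    for (ci in seq_len(ncomp)) {
      nodes <- which(comp == ci)
      remap <- integer(n); remap[nodes] <- seq_along(nodes)
      sel <- comp[graph$edges[, 1]] == ci
      edges <- cbind(remap[graph$edges[sel, 1]], remap[graph$edges[sel, 2]])
      res <- ward_agglomerate(X[nodes, , drop = FALSE], edges, kc[ci])
      labels[nodes] <- res$labels + offset
      offset <- offset + max(res$labels)
      if (nrow(res$merges))  # merge ids are component-local
        merges_all <- rbind(merges_all, cbind(res$merges, component = ci))
    }
  }
  parc <- NULL
  if (inherits(features, "feature_table")) {
    img <- matrix(NA_integer_, nrow(features$mask), ncol(features$mask))
    img[cbind(features$rows, features$cols)] <- labels
    parc <- structure(list(labels = img, n_clusters = max(labels),
                           mode = NA_character_, id = NA_character_),
                      class = "parcellation")
  }
  structure(list(parcellation = parc, labels = labels,
                 dendrogram = merges_all, n_clusters = max(labels)),
            class = "ward_result")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("<parcellation>", x$n_clusters, "clusters over",
      sum(!is.na(x$labels)), "pixels",
      if (!is.na(x$mode)) paste0("(", x$mode, " ", x$id, ")") else "", "\n")
  invisible(x)
}

#' Slice-wise clustering across spinal levels
#'
#' One independent constrained-Ward run per level, using only white-matter
#' pixels, all metric channels min-max normalized per slice.
#'
#' @param stacks named list of [metric_stack()]s (one per level).
#' @param n_clusters clusters per slice.
#' @param scheme neighbourhood scheme, see [build_connectivity()].
#' @param metrics optional metric subset (e.g. density + volume fraction).
#' @return named list of `parcellation` objects.
#' @export
cluster_slicewise <- function(stacks, n_clusters = 8L, scheme = "axial4",
                              metrics = NULL) {
  out <- lapply(names(stacks) %||% seq_along(stacks), function(nm) {
    stack <- stacks[[nm]]
    res <- tryCatch({
      ft <- normalize_metrics(stack, metrics)
      g <- build_connectivity(stack$mask, scheme)
      ward_cluster(ft, g, n_clusters)
    }, error = function(e) stop("level ", nm, ": ", conditionMessage(e), call. = FALSE))
    p <- res$parcellation
    p$mode <- "slice-wise"; p$id <- as.character(stack$level %||% nm)
    p
  })
  names(out) <- names(stacks) %||% vapply(stacks, function(s) s$level, character(1))
  out
}

#' Region-wise clustering of aggregated region stacks
#'
#' @param region_stacks named list of aggregated [metric_stack()]s (one per
#'   region, see [aggregate_region()]).
#' @inheritParams cluster_slicewise
#' @return named list of `parcellation` objects.
#' @export
cluster_regionwise <- function(region_stacks, n_clusters = 8L,
                               scheme = "axial4", metrics = NULL) {
  out <- cluster_slicewise(region_stacks, n_clusters, scheme, metrics)
  for (nm in names(out)) out[[nm]]$mode <- "region-wise"
  out
}
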