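# Constrained Ward clustering: normalization, connectivity, the greedy
# engine against brute-force oracles, and the slice/region drivers.

test_that("min-max normalization scales masked pixels into [0, 1]", {
  base <- matrix(NA_real_, 2, 3)
  base[1, ] <- c(2, 4, 6)
  st <- stack_from_matrix(base, overrides = list(axon_density = base))
  expect_warning(ft <- normalize_metrics(st), "constant")  # g_ratio constant
  expect_equal(unname(ft$features[, "axon_density"]), c(0, 0.5, 1))
  expect_true(all(ft$features >= 0 & ft$features <= 1))
  expect_equal(unname(ft$features[, "g_ratio"]), c(0, 0, 0))
})

test_that("connectivity edge counts match enumeration on a 2x2 mask", {
  mask <- matrix(TRUE, 2, 2)
  expect_identical(nrow(build_connectivity(mask, "axial4")$edges), 4L)
  expect_identical(nrow(build_connectivity(mask, "axial8")$edges), 6L)
  blobs <- matrix(FALSE, 5, 5); blobs[1:2, 1:2] <- TRUE; blobs[4:5, 4:5] <- TRUE
  g <- build_connectivity(blobs, "axial4")
  expect_identical(g$n_components, 2L)
  # edges only between in-mask neighbours, no self loops, stored once
  expect_true(all(g$edges[, 1] < g$edges[, 2]))
})

test_that("degenerate cluster counts behave per contract", {
  X <- matrix(stats::runif(10), 5, 2)
  g <- full_graph(5)
  res <- ward_cluster(X, g, 5)
  expect_identical(sort(res$labels), 1:5)
  expect_identical(nrow(res$dendrogram), 0L)
  res1 <- ward_cluster(matrix(1, 4, 2), full_graph(4), 1)
  expect_identical(res1$n_clusters, 1L)
  expect_true(all(res1$dendrogram$cost == 0))
  expect_error(ward_cluster(X, g, 6), "n_clusters")
})

test_that("a 1x6 strip with a step feature splits exactly at the step", {
  mask <- matrix(TRUE, 1, 6)
  feat <- matrix(c(0, 0, 0, 1, 1, 1), 1, 6)
  st <- stack_from_matrix(feat + 1, overrides = list(axon_density = feat))
  suppressWarnings(ft <- normalize_metrics(st, metrics = "axon_density"))
  g <- build_connectivity(mask, "axial4")
  res <- ward_cluster(ft, g, 2)
  expect_identical(res$labels[1:3], rep(res$labels[1], 3))
  expect_identical(res$labels[4:6], rep(res$labels[4], 3))
  expect_false(res$labels[1] == res$labels[4])
})

test_that("engine matches the brute-force Ward oracle on random instances", {
  set.seed(2024)
  for (rep in 1:60) {
    n <- sample(6:12, 1)
    X <- matrix(stats::rnorm(n * 2), n, 2)
    k <- sample(2:4, 1)
    g <- full_graph(n)
    mine <- ward_cluster(X, g, k)$labels
    oracle <- brute_force_ward(X, k)
    expect_true(same_partition(mine, oracle),
                info = sprintf("rep %d n %d k %d", rep, n, k))
  }
})

test_that("engine agrees with hclust ward.D2 partitions on tie-free data", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 30
    X <- matrix(stats::rnorm(n * 3), n, 3)
    k <- sample(2:6, 1)
    mine <- ward_cluster(X, full_graph(n), k)$labels
    hc <- stats::cutree(stats::hclust(stats::dist(X), method = "ward.D2"), k)
    expect_true(same_partition(mine, hc))
  }
})

test_that("constrained merges only ever join graph-adjacent clusters", {
  set.seed(11)
  mask <- matrix(TRUE, 5, 5)
  g <- build_connectivity(mask, "axial4")
  X <- matrix(stats::rnorm(25 * 2), 25, 2)
  res <- ward_cluster(X, g, 3)
  # replay the merge history and check adjacency at every step
  adj <- matrix(FALSE, 50, 50)
  adj[g$edges] <- TRUE; adj[g$edges[, 2:1]] <- TRUE
  members <- c(as.list(1:25), vector("list", 25))
  for (m in seq_len(nrow(res$dendrogram))) {
    a <- res$dendrogram$a[m]; b <- res$dendrogram$b[m]
    expect_true(any(adj[members[[a]], members[[b]]]),
                info = sprintf("merge %d joins non-adjacent clusters", m))
    members[[25 + m]] <- c(members[[a]], members[[b]])
  }
  # constrained result matches a brute-force oracle honouring the same graph
  oracle <- brute_force_ward(X, 3, edges = g$edges)
  expect_true(same_partition(res$labels, oracle))
  # and every resulting parcel is spatially connected
  for (l in unique(res$labels)) {
    sub <- matrix(FALSE, 5, 5); sub[which(mask)[res$labels == l]] <- TRUE
    expect_identical(cordparc:::mask_components(sub)$n, 1L)
  }
})

test_that("merge costs are non-decreasing under unconstrained Ward", {
  # (with a sparse connectivity constraint, newly created adjacencies can
  # legitimately expose cheaper pairs, so monotonicity is only guaranteed on
  # a complete graph)
  set.seed(5)
  X <- matrix(stats::rnorm(24 * 3), 24, 3)
  res <- ward_cluster(X, full_graph(24), 1)
  expect_identical(nrow(res$dendrogram), 23L)
  expect_true(all(diff(res$dendrogram$cost) >= -1e-12))
})

test_that("clustering is deterministic across repeated runs", {
  set.seed(9)
  a <- build_reference_atlas(tiny_spec(), "C4")
  sig <- default_signatures()
  s <- sample_subject(a, sig, noise_scale = 1, deform_amplitude = 0, seed = 17)
  ft <- normalize_metrics(s$stack)
  g <- build_connectivity(s$stack$mask, "axial4")
  r1 <- ward_cluster(ft, g, 8)
  r2 <- ward_cluster(ft, g, 8)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$dendrogram, r2$dendrogram)
})

test_that("disconnected masks apportion clusters by component share", {
  mask <- matrix(FALSE, 4, 9)
  mask[, 1:6] <- TRUE        # 24-pixel component
  mask[, 8:9] <- TRUE        # 8-pixel component
  set.seed(3)
  X <- matrix(stats::rnorm(sum(mask) * 2), sum(mask), 2)
  g <- build_connectivity(mask, "axial4")
  res <- ward_cluster(X, g, 4)
  expect_identical(res$n_clusters, 4L)
  comp <- g$component_id
  k_per_comp <- vapply(1:2, function(ci) length(unique(res$labels[comp == ci])),
                       integer(1))
  expect_identical(sort(k_per_comp), c(1L, 3L))   # 24:8 share of 4 clusters
  # component count beats a smaller n_clusters
  res1 <- ward_cluster(X, g, 1)
  expect_identical(res1$n_clusters, 2L)
})

test_that("exact recovery on a noise-free hemisection: ARI = 1", {
  spec <- tiny_spec()
  sig <- default_signatures()
  a <- build_reference_atlas(spec, "C4")
  s <- sample_subject(a, sig, noise_scale = 0, deform_amplitude = 0, seed = 1)
  st <- hemisection_stack(s)
  truth <- hemisection_truth(s)
  ft <- normalize_metrics(st)
  g <- build_connectivity(st$mask, "axial4")
  res <- ward_cluster(ft, g, length(sig$tract_id))
  expect_equal(ari(res$parcellation, truth), 1)
})

test_that("slice-wise driver returns one parcellation per level with k clusters", {
  spec <- tiny_spec()
  sig <- default_signatures(merge_lfvf = TRUE)
  spec$merge_lfvf <- TRUE
  lvls <- c("C4", "T7")
  stacks <- lapply(lvls, function(l) {
    a <- build_reference_atlas(spec, l)
    sample_subject(a, sig, noise_scale = 0.6, deform_amplitude = 0,
                   seed = match(l, lvls))$stack
  })
  names(stacks) <- lvls
  parcs <- cluster_slicewise(stacks, n_clusters = 8)
  expect_named(parcs, lvls)
  for (p in parcs) {
    expect_identical(p$n_clusters, 8L)
    expect_identical(p$mode, "slice-wise")
  }
  # metric-subset variant (density + volume fraction only)
  p2 <- cluster_slicewise(stacks["C4"], 8,
                          metrics = c("axon_density", "axon_volume_fraction"))
  expect_identical(p2$C4$n_clusters, 8L)
})
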