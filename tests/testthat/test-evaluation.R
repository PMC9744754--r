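# Overlap matrices, color matching, ARI, rendering.

make_parc <- function(labels) {
  structure(list(labels = labels, n_clusters = max(labels, na.rm = TRUE),
                 mode = "slice-wise", id = "test"),
            class = "parcellation")
}

make_atlas <- function(labels, tract_names) {
  structure(list(labels = labels, tract_ids = seq_along(tract_names),
                 tract_names = tract_names, mask = labels > 0L,
                 pixel_size = 50, level = "C1", region = "cervical"),
            class = "label_atlas")
}

test_that("overlap matrix counts pixel co-occurrences", {
  lab <- matrix(NA_integer_, 1, 2); lab[1, ] <- 1L
  atl <- make_atlas(matrix(c(1L, 2L), 1, 2), c("tA", "tB"))
  om <- overlap_matrix(make_parc(lab), atl)
  expect_equal(unname(unclass(om)[1, ]), c(1, 1))
  # identical labelings give a diagonal matrix
  truth <- build_reference_atlas(tiny_spec(), "C4")
  om2 <- overlap_matrix(make_parc(ifelse(truth$labels > 0, truth$labels, NA)),
                        truth)
  M <- unclass(om2)
  expect_true(all(M[row(M) != col(M)] == 0))
  expect_identical(unname(rowSums(M)), as.numeric(tabulate(truth$labels)))
})

test_that("soft-atlas overlap sums partial volumes", {
  lab <- matrix(1L, 2, 2)
  pv <- array(0.5, dim = c(2, 2, 1), dimnames = list(NULL, NULL, "tA"))
  soft <- structure(list(pv = pv, tract_names = "tA", pixel_size = 50,
                         region = "cervical"), class = "soft_atlas")
  om <- overlap_matrix(make_parc(lab), soft)
  expect_equal(unclass(om)[1, 1], 2.0)
})

test_that("overlap mass equals the jointly covered pixel count", {
  truth <- build_reference_atlas(tiny_spec(), "T3")
  set.seed(1)
  lab <- truth$labels
  lab[lab > 0] <- sample(1:5, sum(lab > 0), replace = TRUE)
  lab[lab == 0] <- NA
  om <- overlap_matrix(make_parc(lab), truth)
  expect_equal(sum(om), sum(!is.na(lab) & truth$labels > 0))
})

test_that("cluster colors follow the linear intensity rule", {
  # two clusters overlapping one tract with fractions 0.75 / 0.25
  M <- matrix(c(75, 25), 2, 1, dimnames = list(cluster = c("1", "2"), tract = "FC"))
  cols <- match_and_color(structure(M, class = c("overlap_matrix", "matrix")))
  expect_equal(cols$intensity, c(1, 0.2 + 0.8 * (0.25 / 0.75)), tolerance = 1e-9)
  expect_identical(cols$tract, c("FC", "FC"))
  # one cluster fully inside one tract: full intensity
  M2 <- matrix(c(40, 0, 0, 30), 2, 2,
               dimnames = list(cluster = c("1", "2"), tract = c("FG", "dCST")))
  cols2 <- match_and_color(structure(M2, class = c("overlap_matrix", "matrix")))
  expect_equal(cols2$intensity, c(1, 1))
  expect_true(all(cols2$intensity >= 0.2 & cols2$intensity <= 1))
  expect_error(match_and_color(structure(M * 0, class = c("overlap_matrix", "matrix"))),
               "all-zero")
})

test_that("identity parcellation takes every intensity to 1", {
  truth <- build_reference_atlas(tiny_spec(), "C2")
  om <- overlap_matrix(make_parc(ifelse(truth$labels > 0, truth$labels, NA)),
                       truth)
  cols <- match_and_color(om)
  expect_true(all(cols$intensity == 1))
  expect_identical(cols$tract, truth$tract_names)
})

test_that("ARI is 1 for identical partitions and relabelings, ~0 for noise", {
  truth <- build_reference_atlas(tiny_spec(), "C4")
  lab <- ifelse(truth$labels > 0, truth$labels, NA)
  expect_equal(ari(make_parc(lab), truth), 1)
  perm <- c(9L, 1:8)
  relab <- matrix(perm[lab], nrow(lab), ncol(lab))
  expect_equal(ari(make_parc(relab), truth), 1)
  set.seed(0)
  n <- sum(truth$labels > 0)
  aris <- vapply(1:20, function(i) {
    rnd <- lab
    rnd[!is.na(rnd)] <- sample(1:8, n, replace = TRUE)
    truth2 <- truth
    truth2$labels[truth2$labels > 0] <- sample(1:8, n, replace = TRUE)
    ari(make_parc(rnd), truth2)
  }, numeric(1))
  expect_true(all(abs(aris) < 0.05))
})

test_that("per-tract recall picks the best-matching cluster fraction", {
  M <- matrix(c(30, 10, 20, 60), 2, 2,
              dimnames = list(cluster = c("1", "2"), tract = c("FG", "PSdc")))
  r <- tract_recall(structure(M, class = c("overlap_matrix", "matrix")))
  expect_equal(unname(r), c(30 / 40, 60 / 80))
})

test_that("hemisection rendering is deterministic and shows both halves", {
  truth <- build_reference_atlas(tiny_spec(), "C4")
  lab <- ifelse(truth$labels > 0, truth$labels, NA)
  parc <- make_parc(lab)
  om <- overlap_matrix(parc, truth)
  cols <- match_and_color(om)
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  render_hemisection(parc, truth, cols, f1)
  render_hemisection(parc, truth, cols, f2)
  expect_true(file.exists(f1))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # identical symmetric parcellation and atlas: the image mirrors itself
  img <- png::readPNG(f1)
  # (tolerance covers 8-bit rounding in the hue/value round trip)
  expect_equal(img, img[, dim(img)[2]:1, , drop = FALSE], tolerance = 0.005)
  unlink(c(f1, f2))
})
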