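test_that("euclidean distances cover scalar, vector and degenerate cases", {
  d <- euclidean_distances(c(a = 0.4, b = 0.6))
  expect_equal(d["a", "b"], 0.2, tolerance = 1e-12)
  expect_equal(diag(d), c(a = 0, b = 0))

  d2 <- euclidean_distances(list(a = c(0, 0), b = c(3, 4)))
  expect_equal(d2["a", "b"], 5)

  d3 <- euclidean_distances(list(a = c(1, 2), b = c(1, 2)))
  expect_equal(d3["a", "b"], 0)

  expect_error(euclidean_distances(list(a = 1, b = c(1, 2))), "ragged")
})

test_that("upgma reproduces the hand-computed three-leaf example", {
  d <- matrix(c(0, 2, 8,
                2, 0, 6,
                8, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dd <- upgma(d)
  expect_equal(dd$height, c(2, 7))     # (8 + 6) / 2 = 7
  expect_equal(dd$size, c(2L, 3L))
  expect_equal(dd$merge[1, ], c(-1L, -2L))

  coph <- cophenetic_distances(dd)
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 7)
  expect_equal(coph["B", "C"], 7)
})

test_that("equal pairwise distances fuse at the same height", {
  d <- matrix(3, 4, 4); diag(d) <- 0
  dimnames(d) <- list(letters[1:4], letters[1:4])
  dd <- upgma(d)
  expect_equal(dd$height, rep(3, 3))
})

test_that("upgma rejects invalid inputs", {
  expect_error(upgma(matrix(0, 1, 1)), "at least 2")
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(upgma(m), "symmetric")
  m2 <- matrix(c(0, NA, NA, 0), 2, 2)
  expect_error(upgma(m2), "NA")
})

test_that("upgma heights match the cross-pair-mean oracle and hclust", {
  set.seed(1234)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    d <- if (i %% 2 == 0) random_euclidean_dm(n) else random_nonmetric_dm(n)
    dd <- upgma(d)
    expect_equal(sort(dd$height), sort(naive_upgma_heights(d)),
                 tolerance = 1e-9)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(sort(dd$height), sort(hc$height), tolerance = 1e-9)
    ## monotone fusion heights
    expect_true(all(diff(dd$height) >= -1e-12))
  }
})

test_that("cophenetic distances are ultrametric and agree with stats", {
  set.seed(55)
  for (i in 1:10) {
    d <- random_nonmetric_dm(sample(4:10, 1))
    dd <- upgma(d)
    coph <- cophenetic_distances(dd)
    ref <- as.matrix(stats::cophenetic(as.hclust(dd)))
    expect_equal(coph[rownames(ref), colnames(ref)], ref, tolerance = 1e-12)
    n <- nrow(coph)
    for (a in 1:n) for (b in 1:n) for (c in 1:n) {
      expect_true(coph[a, b] <= max(coph[a, c], coph[b, c]) + 1e-12)
    }
  }
})

test_that("mojena cut reproduces the hand-computed threshold and group count", {
  dd <- chain_dendrogram(c(1.0, 1.1, 1.2, 5.0))
  cut <- mojena_cut(dd, k = 1.25)
  expect_equal(cut$alpha_mean, 2.075)
  expect_equal(cut$alpha_sd, sqrt(11.4275 / 3), tolerance = 1e-12)
  expect_equal(cut$theta, 2.075 + 1.25 * sqrt(11.4275 / 3),
               tolerance = 1e-12)
  expect_equal(cut$cut_index, 4L)
  expect_equal(cut$n_groups, 2L)
  ## s5 joins last, so it is alone; labels follow leaf order
  grp <- stats::setNames(cut$assignment$group, cut$assignment$sample_id)
  expect_equal(unname(grp["s5"]), "G1")
  expect_equal(unname(grp[c("s1", "s2", "s3", "s4")]), rep("G2", 4))
})

test_that("zero height variance yields one group under strict exceedance", {
  d <- matrix(3, 4, 4); diag(d) <- 0
  dimnames(d) <- list(letters[1:4], letters[1:4])
  cut <- mojena_cut(upgma(d))
  expect_equal(cut$n_groups, 1L)
  expect_true(is.na(cut$cut_index))
  expect_equal(unique(cut$assignment$group), "G1")

  ## two leaves: the single height has sd 0, strict > fails
  cut2 <- mojena_cut(upgma(euclidean_distances(c(a = 0, b = 1))))
  expect_equal(cut2$alpha_sd, 0)
  expect_equal(cut2$n_groups, 1L)
})

test_that("well-separated 1-D clusters are recovered", {
  set.seed(321)
  centers <- c(0, 50, 100)
  x <- stats::setNames(rnorm(15, rep(centers, each = 5), 0.5),
                       paste0("s", 1:15))
  cut <- mojena_cut(upgma(euclidean_distances(x)))
  expect_equal(cut$n_groups, 3L)
  truth <- rep(paste0("c", 1:3), each = 5)
  cross <- table(truth[as.integer(sub("s", "", cut$assignment$sample_id))],
                 cut$assignment$group)
  ## each planted cluster maps onto exactly one recovered group
  expect_equal(sum(cross > 0), 3)
  expect_true(all(apply(cross, 1, max) == 5))
})

test_that("label permutation permutes the assignment but not the partition", {
  set.seed(77)
  x <- stats::setNames(c(rnorm(4, 0, .1), rnorm(4, 10, .1)), letters[1:8])
  cut1 <- mojena_cut(upgma(euclidean_distances(x)))
  perm <- sample(names(x))
  cut2 <- mojena_cut(upgma(euclidean_distances(x[perm])))
  expect_equal(cut2$n_groups, cut1$n_groups)
  expect_equal(sort(as.integer(table(cut2$assignment$group))),
               sort(as.integer(table(cut1$assignment$group))))
  ## same samples co-clustered regardless of labelling
  g1 <- stats::setNames(cut1$assignment$group, cut1$assignment$sample_id)
  g2 <- stats::setNames(cut2$assignment$group, cut2$assignment$sample_id)
  for (a in names(x)) for (b in names(x)) {
    expect_equal(g1[a] == g1[b], g2[a] == g2[b], ignore_attr = TRUE)
  }
})

test_that("newick export is ultrametric, parseable and halves fusion heights", {
  two <- upgma(euclidean_distances(c(A = 0, B = 2)))
  expect_equal(to_newick(two), "(A:1,B:1);")

  d <- matrix(c(0, 2, 8,
                2, 0, 6,
                8, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dd <- upgma(d)
  phy <- ape::read.tree(text = to_newick(dd))
  expect_setequal(phy$tip.label, c("A", "B", "C"))
  pd <- ape::cophenetic.phylo(phy)
  coph <- cophenetic_distances(dd)
  expect_equal(pd[rownames(coph), colnames(coph)], coph, tolerance = 1e-9)

  ## round-trip preserves topology on a larger random tree
  set.seed(8)
  dd2 <- upgma(random_euclidean_dm(9))
  phy2 <- ape::read.tree(text = to_newick(dd2))
  pd2 <- ape::cophenetic.phylo(phy2)
  coph2 <- cophenetic_distances(dd2)
  expect_equal(pd2[rownames(coph2), colnames(coph2)], coph2,
               tolerance = 1e-6)
})
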