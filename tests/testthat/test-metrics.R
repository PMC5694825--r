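test_that("clustering coefficient matches closed forms on canonical graphs", {
  k4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(unname(clustering_coefficient(k4)), rep(1, 4))
  star <- adjacency_from_edges(6, cbind(1, 2:6))
  expect_equal(unname(clustering_coefficient(star)), rep(0, 6))
})

test_that("clustering and betweenness equal brute-force enumeration", {
  for (seed in 1:10) {
    n <- sample(6:12, 1)
    a <- random_adjacency(n, 0.4, seed * 13)
    expect_equal(unname(clustering_coefficient(a)), oracle_clustering(a))
    expect_equal(unname(betweenness_centrality(a)), oracle_betweenness(a),
                 tolerance = 1e-12)
  }
})

test_that("betweenness matches hand counts on path and star", {
  path <- adjacency_from_edges(5, cbind(1:4, 2:5))
  expect_equal(unname(betweenness_centrality(path)), c(0, 3, 4, 3, 0))
  star <- adjacency_from_edges(5, cbind(1, 2:5))
  expect_equal(unname(betweenness_centrality(star))[1], 6)
})

test_that("module detection separates weakly joined triangles", {
  two_tri <- adjacency_from_edges(6, rbind(c(1, 2), c(1, 3), c(2, 3),
                                           c(4, 5), c(4, 6), c(5, 6),
                                           c(3, 4)))
  part <- detect_modules(two_tri)
  expect_equal(part$n_modules, 2)
  expect_equal(length(unique(part$membership[1:3])), 1)
  expect_equal(length(unique(part$membership[4:6])), 1)
  expect_equal(part$modularity, 2 * (3 / 7 - (7 / 14)^2))
})

test_that("modularity Q matches closed forms", {
  two_tri_disc <- adjacency_from_edges(6, rbind(c(1, 2), c(1, 3), c(2, 3),
                                                c(4, 5), c(4, 6), c(5, 6)))
  expect_equal(modularity_q(two_tri_disc, c(1, 1, 1, 2, 2, 2)), 0.5)
  k5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(modularity_q(k5, rep(1, 5)), 0)
  part <- detect_modules(two_tri_disc)
  expect_equal(part$modularity, 0.5)
})

test_that("detected partition never scores below the one-module partition", {
  for (seed in c(2, 4, 8)) {
    a <- random_adjacency(10, 0.35, seed)
    net <- tryCatch(binarize_min_density(a), error = function(e) NULL)
    if (is.null(net)) next
    part <- detect_modules(net)
    expect_gte(part$modularity, 0)
  }
})

test_that("participation coefficient matches its closed forms", {
  # all neighbors in own module -> 0
  tri <- adjacency_from_edges(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
  expect_equal(unname(participation_coefficient(tri, c(1, 1, 1))),
               rep(0, 3))
  # degree 4 split 2/2 across two modules -> 0.5
  star4 <- adjacency_from_edges(5, cbind(1, 2:5))
  expect_equal(unname(participation_coefficient(star4,
                                                c(1, 1, 1, 2, 2)))[1], 0.5)
  # degree 3 split 1/1/1 across three modules -> 2/3
  star3 <- adjacency_from_edges(4, cbind(1, 2:4))
  expect_equal(unname(participation_coefficient(star3,
                                                c(1, 1, 2, 3)))[1], 2 / 3)
})

test_that("participation coefficient respects the 1 - 1/M upper bound", {
  for (seed in 1:5) {
    a <- random_adjacency(12, 0.5, seed * 7)
    memb <- withr::with_seed(seed, sample(1:3, 12, replace = TRUE))
    p <- participation_coefficient(a, memb)
    m <- length(unique(memb))
    expect_true(all(p <= 1 - 1 / m + 1e-12))
    expect_true(all(p >= 0))
  }
})

test_that("metrics are equivariant under region relabeling", {
  a <- random_adjacency(10, 0.4, 31)
  rownames(a) <- colnames(a) <- paste0("R", 1:10)
  perm <- withr::with_seed(1, sample(10))
  ap <- a[perm, perm]
  expect_equal(unname(clustering_coefficient(ap)),
               unname(clustering_coefficient(a))[perm])
  expect_equal(unname(betweenness_centrality(ap)),
               unname(betweenness_centrality(a))[perm])
})

test_that("group-mean metrics average subjects and use a group partition", {
  mats <- lapply(c(5, 6, 7), function(s) random_weights(16, s))
  names(mats) <- paste0("s", 1:3)
  nets <- binarize_cohort(mats)
  gm <- group_mean_metrics(nets)
  manual_deg <- rowMeans(vapply(nets, function(nw) rowSums(nw$adjacency),
                                numeric(16)))
  expect_equal(gm$metrics$degree, unname(manual_deg))
  expect_true(all(gm$metrics$participation >= 0))
  expect_s3_class(gm$partition, "cc_partition")
})
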