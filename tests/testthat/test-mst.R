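test_that("the triangle MST keeps the two lightest edges", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.1
  w[2, 3] <- w[3, 2] <- 0.2
  w[1, 3] <- w[3, 1] <- 0.3
  t <- prim_mst(w)
  expect_equal(nrow(t$edges), 2)
  expect_equal(t$total_weight, 0.3, tolerance = 1e-12)
  expect_equal(t$edges[, c("i", "j")], data.frame(i = c(1L, 2L), j = c(2L, 3L)))
})

test_that("Prim matches the exhaustive minimum over all spanning trees", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    w <- random_adjacency(n) + 0.01
    expect_equal(prim_mst(w)$total_weight, exhaustive_mst_weight(w),
                 tolerance = 1e-12)
  }
})

test_that("Prim agrees with igraph's MST and is deterministic under ties", {
  set.seed(8)
  w <- random_adjacency(60) + 0.01
  t1 <- prim_mst(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  t2 <- igraph::mst(g, weights = igraph::E(g)$weight)
  expect_equal(t1$total_weight, sum(igraph::E(t2)$weight), tolerance = 1e-10)
  expect_equal(nrow(t1$edges), 59)
  # all-equal weights: repeated runs give the identical tree
  weq <- matrix(1, 10, 10); diag(weq) <- 0
  expect_identical(prim_mst(weq)$edges, prim_mst(weq)$edges)
})

test_that("tree betweenness equals pair-path enumeration", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    edges <- random_tree_edges(n)
    t <- mst_tree(edges, n)
    counts <- numeric(n)
    for (s in 1:(n - 1)) for (d in (s + 1):n) {
      path <- bfs_path(edges, n, s, d)
      interior <- setdiff(path, c(s, d))
      counts[interior] <- counts[interior] + 1
    }
    expect_equal(t$betweenness_raw, counts)
    # and the fast igraph algorithm concurs
    g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                       vertices = data.frame(name = 1:n))
    expect_equal(t$betweenness_raw,
                 unname(igraph::betweenness(g, weights = NA)))
  }
})

test_that("star and path trees obey the closed-form metrics", {
  for (n in c(5, 23, 116)) {
    ms <- mst_metrics(star_tree(n))
    expect_equal(ms$Lf, 1)
    expect_equal(ms$d, 2)
    expect_equal(ms$k_max, n - 1)
    expect_equal(ms$K, n / 2)
    expect_equal(ms$B_max, 1) # centre lies on every pair path
    expect_equal(ms$Ecc, (2 * (n - 1) + 1) / n)
    if (n >= 4) expect_lt(ms$Ass, 0)
    mp <- mst_metrics(path_tree(n))
    expect_equal(mp$Lf, 2 / (n - 1))
    expect_equal(mp$d, n - 1)
    expect_equal(mp$k_max, 2)
  }
  expect_error(mst_metrics(mst_tree(data.frame(i = 1, j = 2, weight = 1), 2)),
               "fewer than 3")
})

test_that("assortativity equals the edge-endpoint degree correlation", {
  set.seed(10)
  edges <- random_tree_edges(12)
  t <- mst_tree(edges, 12)
  deg <- t$degree
  x <- c(deg[edges$i], deg[edges$j])
  y <- c(deg[edges$j], deg[edges$i])
  expect_equal(mst_metrics(t)$Ass, cor(x, y), tolerance = 1e-12)
  expect_true(abs(mst_metrics(t)$Ass) <= 1)
})

test_that("the extreme value index is recovered from simulated weights", {
  set.seed(11)
  x <- runif(2000)^(1 / 0.5) # exact CDF F(x) = x^0.5
  fit <- fit_extreme_value_index(x)
  expect_lt(abs(fit$alpha_hat - 0.5), 0.05)
  expect_gt(fit$r_squared, 0.98)
  expect_true(fit$strong_disorder)
  # uniform weights sit at the alpha = 1 boundary
  fit1 <- fit_extreme_value_index(runif(2000))
  expect_lt(abs(fit1$alpha_hat - 1), 0.05)
  # saturated/degenerate input is rejected
  expect_error(fit_extreme_value_index(rep(1, 100)), "degenerate")
})

test_that("survival ratio counts shared unordered edges", {
  t1 <- star_tree(6)
  expect_equal(survival_ratio(t1, t1), 1)
  pathA <- mst_tree(data.frame(i = 1:5, j = 2:6, weight = 1), 6)
  pathB <- mst_tree(data.frame(i = c(2, 1, 1, 3, 3),
                               j = c(4, 4, 5, 5, 6), weight = 1), 6)
  expect_equal(survival_ratio(pathA, pathB), 0)
  expect_error(survival_ratio(t1, star_tree(7)), "same node set")
})
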