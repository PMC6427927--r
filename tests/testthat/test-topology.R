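test_that("group averaging is the element-wise mean", {
  set.seed(12)
  m1 <- fake_wavelet_cor(random_adjacency(5) + diag(5))
  expect_equal(group_average(list(m1))$r, m1$r)
  m2 <- fake_wavelet_cor(-m1$r)
  expect_equal(group_average(list(m1, m2))$r, matrix(0, 5, 5))
  mats <- lapply(1:5, function(k) fake_wavelet_cor(random_adjacency(6) + diag(6)))
  acc <- matrix(0, 6, 6)
  for (m in mats) acc <- acc + m$r
  expect_equal(group_average(mats)$r, acc / 5, tolerance = 1e-15)
  expect_error(group_average(list(m1, fake_wavelet_cor(diag(3)))), "dimensions")
})

test_that("superhighways follow the hand-traced K<2 percolation on a two-tier toy", {
  # 8 nodes: a strong core star on 1..5 (spokes (1,k) with distinct small
  # weights), medium core edges among 2..5 (0.2), weak tail edges (0.9)
  # touching 6,7,8. Removing edges from heaviest down, K stays >= 2 through
  # the weak and medium tiers (star on 1..5 gives K = 2.5), then drops:
  # after deleting spokes (1,5) (K = 2) and (1,4) (K = 1.5 < 2) the process
  # stops with component {1,2,3}, so the superhighways are the MST spokes
  # (1,2) and (1,3).
  w <- matrix(0.9, 8, 8)
  w[2:5, 2:5] <- 0.2
  w[1, 2:5] <- w[2:5, 1] <- c(0.01, 0.02, 0.03, 0.04)
  diag(w) <- 0
  tree <- prim_mst(w)
  expect_equal(tree$edges$i, rep(1L, 7)) # MST is the star at node 1
  g <- structure(list(w = w), class = "fc_tom_graph")
  shw <- extract_superhighways(g, tree)
  expect_equal(shw$K_stop, 1.5)
  expect_setequal(shw$component_nodes, 1:3)
  expect_equal(shw$edges[, c("i", "j")],
               data.frame(i = c(1L, 1L), j = c(2L, 3L)))
  expect_equal(sum(shw$shw_flag), 2)
})

test_that("star-structured weights concentrate superhighways on the hub", {
  w <- matrix(0.9, 9, 9)
  w[1, ] <- w[, 1] <- 0.05 # strong spokes on node 1
  diag(w) <- 0
  tree <- prim_mst(w)
  shw <- extract_superhighways(structure(list(w = w), class = "fc_tom_graph"),
                               tree)
  expect_true(1 %in% shw$component_nodes)
  expect_true(all(shw$edges$i == 1)) # all SHW edges are spokes
})

test_that("superhighway extraction is equivariant under node relabelling", {
  set.seed(13)
  w <- random_adjacency(12) + 0.01
  tree <- prim_mst(w)
  res <- extract_superhighways(structure(list(w = w), class = "fc_tom_graph"),
                               tree)
  perm <- sample(12)
  wp <- w[perm, perm] # node v becomes position match(v, perm)
  inv <- order(perm)
  treep <- prim_mst(wp)
  resp <- extract_superhighways(structure(list(w = wp), class = "fc_tom_graph"),
                                treep)
  expect_setequal(perm[resp$component_nodes], res$component_nodes)
  expect_equal(resp$K_stop, res$K_stop)
  expect_equal(resp$n_removed, res$n_removed)
})

test_that("identical trees produce a null betweenness-difference table", {
  t <- star_tree(10)
  bd <- betweenness_differences(t, t)
  expect_true(all(bd$table$diff == 0))
  expect_true(is.na(bd$b))
  expect_true(all(bd$table$label == "neutral"))
})

test_that("star-vs-path differences follow the closed forms", {
  n <- 12
  st <- star_tree(n)
  pt <- path_tree(n)
  bd <- betweenness_differences(st, pt)
  # hub of the star is node 1; on the path node 1 is an end leaf (B = 0)
  expect_equal(bd$table$diff[1], choose(n - 1, 2))
  # path node k (1-based) lies on (k-1)(n-k) pair paths
  k <- 5
  expect_equal(bd$table$b_control[k], (k - 1) * (n - k))
  expect_equal(bd$b, median(abs(bd$table$diff[bd$table$diff != 0])))
  expect_true(all(bd$table$label[bd$table$diff > bd$b] == "gain"))
})

test_that("geodesic clustering separates two bridged stars", {
  # stars at nodes 1 (leaves 2:5) and 6 (leaves 7:9), bridged 1-6
  edges <- data.frame(i = c(1, 1, 1, 1, 1, 6, 6, 6),
                      j = c(2, 3, 4, 5, 6, 7, 8, 9), weight = 1)
  t <- mst_tree(edges, 9)
  cl <- geodesic_cluster(t, cut_height = 0.2)
  expect_equal(length(cl$labels), 9)
  expect_true(all(cl$labels[c(2:5)] == cl$labels[2]))
  expect_true(all(cl$labels[c(7:9)] == cl$labels[7]))
  expect_true(cl$labels[2] != cl$labels[7])
  # sibling leaves have identical distance profiles: d_S = 0, merged first
  expect_equal(cl$d_s[2, 3], 0)
  expect_equal(cl$hclust$height[1], 0)
  # a cut above the root yields a single cluster
  cl1 <- geodesic_cluster(t, cut_height = max(cl$hclust$height) + 1)
  expect_equal(cl1$n_clusters, 1)
})

test_that("cluster labels are permutation-equivariant", {
  set.seed(14)
  edges <- random_tree_edges(15)
  t <- mst_tree(edges, 15)
  cl <- geodesic_cluster(t, cut_height = 0.2)
  perm <- sample(15)
  pedges <- data.frame(i = pmin(match(edges$i, perm), match(edges$j, perm)),
                       j = pmax(match(edges$i, perm), match(edges$j, perm)),
                       weight = 1)
  clp <- geodesic_cluster(mst_tree(pedges, 15), cut_height = 0.2)
  # same partition after mapping back
  a <- cl$labels
  b <- clp$labels[match(seq_len(15), perm)]
  expect_equal(length(unique(a)), length(unique(b)))
  expect_true(all(outer(a, a, "==") == outer(b, b, "==")))
})

test_that("hubs are the nodes with degree above the threshold", {
  expect_identical(hub_nodes(path_tree(20)), integer(0))
  expect_identical(hub_nodes(star_tree(10)), 1L)
  expect_identical(hub_nodes(star_tree(10), threshold = 9), integer(0))
})
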