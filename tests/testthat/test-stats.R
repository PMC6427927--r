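make_measure_table <- function(n_per_group = 20, seed = 1, shift = 0) {
  set.seed(seed)
  n <- 2 * n_per_group
  data.frame(subject_id = sprintf("s%02d", 1:n),
             group = rep(c("control", "case"), each = n_per_group),
             age = rnorm(n, 65, 7),
             sex = sample(c("M", "F"), n, replace = TRUE),
             strength = rnorm(n) + shift * rep(c(0, 1), each = n_per_group),
             diversity = rnorm(n))
}

test_that("residualisation removes exact covariate effects", {
  tbl <- make_measure_table(seed = 2)
  tbl$strength <- 2 * tbl$age
  out <- residualize(tbl, measures = c("strength", "diversity"))
  expect_lt(max(abs(out$strength)), 1e-9)
  expect_lt(abs(mean(out$diversity)), 1e-12) # residuals are mean-zero
})

test_that("a single-sex design skips correction with a warning", {
  tbl <- make_measure_table(seed = 3)
  tbl$sex <- "M"
  expect_warning(out <- residualize(tbl, measures = "strength"), "skipped")
  expect_equal(out$strength, tbl$strength)
})

test_that("a simulated age slope is recovered by the correction model", {
  set.seed(4)
  hits <- 0
  for (rep in 1:200) {
    age <- rnorm(60, 65, 7)
    sex <- factor(sample(c("M", "F"), 60, replace = TRUE))
    y <- 0.3 * age + rnorm(60)
    fit <- lm(y ~ age * sex)
    ci <- confint(fit)["age", ]
    if (ci[1] <= 0.3 && 0.3 <= ci[2]) hits <- hits + 1
  }
  expect_gt(hits / 200, 0.9) # nominal 95% coverage
})

test_that("rank tests detect strong shifts and ignore null ones", {
  null_tbl <- make_measure_table(n_per_group = 40, seed = 5)
  res0 <- rank_tests(null_tbl, measures = c("strength", "diversity"))
  expect_true(all(res0$p_adj >= res0$p))
  shifted <- make_measure_table(n_per_group = 40, seed = 6, shift = 3)
  res1 <- rank_tests(shifted, measures = c("strength", "diversity"))
  expect_lt(res1$p_adj[res1$measure == "strength"], 0.05)
  expect_equal(res1$direction[res1$measure == "strength"], "case>control")
  const <- make_measure_table(seed = 7)
  const$strength <- 5
  resc <- rank_tests(const, measures = c("strength", "diversity"))
  expect_equal(resc$p[resc$measure == "strength"], 1)
  expect_true(resc$constant[resc$measure == "strength"])
})

test_that("location shifts of 3 SD are detected in nearly all replicates", {
  set.seed(8)
  detected <- vapply(1:60, function(rep) {
    tbl <- make_measure_table(n_per_group = 40, seed = 1000 + rep, shift = 3)
    res <- rank_tests(tbl, measures = c("strength", "diversity"))
    res$p_adj[res$measure == "strength"] < 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.99)
})

test_that("BH adjustment matches the hand step-up rule", {
  # step-up: p_(k) * m / k, cumulative minimum from the largest rank down
  hand_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  set.seed(9)
  tbl <- make_measure_table(n_per_group = 15, seed = 10)
  tbl$k_max <- rnorm(30); tbl$Lf <- rnorm(30)
  res <- rank_tests(tbl, measures = c("strength", "diversity", "k_max", "Lf"))
  expect_equal(res$p_adj, hand_bh(res$p), tolerance = 1e-12)
  # and on a fixed vector
  expect_equal(hand_bh(c(0.001, 0.02, 0.8)),
               p.adjust(c(0.001, 0.02, 0.8), "BH"), tolerance = 1e-12)
})

test_that("the permutation test is exact in its degenerate limits", {
  x <- c(1, 2, 3, 4)
  expect_equal(permutation_test(x, x, B = 500, seed = 1)$p, 1)
  set.seed(2)
  a <- rnorm(20); b <- rnorm(20) + 5 # 5 SD shift
  res <- permutation_test(a + 5, a - 5, B = 1000, seed = 3)
  expect_equal(res$p, 1 / 1001)
  # label-swap symmetry of the two-sided statistic
  r1 <- permutation_test(a, b, B = 2000, seed = 4)
  r2 <- permutation_test(b, a, B = 2000, seed = 4)
  expect_equal(r1$observed, r2$observed)
})

test_that("permutation p-values are near-uniform under the null", {
  set.seed(15)
  ps <- vapply(1:300, function(rep) {
    x <- rnorm(15); y <- rnorm(15)
    permutation_test(x, y, B = 199)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a null cohort yields no significant adjusted measures in most seeds", {
  clean <- vapply(1:5, function(k) {
    co <- generate_cohort(small_spec(3000 + k, n_per_group = 8,
                                     case_attenuation = 1))
    tbl <- cohort_measures(co)
    res <- rank_tests(residualize(tbl))
    !any(res$significant)
  }, logical(1))
  expect_gte(sum(clean), 4)
})
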