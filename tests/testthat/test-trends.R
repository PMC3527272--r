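test_that("moving average matches brute-force window enumeration", {
  crv <- moving_average_trend(1:10, as.numeric(1:10), window = 3)
  bf <- brute_moving_average(1:10, as.numeric(1:10), 3)
  expect_equal(crv$n_windows, 8L)
  expect_equal(crv$x_points, bf$x)
  expect_equal(crv$y_points, bf$y)
  set.seed(99)
  for (i in 1:25) {
    n <- sample(20:80, 1); w <- sample(2:10, 1)
    x <- rnorm(n); y <- rnorm(n)
    crv <- moving_average_trend(x, y, window = w)
    bf <- brute_moving_average(x, y, w)
    expect_equal(crv$x_points, bf$x)
    expect_equal(crv$y_points, bf$y)
  }
})

test_that("moving average trivial shapes and input-order invariance hold", {
  expect_equal(moving_average_trend(rnorm(30), rep(2.5, 30), 5)$y_points,
               rep(2.5, 26))
  one <- moving_average_trend(1:6, c(4, 2, 0, 6, 1, 5), window = 6)
  expect_equal(one$x_points, 3.5)
  expect_equal(one$y_points, 3)
  set.seed(1)
  x <- rnorm(50); y <- rnorm(50); ids <- sprintf("g%02d", 1:50)
  p <- sample(50)
  expect_equal(moving_average_trend(x, y, 7, ids),
               moving_average_trend(x[p], y[p], 7, ids[p]))
  expect_error(moving_average_trend(1:5, 1:5, window = 6), "smaller window")
})

test_that("permutation Pearson reports exact correlations and sane p", {
  x <- 1:20
  expect_equal(pearson_with_permutation(x, 2 * x + 1, n_perm = 99)$r, 1)
  res <- pearson_with_permutation(x, -x, n_perm = 999, seed = 4)
  expect_equal(res$r, -1)
  expect_equal(res$p, 1 / 1000)   # add-one minimum
  expect_error(pearson_with_permutation(x, rep(1, 20)), "variance")
})

test_that("exact permutation p equals independent enumeration at n = 5", {
  set.seed(7)
  x <- rnorm(5); y <- rnorm(5)
  res <- pearson_with_permutation(x, y, exact = TRUE)
  perms <- oracle_permutations(5)
  rp <- apply(perms, 1, function(p) cor(x, y[p]))
  expect_equal(res$p, mean(abs(rp) >= abs(cor(x, y)) - 1e-12))
  expect_equal(nrow(perms), 120L)
})

test_that("rank-sum test is exact for small groups and near-exact beyond", {
  res <- rank_sum_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)         # 2 of 20 arrangements as extreme
  same <- rank_sum_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  set.seed(12)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6)
    exact <- rank_sum_compare(a, b, method = "exact")
    approx <- rank_sum_compare(a, b, method = "normal")
    # 0.016 bounds the approximation error at nA = nB = 6: the maximum of
    # |p_exact - p_normal| over all attainable U is 0.0155 by enumeration
    expect_lt(abs(exact$p - approx$p), 0.016)
    # independent oracle: base R exact Wilcoxon on untied data
    expect_equal(exact$p, wilcox.test(a, b, exact = TRUE)$p.value)
  }
  expect_error(rank_sum_compare(numeric(0), 1), "empty")
})

test_that("large-sample rank-sum agrees with the base implementation", {
  set.seed(3)
  a <- rnorm(40); b <- rnorm(35, 0.5)
  mine <- rank_sum_compare(a, b)
  expect_equal(mine$method, "normal")
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mine$U, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
})

test_that("monotonicity is judged across abutting windows", {
  y <- seq(10, 1, length.out = 100) + rnorm(100, 0, 1e-3)
  crv <- moving_average_trend(1:100, y, window = 10)
  expect_equal(trend_monotonicity(crv), 1)
  up <- moving_average_trend(1:100, seq(1, 10, length.out = 100), 10)
  expect_equal(trend_monotonicity(up), 0)
})

test_that("quartile stratification splits evenly and recovers planted trends", {
  qs <- quartile_stratified_trend(rep(1, 40), 1:40, as.numeric(40:1),
                                  window = 10,
                                  ids = sprintf("g%02d", 1:40))
  expect_equal(vapply(qs, function(c) c$n_windows, integer(1)),
               c(quartile_1 = 1L, quartile_2 = 1L, quartile_3 = 1L,
                 quartile_4 = 1L))
  # window = quartile size: one point per quartile, equal to quartile means
  expect_equal(qs$quartile_1$y_points,
               mean(40:31) + 0)  # quartile 1 = first ids under full ties
  # planted: plasticity falls with SLR in every abundance quartile
  cfg <- small_config(seed = 21, n_genes = 1600, frac_affected = 0.5,
                      up_share = 0, noise_sd = 0.05)
  ann <- simulate_genome(cfg, build_track = FALSE)$annotation
  em <- simulate_arrays(cfg, ann)
  slr <- compute_slr(fit_spikein_scale(em), "top1top2", "wt")
  pl <- plasticity(simulate_compendium(cfg, ann))
  qs <- quartile_stratified_trend(ann$abundance_wt, slr$slr,
                                  unname(pl[ann$gene_id]), window = 100,
                                  ids = ann$gene_id)
  slopes <- vapply(qs, function(crv)
    unname(coef(lm(crv$y_points ~ crv$x_points))[2]), numeric(1))
  expect_true(all(slopes < 0))
  expect_error(quartile_stratified_trend(1:30, 1:30, 1:30, window = 10),
               "4 \\* window")
})
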