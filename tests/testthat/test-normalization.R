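make_em <- function(intensities, n_spike = 2, strains = c("wt", "mut"),
                    reps = ncol(intensities) / 2) {
  n <- nrow(intensities)
  expression_matrix(
    intensities,
    gene_ids = c(sprintf("g%03d", seq_len(n - n_spike)),
                 sprintf("spike_%02d", seq_len(n_spike))),
    spikein = c(rep(FALSE, n - n_spike), rep(TRUE, n_spike)),
    arrays = data.frame(strain = rep(strains, each = reps),
                        replicate = rep(seq_len(reps), length(strains))))
}

test_that("identical arrays get unit scale factors", {
  m <- matrix(rep(c(5, 10, 2, 7), 4), ncol = 4)
  em <- make_em(m)
  res <- fit_spikein_scale(em)
  expect_equal(unname(res$scale_factors), rep(1, 4))
  expect_equal(res$normalized$intensities, em$intensities)
})

test_that("normalization is equivariant to per-array rescaling", {
  # scaling one array by c moves the geometric-mean pseudo-array by c^(1/A):
  # the normalized matrix is reproduced up to exactly that global constant,
  # the scaled array's relative factor halves, and every downstream ratio
  # statistic is bitwise invariant
  set.seed(42)
  m <- matrix(rexp(40, 0.1), ncol = 4)
  em <- make_em(m, n_spike = 3)
  base <- fit_spikein_scale(em)
  m2 <- m; m2[, 2] <- m2[, 2] * 2   # all rows of one array, spike-ins too
  scaled <- fit_spikein_scale(make_em(m2, n_spike = 3))
  expect_equal(scaled$normalized$intensities,
               base$normalized$intensities * 2^(1 / 4), tolerance = 1e-12)
  rel <- scaled$scale_factors / base$scale_factors
  expect_equal(unname(rel[2] / rel[1]), 0.5, tolerance = 1e-12)
  # tiny floor: these toy intensities straddle the default detection floor,
  # which would otherwise interact with the global c^(1/A) constant
  expect_equal(compute_slr(scaled, "mut", "wt", floor = 1e-9)$slr,
               compute_slr(base, "mut", "wt", floor = 1e-9)$slr,
               tolerance = 1e-12)
  expect_equal(global_mrna_level(scaled, "mut", "wt", floor = 1e-9)$level,
               global_mrna_level(base, "mut", "wt", floor = 1e-9)$level,
               tolerance = 1e-12)
})

test_that("planted per-array distortions are recovered exactly", {
  factors <- c(1.0, 0.8, 1.25)   # geometric mean 1
  cfg <- small_config(noise_sd = 0, n_replicates = 3)
  ann <- simulate_genome(cfg, build_track = FALSE)$annotation
  em <- simulate_arrays(cfg, ann, array_scales = rep(1 / factors, 2))
  res <- fit_spikein_scale(em)
  expect_equal(unname(res$scale_factors), rep(factors, 2), tolerance = 1e-9)
})

test_that("errors name the offending array and require spike-ins", {
  m <- matrix(1:16, ncol = 4)
  em <- make_em(m)
  em$intensities[4, 2] <- 0
  expect_error(fit_spikein_scale(em), "wt_2")
  expect_error(make_em(m, n_spike = 0), "spike-in")
})

test_that("wild-type vs wild-type mRNA level is exactly 100", {
  cfg <- small_config()
  ann <- simulate_genome(cfg, build_track = FALSE)$annotation
  res <- fit_spikein_scale(simulate_arrays(cfg, ann))
  lvl <- global_mrna_level(res, "wt", "wt")
  expect_identical(lvl$level, 100)
})

test_that("noise-free synthetic data are recovered to 1e-9", {
  cfg <- small_config(noise_sd = 0, global_scale = 0.7)
  ann <- simulate_genome(cfg, build_track = FALSE)$annotation
  em <- simulate_arrays(cfg, ann)
  res <- fit_spikein_scale(em)
  expect_equal(unname(res$scale_factors), rep(1, 6), tolerance = 1e-9)
  lvl <- global_mrna_level(res, "top1top2", "wt", floor = 1e-9)
  expect_equal(lvl$level, 70, tolerance = 70 * 1e-9)
  slr <- compute_slr(res, "top1top2", "wt", floor = 1e-9)
  gt <- attr(em, "ground_truth")
  expect_equal(slr$slr, gt$slr_top1top2, tolerance = 1e-9)
})

test_that("the estimated level tracks a planted 70% with noise", {
  cfg <- small_config(seed = 3, noise_sd = 0.1, global_scale = 0.7,
                      frac_affected = 0, activity_effect = 0,
                      n_genes = 2000, n_spikeins = 96)
  ann <- simulate_genome(cfg, build_track = FALSE)$annotation
  res <- fit_spikein_scale(simulate_arrays(cfg, ann))
  lvl <- global_mrna_level(res, "top1top2", "wt")
  expect_lt(abs(lvl$level - 70), 2)
  expect_length(lvl$per_replicate, 3)
})

test_that("raising the detection floor never increases the detectable count", {
  cfg <- small_config(seed = 5)
  ann <- simulate_genome(cfg, build_track = FALSE)$annotation
  res <- fit_spikein_scale(simulate_arrays(cfg, ann))
  floors <- c(0.1, 1, 10, 100, 1000)
  counts <- vapply(floors, function(f)
    global_mrna_level(res, "top1top2", "wt", floor = f)$n_detectable,
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("SLR is the mean replicate log2 ratio", {
  # genes doubled in the mutant, spike-ins unchanged
  m <- rbind(c(4, 4, 8, 8), c(16, 16, 32, 32), c(5, 5, 5, 5))
  em <- make_em(m, n_spike = 1)
  res <- fit_spikein_scale(em)
  slr <- compute_slr(res, "mut", "wt")
  expect_equal(slr$slr, rep(1, 2))
  m0 <- cbind(m[, 1:2], m[, 1:2])      # mutant = wild-type
  slr0 <- compute_slr(fit_spikein_scale(make_em(m0, n_spike = 1)),
                      "mut", "wt")
  expect_equal(slr0$slr, rep(0, 2))
})

test_that("deregulated fractions count cutoff exceedances", {
  tab <- data.frame(gene_id = letters[1:4], slr = c(1.5, -1.2, 0.3, -0.5))
  fr <- deregulated_fraction(tab, 1, -1)
  expect_equal(fr$frac_up, 0.25)
  expect_equal(fr$frac_down, 0.25)
  # asymmetric cutoffs used for functional-group summaries
  fr2 <- deregulated_fraction(tab, 0.5, -1)
  expect_equal(fr2$frac_up, 0.25)
  expect_equal(fr2$frac_down, 0.25)
  tab5 <- rbind(tab, data.frame(gene_id = "e", slr = 0.6))
  expect_equal(deregulated_fraction(tab5, 0.5, -1)$frac_up, 0.4)
  null <- data.frame(gene_id = letters[1:3], slr = numeric(3))
  fr0 <- deregulated_fraction(null, 1, -1)
  expect_equal(c(fr0$frac_up, fr0$frac_down), c(0, 0))
  expect_error(deregulated_fraction(null[0, ], 1, -1), "empty")
  expect_error(deregulated_fraction(tab, -1, 1))
})

test_that("replicate-level fraction standard errors are reported", {
  cfg <- small_config(seed = 11)
  ann <- simulate_genome(cfg, build_track = FALSE)$annotation
  res <- fit_spikein_scale(simulate_arrays(cfg, ann))
  slr <- compute_slr(res, "top1top2", "wt")
  fr <- deregulated_fraction(slr, 1, -1)
  expect_true(is.finite(fr$se_up) && is.finite(fr$se_down))
})
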