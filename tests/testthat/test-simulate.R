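test_that("identical configs give bit-identical outputs", {
  cfg <- small_config(seed = 7)
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(g1$annotation, g2$annotation)
  expect_identical(g1$track$bins, g2$track$bins)
  e1 <- simulate_arrays(cfg, g1$annotation)
  e2 <- simulate_arrays(cfg, g2$annotation)
  expect_identical(e1$intensities, e2$intensities)
  expect_identical(simulate_compendium(cfg, g1$annotation),
                   simulate_compendium(cfg, g2$annotation))
  q1 <- simulate_qpcr(cfg); q2 <- simulate_qpcr(cfg)
  expect_identical(q1, q2)
  g3 <- simulate_genome(small_config(seed = 8))
  expect_false(identical(g1$annotation$abundance_wt,
                         g3$annotation$abundance_wt))
})

test_that("class assignment is deterministic by activity quantile", {
  cfg <- small_config(frac_affected = 0.2, up_share = 0.15)
  ann <- simulate_genome(cfg, build_track = FALSE)$annotation
  expect_identical(sum(ann$dependency_class != "unaffected"),
                   as.integer(round(0.2 * cfg$n_genes)))
  # affected_down occupy the top of the activity ranking, affected_up the
  # bottom
  act <- ann$abundance_wt / ann$half_life
  expect_true(min(act[ann$dependency_class == "affected_down"]) >
              max(act[ann$dependency_class == "unaffected"]))
  expect_true(max(act[ann$dependency_class == "affected_up"]) <
              min(act[ann$dependency_class == "unaffected"]))
})

test_that("frac_affected = 0 gives a fully unaffected genome with uniform NFR", {
  cfg <- small_config(frac_affected = 0, track_noise_sd = 0)
  g <- simulate_genome(cfg)
  expect_true(all(g$annotation$dependency_class == "unaffected"))
  tssm <- align_to_tss(g$track, g$annotation)
  nfr <- rowMeans(tssm$occupancy[, tssm$offsets >= -200 & tssm$offsets < 0])
  expect_equal(unname(nfr), rep(cfg$nfr_depth_unaffected, nrow(g$annotation)))
})

test_that("planted NFR depth difference equals the profile-template mean difference", {
  # closed form: the template is flat over the NFR window, so the per-class
  # group means differ by exactly the configured depth difference
  cfg <- small_config(frac_affected = 0.5, up_share = 0, track_noise_sd = 0,
                      nfr_depth_affected = 0.5, nfr_depth_unaffected = 0.2)
  g <- simulate_genome(cfg)
  tssm <- align_to_tss(g$track, g$annotation)
  nfr <- rowMeans(tssm$occupancy[, tssm$offsets >= -200 & tssm$offsets < 0])
  aff <- g$annotation$dependency_class != "unaffected"
  expect_equal(mean(nfr[aff]) - mean(nfr[!aff]), 0.3, tolerance = 1e-12)
})

test_that("spike-ins are strain-independent and the null simulation is exact", {
  cfg <- small_config(noise_sd = 0, global_scale = 1, frac_affected = 0,
                      activity_effect = 0)
  ann <- simulate_genome(cfg, build_track = FALSE)$annotation
  em <- simulate_arrays(cfg, ann)
  # all arrays identical when nothing is planted and noise is off
  expect_true(all(em$intensities == em$intensities[, 1]))
})

test_that("a planted global scale halves every gene but no spike-in, exactly", {
  cfg <- small_config(noise_sd = 0, global_scale = 0.5, frac_affected = 0,
                      activity_effect = 0)
  ann <- simulate_genome(cfg, build_track = FALSE)$annotation
  em <- simulate_arrays(cfg, ann)
  mut_cols <- em$arrays$strain == "top1top2"
  for (j in which(mut_cols)) {
    expect_identical(em$intensities[!em$spikein, j],
                     em$intensities[!em$spikein, 1] * 0.5)
    expect_identical(em$intensities[em$spikein, j],
                     em$intensities[em$spikein, 1])
  }
})

test_that("stored ground-truth SLR matches its own planted structure", {
  cfg <- small_config(frac_affected = 1, up_share = 0, activity_effect = -1)
  ann <- simulate_genome(cfg, build_track = FALSE)$annotation
  em <- simulate_arrays(cfg, ann)
  gt <- attr(em, "ground_truth")
  # brute-force correlation of the stored vectors: a pure rank-slope plant
  # is perfectly anticorrelated with the activity rank margin
  expect_equal(cor(gt$slr_top1top2, ann$activity_rank_margin), -1,
               tolerance = 1e-12)
})

test_that("compendium variance is set by the planted class", {
  cfg <- small_config(frac_affected = 0.5, up_share = 0,
                      plasticity_sd_high = 1, plasticity_sd_low = 0.2,
                      n_conditions = 173)
  ann <- simulate_genome(cfg, build_track = FALSE)$annotation
  comp <- simulate_compendium(cfg, ann)
  msq <- rowMeans(comp^2)
  aff <- ann$dependency_class != "unaffected"
  # E[mean squared ratio] = sd^2 per class
  expect_equal(mean(msq[aff]), 1, tolerance = 0.05)
  expect_equal(mean(msq[!aff]), 0.04, tolerance = 0.05)
  # ranking genes by responsiveness recovers the planted class; AUROC by
  # brute force from the generated matrix (rank-sum identity)
  z <- responsiveness(comp)
  r <- rank(z)
  auroc <- (sum(r[aff]) - sum(aff) * (sum(aff) + 1) / 2) /
    (sum(aff) * sum(!aff))
  expect_gt(auroc, 0.95)
})

test_that("equal plasticity spreads leave no class difference beyond noise", {
  cfg <- small_config(frac_affected = 0.5, plasticity_sd_high = 0.5,
                      plasticity_sd_low = 0.5, n_conditions = 40)
  ann <- simulate_genome(cfg, build_track = FALSE)$annotation
  z <- responsiveness(simulate_compendium(cfg, ann))
  aff <- ann$dependency_class != "unaffected"
  tt <- pooled_ttest(z[aff], z[!aff])
  expect_gt(tt$p, 1e-3)
})

test_that("qPCR generator obeys the log2 identity and stores ground truth", {
  kin <- list(timepoints = c(0, 60),
              chip = list(L = list(wt = c(1, 8))),
              expression = list(G = list(wt = c(1, 2))))
  cfg <- small_config(ct_noise_sd = 0, chip_kinetics = kin)
  tab <- simulate_qpcr(cfg)
  expr <- tab[tab$channel == "input_cDNA", ]
  # quantity doubles from t0 to t60 => Ct drops by exactly one cycle
  expect_equal(expr$ct_1[expr$timepoint_min == 0] -
               expr$ct_1[expr$timepoint_min == 60], 1)
  truth <- attr(tab, "ground_truth")
  expect_identical(truth$value[truth$type == "chip_fold"], c(1, 8))
})

test_that("generator rejects invalid configurations", {
  expect_error(small_config(n_genes = 0), "n_genes")
  expect_error(small_config(global_scale = 0), "global_scale")
  expect_error(small_config(noise_sd = -1), "noise_sd")
  expect_error(small_config(frac_affected = 2), "frac_affected")
  expect_error(small_config(n_conditions = 1), "n_conditions")
})
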