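# A minimal hand-built track: one chromosome, 10 bp bins.
toy_track <- function(values, chrom = "chr1", bs = 10L) {
  structure(list(bins = setNames(list(values), chrom),
                 bin_size = bs,
                 chrom_lengths = setNames(length(values) * bs, chrom)),
            class = "nucleosome_track")
}

test_that("TSS alignment extracts strand-corrected windows", {
  track <- toy_track(rep(3, 400))
  ann <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                    tss = c(2000, 2000), strand = c("+", "-"))
  tssm <- align_to_tss(track, ann, 100, 100)
  expect_equal(tssm$offsets, seq(-100, 90, 10))
  expect_true(all(tssm$occupancy == 3))   # uniform track -> constant matrix
  # mirror-image profiles on opposite strands give identical rows
  v <- rep(0, 400)
  v[150:250] <- seq_along(150:250)        # asymmetric bump around bin 200
  mirrored <- rev(v)
  track2 <- structure(list(
    bins = list(chr1 = v, chr2 = mirrored), bin_size = 10L,
    chrom_lengths = c(chr1 = 4000, chr2 = 4000)),
    class = "nucleosome_track")
  ann2 <- data.frame(gene_id = c("fwd", "rev"),
                     chrom = c("chr1", "chr2"),
                     tss = c(2000, 4000 - 2000), strand = c("+", "-"))
  m2 <- align_to_tss(track2, ann2, 300, 300)
  expect_equal(unname(m2$occupancy["fwd", ]), unname(m2$occupancy["rev", ]))
})

test_that("out-of-bounds genes are dropped and unknown chromosomes error", {
  track <- toy_track(rep(1, 100))
  ann <- data.frame(gene_id = c("in", "edge"), chrom = "chr1",
                    tss = c(500, 20), strand = "+")
  expect_message(tssm <- align_to_tss(track, ann, 100, 100), "dropped 1")
  expect_equal(rownames(tssm$occupancy), "in")
  bad <- data.frame(gene_id = "x", chrom = "chrZ", tss = 50, strand = "+")
  expect_error(align_to_tss(track, bad, 10, 10), "chrZ")
})

test_that("noise-free genes reproduce the generator's stereotyped profile", {
  cfg <- small_config(track_noise_sd = 0, frac_affected = 0)
  g <- simulate_genome(cfg)
  tssm <- align_to_tss(g$track, g$annotation)
  centres <- tssm$offsets + g$track$bin_size / 2
  tmpl <- topotrans:::profile_template(centres, cfg$nfr_depth_unaffected)
  for (i in c(1, 57, 333)) {
    expect_equal(unname(tssm$occupancy[i, ]), tmpl)
  }
})

test_that("meta-profile means and confidence intervals behave", {
  occ <- matrix(rep(c(1, 2, 3, 4), each = 5), nrow = 5)
  tssm <- structure(list(occupancy = occ, offsets = c(-20, -10, 0, 10),
                         bin_size = 10L), class = "tss_matrix")
  rownames(tssm$occupancy) <- sprintf("g%d", 1:5)
  prof <- meta_profile(tssm)
  expect_equal(prof$mean, c(1, 2, 3, 4))
  expect_equal(prof$ci_low, prof$mean)    # identical rows -> zero-width CI
  expect_equal(prof$ci_high, prof$mean)
  expect_error(meta_profile(tssm, group = "g1"), "fewer than 2")
  # linearity: the all-genes profile is the size-weighted group combination
  set.seed(2)
  occ2 <- matrix(rnorm(60), nrow = 6,
                 dimnames = list(sprintf("g%d", 1:6), NULL))
  tss2 <- structure(list(occupancy = occ2, offsets = seq(-30, 60, 10),
                         bin_size = 10L), class = "tss_matrix")
  pa <- meta_profile(tss2, sprintf("g%d", 1:2))
  pb <- meta_profile(tss2, sprintf("g%d", 3:6))
  pall <- meta_profile(tss2)
  expect_equal(pall$mean, (2 * pa$mean + 4 * pb$mean) / 6)
})

test_that("extreme-gene selection matches brute force and stays disjoint", {
  tab <- data.frame(gene_id = sprintf("g%03d", 1:300),
                    slr = as.numeric(1:300))
  gr <- select_extreme_genes(tab, n = 100)
  expect_setequal(gr$most_down, sprintf("g%03d", 1:100))
  expect_setequal(gr$most_up, sprintf("g%03d", 201:300))
  expect_setequal(gr$most_unaffected, sprintf("g%03d", 101:200))
  expect_length(intersect(gr$most_up, gr$most_down), 0L)
  one <- select_extreme_genes(tab, n = 1)
  expect_equal(one$most_up, "g300")
  expect_equal(one$most_down, "g001")
  tied <- data.frame(gene_id = sprintf("g%03d", 1:30), slr = rep(0, 30))
  expect_warning(grt <- select_extreme_genes(tied, n = 10), "degenerate")
  expect_equal(grt$most_down, sprintf("g%03d", 1:10))   # lexicographic
  expect_error(select_extreme_genes(tab, n = 200), "3 \\* n")
})

test_that("NFR occupancy test recovers the planted depth difference", {
  cfg <- small_config(seed = 13, frac_affected = 0.5, up_share = 0)
  g <- simulate_genome(cfg)
  tssm <- align_to_tss(g$track, g$annotation)
  aff <- g$annotation$gene_id[g$annotation$dependency_class != "unaffected"]
  unaff <- g$annotation$gene_id[g$annotation$dependency_class == "unaffected"]
  res <- nfr_occupancy_test(tssm, aff[1:100], unaff[1:100])
  expect_lt(abs(res$diff - 0.3), 0.05)
  expect_lt(res$p, 0.01)
  # shared t implementation with the feature-group test
  v <- setNames(res$per_gene$nfr_occupancy, res$per_gene$gene_id)
  ref <- group_feature_ttest(v[res$per_gene$group %in% c("A", "B")],
                             res$per_gene$gene_id[res$per_gene$group == "A"])
  expect_equal(res$t, ref$t)
  expect_equal(res$p, ref$p)
})

test_that("NFR window handling is exact at the edges", {
  occ <- matrix(c(1, 2, 3, 4, 5, 6, 8, 7, 9, 10, 12, 11, 13, 16, 15, 14),
                nrow = 4)
  dimnames(occ) <- list(c("a", "b", "c", "d"), NULL)
  tssm <- structure(list(occupancy = occ, offsets = c(-20, -10, 0, 10),
                         bin_size = 10L), class = "tss_matrix")
  # single-bin window reproduces that bin's per-gene values
  res <- nfr_occupancy_test(tssm, c("a", "b"), c("c", "d"),
                            nfr_window = c(-10, 0))
  expect_equal(res$per_gene$nfr_occupancy, unname(occ[, 2]))
  expect_error(nfr_occupancy_test(tssm, "a", "b", nfr_window = c(50, 60)),
               "empty NFR window")
  # identical group distributions: t = 0, p = 1
  occ2 <- matrix(c(1, 2, 3, 1, 2, 3), nrow = 6)
  dimnames(occ2) <- list(sprintf("g%d", 1:6), NULL)
  tss2 <- structure(list(occupancy = occ2, offsets = 0, bin_size = 10L),
                    class = "tss_matrix")
  same <- nfr_occupancy_test(tss2, sprintf("g%d", 1:3), sprintf("g%d", 4:6),
                             nfr_window = c(0, 10))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})
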