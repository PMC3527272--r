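#' Run the full synthetic study end to end
#'
#' Executes every stage on synthetic data generated from `config`: simulate
#' (genome, arrays, compendium, qPCR) -> spike-in normalization (global mRNA
#' levels, SLR tables, deregulated fractions) -> moving-average trends and
#' correlation tests against abundance / activity / transcript length ->
#' responsiveness, plasticity and group t-tests -> TATA/SAGA overlaps,
#' category enrichment and the profile correlation screen -> TSS meta-
#' profiles and the NFR occupancy test -> qPCR/ChIP time courses. All
#' tabular outputs are written as TSV under `outdir`, headline numbers to
#' `summary.json`, and a machine-readable run manifest (config echo, seed,
#' dialect decisions, per-file checksums, stage timings) to
#' `manifest.json`; re-running from the manifest reproduces every output
#' checksum-identically.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param n_perm permutations for correlation p-values.
#' @return (invisibly) a list with the summary, the manifest, and the main
#'   in-memory objects.
#' @export
run_pipeline <- function(config, outdir, n_perm = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t_start <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t_start, 2)
  }
  out <- function(f) file.path(outdir, f)
  summary <- list(seed = config$seed)

  ## stage: simulate --------------------------------------------------------
  genome <- simulate_genome(config)
  ann <- genome$annotation
  em <- simulate_arrays(config, ann)
  comp <- simulate_compendium(config, ann)
  ct_tab <- simulate_qpcr(config)
  write_annotation_tsv(ann, out("annotation.tsv"))
  write_expression_tsv(em, out("expression.tsv"))
  write_compendium_tsv(comp, out("compendium.tsv"))
  write_bedgraph(genome$track, out("occupancy.bedGraph"))
  write_tss_bed(ann, genome$chrom_lengths, out("genes.bed"))
  write_ct_tsv(ct_tab, out("qpcr_ct.tsv"))
  tick("simulate")

  ## stage: normalize -------------------------------------------------------
  norm <- fit_spikein_scale(em)
  mutants <- setdiff(config$strains, "wt")
  focal <- if ("top1top2" %in% mutants) "top1top2" else mutants[length(mutants)]
  norm_rows <- list()
  slr_tables <- list()
  for (m in mutants) {
    lvl <- global_mrna_level(norm, m, "wt", floor = config$detection_floor)
    slr_tables[[m]] <- compute_slr(norm, m, "wt",
                                   floor = config$detection_floor)
    fr2 <- deregulated_fraction(slr_tables[[m]], 1, -1)
    fr_asym <- deregulated_fraction(slr_tables[[m]], 0.5, -1)
    norm_rows[[m]] <- data.frame(
      strain = m, mrna_level_pct = lvl$level, mrna_level_sd = lvl$sd,
      pct_up_2fold = 100 * fr2$frac_up, pct_down_2fold = 100 * fr2$frac_down,
      pct_up_0.5slr = 100 * fr_asym$frac_up,
      pct_down_1slr = 100 * fr_asym$frac_down,
      n_detectable = lvl$n_detectable)
    write_tsv(slr_tables[[m]], out(sprintf("slr_%s.tsv", m)))
  }
  norm_report <- do.call(rbind, norm_rows)
  write_tsv(data.frame(array = colnames(em$intensities),
                       scale_factor = norm$scale_factors),
            out("scale_factors.tsv"))
  write_tsv(norm_report, out("normalization_report.tsv"))
  slr <- slr_tables[[focal]]
  summary$global_mrna_level_pct <-
    norm_report$mrna_level_pct[norm_report$strain == focal]
  summary$pct_up_2fold <- norm_report$pct_up_2fold[norm_report$strain == focal]
  summary$pct_down_2fold <-
    norm_report$pct_down_2fold[norm_report$strain == focal]
  tick("normalize")

  ## stage: trends ----------------------------------------------------------
  act <- transcriptional_activity(ann$abundance_wt, ann$half_life,
                                  ann$gene_id)
  covs <- list(abundance = ann$abundance_wt, activity = act$activity,
               length = ann$transcript_length)
  trend_rows <- list(); corr_rows <- list()
  win <- min(200L, max(2L, nrow(ann) %/% 4L))
  for (nm in names(covs)) {
    cv <- covs[[nm]]
    crv <- moving_average_trend(cv, slr$slr, window = win, ids = ann$gene_id)
    pc <- pearson_with_permutation(cv, slr$slr, n_perm = n_perm,
                                   seed = config$seed)
    trend_rows[[nm]] <- data.frame(covariate = nm,
                                   window_index = seq_len(crv$n_windows),
                                   x = crv$x_points, y = crv$y_points)
    corr_rows[[nm]] <- data.frame(
      covariate = nm, r = pc$r, p_permutation = pc$p, window = win,
      frac_nonincreasing = trend_monotonicity(crv))
  }
  write_tsv(do.call(rbind, trend_rows), out("trend_curves.tsv"))
  corr_report <- do.call(rbind, corr_rows)
  write_tsv(corr_report, out("trend_correlations.tsv"))
  summary$pearson_slr_vs_abundance <-
    corr_report$r[corr_report$covariate == "abundance"]
  summary$pearson_slr_vs_activity <-
    corr_report$r[corr_report$covariate == "activity"]
  summary$pearson_slr_vs_length <-
    corr_report$r[corr_report$covariate == "length"]
  summary$perm_p_slr_vs_activity <-
    corr_report$p_permutation[corr_report$covariate == "activity"]
  # transcript-length extreme groups (rank-sum, distribution difference)
  short <- slr$slr[ann$transcript_length < 500]
  long <- slr$slr[ann$transcript_length > 4500]
  if (length(short) >= 1L && length(long) >= 1L) {
    rs <- rank_sum_compare(short, long)
    summary$length_groups_ranksum_p <- rs$p
    summary$n_short <- length(short); summary$n_long <- length(long)
  }
  tick("trends")

  ## stage: features --------------------------------------------------------
  resp <- responsiveness(comp)
  plast <- plasticity(comp)
  feature_tab <- data.frame(gene_id = ann$gene_id,
                            activity = act$activity,
                            responsiveness = unname(resp[ann$gene_id]),
                            plasticity = unname(plast[ann$gene_id]),
                            telomere_distance = ann$telomere_distance)
  write_tsv(feature_tab, out("features.tsv"))
  up_set <- slr$gene_id[slr$slr >= 1]
  down_set <- slr$gene_id[slr$slr <= -1]
  # group comparisons need at least 2 genes on each side
  safe_ttest <- function(values, set, alternative) {
    if (length(set) < 2L || length(set) > length(values) - 2L) {
      return(list(t = NA_real_, df = NA_real_, p = NA_real_))
    }
    group_feature_ttest(values, set, alternative)
  }
  tt_up <- safe_ttest(resp, up_set, "greater")
  tt_down <- safe_ttest(resp, down_set, "greater")
  tel <- stats::setNames(ann$telomere_distance, ann$gene_id)
  tt_tel <- safe_ttest(tel, union(up_set, down_set), "two.sided")
  write_tsv(data.frame(
    test = c("responsiveness_up_vs_rest", "responsiveness_down_vs_rest",
             "telomere_distance_deregulated_vs_rest"),
    t = c(tt_up$t, tt_down$t, tt_tel$t),
    df = c(tt_up$df, tt_down$df, tt_tel$df),
    p = c(tt_up$p, tt_down$p, tt_tel$p),
    alternative = c("greater", "greater", "two.sided")),
    out("feature_ttests.tsv"))
  summary$responsiveness_down_p <- tt_down$p
  summary$responsiveness_up_p <- tt_up$p
  summary$telomere_ttest_p <- tt_tel$p
  # plasticity vs SLR trend (curvilinear: high at both extremes) and
  # abundance-quartile stratification
  pl_curve <- moving_average_trend(slr$slr, feature_tab$plasticity,
                                   window = win, ids = ann$gene_id)
  write_tsv(data.frame(window_index = seq_len(pl_curve$n_windows),
                       x = pl_curve$x_points, y = pl_curve$y_points),
            out("plasticity_vs_slr_curve.tsv"))
  thirds <- max(1L, pl_curve$n_windows %/% 3L)
  summary$plasticity_extremes_minus_middle <-
    mean(c(pl_curve$y_points[seq_len(thirds)],
           pl_curve$y_points[seq(pl_curve$n_windows - thirds + 1L,
                                 pl_curve$n_windows)])) -
    mean(pl_curve$y_points[seq(thirds + 1L, pl_curve$n_windows - thirds)])
  if (nrow(ann) >= 4L * win) {
    qs <- quartile_stratified_trend(ann$abundance_wt, slr$slr,
                                    feature_tab$plasticity, window = win,
                                    ids = ann$gene_id)
    qtab <- do.call(rbind, lapply(names(qs), function(k)
      data.frame(quartile = k, window_index = seq_len(qs[[k]]$n_windows),
                 x = qs[[k]]$x_points, y = qs[[k]]$y_points)))
    write_tsv(qtab, out("plasticity_vs_slr_by_abundance_quartile.tsv"))
  }
  tick("features")

  ## stage: enrichment ------------------------------------------------------
  dereg <- union(up_set, down_set)
  universe <- ann$gene_id
  tata_set <- ann$gene_id[ann$tata]
  saga_set <- ann$gene_id[ann$saga]
  overlap_p <- function(set) {
    k <- length(intersect(dereg, set))
    hypergeometric_overlap(k, length(set), length(dereg), length(universe))
  }
  summary$tata_overlap_p <- overlap_p(tata_set)
  summary$saga_overlap_p <- overlap_p(saga_set)
  ann_map <- c(list(TATA = tata_set, SAGA = saga_set),
               split(ann$gene_id, ann$chrom))
  enr <- if (length(dereg)) {
    annotation_enrichment(dereg, ann_map, universe = universe,
                          p_cutoff = 1e-3)
  } else {
    data.frame(category_id = character(), k = integer(), f = integer(),
               set_size = integer(), universe_size = integer(),
               p = numeric(), p_bonferroni = numeric())
  }
  write_tsv(enr, out("enrichment.tsv"))
  summary$n_enriched_categories <- nrow(enr)
  # correlation screen: compendium conditions (null profiles) plus a
  # half-scaled copy of the focal profile (positive control; a linear
  # rescaling must leave R, P, P_o unchanged)
  lib <- lapply(seq_len(min(6L, ncol(comp))), function(j)
    data.frame(gene_id = rownames(comp), slr = comp[, j]))
  names(lib) <- colnames(comp)[seq_along(lib)]
  lib$self_halved <- data.frame(gene_id = slr$gene_id, slr = slr$slr / 2)
  if (nrow(slr) >= 100L) {
    screen <- compendium_correlation_screen(slr, lib, n_perm = n_perm,
                                            seed = config$seed)
    write_tsv(screen, out("correlation_screen.tsv"))
    summary$screen_top_R <- screen$R[1L]
    summary$screen_top_P_o <- screen$P_o[1L]
  }
  tick("enrichment")

  ## stage: nucleosome profiles ---------------------------------------------
  tssm <- align_to_tss(genome$track, ann)
  groups <- select_extreme_genes(slr, n = min(100L, nrow(slr) %/% 3L))
  prof_tab <- do.call(rbind, lapply(
    c(groups, list(all_genes = ann$gene_id)), meta_profile,
    tss_matrix = tssm))
  prof_tab$group <- rep(c(names(groups), "all_genes"),
                        each = length(tssm$offsets))
  write_tsv(prof_tab, out("tss_meta_profiles.tsv"))
  nfr_down <- nfr_occupancy_test(tssm, groups$most_down,
                                 groups$most_unaffected)
  nfr_up <- nfr_occupancy_test(tssm, groups$most_up, groups$most_unaffected)
  write_tsv(data.frame(
    comparison = c("down_vs_unaffected", "up_vs_unaffected"),
    diff = c(nfr_down$diff, nfr_up$diff),
    t = c(nfr_down$t, nfr_up$t), df = c(nfr_down$df, nfr_up$df),
    p = c(nfr_down$p, nfr_up$p)), out("nfr_test.tsv"))
  summary$nfr_diff_down_vs_unaffected <- nfr_down$diff
  summary$nfr_p_down_vs_unaffected <- nfr_down$p
  summary$nfr_diff_up_vs_unaffected <- nfr_up$diff
  tick("nucleosome")

  ## stage: qPCR ------------------------------------------------------------
  kin <- config$chip_kinetics
  qpcr_rows <- list()
  for (locus in names(kin$chip)) for (strain in names(kin$chip[[locus]])) {
    tc <- chip_fold_timecourse(ct_tab, locus, strain)
    tc$normalized <- timecourse_normalize(tc$fold, "t0_to_1")
    tc$locus <- locus; tc$strain <- strain; tc$type <- "chip_fold"
    qpcr_rows[[paste(locus, strain)]] <- tc
  }
  for (locus in names(kin$expression)) {
    strains <- names(kin$expression[[locus]])
    q_by_strain <- lapply(strains, function(strain) {
      sub <- ct_tab[ct_tab$locus == locus & ct_tab$strain == strain &
                    ct_tab$channel == "input_cDNA", ]
      sub <- sub[order(sub$timepoint_min), ]
      vapply(seq_len(nrow(sub)), function(i)
        relative_quantity(as.numeric(sub[i, paste0("ct_", 1:3)]))$quantity,
        numeric(1))
    })
    names(q_by_strain) <- strains
    wt_ref <- q_by_strain[[if ("wt" %in% strains) "wt" else strains[1L]]]
    for (strain in strains) {
      tc <- data.frame(timepoint_min = sort(unique(
        ct_tab$timepoint_min[ct_tab$locus == locus])),
        fold = q_by_strain[[strain]])
      tc$normalized <- timecourse_normalize(tc$fold, "wt_max_100",
                                            reference_series = wt_ref)
      tc$locus <- locus; tc$strain <- strain; tc$type <- "expression"
      qpcr_rows[[paste(locus, strain, "expr")]] <- tc
    }
  }
  qpcr_report <- do.call(rbind, qpcr_rows)
  rownames(qpcr_report) <- NULL
  write_tsv(qpcr_report, out("qpcr_timecourses.tsv"))
  truth <- attr(ct_tab, "ground_truth")
  chip_truth <- truth[truth$type == "chip_fold", ]
  est <- qpcr_report[qpcr_report$type == "chip_fold", ]
  key <- function(d) paste(d$locus, d$strain, d$timepoint_min)
  matched <- est$normalized[match(key(chip_truth), key(est))]
  summary$chip_fold_max_abs_log2_error <-
    max(abs(log2(matched) - log2(chip_truth$value)))
  tick("qpcr")

  ## manifest + summary -----------------------------------------------------
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  outputs <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    dialects = list(
      normalization_anchor = "median-of-ratios vs geometric-mean spike-in pseudo-array",
      slr = "mean of replicate log2 intensities, unpaired, floor-guarded",
      moving_average = "trailing windows of exactly `window` genes, step 1, no edge padding; monotonicity judged across abutting windows",
      permutation_p = "two-sided add-one estimator, y permuted",
      rank_sum = "midrank ties; exact enumeration at combined n <= 12, else normal approximation with continuity correction",
      responsiveness_sd = "standardized after per-gene averaging, sample sd (n-1)",
      hypergeometric_tail = "upper tail P(X >= k), enrichment only",
      percentile_ties = "boundary ties included on the extreme side",
      nfr_window = "[-200, 0) bp relative to TSS; profile window [-500, 500)",
      ci = "t-distribution 95% confidence intervals",
      qpcr_model = "quantity = efficiency^(-mean Ct), default efficiency 2"
    ),
    checksums = as.list(tools::md5sum(file.path(outdir, outputs))),
    timings_sec = timings
  )
  names(manifest$checksums) <- outputs
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(summary = summary, manifest = manifest, config = config,
                 annotation = ann, slr_tables = slr_tables,
                 norm_report = norm_report, features = feature_tab,
                 groups = groups, outdir = outdir))
}

#' Re-run the pipeline from a run manifest
#'
#' The manifest's verbatim config echo suffices to reproduce the run
#' bit-identically; output checksums are compared against the manifest's
#' record.
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param outdir output directory for the re-run.
#' @param n_perm as in [run_pipeline()].
#' @return the [run_pipeline()] result, with `checksums_match` (logical)
#'   added.
#' @export
run_from_manifest <- function(manifest_path, outdir, n_perm = 1000L) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfgl <- man$config
  kin <- cfgl$chip_kinetics
  args <- cfgl[setdiff(names(cfgl), "chip_kinetics")]
  args$chip_kinetics <- relist_kinetics(kin)
  cfg <- do.call(sim_config, args)
  res <- run_pipeline(cfg, outdir, n_perm = n_perm)
  new_sums <- res$manifest$checksums
  old_sums <- man$checksums
  res$checksums_match <- identical(
    unname(unlist(new_sums[names(old_sums)])),
    unname(unlist(old_sums)))
  res
}

# jsonlite round-trips the kinetics lists faithfully apart from turning
# length-1 vectors into scalars; normalize to plain numeric vectors.
relist_kinetics <- function(kin) {
  list(timepoints = as.numeric(kin$timepoints),
       chip = lapply(kin$chip, function(l) lapply(l, as.numeric)),
       expression = lapply(kin$expression, function(l)
         lapply(l, as.numeric)))
}
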