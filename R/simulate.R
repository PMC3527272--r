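#' Simulate the genome: gene annotation and nucleosome occupancy track
#'
#' Generates a per-gene annotation table (abundance, half-life, transcript
#' length, TSS/strand, TATA/SAGA membership, telomere distance, planted
#' dependency class) and, optionally, a binned genome-wide nucleosome
#' occupancy track in which every gene carries a stereotyped promoter
#' profile: a flat nucleosome-free region (NFR) over \[-200, 0) bp relative
#' to the TSS whose depth is set by the gene's dependency class, and ~165 bp
#' periodic nucleosome peaks downstream of the TSS. Minus-strand genes get
#' mirrored profiles.
#'
#' Wild-type abundances are log-normal; half-lives (minutes) and transcript
#' lengths (nt) are log-normal and independent of abundance. The dependency
#' class is assigned deterministically by transcriptional-activity
#' (abundance / half-life) quantile: the top of the activity ranking is
#' `affected_down`, the bottom `affected_up` (see [sim_config()]), so planted
#' trend shapes are reproducible. TATA and SAGA membership are enriched in
#' the affected class, emulating the association of inducible/repressible
#' regulation with topoisomerase dependency.
#'
#' @param config a [sim_config()].
#' @param build_track build the occupancy track (the expensive part); set
#'   `FALSE` when only the annotation is needed.
#' @return list with `annotation` (data.frame), `track` (a `nucleosome_track`
#'   or `NULL`), and `chrom_lengths` (named integer vector).
#' @export
simulate_genome <- function(config, build_track = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  with_sim_seed(config$seed, 1L, {
    gene_id <- sprintf("gene_%05d", seq_len(n))
    abundance_wt <- stats::rlnorm(n, meanlog = log(100), sdlog = 1)
    half_life <- stats::rlnorm(n, meanlog = log(20), sdlog = 0.6)
    transcript_length <- pmax(
      200, round(stats::rlnorm(n, meanlog = log(1250), sdlog = 0.65)))
    strand <- sample(c("+", "-"), n, replace = TRUE)

    activity <- abundance_wt / half_life
    rk <- rank(activity, ties.method = "first")
    u <- (rk - 0.5) / n   # activity rank margin in (0, 1)
    n_aff <- round(config$frac_affected * n)
    n_up <- round(config$up_share * n_aff)
    n_down <- n_aff - n_up
    dependency_class <- rep("unaffected", n)
    if (n_down > 0L) dependency_class[rk > n - n_down] <- "affected_down"
    if (n_up > 0L) dependency_class[rk <= n_up] <- "affected_up"
    affected <- dependency_class != "unaffected"

    # regulated-gene features enriched in the affected class
    tata <- stats::runif(n) < ifelse(affected, 0.6, 0.15)
    saga <- stats::runif(n) < ifelse(affected, 0.5, 0.08)

    # genome layout: genes round-robin across chromosomes, evenly spaced,
    # TSS aligned to the track bin grid so noise-free profile extraction is
    # exact
    chrom_idx <- rep(seq_len(config$n_chromosomes), length.out = n)
    pos_idx <- stats::ave(seq_len(n), chrom_idx, FUN = seq_along)
    spacing <- config$gene_spacing
    tss <- as.integer(pos_idx * spacing)
    tss <- tss - tss %% config$bin_size
    chrom <- sprintf("chr%02d", chrom_idx)
    per_chrom <- tabulate(chrom_idx, config$n_chromosomes)
    chrom_lengths <- as.integer((per_chrom + 1L) * spacing)
    names(chrom_lengths) <- sprintf("chr%02d", seq_len(config$n_chromosomes))

    annotation <- data.frame(
      gene_id = gene_id, chrom = chrom, tss = tss, strand = strand,
      transcript_length = transcript_length, half_life = half_life,
      abundance_wt = abundance_wt, tata = tata, saga = saga,
      dependency_class = dependency_class,
      activity_rank_margin = u,
      stringsAsFactors = FALSE
    )
    annotation$telomere_distance <-
      telomere_distance(annotation, chrom_lengths)

    track <- if (build_track) {
      simulate_track(config, annotation, chrom_lengths)
    } else NULL
    list(annotation = annotation, track = track,
         chrom_lengths = chrom_lengths)
  })
}

# Stereotyped promoter occupancy template at bin-centre offset `o` (bp,
# transcription direction). Baseline 0.8; flat NFR over [-200, 0); ~165 bp
# periodic nucleosomes downstream with the +1 peak at +60 bp.
profile_template <- function(o, nfr_depth) {
  v <- rep(0.8, length(o))
  v[o >= -200 & o < 0] <- nfr_depth
  dn <- o >= 0
  v[dn] <- 0.85 + 0.45 * cos(2 * pi * (o[dn] - 60) / 165)
  v
}

simulate_track <- function(config, annotation, chrom_lengths) {
  bs <- config$bin_size
  bins <- lapply(chrom_lengths, function(len) rep(0.8, ceiling(len / bs)))
  half <- 500L
  offs <- seq(-half, half - bs, by = bs)          # bin start offsets
  centres <- offs + bs / 2
  depth <- ifelse(annotation$dependency_class == "unaffected",
                  config$nfr_depth_unaffected, config$nfr_depth_affected)
  for (i in seq_len(nrow(annotation))) {
    tmpl <- profile_template(centres, depth[i])
    tss <- annotation$tss[i]
    if (annotation$strand[i] == "+") {
      idx <- (tss + offs) %/% bs + 1L
    } else {
      # mirrored: genomic bin covering tss - o - bs .. tss - o
      idx <- (tss - offs - bs) %/% bs + 1L
    }
    chr <- annotation$chrom[i]
    ok <- idx >= 1L & idx <= length(bins[[chr]])
    bins[[chr]][idx[ok]] <- tmpl[ok]
  }
  if (config$track_noise_sd > 0) {
    bins <- lapply(bins, function(v)
      v + stats::rnorm(length(v), 0, config$track_noise_sd))
  }
  structure(list(bins = bins, bin_size = bs, chrom_lengths = chrom_lengths),
            class = "nucleosome_track")
}

#' @export
print.nucleosome_track <- function(x, ...) {
  cat(sprintf("<nucleosome_track> %d chromosomes, %d bp bins, %d bins total\n",
              length(x$bins), x$bin_size,
              sum(lengths(x$bins))))
  invisible(x)
}

#' Simulate expression arrays with spike-ins and planted effects
#'
#' Builds a gene-by-array intensity matrix for all configured strains in
#' `config$n_replicates` biological replicates. Wild-type expectation is the
#' annotated abundance. For the double mutant (`top1top2`) the expectation is
#' `abundance * global_scale * 2^effect` where `effect` is
#' `activity_effect * u` (activity rank margin `u`) for `affected_down`
#' genes, `+up_offset` for `affected_up` genes, and 0 otherwise, recentred
#' by the abundance-weighted mean fold change so that `global_scale` is
#' exactly the planted mutant/wild-type total-mRNA ratio; single
#' mutants are scaled by `single_scale` with no class effects. Spike-in rows
#' have a class- and strain-independent expectation (added per equal cell
#' number), spanning three decades. Multiplicative log-normal noise with
#' log2-sd `noise_sd` is applied to every intensity.
#'
#' The expected measured SLR (after exact spike-in normalization), i.e.
#' `log2(scale) + effect`, is stored per mutant strain in
#' `attr(, "ground_truth")`.
#'
#' @param config a [sim_config()].
#' @param annotation annotation table from [simulate_genome()].
#' @param array_scales optional numeric vector (one value per array, in
#'   strain-major replicate order) of technical per-array scale distortions
#'   applied to all rows including spike-ins; exactly what spike-in
#'   normalization must undo.
#' @return an [expression_matrix()] with attributes `ground_truth`
#'   (data.frame: gene_id, dependency_class, one expected-SLR column per
#'   mutant strain) and `array_scales`.
#' @export
simulate_arrays <- function(config, annotation, array_scales = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(annotation)
  strains <- config$strains
  reps <- config$n_replicates
  arrays <- data.frame(
    strain = rep(strains, each = reps),
    replicate = rep(seq_len(reps), times = length(strains)),
    stringsAsFactors = FALSE
  )
  n_arr <- nrow(arrays)
  if (is.null(array_scales)) array_scales <- rep(1, n_arr)
  stopifnot(length(array_scales) == n_arr, all(array_scales > 0))

  spike_abund <- 10^seq(1, 4, length.out = config$n_spikeins)
  spike_ids <- sprintf("spike_%03d", seq_len(config$n_spikeins))

  effect <- planted_effects(config, annotation)
  expect_gene <- vapply(seq_len(n_arr), function(a) {
    s <- arrays$strain[a]
    annotation$abundance_wt * 2^effect[[s]]
  }, numeric(n))
  expect_spike <- matrix(spike_abund, nrow = config$n_spikeins, ncol = n_arr)

  expectation <- rbind(expect_gene, expect_spike)
  expectation <- sweep(expectation, 2, array_scales, `*`)
  with_sim_seed(config$seed, 2L, {
    noise <- if (config$noise_sd > 0) {
      matrix(2^stats::rnorm(length(expectation), 0, config$noise_sd),
             nrow = nrow(expectation))
    } else 1
    intensities <- expectation * noise
  })
  ids <- c(annotation$gene_id, spike_ids)
  spikein <- c(rep(FALSE, n), rep(TRUE, config$n_spikeins))
  em <- expression_matrix(intensities, gene_ids = ids, spikein = spikein,
                          arrays = arrays)
  gt <- data.frame(gene_id = annotation$gene_id,
                   dependency_class = annotation$dependency_class,
                   stringsAsFactors = FALSE)
  for (s in setdiff(strains, "wt")) gt[[paste0("slr_", s)]] <- effect[[s]]
  attr(em, "ground_truth") <- gt
  attr(em, "array_scales") <- array_scales
  em
}

# Expected log2 effect (vs wild-type expectation) per strain, per gene.
# Class effects are recentred on the total-signal scale (divided by their
# abundance-weighted mean fold change W) so that `global_scale` is exactly
# the planted mutant/wild-type total-mRNA ratio, on top of which the class
# effects redistribute signal between genes.
planted_effects <- function(config, annotation) {
  n <- nrow(annotation)
  out <- list(wt = rep(0, n))
  class_effect <- rep(0, n)
  down <- annotation$dependency_class == "affected_down"
  up <- annotation$dependency_class == "affected_up"
  class_effect[down] <- config$activity_effect *
    annotation$activity_rank_margin[down]
  class_effect[up] <- config$up_offset
  w <- sum(annotation$abundance_wt * 2^class_effect) /
    sum(annotation$abundance_wt)
  class_effect <- class_effect - log2(w)
  for (s in setdiff(config$strains, "wt")) {
    out[[s]] <- if (s == "top1top2") {
      log2(config$global_scale) + class_effect
    } else {
      rep(log2(config$single_scale), n)
    }
  }
  out
}

#' Simulate a condition compendium of log2 expression ratios
#'
#' Gene-by-condition log2 ratios, mean 0, with per-gene sd
#' `plasticity_sd_high` for affected genes and `plasticity_sd_low` otherwise.
#' This emulates both the environmental-change compendium used for the
#' responsiveness statistic and the larger collection behind transcriptional
#' plasticity: affected genes have a wide dynamic range across conditions.
#'
#' @param config a [sim_config()].
#' @param annotation annotation from [simulate_genome()].
#' @return numeric matrix (genes x conditions) with dimnames, class
#'   `compendium_matrix`.
#' @export
simulate_compendium <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_conditions < 2L)
    stop("invalid simulation config: n_conditions must be >= 2")
  n <- nrow(annotation)
  sd_g <- ifelse(annotation$dependency_class == "unaffected",
                 config$plasticity_sd_low, config$plasticity_sd_high)
  with_sim_seed(config$seed, 3L, {
    m <- matrix(stats::rnorm(n * config$n_conditions, 0, sd_g),
                nrow = n, ncol = config$n_conditions)
  })
  dimnames(m) <- list(annotation$gene_id,
                      sprintf("cond_%03d", seq_len(config$n_conditions)))
  class(m) <- c("compendium_matrix", class(m))
  m
}

#' Default qPCR/ChIP kinetics for the synthetic study
#'
#' Two ChIP targets at an inducible promoter (transcription-factor binding
#' rising upon induction in wild-type, flat in the double mutant; histone H3
#' occupancy falling in wild-type as promoter nucleosomes are evicted, flat
#' in the mutant) plus mRNA induction time courses (strong induction in
#' wild-type, none in the mutant). Trajectories are IP/background fold
#' enrichments at the target region after control-locus normalization
#' (`fold`), or relative mRNA quantities (`quantity`), at `timepoints`
#' minutes after induction.
#'
#' @return nested list: `timepoints`, `chip` (locus -> strain -> fold
#'   trajectory), `expression` (locus -> strain -> quantity trajectory).
#' @export
default_chip_kinetics <- function() {
  list(
    timepoints = c(0, 45, 90, 135, 180),
    chip = list(
      TF_UAS = list(wt = c(1, 2, 4, 6, 8),
                    top1top2 = c(1, 1, 1, 1, 1)),
      H3_prom = list(wt = c(1, 0.8, 0.55, 0.4, 0.3),
                     top1top2 = c(1, 1, 1, 1, 1))
    ),
    expression = list(
      PHO5 = list(wt = c(1, 2, 8, 30, 100),
                  top1top2 = c(1, 1, 1, 1, 1))
    )
  )
}

#' Simulate qPCR Ct tables (expression and ChIP series)
#'
#' Converts the planted trajectories in `config$chip_kinetics` into triplicate
#' Ct values via `Ct = -log2(quantity) + offset + noise`. For ChIP loci, four
#' channels are emitted per timepoint: IP and background at the target region
#' and at a control region; the planted normalized fold enrichment
#' `(IP/background at target) / (IP/background at control)` equals the
#' trajectory value. For expression loci a single `input_cDNA` channel is
#' emitted.
#'
#' @param config a [sim_config()]; `ct_noise_sd` controls per-well Ct noise.
#' @return data.frame with columns locus, strain, timepoint_min, channel
#'   (IP/background/input_cDNA), region (target/control), ct_1..ct_3, and
#'   attribute `ground_truth` (data.frame of planted fold/quantity per locus,
#'   strain, timepoint).
#' @export
simulate_qpcr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  kin <- config$chip_kinetics
  tps <- kin$timepoints
  offset <- 30          # cycles; cancels in every downstream ratio
  base_q <- 2^-10       # background quantity at the target region
  ctrl_q <- 2^-9        # input quantity at the control region
  ip_eff <- 4           # antibody capture fold at the control locus
  rows <- list(); truth <- list()
  add_row <- function(locus, strain, tp, channel, region, q) {
    if (any(q <= 0)) stop("non-positive qPCR quantity for locus ", locus)
    rows[[length(rows) + 1L]] <<- data.frame(
      locus = locus, strain = strain, timepoint_min = tp, channel = channel,
      region = region, ct = -log2(q) + offset, stringsAsFactors = FALSE)
  }
  for (locus in names(kin$chip)) {
    for (strain in names(kin$chip[[locus]])) {
      fold <- kin$chip[[locus]][[strain]]
      stopifnot(length(fold) == length(tps))
      for (j in seq_along(tps)) {
        add_row(locus, strain, tps[j], "IP", "target",
                base_q * ip_eff * fold[j])
        add_row(locus, strain, tps[j], "background", "target", base_q)
        add_row(locus, strain, tps[j], "IP", "control", ctrl_q * ip_eff)
        add_row(locus, strain, tps[j], "background", "control", ctrl_q)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        locus = locus, strain = strain, timepoint_min = tps,
        type = "chip_fold", value = fold, stringsAsFactors = FALSE)
    }
  }
  for (locus in names(kin$expression)) {
    for (strain in names(kin$expression[[locus]])) {
      q <- kin$expression[[locus]][[strain]]
      stopifnot(length(q) == length(tps))
      for (j in seq_along(tps)) {
        add_row(locus, strain, tps[j], "input_cDNA", "target", 2^-12 * q[j])
      }
      truth[[length(truth) + 1L]] <- data.frame(
        locus = locus, strain = strain, timepoint_min = tps,
        type = "quantity", value = q, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  with_sim_seed(config$seed, 4L, {
    for (k in 1:3) {
      tab[[paste0("ct_", k)]] <-
        tab$ct + stats::rnorm(nrow(tab), 0, config$ct_noise_sd)
    }
  })
  tab$ct <- NULL
  attr(tab, "ground_truth") <- do.call(rbind, truth)
  tab
}
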