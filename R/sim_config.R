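#' Simulation configuration for the synthetic topoisomerase study
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' emulate the design of the study the pipeline analyses: four strains
#' (wild-type, two single topoisomerase mutants, the double mutant) in
#' biological triplicate, external spike-ins added per equal cell number, a
#' ~30% global mRNA drop in the double mutant with activity-dependent
#' down-regulation, an environmental-response compendium of 173 profiles, and
#' a nucleosome occupancy track with a class-dependent nucleosome-free region
#' (NFR).
#'
#' Planted structure:
#' * `global_scale` is the total-mRNA level of the double mutant relative to
#'   wild-type (0.7 = 30% drop); `single_scale` the same for each single
#'   mutant.
#' * A fraction `frac_affected` of genes is topoisomerase-dependent,
#'   deterministically assigned by transcriptional-activity quantile:
#'   the top `(1 - up_share) * frac_affected` of the activity ranking is
#'   `affected_down`, the bottom `up_share * frac_affected` is `affected_up`.
#' * In the double mutant, `affected_down` genes get an expected SLR
#'   contribution `activity_effect * u` where `u` in (0,1) is the gene's
#'   activity rank margin; `affected_up` genes get `+up_offset`; unaffected
#'   genes 0. The measured SLR additionally carries `log2(global_scale)`.
#' * Affected genes have high per-condition compendium spread
#'   (`plasticity_sd_high`) and a shallower (more occupied) NFR
#'   (`nfr_depth_affected`); unaffected genes the low/deep counterparts.
#'
#' @param seed integer seed; identical configs give bit-identical outputs.
#' @param n_genes number of (non-spike-in) genes.
#' @param n_spikeins number of external spike-in rows, spanning three decades
#'   of abundance (a generic external-control kit layout; the real kit's
#'   composition is not modelled).
#' @param n_replicates biological replicates per strain.
#' @param strains character vector of strains to simulate; the first must be
#'   `"wt"`; `"top1top2"` is the double mutant carrying the planted class
#'   effects, any other strain is treated as a single mutant with
#'   `single_scale` only.
#' @param global_scale total-mRNA level of the double mutant relative to
#'   wild-type, in (0, 1].
#' @param single_scale same for single mutants.
#' @param activity_effect slope (log2 units, <= 0) of expected SLR on
#'   activity-rank margin for `affected_down` genes.
#' @param up_offset positive expected SLR offset (log2) for `affected_up`
#'   genes.
#' @param noise_sd log2-scale sd of multiplicative measurement noise on
#'   intensities.
#' @param frac_affected fraction of genes in the topoisomerase-dependent
#'   class, in \[0, 1\].
#' @param up_share share of the affected class assigned `affected_up`.
#' @param n_conditions number of compendium profiles.
#' @param plasticity_sd_high,plasticity_sd_low per-condition log2-ratio sd for
#'   affected / unaffected genes.
#' @param nfr_depth_affected,nfr_depth_unaffected NFR occupancy level planted
#'   for affected / unaffected genes (occupancy units).
#' @param track_noise_sd per-bin Gaussian noise sd on the occupancy track.
#' @param bin_size occupancy track resolution in bp.
#' @param n_chromosomes number of chromosomes genes are laid out on.
#' @param gene_spacing distance between consecutive TSSs on a chromosome (bp).
#' @param detection_floor default intensity floor used downstream.
#' @param ct_noise_sd per-well Ct noise sd (cycles) in the qPCR generator.
#' @param chip_kinetics per-locus enrichment trajectories for the qPCR/ChIP
#'   generator; see [simulate_qpcr()] for the structure and the default.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 6000L,
                       n_spikeins = 96L,
                       n_replicates = 3L,
                       strains = c("wt", "top1", "top2", "top1top2"),
                       global_scale = 0.7,
                       single_scale = 0.9,
                       activity_effect = -2,
                       up_offset = 2,
                       noise_sd = 0.1,
                       frac_affected = 0.2,
                       up_share = 0.15,
                       n_conditions = 173L,
                       plasticity_sd_high = 1.0,
                       plasticity_sd_low = 0.35,
                       nfr_depth_affected = 0.5,
                       nfr_depth_unaffected = 0.2,
                       track_noise_sd = 0.2,
                       bin_size = 10L,
                       n_chromosomes = 16L,
                       gene_spacing = 2000L,
                       detection_floor = 1,
                       ct_noise_sd = 0.15,
                       chip_kinetics = NULL) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_spikeins = as.integer(n_spikeins),
    n_replicates = as.integer(n_replicates), strains = as.character(strains),
    global_scale = global_scale, single_scale = single_scale,
    activity_effect = activity_effect, up_offset = up_offset,
    noise_sd = noise_sd, frac_affected = frac_affected, up_share = up_share,
    n_conditions = as.integer(n_conditions),
    plasticity_sd_high = plasticity_sd_high,
    plasticity_sd_low = plasticity_sd_low,
    nfr_depth_affected = nfr_depth_affected,
    nfr_depth_unaffected = nfr_depth_unaffected,
    track_noise_sd = track_noise_sd, bin_size = as.integer(bin_size),
    n_chromosomes = as.integer(n_chromosomes),
    gene_spacing = as.integer(gene_spacing),
    detection_floor = detection_floor, ct_noise_sd = ct_noise_sd,
    chip_kinetics = if (is.null(chip_kinetics)) default_chip_kinetics()
                    else chip_kinetics
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot_config(cfg$n_genes >= 1L, "n_genes must be >= 1")
  stopifnot_config(cfg$n_spikeins >= 1L, "n_spikeins must be >= 1")
  stopifnot_config(cfg$n_replicates >= 1L, "n_replicates must be >= 1")
  stopifnot_config(cfg$n_conditions >= 2L, "n_conditions must be >= 2")
  stopifnot_config(cfg$n_chromosomes >= 1L, "n_chromosomes must be >= 1")
  stopifnot_config(cfg$global_scale > 0 && cfg$global_scale <= 1,
                   "global_scale must be in (0, 1]")
  stopifnot_config(cfg$single_scale > 0 && cfg$single_scale <= 1,
                   "single_scale must be in (0, 1]")
  stopifnot_config(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  stopifnot_config(cfg$activity_effect <= 0, "activity_effect must be <= 0")
  stopifnot_config(cfg$frac_affected >= 0 && cfg$frac_affected <= 1,
                   "frac_affected must be in [0, 1]")
  stopifnot_config(cfg$up_share >= 0 && cfg$up_share <= 1,
                   "up_share must be in [0, 1]")
  stopifnot_config(identical(cfg$strains[1L], "wt"),
                   "first strain must be 'wt'")
  stopifnot_config(!anyDuplicated(cfg$strains), "strains must be unique")
  invisible(cfg)
}

stopifnot_config <- function(ok, msg) {
  if (!isTRUE(ok)) stop("invalid simulation config: ", msg, call. = FALSE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  flat <- config_to_pairs(x)
  cat(sprintf("  %s: %s\n", names(flat), unlist(flat)), sep = "")
  invisible(x)
}

# Flatten a config into key: value pairs (chip_kinetics serialized as YAML)
# for the run manifest's verbatim config echo.
config_to_pairs <- function(cfg) {
  keys <- setdiff(names(cfg), "chip_kinetics")
  out <- lapply(cfg[keys], function(v) paste(format(v, digits = 15),
                                             collapse = ","))
  out$chip_kinetics <- gsub("\n", " | ",
                            yaml::as.yaml(cfg$chip_kinetics))
  out
}

# Scoped RNG: every generator op draws from its own deterministic stream so
# outputs do not depend on call order; the caller's RNG state is restored.
with_sim_seed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed + offset, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}
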