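#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the design of the genome-wide experiment: wild-type, two single
# topoisomerase mutants and the top1/top2 double mutant in biological
# triplicate, external spike-ins added per equal cell number, plus the
# external covariates the analysis consumes (half-lives, transcript lengths,
# a binned nucleosome occupancy track, a 173-profile condition compendium,
# and qPCR/ChIP time courses). All downstream stages read these files.

suppressPackageStartupMessages(library(topotrans))

seed <- 1L
data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
genome <- simulate_genome(cfg)
ann <- genome$annotation
em <- simulate_arrays(cfg, ann)
comp <- simulate_compendium(cfg, ann)
ct <- simulate_qpcr(cfg)

write_annotation_tsv(ann, file.path(data_dir, "annotation.tsv"))
write_expression_tsv(em, file.path(data_dir, "expression.tsv"))
write_compendium_tsv(comp, file.path(data_dir, "compendium.tsv"))
write_bedgraph(genome$track, file.path(data_dir, "occupancy.bedGraph"))
write_tss_bed(ann, genome$chrom_lengths, file.path(data_dir, "genes.bed"))
write_ct_tsv(ct, file.path(data_dir, "qpcr_ct.tsv"))
# ground truth kept alongside for the final comparison stages
write_tsv <- function(df, p) utils::write.table(df, p, sep = "\t",
                                                quote = FALSE,
                                                row.names = FALSE)
write_tsv(attr(em, "ground_truth"), file.path(data_dir, "ground_truth.tsv"))

cls <- table(ann$dependency_class)
cat(sprintf(
  "simulated %d genes (+%d spike-ins) x %d arrays; classes: %s\n",
  cfg$n_genes, cfg$n_spikeins, ncol(em$intensities),
  paste(names(cls), cls, sep = "=", collapse = ", ")))
cat(sprintf("planted: total mRNA in top1top2 = %.0f%% of wild-type, %d compendium conditions, NFR depths %.1f vs %.1f\n",
            100 * cfg$global_scale, cfg$n_conditions,
            cfg$nfr_depth_affected, cfg$nfr_depth_unaffected))
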