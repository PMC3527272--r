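#!/usr/bin/env Rscript
# Stage 5: set overlaps and the profile correlation screen.
#
# Tests the 2-fold deregulated genes for hypergeometric overlap with the
# TATA-containing and SAGA-dependent gene classes, runs flat-category
# enrichment at the stringent 1e-3 cutoff, and screens the double-mutant SLR
# profile against a library of expression profiles (Pearson R, permutation
# P, and overlap P_o between each pair's 5th/95th-percentile deregulated
# sets).

suppressPackageStartupMessages(library(topotrans))

out_dir <- "results/enrichment"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
ann <- read_annotation_tsv("results/data/annotation.tsv")
slr <- utils::read.delim("results/normalization/slr_top1top2.tsv")
comp <- read_compendium_tsv("results/data/compendium.tsv")

dereg <- slr$gene_id[abs(slr$slr) >= 1]
tata <- ann$gene_id[ann$tata]
saga <- ann$gene_id[ann$saga]
p_tata <- hypergeometric_overlap(length(intersect(dereg, tata)),
                                 length(tata), length(dereg), nrow(ann))
p_saga <- hypergeometric_overlap(length(intersect(dereg, saga)),
                                 length(saga), length(dereg), nrow(ann))
cat(sprintf("deregulated set (n=%d): TATA overlap P = %.3g; SAGA overlap P = %.3g\n",
            length(dereg), p_tata, p_saga))

ann_map <- c(list(TATA = tata, SAGA = saga), split(ann$gene_id, ann$chrom))
enr <- annotation_enrichment(dereg, ann_map, universe = ann$gene_id,
                             p_cutoff = 1e-3)
utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("categories enriched at P <= 1e-3: %s\n",
            paste(enr$category_id, collapse = ", ")))

lib <- lapply(seq_len(6), function(j)
  data.frame(gene_id = rownames(comp), slr = comp[, j]))
names(lib) <- colnames(comp)[1:6]
lib$self_halved <- data.frame(gene_id = slr$gene_id, slr = slr$slr / 2)
screen <- compendium_correlation_screen(slr, lib, n_perm = 1000, seed = 1)
utils::write.table(screen, file.path(out_dir, "correlation_screen.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("screen top hit: %s (R = %.2f, P = %.3g, P_o = %.3g); compendium conditions stay null\n",
            screen$profile[1], screen$R[1], screen$P[1], screen$P_o[1]))
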