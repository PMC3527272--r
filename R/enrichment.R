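#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing an overlap of at least `k` genes between a set of
#' size `set_a_size` and one of size `set_b_size` drawn from a universe of
#' `universe` genes: `P(X >= k)` for
#' `X ~ Hypergeometric(universe, set_a_size, set_b_size)`. Enrichment only
#' (upper tail); computed via [stats::phyper()], which works on stable log
#' scales internally.
#'
#' @param k observed overlap count.
#' @param set_a_size,set_b_size set sizes.
#' @param universe universe size.
#' @return p-value in (0, 1].
#' @export
hypergeometric_overlap <- function(k, set_a_size, set_b_size, universe) {
  if (k < 0 || set_a_size < 0 || set_b_size < 0 ||
      set_a_size > universe || set_b_size > universe ||
      k > min(set_a_size, set_b_size))
    stop("inconsistent hypergeometric bounds")
  stats::phyper(k - 1, set_a_size, universe - set_a_size, set_b_size,
                lower.tail = FALSE)
}

#' Annotation-category enrichment of a gene set
#'
#' Per flat category, the upper-tail hypergeometric probability of the
#' observed overlap with `gene_set`; records with `p <= p_cutoff` are
#' returned sorted by p. Mirroring the category-analysis convention the
#' pipeline emulates, no multiple-testing correction gates the cutoff, but a
#' Bonferroni column is reported for transparency.
#'
#' @param gene_set character vector of gene ids (the input cluster).
#' @param annotation_map named list: category id -> character vector of
#'   member gene ids.
#' @param universe character vector of universe gene ids; defaults to the
#'   union of all annotated genes.
#' @param p_cutoff report categories at or below this raw p.
#' @return data.frame: category_id, k (overlap), f (category size),
#'   set_size, universe_size, p, p_bonferroni; sorted ascending by p.
#' @export
annotation_enrichment <- function(gene_set, annotation_map, universe = NULL,
                                  p_cutoff = 1e-3) {
  if (is.null(universe)) universe <- unique(unlist(annotation_map))
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  gene_set <- unique(intersect(gene_set, universe))
  if (!length(gene_set)) stop("empty gene set (after universe restriction)")
  n_cat <- length(annotation_map)
  rows <- lapply(names(annotation_map), function(cat) {
    members <- intersect(annotation_map[[cat]], universe)
    k <- length(intersect(gene_set, members))
    p <- hypergeometric_overlap(k, length(members), length(gene_set),
                                length(universe))
    data.frame(category_id = cat, k = k, f = length(members),
               set_size = length(gene_set),
               universe_size = length(universe),
               p = p, p_bonferroni = min(1, p * n_cat),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$p <= p_cutoff, , drop = FALSE]
  out[order(out$p, out$category_id), , drop = FALSE]
}

#' Most-deregulated genes by SLR percentile
#'
#' Union of genes at or below the `lower` quantile and at or above the
#' `upper` quantile of SLR, by rank: the extreme `floor(lower * n)` /
#' `n - ceiling(upper * n)` genes, with boundary ties included on the
#' extreme side (the set may therefore exceed its nominal size). A fully
#' tied SLR vector returns all genes with a warning.
#'
#' @param slr_table data.frame with `gene_id` and `slr` (n >= 20).
#' @param lower,upper percentile bounds.
#' @return character vector of gene ids, attributes `lower_set`/`upper_set`.
#' @export
percentile_deregulated <- function(slr_table, lower = 0.05, upper = 0.95) {
  n <- nrow(slr_table)
  stopifnot(n >= 20L)
  slr <- slr_table$slr
  if (stats::sd(slr) == 0) {
    warning("degenerate SLR distribution: all values tied; returning all genes")
    return(structure(slr_table$gene_id,
                     lower_set = slr_table$gene_id,
                     upper_set = slr_table$gene_id))
  }
  srt <- sort(slr)
  n_low <- floor(lower * n)
  n_high <- n - ceiling(upper * n)
  lo_set <- if (n_low > 0) slr_table$gene_id[slr <= srt[n_low]] else character()
  hi_set <- if (n_high > 0)
    slr_table$gene_id[slr >= srt[n - n_high + 1L]] else character()
  structure(union(lo_set, hi_set), lower_set = lo_set, upper_set = hi_set)
}

#' Correlation screen of an SLR profile against a profile library
#'
#' For each library profile sharing at least `min_overlap` genes with the
#' SLR table: the Pearson correlation R with a permutation p-value P (see
#' [pearson_with_permutation()]), and the hypergeometric overlap probability
#' P_o between the two profiles' most-deregulated gene sets (5th/95th SLR
#' percentiles of each, universe = jointly measured genes). Profiles with
#' insufficient overlap are skipped with a message. A Benjamini-Hochberg
#' column over the permutation Ps is added as optional metadata.
#'
#' @param slr_table data.frame with `gene_id` and `slr`.
#' @param profile_library named list of data.frames, each with `gene_id` and
#'   `slr` columns (or two columns id/value).
#' @param n_perm,seed permutation-test settings.
#' @param min_overlap minimum number of shared genes.
#' @return data.frame: profile, n_genes, R, P, P_o, P_bh; sorted by P then
#'   P_o.
#' @export
compendium_correlation_screen <- function(slr_table, profile_library,
                                          n_perm = 1000L, seed = 1L,
                                          min_overlap = 100L) {
  rows <- list()
  for (nm in names(profile_library)) {
    prof <- profile_library[[nm]]
    if (!all(c("gene_id", "slr") %in% names(prof))) {
      names(prof)[1:2] <- c("gene_id", "slr")
    }
    shared <- intersect(slr_table$gene_id, prof$gene_id)
    if (length(shared) < min_overlap) {
      message("screen: skipping profile '", nm, "' (only ", length(shared),
              " shared genes)")
      next
    }
    a <- slr_table[match(shared, slr_table$gene_id), c("gene_id", "slr")]
    b <- prof[match(shared, prof$gene_id), c("gene_id", "slr")]
    ok <- is.finite(a$slr) & is.finite(b$slr)
    a <- a[ok, ]; b <- b[ok, ]
    pc <- pearson_with_permutation(a$slr, b$slr, n_perm = n_perm, seed = seed)
    da <- percentile_deregulated(a)
    db <- percentile_deregulated(b)
    k <- length(intersect(da, db))
    po <- hypergeometric_overlap(k, length(da), length(db), nrow(a))
    rows[[nm]] <- data.frame(profile = nm, n_genes = nrow(a),
                             R = pc$r, P = pc$p, P_o = po,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no profile had sufficient gene overlap")
  out <- do.call(rbind, rows)
  out$P_bh <- stats::p.adjust(out$P, method = "BH")
  out[order(out$P, out$P_o), , drop = FALSE]
}
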