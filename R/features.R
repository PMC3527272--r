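#' Transcriptional activity: abundance over half-life
#'
#' A synthesis-rate proxy: average wild-type expression divided by the
#' gene's mRNA half-life, median-normalized over genes with both covariates
#' (so the reported activity is scale-free). Genes lacking a positive
#' half-life are excluded and flagged.
#'
#' @param abundance_wt per-gene wild-type abundance (averaged over
#'   replicates).
#' @param half_life per-gene mRNA half-life in minutes (> 0; NA allowed).
#' @param gene_id optional identifiers.
#' @return data.frame: gene_id, raw_activity, activity (median-normalized;
#'   NA for excluded genes), excluded (logical).
#' @export
transcriptional_activity <- function(abundance_wt, half_life,
                                     gene_id = NULL) {
  n <- length(abundance_wt)
  stopifnot(length(half_life) == n)
  if (is.null(gene_id)) gene_id <- sprintf("g%09d", seq_len(n))
  excluded <- is.na(half_life) | half_life <= 0
  raw <- ifelse(excluded, NA_real_, abundance_wt / half_life)
  med <- stats::median(raw, na.rm = TRUE)
  data.frame(gene_id = gene_id, raw_activity = raw, activity = raw / med,
             excluded = excluded, stringsAsFactors = FALSE)
}

#' Responsiveness to environmental change / transcriptional plasticity
#'
#' Per gene, the mean over conditions of the squared log2 expression ratio
#' (missing entries ignored), standardized over genes to mean 0 and sd 1
#' (sample sd, n-1 denominator). Computed on an environmental-stress
#' compendium this is the responsiveness statistic; computed on a large
#' general profile collection it is transcriptional plasticity — the same
#' dynamic-range statistic on a different compendium, so [plasticity()] is
#' an alias.
#'
#' Standardization is applied to the per-gene means (after averaging), a
#' convention recorded in the result's `convention` attribute.
#'
#' @param compendium numeric gene-by-condition matrix of log2 ratios
#'   (rownames = gene ids); NAs allowed.
#' @param max_missing maximum tolerated per-gene fraction of missing
#'   conditions; genes above it get NA.
#' @return named numeric vector of standardized per-gene measures, attribute
#'   `convention`.
#' @export
responsiveness <- function(compendium, max_missing = 0.5) {
  m <- as.matrix(compendium)
  if (ncol(m) < 2L) stop("compendium needs >= 2 conditions")
  msq <- rowMeans(m^2, na.rm = TRUE)
  frac_na <- rowMeans(is.na(m))
  msq[frac_na > max_missing] <- NA_real_
  s <- stats::sd(msq, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("degenerate compendium: zero variance of per-gene mean squared ratios")
  z <- (msq - mean(msq, na.rm = TRUE)) / s
  names(z) <- rownames(m)
  attr(z, "convention") <-
    "mean over conditions of squared log2 ratio, then standardized over genes (sample sd, n-1)"
  z
}

#' @rdname responsiveness
#' @param ... passed to [responsiveness()].
#' @export
plasticity <- function(compendium, ...) responsiveness(compendium, ...)

#' Join an externally supplied per-gene measure by gene id
#'
#' @param gene_ids target gene order.
#' @param table data.frame whose first two columns are gene id and the
#'   measure (any row order).
#' @return numeric vector aligned to `gene_ids` (NA where absent), attribute
#'   `coverage` = joined fraction. Warns below 50% coverage, errors at 0%.
#' @export
ingest_external_measure <- function(gene_ids, table) {
  stopifnot(ncol(table) >= 2L)
  v <- as.numeric(table[[2L]])
  names(v) <- as.character(table[[1L]])
  out <- unname(v[gene_ids])
  coverage <- mean(!is.na(out))
  if (coverage == 0) stop("no gene ids matched the external measure")
  if (coverage < 0.5)
    warning(sprintf("external measure joins only %.0f%% of genes",
                    100 * coverage))
  attr(out, "coverage") <- coverage
  out
}

#' Pooled-variance two-sample t-test
#'
#' Unpaired two-sample t assuming equal variances, df = nA + nB - 2. This
#' single implementation backs both the feature-group comparisons
#' (responsiveness / telomere distance of deregulated genes vs the rest) and
#' the NFR occupancy test.
#'
#' @param a,b numeric vectors (each length >= 2, at least one jointly
#'   non-degenerate).
#' @param alternative "two.sided", "less" (mean(a) < mean(b)) or "greater".
#' @return list: t, df, p, mean_a, mean_b.
#' @export
pooled_ttest <- function(a, b, alternative = c("two.sided", "less",
                                               "greater")) {
  alternative <- match.arg(alternative)
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2L, nb >= 2L)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 == 0) stop("zero pooled variance")
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
              less = stats::pt(t, df),
              greater = stats::pt(t, df, lower.tail = FALSE))
  list(t = t, df = df, p = p, mean_a = mean(a), mean_b = mean(b))
}

#' Compare a per-gene feature between a gene set and the rest
#'
#' @param values named numeric vector (names = gene ids) of the feature.
#' @param member_set gene ids of the group of interest.
#' @param alternative as in [pooled_ttest()]; use "greater" for a one-sided
#'   test of higher feature values in the set.
#' @return [pooled_ttest()] result plus `n_set`, `n_rest`.
#' @export
group_feature_ttest <- function(values, member_set,
                                alternative = "two.sided") {
  stopifnot(!is.null(names(values)))
  inset <- names(values) %in% member_set
  a <- values[inset & !is.na(values)]
  b <- values[!inset & !is.na(values)]
  res <- pooled_ttest(a, b, alternative)
  res$n_set <- length(a); res$n_rest <- length(b)
  res
}

#' Distance from each gene's TSS to the closest telomere
#'
#' @param annotation data.frame with `chrom` and `tss` (0-based).
#' @param chrom_lengths named vector of chromosome lengths covering all
#'   genes' chromosomes.
#' @return numeric vector of distances in bp.
#' @export
telomere_distance <- function(annotation, chrom_lengths) {
  missing_chr <- setdiff(unique(annotation$chrom), names(chrom_lengths))
  if (length(missing_chr))
    stop("no chromosome length for: ", paste(missing_chr, collapse = ", "))
  len <- unname(chrom_lengths[annotation$chrom])
  if (any(annotation$tss < 0 | annotation$tss > len))
    stop("TSS outside [0, chromosome length]")
  pmin(annotation$tss, len - annotation$tss)
}
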