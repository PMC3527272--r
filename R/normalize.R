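#' Spike-in-anchored array normalization
#'
#' Because topoisomerase deficiency shifts the total mRNA pool, ordinary
#' total-signal or quantile normalization would erase exactly the effect
#' under study. Spike-ins added per equal cell number are instead used as the
#' anchor: a geometric-mean pseudo-array is formed over the spike-in rows,
#' and each array's scale factor is the median over spike-in rows of
#' (pseudo-array intensity / array intensity). Normalized intensities are raw
#' intensities times the array's factor, so any technical per-array scale
#' distortion is undone while genuine global expression shifts are preserved.
#' The median-of-ratios anchor is this pipeline's own robust choice of
#' external-normalization algorithm.
#'
#' @param em an [expression_matrix()].
#' @return object of class `normalization_result`: `scale_factors` (one per
#'   array), `normalized` (an [expression_matrix()]), `reference`
#'   (description of the anchor).
#' @export
fit_spikein_scale <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  sp <- em$intensities[em$spikein, , drop = FALSE]
  if (nrow(sp) == 0L) stop("no spike-in rows in matrix")
  zero_arrays <- colnames(sp)[apply(sp == 0, 2, any)]
  if (length(zero_arrays))
    stop("zero spike-in intensity on array(s): ",
         paste(zero_arrays, collapse = ", "))
  reference <- exp(rowMeans(log(sp)))   # per-row geometric mean
  factors <- apply(reference / sp, 2, stats::median)
  norm <- em
  norm$intensities <- sweep(em$intensities, 2, factors, `*`)
  structure(list(
    scale_factors = factors,
    normalized = norm,
    reference = "geometric-mean pseudo-array over spike-in rows; per-array factor = median over spike-ins of reference/array (median-of-ratios)"
  ), class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat("<normalization_result>\n  factors:",
      paste(sprintf("%s=%.4g", names(x$scale_factors), x$scale_factors),
            collapse = " "), "\n")
  invisible(x)
}

#' Global mRNA level of a mutant relative to wild-type
#'
#' Total normalized non-spike-in signal per strain (averaged over
#' replicates), restricted to genes detectable in wild-type (mean wild-type
#' intensity above `floor`), expressed as a percentage of the wild-type
#' total (wild-type = 100%).
#'
#' @param result a [fit_spikein_scale()] result.
#' @param mutant_strain,wt_strain strain names.
#' @param floor detection floor (intensity units).
#' @return list: `level` (percent), `per_replicate` (percent per mutant
#'   replicate), `sd` (sd of per-replicate levels), `n_detectable`.
#' @export
global_mrna_level <- function(result, mutant_strain, wt_strain, floor = 1) {
  stopifnot(inherits(result, "normalization_result"))
  em <- result$normalized
  gi <- !em$spikein
  mut <- em$intensities[gi, strain_cols(em, mutant_strain), drop = FALSE]
  wt <- em$intensities[gi, strain_cols(em, wt_strain), drop = FALSE]
  detect <- rowMeans(wt) >= floor
  wt_total <- sum(rowMeans(wt[detect, , drop = FALSE]))
  per_rep <- 100 * colSums(mut[detect, , drop = FALSE]) / wt_total
  list(level = 100 * sum(rowMeans(mut[detect, , drop = FALSE])) / wt_total,
       per_replicate = unname(per_rep),
       sd = stats::sd(per_rep),
       n_detectable = sum(detect))
}

#' Per-gene signal log2 ratio (SLR) between mutant and wild-type
#'
#' For each non-spike-in gene, SLR = mean over mutant replicates of
#' log2(max(intensity, floor)) minus the same mean over wild-type
#' replicates; the standard error assumes independent (unpaired) replicates.
#' The floor guards zero intensities.
#'
#' @param result a [fit_spikein_scale()] result.
#' @param mutant_strain,wt_strain strain names.
#' @param floor intensity floor (> 0).
#' @return data.frame (`differential_table`): gene_id, slr, se,
#'   mean_wt_intensity. Attribute `replicate_slr` holds the per-mutant-
#'   replicate SLRs (each mutant replicate's log2 intensities minus the mean
#'   wild-type log2), used for replicate-level error bars downstream.
#' @export
compute_slr <- function(result, mutant_strain, wt_strain, floor = 1) {
  stopifnot(inherits(result, "normalization_result"), floor > 0)
  em <- result$normalized
  gi <- !em$spikein
  lmut <- log2(pmax(em$intensities[gi, strain_cols(em, mutant_strain),
                                   drop = FALSE], floor))
  lwt <- log2(pmax(em$intensities[gi, strain_cols(em, wt_strain),
                                  drop = FALSE], floor))
  mmut <- rowMeans(lmut); mwt <- rowMeans(lwt)
  vmut <- apply(lmut, 1, stats::var); vwt <- apply(lwt, 1, stats::var)
  se <- sqrt(vmut / ncol(lmut) + vwt / ncol(lwt))
  tab <- data.frame(gene_id = em$gene_ids[gi],
                    slr = mmut - mwt,
                    se = se,
                    mean_wt_intensity = rowMeans(
                      em$intensities[gi, strain_cols(em, wt_strain),
                                     drop = FALSE]),
                    stringsAsFactors = FALSE)
  attr(tab, "replicate_slr") <- lmut - mwt
  class(tab) <- c("differential_table", class(tab))
  tab
}

#' Fractions of up- and down-regulated genes
#'
#' Counts genes with SLR at or beyond the cutoffs. The default cutoffs +1/-1
#' correspond to 2-fold deregulation; the asymmetric +0.5/-1 variant is used
#' for functional-group summaries. If the table carries per-replicate SLRs
#' (see [compute_slr()]), a standard error of the fractions across replicates
#' is reported.
#'
#' @param table a `differential_table` from [compute_slr()] (or any
#'   data.frame with `slr`).
#' @param up_cutoff log2 cutoff (> 0) for up-regulation.
#' @param down_cutoff log2 cutoff (< 0) for down-regulation.
#' @return list: frac_up, frac_down, n_up, n_down, n_total, se_up, se_down
#'   (NA without replicate information).
#' @export
deregulated_fraction <- function(table, up_cutoff = 1, down_cutoff = -1) {
  stopifnot(up_cutoff > 0, down_cutoff < 0)
  if (!nrow(table)) stop("empty differential table")
  slr <- table$slr
  n <- length(slr)
  out <- list(frac_up = sum(slr >= up_cutoff) / n,
              frac_down = sum(slr <= down_cutoff) / n,
              n_up = sum(slr >= up_cutoff),
              n_down = sum(slr <= down_cutoff),
              n_total = n, se_up = NA_real_, se_down = NA_real_)
  rep_slr <- attr(table, "replicate_slr")
  if (!is.null(rep_slr) && ncol(rep_slr) > 1L) {
    fu <- colMeans(rep_slr >= up_cutoff)
    fd <- colMeans(rep_slr <= down_cutoff)
    out$se_up <- stats::sd(fu) / sqrt(length(fu))
    out$se_down <- stats::sd(fd) / sqrt(length(fd))
  }
  out
}
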