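#' TSS-aligned occupancy matrix
#'
#' Extracts, per gene, the occupancy bins covering
#' `[tss - upstream, tss + downstream)` in the direction of transcription:
#' minus-strand genes are read mirrored, so a negative offset is biologically
#' upstream for every gene. Genes whose window falls outside their
#' chromosome are dropped with a message; unknown chromosomes are an error.
#'
#' @param track a `nucleosome_track` (see [simulate_genome()] /
#'   [read_bedgraph()]).
#' @param annotation data.frame with gene_id, chrom, tss, strand.
#' @param upstream,downstream window half-widths in bp (multiples of the
#'   track bin size).
#' @return object of class `tss_matrix`: `occupancy` (gene x offset matrix),
#'   `offsets` (bp, bin starts relative to TSS), `bin_size`.
#' @export
align_to_tss <- function(track, annotation, upstream = 500L,
                         downstream = 500L) {
  stopifnot(inherits(track, "nucleosome_track"))
  bs <- track$bin_size
  stopifnot(upstream %% bs == 0, downstream %% bs == 0)
  unknown <- setdiff(unique(annotation$chrom), names(track$bins))
  if (length(unknown))
    stop("chromosome(s) not in track: ", paste(unknown, collapse = ", "))
  offs <- seq(-upstream, downstream - bs, by = bs)
  centres <- offs + bs / 2
  rows <- matrix(NA_real_, nrow(annotation), length(offs),
                 dimnames = list(annotation$gene_id, offs))
  keep <- logical(nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    chr <- annotation$chrom[i]
    v <- track$bins[[chr]]
    pos <- if (annotation$strand[i] == "+") {
      annotation$tss[i] + centres
    } else {
      annotation$tss[i] - centres
    }
    idx <- pos %/% bs + 1L
    if (any(idx < 1L | idx > length(v))) next
    rows[i, ] <- v[idx]
    keep[i] <- TRUE
  }
  if (!all(keep))
    message("align_to_tss: dropped ", sum(!keep),
            " gene(s) with windows outside their chromosome")
  structure(list(occupancy = rows[keep, , drop = FALSE],
                 offsets = offs, bin_size = bs),
            class = "tss_matrix")
}

#' @export
print.tss_matrix <- function(x, ...) {
  cat(sprintf("<tss_matrix> %d genes x %d offsets [%d, %d] bp, %d bp bins\n",
              nrow(x$occupancy), length(x$offsets), min(x$offsets),
              max(x$offsets) + x$bin_size, x$bin_size))
  invisible(x)
}

#' Meta-profile of a gene group around the TSS
#'
#' Per offset: the group mean occupancy with a 95% t-based confidence
#' interval (`mean +- t_{0.975, n-1} * se`).
#'
#' @param tss_matrix a [align_to_tss()] result.
#' @param group gene ids (>= 2 present in the matrix); defaults to all.
#' @param conf confidence level.
#' @return data.frame: offset, mean, ci_low, ci_high, n.
#' @export
meta_profile <- function(tss_matrix, group = NULL, conf = 0.95) {
  occ <- tss_matrix$occupancy
  if (!is.null(group)) occ <- occ[rownames(occ) %in% group, , drop = FALSE]
  n <- nrow(occ)
  if (n < 2L) stop("group has fewer than 2 genes in the TSS matrix")
  mu <- colMeans(occ)
  se <- apply(occ, 2, stats::sd) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  data.frame(offset = tss_matrix$offsets, mean = mu,
             ci_low = mu - tq * se, ci_high = mu + tq * se, n = n,
             row.names = NULL)
}

#' Select the most up-, most down-, and least-regulated gene groups
#'
#' `most_up` = the `n` largest SLRs, `most_down` = the `n` smallest,
#' `most_unaffected` = the `n` smallest |SLR|; ties broken by gene id. The
#' groups are made disjoint with priority down > up > unaffected (a gene
#' claimed by a higher-priority group is skipped by the later ones).
#'
#' @param diff_table data.frame with `gene_id` and `slr` (>= 3n genes).
#' @param n group size (100 in the genome-wide analyses).
#' @return list of character vectors: most_up, most_down, most_unaffected.
#' @export
select_extreme_genes <- function(diff_table, n = 100L) {
  if (nrow(diff_table) < 3L * n)
    stop("need at least 3 * n genes to form disjoint groups")
  if (stats::sd(diff_table$slr) == 0)
    warning("degenerate SLR distribution: selection by gene id only")
  id <- diff_table$gene_id; slr <- diff_table$slr
  down <- id[order(slr, id)][seq_len(n)]
  up_order <- id[order(-slr, id)]
  up <- setdiff(up_order, down)[seq_len(n)]
  un_order <- id[order(abs(slr), id)]
  unaffected <- setdiff(un_order, c(down, up))[seq_len(n)]
  list(most_up = up, most_down = down, most_unaffected = unaffected)
}

#' NFR occupancy comparison between two gene groups
#'
#' Per gene, mean occupancy over the nucleosome-free-region window (default
#' `[-200, 0)` bp relative to the TSS); the groups are compared by the
#' pooled-variance two-sample t-test ([pooled_ttest()], two-sided), and
#' box-plot statistics (median, quartiles, whiskers at 1.5 IQR) are reported
#' per group.
#'
#' @param tss_matrix a [align_to_tss()] result covering the NFR window.
#' @param group_a,group_b gene id vectors.
#' @param nfr_window `c(start, end)` bp relative to TSS, half-open.
#' @return list: per_gene (data.frame gene_id, group, nfr_occupancy),
#'   summary (per-group boxplot stats), diff (mean A - mean B), t, df, p.
#' @export
nfr_occupancy_test <- function(tss_matrix, group_a, group_b,
                               nfr_window = c(-200, 0)) {
  offs <- tss_matrix$offsets
  sel <- offs >= nfr_window[1] & offs < nfr_window[2]
  if (!any(sel)) stop("empty NFR window")
  nfr <- rowMeans(tss_matrix$occupancy[, sel, drop = FALSE])
  a <- nfr[names(nfr) %in% group_a]
  b <- nfr[names(nfr) %in% group_b]
  tt <- pooled_ttest(a, b, "two.sided")
  boxstats <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    c(q1 = q[1], median = q[2], q3 = q[3],
      whisker_low = min(v[v >= q[1] - 1.5 * iqr]),
      whisker_high = max(v[v <= q[3] + 1.5 * iqr]),
      mean = mean(v), n = length(v))
  }
  per_gene <- data.frame(
    gene_id = c(names(a), names(b)),
    group = rep(c("A", "B"), c(length(a), length(b))),
    nfr_occupancy = c(unname(a), unname(b)), stringsAsFactors = FALSE)
  list(per_gene = per_gene,
       summary = rbind(A = boxstats(a), B = boxstats(b)),
       diff = tt$mean_a - tt$mean_b, t = tt$t, df = tt$df, p = tt$p)
}
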