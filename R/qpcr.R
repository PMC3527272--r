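#' Relative quantity from triplicate Ct values
#'
#' `quantity = efficiency^(-mean(ct))`: one cycle equals one
#' `efficiency`-fold difference in template (2-fold at perfect efficiency).
#' The replicate sd is propagated to a log2-scale standard error.
#'
#' @param ct numeric vector of replicate Ct values (non-empty).
#' @param efficiency amplification efficiency in (1, 2].
#' @return list: quantity, log2_quantity, se_log2, n.
#' @export
relative_quantity <- function(ct, efficiency = 2.0) {
  if (!length(ct) || any(!is.finite(ct))) stop("empty or non-finite Ct values")
  stopifnot(efficiency > 1, efficiency <= 2)
  m <- mean(ct)
  l2 <- -m * log2(efficiency)
  se <- if (length(ct) > 1L) {
    stats::sd(ct) / sqrt(length(ct)) * log2(efficiency)
  } else NA_real_
  list(quantity = 2^l2, log2_quantity = l2, se_log2 = se, n = length(ct))
}

#' ChIP fold enrichment with control-locus normalization
#'
#' Fold increase between the immunoprecipitated (IP) and background channels
#' at the target region, divided by the same fold at a control region:
#' `(q_IP / q_bg)_target / (q_IP / q_bg)_control`. A global Ct offset common
#' to all four records cancels exactly.
#'
#' @param ip,background triplicate Ct vectors at the target region.
#' @param ip_ctrl,background_ctrl triplicate Ct vectors at the control
#'   region.
#' @param efficiency amplification efficiency.
#' @return normalized fold enrichment (numeric scalar).
#' @export
chip_fold_enrichment <- function(ip, background, ip_ctrl, background_ctrl,
                                 efficiency = 2.0) {
  q <- function(ct) relative_quantity(ct, efficiency)$quantity
  fold_target <- q(ip) / q(background)
  fold_ctrl <- q(ip_ctrl) / q(background_ctrl)
  if (!is.finite(fold_ctrl) || fold_ctrl == 0)
    stop("degenerate control-region fold")
  fold_target / fold_ctrl
}

#' ChIP fold-enrichment time course from a Ct table
#'
#' Groups a Ct table (the [simulate_qpcr()] dialect: locus, strain,
#' timepoint_min, channel, region, ct_1..ct_3) by timepoint and applies
#' [chip_fold_enrichment()].
#'
#' @param ct_table Ct data.frame.
#' @param locus,strain which series to extract.
#' @param efficiency amplification efficiency.
#' @return data.frame: timepoint_min, fold.
#' @export
chip_fold_timecourse <- function(ct_table, locus, strain, efficiency = 2.0) {
  sub <- ct_table[ct_table$locus == locus & ct_table$strain == strain, ]
  if (!nrow(sub)) stop("no Ct rows for locus ", locus, ", strain ", strain)
  tps <- sort(unique(sub$timepoint_min))
  ctv <- function(s, chan, reg, tp) {
    r <- s[s$channel == chan & s$region == reg & s$timepoint_min == tp, ]
    if (nrow(r) != 1L) stop("expected one Ct record per channel/region/time")
    as.numeric(r[paste0("ct_", 1:3)])
  }
  fold <- vapply(tps, function(tp) {
    chip_fold_enrichment(ctv(sub, "IP", "target", tp),
                         ctv(sub, "background", "target", tp),
                         ctv(sub, "IP", "control", tp),
                         ctv(sub, "background", "control", tp),
                         efficiency = efficiency)
  }, numeric(1))
  data.frame(timepoint_min = tps, fold = fold)
}

#' Normalize a time-course series to a reference point
#'
#' Conventions used throughout the single-gene analyses:
#' * `t0_to_1`: divide by the value at the first timepoint (set to 1);
#' * `t0_to_100`: same, expressed in percent;
#' * `wt_max_100`: divide by the LAST value of `reference_series` (the
#'   wild-type series), in percent — cross-series normalization;
#' * `named_reference`: divide by the value at index/name `reference`.
#'
#' Normalization to the own first point is idempotent. The fold-increase
#' summary of a series is `last / first` ([fold_increase()]).
#'
#' @param series numeric vector of values per timepoint.
#' @param mode normalization convention.
#' @param reference_series reference series for `wt_max_100`.
#' @param reference index or name of the reference point for
#'   `named_reference`.
#' @return normalized numeric vector.
#' @export
timecourse_normalize <- function(series,
                                 mode = c("t0_to_1", "t0_to_100",
                                          "wt_max_100", "named_reference"),
                                 reference_series = NULL, reference = NULL) {
  mode <- match.arg(mode)
  ref <- switch(mode,
    t0_to_1 = series[[1L]],
    t0_to_100 = series[[1L]],
    wt_max_100 = {
      if (is.null(reference_series)) stop("wt_max_100 needs reference_series")
      reference_series[[length(reference_series)]]
    },
    named_reference = {
      if (is.null(reference)) stop("named_reference needs reference")
      series[[reference]]
    })
  if (!is.finite(ref) || ref == 0) stop("zero or non-finite reference value")
  scale <- if (mode %in% c("t0_to_100", "wt_max_100")) 100 else 1
  series / ref * scale
}

#' @rdname timecourse_normalize
#' @export
fold_increase <- function(series) {
  if (series[[1L]] == 0) stop("zero first value: fold increase undefined")
  series[[length(series)]] / series[[1L]]
}

#' Read / write the Ct table TSV dialect
#' @param tab Ct data.frame ([simulate_qpcr()] layout).
#' @param path file path.
#' @return data.frame (read) or `path`, invisibly (write).
#' @export
write_ct_tsv <- function(tab, path) write_tsv(tab, path)

#' @rdname write_ct_tsv
#' @export
read_ct_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
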