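#' Read and write the pipeline's tabular and genomic file formats
#'
#' Annotation tables and compendia travel as TSV; occupancy tracks as
#' bedGraph (0-based, half-open) and gene TSS intervals as BED6, both via
#' rtracklayer.
#'
#' @param annotation annotation data.frame ([simulate_genome()] layout).
#' @param path file path.
#' @name topotrans_io
NULL

#' @rdname topotrans_io
#' @export
write_annotation_tsv <- function(annotation, path) write_tsv(annotation, path)

#' @rdname topotrans_io
#' @export
read_annotation_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname topotrans_io
#' @param compendium gene x condition matrix with rownames.
#' @export
write_compendium_tsv <- function(compendium, path) {
  df <- data.frame(gene_id = rownames(compendium),
                   as.data.frame(unclass(compendium)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname topotrans_io
#' @export
read_compendium_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[-1L])
  rownames(m) <- df$gene_id
  class(m) <- c("compendium_matrix", class(m))
  m
}

#' @rdname topotrans_io
#' @param track a `nucleosome_track`.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "nucleosome_track"))
  bs <- track$bin_size
  nb <- lengths(track$bins)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(names(track$bins), nb),
    ranges = IRanges::IRanges(
      start = unlist(lapply(nb, function(k)
        seq(1L, by = bs, length.out = k)), use.names = FALSE),
      width = bs),
    score = unlist(track$bins, use.names = FALSE))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname topotrans_io
#' @param bin_size expected bin width in bp.
#' @export
read_bedgraph <- function(path, bin_size = 10L) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # back to 0-based
                   end = GenomicRanges::end(gr),
                   value = gr$score, stringsAsFactors = FALSE)
  bins <- lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start), ]
    if (any(d$end - d$start != bin_size) ||
        any(diff(d$start) != bin_size))
      stop("bedGraph is not a contiguous ", bin_size, " bp binned track")
    d$value
  })
  chrom_lengths <- vapply(bins, function(v) length(v) * bin_size, numeric(1))
  structure(list(bins = bins, bin_size = as.integer(bin_size),
                 chrom_lengths = chrom_lengths),
            class = "nucleosome_track")
}

#' @rdname topotrans_io
#' @param chrom_lengths named chromosome lengths (bp), used to clip
#'   intervals.
#' @export
write_tss_bed <- function(annotation, chrom_lengths, path) {
  len <- unname(chrom_lengths[annotation$chrom])
  plus <- annotation$strand == "+"
  start <- ifelse(plus, annotation$tss,
                  pmax(0L, annotation$tss - annotation$transcript_length + 1L))
  end <- ifelse(plus,
                pmin(len, annotation$tss + annotation$transcript_length),
                annotation$tss + 1L)
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),  # 1-based
    strand = annotation$strand,
    name = annotation$gene_id,
    score = 0L)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
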