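#' Expression matrix with spike-in flags and array metadata
#'
#' The pipeline's raw input: a non-negative gene-by-array intensity matrix,
#' a logical spike-in flag per row, and per-array metadata (strain,
#' replicate). Column names are `strain_replicate`.
#'
#' @param intensities numeric matrix, genes x arrays, all values >= 0.
#' @param gene_ids unique row identifiers.
#' @param spikein logical vector flagging spike-in rows.
#' @param arrays data.frame with columns `strain` and `replicate`; no
#'   duplicate (strain, replicate) pairs.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(intensities, gene_ids, spikein, arrays) {
  intensities <- as.matrix(intensities)
  stopifnot(is.numeric(intensities),
            length(gene_ids) == nrow(intensities),
            length(spikein) == nrow(intensities),
            nrow(arrays) == ncol(intensities),
            all(c("strain", "replicate") %in% names(arrays)))
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (!any(spikein) || all(spikein))
    stop("need at least one spike-in row and one non-spike-in row")
  key <- paste(arrays$strain, arrays$replicate)
  if (anyDuplicated(key)) stop("duplicate (strain, replicate) pairs")
  dimnames(intensities) <- list(gene_ids,
                                paste(arrays$strain, arrays$replicate,
                                      sep = "_"))
  structure(list(intensities = intensities,
                 gene_ids = as.character(gene_ids),
                 spikein = as.logical(spikein),
                 arrays = as.data.frame(arrays)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d genes + %d spike-ins x %d arrays (%s)\n",
    sum(!x$spikein), sum(x$spikein), ncol(x$intensities),
    paste(unique(x$arrays$strain), collapse = ", ")))
  invisible(x)
}

# Column indices for one strain's arrays.
strain_cols <- function(em, strain) {
  idx <- which(em$arrays$strain == strain)
  if (!length(idx)) stop("strain not present in matrix: ", strain)
  idx
}

#' Read / write the expression matrix TSV dialect
#'
#' Layout: first column `gene_id`, logical column `spikein`, then one
#' intensity column per array named `strain_replicate`.
#'
#' @param em an [expression_matrix()].
#' @param path file path.
#' @return `read_expression_tsv` returns an [expression_matrix()];
#'   `write_expression_tsv` returns `path` invisibly.
#' @export
write_expression_tsv <- function(em, path) {
  df <- data.frame(gene_id = em$gene_ids, spikein = em$spikein,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(em$intensities, check.names = FALSE))
  write_tsv(df, path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  arr_cols <- setdiff(names(df), c("gene_id", "spikein"))
  parts <- regmatches(arr_cols, regexpr("_[^_]+$", arr_cols))
  arrays <- data.frame(
    strain = substr(arr_cols, 1L, nchar(arr_cols) - nchar(parts)),
    replicate = as.integer(sub("^_", "", parts)),
    stringsAsFactors = FALSE)
  expression_matrix(as.matrix(df[arr_cols]), df$gene_id,
                    as.logical(df$spikein), arrays)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
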