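#' Per-sample single-cell expression summary
#'
#' For every (sample, gene) pair, computes the fraction of the sample's
#' cells with non-zero expression and the mean expression over all cells of
#' the sample (zeros included) — the quantities behind dot-plot style
#' summaries of single-cell data.
#'
#' @param cells Cells x genes numeric matrix with cell identifiers as
#'   rownames.
#' @param cell_map Data.frame with columns \code{cell_id} and
#'   \code{sample_id} mapping every cell to its sample.
#' @param genes Genes to summarize (default: all columns of \code{cells}).
#' @return Data.frame with columns \code{sample_id}, \code{gene_id},
#'   \code{frac_expressing} and \code{mean_expression}.
#' @export
summarize_single_cell <- function(cells, cell_map, genes = colnames(cells)) {
  if (is.data.frame(cells)) cells <- as.matrix(cells)
  if (!is.matrix(cells) || !is.numeric(cells))
    stop("cells must be a numeric matrix")
  if (is.null(rownames(cells))) stop("cells must carry cell ids as rownames")
  if (!all(c("cell_id", "sample_id") %in% names(cell_map)))
    stop("cell_map needs cell_id and sample_id columns")
  unmapped <- setdiff(rownames(cells), cell_map$cell_id)
  if (length(unmapped) > 0)
    stop("unmapped cell id(s): ", paste(utils::head(unmapped, 5), collapse = ", "))
  genes <- as.character(genes)
  if (!all(genes %in% colnames(cells)))
    stop("gene(s) absent from the matrix: ",
         paste(setdiff(genes, colnames(cells)), collapse = ", "))
  sample_of <- cell_map$sample_id[match(rownames(cells), cell_map$cell_id)]
  samples <- unique(cell_map$sample_id[cell_map$cell_id %in% rownames(cells)])
  out <- expand.grid(sample_id = samples, gene_id = genes,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out$frac_expressing <- NA_real_
  out$mean_expression <- NA_real_
  for (j in seq_len(nrow(out))) {
    v <- cells[sample_of == out$sample_id[j], out$gene_id[j]]
    out$frac_expressing[j] <- mean(v > 0)
    out$mean_expression[j] <- mean(v)
  }
  out
}
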