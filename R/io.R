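#' Read and write the package's tab-separated file formats
#'
#' All files are UTF-8 TSV with a header row and \code{NA} for missing
#' values. The expression format puts gene identifiers in a first
#' \code{gene_id} column with one column per sample.
#'
#' @param path File path.
#' @param m Genes x samples numeric matrix.
#' @return \code{read_expression_tsv} returns a genes x samples matrix; the
#'   writers return the path invisibly.
#' @name expression_io
NULL

#' @rdname expression_io
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("expression file needs a gene_id column and at least one sample: ",
         path)
  if (names(df)[1] != "gene_id")
    stop("first column of an expression TSV must be 'gene_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  as_expression_matrix(m)
}

#' @rdname expression_io
#' @export
write_expression_tsv <- function(m, path) {
  m <- as_expression_matrix(m)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

# Plain TSV writer shared by all outputs (no quoting, NA for missing).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, na = c("NA", "")) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = na)
}

#' Read a clinical annotation table
#'
#' Expects columns \code{sample_id} and \code{phenotype}; \code{time},
#' \code{event} and \code{response} are optional depending on the analysis.
#'
#' @param path File path.
#' @return Data.frame.
#' @export
read_clinical_tsv <- function(path) {
  df <- read_tsv(path)
  if (!all(c("sample_id", "phenotype") %in% names(df)))
    stop("clinical TSV needs sample_id and phenotype columns: ", path)
  df
}

#' Read/write a DNA-RNA variant pair table
#'
#' Columns \code{sample_id}, \code{gene}, \code{dna_variant},
#' \code{dna_vaf}, \code{rna_variant}, \code{rna_vaf}; \code{NA} (or
#' \code{-} / \code{na} on reading) marks missing values and \code{WT} wild
#' type.
#'
#' @param path File path.
#' @param pairs Variant pair data.frame.
#' @return \code{read_variant_table} returns a data.frame; the writer
#'   returns the path invisibly.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", "na", "-", ""),
                          colClasses = c(dna_vaf = "numeric",
                                         rna_vaf = "numeric"))
  req <- c("sample_id", "gene", "dna_variant", "dna_vaf",
           "rna_variant", "rna_vaf")
  if (!all(req %in% names(df)))
    stop("variant TSV needs columns: ", paste(req, collapse = ", "))
  df
}

#' @rdname read_variant_table
#' @export
write_variant_table <- function(pairs, path) {
  write_tsv(pairs, path)
}

#' Read/write a gene signature as JSON
#'
#' Format: \code{{"up": [...], "down": [...]}}.
#'
#' @param path File path.
#' @param signature A [gene_signature()].
#' @return \code{read_signature_json} returns a [gene_signature()].
#' @export
read_signature_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("up", "down") %in% names(obj)))
    stop("signature JSON needs 'up' and 'down' arrays: ", path)
  gene_signature(obj$up, obj$down)
}

#' @rdname read_signature_json
#' @export
write_signature_json <- function(signature, path) {
  stopifnot(inherits(signature, "gene_signature"))
  jsonlite::write_json(list(up = signature$up, down = signature$down),
                       path, pretty = TRUE)
  invisible(path)
}

#' Read/write single-cell expression in long TSV form
#'
#' Columns \code{cell_id}, \code{sample_id}, \code{gene_id}, \code{value};
#' the reader reconstructs a cells x genes matrix (absent combinations are
#' zero) plus the cell-to-sample map.
#'
#' @param path File path.
#' @param counts Cells x genes matrix.
#' @param cell_map Data.frame \code{cell_id}, \code{sample_id}.
#' @return \code{read_single_cell_tsv} returns \code{list(counts, cell_map)}.
#' @export
read_single_cell_tsv <- function(path) {
  df <- read_tsv(path)
  req <- c("cell_id", "sample_id", "gene_id", "value")
  if (!all(req %in% names(df)))
    stop("single-cell TSV needs columns: ", paste(req, collapse = ", "))
  cells <- unique(df$cell_id)
  genes <- unique(df$gene_id)
  counts <- matrix(0, nrow = length(cells), ncol = length(genes),
                   dimnames = list(cells, genes))
  counts[cbind(match(df$cell_id, cells), match(df$gene_id, genes))] <- df$value
  cell_map <- unique(df[, c("cell_id", "sample_id")])
  rownames(cell_map) <- NULL
  list(counts = counts, cell_map = cell_map)
}

#' @rdname read_single_cell_tsv
#' @export
write_single_cell_tsv <- function(counts, cell_map, path) {
  sample_of <- cell_map$sample_id[match(rownames(counts), cell_map$cell_id)]
  df <- data.frame(
    cell_id = rep(rownames(counts), times = ncol(counts)),
    sample_id = rep(sample_of, times = ncol(counts)),
    gene_id = rep(colnames(counts), each = nrow(counts)),
    value = as.vector(counts), stringsAsFactors = FALSE)
  write_tsv(df, path)
}
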