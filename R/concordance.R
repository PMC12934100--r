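#' Normalize a variant label as printed in clinical tables
#'
#' Accepts strings such as \code{"BRAF p.V600E"}, \code{"NRAS Q61K"} or a
#' bare protein change \code{"V600E"} / \code{"p.V600E"}; strips an optional
#' \code{"p."} prefix and upper-cases. \code{"WT"} maps to the wild-type
#' marker; \code{"na"}, \code{"-"}, the empty string and \code{NA} map to
#' missing. Gene symbols are treated as opaque strings and not validated
#' against a registry (so a typo like \code{"BRAV"} survives unless the
#' caller remaps it, e.g. \code{c(BRAV = "BRAF")}).
#'
#' @param raw Character scalar.
#' @param alias Optional named character vector remapping gene symbols.
#' @return List with \code{gene} (or \code{NA}) and \code{change}: a protein
#'   change string, \code{"WT"}, or \code{NA} for missing.
#' @examples
#' normalize_variant_label("BRAF p.V600E")  # gene BRAF, change V600E
#' normalize_variant_label("WT")$change     # "WT"
#' @export
normalize_variant_label <- function(raw, alias = NULL) {
  if (length(raw) != 1) stop("raw must be a single string")
  if (is.na(raw)) return(list(gene = NA_character_, change = NA_character_))
  s <- trimws(as.character(raw))
  if (tolower(s) %in% c("", "-", "na", "n/a", "."))
    return(list(gene = NA_character_, change = NA_character_))
  if (toupper(s) == "WT")
    return(list(gene = NA_character_, change = "WT"))
  s <- toupper(s)
  change_pat <- "(?:P\\.)?([A-Z][0-9]+(?:[A-Z*]+|FS\\*?[0-9]*|DEL|DUP|INS[A-Z]*))"
  m <- regmatches(s, regexec(paste0("^([A-Z][A-Z0-9-]*)\\s+", change_pat, "$"), s))[[1]]
  if (length(m) == 3) {
    gene <- m[2]
    if (!is.null(alias) && gene %in% names(alias)) gene <- unname(alias[gene])
    return(list(gene = gene, change = m[3]))
  }
  m <- regmatches(s, regexec(paste0("^", change_pat, "$"), s))[[1]]
  if (length(m) == 2)
    return(list(gene = NA_character_, change = m[2]))
  stop("malformed variant label: '", raw, "'")
}

#' Classify transcriptional concordance of DNA/RNA variant pairs
#'
#' Applies, per record, the rules used to read a DNA-vs-RNA variant table:
#' an RNA call missing makes the pair \code{not_evaluable}; an RNA wild-type
#' call is \code{not_detected_rna}; a missing or wild-type DNA call with an
#' RNA variant present is \code{not_evaluable} (flagged); the same protein
#' change on both sides is \code{confirmed_same_site}; any other change of
#' the same gene is \code{different_site}. For confirmed pairs with both
#' VAFs observed, the VAF relation is a strict numeric comparison
#' (\code{rna_higher} / \code{rna_lower} / \code{rna_equal}); otherwise it is
#' \code{not_comparable}.
#'
#' @param pairs Data.frame with columns \code{sample_id}, \code{gene},
#'   \code{dna_variant}, \code{dna_vaf}, \code{rna_variant}, \code{rna_vaf}
#'   (VAFs in percent, \code{NA} when missing).
#' @param alias Optional gene-symbol alias map passed to
#'   [normalize_variant_label()].
#' @return Data.frame with \code{sample_id}, \code{gene}, \code{category}
#'   and \code{vaf_relation} per input row (input order preserved).
#' @export
classify_variant_pairs <- function(pairs, alias = NULL) {
  req <- c("sample_id", "gene", "dna_variant", "dna_vaf",
           "rna_variant", "rna_vaf")
  if (!all(req %in% names(pairs)))
    stop("pairs must have columns: ", paste(req, collapse = ", "))
  for (v in c("dna_vaf", "rna_vaf")) {
    bad <- !is.na(pairs[[v]]) & (pairs[[v]] < 0 | pairs[[v]] > 100)
    if (any(bad)) stop(v, " must lie in [0, 100] when present")
  }
  n <- nrow(pairs)
  category <- character(n)
  relation <- rep("not_comparable", n)
  for (i in seq_len(n)) {
    dn <- normalize_variant_label(pairs$dna_variant[i], alias)
    rn <- normalize_variant_label(pairs$rna_variant[i], alias)
    dgene <- if (!is.na(dn$gene)) dn$gene else pairs$gene[i]
    rgene <- if (!is.na(rn$gene)) rn$gene else pairs$gene[i]
    if (is.na(rn$change)) {
      category[i] <- "not_evaluable"
    } else if (rn$change == "WT") {
      category[i] <- "not_detected_rna"
    } else if (is.na(dn$change) || dn$change == "WT") {
      category[i] <- "not_evaluable"
    } else if (identical(dgene, rgene) && identical(dn$change, rn$change)) {
      category[i] <- "confirmed_same_site"
      dv <- pairs$dna_vaf[i]; rv <- pairs$rna_vaf[i]
      if (!is.na(dv) && !is.na(rv)) {
        relation[i] <- if (rv > dv) "rna_higher"
                       else if (rv < dv) "rna_lower" else "rna_equal"
      }
    } else {
      category[i] <- "different_site"
    }
  }
  data.frame(sample_id = pairs$sample_id, gene = pairs$gene,
             category = category, vaf_relation = relation,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-gene concordance summary of a DNA/RNA variant table
#'
#' Aggregates [classify_variant_pairs()] per gene symbol. The categories
#' partition the records (\code{n_total = n_confirmed + n_different_site +
#' n_not_detected + n_not_evaluable}) and the VAF relations partition the
#' confirmed pairs with both VAFs
#' (\code{n_rna_higher + n_rna_lower + n_rna_equal = n_with_both_vafs}).
#'
#' @inheritParams classify_variant_pairs
#' @return Data.frame with one row per gene symbol (records without a gene
#'   symbol are aggregated under \code{NA}) and the count columns above,
#'   ordered by gene.
#' @examples
#' tab2 <- read_variant_table(system.file("extdata", "table2_variants.tsv",
#'                                        package = "dormsig"))
#' summarize_concordance(tab2)
#' @export
summarize_concordance <- function(pairs, alias = NULL) {
  cols <- c("n_total", "n_confirmed", "n_with_both_vafs", "n_rna_higher",
            "n_rna_lower", "n_rna_equal", "n_different_site",
            "n_not_detected", "n_not_evaluable")
  if (nrow(pairs) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(integer(0)), length(cols)),
                                         cols))
    return(cbind(data.frame(gene = character(0), stringsAsFactors = FALSE),
                 out))
  }
  calls <- classify_variant_pairs(pairs, alias)
  both <- !is.na(pairs$dna_vaf) & !is.na(pairs$rna_vaf)
  genes <- unique(calls$gene)
  genes <- c(sort(genes[!is.na(genes)]), if (anyNA(genes)) NA_character_)
  rows <- lapply(genes, function(g) {
    sel <- if (is.na(g)) is.na(calls$gene) else !is.na(calls$gene) & calls$gene == g
    cc <- calls[sel, , drop = FALSE]
    conf_both <- cc$category == "confirmed_same_site" & both[sel]
    data.frame(
      gene = g,
      n_total = nrow(cc),
      n_confirmed = sum(cc$category == "confirmed_same_site"),
      n_with_both_vafs = sum(conf_both),
      n_rna_higher = sum(cc$vaf_relation == "rna_higher"),
      n_rna_lower = sum(cc$vaf_relation == "rna_lower"),
      n_rna_equal = sum(cc$vaf_relation == "rna_equal"),
      n_different_site = sum(cc$category == "different_site"),
      n_not_detected = sum(cc$category == "not_detected_rna"),
      n_not_evaluable = sum(cc$category == "not_evaluable"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
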