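#' Rank genes by nonparametric differential expression between phenotypes
#'
#' Two-sided Wilcoxon rank-sum test per gene on log2(TPM+1) values, with the
#' exact distribution when the combined sample size is at most 20 and there
#' are no ties, and the normal approximation with continuity correction
#' otherwise. The direction is the sign of (dormant median − proliferative
#' median); p-values are Bonferroni-adjusted over the tested genes. Groups
#' whose values are completely tied get p = 1.
#'
#' @param m Genes x samples TPM matrix.
#' @param labels Vector of phenotype labels aligned with the columns of
#'   \code{m}; exactly two distinct labels with at least 2 samples each.
#' @param positive Label treated as the dormant-side group (default
#'   \code{"dormant"}; falls back to the alphabetically first label if
#'   absent).
#' @return Data.frame (gene order preserved) with columns \code{gene_id},
#'   \code{statistic} (Wilcoxon W of the dormant-side group), \code{p_value},
#'   \code{p_adjusted}, \code{direction} (\code{"up"}, \code{"down"} or
#'   \code{"none"}, relative to the dormant side).
#' @export
rank_de_genes <- function(m, labels, positive = "dormant") {
  m <- as_expression_matrix(m)
  labels <- as.character(labels)
  if (length(labels) != ncol(m))
    stop("labels must align with the matrix columns")
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("exactly two phenotype groups are required")
  if (!positive %in% lev) positive <- lev[1]
  pos <- labels == positive
  if (sum(pos) < 2 || sum(!pos) < 2)
    stop("each group needs at least 2 samples")
  lm <- log_transform(m)
  n_genes <- nrow(lm)
  stat <- p <- numeric(n_genes)
  direction <- character(n_genes)
  for (i in seq_len(n_genes)) {
    x <- lm[i, pos]; y <- lm[i, !pos]
    combined <- c(x, y)
    use_exact <- length(combined) <= 20 && !anyDuplicated(combined)
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
    stat[i] <- unname(wt$statistic)
    p[i] <- if (is.na(wt$p.value)) 1 else min(1, wt$p.value)
    dmed <- stats::median(x) - stats::median(y)
    direction[i] <- if (dmed > 0) "up" else if (dmed < 0) "down" else "none"
  }
  data.frame(gene_id = rownames(lm), statistic = stat, p_value = p,
             p_adjusted = stats::p.adjust(p, method = "bonferroni"),
             direction = direction, stringsAsFactors = FALSE, row.names = NULL)
}

#' Derive a k-gene dormancy signature from labelled expression data
#'
#' Restricts to genes significant after Bonferroni correction
#' (\code{p_adjusted < alpha} in [rank_de_genes()]), z-scores their
#' log2(TPM+1) values, runs a PCA of the samples over those genes
#' (correlation-scale, via SVD) and selects the principal component whose
#' sample scores have maximal absolute point-biserial correlation with the
#' phenotype. The component is oriented to correlate positively with the
#' dormant label; genes are ranked by absolute loading (ties broken by
#' larger |loading|, then lexicographic gene id) and the top k are assigned
#' to the up or down set by their differential-expression direction.
#'
#' @inheritParams rank_de_genes
#' @param k Signature size (>= 2).
#' @param alpha Bonferroni-adjusted significance cutoff for the DE filter.
#' @return A [gene_signature()] with attributes \code{"component"} (index of
#'   the chosen PC), \code{"loadings"} (named, oriented loadings of the
#'   selected genes) and \code{"de"} (the DE table of passing genes).
#' @export
select_discriminative_genes <- function(m, labels, k = 8, alpha = 0.05,
                                        positive = "dormant") {
  if (k < 2) stop("k must be >= 2")
  de <- rank_de_genes(m, labels, positive = positive)
  passing <- de[de$p_adjusted < alpha, , drop = FALSE]
  if (nrow(passing) < k)
    stop(sprintf(paste0("only %d gene(s) pass the differential-expression ",
                        "filter at adjusted p < %g; %d requested"),
                 nrow(passing), alpha, k))
  z <- zscore_genes(log_transform(as_expression_matrix(m)[passing$gene_id, ,
                                                          drop = FALSE]))
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (!positive %in% lev) positive <- lev[1]
  y <- as.numeric(labels == positive)
  pca <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  pb <- suppressWarnings(apply(pca$x, 2, function(s)
    if (stats::sd(s) < 1e-12) 0 else stats::cor(s, y)))
  pb[is.na(pb)] <- 0
  comp <- which.max(abs(pb))
  loadings <- pca$rotation[, comp]
  if (pb[comp] < 0) loadings <- -loadings
  ord <- order(-abs(loadings), names(loadings))
  top <- names(loadings)[ord][seq_len(k)]
  dir <- passing$direction[match(top, passing$gene_id)]
  # a median tie ("none") is resolved by the oriented loading sign
  dir[dir == "none"] <- ifelse(loadings[top][dir == "none"] > 0, "up", "down")
  up <- top[dir == "up"]; down <- top[dir == "down"]
  if (length(up) == 0 || length(down) == 0)
    stop("derived signature has an empty ",
         if (length(up) == 0) "up" else "down",
         " set; increase k or revisit the cohort")
  sig <- gene_signature(up, down)
  attr(sig, "component") <- unname(comp)
  attr(sig, "loadings") <- loadings[top]
  attr(sig, "de") <- passing
  sig
}
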