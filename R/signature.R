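#' Log-transform a TPM expression matrix
#'
#' Replaces every value by \code{log2(value + 1)}. Input values must be
#' finite and non-negative.
#'
#' @param m Numeric genes x samples matrix of TPM values.
#' @return Matrix of the same shape on the log2(TPM+1) scale.
#' @examples
#' log_transform(matrix(c(0, 1, 7), 1))  # 0, 1, 3
#' @export
log_transform <- function(m) {
  m <- as_expression_matrix(m)
  log2(m + 1)
}

# Common validation for expression-matrix inputs.
as_expression_matrix <- function(m) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression input must be a numeric matrix")
  if (anyNA(m) || any(!is.finite(m)))
    stop("expression values must be finite (no NA/Inf)")
  if (any(m < 0)) stop("expression values must be non-negative")
  if (!is.null(rownames(m)) && anyDuplicated(rownames(m)))
    stop("duplicate gene identifiers")
  if (!is.null(colnames(m)) && anyDuplicated(colnames(m)))
    stop("duplicate sample identifiers")
  m
}

#' Per-gene z-scores across samples
#'
#' Standardizes each gene row to mean 0 and sample standard deviation 1
#' (divisor n−1). Constant (degenerate) rows are set to all zeros and their
#' identifiers are recorded in the \code{"degenerate"} attribute of the
#' result.
#'
#' @param m Numeric genes x samples matrix (at least 2 samples), typically
#'   log2(TPM+1) values.
#' @return Matrix of z-scores with attribute \code{"degenerate"} (character
#'   vector of constant gene ids, possibly empty).
#' @examples
#' zscore_genes(matrix(1:3, 1, dimnames = list("g", NULL)))  # -1 0 1
#' @export
zscore_genes <- function(m) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!is.matrix(m) || !is.numeric(m)) stop("input must be a numeric matrix")
  if (ncol(m) < 2) stop("z-scoring needs at least 2 samples")
  if (anyNA(m) || any(!is.finite(m))) stop("values must be finite")
  mu <- rowMeans(m)
  sdev <- apply(m, 1, stats::sd)
  degenerate <- sdev < .Machine$double.eps * 100
  z <- (m - mu) / ifelse(degenerate, 1, sdev)
  z[degenerate, ] <- 0
  attr(z, "degenerate") <- if (is.null(rownames(m))) {
    as.character(which(degenerate))
  } else rownames(m)[degenerate]
  z
}

#' Define a dormancy gene signature
#'
#' @param up Genes summed into the up component (higher in dormant samples).
#' @param down Genes summed into the down component.
#' @return Object of class \code{"gene_signature"}.
#' @export
gene_signature <- function(up, down) {
  up <- as.character(up); down <- as.character(down)
  if (length(up) == 0 || length(down) == 0)
    stop("both the up and down gene sets must be non-empty")
  if (length(intersect(up, down)) > 0)
    stop("up and down gene sets must be disjoint")
  structure(list(up = up, down = down), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature\n")
  cat("  up  :", paste(x$up, collapse = ", "), "\n")
  cat("  down:", paste(x$down, collapse = ", "), "\n")
  invisible(x)
}

#' The packaged eight-gene dormancy signature
#'
#' Up component TACSTD2 (TROP2), EREG, SOX9, LPPR4; down component LAMA1,
#' TMEM27, AMIGO2, MGAT5B. Shipped as JSON in \code{extdata/}.
#'
#' @return A [gene_signature()].
#' @export
default_signature <- function() {
  path <- system.file("extdata", "default_signature.json",
                      package = "dormsig", mustWork = TRUE)
  read_signature_json(path)
}

#' Composite dormancy score per sample
#'
#' For each sample s, sums the z-scores of the up genes (U) and the down
#' genes (D) and forms the normalized difference
#' \deqn{S = (U - D) / (|U| + |D|),} with S = 0 when |U| + |D| = 0. The
#' score spans −1 (proliferative) to +1 (dormant) with zero as the decision
#' boundary; samples with S > 0 are labelled dormant, S <= 0 proliferative.
#'
#' @param z Genes x samples z-score matrix (see [zscore_genes()]).
#' @param signature A [gene_signature()]; defaults to the packaged
#'   eight-gene signature.
#' @param allow_missing If TRUE, signature genes absent from \code{z} are
#'   dropped from the sums and recorded in the \code{"missing_genes"}
#'   attribute; if FALSE (default) missing genes are an error.
#' @return A data.frame (class \code{"score_table"}) with columns
#'   \code{sample_id}, \code{U}, \code{D}, \code{score}, \code{label}.
#' @examples
#' z <- matrix(c(1, -1), 2, 3, dimnames = list(c("u1", "d1"), c("a", "b", "c")))
#' dormancy_score(z, gene_signature("u1", "d1"))  # score +1 everywhere
#' @export
dormancy_score <- function(z, signature = default_signature(),
                           allow_missing = FALSE) {
  stopifnot(inherits(signature, "gene_signature"))
  if (is.data.frame(z)) z <- as.matrix(z)
  if (!is.matrix(z) || !is.numeric(z)) stop("z must be a numeric matrix")
  if (is.null(rownames(z))) stop("z must carry gene identifiers as rownames")
  missing <- setdiff(c(signature$up, signature$down), rownames(z))
  if (length(missing) > 0 && !allow_missing)
    stop("signature genes missing from the matrix: ",
         paste(missing, collapse = ", "))
  up <- intersect(signature$up, rownames(z))
  down <- intersect(signature$down, rownames(z))
  U <- colSums(z[up, , drop = FALSE])
  D <- colSums(z[down, , drop = FALSE])
  if (length(up) == 0) U <- rep(0, ncol(z))
  if (length(down) == 0) D <- rep(0, ncol(z))
  denom <- abs(U) + abs(D)
  score <- ifelse(denom == 0, 0, (U - D) / denom)
  out <- data.frame(
    sample_id = if (is.null(colnames(z))) as.character(seq_len(ncol(z)))
                else colnames(z),
    U = unname(U), D = unname(D), score = unname(score),
    label = ifelse(score > 0, "dormant", "proliferative"),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "missing_genes") <- missing
  class(out) <- c("score_table", "data.frame")
  out
}

#' Score raw TPM values with a dormancy signature
#'
#' Convenience wrapper: log2(TPM+1) transform, per-gene z-scoring across the
#' cohort being scored (cohort-relative scoring), then [dormancy_score()].
#'
#' @inheritParams dormancy_score
#' @param m Genes x samples TPM matrix.
#' @return A \code{score_table} data.frame.
#' @export
score_samples <- function(m, signature = default_signature(),
                          allow_missing = FALSE) {
  dormancy_score(zscore_genes(log_transform(m)), signature,
                 allow_missing = allow_missing)
}

#' ROC curve and AUC for dormancy scores against known phenotypes
#'
#' The AUC is computed from ranks so that it equals the Mann-Whitney U
#' statistic divided by n1*n0 with ties counted 1/2; the ROC points come
#' from a threshold sweep over the observed scores and integrate (trapezoid
#' rule) to the same AUC.
#'
#' @param scores Numeric vector of scores, or a \code{score_table} (its
#'   \code{score} column is used).
#' @param truth Vector of true class labels, same length/order as scores.
#' @param positive Label treated as the positive (dormant) class.
#' @return List of class \code{"auc_result"}: \code{auc} and \code{roc}, a
#'   data.frame of (\code{fpr}, \code{tpr}) points from (0,0) to (1,1).
#' @examples
#' roc_auc(c(0.8, 0.3, 0.5, 0.1),
#'         c("dormant", "dormant", "proliferative", "proliferative"))$auc
#' @export
roc_auc <- function(scores, truth, positive = "dormant") {
  if (inherits(scores, "score_table")) scores <- scores$score
  scores <- as.numeric(scores)
  truth <- as.character(truth)
  if (length(scores) != length(truth))
    stop("scores and truth must have the same length")
  if (anyNA(scores) || anyNA(truth)) stop("missing values not allowed")
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present in the truth labels")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(thresholds, function(t) mean(scores[!pos] >= t), 0)
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1)
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1))
  structure(list(auc = unname(auc), roc = roc), class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (%d ROC points)\n", x$auc, nrow(x$roc)))
  invisible(x)
}
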