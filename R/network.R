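#' Parameters of the weighted co-expression network analysis
#'
#' @param beta Soft-threshold power applied to absolute Pearson correlations
#'   (unsigned network convention); must be >= 1.
#' @param min_module_size Smallest gene set reported as a module (>= 2).
#' @param cut_height Static cut height on the topological-overlap
#'   dissimilarity dendrogram, in (0, 1]. The default 0.6 sits between the
#'   dissimilarity of strongly co-expressed gene blocks (about 0.5 for
#'   pairwise |r| near 0.9 at beta = 6) and that of unrelated genes (near 1).
#' @return Object of class \code{"network_params"}.
#' @export
network_params <- function(beta = 6, min_module_size = 5, cut_height = 0.6) {
  if (!is.finite(beta) || beta < 1) stop("beta must be >= 1")
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  if (!is.finite(cut_height) || cut_height <= 0 || cut_height > 1)
    stop("cut_height must lie in (0, 1]")
  structure(list(beta = beta, min_module_size = as.integer(min_module_size),
                 cut_height = cut_height), class = "network_params")
}

#' Soft-threshold adjacency matrix
#'
#' Unsigned weighted-network adjacency \eqn{a_{ij} = |cor(g_i, g_j)|^\beta}
#' over genes, with unit diagonal. Degenerate (constant) genes get zero
#' off-diagonal adjacency.
#'
#' @param z Genes x samples matrix (z-scores or log-expression); at least 3
#'   samples and 2 genes.
#' @param params A [network_params()] object.
#' @return Symmetric gene x gene matrix with entries in `[0, 1]`, diagonal 1.
#' @export
adjacency <- function(z, params = network_params()) {
  stopifnot(inherits(params, "network_params"))
  if (is.data.frame(z)) z <- as.matrix(z)
  if (!is.matrix(z) || !is.numeric(z)) stop("z must be a numeric matrix")
  if (ncol(z) < 3) stop("adjacency needs at least 3 samples")
  if (nrow(z) < 2) stop("adjacency needs at least 2 genes")
  r <- suppressWarnings(stats::cor(t(z)))
  r[!is.finite(r)] <- 0
  a <- abs(r)^params$beta
  a <- pmin(pmax(a, 0), 1)
  diag(a) <- 1
  (a + t(a)) / 2
}

#' Topological overlap matrix
#'
#' For a valid adjacency matrix computes
#' \deqn{TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'                       {\min(k_i, k_j) + 1 - a_{ij}},\quad
#'       k_i = \sum_{u \ne i} a_{iu},}
#' with unit diagonal: the similarity of two genes through their shared
#' network neighbours as well as their direct connection.
#'
#' @param a Symmetric adjacency matrix (diagonal 1, entries in `[0, 1]`).
#' @return Symmetric TOM matrix with entries in `[0, 1]`, diagonal 1.
#' @export
topological_overlap <- function(a) {
  if (!is.matrix(a) || !is.numeric(a)) stop("adjacency must be a numeric matrix")
  if (nrow(a) != ncol(a) || max(abs(a - t(a))) > 1e-8)
    stop("adjacency must be symmetric")
  if (any(a < -1e-12) || any(a > 1 + 1e-12))
    stop("adjacency entries must lie in [0, 1]")
  a0 <- a
  diag(a0) <- 0
  shared <- a0 %*% a0            # (i,j): sum over u != i,j of a_iu a_uj
  k <- rowSums(a0)
  kmin <- outer(k, k, pmin)
  tom <- (shared + a0) / (kmin + 1 - a0)
  diag(tom) <- 1
  tom <- pmin(pmax(tom, 0), 1)
  (tom + t(tom)) / 2
}

#' Detect co-expression modules by static dendrogram cut
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 − TOM,
#' cut at a fixed height; clusters smaller than \code{min_module_size} are
#' discarded (their genes stay unassigned). Deterministic given its input,
#' and invariant (up to relabelling) under gene permutations.
#'
#' @param tom Topological overlap matrix from [topological_overlap()].
#' @param params A [network_params()] object.
#' @return Named list (\code{"M1"}, \code{"M2"}, ...) of lexicographically
#'   sorted gene-id vectors, ordered by decreasing module size (ties by
#'   first gene id). Empty list when nothing passes the size filter.
#' @export
detect_modules <- function(tom, params = network_params()) {
  stopifnot(inherits(params, "network_params"))
  if (!is.matrix(tom) || nrow(tom) != ncol(tom))
    stop("tom must be a square matrix")
  genes <- rownames(tom)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(tom)))
  if (nrow(tom) < 2 || nrow(tom) < params$min_module_size) return(list())
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  ct <- stats::cutree(hc, h = params$cut_height)
  groups <- split(genes, ct)
  groups <- groups[vapply(groups, length, 0L) >= params$min_module_size]
  if (length(groups) == 0) return(list())
  groups <- lapply(groups, sort)
  ord <- order(-vapply(groups, length, 0L),
               vapply(groups, function(g) g[1], ""))
  groups <- groups[ord]
  names(groups) <- paste0("M", seq_along(groups))
  groups
}

#' Module eigengene
#'
#' First right-singular vector (sample dimension) of the module's z-score
#' submatrix: a unit-norm per-sample summary profile, sign-oriented so that
#' its correlation with the module's per-sample mean z-score is
#' non-negative.
#'
#' @param z Genes x samples z-score matrix containing the module genes.
#' @param module Character vector of module gene ids (non-empty).
#' @return Named numeric vector (one value per sample, unit Euclidean norm).
#' @export
module_eigengene <- function(z, module) {
  if (length(module) == 0) stop("module must be non-empty")
  if (is.data.frame(z)) z <- as.matrix(z)
  if (is.null(rownames(z))) stop("z must carry gene ids as rownames")
  missing <- setdiff(module, rownames(z))
  if (length(missing) > 0)
    stop("module gene(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  if (ncol(z) < 2) stop("eigengene needs at least 2 samples")
  zm <- z[module, , drop = FALSE]
  sv <- svd(zm)
  eig <- sv$v[, 1]
  profile <- colMeans(zm)
  s <- sum(eig * (profile - mean(profile)))
  if (abs(s) < 1e-12) s <- sum(eig * profile)
  if (s < 0) eig <- -eig
  stats::setNames(eig, colnames(z))
}

#' Correlation between a module eigengene and a sample trait
#'
#' Pearson correlation with the usual two-sided p-value from the
#' t-transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}}.
#'
#' @param eigengene Per-sample eigengene values.
#' @param trait Per-sample trait (e.g. dormancy scores), same order.
#' @return List with \code{r}, \code{p} and \code{n}.
#' @export
module_trait_correlation <- function(eigengene, trait) {
  eigengene <- as.numeric(eigengene); trait <- as.numeric(trait)
  if (length(eigengene) != length(trait))
    stop("eigengene and trait must have the same length")
  n <- length(trait)
  if (n < 3) stop("trait correlation needs at least 3 samples")
  if (stats::sd(trait) < 1e-12) stop("trait has zero variance")
  if (stats::sd(eigengene) < 1e-12) stop("eigengene has zero variance")
  ct <- stats::cor.test(eigengene, trait, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Hub gene of a module
#'
#' The module member with maximal intramodular connectivity
#' \eqn{k_i = \sum_{j \in module, j \ne i} a_{ij}}; ties are broken by
#' lexicographic gene id.
#'
#' @param a Adjacency matrix covering the module genes.
#' @param module Character vector of module gene ids (non-empty).
#' @return The hub gene id (character scalar).
#' @export
hub_gene <- function(a, module) {
  if (length(module) == 0) stop("module must be non-empty")
  missing <- setdiff(module, rownames(a))
  if (length(missing) > 0)
    stop("module gene(s) absent from the adjacency: ",
         paste(missing, collapse = ", "))
  sub <- a[module, module, drop = FALSE]
  k <- rowSums(sub) - diag(sub)
  module[order(-k, module)][1]
}

#' Intramodular connectivity of every module member
#'
#' @inheritParams hub_gene
#' @return Named numeric vector of \eqn{k_i} values.
#' @export
intramodular_connectivity <- function(a, module) {
  if (length(module) == 0) stop("module must be non-empty")
  missing <- setdiff(module, rownames(a))
  if (length(missing) > 0)
    stop("module gene(s) absent from the adjacency: ",
         paste(missing, collapse = ", "))
  sub <- a[module, module, drop = FALSE]
  stats::setNames(rowSums(sub) - diag(sub), module)
}

#' Full co-expression pipeline on an expression matrix
#'
#' log2(TPM+1) transform, per-gene z-scoring, soft-threshold adjacency,
#' topological overlap, static-cut module detection, then per module the
#' eigengene, intramodular connectivities, hub gene and (when a trait is
#' supplied) the eigengene-trait correlation.
#'
#' @param m Genes x samples TPM matrix.
#' @param trait Optional per-sample trait (e.g. dormancy scores) aligned
#'   with the matrix columns.
#' @param params A [network_params()] object.
#' @return List with \code{modules} (per-module list: \code{genes},
#'   \code{eigengene}, \code{connectivity}, \code{hub}, and \code{trait_r},
#'   \code{trait_p} when a trait was supplied), \code{assignment} (per-gene
#'   data.frame) and \code{params}.
#' @export
coexpression_analysis <- function(m, trait = NULL, params = network_params()) {
  z <- zscore_genes(log_transform(m))
  a <- adjacency(z, params)
  tom <- topological_overlap(a)
  mods <- detect_modules(tom, params)
  modules <- lapply(mods, function(genes) {
    res <- list(genes = genes,
                eigengene = module_eigengene(z, genes),
                connectivity = intramodular_connectivity(a, genes),
                hub = hub_gene(a, genes))
    if (!is.null(trait)) {
      tc <- module_trait_correlation(res$eigengene, trait)
      res$trait_r <- tc$r
      res$trait_p <- tc$p
    }
    res
  })
  assignment <- data.frame(gene_id = rownames(z),
                           module = NA_character_,
                           connectivity = NA_real_,
                           is_hub = FALSE,
                           stringsAsFactors = FALSE, row.names = NULL)
  for (nm in names(modules)) {
    mod <- modules[[nm]]
    i <- match(mod$genes, assignment$gene_id)
    assignment$module[i] <- nm
    assignment$connectivity[i] <- unname(mod$connectivity[mod$genes])
    assignment$is_hub[match(mod$hub, assignment$gene_id)] <- TRUE
  }
  list(modules = modules, assignment = assignment, params = params)
}
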