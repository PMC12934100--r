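#' Pipeline stage runners over the shared file formats
#'
#' Each `run_*` function orchestrates one analysis stage: it reads the TSV /
#' JSON inputs, calls the corresponding package functions and writes the
#' stage outputs plus a `*_manifest.json` recording inputs, parameters, seed
#' and package version (no timestamps, so repeated runs are byte-identical).
#' The `exec/dormsig` script exposes the same stages as shell subcommands.
#'
#' @param out_dir Output directory, created if absent.
#' @name pipeline
NULL

ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  invisible(path)
}

write_manifest <- function(out_dir, stage, inputs, params, seed = NULL) {
  manifest <- list(
    stage = stage, inputs = inputs, params = params, seed = seed,
    package = "dormsig",
    version = as.character(utils::packageVersion("dormsig")))
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline
#' @param config A [sim_config()]; drives all four generators.
#' @return \code{run_simulate}: writes \code{expression.tsv},
#'   \code{clinical.tsv}, \code{variants.tsv}, \code{single_cell.tsv},
#'   \code{config.yaml} and a manifest; invisibly returns the file paths.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  ensure_dir(out_dir)
  cohort <- simulate_expression(config)
  clinical <- simulate_clinical(config, cohort$phenotype)
  variants <- simulate_variant_table(config)
  sc <- simulate_single_cell(config)
  paths <- list(
    expression = file.path(out_dir, "expression.tsv"),
    clinical = file.path(out_dir, "clinical.tsv"),
    variants = file.path(out_dir, "variants.tsv"),
    single_cell = file.path(out_dir, "single_cell.tsv"),
    config = file.path(out_dir, "config.yaml"))
  write_expression_tsv(cohort$expression, paths$expression)
  write_tsv(clinical, paths$clinical)
  write_variant_table(variants, paths$variants)
  write_single_cell_tsv(sc$counts, sc$cell_map, paths$single_cell)
  yaml::write_yaml(unclass(config), paths$config)
  write_manifest(out_dir, "simulate", inputs = list(),
                 params = unclass(config), seed = config$seed)
  invisible(paths)
}

resolve_signature <- function(signature_path) {
  if (is.null(signature_path) || identical(signature_path, "default"))
    default_signature()
  else read_signature_json(signature_path)
}

#' @rdname pipeline
#' @param expression_path Expression TSV (first column \code{gene_id}).
#' @param signature_path Signature JSON path, or \code{"default"} for the
#'   packaged eight-gene signature.
#' @param clinical_path Optional clinical TSV; when present its
#'   \code{phenotype} column is used as truth labels and an AUC is reported.
#' @param allow_missing Drop signature genes absent from the matrix instead
#'   of erroring.
#' @return \code{run_score}: writes \code{scores.tsv} (and \code{roc.tsv} +
#'   \code{auc.json} when labels are available); invisibly returns the
#'   score table.
#' @export
run_score <- function(expression_path, out_dir,
                      signature_path = "default", clinical_path = NULL,
                      allow_missing = FALSE) {
  ensure_dir(out_dir)
  m <- read_expression_tsv(expression_path)
  sig <- resolve_signature(signature_path)
  scores <- score_samples(m, sig, allow_missing = allow_missing)
  write_tsv(scores, file.path(out_dir, "scores.tsv"))
  if (!is.null(clinical_path)) {
    clin <- read_clinical_tsv(clinical_path)
    truth <- clin$phenotype[match(scores$sample_id, clin$sample_id)]
    if (anyNA(truth)) stop("clinical table does not cover all scored samples")
    res <- roc_auc(scores$score, truth)
    write_tsv(res$roc, file.path(out_dir, "roc.tsv"))
    jsonlite::write_json(list(auc = res$auc, n = length(truth)),
                         file.path(out_dir, "auc.json"), auto_unbox = TRUE)
  }
  write_manifest(out_dir, "score",
                 inputs = list(expression = expression_path,
                               signature = signature_path,
                               clinical = clinical_path),
                 params = list(allow_missing = allow_missing))
  invisible(scores)
}

#' @rdname pipeline
#' @param k Derived signature size.
#' @return \code{run_derive}: writes \code{derived_signature.json} and
#'   \code{de_ranking.tsv}; invisibly returns the signature.
#' @export
run_derive <- function(expression_path, clinical_path, out_dir, k = 8) {
  ensure_dir(out_dir)
  m <- read_expression_tsv(expression_path)
  clin <- read_clinical_tsv(clinical_path)
  labels <- clin$phenotype[match(colnames(m), clin$sample_id)]
  if (anyNA(labels)) stop("clinical table does not cover all samples")
  de <- rank_de_genes(m, labels)
  sig <- select_discriminative_genes(m, labels, k = k)
  write_tsv(de, file.path(out_dir, "de_ranking.tsv"))
  write_signature_json(sig, file.path(out_dir, "derived_signature.json"))
  write_manifest(out_dir, "derive",
                 inputs = list(expression = expression_path,
                               clinical = clinical_path),
                 params = list(k = k))
  invisible(sig)
}

#' @rdname pipeline
#' @param scores_path Optional score table TSV; its \code{score} column is
#'   the trait for module-trait correlations.
#' @param params A [network_params()] object.
#' @param edge_threshold Minimum adjacency weight written to the edge list.
#' @return \code{run_network}: writes \code{modules.tsv} (gene_id, module,
#'   connectivity, is_hub), \code{eigengenes.tsv}, \code{edges.tsv} and,
#'   with a trait, \code{module_trait.json}; invisibly returns the
#'   [coexpression_analysis()] result.
#' @export
run_network <- function(expression_path, out_dir, scores_path = NULL,
                        params = network_params(), edge_threshold = 0.1) {
  ensure_dir(out_dir)
  m <- read_expression_tsv(expression_path)
  trait <- NULL
  if (!is.null(scores_path)) {
    st <- read_tsv(scores_path)
    trait <- st$score[match(colnames(m), st$sample_id)]
    if (anyNA(trait)) stop("score table does not cover all samples")
  }
  res <- coexpression_analysis(m, trait = trait, params = params)
  write_tsv(res$assignment, file.path(out_dir, "modules.tsv"))
  if (length(res$modules) > 0) {
    eig <- data.frame(sample_id = colnames(m),
                      sapply(res$modules, `[[`, "eigengene"),
                      check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(eig, file.path(out_dir, "eigengenes.tsv"))
    if (!is.null(trait)) {
      mt <- lapply(res$modules, function(mod)
        list(hub = mod$hub, size = length(mod$genes),
             r = mod$trait_r, p = mod$trait_p))
      jsonlite::write_json(mt, file.path(out_dir, "module_trait.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
  }
  z <- zscore_genes(log_transform(m))
  a <- adjacency(z, params)
  idx <- which(upper.tri(a) & a >= edge_threshold, arr.ind = TRUE)
  edges <- data.frame(gene_a = rownames(a)[idx[, 1]],
                      gene_b = colnames(a)[idx[, 2]],
                      weight = a[idx], stringsAsFactors = FALSE)
  edges <- edges[order(-edges$weight, edges$gene_a, edges$gene_b), ]
  write_tsv(edges, file.path(out_dir, "edges.tsv"))
  write_manifest(out_dir, "network",
                 inputs = list(expression = expression_path,
                               scores = scores_path),
                 params = c(unclass(params),
                            list(edge_threshold = edge_threshold)))
  invisible(res)
}

#' @rdname pipeline
#' @param variants_path Variant pair TSV.
#' @return \code{run_concordance}: writes \code{concordance_calls.tsv},
#'   \code{concordance_summary.tsv} and \code{concordance_summary.json};
#'   invisibly returns the summary data.frame.
#' @export
run_concordance <- function(variants_path, out_dir) {
  ensure_dir(out_dir)
  pairs <- read_variant_table(variants_path)
  calls <- classify_variant_pairs(pairs)
  summary <- summarize_concordance(pairs)
  write_tsv(calls, file.path(out_dir, "concordance_calls.tsv"))
  write_tsv(summary, file.path(out_dir, "concordance_summary.tsv"))
  jsonlite::write_json(summary, file.path(out_dir, "concordance_summary.json"),
                       pretty = TRUE, na = "null")
  write_manifest(out_dir, "concordance",
                 inputs = list(variants = variants_path), params = list())
  invisible(summary)
}

join_scores_clinical <- function(clinical_path, scores_path) {
  clin <- read_clinical_tsv(clinical_path)
  st <- read_tsv(scores_path)
  i <- match(clin$sample_id, st$sample_id)
  if (anyNA(i)) stop("score table does not cover all clinical samples")
  clin$label <- st$label[i]
  clin$score <- st$score[i]
  clin
}

#' @rdname pipeline
#' @return \code{run_survival}: writes one \code{km_<group>.tsv} per group
#'   and \code{logrank.json}; invisibly returns the log-rank result.
#' @export
run_survival <- function(clinical_path, scores_path, out_dir) {
  ensure_dir(out_dir)
  clin <- join_scores_clinical(clinical_path, scores_path)
  if (!all(c("time", "event") %in% names(clin)))
    stop("clinical table needs time and event columns")
  for (g in sort(unique(clin$label))) {
    sel <- clin$label == g
    km <- km_estimate(clin$time[sel], clin$event[sel])
    write_tsv(km, file.path(out_dir, paste0("km_", g, ".tsv")))
  }
  lr <- logrank_test(clin$time, clin$event, clin$label)
  jsonlite::write_json(list(statistic = lr$statistic, df = lr$df, p = lr$p),
                       file.path(out_dir, "logrank.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "survival",
                 inputs = list(clinical = clinical_path,
                               scores = scores_path), params = list())
  invisible(lr)
}

#' @rdname pipeline
#' @param scores_path Score table TSV used to stratify samples
#'   (\code{label} column: score > 0 is dormant).
#' @return \code{run_response}: writes \code{response_table.tsv} and
#'   \code{response_chisq.json}; invisibly returns the test result.
#' @export
run_response <- function(clinical_path, scores_path, out_dir) {
  ensure_dir(out_dir)
  clin <- join_scores_clinical(clinical_path, scores_path)
  if (!"response" %in% names(clin))
    stop("clinical table needs a response column")
  tab <- response_table(clin$label, clin$response)
  res <- response_chisq(tab)
  df <- data.frame(group = rownames(tab), tab, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, file.path(out_dir, "response_table.tsv"))
  jsonlite::write_json(list(statistic = res$statistic, df = res$df,
                            p = res$p),
                       file.path(out_dir, "response_chisq.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "response",
                 inputs = list(clinical = clinical_path,
                               scores = scores_path), params = list())
  invisible(res)
}

#' @rdname pipeline
#' @param single_cell_path Long-format single-cell TSV.
#' @return \code{run_sc_summary}: writes \code{sc_summary.tsv}; invisibly
#'   returns the summary.
#' @export
run_sc_summary <- function(single_cell_path, out_dir) {
  ensure_dir(out_dir)
  sc <- read_single_cell_tsv(single_cell_path)
  summary <- summarize_single_cell(sc$counts, sc$cell_map)
  write_tsv(summary, file.path(out_dir, "sc_summary.tsv"))
  write_manifest(out_dir, "sc-summary",
                 inputs = list(single_cell = single_cell_path),
                 params = list())
  invisible(summary)
}
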