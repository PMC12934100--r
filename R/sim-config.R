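#' Configuration for the synthetic dormancy cohort generator
#'
#' Bundles every tunable of the simulated two-phenotype (dormant vs
#' proliferative) melanoma cohort: cohort size, the planted eight-gene
#' signature, the planted co-expression module and its hub, survival and
#' response parameters, the variant-table mechanism and single-cell settings.
#' Defaults emulate the discovery conditions the downstream analysis assumes:
#' 11 + 11 samples, a 4-up / 4-down signature shifted by 2 on the log2 scale
#' with residual SD 0.5, a 13-gene module (hub + 12 members) whose eigengene
#' correlates with the dormancy score at 0.6, worse survival and lower
#' responder rates for dormant samples, RNA VAF usually above DNA VAF, and a
#' hub gene expressed in under 20% of cells per sample.
#'
#' @param n_dormant,n_proliferative Samples per phenotype (both must be >= 1
#'   for expression simulation).
#' @param n_background_genes Number of unstructured background genes.
#' @param up_genes,down_genes Identifiers of signature genes up- respectively
#'   down-regulated in the dormant phenotype.
#' @param effect_size Mean log2-scale shift of signature genes between
#'   phenotypes.
#' @param noise_sd Residual SD on the log2 scale for signature and background
#'   genes.
#' @param module_genes Number of planted module member genes (excluding the
#'   hub). Set to 0 to disable the module.
#' @param module_hub Identifier of the module hub; may coincide with an up
#'   gene (default \code{"TACSTD2"} does).
#' @param module_correlation Target pairwise correlation among module members.
#' @param hub_boost Extra factor-variance share of the hub, so its average
#'   correlation to members strictly exceeds the member-member correlation.
#' @param module_trait_r Target correlation between the module factor and the
#'   per-sample dormancy score (planted exactly in-sample).
#' @param hazard_ratio Multiplicative hazard of dormant vs proliferative
#'   samples; must be > 0.
#' @param baseline_median_survival Median survival (months) of the
#'   proliferative arm under the exponential model.
#' @param censor_rate Probability that a subject is censored.
#' @param responder_prob_dormant,responder_prob_proliferative Bernoulli
#'   responder probabilities per phenotype.
#' @param rna_higher_prob Among variant pairs confirmed at the same site with
#'   both VAFs observed, probability that the RNA VAF exceeds the DNA VAF.
#' @param dna_missing_prob Probability that the DNA VAF is unavailable.
#' @param rna_wt_prob Probability that the RNA call is wild type.
#' @param diff_site_prob Probability that the RNA variant hits a different
#'   site of the same gene.
#' @param n_cells_per_sample Cells simulated per sample in the single-cell
#'   generator.
#' @param rare_pos_fraction_max Upper bound on the fraction of cells per
#'   sample expressing the hub gene; must lie in (0, 1].
#' @param seed Integer master seed; every generator derives an independent
#'   child stream from it.
#'
#' @return An object of class \code{"sim_config"} (a validated list).
#' @examples
#' cfg <- sim_config(seed = 7)
#' cohort <- simulate_expression(cfg)
#' dim(cohort$expression)
#' @export
sim_config <- function(n_dormant = 11, n_proliferative = 11,
                       n_background_genes = 200,
                       up_genes = c("TACSTD2", "EREG", "SOX9", "LPPR4"),
                       down_genes = c("LAMA1", "TMEM27", "AMIGO2", "MGAT5B"),
                       effect_size = 2, noise_sd = 0.5,
                       module_genes = 12, module_hub = "TACSTD2",
                       module_correlation = 0.9, hub_boost = 0.09,
                       module_trait_r = 0.6,
                       hazard_ratio = 2.5, baseline_median_survival = 24,
                       censor_rate = 0.2,
                       responder_prob_dormant = 0.15,
                       responder_prob_proliferative = 0.55,
                       rna_higher_prob = 0.85, dna_missing_prob = 0.12,
                       rna_wt_prob = 0.08, diff_site_prob = 0.08,
                       n_cells_per_sample = 200,
                       rare_pos_fraction_max = 0.20,
                       seed = 1L) {
  counts <- c(n_dormant = n_dormant, n_proliferative = n_proliferative,
              n_background_genes = n_background_genes,
              module_genes = module_genes,
              n_cells_per_sample = n_cells_per_sample)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("all counts must be non-negative integers")
  probs <- c(censor_rate = censor_rate,
             responder_prob_dormant = responder_prob_dormant,
             responder_prob_proliferative = responder_prob_proliferative,
             rna_higher_prob = rna_higher_prob,
             dna_missing_prob = dna_missing_prob,
             rna_wt_prob = rna_wt_prob, diff_site_prob = diff_site_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[!is.finite(probs) | probs < 0 | probs > 1],
               collapse = ", "))
  if (!is.finite(rare_pos_fraction_max) || rare_pos_fraction_max <= 0 ||
      rare_pos_fraction_max > 1)
    stop("rare_pos_fraction_max must lie in (0, 1]")
  if (!is.finite(hazard_ratio) || hazard_ratio <= 0)
    stop("hazard_ratio must be > 0")
  if (!is.finite(baseline_median_survival) || baseline_median_survival <= 0)
    stop("baseline_median_survival must be > 0")
  if (!is.finite(effect_size) || !is.finite(noise_sd) || noise_sd < 0)
    stop("effect_size must be finite and noise_sd >= 0")
  if (module_correlation < 0 || module_correlation >= 1)
    stop("module_correlation must lie in [0, 1)")
  if (hub_boost < 0 || module_correlation + hub_boost > 0.99)
    stop("hub_boost must be >= 0 with module_correlation + hub_boost <= 0.99")
  if (abs(module_trait_r) > 1)
    stop("module_trait_r must lie in [-1, 1]")
  up_genes <- as.character(up_genes)
  down_genes <- as.character(down_genes)
  if (length(up_genes) == 0 || length(down_genes) == 0)
    stop("up_genes and down_genes must be non-empty")
  if (length(intersect(up_genes, down_genes)) > 0)
    stop("up_genes and down_genes must be disjoint")
  if (anyDuplicated(c(up_genes, down_genes)))
    stop("duplicate signature gene identifiers")
  module_hub <- as.character(module_hub)
  if (module_hub %in% down_genes)
    stop("module_hub may coincide with an up gene but not a down gene")
  member_ids <- if (module_genes > 0)
    sprintf("MODG%02d", seq_len(module_genes)) else character(0)
  background_ids <- if (n_background_genes > 0)
    sprintf("BG%04d", seq_len(n_background_genes)) else character(0)
  reserved <- c(up_genes, down_genes, module_hub)
  if (length(intersect(reserved, c(member_ids, background_ids))) > 0)
    stop("signature/hub gene identifiers collide with generated module or ",
         "background identifiers")
  cfg <- list(
    n_dormant = as.integer(n_dormant),
    n_proliferative = as.integer(n_proliferative),
    n_background_genes = as.integer(n_background_genes),
    up_genes = up_genes, down_genes = down_genes,
    effect_size = effect_size, noise_sd = noise_sd,
    module_genes = as.integer(module_genes), module_hub = module_hub,
    module_member_ids = member_ids, background_ids = background_ids,
    module_correlation = module_correlation, hub_boost = hub_boost,
    module_trait_r = module_trait_r,
    hazard_ratio = hazard_ratio,
    baseline_median_survival = baseline_median_survival,
    censor_rate = censor_rate,
    responder_prob_dormant = responder_prob_dormant,
    responder_prob_proliferative = responder_prob_proliferative,
    rna_higher_prob = rna_higher_prob, dna_missing_prob = dna_missing_prob,
    rna_wt_prob = rna_wt_prob, diff_site_prob = diff_site_prob,
    n_cells_per_sample = as.integer(n_cells_per_sample),
    rare_pos_fraction_max = rare_pos_fraction_max,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic dormancy cohort configuration\n")
  cat(sprintf("  samples: %d dormant + %d proliferative\n",
              x$n_dormant, x$n_proliferative))
  cat(sprintf("  signature: %s (up) vs %s (down), effect %.2g, noise SD %.2g\n",
              paste(x$up_genes, collapse = ","),
              paste(x$down_genes, collapse = ","),
              x$effect_size, x$noise_sd))
  cat(sprintf("  module: hub %s + %d members, rho %.2f (+%.2f hub), trait r %.2f\n",
              x$module_hub, x$module_genes, x$module_correlation,
              x$hub_boost, x$module_trait_r))
  cat(sprintf("  background genes: %d; seed: %d\n",
              x$n_background_genes, x$seed))
  invisible(x)
}

# Run code under a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so generators behave as pure functions.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Independent child stream k of a master seed (kept well below 2^31).
child_seed <- function(seed, k) {
  (abs(as.integer(seed)) %% 100003L) * 10007L + as.integer(k)
}
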