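#' Simulate a two-phenotype TPM expression matrix with planted structure
#'
#' Generates a genes x samples matrix of non-negative TPM-like values
#' (log-normal: Gaussian on the log2 scale, exponentiated) for a cohort of
#' dormant and proliferative samples. Three gene strata are planted:
#' \itemize{
#'   \item signature genes, shifted between phenotypes by
#'     \code{effect_size} on the log2 scale (up genes higher in dormant,
#'     down genes lower);
#'   \item a co-expression module driven by a shared latent factor whose
#'     in-sample correlation with the cohort's dormancy score equals
#'     \code{module_trait_r} exactly; members load \code{sqrt(rho)} on the
#'     factor and the hub loads highest (variance share \code{rho + hub_boost}),
#'     so the hub's average correlation to members is strictly maximal. The
#'     hub's loading is calibrated so its empirical between-phenotype shift
#'     equals \code{effect_size};
#'   \item unstructured background genes.
#' }
#' Identical configurations (including the seed) give bit-identical output.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements \code{expression} (genes x samples TPM
#'   matrix), \code{phenotype} (named character vector, \code{"dormant"} or
#'   \code{"proliferative"}) and \code{truth} (planted signature, module
#'   members and hub, for recovery experiments).
#' @examples
#' cohort <- simulate_expression(sim_config(seed = 1))
#' table(cohort$phenotype)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_dormant < 1 || config$n_proliferative < 1)
    stop("both phenotypes need at least one sample")
  with_seed(child_seed(config$seed, 1L), {
    nd <- config$n_dormant; np <- config$n_proliferative
    n <- nd + np
    samples <- c(sprintf("DOR%02d", seq_len(nd)),
                 sprintf("PRO%02d", seq_len(np)))
    phenotype <- stats::setNames(
      rep(c("dormant", "proliferative"), c(nd, np)), samples)
    pheno_c <- ifelse(phenotype == "dormant", 0.5, -0.5)

    sig_genes <- c(config$up_genes, config$down_genes)
    hub <- config$module_hub
    hub_is_up <- hub %in% config$up_genes
    plain_genes <- unique(c(sig_genes,
                            if (!hub_is_up) hub,
                            config$background_ids))
    direction <- stats::setNames(rep(0, length(plain_genes)), plain_genes)
    direction[config$up_genes] <- 1
    direction[config$down_genes] <- -1

    mu <- stats::setNames(stats::runif(length(plain_genes), 4, 8), plain_genes)
    L <- matrix(stats::rnorm(length(plain_genes) * n, sd = config$noise_sd),
                nrow = length(plain_genes), dimnames = list(plain_genes, samples))
    L <- L + mu + outer(direction, pheno_c) * config$effect_size

    if (config$module_genes > 0) {
      # Provisional dormancy score of the cohort, used to plant the module
      # factor with an exact in-sample trait correlation.
      tpm_sig <- pmax(2^L[sig_genes, , drop = FALSE] - 1, 0)
      st <- dormancy_score(zscore_genes(log_transform(tpm_sig)),
                           gene_signature(config$up_genes, config$down_genes))
      trait <- st$score
      f <- plant_factor(trait, config$module_trait_r, n)

      rho <- config$module_correlation
      members <- config$module_member_ids
      mu_m <- stats::runif(length(members), 4, 8)
      Lm <- mu_m + sqrt(rho) * matrix(rep(f, each = length(members)),
                                      nrow = length(members)) +
        sqrt(1 - rho) * matrix(stats::rnorm(length(members) * n),
                               nrow = length(members))
      dimnames(Lm) <- list(members, samples)

      # Hub: differential expression delivered through the factor.
      fdiff <- mean(f[phenotype == "dormant"]) -
        mean(f[phenotype == "proliferative"])
      a <- if (hub_is_up && config$effect_size != 0 && abs(fdiff) > 0.2)
        config$effect_size / fdiff else 1
      rho_h <- min(rho + config$hub_boost, 0.99)
      sd_h <- abs(a) * sqrt((1 - rho_h) / rho_h)
      hub_mu <- stats::runif(1, 4, 8)
      hub_row <- hub_mu + a * f + sd_h * stats::rnorm(n)
      L <- rbind(L, matrix(hub_row, nrow = 1,
                           dimnames = list("..hub..", samples)))
      L[hub, ] <- L["..hub..", ]
      L <- L[rownames(L) != "..hub..", , drop = FALSE]
      L <- rbind(L, Lm)
    }

    expression <- pmax(2^L - 1, 0)
    truth <- list(
      signature = gene_signature(config$up_genes, config$down_genes),
      module_genes = c(hub, config$module_member_ids),
      hub = hub)
    list(expression = expression, phenotype = phenotype, truth = truth)
  })
}

# Latent vector with *empirical* correlation r to `trait`: standardize the
# trait, draw noise, remove its projection on the trait, restandardize and mix.
plant_factor <- function(trait, r, n) {
  if (stats::sd(trait) < 1e-12) {
    # degenerate trait (e.g. all-zero scores under a null config): factor is
    # pure noise, standardized
    e <- stats::rnorm(n)
    return(as.numeric(scale(e)))
  }
  t_std <- as.numeric(scale(trait))
  e <- stats::rnorm(n)
  e <- e - mean(e)
  e <- e - sum(e * t_std) / sum(t_std^2) * t_std
  if (stats::sd(e) < 1e-12) e <- rep(0, n) else e <- as.numeric(scale(e))
  r * t_std + sqrt(1 - r^2) * e
}

#' Simulate clinical follow-up for a labelled cohort
#'
#' Exponential survival times with dormant hazard equal to
#' \code{hazard_ratio} times the proliferative baseline (baseline median
#' \code{baseline_median_survival} months), independent censoring with
#' probability \code{censor_rate} (censored subjects get a uniform fraction
#' of their latent event time), and Bernoulli responder flags with
#' phenotype-specific probabilities.
#'
#' @param config A [sim_config()] object; \code{hazard_ratio} must be > 0.
#' @param phenotype Named character vector of \code{"dormant"} /
#'   \code{"proliferative"} labels covering all samples (as returned by
#'   [simulate_expression()]).
#' @return A data.frame with columns \code{sample_id}, \code{phenotype},
#'   \code{time} (months), \code{event} (1 = event, 0 = censored) and
#'   \code{response} (\code{"responder"} / \code{"non_responder"}).
#' @export
simulate_clinical <- function(config, phenotype) {
  stopifnot(inherits(config, "sim_config"))
  if (config$hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (is.null(names(phenotype)) || any(!nzchar(names(phenotype))))
    stop("phenotype must be a named vector of sample labels")
  if (!all(phenotype %in% c("dormant", "proliferative")))
    stop("phenotype labels must be 'dormant' or 'proliferative'")
  with_seed(child_seed(config$seed, 2L), {
    n <- length(phenotype)
    base_rate <- log(2) / config$baseline_median_survival
    rate <- base_rate * ifelse(phenotype == "dormant", config$hazard_ratio, 1)
    latent <- stats::rexp(n, rate)
    event <- stats::rbinom(n, 1, 1 - config$censor_rate)
    time <- ifelse(event == 1, latent, latent * stats::runif(n))
    p_resp <- ifelse(phenotype == "dormant",
                     config$responder_prob_dormant,
                     config$responder_prob_proliferative)
    response <- ifelse(stats::rbinom(n, 1, p_resp) == 1,
                       "responder", "non_responder")
    data.frame(sample_id = names(phenotype),
               phenotype = unname(phenotype),
               time = unname(time), event = unname(event),
               response = unname(response),
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Simulate a per-sample DNA/RNA variant pair table
#'
#' One record per sample: a BRAF or NRAS protein change with a DNA VAF in
#' `[5, 95]` percent (missing with probability \code{dna_missing_prob}) paired
#' with an RNA-level call that is wild type with probability
#' \code{rna_wt_prob}, hits a different site of the same gene with
#' probability \code{diff_site_prob}, and otherwise confirms the DNA variant
#' with an RNA VAF strictly above the DNA VAF with probability
#' \code{rna_higher_prob} (strictly below otherwise) — emulating elevated
#' mutant transcript levels from copy-number gains at the mutant locus.
#'
#' @param config A [sim_config()] object.
#' @param n_samples Number of records; defaults to the cohort size.
#' @return A data.frame with columns \code{sample_id}, \code{gene},
#'   \code{dna_variant}, \code{dna_vaf}, \code{rna_variant}, \code{rna_vaf}.
#'   Wild type calls are \code{"WT"}; missing values are \code{NA}.
#' @export
simulate_variant_table <- function(config, n_samples = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(n_samples)) n_samples <- config$n_dormant + config$n_proliferative
  changes <- list(BRAF = c("V600E", "V600K", "D594N", "L597S"),
                  NRAS = c("Q61K", "Q61R", "Q61L", "G13D"))
  with_seed(child_seed(config$seed, 3L), {
    gene <- sample(c("BRAF", "NRAS"), n_samples, replace = TRUE,
                   prob = c(0.7, 0.3))
    dna_variant <- vapply(gene, function(g) sample(changes[[g]], 1), "")
    dna_vaf <- round(stats::runif(n_samples, 5, 90))
    dna_vaf[stats::runif(n_samples) < config$dna_missing_prob] <- NA_real_
    rna_variant <- dna_variant
    rna_vaf <- rep(NA_real_, n_samples)
    u <- stats::runif(n_samples)
    is_wt <- u < config$rna_wt_prob
    is_diff <- !is_wt & u < config$rna_wt_prob + config$diff_site_prob
    for (i in seq_len(n_samples)) {
      if (is_wt[i]) {
        rna_variant[i] <- "WT"
      } else if (is_diff[i]) {
        alt <- setdiff(changes[[gene[i]]], dna_variant[i])
        rna_variant[i] <- sample(alt, 1)
        rna_vaf[i] <- round(stats::runif(1, 5, 95))
      } else if (is.na(dna_vaf[i])) {
        rna_vaf[i] <- round(stats::runif(1, 20, 95))
      } else if (stats::runif(1) < config$rna_higher_prob) {
        rna_vaf[i] <- min(95, dna_vaf[i] + max(1, round(stats::runif(1, 1, 35))))
      } else {
        rna_vaf[i] <- max(1, dna_vaf[i] - max(1, round(stats::runif(1, 1, min(30, dna_vaf[i] - 1)))))
      }
    }
    data.frame(sample_id = sprintf("SIM%04d", seq_len(n_samples)),
               gene = gene, dna_variant = dna_variant, dna_vaf = dna_vaf,
               rna_variant = rna_variant, rna_vaf = rna_vaf,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Simulate single-cell expression of the signature genes
#'
#' For every sample, \code{n_cells_per_sample} cells are generated for the
#' signature genes. The hub gene is expressed in a rare fraction of cells per
#' sample — the positive-cell count is capped so the fraction never exceeds
#' \code{rare_pos_fraction_max} — while the remaining signature genes are
#' expressed in broad fractions (30-90%). Positive cells get log-normal
#' TPM-like values; all other entries are zero.
#'
#' @param config A [sim_config()] object with \code{n_cells_per_sample >= 1}.
#' @param hub_fraction Optional override in (0, 1] forcing the hub-positive
#'   fraction in every sample (1 forces full expression).
#' @return A list with \code{counts} (cells x genes matrix) and
#'   \code{cell_map} (data.frame \code{cell_id}, \code{sample_id}).
#' @export
simulate_single_cell <- function(config, hub_fraction = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_cells_per_sample < 1) stop("n_cells_per_sample must be >= 1")
  if (!is.null(hub_fraction) &&
      (hub_fraction <= 0 || hub_fraction > 1))
    stop("hub_fraction must lie in (0, 1]")
  with_seed(child_seed(config$seed, 4L), {
    nd <- config$n_dormant; np <- config$n_proliferative
    samples <- c(sprintf("DOR%02d", seq_len(nd)),
                 sprintf("PRO%02d", seq_len(np)))
    genes <- c(config$up_genes, config$down_genes)
    ncells <- config$n_cells_per_sample
    cell_ids <- as.vector(vapply(samples, function(s)
      sprintf("%s_C%03d", s, seq_len(ncells)), character(ncells)))
    counts <- matrix(0, nrow = length(cell_ids), ncol = length(genes),
                     dimnames = list(cell_ids, genes))
    cell_map <- data.frame(cell_id = cell_ids,
                           sample_id = rep(samples, each = ncells),
                           stringsAsFactors = FALSE)
    for (s in samples) {
      idx <- which(cell_map$sample_id == s)
      for (g in genes) {
        if (g == config$module_hub) {
          frac <- if (is.null(hub_fraction))
            stats::runif(1, 0.005, config$rare_pos_fraction_max)
          else hub_fraction
          npos <- max(1L, floor(frac * ncells))
          if (is.null(hub_fraction))
            npos <- min(npos, floor(config$rare_pos_fraction_max * ncells))
        } else {
          frac <- stats::runif(1, 0.3, 0.9)
          npos <- max(1L, round(frac * ncells))
        }
        pos <- sample(idx, npos)
        counts[pos, g] <- round(2^stats::rnorm(npos, mean = 3, sd = 1), 3)
      }
    }
    list(counts = counts, cell_map = cell_map)
  })
}
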