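test_that("generators are pure functions of the configuration and seed", {
  cfg <- sim_config(seed = 11, n_background_genes = 30, module_genes = 5,
                    n_cells_per_sample = 20)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a, b)
  expect_identical(simulate_clinical(cfg, a$phenotype),
                   simulate_clinical(cfg, a$phenotype))
  expect_identical(simulate_variant_table(cfg), simulate_variant_table(cfg))
  expect_identical(simulate_single_cell(cfg), simulate_single_cell(cfg))
  # a different seed changes the draw
  c2 <- simulate_expression(sim_config(seed = 12, n_background_genes = 30,
                                       module_genes = 5,
                                       n_cells_per_sample = 20))
  expect_false(identical(a$expression, c2$expression))
})

test_that("expression cohort has the configured shape and planted shifts", {
  cfg <- sim_config(seed = 3)
  co <- simulate_expression(cfg)
  expect_equal(dim(co$expression), c(8 + 12 + 200, 22))
  expect_true(all(co$expression >= 0))
  expect_equal(unname(table(co$phenotype)[c("dormant", "proliferative")]),
               c(11, 11), ignore_attr = TRUE)
  lg <- log_transform(co$expression)
  d <- co$phenotype == "dormant"
  shift <- rowMeans(lg[, d]) - rowMeans(lg[, !d])
  # planted directions, with room for sampling noise at n = 22
  expect_true(all(shift[cfg$up_genes] > 1))
  expect_true(all(shift[cfg$down_genes] < -1))
  expect_lt(max(abs(shift[cfg$background_ids])), 1)
})

test_that("module members are mutually correlated near the target with the hub strictly highest", {
  cfg <- sim_config(seed = 5)
  co <- simulate_expression(cfg)
  lg <- log_transform(co$expression)
  r <- cor(t(lg[co$truth$module_genes, ]))
  members <- setdiff(co$truth$module_genes, co$truth$hub)
  pair <- r[members, members][upper.tri(r[members, members])]
  expect_gt(mean(pair), cfg$module_correlation - 0.1)
  expect_lt(mean(pair), cfg$module_correlation + 0.07)
  avg_cor <- sapply(co$truth$module_genes, function(g)
    mean(r[g, setdiff(co$truth$module_genes, g)]))
  expect_identical(names(which.max(avg_cor)), co$truth$hub)
})

test_that("zeroed effects leave signature genes null-distributed across phenotypes", {
  rejections <- 0; tests <- 0
  for (s in 1:60) {
    cfg <- sim_config(seed = s, effect_size = 0, module_correlation = 0,
                      module_trait_r = 0, n_background_genes = 5)
    co <- simulate_expression(cfg)
    lg <- log_transform(co$expression)
    d <- co$phenotype == "dormant"
    for (g in c(cfg$up_genes, cfg$down_genes)) {
      tests <- tests + 1
      rejections <- rejections + (t.test(lg[g, d], lg[g, !d])$p.value < 0.05)
    }
  }
  expect_gt(rejections / tests, 0.005)
  expect_lt(rejections / tests, 0.10)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(censor_rate = 1.2), "probabilities")
  expect_error(sim_config(hazard_ratio = 0), "hazard_ratio")
  expect_error(sim_config(rare_pos_fraction_max = 0), "rare_pos_fraction_max")
  expect_error(sim_config(up_genes = c("A", "B"), down_genes = c("B", "C")),
               "disjoint")
  expect_error(sim_config(module_hub = "LAMA1"), "down gene")
  expect_error(sim_config(n_dormant = -1), "counts")
  expect_error(simulate_expression(sim_config(n_dormant = 0)),
               "at least one sample")
})

test_that("clinical simulation honours censoring bounds and hazard ordering", {
  cfg <- sim_config(seed = 9, censor_rate = 1)
  pheno <- setNames(rep(c("dormant", "proliferative"), each = 11),
                    sprintf("S%02d", 1:22))
  clin <- simulate_clinical(cfg, pheno)
  expect_true(all(clin$event == 0))

  cfg0 <- sim_config(seed = 9, censor_rate = 0)
  expect_true(all(simulate_clinical(cfg0, pheno)$event == 1))

  # dormant arm has worse survival under a strong hazard ratio
  lower <- 0
  for (s in 1:100) {
    cfgh <- sim_config(seed = s, n_dormant = 50, n_proliferative = 50,
                       hazard_ratio = 3, censor_rate = 0)
    ph <- setNames(rep(c("dormant", "proliferative"), each = 50),
                   sprintf("S%03d", 1:100))
    cl <- simulate_clinical(cfgh, ph)
    lower <- lower + (median(cl$time[cl$phenotype == "dormant"]) <
                        median(cl$time[cl$phenotype == "proliferative"]))
  }
  expect_gte(lower, 95)
})

test_that("variant tables respect forced outcomes and configured rates", {
  cfg <- sim_config(seed = 21, rna_higher_prob = 1, dna_missing_prob = 0,
                    rna_wt_prob = 0, diff_site_prob = 0)
  vt <- simulate_variant_table(cfg, 50)
  sm <- summarize_concordance(vt)
  expect_equal(sum(sm$n_rna_higher), 50)
  expect_equal(sum(sm$n_rna_lower), 0)
  expect_true(all(vt$dna_vaf >= 5 & vt$dna_vaf <= 95))

  vt2 <- simulate_variant_table(sim_config(seed = 22), 1000)
  sm2 <- summarize_concordance(vt2)
  frac_higher <- sum(sm2$n_rna_higher) / sum(sm2$n_with_both_vafs)
  expect_lt(abs(frac_higher - 0.85), 0.05)
})

test_that("single-cell hub expression is rare, bounded, and forceable", {
  cfg <- sim_config(seed = 13, n_cells_per_sample = 100)
  sc <- simulate_single_cell(cfg)
  sm <- summarize_single_cell(sc$counts, sc$cell_map)
  hub <- sm[sm$gene_id == cfg$module_hub, ]
  expect_true(all(hub$frac_expressing > 0))
  expect_true(all(hub$frac_expressing <= cfg$rare_pos_fraction_max))
  others <- sm[sm$gene_id != cfg$module_hub, ]
  expect_gt(min(others$frac_expressing), 0.2)

  full <- simulate_single_cell(cfg, hub_fraction = 1)
  smf <- summarize_single_cell(full$counts, full$cell_map)
  expect_true(all(smf$frac_expressing[smf$gene_id == cfg$module_hub] == 1))
})
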