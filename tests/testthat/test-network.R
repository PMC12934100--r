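test_that("adjacency follows the soft-threshold closed form", {
  # r = 0.5 pair at beta = 6 -> 0.5^6; anticorrelated pair -> 1
  x <- c(1, 2, 3, 4)
  y_half <- c(2.0, 1.0, 4.0, 3.0)  # cor = 0.6 with x? construct exactly below
  z <- rbind(a = x, b = -2 * x + 1)
  a <- adjacency(z, network_params(beta = 6))
  expect_equal(unname(diag(a)), c(1, 1))
  expect_equal(a["a", "b"], 1)  # |cor| = 1 regardless of sign

  # build a pair with exact correlation 0.5
  u <- c(1, -1, 1, -1, 1, -1)
  v <- c(1, -1, -1, 1, 1, 1)   # cor(u, v) = 1/3; instead construct directly:
  set.seed(1)
  g1 <- rnorm(200)
  g2 <- 0.5 * g1 + sqrt(1 - 0.25) * rnorm(200)
  g2 <- 0.5 * scale(g1)[, 1] + sqrt(0.75) * scale(resid(lm(g2 ~ g1)))[, 1]
  zz <- rbind(p = g1, q = g2)
  aa <- adjacency(zz, network_params(beta = 6))
  expect_equal(aa["p", "q"], 0.5^6, tolerance = 1e-9)

  # degenerate gene: zero off-diagonal adjacency
  zd <- rbind(c1 = rep(2, 5), r1 = c(1, 3, 2, 5, 4))
  ad <- adjacency(zd, network_params())
  expect_equal(ad["c1", "r1"], 0)
  expect_error(adjacency(z[, 1:2], network_params()), "3 samples")
})

test_that("topological overlap matches hand-computed small networks", {
  # 2-gene network: TOM equals the adjacency entry
  for (c0 in c(0.2, 0.5, 0.9)) {
    a <- matrix(c(1, c0, c0, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
    tom <- topological_overlap(a)
    expect_equal(tom["x", "y"], c0)
    expect_equal(unname(diag(tom)), c(1, 1))
  }
  # 3-gene fully connected network with all adjacencies 1
  a3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tom3 <- topological_overlap(a3)
  expect_true(all(tom3 == 1))
  # asymmetric input is rejected
  bad <- matrix(c(1, 0.2, 0.5, 1), 2)
  expect_error(topological_overlap(bad), "symmetric")
})

test_that("TOM entries stay in [0,1] and symmetric on random inputs", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(3:15, 1)
    z <- matrix(rnorm(n * 12), n, 12,
                dimnames = list(paste0("g", seq_len(n)), NULL))
    a <- adjacency(z, network_params(beta = sample(2:8, 1)))
    tom <- topological_overlap(a)
    expect_true(all(tom >= 0 & tom <= 1))
    expect_equal(tom, t(tom))
    expect_equal(unname(diag(tom)), rep(1, n))
  }
})

test_that("module detection recovers planted blocks and stays silent on noise", {
  m <- planted_block_matrix(n_block = 8, n_noise = 20, n_samples = 30, seed = 2)
  z <- zscore_genes(log_transform(m))
  tom <- topological_overlap(adjacency(z, network_params()))
  mods <- detect_modules(tom, network_params(min_module_size = 5))
  expect_length(mods, 2)
  expect_setequal(unlist(lapply(mods, function(g) substr(g, 1, 1))),
                  c("A", "B"))
  expect_setequal(mods[[1]], paste0("A", 1:8))
  expect_setequal(mods[[2]], paste0("B", 1:8))

  # pure noise: no modules
  set.seed(3)
  zn <- matrix(rnorm(30 * 25), 30, 25,
               dimnames = list(paste0("n", 1:30), NULL))
  tn <- topological_overlap(adjacency(zn, network_params()))
  expect_length(detect_modules(tn, network_params(min_module_size = 5)), 0)

  # fewer genes than the minimum module size
  expect_length(detect_modules(tn[1:3, 1:3],
                               network_params(min_module_size = 5)), 0)
})

test_that("module detection is invariant under gene permutation", {
  m <- planted_block_matrix(n_block = 6, n_noise = 10, n_samples = 25, seed = 9)
  z <- zscore_genes(log_transform(m))
  p <- network_params(min_module_size = 4)
  mods1 <- detect_modules(topological_overlap(adjacency(z, p)), p)
  set.seed(4)
  perm <- sample(nrow(z))
  mods2 <- detect_modules(topological_overlap(adjacency(z[perm, ], p)), p)
  expect_equal(mods1, mods2)
  # partition: no gene in two modules
  expect_false(anyDuplicated(unlist(mods1)) > 0)
})

test_that("eigengene summarizes a rank-1 module and obeys the sign rule", {
  profile <- c(2, -1, 0.5, -3, 1.5)
  z <- rbind(m1 = profile, m2 = profile, m3 = profile)
  eig <- module_eigengene(z, c("m1", "m2", "m3"))
  expect_equal(sqrt(sum(eig^2)), 1)
  expect_equal(abs(cor(eig, profile)), 1)
  expect_gte(cor(eig, colMeans(z)), 0)

  set.seed(31)
  for (i in 1:10) {
    zz <- matrix(rnorm(5 * 8), 5, 8, dimnames = list(paste0("g", 1:5), NULL))
    e <- module_eigengene(zz, rownames(zz))
    expect_gte(cor(e, colMeans(zz)), 0)
  }
  expect_error(module_eigengene(z, character(0)), "non-empty")
  expect_error(module_eigengene(z, "absent"), "absent")
})

test_that("module-trait correlation matches the t-transform and its edge cases", {
  set.seed(17)
  eig <- rnorm(18)
  expect_equal(module_trait_correlation(eig, eig)$r, 1)
  # constructed orthogonal trait
  tr <- rnorm(18)
  tr <- tr - mean(tr)
  e_c <- eig - mean(eig)
  tr <- tr - sum(tr * e_c) / sum(e_c^2) * e_c
  expect_lt(abs(module_trait_correlation(eig, tr)$r), 1e-9)
  # p equals the closed-form t transform
  x <- rnorm(12); y <- 0.5 * x + rnorm(12)
  res <- module_trait_correlation(x, y)
  tstat <- res$r * sqrt((12 - 2) / (1 - res$r^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), df = 10), tolerance = 1e-12)
  expect_error(module_trait_correlation(x[1:2], y[1:2]), "at least 3")
  expect_error(module_trait_correlation(x, rep(1, 12)), "zero variance")
})

test_that("hub gene maximizes intramodular connectivity with brute-force check", {
  set.seed(23)
  # star topology: center correlated with all members, members near-independent
  center <- rnorm(40)
  members <- sapply(1:6, function(i) 0.9 * center + sqrt(1 - 0.81) * rnorm(40))
  z <- rbind(t(members), hubg = center)
  rownames(z) <- c(paste0("leaf", 1:6), "hubg")
  a <- adjacency(z, network_params())
  mod <- rownames(z)
  expect_identical(hub_gene(a, mod), "hubg")
  k <- intramodular_connectivity(a, mod)
  brute <- sapply(mod, function(g) sum(a[g, setdiff(mod, g)]))
  expect_equal(k, brute)
  expect_identical(names(which.max(brute)), "hubg")

  expect_identical(hub_gene(a, "leaf3"), "leaf3")  # single-gene module
  expect_error(hub_gene(a, c("leaf1", "ghost")), "ghost")
  # deterministic lexicographic tie-break
  at <- matrix(0.5, 3, 3, dimnames = list(c("b", "a", "c"), c("b", "a", "c")))
  diag(at) <- 1
  expect_identical(hub_gene(at, c("b", "a", "c")), "a")
})

test_that("full pipeline finds one score-associated module on the default cohort", {
  co <- simulate_expression(sim_config(seed = 31))
  st <- score_samples(co$expression)
  net <- coexpression_analysis(co$expression, trait = st$score)
  sig_mods <- Filter(function(m) m$trait_p < 0.05, net$modules)
  expect_length(sig_mods, 1)
  expect_setequal(sig_mods[[1]]$genes, co$truth$module_genes)
  expect_identical(sig_mods[[1]]$hub, co$truth$hub)
  expect_true(net$assignment$is_hub[net$assignment$gene_id == co$truth$hub])
})
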