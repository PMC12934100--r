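# Independent oracles and small shared fixtures for the suite.

# Brute-force AUC: fraction of (positive, negative) pairs where the positive
# scores higher, ties counted one half.
brute_force_auc <- function(scores, truth, positive = "dormant") {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Trapezoid integration of an ROC polygon.
trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

# A small deterministic z-matrix holding the default signature genes plus
# spares, for score-level tests.
make_signature_z <- function(up_z, down_z, samples = length(up_z)) {
  sig <- default_signature()
  z <- matrix(0, nrow = 8, ncol = samples,
              dimnames = list(c(sig$up, sig$down), NULL))
  for (g in sig$up) z[g, ] <- up_z
  for (g in sig$down) z[g, ] <- down_z
  z
}

# Expression matrix with two planted correlated blocks on top of noise,
# used by the module-detection tests.
planted_block_matrix <- function(n_block = 8, n_noise = 20, n_samples = 30,
                                 rho = 0.9, seed = 1) {
  set.seed(seed)
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  rows <- list()
  for (i in seq_len(n_block))
    rows[[paste0("A", i)]] <- sqrt(rho) * f1 + sqrt(1 - rho) * rnorm(n_samples)
  for (i in seq_len(n_block))
    rows[[paste0("B", i)]] <- sqrt(rho) * f2 + sqrt(1 - rho) * rnorm(n_samples)
  for (i in seq_len(n_noise))
    rows[[paste0("N", i)]] <- rnorm(n_samples)
  m <- do.call(rbind, rows)
  2^(m + 6)  # to the TPM-like scale consumed by the pipeline
}
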