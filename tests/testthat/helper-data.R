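# Small fixture builders shared across test files. Everything is generated
# in code; nothing is read from disk except explicit round-trip tests that
# write to tempfiles.

# Batch-mean table for a strongly separated two-control design: variants
# "ben" (benign, around 0) and "path" (pathogenic, around `sep`), plus
# optional unlabeled variants at stated centres, observed in `n_batches`
# batches with tiny residual noise.
separated_batch_means <- function(n_batches = 50, sep = 5, noise = 0.05,
                                  unlabeled = c(u1 = 5), seed = 42,
                                  n_per_class = 2) {
  set.seed(seed)
  batches <- sprintf("b%02d", seq_len(n_batches))
  rows <- list()
  for (i in seq_len(n_per_class)) {
    rows[[length(rows) + 1]] <- data.frame(
      variant_id = if (i == 1) "ben" else paste0("ben", i),
      batch_id = batches,
      mean_log_ratio = rnorm(n_batches, 0, noise),
      n_replicates = 1L, label = "benign_control",
      stringsAsFactors = FALSE
    )
    rows[[length(rows) + 1]] <- data.frame(
      variant_id = if (i == 1) "path" else paste0("path", i),
      batch_id = batches,
      mean_log_ratio = rnorm(n_batches, sep, noise),
      n_replicates = 1L, label = "pathogenic_control",
      stringsAsFactors = FALSE
    )
  }
  for (nm in names(unlabeled)) {
    rows[[length(rows) + 1]] <- data.frame(
      variant_id = nm, batch_id = batches,
      mean_log_ratio = rnorm(n_batches, unlabeled[[nm]], noise),
      n_replicates = 1L, label = "unlabeled",
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# A fast MCMC configuration for tests (short chains, two of them).
fast_config <- function(...) {
  varcall_config(n_iter = 1200, n_burn = 400, thin = 2, n_chains = 2,
                 seed = 99, ...)
}

# Tiny fixed-hyperparameter instance used against the closed-form oracle:
# one labeled control per class and two unlabeled variants (one close to the
# benign centre, one ambiguous), in 2 batches, all cells observed.
oracle_instance <- function(seed = 5) {
  set.seed(seed)
  fx <- list(mu0 = 0, mu1 = -2, tau2_0 = 0.2, tau2_1 = 0.3,
             sigma_b2 = 0.1, sigma_e2 = 0.15, pi = 0.4)
  ids <- c("benA", "pathA", "u_cold", "u_mid")
  d_label <- c(benA = 0L, pathA = 1L, u_cold = NA, u_mid = NA)
  centers <- c(benA = 0, pathA = -2, u_cold = 0.2, u_mid = -1)
  batches <- c("b1", "b2")
  beta_true <- c(0.2, -0.1)
  grid <- expand.grid(variant_id = ids, batch_id = batches,
                      stringsAsFactors = FALSE)
  grid$mean_log_ratio <- centers[grid$variant_id] +
    beta_true[match(grid$batch_id, batches)] +
    rnorm(nrow(grid), 0, sqrt(fx$sigma_e2))
  grid$n_replicates <- 1L
  grid$label <- c(benA = "benign_control", pathA = "pathogenic_control",
                  u_cold = "unlabeled", u_mid = "unlabeled")[grid$variant_id]
  list(assay = grid, d_label = d_label, fx = fx)
}
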