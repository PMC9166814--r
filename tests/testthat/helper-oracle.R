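# Independent oracles used by the model tests. These never call the
# package's sampler internals: the D-posterior oracle integrates the variant
# and batch effects analytically through the implied Gaussian covariance of
# the batch means and enumerates the pathogenicity configurations.

log_dmvnorm <- function(y, mean, Sigma) {
  L <- chol(Sigma)
  z <- backsolve(L, y - mean, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

# Exact Pr(D_v = 1 | y) for a fixed-hyperparameter model.
# assay: data.frame(variant_id, batch_id, mean_log_ratio)
# d_label: named integer vector (0/1/NA) keyed by variant_id
# fx: list(mu0, mu1, tau2_0, tau2_1, sigma_b2, sigma_e2, pi)
# extra_lbf: optional named vector of per-variant log Bayes factors added
#   to the classification log-odds (family / Align-GVGD style evidence)
oracle_d_posterior <- function(assay, d_label, fx, extra_lbf = NULL) {
  ids <- sort(unique(assay$variant_id))
  V <- length(ids)
  batches <- sort(unique(assay$batch_id))
  v_idx <- match(assay$variant_id, ids)
  b_idx <- match(assay$batch_id, batches)
  y <- assay$mean_log_ratio
  n <- length(y)
  Zv <- matrix(0, n, V); Zv[cbind(seq_len(n), v_idx)] <- 1
  Zb <- matrix(0, n, length(batches)); Zb[cbind(seq_len(n), b_idx)] <- 1

  d_known <- d_label[ids]
  free <- which(is.na(d_known))
  configs <- if (length(free) == 0) {
    matrix(integer(0), nrow = 1)
  } else {
    as.matrix(expand.grid(rep(list(0:1), length(free))))
  }
  log_w <- numeric(nrow(configs))
  d_mat <- matrix(NA_integer_, nrow(configs), V)
  for (i in seq_len(nrow(configs))) {
    d <- d_known
    if (length(free) > 0) d[free] <- as.integer(configs[i, ])
    d_mat[i, ] <- d
    mu_v <- ifelse(d == 1, fx$mu1, fx$mu0)
    tau2_v <- ifelse(d == 1, fx$tau2_1, fx$tau2_0)
    Sigma <- Zv %*% (tau2_v * t(Zv)) + fx$sigma_b2 * (Zb %*% t(Zb)) +
      fx$sigma_e2 * diag(n)
    lp_prior <- sum(ifelse(is.na(d_known), # only free D carry the Bernoulli prior
      ifelse(d == 1, log(fx$pi), log1p(-fx$pi)), 0
    ))
    lp_extra <- if (is.null(extra_lbf)) 0 else sum(extra_lbf[ids] * d, na.rm = TRUE)
    log_w[i] <- lp_prior + lp_extra + log_dmvnorm(y, mu_v[v_idx], Sigma)
  }
  w <- exp(log_w - max(log_w))
  w <- w / sum(w)
  setNames(as.numeric(w %*% d_mat), ids)
}

# Closed-form GLS posterior mean of (theta, beta) given y at fixed variances
# and fixed component means (all variants labeled).
oracle_gls_effects <- function(assay, d_label, fx) {
  ids <- sort(unique(assay$variant_id))
  batches <- sort(unique(assay$batch_id))
  V <- length(ids); B <- length(batches)
  v_idx <- match(assay$variant_id, ids)
  b_idx <- match(assay$batch_id, batches)
  y <- assay$mean_log_ratio
  n <- length(y)
  A <- matrix(0, n, V + B)
  A[cbind(seq_len(n), v_idx)] <- 1
  A[cbind(seq_len(n), V + b_idx)] <- 1
  d <- d_label[ids]
  prior_mean <- c(ifelse(d == 1, fx$mu1, fx$mu0), rep(0, B))
  prior_prec <- diag(c(
    1 / ifelse(d == 1, fx$tau2_1, fx$tau2_0),
    rep(1 / fx$sigma_b2, B)
  ))
  post_prec <- prior_prec + crossprod(A) / fx$sigma_e2
  post_mean <- solve(post_prec, prior_prec %*% prior_mean + crossprod(A, y) / fx$sigma_e2)
  list(theta = setNames(post_mean[seq_len(V)], ids),
       beta = setNames(post_mean[V + seq_len(B)], batches))
}

# Brute-force rank score: fraction strictly below plus half the ties,
# rescaled to the (rank - 1)/(n - 1) convention.
oracle_rank_score <- function(x) {
  n <- length(x)
  vapply(x, function(xi) {
    (sum(x < xi) + (sum(x == xi) - 1) / 2) / (n - 1)
  }, 0)
}
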