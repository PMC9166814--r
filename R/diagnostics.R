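# Split-chain convergence diagnostics for the scalar model parameters.

split_chains <- function(draws_list) {
  out <- list()
  for (m in draws_list) {
    n <- nrow(m)
    h <- floor(n / 2)
    if (h < 2) return(draws_list)
    out <- c(out, list(m[seq_len(h), , drop = FALSE],
                       m[(n - h + 1):n, , drop = FALSE]))
  }
  out
}

rhat_one <- function(cols) {
  # cols: list of numeric vectors (split half-chains) for one parameter
  m <- length(cols)
  n <- length(cols[[1]])
  means <- vapply(cols, mean, 0)
  vars <- vapply(cols, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_one <- function(cols) {
  # crude initial-positive-sequence estimator on pooled split chains
  m <- length(cols)
  n <- length(cols[[1]])
  W <- mean(vapply(cols, stats::var, 0))
  B <- n * stats::var(vapply(cols, mean, 0))
  var_plus <- (n - 1) / n * W + B / n
  if (!is.finite(var_plus) || var_plus <= 0) return(NA_real_)
  rho_sum <- 0
  max_lag <- min(n - 1, 100)
  for (lag in seq_len(max_lag)) {
    acov <- mean(vapply(cols, function(x) {
      xm <- x - mean(x)
      mean(xm[seq_len(n - lag)] * xm[(lag + 1):n])
    }, 0))
    rho <- 1 - (W - acov) / var_plus
    if (rho < 0) break
    rho_sum <- rho_sum + rho
  }
  m * n / (1 + 2 * rho_sum)
}

# draws_list: one scalar-draw matrix (iterations x parameters) per chain
mcmc_diagnostics <- function(draws_list) {
  pars <- colnames(draws_list[[1]])
  halves <- split_chains(draws_list)
  out <- data.frame(
    parameter = pars,
    rhat = NA_real_, ess = NA_real_,
    stringsAsFactors = FALSE
  )
  for (j in seq_along(pars)) {
    cols <- lapply(halves, function(m) m[, j])
    # a parameter frozen at a point mass has zero variance by construction
    if (all(vapply(cols, function(x) stats::var(x) == 0, TRUE))) next
    out$rhat[j] <- rhat_one(cols)
    out$ess[j] <- ess_one(cols)
  }
  out$converged <- is.na(out$rhat) | out$rhat <= 1.01
  out
}
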