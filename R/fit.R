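# The hierarchical model and its Gibbs sampler.
#
# Observation level (within-batch means):  y_vb = theta_v + beta_b + e,
#   e ~ N(0, sigma_e2) (optionally scaled by replicate count).
# Variant level:  theta_v | D_v = d ~ N(mu_d, tau2_d)  -- a two-component
#   Gaussian mixture over variant effects, semi-supervised by labeled
#   controls (D frozen at the label).
# Batch level:    beta_b ~ N(0, sigma_b2).
# Classification: D_v ~ Bernoulli(pi) a priori; the full conditional of D_v
#   multiplies the mixture density of theta_v, the class-conditional PC
#   density, and exp(d * log BF) terms for family and Align-GVGD evidence
#   where available. Missing evidence contributes a factor of one.

rinvgamma <- function(n, shape, rate) 1 / stats::rgamma(n, shape = shape, rate = rate)

rtruncnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo < 1e-12) {
    # numerically degenerate truncation region: clamp to the nearer bound
    return(if (is.finite(lower)) lower else upper)
  }
  stats::qnorm(stats::runif(1, plo, phi), mean, sd)
}

label_to_d <- function(label) {
  ifelse(label == "pathogenic_control", 1L,
    ifelse(label == "benign_control", 0L, NA_integer_)
  )
}

# Assemble aligned model inputs from the assay / evidence tables.
prepare_model_data <- function(assay, evidence, config) {
  use_function <- "function" %in% config$evidence_set
  if (use_function) {
    if (is.null(assay)) {
      vc_stop("evidence_set includes 'function' but no assay data supplied",
              "varcallxt_validation_error")
    }
    if (!"mean_log_ratio" %in% names(assay)) {
      if ("log_ratio" %in% names(assay)) {
        assay <- average_within_batch(assay)
      } else {
        vc_stop("assay table has neither mean_log_ratio nor log_ratio",
                "varcallxt_schema_error")
      }
    }
  } else {
    assay <- NULL
  }

  ids <- character(0)
  labels <- character(0)
  add_labels <- function(id, lab) {
    if (is.null(lab)) lab <- "unlabeled"
    lab <- rep_len(lab, length(id))
    lab[is.na(lab)] <- "unlabeled"
    first <- !duplicated(id)
    id <- id[first]; lab <- lab[first]
    for (i in seq_along(id)) {
      j <- match(id[i], ids)
      if (is.na(j)) {
        ids <<- c(ids, id[i]); labels <<- c(labels, lab[i])
      } else if (labels[j] == "unlabeled") {
        labels[j] <<- lab[i]
      } else if (lab[i] != "unlabeled" && lab[i] != labels[j]) {
        vc_stop(sprintf("conflicting labels for variant %s", id[i]),
                "varcallxt_validation_error")
      }
    }
  }
  if (!is.null(assay)) add_labels(assay$variant_id, assay$label %||% "unlabeled")
  if (!is.null(evidence)) add_labels(evidence$variant_id, evidence$label %||% "unlabeled")
  if (length(ids) == 0) {
    vc_stop("no variants found in the supplied inputs", "varcallxt_validation_error")
  }
  ord <- order(ids)
  ids <- ids[ord]; labels <- labels[ord]
  V <- length(ids)
  d_label <- label_to_d(labels)

  dat <- list(
    variant_id = ids, label = labels, d_label = d_label, V = V,
    use_function = use_function,
    use_family = "family" %in% config$evidence_set,
    use_pc = "protein_pred" %in% config$evidence_set,
    use_agvgd = "agvgd" %in% config$evidence_set
  )

  if (use_function) {
    v_idx <- match(assay$variant_id, ids)
    batches <- sort(unique(assay$batch_id))
    b_idx <- match(assay$batch_id, batches)
    w <- if (isTRUE(config$weight_by_replicates) && "n_replicates" %in% names(assay)) {
      as.numeric(assay$n_replicates)
    } else {
      rep(1, nrow(assay))
    }
    has_y <- tabulate(v_idx, V) > 0
    lab_y <- d_label[has_y]
    if (!any(lab_y %in% 0L) || !any(lab_y %in% 1L)) {
      vc_stop(paste(
        "function data present but a mixture component has no labeled",
        "variant with assay observations; the mixture is unidentifiable"
      ), "varcallxt_identifiability_error")
    }
    dat$y <- assay$mean_log_ratio
    dat$v_idx <- v_idx
    dat$b_idx <- b_idx
    dat$w <- w
    dat$batch_id <- batches
    dat$B <- length(batches)
    dat$has_y <- has_y
    # data-derived hyperprior centres for the component means
    vmeans <- tapply(assay$mean_log_ratio, assay$variant_id, mean)
    vm <- as.numeric(vmeans[ids[has_y]])
    cls <- d_label[has_y]
    m0 <- mean(vm[cls %in% 0L]); m1 <- mean(vm[cls %in% 1L])
    s0 <- stats::sd(vm[cls %in% 0L]); s1 <- stats::sd(vm[cls %in% 1L])
    fallback_sd <- stats::sd(vm)
    if (!is.finite(fallback_sd) || fallback_sd == 0) fallback_sd <- 1
    if (!is.finite(s0) || s0 == 0) s0 <- fallback_sd
    if (!is.finite(s1) || s1 == 0) s1 <- fallback_sd
    dat$mu0_mean <- config$mu0_mean %||% m0
    dat$mu0_sd <- config$mu0_sd %||% (10 * s0)
    dat$mu1_mean <- config$mu1_mean %||% m1
    dat$mu1_sd <- config$mu1_sd %||% (10 * s1)
    # ordering direction for the label-switching guard
    dat$mu_dir <- sign(dat$mu1_mean - dat$mu0_mean)
  }

  if (!is.null(evidence)) {
    e_row <- match(ids, evidence$variant_id)
    pc_cols <- grep("^pc_[0-9]+$", names(evidence), value = TRUE)
    if (dat$use_pc && length(pc_cols) > 0) {
      pc_cols <- pc_cols[order(as.integer(sub("^pc_", "", pc_cols)))]
      X <- as.matrix(evidence[e_row, pc_cols, drop = FALSE])
      rownames(X) <- ids
      dat$X <- X
      dat$has_pc <- rowSums(is.na(X)) == 0
      dat$K <- ncol(X)
    }
    if (dat$use_family && "family_log_bf" %in% names(evidence)) {
      dat$fam_lbf <- as.numeric(evidence$family_log_bf[e_row])
    }
    if (dat$use_agvgd && "agvgd_prob" %in% names(evidence)) {
      p <- as.numeric(evidence$agvgd_prob[e_row])
      dat$agvgd_lbf <- ifelse(
        is.na(p), NA_real_,
        suppressWarnings(agvgd_to_log_bf(p, config$agvgd_reference_prior))
      )
    }
  }
  if (dat$use_pc && is.null(dat$X)) {
    vc_stop("evidence_set includes 'protein_pred' but no pc_* columns supplied",
            "varcallxt_validation_error")
  }
  if (dat$use_family && is.null(dat$fam_lbf)) {
    vc_stop("evidence_set includes 'family' but no family_log_bf column supplied",
            "varcallxt_validation_error")
  }
  if (dat$use_agvgd && is.null(dat$agvgd_lbf)) {
    vc_stop("evidence_set includes 'agvgd' but no agvgd_prob column supplied",
            "varcallxt_validation_error")
  }
  dat
}

chain_init <- function(dat, config) {
  state <- list()
  d <- dat$d_label
  miss <- is.na(d)
  d[miss] <- stats::rbinom(sum(miss), 1, 0.5)
  state$D <- d
  n1 <- sum(dat$d_label %in% 1L); n0 <- sum(dat$d_label %in% 0L)
  state$pi <- config$fixed$pi %||% ((config$pi_a + n1) / (config$pi_a + config$pi_b + n0 + n1))
  if (dat$use_function) {
    vm <- rep(NA_real_, dat$V)
    agg <- tapply(dat$y, dat$v_idx, mean)
    vm[as.integer(names(agg))] <- as.numeric(agg)
    vm[is.na(vm)] <- mean(dat$y)
    state$theta <- vm
    state$beta <- rep(0, dat$B)
    state$mu <- c(config$fixed$mu0 %||% dat$mu0_mean,
                  config$fixed$mu1 %||% dat$mu1_mean)
    v_all <- stats::var(dat$y)
    if (!is.finite(v_all) || v_all == 0) v_all <- 1
    state$tau2 <- c(config$fixed$tau2_0 %||% v_all,
                    config$fixed$tau2_1 %||% v_all)
    state$sigma_b2 <- config$fixed$sigma_b2 %||% (v_all / 2)
    state$sigma_e2 <- config$fixed$sigma_e2 %||% (v_all / 2)
  }
  if (dat$use_pc) {
    X <- dat$X[dat$has_pc, , drop = FALSE]
    state$pc_m0 <- rep(0, dat$K)
    state$pc_m1 <- rep(0, dat$K)
    cm <- colMeans(X)
    state$pc_m0 <- cm
    state$pc_m1 <- cm
    pv <- apply(X, 2, stats::var)
    pv[!is.finite(pv) | pv == 0] <- 1
    state$pc_var <- pv
  }
  state
}

# One Gibbs chain. Returns thinned post-burn-in draws plus the final state
# (used to warm-start leave-one-variant-out refits).
run_chain <- function(dat, config, chain_seed, init = NULL) {
  set.seed(chain_seed)
  st <- init %||% chain_init(dat, config)
  if (!is.null(init)) {
    # a warm start must still respect the (possibly re-masked) labels
    fixed_d <- !is.na(dat$d_label)
    st$D[fixed_d] <- dat$d_label[fixed_d]
  }
  fx <- config$fixed
  V <- dat$V
  free_d <- is.na(dat$d_label)
  n_keep <- floor((config$n_iter - config$n_burn) / config$thin)
  keep_iters <- config$n_burn + config$thin * seq_len(n_keep)

  scalar_names <- "pi"
  if (dat$use_function) {
    scalar_names <- c(scalar_names, "mu0", "mu1", "tau2_0", "tau2_1",
                      "sigma_b2", "sigma_e2")
  }
  scalars <- matrix(NA_real_, n_keep, length(scalar_names),
                    dimnames = list(NULL, scalar_names))
  D_draws <- matrix(NA_integer_, n_keep, V)
  theta_draws <- if (dat$use_function) matrix(NA_real_, n_keep, V) else NULL
  beta_sum <- if (dat$use_function) rep(0, dat$B) else NULL
  pc_m_draws <- if (dat$use_pc) matrix(NA_real_, n_keep, 2 * dat$K) else NULL

  if (dat$use_function) {
    wy <- dat$w * dat$y
    n_v <- as.numeric(rowsum(dat$w, dat$v_idx, reorder = TRUE))
    v_levels <- sort(unique(dat$v_idx))
    n_b <- as.numeric(rowsum(dat$w, dat$b_idx, reorder = TRUE))
    N_eff <- sum(dat$w)
  }

  kept <- 0L
  for (iter in seq_len(config$n_iter)) {
    if (dat$use_function) {
      # --- variant effects theta_v (variants with assay observations)
      resid_b <- dat$y - st$beta[dat$b_idx]
      s_v <- as.numeric(rowsum(dat$w * resid_b, dat$v_idx, reorder = TRUE))
      mu_d <- st$mu[st$D + 1L]
      tau2_d <- st$tau2[st$D + 1L]
      prec <- n_v / st$sigma_e2 + 1 / tau2_d[v_levels]
      mean_post <- (s_v / st$sigma_e2 + mu_d[v_levels] / tau2_d[v_levels]) / prec
      st$theta[v_levels] <- stats::rnorm(length(v_levels), mean_post, sqrt(1 / prec))
      # variants without assay data: theta from its mixture prior (kept for
      # completeness; carries no information about D beyond the prior)
      no_y <- which(!dat$has_y)
      if (length(no_y) > 0) {
        st$theta[no_y] <- stats::rnorm(length(no_y), mu_d[no_y], sqrt(tau2_d[no_y]))
      }

      # --- batch effects
      resid_t <- dat$y - st$theta[dat$v_idx]
      s_b <- as.numeric(rowsum(dat$w * resid_t, dat$b_idx, reorder = TRUE))
      prec_b <- n_b / st$sigma_e2 + 1 / st$sigma_b2
      st$beta <- stats::rnorm(dat$B, (s_b / st$sigma_e2) / prec_b, sqrt(1 / prec_b))

      # --- variances
      r <- dat$y - st$theta[dat$v_idx] - st$beta[dat$b_idx]
      if (is.null(fx$sigma_e2)) {
        st$sigma_e2 <- rinvgamma(1, config$sigma_e_shape + N_eff / 2,
                                 config$sigma_e_rate + 0.5 * sum(dat$w * r^2))
      }
      if (is.null(fx$sigma_b2)) {
        st$sigma_b2 <- rinvgamma(1, config$sigma_b_shape + dat$B / 2,
                                 config$sigma_b_rate + 0.5 * sum(st$beta^2))
      }

      # --- component means (with ordering guard) and variances,
      #     using only variants that have assay observations
      th <- st$theta[dat$has_y]
      dcl <- st$D[dat$has_y]
      pm <- c(dat$mu0_mean, dat$mu1_mean)
      ps <- c(dat$mu0_sd, dat$mu1_sd)
      post_mean <- numeric(2); post_sd <- numeric(2)
      for (d in 0:1) {
        sel <- dcl == d
        nd <- sum(sel)
        prec_mu <- nd / st$tau2[d + 1] + 1 / ps[d + 1]^2
        post_mean[d + 1] <- (sum(th[sel]) / st$tau2[d + 1] + pm[d + 1] / ps[d + 1]^2) / prec_mu
        post_sd[d + 1] <- sqrt(1 / prec_mu)
      }
      if (is.null(fx$mu0)) {
        st$mu[1] <- stats::rnorm(1, post_mean[1], post_sd[1])
      }
      if (is.null(fx$mu1)) {
        st$mu[2] <- if (dat$mu_dir > 0) {
          rtruncnorm1(post_mean[2], post_sd[2], lower = st$mu[1])
        } else if (dat$mu_dir < 0) {
          rtruncnorm1(post_mean[2], post_sd[2], upper = st$mu[1])
        } else {
          stats::rnorm(1, post_mean[2], post_sd[2])
        }
      }
      for (d in 0:1) {
        if (d == 0 && !is.null(fx$tau2_0)) next
        if (d == 1 && !is.null(fx$tau2_1)) next
        sel <- dcl == d
        st$tau2[d + 1] <- rinvgamma(
          1, config$tau_shape + sum(sel) / 2,
          config$tau_rate + 0.5 * sum((th[sel] - st$mu[d + 1])^2)
        )
      }
    }

    if (dat$use_pc) {
      Xo <- dat$X[dat$has_pc, , drop = FALSE]
      Do <- st$D[dat$has_pc]
      for (d in 0:1) {
        sel <- Do == d
        nd <- sum(sel)
        prec_m <- nd / st$pc_var + 1 / config$pc_mean_sd^2
        s <- if (nd > 0) colSums(Xo[sel, , drop = FALSE]) else rep(0, dat$K)
        m <- (s / st$pc_var) / prec_m
        draw <- stats::rnorm(dat$K, m, sqrt(1 / prec_m))
        if (d == 0) st$pc_m0 <- draw else st$pc_m1 <- draw
      }
      M <- rbind(st$pc_m0, st$pc_m1)[Do + 1L, , drop = FALSE]
      ss <- colSums((Xo - M)^2)
      st$pc_var <- rinvgamma(dat$K, config$tau_shape + nrow(Xo) / 2,
                             config$tau_rate + 0.5 * ss)
    }

    # --- prevalence: the Bernoulli(pi) prior governs the unlabeled variants
    # only; controls are ascertained by design, so their frozen labels carry
    # no information about the VUS prevalence
    if (is.null(fx$pi)) {
      n_free <- sum(free_d)
      s_free <- sum(st$D[free_d])
      st$pi <- stats::rbeta(1, config$pi_a + s_free, config$pi_b + n_free - s_free)
    }

    # --- pathogenicity indicators for unlabeled variants
    if (any(free_d)) {
      logit <- rep(stats::qlogis(st$pi), V)
      if (dat$use_function) {
        sel <- dat$has_y
        logit[sel] <- logit[sel] +
          stats::dnorm(st$theta[sel], st$mu[2], sqrt(st$tau2[2]), log = TRUE) -
          stats::dnorm(st$theta[sel], st$mu[1], sqrt(st$tau2[1]), log = TRUE)
      }
      if (dat$use_pc) {
        sel <- dat$has_pc
        Xs <- dat$X[sel, , drop = FALSE]
        ll1 <- Xs %*% (st$pc_m1 / st$pc_var) - sum(st$pc_m1^2 / (2 * st$pc_var))
        ll0 <- Xs %*% (st$pc_m0 / st$pc_var) - sum(st$pc_m0^2 / (2 * st$pc_var))
        logit[sel] <- logit[sel] + as.numeric(ll1 - ll0)
      }
      if (dat$use_family) {
        sel <- !is.na(dat$fam_lbf)
        logit[sel] <- logit[sel] + dat$fam_lbf[sel]
      }
      if (dat$use_agvgd) {
        sel <- !is.na(dat$agvgd_lbf)
        logit[sel] <- logit[sel] + dat$agvgd_lbf[sel]
      }
      if (any(!is.finite(logit[free_d]))) {
        vc_stop("non-finite log-odds in the D update; model state degenerate",
                "varcallxt_numerics_error")
      }
      p1 <- stats::plogis(logit[free_d])
      st$D[free_d] <- stats::rbinom(sum(free_d), 1, p1)
    }

    if (kept < n_keep && iter == keep_iters[kept + 1L]) {
      kept <- kept + 1L
      D_draws[kept, ] <- st$D
      scalars[kept, "pi"] <- st$pi
      if (dat$use_function) {
        scalars[kept, c("mu0", "mu1")] <- st$mu
        scalars[kept, c("tau2_0", "tau2_1")] <- st$tau2
        scalars[kept, "sigma_b2"] <- st$sigma_b2
        scalars[kept, "sigma_e2"] <- st$sigma_e2
        theta_draws[kept, ] <- st$theta
        beta_sum <- beta_sum + st$beta
      }
      if (dat$use_pc) pc_m_draws[kept, ] <- c(st$pc_m0, st$pc_m1)
    }
  }

  list(
    scalars = scalars, D = D_draws, theta = theta_draws,
    beta_mean = if (dat$use_function) beta_sum / n_keep else NULL,
    pc_means = pc_m_draws, final_state = st, n_keep = n_keep
  )
}

chain_seeds <- function(seed, n_chains) {
  (abs(as.integer(seed)) + 104729 * seq_len(n_chains)) %% 2147483629L + 1L
}

#' Fit the semi-supervised variant-classification model
#'
#' Runs the Gibbs sampler for the hierarchical model: within-batch mean
#' log-ratios decompose into a variant effect, a batch effect and residual
#' noise; variant effects follow a two-component Gaussian mixture whose
#' membership indicator `D` (0 benign, 1 damaging) is frozen for labeled
#' controls and inferred for the rest. Family-history and Align-GVGD log
#' Bayes factors and class-conditional Gaussian densities of predictor PCs
#' multiply the full conditional of `D` for the evidence types in
#' `config$evidence_set`.
#'
#' @param assay Replicate-level assay data.frame (`log_ratio` column; will
#'   be averaged within batch) or an already-averaged batch-mean table
#'   (`mean_log_ratio` column). May be `NULL` when `"function"` is not in
#'   the evidence set.
#' @param evidence Per-variant evidence data.frame (see
#'   [read_evidence_table()]); may be `NULL` for a function-only fit whose
#'   labels live in the assay table.
#' @param config A [varcall_config()].
#' @param init Optional list of per-chain states to warm-start from
#'   (used internally by [lovo_evaluate()]).
#' @return An object of class `varcall_fit` with components `variants`
#'   (per-variant posterior summary: `prob_pathogenic`, `log_odds`, `call`,
#'   `theta_mean`, `theta_sd`, `label`), `params` (posterior means and SDs
#'   of the model-level parameters), `diagnostics` (split-chain Rhat and
#'   effective sample size), `draws`, `config` and the prepared `data`.
#' @seealso [classify()], [lovo_evaluate()], [simulate_dataset()]
#' @examples
#' sim <- simulate_dataset(sim_config(
#'   preset = "small", n_vus = 20, n_benign_labeled = 8,
#'   n_pathogenic_labeled = 8, n_batches = 6, seed = 7
#' ))
#' cfg <- varcall_config(n_iter = 400, n_burn = 200, thin = 2, n_chains = 2)
#' fit <- varcall(sim$assay, config = cfg)
#' head(fit$variants)
#' @export
varcall <- function(assay = NULL, evidence = NULL,
                    config = varcall_config(), init = NULL) {
  stopifnot(inherits(config, "varcall_config"))
  dat <- prepare_model_data(assay, evidence, config)
  seeds <- chain_seeds(config$seed, config$n_chains)
  chains <- lapply(seq_len(config$n_chains), function(ch) {
    run_chain(dat, config, seeds[ch], init = init[[ch]] %||% NULL)
  })
  build_fit(dat, chains, config, match.call())
}

build_fit <- function(dat, chains, config, call) {
  M <- sum(vapply(chains, function(c) as.integer(c$n_keep), 0L))
  D_all <- do.call(rbind, lapply(chains, `[[`, "D"))
  prob_raw <- colMeans(D_all)
  prob <- pmin(pmax(prob_raw, 1 / (M + 1)), M / (M + 1))
  log_odds <- stats::qlogis(prob)
  calls <- classify(prob, config)

  variants <- data.frame(
    variant_id = dat$variant_id,
    prob_pathogenic = prob,
    log_odds = log_odds,
    call = calls,
    theta_mean = NA_real_,
    theta_sd = NA_real_,
    label = dat$label,
    stringsAsFactors = FALSE
  )
  if (dat$use_function) {
    th_all <- do.call(rbind, lapply(chains, `[[`, "theta"))
    variants$theta_mean <- colMeans(th_all)
    variants$theta_sd <- apply(th_all, 2, stats::sd)
  }

  sc_all <- do.call(rbind, lapply(chains, `[[`, "scalars"))
  params <- data.frame(
    parameter = colnames(sc_all),
    mean = colMeans(sc_all),
    sd = apply(sc_all, 2, stats::sd),
    q2.5 = apply(sc_all, 2, stats::quantile, 0.025),
    q97.5 = apply(sc_all, 2, stats::quantile, 0.975),
    row.names = NULL, stringsAsFactors = FALSE
  )

  diag <- mcmc_diagnostics(lapply(chains, `[[`, "scalars"))

  out <- list(
    variants = variants, params = params, diagnostics = diag,
    draws = list(
      scalars = lapply(chains, `[[`, "scalars"),
      pc_means = lapply(chains, `[[`, "pc_means"),
      n_draws = M
    ),
    chain_states = lapply(chains, `[[`, "final_state"),
    beta_mean = if (dat$use_function) {
      Reduce(`+`, lapply(chains, `[[`, "beta_mean")) / length(chains)
    } else {
      NULL
    },
    data = dat, config = config, call = call
  )
  class(out) <- "varcall_fit"
  out
}

#' Apply the IARC-style calling thresholds to posterior probabilities
#'
#' A variant is called benign when `Pr(D = 1 | data) < benign_cut`
#' (default 0.05), called pathogenic when `Pr >= pathogenic_cut`
#' (default 0.99, boundary inclusive), and left unclassified (`no_call`)
#' otherwise.
#'
#' @param prob Numeric vector of posterior probabilities in `[0, 1]`.
#' @param config A [varcall_config()] supplying the thresholds.
#' @return Character vector with values `called_benign`, `no_call`,
#'   `called_pathogenic`.
#' @export
classify <- function(prob, config = varcall_config()) {
  if (any(!is.na(prob) & (prob < 0 | prob > 1))) {
    vc_stop("probabilities must lie in [0, 1]", "varcallxt_validation_error")
  }
  ifelse(prob < config$benign_cut, "called_benign",
    ifelse(prob >= config$pathogenic_cut, "called_pathogenic", "no_call")
  )
}

#' Enumerate all evidence-set combinations
#'
#' Returns every non-empty subset of the supplied evidence types in a
#' deterministic order (by subset size, then lexicographically); with the
#' four standard types this yields the 15 candidate classification models.
#'
#' @param evidence_types Character vector of available evidence types.
#' @return List of character vectors, one per model.
#' @export
enumerate_models <- function(evidence_types = EVIDENCE_TYPES) {
  if (length(evidence_types) == 0) {
    vc_stop("evidence_types must be non-empty", "varcallxt_validation_error")
  }
  evidence_types <- sort(unique(evidence_types))
  subsets <- list()
  for (k in seq_along(evidence_types)) {
    combos <- utils::combn(evidence_types, k, simplify = FALSE)
    subsets <- c(subsets, combos)
  }
  subsets
}

#' Combine model log-odds with an additional log Bayes factor
#'
#' Bayes-factor updating is additive on the log-odds scale: the posterior
#' odds given extra independent evidence are the model odds times the Bayes
#' factor. Used for reporting and diagnostics; inside [varcall()] the
#' evidence terms enter the sampler directly.
#'
#' @param model_log_odds Log-odds of pathogenicity from a fitted model.
#' @param extra_log_bf Log Bayes factor of the additional evidence.
#' @return `model_log_odds + extra_log_bf`.
#' @export
combine_log_odds <- function(model_log_odds, extra_log_bf) {
  if (any(!is.finite(model_log_odds)) || any(!is.finite(extra_log_bf))) {
    vc_stop("log-odds inputs must be finite", "varcallxt_validation_error")
  }
  model_log_odds + extra_log_bf
}
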