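# S3 methods for fitted models.

#' @export
print.varcall_fit <- function(x, ...) {
  cat("Semi-supervised variant pathogenicity model\n")
  cat("  evidence: ", paste(x$config$evidence_set, collapse = " + "), "\n", sep = "")
  tab <- table(factor(x$variants$call,
    levels = c("called_benign", "no_call", "called_pathogenic")
  ))
  n_lab <- sum(x$variants$label != "unlabeled")
  cat(sprintf(
    "  %d variants (%d labeled), %d chains x %d kept draws\n",
    nrow(x$variants), n_lab, x$config$n_chains,
    x$draws$n_draws / x$config$n_chains
  ))
  cat(sprintf(
    "  calls: %d benign / %d no-call / %d pathogenic\n",
    tab[1], tab[2], tab[3]
  ))
  bad <- !x$diagnostics$converged
  if (any(bad)) {
    cat("  WARNING: split-chain Rhat > 1.01 for:",
        paste(x$diagnostics$parameter[bad], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.varcall_fit <- function(object, ...) {
  out <- list(
    params = object$params,
    calls = table(
      label = object$variants$label,
      call = factor(object$variants$call,
        levels = c("called_benign", "no_call", "called_pathogenic")
      )
    ),
    diagnostics = object$diagnostics,
    config = object$config
  )
  class(out) <- "summary.varcall_fit"
  out
}

#' @export
print.summary.varcall_fit <- function(x, ...) {
  cat("Model-level posterior summaries:\n")
  print(x$params, digits = 4)
  cat("\nCalls by known label:\n")
  print(x$calls)
  cat("\nConvergence (split-chain Rhat, ESS):\n")
  print(x$diagnostics, digits = 4)
  invisible(x)
}

#' @export
coef.varcall_fit <- function(object, ...) {
  stats::setNames(object$params$mean, object$params$parameter)
}

#' Residuals of the within-batch mean regression
#'
#' Returns `y_vb - E[theta_v] - E[beta_b]`, the batch-mean observations
#' minus the posterior-mean variant and batch effects; only defined for
#' fits that include functional data.
#'
#' @param object A `varcall_fit`.
#' @param ... Unused.
#' @export
residuals.varcall_fit <- function(object, ...) {
  dat <- object$data
  if (!dat$use_function) {
    vc_stop("residuals are defined only for fits with functional data",
            "varcallxt_validation_error")
  }
  dat$y - object$variants$theta_mean[dat$v_idx] - object$beta_mean[dat$b_idx]
}

#' Predict pathogenicity probabilities for new variants from evidence alone
#'
#' Scores variants that were not in the fitted data using the posterior
#' draws of the prevalence, class-conditional PC distributions and the
#' supplied per-variant log Bayes factors. Functional-assay information
#' cannot be transferred to unseen variants (their random effects are not
#' identified), so only the evidence types among family, protein_pred and
#' agvgd contribute.
#'
#' @param object A `varcall_fit`.
#' @param newdata Evidence data.frame with `variant_id` and whichever of
#'   `pc_*`, `family_log_bf`, `agvgd_prob` columns the fit used.
#' @param ... Unused.
#' @return Data.frame with `variant_id`, `prob_pathogenic`, `log_odds`,
#'   `call`.
#' @export
predict.varcall_fit <- function(object, newdata, ...) {
  cfg <- object$config
  dat <- object$data
  sc <- do.call(rbind, object$draws$scalars)
  pi_draws <- sc[, "pi"]
  M <- length(pi_draws)
  n <- nrow(newdata)
  logit <- matrix(stats::qlogis(pi_draws), M, n)
  if (dat$use_pc) {
    pcm <- do.call(rbind, object$draws$pc_means)
    K <- dat$K
    pc_cols <- paste0("pc_", seq_len(K))
    if (!all(pc_cols %in% names(newdata))) {
      vc_stop("newdata lacks the pc_* columns used by the fit", "varcallxt_schema_error")
    }
    X <- as.matrix(newdata[pc_cols])
    pv <- apply(dat$X[dat$has_pc, , drop = FALSE], 2, stats::var) # plug-in scale
    for (i in seq_len(n)) {
      if (anyNA(X[i, ])) next
      m0 <- pcm[, seq_len(K), drop = FALSE]
      m1 <- pcm[, K + seq_len(K), drop = FALSE]
      ll1 <- rowSums(sweep(-(sweep(m1, 2, X[i, ]))^2, 2, 2 * pv, `/`))
      ll0 <- rowSums(sweep(-(sweep(m0, 2, X[i, ]))^2, 2, 2 * pv, `/`))
      logit[, i] <- logit[, i] + ll1 - ll0
    }
  }
  if (dat$use_family && "family_log_bf" %in% names(newdata)) {
    lbf <- ifelse(is.na(newdata$family_log_bf), 0, newdata$family_log_bf)
    logit <- logit + matrix(lbf, M, n, byrow = TRUE)
  }
  if (dat$use_agvgd && "agvgd_prob" %in% names(newdata)) {
    p <- newdata$agvgd_prob
    lbf <- ifelse(is.na(p), 0,
      suppressWarnings(agvgd_to_log_bf(p, cfg$agvgd_reference_prior))
    )
    logit <- logit + matrix(lbf, M, n, byrow = TRUE)
  }
  prob <- colMeans(stats::plogis(logit))
  prob <- pmin(pmax(prob, 1 / (M + 1)), M / (M + 1))
  data.frame(
    variant_id = newdata$variant_id,
    prob_pathogenic = prob,
    log_odds = stats::qlogis(prob),
    call = classify(prob, cfg),
    stringsAsFactors = FALSE
  )
}

#' Plot per-variant log-odds of pathogenicity
#'
#' Dot plot of the posterior log-odds, ordered by value and colored by known
#' label, with the calling thresholds drawn as horizontal lines (the no-call
#' band lies between them).
#'
#' @param x A `varcall_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.varcall_fit <- function(x, ...) {
  v <- x$variants[order(x$variants$log_odds), ]
  col <- ifelse(v$label == "benign_control", "forestgreen",
    ifelse(v$label == "pathogenic_control", "firebrick", "grey40")
  )
  graphics::plot(seq_len(nrow(v)), v$log_odds,
    col = col, pch = 16, xlab = "variant rank",
    ylab = "log-odds of pathogenicity", ...
  )
  graphics::abline(h = stats::qlogis(x$config$benign_cut), lty = 2, col = "forestgreen")
  graphics::abline(h = stats::qlogis(x$config$pathogenic_cut), lty = 2, col = "firebrick")
  graphics::legend("topleft",
    legend = c("benign control", "pathogenic control", "VUS"),
    col = c("forestgreen", "firebrick", "grey40"), pch = 16, bty = "n"
  )
  invisible(x)
}
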