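# Evaluation machinery: leave-one-variant-out calling and count-based
# operating characteristics (Dirichlet-multinomial posterior means, HDR
# intervals, raw accuracy, scaled Brier scores).

CALL_LEVELS <- c("called_benign", "no_call", "called_pathogenic")

#' Leave-one-variant-out evaluation of known variants
#'
#' Masks each labeled variant in turn (treating it as a VUS), refits the
#' model, and records the masked variant's posterior probability and call.
#' Refits are warm-started from the full fit's final chain states; burn-in
#' is still discarded, so only runtime is affected.
#'
#' @inheritParams varcall
#' @param n_iter,n_burn Optional MCMC overrides for the refits (warm starts
#'   permit shorter runs); defaults keep the config's values.
#' @param full_fit Optional pre-computed full fit (avoids refitting).
#' @return List with `per_variant` (data.frame: `variant_id`, `condition`,
#'   `prob_pathogenic`, `call`), `counts` (data.frame of call counts per
#'   known condition), `skipped` (variant IDs whose masking would leave a
#'   class unlabeled), and `full_fit`.
#' @export
lovo_evaluate <- function(assay = NULL, evidence = NULL,
                          config = varcall_config(),
                          n_iter = NULL, n_burn = NULL, full_fit = NULL) {
  fit0 <- full_fit %||% varcall(assay, evidence, config)
  dat <- fit0$data
  labeled <- which(!is.na(dat$d_label))
  if (length(labeled) == 0) {
    vc_stop("no labeled variants to evaluate", "varcallxt_validation_error")
  }
  refit_cfg <- config
  if (!is.null(n_iter)) refit_cfg$n_iter <- n_iter
  if (!is.null(n_burn)) refit_cfg$n_burn <- n_burn
  validate_config(refit_cfg)

  rows <- list()
  skipped <- character(0)
  for (i in labeled) {
    d_i <- dat$d_label[i]
    remaining <- dat$d_label[-i]
    need_y <- dat$use_function
    ok <- if (need_y) {
      keep <- dat$has_y
      keep[i] <- FALSE
      any(dat$d_label[keep] %in% 0L) && any(dat$d_label[keep] %in% 1L)
    } else {
      any(remaining %in% 0L) && any(remaining %in% 1L)
    }
    if (!ok) {
      warning(sprintf(
        "skipping %s: masking would leave a class unlabeled", dat$variant_id[i]
      ))
      skipped <- c(skipped, dat$variant_id[i])
      next
    }
    dat_i <- dat
    dat_i$d_label[i] <- NA_integer_
    dat_i$label[i] <- "unlabeled"
    seeds <- chain_seeds(refit_cfg$seed + i, refit_cfg$n_chains)
    chains <- lapply(seq_len(refit_cfg$n_chains), function(ch) {
      run_chain(dat_i, refit_cfg, seeds[ch], init = fit0$chain_states[[ch]])
    })
    fit_i <- build_fit(dat_i, chains, refit_cfg, call = NULL)
    row <- fit_i$variants[i, ]
    rows[[length(rows) + 1]] <- data.frame(
      variant_id = row$variant_id,
      condition = if (d_i == 1L) "known_pathogenic" else "known_benign",
      prob_pathogenic = row$prob_pathogenic,
      call = row$call,
      stringsAsFactors = FALSE
    )
  }
  per_variant <- do.call(rbind, rows)
  list(
    per_variant = per_variant,
    counts = call_counts(per_variant),
    skipped = skipped,
    full_fit = fit0
  )
}

#' Tally calls per known condition
#'
#' @param per_variant Data.frame with `condition` (`known_benign` /
#'   `known_pathogenic`) and `call` columns.
#' @return Data.frame with one row per condition and columns
#'   `n_called_benign`, `n_no_call`, `n_called_pathogenic`, `n`.
#' @export
call_counts <- function(per_variant) {
  conds <- c("known_benign", "known_pathogenic")
  out <- data.frame(
    condition = conds,
    n_called_benign = 0L, n_no_call = 0L, n_called_pathogenic = 0L,
    stringsAsFactors = FALSE
  )
  if (!is.null(per_variant) && nrow(per_variant) > 0) {
    tab <- table(
      factor(per_variant$condition, levels = conds),
      factor(per_variant$call, levels = CALL_LEVELS)
    )
    out$n_called_benign <- as.integer(tab[, "called_benign"])
    out$n_no_call <- as.integer(tab[, "no_call"])
    out$n_called_pathogenic <- as.integer(tab[, "called_pathogenic"])
  }
  out$n <- out$n_called_benign + out$n_no_call + out$n_called_pathogenic
  out
}

#' Dirichlet-multinomial posterior means of the call-category rates
#'
#' Under a three-category multinomial with Jeffreys prior
#' Dirichlet(1/2, 1/2, 1/2), the posterior mean of category `i` given counts
#' is `(count_i + 1/2) / (n + 3/2)`; reported as percentages.
#'
#' @param counts Integer vector of length 3
#'   (called benign, no call, called pathogenic), or a one-row slice of the
#'   data.frame produced by [call_counts()].
#' @return Named numeric vector of three percentages (summing to 100).
#' @export
dirichlet_oc <- function(counts) {
  counts <- as_count_vector(counts)
  n <- sum(counts)
  p <- (counts + 0.5) / (n + 1.5)
  stats::setNames(100 * p, CALL_LEVELS)
}

as_count_vector <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot(nrow(counts) == 1)
    counts <- c(
      counts$n_called_benign, counts$n_no_call, counts$n_called_pathogenic
    )
  }
  counts <- as.numeric(counts)
  if (length(counts) != 3 || any(counts < 0) || any(counts != floor(counts))) {
    vc_stop("counts must be 3 non-negative integers", "varcallxt_validation_error")
  }
  counts
}

#' Highest-density interval of a Beta distribution
#'
#' For shapes both greater than one the density is unimodal in the interior
#' and the HDR is the narrowest interval of the requested mass, found by
#' minimizing the interval width over its lower-tail mass. When one shape is
#' at most one the density is monotone and the HDR attaches to the
#' corresponding boundary: `[0, q_mass]` for a decreasing density,
#' `[q_{1-mass}, 1]` for an increasing one.
#'
#' @param shape1,shape2 Beta shape parameters.
#' @param mass Interval probability mass in (0, 1); default 0.95.
#' @return Numeric vector `c(lo, hi)` in `[0, 1]`.
#' @export
beta_hdr <- function(shape1, shape2, mass = 0.95) {
  if (mass <= 0 || mass >= 1) {
    vc_stop("mass must be in (0, 1)", "varcallxt_validation_error")
  }
  lower_attached <- c(0, stats::qbeta(mass, shape1, shape2))
  upper_attached <- c(stats::qbeta(1 - mass, shape1, shape2), 1)
  if (shape1 <= 1 && shape2 <= 1) {
    # U-shaped or flat: no interior mode; take the narrower boundary interval
    if (diff(lower_attached) <= diff(upper_attached)) {
      return(lower_attached)
    }
    return(upper_attached)
  }
  if (shape1 <= 1) return(lower_attached)  # monotone decreasing
  if (shape2 <= 1) return(upper_attached)  # monotone increasing
  width <- function(p) {
    stats::qbeta(p + mass, shape1, shape2) - stats::qbeta(p, shape1, shape2)
  }
  opt <- stats::optimize(width, interval = c(0, 1 - mass), tol = 1e-10)
  p <- opt$minimum
  c(stats::qbeta(p, shape1, shape2), stats::qbeta(p + mass, shape1, shape2))
}

#' HDR interval for one call-category rate
#'
#' The marginal posterior of a single category's rate under the Jeffreys
#' Dirichlet(1/2, 1/2, 1/2) posterior is
#' `Beta(count + 1/2, n - count + 1)`; returns its highest-density interval
#' as percentages.
#'
#' @inheritParams dirichlet_oc
#' @param category One of `"called_benign"`, `"no_call"`,
#'   `"called_pathogenic"`, or an index 1--3.
#' @param mass Interval mass, default 0.95.
#' @return Numeric vector `c(hdr_lo, hdr_hi)` in percent.
#' @export
dirichlet_hdr <- function(counts, category, mass = 0.95) {
  counts <- as_count_vector(counts)
  if (is.character(category)) category <- match(category, CALL_LEVELS)
  stopifnot(category %in% 1:3)
  n <- sum(counts)
  k <- counts[category]
  100 * beta_hdr(k + 0.5, n - k + 1, mass)
}

#' Raw predictive accuracy with no-calls counted as errors
#'
#' The fraction of known variants called into their true category; variants
#' in the no-call band count as incorrect. Reported as a percentage.
#'
#' @param counts Data.frame from [call_counts()] (both conditions).
#' @return Accuracy percentage.
#' @export
raw_accuracy <- function(counts) {
  stopifnot(is.data.frame(counts), all(c("known_benign", "known_pathogenic") %in% counts$condition))
  nb <- counts[counts$condition == "known_benign", ]
  np <- counts[counts$condition == "known_pathogenic", ]
  total <- nb$n + np$n
  if (total == 0) {
    vc_stop("no known variants to score", "varcallxt_validation_error")
  }
  100 * (nb$n_called_benign + np$n_called_pathogenic) / total
}

#' Scaled Brier score
#'
#' Mean squared error of the predicted probabilities against the binary
#' pathogenicity status, divided by the Brier score of the constant
#' prevalence predictor `mean(labels)`. Values below 1 beat the prevalence
#' predictor; anti-calibrated predictors can exceed 1.
#'
#' @param probs Predicted probabilities in `[0, 1]`.
#' @param labels Binary true status (0 benign, 1 pathogenic).
#' @return Non-negative scalar. When all labels are identical the reference
#'   score is undefined; the unscaled Brier score is returned with a
#'   warning.
#' @export
scaled_brier <- function(probs, labels) {
  stopifnot(length(probs) == length(labels), length(probs) > 0)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) {
    vc_stop("labels must be 0/1", "varcallxt_validation_error")
  }
  brier <- mean((probs - labels)^2)
  pbar <- mean(labels)
  if (pbar == 0 || pbar == 1) {
    warning("all labels identical; returning the unscaled Brier score")
    return(brier)
  }
  ref <- mean((pbar - labels)^2)
  brier / ref
}

#' Operating-characteristic table for one model
#'
#' Assembles, per known condition and call category, the Jeffreys Dirichlet
#' posterior mean and 95% HDR interval, plus raw accuracy and the scaled
#' Brier score -- one model's worth of the standard operating-characteristic
#' report.
#'
#' @param lovo Result of [lovo_evaluate()].
#' @param mass HDR mass, default 0.95.
#' @return List with `rates` (data.frame: condition, category, mean,
#'   hdr_lo, hdr_hi, all percent), `raw_accuracy` (percent) and
#'   `scaled_brier`.
#' @export
oc_table <- function(lovo, mass = 0.95) {
  counts <- lovo$counts
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    cvec <- as_count_vector(counts[i, ])
    means <- dirichlet_oc(cvec)
    for (j in 1:3) {
      hdr <- dirichlet_hdr(cvec, j, mass)
      rows[[length(rows) + 1]] <- data.frame(
        condition = counts$condition[i],
        category = CALL_LEVELS[j],
        mean = unname(means[j]),
        hdr_lo = hdr[1], hdr_hi = hdr[2],
        stringsAsFactors = FALSE
      )
    }
  }
  pv <- lovo$per_variant
  sb <- if (!is.null(pv) && nrow(pv) > 0) {
    suppressWarnings(scaled_brier(
      pv$prob_pathogenic,
      as.integer(pv$condition == "known_pathogenic")
    ))
  } else {
    NA_real_
  }
  list(
    rates = do.call(rbind, rows),
    raw_accuracy = raw_accuracy(counts),
    scaled_brier = sb
  )
}

#' Compare two fits: per-variant odds ratios and call transitions
#'
#' For each shared variant, the odds ratio of pathogenicity under fit B
#' versus fit A (`exp(log_odds_B - log_odds_A)`) and the call transition
#' `call_A -> call_B`; summarizes the geometric-mean odds ratio per known
#' class.
#'
#' @param fit_a,fit_b `varcall_fit` objects or their `variants` data.frames
#'   covering the same variant set.
#' @return List with `per_variant` (variant_id, odds_ratio, call_a, call_b,
#'   transition, label) and `geometric_mean_or` (by known label).
#' @export
odds_shift_report <- function(fit_a, fit_b) {
  a <- if (inherits(fit_a, "varcall_fit")) fit_a$variants else fit_a
  b <- if (inherits(fit_b, "varcall_fit")) fit_b$variants else fit_b
  only_a <- setdiff(a$variant_id, b$variant_id)
  only_b <- setdiff(b$variant_id, a$variant_id)
  if (length(only_a) > 0 || length(only_b) > 0) {
    vc_stop(
      sprintf(
        "variant sets differ (only in A: %s; only in B: %s)",
        paste(only_a, collapse = ","), paste(only_b, collapse = ",")
      ),
      "varcallxt_validation_error"
    )
  }
  b <- b[match(a$variant_id, b$variant_id), ]
  lor <- b$log_odds - a$log_odds
  per_variant <- data.frame(
    variant_id = a$variant_id,
    odds_ratio = exp(lor),
    call_a = a$call, call_b = b$call,
    transition = paste(a$call, b$call, sep = " -> "),
    label = a$label,
    stringsAsFactors = FALSE
  )
  gm <- tapply(lor, a$label, function(x) exp(mean(x)))
  list(
    per_variant = per_variant,
    geometric_mean_or = gm,
    n_transitions = sum(a$call != b$call)
  )
}

#' Evaluate a grid of evidence-set models
#'
#' Runs [lovo_evaluate()] for every candidate evidence set -- all 15
#' non-empty subsets of the four standard types by default, or one of the
#' two cumulative progression series -- and ranks the models by raw accuracy
#' and scaled Brier score. Models that fail (e.g. for lack of the relevant
#' evidence columns) are skipped with a warning.
#'
#' @inheritParams lovo_evaluate
#' @param evidence_types Types available in the data; the grid enumerates
#'   their non-empty subsets.
#' @param series `NULL` for the full grid; `"forward"` for the series
#'   starting from family data and adding protein predictors, Align-GVGD,
#'   then function; `"reverse"` for the series starting from function data
#'   and adding family, protein predictors, then Align-GVGD.
#' @return List with `reports` (named list of [oc_table()] results),
#'   `ranking` (data.frame sorted by raw accuracy then Brier score), and
#'   `failed` (model names that errored).
#' @export
run_grid <- function(assay = NULL, evidence = NULL, config = varcall_config(),
                     evidence_types = EVIDENCE_TYPES, series = NULL,
                     n_iter = NULL, n_burn = NULL) {
  sets <- if (is.null(series)) {
    enumerate_models(evidence_types)
  } else if (series == "forward") {
    list(
      "family",
      c("family", "protein_pred"),
      c("family", "protein_pred", "agvgd"),
      c("family", "protein_pred", "agvgd", "function")
    )
  } else if (series == "reverse") {
    list(
      "function",
      c("function", "family"),
      c("function", "family", "protein_pred"),
      c("function", "family", "protein_pred", "agvgd")
    )
  } else {
    vc_stop("series must be NULL, 'forward' or 'reverse'", "varcallxt_validation_error")
  }
  reports <- list()
  failed <- character(0)
  rank_rows <- list()
  for (s in sets) {
    name <- paste(sort(s), collapse = "+")
    cfg <- config
    cfg$evidence_set <- s
    res <- tryCatch(
      {
        lovo <- lovo_evaluate(assay, evidence, cfg, n_iter = n_iter, n_burn = n_burn)
        oc_table(lovo)
      },
      error = function(e) {
        warning(sprintf("model %s failed: %s", name, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(res)) {
      failed <- c(failed, name)
      next
    }
    reports[[name]] <- res
    rank_rows[[name]] <- data.frame(
      model = name,
      raw_accuracy = res$raw_accuracy,
      scaled_brier = res$scaled_brier,
      stringsAsFactors = FALSE
    )
  }
  if (length(reports) == 0) {
    vc_stop("all candidate models failed", "varcallxt_model_error")
  }
  ranking <- do.call(rbind, rank_rows)
  ranking <- ranking[order(-ranking$raw_accuracy, ranking$scaled_brier), ]
  rownames(ranking) <- NULL
  list(reports = reports, ranking = ranking, failed = failed)
}
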