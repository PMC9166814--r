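# Synthetic datasets with the statistical structure the model assumes:
# variants replicated within batches, controls in every batch, variant
# effects drawn from a two-component mixture, sparse family evidence.

#' Configuration of the synthetic-data generator
#'
#' The defaults describe a mid-sized functional-assay study; the presets
#' reproduce the dimensions of two published assay designs. The generative
#' process is exactly the model's own: replicate log-ratios are
#' `theta_v + beta_b + noise` with `theta_v` drawn from the benign or
#' damaging mixture component according to the variant's true status.
#'
#' @param preset `"brca1_ta"` (281 VUS, 42 + 21 labeled plus the two
#'   per-batch controls, 126 batches, 3 replicates -- the shape of a
#'   transcriptional-activation assay), `"brca2_hr"` (168 VUS, 22 + 11
#'   labeled plus two controls, 162 batches, 2 replicates -- a
#'   homologous-recombination assay), `"small"` (150 VUS, 30 + 30 labeled,
#'   30 batches -- sized for calibration experiments), or `NULL` to take
#'   the argument defaults. Explicit arguments override preset values.
#' @param n_benign_labeled,n_pathogenic_labeled,n_vus Variant counts by
#'   labeling status (the first variant of each labeled class doubles as
#'   the every-batch control when `controls_in_every_batch` is set).
#' @param n_batches Number of experimental batches.
#' @param replicates_per_cell Replicates per observed (variant, batch)
#'   cell; a length-2 vector gives a uniform integer range.
#' @param batch_occupancy Probability that a non-control (variant, batch)
#'   cell is observed; every variant is guaranteed at least one cell.
#' @param controls_in_every_batch Force one benign and one pathogenic
#'   control into every batch (as wild-type and loss-of-function controls
#'   are in practice).
#' @param mu0,mu1 True mixture-component means of the variant effects on
#'   the log-ratio scale (benign near 0; damaging shifted, negative for
#'   loss-of-function assays).
#' @param tau0,tau1 True component SDs.
#' @param sigma_b,sigma_e True batch-effect and residual SDs.
#' @param pi_true Probability that an unlabeled variant is pathogenic.
#' @param pc_dim Number of simulated predictor PCs.
#' @param pc_effect Class-mean separation per PC (unit-variance scale).
#' @param family_coverage Fraction of variants carrying family evidence
#'   (informative family data are the exception in practice).
#' @param family_bf_scale Location and SD of the simulated family log
#'   Bayes factors (sign aligned with the true status).
#' @param agvgd_noise SD of the logit-scale noise on the simulated
#'   Align-GVGD probabilities.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(preset = NULL,
                       n_benign_labeled = 20, n_pathogenic_labeled = 20,
                       n_vus = 60, n_batches = 20,
                       replicates_per_cell = 3, batch_occupancy = 0.25,
                       controls_in_every_batch = TRUE,
                       mu0 = 0, mu1 = -2, tau0 = 0.3, tau1 = 0.5,
                       sigma_b = 0.3, sigma_e = 0.4,
                       pi_true = 0.3, pc_dim = 10, pc_effect = 0.5,
                       family_coverage = 0.2, family_bf_scale = 1.5,
                       agvgd_noise = 1.5, seed = 1) {
  presets <- list(
    brca1_ta = list(
      n_benign_labeled = 43, n_pathogenic_labeled = 22, n_vus = 281,
      n_batches = 126, replicates_per_cell = 3, batch_occupancy = 0.021
    ),
    brca2_hr = list(
      n_benign_labeled = 23, n_pathogenic_labeled = 12, n_vus = 168,
      n_batches = 162, replicates_per_cell = c(2, 3), batch_occupancy = 0.02
    ),
    small = list(
      n_benign_labeled = 30, n_pathogenic_labeled = 30, n_vus = 150,
      n_batches = 30, replicates_per_cell = 3, batch_occupancy = 0.25
    )
  )
  cfg <- as.list(environment())
  cfg$preset <- NULL
  cfg$presets <- NULL
  if (!is.null(preset)) {
    preset <- match.arg(preset, names(presets))
    supplied <- names(match.call())[-1]
    for (nm in names(presets[[preset]])) {
      if (!nm %in% supplied) cfg[[nm]] <- presets[[preset]][[nm]]
    }
  }
  stopifnot(
    cfg$n_benign_labeled >= 1, cfg$n_pathogenic_labeled >= 1,
    cfg$n_vus >= 0, cfg$n_batches >= 1,
    cfg$batch_occupancy >= 0, cfg$batch_occupancy <= 1,
    cfg$family_coverage >= 0, cfg$family_coverage <= 1,
    cfg$tau0 > 0, cfg$tau1 > 0, cfg$sigma_b > 0, cfg$sigma_e >= 0,
    cfg$pi_true > 0, cfg$pi_true < 1
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an assay + evidence dataset with known ground truth
#'
#' Draws true pathogenicity indicators, variant and batch effects, and
#' replicate-level log-ratios from the hierarchical mixture model, plus
#' per-variant evidence: class-conditional Gaussian PC scores, sparse
#' family log Bayes factors with sign aligned to the true status, and
#' Align-GVGD probabilities as logistic-transformed noisy copies of the
#' status. Output is byte-identical for a given seed.
#'
#' @param config A [sim_config()].
#' @return List with `assay` (replicate-level data.frame matching the
#'   assay schema), `evidence` (per-variant evidence data.frame), and
#'   `truth` (list: `variants` with true `D` and `theta`, `batches` with
#'   true `beta`, and the generating `params`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nb <- config$n_benign_labeled
  np <- config$n_pathogenic_labeled
  nv <- config$n_vus
  V <- nb + np + nv
  B <- config$n_batches

  variant_id <- sprintf("v%03d", seq_len(V))
  label <- c(
    rep("benign_control", nb), rep("pathogenic_control", np),
    rep("unlabeled", nv)
  )
  D <- c(rep(0L, nb), rep(1L, np), stats::rbinom(nv, 1, config$pi_true))
  theta <- ifelse(D == 1,
    stats::rnorm(V, config$mu1, config$tau1),
    stats::rnorm(V, config$mu0, config$tau0)
  )
  beta <- stats::rnorm(B, 0, config$sigma_b)

  # occupancy mask: independent Bernoulli cells, controls forced present
  mask <- matrix(stats::runif(V * B) < config$batch_occupancy, V, B)
  if (isTRUE(config$controls_in_every_batch)) {
    mask[1, ] <- TRUE          # benign (wild-type-like) control
    mask[nb + 1, ] <- TRUE     # pathogenic (loss-of-function) control
  }
  empty <- which(rowSums(mask) == 0)
  for (v in empty) mask[v, sample.int(B, 1)] <- TRUE

  cells <- which(mask, arr.ind = TRUE)
  reps <- config$replicates_per_cell
  n_rep <- if (length(reps) == 2) {
    sample(seq(reps[1], reps[2]), nrow(cells), replace = TRUE)
  } else {
    rep(reps, nrow(cells))
  }
  v_idx <- rep(cells[, 1], n_rep)
  b_idx <- rep(cells[, 2], n_rep)
  rep_id <- sequence(n_rep)
  y <- theta[v_idx] + beta[b_idx] +
    stats::rnorm(length(v_idx), 0, config$sigma_e)
  assay <- data.frame(
    variant_id = variant_id[v_idx],
    batch_id = sprintf("b%03d", b_idx),
    replicate_id = as.character(rep_id),
    log_ratio = y,
    label = label[v_idx],
    stringsAsFactors = FALSE
  )
  assay <- assay[order(assay$variant_id, assay$batch_id, as.integer(assay$replicate_id)), ]
  rownames(assay) <- NULL

  # evidence: class-conditional Gaussian PCs, sparse family BFs, Align-GVGD
  K <- config$pc_dim
  evidence <- data.frame(variant_id = variant_id, stringsAsFactors = FALSE)
  half <- config$pc_effect / 2
  for (k in seq_len(K)) {
    evidence[[paste0("pc_", k)]] <-
      stats::rnorm(V, ifelse(D == 1, half, -half), 1)
  }
  has_fam <- stats::runif(V) < config$family_coverage
  fam <- rep(NA_real_, V)
  fam[has_fam] <- stats::rnorm(
    sum(has_fam),
    ifelse(D[has_fam] == 1, config$family_bf_scale, -config$family_bf_scale),
    config$family_bf_scale
  )
  evidence$family_log_bf <- fam
  agvgd_logit <- stats::qlogis(0.9) * (2 * D - 1) +
    stats::rnorm(V, 0, config$agvgd_noise)
  evidence$agvgd_prob <- stats::plogis(agvgd_logit)
  evidence$label <- label

  list(
    assay = assay,
    evidence = evidence,
    truth = list(
      variants = data.frame(
        variant_id = variant_id, D = D, theta = theta, label = label,
        stringsAsFactors = FALSE
      ),
      batches = data.frame(
        batch_id = sprintf("b%03d", seq_len(B)), beta = beta,
        stringsAsFactors = FALSE
      ),
      params = config
    )
  )
}

#' Simulate-fit-recover calibration experiment
#'
#' Repeatedly simulates a dataset, fits the model, and compares posterior
#' summaries with the generating truth: coverage of nominal 95% posterior
#' intervals for the model-level parameters, mean absolute error of the
#' pathogenicity probabilities against the true indicators, and (optionally)
#' leave-one-variant-out operating characteristics against truth.
#'
#' @param sim_cfg A [sim_config()]; replicate `r` uses seed
#'   `sim_cfg$seed + r`.
#' @param model_cfg A [varcall_config()] for the fits.
#' @param n_reps Number of simulation replicates.
#' @param include_lovo Also run [lovo_evaluate()] per replicate (slower).
#' @return List with `coverage` (per-parameter fraction of replicates whose
#'   95% posterior interval covered the truth), `mae` (per-replicate MAE of
#'   `prob_pathogenic` vs. true `D` over unlabeled variants), `lovo`
#'   (list of [oc_table()] results or NULL), and `errors` (messages from
#'   failed replicates; failures are collected, not fatal).
#' @export
recovery_experiment <- function(sim_cfg = sim_config(), model_cfg = varcall_config(),
                                n_reps = 5, include_lovo = FALSE) {
  stopifnot(n_reps >= 1)
  # the model analyzes within-batch means, so its residual variance is the
  # replicate-level variance divided by the replicate count (averaged over
  # the configured range when counts vary)
  reps <- sim_cfg$replicates_per_cell
  inv_r <- if (length(reps) == 2) mean(1 / seq(reps[1], reps[2])) else 1 / reps
  true_vals <- c(
    mu0 = sim_cfg$mu0, mu1 = sim_cfg$mu1,
    tau2_0 = sim_cfg$tau0^2, tau2_1 = sim_cfg$tau1^2,
    sigma_b2 = sim_cfg$sigma_b^2, sigma_e2 = sim_cfg$sigma_e^2 * inv_r,
    pi = sim_cfg$pi_true
  )
  cover <- matrix(NA, n_reps, length(true_vals),
                  dimnames = list(NULL, names(true_vals)))
  mae <- rep(NA_real_, n_reps)
  lovo_out <- if (include_lovo) vector("list", n_reps) else NULL
  errors <- character(0)
  for (r in seq_len(n_reps)) {
    res <- tryCatch(
      {
        scfg <- sim_cfg
        scfg$seed <- sim_cfg$seed + r
        sim <- simulate_dataset(scfg)
        mcfg <- model_cfg
        mcfg$seed <- model_cfg$seed + r
        fit <- varcall(sim$assay, sim$evidence, mcfg)
        idx <- match(fit$params$parameter, names(true_vals))
        ok <- !is.na(idx)
        cover[r, idx[ok]] <- true_vals[idx[ok]] >= fit$params$q2.5[ok] &
          true_vals[idx[ok]] <= fit$params$q97.5[ok]
        m <- merge(fit$variants, sim$truth$variants[c("variant_id", "D")],
                   by = "variant_id")
        m <- m[m$label == "unlabeled", ]
        mae[r] <- mean(abs(m$prob_pathogenic - m$D))
        if (include_lovo) {
          lv <- lovo_evaluate(sim$assay, sim$evidence, mcfg, full_fit = fit)
          lovo_out[[r]] <- oc_table(lv)
        }
        TRUE
      },
      error = function(e) conditionMessage(e)
    )
    if (!isTRUE(res)) errors <- c(errors, sprintf("rep %d: %s", r, res))
  }
  list(
    coverage = colMeans(cover, na.rm = TRUE),
    coverage_matrix = cover,
    mae = mae,
    lovo = lovo_out,
    errors = errors
  )
}
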