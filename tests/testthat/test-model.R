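test_that("classification thresholds follow the IARC-style rule", {
  cfg <- varcall_config()
  expect_equal(classify(0.049, cfg), "called_benign")
  expect_equal(classify(0.05, cfg), "no_call")
  expect_equal(classify(0.5, cfg), "no_call")
  expect_equal(classify(0.9899, cfg), "no_call")
  expect_equal(classify(0.99, cfg), "called_pathogenic")  # boundary inclusive
  expect_equal(classify(1, cfg), "called_pathogenic")
  expect_error(classify(1.2, cfg), class = "varcallxt_validation_error")
  cfg2 <- varcall_config(benign_cut = 0.1, pathogenic_cut = 0.8)
  expect_equal(classify(c(0.09, 0.5, 0.8), cfg2),
               c("called_benign", "no_call", "called_pathogenic"))
})

test_that("evidence-set enumeration yields all non-empty subsets in stable order", {
  all4 <- enumerate_models()
  expect_length(all4, 15)
  expect_length(enumerate_models("family"), 1)
  expect_length(enumerate_models(c("a", "b", "c")), 7)
  # deterministic order: by size, then lexicographic
  sizes <- lengths(all4)
  expect_true(all(diff(sizes) >= 0))
  expect_equal(all4[[1]], "agvgd")
  expect_equal(all4[[15]], sort(c("function", "family", "protein_pred", "agvgd")))
  expect_error(enumerate_models(character(0)), class = "varcallxt_validation_error")
})

test_that("log-odds combine additively with extra Bayes factors", {
  expect_equal(combine_log_odds(0, 0), 0)
  expect_equal(combine_log_odds(1, -1), 0)
  set.seed(4)
  lo <- rnorm(20); lb <- rnorm(20)
  expect_equal(exp(combine_log_odds(lo, lb)), exp(lo) * exp(lb))
  expect_error(combine_log_odds(Inf, 0), class = "varcallxt_validation_error")
})

test_that("a well-separated unlabeled variant is called with its control's class", {
  assay <- separated_batch_means(n_batches = 50, sep = 5, noise = 0.05,
                                 unlabeled = c(u_path = 5, u_ben = 0))
  fit <- varcall(assay, config = fast_config())
  v <- fit$variants
  expect_gt(v$prob_pathogenic[v$variant_id == "u_path"], 0.99)
  expect_lt(v$prob_pathogenic[v$variant_id == "u_ben"], 0.01)
  expect_equal(v$call[v$variant_id == "u_path"], "called_pathogenic")
  # labeled controls keep their frozen status
  expect_gt(v$prob_pathogenic[v$variant_id == "path"], 0.99)
  expect_lt(v$prob_pathogenic[v$variant_id == "ben"], 0.01)
})

test_that("family-only model with a zero Bayes factor is indifferent", {
  ev <- data.frame(
    variant_id = "v1", family_log_bf = 0, label = "unlabeled",
    stringsAsFactors = FALSE
  )
  cfg <- varcall_config(
    evidence_set = "family", pi_a = 1, pi_b = 1,
    n_iter = 6000, n_burn = 1000, thin = 1, n_chains = 2, seed = 7
  )
  fit <- varcall(evidence = ev, config = cfg)
  p <- fit$variants$prob_pathogenic
  mcse <- sd(do.call(rbind, fit$draws$scalars)[, "pi"]) / sqrt(fit$draws$n_draws) +
    0.5 / sqrt(fit$draws$n_draws)
  expect_lt(abs(p - 0.5), 3 * max(mcse, 0.02))
})

test_that("sampler posterior matches the closed-form enumeration oracle", {
  inst <- oracle_instance(seed = 5)
  exact <- oracle_d_posterior(inst$assay, inst$d_label, inst$fx)
  cfg <- varcall_config(
    evidence_set = "function", fixed = inst$fx,
    n_iter = 30000, n_burn = 3000, thin = 1, n_chains = 2, seed = 17
  )
  fit <- varcall(inst$assay, config = cfg)
  got <- setNames(fit$variants$prob_pathogenic, fit$variants$variant_id)
  for (id in c("u_cold", "u_mid")) {
    expect_lt(abs(got[id] - exact[id]), 0.01)
  }
  # labeled variants stay frozen at their labels
  expect_equal(unname(got["benA"] < 0.001), TRUE)
  expect_equal(unname(got["pathA"] > 0.999), TRUE)
})

test_that("family evidence shifts the oracle and sampler posteriors identically", {
  inst <- oracle_instance(seed = 6)
  lbf <- c(benA = NA, pathA = NA, u_cold = 2, u_mid = -1)
  exact <- oracle_d_posterior(inst$assay, inst$d_label, inst$fx, extra_lbf = lbf)
  ev <- data.frame(
    variant_id = names(lbf), family_log_bf = unname(lbf),
    stringsAsFactors = FALSE
  )
  cfg <- varcall_config(
    evidence_set = c("function", "family"), fixed = inst$fx,
    n_iter = 30000, n_burn = 3000, thin = 1, n_chains = 2, seed = 23
  )
  fit <- varcall(inst$assay, ev, cfg)
  got <- setNames(fit$variants$prob_pathogenic, fit$variants$variant_id)
  expect_lt(abs(got["u_cold"] - exact["u_cold"]), 0.01)
  expect_lt(abs(got["u_mid"] - exact["u_mid"]), 0.01)
})

test_that("with all variants labeled the effects match closed-form GLS", {
  inst <- oracle_instance(seed = 11)
  d_all <- c(benA = 0L, pathA = 1L, u_cold = 0L, u_mid = 1L)
  assay <- inst$assay
  assay$label <- ifelse(d_all[assay$variant_id] == 1,
                        "pathogenic_control", "benign_control")
  gls <- oracle_gls_effects(assay, d_all, inst$fx)
  cfg <- varcall_config(
    evidence_set = "function", fixed = inst$fx,
    n_iter = 12000, n_burn = 2000, thin = 1, n_chains = 2, seed = 31
  )
  fit <- varcall(assay, config = cfg)
  th <- setNames(fit$variants$theta_mean, fit$variants$variant_id)
  mcse <- setNames(fit$variants$theta_sd, fit$variants$variant_id) /
    sqrt(fit$draws$n_draws / 20)  # conservative autocorrelation allowance
  for (id in names(gls$theta)) {
    expect_lt(abs(th[id] - gls$theta[id]), 3 * mcse[id] + 0.01)
  }
  expect_equal(as.numeric(fit$beta_mean), as.numeric(gls$beta), tolerance = 0.05)
})

test_that("fits are reproducible for a seed and chains agree across seeds", {
  assay <- separated_batch_means(n_batches = 12, unlabeled = c(u1 = 2.5))
  cfg <- fast_config()
  f1 <- varcall(assay, config = cfg)
  f2 <- varcall(assay, config = cfg)
  expect_identical(f1$variants, f2$variants)
  expect_identical(f1$draws$scalars, f2$draws$scalars)

  cfg2 <- fast_config()
  cfg2$seed <- 1234
  f3 <- varcall(assay, config = cfg2)
  # different seed, same posterior within Monte-Carlo error
  expect_lt(abs(
    f1$variants$prob_pathogenic[f1$variants$variant_id == "u1"] -
      f3$variants$prob_pathogenic[f3$variants$variant_id == "u1"]
  ), 0.1)
})

test_that("label swap with mirrored data reflects the probabilities", {
  assay <- separated_batch_means(n_batches = 30, sep = 4, noise = 0.3,
                                 unlabeled = c(u1 = 2.2), seed = 77)
  cfg <- varcall_config(n_iter = 4000, n_burn = 1000, thin = 1,
                        n_chains = 2, seed = 55)
  fit <- varcall(assay, config = cfg)

  mirrored <- assay
  mirrored$mean_log_ratio <- -mirrored$mean_log_ratio
  mirrored$label <- c(
    benign_control = "pathogenic_control",
    pathogenic_control = "benign_control",
    unlabeled = "unlabeled"
  )[mirrored$label]
  fit_m <- varcall(mirrored, config = cfg)
  p <- fit$variants$prob_pathogenic[fit$variants$variant_id == "u1"]
  pm <- fit_m$variants$prob_pathogenic[fit_m$variants$variant_id == "u1"]
  expect_lt(abs(pm - (1 - p)), 0.05)
})

test_that("posterior probability is monotone in an added family Bayes factor", {
  assay <- separated_batch_means(n_batches = 8, sep = 4, noise = 0.5,
                                 unlabeled = c(u1 = 2), seed = 12)
  probs <- sapply(c(-2, 0, 2), function(lbf) {
    ev <- data.frame(
      variant_id = c("ben", "path", "u1"),
      family_log_bf = c(NA, NA, lbf),
      stringsAsFactors = FALSE
    )
    cfg <- varcall_config(
      evidence_set = c("function", "family"),
      n_iter = 4000, n_burn = 1000, thin = 1, n_chains = 2, seed = 9
    )
    fit <- varcall(assay, ev, cfg)
    fit$variants$prob_pathogenic[fit$variants$variant_id == "u1"]
  })
  expect_true(all(diff(probs) > 0))
})

test_that("a zero Bayes factor term leaves the fit unchanged at fixed hyperparameters", {
  inst <- oracle_instance(seed = 19)
  cfg_fun <- varcall_config(
    evidence_set = "function", fixed = inst$fx,
    n_iter = 2000, n_burn = 500, thin = 1, n_chains = 2, seed = 3
  )
  fit_fun <- varcall(inst$assay, config = cfg_fun)
  ev <- data.frame(
    variant_id = unique(inst$assay$variant_id), family_log_bf = 0,
    stringsAsFactors = FALSE
  )
  cfg_fam <- cfg_fun
  cfg_fam$evidence_set <- c("function", "family")
  fit_fam <- varcall(inst$assay, ev, cfg_fam)
  expect_identical(fit_fun$variants$prob_pathogenic,
                   fit_fam$variants$prob_pathogenic)
})

test_that("identifiability and schema preconditions are enforced", {
  assay <- separated_batch_means(n_batches = 5, unlabeled = c(u1 = 1))
  no_path <- assay[assay$label != "pathogenic_control", ]
  expect_error(varcall(no_path, config = fast_config()),
               class = "varcallxt_identifiability_error")
  expect_error(
    varcall(assay, config = varcall_config(evidence_set = c("function", "family"),
                                           n_iter = 100, n_burn = 50)),
    class = "varcallxt_validation_error"
  )
  expect_error(varcall_config(evidence_set = character(0)),
               class = "varcallxt_validation_error")
  expect_error(varcall_config(benign_cut = 0.5, pathogenic_cut = 0.4),
               class = "varcallxt_validation_error")
})

test_that("config YAML round-trips through read_config/write_config", {
  cfg <- varcall_config(
    evidence_set = c("function", "agvgd"), n_iter = 500, n_burn = 100,
    thin = 2, n_chains = 1, seed = 42, pathogenic_cut = 0.95
  )
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$evidence_set, cfg$evidence_set)
  expect_equal(back$n_iter, cfg$n_iter)
  expect_equal(back$pathogenic_cut, cfg$pathogenic_cut)
  unlink(path)
})
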