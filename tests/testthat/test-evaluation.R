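test_that("Jeffreys Dirichlet posterior means reproduce the published rates", {
  # 21 known pathogenic, all called pathogenic
  oc_path <- dirichlet_oc(c(0, 0, 21))
  expect_equal(round(unname(oc_path), 1), c(2.2, 2.2, 95.6))
  # 42 known benign: 41 called benign, 1 no-call
  oc_ben <- dirichlet_oc(c(41, 1, 0))
  expect_equal(round(unname(oc_ben), 1), c(95.4, 3.4, 1.1))
  # empty counts fall back to the prior mean of 1/3 per category
  expect_equal(unname(dirichlet_oc(c(0, 0, 0))), rep(100 / 3, 3))
})

test_that("Dirichlet category means always sum to one", {
  set.seed(10)
  for (i in 1:25) {
    counts <- rpois(3, lambda = sample(0:30, 1))
    expect_equal(sum(dirichlet_oc(counts)), 100, tolerance = 1e-10)
  }
  expect_error(dirichlet_oc(c(-1, 0, 2)), class = "varcallxt_validation_error")
})

test_that("Beta HDR intervals handle monotone and interior-mode cases", {
  # monotone increasing density: boundary-attached interval with the
  # closed-form lower bound 0.05^(1/21.5)
  hdr <- beta_hdr(21.5, 1, 0.95)
  expect_equal(hdr[2], 1)
  expect_equal(hdr[1], 0.05^(1 / 21.5), tolerance = 1e-10)
  expect_equal(round(dirichlet_hdr(c(0, 0, 21), "called_pathogenic")), c(87, 100))

  # symmetric Beta(2,2): interval symmetric about 1/2
  hdr2 <- beta_hdr(2, 2, 0.9)
  expect_equal(hdr2[1], 1 - hdr2[2], tolerance = 1e-6)

  # monotone decreasing density attaches to zero
  hdr3 <- beta_hdr(0.5, 43, 0.95)
  expect_equal(hdr3[1], 0)
  expect_equal(hdr3[2], qbeta(0.95, 0.5, 43), tolerance = 1e-10)
})

test_that("interior-mode HDR is the narrowest 95% interval (grid-search oracle)", {
  a <- 41.5; b <- 2
  hdr <- beta_hdr(a, b, 0.95)
  # mass check by the distribution function
  expect_equal(pbeta(hdr[2], a, b) - pbeta(hdr[1], a, b), 0.95, tolerance = 1e-6)
  # density equal at both ends (interior optimum condition)
  expect_equal(dbeta(hdr[1], a, b), dbeta(hdr[2], a, b), tolerance = 1e-3)
  # no equal-mass interval on a fine grid of left endpoints is narrower
  p_grid <- seq(0, 0.05, length.out = 10000)
  widths <- qbeta(p_grid + 0.95, a, b) - qbeta(p_grid, a, b)
  expect_lte(hdr[2] - hdr[1], min(widths) + 1e-8)
})

test_that("raw accuracy counts no-calls as errors", {
  counts_brca1 <- data.frame(
    condition = c("known_benign", "known_pathogenic"),
    n_called_benign = c(41L, 0L), n_no_call = c(1L, 0L),
    n_called_pathogenic = c(0L, 21L), n = c(42L, 21L),
    stringsAsFactors = FALSE
  )
  expect_equal(round(raw_accuracy(counts_brca1), 1), 98.4)
  counts_brca2 <- data.frame(
    condition = c("known_benign", "known_pathogenic"),
    n_called_benign = c(22L, 0L), n_no_call = c(0L, 1L),
    n_called_pathogenic = c(0L, 10L), n = c(22L, 11L),
    stringsAsFactors = FALSE
  )
  expect_equal(round(raw_accuracy(counts_brca2), 0), 97)
  counts_perfect <- counts_brca1
  counts_perfect$n_no_call <- c(0L, 0L)
  counts_perfect$n_called_benign <- c(42L, 0L)
  expect_equal(raw_accuracy(counts_perfect), 100)
})

test_that("scaled Brier score matches its definition and reference behavior", {
  expect_equal(scaled_brier(c(1, 0, 1), c(1, 0, 1)), 0)
  labels <- c(1, 1, 0, 0, 0)
  expect_equal(scaled_brier(rep(mean(labels), 5), labels), 1)
  expect_equal(scaled_brier(c(0.9, 0.2), c(1, 0)), 0.1)
  # anti-calibrated predictions exceed 1
  expect_gt(scaled_brier(1 - labels, labels), 1)
  # order invariance and brute-force agreement on random instances
  set.seed(33)
  for (i in 1:10) {
    p <- runif(12); y <- rbinom(12, 1, 0.5)
    if (length(unique(y)) < 2) y[1] <- 1 - y[1]
    ref <- mean((mean(y) - y)^2)
    expect_equal(scaled_brier(p, y), mean((p - y)^2) / ref)
    o <- sample(12)
    expect_equal(scaled_brier(p[o], y[o]), scaled_brier(p, y))
  }
  expect_warning(sb <- scaled_brier(c(0.2, 0.3), c(1, 1)), "identical")
  expect_equal(sb, mean((c(0.2, 0.3) - 1)^2))
})

test_that("LOVO calls separated controls into their own classes", {
  assay <- separated_batch_means(n_batches = 40, sep = 5, noise = 0.05,
                                 unlabeled = c(u1 = 5, u2 = 0, u3 = 0))
  lovo <- lovo_evaluate(assay, config = fast_config(),
                        n_iter = 800, n_burn = 300)
  counts <- lovo$counts
  expect_equal(counts$n_called_benign[counts$condition == "known_benign"], 2L)
  expect_equal(counts$n_called_pathogenic[counts$condition == "known_pathogenic"], 2L)
  expect_equal(sum(counts$n_no_call), 0L)
  expect_length(lovo$skipped, 0)
  # count tallies agree with classify applied element-wise
  expect_equal(
    as.integer(table(factor(classify(lovo$per_variant$prob_pathogenic, fast_config()),
                            levels = c("called_benign", "no_call", "called_pathogenic")))),
    c(sum(counts$n_called_benign), sum(counts$n_no_call),
      sum(counts$n_called_pathogenic))
  )
})

test_that("LOVO with uninformative family-only evidence yields no-calls", {
  ev <- data.frame(
    variant_id = sprintf("v%02d", 1:10),
    family_log_bf = 0,
    label = rep(c("benign_control", "pathogenic_control"), each = 5),
    stringsAsFactors = FALSE
  )
  cfg <- varcall_config(evidence_set = "family", n_iter = 2000, n_burn = 500,
                        thin = 1, n_chains = 2, seed = 13)
  lovo <- lovo_evaluate(evidence = ev, config = cfg)
  expect_true(all(lovo$per_variant$call == "no_call"))
})

test_that("LOVO flags a planted misclassification and nothing else", {
  assay <- separated_batch_means(n_batches = 40, sep = 5, noise = 0.05,
                                 unlabeled = NULL, seed = 3, n_per_class = 6)
  # plant one extra benign-labeled variant whose signal is pathogenic-level
  batches <- unique(assay$batch_id)
  set.seed(4)
  planted <- data.frame(
    variant_id = "ben_mislab", batch_id = batches,
    mean_log_ratio = rnorm(length(batches), 5, 0.05),
    n_replicates = 1L, label = "benign_control",
    stringsAsFactors = FALSE
  )
  lovo <- lovo_evaluate(rbind(assay, planted), config = fast_config(),
                        n_iter = 1500, n_burn = 500)
  pv <- lovo$per_variant
  expect_equal(pv$call[pv$variant_id == "ben_mislab"], "called_pathogenic")
  clean <- pv[pv$variant_id != "ben_mislab", ]
  expect_true(all(
    clean$call[clean$condition == "known_benign"] == "called_benign"
  ))
  expect_true(all(
    clean$call[clean$condition == "known_pathogenic"] == "called_pathogenic"
  ))
})

test_that("oc_table assembles rates, intervals, accuracy and Brier score", {
  per_variant <- data.frame(
    variant_id = sprintf("v%d", 1:9),
    condition = rep(c("known_benign", "known_pathogenic"), c(5, 4)),
    prob_pathogenic = c(0.01, 0.02, 0.01, 0.3, 0.02, 0.99, 0.995, 1, 0.97),
    call = c("called_benign", "called_benign", "called_benign", "no_call",
             "called_benign", "called_pathogenic", "called_pathogenic",
             "called_pathogenic", "no_call"),
    stringsAsFactors = FALSE
  )
  lovo <- list(per_variant = per_variant, counts = call_counts(per_variant))
  oc <- oc_table(lovo)
  expect_equal(nrow(oc$rates), 6)
  expect_true(all(oc$rates$hdr_lo <= oc$rates$mean + 1e-9))
  expect_true(all(oc$rates$hdr_hi >= oc$rates$mean - 1e-9))
  spec <- oc$rates[oc$rates$condition == "known_benign" &
                     oc$rates$category == "called_benign", ]
  expect_equal(spec$mean, 100 * 4.5 / 6.5, tolerance = 1e-10)
  expect_equal(round(raw_accuracy(lovo$counts), 1), round(100 * 7 / 9, 1))
  expect_lt(oc$scaled_brier, 1)
})

test_that("odds-shift reports capture ratios and transitions", {
  a <- data.frame(
    variant_id = c("v1", "v2"), prob_pathogenic = c(0.5, 0.2),
    log_odds = qlogis(c(0.5, 0.2)),
    call = c("no_call", "no_call"), label = c("unlabeled", "unlabeled"),
    stringsAsFactors = FALSE
  )
  expect_equal(odds_shift_report(a, a)$per_variant$odds_ratio, c(1, 1))
  expect_equal(odds_shift_report(a, a)$n_transitions, 0)

  b <- a
  b$prob_pathogenic <- c(0.9, 0.2)
  b$log_odds <- qlogis(b$prob_pathogenic)
  b$call <- c("no_call", "no_call")
  rep_ab <- odds_shift_report(a, b)
  expect_equal(rep_ab$per_variant$odds_ratio[1], 9, tolerance = 1e-12)

  # a uniform log(2) shift multiplies every odds by 2 exactly
  c2 <- a
  c2$log_odds <- combine_log_odds(a$log_odds, log(2))
  c2$prob_pathogenic <- plogis(c2$log_odds)
  rep_ac <- odds_shift_report(a, c2)
  expect_equal(rep_ac$per_variant$odds_ratio, c(2, 2), tolerance = 1e-12)

  b$variant_id <- c("v1", "v3")
  expect_error(odds_shift_report(a, b), "v3", class = "varcallxt_validation_error")
})

test_that("the model grid runs every subset and ranks them", {
  assay <- separated_batch_means(n_batches = 25, sep = 5, noise = 0.1,
                                 unlabeled = c(u1 = 2.5), seed = 9)
  ev <- data.frame(
    variant_id = c("ben", "ben2", "path", "path2", "u1"),
    family_log_bf = c(-1, -2, 2, 1.5, 0),
    label = c("benign_control", "benign_control",
              "pathogenic_control", "pathogenic_control", "unlabeled"),
    stringsAsFactors = FALSE
  )
  cfg <- varcall_config(n_iter = 600, n_burn = 200, thin = 1,
                        n_chains = 1, seed = 5)
  grid <- run_grid(assay, ev, cfg, evidence_types = c("function", "family"))
  expect_length(grid$reports, 3)
  expect_equal(nrow(grid$ranking), 3)
  expect_equal(sort(names(grid$reports)),
               sort(c("function", "family", "family+function")))
  # ranking is sorted by raw accuracy, best first
  expect_true(all(diff(grid$ranking$raw_accuracy) <= 1e-9))
})
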