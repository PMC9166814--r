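# Model configuration: evidence set, priors, MCMC settings and calling
# thresholds, with YAML round-trip for the command-line interface.

EVIDENCE_TYPES <- c("function", "family", "protein_pred", "agvgd")

#' Model configuration for [varcall()]
#'
#' Collects the evidence set, prior hyperparameters, MCMC settings and
#' calling thresholds. All priors are weakly informative by default; the
#' component-mean hyperpriors default to data-derived values (labeled-class
#' mean, 10x labeled-class SD) when left `NULL`.
#'
#' @param evidence_set Character subset of
#'   `c("function", "family", "protein_pred", "agvgd")`: which data types
#'   enter the model.
#' @param mu0_mean,mu0_sd,mu1_mean,mu1_sd Normal hyperprior on the benign
#'   (0) and damaging (1) mixture-component means of the variant effects;
#'   `NULL` means centre on the labeled-control class mean with SD equal to
#'   10 times the labeled class SD.
#' @param tau_shape,tau_rate Inverse-gamma prior on each component variance
#'   (also reused for the pooled per-PC variance).
#' @param sigma_b_shape,sigma_b_rate Inverse-gamma prior on the batch-effect
#'   variance.
#' @param sigma_e_shape,sigma_e_rate Inverse-gamma prior on the residual
#'   variance of the within-batch means.
#' @param pi_a,pi_b Beta prior on the prevalence of pathogenic variants.
#' @param pc_mean_sd SD of the zero-centred normal hyperprior on the
#'   class-conditional PC means.
#' @param n_iter,n_burn,thin,n_chains MCMC settings: iterations per chain,
#'   burn-in discarded, thinning interval, number of chains.
#' @param seed Integer seed; chain seeds are derived deterministically.
#' @param benign_cut,pathogenic_cut Calling thresholds: called benign when
#'   `Pr(D = 1 | data) < benign_cut`, called pathogenic when
#'   `>= pathogenic_cut`, otherwise no call.
#' @param agvgd_reference_prior Reference prior used to convert Align-GVGD
#'   probabilities to log Bayes factors; see [agvgd_to_log_bf()].
#' @param weight_by_replicates If `TRUE`, batch-mean observations are
#'   weighted by their replicate counts; the default analyses the unweighted
#'   within-batch means.
#' @param fixed Named list freezing hyperparameters at point masses, e.g.
#'   `list(mu0 = 0, mu1 = -2, tau2_0 = 0.1, tau2_1 = 0.1, sigma_b2 = 0.1,
#'   sigma_e2 = 0.2, pi = 0.5)`. Used for oracle checks and sensitivity
#'   analyses; frozen parameters are not updated by the sampler.
#' @return An object of class `varcall_config`.
#' @export
varcall_config <- function(evidence_set = "function",
                           mu0_mean = NULL, mu0_sd = NULL,
                           mu1_mean = NULL, mu1_sd = NULL,
                           tau_shape = 0.01, tau_rate = 0.01,
                           sigma_b_shape = 0.01, sigma_b_rate = 0.01,
                           sigma_e_shape = 0.01, sigma_e_rate = 0.01,
                           pi_a = 1, pi_b = 1,
                           pc_mean_sd = 3,
                           n_iter = 20000, n_burn = 10000, thin = 5,
                           n_chains = 4, seed = 1,
                           benign_cut = 0.05, pathogenic_cut = 0.99,
                           agvgd_reference_prior = 0.5,
                           weight_by_replicates = FALSE,
                           fixed = list()) {
  cfg <- list(
    evidence_set = evidence_set,
    mu0_mean = mu0_mean, mu0_sd = mu0_sd,
    mu1_mean = mu1_mean, mu1_sd = mu1_sd,
    tau_shape = tau_shape, tau_rate = tau_rate,
    sigma_b_shape = sigma_b_shape, sigma_b_rate = sigma_b_rate,
    sigma_e_shape = sigma_e_shape, sigma_e_rate = sigma_e_rate,
    pi_a = pi_a, pi_b = pi_b,
    pc_mean_sd = pc_mean_sd,
    n_iter = n_iter, n_burn = n_burn, thin = thin,
    n_chains = n_chains, seed = seed,
    benign_cut = benign_cut, pathogenic_cut = pathogenic_cut,
    agvgd_reference_prior = agvgd_reference_prior,
    weight_by_replicates = weight_by_replicates,
    fixed = fixed
  )
  class(cfg) <- "varcall_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  bad <- setdiff(cfg$evidence_set, EVIDENCE_TYPES)
  if (length(bad) > 0 || length(cfg$evidence_set) == 0) {
    vc_stop(
      sprintf(
        "evidence_set must be a non-empty subset of {%s}",
        paste(EVIDENCE_TYPES, collapse = ", ")
      ),
      "varcallxt_validation_error"
    )
  }
  if (!(cfg$benign_cut > 0 && cfg$benign_cut < cfg$pathogenic_cut &&
        cfg$pathogenic_cut <= 1)) {
    vc_stop("need 0 < benign_cut < pathogenic_cut <= 1", "varcallxt_validation_error")
  }
  if (cfg$n_burn >= cfg$n_iter) {
    vc_stop("n_burn must be smaller than n_iter", "varcallxt_validation_error")
  }
  for (nm in c(
    "tau_shape", "tau_rate", "sigma_b_shape", "sigma_b_rate",
    "sigma_e_shape", "sigma_e_rate", "pi_a", "pi_b", "pc_mean_sd"
  )) {
    if (cfg[[nm]] <= 0) {
      vc_stop(sprintf("%s must be positive", nm), "varcallxt_validation_error")
    }
  }
  if (cfg$thin < 1 || cfg$n_chains < 1) {
    vc_stop("thin and n_chains must be >= 1", "varcallxt_validation_error")
  }
  invisible(cfg)
}

#' Read or write a model configuration as YAML
#'
#' The YAML field names mirror the arguments of [varcall_config()] exactly;
#' unspecified fields keep their defaults.
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `varcall_config`; `write_config()`
#'   returns the path invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    vc_stop(sprintf("config file not found: %s", path), "varcallxt_io_error")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(varcall_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    vc_stop(
      sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
      "varcallxt_schema_error"
    )
  }
  do.call(varcall_config, vals)
}

#' @rdname read_config
#' @param config A `varcall_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "varcall_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @export
print.varcall_config <- function(x, ...) {
  cat("varcall model configuration\n")
  cat("  evidence set: ", paste(x$evidence_set, collapse = " + "), "\n", sep = "")
  cat(sprintf(
    "  MCMC: %d chain(s) x %d iterations (%d burn-in, thin %d), seed %d\n",
    x$n_chains, x$n_iter, x$n_burn, x$thin, x$seed
  ))
  cat(sprintf(
    "  calling thresholds: benign < %g, pathogenic >= %g\n",
    x$benign_cut, x$pathogenic_cut
  ))
  if (length(x$fixed) > 0) {
    cat("  fixed hyperparameters:", paste(names(x$fixed), collapse = ", "), "\n")
  }
  invisible(x)
}
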