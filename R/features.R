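# In-silico predictor preprocessing: rank scaling, PCA summarization, and
# conversion of Align-GVGD pathogenicity probabilities to log Bayes factors.

#' Rank-scale predictor scores to [0, 1]
#'
#' Per column, non-missing values are replaced by `(rank - 1) / (n - 1)` with
#' average ranks for ties, so the column minimum maps to 0 and the maximum to
#' 1. A rank score of 0.9 then means the variant scores higher (more likely
#' damaging, for predictors oriented that way) than 90% of the other variants
#' scored by that predictor. Missing entries stay missing.
#'
#' @param x Numeric matrix or data.frame of raw predictor scores
#'   (variants x predictors); row/column names are preserved.
#' @return Matrix of rank scores in `[0, 1]` (NA where input was NA).
#'   A constant column (no variation, so ranks are uninformative) maps to
#'   0.5 everywhere with a warning.
#' @export
rank_scale <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) vc_stop("predictor matrix must be numeric", "varcallxt_validation_error")
  out <- x
  for (j in seq_len(ncol(x))) {
    obs <- !is.na(x[, j])
    n <- sum(obs)
    if (n < 2) {
      vc_stop(
        sprintf("predictor column %d has fewer than 2 non-missing values", j),
        "varcallxt_validation_error"
      )
    }
    v <- x[obs, j]
    if (max(v) == min(v)) {
      warning(sprintf(
        "predictor column %s is constant; rank scores set to 0.5",
        colnames(x)[j] %||% j
      ))
      out[obs, j] <- 0.5
    } else {
      out[obs, j] <- (rank(v, ties.method = "average") - 1) / (n - 1)
    }
  }
  out
}

#' Impute missing rank scores by the column median
#'
#' PCA requires a complete matrix; missing predictor entries (rare in
#' practice, since predictor coverage of assayed missense variants is
#' typically complete) are filled with the column median of the observed
#' rank scores, or 0.5 when a column is entirely missing.
#'
#' @param x Matrix of rank scores with possible NAs.
#' @return Completed matrix; a warning reports how many cells were imputed.
#' @export
impute_rank_scores <- function(x) {
  x <- as.matrix(x)
  n_missing <- sum(is.na(x))
  if (n_missing == 0) return(x)
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) {
      med <- stats::median(x[!miss, j])
      if (!is.finite(med)) med <- 0.5
      x[miss, j] <- med
    }
  }
  warning(sprintf("imputed %d missing predictor cell(s) by column medians", n_missing))
  x
}

#' Summarize correlated predictors by principal components
#'
#' Mean-centers the (already rank-scaled) predictor matrix and extracts the
#' smallest number of principal components whose cumulative explained
#' variance reaches `target_fraction`, capped at `max_k`. Because the 27-odd
#' in-silico predictors are strongly correlated, around ten components
#' typically carry 90% of their variation.
#'
#' @param x Complete numeric matrix (variants x predictors); rank scaling
#'   has already homogenized the columns' scales, so no further
#'   standardization is applied.
#' @param target_fraction Cumulative explained-variance target in (0, 1].
#' @param max_k Upper bound on the number of retained components.
#' @return An object of class `pc_summary`: list with `pc_scores`
#'   (variants x K), `loadings` (predictors x K),
#'   `explained_variance_fraction` (length K), `K`, and
#'   `cumulative_fraction`.
#' @export
pca_summarize <- function(x, target_fraction = 0.90, max_k = 10) {
  x <- as.matrix(x)
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)
    vc_stop(
      sprintf(
        "predictor matrix has missing entries (e.g. row %d, col %d); impute first",
        idx[1, 1], idx[1, 2]
      ),
      "varcallxt_validation_error"
    )
  }
  if (nrow(x) < 2 || ncol(x) < 2) {
    vc_stop("PCA needs at least 2 variants and 2 predictors", "varcallxt_validation_error")
  }
  if (target_fraction <= 0 || target_fraction > 1) {
    vc_stop("target_fraction must be in (0, 1]", "varcallxt_validation_error")
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  frac <- p$sdev^2 / sum(p$sdev^2)
  k <- which(cumsum(frac) >= target_fraction - 1e-12)[1]
  if (is.na(k)) k <- length(frac)
  k <- min(k, max_k, length(frac))
  out <- list(
    pc_scores = p$x[, seq_len(k), drop = FALSE],
    loadings = p$rotation[, seq_len(k), drop = FALSE],
    explained_variance_fraction = frac[seq_len(k)],
    cumulative_fraction = cumsum(frac)[k],
    K = k
  )
  class(out) <- "pc_summary"
  out
}

#' @export
print.pc_summary <- function(x, ...) {
  cat(sprintf(
    "PC summary: %d components over %d predictors, %.1f%% of variance\n",
    x$K, nrow(x$loadings), 100 * x$cumulative_fraction
  ))
  invisible(x)
}

#' Convert an Align-GVGD pathogenicity probability to a log Bayes factor
#'
#' Treats the supplied probability as a posterior computed under a stated
#' reference prior and backs out the implied log Bayes factor:
#' `log[(p / (1 - p)) / (r / (1 - r))]` with `r` the reference prior. The
#' result enters the pathogenicity indicator's full conditional additively
#' on the log-odds scale.
#'
#' @param p Probability (or vector) in (0, 1); values of exactly 0 or 1 are
#'   clipped to `[eps, 1 - eps]` with a warning.
#' @param reference_prior Prior probability under which `p` was computed;
#'   defaults to 0.5 (the conversion is then plain log-odds).
#' @param eps Clipping bound for degenerate probabilities.
#' @return Log Bayes factor(s) in favor of pathogenicity.
#' @export
agvgd_to_log_bf <- function(p, reference_prior = 0.5, eps = 1e-4) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    vc_stop("agvgd probability outside [0, 1]", "varcallxt_validation_error")
  }
  if (reference_prior <= 0 || reference_prior >= 1) {
    vc_stop("reference_prior must be in (0, 1)", "varcallxt_validation_error")
  }
  degenerate <- !is.na(p) & (p <= 0 | p >= 1)
  if (any(degenerate)) {
    warning(sprintf("clipped %d degenerate probability value(s) to [%g, %g]",
                    sum(degenerate), eps, 1 - eps))
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  stats::qlogis(p) - stats::qlogis(reference_prior)
}

#' Build an evidence table from raw predictor scores
#'
#' Convenience pipeline: rank-scale the raw predictor matrix, impute any
#' missing cells, summarize by PCA, and assemble an evidence data.frame with
#' `pc_1 ... pc_K` columns merged onto any existing family / Align-GVGD
#' columns.
#'
#' @param predictors Numeric matrix or data.frame of raw scores with variant
#'   IDs as row names.
#' @param evidence Optional existing evidence data.frame (keyed by
#'   `variant_id`) to merge the PC scores into.
#' @param target_fraction,max_k Passed to [pca_summarize()].
#' @return Evidence data.frame with PC score columns.
#' @export
build_evidence <- function(predictors, evidence = NULL,
                           target_fraction = 0.90, max_k = 10) {
  rs <- rank_scale(predictors)
  rs <- suppressWarnings(impute_rank_scores(rs))
  pcs <- pca_summarize(rs, target_fraction = target_fraction, max_k = max_k)
  pc_df <- data.frame(
    variant_id = rownames(rs) %||% as.character(seq_len(nrow(rs))),
    stringsAsFactors = FALSE
  )
  for (k in seq_len(pcs$K)) pc_df[[paste0("pc_", k)]] <- pcs$pc_scores[, k]
  if (is.null(evidence)) {
    pc_df$label <- "unlabeled"
    return(pc_df)
  }
  evidence <- evidence[setdiff(names(evidence), grep("^pc_", names(evidence), value = TRUE))]
  merge(pc_df, evidence, by = "variant_id", all = TRUE, sort = TRUE)
}
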