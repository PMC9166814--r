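# Delimited-text schemas for assay measurements, per-variant evidence and
# posterior summaries. All tables are plain data.frames; missing values are
# NA internally, empty cells on disk.

ASSAY_COLUMNS <- c("variant_id", "batch_id", "log_ratio", "label")
LABEL_LEVELS <- c("benign_control", "pathogenic_control", "unlabeled")

#' Default label alias map
#'
#' Maps the label vocabulary found in curation practice (IARC classes 1--5,
#' free-text "benign"/"pathogenic"/"VUS") onto the three internal labels
#' `benign_control`, `pathogenic_control` and `unlabeled`. IARC classes 1 and
#' 2 are benign controls, 4 and 5 pathogenic controls, 3 unlabeled.
#'
#' @return Named character vector: names are accepted input spellings
#'   (matched case-insensitively), values are internal labels.
#' @export
default_label_aliases <- function() {
  c(
    benign_control = "benign_control", benign = "benign_control",
    iarc1 = "benign_control", iarc2 = "benign_control",
    "1" = "benign_control", "2" = "benign_control",
    pathogenic_control = "pathogenic_control", pathogenic = "pathogenic_control",
    damaging = "pathogenic_control",
    iarc4 = "pathogenic_control", iarc5 = "pathogenic_control",
    "4" = "pathogenic_control", "5" = "pathogenic_control",
    unlabeled = "unlabeled", vus = "unlabeled", unknown = "unlabeled",
    iarc3 = "unlabeled", "3" = "unlabeled"
  )
}

normalize_labels <- function(x, aliases = default_label_aliases()) {
  x <- trimws(as.character(x))
  x[is.na(x) | x == ""] <- "unlabeled"
  key <- tolower(x)
  out <- unname(aliases[key])
  bad <- is.na(out)
  if (any(bad)) {
    vc_stop(
      sprintf(
        "unrecognized label value(s): %s",
        paste(unique(x[bad]), collapse = ", ")
      ),
      "varcallxt_validation_error"
    )
  }
  out
}

sniff_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_delim_table <- function(path, delim) {
  if (!file.exists(path)) {
    vc_stop(sprintf("file not found: %s", path), "varcallxt_io_error")
  }
  utils::read.table(path,
    header = TRUE, sep = delim, na.strings = c("", "NA"),
    colClasses = "character", check.names = FALSE, quote = "",
    comment.char = "", stringsAsFactors = FALSE
  )
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    vc_stop(
      sprintf(
        "%s: missing required column(s): %s",
        path, paste(missing, collapse = ", ")
      ),
      "varcallxt_schema_error"
    )
  }
}

parse_numeric_column <- function(x, name, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    vc_stop(
      sprintf(
        "%s: non-numeric value in column '%s' at data row(s) %s",
        path, name, paste(utils::head(bad, 5), collapse = ", ")
      ),
      "varcallxt_parse_error"
    )
  }
  out
}

#' Read a replicate-level functional-assay table
#'
#' Reads a delimited text file with one row per replicate measurement.
#' Required columns: `variant_id`, `batch_id`, `log_ratio`, `label`; an
#' optional `replicate_id` column disambiguates replicates within a
#' (variant, batch) cell. Labels are normalized through an alias map so that
#' IARC-class vocabularies can be consumed directly.
#'
#' @param path Path to a TSV/CSV file. The delimiter is inferred from the
#'   extension (`.csv` comma, anything else tab) unless `delim` is given.
#' @param delim Field delimiter override, e.g. `","`.
#' @param label_aliases Named character vector mapping input label spellings
#'   to internal labels; see [default_label_aliases()].
#' @return A data.frame with columns `variant_id`, `batch_id`,
#'   `replicate_id` (may be NA), `log_ratio` (numeric), `label`.
#' @details Validation: all `log_ratio` values must parse as finite numbers;
#'   every variant must carry a single consistent label across its rows;
#'   duplicated (variant, batch, replicate) triples are rejected.
#' @export
read_assay_table <- function(path, delim = NULL,
                             label_aliases = default_label_aliases()) {
  delim <- sniff_delim(path, delim)
  df <- read_delim_table(path, delim)
  require_columns(df, ASSAY_COLUMNS, path)
  out <- data.frame(
    variant_id = as.character(df$variant_id),
    batch_id = as.character(df$batch_id),
    replicate_id = if ("replicate_id" %in% names(df)) {
      as.character(df$replicate_id)
    } else {
      NA_character_
    },
    log_ratio = parse_numeric_column(df$log_ratio, "log_ratio", path),
    label = normalize_labels(df$label, label_aliases),
    stringsAsFactors = FALSE
  )
  validate_assay_table(out)
  out
}

validate_assay_table <- function(x) {
  if (nrow(x) == 0) {
    vc_stop("assay table is empty", "varcallxt_validation_error")
  }
  if (any(!is.finite(x$log_ratio))) {
    vc_stop("log_ratio contains non-finite values", "varcallxt_validation_error")
  }
  lab_per_var <- tapply(x$label, x$variant_id, function(l) length(unique(l)))
  if (any(lab_per_var > 1)) {
    vc_stop(
      sprintf(
        "inconsistent label within variant(s): %s",
        paste(names(lab_per_var)[lab_per_var > 1], collapse = ", ")
      ),
      "varcallxt_validation_error"
    )
  }
  if (!all(is.na(x$replicate_id))) {
    key <- paste(x$variant_id, x$batch_id, x$replicate_id, sep = "\r")
    if (anyDuplicated(key)) {
      vc_stop(
        "duplicated (variant_id, batch_id, replicate_id) rows",
        "varcallxt_validation_error"
      )
    }
  }
  invisible(x)
}

#' Average replicate measurements within each (variant, batch) cell
#'
#' Collapses replicate-level assay rows to one row per observed
#' (variant, batch) pair, carrying the arithmetic mean log-ratio and the
#' replicate count. These within-batch means are the response analyzed by
#' [varcall()].
#'
#' @param measurements Data.frame as returned by [read_assay_table()].
#' @return Data.frame with columns `variant_id`, `batch_id`,
#'   `mean_log_ratio`, `n_replicates`, `label`, one row per observed cell.
#' @export
average_within_batch <- function(measurements) {
  if (is.null(measurements) || nrow(measurements) == 0) {
    vc_stop("cannot average an empty measurement table", "varcallxt_validation_error")
  }
  key <- interaction(measurements$variant_id, measurements$batch_id,
    drop = TRUE, sep = "\r"
  )
  means <- tapply(measurements$log_ratio, key, mean)
  ns <- tapply(measurements$log_ratio, key, length)
  parts <- strsplit(names(means), "\r", fixed = TRUE)
  out <- data.frame(
    variant_id = vapply(parts, `[`, "", 1L),
    batch_id = vapply(parts, `[`, "", 2L),
    mean_log_ratio = as.numeric(means),
    n_replicates = as.integer(ns),
    stringsAsFactors = FALSE
  )
  lab <- measurements$label[!duplicated(measurements$variant_id)]
  names(lab) <- measurements$variant_id[!duplicated(measurements$variant_id)]
  out$label <- unname(lab[out$variant_id])
  out <- out[order(out$variant_id, out$batch_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a per-variant evidence table
#'
#' Reads a delimited text file keyed by `variant_id` with optional columns
#' `pc_1 ... pc_K` (principal-component scores of in-silico predictors),
#' `family_log_bf` (aggregated family-history log Bayes factor),
#' `agvgd_prob` with optional interval bounds `agvgd_lo`, `agvgd_hi`, and
#' `label`. Empty cells become NA, the explicit "absent" representation.
#'
#' @inheritParams read_assay_table
#' @return Data.frame with one row per variant; absent evidence is NA.
#' @export
read_evidence_table <- function(path, delim = NULL,
                                label_aliases = default_label_aliases()) {
  delim <- sniff_delim(path, delim)
  df <- read_delim_table(path, delim)
  require_columns(df, "variant_id", path)
  out <- data.frame(
    variant_id = as.character(df$variant_id),
    stringsAsFactors = FALSE
  )
  pc_cols <- grep("^pc_[0-9]+$", names(df), value = TRUE)
  if (length(pc_cols) > 0) {
    pc_cols <- pc_cols[order(as.integer(sub("^pc_", "", pc_cols)))]
    for (pc in pc_cols) out[[pc]] <- parse_numeric_column(df[[pc]], pc, path)
    # the PC vector must be all-present or all-absent for a variant
    pcm <- as.matrix(out[pc_cols])
    partial <- rowSums(is.na(pcm)) %in% seq_len(length(pc_cols) - 1)
    if (any(partial)) {
      vc_stop(
        sprintf(
          "variant(s) with partially missing PC scores: %s",
          paste(out$variant_id[partial], collapse = ", ")
        ),
        "varcallxt_validation_error"
      )
    }
  }
  for (col in c("family_log_bf", "agvgd_prob", "agvgd_lo", "agvgd_hi")) {
    if (col %in% names(df)) {
      out[[col]] <- parse_numeric_column(df[[col]], col, path)
    }
  }
  for (col in c("agvgd_prob", "agvgd_lo", "agvgd_hi")) {
    if (col %in% names(out)) {
      bad <- !is.na(out[[col]]) & (out[[col]] < 0 | out[[col]] > 1)
      if (any(bad)) {
        vc_stop(
          sprintf(
            "%s outside [0,1] for variant(s): %s",
            col, paste(out$variant_id[bad], collapse = ", ")
          ),
          "varcallxt_validation_error"
        )
      }
    }
  }
  out$label <- if ("label" %in% names(df)) {
    normalize_labels(df$label, label_aliases)
  } else {
    "unlabeled"
  }
  if (anyDuplicated(out$variant_id)) {
    vc_stop("duplicated variant_id rows in evidence table", "varcallxt_validation_error")
  }
  out
}

write_vc_table <- function(x, path, delim = NULL, digits = 6) {
  delim <- sniff_delim(path, delim)
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(col) {
    ifelse(is.na(col), NA_character_, formatC(signif(col, digits), format = "fg", digits = digits))
  })
  utils::write.table(x, path,
    sep = delim, quote = FALSE, row.names = FALSE,
    col.names = TRUE, na = ""
  )
  invisible(path)
}

#' Write an assay, evidence or summary table to delimited text
#'
#' Writes with a header line, fixed column order, empty string for missing
#' values and 6 significant digits by default; the delimiter follows the
#' file extension unless overridden.
#'
#' @param x Data.frame to write.
#' @param path Output path (`.tsv` or `.csv`).
#' @param delim Delimiter override.
#' @param digits Significant digits for numeric columns.
#' @return The path, invisibly.
#' @export
write_assay_table <- function(x, path, delim = NULL, digits = 6) {
  write_vc_table(x, path, delim, digits)
}

#' @rdname write_assay_table
#' @export
write_evidence_table <- function(x, path, delim = NULL, digits = 6) {
  write_vc_table(x, path, delim, digits)
}

#' @rdname write_assay_table
#' @export
write_posterior_table <- function(x, path, delim = NULL, digits = 6) {
  if (inherits(x, "varcall_fit")) x <- x$variants
  write_vc_table(x, path, delim, digits)
}
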