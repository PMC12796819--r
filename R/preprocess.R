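# Row filtering, log2 transform, optional median normalization and
# left-censored imputation.
#
# LFQ dropout is missing-not-at-random: low-abundance proteins fall below the
# detection limit. Imputation therefore draws from a Gaussian anchored at the
# low tail of each sample's observed log2 distribution ("MinProb-like"),
# never from the centre.

#' Remove decoy, contaminant and site-only rows
#'
#' Drops rows flagged as reverse decoys, potential contaminants, or
#' identified only by a modification site, and reports the counts removed.
#'
#' @param pg a \code{protein_groups}.
#' @return the filtered \code{protein_groups}.
#' @export
remove_flagged_rows <- function(pg) {
  stopifnot(inherits(pg, "protein_groups"))
  f <- pg$flags
  drop <- f$reverse | f$contaminant | f$site
  message(sprintf(
    "removed %d flagged rows (%d reverse, %d contaminant, %d site-only)",
    sum(drop), sum(f$reverse), sum(f$contaminant), sum(f$site)))
  if (all(drop)) warning("all rows were flagged; table is empty",
                         call. = FALSE)
  keep <- which(!drop)
  pg$protein_ids <- pg$protein_ids[keep]
  pg$majority_protein_ids <- pg$majority_protein_ids[keep]
  pg$gene_names <- pg$gene_names[keep]
  pg$unique_id <- pg$unique_id[keep]
  pg$flags <- pg$flags[keep, , drop = FALSE]
  pg$lfq <- pg$lfq[keep, , drop = FALSE]
  pg
}

#' Assemble an expression dataset from parsed data and design
#'
#' Columns are reordered to the design's row order. The matrix initially
#' holds raw (linear-scale) intensities with \code{NA} for unquantified
#' entries; \code{\link{log2_transform}} switches it to the log2 scale on
#' which all downstream statistics run.
#'
#' @param pg a \code{protein_groups} (normally after
#'   \code{\link{remove_flagged_rows}}).
#' @param design an \code{experiment_design} whose labels match the data.
#' @return an \code{expression_dataset} with stage \code{"raw"}.
#' @export
make_expression_dataset <- function(pg, design) {
  stopifnot(inherits(pg, "protein_groups"))
  validate_design(design, pg$sample_labels)
  mat <- pg$lfq[, design$label, drop = FALSE]
  structure(list(
    mat = mat,
    design = design,
    ids = pg$unique_id,
    protein_ids = pg$protein_ids,
    stage = "raw",
    log2 = FALSE,
    threshold_used = NA_integer_,
    seed_used = NA_integer_
  ), class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset: %d proteins x %d samples (%d conditions), stage %s%s\n",
    nrow(x$mat), ncol(x$mat), length(unique(x$design$condition)), x$stage,
    if (x$log2) ", log2 scale" else ", linear scale"))
  invisible(x)
}

condition_columns <- function(ds) {
  split(seq_len(ncol(ds$mat)), ds$design$condition)
}

#' Missing-value threshold filter
#'
#' A protein is kept if there is at least one condition in which it was
#' detected in all replicates; raising the threshold relaxes that requirement
#' by one detection per unit. Formally, keep a protein iff some condition
#' \code{c} has at least \code{n_c - thr} detections, where \code{n_c} is the
#' condition's replicate count. With \code{thr = 1} in a 4-replicate
#' experiment a protein needs 3 of 4 detections in at least one condition.
#'
#' @param ds an \code{expression_dataset}.
#' @param thr nonnegative integer threshold; must be smaller than the
#'   smallest replicate count (larger values would make the rule vacuous).
#' @return the filtered dataset, stage \code{"filtered"},
#'   \code{threshold_used} recorded; a \code{filter_report} attribute holds
#'   the before/after row counts.
#' @export
filter_missing <- function(ds, thr = 0L) {
  stopifnot(inherits(ds, "expression_dataset"))
  thr <- as.integer(thr)
  if (is.na(thr) || thr < 0L) stop_user("threshold must be a nonnegative integer")
  n_rep <- table(ds$design$condition)
  if (thr >= min(n_rep)) {
    stop_user("threshold ", thr, " must be smaller than the smallest ",
              "replicate count (", min(n_rep), ")")
  }
  det <- !is.na(ds$mat)
  keep_rule <- rep(FALSE, nrow(ds$mat))
  for (cols in condition_columns(ds)) {
    need <- length(cols) - thr
    keep_rule <- keep_rule |
      rowSums(det[, cols, drop = FALSE]) >= need
  }
  out <- ds
  out$mat <- ds$mat[keep_rule, , drop = FALSE]
  out$ids <- ds$ids[keep_rule]
  out$protein_ids <- ds$protein_ids[keep_rule]
  out$stage <- "filtered"
  out$threshold_used <- thr
  attr(out, "filter_report") <- data.frame(
    n_before = nrow(ds$mat), n_after = sum(keep_rule), threshold = thr)
  out
}

#' Log2-transform the intensity matrix
#'
#' @param ds a filtered \code{expression_dataset} on the linear scale.
#' @return the dataset with entrywise log2 values; missing stays missing.
#' @export
log2_transform <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$log2) stop("dataset is already on the log2 scale")
  if (ds$stage != "filtered") stop("log2_transform expects a filtered dataset")
  if (any(ds$mat <= 0, na.rm = TRUE)) {
    stop("nonpositive intensities present; 0 must be encoded as missing")
  }
  ds$mat <- log2(ds$mat)
  ds$log2 <- TRUE
  ds
}

#' Median-align sample columns (optional, off by default in the pipeline)
#'
#' Shifts each sample's log2 values so its observed median equals the grand
#' median of all observed values. Columns with no observed values are left
#' untouched with a warning.
#'
#' @param ds a log2-scale \code{expression_dataset}.
#' @return the normalized dataset, stage \code{"normalized"}.
#' @export
normalize_median <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"), ds$log2)
  grand <- stats::median(ds$mat, na.rm = TRUE)
  for (j in seq_len(ncol(ds$mat))) {
    col <- ds$mat[, j]
    if (all(is.na(col))) {
      warning("sample '", colnames(ds$mat)[j],
              "' has no observed values; not shifted", call. = FALSE)
      next
    }
    ds$mat[, j] <- col - stats::median(col, na.rm = TRUE) + grand
  }
  ds$stage <- "normalized"
  ds
}

#' Impute left-censored missing values
#'
#' Each missing entry in sample \code{s} is drawn from
#' \code{Normal(mu_s, sigma)} where \code{mu_s} is the
#' \code{downshift_quantile} quantile of the sample's observed log2 values
#' and \code{sigma} is \code{width} times the median per-protein observed
#' standard deviation. This places imputed values in the sample's low tail,
#' matching the missing-not-at-random dropout of LFQ data. Observed entries
#' are never altered; the draw is reproducible given \code{seed}.
#'
#' @param ds a filtered or normalized log2-scale \code{expression_dataset}.
#' @param seed integer master seed (the imputation substream is derived from
#'   it).
#' @param width positive scale factor for the imputation SD (default 0.3).
#' @param downshift_quantile quantile in (0,1) anchoring the imputation mean
#'   (default 0.01).
#' @return a complete dataset, stage \code{"imputed"}, \code{seed_used}
#'   recorded.
#' @export
impute_left_censored <- function(ds, seed, width = 0.3,
                                 downshift_quantile = 0.01) {
  stopifnot(inherits(ds, "expression_dataset"), ds$log2,
            ds$stage %in% c("filtered", "normalized"),
            is.numeric(width), width > 0,
            downshift_quantile > 0, downshift_quantile < 1)
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("an explicit seed is required for imputation")
  }
  n_obs <- colSums(!is.na(ds$mat))
  if (any(n_obs < 2L)) {
    stop_user("sample(s) with fewer than 2 observed values, cannot estimate ",
              "a censoring distribution: ",
              paste(colnames(ds$mat)[n_obs < 2], collapse = ", "))
  }
  out <- ds
  if (anyNA(ds$mat)) {
    row_sd <- apply(ds$mat, 1L, stats::sd, na.rm = TRUE)
    sigma <- width * stats::median(row_sd, na.rm = TRUE)
    if (!is.finite(sigma) || sigma <= 0) {
      stop("cannot estimate imputation SD: no per-protein variation observed")
    }
    set.seed(derive_seed(seed, "impute"))
    for (j in seq_len(ncol(out$mat))) {
      miss <- which(is.na(out$mat[, j]))
      if (!length(miss)) next
      mu <- stats::quantile(ds$mat[, j], probs = downshift_quantile,
                            na.rm = TRUE, names = FALSE)
      out$mat[miss, j] <- stats::rnorm(length(miss), mean = mu, sd = sigma)
    }
  }
  out$stage <- "imputed"
  out$seed_used <- as.integer(seed)
  out
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: flag removal, dataset assembly, threshold filter,
#' log2 transform, optional median normalization, left-censored imputation.
#'
#' @param pg a parsed \code{protein_groups}.
#' @param design an \code{experiment_design}.
#' @param threshold missing-value threshold (default 0).
#' @param seed master seed for the stochastic steps.
#' @param normalize logical; median-align samples before imputing (default
#'   \code{FALSE}).
#' @param width,downshift_quantile imputation parameters, see
#'   \code{\link{impute_left_censored}}.
#' @return an imputed \code{expression_dataset}.
#' @export
preprocess <- function(pg, design, threshold = 0L, seed,
                       normalize = FALSE, width = 0.3,
                       downshift_quantile = 0.01) {
  ds <- make_expression_dataset(remove_flagged_rows(pg), design)
  ds <- log2_transform(filter_missing(ds, threshold))
  if (normalize) ds <- normalize_median(ds)
  impute_left_censored(ds, seed = seed, width = width,
                       downshift_quantile = downshift_quantile)
}
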