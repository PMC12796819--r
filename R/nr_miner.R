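# Nuclear-receptor consensome mining: percentile thresholding, annotated
# dataset extraction, enrichment summaries and cross-receptor overlap.
#
# A consensome ranks a receptor's likely target genes by a percentile score
# in [0, 100] compiled across transcriptomic/cistromic experiments; "top
# 95th percentile" is read inclusively (score >= 95).

#' Default nuclear-receptor list
#'
#' The receptor families with available consensomes: AR, ER, ERR, FXR, GR,
#' MR, PPAR, PR, RAR, ROR, THR, TR and CAR/PXR.
#' @export
NR_RECEPTORS <- c("AR", "ER", "ERR", "FXR", "GR", "MR", "PPAR", "PR",
                  "RAR", "ROR", "THR", "TR", "CAR/PXR")

#' Load a consensome table
#'
#' Accepts two tab-delimited schemas: \emph{long} form with columns
#' \code{gene}, \code{receptor}, \code{percentile}; or \emph{wide} form with
#' a \code{gene} column and one column per receptor (blank = gene absent
#' from that receptor's consensome). Duplicate (receptor, gene) entries keep
#' the maximum percentile with a warning.
#'
#' @param path TSV file.
#' @return a \code{consensome_table}: long-form data.frame (\code{gene},
#'   \code{receptor}, \code{percentile}) with a \code{receptors} attribute.
#' @export
load_consensome <- function(path) {
  if (!file.exists(path)) stop_user("consensome file '", path,
                                    "' does not exist")
  d <- read_tsv(path)
  names(d)[1] <- tolower(names(d)[1])
  if (all(c("gene", "receptor", "percentile") %in% tolower(names(d)))) {
    names(d) <- tolower(names(d))
    long <- d[c("gene", "receptor", "percentile")]
  } else if (tolower(names(d)[1]) == "gene" && ncol(d) >= 2L) {
    recs <- names(d)[-1]
    long <- do.call(rbind, lapply(recs, function(r) {
      v <- suppressWarnings(as.numeric(d[[r]]))
      keep <- !is.na(v)
      data.frame(gene = d$gene[keep], receptor = r, percentile = v[keep],
                 stringsAsFactors = FALSE)
    }))
  } else {
    stop_user("consensome file '", path, "' must be long form ",
              "(gene/receptor/percentile) or wide form (gene + one column ",
              "per receptor)")
  }
  long$percentile <- suppressWarnings(as.numeric(long$percentile))
  bad <- which(is.na(long$percentile) | long$percentile < 0 |
                 long$percentile > 100)
  if (length(bad)) {
    stop_user("percentile outside [0, 100] in consensome row(s) ",
              paste(utils::head(bad, 10), collapse = ", "))
  }
  key <- paste(long$receptor, match_key(long$gene), sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (receptor, gene) consensome entries; keeping the ",
            "maximum percentile", call. = FALSE)
    long <- long[order(key, -long$percentile), ]
    long <- long[!duplicated(paste(long$receptor, match_key(long$gene),
                                   sep = "\r")), ]
    rownames(long) <- NULL
  }
  structure(long, receptors = sort(unique(long$receptor)),
            class = c("consensome_table", "data.frame"))
}

#' Threshold a receptor's consensome into a target gene set
#'
#' @param ct a \code{consensome_table}.
#' @param receptor receptor name present in the table.
#' @param pct percentile cutoff in [0, 100]; genes scoring \code{>= pct}
#'   (inclusive) are selected. Default 95.
#' @return a \code{gene_set} of target genes.
#' @export
threshold_targets <- function(ct, receptor, pct = 95) {
  stopifnot(inherits(ct, "consensome_table"))
  recs <- attr(ct, "receptors")
  if (!receptor %in% recs) {
    stop_user("unknown receptor '", receptor, "'; available: ",
              paste(recs, collapse = ", "))
  }
  rows <- ct$receptor == receptor & ct$percentile >= pct
  if (!any(rows)) {
    stop_user("no ", receptor, " consensome genes at or above the ",
              pct, "th percentile")
  }
  gene_set(receptor, sprintf("%s consensome, >= %gth percentile",
                             receptor, pct),
           ct$gene[rows], species = "mouse")
}

#' Extract consensome targets with per-receptor annotation
#'
#' Matches the target gene set against the dataset exactly as
#' \code{\link{extract_pathway}} does, then appends one percentile column
#' per receptor to the export: the cell holds the gene's percentile when it
#' meets that receptor's threshold and is blank (NA) otherwise.
#'
#' @param ds an imputed \code{expression_dataset}.
#' @param gs the thresholded target \code{gene_set}
#'   (from \code{\link{threshold_targets}}).
#' @param ct the full \code{consensome_table} (all receptors).
#' @param results optional \code{contrast_results} for the statistics
#'   columns.
#' @param pct the percentile threshold applied to every receptor's
#'   annotation column (default 95).
#' @return a \code{mining_result} whose export carries the annotation
#'   columns.
#' @export
extract_targets <- function(ds, gs, ct, results = NULL, pct = 95) {
  stopifnot(inherits(ct, "consensome_table"))
  mr <- extract_pathway(ds, gs, results)
  keys <- match_key(mr$export$id)
  for (rec in attr(ct, "receptors")) {
    sub <- ct[ct$receptor == rec & ct$percentile >= pct, ]
    ix <- match(keys, match_key(sub$gene))
    mr$export[[paste0("pctl.", rec)]] <- sub$percentile[ix]
  }
  mr
}

#' Enrichment summary of a target set among differentially expressed proteins
#'
#' Compares the fraction of up- and down-regulated proteins that are targets
#' of a receptor against the base rate expected from the detected proteome.
#' Percentages mirror the field's reporting precision: the base rate to one
#' decimal, the up/down percentages to the nearest integer. One-sided
#' hypergeometric enrichment p-values are included as an extension of the
#' informal proportion comparison.
#'
#' @param de_up,de_down character vectors of up-/down-regulated protein ids
#'   (subsets of \code{detected}).
#' @param detected character vector of all detected protein ids.
#' @param targets a target \code{gene_set} (or character vector of symbols).
#' @return an \code{enrichment_summary} list: \code{n_detected},
#'   \code{n_targets_detected}, \code{base_rate_pct}, \code{n_up},
#'   \code{n_up_targets}, \code{up_pct}, \code{n_down},
#'   \code{n_down_targets}, \code{down_pct}, \code{p_up}, \code{p_down}.
#' @export
enrichment_summary <- function(de_up, de_down, detected, targets) {
  if (inherits(targets, "gene_set")) targets <- targets$genes
  if (!length(detected)) stop_user("empty detected set")
  norm <- function(x) unique(match_key(x))
  detected <- norm(detected)
  de_up <- norm(de_up); de_down <- norm(de_down)
  tkeys <- norm(targets)
  if (!all(de_up %in% detected) || !all(de_down %in% detected)) {
    stop_user("de_up and de_down must be subsets of detected")
  }
  n <- length(detected)
  k <- sum(detected %in% tkeys)
  n_up <- length(de_up); up_t <- sum(de_up %in% tkeys)
  n_down <- length(de_down); down_t <- sum(de_down %in% tkeys)
  hyper <- function(q, draws) {
    if (draws == 0L) return(NA_real_)
    stats::phyper(q - 1, k, n - k, draws, lower.tail = FALSE)
  }
  structure(list(
    n_detected = n, n_targets_detected = k,
    base_rate_pct = round(100 * k / n, 1),
    n_up = n_up, n_up_targets = up_t,
    up_pct = if (n_up) round(100 * up_t / n_up) else NA_real_,
    n_down = n_down, n_down_targets = down_t,
    down_pct = if (n_down) round(100 * down_t / n_down) else NA_real_,
    p_up = hyper(up_t, n_up), p_down = hyper(down_t, n_down)
  ), class = "enrichment_summary")
}

#' @export
print.enrichment_summary <- function(x, ...) {
  cat(sprintf("base rate: %d of %d detected proteins are targets (%.1f%%)\n",
              x$n_targets_detected, x$n_detected, x$base_rate_pct))
  if (!is.na(x$up_pct))
    cat(sprintf("up:   %d of %d are targets (%d%%), hypergeometric p = %.3g\n",
                x$n_up_targets, x$n_up, x$up_pct, x$p_up))
  if (!is.na(x$down_pct))
    cat(sprintf("down: %d of %d are targets (%d%%), hypergeometric p = %.3g\n",
                x$n_down_targets, x$n_down, x$down_pct, x$p_down))
  invisible(x)
}

#' Pairwise consensome overlap (Venn-style) analysis
#'
#' Receptor consensomes share target genes, so apparent activity of one
#' receptor can reflect another's targets; this computes every pairwise
#' intersection size and, per receptor, the genes unique to it among the
#' supplied sets.
#'
#' @param gs_by_receptor named list of \code{gene_set}s (or character
#'   vectors), one per receptor.
#' @return list with \code{pairwise} (symmetric integer matrix of
#'   intersection sizes; diagonal = set sizes) and \code{unique_targets}
#'   (named list of genes found in exactly one set).
#' @export
consensome_overlap <- function(gs_by_receptor) {
  stopifnot(is.list(gs_by_receptor), length(gs_by_receptor) >= 1L,
            !is.null(names(gs_by_receptor)))
  sets <- lapply(gs_by_receptor, function(g) {
    if (inherits(g, "gene_set")) g <- g$genes
    unique(match_key(g))
  })
  n <- length(sets)
  pw <- matrix(0L, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  uniq <- lapply(seq_len(n), function(i) {
    others <- unique(unlist(sets[-i], use.names = FALSE))
    setdiff(sets[[i]], others)
  })
  names(uniq) <- names(sets)
  list(pairwise = pw, unique_targets = uniq)
}
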