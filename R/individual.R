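# Single-protein lookup and bar-plot data (mean +/- SEM per condition) with
# the full per-comparison p-value table.

#' Look up a protein by gene symbol or accession
#'
#' Matches the query case-insensitively against the gene symbols first
#' (ignoring uniquification suffixes, so "Pklr" finds both Pklr and Pklr.1),
#' then against the UniProt accessions. A symbol shared by several rows
#' returns all of them for the caller to disambiguate.
#'
#' @param ds an \code{expression_dataset}.
#' @param query gene symbol or accession string.
#' @return character vector of matching row ids (length >= 1).
#' @export
lookup_protein <- function(ds, query) {
  stopifnot(inherits(ds, "expression_dataset"), is.character(query),
            length(query) == 1L, nzchar(query))
  qk <- match_key(query)
  hit <- match_key(ds$ids) == qk
  if (!any(hit) && !is.null(ds$protein_ids)) {
    hit <- vapply(ds$protein_ids, function(acc) {
      any(toupper(acc) == toupper(query))
    }, logical(1))
  }
  if (!any(hit)) {
    stop(errorCondition(
      paste0("no protein matching '", query, "' in the dataset"),
      class = c("lfq_not_found", "lfq_user_error", "error"),
      query = query))
  }
  ds$ids[hit]
}

#' Per-condition bar-plot data for one protein
#'
#' Means and standard errors (SD/sqrt(n), sample SD with n-1 denominator) of
#' the imputed log2 intensities per condition, in a user-chosen condition
#' order, together with the protein's p and adjusted p from every fitted
#' contrast. The group means are the same quantities the differential tests
#' use.
#'
#' @param ds an imputed \code{expression_dataset}.
#' @param id a row id (as returned by \code{\link{lookup_protein}}).
#' @param results a \code{contrast_results} (optional; omit for no p-table).
#' @param order optional character vector: a permutation of the condition
#'   names giving the bar order. Default: order of first appearance in the
#'   design.
#' @param colors optional named vector of colors per condition.
#' @return a \code{barplot_data}: \code{id}, \code{bars} (condition, mean,
#'   sem, n, color), \code{p_table} (contrast, log2fc, p, padj).
#' @export
barplot_data <- function(ds, id, results = NULL, order = NULL,
                         colors = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$stage != "imputed") stop("bar-plot data requires an imputed dataset")
  row <- which(ds$ids == id)
  if (length(row) != 1L) stop_user("unknown or ambiguous row id '", id, "'")
  conds <- unique(ds$design$condition)
  if (is.null(order)) {
    order <- conds
  } else if (!setequal(order, conds) || length(order) != length(conds)) {
    stop_user("order must be a permutation of the conditions: ",
              paste(conds, collapse = ", "))
  }
  vals <- split(ds$mat[row, ], ds$design$condition)
  bars <- data.frame(
    condition = order,
    mean = vapply(vals[order], mean, numeric(1)),
    sem = vapply(vals[order], function(v) stats::sd(v) / sqrt(length(v)),
                 numeric(1)),
    n = vapply(vals[order], length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  bars$color <- if (is.null(colors)) NA_character_ else
    unname(colors[bars$condition])
  p_table <- NULL
  if (!is.null(results)) {
    p_table <- do.call(rbind, lapply(names(results), function(nm) {
      r <- results[[nm]]
      i <- match(id, r$id)
      data.frame(contrast = nm, log2fc = r$log2fc[i], p = r$p[i],
                 padj = r$padj[i], stringsAsFactors = FALSE)
    }))
  }
  structure(list(id = id, bars = bars, p_table = p_table),
            class = "barplot_data")
}

#' Bar plot with SE for one protein
#' @param bd a \code{barplot_data}.
#' @return a ggplot object (log2 intensity scale).
#' @export
plot_barplot <- function(bd) {
  stopifnot(inherits(bd, "barplot_data"))
  df <- bd$bars
  df$condition <- factor(df$condition, levels = df$condition)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$mean,
                                        fill = .data$condition)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.3) +
    ggplot2::labs(title = bd$id, x = NULL, y = "log2 LFQ intensity") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
  if (!all(is.na(df$color))) {
    p <- p + ggplot2::scale_fill_manual(values = stats::setNames(
      df$color, as.character(df$condition)))
  }
  p
}

#' Write bar-plot numbers and p-table
#' @param bd a \code{barplot_data}.
#' @param path_base path without extension; \code{_bars.tsv} and
#'   \code{_pvalues.tsv} are appended.
#' @export
write_barplot_data <- function(bd, path_base) {
  write_tsv(bd$bars, paste0(path_base, "_bars.tsv"))
  if (!is.null(bd$p_table)) {
    write_tsv(bd$p_table, paste0(path_base, "_pvalues.tsv"))
  }
  invisible(path_base)
}
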