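# Pathway gene-set handling: GMT-style files, human-to-mouse symbol
# conversion and extraction of pathway members from the dataset.
#
# Gene sets ship as offline GMT-style files; matching against the dataset is
# case-insensitive and ignores the ".1"/".2" uniquification suffixes, so a
# human-cased set (PKLR) matches mouse-cased rows (Pklr, Pklr.1).

#' Construct a gene set
#' @param set_id identifier (Reactome-style ids look like R-HSA-12345).
#' @param name human-readable name.
#' @param genes character vector of gene symbols (deduplicated, non-empty).
#' @param species "human" or "mouse".
#' @return a \code{gene_set}.
#' @export
gene_set <- function(set_id, name, genes, species = c("human", "mouse")) {
  species <- match.arg(species)
  genes <- unique(genes[!is.na(genes) & genes != ""])
  if (!length(genes)) stop_user("gene set '", set_id, "' has no genes")
  structure(list(set_id = set_id, name = name, genes = genes,
                 species = species), class = "gene_set")
}

#' Load gene sets from a GMT-style file
#'
#' Each line: \code{set_id<TAB>name<TAB>gene<TAB>gene...}. Duplicate genes
#' within a line are counted once. Sets whose id starts with \code{R-MMU-}
#' are tagged mouse; all others default to \code{species}.
#'
#' @param path GMT-style file.
#' @param species default species tag for sets without a species-coded id.
#' @return named list of \code{gene_set} objects, keyed by set id.
#' @export
load_gene_sets <- function(path, species = "human") {
  if (!file.exists(path)) stop_user("gene-set file '", path, "' does not exist")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    fields <- fields[fields != ""]
    if (length(fields) < 3L) {
      stop_user("malformed gene-set line ", i, " in '", path,
                "': need set_id, name and at least one gene")
    }
    sp <- if (grepl("^R-MMU-", fields[1])) "mouse" else species
    out[[fields[1]]] <- gene_set(fields[1], fields[2],
                                 fields[-(1:2)], species = sp)
  }
  out
}

#' Convert a human gene set to mouse symbols
#'
#' With an ortholog mapping table each human symbol is replaced by its mouse
#' ortholog(s); one-to-many mappings contribute all their mouse symbols.
#' Symbols absent from the table fall back to the case heuristic (first
#' letter upper, rest lower: CYP4A14 -> Cyp4a14), which is also used when no
#' table is supplied. Mouse-species input is returned unchanged.
#'
#' @param gs a \code{gene_set}.
#' @param mapping optional data.frame with columns \code{human_symbol},
#'   \code{mouse_symbol} (one row per ortholog pair).
#' @return a mouse-species \code{gene_set}.
#' @export
to_mouse_symbols <- function(gs, mapping = NULL) {
  stopifnot(inherits(gs, "gene_set"))
  if (gs$species == "mouse") return(gs)
  heuristic <- function(g) {
    paste0(toupper(substr(g, 1, 1)), tolower(substring(g, 2)))
  }
  if (is.null(mapping)) {
    genes <- heuristic(gs$genes)
  } else {
    stopifnot(all(c("human_symbol", "mouse_symbol") %in% names(mapping)))
    genes <- unlist(lapply(gs$genes, function(g) {
      hit <- mapping$mouse_symbol[toupper(mapping$human_symbol) == toupper(g)]
      if (length(hit)) hit else heuristic(g)
    }), use.names = FALSE)
  }
  gene_set(gs$set_id, gs$name, genes, species = "mouse")
}

# Case- and suffix-insensitive key for symbol matching.
match_key <- function(x) toupper(strip_suffix(x))

#' Read an ortholog mapping table
#' @param path TSV with columns \code{human_symbol}, \code{mouse_symbol}.
#' @return the mapping data.frame.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) stop_user("ortholog map '", path, "' does not exist")
  m <- read_tsv(path)
  if (!all(c("human_symbol", "mouse_symbol") %in% names(m))) {
    stop_user("ortholog map must have columns human_symbol, mouse_symbol")
  }
  m
}

#' Extract a gene set's members from the dataset
#'
#' Rows whose base gene symbol (case-insensitive, uniquification suffix
#' stripped) matches a set gene are pulled out; the set genes not present in
#' the dataset are reported alongside, so matched genes and not-detected
#' genes partition the set.
#'
#' @param ds an imputed \code{expression_dataset}.
#' @param gs a \code{gene_set} (already species-converted as needed).
#' @param results optional \code{contrast_results}; when given, all contrast
#'   statistics are joined onto the export table.
#' @return a \code{mining_result}: \code{matched_ids} (dataset row ids),
#'   \code{matched_genes}, \code{not_detected}, \code{mat} (log2 submatrix),
#'   \code{z} (row z-scores; NULL when < 1 match), \code{export}
#'   (data.frame).
#' @export
extract_pathway <- function(ds, gs, results = NULL) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(gs, "gene_set"))
  if (ds$stage != "imputed") stop("extraction requires an imputed dataset")
  keys <- match_key(ds$ids)
  set_keys <- unique(match_key(gs$genes))
  hit <- keys %in% set_keys
  matched_genes <- gs$genes[match_key(gs$genes) %in% keys]
  not_detected <- gs$genes[!match_key(gs$genes) %in% keys]
  if (!any(hit)) {
    warning("no genes of set '", gs$set_id, "' found in the dataset",
            call. = FALSE)
  }
  mat <- ds$mat[hit, , drop = FALSE]
  rownames(mat) <- ds$ids[hit]
  export <- data.frame(id = ds$ids[hit],
                       gene = strip_suffix(ds$ids[hit]),
                       stringsAsFactors = FALSE)
  export <- cbind(export, as.data.frame(mat, optional = TRUE))
  if (!is.null(results)) {
    for (nm in names(results)) {
      r <- results[[nm]]
      ix <- match(export$id, r$id)
      for (col in c("log2fc", "p", "padj", "significant")) {
        export[[paste0(nm, ".", col)]] <- r[[col]][ix]
      }
    }
  }
  structure(list(
    set_id = gs$set_id, set_name = gs$name,
    matched_ids = ds$ids[hit],
    matched_genes = unique(matched_genes),
    not_detected = unique(not_detected),
    mat = mat,
    z = if (sum(hit) >= 1L) suppressWarnings(zscore_rows(mat)),
    export = export
  ), class = "mining_result")
}

#' @export
print.mining_result <- function(x, ...) {
  cat(sprintf("mining_result '%s' (%s): %d matched rows, %d set genes not detected\n",
              x$set_id, x$set_name, length(x$matched_ids),
              length(x$not_detected)))
  invisible(x)
}

#' Write a mining result's export table
#' @param mr a \code{mining_result}.
#' @param path output TSV.
#' @export
write_mining_result <- function(mr, path) {
  stopifnot(inherits(mr, "mining_result"))
  write_tsv(mr$export, path)
}
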