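# Reading MaxQuant proteinGroups.txt and the experiment design table.
#
# MaxQuant writes one row per protein group with "LFQ intensity <label>"
# columns (one per sample) and "+"-coded flag columns. An LFQ intensity of 0
# means the protein was not quantified in that sample; it is stored as NA.

MQ_FLAG_COLUMNS <- c(reverse = "Reverse",
                     contaminant = "Potential contaminant",
                     site = "Only identified by site")

#' Parse a MaxQuant proteinGroups.txt file
#'
#' Reads the tab-delimited protein-group table, recovers the sample labels
#' from the \code{"LFQ intensity <label>"} headers, decodes the "+"-coded
#' flag columns (reverse decoy, potential contaminant, only identified by
#' site) and builds a uniquified display identifier per row from the gene
#' symbol (falling back to the first accession). Zero intensities are stored
#' as missing (\code{NA}).
#'
#' @param path path to a proteinGroups.txt-dialect file.
#' @return an object of class \code{protein_groups}: a list with elements
#'   \code{protein_ids} (list of accession vectors), \code{majority_protein_ids},
#'   \code{gene_names} (raw symbol strings), \code{unique_id}, \code{flags}
#'   (logical data.frame), \code{lfq} (numeric matrix, proteins x samples,
#'   \code{NA} = not quantified) and \code{sample_labels}.
#' @export
read_protein_groups <- function(path) {
  if (!file.exists(path)) {
    stop_user("cannot read protein groups file: '", path, "' does not exist")
  }
  raw <- tryCatch(
    utils::read.delim(path, sep = "\t", check.names = FALSE, quote = "",
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) stop_user("failed to read '", path, "': ",
                                  conditionMessage(e)))
  if (nrow(raw) == 0L || ncol(raw) == 0L) {
    stop_user("protein groups file '", path, "' is empty")
  }
  lfq_cols <- grep("^LFQ intensity .", names(raw), value = TRUE)
  if (length(lfq_cols) == 0L) {
    stop_user("no 'LFQ intensity <label>' columns found in '", path,
              "': not a MaxQuant LFQ proteinGroups.txt")
  }
  labels <- sub("^LFQ intensity ", "", lfq_cols)
  if (anyDuplicated(labels)) {
    stop_user("duplicate sample labels in LFQ intensity columns: ",
              paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  lfq <- as.matrix(raw[lfq_cols])
  storage.mode(lfq) <- "double"
  if (any(lfq < 0, na.rm = TRUE)) {
    stop_user("negative LFQ intensities in '", path, "'")
  }
  lfq[lfq == 0] <- NA_real_           # 0 = not quantified
  colnames(lfq) <- labels

  flags <- as.data.frame(lapply(MQ_FLAG_COLUMNS, function(col) {
    if (col %in% names(raw)) !is.na(raw[[col]]) & raw[[col]] == "+" else
      rep(FALSE, nrow(raw))
  }))
  missing_flags <- MQ_FLAG_COLUMNS[!MQ_FLAG_COLUMNS %in% names(raw)]
  if (length(missing_flags)) {
    warning("flag column(s) missing, treated as all-negative: ",
            paste(missing_flags, collapse = ", "), call. = FALSE)
  }

  get_chr <- function(col) {
    if (col %in% names(raw)) as.character(raw[[col]]) else
      rep("", nrow(raw))
  }
  protein_ids <- strsplit(get_chr("Protein IDs"), ";", fixed = TRUE)
  protein_ids[lengths(protein_ids) == 0L] <-
    list(sprintf("ROW%d", which(lengths(protein_ids) == 0L)))
  gene_names <- get_chr("Gene names")

  pg <- structure(list(
    protein_ids = protein_ids,
    majority_protein_ids = strsplit(get_chr("Majority protein IDs"), ";",
                                    fixed = TRUE),
    gene_names = gene_names,
    unique_id = uniquify_ids(gene_names,
                             vapply(protein_ids, `[`, character(1), 1L)),
    flags = flags,
    lfq = lfq,
    sample_labels = labels
  ), class = "protein_groups")
  rownames(pg$lfq) <- pg$unique_id
  pg
}

#' @export
print.protein_groups <- function(x, ...) {
  cat(sprintf("protein_groups: %d protein groups x %d samples\n",
              nrow(x$lfq), length(x$sample_labels)))
  cat(sprintf("  flagged rows: %d reverse, %d contaminant, %d site-only\n",
              sum(x$flags$reverse), sum(x$flags$contaminant),
              sum(x$flags$site)))
  invisible(x)
}

#' Build unique display identifiers from gene symbols
#'
#' Semicolon-delimited symbols keep their first token; an empty symbol is
#' replaced by the first accession of the row; duplicates get ".1", ".2", ...
#' suffixes in row order, with the first occurrence left bare (so a symbol
#' duplicated once appears as e.g. \code{Pklr} and \code{Pklr.1}).
#'
#' @param gene_names character vector of raw gene-symbol strings (may be
#'   empty or semicolon-delimited).
#' @param fallback_ids character vector (or list of vectors) of accessions,
#'   same length; the first accession fills in for an empty symbol.
#' @return character vector of unique identifiers, same length.
#' @export
uniquify_ids <- function(gene_names, fallback_ids) {
  if (is.list(fallback_ids)) {
    fallback_ids <- vapply(fallback_ids, `[`, character(1), 1L)
  }
  stopifnot(length(gene_names) == length(fallback_ids))
  first_token <- function(x) trimws(sub(";.*$", "", x))
  base <- first_token(ifelse(is.na(gene_names) | trimws(gene_names) == "",
                             first_token(fallback_ids), gene_names))
  if (any(is.na(base) | base == "")) {
    stop("empty identifier with empty fallback accession")
  }
  out <- character(length(base))
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(base)) {
    cand <- base[i]
    n <- 0L
    while (!is.null(seen[[cand]])) {
      n <- n + 1L
      cand <- paste0(base[i], ".", n)
    }
    seen[[cand]] <- TRUE
    out[i] <- cand
  }
  out
}

DESIGN_COLUMNS <- c("label", "condition", "replicate", "order")

#' Generate a blank experiment-design template
#'
#' One row per sample label in column order, with empty condition, replicate
#' and order fields for the user to complete.
#'
#' @param pg a \code{protein_groups} object.
#' @param path optional file to write the tab-delimited template to.
#' @return the template data.frame (invisibly when \code{path} is given).
#' @export
design_template <- function(pg, path = NULL) {
  stopifnot(inherits(pg, "protein_groups"))
  tpl <- data.frame(label = pg$sample_labels, condition = "",
                    replicate = "", order = "", stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(tpl, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(tpl))
  }
  tpl
}

#' Construct and validate an experiment design
#'
#' @param label,condition,replicate,order vectors of equal length: sample
#'   label, condition name, replicate number, acquisition order. \code{order}
#'   defaults to the row number; it is carried through but not used by any
#'   analysis step.
#' @param sample_labels optional: the data table's sample labels; when given,
#'   the design labels must match them as a set.
#' @return an \code{experiment_design} data.frame.
#' @export
experiment_design <- function(label, condition, replicate,
                              order = seq_along(label),
                              sample_labels = NULL) {
  d <- data.frame(label = as.character(label),
                  condition = as.character(condition),
                  replicate = as.integer(replicate),
                  order = as.integer(order),
                  stringsAsFactors = FALSE)
  validate_design(d, sample_labels)
  class(d) <- c("experiment_design", "data.frame")
  d
}

validate_design <- function(d, sample_labels = NULL) {
  if (!all(DESIGN_COLUMNS %in% names(d))) {
    stop_user("design must have columns: ",
              paste(DESIGN_COLUMNS, collapse = ", "))
  }
  bad <- which(is.na(d$label) | d$label == "")
  if (length(bad)) stop_user("empty label in design row(s) ",
                             paste(bad, collapse = ", "))
  if (anyDuplicated(d$label)) {
    stop_user("duplicate labels in design: ",
              paste(unique(d$label[duplicated(d$label)]), collapse = ", "))
  }
  bad <- which(is.na(d$condition) | d$condition == "")
  if (length(bad)) stop_user("missing condition in design row(s) ",
                             paste(bad, collapse = ", "))
  if (any(is.na(d$replicate)) || any(d$replicate < 1)) {
    stop_user("replicate must be a positive integer; offending row(s): ",
              paste(which(is.na(d$replicate) | d$replicate < 1),
                    collapse = ", "))
  }
  if (length(unique(d$condition)) < 2L) {
    stop_user("design must contain at least 2 conditions")
  }
  reps <- table(d$condition)
  if (any(reps < 2L)) {
    stop_user("every condition needs >= 2 replicates; offending: ",
              paste(names(reps)[reps < 2], collapse = ", "))
  }
  if (anyDuplicated(d[c("condition", "replicate")])) {
    stop_user("duplicate (condition, replicate) pairs in design")
  }
  if (!is.null(sample_labels)) {
    extra <- setdiff(d$label, sample_labels)
    miss <- setdiff(sample_labels, d$label)
    if (length(extra) || length(miss)) {
      stop_user("design labels do not match the data's sample labels",
                if (length(extra)) paste0("; not in data: ",
                                          paste(extra, collapse = ", ")),
                if (length(miss)) paste0("; missing from design: ",
                                         paste(miss, collapse = ", ")))
    }
  }
  invisible(d)
}

#' Read a completed design table
#'
#' @param path tab-delimited file with header
#'   \code{label<TAB>condition<TAB>replicate<TAB>order}.
#' @param pg optional \code{protein_groups}; the design labels must then match
#'   its sample labels as a set.
#' @return an \code{experiment_design}.
#' @export
read_design <- function(path, pg = NULL) {
  if (!file.exists(path)) stop_user("design file '", path, "' does not exist")
  d <- read_tsv(path)
  if (!all(DESIGN_COLUMNS[1:3] %in% names(d))) {
    stop_user("design file '", path, "' must have header ",
              paste(DESIGN_COLUMNS, collapse = "\\t"))
  }
  if (is.null(d$order) || all(is.na(d$order)) ||
      all(trimws(as.character(d$order)) == "")) {
    d$order <- seq_len(nrow(d))
  }
  rep_num <- suppressWarnings(as.numeric(d$replicate))
  if (any(is.na(rep_num)) || any(rep_num != round(rep_num))) {
    stop_user("non-integer replicate in design row(s) ",
              paste(which(is.na(rep_num) | rep_num != round(rep_num)),
                    collapse = ", "))
  }
  experiment_design(d$label, d$condition, rep_num, as.integer(d$order),
                    sample_labels = if (!is.null(pg)) pg$sample_labels)
}

#' Write a design table
#' @param design an \code{experiment_design}.
#' @param path output path.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design)[DESIGN_COLUMNS], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
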