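# Fixtures are built in code at test time; nothing is stored on disk.

# Write a minimal proteinGroups.txt-dialect file. `lfq` is a matrix whose
# column names become the sample labels; NA entries are written as 0.
write_pg_file <- function(path, lfq, genes = NULL, accessions = NULL,
                          reverse = NULL, contaminant = NULL, site = NULL,
                          intensity_prefix = "LFQ intensity ") {
  n <- nrow(lfq)
  genes <- genes %||% sprintf("Gene%03d", seq_len(n))
  accessions <- accessions %||% sprintf("P%05d", seq_len(n))
  plus <- function(x) if (is.null(x)) rep("", n) else ifelse(x, "+", "")
  out <- lfq
  out[is.na(out)] <- 0
  colnames(out) <- paste0(intensity_prefix, colnames(lfq))
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                   `Protein IDs` = accessions,
                   `Majority protein IDs` = accessions,
                   `Gene names` = genes,
                   Reverse = plus(reverse),
                   `Potential contaminant` = plus(contaminant),
                   `Only identified by site` = plus(site))
  df <- cbind(df, as.data.frame(out, optional = TRUE, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Directly assemble an expression_dataset at a given stage (white-box test
# helper; production datasets come through make_expression_dataset).
make_ds <- function(mat, conditions, stage = "imputed", log2 = TRUE) {
  labels <- colnames(mat)
  if (is.null(labels) || anyDuplicated(labels) || any(labels == "")) {
    labels <- sprintf("S%02d", seq_len(ncol(mat)))
  }
  design <- lfqminer::experiment_design(
    labels,
    conditions,
    stats::ave(seq_along(conditions), conditions, FUN = seq_along))
  colnames(mat) <- design$label
  ids <- rownames(mat) %||% sprintf("Prot%04d", seq_len(nrow(mat)))
  rownames(mat) <- ids
  structure(list(mat = mat, design = design, ids = ids,
                 protein_ids = as.list(ids), stage = stage, log2 = log2,
                 threshold_used = 0L, seed_used = NA_integer_),
            class = "expression_dataset")
}

# A small simulated experiment shared by several test files.
toy_simulation <- function(n_proteins = 200, seed = 11, dir = tempfile(),
                           ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  extra <- list(...)
  if (is.null(extra$effects) && n_proteins < 80) {
    # scale the planted subsets down with the protein count
    extra$effects <- list(
      up = list(n = max(3L, n_proteins %/% 6),
                shifts = c(Chow_LDT409 = 2, HFD_LDT409 = 2)),
      down = list(n = max(2L, n_proteins %/% 10),
                  shifts = c(Chow_LDT409 = -2, HFD_LDT409 = -2)))
  }
  spec <- do.call(lfqminer::simulation_spec,
                  c(list(n_proteins = n_proteins, seed = seed), extra))
  sim <- lfqminer::simulate_protein_groups(spec, dir)
  sim$dir <- dir
  sim$spec <- spec
  sim
}

# Brute-force keep rule: a protein survives iff some condition has at least
# n_c - thr detections.
brute_keep <- function(det_row, conditions, thr) {
  any(vapply(unique(conditions), function(cc) {
    idx <- conditions == cc
    sum(det_row[idx]) >= sum(idx) - thr
  }, logical(1)))
}

# O(m^2) step-up FDR oracle.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  rank_of <- match(seq_len(m), ord)
  vapply(seq_len(m), function(i) {
    js <- which(p[ord] >= p[i])
    min(pmin(1, m * p[ord][js] / js))
  }, numeric(1))
}
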