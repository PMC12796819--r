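# Synthetic MaxQuant-dialect data with known ground truth.
#
# The generator emulates a multi-condition LFQ experiment: per-protein log2
# abundances drawn around a baseline, planted per-condition log2 shifts,
# logistic missing-not-at-random dropout (low-abundance entries drop out
# preferentially) plus a uniform missing-at-random rate, and decoy /
# contaminant rows flagged in the MaxQuant "+" dialect. Everything is
# deterministic given the spec's seed.

#' Specify a synthetic LFQ experiment
#'
#' Defaults emulate the shape of a typical mouse-liver LFQ study: four
#' conditions (two diets x two treatments) with three replicates each,
#' baseline log2 intensities around 25 +/- 2 across proteins, replicate
#' noise SD 0.5, logistic MNAR dropout centred two SD below the baseline
#' mean, a small MAR rate, and a handful of decoy/contaminant rows.
#'
#' @param n_proteins number of real protein groups.
#' @param conditions character vector of condition names (>= 2).
#' @param replicates replicates per condition (>= 2).
#' @param baseline_mean,baseline_sd mean/SD of per-protein baseline log2
#'   intensity across proteins.
#' @param noise_sd within-group replicate SD on the log2 scale.
#' @param effects named list of planted effects; each element is
#'   \code{list(n = <proteins>, shifts = c(<condition> = <log2 shift>, ...))}.
#'   Effect subsets are disjoint, assigned from the first protein on.
#' @param mnar_midpoint,mnar_slope logistic dropout parameters: an entry
#'   with true log2 intensity v drops out with probability
#'   \code{plogis((mnar_midpoint - v) * mnar_slope)}.
#' @param mar_rate additional uniform missing-at-random rate.
#' @param n_decoys,n_contaminants flagged rows appended to the file.
#' @param n_duplicate_symbols how many gene symbols are reused once, to
#'   exercise identifier uniquification.
#' @param seed mandatory integer seed.
#' @return a \code{simulation_spec} list.
#' @export
simulation_spec <- function(n_proteins = 1000L,
                            conditions = c("Chow_Veh", "Chow_LDT409",
                                           "HFD_Veh", "HFD_LDT409"),
                            replicates = 3L,
                            baseline_mean = 25, baseline_sd = 2,
                            noise_sd = 0.5,
                            effects = list(
                              up = list(n = 50L,
                                        shifts = c(Chow_LDT409 = 2,
                                                   HFD_LDT409 = 2)),
                              down = list(n = 30L,
                                          shifts = c(Chow_LDT409 = -2,
                                                     HFD_LDT409 = -2))),
                            mnar_midpoint = baseline_mean - 2 * baseline_sd,
                            mnar_slope = 1.2,
                            mar_rate = 0.02,
                            n_decoys = 20L, n_contaminants = 10L,
                            n_duplicate_symbols = 2L,
                            seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop_user("simulation_spec requires an explicit seed")
  }
  stopifnot(n_proteins >= 1L, length(conditions) >= 2L, replicates >= 2L,
            noise_sd > 0, mar_rate >= 0, mar_rate <= 1)
  n_eff <- sum(vapply(effects, function(e) e$n, numeric(1)))
  if (n_eff > n_proteins) stop_user("planted effect subsets exceed n_proteins")
  for (e in effects) {
    if (!all(names(e$shifts) %in% conditions)) {
      stop_user("effect shift names must be condition names")
    }
  }
  structure(list(
    n_proteins = as.integer(n_proteins), conditions = conditions,
    replicates = as.integer(replicates),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    noise_sd = noise_sd, effects = effects,
    mnar_midpoint = mnar_midpoint, mnar_slope = mnar_slope,
    mar_rate = mar_rate, n_decoys = as.integer(n_decoys),
    n_contaminants = as.integer(n_contaminants),
    n_duplicate_symbols = as.integer(n_duplicate_symbols),
    seed = as.integer(seed)
  ), class = "simulation_spec")
}

sim_design <- function(spec) {
  n <- length(spec$conditions) * spec$replicates
  labels <- sprintf("MS%02d", seq_len(n))
  experiment_design(labels,
                    rep(spec$conditions, each = spec$replicates),
                    rep(seq_len(spec$replicates),
                        times = length(spec$conditions)))
}

#' Generate a synthetic proteinGroups.txt with ground truth
#'
#' Writes \code{proteinGroups.txt} and a completed \code{design.tsv}, plus
#' truth tables under \code{truth/}: the per-contrast true log2 fold changes
#' (\code{truth_effects.tsv}), the dropout mask
#' (\code{truth_missing.tsv}) and the true differentially expressed set per
#' contrast (\code{truth_de.tsv}). Identical spec and seed give
#' byte-identical files.
#'
#' @param spec a \code{simulation_spec}.
#' @param dir output directory (created).
#' @return invisibly, a list with the file paths and the in-memory truth:
#'   \code{true_log2} (complete matrix before dropout), \code{true_shifts}
#'   (proteins x conditions), \code{missing_mask}, \code{effect_proteins}
#'   (named list of id vectors), \code{design}.
#' @export
simulate_protein_groups <- function(spec, dir) {
  stopifnot(inherits(spec, "simulation_spec"))
  dir.create(file.path(dir, "truth"), showWarnings = FALSE, recursive = TRUE)
  design <- sim_design(spec)
  n_samp <- nrow(design)
  set.seed(derive_seed(spec$seed, "simulate"))

  # gene symbols; the first n_duplicate_symbols reuse the previous symbol
  genes <- sprintf("Gene%04d", seq_len(spec$n_proteins))
  if (spec$n_duplicate_symbols > 0L && spec$n_proteins > 2L) {
    dup_at <- seq_len(min(spec$n_duplicate_symbols,
                          spec$n_proteins %/% 2)) * 2L
    genes[dup_at] <- genes[dup_at - 1L]
  }
  acc <- sprintf("P%05d", seq_len(spec$n_proteins))

  shifts <- matrix(0, spec$n_proteins, length(spec$conditions),
                   dimnames = list(NULL, spec$conditions))
  effect_proteins <- list()
  at <- 1L
  for (nm in names(spec$effects)) {
    e <- spec$effects[[nm]]
    idx <- seq.int(at, length.out = e$n)
    at <- at + e$n
    shifts[idx, names(e$shifts)] <-
      matrix(e$shifts, nrow = e$n, ncol = length(e$shifts), byrow = TRUE)
    effect_proteins[[nm]] <- idx
  }

  base <- stats::rnorm(spec$n_proteins, spec$baseline_mean, spec$baseline_sd)
  true_log2 <- base + shifts[, design$condition, drop = FALSE] +
    matrix(stats::rnorm(spec$n_proteins * n_samp, 0, spec$noise_sd),
           spec$n_proteins, n_samp)
  colnames(true_log2) <- design$label

  p_drop <- stats::plogis((spec$mnar_midpoint - true_log2) * spec$mnar_slope)
  p_drop <- pmin(1, p_drop + spec$mar_rate)
  missing_mask <- matrix(
    stats::runif(length(true_log2)) < p_drop,
    nrow(true_log2), ncol(true_log2), dimnames = dimnames(true_log2))

  lfq <- 2^true_log2
  lfq[missing_mask] <- 0

  # decoy / contaminant rows, visibly fake values
  extra_n <- spec$n_decoys + spec$n_contaminants
  extra_lfq <- matrix(
    round(2^stats::rnorm(extra_n * n_samp, spec$baseline_mean - 5, 1), 4),
    extra_n, n_samp)
  file_df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    `Protein IDs` = c(acc,
                      sprintf("REV__Q%05d", seq_len(spec$n_decoys)),
                      sprintf("CON__C%05d", seq_len(spec$n_contaminants))),
    `Majority protein IDs` = c(acc,
                               sprintf("REV__Q%05d", seq_len(spec$n_decoys)),
                               sprintf("CON__C%05d",
                                       seq_len(spec$n_contaminants))),
    `Gene names` = c(genes, rep("", extra_n)),
    Reverse = c(rep("", spec$n_proteins),
                rep("+", spec$n_decoys), rep("", spec$n_contaminants)),
    `Potential contaminant` = c(rep("", spec$n_proteins + spec$n_decoys),
                                rep("+", spec$n_contaminants)),
    `Only identified by site` = rep("", spec$n_proteins + extra_n))
  intens <- rbind(round(lfq, 4), extra_lfq)
  colnames(intens) <- paste0("LFQ intensity ", design$label)
  file_df <- cbind(file_df, as.data.frame(intens, optional = TRUE,
                                          check.names = FALSE))

  pg_path <- file.path(dir, "proteinGroups.txt")
  utils::write.table(file_df, pg_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  design_path <- file.path(dir, "design.tsv")
  write_design(design, design_path)

  ids <- uniquify_ids(genes, acc)
  rownames(true_log2) <- ids
  rownames(missing_mask) <- ids
  rownames(shifts) <- ids

  # truth tables
  conds <- sort(spec$conditions)
  eff <- data.frame(id = ids, stringsAsFactors = FALSE)
  de <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (i in seq_along(conds)) {
    for (j in seq_along(conds)) {
      if (i < j) {
        nm <- paste0(conds[i], "_vs_", conds[j])
        eff[[nm]] <- shifts[, conds[i]] - shifts[, conds[j]]
        de[[nm]] <- eff[[nm]] != 0
      }
    }
  }
  write_tsv(eff, file.path(dir, "truth", "truth_effects.tsv"))
  write_tsv(de, file.path(dir, "truth", "truth_de.tsv"))
  miss_df <- cbind(data.frame(id = ids, stringsAsFactors = FALSE),
                   as.data.frame(missing_mask, optional = TRUE))
  write_tsv(miss_df, file.path(dir, "truth", "truth_missing.tsv"))

  invisible(list(
    protein_groups = pg_path, design_file = design_path,
    true_log2 = true_log2, true_shifts = shifts,
    missing_mask = missing_mask,
    effect_proteins = lapply(effect_proteins, function(i) ids[i]),
    ids = ids, design = design))
}

#' Generate gene-set and consensome fixtures with planned overlaps
#'
#' Builds a GMT-style pathway file and a long-form consensome table whose
#' overlap with a given gene universe is exact by construction, so mining
#' results have closed-form expected values.
#'
#' @param genes character vector: the dataset's gene ids (uniquified;
#'   suffixes are stripped for set membership).
#' @param dir output directory.
#' @param pathways list of \code{list(id, name, n_detected, n_absent)}: each
#'   set takes its first \code{n_detected} genes from the universe (round
#'   robin over blocks) and invents \code{n_absent} genes not present.
#' @param receptors named list: receptor name -> \code{list(n_targets =
#'   <genes drawn from the universe scoring >= 95>, n_low = <universe genes
#'   scoring below 95>, n_absent = <invented target genes>)}.
#' @param seed integer seed.
#' @return invisibly, list with paths \code{gmt}, \code{consensome} and the
#'   planned truth per set/receptor (gene vectors).
#' @export
simulate_gene_annotations <- function(genes, dir,
                                      pathways = list(
                                        list(id = "R-HSA-0000001",
                                             name = "synthetic pathway",
                                             n_detected = 6L,
                                             n_absent = 2L)),
                                      receptors = list(
                                        PPAR = list(n_targets = 40L,
                                                    n_low = 20L,
                                                    n_absent = 5L),
                                        GR = list(n_targets = 30L,
                                                  n_low = 20L,
                                                  n_absent = 5L)),
                                      seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base_genes <- unique(strip_suffix(genes))
  set.seed(derive_seed(seed, "annotations"))
  gmt_path <- file.path(dir, "pathways_synthetic.gmt")
  truth <- list(pathways = list(), receptors = list())
  offset <- 0L
  gmt_lines <- character(0)
  for (p in pathways) {
    stopifnot(offset + p$n_detected <= length(base_genes))
    present <- base_genes[seq.int(offset + 1L, length.out = p$n_detected)]
    offset <- offset + p$n_detected
    absent <- sprintf("Absent%s%02d", gsub("[^0-9]", "", p$id),
                      seq_len(p$n_absent))
    gmt_lines <- c(gmt_lines,
                   paste(c(p$id, p$name, present, absent), collapse = "\t"))
    truth$pathways[[p$id]] <- list(present = present, absent = absent)
  }
  writeLines(gmt_lines, gmt_path)

  cons_rows <- list()
  for (rec in names(receptors)) {
    r <- receptors[[rec]]
    pool <- sample(base_genes)
    tg <- pool[seq_len(r$n_targets)]
    low <- pool[seq.int(r$n_targets + 1L, length.out = r$n_low)]
    absent <- sprintf("%sOnly%02d", gsub("[^A-Za-z]", "", rec),
                      seq_len(r$n_absent))
    cons_rows[[rec]] <- data.frame(
      gene = c(tg, absent, low),
      receptor = rec,
      percentile = c(round(stats::runif(r$n_targets, 95, 100), 2),
                     round(stats::runif(r$n_absent, 95, 100), 2),
                     round(stats::runif(r$n_low, 10, 94.9), 2)),
      stringsAsFactors = FALSE)
    truth$receptors[[rec]] <- list(targets_detected = tg,
                                   targets_absent = absent,
                                   below_threshold = low)
  }
  cons_path <- file.path(dir, "consensome_synthetic.tsv")
  write_tsv(do.call(rbind, cons_rows), cons_path)
  invisible(list(gmt = gmt_path, consensome = cons_path, truth = truth))
}
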