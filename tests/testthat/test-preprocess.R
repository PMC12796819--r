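make_raw_ds <- function(mat, conditions) {
  make_ds(mat, conditions, stage = "raw", log2 = FALSE)
}

test_that("flagged rows are removed and counted", {
  lfq <- matrix(1e7, 10, 4, dimnames = list(NULL, sprintf("S%d", 1:4)))
  f <- write_pg_file(tempfile(), lfq,
                     reverse = c(TRUE, TRUE, rep(FALSE, 8)),
                     contaminant = c(FALSE, FALSE, TRUE, rep(FALSE, 7)))
  pg <- read_protein_groups(f)
  expect_message(out <- remove_flagged_rows(pg), "2 reverse, 1 contaminant")
  expect_equal(nrow(out$lfq), 7L)
  # no flags: identity
  pg2 <- read_protein_groups(write_pg_file(tempfile(), lfq))
  expect_equal(nrow(suppressMessages(remove_flagged_rows(pg2))$lfq), 10L)
  # all flagged: empty with warning
  pg3 <- read_protein_groups(write_pg_file(tempfile(), lfq,
                                           reverse = rep(TRUE, 10)))
  expect_warning(suppressMessages(out3 <- remove_flagged_rows(pg3)),
                 "all rows")
  expect_equal(nrow(out3$lfq), 0L)
})

test_that("threshold filter keeps a protein iff some condition has n_c - thr detections", {
  conds <- rep(c("A", "B", "C", "D"), each = 3)
  # fully detected in A only -> kept at thr 0
  m1 <- matrix(NA_real_, 1, 12); m1[1, 1:3] <- 1e7
  # 2/3 in every condition -> removed at thr 0
  m2 <- matrix(1e7, 1, 12); m2[1, c(3, 6, 9, 12)] <- NA
  ds <- make_raw_ds(rbind(m1, m2), conds)
  out <- filter_missing(ds, 0)
  expect_identical(out$ids, ds$ids[1])
  expect_equal(out$threshold_used, 0L)
  expect_equal(out$stage, "filtered")

  # thr=1 in a 4-replicate experiment: 3/4 in one condition suffices
  conds4 <- rep(c("A", "B"), each = 4)
  m <- matrix(NA_real_, 1, 8); m[1, 1:3] <- 1e7
  expect_equal(nrow(filter_missing(make_raw_ds(m, conds4), 1)$mat), 1L)
  expect_equal(nrow(filter_missing(make_raw_ds(m, conds4), 0)$mat), 0L)
})

test_that("threshold filter matches exhaustive brute-force evaluation", {
  # every detection pattern for 2-4 conditions x 2-4 replicates
  for (n_cond in 2:4) {
    for (n_rep in 2:4) {
      conds <- rep(LETTERS[1:n_cond], each = n_rep)
      patterns <- as.matrix(expand.grid(
        rep(list(0:n_rep), n_cond)))     # detections per condition
      mat <- matrix(NA_real_, nrow(patterns), n_cond * n_rep)
      for (p in seq_len(nrow(patterns))) {
        for (cc in seq_len(n_cond)) {
          k <- patterns[p, cc]
          if (k > 0) mat[p, (cc - 1) * n_rep + seq_len(k)] <- 1e7
        }
      }
      ds <- make_raw_ds(mat, conds)
      prev_keep <- NULL
      for (thr in 0:(n_rep - 1)) {
        keep <- ds$ids %in% filter_missing(ds, thr)$ids
        expected <- apply(!is.na(mat), 1, brute_keep, conds, thr)
        expect_identical(keep, unname(expected))
        if (!is.null(prev_keep)) {
          expect_true(all(keep | !prev_keep))  # monotone in thr
        }
        prev_keep <- keep
      }
    }
  }
})

test_that("thresholds at or above the smallest replicate count are rejected", {
  ds <- make_raw_ds(matrix(1e7, 3, 6), rep(c("A", "B"), each = 3))
  expect_error(filter_missing(ds, 3), "smaller than",
               class = "lfq_user_error")
  expect_error(filter_missing(ds, -1), class = "lfq_user_error")
})

test_that("log2 transform maps values entrywise and keeps missing missing", {
  m <- matrix(c(1024, NA, 1, 2), 1, 4)
  ds <- filter_missing(make_raw_ds(m, rep(c("A", "B"), each = 2)), 1)
  out <- log2_transform(ds)
  expect_equal(out$mat[1, ], c(10, NA, 0, 1), ignore_attr = TRUE)
  expect_error(log2_transform(out), "already")
})

test_that("median normalization removes a column shift and is identity when aligned", {
  m <- matrix(rnorm(60, 20), 10, 6)
  ds <- make_ds(m, rep(c("A", "B"), each = 3), stage = "filtered")
  shifted <- ds
  shifted$mat[, 2] <- shifted$mat[, 2] + 2
  out <- normalize_median(shifted)
  expect_equal(stats::median(out$mat[, 2]), stats::median(out$mat[, 1]),
               tolerance = 1e-12)
  # aligned columns move only by a common constant (grand-median re-anchor)
  aligned <- normalize_median(ds)
  expect_equal(apply(aligned$mat, 2, stats::median),
               rep(stats::median(ds$mat), 6), ignore_attr = TRUE)
})

test_that("imputation preserves observed values, completes the matrix, and is seeded", {
  set.seed(42)
  m <- matrix(rnorm(400, 25, 2), 100, 4)
  m[sample(length(m), 80)] <- NA
  ds <- make_ds(m, rep(c("A", "B"), each = 2), stage = "filtered")
  out1 <- impute_left_censored(ds, seed = 7)
  out2 <- impute_left_censored(ds, seed = 7)
  expect_false(anyNA(out1$mat))
  expect_identical(out1$mat, out2$mat)          # same seed, bitwise
  obs <- !is.na(m)
  expect_identical(out1$mat[obs], m[obs])       # observed untouched
  expect_equal(out1$stage, "imputed")
  out3 <- impute_left_censored(ds, seed = 8)
  expect_false(identical(out1$mat, out3$mat))
  # complete matrix returns unchanged values
  full <- make_ds(matrix(rnorm(40, 25), 10, 4), rep(c("A", "B"), each = 2),
                  stage = "filtered")
  expect_identical(impute_left_censored(full, seed = 1)$mat, full$mat)
})

test_that("imputed values sit in the left tail of the observed distribution", {
  # Monte-Carlo check of the left-censoring contract under 30% missingness
  set.seed(99)
  hits <- 0L
  n_sim <- 200L
  for (i in seq_len(n_sim)) {
    m <- matrix(rnorm(200, 25, 2), 50, 4)
    m[sample(length(m), 60)] <- NA
    ds <- make_ds(m, rep(c("A", "B"), each = 2), stage = "filtered")
    out <- impute_left_censored(ds, seed = i)
    imputed <- out$mat[is.na(m)]
    if (mean(imputed) < stats::quantile(m, 0.05, na.rm = TRUE)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("samples with fewer than two observed values are fatal", {
  m <- matrix(rnorm(8, 25), 4, 2)
  m[2:4, 1] <- NA
  ds <- make_ds(cbind(m, m), rep(c("A", "B"), each = 2), stage = "filtered")
  expect_error(impute_left_censored(ds, seed = 1), "fewer than 2",
               class = "lfq_user_error")
})

test_that("the full preprocessing chain is reproducible given a seed", {
  sim <- toy_simulation(n_proteins = 120, seed = 5)
  pg <- read_protein_groups(sim$protein_groups)
  des <- read_design(sim$design_file, pg)
  a <- suppressMessages(preprocess(pg, des, seed = 3))
  b <- suppressMessages(preprocess(pg, des, seed = 3))
  expect_identical(a$mat, b$mat)
  expect_equal(a$seed_used, 3L)
})
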