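fit_one <- function(x1, x2, ...) {
  mat <- cbind(x1, x2)
  conds <- rep(c("A", "B"), c(ncol(x1), ncol(x2)))
  ds <- make_ds(mat, conds)
  fit_all_contrasts(ds, ...)[["A_vs_B"]]
}

test_that("unmoderated test equals the textbook pooled two-sample t", {
  r <- fit_one(matrix(1:3, 1), matrix(4:6, 1), moderated = FALSE)
  oracle <- stats::t.test(1:3, 4:6, var.equal = TRUE)
  expect_equal(r$t, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(r$p, oracle$p.value, tolerance = 1e-10)
  expect_equal(r$log2fc, -3)
  # and on random matrices, protein by protein
  set.seed(17)
  x1 <- matrix(rnorm(40, 20), 10, 4)
  x2 <- matrix(rnorm(30, 20), 10, 3)
  r <- fit_one(x1, x2, moderated = FALSE)
  for (i in 1:10) {
    o <- stats::t.test(x1[i, ], x2[i, ], var.equal = TRUE)
    expect_equal(r$p[i], o$p.value, tolerance = 1e-10)
  }
})

test_that("identical groups give zero fold changes and nothing significant", {
  x <- matrix(rnorm(30, 20), 10, 3)
  r <- fit_one(x, x)
  expect_equal(r$log2fc, rep(0, 10))
  expect_false(any(r$significant))
})

test_that("reversing a contrast negates log2fc bitwise and keeps p", {
  set.seed(23)
  mat <- matrix(rnorm(120, 20), 20, 6)
  ds <- make_ds(mat, rep(c("A", "B"), each = 3))
  fwd <- fit_all_contrasts(ds, contrasts = list(c("A", "B")))[[1]]
  rev <- fit_all_contrasts(ds, contrasts = list(c("B", "A")))[[1]]
  expect_identical(fwd$log2fc, -rev$log2fc)
  expect_identical(fwd$p, rev$p)
})

test_that("BH adjustment matches the O(m^2) step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)            # m = 1 identity
  set.seed(5)
  for (i in 1:1000) {
    p <- stats::runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
  # permutation equivariance
  p <- stats::runif(20)
  perm <- sample(20)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("padj is monotone in p-rank and >= p within a contrast", {
  set.seed(31)
  r <- fit_one(matrix(rnorm(200, 20), 50, 4), matrix(rnorm(200, 20), 50, 4))
  expect_true(all(r$padj >= r$p))
  ord <- order(r$p)
  expect_true(all(diff(r$padj[ord]) >= -1e-15))
})

test_that("moderation shrinks towards the prior and vanishes at d0 = 0", {
  set.seed(41)
  x1 <- matrix(rnorm(400, 20, 1), 100, 4)
  x2 <- matrix(rnorm(400, 20, 1), 100, 4)
  plain <- fit_one(x1, x2, moderated = FALSE)
  expect_identical(attr(plain, "d0"), 0)
  expect_equal(attr(plain, "df_total"), 6)
  # homogeneous true variances: the prior takes over (d0 = Inf, s2post = s0^2)
  prior <- lfqminer:::estimate_var_prior(rep(1.3, 50), df = 6)
  expect_identical(prior$d0, Inf)
  # expected log s^2 bias correction: s0^2 recovers the common variance
  expect_equal(log(prior$s0sq), log(1.3) - digamma(3) + log(3),
               tolerance = 1e-10)
  # trigamma inverse round-trips
  for (y in c(0.01, 0.5, 3, 200)) {
    expect_equal(lfqminer:::trigamma_inverse(trigamma(y)), y,
                 tolerance = 1e-6)
  }
})

test_that("moderated statistics agree with limma's empirical Bayes", {
  skip_if_not_installed("limma")
  set.seed(53)
  n1 <- 3; n2 <- 3
  mat <- matrix(rnorm(200 * (n1 + n2), 20, 1), 200)
  sds <- sqrt(1 / stats::rgamma(200, shape = 3, rate = 3))
  mat <- mat * sds  # heterogeneous variances so d0 is finite
  ds <- make_ds(mat, rep(c("A", "B"), c(n1, n2)))
  r <- fit_all_contrasts(ds)[["A_vs_B"]]
  design <- cbind(1, rep(c(1, 0), c(n1, n2)))
  fit <- limma::eBayes(limma::lmFit(ds$mat, design))
  expect_equal(attr(r, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(r, "s0sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(r$t, fit$t[, 2], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(r$p, fit$p.value[, 2], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the significance rule uses strict inequalities on both cutoffs", {
  expect_true(significance_flag(0.6, 0.04))
  expect_false(significance_flag(0.5, 0.04))   # exactly at the lfc cutoff
  expect_false(significance_flag(2, 0.05))     # exactly at alpha
  expect_true(significance_flag(-0.6, 0.04))   # sign-symmetric
})

test_that("changed_in_any is the union of per-contrast significant sets", {
  sim <- toy_simulation(n_proteins = 150, seed = 19)
  pg <- read_protein_groups(sim$protein_groups)
  ds <- suppressMessages(preprocess(pg, read_design(sim$design_file, pg),
                                    seed = 19))
  res <- fit_all_contrasts(ds)
  brute <- sort(unique(unlist(lapply(res, function(r) r$id[r$significant]))))
  expect_identical(changed_in_any(res), brute)
  # and volcano tables carry the same flags
  vt <- volcano_table(res[[1]])
  expect_identical(vt$significant, res[[1]]$significant)
  expect_equal(vt$minus_log10_padj, -log10(res[[1]]$padj))
})

test_that("all-pairs fitting produces one contrast per unordered pair", {
  sim <- toy_simulation(n_proteins = 80, seed = 29)
  pg <- read_protein_groups(sim$protein_groups)
  ds <- suppressMessages(preprocess(pg, read_design(sim$design_file, pg),
                                    seed = 29))
  res <- fit_all_contrasts(ds)
  expect_length(res, choose(4, 2))
  expect_true(all(grepl("_vs_", names(res))))
  # contrast export round-trips
  out <- tempfile(); dir.create(out)
  write_contrast_results(res, out)
  wide <- utils::read.delim(file.path(out, "contrasts_combined.tsv"))
  expect_equal(nrow(wide), nrow(res[[1]]))
  expect_equal(ncol(wide), 1 + 4 * length(res))
})

test_that("degenerate inputs are fatal", {
  ds <- make_ds(matrix(5, 4, 4), rep(c("A", "B"), each = 2))
  expect_error(fit_all_contrasts(ds), "zero residual variance")
  ds2 <- make_ds(matrix(rnorm(8), 2, 4), rep(c("A", "B"), each = 2),
                 stage = "filtered")
  expect_error(fit_all_contrasts(ds2), "imputed")
})
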