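long_fixture <- function() {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\treceptor\tpercentile",
               "Acot1\tPPAR\t99.5", "Ehhadh\tPPAR\t96", "Hmgcs2\tPPAR\t95",
               "Abcd1\tPPAR\t90", "Tsc22d3\tGR\t98", "Acot1\tGR\t60"), f)
  f
}

test_that("long- and wide-form consensome tables load identically", {
  ct <- load_consensome(long_fixture())
  expect_s3_class(ct, "consensome_table")
  expect_setequal(attr(ct, "receptors"), c("PPAR", "GR"))
  expect_equal(nrow(ct), 6)
  w <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tPPAR\tGR",
               "Acot1\t99.5\t60", "Ehhadh\t96\t", "Hmgcs2\t95\t",
               "Abcd1\t90\t", "Tsc22d3\t\t98"), w)
  cw <- load_consensome(w)
  get <- function(ct, g, r) ct$percentile[ct$gene == g & ct$receptor == r]
  expect_equal(get(cw, "Acot1", "PPAR"), 99.5)
  expect_equal(get(cw, "Tsc22d3", "GR"), 98)
  expect_length(get(cw, "Tsc22d3", "PPAR"), 0)
})

test_that("out-of-range percentiles are fatal; duplicates keep the maximum", {
  f <- tempfile()
  writeLines(c("gene\treceptor\tpercentile", "A\tPPAR\t101"), f)
  expect_error(load_consensome(f), "\\[0, 100\\]", class = "lfq_user_error")
  f2 <- tempfile()
  writeLines(c("gene\treceptor\tpercentile",
               "A\tPPAR\t90", "A\tPPAR\t97"), f2)
  expect_warning(ct <- load_consensome(f2), "duplicate")
  expect_equal(ct$percentile[ct$gene == "A"], 97)
})

test_that("percentile thresholding is inclusive and monotone", {
  ct <- load_consensome(long_fixture())
  gs <- threshold_targets(ct, "PPAR", 95)
  expect_setequal(gs$genes, c("Acot1", "Ehhadh", "Hmgcs2"))  # 95 included
  expect_setequal(threshold_targets(ct, "PPAR", 0)$genes,
                  c("Acot1", "Ehhadh", "Hmgcs2", "Abcd1"))
  expect_error(threshold_targets(ct, "NOPE"), "available",
               class = "lfq_user_error")
  # monotone: higher cutoff always selects a subset
  prev <- threshold_targets(ct, "PPAR", 0)$genes
  for (pct in c(50, 90, 95, 96, 99.5)) {
    cur <- threshold_targets(ct, "PPAR", pct)$genes
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("target extraction annotates per-receptor percentiles with blanks", {
  mat <- matrix(rnorm(16, 25), 4, 4)
  rownames(mat) <- c("Acot1", "Ehhadh", "Tsc22d3", "Other")
  ds <- make_ds(mat, rep(c("A", "B"), each = 2))
  ct <- load_consensome(long_fixture())
  gs <- threshold_targets(ct, "PPAR", 95)
  mr <- extract_targets(ds, gs, ct, pct = 95)
  exp_row <- function(g) mr$export[mr$export$id == g, ]
  # Acot1: above PPAR threshold, below GR threshold -> GR cell blank
  expect_equal(exp_row("Acot1")$pctl.PPAR, 99.5)
  expect_true(is.na(exp_row("Acot1")$pctl.GR))
  expect_length(mr$matched_ids, 2)
})

test_that("enrichment percentages follow the field's reporting precision", {
  detected <- sprintf("P%04d", 1:1918)
  targets <- detected[1:399]
  s <- enrichment_summary(character(0), character(0), detected, targets)
  expect_identical(s$base_rate_pct, 20.8)
  s2 <- enrichment_summary(detected[400:430], detected[500:531],
                           detected, c(targets, detected[500:508]))
  expect_identical(s2$n_down, 32L)
  expect_identical(s2$n_down_targets, 9L)
  expect_identical(s2$down_pct, 28)
  # targets covering everything detected
  s3 <- enrichment_summary(detected[1:5], character(0), detected, detected)
  expect_identical(s3$base_rate_pct, 100)
  expect_identical(s3$up_pct, 100)
  expect_error(enrichment_summary(character(0), character(0), character(0),
                                  targets), class = "lfq_user_error")
  expect_error(enrichment_summary("NOTDETECTED", character(0), detected,
                                  targets), "subset",
               class = "lfq_user_error")
})

test_that("hypergeometric p-values flag a target-enriched up-set", {
  detected <- sprintf("P%03d", 1:200)
  targets <- detected[1:40]                 # base rate 20%
  up_enr <- c(detected[1:15], detected[100:104])   # 15/20 targets
  s <- enrichment_summary(up_enr, character(0), detected, targets)
  expect_lt(s$p_up, 0.001)
  expect_identical(s$up_pct, 75)
  # oracle: stats::fisher.test one-sided
  tab <- matrix(c(15, 5, 40 - 15, 200 - 40 - 5), 2)
  expect_equal(s$p_up,
               stats::fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-12)
})

test_that("null draws keep the up-set target fraction near the base rate", {
  set.seed(113)
  detected <- sprintf("P%03d", 1:300)
  targets <- detected[1:60]                 # base rate 0.2
  n_sim <- 500
  ok <- 0L
  for (i in seq_len(n_sim)) {
    up <- sample(detected, 40)
    s <- enrichment_summary(up, character(0), detected, targets)
    frac <- s$n_up_targets / s$n_up
    sd3 <- 3 * sqrt(0.2 * 0.8 / 40)
    if (abs(frac - 0.2) <= sd3) ok <- ok + 1L
  }
  expect_gte(ok / n_sim, 0.99)
})

test_that("consensome overlap matches brute-force set algebra", {
  sets <- list(A = c("x", "y", "z"), B = c("z", "w"), C = c("q"))
  ov <- consensome_overlap(sets)
  expect_equal(ov$pairwise["A", "B"], 1L)
  expect_equal(ov$pairwise["A", "C"], 0L)
  expect_equal(diag(ov$pairwise), c(A = 3L, B = 2L, C = 1L))
  expect_setequal(ov$unique_targets$A, toupper(c("x", "y")))
  # identical sets: nothing unique
  ov2 <- consensome_overlap(list(A = c("x", "y"), B = c("x", "y")))
  expect_length(ov2$unique_targets$A, 0)
  # random sets vs brute force
  set.seed(127)
  for (i in 1:20) {
    ls <- lapply(1:3, function(j) sample(sprintf("g%02d", 1:30),
                                         sample(3:15, 1)))
    names(ls) <- c("R1", "R2", "R3")
    ov <- consensome_overlap(ls)
    for (a in names(ls)) for (b in names(ls)) {
      expect_equal(ov$pairwise[a, b],
                   length(intersect(toupper(ls[[a]]), toupper(ls[[b]]))))
    }
    for (a in names(ls)) {
      others <- toupper(unlist(ls[setdiff(names(ls), a)]))
      expect_setequal(ov$unique_targets[[a]],
                      setdiff(toupper(ls[[a]]), others))
    }
  }
})
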