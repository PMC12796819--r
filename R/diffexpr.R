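# All-pairwise differential testing with empirical-Bayes variance
# moderation and Benjamini-Hochberg FDR.
#
# Per contrast, the two groups' residual variances are pooled
# (df d = n1 + n2 - 2) and shrunk towards a prior:
#   s_tilde^2 = (d0 * s0^2 + d * s^2) / (d0 + d)
# with (d0, s0^2) estimated across proteins by method of moments on
# log s^2, using
#   E[log s^2]   = log s0^2 + psi(d/2) - log(d/2) - psi(d0/2) + log(d0/2)
#   Var[log s^2] = psi'(d/2) + psi'(d0/2)
# (psi = digamma, psi' = trigamma). The moderated t has d + d0 degrees of
# freedom; d0 = 0 recovers the ordinary pooled two-sample t.

# Invert the trigamma function by Newton iteration on 1/trigamma (which is
# nearly linear); asymptotic shortcuts at the extremes.
trigamma_inverse <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# Method-of-moments prior for the variance distribution. Returns
# list(d0, s0sq); d0 = Inf when the observed log-variance spread is no wider
# than sampling noise alone (all true variances equal).
estimate_var_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2L) stop("too few positive residual variances to moderate")
  e <- log(s2)
  excess <- stats::var(e) - trigamma(df / 2)
  if (excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0sq <- exp(mean(e) - digamma(df / 2) + log(df / 2) +
                  digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0sq <- exp(mean(e) - digamma(df / 2) + log(df / 2))
  }
  list(d0 = d0, s0sq = s0sq)
}

#' Moderated (or ordinary) two-sample t-test for one contrast
#'
#' @param x1,x2 numeric matrices (proteins x replicates) for the numerator
#'   and denominator condition.
#' @param moderated logical; \code{FALSE} gives the ordinary pooled t
#'   (\code{d0 = 0}).
#' @return data.frame with \code{log2fc}, \code{t}, \code{p}; attributes
#'   \code{d0}, \code{s0sq}, \code{df_total}.
#' @keywords internal
moderated_t <- function(x1, x2, moderated = TRUE) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  stopifnot(n1 >= 2L, n2 >= 2L, nrow(x1) == nrow(x2))
  d <- n1 + n2 - 2
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  if (all(s2 == 0)) stop("zero residual variance for every protein; degenerate input")
  log2fc <- m1 - m2
  if (moderated) {
    prior <- estimate_var_prior(s2, d)
    d0 <- prior$d0; s0sq <- prior$s0sq
    s2_post <- if (is.infinite(d0)) rep(s0sq, length(s2)) else
      (d0 * s0sq + d * s2) / (d0 + d)
  } else {
    d0 <- 0; s0sq <- NA_real_
    s2_post <- s2
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- log2fc / se
  p <- 2 * stats::pt(-abs(tstat), df = d + d0)
  out <- data.frame(log2fc = log2fc, t = tstat, p = p)
  attr(out, "d0") <- d0
  attr(out, "s0sq") <- s0sq
  attr(out, "df_total") <- d + d0
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a vector of p-values; a thin wrapper around
#' \code{stats::p.adjust(method = "BH")} that validates its input.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1] and not be NA")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Significance rule for volcano plots and DEP calling
#'
#' A protein is significant when its adjusted p-value is strictly below
#' \code{alpha} and its absolute log2 fold change is strictly above
#' \code{lfc_cutoff}; values exactly at either cutoff are not flagged.
#'
#' @param log2fc,padj numeric vectors.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param lfc_cutoff absolute log2 fold-change cutoff (default 0.5).
#' @return logical vector.
#' @export
significance_flag <- function(log2fc, padj, alpha = 0.05,
                              lfc_cutoff = 0.5) {
  padj < alpha & abs(log2fc) > lfc_cutoff
}

#' Fit all pairwise condition contrasts
#'
#' For every unordered pair of conditions a moderated t-test is computed per
#' protein, with BH adjustment within each contrast. A protein is flagged
#' significant when \code{padj < alpha} and \code{|log2fc| > lfc_cutoff}
#' (both strict). The default contrast direction is lexicographic: for a
#' pair \{a, b\} with a < b the contrast is \code{"a_vs_b"} with numerator a
#' and denominator b (\code{log2fc = mean(a) - mean(b)}).
#'
#' @param ds an imputed \code{expression_dataset}.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param lfc_cutoff absolute log2 fold-change cutoff (default 0.5).
#' @param moderated logical; empirical-Bayes moderation on by default.
#' @param contrasts optional list of \code{c(numerator, denominator)} pairs
#'   overriding the all-pairs lexicographic default.
#' @return a named list of \code{contrast_result} data.frames (class
#'   \code{contrast_results}), each with columns \code{id}, \code{log2fc},
#'   \code{t}, \code{p}, \code{padj}, \code{significant} and attributes
#'   \code{numerator}, \code{denominator}, \code{alpha}, \code{lfc_cutoff},
#'   \code{d0}, \code{s0sq}.
#' @export
fit_all_contrasts <- function(ds, alpha = 0.05, lfc_cutoff = 0.5,
                              moderated = TRUE, contrasts = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$stage != "imputed") stop("contrasts require an imputed dataset")
  reps <- table(ds$design$condition)
  if (any(reps < 2L)) {
    stop_user("condition(s) with < 2 replicates: ",
              paste(names(reps)[reps < 2], collapse = ", "))
  }
  conds <- sort(unique(ds$design$condition))
  if (is.null(contrasts)) {
    contrasts <- list()
    for (i in seq_along(conds)) {
      for (j in seq_along(conds)) {
        if (i < j) contrasts <- c(contrasts, list(c(conds[i], conds[j])))
      }
    }
  }
  cols <- condition_columns(ds)
  out <- list()
  for (ct in contrasts) {
    num <- ct[1]; den <- ct[2]
    if (!num %in% conds || !den %in% conds) {
      stop_user("unknown condition in contrast ", num, "_vs_", den,
                "; available: ", paste(conds, collapse = ", "))
    }
    fit <- moderated_t(ds$mat[, cols[[num]], drop = FALSE],
                       ds$mat[, cols[[den]], drop = FALSE],
                       moderated = moderated)
    res <- data.frame(id = ds$ids, log2fc = fit$log2fc, t = fit$t,
                      p = fit$p, padj = bh_adjust(fit$p),
                      stringsAsFactors = FALSE, row.names = NULL)
    res$significant <- significance_flag(res$log2fc, res$padj, alpha,
                                         lfc_cutoff)
    attr(res, "numerator") <- num
    attr(res, "denominator") <- den
    attr(res, "alpha") <- alpha
    attr(res, "lfc_cutoff") <- lfc_cutoff
    attr(res, "d0") <- attr(fit, "d0")
    attr(res, "s0sq") <- attr(fit, "s0sq")
    attr(res, "df_total") <- attr(fit, "df_total")
    class(res) <- c("contrast_result", "data.frame")
    out[[paste0(num, "_vs_", den)]] <- res
  }
  structure(out, class = "contrast_results")
}

#' @export
print.contrast_results <- function(x, ...) {
  cat("contrast_results:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-30s %5d significant of %d\n", nm,
                sum(x[[nm]]$significant), nrow(x[[nm]])))
  }
  invisible(x)
}

#' Proteins significant in at least one contrast
#'
#' @param results a \code{contrast_results} list.
#' @return character vector of protein ids (the differentially expressed
#'   set).
#' @export
changed_in_any <- function(results) {
  stopifnot(inherits(results, "contrast_results"))
  ids <- unlist(lapply(results, function(r) r$id[r$significant]),
                use.names = FALSE)
  sort(unique(ids))
}

#' Volcano-plot table for one contrast
#'
#' @param result a \code{contrast_result}.
#' @return data.frame of \code{id}, \code{log2fc}, \code{minus_log10_padj},
#'   \code{significant}.
#' @export
volcano_table <- function(result) {
  stopifnot(inherits(result, "contrast_result"))
  data.frame(id = result$id, log2fc = result$log2fc,
             minus_log10_padj = -log10(result$padj),
             significant = result$significant, stringsAsFactors = FALSE)
}

#' Write per-contrast and combined result tables
#'
#' One TSV per contrast (id, log2fc, p, padj, significant) plus a combined
#' wide table with one column group per contrast.
#'
#' @param results a \code{contrast_results}.
#' @param dir output directory (created if needed).
#' @return paths written, invisibly.
#' @export
write_contrast_results <- function(results, dir) {
  stopifnot(inherits(results, "contrast_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wide <- data.frame(id = results[[1]]$id, stringsAsFactors = FALSE)
  for (nm in names(results)) {
    r <- results[[nm]]
    p <- file.path(dir, paste0("contrast_", nm, ".tsv"))
    write_tsv(r[c("id", "log2fc", "p", "padj", "significant")], p)
    paths <- c(paths, p)
    for (col in c("log2fc", "p", "padj", "significant")) {
      wide[[paste0(nm, ".", col)]] <- r[[col]]
    }
  }
  p <- file.path(dir, "contrasts_combined.tsv")
  write_tsv(wide, p)
  invisible(c(paths, p))
}
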