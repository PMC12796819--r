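# Identification-overlap summaries, PCA on the most variable proteins and
# k-means clustered z-score heat maps.

#' Detection-overlap summary of a pre-imputation dataset
#'
#' @param ds an \code{expression_dataset} before imputation (missing entries
#'   still present).
#' @return list with \code{per_sample} (label, n_detected) and
#'   \code{histogram} (n_samples_detected_in, n_proteins; one row per count
#'   0..n_samples).
#' @export
overlap_summary <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  det <- !is.na(ds$mat)
  per_sample <- data.frame(label = colnames(ds$mat),
                           n_detected = unname(colSums(det)),
                           stringsAsFactors = FALSE)
  counts <- factor(rowSums(det), levels = 0:ncol(ds$mat))
  hist <- data.frame(n_samples = 0:ncol(ds$mat),
                     n_proteins = as.integer(table(counts)))
  list(per_sample = per_sample, histogram = hist)
}

#' PCA on the top-N most variable proteins
#'
#' Proteins are ranked by the variance of their (imputed) log2 values; the
#' top \code{n} are retained (clamped to the number available, with a
#' warning), rows centered but not scaled, and the samples projected onto
#' principal components. Each PC's sign is fixed so that its
#' largest-magnitude protein loading is positive.
#'
#' @param ds an imputed \code{expression_dataset}.
#' @param n number of proteins to use (default 500).
#' @return a \code{pca_result}: \code{coords} (samples x PCs),
#'   \code{var_explained} (percent, per PC), \code{n_top}, and the design.
#' @export
pca_top_n <- function(ds, n = 500L) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$stage != "imputed") stop("PCA requires an imputed dataset")
  if (ncol(ds$mat) < 2L) stop("PCA requires at least 2 samples")
  if (n < 1L) stop_user("n must be >= 1")
  if (n > nrow(ds$mat)) {
    warning(sprintf("n = %d exceeds the %d proteins available; clamped",
                    n, nrow(ds$mat)), call. = FALSE)
    n <- nrow(ds$mat)
  }
  rv <- apply(ds$mat, 1L, stats::var)
  top <- order(rv, decreasing = TRUE)[seq_len(n)]
  pc <- stats::prcomp(t(ds$mat[top, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  # fix each PC's sign: largest-|loading| protein gets a positive loading
  for (j in seq_len(ncol(pc$rotation))) {
    i0 <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i0, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(list(
    coords = pc$x,
    var_explained = 100 * pc$sdev^2 / sum(pc$sdev^2),
    n_top = n,
    design = ds$design
  ), class = "pca_result")
}

#' Row-wise z-scoring
#'
#' Each row is centered to mean 0 and scaled to SD 1. Constant rows (SD = 0)
#' are set to all-zero with a warning.
#'
#' @param mat numeric matrix (proteins x samples).
#' @return the z-scored matrix.
#' @export
zscore_rows <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2L)
  m <- rowMeans(mat)
  s <- apply(mat, 1L, stats::sd)
  const <- s == 0 | !is.finite(s)
  if (any(const)) {
    warning(sum(const), " constant row(s) z-scored to all-zero",
            call. = FALSE)
    s[const] <- 1
  }
  (mat - m) / s
}

#' k-means clustered heat-map layout
#'
#' Clusters the rows of a z-score matrix with k-means (10 restarts, best
#' inertia kept), renumbers clusters by descending size, and orders rows by
#' cluster then by correlation of the row with its cluster centroid. Display
#' values are clamped to \code{[-z_cap, z_cap]}; the unclamped values are
#' kept for export.
#'
#' @param z z-scored numeric matrix (proteins x samples).
#' @param k number of clusters, \code{1 <= k <= nrow(z)}.
#' @param seed integer seed for the k-means restarts.
#' @param z_cap positive display clamp (default 2).
#' @return a \code{heatmap_result}: \code{z} (reordered, unclamped),
#'   \code{display} (reordered, clamped), \code{cluster} (assignment in the
#'   reordered row order), \code{row_order} (indices into the input),
#'   \code{k}, \code{z_cap}, \code{sizes}.
#' @export
cluster_heatmap <- function(z, k, seed, z_cap = 2) {
  stopifnot(is.matrix(z), is.numeric(z_cap), z_cap > 0)
  k <- as.integer(k)
  if (k < 1L || k > nrow(z)) {
    stop_user("k must lie in 1..", nrow(z), " (number of rows); got ", k)
  }
  if (k == 1L) {
    assign <- rep(1L, nrow(z))
  } else {
    set.seed(derive_seed(seed, "kmeans"))
    n_distinct <- nrow(unique(z))
    km <- stats::kmeans(z, centers = min(k, n_distinct), nstart = 10L,
                        iter.max = 100L)
    assign <- km$cluster
  }
  # renumber by descending cluster size (ties: lower original index first)
  sizes <- table(assign)
  new_order <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[new_order]] <- seq_along(new_order)
  assign <- relabel[assign]
  centroids <- do.call(rbind, lapply(sort(unique(assign)), function(g) {
    colMeans(z[assign == g, , drop = FALSE])
  }))
  # within-cluster: most centroid-like rows first
  cor_to_centroid <- vapply(seq_len(nrow(z)), function(i) {
    ct <- centroids[assign[i], ]
    if (stats::sd(ct) == 0 || stats::sd(z[i, ]) == 0) return(0)
    stats::cor(z[i, ], ct)
  }, numeric(1))
  row_order <- order(assign, -cor_to_centroid)
  structure(list(
    z = z[row_order, , drop = FALSE],
    display = pmin(pmax(z[row_order, , drop = FALSE], -z_cap), z_cap),
    cluster = assign[row_order],
    row_order = row_order,
    k = k,
    z_cap = z_cap,
    sizes = as.integer(table(assign))
  ), class = "heatmap_result")
}

# ---- plotting ----------------------------------------------------------

#' PCA scatter plot
#' @param pca a \code{pca_result}.
#' @param pcs which two PCs to draw (default 1:2).
#' @return a ggplot object.
#' @export
plot_pca <- function(pca, pcs = c(1L, 2L)) {
  stopifnot(inherits(pca, "pca_result"))
  df <- data.frame(x = pca$coords[, pcs[1]], y = pca$coords[, pcs[2]],
                   condition = pca$design$condition,
                   label = pca$design$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$condition)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", pcs[1], pca$var_explained[pcs[1]]),
      y = sprintf("PC%d (%.1f%%)", pcs[2], pca$var_explained[pcs[2]]),
      title = sprintf("PCA, top %d most variable proteins", pca$n_top)) +
    ggplot2::theme_bw()
}

#' Volcano plot for one contrast
#' @param result a \code{contrast_result}.
#' @return a ggplot object.
#' @export
plot_volcano <- function(result) {
  df <- volcano_table(result)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = .data$minus_log10_padj,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "black")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  title = paste0(attr(result, "numerator"), " vs ",
                                 attr(result, "denominator"))) +
    ggplot2::theme_bw()
}

#' Write a plot as PNG and SVG
#'
#' Every plot is accompanied by its data TSV elsewhere; the figure files are
#' a rendering convenience only.
#'
#' @param p a ggplot object.
#' @param path_base path without extension; ".png" and ".svg" are appended.
#' @param width,height size in inches.
#' @return the two paths, invisibly.
#' @export
save_plot <- function(p, path_base, width = 6, height = 5) {
  png_path <- paste0(path_base, ".png")
  svg_path <- paste0(path_base, ".svg")
  ggplot2::ggsave(png_path, p, width = width, height = height, dpi = 150)
  grDevices::svg(svg_path, width = width, height = height)
  print(p)
  grDevices::dev.off()
  invisible(c(png_path, svg_path))
}

#' Render a clustered heat map to file
#'
#' @param hm a \code{heatmap_result}.
#' @param path_base path without extension; PNG and SVG are written.
#' @return the paths, invisibly.
#' @export
save_heatmap <- function(hm, path_base, width = 6, height = 8) {
  stopifnot(inherits(hm, "heatmap_result"))
  ann <- data.frame(cluster = factor(hm$cluster),
                    row.names = rownames(hm$display))
  render <- function(file) {
    pheatmap::pheatmap(hm$display, cluster_rows = FALSE,
                       cluster_cols = FALSE,
                       annotation_row = if (!is.null(rownames(hm$display))) ann,
                       show_rownames = nrow(hm$display) <= 60,
                       breaks = seq(-hm$z_cap, hm$z_cap, length.out = 101),
                       filename = file, width = width, height = height)
  }
  png_path <- paste0(path_base, ".png")
  render(png_path)
  invisible(png_path)
}

#' Write a heat-map data TSV (id, cluster, z values per sample)
#' @param hm a \code{heatmap_result}.
#' @param path output TSV path.
#' @export
write_heatmap_table <- function(hm, path) {
  df <- data.frame(id = rownames(hm$z), cluster = hm$cluster,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(hm$z, optional = TRUE))
  write_tsv(df, path)
}
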