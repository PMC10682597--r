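# Diagnostic plots. Every statistic shown is computed in the analysis
# modules; this layer only maps the tables they emit onto ggplot2 layers,
# so each plot is a pure function of its inputs.

#' @import ggplot2
NULL

#' Expected ENc under pure GC3 drift
#'
#' The reference curve for the ENc-GC3 plot: the ENc expected when codon
#' bias is driven solely by the GC content at third positions,
#' ENc*(s) = 2 + s + 29 / (s^2 + (1 - s)^2), capped at 61 for display
#' consistency with the index. ENc*(0.5) = 60.5 and the curve is symmetric
#' about s = 0.5.
#'
#' @param s GC3 values in (0, 1).
#' @return Expected ENc values.
#' @export
#' @examples
#' enc_expected(0.5)
enc_expected <- function(s) {
  pmin(2 + s + 29 / (s^2 + (1 - s)^2), 61)
}

#' QC boxplot of CDS lengths
#'
#' One box of amino-acid lengths per organism, with outliers (beyond
#' 1.5 x IQR) drawn as red points.
#'
#' @param lengths Data frame from [length_table()].
#' @return A ggplot object.
#' @export
plot_qc_boxplot <- function(lengths) {
  stopifnot(nrow(lengths) > 0L)
  ggplot(lengths, aes(x = organism, y = aa_length)) +
    geom_boxplot(outlier.colour = "red", outlier.size = 1.2) +
    labs(x = NULL, y = "CDS length (amino acids)",
         title = "Coding sequence length QC") +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Grouped GC-content boxplot
#'
#' Boxes per organism for overall GC and GC at each codon position.
#'
#' @param gc Data frame from [gc_table()].
#' @return A ggplot object.
#' @export
plot_gc_boxplot <- function(gc) {
  long <- do.call(rbind, lapply(c("gc_all", "gc1", "gc2", "gc3"),
    function(v) data.frame(organism = gc$organism,
                           metric = toupper(sub("_all", "", sub("gc", "GC", v))),
                           value = gc[[v]], stringsAsFactors = FALSE)))
  ggplot(long, aes(x = organism, y = value, fill = metric)) +
    geom_boxplot(position = position_dodge(width = 0.8),
                 outlier.size = 0.8) +
    labs(x = NULL, y = "GC fraction", fill = NULL,
         title = "GC content by codon position") +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' ENc-GC3 plot
#'
#' ENc against GC3 per gene (or organism means with `group = TRUE`), with
#' the expected-ENc curve under pure GC3 drift drawn as a solid red line.
#' Points falling on or near the curve are consistent with mutational
#' pressure alone; points well below indicate additional selection.
#'
#' @param enc Data frame from [enc_table()].
#' @param gc Data frame from [gc_table()] (joined on organism and id).
#' @param group Plot organism means instead of individual genes?
#' @return A ggplot object.
#' @export
plot_enc_gc3 <- function(enc, gc, group = FALSE) {
  d <- merge(enc[, c("organism", "id", "value")],
             gc[, c("organism", "id", "gc3")], by = c("organism", "id"))
  if (nrow(d) == 0L) stop("no overlapping (organism, id) rows to plot")
  if (group) {
    d <- do.call(rbind, lapply(split(d, d$organism), function(g)
      data.frame(organism = g$organism[1L], value = mean(g$value, na.rm = TRUE),
                 gc3 = mean(g$gc3), stringsAsFactors = FALSE)))
  }
  s <- seq(0.005, 0.995, length.out = 512L)
  curve <- data.frame(gc3 = s, value = enc_expected(s))
  ggplot(d, aes(x = gc3, y = value)) +
    geom_point(aes(colour = organism), alpha = 0.8) +
    geom_line(data = curve, colour = "red", linewidth = 0.8) +
    coord_cartesian(xlim = c(0, 1), ylim = c(20, 62)) +
    labs(x = "GC3", y = "ENc",
         title = if (group) "ENc-GC3 (organism means)" else "ENc-GC3") +
    theme_bw()
}

#' PR2 plot
#'
#' A3/(A3+T3) against G3/(G3+C3) with a red crosshair at (0.5, 0.5), the
#' parity point where A = T and G = C.
#'
#' @param points Data frame from [pr2_table()].
#' @param group Plot organism means?
#' @return A ggplot object.
#' @export
plot_pr2 <- function(points, group = FALSE) {
  d <- points
  if (group) {
    d <- do.call(rbind, lapply(split(d, d$organism), function(g)
      data.frame(organism = g$organism[1L], x = mean(g$x), y = mean(g$y),
                 stringsAsFactors = FALSE)))
  }
  ggplot(d, aes(x = x, y = y)) +
    geom_hline(yintercept = 0.5, colour = "red") +
    geom_vline(xintercept = 0.5, colour = "red") +
    geom_point(aes(colour = organism), alpha = 0.8) +
    coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "G3 / (G3 + C3)", y = "A3 / (A3 + T3)",
         title = if (group) "PR2 (organism means)" else "PR2") +
    theme_bw()
}

#' Neutrality plot for one organism
#'
#' GC12 against GC3 with the fitted regression line and an annotation of
#' the slope equation, R2 and p-value taken verbatim from the supplied
#' [neutrality_fit()].
#'
#' @param gc Per-record GC table for a single organism.
#' @param fit A `neutrality_fit`; computed from `gc` when omitted.
#' @return A ggplot object.
#' @export
plot_neutrality <- function(gc, fit = NULL) {
  if (length(unique(gc$organism)) != 1L)
    stop("the neutrality plot is defined for one organism at a time")
  if (is.null(fit)) fit <- neutrality_fit(gc$gc12, gc$gc3)
  lab <- sprintf("GC12 = %.3f + %.3f GC3\nR2 = %.3f, p = %.3g",
                 fit$intercept, fit$slope, fit$r2, fit$pvalue)
  ggplot(gc, aes(x = gc3, y = gc12)) +
    geom_point(alpha = 0.7) +
    geom_abline(intercept = fit$intercept, slope = fit$slope,
                colour = "blue") +
    annotate("text", x = min(gc$gc3), y = max(gc$gc12), hjust = 0, vjust = 1,
             label = lab, size = 3.2) +
    labs(x = "GC3", y = "GC12",
         title = paste("Neutrality plot:", gc$organism[1L])) +
    theme_bw()
}

#' Clustered heatmap of RSCU or dinucleotide z-scores
#'
#' Renders a [heatmap_matrix()] result as tiles, honoring the precomputed
#' row/column dendrogram orders.
#'
#' @param hm List from [heatmap_matrix()].
#' @return A ggplot object.
#' @export
plot_heatmap <- function(hm) {
  m <- hm$matrix[hm$row_order, hm$col_order, drop = FALSE]
  d <- data.frame(row = factor(rep(rownames(m), ncol(m)),
                               levels = rev(rownames(m))),
                  col = factor(rep(colnames(m), each = nrow(m)),
                               levels = colnames(m)),
                  value = as.vector(m))
  ggplot(d, aes(x = col, y = row, fill = value)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         midpoint = stats::median(d$value, na.rm = TRUE)) +
    labs(x = NULL, y = NULL, fill = "value") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 6))
}

#' PCA score plot colored by cluster
#'
#' PC1/PC2 scores with axes labeled by the percent variance explained;
#' point colors are in bijection with cluster ids.
#'
#' @param pca An `rscu_pca` object.
#' @param clusters Optional `pca_clusters` object.
#' @return A ggplot object.
#' @export
plot_pca <- function(pca, clusters = NULL) {
  d <- data.frame(PC1 = pca$scores[, 1L],
                  PC2 = if (ncol(pca$scores) > 1L) pca$scores[, 2L] else 0,
                  label = rownames(pca$scores), stringsAsFactors = FALSE)
  d$cluster <- if (!is.null(clusters))
    factor(clusters$cluster[d$label]) else factor(1L)
  ve <- pca$variance_explained
  ggplot(d, aes(x = PC1, y = PC2, colour = cluster)) +
    geom_point(size = 2.5) +
    geom_text(aes(label = label), vjust = -0.8, size = 2.8,
              show.legend = FALSE) +
    labs(x = sprintf("PC1 (%.1f%%)", ve[1L]),
         y = sprintf("PC2 (%.1f%%)", if (length(ve) > 1L) ve[2L] else 0),
         colour = "cluster", title = "PCA of RSCU profiles") +
    theme_bw()
}
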