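# Multivariate analysis of RSCU profiles: the organisms-by-codons matrix,
# PCA with deterministic component signs, clustering on PCA scores, and
# clustered heatmap matrices shared with the plotting layer.

#' Build the organisms-by-codons RSCU matrix
#'
#' One row per parasite organism (organism-mean RSCU) plus one host row;
#' codons in the exclusion list are dropped (default: start, stops and Trp,
#' leaving the 59 family codons).
#'
#' @param collections Parasite `cds_collection`(s).
#' @param host Optional host `cds_collection` appended as a final row.
#' @param exclude Codons to drop (default `c("ATG","TAA","TAG","TGA","TGG")`).
#' @param per_sequence Use one row per sequence instead of organism means?
#' @return Numeric matrix, rows named by organism (or organism/id).
#' @export
build_rscu_matrix <- function(collections, host = NULL,
                              exclude = DEFAULT_EXCLUDE,
                              per_sequence = FALSE) {
  collections <- as_collection_list(collections)
  if (per_sequence) {
    tab <- rscu_table(collections)
    m <- as.matrix(tab[, FAMILY_CODONS, drop = FALSE])
    rownames(m) <- paste(tab$organism, tab$id, sep = "/")
  } else {
    m <- t(vapply(collections, organism_mean_rscu,
                  numeric(length(FAMILY_CODONS))))
    rownames(m) <- vapply(collections, `[[`, character(1), "name")
  }
  if (!is.null(host)) {
    stopifnot(inherits(host, "cds_collection"))
    hrow <- as.numeric(rscu(codon_counts(host)))
    m <- rbind(m, host = hrow)
    rownames(m)[nrow(m)] <- host$name
  }
  keep <- setdiff(colnames(m), exclude)
  if (length(keep) == 0L) stop("exclusion list removes every codon column")
  m[, keep, drop = FALSE]
}

#' PCA of an RSCU matrix
#'
#' Centered (by default unscaled) principal component analysis. RSCU is
#' already normalized within synonymous families, so scaling to unit
#' variance — which would overweight rare families — is off by default.
#' Component signs are fixed by forcing the largest-magnitude loading of
#' each component to be positive, making scores reproducible across linear
#' algebra backends.
#'
#' @param mat Matrix from [build_rscu_matrix()] (>= 2 rows).
#' @param center,scale. Passed to [stats::prcomp()].
#' @return Object of class `rscu_pca`: list with `scores`, `loadings`,
#'   `variance_explained` (percent, summing to 100 over all components) and
#'   the underlying `prcomp` fit.
#' @export
pca_rscu <- function(mat, center = TRUE, scale. = FALSE) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  if (all(apply(mat, 2L, stats::sd) == 0))
    stop("RSCU matrix is constant; PCA undefined")
  if (scale.) {
    keep <- apply(mat, 2L, stats::sd) > 0
    mat <- mat[, keep, drop = FALSE]
  }
  fit <- stats::prcomp(mat, center = center, scale. = scale.)
  for (j in seq_len(ncol(fit$rotation))) {
    i <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  ve <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = fit$x, loadings = fit$rotation,
                 variance_explained = ve, prcomp = fit),
            class = "rscu_pca")
}

#' @export
print.rscu_pca <- function(x, ...) {
  cat(sprintf("<rscu_pca> %d rows, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores), x$variance_explained[1L],
              if (length(x$variance_explained) > 1L)
                x$variance_explained[2L] else 0))
  invisible(x)
}

#' Cluster organisms on PCA scores
#'
#' K-means (with multiple restarts under the given seed) or hierarchical
#' clustering on the first `rank` principal component scores. The
#' hierarchical route accepts the usual distance names and the
#' "ward.D"/"ward.D2" linkage spellings (Ward on squared vs unsquared
#' Euclidean distances).
#'
#' @param pca An `rscu_pca` object.
#' @param k Number of clusters (>= 1, <= rows).
#' @param rank Number of leading components to use.
#' @param method `"kmeans"` or `"hierarchical"`.
#' @param metric Distance for hierarchical clustering.
#' @param linkage Linkage for hierarchical clustering.
#' @param seed Integer seed for k-means restarts.
#' @return Object of class `pca_clusters`: list with `cluster` (named
#'   integer vector), `k`, `rank`, `method`, `metric`, `linkage`.
#' @export
cluster_on_pca <- function(pca, k, rank = 2L,
                           method = c("kmeans", "hierarchical"),
                           metric = "euclidean", linkage = "ward.D2",
                           seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(pca, "rscu_pca"), k >= 1L,
            rank >= 1L, rank <= ncol(pca$scores))
  x <- pca$scores[, seq_len(rank), drop = FALSE]
  if (k > nrow(x)) stop("k exceeds the number of rows")
  if (method == "kmeans") {
    set.seed(as.integer(seed))
    cl <- stats::kmeans(x, centers = k, nstart = 25L)$cluster
  } else {
    hc <- stats::hclust(stats::dist(x, method = metric), method = linkage)
    cl <- stats::cutree(hc, k = k)
  }
  structure(list(cluster = cl, k = as.integer(k), rank = as.integer(rank),
                 method = method, metric = metric, linkage = linkage),
            class = "pca_clusters")
}

#' Matrix and dendrogram orders for a clustered heatmap
#'
#' Prepares RSCU or dinucleotide z-score tables for heatmap display:
#' optionally collapses rows to organism means, then orders rows/columns by
#' hierarchical clustering with the named distance and linkage. Undefined
#' cells (`NA` z-scores) are handled pairwise by the distance computation;
#' rows that are entirely undefined are dropped with a warning.
#'
#' @param values Data frame with `organism`, optional `id`, and numeric
#'   value columns (RSCU codons or dinucleotide z-scores).
#' @param average_per_organism Collapse to organism means?
#' @param cluster_rows,cluster_cols Cluster each margin?
#' @param distance Distance name for [stats::dist()].
#' @param method Linkage name for [stats::hclust()] (`"ward.D"`,
#'   `"ward.D2"`, `"complete"`, ...).
#' @return List: `matrix`, `row_order`, `col_order`, and the `hclust`
#'   objects (`NULL` for unclustered margins).
#' @export
heatmap_matrix <- function(values, average_per_organism = FALSE,
                           cluster_rows = TRUE, cluster_cols = TRUE,
                           distance = "euclidean", method = "ward.D2") {
  num_cols <- names(values)[vapply(values, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("permutations", "seed"))
  m <- as.matrix(values[, num_cols, drop = FALSE])
  rownames(m) <- if (!is.null(values$id) && !average_per_organism)
    paste(values$organism, values$id, sep = "/") else values$organism
  if (average_per_organism) {
    m <- do.call(rbind, lapply(split(as.data.frame(m), values$organism),
                               function(d) colMeans(as.matrix(d),
                                                    na.rm = TRUE)))
  }
  all_na <- apply(m, 1L, function(r) all(!is.finite(r)))
  if (any(all_na)) {
    warning("dropping ", sum(all_na), " all-undefined row(s)",
            call. = FALSE)
    m <- m[!all_na, , drop = FALSE]
  }
  row_hc <- col_hc <- NULL
  row_order <- seq_len(nrow(m)); col_order <- seq_len(ncol(m))
  if (cluster_rows && nrow(m) > 1L) {
    row_hc <- stats::hclust(stats::dist(m, method = distance),
                            method = method)
    row_order <- row_hc$order
  }
  if (cluster_cols && ncol(m) > 1L) {
    col_hc <- stats::hclust(stats::dist(t(m), method = distance),
                            method = method)
    col_order <- col_hc$order
  }
  list(matrix = m, row_order = row_order, col_order = col_order,
       row_hclust = row_hc, col_hclust = col_hc)
}
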