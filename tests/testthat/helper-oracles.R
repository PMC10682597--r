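# Independent brute-force oracles: step-by-step transcriptions of the
# published formulas, written without reusing the package's family tables
# or internal helpers, for equivalence tests on fixed toy inputs.

oracle_code <- Biostrings::GENETIC_CODE
oracle_families <- local({
  fam <- split(names(oracle_code), oracle_code)
  fam[["*"]] <- NULL
  fam[lengths(fam) > 1L]
})

oracle_enc_wright <- function(counts) {
  Fs <- data.frame(k = integer(), F = numeric())
  for (aa in names(oracle_families)) {
    cods <- oracle_families[[aa]]
    n <- sum(counts[cods])
    if (n < 2) next
    p <- counts[cods] / n
    Fs <- rbind(Fs, data.frame(k = length(cods),
                               F = (n * sum(p^2) - 1) / (n - 1)))
  }
  avg <- function(k) mean(Fs$F[Fs$k == k])
  F2 <- avg(2); F3 <- avg(3); F4 <- avg(4); F6 <- avg(6)
  if (is.nan(F3)) F3 <- (F2 + F4) / 2
  enc <- 2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6
  min(enc, 61)
}

# family pseudocount on the reference, as documented for the package
oracle_ref_pseudo <- function(ref) {
  for (aa in names(oracle_families)) {
    cods <- oracle_families[[aa]]
    if (any(ref[cods] == 0)) ref[cods] <- ref[cods] + 1
  }
  ref
}

oracle_milc <- function(counts, ref) {
  ref <- oracle_ref_pseudo(ref)
  L <- 0; Msum <- 0; corr_df <- 0
  for (aa in names(oracle_families)) {
    cods <- oracle_families[[aa]]
    n <- sum(counts[cods])
    L <- L + n
    if (n == 0) next
    f <- counts[cods] / n
    g <- ref[cods] / sum(ref[cods])
    use <- counts[cods] > 0
    Msum <- Msum + 2 * sum(counts[cods][use] * log(f[use] / g[use]))
    corr_df <- corr_df + (length(cods) - 1)
  }
  Msum / L - (corr_df / L - 0.5)
}

oracle_b <- function(counts, ref) {
  ref <- oracle_ref_pseudo(ref)
  L <- 0
  for (aa in names(oracle_families)) L <- L + sum(counts[oracle_families[[aa]]])
  total <- 0
  for (aa in names(oracle_families)) {
    cods <- oracle_families[[aa]]
    n <- sum(counts[cods])
    if (n == 0) next
    g <- ref[cods] / sum(ref[cods])
    total <- total + (n / L) * sum(abs(counts[cods] / n - g))
  }
  total
}

oracle_rscu <- function(counts) {
  out <- c()
  for (aa in names(oracle_families)) {
    cods <- oracle_families[[aa]]
    tot <- sum(counts[cods])
    v <- if (tot == 0) rep(0, length(cods))
         else counts[cods] / (tot / length(cods))
    out <- c(out, stats::setNames(v, cods))
  }
  out[sort(names(out))]
}

# PCA via explicit eigendecomposition of the covariance of centered rows
oracle_pca_scores <- function(m) {
  mc <- scale(m, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(mc), symmetric = TRUE)
  mc %*% ev$vectors
}

# naive agglomerative clustering (single or complete linkage): returns the
# sorted merge heights
oracle_linkage_heights <- function(d, linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  diag(d) <- Inf
  groups <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(groups) > 1L) {
    best <- c(1L, 2L); best_h <- Inf
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      pair_d <- d[groups[[i]], groups[[j]], drop = FALSE]
      h <- if (linkage == "single") min(pair_d) else max(pair_d)
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    groups[[best[1L]]] <- c(groups[[best[1L]]], groups[[best[2L]]])
    groups[[best[2L]]] <- NULL
  }
  sort(heights)
}
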