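# Gene-level codon usage bias indices. All functions work on 64-codon count
# vectors (see codon_counts()); per-collection wrappers return tidy
# data frames (organism, id, value, reference_used) — the universal results
# container. Stops and the Met/Trp singletons never enter synonymous-family
# statistics.

family_counts <- function(counts, aa) counts[SYN_FAMILIES[[aa]]]

# Pseudocount policy for reference tables: whenever any codon of a family
# has zero count in the reference, add 1 to every codon of that family
# (and only that family). Keeps all reference frequencies strictly positive
# without touching well-observed families.
reference_pseudocount <- function(reference, quiet = TRUE) {
  touched <- character(0)
  for (aa in names(SYN_FAMILIES)) {
    fam <- SYN_FAMILIES[[aa]]
    if (any(reference[fam] == 0)) {
      reference[fam] <- reference[fam] + 1
      touched <- c(touched, aa)
    }
  }
  if (!quiet && length(touched) > 0L)
    warning("reference pseudocount applied to family(ies): ",
            paste(touched, collapse = ", "), call. = FALSE)
  reference
}

#' Effective number of codons (Wright's estimator)
#'
#' Wright's ENc: for each amino acid with n >= 2 codons in the gene, the
#' codon homozygosity is F = (n * sum(p_i^2) - 1) / (n - 1); F values are
#' averaged within degeneracy classes (9 two-fold, 1 three-fold, 5 four-fold,
#' 3 six-fold families) and ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, capped at
#' 61. When the three-fold class (Ile) is missing its average is replaced by
#' (F2 + F4)/2; a missing or zero two-, four- or six-fold class average makes
#' the estimator undefined (`NA`) — use [enc_modified()] for short genes.
#' Range [20, 61]: 20 = one codon per family (maximal bias), 61 = uniform
#' usage (no bias).
#'
#' @param counts Named 64-codon count vector from [codon_counts()].
#' @return ENc value, or `NA` when undefined.
#' @export
enc_wright <- function(counts) {
  Fvals <- lapply(names(SYN_FAMILIES), function(aa) {
    nc <- family_counts(counts, aa)
    n <- sum(nc)
    if (n < 2) return(NULL)
    p <- nc / n
    data.frame(k = FAMILY_SIZES[[aa]], F = (n * sum(p^2) - 1) / (n - 1))
  })
  Fdf <- do.call(rbind, Fvals)
  if (is.null(Fdf)) return(NA_real_)
  classbar <- function(k) {
    v <- Fdf$F[Fdf$k == k]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  F2 <- classbar(2); F3 <- classbar(3); F4 <- classbar(4); F6 <- classbar(6)
  if (is.na(F3) && !is.na(F2) && !is.na(F4)) F3 <- (F2 + F4) / 2
  if (anyNA(c(F2, F3, F4, F6)) || any(c(F2, F3, F4, F6) <= 0))
    return(NA_real_)
  min(2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6, 61)
}

#' Effective number of codons (pseudocount-modified estimator)
#'
#' A modified ENc in which every family's homozygosity is computed from
#' pseudocounted frequencies p_i = (n_i + 1) / (n + k) as
#' F = sum(p_i^2), so the estimator is defined for every non-empty gene —
#' including genes too short for Wright's version. Class aggregation and the
#' cap at 61 are as in [enc_wright()]; families absent from the gene
#' contribute their uniform value F = 1/k.
#'
#' @inheritParams enc_wright
#' @return Modified ENc value in [20, 61].
#' @export
enc_modified <- function(counts) {
  Fdf <- do.call(rbind, lapply(names(SYN_FAMILIES), function(aa) {
    nc <- family_counts(counts, aa)
    k <- FAMILY_SIZES[[aa]]
    p <- (nc + 1) / (sum(nc) + k)
    data.frame(k = k, F = sum(p^2))
  }))
  F2 <- mean(Fdf$F[Fdf$k == 2]); F3 <- mean(Fdf$F[Fdf$k == 3])
  F4 <- mean(Fdf$F[Fdf$k == 4]); F6 <- mean(Fdf$F[Fdf$k == 6])
  min(2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6, 61)
}

# Shared loop over families used by a gene: calls fun(nc, g, k) with the
# gene's counts nc and the reference's within-family frequencies g.
map_used_families <- function(counts, reference, fun) {
  reference <- reference_pseudocount(reference)
  out <- list()
  for (aa in names(SYN_FAMILIES)) {
    nc <- family_counts(counts, aa)
    n <- sum(nc)
    if (n == 0) next
    gref <- family_counts(reference, aa)
    out[[aa]] <- fun(nc, gref / sum(gref), FAMILY_SIZES[[aa]])
  }
  out
}

#' MILC: measure independent of length and composition
#'
#' Per amino acid, M_a = 2 * sum_c n_c * ln(f_c / g_c), with f the gene's
#' within-family codon frequencies and g the reference's; MILC =
#' sum(M_a) / L - C where L is the number of family codons in the gene and
#' the length-correction term C = sum_a (k_a - 1) / L - 0.5 runs over the
#' families the gene uses. Zero-count reference codons are handled by the
#' family pseudocount policy. When the gene's frequencies equal the
#' reference's exactly, MILC equals -C.
#'
#' @param counts Gene 64-codon counts.
#' @param reference Reference 64-codon counts; defaults (in the
#'   [milc_table()] wrapper) to the gene's own organism pooled counts.
#' @return MILC value, with the correction term attached as attribute
#'   `"correction"`.
#' @export
milc <- function(counts, reference) {
  L <- sum(counts[FAMILY_CODONS])
  if (L == 0) return(NA_real_)
  Ms <- map_used_families(counts, reference, function(nc, g, k) {
    f <- nc / sum(nc)
    use <- nc > 0
    c(M = 2 * sum(nc[use] * log(f[use] / g[use])), km1 = k - 1)
  })
  m <- do.call(rbind, Ms)
  C <- sum(m[, "km1"]) / L - 0.5
  structure(sum(m[, "M"]) / L - C, correction = C)
}

#' B index: Karlin-Mrazek codon usage difference
#'
#' B(g|ref) = sum_a p_a * sum_c |f(c|a, gene) - f(c|a, ref)| where p_a is
#' the amino-acid frequency in the gene (over family codons). Ranges over
#' [0, 2]; 0 when the gene matches the reference family-wise.
#'
#' @inheritParams milc
#' @return B value in [0, 2].
#' @export
b_index <- function(counts, reference) {
  L <- sum(counts[FAMILY_CODONS])
  if (L == 0) return(NA_real_)
  parts <- map_used_families(counts, reference, function(nc, g, k) {
    n <- sum(nc)
    (n / L) * sum(abs(nc / n - g))
  })
  sum(unlist(parts))
}

#' MCB: maximum-likelihood codon bias
#'
#' Per family, B_a = sum_c (f_c - g_c)^2 / g_c; MCB is the
#' log10(n_a)-weighted mean of B_a over the families the gene uses
#' (families observed once carry zero weight). Non-negative; 0 when the
#' gene matches the reference expectation.
#'
#' @inheritParams milc
#' @return MCB value (>= 0), `NA` when no family has n >= 2.
#' @export
mcb <- function(counts, reference) {
  parts <- map_used_families(counts, reference, function(nc, g, k) {
    n <- sum(nc)
    f <- nc / n
    c(B = sum((f - g)^2 / g), w = log10(n))
  })
  m <- do.call(rbind, parts)
  if (is.null(m) || sum(m[, "w"]) == 0) return(NA_real_)
  sum(m[, "B"] * m[, "w"]) / sum(m[, "w"])
}

#' Relative adaptiveness weights for CAI
#'
#' Sharp-Li weights from a reference (ideally highly expressed) gene set:
#' within each synonymous family, w_c = n_c / max(n_family). The family
#' pseudocount policy keeps every weight strictly positive; the most
#' frequent codon of each family has w = 1.
#'
#' @param reference Reference 64-codon counts.
#' @return Named numeric vector of weights in (0, 1] over the 59 family
#'   codons.
#' @export
cai_weights <- function(reference) {
  reference <- reference_pseudocount(reference)
  w <- numeric(0)
  for (aa in names(SYN_FAMILIES)) {
    nc <- family_counts(reference, aa)
    w <- c(w, nc / max(nc))
  }
  w[FAMILY_CODONS]
}

#' Codon adaptation index
#'
#' Geometric mean of the reference-derived relative adaptiveness weights
#' over the gene's family codons (ATG, TGG and stops excluded). CAI is 1
#' for a gene using only each family's preferred reference codon.
#'
#' @param counts Gene 64-codon counts.
#' @param weights Weights from [cai_weights()].
#' @return CAI in (0, 1].
#' @export
cai <- function(counts, weights) {
  nc <- counts[FAMILY_CODONS]
  L <- sum(nc)
  if (L == 0) return(NA_real_)
  exp(sum(nc * log(weights[FAMILY_CODONS])) / L)
}

#' Optimal codon set from a reference
#'
#' The most frequent codon of each synonymous family in the reference;
#' family-internal ties make every tied codon optimal (reported via a
#' message).
#'
#' @param reference Reference 64-codon counts.
#' @return Character vector of optimal codons.
#' @export
optimal_codons <- function(reference) {
  out <- character(0)
  for (aa in names(SYN_FAMILIES)) {
    nc <- family_counts(reference, aa)
    top <- names(nc)[nc == max(nc)]
    if (length(top) > 1L)
      message("optimal-codon tie in family ", aa, ": ",
              paste(top, collapse = ", "))
    out <- c(out, top)
  }
  out
}

#' Frequency of optimal codons
#'
#' Fraction of the gene's family codons (ATG/TGG and stops excluded) that
#' belong to the reference's optimal set.
#'
#' @param counts Gene 64-codon counts.
#' @param optimal_set Codons from [optimal_codons()].
#' @return FOP in [0, 1].
#' @export
fop <- function(counts, optimal_set) {
  nc <- counts[FAMILY_CODONS]
  L <- sum(nc)
  if (L == 0) return(NA_real_)
  sum(nc[names(nc) %in% optimal_set]) / L
}

#' MELP: MILC-based expression level predictor
#'
#' Ratio MILC(gene | background) / MILC(gene | reference), with the
#' organism's own pooled counts as background and the host set as
#' reference. Values above 1 suggest reference-like (putatively highly
#' expressed) codon usage.
#'
#' @param counts Gene 64-codon counts.
#' @param background Organism pooled 64-codon counts.
#' @param reference Host/reference 64-codon counts.
#' @return MELP value; `NA` (flagged by a warning) when the denominator
#'   MILC is not positive.
#' @export
melp <- function(counts, background, reference) {
  den <- as.numeric(milc(counts, reference))
  if (is.na(den) || den <= 0) {
    warning("MELP undefined: reference MILC <= 0", call. = FALSE)
    return(NA_real_)
  }
  as.numeric(milc(counts, background)) / den
}

#' E index: Karlin-Mrazek expression measure
#'
#' Ratio of B-index contrasts, B(gene | background) / B(gene | reference);
#' values above 1 indicate codon usage closer to the reference set than to
#' the organism background. A gene identical to both sets is assigned 1.
#'
#' @inheritParams melp
#' @return E value; `NA` when only the denominator vanishes.
#' @export
e_index <- function(counts, background, reference) {
  num <- b_index(counts, background)
  den <- b_index(counts, reference)
  if (is.na(num) || is.na(den)) return(NA_real_)
  if (den == 0) {
    if (num == 0) return(1)
    warning("E index undefined: zero reference B with nonzero background B",
            call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Relative synonymous codon usage
#'
#' RSCU_c = n_c / ((1/k) * sum over the family), i.e. observed over
#' expected-under-uniform within each synonymous family. Families with zero
#' total get RSCU 0 for all members (flagged in the `"empty_families"`
#' attribute); over a family with nonzero total the values sum to k.
#'
#' @param counts 64-codon counts (gene or pooled).
#' @return Named numeric vector of length 59 over the family codons, in
#'   fixed lexicographic order.
#' @export
#' @examples
#' rec <- validate_cds("GAAGAAGAAGAG", id = "g", organism = "toy")$record
#' rscu(codon_counts(rec))[c("GAA", "GAG")]
rscu <- function(counts) {
  out <- numeric(0)
  empty <- character(0)
  for (aa in names(SYN_FAMILIES)) {
    nc <- family_counts(counts, aa)
    tot <- sum(nc)
    if (tot == 0) {
      empty <- c(empty, aa)
      out <- c(out, nc * 0)
    } else {
      out <- c(out, nc * FAMILY_SIZES[[aa]] / tot)
    }
  }
  structure(out[FAMILY_CODONS], empty_families = empty)
}

# ---- per-collection wrappers -------------------------------------------

index_table <- function(collections, fun, index_name, reference_used) {
  collections <- as_collection_list(collections)
  rows <- lapply(collections, function(col) {
    if (length(col$records) == 0L) return(NULL)
    vals <- vapply(col$records,
                   function(r) as.numeric(fun(codon_counts(r), col)),
                   numeric(1))
    data.frame(organism = col$name,
               id = vapply(col$records, `[[`, character(1), "id"),
               value = vals, index = index_name,
               reference_used = reference_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

host_counts_or_stop <- function(host, needed_by) {
  if (is.null(host))
    stop(needed_by, " requires a host reference gene set", call. = FALSE)
  stopifnot(inherits(host, "cds_collection"))
  codon_counts(host)
}

#' Per-gene ENc table
#'
#' @param collections A `cds_collection` or list of them.
#' @param modified Use the pseudocount-modified estimator?
#' @return Data frame (organism, id, value, index, reference_used).
#' @export
enc_table <- function(collections, modified = FALSE) {
  fun <- if (modified) function(cc, col) enc_modified(cc)
         else function(cc, col) enc_wright(cc)
  index_table(collections, fun,
              if (modified) "ENc_modified" else "ENc", "none")
}

with_reference_table <- function(collections, host, fun, name) {
  collections <- as_collection_list(collections)
  if (is.null(host)) {
    # host-free form: each organism's pooled counts act as the reference
    out <- do.call(rbind, lapply(collections, function(col) {
      ref <- codon_counts(col)
      index_table(list(col), function(cc, c2) fun(cc, ref), name, "self")
    }))
  } else {
    ref <- host_counts_or_stop(host, name)
    out <- index_table(collections, function(cc, c2) fun(cc, ref), name,
                       "host")
  }
  rownames(out) <- NULL
  out
}

#' Per-gene MILC table
#'
#' Host-free form uses each organism's pooled counts as the implicit
#' reference; with `host` given, the host pooled counts are the reference.
#'
#' @inheritParams enc_table
#' @param host Optional host `cds_collection`.
#' @export
milc_table <- function(collections, host = NULL)
  with_reference_table(collections, host, milc, "MILC")

#' Per-gene B-index table
#' @inheritParams milc_table
#' @export
b_table <- function(collections, host = NULL)
  with_reference_table(collections, host, b_index, "B")

#' Per-gene MCB table
#' @inheritParams milc_table
#' @export
mcb_table <- function(collections, host = NULL)
  with_reference_table(collections, host, mcb, "MCB")

#' Per-gene CAI table (host reference required)
#' @inheritParams milc_table
#' @export
cai_table <- function(collections, host) {
  w <- cai_weights(host_counts_or_stop(host, "CAI"))
  index_table(collections, function(cc, col) cai(cc, w), "CAI", "host")
}

#' Per-gene FOP table (host reference required)
#' @inheritParams milc_table
#' @export
fop_table <- function(collections, host) {
  opt <- optimal_codons(host_counts_or_stop(host, "FOP"))
  index_table(collections, function(cc, col) fop(cc, opt), "FOP", "host")
}

#' Per-gene MELP table (host reference required)
#' @inheritParams milc_table
#' @export
melp_table <- function(collections, host) {
  ref <- host_counts_or_stop(host, "MELP")
  collections <- as_collection_list(collections)
  out <- do.call(rbind, lapply(collections, function(col) {
    bg <- codon_counts(col)
    index_table(list(col), function(cc, c2) melp(cc, bg, ref), "MELP",
                "host")
  }))
  rownames(out) <- NULL
  out
}

#' Per-gene E-index table (host reference required)
#' @inheritParams milc_table
#' @export
e_table <- function(collections, host) {
  ref <- host_counts_or_stop(host, "E")
  collections <- as_collection_list(collections)
  out <- do.call(rbind, lapply(collections, function(col) {
    bg <- codon_counts(col)
    index_table(list(col), function(cc, c2) e_index(cc, bg, ref), "E",
                "host")
  }))
  rownames(out) <- NULL
  out
}

#' Per-sequence RSCU table
#'
#' @param collections A `cds_collection` or list of them.
#' @return Data frame: organism, id, then 59 codon columns in fixed
#'   lexicographic order.
#' @export
rscu_table <- function(collections) {
  collections <- as_collection_list(collections)
  rows <- lapply(collections, function(col) {
    if (length(col$records) == 0L) return(NULL)
    m <- t(vapply(col$records, function(r) as.numeric(rscu(codon_counts(r))),
                  numeric(length(FAMILY_CODONS))))
    colnames(m) <- FAMILY_CODONS
    data.frame(organism = col$name,
               id = vapply(col$records, `[[`, character(1), "id"),
               m, stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Organism-mean RSCU vector
#'
#' Mean of the per-sequence RSCU vectors of one collection — the profile
#' used for SiD and for organism-level multivariate analysis.
#'
#' @param collection A `cds_collection`.
#' @return Named numeric vector of length 59.
#' @export
organism_mean_rscu <- function(collection) {
  stopifnot(inherits(collection, "cds_collection"))
  if (length(collection$records) == 0L)
    stop("collection ", collection$name, " has no records")
  m <- vapply(collection$records,
              function(r) as.numeric(rscu(codon_counts(r))),
              numeric(length(FAMILY_CODONS)))
  stats::setNames(rowMeans(m), FAMILY_CODONS)
}
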