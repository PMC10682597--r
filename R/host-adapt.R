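# Parasite-host co-adaptation statistics: the similarity index SiD between
# RSCU profiles and the relative codon deoptimization index RCDI against
# host per-family codon frequencies.

#' Similarity index between two RSCU profiles
#'
#' Cosine similarity R = sum(a*b) / sqrt(sum(a^2) * sum(b^2)) over the 59
#' family codons, reported as SiD = (1 - R) / 2 in [0, 0.5]: 0 for
#' identical profiles, 0.5 for profiles with disjoint codon support. SiD is
#' symmetric and invariant to positive rescaling of either profile.
#'
#' @param rscu_parasite,rscu_host Numeric RSCU vectors over the same codon
#'   order (typically [organism_mean_rscu()] outputs).
#' @return SiD value in [0, 0.5].
#' @export
#' @examples
#' sid(c(2, 1, 0), c(0, 1, 2))  # cosine 1/5 -> 0.4
sid <- function(rscu_parasite, rscu_host) {
  a <- as.numeric(rscu_parasite); b <- as.numeric(rscu_host)
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("SiD undefined for a zero RSCU vector")
  (1 - sum(a * b) / (na * nb)) / 2
}

#' SiD table for parasite collections against one host
#'
#' By default one row per parasite organism, comparing the organism-mean
#' parasite RSCU with the host pooled RSCU; `per_sequence = TRUE` instead
#' scores every parasite gene separately.
#'
#' @param collections Parasite `cds_collection`(s).
#' @param host Host `cds_collection`.
#' @param per_sequence Score each sequence instead of organism means?
#' @return Data frame (organism, [id,] sid).
#' @export
sid_table <- function(collections, host, per_sequence = FALSE) {
  collections <- as_collection_list(collections)
  host_rscu <- as.numeric(rscu(host_counts_or_stop(host, "SiD")))
  if (!per_sequence) {
    out <- data.frame(
      organism = vapply(collections, `[[`, character(1), "name"),
      sid = vapply(collections,
                   function(col) sid(organism_mean_rscu(col), host_rscu),
                   numeric(1)),
      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, lapply(collections, function(col) {
      data.frame(
        organism = col$name,
        id = vapply(col$records, `[[`, character(1), "id"),
        sid = vapply(col$records,
                     function(r) sid(rscu(codon_counts(r)), host_rscu),
                     numeric(1)),
        stringsAsFactors = FALSE)
    }))
  }
  rownames(out) <- NULL
  out
}

#' Host per-family codon frequencies
#'
#' CiF_h(c) = n_c / sum over the codon's synonymous family, computed from a
#' (host) codon count table; families containing a zero count receive the
#' family pseudocount first, so all frequencies are strictly positive.
#'
#' @param reference 64-codon count vector (e.g. `codon_counts(host)`).
#' @return Named numeric vector over the 59 family codons; within each
#'   family the values sum to 1.
#' @export
host_frequencies <- function(reference) {
  reference <- reference_pseudocount(reference, quiet = FALSE)
  out <- numeric(0)
  for (aa in names(SYN_FAMILIES)) {
    nc <- family_counts(reference, aa)
    out <- c(out, nc / sum(nc))
  }
  out[FAMILY_CODONS]
}

#' Relative codon deoptimization index
#'
#' RCDI = sum_c (CiF_a(c) / CiF_h(c)) * N_c / N over the gene's family
#' codons (ATG, TGG and stops excluded), where CiF_a is the gene's
#' within-family frequency of codon c, CiF_h the host's, N_c the codon's
#' count and N the total family-codon count. RCDI = 1 when the gene's
#' per-family frequencies equal the host's; larger values indicate
#' deoptimization away from host usage. Invariant to gene duplication.
#'
#' @param x A `cds_record` or a 64-codon count vector.
#' @param host_freqs Frequencies from [host_frequencies()].
#' @return RCDI value (> 0).
#' @export
rcdi <- function(x, host_freqs) {
  counts <- if (inherits(x, "cds_record")) codon_counts(x) else x
  N <- sum(counts[FAMILY_CODONS])
  if (N == 0) stop("RCDI needs at least one family codon")
  total <- 0
  for (aa in names(SYN_FAMILIES)) {
    nc <- family_counts(counts, aa)
    n <- sum(nc)
    if (n == 0) next
    cif_a <- nc / n
    cif_h <- host_freqs[SYN_FAMILIES[[aa]]]
    total <- total + sum((cif_a / cif_h) * nc)
  }
  total / N
}

#' Per-gene RCDI table against one host
#'
#' @param collections Parasite `cds_collection`(s).
#' @param host Host `cds_collection`.
#' @return Data frame (organism, id, value, index, reference_used).
#' @export
rcdi_table <- function(collections, host) {
  hf <- host_frequencies(host_counts_or_stop(host, "RCDI"))
  index_table(collections, function(cc, col) rcdi(cc, hf), "RCDI", "host")
}
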