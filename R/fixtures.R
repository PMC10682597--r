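# Deterministic synthetic CDS generator. Sequences are drawn codon-by-codon
# from per-family codon weight profiles over a random (or supplied) protein,
# so every index has a generator spec that realizes its identity case, and
# all tests run without downloads. Identical spec + seed => identical FASTA
# bytes.

#' Uniform codon weight profile
#'
#' Weight 1 for every sense codon: within each synonymous family codons are
#' drawn uniformly, the no-bias null (RSCU -> 1 everywhere).
#'
#' @return Named numeric weight vector over the 61 sense codons.
#' @export
uniform_profile <- function() {
  stats::setNames(rep(1, length(SENSE_CODONS)), SENSE_CODONS)
}

#' One-codon-per-family weight profile
#'
#' Concentrates all weight on the lexicographically first codon of each
#' family: the maximal-bias generator (Wright ENc = 20 in the large-gene
#' limit).
#'
#' @return Named numeric weight vector over the 61 sense codons.
#' @export
single_codon_profile <- function() {
  w <- stats::setNames(rep(0, length(SENSE_CODONS)), SENSE_CODONS)
  for (fam in SYN_FAMILIES) w[fam[1L]] <- 1
  w[SINGLETON_CODONS] <- 1
  w
}

#' GC3-biased codon weight profile
#'
#' Within every family, codons ending in G or C get weight `target_gc3` and
#' codons ending in A or T get `1 - target_gc3`, tilting third-position GC
#' without touching amino-acid composition.
#'
#' @param target_gc3 Desired third-position GC tendency in (0, 1).
#' @return Named numeric weight vector over the 61 sense codons.
#' @export
gc3_biased_profile <- function(target_gc3) {
  stopifnot(target_gc3 > 0, target_gc3 < 1)
  third <- substr(SENSE_CODONS, 3L, 3L)
  stats::setNames(ifelse(third %in% c("G", "C"), target_gc3, 1 - target_gc3),
                  SENSE_CODONS)
}

# normalize weights within each synonymous family (plus M/W singletons)
profile_family_freqs <- function(profile) {
  freqs <- stats::setNames(rep(1, length(SENSE_CODONS)), SENSE_CODONS)
  for (fam in SYN_FAMILIES) {
    w <- profile[fam]
    if (any(w < 0) || sum(w) <= 0)
      stop("degenerate codon weights in family ", AA_OF_CODON[fam[1L]])
    freqs[fam] <- w / sum(w)
  }
  freqs
}

#' Simulate a synthetic CDS collection
#'
#' Each sequence is an ATG start, `aa_length - 2` body codons and one stop
#' codon (TAA). Body amino acids are drawn from `aa_weights` (default:
#' uniform over the 18 amino acids with a synonymous family, keeping every
#' family statistic well populated); the codon for each amino acid is drawn
#' from the within-family normalization of `profile`. The true generating
#' frequencies are attached as the `"truth"` attribute for recovery tests.
#'
#' @param name Organism name.
#' @param n Number of sequences.
#' @param aa_length Sequence length(s) in codons: a scalar, a length-2
#'   range sampled uniformly, or a vector of per-sequence lengths.
#' @param profile Codon weight vector over the 61 sense codons
#'   (default [uniform_profile()]).
#' @param aa_weights Optional named weights over body amino acids.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param role `"parasite"` or `"host"`.
#' @return A `cds_collection` with a `"truth"` attribute (list of the
#'   per-family codon frequencies, expected body GC3 and the parameters).
#' @export
#' @examples
#' col <- simulate_cds_collection("toy", n = 3, aa_length = 50, seed = 1)
#' length(col$records)
simulate_cds_collection <- function(name, n = 10L, aa_length = 300L,
                                    profile = uniform_profile(),
                                    aa_weights = NULL, seed = 1L,
                                    role = "parasite") {
  stopifnot(n >= 1L)
  freqs <- profile_family_freqs(profile)
  if (is.null(aa_weights))
    aa_weights <- stats::setNames(rep(1, length(SYN_FAMILIES)),
                                  names(SYN_FAMILIES))
  aa_weights <- aa_weights / sum(aa_weights)
  lens <- if (length(aa_length) == 2L && n != 2L) {
    NULL  # range; drawn below
  } else if (length(aa_length) %in% c(1L, n)) {
    rep_len(as.integer(aa_length), n)
  } else stop("aa_length must be a scalar, a range, or one value per sequence")

  set.seed(as.integer(seed))
  if (is.null(lens))
    lens <- sample(seq(aa_length[1L], aa_length[2L]), n, replace = TRUE)
  stopifnot(all(lens >= 3L))

  records <- vector("list", n)
  for (i in seq_len(n)) {
    body_aa <- sample(names(aa_weights), lens[i] - 2L, replace = TRUE,
                      prob = aa_weights)
    body <- character(length(body_aa))
    for (aa in unique(body_aa)) {
      pos <- which(body_aa == aa)
      fam <- SHUFFLE_GROUPS[[aa]]
      body[pos] <- if (length(fam) == 1L) fam
                   else sample(fam, length(pos), replace = TRUE,
                               prob = freqs[fam])
    }
    seqs <- paste(c("ATG", body, "TAA"), collapse = "")
    records[[i]] <- new_cds_record(sprintf("%s_g%03d", name, i), name, seqs)
  }
  qc <- data.frame(organism = name,
                   id = vapply(records, `[[`, character(1), "id"),
                   aa_length = lens, status = "retained", reason = "",
                   stringsAsFactors = FALSE)
  col <- new_cds_collection(name, records, role, qc)

  body_codon_p <- freqs * 0
  for (aa in names(aa_weights)) {
    fam <- SHUFFLE_GROUPS[[aa]]
    body_codon_p[fam] <- aa_weights[[aa]] *
      (if (length(fam) == 1L) 1 else freqs[fam])
  }
  third <- substr(names(body_codon_p), 3L, 3L)
  attr(col, "truth") <- list(
    name = name, n = n, aa_length = lens, seed = as.integer(seed),
    family_freqs = freqs[FAMILY_CODONS], aa_weights = aa_weights,
    expected_body_gc3 = sum(body_codon_p[third %in% c("G", "C")]))
  col
}

#' Generate a synthetic collection on disk
#'
#' Writes the simulated collection as a plain FASTA file plus a JSON truth
#' sidecar recording the generating per-family frequencies, the expected
#' body GC3 and all parameters, so recovery tests can be run against the
#' file alone.
#'
#' @inheritParams simulate_cds_collection
#' @param dir Output directory (created if absent).
#' @return Named list with the `fasta` and `truth` file paths, invisibly.
#' @export
generate_collection <- function(name, dir, n = 10L, aa_length = 300L,
                                profile = uniform_profile(),
                                aa_weights = NULL, seed = 1L,
                                role = "parasite") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  col <- simulate_cds_collection(name, n = n, aa_length = aa_length,
                                 profile = profile, aa_weights = aa_weights,
                                 seed = seed, role = role)
  fasta <- file.path(dir, paste0(name, ".fasta"))
  write_collection_fasta(col, fasta)
  truth_path <- file.path(dir, paste0(name, ".truth.json"))
  truth <- attr(col, "truth")
  truth$role <- role
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(fasta = fasta, truth = truth_path))
}

#' Generate a synthetic host reference on disk
#'
#' Convenience wrapper over [generate_collection()] with role `"host"`.
#'
#' @inheritParams generate_collection
#' @return Named list with the `fasta` and `truth` file paths, invisibly.
#' @export
generate_host <- function(name, dir, n = 20L, aa_length = 400L,
                          profile = uniform_profile(), aa_weights = NULL,
                          seed = 1L) {
  generate_collection(name, dir, n = n, aa_length = aa_length,
                      profile = profile, aa_weights = aa_weights,
                      seed = seed, role = "host")
}
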