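# Dinucleotide over-/under-representation by permutation z-scores under
# three sequence-randomization null models: shuffling of bases, of codons,
# or of synonymous codons (which preserves the encoded protein exactly).

BASES <- c("A", "C", "G", "T")
DINUCS <- paste0(rep(BASES, each = 4L), BASES)  # AA, AC, AG, AT, CA, ...

seq_to_int <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1L]], BASES)
}

dinuc_counts_int <- function(x) {
  n <- length(x)
  if (n < 2L) return(integer(16L))
  tabulate(4L * (x[-n] - 1L) + x[-1L], nbins = 16L)
}

#' Overlapping dinucleotide counts of a sequence
#'
#' Counts the 16 dinucleotides in overlapping windows read 5' to 3',
#' including windows spanning codon boundaries; the counts sum to
#' `length - 1`.
#'
#' @param x A `cds_record` or a nucleotide string.
#' @return Named integer vector over the 16 dinucleotides (AA, AC, ...).
#' @export
#' @examples
#' dinuc_counts("ACGT")
dinuc_counts <- function(x) {
  seq <- if (inherits(x, "cds_record")) x$nucleotides else as.character(x)
  if (nchar(seq) < 2L) {
    warning("sequence shorter than 2 nt; all dinucleotide counts zero",
            call. = FALSE)
    return(stats::setNames(integer(16L), DINUCS))
  }
  stats::setNames(dinuc_counts_int(seq_to_int(seq)), DINUCS)
}

# Integer-coded randomizers. `x` is the base-int vector, `cod` the codon
# index vector (1..64). Each returns a base-int vector.
shuffle_bases_int <- function(x, replace) {
  if (replace) x[sample.int(length(x), length(x), replace = TRUE)]
  else x[sample.int(length(x))]
}

codons_to_bases_int <- function(cod) {
  # codon index (lexicographic over A,C,G,T) -> its three base ints
  c3 <- (cod - 1L) %% 4L + 1L
  c2 <- ((cod - 1L) %/% 4L) %% 4L + 1L
  c1 <- (cod - 1L) %/% 16L + 1L
  as.vector(rbind(c1, c2, c3))
}

shuffle_codons_int <- function(cod, replace) {
  if (replace) cod[sample.int(length(cod), length(cod), replace = TRUE)]
  else cod[sample.int(length(cod))]
}

resample_syncodons_int <- function(cod) {
  sizes <- SYN_GROUP_SIZE[cod]
  pick <- 1L + as.integer(floor(stats::runif(length(cod)) * sizes))
  pick[pick > sizes] <- sizes[pick > sizes]  # guard against runif() == 1
  SYN_GROUP_MEMBERS[cbind(cod, pick)]
}

#' Randomize a coding sequence under a null model
#'
#' * `base`: shuffle (or resample, with `replace = TRUE`) individual bases.
#' * `codon`: shuffle/resample whole codons, preserving the reading frame.
#' * `syncodon`: replace every codon by a synonymous codon drawn uniformly
#'   from its family under the standard code, preserving the amino-acid
#'   sequence exactly (stops are resampled among the three stop codons).
#'
#' Uses the current RNG state; seed management lives in [dinuc_zscores()].
#'
#' @param record A `cds_record`.
#' @param model One of `"base"`, `"codon"`, `"syncodon"`.
#' @param replace Sample with replacement? (ignored by `syncodon`, which is
#'   always a per-codon draw).
#' @return Randomized nucleotide string of the same length.
#' @export
shuffle_null <- function(record, model = c("base", "codon", "syncodon"),
                         replace = FALSE) {
  model <- match.arg(model)
  cod <- match(record$codons, CODONS)
  out <- switch(model,
    base = shuffle_bases_int(seq_to_int(record$nucleotides), replace),
    codon = codons_to_bases_int(shuffle_codons_int(cod, replace)),
    syncodon = codons_to_bases_int(resample_syncodons_int(cod)))
  paste(BASES[out], collapse = "")
}

# Deterministic per-record seed: djb2-style hash of organism/id folded with
# the global seed, so per-record results do not depend on collection order.
record_seed <- function(global_seed, organism, id) {
  h <- 5381
  for (ch in utf8ToInt(paste(organism, id, sep = "\r"))) {
    h <- (h * 33 + ch) %% 2147483647
  }
  as.integer((h + as.numeric(global_seed)) %% 2147483647)
}

dinuc_z_one <- function(record, model, permutations, replace) {
  x <- seq_to_int(record$nucleotides)
  cod <- match(record$codons, CODONS)
  obs <- dinuc_counts_int(x)
  perm <- matrix(0L, nrow = permutations, ncol = 16L)
  for (p in seq_len(permutations)) {
    y <- switch(model,
      base = shuffle_bases_int(x, replace),
      codon = codons_to_bases_int(shuffle_codons_int(cod, replace)),
      syncodon = codons_to_bases_int(resample_syncodons_int(cod)))
    perm[p, ] <- dinuc_counts_int(y)
  }
  mu <- colMeans(perm)
  sdv <- apply(perm, 2L, stats::sd)  # n - 1 denominator
  z <- (obs - mu) / sdv
  z[sdv == 0] <- NA_real_  # degenerate null: undefined, not 0
  z
}

#' Dinucleotide permutation z-scores
#'
#' For every record and each of the 16 dinucleotides, the observed
#' overlapping count is compared with its distribution over `permutations`
#' randomizations of the sequence under the chosen null model:
#' z = (obs - mean) / sd, with the sd using the n - 1 denominator. Cells
#' whose permutation sd is zero (e.g. homopolymers under pure shuffling) are
#' reported as `NA`. Each record gets its own RNG stream derived from
#' `seed`, the organism and the record id, so results are independent of
#' collection order and reproducible bit-for-bit.
#'
#' @param collections A `cds_collection` or list of them.
#' @param model Null model: `"base"`, `"codon"` or `"syncodon"`.
#' @param permutations Number of randomizations (>= 2; default 100).
#' @param replace Shuffle with replacement?
#' @param seed Global integer seed.
#' @return Data frame: organism, id, model, permutations, replace, seed,
#'   then 16 z-score columns named by dinucleotide.
#' @export
dinuc_zscores <- function(collections, model = c("base", "codon", "syncodon"),
                          permutations = 100L, replace = FALSE, seed = 1L) {
  model <- match.arg(model)
  stopifnot(permutations >= 2L)
  collections <- as_collection_list(collections)
  rows <- lapply(collections, function(col) {
    if (length(col$records) == 0L) return(NULL)
    zs <- t(vapply(col$records, function(rec) {
      old <- globalenv()$.Random.seed
      set.seed(record_seed(seed, col$name, rec$id))
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      dinuc_z_one(rec, model, permutations, replace)
    }, numeric(16L)))
    colnames(zs) <- DINUCS
    data.frame(organism = col$name,
               id = vapply(col$records, `[[`, character(1), "id"),
               model = model, permutations = as.integer(permutations),
               replace = replace, seed = as.integer(seed),
               zs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
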