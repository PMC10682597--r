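# Standard genetic code (NCBI translation table 1) constants shared by every
# module. All codon vectors are kept in fixed lexicographic order so that
# tables, RSCU vectors and matrices line up across functions.

#' @importFrom Biostrings GENETIC_CODE
NULL

CODONS <- sort(names(Biostrings::GENETIC_CODE))
AA_OF_CODON <- Biostrings::GENETIC_CODE[CODONS]

STOP_CODONS <- CODONS[AA_OF_CODON == "*"]
SENSE_CODONS <- CODONS[AA_OF_CODON != "*"]

# Met and Trp have a single codon: no synonymous family, excluded from all
# family statistics together with the stops.
SINGLETON_CODONS <- c("ATG", "TGG")

# The 59 codons that belong to a synonymous family of size >= 2.
FAMILY_CODONS <- setdiff(SENSE_CODONS, SINGLETON_CODONS)

# 18 synonymous families keyed by one-letter amino acid:
# 9 two-fold, 1 three-fold (Ile), 5 four-fold, 3 six-fold (Leu, Ser, Arg).
# Six-fold families are kept whole (never split 4+2) everywhere.
SYN_FAMILIES <- split(FAMILY_CODONS, factor(AA_OF_CODON[FAMILY_CODONS]))
FAMILY_SIZES <- lengths(SYN_FAMILIES)

# Amino acids whose four codons differ only at the third position.
FOURFOLD_AA <- c("A", "G", "P", "T", "V")
FOURFOLD_CODONS <- unlist(SYN_FAMILIES[FOURFOLD_AA], use.names = FALSE)

# Default codon exclusion list for RSCU matrices (start, stops, Trp).
DEFAULT_EXCLUDE <- c("ATG", "TAA", "TAG", "TGA", "TGG")

# Synonymy groups used by the synonymous-codon shuffling null: every codon,
# including the three stops (grouped together) and the Met/Trp singletons.
SHUFFLE_GROUPS <- split(CODONS, factor(AA_OF_CODON))

# Integer lookup tables for the fast samplers: for codon i (index in CODONS),
# SYN_GROUP_SIZE[i] members in row i of SYN_GROUP_MEMBERS (codon indices).
SYN_GROUP_SIZE <- integer(64)
SYN_GROUP_MEMBERS <- matrix(NA_integer_, nrow = 64, ncol = 6)
for (.grp in SHUFFLE_GROUPS) {
  .idx <- match(.grp, CODONS)
  for (.i in .idx) {
    SYN_GROUP_SIZE[.i] <- length(.idx)
    SYN_GROUP_MEMBERS[.i, seq_along(.idx)] <- .idx
  }
}
rm(.grp, .idx, .i)

#' Synonymous family table under the standard genetic code
#'
#' @return A data frame with one row per codon of a synonymous family
#'   (59 rows): codon, one-letter amino acid, and family degeneracy.
#' @export
#' @examples
#' head(synonymous_families())
synonymous_families <- function() {
  aa <- rep(names(SYN_FAMILIES), FAMILY_SIZES)
  data.frame(
    codon = unlist(SYN_FAMILIES, use.names = FALSE),
    aa = aa,
    degeneracy = unname(FAMILY_SIZES[aa]),
    stringsAsFactors = FALSE
  )
}

# Count codons into the fixed 64-codon order.
count_codons <- function(codons) {
  n <- tabulate(factor(codons, levels = CODONS), nbins = 64L)
  names(n) <- CODONS
  n
}

#' Codon count table for a record or a whole collection
#'
#' Counts the 64 codons of one CDS record, or pools the counts of every
#' record in a collection. Stop-codon counts are carried in the table but are
#' excluded from all synonymous-family statistics downstream.
#'
#' @param x A `cds_record` or `cds_collection`.
#' @return Named integer vector of length 64 in fixed codon order.
#' @export
codon_counts <- function(x) {
  if (inherits(x, "cds_record")) return(count_codons(x$codons))
  if (inherits(x, "cds_collection")) {
    if (length(x$records) == 0L) return(count_codons(character(0)))
    tabs <- vapply(x$records, function(r) count_codons(r$codons),
                   integer(64))
    n <- as.integer(rowSums(tabs))
    names(n) <- CODONS
    return(n)
  }
  if (is.character(x)) return(count_codons(x))
  stop("`x` must be a cds_record, cds_collection or character codon vector")
}
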