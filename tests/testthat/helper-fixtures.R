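# Shared in-code fixtures. Everything is generated at test time under fixed
# seeds; nothing is read from disk unless a test writes it first.

all_codons <- sort(names(Biostrings::GENETIC_CODE))

zero_counts <- function() stats::setNames(rep(0L, 64L), all_codons)

# a small deterministic count table exercising every degeneracy class
toy_counts <- function() {
  n <- zero_counts()
  n[c("GAA", "GAG")] <- c(6L, 2L)              # Glu, 2-fold
  n[c("AAA", "AAG")] <- c(1L, 5L)              # Lys, 2-fold
  n[c("ATT", "ATC", "ATA")] <- c(4L, 3L, 1L)   # Ile, 3-fold
  n[c("GCT", "GCC", "GCA", "GCG")] <- c(5L, 1L, 1L, 1L)  # Ala, 4-fold
  n[c("GGT", "GGC", "GGA", "GGG")] <- c(2L, 2L, 2L, 2L)  # Gly, 4-fold
  n[c("CTG", "CTT", "TTA", "TTG", "CTC", "CTA")] <- c(7L, 2L, 1L, 1L, 1L, 0L)
  n[c("ATG", "TGG", "TAA")] <- c(3L, 2L, 1L)
  n
}

toy_reference <- function() {
  n <- zero_counts()
  n[all_codons] <- 1L           # uniform floor, no zero families
  n[c("GAA", "AAG", "ATT", "GCT", "GGC", "CTG")] <-
    c(10L, 8L, 6L, 9L, 4L, 12L) # preferred codons
  n
}

make_record <- function(seq, id = "r1", organism = "toy") {
  validate_cds(seq, id = id, organism = organism)$record
}

make_collection <- function(seqs, name = "toy", role = "parasite") {
  recs <- lapply(seq_along(seqs), function(i)
    make_record(seqs[[i]], id = paste0("g", i), organism = name))
  qc <- data.frame(organism = name,
                   id = vapply(recs, `[[`, character(1), "id"),
                   aa_length = vapply(recs, `[[`, integer(1), "aa_length"),
                   status = "retained", reason = "",
                   stringsAsFactors = FALSE)
  structure(list(name = name, records = recs, role = role, qc = qc),
            class = "cds_collection")
}

write_fasta_fixture <- function(headers, seqs, path, width = 60L) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", headers[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  path
}

# random fuzzed CDS: random base composition per record, length in codons
random_cds <- function(n_codons, base_probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), 3L * n_codons, replace = TRUE,
               prob = base_probs), collapse = "")
}
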