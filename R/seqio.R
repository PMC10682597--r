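# FASTA CDS input, validation and quality filtering. Collections are plain
# S3 lists: one `cds_collection` per organism (file), holding validated
# `cds_record`s plus a QC report that accounts for every parsed sequence.

new_cds_record <- function(id, organism, nucleotides, internal_stop = FALSE) {
  codons <- substring(nucleotides,
                      seq(1L, nchar(nucleotides) - 2L, by = 3L),
                      seq(3L, nchar(nucleotides), by = 3L))
  structure(
    list(id = id, organism = organism, nucleotides = nucleotides,
         codons = codons, aa_length = length(codons),
         internal_stop = internal_stop),
    class = "cds_record"
  )
}

#' Validate one raw coding sequence
#'
#' Applies the default validation policy: the sequence is upper-cased, a
#' trailing partial codon (1-2 nt) is dropped with a warning, sequences
#' containing any character other than A/C/G/T are rejected, and sequences
#' with internal stop codons are kept but flagged (stops never enter
#' synonymous-family statistics). Rejection is a reported outcome, not an
#' error.
#'
#' @param sequence Raw nucleotide string.
#' @param id Record identifier.
#' @param organism Organism name the record belongs to.
#' @return A list with elements `record` (a `cds_record`, or `NULL` when
#'   rejected), `status` (`"retained"` or `"rejected"`) and `reason`.
#' @export
#' @examples
#' validate_cds("atggcgtaa", id = "g1", organism = "toy")$record$codons
validate_cds <- function(sequence, id = "seq", organism = "unknown") {
  seq <- toupper(as.character(sequence))
  rem <- nchar(seq) %% 3L
  if (rem > 0L) {
    warning(sprintf("%s/%s: trailing partial codon (%d nt) dropped",
                    organism, id, rem), call. = FALSE)
    seq <- substr(seq, 1L, nchar(seq) - rem)
  }
  if (nchar(seq) < 3L) {
    return(list(record = NULL, status = "rejected", reason = "too short"))
  }
  if (grepl("[^ACGT]", seq)) {
    return(list(record = NULL, status = "rejected", reason = "ambiguous base"))
  }
  rec <- new_cds_record(id, organism, seq)
  n <- length(rec$codons)
  internal <- n > 1L && any(rec$codons[-n] %in% STOP_CODONS)
  rec$internal_stop <- internal
  list(record = rec, status = "retained",
       reason = if (internal) "internal stop (flagged)" else "")
}

new_cds_collection <- function(name, records, role, qc) {
  structure(list(name = name, records = records, role = role, qc = qc),
            class = "cds_collection")
}

#' @export
print.cds_collection <- function(x, ...) {
  cat(sprintf("<cds_collection> %s (%s): %d retained record(s)\n",
              x$name, x$role, length(x$records)))
  invisible(x)
}

read_one_collection <- function(path, sep, role) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e)
                    stop("could not read FASTA file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  name <- tools::file_path_sans_ext(basename(path))

  headers <- names(set)
  ids <- vapply(headers, function(h) {
    pos <- regexpr(sep, h, fixed = TRUE)
    if (pos > 0L) substr(h, 1L, pos - 1L) else h
  }, character(1), USE.NAMES = FALSE)
  dup <- duplicated(ids)
  if (any(dup)) {
    warning(sprintf("%s: %d duplicate record id(s); suffixed with ordinal",
                    name, sum(dup)), call. = FALSE)
    ids <- make.unique(ids, sep = "_")
  }

  records <- vector("list", length(set))
  qc <- data.frame(organism = character(), id = character(),
                   aa_length = integer(), status = character(),
                   reason = character(), stringsAsFactors = FALSE)
  kept <- 0L
  for (i in seq_along(set)) {
    v <- validate_cds(as.character(set[[i]]), id = ids[i], organism = name)
    aa <- if (is.null(v$record)) NA_integer_ else v$record$aa_length
    qc <- rbind(qc, data.frame(organism = name, id = ids[i], aa_length = aa,
                               status = v$status, reason = v$reason,
                               stringsAsFactors = FALSE))
    if (!is.null(v$record)) {
      kept <- kept + 1L
      records[[kept]] <- v$record
    }
  }
  if (role == "host" && kept == 0L) {
    stop("host file ", path, " contains no valid CDS after validation",
         call. = FALSE)
  }
  new_cds_collection(name, records[seq_len(kept)], role, qc)
}

#' Read parasite CDS FASTA files
#'
#' Reads one multi-FASTA file per parasite. Each file becomes one collection
#' named after the file (basename without extension); each record id is the
#' FASTA header truncated at the first occurrence of `sep` (the whole header
#' when `sep` is absent), which keeps long composite headers manageable.
#'
#' @param paths Character vector of FASTA file paths, one per organism.
#' @param sep Single-character id separator (default `"|"`).
#' @return A named list of `cds_collection` objects with role `"parasite"`.
#' @seealso [read_host()], [filter_by_length()], [qc_report()]
#' @export
read_collections <- function(paths, sep = "|") {
  stopifnot(length(paths) >= 1L, is.character(sep), nchar(sep) == 1L)
  out <- lapply(paths, read_one_collection, sep = sep, role = "parasite")
  names(out) <- vapply(out, `[[`, character(1), "name")
  if (anyDuplicated(names(out)))
    stop("duplicate organism names across files: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  out
}

#' Read the host reference CDS FASTA
#'
#' Exactly one host is permitted per analysis; passing more than one path is
#' an error. The host set should ideally contain highly expressed genes, as
#' reference-based indices (CAI, MELP, FOP, E, RCDI) interpret it that way.
#'
#' @inheritParams read_collections
#' @param path A single FASTA file path.
#' @return A `cds_collection` with role `"host"`.
#' @export
read_host <- function(path, sep = "|") {
  if (length(path) != 1L)
    stop("only one host selection is permitted (got ", length(path),
         " paths)", call. = FALSE)
  stopifnot(is.character(sep), nchar(sep) == 1L)
  read_one_collection(path, sep = sep, role = "host")
}

as_collection_list <- function(collections) {
  if (inherits(collections, "cds_collection")) {
    collections <- list(collections)
    names(collections) <- collections[[1L]]$name
  }
  stopifnot(all(vapply(collections, inherits, logical(1), "cds_collection")))
  collections
}

#' Table of CDS lengths
#'
#' @param collections A `cds_collection` or list of them.
#' @return Data frame (organism, id, aa_length), one row per retained record.
#' @export
length_table <- function(collections) {
  collections <- as_collection_list(collections)
  rows <- lapply(collections, function(col) {
    if (length(col$records) == 0L) {
      warning("collection ", col$name, " has no retained records",
              call. = FALSE)
      return(NULL)
    }
    data.frame(organism = col$name,
               id = vapply(col$records, `[[`, character(1), "id"),
               aa_length = vapply(col$records, `[[`, integer(1), "aa_length"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(organism = character(), id = character(),
                      aa_length = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter coding sequences by length
#'
#' Retains records whose length in amino acids (codons) lies inside the
#' inclusive bounds, and records the removals in each collection's QC report.
#' Very short and very long CDS are the usual targets of this step, since
#' both can distort downstream index distributions.
#'
#' @param collections A `cds_collection` or list of them.
#' @param cut_off_down,cut_off_up Lower/upper bounds in amino acids,
#'   `0 <= cut_off_down < cut_off_up`; bounds are inclusive.
#' @return Collections of the same shape with out-of-range records removed.
#' @export
filter_by_length <- function(collections, cut_off_down, cut_off_up) {
  single <- inherits(collections, "cds_collection")
  collections <- as_collection_list(collections)
  if (!(cut_off_down >= 0 && cut_off_down < cut_off_up))
    stop("require 0 <= cut_off_down < cut_off_up")
  out <- lapply(collections, function(col) {
    len <- vapply(col$records, `[[`, integer(1), "aa_length")
    keep <- len >= cut_off_down & len <= cut_off_up
    if (any(!keep)) {
      dropped <- col$records[!keep]
      add <- data.frame(
        organism = col$name,
        id = vapply(dropped, `[[`, character(1), "id"),
        aa_length = vapply(dropped, `[[`, integer(1), "aa_length"),
        status = "filtered",
        reason = sprintf("length outside [%d, %d] aa",
                         as.integer(cut_off_down), as.integer(cut_off_up)),
        stringsAsFactors = FALSE)
      # a record already counted as retained moves to filtered
      col$qc <- col$qc[!(col$qc$id %in% add$id & col$qc$status == "retained"), ]
      col$qc <- rbind(col$qc, add)
      message(sprintf("%s: removed %d/%d record(s) by length filter",
                      col$name, sum(!keep), length(keep)))
    }
    col$records <- col$records[keep]
    col
  })
  if (single) out[[1L]] else out
}

#' QC report across collections
#'
#' One row per parsed sequence with its fate: retained, rejected (validation)
#' or filtered (length cutoff), plus the reason. Counts are conserved:
#' retained + rejected + filtered equals the number of parsed sequences.
#'
#' @param collections A `cds_collection` or list of them.
#' @return Data frame (organism, id, aa_length, status, reason).
#' @export
qc_report <- function(collections) {
  collections <- as_collection_list(collections)
  out <- do.call(rbind, lapply(collections, `[[`, "qc"))
  rownames(out) <- NULL
  out
}

#' Write a collection to a FASTA file
#'
#' @param collection A `cds_collection`.
#' @param path Output file path.
#' @param width Line-wrap width in nucleotides.
#' @return `path`, invisibly.
#' @export
write_collection_fasta <- function(collection, path, width = 70L) {
  stopifnot(inherits(collection, "cds_collection"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (rec in collection$records) {
    writeLines(paste0(">", rec$id), con)
    s <- rec$nucleotides
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
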