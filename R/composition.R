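# Nucleotide composition diagnostics: GC content by codon position,
# third-position base counts, parity-rule-2 (PR2) coordinates and the
# neutrality (GC12 ~ GC3) regression.

position_bases <- function(record, pos) {
  substr(record$codons, pos, pos)
}

#' GC content of one coding sequence
#'
#' GC fraction overall and at each codon position; `gc12` is the mean of the
#' first- and second-position fractions, the quantity regressed on GC3 in
#' the neutrality plot.
#'
#' @param record A `cds_record` with at least one codon.
#' @return Named list: `gc_all`, `gc1`, `gc2`, `gc3`, `gc12`, all in [0, 1].
#' @export
#' @examples
#' rec <- validate_cds("ATGGCA", id = "g", organism = "toy")$record
#' gc_metrics(rec)$gc_all
gc_metrics <- function(record) {
  stopifnot(inherits(record, "cds_record"))
  n <- record$aa_length
  if (n < 1L) stop("record has zero codons")
  gc_at <- function(pos) {
    b <- position_bases(record, pos)
    sum(b == "G" | b == "C") / n
  }
  gc1 <- gc_at(1L); gc2 <- gc_at(2L); gc3 <- gc_at(3L)
  list(gc_all = (gc1 + gc2 + gc3) / 3, gc1 = gc1, gc2 = gc2, gc3 = gc3,
       gc12 = (gc1 + gc2) / 2)
}

#' Per-record GC table for one or more collections
#'
#' @param collections A `cds_collection` or list of them.
#' @return Data frame (organism, id, gc_all, gc1, gc2, gc3, gc12).
#' @export
gc_table <- function(collections) {
  collections <- as_collection_list(collections)
  rows <- lapply(collections, function(col) {
    if (length(col$records) == 0L) return(NULL)
    m <- t(vapply(col$records, function(r) unlist(gc_metrics(r)), numeric(5)))
    data.frame(organism = col$name,
               id = vapply(col$records, `[[`, character(1), "id"),
               m, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Third-codon-position base counts
#'
#' Counts A/T/G/C at the third codon position. With `fold4_only = TRUE` the
#' tally is restricted to codons of the five fourfold-degenerate families
#' (Ala, Gly, Pro, Thr, Val), where the third position is free of amino-acid
#' constraint — the conventional basis for PR2 analysis. Stop codons are not
#' in any fourfold family and so are excluded there; they are included in the
#' plain tally.
#'
#' @param record A `cds_record`.
#' @param fold4_only Restrict to fourfold-degenerate codons?
#' @return Named list: `a3`, `t3`, `g3`, `c3` (integers), `fold4_only`,
#'   `n` (codons counted).
#' @export
third_position_counts <- function(record, fold4_only = FALSE) {
  stopifnot(inherits(record, "cds_record"))
  codons <- record$codons
  if (fold4_only) codons <- codons[codons %in% FOURFOLD_CODONS]
  b <- substr(codons, 3L, 3L)
  list(a3 = sum(b == "A"), t3 = sum(b == "T"),
       g3 = sum(b == "G"), c3 = sum(b == "C"),
       fold4_only = fold4_only, n = length(codons))
}

#' PR2 plot coordinates from third-position counts
#'
#' Parity rule 2 predicts A = T and G = C at unconstrained positions, i.e.
#' the point (0.5, 0.5). Deviations along x = G3/(G3+C3) and
#' y = A3/(A3+T3) separate mutational from selective strand biases.
#'
#' @param counts Result of [third_position_counts()].
#' @return Named list `x`, `y`, each in [0, 1]; `NULL` with a warning when a
#'   denominator is zero (the record is then excluded from the PR2 plot).
#' @export
pr2_point <- function(counts) {
  gc <- counts$g3 + counts$c3
  at <- counts$a3 + counts$t3
  if (gc == 0L || at == 0L) {
    warning("PR2 point undefined (zero denominator); record excluded",
            call. = FALSE)
    return(NULL)
  }
  list(x = counts$g3 / gc, y = counts$a3 / at)
}

#' Per-record PR2 coordinate table
#'
#' @param collections A `cds_collection` or list of them.
#' @param fold4_only Restrict to fourfold-degenerate codons (default `TRUE`,
#'   the standard PR2 convention).
#' @return Data frame (organism, id, x, y); records with undefined points
#'   are dropped with a warning.
#' @export
pr2_table <- function(collections, fold4_only = TRUE) {
  collections <- as_collection_list(collections)
  rows <- lapply(collections, function(col) {
    pts <- lapply(col$records, function(r) {
      p <- suppressWarnings(pr2_point(third_position_counts(r, fold4_only)))
      if (is.null(p)) return(NULL)
      data.frame(organism = col$name, id = r$id, x = p$x, y = p$y,
                 stringsAsFactors = FALSE)
    })
    dropped <- sum(vapply(pts, is.null, logical(1)))
    if (dropped > 0L)
      warning(sprintf("%s: %d record(s) with undefined PR2 point excluded",
                      col$name, dropped), call. = FALSE)
    do.call(rbind, pts)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least squares of per-gene GC12 on GC3. A slope near 1 indicates
#' that directional mutation pressure acts equally on all codon positions;
#' a slope near 0 indicates selection/constraint decoupling positions 1-2
#' from the third.
#'
#' @param gc12,gc3 Paired numeric vectors (one value per gene), n >= 3.
#' @return Object of class `neutrality_fit`: list with `slope`, `intercept`,
#'   `r2`, `r`, `pvalue` (two-sided, for slope != 0), `n`, and the fitted
#'   `model`.
#' @export
#' @examples
#' set.seed(1)
#' gc3 <- runif(50, 0.2, 0.8)
#' fit <- neutrality_fit(0.3 * gc3 + rnorm(50, 0, 0.01), gc3)
#' fit$slope
neutrality_fit <- function(gc12, gc3) {
  stopifnot(length(gc12) == length(gc3))
  ok <- is.finite(gc12) & is.finite(gc3)
  gc12 <- gc12[ok]; gc3 <- gc3[ok]
  n <- length(gc3)
  if (n < 3L) stop("neutrality fit needs at least 3 genes")
  if (stats::sd(gc3) == 0) stop("GC3 is constant; slope undefined")
  fit <- stats::lm(gc12 ~ gc3)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2L])
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1L]),
         r2 = sm$r.squared,
         r = sign(slope) * sqrt(sm$r.squared),
         pvalue = sm$coefficients[2L, 4L],
         slope_se = sm$coefficients[2L, 2L],
         n = n, model = fit),
    class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(
    "Neutrality regression (n = %d)\n  GC12 = %.4f + %.4f * GC3\n  R2 = %.4f (R = %.4f), p = %.3g\n",
    x$n, x$intercept, x$slope, x$r2, x$r, x$pvalue))
  invisible(x)
}
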