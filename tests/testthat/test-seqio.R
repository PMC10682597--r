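test_that("collections are named after files and ids split at the separator", {
  d <- withr::local_tempdir()
  write_fasta_fixture(c("NC_007373.1|PB2|segment1", "plainheader"),
                      c(strrep("ATGGCA", 40), strrep("GATTCA", 40)),
                      file.path(d, "fluA.fasta"))
  write_fasta_fixture("x|y", strrep("ATGCCA", 30),
                      file.path(d, "fluB.fasta"))
  cols <- read_collections(file.path(d, c("fluA.fasta", "fluB.fasta")),
                           sep = "|")
  expect_named(cols, c("fluA", "fluB"))
  expect_equal(vapply(cols$fluA$records, `[[`, character(1), "id"),
               c("NC_007373.1", "plainheader"))
  expect_equal(cols$fluB$name, "fluB")
  expect_equal(cols$fluB$role, "parasite")
})

test_that("read_host enforces single-host cardinality and role", {
  d <- withr::local_tempdir()
  p <- write_fasta_fixture("h1", strrep("ATGGCA", 50),
                           file.path(d, "host.fasta"))
  host <- read_host(p)
  expect_s3_class(host, "cds_collection")
  expect_equal(host$role, "host")
  expect_error(read_host(c(p, p)), "one host")
})

test_that("unreadable and empty FASTA inputs raise errors naming the file", {
  d <- withr::local_tempdir()
  expect_error(read_collections(file.path(d, "nope.fasta")), "nope.fasta")
  empty <- file.path(d, "empty.fasta")
  writeLines(character(0), empty)
  expect_error(read_collections(empty), "empty.fasta")
})

test_that("duplicate ids are suffixed with a warning", {
  d <- withr::local_tempdir()
  p <- write_fasta_fixture(c("a|1", "a|2", "b"),
                           c(strrep("ATGGCA", 10), strrep("ATGGGA", 10),
                             strrep("ATGTCA", 10)),
                           file.path(d, "dup.fasta"))
  expect_warning(cols <- read_collections(p), "duplicate")
  ids <- vapply(cols$dup$records, `[[`, character(1), "id")
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("validation policy: truncation, ambiguity rejection, stop flagging", {
  v <- validate_cds("atggcgtaa")
  expect_equal(v$record$codons, c("ATG", "GCG", "TAA"))
  expect_false(v$record$internal_stop)

  expect_warning(v2 <- validate_cds("ATGGC"), "trailing")
  expect_equal(v2$record$codons, "ATG")
  expect_equal(v2$record$aa_length, 1L)

  v3 <- validate_cds("ATGNNNAAA")
  expect_null(v3$record)
  expect_equal(v3$reason, "ambiguous base")

  v4 <- validate_cds("ATGTAAGCG")   # internal stop, retained but flagged
  expect_true(v4$record$internal_stop)
  expect_equal(v4$status, "retained")
})

test_that("codon decomposition invariants hold for fuzzed sequences", {
  set.seed(401)
  for (i in 1:25) {
    len <- sample(3:300, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    v <- suppressWarnings(validate_cds(seq))
    if (is.null(v$record)) next
    expect_equal(length(v$record$codons), nchar(v$record$nucleotides) %/% 3)
    expect_equal(v$record$aa_length, length(v$record$codons))
  }
})

test_that("length filtering is inclusive, idempotent and QC-conserving", {
  col <- make_collection(list(strrep("GCA", 50), strrep("GCA", 500),
                              strrep("GCA", 5000)))
  suppressMessages({
    f <- filter_by_length(col, 100, 4000)
    f2 <- filter_by_length(f, 100, 4000)
  })
  expect_equal(length(f$records), 1L)
  expect_equal(f$records[[1]]$aa_length, 500L)
  expect_equal(length_table(f2), length_table(f))

  # bounds at the record length retain it
  at_bound <- make_collection(list(strrep("GCA", 100)))
  expect_equal(length(filter_by_length(at_bound, 100, 4000)$records), 1L)

  # identity bounds
  expect_equal(length(filter_by_length(col, 0, .Machine$integer.max)$records),
               3L)
  expect_error(filter_by_length(col, 4000, 100))

  # parsed = retained + filtered + rejected
  rep <- qc_report(f)
  expect_equal(nrow(rep), 3L)
  expect_equal(sum(rep$status == "retained"), 1L)
  expect_equal(sum(rep$status == "filtered"), 2L)
})

test_that("length_table has one row per record grouped by organism", {
  a <- make_collection(list(strrep("GCA", 100), strrep("GCA", 200)), "orgA")
  b <- make_collection(list(strrep("GCA", 300)), "orgB")
  lt <- length_table(list(orgA = a, orgB = b))
  expect_equal(lt$aa_length, c(100L, 200L, 300L))
  expect_equal(lt$organism, c("orgA", "orgA", "orgB"))
})

test_that("indices are invariant to FASTA line re-wrapping", {
  d <- withr::local_tempdir()
  seqs <- vapply(1:3, function(i) {
    set.seed(i); random_cds(120)
  }, character(1))
  p1 <- write_fasta_fixture(paste0("s", 1:3), seqs,
                            file.path(d, "w60.fasta"), width = 60L)
  p2 <- write_fasta_fixture(paste0("s", 1:3), seqs,
                            file.path(d, "w11.fasta"), width = 11L)
  c1 <- read_collections(p1)[[1]]
  c2 <- read_collections(p2)[[1]]
  expect_equal(codon_counts(c1), codon_counts(c2))
  expect_equal(enc_table(c1)$value, enc_table(c2)$value)
})
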