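mv_fixture <- function() {
  set.seed(416)
  list(
    a = make_collection(lapply(1:3, function(i) random_cds(150)), "vA"),
    b = make_collection(lapply(1:3, function(i) random_cds(150)), "vB"),
    host = make_collection(lapply(1:4, function(i) random_cds(200)), "hum",
                           role = "host"))
}

test_that("RSCU matrix has the contracted shape and exclusions", {
  fx <- mv_fixture()
  m <- build_rscu_matrix(list(vA = fx$a, vB = fx$b), fx$host)
  expect_equal(ncol(m), 59L)
  expect_equal(rownames(m), c("vA", "vB", "hum"))

  m2 <- build_rscu_matrix(list(vA = fx$a, vB = fx$b), fx$host,
                          exclude = c("ATG", "TAA", "TAG", "TGA", "TGG",
                                      "GAA", "GAG"))
  expect_equal(ncol(m2), 57L)

  # identical organisms give identical rows
  twin <- fx$a; twin$name <- "vA2"
  m3 <- build_rscu_matrix(list(vA = fx$a, vA2 = twin))
  expect_equal(unname(m3[1, ]), unname(m3[2, ]))

  expect_error(build_rscu_matrix(list(vA = fx$a), exclude = all_codons),
               "every codon")
})

test_that("PCA matches an independent eigendecomposition up to sign", {
  set.seed(417)
  m <- matrix(rnorm(4 * 3), nrow = 4,
              dimnames = list(paste0("r", 1:4), paste0("c", 1:3)))
  p <- pca_rscu(m)
  oracle <- oracle_pca_scores(m)
  for (j in seq_len(ncol(p$scores)))
    expect_equal(abs(p$scores[, j]), unname(abs(oracle[, j])),
                 tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sum(p$variance_explained), 100, tolerance = 1e-9)
  expect_true(all(diff(p$variance_explained) <= 1e-12))
})

test_that("PCA sign convention and row-permutation invariance", {
  fx <- mv_fixture()
  m <- build_rscu_matrix(list(vA = fx$a, vB = fx$b), fx$host)
  p1 <- pca_rscu(m)
  p2 <- pca_rscu(m[c(2, 3, 1), ])
  expect_equal(p1$scores[rownames(m), ], p2$scores[rownames(m), ],
               tolerance = 1e-9)
  # largest-magnitude loading of each component is positive
  for (j in seq_len(ncol(p1$loadings)))
    expect_gt(p1$loadings[which.max(abs(p1$loadings[, j])), j], 0)
  # duplicated rows map to identical score points
  mdup <- rbind(m, dup = m[1, ])
  pd <- pca_rscu(mdup)
  expect_equal(unname(pd$scores["vA", ]), unname(pd$scores["dup", ]),
               tolerance = 1e-9)
  expect_error(pca_rscu(matrix(1, 3, 4)), "constant")
})

test_that("clustering on PCA scores recovers structure deterministically", {
  set.seed(418)
  blob1 <- matrix(rnorm(5 * 10, 0, 0.05), nrow = 5)
  blob2 <- matrix(rnorm(5 * 10, 3, 0.05), nrow = 5)
  m <- rbind(blob1, blob2)
  rownames(m) <- paste0("s", 1:10)
  p <- pca_rscu(m)
  cl <- cluster_on_pca(p, k = 2, rank = 2, seed = 11)
  expect_equal(length(unique(cl$cluster[1:5])), 1L)
  expect_equal(length(unique(cl$cluster[6:10])), 1L)
  expect_false(cl$cluster[1] == cl$cluster[10])

  cl2 <- cluster_on_pca(p, k = 2, rank = 2, seed = 11)
  expect_identical(cl$cluster, cl2$cluster)

  clh <- cluster_on_pca(p, k = 2, method = "hierarchical",
                        metric = "euclidean", linkage = "ward.D2")
  expect_equal(length(unique(clh$cluster)), 2L)

  expect_equal(unname(cluster_on_pca(p, k = 1, rank = 1)$cluster),
               rep(1L, 10))
  expect_error(cluster_on_pca(p, k = 50), "exceeds")
})

test_that("hierarchical linkage heights match the brute-force oracle", {
  set.seed(419)
  m <- matrix(rnorm(8 * 4), nrow = 8)
  d <- dist(m)
  for (link in c("single", "complete")) {
    hc <- hclust(d, method = link)
    expect_equal(sort(hc$height), oracle_linkage_heights(d, link),
                 tolerance = 1e-9)
  }
})

test_that("heatmap matrices average, order and drop rows correctly", {
  fx <- mv_fixture()
  tab <- rscu_table(list(vA = fx$a, vB = fx$b))
  hm <- heatmap_matrix(tab, average_per_organism = TRUE)
  expect_equal(sort(rownames(hm$matrix)), c("vA", "vB"))
  expect_equal(unname(hm$matrix["vA", ]),
               unname(organism_mean_rscu(fx$a)), tolerance = 1e-12)

  # organism with identical sequences: its mean row equals any member row
  same <- make_collection(list(strrep("GAAGCT", 30), strrep("GAAGCT", 30)),
                          "same")
  tab2 <- rscu_table(same)
  hm2 <- heatmap_matrix(tab2, average_per_organism = TRUE)
  expect_equal(unname(hm2$matrix["same", ]),
               as.numeric(tab2[1, -(1:2)]), tolerance = 1e-12)

  # identical rows are adjacent in the dendrogram order
  tab3 <- rbind(tab, tab[1, ])
  tab3$id[nrow(tab3)] <- "copy"
  hm3 <- heatmap_matrix(tab3)
  pos <- match(c("vA/g1", "vA/copy"), rownames(hm3$matrix)[hm3$row_order])
  expect_equal(abs(diff(pos)), 1L)

  # all-NA rows are dropped with a warning
  tabNA <- tab
  tabNA[1, -(1:2)] <- NA_real_
  expect_warning(hm4 <- heatmap_matrix(tabNA), "all-undefined")
  expect_equal(nrow(hm4$matrix), nrow(tab) - 1L)
})

test_that("organism averaging commutes with record duplication", {
  fx <- mv_fixture()
  dup <- fx$a
  dup$records <- c(dup$records, dup$records)
  expect_equal(organism_mean_rscu(dup), organism_mean_rscu(fx$a),
               tolerance = 1e-12)
})
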