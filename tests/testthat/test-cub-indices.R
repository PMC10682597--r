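test_that("ENc hits its closed-form bounds", {
  one_per_family <- zero_counts()
  for (fam in cubtools::synonymous_families()$codon[
         !duplicated(cubtools::synonymous_families()$aa)])
    one_per_family[fam] <- 30L
  expect_equal(enc_wright(one_per_family), 20)

  uniform <- zero_counts()
  uniform[cubtools::synonymous_families()$codon] <- 10000L
  expect_lt(abs(enc_wright(uniform) - 61), 0.5)
  expect_lt(abs(enc_modified(uniform) - 61), 0.5)
})

test_that("Wright ENc matches the step-by-step oracle on fixed tables", {
  expect_equal(enc_wright(toy_counts()), oracle_enc_wright(toy_counts()),
               tolerance = 1e-12)
  expect_equal(enc_wright(toy_reference()),
               oracle_enc_wright(toy_reference()), tolerance = 1e-12)
})

test_that("modified ENc is defined where Wright's is not", {
  tiny <- zero_counts()
  tiny["GCT"] <- 1L   # one codon total
  expect_true(is.na(enc_wright(tiny)))
  em <- enc_modified(tiny)
  expect_true(is.finite(em))
  expect_gte(em, 20)
  expect_lte(em, 61)

  # large single-codon-per-family gene: modified approaches 20 from above
  big <- zero_counts()
  for (fam in split(cubtools::synonymous_families()$codon,
                    cubtools::synonymous_families()$aa))
    big[fam[1]] <- 5000L
  expect_gt(enc_modified(big), 20)
  expect_lt(enc_modified(big), 20.5)
})

test_that("MILC identity, monotonicity and oracle equivalence", {
  ref <- toy_reference()
  m_id <- milc(ref, ref)
  expect_equal(as.numeric(m_id), -attr(m_id, "correction"), tolerance = 1e-12)

  expect_equal(as.numeric(milc(toy_counts(), ref)),
               oracle_milc(toy_counts(), ref), tolerance = 1e-12)

  # shifting one family's usage away from the reference increases MILC
  near <- zero_counts(); far <- zero_counts()
  near[c("GAA", "GAG")] <- c(55L, 45L)
  far[c("GAA", "GAG")] <- c(90L, 10L)
  ref2 <- zero_counts(); ref2[c("GAA", "GAG")] <- c(50L, 50L)
  expect_gt(as.numeric(milc(far, ref2)), as.numeric(milc(near, ref2)))
})

test_that("B index identity, range and maximal contrast", {
  ref <- toy_reference()
  expect_equal(b_index(ref, ref), 0, tolerance = 1e-12)
  expect_equal(b_index(toy_counts(), ref), oracle_b(toy_counts(), ref),
               tolerance = 1e-12)

  # gene on one 2-fold codon, reference purely on the other: L1 distance 2
  g <- zero_counts(); g["GAA"] <- 20L
  r <- zero_counts(); r[all_codons] <- 1L; r["GAG"] <- 1000L; r["GAA"] <- 0L
  # no pseudocount fires (all reference codons nonzero except via GAA=0)
  r["GAA"] <- 1L
  b <- b_index(g, r)
  expect_gt(b, 1.9)
  expect_lte(b, 2)
})

test_that("MCB is zero at identity and monotone in divergence", {
  ref <- toy_reference()
  expect_equal(mcb(ref, ref), 0, tolerance = 1e-12)
  near <- zero_counts(); far <- zero_counts()
  near[c("GGT", "GGC", "GGA", "GGG")] <- c(26L, 26L, 24L, 24L)
  far[c("GGT", "GGC", "GGA", "GGG")] <- c(70L, 10L, 10L, 10L)
  runi <- zero_counts(); runi[all_codons] <- 25L
  expect_gt(mcb(far, runi), mcb(near, runi))
  expect_gte(mcb(near, runi), 0)
})

test_that("CAI weights and geometric mean behave per Sharp-Li", {
  ref <- toy_reference()
  w <- cai_weights(ref)
  fams <- split(cubtools::synonymous_families()$codon,
                cubtools::synonymous_families()$aa)
  for (fam in fams) expect_equal(max(w[fam]), 1)
  expect_true(all(w > 0 & w <= 1))

  # gene of only family-maximal codons scores 1
  opt <- vapply(fams, function(fam) names(which.max(w[fam])), character(1))
  g <- zero_counts(); g[opt] <- 5L
  expect_equal(cai(g, w), 1)

  # two-codon gene with w = 1 and w = 0.25: geometric mean 0.5
  w2 <- stats::setNames(rep(1, length(w)), names(w))
  w2["GAG"] <- 0.25
  g2 <- zero_counts(); g2[c("GAA", "GAG")] <- 1L
  expect_equal(cai(g2, w2), 0.5)

  # uniform reference makes every weight 1, so CAI = 1 for any gene
  runi <- zero_counts(); runi[all_codons] <- 7L
  expect_equal(cai(toy_counts(), cai_weights(runi)), 1)
})

test_that("FOP counts optimal codons as fractions", {
  ref <- toy_reference()
  opt <- optimal_codons(ref)
  g_all <- zero_counts(); g_all[opt] <- 3L
  expect_equal(fop(g_all, opt), 1)
  g_none <- zero_counts()
  g_none[setdiff(cubtools::synonymous_families()$codon, opt)[1:5]] <- 2L
  expect_equal(fop(g_none, opt), 0)
  g_mix <- zero_counts(); g_mix[c("GAA", "GAG")] <- c(4L, 6L)  # GAA optimal
  expect_equal(fop(g_mix, opt), 0.4)
})

test_that("MELP and E compose their building blocks and flag degeneracy", {
  set.seed(410)
  bg <- codon_counts(make_collection(lapply(1:5, function(i) random_cds(200))))
  ref <- toy_reference()
  g <- codon_counts(make_record(random_cds(150)))
  expect_equal(melp(g, bg, ref),
               as.numeric(milc(g, bg)) / as.numeric(milc(g, ref)),
               tolerance = 1e-12)
  expect_equal(e_index(g, bg, ref), b_index(g, bg) / b_index(g, ref),
               tolerance = 1e-12)
  expect_equal(e_index(ref, ref, ref), 1)

  # gene closer to the reference than to background scores E > 1
  gene_like_ref <- zero_counts(); gene_like_ref[c("GAA", "GAG")] <- c(85L, 15L)
  ref3 <- zero_counts(); ref3[c("GAA", "GAG")] <- c(9L, 1L)
  bg3 <- zero_counts(); bg3[c("GAA", "GAG")] <- c(5L, 5L)
  expect_gt(e_index(gene_like_ref, bg3, ref3), 1)
})

test_that("RSCU normalization, concentration and oracle equivalence", {
  runi <- zero_counts(); runi[all_codons] <- 4L
  expect_true(all(abs(rscu(runi) - 1) < 1e-12))

  leu <- zero_counts(); leu["CTG"] <- 11L
  r <- rscu(leu)
  expect_equal(r[["CTG"]], 6)
  expect_equal(sum(r[c("CTT", "CTC", "CTA", "TTA", "TTG")]), 0)

  glu <- zero_counts(); glu[c("GAA", "GAG")] <- c(3L, 1L)
  expect_equal(rscu(glu)[c("GAA", "GAG")], c(GAA = 1.5, GAG = 0.5))

  expect_equal(as.numeric(rscu(toy_counts())),
               as.numeric(oracle_rscu(toy_counts())[names(rscu(toy_counts()))]),
               tolerance = 1e-12)
})

test_that("reference-based indices are invariant to reference duplication", {
  ref <- toy_reference()
  g <- toy_counts()
  for (m in c(2L, 7L)) {
    expect_equal(as.numeric(milc(g, ref * m)), as.numeric(milc(g, ref)),
                 tolerance = 1e-12)
    expect_equal(b_index(g, ref * m), b_index(g, ref), tolerance = 1e-12)
    expect_equal(mcb(g, ref * m), mcb(g, ref), tolerance = 1e-12)
    expect_equal(cai(g, cai_weights(ref * m)), cai(g, cai_weights(ref)),
                 tolerance = 1e-12)
  }
})

test_that("table wrappers carry reference provenance and fall back to self", {
  set.seed(411)
  col <- make_collection(lapply(1:3, function(i) random_cds(150)), "orgA")
  host <- make_collection(lapply(1:4, function(i) random_cds(200)), "hostX",
                          role = "host")
  self_tab <- milc_table(col)
  expect_equal(unique(self_tab$reference_used), "self")
  host_tab <- milc_table(col, host)
  expect_equal(unique(host_tab$reference_used), "host")
  expect_error(cai_table(col, NULL), "host")
  expect_error(fop_table(col, NULL), "host")
})
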