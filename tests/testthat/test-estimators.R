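test_that("allele frequencies, H_obs and E are counted correctly", {
  g <- make_geno(list(i1 = list(L1 = c("A", "A")),
                      i2 = list(L1 = c("A", "B"))))
  fr <- allele_frequencies(g)
  expect_equal(fr$freq$L1, c(A = 0.75, B = 0.25))
  expect_equal(unname(fr$h_obs["L1"]), 0.5)
  expect_equal(unname(fr$e_het["L1"]), 0.375)

  # missing genotypes are excluded from the counts
  g2 <- make_geno(list(i1 = list(L1 = c("A", "A"), L2 = c("C", "D")),
                       i2 = list(L1 = c("A", "B")),
                       i3 = list(L1 = c("B", "B"))))
  fr2 <- allele_frequencies(g2)
  expect_equal(unname(fr2$n_typed["L2"]), 1L)
  expect_equal(fr2$freq$L1, c(A = 0.5, B = 0.5))

  # monomorphic locus
  g3 <- make_geno(list(i1 = list(L1 = c("A", "A")),
                       i2 = list(L1 = c("A", "A"))))
  fr3 <- allele_frequencies(g3)
  expect_equal(unname(fr3$e_het["L1"]), 0)
  expect_equal(unname(fr3$h_obs["L1"]), 0)

  expect_error(allele_frequencies(g, exclude = c("i1", "i2")), "no individuals")
  expect_error(genotype_table("i1", matrix("A", 1, 1), matrix(NA, 1, 1)),
               "half-called")
})

test_that("SH matches hand-computed values", {
  # focal het at 2 of 4 loci, population H_obs = 0.5 at each -> SH = 1
  pop <- lapply(1:8, function(i) {
    setNames(lapply(1:4, function(l) {
      if (i %% 2 == 0) c("A", "B") else c("A", "A")
    }), paste0("L", 1:4))
  })
  names(pop) <- paste0("p", 1:8)
  pop$focal <- list(L1 = c("A", "B"), L2 = c("A", "B"),
                    L3 = c("A", "A"), L4 = c("A", "A"))
  g <- make_geno(pop)
  fr <- allele_frequencies(g, exclude = "focal")
  expect_equal(unname(fr$h_obs), rep(0.5, 4))
  expect_equal(standardized_heterozygosity("focal", g, fr, min_loci = 4), 1.0)

  # all-homozygous individual -> SH = 0
  pop$focal <- setNames(lapply(1:4, function(l) c("A", "A")), paste0("L", 1:4))
  g <- make_geno(pop)
  expect_equal(standardized_heterozygosity("focal", g,
                                           allele_frequencies(g, exclude = "focal"),
                                           min_loci = 4), 0)

  # het at every locus with mean population H_obs = 0.8 -> SH = 1.25
  pop2 <- lapply(1:10, function(i) {
    setNames(lapply(1:5, function(l) {
      if (i <= 8) c("A", "B") else c("A", "A")  # H_obs = 0.8 per locus
    }), paste0("L", 1:5))
  })
  names(pop2) <- paste0("p", 1:10)
  pop2$focal <- setNames(lapply(1:5, function(l) c("A", "B")), paste0("L", 1:5))
  g2 <- make_geno(pop2)
  fr2 <- allele_frequencies(g2, exclude = "focal")
  expect_equal(unname(fr2$h_obs), rep(0.8, 5))
  expect_equal(standardized_heterozygosity("focal", g2, fr2, min_loci = 5), 1.25)
})

test_that("IR matches hand-computed values", {
  # homozygous everywhere -> IR = 1 regardless of frequencies
  g <- make_geno(list(f = list(L1 = c("A", "A"), L2 = c("C", "C")),
                      o1 = list(L1 = c("A", "B"), L2 = c("C", "D")),
                      o2 = list(L1 = c("B", "B"), L2 = c("D", "D"))))
  expect_equal(internal_relatedness("f", g, min_loci = 2), 1)

  # one heterozygous locus with p = 0.5/0.5 -> IR = -1
  g2 <- make_geno(list(f = list(L1 = c("A", "B")),
                       o = list(L1 = c("A", "B"))))
  expect_equal(internal_relatedness("f", g2, min_loci = 1), -1)

  # hom for a freq-0.5 allele plus het with two freq-0.25 alleles -> IR = 0.2
  # frequencies are fixed by an explicit reference sample
  ref <- list(
    f  = list(L1 = c("A", "A"), L2 = c("C", "D")),
    o1 = list(L1 = c("A", "A"), L2 = c("C", "D")),
    o2 = list(L1 = c("B", "B"), L2 = c("E", "F")),
    o3 = list(L1 = c("B", "B"), L2 = c("E", "F")))
  g3 <- make_geno(ref)
  fr <- allele_frequencies(g3)
  expect_equal(unname(fr$freq$L1["A"]), 0.5)
  expect_equal(unname(fr$freq$L2["C"]), 0.25)
  expect_equal(internal_relatedness("f", g3, fr, min_loci = 2),
               (2 - 1.5) / (4 - 1.5))
})

test_that("HL matches its boundary identities and hand values", {
  g <- make_geno(list(f = list(L1 = c("A", "A"), L2 = c("C", "C")),
                      o1 = list(L1 = c("A", "B"), L2 = c("C", "D")),
                      o2 = list(L1 = c("B", "B"), L2 = c("D", "D"))))
  expect_equal(homozygosity_by_loci("f", g, min_loci = 2), 1)
  expect_equal(homozygosity_by_loci("o1", g, min_loci = 2), 0)

  # two loci with E = 0.5 each, one homozygous and one heterozygous -> 0.5
  ref <- list(f = list(L1 = c("A", "A"), L2 = c("C", "D")),
              o1 = list(L1 = c("A", "B"), L2 = c("C", "D")),
              o2 = list(L1 = c("B", "A"), L2 = c("D", "C")),
              o3 = list(L1 = c("B", "B"), L2 = c("D", "C")))
  g2 <- make_geno(ref)
  fr <- allele_frequencies(g2)
  expect_equal(unname(fr$e_het), c(0.5, 0.5))
  expect_equal(homozygosity_by_loci("f", g2, fr, min_loci = 2), 0.5)

  # all typed loci monomorphic -> undefined
  g3 <- make_geno(list(f = list(L1 = c("A", "A")),
                       o = list(L1 = c("A", "A"))))
  expect_warning(hl <- homozygosity_by_loci("f", g3, min_loci = 1),
                 "monomorphic")
  expect_true(is.na(hl))
})

test_that("estimators are invariant to locus order and respect bounds", {
  set.seed(31)
  sim <- small_sim()
  g <- sim$genotypes
  fr <- allele_frequencies(g)
  ids <- sample(g$ids, 12)
  perm <- sample(length(g$loci))
  gp <- genotype_table(g$ids, g$a1[, perm], g$a2[, perm])
  frp <- allele_frequencies(gp)
  for (i in ids) {
    sh <- standardized_heterozygosity(i, g, fr, min_loci = 5)
    ir <- internal_relatedness(i, g, fr, min_loci = 5)
    hl <- homozygosity_by_loci(i, g, fr, min_loci = 5)
    expect_equal(standardized_heterozygosity(i, gp, frp, min_loci = 5), sh)
    expect_equal(internal_relatedness(i, gp, frp, min_loci = 5), ir)
    expect_equal(homozygosity_by_loci(i, gp, frp, min_loci = 5), hl)
    expect_gte(sh, 0)
    expect_gte(ir, -1); expect_lte(ir, 1)
    expect_gte(hl, 0);  expect_lte(hl, 1)
  }
})

test_that("estimate_all flags degenerate inputs instead of guessing", {
  # single individual: correlations undefined
  g1 <- make_geno(list(f = list(L1 = c("A", "B"), L2 = c("C", "C"))))
  expect_warning(e1 <- estimate_all(g1, min_loci = 2), "fewer than 2")
  expect_true(all(is.na(e1$correlations)))

  # identical genotypes for everyone: zero variance, correlations undefined
  same <- setNames(lapply(1:3, function(l) c("A", "B")), paste0("L", 1:3))
  g2 <- make_geno(list(i1 = same, i2 = same, i3 = same))
  expect_warning(e2 <- estimate_all(g2, min_loci = 3), "zero-variance")
  expect_true(all(is.na(e2$correlations)))

  # individuals under the locus filter are reported with NA, not dropped
  g3 <- make_geno(list(rich = list(L1 = c("A", "B"), L2 = c("C", "D")),
                       rich2 = list(L1 = c("A", "A"), L2 = c("C", "C")),
                       poor = list(L1 = c("A", "B"))))
  e3 <- suppressWarnings(estimate_all(g3, min_loci = 2))
  expect_equal(nrow(e3$results), 3L)
  expect_true(is.na(e3$results$SH[e3$results$id == "poor"]))
})
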