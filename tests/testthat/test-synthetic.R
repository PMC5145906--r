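test_that("the founder cohort matches the configured composition", {
  st <- generate_founders(founder_config(), seed = 17)
  expect_length(st$id, 409L)
  age <- as.numeric(st$start_date - st$birth_date) / 365.25
  expect_equal(sum(st$sex == "F" & age >= 4), 183L)
  expect_equal(sum(st$sex == "M" & age >= 4), 40L)
  expect_equal(length(unique(st$cur_group)), 6L)
  # adult males are immigrants: never natal to their current group
  adult_m <- st$sex == "M" & age >= 4
  expect_true(all(st$birth_group[adult_m] != st$cur_group[adult_m]))

  # founder heterozygosity is binomial around 1 - sum(p^2)
  st2 <- generate_founders(founder_config(n_founders = 400,
                                          n_adult_females = 180,
                                          n_adult_males = 40,
                                          n_loci = 1, alleles_per_locus = 8),
                           seed = 18)
  e <- 1 - sum((rep(1 / 8, 8))^2)  # 0.875
  h <- mean(st2$founder_geno$a1[, 1] != st2$founder_geno$a2[, 1])
  expect_lt(abs(h - e), 3 * sqrt(e * (1 - e) / 400))

  expect_error(generate_founders(founder_config(n_founders = 10,
                                                n_adult_females = 8,
                                                n_adult_males = 8)),
               "exceed")
})

test_that("pedigree-only simulation is possible with zero loci", {
  cfg <- founder_config(n_founders = 20, n_adult_females = 8,
                        n_adult_males = 4, n_groups = 2, n_loci = 0)
  sim <- simulate_population(cfg, demography_config(n_years = 4),
                             mate_choice_model(0), seed = 2)
  expect_null(sim$genotypes)
  expect_gt(sim$pedigree$n, 20)
})

test_that("gene-dropped genotypes are Mendelian-consistent everywhere", {
  sim <- small_sim()
  g <- sim$genotypes
  p <- sim$pedigree
  for (k in seq_len(p$n)) {
    s <- p$sire_idx[k]
    d <- p$dam_idx[k]
    if (is.na(s)) next
    expect_true(g$a1[k, ] %in% c(g$a1[s, ], g$a2[s, ]) |> all())
    expect_true(g$a2[k, ] %in% c(g$a1[d, ], g$a2[d, ]) |> all())
  }
})

test_that("genotype missingness and seeding behave as configured", {
  sim <- small_sim()
  founder <- is.na(sim$pedigree$sire_idx)
  fg <- list(a1 = sim$genotypes$a1[founder, ],
             a2 = sim$genotypes$a2[founder, ])
  g1 <- drop_genotypes(sim$pedigree, fg, missing_rate = 0.1, seed = 5)
  frac <- mean(is.na(g1$a1))
  n_cells <- length(g1$a1)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / n_cells))
  # identical seed, identical table
  g2 <- drop_genotypes(sim$pedigree, fg, missing_rate = 0.1, seed = 5)
  expect_identical(g1$a1, g2$a1)
  expect_identical(g1$a2, g2$a2)

  # ungenotyped founder is an error
  fg1 <- list(a1 = fg$a1[-1, ], a2 = fg$a2[-1, ])
  expect_error(drop_genotypes(sim$pedigree, fg1), "ungenotyped founder")
})

test_that("generative sire categories hit the configured fractions", {
  sim <- small_sim()
  asg <- sim$assignments
  n <- nrow(asg)
  expect_gt(n, 100)
  for (cat in c("extra", "natal")) {
    p0 <- c(extra = 0.24, natal = 0.16)[[cat]]
    frac <- mean(asg$category == cat)
    expect_lt(abs(frac - p0), 3 * sqrt(p0 * (1 - p0) / n) + 2 / n)
  }
})

test_that("degenerate demographies behave sensibly", {
  cfg <- founder_config(n_founders = 16, n_adult_females = 6,
                        n_adult_males = 4, n_groups = 2, n_loci = 0)
  # zero birth probability: no offspring at all
  sim0 <- simulate_population(cfg, demography_config(n_years = 3,
                                                     birth_prob = 0),
                              mate_choice_model(0), seed = 4)
  expect_equal(sim0$pedigree$n, 16L)
  # catastrophic mortality: extinction warning, partial output
  expect_warning(
    simx <- simulate_population(cfg,
                                demography_config(n_years = 10,
                                                  adult_mortality = 0.95,
                                                  infant_mortality = 0.95),
                                mate_choice_model(0), seed = 4),
    "extinct")
  expect_true(simx$extinct)

  # single group with p_extra = 0: every sire shares the mother's group
  cfg1 <- founder_config(n_founders = 20, n_adult_females = 8,
                         n_adult_males = 4, n_groups = 1, n_loci = 0)
  sim1 <- simulate_population(cfg1,
                              demography_config(n_years = 6, p_extra = 0),
                              mate_choice_model(0), seed = 6)
  expect_true(all(sim1$demography$group == "G1"))
})

test_that("strict kin avoidance lowers inbreeding relative to random mating", {
  cfg <- founder_config(n_founders = 40, n_adult_females = 16,
                        n_adult_males = 6, n_groups = 2, n_loci = 0)
  dcfg <- demography_config(n_years = 14, adult_mortality = 0.07)
  diff <- numeric(5)
  for (k in 1:5) {
    s0 <- simulate_population(cfg, dcfg, mate_choice_model(theta = 0),
                              seed = 500 + k)
    s1 <- simulate_population(cfg, dcfg, mate_choice_model(theta = 1),
                              seed = 500 + k)
    # compare fractions with F at least the avoidance threshold
    f0 <- mean(s0$true_F >= 0.03125, na.rm = TRUE)
    f1 <- mean(s1$true_F >= 0.03125, na.rm = TRUE)
    diff[k] <- f0 - f1
  }
  expect_gt(mean(diff), 0)
  # under theta = 1 no realised pair is related at or above the threshold
  pairs <- sim_breeding_records(s1 <- simulate_population(
    cfg, dcfg, mate_choice_model(theta = 1), seed = 901))
  r <- mapply(function(m, s) relatedness(s1$pedigree, m, s),
              pairs$mother, pairs$sire)
  expect_true(all(r < 0.0625))
})

test_that("simulation output is reproducible under a fixed seed", {
  cfg <- founder_config(n_founders = 30, n_adult_females = 12,
                        n_adult_males = 5, n_groups = 2, n_loci = 5)
  dcfg <- demography_config(n_years = 6)
  s1 <- simulate_population(cfg, dcfg, mate_choice_model(0), seed = 11)
  s2 <- simulate_population(cfg, dcfg, mate_choice_model(0), seed = 11)
  expect_identical(s1$pedigree$ped, s2$pedigree$ped)
  expect_identical(s1$genotypes$a1, s2$genotypes$a1)
  expect_identical(s1$demography, s2$demography)
  expect_identical(s1$true_F, s2$true_F)
})

test_that("recovery harness reproduces truth from emitted files", {
  sim <- small_sim()
  rep <- recovery_harness(sim, avoidance_scheme(n_sim = 20,
                                                completeness_filter_depth = 1),
                          min_loci = 5)
  expect_true(rep$f_recovery$exact)
  expect_equal(rep$f_recovery$max_abs_diff, 0)
  expect_true(!is.null(rep$estimator_correlations))
  expect_true(is.numeric(rep$avoidance$P))
})
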