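# hand-built demography scenario: one mother in G1 and males of every kind
.toy_scenario <- function() {
  ped <- build_pedigree(data.frame(
    id = c("MOM", "M_natal", "M_within", "M_extra", "M_dead", "M_young"),
    sire = NA, dam = NA,
    sex = c("F", "M", "M", "M", "M", "M"),
    birth_date = c("2000-01-01", "2005-03-01", "2005-03-01", "2005-03-01",
                   "2005-03-01", "2011-10-01"),
    death_date = c(NA, NA, NA, NA, "2014-01-01", NA),
    birth_group = c("G1", "G1", "G2", "G2", "G1", "G1")))
  demog <- data.frame(
    id = c("MOM", "M_natal", "M_within", "M_within", "M_extra", "M_dead",
           "M_young"),
    group = c("G1", "G1", "G2", "G1", "G2", "G1", "G1"),
    start_date = as.Date(c("2000-01-01", "2005-03-01", "2005-03-01",
                           "2010-06-01", "2005-03-01", "2005-03-01",
                           "2011-10-01")),
    end_date = as.Date(c(NA, NA, "2010-06-01", NA, NA, "2014-01-01", NA)))
  list(ped = ped, demog = demog)
}

test_that("eligible sire pools respect survival, maturity, groups and natality", {
  sc <- .toy_scenario()
  scheme <- avoidance_scheme(completeness_filter_depth = 0)
  # offspring born 2015-06-15, conceived 166 days earlier (2014-12-31)
  pools <- eligible_sires(sc$ped, sc$demog,
                          list(mother = "MOM", birth_date = "2015-06-15"),
                          scheme)
  expect_equal(pools$natal, "M_natal")    # natal male is not in the within pool
  expect_equal(pools$within, "M_within")  # immigrant male in mother's group
  expect_equal(pools$extra, "M_extra")
  # dead before conception and 3.2-year-old are excluded everywhere
  expect_false("M_dead" %in% unlist(pools))
  expect_false("M_young" %in% unlist(pools))
  # default completeness filter (depth 2) excludes all these founder males
  expect_error(eligible_sires(sc$ped, sc$demog,
                              list(mother = "MOM", birth_date = "2015-06-15")),
               "no eligible sire")
})

test_that("group_at resolves half-open membership intervals", {
  sc <- .toy_scenario()
  expect_equal(group_at(sc$demog, "M_within", as.Date("2009-01-01")), "G2")
  expect_equal(group_at(sc$demog, "M_within", as.Date("2010-06-01")), "G1")
  expect_equal(group_at(sc$demog, "M_dead", as.Date("2014-01-01")),
               NA_character_)
})

test_that("skew subsampling sizes, age window and degenerate pools behave", {
  set.seed(1)
  pool <- paste0("m", 1:10)
  expect_length(skew_subsample(pool, 0.2), 2L)
  expect_length(skew_subsample(paste0("m", 1:3), 0.2), 1L)  # minimum of one
  expect_setequal(skew_subsample(pool, 1.0), pool)
  # age window restricts, and falls back to the whole pool when empty
  ages <- c(rep(10, 3), rep(20, 7))
  s <- skew_subsample(pool, 0.5, ages = ages, window = c(9, 11))
  expect_true(all(s %in% pool[1:3]))
  s2 <- skew_subsample(pool, 0.2, ages = rep(20, 10), window = c(9, 11))
  expect_length(s2, 2L)
  expect_error(skew_subsample(character(0), 0.2), "empty")
})

test_that("simulated datasets use exact category counts", {
  sim <- small_sim()
  pairs <- head(sim_breeding_records(sim), 100)
  scheme <- avoidance_scheme(completeness_filter_depth = 0)
  set.seed(8)
  d <- simulate_dataset(sim$pedigree, sim$demography, pairs, scheme)
  expect_equal(nrow(d), 100L)
  tab <- table(d$category)
  expect_equal(unname(tab[c("extra", "natal", "within")]),
               c(24L, 16L, 60L), ignore_attr = TRUE)
  expect_true(all(!is.na(d$sire)))

  # excluding natal breeding reassigns the natal share to within-group
  set.seed(8)
  d2 <- simulate_dataset(sim$pedigree, sim$demography, pairs,
                         avoidance_scheme(completeness_filter_depth = 0,
                                          include_natal = FALSE))
  expect_equal(sum(d2$category == "natal"), 0L)
  expect_equal(sum(d2$category == "within"), 76L)
})

test_that("a single-group population forces extra-group draws to fall back", {
  cfg <- founder_config(n_founders = 30, n_adult_females = 12,
                        n_adult_males = 6, n_groups = 1, n_loci = 0)
  sim1 <- simulate_population(cfg, demography_config(n_years = 8),
                              mate_choice_model(0), seed = 77)
  pairs <- sim_breeding_records(sim1)
  set.seed(3)
  expect_warning(
    d <- simulate_dataset(sim1$pedigree, sim1$demography, pairs,
                          avoidance_scheme(completeness_filter_depth = 0)),
    "fallback")
  expect_true(all(d$category_used[d$category == "extra"] != "extra"))
})

test_that("the permutation convention includes the observed dataset", {
  pp <- permutation_p(0.001, rep(0.01, 999))
  expect_equal(pp$P, 0.001)
  expect_equal(pp$n_sim, 1000L)
  # observed appears exactly once in the null means
  expect_equal(sum(pp$null_means == 0.001), 1L)
  # all tied -> P = 1
  expect_equal(permutation_p(0.5, rep(0.5, 99))$P, 1)
  # observed above all simulated -> P = 1
  expect_equal(permutation_p(0.9, runif(99, 0, 0.1))$P, 1)
  expect_error(permutation_p(0.1, numeric(0)), "at least one")
})

test_that("observed statistics summarise relatedness classes", {
  s <- summarize_r_values(c(0, 0, 0.0625, 0.125, 0.25, 0.5, 0.3))
  expect_equal(unname(s$histogram["other"]), 1L, ignore_attr = TRUE)
  expect_equal(unname(s$histogram["0"]), 2L, ignore_attr = TRUE)
  expect_error(summarize_r_values(numeric(0)), "empty")

  # founder x founder pairs: all unrelated
  ped <- build_pedigree(data.frame(
    id = c("A", "B", "C", "D", "X", "Y"),
    sire = c(NA, NA, NA, NA, "A", "C"),
    dam = c(NA, NA, NA, NA, "B", "D"),
    sex = c("M", "F", "M", "F", "U", "U")))
  pairs <- data.frame(offspring = c("X", "Y"), mother = c("B", "D"),
                      sire = c("A", "C"))
  obs <- observed_statistic(ped, pairs, depth_limit = 2)
  expect_equal(obs$mean, 0)
  expect_equal(obs$prop_unrelated, 1)
})

test_that("excluding natal breeders lowers the null mean relatedness", {
  # natal males are the locally related candidates; removing them shifts
  # their share to non-natal group males and the expected parental
  # relatedness drops
  sim <- small_sim()
  pairs <- sim_breeding_records(sim)
  ri <- run_avoidance(sim$pedigree, sim$demography, pairs,
                      avoidance_scheme(n_sim = 200,
                                       completeness_filter_depth = 1),
                      seed = 5)
  re <- run_avoidance(sim$pedigree, sim$demography, pairs,
                      avoidance_scheme(n_sim = 200,
                                       completeness_filter_depth = 1,
                                       include_natal = FALSE),
                      seed = 5)
  expect_lt(re$null_summary$mean, ri$null_summary$mean)
})

test_that("identical seeds reproduce the null distribution bit for bit", {
  sim <- small_sim()
  pairs <- sim_breeding_records(sim)
  scheme <- avoidance_scheme(n_sim = 30, completeness_filter_depth = 1)
  r1 <- run_avoidance(sim$pedigree, sim$demography, pairs, scheme, seed = 123)
  r2 <- run_avoidance(sim$pedigree, sim$demography, pairs, scheme, seed = 123)
  expect_identical(r1$null_means, r2$null_means)
  expect_identical(r1$P, r2$P)
  expect_equal(r1$null_means[1], r1$observed_mean_r)
  expect_gte(r1$P, 1 / scheme$n_sim)
  expect_lte(r1$P, 1)
})
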