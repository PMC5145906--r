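#' Founder cohort configuration
#'
#' Defaults mirror a large managed island colony founded from wild-caught
#' animals: 409 founders of which 183 adult females and 40 adult males, the
#' remainder immatures, living in several social groups, genotyped at ~30
#' highly polymorphic codominant loci.
#'
#' @param n_founders Total founders (default 409).
#' @param n_adult_females,n_adult_males Adult founders by sex (183 / 40).
#' @param n_groups Number of social groups (default 6).
#' @param n_loci Marker loci (default 30; 0 = pedigree-only simulation).
#' @param alleles_per_locus Alleles per locus (default 8).
#' @param freq_dist Founder allele-frequency distribution: `"uniform"` (equal
#'   frequencies) or `"dirichlet"`.
#' @param dirichlet_alpha Concentration for `"dirichlet"` (default 1).
#' @param adult_age_range Age range (years) of adult founders at release.
#' @param immature_age_max Maximum age of immature founders.
#' @param start_date Release date of the founder cohort.
#' @return Object of class `founder_config`.
#' @export
founder_config <- function(n_founders = 409, n_adult_females = 183,
                           n_adult_males = 40, n_groups = 6, n_loci = 30,
                           alleles_per_locus = 8,
                           freq_dist = c("uniform", "dirichlet"),
                           dirichlet_alpha = 1,
                           adult_age_range = c(4, 15), immature_age_max = 4,
                           start_date = as.Date("1938-12-01")) {
  freq_dist <- match.arg(freq_dist)
  if (n_adult_females + n_adult_males > n_founders) {
    stop("adult founders exceed n_founders")
  }
  stopifnot(n_groups >= 1, n_loci >= 0, alleles_per_locus >= 1,
            adult_age_range[1] < adult_age_range[2], immature_age_max > 0)
  structure(list(n_founders = n_founders, n_adult_females = n_adult_females,
                 n_adult_males = n_adult_males, n_groups = n_groups,
                 n_loci = n_loci, alleles_per_locus = alleles_per_locus,
                 freq_dist = freq_dist, dirichlet_alpha = dirichlet_alpha,
                 adult_age_range = adult_age_range,
                 immature_age_max = immature_age_max,
                 start_date = as.Date(start_date)),
            class = "founder_config")
}

#' Demographic configuration for the population simulator
#'
#' Yearly-step demography with overlapping generations and one birth season
#' per year: each adult female gives birth to at most one offspring per
#' season; males disperse from their natal group around puberty; sires are
#' assigned under the extra-group / natal / within-group scheme with
#' reproductive skew, the same scheme the avoidance test uses as its null.
#'
#' @param n_years Breeding seasons to simulate.
#' @param birth_prob Per-season birth probability per adult female.
#' @param infant_mortality Probability of death in the first year of life
#'   (default 0.144).
#' @param adult_mortality Annual death probability after the first year.
#' @param dispersal_age_range Uniform range (years) of male natal dispersal
#'   age (default 3-6, median 4.5).
#' @param maturity_age Age (years) at which both sexes can breed.
#' @param p_extra,p_natal,skew_fraction,skew_age_window Generative sire
#'   assignment parameters, as in [avoidance_scheme()].
#' @param conception_offset Gestation length in days.
#' @param culling_target Optional population ceiling; when exceeded at the
#'   end of a year, random 1-3 year olds are removed (flagged `removed`).
#' @return Object of class `demography_config`.
#' @export
demography_config <- function(n_years = 20, birth_prob = 0.65,
                              infant_mortality = 0.144,
                              adult_mortality = 0.05,
                              dispersal_age_range = c(3, 6),
                              maturity_age = 4.0,
                              p_extra = 0.24, p_natal = 0.16,
                              skew_fraction = 0.20, skew_age_window = NULL,
                              conception_offset = 166,
                              culling_target = NULL) {
  stopifnot(n_years >= 1, birth_prob >= 0, birth_prob <= 1,
            infant_mortality >= 0, infant_mortality <= 1,
            adult_mortality >= 0, adult_mortality <= 1,
            dispersal_age_range[1] < dispersal_age_range[2],
            maturity_age >= 0, p_extra + p_natal <= 1)
  structure(list(n_years = as.integer(n_years), birth_prob = birth_prob,
                 infant_mortality = infant_mortality,
                 adult_mortality = adult_mortality,
                 dispersal_age_range = dispersal_age_range,
                 maturity_age = maturity_age, p_extra = p_extra,
                 p_natal = p_natal, skew_fraction = skew_fraction,
                 skew_age_window = skew_age_window,
                 conception_offset = conception_offset,
                 culling_target = culling_target),
            class = "demography_config")
}

#' Kin-avoidant mate choice model
#'
#' `theta` is the probability that a candidate sire related to the mother at
#' `r >= r_threshold` is rejected and redrawn. `theta = 0` reproduces the
#' null sire-assignment scheme exactly; `theta = 1` guarantees that no
#' realised pair has `r >= r_threshold` (a female skips breeding when no
#' unrelated candidate exists anywhere).
#'
#' @param theta Avoidance strength in `[0, 1]`.
#' @param r_threshold Relatedness threshold (default 0.0625).
#' @param max_redraws Redraw cap for `0 < theta < 1`.
#' @return Object of class `mate_choice_model`.
#' @export
mate_choice_model <- function(theta = 0, r_threshold = 0.0625,
                              max_redraws = 50) {
  stopifnot(theta >= 0, theta <= 1, r_threshold > 0, max_redraws >= 1)
  structure(list(theta = theta, r_threshold = r_threshold,
                 max_redraws = as.integer(max_redraws)),
            class = "mate_choice_model")
}

#' Generate the founder cohort
#'
#' Founders are assumed unrelated and non-inbred. Adults get ages drawn from
#' the configured adult range, immatures below `immature_age_max`; everyone
#' is assigned a group uniformly. Adult founder males are treated as
#' immigrants (their birth group differs from their current group), so they
#' never count as natal males; immature males carry their group as birth
#' group and disperse later. Genotypes are Hardy-Weinberg draws from the
#' founder allele frequencies, locus-wise.
#'
#' @param cfg A [founder_config()].
#' @param seed Optional integer seed.
#' @return A founder state list consumed by [simulate_years()]; contains the
#'   founder records, genotype matrices (`NULL` when `n_loci = 0`) and the
#'   per-locus founder allele frequencies.
#' @export
generate_founders <- function(cfg = founder_config(), seed = NULL) {
  stopifnot(inherits(cfg, "founder_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_founders
  nf <- cfg$n_adult_females
  nm <- cfg$n_adult_males
  ni <- n - nf - nm
  sex <- c(rep("F", nf), rep("M", nm),
           sample(c("F", "M"), ni, replace = TRUE))
  age <- c(stats::runif(nf, cfg$adult_age_range[1], cfg$adult_age_range[2]),
           stats::runif(nm, cfg$adult_age_range[1], cfg$adult_age_range[2]),
           stats::runif(ni, 0.5, cfg$immature_age_max))
  id <- sprintf("F%04d", seq_len(n))
  groups <- paste0("G", seq_len(cfg$n_groups))
  cur_group <- sample(groups, n, replace = TRUE)
  birth_group <- cur_group
  adult_male <- sex == "M" & age >= cfg$adult_age_range[1]
  if (cfg$n_groups > 1) {
    # adult immigrant males: natal group elsewhere
    for (k in which(adult_male)) {
      birth_group[k] <- sample(setdiff(groups, cur_group[k]), 1L)
    }
  }
  birth_date <- cfg$start_date - round(age * 365.25)

  geno <- NULL
  freqs <- NULL
  if (cfg$n_loci > 0) {
    freqs <- vector("list", cfg$n_loci)
    names(freqs) <- sprintf("L%02d", seq_len(cfg$n_loci))
    a1 <- a2 <- matrix(NA_character_, n, cfg$n_loci,
                       dimnames = list(id, names(freqs)))
    for (l in seq_len(cfg$n_loci)) {
      k <- cfg$alleles_per_locus
      p <- if (cfg$freq_dist == "uniform") {
        rep(1 / k, k)
      } else {
        g <- stats::rgamma(k, cfg$dirichlet_alpha)
        g / sum(g)
      }
      names(p) <- as.character(seq_len(k))
      freqs[[l]] <- p
      a1[, l] <- sample(names(p), n, replace = TRUE, prob = p)
      a2[, l] <- sample(names(p), n, replace = TRUE, prob = p)
    }
    geno <- list(a1 = a1, a2 = a2)
  }
  list(cfg = cfg, id = id, sex = sex, birth_date = birth_date,
       birth_group = birth_group, cur_group = cur_group,
       founder_geno = geno, founder_freqs = freqs,
       start_date = cfg$start_date, groups = groups)
}

#' Simulate a population forward through breeding seasons
#'
#' Runs the founder state forward: per season every mature female gives birth
#' with the configured probability; sires are drawn under the extra-group /
#' natal / within-group scheme with reproductive skew and filtered through
#' the kin-avoidant mate choice model; offspring join the mother's group
#' (female philopatry); males disperse to another group at their drawn natal
#' dispersal age; infant and adult mortality and optional culling apply. All
#' events are dated, so the emitted demography table supports the avoidance
#' test's eligibility rules.
#'
#' @param state Founder state from [generate_founders()].
#' @param dcfg A [demography_config()].
#' @param mate A [mate_choice_model()].
#' @param seed Optional integer seed.
#' @param missing_rate Genotype missingness applied when dropping marker
#'   genotypes down the pedigree.
#' @return Object of class `sim_population`: list with `pedigree`
#'   (a `pedigree_table`), `genotypes` (a `genotype_table` or `NULL`),
#'   `demography` (interval table), `true_F` (full-depth pedigree F for every
#'   individual with two known parents), `assignments` (per-offspring sire
#'   category drawn and actually used), and the provenance (`configs`,
#'   `seed`).
#' @export
simulate_years <- function(state, dcfg = demography_config(),
                           mate = mate_choice_model(), seed = NULL,
                           missing_rate = 0) {
  stopifnot(inherits(dcfg, "demography_config"),
            inherits(mate, "mate_choice_model"))
  if (!is.null(seed)) set.seed(seed)
  groups <- state$groups
  n_groups <- length(groups)

  id <- state$id
  sex <- state$sex
  birth <- state$birth_date
  death <- rep(as.Date(NA), length(id))
  removed <- rep(FALSE, length(id))
  bgrp <- state$birth_group
  cgrp <- state$cur_group
  sidx <- rep(NA_integer_, length(id))
  didx <- rep(NA_integer_, length(id))
  gen <- rep(0L, length(id))
  disp_age <- rep(NA_real_, length(id))
  disp_age[sex == "M"] <- stats::runif(sum(sex == "M"),
                                       dcfg$dispersal_age_range[1],
                                       dcfg$dispersal_age_range[2])

  # demography interval bookkeeping
  d_id <- id
  d_grp <- cgrp
  d_start <- rep(state$start_date, length(id))
  d_end <- rep(as.Date(NA), length(id))
  open_row <- seq_along(id)
  close_open <- function(k, when) d_end[open_row[k]] <<- when
  open_new <- function(k, grp, when) {
    d_id <<- c(d_id, id[k])
    d_grp <<- c(d_grp, grp)
    d_start <<- c(d_start, when)
    d_end <<- c(d_end, as.Date(NA))
    open_row[k] <<- length(d_id)
  }

  cache <- .new_kin_cache()
  rel <- function(i, j) 2 * .kin_pair(sidx, didx, gen, cache, i, Inf, j, Inf)

  scheme <- avoidance_scheme(
    p_extra = dcfg$p_extra, p_natal = dcfg$p_natal,
    skew_fraction = dcfg$skew_fraction,
    skew_age_window = dcfg$skew_age_window,
    maturity_age = dcfg$maturity_age,
    conception_offset = dcfg$conception_offset,
    completeness_filter_depth = 0  # reproduction is not pedigree-filtered
  )
  counter <- 0L
  extinct <- FALSE
  asg_off <- character(0)   # per-offspring assignment bookkeeping
  asg_cat <- character(0)
  asg_used <- character(0)

  for (y in seq_len(dcfg$n_years)) {
    season0 <- state$start_date + round(y * 365.25)
    alive <- is.na(death)
    age_y <- as.numeric(season0 - birth) / 365.25

    mothers <- which(alive & sex == "F" & age_y >= dcfg$maturity_age)
    mothers <- mothers[stats::runif(length(mothers)) < dcfg$birth_prob]
    if (length(mothers)) {
      b_date <- season0 + sample.int(90L, length(mothers), replace = TRUE) - 1L
      c_date <- b_date - dcfg$conception_offset
      m_grp <- cgrp[mothers]

      # candidate sires per offspring (state-based pools)
      males <- which(sex == "M" & is.na(death))
      pools <- vector("list", length(mothers))
      for (o in seq_along(mothers)) {
        conc <- c_date[o]
        ok <- males[birth[males] < conc &
                      (as.numeric(conc - birth[males]) / 365.25) >= dcfg$maturity_age]
        if (length(ok)) {
          natal <- bgrp[ok] == cgrp[ok] & cgrp[ok] == m_grp[o]
          within <- cgrp[ok] == m_grp[o] & !natal
          extra <- cgrp[ok] != m_grp[o]
          pools[[o]] <- list(natal = ok[natal], within = ok[within],
                             extra = ok[extra])
        } else {
          pools[[o]] <- list(natal = integer(0), within = integer(0),
                             extra = integer(0))
        }
      }
      cats <- .partition_categories(length(mothers), scheme)
      # skew subsample per group for this cohort
      subs <- list()
      for (grp in unique(m_grp)) {
        pool <- sort(unique(unlist(lapply(pools[m_grp == grp], `[[`, "within"))))
        subs[[grp]] <- if (length(pool)) {
          ages <- as.numeric(season0 - birth[pool]) / 365.25
          match(skew_subsample(id[pool], dcfg$skew_fraction,
                               ages = ages, window = dcfg$skew_age_window), id)
        } else integer(0)
      }

      for (o in seq_along(mothers)) {
        po <- pools[[o]]
        sw <- intersect(subs[[m_grp[o]]], po$within)
        if (!length(sw)) sw <- po$within
        pick <- function(cat) switch(cat, extra = po$extra, natal = po$natal,
                                     within = sw)
        order_try <- switch(cats[o],
                            extra = c("extra", "within", "natal"),
                            natal = c("natal", "within", "extra"),
                            within = c("within", "extra", "natal"))
        sire <- NA_integer_
        used_cat <- NA_character_
        if (mate$theta >= 1) {
          # strict avoidance: the first unrelated candidate in random order
          # (uniform over the pool's unrelated subset)
          for (catg in order_try) {
            pool <- pick(catg)
            if (!length(pool)) next
            for (mm in pool[sample.int(length(pool))]) {
              if (rel(mothers[o], mm) < mate$r_threshold) {
                sire <- mm
                used_cat <- catg
                break
              }
            }
            if (!is.na(sire)) break
          }
        } else {
          pool <- NULL
          for (catg in order_try) {
            pool <- pick(catg)
            if (length(pool)) {
              used_cat <- catg
              break
            }
          }
          if (length(pool)) {
            sire <- pool[sample.int(length(pool), 1L)]
            if (mate$theta > 0) {
              tries <- 0L
              while (rel(mothers[o], sire) >= mate$r_threshold &&
                     tries < mate$max_redraws &&
                     stats::runif(1) < mate$theta) {
                sire <- pool[sample.int(length(pool), 1L)]
                tries <- tries + 1L
              }
            }
          }
        }
        if (is.na(sire)) next  # no (acceptable) sire: female skips this season

        counter <- counter + 1L
        k <- length(id) + 1L
        id <- c(id, sprintf("I%05d", counter))
        sex <- c(sex, sample(c("F", "M"), 1L))
        birth <- c(birth, b_date[o])
        death <- c(death, as.Date(NA))
        removed <- c(removed, FALSE)
        bgrp <- c(bgrp, m_grp[o])
        cgrp <- c(cgrp, m_grp[o])
        sidx <- c(sidx, sire)
        didx <- c(didx, mothers[o])
        gen <- c(gen, 1L + max(gen[sire], gen[mothers[o]]))
        disp_age <- c(disp_age,
                      if (sex[k] == "M") {
                        stats::runif(1, dcfg$dispersal_age_range[1],
                                     dcfg$dispersal_age_range[2])
                      } else NA_real_)
        d_id <- c(d_id, id[k])
        d_grp <- c(d_grp, m_grp[o])
        d_start <- c(d_start, b_date[o])
        d_end <- c(d_end, as.Date(NA))
        open_row <- c(open_row, length(d_id))
        asg_off <- c(asg_off, id[k])
        asg_cat <- c(asg_cat, cats[o])
        asg_used <- c(asg_used, used_cat)
        # infant mortality
        if (stats::runif(1) < dcfg$infant_mortality) {
          death[k] <- b_date[o] + sample.int(358L, 1L) + 6L
          close_open(k, death[k])
        }
      }
    }

    # adult mortality (individuals born before this season)
    year_end <- season0 + 365L
    older <- which(is.na(death) & birth < season0)
    dies <- older[stats::runif(length(older)) < dcfg$adult_mortality]
    for (k in dies) {
      death[k] <- season0 + sample.int(365L, 1L) - 1L
      if (death[k] <= birth[k]) death[k] <- birth[k] + 1L
      close_open(k, death[k])
    }

    # male natal dispersal
    if (n_groups > 1) {
      movers <- which(is.na(death) & sex == "M" & bgrp == cgrp &
                        (as.numeric(year_end - birth) / 365.25) >= disp_age)
      for (k in movers) {
        when <- max(birth[k] + round(disp_age[k] * 365.25), season0)
        newg <- sample(setdiff(groups, cgrp[k]), 1L)
        close_open(k, when)
        cgrp[k] <- newg
        open_new(k, newg, when)
      }
    }

    # optional culling of 1-3 year olds down to the target
    if (!is.null(dcfg$culling_target)) {
      n_alive <- sum(is.na(death))
      excess <- n_alive - dcfg$culling_target
      if (excess > 0) {
        agec <- as.numeric(year_end - birth) / 365.25
        cand <- which(is.na(death) & agec >= 1 & agec <= 3)
        take <- utils::head(sample(cand), excess)
        for (k in take) {
          death[k] <- year_end
          removed[k] <- TRUE
          close_open(k, year_end)
        }
      }
    }

    alive_now <- is.na(death)
    if (!any(alive_now & sex == "F") || !any(alive_now & sex == "M")) {
      warning("population extinct after season ", y, "; partial output returned")
      extinct <- TRUE
      break
    }
  }

  records <- data.frame(
    id = id,
    sire = ifelse(is.na(sidx), NA_character_, id[sidx]),
    dam = ifelse(is.na(didx), NA_character_, id[didx]),
    sex = sex, birth_date = birth, death_date = death,
    removed = removed, birth_group = bgrp, stringsAsFactors = FALSE
  )
  ped <- build_pedigree(records)
  demog <- data.frame(id = d_id, group = d_grp, start_date = d_start,
                      end_date = d_end, stringsAsFactors = FALSE)
  true_F <- inbreeding_coefficients(ped)
  genotypes <- NULL
  if (!is.null(state$founder_geno)) {
    genotypes <- drop_genotypes(ped, state$founder_geno,
                                missing_rate = missing_rate)
  }
  structure(list(pedigree = ped, genotypes = genotypes, demography = demog,
                 true_F = true_F, founder_freqs = state$founder_freqs,
                 assignments = data.frame(offspring = asg_off,
                                          category = asg_cat,
                                          category_used = asg_used,
                                          stringsAsFactors = FALSE),
                 configs = list(founder = state$cfg, demography = dcfg,
                                mate = mate),
                 seed = seed, extinct = extinct),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  nf <- sum(is.na(x$pedigree$sire_idx) & is.na(x$pedigree$dam_idx))
  cat("sim_population:", x$pedigree$n, "individuals (", nf, "founders ),",
      sum(x$true_F > 0, na.rm = TRUE), "inbred\n")
  invisible(x)
}

#' One-call population simulation
#'
#' Convenience wrapper: [generate_founders()] then [simulate_years()], with a
#' single seed governing both stages.
#'
#' @inheritParams simulate_years
#' @param cfg A [founder_config()].
#' @return A `sim_population` (see [simulate_years()]).
#' @export
simulate_population <- function(cfg = founder_config(),
                                dcfg = demography_config(),
                                mate = mate_choice_model(), seed = NULL,
                                missing_rate = 0) {
  if (!is.null(seed)) set.seed(seed)
  state <- generate_founders(cfg)
  simulate_years(state, dcfg, mate, missing_rate = missing_rate)
}

#' Drop marker genotypes down a pedigree
#'
#' Standard Mendelian gene dropping: every non-founder inherits one uniformly
#' chosen allele per locus from each parent; founders must be genotyped.
#' Whole genotypes are masked at `missing_rate`.
#'
#' @param p A `pedigree_table` in which every individual has either two known
#'   parents or none.
#' @param founder_geno List with character matrices `a1`, `a2` (founder ids
#'   as rownames, loci as colnames).
#' @param missing_rate Probability that an (individual, locus) genotype is
#'   masked.
#' @param seed Optional integer seed.
#' @return A `genotype_table` covering every individual in `p`.
#' @export
drop_genotypes <- function(p, founder_geno, missing_rate = 0, seed = NULL) {
  stopifnot(inherits(p, "pedigree_table"),
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  fa1 <- founder_geno$a1
  fa2 <- founder_geno$a2
  L <- ncol(fa1)
  n <- p$n
  founder <- is.na(p$sire_idx) & is.na(p$dam_idx)
  half <- xor(is.na(p$sire_idx), is.na(p$dam_idx))
  if (any(half)) {
    stop("individual(s) with exactly one known parent cannot be gene-dropped: ",
         paste(p$ped$id[half], collapse = ", "))
  }
  missing_f <- setdiff(p$ped$id[founder], rownames(fa1))
  if (length(missing_f)) {
    stop("ungenotyped founder(s): ", paste(missing_f, collapse = ", "))
  }
  a1 <- a2 <- matrix(NA_character_, n, L,
                     dimnames = list(p$ped$id, colnames(fa1)))
  a1[p$ped$id[founder], ] <- fa1[p$ped$id[founder], , drop = FALSE]
  a2[p$ped$id[founder], ] <- fa2[p$ped$id[founder], , drop = FALSE]
  for (k in order(p$gen)) {
    if (founder[k]) next
    s <- p$sire_idx[k]
    d <- p$dam_idx[k]
    pick_s <- stats::runif(L) < 0.5
    pick_d <- stats::runif(L) < 0.5
    a1[k, ] <- ifelse(pick_s, a1[s, ], a2[s, ])
    a2[k, ] <- ifelse(pick_d, a1[d, ], a2[d, ])
  }
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(n * L) < missing_rate, n, L)
    a1[mask] <- NA_character_
    a2[mask] <- NA_character_
  }
  genotype_table(p$ped$id, a1, a2)
}

#' Realised breeding records of a simulated population
#'
#' Extracts one row per non-founder: offspring, mother (dam), sire and birth
#' date. This is the observed-pairs input of the avoidance test.
#'
#' @param sim A `sim_population`.
#' @return Data frame `offspring`, `mother`, `sire`, `birth_date`.
#' @export
sim_breeding_records <- function(sim) {
  stopifnot(inherits(sim, "sim_population"))
  p <- sim$pedigree
  off <- which(!is.na(p$sire_idx) & !is.na(p$dam_idx))
  data.frame(offspring = p$ped$id[off],
             mother = p$ped$id[p$dam_idx[off]],
             sire = p$ped$id[p$sire_idx[off]],
             birth_date = p$ped$birth_date[off],
             stringsAsFactors = FALSE)
}

#' End-to-end recovery checks on a simulated population
#'
#' Validates the pipeline against the simulator's ground truth:
#' (a) the pedigree written to disk and read back yields exactly the true
#' per-individual inbreeding coefficients; (b) marker-based estimators on the
#' gene-dropped genotypes correlate with pedigree F in the expected
#' directions (HL and IR positively, SH negatively) and with each other with
#' the expected signs; (c) a small avoidance run executes and returns a valid
#' P-value.
#'
#' @param sim A `sim_population` with genotypes.
#' @param scheme Scheme for the avoidance smoke test.
#' @param min_loci Estimator locus filter.
#' @return List report: `f_recovery` (max |recomputed - true| and pass flag),
#'   `estimator_correlations` (with F, and among estimators), `avoidance`
#'   (P and number of pairs), each `NULL` when not computable.
#' @export
recovery_harness <- function(sim, scheme = avoidance_scheme(n_sim = 50),
                             min_loci = 5) {
  stopifnot(inherits(sim, "sim_population"))
  dir <- tempfile("recovery")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  pf <- file.path(dir, "pedigree.tsv")
  write_pedigree(sim$pedigree, pf)
  ped2 <- read_pedigree(pf)
  F2 <- inbreeding_coefficients(ped2)
  common <- intersect(names(F2), names(sim$true_F))
  dF <- abs(F2[common] - sim$true_F[common])
  f_recovery <- list(max_abs_diff = max(c(0, dF), na.rm = TRUE),
                     exact = all(dF == 0, na.rm = TRUE))

  est_cor <- NULL
  if (!is.null(sim$genotypes)) {
    est <- estimate_all(sim$genotypes, min_loci = min_loci)
    res <- est$results
    Fv <- sim$true_F[res$id]
    use <- !is.na(Fv) & stats::complete.cases(res[, c("SH", "IR", "HL")])
    with_F <- c(F_HL = NA_real_, F_IR = NA_real_, F_SH = NA_real_)
    if (sum(use) >= 3 && stats::sd(Fv[use]) > 0) {
      with_F["F_HL"] <- stats::cor(Fv[use], res$HL[use], method = "spearman")
      with_F["F_IR"] <- stats::cor(Fv[use], res$IR[use], method = "spearman")
      with_F["F_SH"] <- stats::cor(Fv[use], res$SH[use], method = "spearman")
    }
    est_cor <- list(with_F = with_F, among = est$correlations)
  }

  avoid <- NULL
  pairs <- sim_breeding_records(sim)
  avoid <- tryCatch({
    res <- run_avoidance(sim$pedigree, sim$demography, pairs, scheme)
    list(P = res$P, n_pairs = res$n_pairs)
  }, error = function(e) list(error = conditionMessage(e)))

  list(f_recovery = f_recovery, estimator_correlations = est_cor,
       avoidance = avoid)
}

#' Type-I error calibration of the avoidance test
#'
#' With mate choice drawn from the same scheme as the null (`theta = 0`), the
#' observed dataset is exchangeable with the simulated ones and the
#' permutation P-value is uniform, so the rejection rate at level `alpha`
#' should match `alpha`. This experiment draws `n_runs` observed datasets
#' from the null scheme on one simulated population and runs the full test on
#' each.
#'
#' @param sim A `sim_population` (any mate model; only its pedigree,
#'   demography and offspring set are used).
#' @param scheme Avoidance scheme; `scheme$n_sim` datasets per test.
#' @param n_runs Number of replicate tests.
#' @param alpha Nominal level.
#' @param seed Optional integer seed.
#' @return List with `rejection_rate`, the binomial 95% CI half-width around
#'   `alpha`, the vector of P-values and `n_runs`.
#' @export
avoidance_calibration <- function(sim, scheme = avoidance_scheme(n_sim = 100),
                                  n_runs = 200, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(sim, "sim_population"))
  if (!is.null(seed)) set.seed(seed)
  pairs <- sim_breeding_records(sim)
  prep <- .prepare_avoidance(sim$pedigree, sim$demography, pairs, scheme)
  P <- numeric(n_runs)
  for (run in seq_len(n_runs)) {
    obs <- .sim_stats(prep, .assign_sires(prep))[["mean"]]
    sims <- numeric(scheme$n_sim - 1L)
    for (s in seq_along(sims)) {
      sims[s] <- .sim_stats(prep, .assign_sires(prep))[["mean"]]
    }
    P[run] <- permutation_p(obs, sims)$P
  }
  rate <- mean(P <= alpha)
  list(rejection_rate = rate,
       ci_half_width = 1.96 * sqrt(alpha * (1 - alpha) / n_runs),
       alpha = alpha, P = P, n_runs = n_runs)
}

#' Power of the avoidance test under strict kin avoidance
#'
#' Simulates `n_runs` independent populations with strict kin-avoidant mate
#' choice (`theta = 1`) and reports how often the avoidance test rejects at
#' level `alpha`.
#'
#' @param cfg,dcfg Founder and demography configurations for each replicate
#'   population.
#' @param scheme Avoidance scheme; `scheme$n_sim` datasets per test.
#' @param n_runs Number of replicate populations.
#' @param alpha Nominal level.
#' @param r_threshold Mate-choice rejection threshold.
#' @param seed Integer seed; replicate `i` uses `seed + i`.
#' @return List with `rejection_rate`, the vector of P-values, and the count
#'   of replicates where the test could not run (no eligible pairs), which
#'   score as non-rejections.
#' @export
avoidance_power <- function(cfg, dcfg, scheme = avoidance_scheme(n_sim = 100),
                            n_runs = 100, alpha = 0.05,
                            r_threshold = 0.0625, seed = 1) {
  P <- rep(NA_real_, n_runs)
  n_failed <- 0L
  for (run in seq_len(n_runs)) {
    sim <- simulate_population(cfg, dcfg,
                               mate_choice_model(theta = 1,
                                                 r_threshold = r_threshold),
                               seed = seed + run)
    res <- tryCatch(
      suppressWarnings(run_avoidance(sim$pedigree, sim$demography,
                                     sim_breeding_records(sim), scheme)),
      error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else P[run] <- res$P
  }
  rej <- sum(P <= alpha, na.rm = TRUE)
  list(rejection_rate = rej / n_runs, P = P, n_failed = n_failed,
       n_runs = n_runs, alpha = alpha)
}
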