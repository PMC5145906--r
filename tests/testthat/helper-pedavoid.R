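# Random valid pedigree: founders first, later individuals draw parents among
# earlier ones (acyclic by construction); small closed populations like these
# accumulate inbreeding loops quickly.
random_pedigree <- function(n = 30, n_founders = 8) {
  sex <- c(rep(c("M", "F"), length.out = n_founders),
           sample(c("M", "F"), n - n_founders, replace = TRUE))
  id <- sprintf("R%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (k in (n_founders + 1):n) {
    prev <- seq_len(k - 1)
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    sire[k] <- id[males[sample.int(length(males), 1)]]
    dam[k] <- id[females[sample.int(length(females), 1)]]
  }
  build_pedigree(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                            stringsAsFactors = FALSE))
}

# genotype table from a compact list: g[[ind]][[locus]] = c(a, b) or NULL
make_geno <- function(g, loci = NULL) {
  ids <- names(g)
  if (is.null(loci)) loci <- unique(unlist(lapply(g, names)))
  a1 <- a2 <- matrix(NA_character_, length(ids), length(loci),
                     dimnames = list(ids, loci))
  for (i in ids) {
    for (l in names(g[[i]])) {
      a1[i, l] <- g[[i]][[l]][1]
      a2[i, l] <- g[[i]][[l]][2]
    }
  }
  genotype_table(ids, a1, a2)
}

# realised breeding pairs straight from a pedigree table
sim_pairs_from <- function(p) {
  off <- which(!is.na(p$sire_idx) & !is.na(p$dam_idx))
  data.frame(offspring = p$ped$id[off],
             mother = p$ped$id[p$dam_idx[off]],
             sire = p$ped$id[p$sire_idx[off]],
             birth_date = p$ped$birth_date[off],
             stringsAsFactors = FALSE)
}

# small, quick simulated population shared by several tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- founder_config(n_founders = 50, n_adult_females = 20,
                            n_adult_males = 8, n_groups = 3, n_loci = 20)
      dcfg <- demography_config(n_years = 12, adult_mortality = 0.07)
      cache <<- simulate_population(cfg, dcfg, mate_choice_model(0), seed = 421)
    }
    cache
  }
})
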