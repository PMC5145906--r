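#' Simulation scheme for the inbreeding-avoidance null
#'
#' Parameters of the null model of sire assignment: a fraction of offspring
#' is sired by extra-group males, a fraction by natal males (males still in
#' their birth group), and the remainder by non-natal group males of which
#' only a subsample is considered per group and birth cohort, emulating male
#' reproductive skew.
#'
#' @param p_extra Proportion of offspring assigned extra-group sires
#'   (default 0.24).
#' @param p_natal Proportion assigned natal sires (default 0.16); reassigned
#'   to the within-group category when `include_natal = FALSE`.
#' @param skew_fraction Fraction of available within-group males considered
#'   as potential sires per group and cohort (default 0.20).
#' @param skew_age_window Optional numeric length-2 vector of ages in years;
#'   when set, the skew subsample is drawn from males inside the window
#'   (falling back to the whole pool if the restriction empties it). Default
#'   `NULL` (all available group males).
#' @param maturity_age Minimum sire age in years at conception (default 4).
#' @param conception_offset Days between conception and birth (default 166,
#'   a macaque gestation).
#' @param n_sim Number of datasets in the null distribution, the observed
#'   dataset counted as one of them (default 1000, i.e. 999 simulations).
#' @param include_natal Allow natal males as potential sires (default `TRUE`).
#' @param completeness_filter_depth Breeding pairs and candidate sires must
#'   have at least this many fully known ancestor generations (default 2:
#'   parents and grandparents known); parental relatedness is evaluated at
#'   the same depth.
#' @param partition `"exact"` (category counts fixed at `round(p * n)`, the
#'   remainder randomly assigned — the default) or `"bernoulli"`
#'   (per-offspring category draws).
#' @param empty_pool_action When an offspring's assigned category pool is
#'   empty, `"within"` (default) falls back to the within-group pool (then
#'   extra-group, then natal); `"drop"` removes the offspring from that
#'   simulated dataset.
#' @return Object of class `avoidance_scheme` (a validated list).
#' @export
avoidance_scheme <- function(p_extra = 0.24, p_natal = 0.16,
                             skew_fraction = 0.20, skew_age_window = NULL,
                             maturity_age = 4.0, conception_offset = 166,
                             n_sim = 1000, include_natal = TRUE,
                             completeness_filter_depth = 2,
                             partition = c("exact", "bernoulli"),
                             empty_pool_action = c("within", "drop")) {
  partition <- match.arg(partition)
  empty_pool_action <- match.arg(empty_pool_action)
  stopifnot(p_extra >= 0, p_extra <= 1, p_natal >= 0, p_natal <= 1,
            p_extra + p_natal <= 1,
            skew_fraction > 0, skew_fraction <= 1,
            maturity_age >= 0, conception_offset >= 0, n_sim >= 2,
            completeness_filter_depth >= 0)
  if (!is.null(skew_age_window)) {
    stopifnot(length(skew_age_window) == 2, skew_age_window[1] < skew_age_window[2])
  }
  structure(list(
    p_extra = p_extra, p_natal = p_natal,
    p_within = 1 - p_extra - p_natal,
    skew_fraction = skew_fraction, skew_age_window = skew_age_window,
    maturity_age = maturity_age, conception_offset = conception_offset,
    n_sim = as.integer(n_sim), include_natal = include_natal,
    completeness_filter_depth = completeness_filter_depth,
    partition = partition, empty_pool_action = empty_pool_action
  ), class = "avoidance_scheme")
}

# ---- demography helpers -----------------------------------------------------

.demog_index <- function(demog) {
  demog <- as.data.frame(demog)
  split(demog[c("group", "start_date", "end_date")], demog$id)
}

#' Group membership at a date
#'
#' Looks up each individual's group in a demography table of half-open
#' membership intervals `[start_date, end_date)`; a missing `end_date` means
#' the interval is open-ended.
#'
#' @param demog Data frame `id`, `group`, `start_date`, `end_date`.
#' @param ids Character vector of ids.
#' @param date A `Date`.
#' @return Character vector of groups (`NA` when not a member of any group).
#' @export
group_at <- function(demog, ids, date) {
  dix <- .demog_index(demog)
  .groups_at_date(dix, as.character(ids), date)
}

.groups_at_date <- function(dix, ids, date) {
  vapply(ids, function(i) {
    iv <- dix[[i]]
    if (is.null(iv)) return(NA_character_)
    hit <- iv$start_date <= date & (is.na(iv$end_date) | date < iv$end_date)
    if (!any(hit)) NA_character_ else as.character(iv$group[which(hit)[1L]])
  }, character(1), USE.NAMES = FALSE)
}

# ---- observed statistic -----------------------------------------------------

#' Summarise a vector of parental relatedness values
#'
#' Mean, SD, histogram over the canonical relatedness classes
#' `{0, 0.0625, 0.125, 0.25, 0.5}` (values between classes fall in an
#' `"other"` class) and the proportion of unrelated pairs.
#'
#' @param r Numeric vector of pairwise relatedness values.
#' @return List with `n`, `mean`, `sd`, `histogram` (named counts),
#'   `prop_unrelated` and `prop_related`.
#' @export
summarize_r_values <- function(r) {
  if (!length(r)) stop("empty set of relatedness values")
  classes <- c(0, 0.0625, 0.125, 0.25, 0.5)
  labels <- vapply(classes, format, character(1))
  bin <- rep("other", length(r))
  for (k in seq_along(classes)) bin[abs(r - classes[k]) < 1e-9] <- labels[k]
  hist <- table(factor(bin, levels = c(labels, "other")))
  list(n = length(r), mean = mean(r), sd = stats::sd(r),
       histogram = hist,
       prop_unrelated = mean(abs(r) < 1e-9),
       prop_related = mean(r > 1e-9))
}

#' Observed parental relatedness of actual breeding pairs
#'
#' Computes pedigree relatedness between mother and sire of each breeding
#' record (at the scheme's completeness depth) and summarises the
#' distribution: mean, SD, class histogram and proportion of unrelated pairs.
#'
#' @param p A `pedigree_table`.
#' @param pairs Data frame of breeding records with columns `offspring`,
#'   `mother`, `sire` (ids present in `p`).
#' @param depth_limit Ancestor generations used for relatedness (default 2).
#' @return As [summarize_r_values()], plus the vector of `r` values.
#' @export
observed_statistic <- function(p, pairs, depth_limit = 2) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0L) stop("empty set of breeding pairs")
  cache <- .new_kin_cache()
  r <- mapply(function(m, s) relatedness(p, m, s, depth_limit, cache),
              pairs$mother, pairs$sire)
  out <- summarize_r_values(r)
  out$r <- as.numeric(r)
  out
}

# ---- candidate sire pools ---------------------------------------------------

#' Candidate sire pools for one offspring
#'
#' Males alive and mature at the offspring's conception, passing the pedigree
#' completeness filter, partitioned into three pools relative to the mother's
#' group at conception: natal (birth group = current group = mother's group),
#' within-group non-natal, and extra-group.
#'
#' @param p A `pedigree_table`.
#' @param demog Demography table (`id`, `group`, `start_date`, `end_date`).
#' @param record List or one-row data frame with `mother` and either
#'   `conception_date` or `birth_date` (conception is then derived with the
#'   scheme's offset).
#' @param scheme An [avoidance_scheme()].
#' @return List with character vectors `natal`, `within`, `extra`, plus the
#'   `conception_date` and `mother_group` used. Errors if all three pools are
#'   empty.
#' @export
eligible_sires <- function(p, demog, record, scheme = avoidance_scheme()) {
  record <- as.list(record)
  conc <- record$conception_date
  if (is.null(conc)) conc <- as.Date(record$birth_date) - scheme$conception_offset
  conc <- as.Date(conc)
  dix <- .demog_index(demog)
  depth <- ancestor_complete_depth(p)
  pools <- .sire_pools_one(p, dix, depth, as.character(record$mother), conc, scheme)
  if (!length(c(pools$natal, pools$within, pools$extra))) {
    stop("no eligible sire in any pool for offspring conceived ", conc)
  }
  pools
}

.sire_pools_one <- function(p, dix, depth, mother, conc, scheme) {
  ped <- p$ped
  mg <- .groups_at_date(dix, mother, conc)
  if (is.na(mg)) stop("mother ", mother, " has no group membership at ", conc)
  male <- ped$sex == "M" & !ped$stub & !is.na(ped$birth_date)
  alive <- male & ped$birth_date < conc &
    (is.na(ped$death_date) | ped$death_date > conc)
  age <- as.numeric(conc - ped$birth_date) / 365.25
  ok <- alive & age >= scheme$maturity_age &
    depth[ped$id] >= scheme$completeness_filter_depth
  ids <- ped$id[which(ok)]
  if (!length(ids)) {
    return(list(natal = character(0), within = character(0),
                extra = character(0), conception_date = conc,
                mother_group = mg))
  }
  cur <- .groups_at_date(dix, ids, conc)
  bg <- ped$birth_group[match(ids, ped$id)]
  present <- !is.na(cur)
  ids <- ids[present]; cur <- cur[present]; bg <- bg[present]
  natal <- !is.na(bg) & bg == cur & cur == mg
  within <- cur == mg & !natal
  extra <- cur != mg
  list(natal = ids[natal], within = ids[within], extra = ids[extra],
       conception_date = conc, mother_group = mg)
}

#' Reproductive-skew subsample of a sire pool
#'
#' Draws the subset of group males considered as potential sires for one
#' group and birth cohort: `max(1, round(fraction * pool size))` males,
#' uniformly without replacement. With an age window set, sampling is
#' restricted to males inside the window, falling back to the whole pool when
#' the restriction leaves none.
#'
#' @param pool Character vector of male ids (non-empty).
#' @param fraction Fraction of the pool retained (0 < fraction <= 1).
#' @param ages Optional numeric ages (years) aligned with `pool`, required
#'   when `window` is set.
#' @param window Optional numeric length-2 age window in years.
#' @return Character vector, the subsample.
#' @export
skew_subsample <- function(pool, fraction, ages = NULL, window = NULL) {
  if (!length(pool)) stop("empty sire pool")
  stopifnot(fraction > 0, fraction <= 1)
  cand <- pool
  if (!is.null(window)) {
    if (is.null(ages) || length(ages) != length(pool)) {
      stop("ages aligned with the pool are required with an age window")
    }
    inw <- ages >= window[1] & ages <= window[2]
    if (any(inw)) cand <- pool[inw]
  }
  k <- max(1L, as.integer(round(fraction * length(cand))))
  cand[sample.int(length(cand), k)]
}

# exact-count partition of n offspring into the three sire categories
.partition_categories <- function(n, scheme) {
  pe <- scheme$p_extra
  pn <- if (scheme$include_natal) scheme$p_natal else 0
  pw <- 1 - pe - pn
  probs <- c(extra = pe, natal = pn, within = pw)
  if (scheme$partition == "bernoulli") {
    return(sample(names(probs), n, replace = TRUE, prob = probs))
  }
  target <- probs * n
  base <- floor(target)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- target - base
    pick <- if (sum(frac) > 0) {
      sample(names(probs), rem, replace = FALSE, prob = frac)
    } else {
      sample(names(probs), rem, replace = FALSE)
    }
    for (cat in pick) base[cat] <- base[cat] + 1
  }
  sample(rep(names(probs), times = base))
}

# ---- preparation shared by observed and simulated datasets ------------------

# Builds, once per analysis: the completeness-filtered pair set, per-offspring
# sire pools, skew cells (group x cohort) and the mother x male relatedness
# lookup. All later simulation draws are cheap.
.prepare_avoidance <- function(p, demog, pairs, scheme) {
  pairs <- as.data.frame(pairs)
  need <- c("offspring", "mother", "sire", "birth_date")
  if (!all(need %in% names(pairs))) {
    stop("pairs must have columns ", paste(need, collapse = ", "))
  }
  pairs$offspring <- as.character(pairs$offspring)
  pairs$mother <- as.character(pairs$mother)
  pairs$sire <- as.character(pairs$sire)
  pairs$birth_date <- as.Date(pairs$birth_date)
  if (nrow(pairs) == 0L) stop("empty set of breeding pairs")

  depth <- ancestor_complete_depth(p)
  dlim <- scheme$completeness_filter_depth
  keep <- depth[pairs$mother] >= dlim & depth[pairs$sire] >= dlim
  n_incomplete <- sum(!keep)
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("no breeding pair passes the completeness filter")
  pairs$conception_date <- pairs$birth_date - scheme$conception_offset
  pairs$cohort <- as.integer(format(pairs$birth_date, "%Y"))

  dix <- .demog_index(demog)
  pools <- vector("list", nrow(pairs))
  mg <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    pools[[k]] <- .sire_pools_one(p, dix, depth, pairs$mother[k],
                                  pairs$conception_date[k], scheme)
    mg[k] <- pools[[k]]$mother_group
  }
  pairs$mother_group <- mg
  empty <- vapply(pools, function(x) {
    length(x$natal) + length(x$within) + length(x$extra) == 0L
  }, logical(1))
  if (any(empty)) {
    warning(sum(empty), " offspring with no eligible sire in any pool ",
            "excluded from the avoidance analysis")
    pairs <- pairs[!empty, , drop = FALSE]
    pools <- pools[!empty]
    if (nrow(pairs) == 0L) stop("no offspring with a non-empty sire pool")
  }

  # skew cells: one per mother-group x cohort
  cell_key <- paste(pairs$mother_group, pairs$cohort, sep = "|")
  cells <- list()
  for (key in unique(cell_key)) {
    rows <- which(cell_key == key)
    pool <- sort(unique(unlist(lapply(pools[rows], `[[`, "within"))))
    ref_date <- stats::median(pairs$conception_date[rows])
    ages <- if (length(pool)) {
      as.numeric(ref_date - p$ped$birth_date[match(pool, p$ped$id)]) / 365.25
    } else numeric(0)
    cells[[key]] <- list(pool = pool, ages = ages)
  }

  males <- sort(unique(c(unlist(lapply(pools, function(x) c(x$natal, x$within, x$extra))),
                         pairs$sire)))
  mothers <- sort(unique(pairs$mother))
  R <- relatedness_matrix(p, mothers, males, depth_limit = dlim)

  list(pairs = pairs, pools = pools, cells = cells, cell_key = cell_key,
       R = R, n_incomplete = n_incomplete, scheme = scheme)
}

# One simulated sire assignment; returns sire ids (NA = dropped) and the
# category actually used.
.assign_sires <- function(prep) {
  scheme <- prep$scheme
  n <- nrow(prep$pairs)
  cats <- .partition_categories(n, scheme)
  subs <- lapply(prep$cells, function(cell) {
    if (!length(cell$pool)) return(character(0))
    skew_subsample(cell$pool, scheme$skew_fraction,
                   ages = cell$ages, window = scheme$skew_age_window)
  })
  sires <- rep(NA_character_, n)
  used <- character(n)
  n_fallback <- 0L
  for (k in seq_len(n)) {
    po <- prep$pools[[k]]
    skewed_within <- intersect(subs[[prep$cell_key[k]]], po$within)
    if (!length(skewed_within)) skewed_within <- po$within
    pick <- function(cat) switch(cat,
                                 extra = po$extra,
                                 natal = po$natal,
                                 within = skewed_within)
    order_try <- switch(cats[k],
                        extra = c("extra", "within", "natal"),
                        natal = c("natal", "within", "extra"),
                        within = c("within", "extra", "natal"))
    if (scheme$empty_pool_action == "drop") order_try <- order_try[1L]
    for (cat in order_try) {
      pool <- pick(cat)
      if (length(pool)) {
        sires[k] <- pool[sample.int(length(pool), 1L)]
        used[k] <- cat
        if (cat != cats[k]) n_fallback <- n_fallback + 1L
        break
      }
    }
  }
  list(sires = sires, category = cats, category_used = used,
       n_fallback = n_fallback, n_dropped = sum(is.na(sires)))
}

.sim_stats <- function(prep, assignment) {
  ok <- !is.na(assignment$sires)
  r <- prep$R[cbind(prep$pairs$mother[ok], assignment$sires[ok])]
  c(mean = mean(r), prop_related = mean(r > 1e-9))
}

#' Simulate one null dataset of sire assignments
#'
#' Partitions offspring into the extra-group / natal / within-group sire
#' categories (exact counts by default), draws the reproductive-skew
#' subsample per group and cohort, and assigns each offspring a uniformly
#' chosen sire from its category pool, falling back to the within-group pool
#' (then the remaining pools) when a category pool is empty.
#'
#' @inheritParams observed_statistic
#' @param demog Demography table.
#' @param scheme An [avoidance_scheme()].
#' @return Data frame `offspring`, `mother`, `sire`, `birth_date`,
#'   `category`, `category_used`; attribute `"n_fallback"` counts category
#'   fallbacks and `"n_dropped"` offspring without any sire.
#' @export
simulate_dataset <- function(p, demog, pairs, scheme = avoidance_scheme()) {
  prep <- .prepare_avoidance(p, demog, pairs, scheme)
  a <- .assign_sires(prep)
  if (a$n_fallback > 0) {
    warning(a$n_fallback, " sire assignment(s) used a fallback category ",
            "(assigned category pool was empty)")
  }
  out <- data.frame(offspring = prep$pairs$offspring,
                    mother = prep$pairs$mother,
                    sire = a$sires,
                    birth_date = prep$pairs$birth_date,
                    category = a$category,
                    category_used = a$category_used,
                    stringsAsFactors = FALSE)
  attr(out, "n_fallback") <- a$n_fallback
  attr(out, "n_dropped") <- a$n_dropped
  out
}

#' One-sided permutation P-value for inbreeding avoidance
#'
#' The observed dataset counts as one of the `n_sim` datasets, so
#' `P = (number of datasets with mean relatedness <= observed) / n_sim`;
#' `P` therefore lies in `[1 / n_sim, 1]` and a significant result means the
#' observed breeders were *less* related than expected under the null, i.e.
#' inbreeding was avoided.
#'
#' @param observed_mean Observed mean parental relatedness.
#' @param simulated_means Numeric vector of `n_sim - 1` simulated dataset
#'   means (the observed value is appended internally).
#' @return List with `P`, `n_sim` and `null_means` (observed first).
#' @export
permutation_p <- function(observed_mean, simulated_means) {
  if (length(simulated_means) < 1) stop("at least one simulated mean required")
  null_means <- c(observed_mean, simulated_means)
  P <- mean(null_means <= observed_mean + 1e-12)
  list(P = P, n_sim = length(null_means), null_means = null_means)
}

#' Permutation test of inbreeding avoidance
#'
#' Compares the observed mean pedigree relatedness of actual breeding pairs
#' with its null distribution under random sire assignment that respects male
#' reproductive skew, extra-group paternity and (optionally) natal breeding.
#' Pairs failing the pedigree completeness filter are removed; relatedness is
#' evaluated at the filter depth. The observed dataset is included in the
#' null as one of `n_sim` datasets and the one-sided P-value is the
#' proportion of datasets with a mean at least as small as observed.
#'
#' @inheritParams simulate_dataset
#' @param seed Optional integer seed; identical seeds reproduce the null
#'   means bit for bit.
#' @return Object of class `avoidance_result`: observed summary (mean, SD,
#'   class histogram, proportion unrelated), `null_means` (observed first),
#'   `P`, per-simulation proportion of related pairs, and a null summary
#'   (mean, SD, range of the simulated means).
#' @export
run_avoidance <- function(p, demog, pairs, scheme = avoidance_scheme(),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prep <- .prepare_avoidance(p, demog, pairs, scheme)
  r_obs <- prep$R[cbind(prep$pairs$mother, prep$pairs$sire)]
  obs <- summarize_r_values(r_obs)
  n_sim <- scheme$n_sim
  sim_means <- numeric(n_sim - 1L)
  sim_prop <- numeric(n_sim - 1L)
  for (s in seq_len(n_sim - 1L)) {
    st <- .sim_stats(prep, .assign_sires(prep))
    sim_means[s] <- st[["mean"]]
    sim_prop[s] <- st[["prop_related"]]
  }
  pp <- permutation_p(obs$mean, sim_means)
  structure(list(
    observed_mean_r = obs$mean,
    observed_sd_r = obs$sd,
    observed_histogram = obs$histogram,
    prop_unrelated = obs$prop_unrelated,
    n_pairs = obs$n,
    n_pairs_incomplete = prep$n_incomplete,
    null_means = pp$null_means,
    P = pp$P,
    n_sim = pp$n_sim,
    prop_related_sim = sim_prop,
    null_summary = list(mean = mean(sim_means), sd = stats::sd(sim_means),
                        range = range(sim_means),
                        mean_prop_related = mean(sim_prop),
                        sd_prop_related = stats::sd(sim_prop)),
    scheme = scheme, seed = seed
  ), class = "avoidance_result")
}

#' @export
print.avoidance_result <- function(x, ...) {
  cat("Inbreeding-avoidance permutation test\n")
  cat(sprintf("  pairs: %d (%d removed by completeness filter)\n",
              x$n_pairs, x$n_pairs_incomplete))
  cat(sprintf("  observed mean r = %.4f (SD %.4f), %.1f%% unrelated\n",
              x$observed_mean_r, x$observed_sd_r, 100 * x$prop_unrelated))
  cat(sprintf("  null mean r = %.4f +- %.4f (range %.4f-%.4f), %d datasets\n",
              x$null_summary$mean, x$null_summary$sd,
              x$null_summary$range[1], x$null_summary$range[2], x$n_sim))
  cat(sprintf("  one-sided P = %.4g\n", x$P))
  invisible(x)
}
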