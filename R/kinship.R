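# Recursive kinship with per-lineage depth budgets.
#
# f(i, j) is expanded through the member that cannot be an ancestor of the
# other (the one with the larger generation number); a missing parent
# contributes 0 and f(i, i) = (1 + F_i) / 2. Depth truncation gives each
# focal individual a budget of ancestor generations: a node whose budget is
# exhausted keeps its identity but loses its parents, i.e. ancestors beyond
# the budget are replaced by fresh, mutually unrelated founders. When the two
# lineages meet the same individual with different residual budgets, the
# smaller budget is used (the conservative choice; see the methods vignette).
.kin_pair <- function(sidx, didx, gen, cache, i, bi, j, bj) {
  bi <- min(bi, gen[i])
  bj <- min(bj, gen[j])
  if (i == j) {
    b <- min(bi, bj)
    key <- paste0("S", i, ":", b)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    s <- sidx[i]
    d <- didx[i]
    val <- if (b < 1 || is.na(s) || is.na(d)) {
      0.5
    } else {
      0.5 * (1 + .kin_pair(sidx, didx, gen, cache, s, b - 1, d, b - 1))
    }
    cache[[key]] <- val
    return(val)
  }
  if (gen[i] < gen[j] || (gen[i] == gen[j] && i > j)) {
    tmp <- i; i <- j; j <- tmp
    tmp <- bi; bi <- bj; bj <- tmp
  }
  key <- paste0(i, ":", bi, "|", j, ":", bj)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  exp_i <- bi >= 1 && (!is.na(sidx[i]) || !is.na(didx[i]))
  exp_j <- bj >= 1 && (!is.na(sidx[j]) || !is.na(didx[j]))
  val <- if (exp_i) {
    v <- 0
    if (!is.na(sidx[i])) v <- v + .kin_pair(sidx, didx, gen, cache, sidx[i], bi - 1, j, bj)
    if (!is.na(didx[i])) v <- v + .kin_pair(sidx, didx, gen, cache, didx[i], bi - 1, j, bj)
    0.5 * v
  } else if (gen[i] == gen[j] && exp_j) {
    v <- 0
    if (!is.na(sidx[j])) v <- v + .kin_pair(sidx, didx, gen, cache, sidx[j], bj - 1, i, bi)
    if (!is.na(didx[j])) v <- v + .kin_pair(sidx, didx, gen, cache, didx[j], bj - 1, i, bi)
    0.5 * v
  } else {
    0
  }
  cache[[key]] <- val
  val
}

.new_kin_cache <- function() new.env(parent = emptyenv(), hash = TRUE)

#' Coefficient of kinship between two individuals
#'
#' The kinship coefficient `f(i, j)` is the probability that two alleles, one
#' drawn at random from each individual, are identical by descent within the
#' pedigree. Founders (and founder stubs) are assumed unrelated and
#' non-inbred. `f(i, i) = (1 + F_i) / 2`, and the inbreeding coefficient of
#' an offspring equals the kinship of its parents.
#'
#' `depth_limit` truncates ancestry: ancestors more than `depth_limit`
#' generations above either focal individual are treated as fresh, unrelated
#' founders. `Inf` (the default) uses the whole known pedigree.
#'
#' @param p A `pedigree_table`.
#' @param i,j Individual ids.
#' @param depth_limit Non-negative integer or `Inf`; ancestor generations
#'   visible above each focal individual.
#' @param cache Optional environment used to memoise the recursion across
#'   calls that share `p` and `depth_limit` semantics (budgets are part of the
#'   memo key, so one cache can serve several depths).
#' @return Kinship coefficient `f` (numeric scalar in `[0, 1]`).
#' @seealso [relatedness()], [inbreeding_coefficient()], [gene_drop_F()]
#' @examples
#' ped <- build_pedigree(data.frame(
#'   id = c("A", "B", "X"), sire = c(NA, NA, "A"), dam = c(NA, NA, "B")))
#' kinship(ped, "A", "X")  # parent-offspring: 0.25
#' @export
kinship <- function(p, i, j, depth_limit = Inf, cache = NULL) {
  stopifnot(inherits(p, "pedigree_table"))
  if (is.na(depth_limit) || depth_limit < 0) stop("depth_limit must be >= 0")
  ii <- .ped_index(p, i)
  jj <- .ped_index(p, j)
  if (is.null(cache)) cache <- .new_kin_cache()
  .kin_pair(p$sire_idx, p$dam_idx, p$gen, cache, ii, depth_limit, jj, depth_limit)
}

#' Additive relatedness between two individuals
#'
#' The coefficient of relatedness `r = 2 f`, where `f` is the kinship
#' coefficient; e.g. parent-offspring and full siblings have `r = 0.5`,
#' half-siblings `r = 0.25`.
#'
#' @inheritParams kinship
#' @return Relatedness `r` (numeric scalar).
#' @export
relatedness <- function(p, i, j, depth_limit = Inf, cache = NULL) {
  2 * kinship(p, i, j, depth_limit = depth_limit, cache = cache)
}

#' Relatedness between many pairs at once
#'
#' Computes the matrix of additive relatedness values `r = 2 f` between two
#' sets of individuals, sharing one memoisation cache. Used by the avoidance
#' test, where all mother x candidate-sire values are needed.
#'
#' @inheritParams kinship
#' @param ids_a,ids_b Character vectors of individual ids (rows / columns).
#' @return Numeric matrix with `dimnames = list(ids_a, ids_b)`.
#' @export
relatedness_matrix <- function(p, ids_a, ids_b, depth_limit = Inf, cache = NULL) {
  stopifnot(inherits(p, "pedigree_table"))
  ia <- .ped_index(p, ids_a)
  ib <- .ped_index(p, ids_b)
  if (is.null(cache)) cache <- .new_kin_cache()
  out <- matrix(0, length(ia), length(ib),
                dimnames = list(as.character(ids_a), as.character(ids_b)))
  for (a in seq_along(ia)) {
    for (b in seq_along(ib)) {
      out[a, b] <- 2 * .kin_pair(p$sire_idx, p$dam_idx, p$gen, cache,
                                 ia[a], depth_limit, ib[b], depth_limit)
    }
  }
  out
}

#' Pedigree inbreeding coefficient, optionally truncated by depth
#'
#' `F` of an individual is the kinship coefficient of its parents, i.e. the
#' probability that its two alleles at a locus are identical by descent.
#' With `depth_limit = d`, ancestors of the *offspring* beyond generation `d`
#' (parents = generation 1) are treated as unrelated founders, so `d = 2`
#' corresponds to a three-generation analysis (common ancestors up to the
#' grandparents) and `d = 3` to a four-generation analysis.
#'
#' @inheritParams kinship
#' @param id Individual id; must have both parents recorded, otherwise `F` is
#'   undefined and `NA` is returned with a warning (never silently 0).
#' @param depth_limit Integer `>= 1` or `Inf`: ancestor generations of the
#'   offspring considered.
#' @return Inbreeding coefficient `F` (numeric scalar, `NA` if undefined).
#' @examples
#' # offspring of a sire x daughter mating: F = 0.25
#' ped <- build_pedigree(data.frame(
#'   id   = c("S", "W", "D", "X"),
#'   sire = c(NA, NA, "S", "S"),
#'   dam  = c(NA, NA, "W", "D"),
#'   sex  = c("M", "F", "F", "F")))
#' inbreeding_coefficient(ped, "X")
#' @export
inbreeding_coefficient <- function(p, id, depth_limit = Inf, cache = NULL) {
  stopifnot(inherits(p, "pedigree_table"))
  if (is.na(depth_limit) || depth_limit < 1) {
    stop("depth_limit must be >= 1 (parents are generation 1)")
  }
  idx <- .ped_index(p, id)
  s <- p$sire_idx[idx]
  d <- p$dam_idx[idx]
  if (is.na(s) || is.na(d)) {
    warning("individual ", id, " has a missing parent; F is undefined")
    return(NA_real_)
  }
  if (is.null(cache)) cache <- .new_kin_cache()
  .kin_pair(p$sire_idx, p$dam_idx, p$gen, cache, s, depth_limit - 1, d, depth_limit - 1)
}

#' Inbreeding coefficients for many individuals
#'
#' Vectorised convenience wrapper around [inbreeding_coefficient()] sharing a
#' single memoisation cache. Individuals with a missing parent get `NA`.
#'
#' @inheritParams inbreeding_coefficient
#' @param ids Character vector of ids (defaults to all individuals).
#' @return Named numeric vector of `F` values.
#' @export
inbreeding_coefficients <- function(p, ids = p$ped$id, depth_limit = Inf) {
  idx <- .ped_index(p, ids)
  cache <- .new_kin_cache()
  out <- rep(NA_real_, length(idx))
  for (k in seq_along(idx)) {
    s <- p$sire_idx[idx[k]]
    d <- p$dam_idx[idx[k]]
    if (!is.na(s) && !is.na(d)) {
      out[k] <- .kin_pair(p$sire_idx, p$dam_idx, p$gen, cache,
                          s, depth_limit - 1, d, depth_limit - 1)
    }
  }
  stats::setNames(out, p$ped$id[idx])
}

# All upward simple paths from `start` of length <= maxlen.
# Returns a list of integer vectors, each starting at `start` (so the trivial
# length-0 path is included).
.ancestor_paths <- function(sidx, didx, start, maxlen) {
  out <- list()
  walk <- function(path) {
    out[[length(out) + 1L]] <<- path
    if (length(path) - 1L >= maxlen) return()
    v <- path[[length(path)]]
    for (par in c(sidx[v], didx[v])) {
      if (!is.na(par) && !(par %in% path)) walk(c(path, par))
    }
  }
  walk(start)
  out
}

#' Classify an inbreeding case by kin type and kin line
#'
#' Enumerates the common-ancestor paths connecting the parents of an inbred
#' individual (Wright's path-counting rule: the two branches of a path may
#' share no individual other than the common ancestor) within the stated
#' depth, labels the relationship of the parents, and assigns the kin line.
#'
#' Relationship labels follow the usual taxonomy: a shared parent gives
#' half-siblings (full siblings when both parents are shared); one breeder
#' being the other's parent gives parent-offspring; a sibling link one
#' generation apart gives uncle-niece (the sire is the sibling) or
#' aunt-nephew (the dam is); shared grandparents give first cousins; anything
#' else collapses to `"other"` with the raw path lengths retained. The kin
#' line is derived from the sex-of-parent of each breeder's first step toward
#' the common ancestor (both via sires = paternal, both via dams = maternal,
#' mixed = maternal-and-paternal; for parent-offspring pairs only the
#' descendant's step counts).
#'
#' @inheritParams inbreeding_coefficient
#' @return An object of class `inbreeding_case`: list with `individual`, `F`,
#'   `depth_limit` and `kin_paths` (a data frame with one row per relationship
#'   group: `ancestors`, `relationship`, `kin_line`, `n_paths`,
#'   `contribution`). With `F = 0` the classification is empty.
#' @examples
#' ped <- build_pedigree(data.frame(
#'   id   = c("A", "M1", "M2", "S", "D", "X"),
#'   sire = c(NA, NA, NA, "A", "A", "S"),
#'   dam  = c(NA, NA, NA, "M1", "M2", "D"),
#'   sex  = c("M", "F", "F", "M", "F", "U")))
#' classify_inbreeding(ped, "X")  # paternal half-sibs, paternal line
#' @export
classify_inbreeding <- function(p, id, depth_limit = Inf, cache = NULL) {
  stopifnot(inherits(p, "pedigree_table"))
  idx <- .ped_index(p, id)
  S <- p$sire_idx[idx]
  D <- p$dam_idx[idx]
  if (is.na(S) || is.na(D)) {
    warning("individual ", id, " has a missing parent; cannot classify")
    return(structure(list(individual = as.character(id), F = NA_real_,
                          depth_limit = depth_limit,
                          kin_paths = .empty_kin_paths()),
                     class = "inbreeding_case"))
  }
  Fv <- inbreeding_coefficient(p, id, depth_limit = depth_limit, cache = cache)
  budget <- min(depth_limit - 1, max(p$gen))
  paths_S <- .ancestor_paths(p$sire_idx, p$dam_idx, S, budget)
  paths_D <- .ancestor_paths(p$sire_idx, p$dam_idx, D, budget)
  step_sex <- function(path, who) {
    # "paternal" when the breeder's first step toward the ancestor is via its
    # sire, "maternal" via its dam; NA for a trivial (length-0) path.
    if (length(path) < 2L) return(NA_character_)
    if (!is.na(p$sire_idx[who]) && path[[2L]] == p$sire_idx[who]) "paternal" else "maternal"
  }
  rows <- list()
  for (ps in paths_S) {
    for (pd in paths_D) {
      A <- ps[[length(ps)]]
      if (A != pd[[length(pd)]]) next
      ls <- length(ps) - 1L
      ld <- length(pd) - 1L
      if (ls == 0L && ld == 0L) next  # S == D is impossible (sexed parents)
      if (length(intersect(ps[-length(ps)], pd[-length(pd)])) > 0L) next
      FA <- 0
      if (!is.na(p$sire_idx[A]) && !is.na(p$dam_idx[A])) {
        bA <- min(budget - ls, budget - ld)
        if (bA >= 1) {
          if (is.null(cache)) cache <- .new_kin_cache()
          FA <- .kin_pair(p$sire_idx, p$dam_idx, p$gen, cache,
                          p$sire_idx[A], bA - 1, p$dam_idx[A], bA - 1)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        ancestor = p$ped$id[A], LS = ls, LD = ld,
        stepS = step_sex(ps, S), stepD = step_sex(pd, D),
        contribution = 0.5^(ls + ld + 1) * (1 + FA),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(structure(list(individual = as.character(id), F = Fv,
                          depth_limit = depth_limit,
                          kin_paths = .empty_kin_paths()),
                     class = "inbreeding_case"))
  }
  raw <- do.call(rbind, rows)
  grp <- split(raw, paste0(raw$LS, "_", raw$LD))
  kin_paths <- do.call(rbind, lapply(grp, function(g) {
    ls <- g$LS[[1L]]
    ld <- g$LD[[1L]]
    rel <- if ((ls == 0L && ld == 1L) || (ls == 1L && ld == 0L)) {
      "parent-offspring"
    } else if (ls == 1L && ld == 1L) {
      if (length(unique(g$ancestor)) >= 2L) {
        "full-sibs"
      } else if (p$ped$sex[.ped_index(p, g$ancestor[[1L]])] == "M") {
        "paternal half-sibs"
      } else {
        "maternal half-sibs"
      }
    } else if (ls == 1L && ld == 2L) {
      "uncle-niece"
    } else if (ls == 2L && ld == 1L) {
      "aunt-nephew"
    } else if (ls == 2L && ld == 2L) {
      "first cousins"
    } else {
      "other"
    }
    steps <- stats::na.omit(c(g$stepS, g$stepD))
    line <- if (all(steps == "paternal")) {
      "paternal"
    } else if (all(steps == "maternal")) {
      "maternal"
    } else {
      "maternal-and-paternal"
    }
    data.frame(
      ancestors = paste(sort(unique(g$ancestor)), collapse = ","),
      relationship = rel, kin_line = line, n_paths = nrow(g),
      contribution = sum(g$contribution),
      path_lengths = paste0(ls, "+", ld),
      stringsAsFactors = FALSE
    )
  }))
  rownames(kin_paths) <- NULL
  structure(list(individual = as.character(id), F = Fv,
                 depth_limit = depth_limit, kin_paths = kin_paths),
            class = "inbreeding_case")
}

.empty_kin_paths <- function() {
  data.frame(ancestors = character(0), relationship = character(0),
             kin_line = character(0), n_paths = integer(0),
             contribution = numeric(0), path_lengths = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.inbreeding_case <- function(x, ...) {
  cat("inbreeding case:", x$individual, " F =", format(x$F, digits = 4),
      " (depth limit ", x$depth_limit, ")\n", sep = "")
  if (nrow(x$kin_paths)) {
    print(x$kin_paths, row.names = FALSE)
  } else {
    cat("  no kin paths within depth\n")
  }
  invisible(x)
}

#' Monte-Carlo gene-dropping estimate of F
#'
#' Independent validation oracle for the kinship recursion: two distinct
#' allele labels are assigned to every founder, transmitted down the pedigree
#' with fair Mendelian draws, and `F` is estimated as the proportion of
#' replicates in which the focal individual receives two copies identical by
#' descent. The whole known pedigree is used (no depth truncation).
#'
#' @inheritParams inbreeding_coefficient
#' @param n_replicates Number of Monte-Carlo replicates (`>= 1`).
#' @param seed Optional integer seed.
#' @return List with `F_hat`, the Monte-Carlo standard error
#'   `se = sqrt(F_hat (1 - F_hat) / n)`, and `n_replicates`.
#' @export
gene_drop_F <- function(p, id, n_replicates = 1e5, seed = NULL) {
  stopifnot(inherits(p, "pedigree_table"))
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  n_replicates <- as.integer(n_replicates)
  if (!is.null(seed)) set.seed(seed)
  idx <- .ped_index(p, id)
  if (is.na(p$sire_idx[idx]) || is.na(p$dam_idx[idx])) {
    stop("individual ", id, " has a missing parent; F is undefined")
  }
  # restrict to the focal individual's ancestor closure
  keep <- logical(p$n)
  stack <- idx
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (keep[v]) next
    keep[v] <- TRUE
    for (par in c(p$sire_idx[v], p$dam_idx[v])) {
      if (!is.na(par) && !keep[par]) stack <- c(stack, par)
    }
  }
  nodes <- which(keep)
  nodes <- nodes[order(p$gen[nodes])]
  a1 <- vector("list", p$n)
  a2 <- vector("list", p$n)
  lab <- 0L
  for (v in nodes) {
    s <- p$sire_idx[v]
    d <- p$dam_idx[v]
    if (is.na(s) && is.na(d)) {
      a1[[v]] <- rep.int(lab + 1L, n_replicates)
      a2[[v]] <- rep.int(lab + 2L, n_replicates)
      lab <- lab + 2L
    } else {
      # founder stub behaviour for half-known parents: the missing side
      # contributes a fresh allele label
      if (!is.na(s)) {
        pick <- stats::runif(n_replicates) < 0.5
        from_s <- ifelse(pick, a1[[s]], a2[[s]])
      } else {
        from_s <- rep.int(lab + 1L, n_replicates)
        lab <- lab + 1L
      }
      if (!is.na(d)) {
        pick <- stats::runif(n_replicates) < 0.5
        from_d <- ifelse(pick, a1[[d]], a2[[d]])
      } else {
        from_d <- rep.int(lab + 1L, n_replicates)
        lab <- lab + 1L
      }
      a1[[v]] <- from_s
      a2[[v]] <- from_d
    }
  }
  f_hat <- mean(a1[[idx]] == a2[[idx]])
  list(F_hat = f_hat,
       se = sqrt(f_hat * (1 - f_hat) / n_replicates),
       n_replicates = n_replicates)
}
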