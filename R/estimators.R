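#' Construct a multilocus genotype table
#'
#' Diploid codominant genotypes: two alleles per locus per individual, with
#' missingness always affecting the whole genotype (no half-calls).
#'
#' @param ids Character vector of individual ids (unique).
#' @param a1,a2 Character matrices (`length(ids)` rows, one column per locus)
#'   holding the two allele calls; column names are the locus names.
#' @return Object of class `genotype_table`: list with `ids`, `loci`, `a1`,
#'   `a2`.
#' @export
genotype_table <- function(ids, a1, a2) {
  ids <- as.character(ids)
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  storage.mode(a1) <- "character"
  storage.mode(a2) <- "character"
  if (anyDuplicated(ids)) stop("duplicate individual ids in genotype table")
  if (!all(dim(a1) == dim(a2))) stop("allele matrices must have equal dimensions")
  if (nrow(a1) != length(ids)) stop("allele matrices must have one row per individual")
  if (is.null(colnames(a1))) colnames(a1) <- paste0("L", seq_len(ncol(a1)))
  colnames(a2) <- colnames(a1)
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    stop("half-called genotypes (one allele missing) are not allowed; ",
         sum(half), " cell(s) affected")
  }
  rownames(a1) <- rownames(a2) <- ids
  structure(list(ids = ids, loci = colnames(a1), a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$ids), "individuals x", length(x$loci),
      "loci;", sprintf("%.1f%%", 100 * mean(is.na(x$a1))), "missing\n")
  invisible(x)
}

#' Number of typed loci per individual
#' @param g A `genotype_table`.
#' @return Named integer vector.
#' @export
n_typed <- function(g) {
  stopifnot(inherits(g, "genotype_table"))
  stats::setNames(rowSums(!is.na(g$a1)), g$ids)
}

#' Sample allele frequencies, observed and expected heterozygosity
#'
#' Counts both alleles of every typed individual at each locus (the focal
#' individual included, matching common practice for these estimators; use
#' `exclude` for a leave-one-out computation). Loci with no typed individual
#' are dropped with a warning.
#'
#' @param g A `genotype_table`.
#' @param exclude Optional ids left out of the counts.
#' @return Object of class `allele_freqs`: list with `loci`, `freq` (per-locus
#'   named frequency vectors summing to 1), `h_obs` (fraction of typed
#'   individuals heterozygous), `e_het` (expected heterozygosity
#'   `1 - sum(p^2)`) and `n_typed` per locus.
#' @export
allele_frequencies <- function(g, exclude = NULL) {
  stopifnot(inherits(g, "genotype_table"))
  keep <- !(g$ids %in% exclude)
  if (!any(keep)) stop("no individuals left after exclusion")
  a1 <- g$a1[keep, , drop = FALSE]
  a2 <- g$a2[keep, , drop = FALSE]
  loci <- g$loci
  freq <- vector("list", length(loci))
  h_obs <- e_het <- rep(NA_real_, length(loci))
  ntyp <- integer(length(loci))
  names(freq) <- names(h_obs) <- names(e_het) <- names(ntyp) <- loci
  for (l in seq_along(loci)) {
    x1 <- a1[, l]
    x2 <- a2[, l]
    typed <- !is.na(x1)
    ntyp[l] <- sum(typed)
    if (ntyp[l] == 0L) next
    tab <- table(c(x1[typed], x2[typed]))
    pl <- as.numeric(tab) / sum(tab)
    names(pl) <- names(tab)
    freq[[l]] <- pl
    h_obs[l] <- mean(x1[typed] != x2[typed])
    e_het[l] <- 1 - sum(pl^2)
  }
  empty <- ntyp == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " locus/loci with no typed individuals: ",
            paste(loci[empty], collapse = ", "))
    freq <- freq[!empty]
    h_obs <- h_obs[!empty]
    e_het <- e_het[!empty]
    ntyp <- ntyp[!empty]
    loci <- loci[!empty]
  }
  if (!length(loci)) stop("no typed loci in genotype table")
  structure(list(loci = loci, freq = freq, h_obs = h_obs, e_het = e_het,
                 n_typed = ntyp),
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat("allele_freqs:", length(x$loci), "loci; mean H_obs",
      sprintf("%.3f", mean(x$h_obs)), "; mean E",
      sprintf("%.3f", mean(x$e_het)), "\n")
  invisible(x)
}

# typed-locus view of one individual; NULL if below min_loci
.ind_loci <- function(ind, g, freqs, min_loci) {
  i <- match(ind, g$ids)
  if (is.na(i)) stop("unknown individual id: ", ind)
  loci <- intersect(g$loci[!is.na(g$a1[i, ])], freqs$loci)
  if (length(loci) < min_loci) {
    warning("individual ", ind, " typed at ", length(loci),
            " loci (< min_loci = ", min_loci, "); estimate undefined")
    return(NULL)
  }
  list(i = i, loci = loci,
       a1 = g$a1[i, loci], a2 = g$a2[i, loci],
       het = g$a1[i, loci] != g$a2[i, loci])
}

#' Standardized heterozygosity (SH)
#'
#' The individual's proportion of heterozygous typed loci divided by the mean
#' population heterozygosity of the loci it was typed at. Values below 1
#' indicate fewer heterozygous loci than expected (more inbred parentage);
#' SH is 0 for an all-homozygous individual and unbounded above.
#'
#' @param ind Individual id.
#' @param g A `genotype_table`.
#' @param freqs An `allele_freqs` object (defaults to frequencies computed
#'   from `g`).
#' @param min_loci Minimum typed loci required (default 10); below it the
#'   estimate is `NA` with a warning, never a silent drop.
#' @param use_expected Use expected (`1 - sum(p^2)`) instead of observed
#'   heterozygosity in the denominator.
#' @return SH (numeric scalar; `NA` when undefined, e.g. all typed loci
#'   monomorphic).
#' @export
standardized_heterozygosity <- function(ind, g, freqs = allele_frequencies(g),
                                        min_loci = 10, use_expected = FALSE) {
  v <- .ind_loci(ind, g, freqs, min_loci)
  if (is.null(v)) return(NA_real_)
  denom <- if (use_expected) mean(freqs$e_het[v$loci]) else mean(freqs$h_obs[v$loci])
  if (!is.finite(denom) || denom <= 0) {
    warning("all typed loci monomorphic for ", ind, "; SH undefined")
    return(NA_real_)
  }
  mean(v$het) / denom
}

#' Internal relatedness (IR)
#'
#' Allele-frequency-weighted homozygosity in `[-1, 1]`:
#' `IR = (2H - sum(f_i)) / (2N - sum(f_i))` with `H` homozygous typed loci,
#' `N` typed loci and `sum(f_i)` the summed sample frequencies of the
#' individual's `2N` allele copies, so that sharing *rare* alleles weighs
#' more. Positive values indicate offspring of more related parents.
#'
#' @inheritParams standardized_heterozygosity
#' @return IR (numeric scalar, `NA` when undefined).
#' @export
internal_relatedness <- function(ind, g, freqs = allele_frequencies(g),
                                 min_loci = 10) {
  v <- .ind_loci(ind, g, freqs, min_loci)
  if (is.null(v)) return(NA_real_)
  N <- length(v$loci)
  H <- sum(!v$het)
  sumf <- 0
  for (k in seq_along(v$loci)) {
    pl <- freqs$freq[[v$loci[[k]]]]
    sumf <- sumf + pl[[v$a1[[k]]]] + pl[[v$a2[[k]]]]
  }
  denom <- 2 * N - sumf
  if (denom <= 0) {
    warning("degenerate allele frequencies for ", ind, "; IR undefined")
    return(NA_real_)
  }
  (2 * H - sumf) / denom
}

#' Homozygosity by loci (HL)
#'
#' Expected-heterozygosity-weighted homozygosity in `[0, 1]`:
#' `HL = sum(E_h) / (sum(E_h) + sum(E_j))`, where `E_h` are the expected
#' heterozygosities of the individual's homozygous typed loci and `E_j` of
#' its heterozygous ones, so that more variable loci weigh more. 1 means all
#' loci homozygous, 0 all heterozygous.
#'
#' @inheritParams standardized_heterozygosity
#' @return HL (numeric scalar, `NA` when all typed loci are monomorphic).
#' @export
homozygosity_by_loci <- function(ind, g, freqs = allele_frequencies(g),
                                 min_loci = 10) {
  v <- .ind_loci(ind, g, freqs, min_loci)
  if (is.null(v)) return(NA_real_)
  E <- freqs$e_het[v$loci]
  tot <- sum(E)
  if (tot <= 0) {
    warning("all typed loci monomorphic for ", ind, "; HL undefined")
    return(NA_real_)
  }
  sum(E[!v$het]) / tot
}

#' All three marker-based inbreeding estimators for every individual
#'
#' Computes SH, IR and HL per individual plus the three pairwise Spearman
#' rank correlations among the estimators. By construction HL and IR rise
#' with homozygosity while SH falls, so corr(HL, SH) and corr(IR, SH) are
#' expected negative and corr(HL, IR) positive.
#'
#' @param g A `genotype_table`.
#' @param min_loci Minimum typed loci per individual (default 10).
#' @param freq_exclude_focal Recompute allele frequencies leaving the focal
#'   individual out of the counts (leave-one-out; slower).
#' @param sh_expected Use expected rather than observed heterozygosity in the
#'   SH denominator.
#' @return Object of class `estimator_results`: list with `results` (data
#'   frame `id`, `n_loci`, `SH`, `IR`, `HL`) and `correlations` (named vector
#'   `HL_SH`, `IR_SH`, `HL_IR`; `NA` with fewer than 2 usable individuals or
#'   zero variance).
#' @export
estimate_all <- function(g, min_loci = 10, freq_exclude_focal = FALSE,
                         sh_expected = FALSE) {
  stopifnot(inherits(g, "genotype_table"))
  base_freqs <- allele_frequencies(g)
  nt <- n_typed(g)
  res <- data.frame(id = g$ids, n_loci = as.integer(nt),
                    SH = NA_real_, IR = NA_real_, HL = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(g$ids)) {
    ind <- g$ids[[k]]
    freqs <- if (freq_exclude_focal) {
      tryCatch(allele_frequencies(g, exclude = ind), error = function(e) NULL)
    } else base_freqs
    if (is.null(freqs)) next
    suppressWarnings({
      res$SH[k] <- standardized_heterozygosity(ind, g, freqs, min_loci,
                                               use_expected = sh_expected)
      res$IR[k] <- internal_relatedness(ind, g, freqs, min_loci)
      res$HL[k] <- homozygosity_by_loci(ind, g, freqs, min_loci)
    })
  }
  ok <- stats::complete.cases(res[, c("SH", "IR", "HL")])
  cors <- c(HL_SH = NA_real_, IR_SH = NA_real_, HL_IR = NA_real_)
  if (sum(ok) >= 2) {
    sdv <- vapply(res[ok, c("SH", "IR", "HL")], stats::sd, numeric(1))
    if (all(sdv > 0)) {
      cors["HL_SH"] <- stats::cor(res$HL[ok], res$SH[ok], method = "spearman")
      cors["IR_SH"] <- stats::cor(res$IR[ok], res$SH[ok], method = "spearman")
      cors["HL_IR"] <- stats::cor(res$HL[ok], res$IR[ok], method = "spearman")
    } else {
      warning("zero-variance estimates; correlations undefined")
    }
  } else {
    warning("fewer than 2 individuals with defined estimates; ",
            "correlations undefined")
  }
  structure(list(results = res, correlations = cors),
            class = "estimator_results")
}

#' @export
print.estimator_results <- function(x, ...) {
  cat("estimator_results:", nrow(x$results), "individuals\n")
  print(utils::head(x$results))
  cat("Spearman correlations: ",
      paste(names(x$correlations),
            sprintf("%.3f", x$correlations), collapse = "  "), "\n")
  invisible(x)
}
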