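#' Build and validate a pedigree table
#'
#' Assembles raw pedigree rows into a validated `pedigree_table`. Parent ids
#' that are referenced but have no row of their own are auto-created as
#' *founder stubs* and flagged; stubs are assumed unrelated and non-inbred,
#' like all founders. `"0"`, `""` and `NA` all denote a missing parent.
#'
#' @param records A data frame with at least columns `id`, `sire`, `dam`.
#'   Optional columns: `sex` (`"M"`, `"F"`, `"U"`; default `"U"`),
#'   `birth_date`, `death_date` (`Date` or ISO-8601 strings), `removed`
#'   (logical; `TRUE` when the animal left by removal rather than death) and
#'   `birth_group`.
#' @param strict_dates If `TRUE`, a parent born on or after its offspring is a
#'   hard error; otherwise such rows only raise a warning (dates in colony
#'   records are occasionally approximate).
#' @return An object of class `pedigree_table`: a list with the validated
#'   record data frame (`$ped`, stubs appended and flagged in `$ped$stub`),
#'   integer parent indices (`$sire_idx`, `$dam_idx`), generation numbers
#'   (`$gen`, founders = 0) and the record count `$n`. The validation report
#'   (stub count and ids, date violations) is attached as attribute
#'   `"validation"`.
#' @examples
#' ped <- build_pedigree(data.frame(
#'   id = c("A", "B", "X"), sire = c(NA, NA, "A"), dam = c(NA, NA, "B"),
#'   sex = c("M", "F", "F")))
#' ped
#' @export
build_pedigree <- function(records, strict_dates = FALSE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("id", "sire", "dam")) {
    if (!col %in% names(records)) {
      stop("pedigree records must contain column '", col, "'")
    }
  }
  n0 <- nrow(records)
  if (n0 == 0L) stop("empty pedigree: no records supplied")

  id  <- as.character(records$id)
  sire <- .as_parent(records$sire)
  dam  <- .as_parent(records$dam)
  sex <- if ("sex" %in% names(records)) {
    toupper(as.character(records$sex))
  } else rep("U", n0)
  sex[is.na(sex)] <- "U"
  bad_sex <- setdiff(unique(sex), c("M", "F", "U"))
  if (length(bad_sex)) stop("invalid sex code(s): ", paste(bad_sex, collapse = ", "))

  birth_date <- .as_date_col(records[["birth_date"]], n0, "birth_date")
  death_date <- .as_date_col(records[["death_date"]], n0, "death_date")
  removed <- if ("removed" %in% names(records)) {
    as.logical(records$removed)
  } else rep(FALSE, n0)
  removed[is.na(removed)] <- FALSE
  birth_group <- if ("birth_group" %in% names(records)) {
    as.character(records$birth_group)
  } else rep(NA_character_, n0)

  if (anyNA(id) || any(id == "")) stop("missing individual id in pedigree records")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate pedigree id(s): ", paste(dup, collapse = ", "))
  }
  self <- id == sire | id == dam
  self[is.na(self)] <- FALSE
  if (any(self)) {
    stop("individual(s) recorded as their own parent: ",
         paste(id[self], collapse = ", "))
  }

  # founder stubs for referenced-but-absent parents
  ref <- unique(c(sire, dam))
  ref <- ref[!is.na(ref)]
  stub_ids <- setdiff(ref, id)
  if (length(stub_ids)) {
    stub_sex <- ifelse(stub_ids %in% sire, "M", "F")
    id <- c(id, stub_ids)
    sire <- c(sire, rep(NA_character_, length(stub_ids)))
    dam <- c(dam, rep(NA_character_, length(stub_ids)))
    sex <- c(sex, stub_sex)
    birth_date <- c(birth_date, rep(as.Date(NA), length(stub_ids)))
    death_date <- c(death_date, rep(as.Date(NA), length(stub_ids)))
    removed <- c(removed, rep(FALSE, length(stub_ids)))
    birth_group <- c(birth_group, rep(NA_character_, length(stub_ids)))
  }
  stub <- c(rep(FALSE, n0), rep(TRUE, length(stub_ids)))
  n <- length(id)

  sire_idx <- match(sire, id)
  dam_idx <- match(dam, id)

  # sex consistency of parent roles
  bad_sire <- unique(sire[!is.na(sire_idx) & sex[sire_idx] == "F"])
  if (length(bad_sire)) {
    stop("individual(s) recorded female but used as sire: ",
         paste(bad_sire, collapse = ", "))
  }
  bad_dam <- unique(dam[!is.na(dam_idx) & sex[dam_idx] == "M"])
  if (length(bad_dam)) {
    stop("individual(s) recorded male but used as dam: ",
         paste(bad_dam, collapse = ", "))
  }

  gen <- .generations(sire_idx, dam_idx, id)

  # date-order validation (parent must be born strictly before offspring)
  viol <- character(0)
  for (pi in list(sire_idx, dam_idx)) {
    both <- !is.na(pi) & !is.na(birth_date) & !is.na(birth_date[pi])
    bad <- both & birth_date[pi] >= birth_date
    if (any(bad)) viol <- c(viol, id[bad])
  }
  viol <- unique(viol)
  if (length(viol)) {
    msg <- paste0("parent born on/after offspring for: ",
                  paste(viol, collapse = ", "))
    if (strict_dates) stop(msg) else warning(msg)
  }

  ped <- data.frame(
    id = id, sire = sire, dam = dam, sex = sex,
    birth_date = birth_date, death_date = death_date,
    removed = removed, birth_group = birth_group, stub = stub,
    stringsAsFactors = FALSE
  )
  out <- structure(
    list(ped = ped, sire_idx = sire_idx, dam_idx = dam_idx, gen = gen, n = n),
    class = "pedigree_table"
  )
  attr(out, "validation") <- list(
    n_records = n0, n_stubs = length(stub_ids), stub_ids = stub_ids,
    date_violations = viol
  )
  out
}

.as_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
  x
}

.as_date_col <- function(x, n, what) {
  if (is.null(x)) return(rep(as.Date(NA), n))
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- rep(as.Date(NA), n)
  known <- !is.na(x) & x != "" & x != "NA"
  if (any(known)) {
    ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x[known])
    if (!all(ok)) {
      stop("malformed ", what, " (expected YYYY-MM-DD): ",
           paste(utils::head(x[known][!ok], 5), collapse = ", "))
    }
    out[known] <- as.Date(x[known])
  }
  out
}

# Generation numbers by Kahn's topological sort over parent->offspring edges;
# detects cycles and names one member.
.generations <- function(sire_idx, dam_idx, id) {
  n <- length(id)
  indeg <- (!is.na(sire_idx)) + (!is.na(dam_idx))
  children <- vector("list", n)
  for (k in seq_len(n)) {
    for (p in c(sire_idx[k], dam_idx[k])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], k)
    }
  }
  gen <- integer(n)
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[v]]) {
      gen[ch] <- max(gen[ch], gen[v] + 1L)
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < n) {
    member <- id[which(indeg > 0L)[1L]]
    stop("cycle in parent links involving individual ", member)
  }
  gen
}

.ped_index <- function(p, ids) {
  idx <- match(as.character(ids), p$ped$id)
  if (anyNA(idx)) {
    stop("unknown individual id(s): ",
         paste(unique(ids[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' @export
print.pedigree_table <- function(x, ...) {
  v <- attr(x, "validation")
  cat("pedigree_table:", x$n, "individuals (",
      sum(x$ped$stub), "founder stubs ),",
      sum(is.na(x$sire_idx) & is.na(x$dam_idx)), "founders, max generation",
      max(x$gen), "\n")
  if (length(v$date_violations)) {
    cat("  date-order violations:", length(v$date_violations), "\n")
  }
  invisible(x)
}

#' Number of fully known ancestor generations
#'
#' The completeness depth of an individual is the largest `d` such that all
#' `2^g` ancestors exist as non-stub records for every generation
#' `1 <= g <= d`. A founder (or a founder stub) has depth 0. In the usual
#' field phrasing, a "complete three-generation pedigree" (focal + parents +
#' grandparents) corresponds to depth `d >= 2`, and a complete four-generation
#' pedigree to `d >= 3`.
#'
#' @param p A `pedigree_table`.
#' @param id One or more individual ids (defaults to all individuals).
#' @return Named integer vector of completeness depths.
#' @examples
#' ped <- build_pedigree(data.frame(
#'   id = c("A", "B", "X"), sire = c(NA, NA, "A"), dam = c(NA, NA, "B")))
#' ancestor_complete_depth(ped, "X")  # 1: parents known founders
#' @export
ancestor_complete_depth <- function(p, id = p$ped$id) {
  stopifnot(inherits(p, "pedigree_table"))
  idx <- .ped_index(p, id)
  depth <- integer(p$n)
  ord <- order(p$gen)
  for (k in ord) {
    s <- p$sire_idx[k]
    d <- p$dam_idx[k]
    if (p$ped$stub[k] || is.na(s) || is.na(d) || p$ped$stub[s] || p$ped$stub[d]) {
      depth[k] <- 0L
    } else {
      depth[k] <- 1L + min(depth[s], depth[d])
    }
  }
  stats::setNames(depth[idx], p$ped$id[idx])
}

#' Prevalence of inbreeding per birth cohort
#'
#' Summarises a collection of inbreeding cases (individuals with a computed
#' inbreeding coefficient and a cohort label) into per-cohort and overall
#' counts: individuals assessed, individuals inbred (`F > 0`), the proportion
#' inbred (also formatted as a percentage to 2 decimals) and the mean `F`
#' among the inbred.
#'
#' @param cases Data frame with columns `F` (numeric inbreeding coefficient;
#'   `NA` = undefined, excluded) and a cohort column.
#' @param cohort Name of the cohort column (default `"cohort"`).
#' @return List with elements `overall` (one-row data frame) and `by_cohort`
#'   (one row per cohort). Counts across cohorts sum to the overall counts.
#' @examples
#' cases <- data.frame(F = c(0, 0.125, 0, 0), cohort = c(1, 1, 2, 2))
#' prevalence_summary(cases)
#' @export
prevalence_summary <- function(cases, cohort = "cohort") {
  cases <- as.data.frame(cases)
  if (!"F" %in% names(cases)) stop("cases must contain a column 'F'")
  if (nrow(cases) == 0L) {
    overall <- data.frame(n_individuals = 0L, n_inbred = 0L,
                          proportion_inbred = 0, pct_inbred = "0.00%",
                          mean_F_inbred = NA_real_)
    return(list(overall = overall,
                by_cohort = overall[0, ]))
  }
  if (!cohort %in% names(cases)) stop("no cohort column '", cohort, "'")
  cases <- cases[!is.na(cases$F), , drop = FALSE]
  one <- function(f) {
    n <- length(f)
    ni <- sum(f > 0)
    prop <- if (n > 0) ni / n else 0
    data.frame(
      n_individuals = n, n_inbred = ni, proportion_inbred = prop,
      pct_inbred = sprintf("%.2f%%", 100 * prop),
      mean_F_inbred = if (ni > 0) mean(f[f > 0]) else NA_real_
    )
  }
  by <- lapply(split(cases$F, cases[[cohort]]), one)
  by_cohort <- do.call(rbind, by)
  by_cohort <- cbind(cohort = names(by), by_cohort)
  rownames(by_cohort) <- NULL
  list(overall = one(cases$F), by_cohort = by_cohort)
}
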