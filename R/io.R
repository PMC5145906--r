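# File dialects
# pedigree:   TSV  id sire dam sex birth_date death_date removed birth_group
# genotypes:  CSV  id,<locus>.1,<locus>.2,...   missing pair = NA,NA
# demography: TSV  id group start_date end_date  (half-open [start, end))
# Missing values are written "NA"; a parent of "0" also reads as missing.

.PED_HEADER <- c("id", "sire", "dam", "sex", "birth_date", "death_date",
                 "removed", "birth_group")

#' Read a pedigree file
#'
#' Tab-separated with the canonical header (see Details). `NA` and `0` both
#' denote a missing parent; dates are ISO-8601. Malformed headers, duplicate
#' ids and bad dates raise errors naming the offending line.
#'
#' @details Header: `id sire dam sex birth_date death_date removed
#' birth_group`, tab-separated; sex in `{M, F, U}`.
#'
#' @param path File path.
#' @param strict_dates Passed to [build_pedigree()].
#' @return A `pedigree_table`.
#' @export
read_pedigree <- function(path, strict_dates = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           na.strings = "NA", check.names = FALSE)
  if (!identical(names(raw), .PED_HEADER)) {
    stop("malformed pedigree header in ", path, "; expected: ",
         paste(.PED_HEADER, collapse = "\t"))
  }
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1
  dup <- duplicated(raw$id)
  if (any(dup)) {
    stop("duplicate id '", raw$id[dup][1], "' on line ",
         line_no[dup][1], " of ", path)
  }
  for (col in c("birth_date", "death_date")) {
    x <- raw[[col]]
    bad <- !is.na(x) & !grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
    if (any(bad)) {
      stop("malformed ", col, " '", x[bad][1], "' on line ",
           line_no[bad][1], " of ", path)
    }
  }
  build_pedigree(raw, strict_dates = strict_dates)
}

#' Write a pedigree file
#'
#' Emits the same dialect [read_pedigree()] accepts; auto-created founder
#' stubs are not written (they are regenerated on read), so write-then-read
#' round trips are stable.
#'
#' @param p A `pedigree_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(p, path) {
  stopifnot(inherits(p, "pedigree_table"))
  ped <- p$ped[!p$ped$stub, .PED_HEADER, drop = FALSE]
  ped$birth_date <- ifelse(is.na(ped$birth_date),
                           NA, format(ped$birth_date, "%Y-%m-%d"))
  ped$death_date <- ifelse(is.na(ped$death_date),
                           NA, format(ped$death_date, "%Y-%m-%d"))
  ped$removed <- ifelse(ped$removed, "TRUE", "FALSE")
  utils::write.table(ped, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' Read a genotype file
#'
#' CSV with header `id,<locus>.1,<locus>.2,...`: two columns per locus named
#' `<locus>.1` and `<locus>.2`. A missing genotype is the pair `NA,NA`
#' (half-calls are rejected).
#'
#' @param path File path.
#' @return A `genotype_table`.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character", na.strings = "NA",
                         check.names = FALSE)
  if (names(raw)[1] != "id") stop("genotype header must start with 'id'")
  ac <- names(raw)[-1]
  if (length(ac) %% 2 != 0) {
    stop("odd number of allele columns (", length(ac),
         "): each locus needs <locus>.1 and <locus>.2")
  }
  c1 <- ac[seq(1, length(ac), by = 2)]
  c2 <- ac[seq(2, length(ac), by = 2)]
  loci1 <- sub("\\.1$", "", c1)
  loci2 <- sub("\\.2$", "", c2)
  if (!all(grepl("\\.1$", c1)) || !all(grepl("\\.2$", c2)) ||
      !identical(loci1, loci2)) {
    stop("allele columns must come in <locus>.1,<locus>.2 pairs")
  }
  a1 <- as.matrix(raw[c1])
  a2 <- as.matrix(raw[c2])
  colnames(a1) <- colnames(a2) <- loci1
  genotype_table(raw$id, a1, a2)
}

#' Write a genotype file
#' @param g A `genotype_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_table"))
  out <- data.frame(id = g$ids, stringsAsFactors = FALSE)
  for (l in g$loci) {
    out[[paste0(l, ".1")]] <- g$a1[, l]
    out[[paste0(l, ".2")]] <- g$a2[, l]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a demography (group membership) file
#'
#' TSV `id group start_date end_date` of half-open membership intervals
#' `[start, end)`; a missing `end_date` means open-ended. An interval ending
#' before it starts, or two overlapping intervals for one individual, are
#' errors.
#'
#' @param path File path.
#' @return Data frame `id`, `group`, `start_date`, `end_date` (`Date`).
#' @export
read_demography <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, colClasses = "character", na.strings = "NA",
                           check.names = FALSE)
  need <- c("id", "group", "start_date", "end_date")
  if (!identical(names(raw), need)) {
    stop("malformed demography header; expected: ", paste(need, collapse = "\t"))
  }
  out <- data.frame(id = raw$id, group = raw$group,
                    start_date = as.Date(raw$start_date),
                    end_date = as.Date(raw$end_date),
                    stringsAsFactors = FALSE)
  if (anyNA(out$start_date)) stop("missing/malformed start_date in ", path)
  bad <- !is.na(out$end_date) & out$end_date < out$start_date
  if (any(bad)) {
    stop("interval ends before it starts for id ", out$id[bad][1])
  }
  for (i in unique(out$id)) {
    iv <- out[out$id == i, ]
    if (nrow(iv) < 2) next
    iv <- iv[order(iv$start_date), ]
    ends <- iv$end_date[-nrow(iv)]
    if (anyNA(ends) || any(ends > iv$start_date[-1])) {
      stop("overlapping group-membership intervals for id ", i)
    }
  }
  out
}

#' Write a demography file
#' @param demog Data frame `id`, `group`, `start_date`, `end_date`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_demography <- function(demog, path) {
  out <- data.frame(
    id = demog$id, group = demog$group,
    start_date = format(as.Date(demog$start_date), "%Y-%m-%d"),
    end_date = ifelse(is.na(demog$end_date), NA,
                      format(as.Date(demog$end_date), "%Y-%m-%d")),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' Read a breeding-pairs file
#'
#' TSV `offspring mother sire birth_date`, the observed-pairs input of the
#' avoidance test.
#'
#' @param path File path.
#' @return Data frame with those columns (`birth_date` as `Date`).
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, colClasses = "character", na.strings = "NA")
  need <- c("offspring", "mother", "sire", "birth_date")
  if (!identical(names(raw), need)) {
    stop("malformed pairs header; expected: ", paste(need, collapse = "\t"))
  }
  raw$birth_date <- as.Date(raw$birth_date)
  raw
}

#' Write a breeding-pairs file
#' @param pairs Data frame `offspring`, `mother`, `sire`, `birth_date`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  out <- data.frame(offspring = pairs$offspring, mother = pairs$mother,
                    sire = pairs$sire,
                    birth_date = format(as.Date(pairs$birth_date), "%Y-%m-%d"),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}
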