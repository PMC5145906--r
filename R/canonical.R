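#' Minimal pedigree realizing a canonical consanguineous mating
#'
#' Builds the smallest pedigree in which the parents of focal individual
#' `"X"` are connected by exactly one kin link of the requested type, all
#' other ancestors being unrelated founders. Useful for reconstructing the
#' case configurations reported in colony pedigree studies, where avuncular
#' and cousin matings are linked through a *single* common ancestor (a
#' half-sibling link), giving `F = 0.0625` and `F = 0.03125` respectively.
#'
#' @param relationship One of `"daughter-sire"`, `"paternal-half-sibs"`,
#'   `"maternal-half-sibs"`, `"full-sibs"`, `"uncle-niece"`, `"aunt-nephew"`,
#'   `"first-cousins"`.
#' @param kin_line For `"uncle-niece"`, `"aunt-nephew"` and
#'   `"first-cousins"`: which parental lines carry the link (`"paternal"`,
#'   `"maternal"` or `"maternal-and-paternal"`). Ignored for the other
#'   relationships, whose line is intrinsic.
#' @param prefix Prepended to every id so that several configurations can be
#'   merged into one table without clashes.
#' @return A `pedigree_table` whose focal inbred individual is
#'   `paste0(prefix, "X")`.
#' @examples
#' ped <- canonical_mating("paternal-half-sibs")
#' inbreeding_coefficient(ped, "X")   # 0.125
#' ped <- canonical_mating("first-cousins", "maternal-and-paternal")
#' inbreeding_coefficient(ped, "X", depth_limit = 3)  # 0.03125
#' @export
canonical_mating <- function(relationship = c("daughter-sire",
                                              "paternal-half-sibs",
                                              "maternal-half-sibs",
                                              "full-sibs",
                                              "uncle-niece",
                                              "aunt-nephew",
                                              "first-cousins"),
                             kin_line = c("paternal", "maternal",
                                          "maternal-and-paternal"),
                             prefix = "") {
  relationship <- match.arg(relationship)
  kin_line <- match.arg(kin_line)
  row <- function(id, sire, dam, sex) {
    data.frame(id = id, sire = sire, dam = dam, sex = sex,
               stringsAsFactors = FALSE)
  }
  fnd <- function(id, sex) row(id, NA, NA, sex)
  recs <- switch(
    relationship,
    "daughter-sire" = rbind(
      fnd("S", "M"), fnd("W", "F"),
      row("D", "S", "W", "F"),
      row("X", "S", "D", "U")
    ),
    "paternal-half-sibs" = rbind(
      fnd("A", "M"), fnd("M1", "F"), fnd("M2", "F"),
      row("S", "A", "M1", "M"), row("D", "A", "M2", "F"),
      row("X", "S", "D", "U")
    ),
    "maternal-half-sibs" = rbind(
      fnd("A", "F"), fnd("F1", "M"), fnd("F2", "M"),
      row("S", "F1", "A", "M"), row("D", "F2", "A", "F"),
      row("X", "S", "D", "U")
    ),
    "full-sibs" = rbind(
      fnd("P", "M"), fnd("Q", "F"),
      row("S", "P", "Q", "M"), row("D", "P", "Q", "F"),
      row("X", "S", "D", "U")
    ),
    "uncle-niece" = {
      # S (male) and D's linking parent are half-sibs through ancestor A;
      # kin_line picks which parent of each breeder leads toward A.
      # A is shared parent of S and of D's parent P. Whether the first steps
      # are paternal is controlled by making A (and P) the sire or the dam.
      if (kin_line == "paternal") {
        # S -> sire A; D -> sire P -> (P's sire = A)
        rbind(fnd("A", "M"), fnd("M1", "F"), fnd("M2", "F"), fnd("M3", "F"),
              row("S", "A", "M1", "M"), row("P", "A", "M2", "M"),
              row("D", "P", "M3", "F"), row("X", "S", "D", "U"))
      } else if (kin_line == "maternal") {
        # S -> dam A; D -> dam P -> (P's dam = A)
        rbind(fnd("A", "F"), fnd("F1", "M"), fnd("F2", "M"), fnd("F3", "M"),
              row("S", "F1", "A", "M"), row("P", "F2", "A", "F"),
              row("D", "F3", "P", "F"), row("X", "S", "D", "U"))
      } else {
        # S -> dam A (maternal step); D -> sire P (paternal step)
        rbind(fnd("A", "F"), fnd("F1", "M"), fnd("F2", "M"), fnd("M3", "F"),
              row("S", "F1", "A", "M"), row("P", "F2", "A", "M"),
              row("D", "P", "M3", "F"), row("X", "S", "D", "U"))
      }
    },
    "aunt-nephew" = {
      if (kin_line == "paternal") {
        # D -> sire A; S -> sire P -> (P's sire = A)
        rbind(fnd("A", "M"), fnd("M1", "F"), fnd("M2", "F"), fnd("M3", "F"),
              row("D", "A", "M1", "F"), row("P", "A", "M2", "M"),
              row("S", "P", "M3", "M"), row("X", "S", "D", "U"))
      } else if (kin_line == "maternal") {
        rbind(fnd("A", "F"), fnd("F1", "M"), fnd("F2", "M"), fnd("F3", "M"),
              row("D", "F1", "A", "F"), row("P", "F2", "A", "F"),
              row("S", "F3", "P", "M"), row("X", "S", "D", "U"))
      } else {
        # D's step maternal, S's step paternal
        rbind(fnd("A", "F"), fnd("F1", "M"), fnd("F2", "M"), fnd("M3", "F"),
              row("D", "F1", "A", "F"), row("P", "F2", "A", "M"),
              row("S", "P", "M3", "M"), row("X", "S", "D", "U"))
      }
    },
    "first-cousins" = {
      # breeders' linking parents are half-sibs via single common ancestor A
      if (kin_line == "paternal") {
        rbind(fnd("A", "M"), fnd("M1", "F"), fnd("M2", "F"),
              fnd("M3", "F"), fnd("M4", "F"),
              row("P1", "A", "M1", "M"), row("P2", "A", "M2", "M"),
              row("S", "P1", "M3", "M"), row("D", "P2", "M4", "F"),
              row("X", "S", "D", "U"))
      } else if (kin_line == "maternal") {
        rbind(fnd("A", "F"), fnd("F1", "M"), fnd("F2", "M"),
              fnd("F3", "M"), fnd("F4", "M"),
              row("U1", "F1", "A", "F"), row("U2", "F2", "A", "F"),
              row("S", "F3", "U1", "M"), row("D", "F4", "U2", "F"),
              row("X", "S", "D", "U"))
      } else {
        # S reaches A via his sire, D via her dam
        rbind(fnd("A", "M"), fnd("M1", "F"), fnd("M2", "F"),
              fnd("M3", "F"), fnd("F4", "M"),
              row("P1", "A", "M1", "M"), row("U2", "A", "M2", "F"),
              row("S", "P1", "M3", "M"), row("D", "F4", "U2", "F"),
              row("X", "S", "D", "U"))
      }
    }
  )
  if (nzchar(prefix)) {
    recs$id <- paste0(prefix, recs$id)
    recs$sire <- ifelse(is.na(recs$sire), NA, paste0(prefix, recs$sire))
    recs$dam <- ifelse(is.na(recs$dam), NA, paste0(prefix, recs$dam))
  }
  build_pedigree(recs)
}
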