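#' Normalize a personal name for linkage
#'
#' Uppercases and strips every non-alphabetic character (spaces, hyphens,
#' apostrophes, diacritic fallout). Both registries must be normalized with
#' the same rule before characters are indexed or names compared: duplicate
#' linkage keys in the field arise mostly from alternate spellings and
#' hyphenation, and identical normalization on both sides removes that
#' failure mode for punctuation variants.
#'
#' @param x Character vector of names; `NA` is treated as an empty name.
#' @return Character vector of uppercase letters only (possibly `""`).
#' @examples
#' normalize_name(c("O'Brien", "smith-jones", "de la Cruz"))
#' @export
normalize_name <- function(x) {
  x[is.na(x)] <- ""
  gsub("[^A-Z]", "", toupper(x))
}

# Extract character `pos` from each normalized name, padding short names
# with the digit "2" (the national convention for a position that does not
# exist in the name).
slk_char <- function(nm, pos) {
  ifelse(nchar(nm) >= pos, substr(nm, pos, pos), "2")
}

#' Build the SLK-581 statistical linkage key
#'
#' Constructs the 14-character AIHW statistical linkage key: positions 1-3
#' are the 2nd, 3rd and 5th letters of the family name, positions 4-5 the
#' 2nd and 3rd letters of the given name, positions 6-13 the date of birth
#' as DDMMYYYY, and position 14 the sex code (1 male, 2 female, 9
#' other/unknown). Names are normalized with [normalize_name()] before
#' indexing; a name position beyond the normalized length is padded with the
#' digit `2`; a wholly missing family name contributes `999` and a wholly
#' missing given name `99`.
#'
#' @param surname,forename Character vectors (may be empty or `NA`).
#' @param dob `Date` vector of dates of birth. A missing `dob` makes the key
#'   unbuildable: the result is `NA` for that element.
#' @param sex Character vector coded `"M"`, `"F"`, or anything else for
#'   other/unknown.
#' @return Character vector of 14-character keys (`NA` where `dob` missing).
#' @examples
#' build_slk("CITIZEN", "JOHN", as.Date("1990-01-01"), "M")  # "ITZOH010119901"
#' build_slk("NG", "JO", as.Date("1985-12-31"), "F")         # "G22O2311219852"
#' @export
build_slk <- function(surname, forename, dob, sex) {
  n <- max(length(surname), length(forename), length(dob), length(sex))
  surname  <- rep_len(normalize_name(surname), n)
  forename <- rep_len(normalize_name(forename), n)
  dob      <- rep_len(as.Date(dob), n)
  sex      <- rep_len(as.character(sex), n)

  fam <- paste0(slk_char(surname, 2), slk_char(surname, 3), slk_char(surname, 5))
  fam[nchar(surname) == 0] <- "999"
  giv <- paste0(slk_char(forename, 2), slk_char(forename, 3))
  giv[nchar(forename) == 0] <- "99"

  sex_code <- ifelse(sex %in% "M", "1", ifelse(sex %in% "F", "2", "9"))
  key <- paste0(fam, giv, format(dob, "%d%m%Y"), sex_code)
  key[is.na(dob)] <- NA_character_
  key
}

#' Compare two SLK-581 keys
#'
#' Exact whole-key comparison, the comparison mode used by every shipped
#' strategy. Returns `"missing"` when either side is empty or `NA`,
#' `"agree"` when the two 14-character strings are identical, `"disagree"`
#' otherwise. A relaxed per-character mode (agreement when at least
#' `14 - max_mismatch` characters coincide) is available but off by default
#' and not used by any headline strategy.
#'
#' @param a,b Character vectors of keys (may be `""` or `NA`).
#' @param max_mismatch Integer; number of character mismatches tolerated.
#'   The default `0` is exact comparison.
#' @return Character vector in `c("agree", "disagree", "missing")`.
#' @export
slk_agree <- function(a, b, max_mismatch = 0L) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  miss <- is.na(a) | is.na(b) | a == "" | b == ""
  if (max_mismatch == 0L) {
    agree <- !miss & a == b
  } else {
    agree <- !miss & mapply(function(x, y) {
      sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]) <= max_mismatch
    }, a, b)
  }
  out <- ifelse(miss, "missing", ifelse(agree, "agree", "disagree"))
  unname(out)
}

#' Append an SLK-581 column to a registry
#'
#' Computes the linkage key from the registry's own identity fields
#' (surname, forename, dob, sex), mirroring how a key is added to a fully
#' identified registry before deidentified sharing.
#'
#' @param registry A registry data frame from [read_registry()] or
#'   [generate_registries()].
#' @param overwrite Replace an existing non-empty `slk` column? Default
#'   `FALSE` keeps keys already present.
#' @return The registry with an `slk` character column.
#' @export
add_slk <- function(registry, overwrite = FALSE) {
  key <- build_slk(registry$surname, registry$forename,
                   registry$dob, registry$sex)
  key[is.na(key)] <- ""
  if (!is.null(registry$slk) && !overwrite) {
    blank <- is.na(registry$slk) | registry$slk == ""
    registry$slk[blank] <- key[blank]
  } else {
    registry$slk <- key
  }
  registry
}
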