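# Periodic-table lookups used by the ligand-graph featurization.
# Elements are identified by atomic number; symbols cover Z = 1..118.

.ELEMENT_SYMBOLS <- c(
  "H", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE",
  "NA", "MG", "AL", "SI", "P", "S", "CL", "AR", "K", "CA",
  "SC", "TI", "V", "CR", "MN", "FE", "CO", "NI", "CU", "ZN",
  "GA", "GE", "AS", "SE", "BR", "KR", "RB", "SR", "Y", "ZR",
  "NB", "MO", "TC", "RU", "RH", "PD", "AG", "CD", "IN", "SN",
  "SB", "TE", "I", "XE", "CS", "BA", "LA", "CE", "PR", "ND",
  "PM", "SM", "EU", "GD", "TB", "DY", "HO", "ER", "TM", "YB",
  "LU", "HF", "TA", "W", "RE", "OS", "IR", "PT", "AU", "HG",
  "TL", "PB", "BI", "PO", "AT", "RN", "FR", "RA", "AC", "TH",
  "PA", "U", "NP", "PU", "AM", "CM", "BK", "CF", "ES", "FM",
  "MD", "NO", "LR", "RF", "DB", "SG", "BH", "HS", "MT", "DS",
  "RG", "CN", "NH", "FL", "MC", "LV", "TS", "OG")

#' Element symbol to atomic number
#' @param sym character vector of element symbols (case-insensitive).
#' @return integer atomic numbers; NA for unknown symbols.
#' @export
element_number <- function(sym) {
  match(toupper(trimws(sym)), .ELEMENT_SYMBOLS)
}

#' Atomic number to element symbol
#' @param z integer atomic numbers in `[1, 118]`.
#' @return character symbols (title case, e.g. "Zn").
#' @export
element_symbol <- function(z) {
  s <- .ELEMENT_SYMBOLS[z]
  paste0(substr(s, 1, 1), tolower(substr(s, 2, 2)))
}

# period boundaries: H..He, ..Ne, ..Ar, ..Kr, ..Xe, ..Rn, ..Og
.PERIOD_END <- c(2L, 10L, 18L, 36L, 54L, 86L, 118L)

#' Chemical group and period of an element
#'
#' Group follows IUPAC numbering 1-18; f-block elements (lanthanides and
#' actinides) are assigned the extra category 0, giving 19 group categories
#' in total. Period is 1-7 (stored 1-8 in one-hot width for head-room).
#'
#' @param z integer atomic numbers.
#' @return list with integer vectors `group` (0-18) and `period` (1-7).
#' @export
element_group_period <- function(z) {
  z <- as.integer(z)
  stopifnot(all(z >= 1L & z <= 118L))
  period <- findInterval(z - 1L, c(0L, .PERIOD_END)) # 1..7
  start <- c(1L, 3L, 11L, 19L, 37L, 55L, 87L)[period]
  idx <- z - start + 1L
  group <- integer(length(z))
  for (i in seq_along(z)) {
    p <- period[i]; k <- idx[i]
    group[i] <- if (p == 1L) {
      if (k == 1L) 1L else 18L
    } else if (p <= 3L) {
      if (k <= 2L) k else k + 10L
    } else if (p <= 5L) {
      k
    } else {
      # periods 6/7: 32 elements; slots 3..17 are the f-block
      if (k <= 2L) k else if (k <= 17L) 0L else k - 14L
    }
  }
  list(group = group, period = period)
}

# element classes considered metals when categorizing lone heteroatoms
.METAL_Z <- local({
  alkali <- c(3L, 11L, 19L, 37L, 55L, 87L)
  alkaline <- c(4L, 12L, 20L, 38L, 56L, 88L)
  transition <- c(21:30, 39:48, 72:80, 104:112)
  post <- c(13L, 31L, 49L, 50L, 81L, 82L, 83L)
  fblock <- c(57:71, 89:103)
  sort(c(alkali, alkaline, transition, post, fblock))
})

#' Is an atomic number a metal?
#' @param z integer atomic numbers.
#' @return logical vector.
#' @export
is_metal_element <- function(z) {
  as.integer(z) %in% .METAL_Z
}
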