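#' The 21-token design alphabet
#'
#' Twenty standard amino acids in alphabetical one-letter order plus a single
#' unknown token `X`. Token indices are 1-based throughout the package;
#' the unknown token is index 21.
#'
#' @return A data.frame with columns `token` (integer), `one` (one-letter
#'   code), `three` (three-letter code).
#' @export
design_alphabet <- function() {
  one <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
  three <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE", "LYS",
             "LEU", "MET", "ASN", "PRO", "GLN", "ARG", "SER", "THR", "VAL",
             "TRP", "TYR", "UNK")
  data.frame(token = seq_along(one), one = one, three = three,
             stringsAsFactors = FALSE)
}

.ALPHABET <- local({
  one <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
  three <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE", "LYS",
             "LEU", "MET", "ASN", "PRO", "GLN", "ARG", "SER", "THR", "VAL",
             "TRP", "TYR", "UNK")
  list(one = one, three = three, n = 21L, unknown = 21L)
})

#' Convert between tokens and residue codes
#'
#' @param x integer token vector, or character vector of one- or three-letter
#'   codes depending on the function.
#' @return `tokens_to_one`/`tokens_to_three` return character vectors;
#'   `three_to_tokens`/`one_to_tokens` return integer tokens (unknown codes
#'   map to the unknown token, 21).
#' @export
tokens_to_one <- function(x) {
  stopifnot(all(x >= 1L & x <= 21L))
  .ALPHABET$one[x]
}

#' @rdname tokens_to_one
#' @export
tokens_to_three <- function(x) {
  stopifnot(all(x >= 1L & x <= 21L))
  .ALPHABET$three[x]
}

#' @rdname tokens_to_one
#' @export
three_to_tokens <- function(x) {
  i <- match(toupper(x), .ALPHABET$three)
  i[is.na(i)] <- .ALPHABET$unknown
  i
}

#' @rdname tokens_to_one
#' @export
one_to_tokens <- function(x) {
  i <- match(toupper(x), .ALPHABET$one)
  i[is.na(i)] <- .ALPHABET$unknown
  i
}

# chi-angle count per token (ALA/GLY 0 ... LYS/ARG 4); unknown treated as 0
.CHI_COUNT <- c(A = 0L, C = 1L, D = 2L, E = 3L, F = 2L, G = 0L, H = 2L,
                I = 2L, K = 4L, L = 2L, M = 3L, N = 2L, P = 2L, Q = 3L,
                R = 4L, S = 1L, T = 1L, V = 1L, W = 2L, Y = 2L, X = 0L)

#' Number of chi angles per residue token
#' @param tokens integer tokens in `[1, 21]`.
#' @return integer vector of chi counts (0-4).
#' @export
chi_count <- function(tokens) {
  unname(.CHI_COUNT[tokens_to_one(tokens)])
}

# chis whose terminal group is 180-degree symmetric (physically
# indistinguishable atom swap): ASP chi2, GLU chi3, PHE chi2, TYR chi2
.SYMMETRIC_CHI <- c(D = 2L, E = 3L, F = 2L, Y = 2L)

#' Index of the 180-degree-symmetric chi for a token (NA if none)
#' @param tokens integer tokens.
#' @return integer vector; NA where the residue has no symmetric terminal chi.
#' @export
symmetric_chi <- function(tokens) {
  out <- .SYMMETRIC_CHI[tokens_to_one(tokens)]
  unname(out)
}
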