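# 26-way token alphabet: 21 protein tokens (20 canonical amino acids + unknown)
# followed by 5 shared nucleic tokens. DNA and RNA letters collapse onto the
# same nucleic tokens (DA/A, DC/C, DG/G, DT/U and the unknown DX/RX).

.PROTEIN_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.NA_LETTERS <- c("A", "C", "G", "T")

#' Token alphabet for the unified biopolymer model
#'
#' Returns the model's 26-token alphabet as a data frame: 20 canonical amino
#' acids plus a protein unknown token, and 5 shared nucleic acid tokens (the
#' four canonical bases, deoxyribo and ribo forms collapsed, plus a nucleic
#' unknown). The polymer classes partition the alphabet.
#'
#' @return A data frame with columns `id` (integer token id), `name` (display
#'   name), `letter` (one-letter code; `T` doubles as `U` for RNA), `class`
#'   (`"protein"` or `"nucleic"`), and `canonical` (logical).
#' @export
#' @examples
#' alph <- token_alphabet()
#' table(alph$class)
token_alphabet <- function() {
  data.frame(
    id = 1:26,
    name = c(.PROTEIN_LETTERS, "X",
             "DA/A", "DC/C", "DG/G", "DT/U", "DX/RX"),
    letter = c(.PROTEIN_LETTERS, "X", .NA_LETTERS, "N"),
    class = c(rep("protein", 21), rep("nucleic", 5)),
    canonical = c(rep(TRUE, 20), FALSE, rep(TRUE, 4), FALSE),
    stringsAsFactors = FALSE
  )
}

# Fixed ids used throughout; kept as plain constants for speed.
.TOK_PROTEIN_UNK <- 21L
.TOK_NA_A <- 22L
.TOK_NA_C <- 23L
.TOK_NA_G <- 24L
.TOK_NA_T <- 25L
.TOK_NA_UNK <- 26L
.TOK_NA_CANONICAL <- 22:25
.TOK_PROTEIN_CANONICAL <- 1:20

#' Polymer class of a token id
#' @param token integer token id(s) in 1..26.
#' @return Character vector, `"protein"` or `"nucleic"`.
#' @export
token_class <- function(token) {
  stopifnot(all(token >= 1L & token <= 26L))
  ifelse(token <= 21L, "protein", "nucleic")
}

#' Is a token canonical (a real amino acid or base, not an unknown)?
#' @inheritParams token_class
#' @return Logical vector.
#' @export
token_is_canonical <- function(token) {
  token %in% c(.TOK_PROTEIN_CANONICAL, .TOK_NA_CANONICAL)
}

# residue-name -> token maps -------------------------------------------------

.AA3 <- c(ALA = 1L, CYS = 2L, ASP = 3L, GLU = 4L, PHE = 5L, GLY = 6L,
          HIS = 7L, ILE = 8L, LYS = 9L, LEU = 10L, MET = 11L, ASN = 12L,
          PRO = 13L, GLN = 14L, ARG = 15L, SER = 16L, THR = 17L, VAL = 18L,
          TRP = 19L, TYR = 20L)
.DNA_RES <- c(DA = .TOK_NA_A, DC = .TOK_NA_C, DG = .TOK_NA_G, DT = .TOK_NA_T)
.RNA_RES <- c(A = .TOK_NA_A, C = .TOK_NA_C, G = .TOK_NA_G, U = .TOK_NA_T)

#' Map one-letter base codes to nucleic token ids
#'
#' `U` is read as the shared `DT/U` token; letters outside `A/C/G/T/U` map to
#' the unknown nucleic token.
#'
#' @param letters character vector of single letters.
#' @return Integer token ids (22..26).
#' @export
base_to_token <- function(letters) {
  up <- toupper(letters)
  up[up == "U"] <- "T"
  idx <- match(up, .NA_LETTERS)
  out <- ifelse(is.na(idx), .TOK_NA_UNK, .TOK_NA_A + ifelse(is.na(idx), 0L, idx - 1L))
  as.integer(out)
}

#' Spell nucleic tokens as sequence letters
#' @param token integer nucleic token ids.
#' @param class `"DNA"` (T spelling) or `"RNA"` (U spelling).
#' @return Character vector of letters; unknown tokens become `N`.
#' @export
token_to_base <- function(token, class = c("DNA", "RNA")) {
  class <- match.arg(class)
  stopifnot(all(token >= .TOK_NA_A & token <= .TOK_NA_UNK))
  letters <- c("A", "C", "G", if (class == "DNA") "T" else "U", "N")
  letters[token - .TOK_NA_A + 1L]
}
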