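# Amino-acid alphabet, background model and digitization.

# Standard 20-letter amino acid ordering used throughout (HMMER column order)
AA_SYMBOLS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Null-model (background) residue frequencies: the standard
# Robinson-Robinson frequencies used as the "null1" model in profile-HMM
# search, in the column order above.
AA_BACKGROUND <- c(
  0.0681407, 0.0120072, 0.0623376, 0.0651391, 0.0313187,
  0.0902538, 0.0241145, 0.0371222, 0.0687410, 0.0676404,
  0.0143085, 0.0548326, 0.0647391, 0.0415250, 0.0551328,
  0.0926552, 0.0623376, 0.0505304, 0.0102061, 0.0269161)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

# Ambiguity/unusual codes mapped to a wildcard residue scored by background
AA_AMBIGUOUS <- c("X", "B", "Z", "J", "U", "O", "*")

#' Amino-acid alphabet
#'
#' The residue alphabet used by all models in the package: the 20 standard
#' amino acids (in the conventional profile-HMM column order) plus a
#' designated wildcard residue to which all ambiguity codes are mapped.  The
#' wildcard is always scored with the background distribution, so it neither
#' rewards nor penalizes any model position.
#'
#' @param symbols Character vector of residue symbols.
#' @param background Background (null-model) probability per symbol; must sum
#'   to one.
#' @return An object of class `cfb_alphabet` with elements `symbols`, `k`
#'   (alphabet size), `background`, and `wildcard` (the digitized code used
#'   for ambiguous residues, equal to `k + 1`).
#' @examples
#' a <- amino_alphabet()
#' a$k
#' sum(a$background)
#' @export
amino_alphabet <- function(symbols = AA_SYMBOLS, background = AA_BACKGROUND) {
  stopifnot(length(symbols) == length(background), length(symbols) >= 2)
  if (abs(sum(background) - 1) > 1e-9)
    stop("alphabet background must sum to 1")
  structure(
    list(symbols = symbols, k = length(symbols),
         background = as.numeric(background),
         wildcard = length(symbols) + 1L),
    class = "cfb_alphabet")
}

# cached default alphabet
.default_alphabet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- amino_alphabet()
    cache
  }
})

#' Digitize a residue string
#'
#' Converts a protein string to 1-based residue indices over the alphabet.
#' Lowercase letters are folded to uppercase; ambiguity codes (X, B, Z, J,
#' U, O) become the wildcard code `k + 1`.
#'
#' @param x Character scalar (residue string).
#' @param alphabet An [amino_alphabet()].
#' @return Integer vector of codes in `1..(k+1)`.
#' @export
digitize <- function(x, alphabet = amino_alphabet()) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  idx <- match(ch, alphabet$symbols)
  amb <- is.na(idx) & ch %in% AA_AMBIGUOUS
  idx[amb] <- alphabet$wildcard
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("illegal residue '%s' at position %d", ch[bad], bad))
  }
  idx
}

#' Convert digitized residues back to a string
#'
#' @param idx Integer codes as produced by [digitize()].
#' @param alphabet An [amino_alphabet()].
#' @return Character scalar; wildcard codes render as `"X"`.
#' @export
undigitize <- function(idx, alphabet = amino_alphabet()) {
  s <- c(alphabet$symbols, "X")[idx]
  paste(s, collapse = "")
}
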