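#' The 20 standard amino acids, HMMER column order
#'
#' One-letter codes in the column order used by HMMER3 amino profiles
#' (alphabetical by letter: A C D E F G H I K L M N P Q R S T V W Y).
#' All emission vectors, background compositions and substitution parsing
#' in this package are restricted to this alphabet; ambiguity codes
#' (B, Z, X) and non-standard residues (U, O) are rejected, never
#' redistributed.
#'
#' @return Character vector of length 20.
#' @examples
#' aminoAcids()
#' @export
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

## internal: validate a probability composition over the 20-letter alphabet
.checkComposition <- function(p, what = "composition", tol = 1e-6) {
  msgs <- character()
  if (!is.numeric(p) || length(p) != 20L)
    return(sprintf("%s must be a numeric vector of length 20", what))
  if (is.null(names(p)) || !identical(sort(names(p)), sort(aminoAcids())))
    msgs <- c(msgs, sprintf("%s must be named by the 20 standard amino acids", what))
  if (any(!is.finite(p)) || any(p <= 0))
    msgs <- c(msgs, sprintf("all %s entries must be finite and strictly > 0", what))
  if (is.finite(sum(p)) && abs(sum(p) - 1) > tol)
    msgs <- c(msgs, sprintf("%s must sum to 1 within %g (got %.8f)", what, tol, sum(p)))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
}

.assertAA <- function(x, what = "residue") {
  bad <- !(x %in% aminoAcids())
  if (any(bad))
    stop(sprintf("%s not in the 20-letter amino acid alphabet: %s",
                 what, paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  invisible(x)
}
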