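#' Parse an amino acid substitution string
#'
#' Parses the conventional `<wild-type><position><mutant>` notation, e.g.
#' `"R175H"`. Only the 20 standard one-letter codes are accepted;
#' synonymous "substitutions" (identical alleles) are rejected because the
#' score of a non-change is undefined.
#'
#' @param text substitution string(s).
#' @return A data.frame with columns `wild_type` (character), `position`
#'   (integer) and `mutant` (character), one row per input.
#' @examples
#' parseSubstitution("R175H")
#' @export
parseSubstitution <- function(text) {
  m <- regmatches(text, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", text))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop(sprintf("malformed substitution notation: %s",
                 paste(unique(text[bad]), collapse = ", ")), call. = FALSE)
  wt <- toupper(vapply(m, `[[`, character(1), 2L))
  pos <- as.integer(vapply(m, `[[`, character(1), 3L))
  mut <- toupper(vapply(m, `[[`, character(1), 4L))
  .assertAA(c(wt, mut), "substitution residue")
  if (any(pos < 1L))
    stop("substitution positions are 1-based and must be >= 1", call. = FALSE)
  syn <- wt == mut
  if (any(syn))
    stop(sprintf("synonymous substitution(s) have no effect to score: %s",
                 paste(unique(text[syn]), collapse = ", ")), call. = FALSE)
  data.frame(wild_type = wt, position = pos, mutant = mut,
             stringsAsFactors = FALSE)
}

#' Build a validated variant table
#'
#' Normalizes a labelled variant catalogue to the columns `protein_id`,
#' `wild_type`, `position`, `mutant`, `label`. Duplicate records (same
#' protein, position, alleles and label) are collapsed to one — catalogues
#' list distinct substitutions, and duplicates would silently double-weight
#' a model. A substitution present with both a CANCER and a NEUTRAL label
#' is a validation error, never arbitrated.
#'
#' @param x data.frame with either the four allele columns or a
#'   `substitution` column in `"R175H"` notation, plus `protein_id` and
#'   `label`.
#' @return A deduplicated data.frame of variant records.
#' @export
variantRecords <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(x) || !"label" %in% names(x))
    stop("variant table needs 'protein_id' and 'label' columns", call. = FALSE)
  if ("substitution" %in% names(x)) {
    sub <- parseSubstitution(x$substitution)
    x <- cbind(x[, c("protein_id", "label"), drop = FALSE], sub)
  }
  need <- c("protein_id", "wild_type", "position", "mutant", "label")
  if (!all(need %in% names(x)))
    stop(sprintf("variant table missing columns: %s",
                 paste(setdiff(need, names(x)), collapse = ", ")), call. = FALSE)
  x <- x[, need]
  x$label <- toupper(x$label)
  if (!all(x$label %in% c("CANCER", "NEUTRAL")))
    stop("labels must be CANCER or NEUTRAL", call. = FALSE)
  .assertAA(c(x$wild_type, x$mutant), "variant residue")
  if (any(x$wild_type == x$mutant))
    stop("wild-type and mutant residues must differ", call. = FALSE)
  if (any(x$position < 1L))
    stop("positions are 1-based and must be >= 1", call. = FALSE)
  key <- paste(x$protein_id, x$position, x$wild_type, x$mutant, sep = "|")
  conflict <- tapply(x$label, key, function(l) length(unique(l)) > 1L)
  if (any(conflict))
    stop(sprintf("conflicting labels for: %s",
                 paste(utils::head(names(conflict)[conflict], 5), collapse = ", ")),
         call. = FALSE)
  x <- x[!duplicated(key), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Read / write labelled variant TSV files
#'
#' The on-disk format is three columns — `protein_id`, `substitution`
#' (e.g. `R175H`), `label` (`CANCER` or `NEUTRAL`) — with `#` comment
#' lines ignored. Reading validates and deduplicates via
#' [variantRecords()].
#'
#' @param path file path.
#' @return [readVariants()]: a validated variant data.frame;
#'   [writeVariants()]: `path`, invisibly.
#' @export
readVariants <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  variantRecords(tb)
}

#' @rdname readVariants
#' @param variants a variant data.frame as returned by [variantRecords()].
#' @export
writeVariants <- function(variants, path) {
  out <- data.frame(
    protein_id = variants$protein_id,
    substitution = paste0(variants$wild_type, variants$position, variants$mutant),
    label = variants$label, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
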