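#' @include AllClasses.R
NULL

#' Construct a ProfileHMM from an emission matrix
#'
#' @param model_id single model identifier.
#' @param emissions numeric matrix with one row per match state and 20
#'   columns; columns are taken in [aminoAcids()] order and named if
#'   unnamed. Rows must be strictly positive compositions.
#' @param background named numeric null composition; defaults to
#'   [defaultBackground()].
#' @param source provenance tag, one of `"SUPERFAMILY"`, `"PFAM_A"`,
#'   `"PFAM_B"`, `"AB_INITIO"`.
#' @return A [ProfileHMM-class] object.
#' @examples
#' em <- matrix(0.05, nrow = 3, ncol = 20)
#' profileHMM("uniform", em)
#' @export
profileHMM <- function(model_id, emissions,
                       background = defaultBackground(),
                       source = "AB_INITIO") {
  emissions <- as.matrix(emissions)
  if (is.null(colnames(emissions)) && ncol(emissions) == 20L)
    colnames(emissions) <- aminoAcids()
  else if (!is.null(colnames(emissions)))
    emissions <- emissions[, aminoAcids(), drop = FALSE]
  rownames(emissions) <- NULL
  if (is(background, "BackgroundComposition"))
    background <- background@probabilities
  new("ProfileHMM", model_id = model_id, source = source,
      emissions = emissions, background = background[aminoAcids()])
}

#' Construct or load a background composition
#'
#' `backgroundComposition()` validates a named probability vector over the
#' 20 standard amino acids. `defaultBackground()` returns the composition
#' shipped with the package (SwissProt-like proteome frequencies), read
#' from `inst/extdata/background_composition.tsv`; supply your own table to
#' override it.
#'
#' @param probabilities named numeric vector of length 20 summing to 1.
#' @return A named numeric vector (class-validated composition).
#' @examples
#' bg <- defaultBackground()
#' sum(bg)
#' @export
backgroundComposition <- function(probabilities) {
  obj <- new("BackgroundComposition", probabilities = probabilities[aminoAcids()])
  obj@probabilities
}

#' @rdname backgroundComposition
#' @param path optional path to a two-column TSV (residue, frequency);
#'   frequencies are renormalized to sum to 1.
#' @export
defaultBackground <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "background_composition.tsv",
                        package = "driverHMM", mustWork = TRUE)
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  p <- stats::setNames(tb[[2]], tb[[1]])
  .assertAA(names(p), "background residue")
  backgroundComposition(p[aminoAcids()] / sum(p))
}

## ---- HMMER3 ASCII I/O -------------------------------------------------

## Scores in the file are -ln(probability); "*" is the format's marker for
## probability zero (which this package's validity rules reject for match
## emissions, but the token must still parse).
.scoreToProb <- function(tok, where) {
  p <- suppressWarnings(as.numeric(tok))
  star <- tok == "*"
  p[star] <- Inf
  if (any(is.na(p) | (!star & !is.finite(p))))
    stop(sprintf("unparseable score token in %s: %s", where,
                 paste(unique(tok[is.na(p) | (!star & !is.finite(p))]), collapse = ", ")),
         call. = FALSE)
  exp(-p)
}

#' Read a profile HMM from a HMMER3 ASCII file
#'
#' Parses the header (`NAME`, `LENG`, `ALPH amino`), the optional `COMPO`
#' null-composition line and the per-match-state emission lines of a
#' HMMER3 ASCII profile, converting the format's negative-natural-log
#' scores back to probabilities. Insert-emission and transition lines are
#' skipped. When no `COMPO` line is present the supplied default
#' background is attached instead.
#'
#' @param path path to a `.hmm` file whose first line declares `HMMER3`.
#' @param background fallback null composition when the file has no
#'   `COMPO` line.
#' @param source provenance tag recorded on the object.
#' @return A [ProfileHMM-class] object.
#' @examples
#' hmm <- profileHMM("toy", matrix(0.05, 2, 20))
#' f <- tempfile(fileext = ".hmm")
#' writeHMMER3Profile(hmm, f)
#' readHMMER3Profile(f)
#' @seealso [writeHMMER3Profile()], [readHMMLibrary()]
#' @export
readHMMER3Profile <- function(path, background = defaultBackground(),
                              source = "AB_INITIO") {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[[1]], "HMMER3"))
    stop(sprintf("'%s' is not a HMMER3 ASCII profile (bad header)", path),
         call. = FALSE)
  name <- NA_character_; leng <- NA_integer_; alphabet <- NULL
  compo <- NULL
  i <- 2L
  while (i <= length(lines)) {
    toks <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    if (!length(toks)) { i <- i + 1L; next }
    key <- toks[[1]]
    if (key == "NAME") name <- toks[[2]]
    else if (key == "LENG") leng <- as.integer(toks[[2]])
    else if (key == "ALPH") {
      if (tolower(toks[[2]]) != "amino")
        stop("only amino acid profiles are supported", call. = FALSE)
    } else if (key == "HMM") {
      alphabet <- toks[-1]
      i <- i + 1L  # skip the transition header line that follows
      break
    }
    i <- i + 1L
  }
  if (is.na(name) || is.na(leng) || is.null(alphabet))
    stop(sprintf("malformed HMMER3 header in '%s' (need NAME, LENG, HMM lines)", path),
         call. = FALSE)
  .assertAA(alphabet, "HMM alphabet column")
  if (length(alphabet) != 20L)
    stop("HMM alphabet line must list the 20 standard amino acids", call. = FALSE)
  em <- matrix(NA_real_, nrow = leng, ncol = 20L,
               dimnames = list(NULL, alphabet))
  state <- 0L
  i <- i + 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[[i]])
    i <- i + 1L
    if (ln == "//") break
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    if (!length(toks)) next
    if (toks[[1]] == "COMPO") {
      compo <- .scoreToProb(toks[2:21], "COMPO line")
      names(compo) <- alphabet
      next
    }
    idx <- suppressWarnings(as.integer(toks[[1]]))
    # match emission lines carry the 1-based state index then >= 20 scores;
    # insert-emission (20 tokens) and transition (7 tokens) lines do not
    if (!is.na(idx) && idx == state + 1L && length(toks) >= 21L) {
      em[idx, ] <- .scoreToProb(toks[2:21], sprintf("match state %d", idx))
      state <- idx
    }
  }
  if (state != leng)
    stop(sprintf("expected %d match states in '%s', found %d", leng, path, state),
         call. = FALSE)
  # scores printed at 5 decimals leave row sums off 1 by up to ~2e-5;
  # renormalize that round-off, but treat larger deviations as real errors
  rs <- rowSums(em)
  if (any(abs(rs - 1) > 1e-3))
    stop(sprintf("match state emissions in '%s' do not form a probability distribution (row sums %s)",
                 path, paste(round(rs[abs(rs - 1) > 1e-3], 4), collapse = ", ")),
         call. = FALSE)
  em <- em / rs
  bg <- if (!is.null(compo)) compo / sum(compo) else background
  profileHMM(name, em[, aminoAcids(), drop = FALSE],
             background = bg, source = source)
}

#' Write a profile HMM as a HMMER3 ASCII file
#'
#' A minimal writer used for fixtures and round-trip testing: emits the
#' HMMER3/f header, `NAME`/`LENG`/`ALPH` lines, a `COMPO` line carrying the
#' model background, flat node-0 insert/transition lines and one
#' match-emission line per state, all in negative-natural-log score space.
#' Scores are written with 12 decimals so probabilities round-trip within
#' 1e-9 (real HMMER files carry 5; the reader accepts both).
#'
#' @param hmm a [ProfileHMM-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readHMMER3Profile()]
#' @export
writeHMMER3Profile <- function(hmm, path) {
  stopifnot(is(hmm, "ProfileHMM"))
  validObject(hmm)
  aa <- aminoAcids()
  fmt <- function(p) paste(sprintf("%.12f", -log(p)), collapse = "  ")
  em <- emissions(hmm)
  L <- nrow(em)
  ins <- rep(1 / 20, 20)  # flat node insert emissions; unused by scoring
  trans <- paste(sprintf("%.5f", rep(1.38629, 7)), collapse = "  ")
  out <- c(
    "HMMER3/f [driverHMM fixture writer]",
    paste0("NAME  ", modelId(hmm)),
    sprintf("LENG  %d", L),
    "ALPH  amino",
    paste0("HMM          ", paste(aa, collapse = "        ")),
    "            m->m     m->i     m->d     i->m     i->i     d->m     d->d",
    paste0("  COMPO   ", fmt(hmmBackground(hmm)[aa])),
    paste0("          ", fmt(ins)),
    paste0("          ", trans),
    unlist(lapply(seq_len(L), function(k) c(
      sprintf("%7d   %s  %d - - - -", k, fmt(em[k, aa]), k),
      paste0("          ", fmt(ins)),
      paste0("          ", trans)))),
    "//")
  writeLines(out, path)
  invisible(path)
}

#' Read a directory (or files) of HMMER3 profiles into a named library
#'
#' @param paths either a directory containing `.hmm` files or a character
#'   vector of file paths.
#' @param background,source passed to [readHMMER3Profile()].
#' @return A named list of [ProfileHMM-class] objects keyed by model id,
#'   usable as the model registry of [selectModel()].
#' @export
readHMMLibrary <- function(paths, background = defaultBackground(),
                           source = "AB_INITIO") {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.hmm$", full.names = TRUE))
  if (!length(paths)) stop("no .hmm files found", call. = FALSE)
  models <- lapply(paths, readHMMER3Profile, background = background,
                   source = source)
  stats::setNames(models, vapply(models, modelId, character(1)))
}

## internal: resolve a model id in a registry (named list of ProfileHMM)
.getModel <- function(registry, model_id) {
  m <- registry[[model_id]]
  if (is.null(m))
    stop(sprintf("model '%s' not found in the registry", model_id), call. = FALSE)
  m
}
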