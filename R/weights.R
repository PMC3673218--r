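#' Route variants through model selection
#'
#' Maps each variant to the profile HMM that would score it: the
#' significant domain assignment covering its position with the largest
#' information gain (see [selectModel()]). Variants with no surviving
#' model get `NA`.
#'
#' @param variants validated variant data.frame (see [variantRecords()]).
#' @param assignments [DomainAssignments-class] store for all proteins.
#' @param registry named list of [ProfileHMM-class] models.
#' @param bg background composition.
#' @param e_max e-value significance cutoff.
#' @return The input data.frame with columns `model_id` (character or NA)
#'   and `match_state` (integer or NA) appended.
#' @export
assignVariantsToModels <- function(variants, assignments, registry,
                                   bg = defaultBackground(), e_max = 0.01) {
  atab <- if (is(assignments, "DomainAssignments"))
    assignmentTable(assignments) else assignments
  byprot <- split(seq_len(nrow(atab)), atab$protein_id)
  model_id <- rep(NA_character_, nrow(variants))
  match_state <- rep(NA_integer_, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    rows <- byprot[[variants$protein_id[i]]]
    if (is.null(rows)) next
    sel <- selectModel(atab[rows, , drop = FALSE], variants$position[i],
                       registry, bg = bg, e_max = e_max)
    if (!is.null(sel)) {
      model_id[i] <- modelId(sel$model)
      match_state[i] <- sel$match_state
    }
  }
  variants$model_id <- model_id
  variants$match_state <- match_state
  variants
}

## internal: tabulate mapped variants into a weight table data.frame
.weightRows <- function(mapped, weight_mode) {
  ok <- !is.na(mapped$model_id)
  models <- sort(unique(mapped$model_id[ok]))
  cc <- vapply(models, function(m)
    sum(ok & mapped$model_id == m & mapped$label == "CANCER"), numeric(1))
  nc <- vapply(models, function(m)
    sum(ok & mapped$model_id == m & mapped$label == "NEUTRAL"), numeric(1))
  tot_c <- sum(cc); tot_n <- sum(nc)
  wc <- if (weight_mode == "raw") cc else if (tot_c > 0) cc / tot_c else cc * 0
  wp <- if (weight_mode == "raw") nc else if (tot_n > 0) nc / tot_n else nc * 0
  list(table = data.frame(model_id = models, cancer_count = cc,
                          neutral_count = nc, w_c = unname(wc),
                          w_p = unname(wp), stringsAsFactors = FALSE,
                          row.names = NULL),
       totals = c(cancer = tot_c, neutral = tot_n))
}

#' Build a pathogenicity weight table from mapped variants
#'
#' Tallies, per model, the CANCER and NEUTRAL variants that map onto it
#' and converts the tallies to pathogenicity weights. Under the default
#' `weight_mode = "relative"`, a model's cancer weight is its cancer count
#' divided by the total mapped cancer count (and likewise for neutral), so
#' each class's weights sum to 1 across models; `"raw"` keeps the counts.
#' Models seen in only one class still get a row (with a zero in the other
#' class). The pseudo-count is stored for use at scoring time, not folded
#' into the frequencies.
#'
#' @param mapped output of [assignVariantsToModels()] (needs `model_id`
#'   and `label` columns).
#' @param pseudo_count positive scoring-time pseudo-count delta (default 1).
#' @param weight_mode `"relative"` (default) or `"raw"`.
#' @return A [PathogenicityWeightTable-class] object.
#' @examples
#' mapped <- data.frame(model_id = c("A", "A", "B"),
#'                      label = c("CANCER", "NEUTRAL", "CANCER"))
#' computeWeightTable(mapped)
#' @export
computeWeightTable <- function(mapped, pseudo_count = 1.0,
                               weight_mode = c("relative", "raw")) {
  weight_mode <- match.arg(weight_mode)
  if (!nrow(mapped)) stop("no variants supplied", call. = FALSE)
  rows <- .weightRows(mapped, weight_mode)
  if (sum(rows$totals) == 0)
    stop("no variant mapped onto any model in either class", call. = FALSE)
  new("PathogenicityWeightTable", table = rows$table,
      pseudo_count = pseudo_count, totals = rows$totals,
      weight_mode = weight_mode)
}

#' Look up the weights applied to a model
#'
#' @param wt a [PathogenicityWeightTable-class].
#' @param model_id model identifier.
#' @return Named numeric `c(w_c, w_p)`. A model with no row gets
#'   `c(0, 0)`: the score then degrades gracefully to the unweighted
#'   log-ratio, since the pseudo-count cancels.
#' @export
weightsFor <- function(wt, model_id) {
  tb <- weightTable(wt)
  i <- match(model_id, tb$model_id)
  if (is.na(i)) c(w_c = 0, w_p = 0)
  else c(w_c = tb$w_c[i], w_p = tb$w_p[i])
}

#' Weight row for an ab-initio model from its member sequences
#'
#' Models built from homologous-sequence alignments (rather than curated
#' domain libraries) have no direct variant-to-model mapping; their
#' weights aggregate over the proteins whose sequences were used to build
#' the model. Counts all CANCER/NEUTRAL variants on member proteins and
#' normalizes against the catalogue-wide class totals — the same totals a
#' domain-based table built from the full catalogue would use — so the two
#' weighting routes are on a common scale.
#'
#' @param member_protein_ids character vector of proteins contributing to
#'   the model; must be non-empty.
#' @param variants validated variant data.frame (the full catalogue).
#' @return Named numeric with `cancer_count`, `neutral_count`, `w_c`, `w_p`.
#' @export
weightsForMembership <- function(member_protein_ids, variants) {
  if (!length(member_protein_ids))
    stop("membership set must be non-empty", call. = FALSE)
  tot_c <- sum(variants$label == "CANCER")
  tot_n <- sum(variants$label == "NEUTRAL")
  inset <- variants$protein_id %in% member_protein_ids
  cc <- sum(inset & variants$label == "CANCER")
  nc <- sum(inset & variants$label == "NEUTRAL")
  c(cancer_count = cc, neutral_count = nc,
    w_c = if (tot_c > 0) cc / tot_c else 0,
    w_p = if (tot_n > 0) nc / tot_n else 0)
}

#' Read a model-membership TSV
#'
#' Two columns: `model_id` and `member_protein_ids` (comma-separated).
#'
#' @param path file path.
#' @return Named list of character vectors keyed by model id.
#' @export
readMembership <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  stats::setNames(strsplit(tb$member_protein_ids, ","), tb$model_id)
}

#' Remove or restore one variant's contribution to a weight table
#'
#' `excludeVariant()` rebuilds the table as if the given mapped variant
#' had not been part of the construction input: its model's count in its
#' class drops by one, the class total drops by one, and all relative
#' frequencies are recomputed. `includeVariant()` is the exact inverse.
#' These give leave-one-out semantics without re-mapping any variant.
#'
#' @param wt a [PathogenicityWeightTable-class].
#' @param model_id model the held-out variant mapped to.
#' @param label `"CANCER"` or `"NEUTRAL"`.
#' @return A new [PathogenicityWeightTable-class].
#' @examples
#' mapped <- data.frame(model_id = c("A", "B"), label = c("CANCER", "NEUTRAL"))
#' wt <- computeWeightTable(mapped)
#' excludeVariant(wt, "A", "CANCER")
#' @export
excludeVariant <- function(wt, model_id, label) {
  .shiftVariant(wt, model_id, label, -1)
}

#' @rdname excludeVariant
#' @export
includeVariant <- function(wt, model_id, label) {
  .shiftVariant(wt, model_id, label, +1)
}

.shiftVariant <- function(wt, model_id, label, delta) {
  label <- match.arg(toupper(label), c("CANCER", "NEUTRAL"))
  tb <- weightTable(wt)
  i <- match(model_id, tb$model_id)
  col <- if (label == "CANCER") "cancer_count" else "neutral_count"
  if (delta < 0 && (is.na(i) || tb[[col]][i] < 1))
    stop(sprintf("no %s variant mapped to model '%s' to exclude", label, model_id),
         call. = FALSE)
  if (is.na(i)) {
    tb <- rbind(tb, data.frame(model_id = model_id, cancer_count = 0,
                               neutral_count = 0, w_c = 0, w_p = 0,
                               stringsAsFactors = FALSE))
    tb <- tb[order(tb$model_id), , drop = FALSE]
    i <- match(model_id, tb$model_id)
  }
  tb[[col]][i] <- tb[[col]][i] + delta
  totals <- totalCounts(wt)
  key <- tolower(label)
  totals[[key]] <- totals[[key]] + delta
  keep <- tb$cancer_count > 0 | tb$neutral_count > 0
  tb <- tb[keep, , drop = FALSE]
  if (weightMode(wt) == "relative") {
    tb$w_c <- if (totals[["cancer"]] > 0) tb$cancer_count / totals[["cancer"]] else tb$cancer_count * 0
    tb$w_p <- if (totals[["neutral"]] > 0) tb$neutral_count / totals[["neutral"]] else tb$neutral_count * 0
  } else {
    tb$w_c <- tb$cancer_count
    tb$w_p <- tb$neutral_count
  }
  rownames(tb) <- NULL
  new("PathogenicityWeightTable", table = tb, pseudo_count = pseudoCount(wt),
      totals = totals, weight_mode = weightMode(wt))
}

#' Read / write pathogenicity weight TSV files
#'
#' The file carries the per-model rows (`model_id`, `cancer_count`,
#' `neutral_count`, `w_c`, `w_p`) preceded by `#`-comment header lines
#' recording the class totals, pseudo-count and weight mode, which the
#' reader restores.
#'
#' @param path file path.
#' @return [readWeightTable()]: a [PathogenicityWeightTable-class];
#'   [writeWeightTable()]: `path`, invisibly.
#' @export
readWeightTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  getval <- function(key, default) {
    hit <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub(sprintf("^#\\s*%s:", key), "", hit[[1]]))
  }
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  new("PathogenicityWeightTable", table = tb,
      pseudo_count = as.numeric(getval("pseudo_count", "1")),
      totals = c(cancer = as.numeric(getval("total_cancer", sum(tb$cancer_count))),
                 neutral = as.numeric(getval("total_neutral", sum(tb$neutral_count)))),
      weight_mode = getval("weight_mode", "relative"))
}

#' @rdname readWeightTable
#' @param wt a [PathogenicityWeightTable-class].
#' @param provenance optional free-text comment line recorded in the header.
#' @export
writeWeightTable <- function(wt, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  totals <- totalCounts(wt)
  writeLines(c(
    sprintf("# total_cancer: %g", totals[["cancer"]]),
    sprintf("# total_neutral: %g", totals[["neutral"]]),
    sprintf("# pseudo_count: %g", pseudoCount(wt)),
    sprintf("# weight_mode: %s", weightMode(wt)),
    if (!is.null(provenance)) paste("#", provenance)), con)
  utils::write.table(weightTable(wt), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
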