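#' @import methods
NULL

#' ProfileHMM: match-state emission probabilities of a profile HMM
#'
#' Holds the per-match-state amino acid emission distributions of a profile
#' hidden Markov model together with the model's null (background)
#' composition. Emissions are stored as probabilities (not the negative-log
#' scores of the HMMER3 file format); every row and the background must be a
#' strictly positive composition summing to 1.
#'
#' @slot model_id single model identifier.
#' @slot source one of `"SUPERFAMILY"`, `"PFAM_A"`, `"PFAM_B"`, `"AB_INITIO"`.
#' @slot emissions numeric matrix, one row per match state (1-based), 20
#'   columns named by [aminoAcids()].
#' @slot background named numeric vector of length 20, the model's null
#'   amino acid composition.
#'
#' @seealso [readHMMER3Profile()], [writeHMMER3Profile()], [profileHMM()]
#' @export
setClass("ProfileHMM",
  representation(model_id = "character", source = "character",
                 emissions = "matrix", background = "numeric"))

setValidity("ProfileHMM", function(object) {
  msgs <- character()
  if (length(object@model_id) != 1L || !nzchar(object@model_id))
    msgs <- c(msgs, "model_id must be a single non-empty string")
  if (!object@source %in% c("SUPERFAMILY", "PFAM_A", "PFAM_B", "AB_INITIO"))
    msgs <- c(msgs, "source must be one of SUPERFAMILY, PFAM_A, PFAM_B, AB_INITIO")
  em <- object@emissions
  if (nrow(em) < 1L)
    msgs <- c(msgs, "model must have at least one match state")
  if (ncol(em) != 20L || !identical(colnames(em), aminoAcids()))
    msgs <- c(msgs, "emissions must have 20 columns named by aminoAcids()")
  else {
    if (any(!is.finite(em)) || any(em <= 0))
      msgs <- c(msgs, "all emission probabilities must be finite and strictly > 0")
    bad <- which(abs(rowSums(em) - 1) > 1e-6)
    if (length(bad))
      msgs <- c(msgs, sprintf("emission rows not summing to 1 within 1e-6: %s",
                              paste(utils::head(bad, 5), collapse = ", ")))
  }
  bg <- .checkComposition(object@background, "background")
  if (!isTRUE(bg)) msgs <- c(msgs, bg)
  if (length(msgs)) msgs else TRUE
})

#' BackgroundComposition: null amino acid frequencies
#'
#' A strictly positive probability vector over the 20 standard amino acids,
#' used as the reference distribution for Kullback-Leibler information gain.
#' The shipped default emulates the SwissProt/TrEMBL proteome composition.
#'
#' @slot probabilities named numeric vector of length 20 summing to 1.
#' @seealso [backgroundComposition()], [defaultBackground()]
#' @export
setClass("BackgroundComposition",
  representation(probabilities = "numeric"))

setValidity("BackgroundComposition", function(object) {
  v <- .checkComposition(object@probabilities, "background composition")
  if (isTRUE(v)) TRUE else v
})

#' DomainAssignments: protein-to-model alignments
#'
#' A table of domain assignments, each aligning a stretch of a protein to a
#' stretch of a profile HMM. The alignment is encoded column-by-column as a
#' string over M (one residue to one match state), I (one residue, no match
#' state) and D (one match state, no residue); `seq_start` and `hmm_start`
#' are 1-based and inclusive, following HMMER convention.
#'
#' @slot table data.frame with columns `protein_id`, `model_id`, `e_value`,
#'   `seq_start`, `hmm_start`, `ops`.
#' @seealso [domainAssignments()], [readDomainAssignments()],
#'   [mapPositionToMatchState()]
#' @export
setClass("DomainAssignments", representation(table = "data.frame"))

setValidity("DomainAssignments", function(object) {
  tb <- object@table
  need <- c("protein_id", "model_id", "e_value", "seq_start", "hmm_start", "ops")
  if (!all(need %in% names(tb)))
    return(sprintf("missing columns: %s", paste(setdiff(need, names(tb)), collapse = ", ")))
  msgs <- character()
  if (nrow(tb)) {
    if (any(tb$e_value < 0)) msgs <- c(msgs, "e_value must be >= 0")
    if (any(tb$seq_start < 1) || any(tb$hmm_start < 1))
      msgs <- c(msgs, "seq_start and hmm_start are 1-based and must be >= 1")
    if (any(!nzchar(tb$ops))) msgs <- c(msgs, "ops must be non-empty")
    if (any(grepl("[^MID]", tb$ops))) msgs <- c(msgs, "ops may contain only M, I, D")
  }
  if (length(msgs)) msgs else TRUE
})

#' PathogenicityWeightTable: per-model cancer and neutral weights
#'
#' Per-model counts of mapped cancer-associated and putatively neutral
#' variants, converted to pathogenicity weights. Under `weight_mode =
#' "relative"` (the default) a model's weight is its count divided by the
#' class total over all mapped variants, so weights lie in \[0, 1\] and sum
#' to 1 per class; under `"raw"` the weights are the counts themselves. The
#' pseudo-count delta is stored here but applied only at scoring time
#' (`w + delta`), so the table remains interpretable as frequencies.
#'
#' @slot table data.frame with columns `model_id`, `cancer_count`,
#'   `neutral_count`, `w_c`, `w_p`.
#' @slot pseudo_count positive real, the scoring-time pseudo-count delta.
#' @slot totals named numeric, total mapped `cancer` and `neutral` counts.
#' @slot weight_mode `"relative"` or `"raw"`.
#' @seealso [computeWeightTable()], [excludeVariant()], [weightsFor()]
#' @export
setClass("PathogenicityWeightTable",
  representation(table = "data.frame", pseudo_count = "numeric",
                 totals = "numeric", weight_mode = "character"))

setValidity("PathogenicityWeightTable", function(object) {
  tb <- object@table
  need <- c("model_id", "cancer_count", "neutral_count", "w_c", "w_p")
  if (!all(need %in% names(tb)))
    return(sprintf("missing columns: %s", paste(setdiff(need, names(tb)), collapse = ", ")))
  msgs <- character()
  if (object@pseudo_count <= 0) msgs <- c(msgs, "pseudo_count must be > 0")
  if (!object@weight_mode %in% c("relative", "raw"))
    msgs <- c(msgs, "weight_mode must be 'relative' or 'raw'")
  if (!identical(sort(names(object@totals)), c("cancer", "neutral")))
    msgs <- c(msgs, "totals must be named 'cancer' and 'neutral'")
  if (nrow(tb)) {
    if (any(tb$cancer_count < 0) || any(tb$neutral_count < 0))
      msgs <- c(msgs, "counts must be >= 0")
    if (anyDuplicated(tb$model_id)) msgs <- c(msgs, "duplicated model_id rows")
    if (object@weight_mode == "relative") {
      if (sum(tb$w_c) > 1 + 1e-9 || sum(tb$w_p) > 1 + 1e-9)
        msgs <- c(msgs, "relative weights must sum to <= 1 per class")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' ClassifierConfig: scoring and classification parameters
#'
#' @slot threshold decision threshold tau on the weighted score; scores at
#'   or below it are called cancer-associated. Default -0.75.
#' @slot pseudo_count pseudo-count delta added to both weights at scoring
#'   time. Default 1.0.
#' @slot weight_mode `"relative"` or `"raw"`, must match the weight table.
#' @slot e_max e-value significance cutoff for domain assignments.
#'   Default 0.01.
#' @seealso [classifierConfig()], [predictVariant()]
#' @export
setClass("ClassifierConfig",
  representation(threshold = "numeric", pseudo_count = "numeric",
                 weight_mode = "character", e_max = "numeric"))

setValidity("ClassifierConfig", function(object) {
  msgs <- character()
  if (!is.finite(object@threshold)) msgs <- c(msgs, "threshold must be finite")
  if (!is.finite(object@pseudo_count) || object@pseudo_count <= 0)
    msgs <- c(msgs, "pseudo_count must be finite and > 0")
  if (!object@weight_mode %in% c("relative", "raw"))
    msgs <- c(msgs, "weight_mode must be 'relative' or 'raw'")
  if (!is.finite(object@e_max) || object@e_max < 0)
    msgs <- c(msgs, "e_max must be finite and >= 0")
  if (length(msgs)) msgs else TRUE
})

#' ConfusionCounts: a 2x2 confusion table
#'
#' @slot tp,fp,tn,fn non-negative counts. Positives are driver
#'   (cancer-associated) calls.
#' @seealso [confusionFromPredictions()], [computeMetrics()]
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", fp = "numeric", tn = "numeric", fn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(tp = object@tp, fp = object@fp, tn = object@tn, fn = object@fn)
  if (any(!is.finite(v)) || any(v < 0)) "all counts must be finite and >= 0" else TRUE
})

#' MetricSet: the six performance parameters
#'
#' Accuracy, precision, specificity, sensitivity, negative predictive value
#' and Matthews correlation coefficient. When `normalized` is TRUE the
#' metrics are computed from per-class rates, so accuracy equals the mean
#' of sensitivity and specificity regardless of class imbalance. A metric
#' whose denominator is zero is carried as `NA` (an explicit undefined
#' marker), never as a silent zero.
#'
#' @slot accuracy,precision,specificity,sensitivity,npv reals in \[0, 1\] or NA.
#' @slot mcc real in \[-1, 1\] or NA.
#' @slot normalized logical flag.
#' @seealso [computeMetrics()]
#' @export
setClass("MetricSet",
  representation(accuracy = "numeric", precision = "numeric",
                 specificity = "numeric", sensitivity = "numeric",
                 npv = "numeric", mcc = "numeric", normalized = "logical"))

#' CumulativeROC: a cumulative true/false positive curve
#'
#' Points of (cumulative false positives, cumulative true positives) as the
#' score threshold sweeps from the most damaging (lowest) score upward.
#' Tied scores are processed as one block, so the curve is independent of
#' input order. Optionally truncated at a false-positive fraction cap.
#'
#' @slot points data.frame with columns `score`, `cum_fp`, `cum_tp`.
#' @slot n_pos,n_neg class totals.
#' @slot fp_cap the cap used, or NA.
#' @seealso [cumulativeROC()], [rocArea()]
#' @export
setClass("CumulativeROC",
  representation(points = "data.frame", n_pos = "numeric", n_neg = "numeric",
                 fp_cap = "numeric"))

setValidity("CumulativeROC", function(object) {
  pts <- object@points
  msgs <- character()
  if (!all(c("score", "cum_fp", "cum_tp") %in% names(pts)))
    return("points needs columns score, cum_fp, cum_tp")
  if (is.unsorted(pts$cum_fp) || is.unsorted(pts$cum_tp))
    msgs <- c(msgs, "cumulative coordinates must be non-decreasing")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticScenario: parameters of the synthetic fixture generator
#'
#' Describes a fully self-contained benchmark: a set of profile HMMs, one
#' domain assignment per synthetic protein, and a labelled variant
#' catalogue with planted effect structure (cancer variants sit at
#' conserved columns with very low mutant emission, preferentially on
#' cancer-enriched models; neutral variants sit at diffuse columns with
#' comparable wild-type and mutant emissions).
#'
#' @slot seed master seed; every artifact type derives its own stream from it.
#' @slot n_models,model_length,n_proteins,n_variants_per_class counts.
#' @slot driver_emission_low maximum mutant emission at planted driver sites.
#' @slot neutral_emission_high minimum emission of both alleles at planted
#'   neutral sites.
#' @slot cancer_enrichment excess placement weight (>= 0) of cancer variants
#'   on the designated driver models; 0 plants no weight signal.
#' @seealso [syntheticScenario()], [generateScenario()]
#' @export
setClass("SyntheticScenario",
  representation(seed = "numeric", n_models = "numeric", model_length = "numeric",
                 n_proteins = "numeric", n_variants_per_class = "numeric",
                 driver_emission_low = "numeric", neutral_emission_high = "numeric",
                 cancer_enrichment = "numeric"))

setValidity("SyntheticScenario", function(object) {
  msgs <- character()
  cnt <- c(object@n_models, object@model_length, object@n_proteins,
           object@n_variants_per_class)
  if (any(cnt < 1)) msgs <- c(msgs, "all counts must be >= 1")
  if (object@seed != round(object@seed)) msgs <- c(msgs, "seed must be an integer")
  pr <- c(object@driver_emission_low, object@neutral_emission_high)
  if (any(pr <= 0) || any(pr >= 1))
    msgs <- c(msgs, "emission bounds must lie in (0, 1)")
  if (object@driver_emission_low * 20 > 1)
    msgs <- c(msgs, "driver_emission_low too large: a 20-residue composition cannot keep every residue below it while one is conserved")
  if (object@cancer_enrichment < 0) msgs <- c(msgs, "cancer_enrichment must be >= 0")
  if (object@n_proteins < object@n_models)
    msgs <- c(msgs, "need at least one protein per model")
  if (length(msgs)) msgs else TRUE
})
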