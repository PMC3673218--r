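#' @include AllClasses.R
NULL

#' Accessors for driverHMM objects
#'
#' `modelId()` returns the model identifier; `modelLength()` the number of
#' match states; `emissions()` the match-state-by-residue probability
#' matrix; `hmmBackground()` the model's null composition;
#' `assignmentTable()`, `weightTable()` and `rocPoints()` the underlying
#' data.frames; `pseudoCount()`, `weightMode()` and `totalCounts()` the
#' weight-table metadata; `counts()` the confusion counts as a named
#' vector; `metricValues()` the six metrics as a named vector.
#'
#' @param x a driverHMM object.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases modelId modelLength emissions hmmBackground assignmentTable
#'   weightTable pseudoCount weightMode totalCounts counts metricValues
#'   rocPoints
#' @examples
#' hmm <- profileHMM("toy", matrix(0.05, 2, 20, dimnames = list(NULL, aminoAcids())))
#' modelId(hmm)
#' modelLength(hmm)
NULL

#' @rdname accessors
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))
#' @rdname accessors
#' @export
setGeneric("modelLength", function(x) standardGeneric("modelLength"))
#' @rdname accessors
#' @export
setGeneric("emissions", function(x) standardGeneric("emissions"))
#' @rdname accessors
#' @export
setGeneric("hmmBackground", function(x) standardGeneric("hmmBackground"))
#' @rdname accessors
#' @export
setGeneric("assignmentTable", function(x) standardGeneric("assignmentTable"))
#' @rdname accessors
#' @export
setGeneric("weightTable", function(x) standardGeneric("weightTable"))
#' @rdname accessors
#' @export
setGeneric("pseudoCount", function(x) standardGeneric("pseudoCount"))
#' @rdname accessors
#' @export
setGeneric("weightMode", function(x) standardGeneric("weightMode"))
#' @rdname accessors
#' @export
setGeneric("totalCounts", function(x) standardGeneric("totalCounts"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))
#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

setMethod("modelId", "ProfileHMM", function(x) x@model_id)
setMethod("modelLength", "ProfileHMM", function(x) nrow(x@emissions))
setMethod("emissions", "ProfileHMM", function(x) x@emissions)
setMethod("hmmBackground", "ProfileHMM", function(x) x@background)
setMethod("assignmentTable", "DomainAssignments", function(x) x@table)
setMethod("weightTable", "PathogenicityWeightTable", function(x) x@table)
setMethod("pseudoCount", "PathogenicityWeightTable", function(x) x@pseudo_count)
setMethod("pseudoCount", "ClassifierConfig", function(x) x@pseudo_count)
setMethod("weightMode", "PathogenicityWeightTable", function(x) x@weight_mode)
setMethod("weightMode", "ClassifierConfig", function(x) x@weight_mode)
setMethod("totalCounts", "PathogenicityWeightTable", function(x) x@totals)
setMethod("counts", "ConfusionCounts",
  function(x) c(tp = x@tp, fp = x@fp, tn = x@tn, fn = x@fn))
setMethod("metricValues", "MetricSet",
  function(x) c(accuracy = x@accuracy, precision = x@precision,
                specificity = x@specificity, sensitivity = x@sensitivity,
                npv = x@npv, mcc = x@mcc))
setMethod("rocPoints", "CumulativeROC", function(x) x@points)

setMethod("show", "ProfileHMM", function(object) {
  cat(sprintf("ProfileHMM '%s' (%s): %d match states\n",
              object@model_id, object@source, nrow(object@emissions)))
})

setMethod("show", "BackgroundComposition", function(object) {
  cat("BackgroundComposition over", length(object@probabilities), "residues\n")
})

setMethod("show", "DomainAssignments", function(object) {
  tb <- object@table
  cat(sprintf("DomainAssignments: %d assignments, %d proteins, %d models\n",
              nrow(tb), length(unique(tb$protein_id)), length(unique(tb$model_id))))
})

setMethod("show", "PathogenicityWeightTable", function(object) {
  cat(sprintf(
    "PathogenicityWeightTable: %d models, %d cancer / %d neutral mapped (mode=%s, delta=%g)\n",
    nrow(object@table), object@totals[["cancer"]], object@totals[["neutral"]],
    object@weight_mode, object@pseudo_count))
})

setMethod("show", "ClassifierConfig", function(object) {
  cat(sprintf("ClassifierConfig: threshold=%g, pseudo_count=%g, weight_mode=%s, e_max=%g\n",
              object@threshold, object@pseudo_count, object@weight_mode, object@e_max))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: tp=%g fp=%g tn=%g fn=%g\n",
              object@tp, object@fp, object@tn, object@fn))
})

setMethod("show", "MetricSet", function(object) {
  v <- metricValues(object)
  cat(sprintf("MetricSet (%s):\n", if (object@normalized) "normalized" else "raw"))
  print(round(v, 4))
})

setMethod("show", "CumulativeROC", function(object) {
  cat(sprintf("CumulativeROC: %d points, %g positives, %g negatives%s\n",
              nrow(object@points), object@n_pos, object@n_neg,
              if (is.na(object@fp_cap)) "" else sprintf(", fp cap %g", object@fp_cap)))
})

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf(
    "SyntheticScenario: seed=%d, %d models x %d states, %d proteins, %d variants/class, enrichment=%g\n",
    object@seed, object@n_models, object@model_length, object@n_proteins,
    object@n_variants_per_class, object@cancer_enrichment))
})
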