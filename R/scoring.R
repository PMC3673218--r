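#' Classifier configuration constructor
#'
#' Bundles the parameters of the scoring/classification step: the decision
#' threshold tau (default -0.75, the shipped operating point derived on
#' germ-line/somatic benchmark data), the pseudo-count delta added to both
#' pathogenicity weights (default 1.0), the weight mode and the e-value
#' significance cutoff for domain assignments.
#'
#' @param threshold decision threshold; scores `<= threshold` are called
#'   cancer-associated (inclusive boundary, so exact-threshold scores are
#'   not silently neutral).
#' @param pseudo_count positive pseudo-count delta.
#' @param weight_mode `"relative"` or `"raw"`.
#' @param e_max e-value cutoff for significant assignments.
#' @return A [ClassifierConfig-class] object.
#' @examples
#' classifierConfig()
#' @export
classifierConfig <- function(threshold = -0.75, pseudo_count = 1.0,
                             weight_mode = c("relative", "raw"),
                             e_max = 0.01) {
  new("ClassifierConfig", threshold = threshold, pseudo_count = pseudo_count,
      weight_mode = match.arg(weight_mode), e_max = e_max)
}

#' Weighted magnitude-of-effect score
#'
#' The core substitution score: the natural-log ratio of the mutant to the
#' wild-type emission probability at the mapped match state, weighted by
#' the model's pathogenicity weights with a pseudo-count,
#'
#' \deqn{score = \ln\frac{p_m \,(w_p + \delta)}{p_w \,(w_c + \delta)}}
#'
#' More negative scores indicate a larger predicted loss of fit to the
#' model, amplified when the model is enriched for cancer-associated
#' variants (large `w_c`) and damped when enriched for neutral ones. The
#' score is strictly increasing in `p_m` and `w_p`, strictly decreasing in
#' `p_w` and `w_c`, and reduces to the unweighted log-ratio
#' `log(p_m / p_w)` whenever `w_c == w_p`.
#'
#' @param p_w,p_m wild-type and mutant emission probabilities in (0, 1].
#' @param w_c,w_p cancer and neutral pathogenicity weights (>= 0).
#' @param pseudo_count positive pseudo-count delta (default 1.0), which
#'   keeps both weight terms away from zero.
#' @return Numeric score (nats).
#' @examples
#' weightedScore(p_w = 0.5, p_m = 0.05, w_c = 0, w_p = 0)  # log(0.1)
#' @export
weightedScore <- function(p_w, p_m, w_c = 0, w_p = 0, pseudo_count = 1.0) {
  if (any(p_w <= 0) || any(p_w > 1) || any(p_m <= 0) || any(p_m > 1))
    stop("emission probabilities must lie in (0, 1]", call. = FALSE)
  if (any(w_c < 0) || any(w_p < 0)) stop("weights must be >= 0", call. = FALSE)
  if (any(pseudo_count <= 0)) stop("pseudo_count must be > 0", call. = FALSE)
  log((p_m * (w_p + pseudo_count)) / (p_w * (w_c + pseudo_count)))
}

#' Classify a score against the decision threshold
#'
#' @param score finite numeric score(s).
#' @param config a [ClassifierConfig-class]; only the threshold is used.
#' @return `"CANCER"` for scores at or below the threshold, else
#'   `"PASSENGER_OR_NEUTRAL"`.
#' @examples
#' classifyScore(c(-2, 0), classifierConfig())
#' @export
classifyScore <- function(score, config = classifierConfig()) {
  stopifnot(all(is.finite(score)))
  ifelse(score <= config@threshold, "CANCER", "PASSENGER_OR_NEUTRAL")
}

.emptyPrediction <- function(protein_id, substitution) {
  n <- length(protein_id)
  data.frame(protein_id = protein_id, substitution = substitution,
             score = rep(NA_real_, n), label = rep("NO_PREDICTION", n),
             model_id = rep(NA_character_, n),
             match_state = rep(NA_integer_, n),
             p_w = rep(NA_real_, n), p_m = rep(NA_real_, n),
             w_c = rep(NA_real_, n), w_p = rep(NA_real_, n),
             error = rep(NA_character_, n), stringsAsFactors = FALSE)
}

#' Score and classify one substitution
#'
#' Runs the full pipeline for a single substitution: parse, select the
#' most informative significant model covering the position, read the
#' wild-type and mutant emission probabilities at the mapped match state,
#' look up the model's pathogenicity weights (a model with no weight row
#' contributes `w_c = w_p = 0`), compute the weighted score and classify
#' it. When no model survives selection the result is `NO_PREDICTION`
#' with an `NA` score.
#'
#' A declared wild-type residue that is not the model's highest-emission
#' residue at the mapped state is reported with a message when
#' `warn_wildtype = TRUE` — homolog alignments routinely differ from the
#' query sequence, so this is advisory, never an error.
#'
#' @param protein_id protein identifier.
#' @param substitution substitution string, e.g. `"R175H"`.
#' @param assignments [DomainAssignments-class] store.
#' @param registry named list of [ProfileHMM-class] models.
#' @param wt a [PathogenicityWeightTable-class].
#' @param bg background composition.
#' @param config a [ClassifierConfig-class].
#' @param warn_wildtype emit a message on wild-type/consensus mismatch.
#' @return One-row data.frame: `protein_id`, `substitution`, `score`,
#'   `label`, `model_id`, `match_state`, `p_w`, `p_m`, `w_c`, `w_p`,
#'   `error`.
#' @seealso [predictBatch()], [weightedScore()], [selectModel()]
#' @export
predictVariant <- function(protein_id, substitution, assignments, registry,
                           wt, bg = defaultBackground(),
                           config = classifierConfig(),
                           warn_wildtype = FALSE) {
  sub <- parseSubstitution(substitution)
  atab <- if (is(assignments, "DomainAssignments"))
    assignmentTable(assignments) else assignments
  atab <- atab[atab$protein_id == protein_id, , drop = FALSE]
  sel <- selectModel(atab, sub$position, registry, bg = bg,
                     e_max = config@e_max)
  out <- .emptyPrediction(protein_id, substitution)
  if (is.null(sel)) return(out)
  em <- emissions(sel$model)[sel$match_state, ]
  p_w <- em[[sub$wild_type]]
  p_m <- em[[sub$mutant]]
  if (warn_wildtype && names(which.max(em)) != sub$wild_type)
    message(sprintf("%s %s: declared wild-type %s is not the consensus residue (%s) at match state %d of %s",
                    protein_id, substitution, sub$wild_type,
                    names(which.max(em)), sel$match_state, modelId(sel$model)))
  w <- weightsFor(wt, modelId(sel$model))
  score <- weightedScore(p_w, p_m, w[["w_c"]], w[["w_p"]], config@pseudo_count)
  out$score <- score
  out$label <- classifyScore(score, config)
  out$model_id <- modelId(sel$model)
  out$match_state <- sel$match_state
  out$p_w <- p_w; out$p_m <- p_m
  out$w_c <- w[["w_c"]]; out$w_p <- w[["w_p"]]
  out
}

#' Score and classify a batch of substitutions
#'
#' One prediction row per input row, input order preserved. Per-row
#' failures (malformed notation, non-standard residues) are recorded in
#' the `error` column and never abort the batch. A summary line with the
#' per-label counts is emitted via `message()` when `verbose = TRUE`.
#'
#' @param variants data.frame with columns `protein_id` and `substitution`
#'   (or a path to such a TSV).
#' @inheritParams predictVariant
#' @param verbose emit a per-label count summary.
#' @return data.frame with the [predictVariant()] columns, one row per
#'   input row.
#' @export
predictBatch <- function(variants, assignments, registry, wt,
                         bg = defaultBackground(),
                         config = classifierConfig(), verbose = FALSE) {
  if (is.character(variants) && length(variants) == 1L)
    variants <- utils::read.table(variants, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE, comment.char = "#")
  if (!nrow(variants)) return(.emptyPrediction(character(0), character(0)))
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    tryCatch(
      predictVariant(variants$protein_id[i], variants$substitution[i],
                     assignments, registry, wt, bg = bg, config = config),
      error = function(e) {
        out <- .emptyPrediction(variants$protein_id[i], variants$substitution[i])
        out$error <- conditionMessage(e)
        out
      })
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- .emptyPrediction(character(0), character(0))
  if (verbose) {
    tab <- table(out$label)
    message("predictions: ",
            paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "))
  }
  out
}

#' Write a prediction table as TSV
#'
#' Scores are rounded to 2 decimal places in the file (full precision is
#' carried in the in-memory table); header comment lines can record
#' provenance.
#'
#' @param predictions data.frame from [predictBatch()].
#' @param path output path.
#' @param header optional character vector of comment lines (without `#`).
#' @param digits decimal places for the score column (default 2); use
#'   `NA` for full precision.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(predictions, path, header = NULL, digits = 2) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste("#", header), con)
  out <- predictions
  if (!is.na(digits)) out$score <- round(out$score, digits)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
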