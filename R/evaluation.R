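#' Confusion counts from scores and labels
#'
#' Positives are driver (cancer-associated) variants; a score at or below
#' the threshold predicts positive, matching [classifyScore()].
#'
#' @param scores numeric scores.
#' @param labels class labels, coerced so that `"CANCER"`/`"positive"`/
#'   `TRUE`/`1` mark positives.
#' @param threshold decision threshold tau.
#' @return A [ConfusionCounts-class] object.
#' @examples
#' confusionFromPredictions(c(-2, -1, 0, 1), c(1, 1, 0, 0), -0.75)
#' @export
confusionFromPredictions <- function(scores, labels, threshold = -0.75) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  pos <- .asPositive(labels)
  pred <- scores <= threshold
  new("ConfusionCounts",
      tp = sum(pred & pos), fp = sum(pred & !pos),
      tn = sum(!pred & !pos), fn = sum(!pred & pos))
}

.asPositive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  toupper(as.character(labels)) %in% c("CANCER", "POSITIVE", "P", "DRIVER", "1", "TRUE")
}

.safeRatio <- function(num, den) if (is.na(den) || den == 0) NA_real_ else num / den

#' The six performance parameters of a 2x2 confusion table
#'
#' With `normalized = TRUE` (the default) the table is first reduced to
#' per-class rates — `s = tp/(tp+fn)`, `e = tn/(tn+fp)`, `f = fp/(tn+fp)`,
#' `m = fn/(tp+fn)` — and the parameters computed from the rates:
#' sensitivity `s`, specificity `e`, accuracy `(s+e)/2`, precision
#' `s/(s+f)`, NPV `e/(e+m)` and MCC
#' `(s*e - f*m) / sqrt((s+f)(s+m)(e+f)(e+m))`. This makes every metric
#' independent of class imbalance, as if both classes had equal size.
#' With `normalized = FALSE` the textbook raw-count formulas are used; the
#' two agree exactly when the classes are balanced. Any metric with a
#' zero denominator is returned as `NA` (an explicit undefined marker).
#'
#' @param x a [ConfusionCounts-class] object.
#' @param normalized compute from per-class rates (default TRUE).
#' @return A [MetricSet-class] object.
#' @examples
#' cc <- new("ConfusionCounts", tp = 2858, fp = 77, tn = 3077, fn = 300)
#' computeMetrics(cc)
#' @export
computeMetrics <- function(x, normalized = TRUE) {
  v <- as.numeric(counts(x))  # doubles: raw-count products overflow integers
  tp <- v[[1]]; fp <- v[[2]]; tn <- v[[3]]; fn <- v[[4]]
  if (tp + fn == 0 || tn + fp == 0)
    stop("normalized metrics need at least one member of each class", call. = FALSE)
  if (normalized) {
    s <- tp / (tp + fn); e <- tn / (tn + fp)
    f <- fp / (tn + fp); m <- fn / (tp + fn)
    den <- (s + f) * (s + m) * (e + f) * (e + m)
    new("MetricSet",
        accuracy = (s + e) / 2,
        precision = .safeRatio(s, s + f),
        specificity = e, sensitivity = s,
        npv = .safeRatio(e, e + m),
        mcc = if (den == 0) NA_real_ else (s * e - f * m) / sqrt(den),
        normalized = TRUE)
  } else {
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    new("MetricSet",
        accuracy = (tp + tn) / (tp + fp + tn + fn),
        precision = .safeRatio(tp, tp + fp),
        specificity = tn / (tn + fp), sensitivity = tp / (tp + fn),
        npv = .safeRatio(tn, tn + fn),
        mcc = if (den == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(den),
        normalized = FALSE)
  }
}

#' Cumulative ROC curve
#'
#' Sweeps the decision threshold from the most damaging (lowest) score
#' upward and accumulates true and false positive counts. Tied scores are
#' processed as one block — every member of the tie is added before a
#' point is emitted — so the curve does not depend on input order. An
#' optional cap truncates the curve once the cumulative false positives
#' exceed `fp_fraction_cap` times the number of negatives (e.g. 0.01 for
#' a view centred on a conservative 1% error rate).
#'
#' @param scores numeric scores (lower = more damaging).
#' @param labels class labels as in [confusionFromPredictions()].
#' @param fp_fraction_cap optional false-positive fraction cap in (0, 1\],
#'   or `NULL` for the full curve.
#' @return A [CumulativeROC-class] object.
#' @seealso [rocArea()]
#' @export
cumulativeROC <- function(scores, labels, fp_fraction_cap = NULL) {
  pos <- .asPositive(labels)
  if (!any(pos) || all(pos))
    stop("need at least one positive and one negative", call. = FALSE)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  ord <- order(scores)
  s <- scores[ord]; p <- pos[ord]
  uniq <- unique(s)
  cum_tp <- cumsum(vapply(split(p, match(s, uniq)), sum, numeric(1)))
  cum_fp <- cumsum(vapply(split(!p, match(s, uniq)), sum, numeric(1)))
  pts <- data.frame(score = uniq, cum_fp = unname(cum_fp),
                    cum_tp = unname(cum_tp))
  cap <- NA_real_
  if (!is.null(fp_fraction_cap)) {
    cap <- fp_fraction_cap
    pts <- pts[pts$cum_fp <= cap * n_neg, , drop = FALSE]
  }
  new("CumulativeROC", points = pts, n_pos = n_pos, n_neg = n_neg, fp_cap = cap)
}

#' Area under the cumulative ROC curve
#'
#' Trapezoidal area on the rate scale (cumulative fractions of each
#' class), with the curve anchored at (0, 0). For an untruncated curve
#' this equals the Mann-Whitney concordance probability that a positive
#' scores below (more damaging than) a negative, with ties counted 1/2.
#'
#' @param roc a [CumulativeROC-class] object.
#' @return Numeric area in \[0, 1\].
#' @export
rocArea <- function(roc) {
  pts <- rocPoints(roc)
  x <- c(0, pts$cum_fp / roc@n_neg)
  y <- c(0, pts$cum_tp / roc@n_pos)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Derive a decision threshold across several scored datasets
#'
#' Scans a fixed grid of candidate thresholds spanning the pooled score
#' range and returns the candidate maximizing the sum over datasets of
#' sensitivity + specificity (the summed Youden index — the standard
#' scalarization of "both maximized"). Grid ties are resolved
#' deterministically: the tied candidate closest to the median of the
#' tied set, then the most negative.
#'
#' @param datasets list of data.frames, each with columns `score` and
#'   `label` (labels as in [confusionFromPredictions()]); each dataset
#'   must contain both classes.
#' @param grid_step spacing of the candidate grid (default 0.05). The
#'   grid is aligned to multiples of `grid_step` so the returned value
#'   does not depend on the score extremes' exact values.
#' @return Numeric threshold.
#' @examples
#' d <- data.frame(score = c(-3, -2.5, 0.5, 1), label = c(1, 1, 0, 0))
#' deriveThreshold(list(d))
#' @export
deriveThreshold <- function(datasets, grid_step = 0.05) {
  if (!length(datasets)) stop("no datasets supplied", call. = FALSE)
  for (d in datasets) {
    pos <- .asPositive(d$label)
    if (!any(pos) || all(pos))
      stop("every dataset must contain both classes", call. = FALSE)
  }
  all_scores <- unlist(lapply(datasets, `[[`, "score"))
  lo <- floor(min(all_scores) / grid_step) * grid_step
  hi <- ceiling(max(all_scores) / grid_step) * grid_step
  grid <- seq(lo, hi, by = grid_step)
  objective <- vapply(grid, function(tau) {
    sum(vapply(datasets, function(d) {
      cc <- confusionFromPredictions(d$score, d$label, tau)
      ms <- computeMetrics(cc, normalized = TRUE)
      ms@sensitivity + ms@specificity
    }, numeric(1)))
  }, numeric(1))
  best <- grid[objective >= max(objective) - 1e-12]
  if (length(best) > 1L) {
    med <- stats::median(best)
    best <- best[abs(best - med) == min(abs(best - med))]
    best <- min(best)
  }
  best
}

## internal: score variants that already carry model_id/match_state
.scoreMapped <- function(mapped, registry, wt, config) {
  score <- rep(NA_real_, nrow(mapped))
  ok <- which(!is.na(mapped$model_id))
  for (i in ok) {
    em <- emissions(.getModel(registry, mapped$model_id[i]))[mapped$match_state[i], ]
    w <- weightsFor(wt, mapped$model_id[i])
    score[i] <- weightedScore(em[[mapped$wild_type[i]]], em[[mapped$mutant[i]]],
                              w[["w_c"]], w[["w_p"]], config@pseudo_count)
  }
  score
}

#' Cross-validate the pathogenicity weighting scheme
#'
#' Splits the variant catalogue into `k` label-stratified folds (seeded,
#' so fold membership is reproducible and independent of input order),
#' rebuilds the weight table from each fold's complement only, scores the
#' held-out fold against that table, and pools the resulting confusion
#' counts. `k = nrow(variants)` gives leave-one-out, in which each
#' variant is scored against a table excluding exactly itself.
#'
#' Exclusion scope: `"variant"` (default) removes only the held-out
#' variants' own count contributions; `"model"` additionally zeroes the
#' weight rows of every model a held-out variant maps to, a stricter
#' guard against information leakage through shared models.
#'
#' @param variants validated variant data.frame.
#' @param assignments,registry,bg as in [assignVariantsToModels()].
#' @param config a [ClassifierConfig-class].
#' @param k number of folds (`>= 2`), or `nrow(variants)` for
#'   leave-one-out.
#' @param seed integer seed for fold assignment.
#' @param exclusion `"variant"` or `"model"`.
#' @return List with `predictions` (the mapped variants plus `fold`,
#'   `score`, `label_pred`), `confusion` (pooled
#'   [ConfusionCounts-class]) and `metrics` (normalized
#'   [MetricSet-class]).
#' @export
kfoldWeightsCV <- function(variants, assignments, registry,
                           bg = defaultBackground(),
                           config = classifierConfig(), k = 20, seed = 1,
                           exclusion = c("variant", "model")) {
  exclusion <- match.arg(exclusion)
  n <- nrow(variants)
  if (k < 2 || k > n) stop("k must be in [2, number of variants]", call. = FALSE)
  mapped <- assignVariantsToModels(variants, assignments, registry,
                                   bg = bg, e_max = config@e_max)
  # stratified, seeded fold assignment keyed to a canonical variant order
  # so shuffled input yields identical membership
  key <- paste(mapped$protein_id, mapped$position, mapped$wild_type,
               mapped$mutant, sep = "|")
  canon <- order(key)
  fold <- integer(n)
  if (k == n) {
    fold[canon] <- seq_len(n)  # leave-one-out: one variant per fold
  } else {
    fold <- .withSeed(seed, {
      for (lab in unique(mapped$label)) {
        idx <- canon[mapped$label[canon] == lab]
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      fold
    })
  }
  if (k < n) {
    single <- vapply(split(mapped$label, fold),
                     function(l) length(unique(l)) < 2L, logical(1))
    if (any(single))
      stop("stratification produced single-class folds; reduce k", call. = FALSE)
  }
  score <- rep(NA_real_, n)
  for (f in sort(unique(fold))) {
    held <- fold == f
    wt_f <- computeWeightTable(mapped[!held, , drop = FALSE],
                               pseudo_count = config@pseudo_count,
                               weight_mode = config@weight_mode)
    if (exclusion == "model") {
      drop_models <- unique(stats::na.omit(mapped$model_id[held]))
      tb <- weightTable(wt_f)
      tb <- tb[!tb$model_id %in% drop_models, , drop = FALSE]
      wt_f <- new("PathogenicityWeightTable", table = tb,
                  pseudo_count = pseudoCount(wt_f),
                  totals = totalCounts(wt_f), weight_mode = weightMode(wt_f))
    }
    score[held] <- .scoreMapped(mapped[held, , drop = FALSE], registry,
                                wt_f, config)
  }
  mapped$fold <- fold
  mapped$score <- score
  mapped$label_pred <- ifelse(is.na(score), "NO_PREDICTION",
                              classifyScore(ifelse(is.na(score), 0, score), config))
  scored <- !is.na(score)
  cc <- confusionFromPredictions(score[scored], mapped$label[scored],
                                 config@threshold)
  list(predictions = mapped, confusion = cc,
       metrics = computeMetrics(cc, normalized = TRUE))
}

## evaluate expr with a local RNG seed, restoring global state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Odds ratio with a 95% Wald confidence interval
#'
#' Compares the odds of a correct call under scheme A against scheme B:
#' `OR = (correct_a * wrong_b) / (wrong_a * correct_b)`, with
#' `CI = exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. When any
#' cell is zero the Haldane-Anscombe correction (0.5 added to every cell)
#' is applied and flagged in the result.
#'
#' @param correct_a,wrong_a,correct_b,wrong_b non-negative counts.
#' @return Named list: `or`, `ci_low`, `ci_high`, `corrected`.
#' @examples
#' oddsRatio(20, 5, 10, 10)
#' @export
oddsRatio <- function(correct_a, wrong_a, correct_b, wrong_b) {
  cells <- c(correct_a, wrong_a, correct_b, wrong_b)
  if (any(cells < 0)) stop("counts must be >= 0", call. = FALSE)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se), corrected = corrected)
}
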