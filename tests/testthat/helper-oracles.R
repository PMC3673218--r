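# Independent brute-force oracles and small in-code fixtures.
# These deliberately re-derive results by enumeration, never by calling the
# implementation they check.

# run expr under a local seed, restoring the caller's RNG state
withSeedLocal <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# random strictly positive composition over n symbols
randComposition <- function(n = 20, names = aminoAcids()[seq_len(n)]) {
  p <- stats::runif(n, 0.01, 1)
  stats::setNames(p / sum(p), names)
}

# brute-force residue -> match-state mapping: materialize every alignment
# column with its (residue, state) coordinates, then look the position up
bruteMapPosition <- function(seq_start, hmm_start, ops, position) {
  cols <- strsplit(ops, "")[[1]]
  seq_pos <- seq_start
  hmm_pos <- hmm_start
  table <- list()
  for (op in cols) {
    if (op == "M") {
      table[[length(table) + 1L]] <- c(res = seq_pos, state = hmm_pos)
      seq_pos <- seq_pos + 1L; hmm_pos <- hmm_pos + 1L
    } else if (op == "I") {
      table[[length(table) + 1L]] <- c(res = seq_pos, state = NA)
      seq_pos <- seq_pos + 1L
    } else {
      hmm_pos <- hmm_pos + 1L
    }
  }
  for (entry in table)
    if (!is.na(entry[["res"]]) && entry[["res"]] == position)
      return(as.integer(entry[["state"]]))
  NA_integer_
}

# per-item confusion counting
bruteConfusion <- function(scores, positive, tau) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(scores)) {
    called <- scores[i] <= tau
    if (called && positive[i]) tp <- tp + 1
    else if (called && !positive[i]) fp <- fp + 1
    else if (!called && !positive[i]) tn <- tn + 1
    else fn <- fn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# cumulative ROC by explicit sweep over every distinct threshold
bruteROC <- function(scores, positive) {
  thresholds <- sort(unique(scores))
  do.call(rbind, lapply(thresholds, function(t) {
    data.frame(score = t,
               cum_fp = sum(scores <= t & !positive),
               cum_tp = sum(scores <= t & positive))
  }))
}

# Mann-Whitney concordance: P(pos scores below neg), ties counted half
bruteConcordance <- function(scores, positive) {
  ps <- scores[positive]; ns <- scores[!positive]
  total <- 0
  for (p in ps) for (q in ns)
    total <- total + (if (p < q) 1 else if (p == q) 0.5 else 0)
  total / (length(ps) * length(ns))
}

# summed sensitivity+specificity objective by direct counting
bruteThresholdObjective <- function(datasets, tau) {
  sum(vapply(datasets, function(d) {
    pos <- d$label %in% c("CANCER", "1", "P") | d$label == 1
    tp <- sum(d$score <= tau & pos); fn <- sum(d$score > tau & pos)
    tn <- sum(d$score > tau & !pos); fp <- sum(d$score <= tau & !pos)
    tp / (tp + fn) + tn / (tn + fp)
  }, numeric(1)))
}

# a hand-built two-model fixture used across unit tests: model "hi" has a
# highly conserved first state, model "lo" is near background
toyRegistry <- function() {
  aa <- aminoAcids()
  bg <- defaultBackground()
  em_hi <- matrix(rep(bg, 3), nrow = 3, byrow = TRUE, dimnames = list(NULL, aa))
  em_hi[1, ] <- 0.4 / 19
  em_hi[1, "W"] <- 0.6
  em_hi[2, ] <- 0.01
  em_hi[2, "G"] <- 1 - 0.19
  em_lo <- matrix(rep(bg, 4), nrow = 4, byrow = TRUE, dimnames = list(NULL, aa))
  list(
    hi = profileHMM("hi", em_hi, background = bg, source = "PFAM_A"),
    lo = profileHMM("lo", em_lo, background = bg, source = "SUPERFAMILY"))
}

toyAssignments <- function() {
  domainAssignments(data.frame(
    protein_id = c("P1", "P1", "P2"),
    model_id = c("hi", "lo", "lo"),
    e_value = c(1e-5, 1e-6, 2e-3),
    seq_start = c(10L, 9L, 1L),
    hmm_start = c(1L, 1L, 1L),
    ops = c("MMM", "MMMM", "MMMM"),
    stringsAsFactors = FALSE))
}

# small scenario used where the full default would be wastefully large
smallScenario <- function(seed = 11, n_per_class = 100) {
  syntheticScenario(seed = seed, n_models = 4, model_length = 60,
                    n_proteins = 12, n_variants_per_class = n_per_class)
}
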