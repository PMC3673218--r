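#' Kullback-Leibler information gain against a background composition
#'
#' Computes `sum(p * log(p / q))` in nats: the information gained by an
#' emission distribution `p` relative to the null amino acid composition
#' `q`. Non-negative, and zero only when the two compositions coincide.
#' Natural logarithms are used throughout, matching the natural-log scale
#' of the substitution score.
#'
#' @param p emission probability vector (a valid composition).
#' @param q background composition (named numeric or
#'   [BackgroundComposition-class] vector) over the same alphabet.
#' @return Non-negative numeric scalar (nats).
#' @examples
#' bg <- defaultBackground()
#' klInformationGain(bg, bg)  # 0
#' @export
klInformationGain <- function(p, q) {
  if (is(q, "BackgroundComposition")) q <- q@probabilities
  if (length(p) != length(q))
    stop("p and q must be compositions over the same alphabet", call. = FALSE)
  if (!is.null(names(p)) && !is.null(names(q))) {
    if (!setequal(names(p), names(q)))
      stop("p and q must be compositions over the same alphabet", call. = FALSE)
    q <- q[names(p)]
  }
  # reduced alphabets are allowed for didactic use; require validity either way
  if (any(p <= 0) || any(q <= 0) ||
      abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("p and q must be strictly positive compositions summing to 1",
         call. = FALSE)
  sum(p * log(p / q))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the most informative model covering a residue
#'
#' Implements the model-selection rule used before scoring: among the
#' domain assignments that (i) are significant (`e_value <= e_max`) and
#' (ii) map the residue at `position` onto a match state, pick the model
#' whose emission vector at that match state has the largest
#' Kullback-Leibler information gain against the background composition.
#' Returns `NULL` when no assignment survives.
#'
#' Information gain is positional (the emission vector at the mapped match
#' state) by default because the substitution score itself is positional;
#' set `kl_scope = "model"` to rank by the mean KL over all match states
#' instead. Ties are broken deterministically: lower e-value first, then
#' lexicographic model id.
#'
#' @param assignments a [DomainAssignments-class] object (or its
#'   data.frame) holding the candidate assignments, typically all rows for
#'   one protein.
#' @param position 1-based residue index.
#' @param registry named list of [ProfileHMM-class] objects keyed by model
#'   id; every `model_id` in `assignments` must resolve.
#' @param bg background composition for the information gain.
#' @param e_max e-value significance cutoff (default 0.01).
#' @param kl_scope `"position"` (default) or `"model"`.
#' @return `NULL`, or a list with elements `model` ([ProfileHMM-class]),
#'   `match_state`, `kl`, `e_value`.
#' @seealso [klInformationGain()], [mapPositionToMatchState()]
#' @export
selectModel <- function(assignments, position, registry,
                        bg = defaultBackground(), e_max = 0.01,
                        kl_scope = c("position", "model")) {
  kl_scope <- match.arg(kl_scope)
  if (is(assignments, "DomainAssignments"))
    assignments <- assignmentTable(assignments)
  if (!nrow(assignments)) return(NULL)
  if (is(bg, "BackgroundComposition")) bg <- bg@probabilities
  best <- NULL
  for (i in seq_len(nrow(assignments))) {
    a <- assignments[i, ]
    if (a$e_value > e_max) next
    state <- mapPositionToMatchState(a, position)
    if (is.na(state)) next
    model <- .getModel(registry, a$model_id)
    kl <- if (kl_scope == "position")
      klInformationGain(emissions(model)[state, ], bg)
    else
      mean(apply(emissions(model), 1L, klInformationGain, q = bg))
    cand <- list(model = model, match_state = as.integer(state),
                 kl = kl, e_value = a$e_value)
    if (is.null(best) ||
        cand$kl > best$kl + 1e-12 ||
        (abs(cand$kl - best$kl) <= 1e-12 &&
         (cand$e_value < best$e_value ||
          (cand$e_value == best$e_value && modelId(model) < modelId(best$model)))))
      best <- cand
  }
  best
}
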