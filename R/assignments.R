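#' @include AllClasses.R
NULL

#' Construct a DomainAssignments table
#'
#' @param table data.frame with columns `protein_id`, `model_id`,
#'   `e_value`, `seq_start`, `hmm_start`, `ops`. `ops` is a string over
#'   `M` (residue aligned to a match state), `I` (insertion: residue
#'   consumed, no match state) and `D` (deletion: match state consumed,
#'   no residue).
#' @param registry optional named list of [ProfileHMM-class] models; when
#'   supplied, each assignment's match-state span (`hmm_start` plus the
#'   number of M/D columns minus 1) is checked against the model length.
#' @return A [DomainAssignments-class] object.
#' @examples
#' domainAssignments(data.frame(
#'   protein_id = "P1", model_id = "m1", e_value = 1e-5,
#'   seq_start = 10, hmm_start = 1, ops = "MMM"))
#' @export
domainAssignments <- function(table, registry = NULL) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  obj <- new("DomainAssignments", table = table)
  if (!is.null(registry)) {
    for (i in seq_len(nrow(table))) {
      m <- .getModel(registry, table$model_id[i])
      span <- table$hmm_start[i] +
        sum(strsplit(table$ops[i], "")[[1]] %in% c("M", "D")) - 1L
      if (span > modelLength(m))
        stop(sprintf("assignment %d: alignment runs to match state %d but model '%s' has %d",
                     i, span, modelId(m), modelLength(m)), call. = FALSE)
    }
  }
  obj
}

#' Read / write domain assignment TSV files
#'
#' One row per assignment: `protein_id`, `model_id`, `e_value`,
#' `seq_start`, `hmm_start`, `ops`. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param registry optional model registry for span validation.
#' @return [readDomainAssignments()]: a [DomainAssignments-class];
#'   [writeDomainAssignments()]: `path`, invisibly.
#' @export
readDomainAssignments <- function(path, registry = NULL) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  domainAssignments(tb, registry = registry)
}

#' @rdname readDomainAssignments
#' @param assignments a [DomainAssignments-class] object.
#' @export
writeDomainAssignments <- function(assignments, path) {
  stopifnot(is(assignments, "DomainAssignments"))
  utils::write.table(assignmentTable(assignments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map a protein residue position onto an HMM match state
#'
#' Walks the assignment's alignment operations from `(seq_start,
#' hmm_start)` and returns the 1-based index of the match state aligned to
#' the residue at `position`. Returns `NA` when the residue falls in an
#' insert column or outside the aligned span; that is a value, not an
#' error — substitutions are scorable only at match states.
#'
#' @param assignment a single-row [DomainAssignments-class] object or a
#'   one-row data.frame/list with the assignment fields.
#' @param position 1-based residue index in the protein.
#' @return Integer match-state index, or `NA_integer_`.
#' @examples
#' a <- data.frame(protein_id = "P", model_id = "m", e_value = 0,
#'                 seq_start = 10, hmm_start = 4, ops = "MDM")
#' mapPositionToMatchState(a, 11)  # 6: the D consumes state 5
#' @export
mapPositionToMatchState <- function(assignment, position) {
  if (is(assignment, "DomainAssignments")) {
    stopifnot(nrow(assignmentTable(assignment)) == 1L)
    assignment <- assignmentTable(assignment)
  }
  stopifnot(position >= 1)
  seq_pos <- as.integer(assignment$seq_start)
  hmm_pos <- as.integer(assignment$hmm_start)
  if (position < seq_pos) return(NA_integer_)
  ops <- strsplit(assignment$ops[[1]], "")[[1]]
  for (op in ops) {
    if (op == "M") {
      if (seq_pos == position) return(hmm_pos)
      seq_pos <- seq_pos + 1L
      hmm_pos <- hmm_pos + 1L
    } else if (op == "I") {
      if (seq_pos == position) return(NA_integer_)
      seq_pos <- seq_pos + 1L
    } else if (op == "D") {
      hmm_pos <- hmm_pos + 1L
    } else {
      stop(sprintf("invalid alignment operation '%s'", op), call. = FALSE)
    }
  }
  NA_integer_
}
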