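#' Describe a synthetic benchmark scenario
#'
#' Constructor for [SyntheticScenario-class]. The defaults describe the
#' package's reference study conditions: 4 models of 100 match states, 24
#' proteins, 500 variants per class, driver sites with mutant emission at
#' or below 0.02 at conserved columns, neutral sites with both alleles at
#' or above 0.04 at diffuse columns, and a cancer placement enrichment of
#' 3 on the designated driver models.
#'
#' @param seed master seed (integer). Each artifact type (profiles,
#'   assignments, variants) draws from its own stream derived from it, so
#'   regenerating one artifact type does not perturb the others.
#' @param n_models,model_length,n_proteins,n_variants_per_class counts.
#' @param driver_emission_low,neutral_emission_high emission bounds for
#'   planted driver and neutral sites.
#' @param cancer_enrichment excess placement weight of cancer variants on
#'   driver models: a driver model receives `1 + cancer_enrichment` times
#'   the placement probability of a non-driver model. 0 plants no weight
#'   signal.
#' @return A [SyntheticScenario-class] object.
#' @examples
#' syntheticScenario(seed = 7)
#' @export
syntheticScenario <- function(seed = 7, n_models = 4, model_length = 100,
                              n_proteins = 24, n_variants_per_class = 500,
                              driver_emission_low = 0.02,
                              neutral_emission_high = 0.04,
                              cancer_enrichment = 3) {
  new("SyntheticScenario", seed = seed, n_models = n_models,
      model_length = model_length, n_proteins = n_proteins,
      n_variants_per_class = n_variants_per_class,
      driver_emission_low = driver_emission_low,
      neutral_emission_high = neutral_emission_high,
      cancer_enrichment = cancer_enrichment)
}

## derive a per-artifact sub-seed from the master seed (kept below 2^31)
.subSeed <- function(seed, k) as.integer((seed * 7919 + k * 1000003) %% 2147483647L)

## symmetric Dirichlet draw; low concentration yields conserved columns
.rdirichlet <- function(n_col, concentration) {
  g <- stats::rgamma(n_col, shape = concentration)
  g <- pmax(g, 1e-12)
  p <- g / sum(g)
  pmax(p, 1e-10) / sum(pmax(p, 1e-10))
}

#' Generate a self-contained synthetic benchmark
#'
#' Builds, deterministically from the scenario seed: a library of profile
#' HMMs whose columns mix conserved (low Dirichlet concentration) and
#' diffuse draws; one significant full-length domain assignment per
#' protein plus one insignificant decoy per protein (exercising the
#' e-value filter); and a labelled variant catalogue with planted effect
#' structure. Cancer variants are placed at conserved columns — wild-type
#' at the column consensus, mutant with emission at or below
#' `driver_emission_low` — preferentially on the designated driver models;
#' neutral variants sit at diffuse columns with both alleles at or above
#' `neutral_emission_high` and mutant emission not below wild-type. The
#' truth table records every planted quantity, including the per-model
#' placement frequencies a weight table should recover.
#'
#' @param scenario a [SyntheticScenario-class] object.
#' @return List with `scenario`, `models` (named list of
#'   [ProfileHMM-class]), `assignments` ([DomainAssignments-class]),
#'   `variants` (validated data.frame), `membership` (named list), and
#'   `truth` (list of planted quantities).
#' @seealso [writeFixtureBundle()]
#' @export
generateScenario <- function(scenario) {
  validObject(scenario)
  s <- scenario
  aa <- aminoAcids()
  bg <- defaultBackground()
  model_ids <- sprintf("SYNM%03d", seq_len(s@n_models))
  driver_model <- seq_len(s@n_models) <= ceiling(s@n_models / 2)
  names(driver_model) <- model_ids

  models <- .withSeed(.subSeed(s@seed, 1L), {
    out <- lapply(model_ids, function(id) {
      conserved <- stats::runif(s@model_length) < 0.5
      em <- t(vapply(conserved,
                     function(cons) .rdirichlet(20L, if (cons) 0.2 else 3.0),
                     numeric(20L)))
      colnames(em) <- aa
      profileHMM(id, em, background = bg, source = "AB_INITIO")
    })
    stats::setNames(out, model_ids)
  })

  protein_ids <- sprintf("SYNP%03d", seq_len(s@n_proteins))
  asg <- .withSeed(.subSeed(s@seed, 2L), {
    model_of <- model_ids[rep_len(seq_len(s@n_models), s@n_proteins)]
    rows <- data.frame(
      protein_id = protein_ids, model_id = model_of,
      e_value = 10^-stats::runif(s@n_proteins, 4, 10),
      seq_start = 1L, hmm_start = 1L,
      ops = strrep("M", s@model_length), stringsAsFactors = FALSE)
    # insignificant decoys: never selected, exercise the e-value filter
    decoy_model <- model_ids[(match(model_of, model_ids) %% s@n_models) + 1L]
    decoys <- data.frame(
      protein_id = protein_ids, model_id = decoy_model,
      e_value = stats::runif(s@n_proteins, 0.05, 1),
      seq_start = 1L, hmm_start = 1L,
      ops = strrep("M", s@model_length), stringsAsFactors = FALSE)
    rbind(rows, decoys)
  })
  model_of_protein <- stats::setNames(
    asg$model_id[seq_len(s@n_proteins)], protein_ids)
  membership <- lapply(stats::setNames(model_ids, model_ids),
                       function(m) protein_ids[model_of_protein == m])

  # eligible columns per model
  driver_cols <- lapply(models, function(m) {
    em <- emissions(m)
    which(apply(em, 1, max) >= 0.3 &
          apply(em, 1, min) <= s@driver_emission_low)
  })
  neutral_cols <- lapply(models, function(m) {
    em <- emissions(m)
    which(apply(em, 1, function(r) sum(r >= s@neutral_emission_high)) >= 2L)
  })
  if (any(vapply(driver_cols, length, integer(1)) == 0L) ||
      any(vapply(neutral_cols, length, integer(1)) == 0L))
    stop("infeasible scenario: a model has no column satisfying the planted emission bounds; increase model_length or relax the bounds", call. = FALSE)

  placement_c <- ifelse(driver_model, 1 + s@cancer_enrichment, 1)
  placement_c <- placement_c / sum(placement_c)
  placement_p <- rep(1 / s@n_models, s@n_models)
  names(placement_p) <- model_ids

  variants <- .withSeed(.subSeed(s@seed, 3L), {
    used <- new.env(parent = emptyenv())
    draw <- function(label) {
      for (attempt in seq_len(200L)) {
        mid <- sample(model_ids, 1L,
                      prob = if (label == "CANCER") placement_c else placement_p)
        prots <- membership[[mid]]
        prot <- prots[sample.int(length(prots), 1L)]
        em <- emissions(models[[mid]])
        if (label == "CANCER") {
          col <- driver_cols[[mid]][sample.int(length(driver_cols[[mid]]), 1L)]
          wt_res <- aa[which.max(em[col, ])]
          muts <- aa[em[col, ] <= s@driver_emission_low]
          muts <- setdiff(muts, wt_res)
          if (!length(muts)) next
          mut_res <- muts[sample.int(length(muts), 1L)]
        } else {
          col <- neutral_cols[[mid]][sample.int(length(neutral_cols[[mid]]), 1L)]
          elig <- aa[em[col, ] >= s@neutral_emission_high]
          pair <- elig[sample.int(length(elig), 2L)]
          pair <- pair[order(em[col, pair])]  # mutant gets the larger emission
          wt_res <- pair[1L]; mut_res <- pair[2L]
        }
        key <- paste(prot, col, wt_res, mut_res, sep = "|")
        if (!is.null(used[[key]])) next
        used[[key]] <- TRUE
        return(data.frame(protein_id = prot, wild_type = wt_res,
                          position = col, mutant = mut_res, label = label,
                          model_id = mid, stringsAsFactors = FALSE))
      }
      stop("infeasible scenario: could not place a distinct variant after 200 attempts; increase model_length or n_proteins", call. = FALSE)
    }
    do.call(rbind, c(
      lapply(seq_len(s@n_variants_per_class), function(i) draw("CANCER")),
      lapply(seq_len(s@n_variants_per_class), function(i) draw("NEUTRAL"))))
  })

  planted_model <- variants$model_id
  variants$model_id <- NULL
  planted_counts <- table(factor(planted_model, levels = model_ids),
                          variants$label)
  truth <- list(
    scenario = list(seed = s@seed, n_models = s@n_models,
                    model_length = s@model_length, n_proteins = s@n_proteins,
                    n_variants_per_class = s@n_variants_per_class,
                    driver_emission_low = s@driver_emission_low,
                    neutral_emission_high = s@neutral_emission_high,
                    cancer_enrichment = s@cancer_enrichment),
    model_ids = model_ids,
    driver_model = as.list(driver_model),
    placement_w_c = as.list(placement_c),
    placement_w_p = as.list(placement_p),
    planted_cancer_count = as.list(stats::setNames(
      as.numeric(planted_counts[, "CANCER"]), model_ids)),
    planted_neutral_count = as.list(stats::setNames(
      as.numeric(planted_counts[, "NEUTRAL"]), model_ids)),
    planted_model = planted_model,
    labels = variants$label)

  list(scenario = s, models = models,
       assignments = domainAssignments(asg, registry = models),
       variants = variantRecords(variants), membership = membership,
       truth = truth)
}

#' Write a generated scenario as a fixture bundle
#'
#' Emits, under `dir`: one HMMER3 ASCII profile per model
#' (`<model_id>.hmm`), `assignments.tsv`, `variants.tsv`,
#' `membership.tsv`, `truth.json`, and a `manifest.json` listing the MD5
#' hash of every written file. The bundle round-trips through the
#' package's readers, and its manifest changes iff any generation
#' parameter changes.
#'
#' @param bundle output of [generateScenario()].
#' @param dir output directory (created if absent).
#' @return The manifest as a named list of MD5 hashes, invisibly.
#' @export
writeFixtureBundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  for (m in bundle$models) {
    f <- file.path(dir, paste0(modelId(m), ".hmm"))
    tryCatch(writeHMMER3Profile(m, f),
             error = function(e) stop(sprintf("writing '%s': %s", f,
                                              conditionMessage(e)), call. = FALSE))
    written <- c(written, f)
  }
  f <- file.path(dir, "assignments.tsv")
  writeDomainAssignments(bundle$assignments, f); written <- c(written, f)
  f <- file.path(dir, "variants.tsv")
  writeVariants(bundle$variants, f); written <- c(written, f)
  f <- file.path(dir, "membership.tsv")
  memb <- data.frame(
    model_id = names(bundle$membership),
    member_protein_ids = vapply(bundle$membership, paste, character(1),
                                collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(memb, f, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, f)
  f <- file.path(dir, "truth.json")
  jsonlite::write_json(bundle$truth, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, f)
  hashes <- as.list(tools::md5sum(written))
  names(hashes) <- basename(written)
  jsonlite::write_json(hashes, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(hashes)
}
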