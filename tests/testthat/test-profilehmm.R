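test_that("HMMER3 profiles round-trip through the writer and reader", {
  set.seed(42)
  em <- t(vapply(1:5, function(i) randComposition(), numeric(20)))
  hmm <- profileHMM("rt_model", em, source = "PFAM_A")
  f <- withr::local_tempfile(fileext = ".hmm")
  writeHMMER3Profile(hmm, f)
  back <- readHMMER3Profile(f, source = "PFAM_A")
  expect_equal(modelId(back), "rt_model")
  expect_equal(modelLength(back), 5L)
  expect_lt(max(abs(emissions(back) - emissions(hmm))), 1e-9)
  expect_lt(max(abs(hmmBackground(back) - hmmBackground(hmm))), 1e-9)
})

test_that("uniform scores ln(20) decode to probability 0.05 each", {
  lines <- c(
    "HMMER3/f [test]",
    "NAME  unif", "LENG  2", "ALPH  amino",
    paste0("HMM          ", paste(aminoAcids(), collapse = "  ")),
    "            m->m     m->i     m->d     i->m     i->i     d->m     d->d",
    paste0("      1   ", paste(rep(sprintf("%.5f", log(20)), 20), collapse = "  "), "  1 - - - -"),
    paste0("          ", paste(rep("2.99573", 20), collapse = "  ")),
    "          0.1 0.1 0.1 0.1 0.1 0.1 0.1",
    paste0("      2   ", paste(rep(sprintf("%.5f", log(20)), 20), collapse = "  "), "  2 - - - -"),
    paste0("          ", paste(rep("2.99573", 20), collapse = "  ")),
    "          0.1 0.1 0.1 0.1 0.1 0.1 0.1",
    "//")
  f <- withr::local_tempfile(fileext = ".hmm")
  writeLines(lines, f)
  hmm <- readHMMER3Profile(f)
  expect_true(all(abs(emissions(hmm) - 0.05) < 1e-6))
})

test_that("degenerate and malformed profiles are rejected", {
  # a score of 0.0 means probability 1.0, leaving nothing for the other 19
  mk <- function(first_score) c(
    "HMMER3/f [test]", "NAME  bad", "LENG  1", "ALPH  amino",
    paste0("HMM          ", paste(aminoAcids(), collapse = "  ")),
    "            m->m     m->i     m->d     i->m     i->i     d->m     d->d",
    paste0("      1   ", paste(c(first_score, rep("2.99573", 19)), collapse = "  "), "  1 - - - -"),
    paste0("          ", paste(rep("2.99573", 20), collapse = "  ")),
    "          0.1 0.1 0.1 0.1 0.1 0.1 0.1",
    "//")
  f <- withr::local_tempfile(fileext = ".hmm")
  writeLines(mk("0.00000"), f)
  expect_error(readHMMER3Profile(f), "sum|> 0|invalid")
  writeLines(mk("NaN"), f)
  expect_error(readHMMER3Profile(f), "unparseable")
  writeLines(c("not a profile", "NAME x"), f)
  expect_error(readHMMER3Profile(f), "HMMER3")
  writeLines(c("HMMER3/f", "NAME  x", "LENG  1"), f)
  expect_error(readHMMER3Profile(f), "malformed")
})

test_that("the format's zero-probability marker parses but fails validity", {
  lines <- c(
    "HMMER3/f [test]", "NAME  star", "LENG  1", "ALPH  amino",
    paste0("HMM          ", paste(aminoAcids(), collapse = "  ")),
    "            m->m     m->i     m->d     i->m     i->i     d->m     d->d",
    paste0("      1   ", paste(c("*", rep(sprintf("%.7f", -log(1/19)), 19)), collapse = "  "), "  1 - - - -"),
    paste0("          ", paste(rep("2.99573", 20), collapse = "  ")),
    "          0.1 0.1 0.1 0.1 0.1 0.1 0.1",
    "//")
  f <- withr::local_tempfile(fileext = ".hmm")
  writeLines(lines, f)
  expect_error(readHMMER3Profile(f), "> 0")
})

test_that("position-to-match-state mapping follows the alignment walk", {
  a <- function(ss, hs, ops) data.frame(
    protein_id = "P", model_id = "m", e_value = 0,
    seq_start = ss, hmm_start = hs, ops = ops, stringsAsFactors = FALSE)
  expect_identical(mapPositionToMatchState(a(10, 1, "MMM"), 11), 2L)
  expect_identical(mapPositionToMatchState(a(10, 1, "MIM"), 11), NA_integer_)
  expect_identical(mapPositionToMatchState(a(10, 4, "MDM"), 11), 6L)
  # outside the aligned span, both sides
  expect_identical(mapPositionToMatchState(a(10, 1, "MMM"), 9), NA_integer_)
  expect_identical(mapPositionToMatchState(a(10, 1, "MMM"), 13), NA_integer_)
})

test_that("mapping agrees with the brute-force column interpreter", {
  set.seed(97)
  for (i in 1:1000) {
    ops <- paste(sample(c("M", "I", "D"), sample(1:12, 1), replace = TRUE),
                 collapse = "")
    ss <- sample(1:20, 1); hs <- sample(1:5, 1)
    pos <- sample(1:35, 1)
    a <- data.frame(protein_id = "P", model_id = "m", e_value = 0,
                    seq_start = ss, hmm_start = hs, ops = ops,
                    stringsAsFactors = FALSE)
    expect_identical(mapPositionToMatchState(a, pos),
                     bruteMapPosition(ss, hs, ops, pos),
                     info = sprintf("ops=%s ss=%d hs=%d pos=%d", ops, ss, hs, pos))
  }
})

test_that("KL information gain matches hand-derived values and properties", {
  bg <- defaultBackground()
  expect_equal(klInformationGain(bg, bg), 0)
  # two-symbol reduction, by hand: 0.5*ln2 + 0.5*ln(2/3)
  expect_equal(klInformationGain(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-4)
  # concentration increases divergence from a uniform background
  u <- stats::setNames(rep(0.05, 20), aminoAcids())
  peak <- function(mass) {
    p <- rep((1 - mass) / 19, 20); p[1] <- mass
    stats::setNames(p, aminoAcids())
  }
  expect_gt(klInformationGain(peak(0.999), u), klInformationGain(peak(0.5), u))
  expect_error(klInformationGain(c(0.5, 0.5), c(0.2, 0.3, 0.5)), "alphabet")
})

test_that("KL is non-negative on random pairs and zero only at equality", {
  set.seed(13)
  for (i in 1:200) {
    p <- randComposition(); q <- randComposition()
    kl <- klInformationGain(p, q)
    expect_gte(kl, 0)
    if (max(abs(p - q)) > 1e-8) expect_gt(kl, 1e-12)
    expect_lt(abs(klInformationGain(p, p)), 1e-12)
  }
})

test_that("model selection filters on e-value and match-state coverage", {
  reg <- toyRegistry()
  asg <- toyAssignments()
  bg <- defaultBackground()
  # P1 position 10 is covered by both models; 'hi' state 1 is far more
  # informative than the background-like 'lo'
  sel <- selectModel(assignmentTable(asg)[1:2, ], 10, reg, bg)
  expect_equal(modelId(sel$model), "hi")
  expect_equal(sel$match_state, 1L)
  # insignificant e-value excludes the only candidate
  asg2 <- assignmentTable(asg)[1, , drop = FALSE]
  asg2$e_value <- 0.02
  expect_null(selectModel(asg2, 10, reg, bg))
  # significant but the residue falls in an insert column
  asg3 <- asg2; asg3$e_value <- 1e-6; asg3$ops <- "IMM"
  expect_null(selectModel(asg3, 10, reg, bg))
  # forced by the max-KL rule regardless of list order
  two <- assignmentTable(asg)[1:2, ]
  expect_equal(modelId(selectModel(two[2:1, ], 10, reg, bg)$model), "hi")
})

test_that("model selection is permutation invariant with documented ties", {
  reg <- toyRegistry()
  set.seed(5)
  asg <- data.frame(
    protein_id = "P1", model_id = sample(c("hi", "lo"), 6, replace = TRUE),
    e_value = round(stats::runif(6, 0, 0.009), 6),
    seq_start = 8L, hmm_start = 1L, ops = "MMM", stringsAsFactors = FALSE)
  base <- selectModel(asg, 9, reg)
  for (i in 1:10) {
    perm <- asg[sample(nrow(asg)), ]
    sel <- selectModel(perm, 9, reg)
    expect_equal(modelId(sel$model), modelId(base$model))
    expect_equal(sel$e_value, base$e_value)
  }
  # exact tie: same model via two assignments -> lower e-value wins
  tie <- data.frame(protein_id = "P1", model_id = "hi",
                    e_value = c(0.005, 0.001), seq_start = 8L, hmm_start = 1L,
                    ops = "MMM", stringsAsFactors = FALSE)
  expect_equal(selectModel(tie, 9, reg)$e_value, 0.001)
})

test_that("assignment span validation catches overruns", {
  reg <- toyRegistry()  # 'hi' has 3 match states
  expect_error(domainAssignments(data.frame(
    protein_id = "P1", model_id = "hi", e_value = 0, seq_start = 1L,
    hmm_start = 2L, ops = "MMM", stringsAsFactors = FALSE), registry = reg),
    "match state")
  expect_error(domainAssignments(data.frame(
    protein_id = "P1", model_id = "hi", e_value = -1, seq_start = 1L,
    hmm_start = 1L, ops = "MMM", stringsAsFactors = FALSE)), "e_value")
})
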