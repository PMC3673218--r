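---
title: "Scoring cancer driver substitutions with weighted profile HMMs"
author: "driverHMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cancer driver substitutions with weighted profile HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driverHMM)
```

## The problem

Tumour genomes accumulate large numbers of missense substitutions, most of
which are passengers: they arise as a by-product of tumorigenesis and have
no effect on tumour progression. Separating the minority of drivers —
substitutions that confer a growth advantage — from passengers and from
ordinary germ-line variation is the classification problem this package
addresses.

The approach rests on two signals. First, *sequence conservation*: a
profile hidden Markov model of a protein family carries, at every match
state, an emission distribution over the 20 amino acids. A substitution
that replaces a residue the family strongly prefers with one it almost
never emits is likely to damage the protein. Second, *disease context*:
some protein families are heavily hit by cancer-associated mutations while
others mostly harbour benign polymorphism, and the same emission ratio
deserves a different interpretation in the two kinds of family.

## The score

For a substitution that maps onto match state $k$ of a model, write $P_w$
and $P_m$ for the emission probabilities of the wild-type and mutant
residues at that state. Each model also carries a pair of pathogenicity
weights: $W_c$, the fraction of all catalogued cancer-associated variants
that map onto this model, and $W_p$, the corresponding fraction of
putatively neutral polymorphisms. The predicted magnitude of effect is

$$
S \;=\; \ln \frac{P_m \,(W_p + \delta)}{P_w \,(W_c + \delta)},
$$

with a pseudo-count $\delta = 1$ added to both weights so that models
with an empty weight row contribute a neutral factor rather than a
division by zero. The score is strictly increasing in $P_m$ and $W_p$ and
strictly decreasing in $P_w$ and $W_c$, and it reduces to the plain
log-ratio $\ln(P_m/P_w)$ whenever $W_c = W_p$ — in particular for any
model absent from the weight table, whose weights default to zero.

A substitution is called cancer-associated when $S \le \tau$ with
$\tau = -0.75$ by default. The boundary is inclusive, so a score exactly
at the threshold is never silently classified as neutral. The default
threshold is the operating point derived on germ-line/somatic benchmark
data and is shipped as a documented constant; `deriveThreshold()` can
refit it on any collection of scored, labelled datasets by maximizing the
summed Youden index (sensitivity + specificity) over a fixed grid.
"Both maximized" does not by itself name an objective; the sum is the
standard scalarization, and the 0.05 grid step is configurable. Grid ties
are resolved toward the median of the tied set, then toward the more
negative value, so the result is deterministic.

## Model selection

A residue is frequently covered by several domain assignments (superfamily
and family models, overlapping hits). An assignment is considered at all
only when it is significant (e-value $\le 0.01$) *and* it places the
residue on a match state — insertions are unscorable. Among the
survivors, the model whose emission vector at the mapped match state has
the largest Kullback–Leibler information gain
$\sum_i p_i \ln (p_i / q_i)$ against the background amino acid
composition is used.

Two choices here were genuinely open:

* **Positional versus model-wide information gain.** The gain could be
  measured at the mapped match state or averaged over the whole model. We
  default to the positional form because the score itself is positional —
  the question is which model is most informative *about this residue* —
  and expose `kl_scope = "model"` for the whole-model mean.
* **Tie-breaking.** Exact KL ties are broken by lower e-value, then
  lexicographic model id, making `selectModel()` invariant to the order
  in which assignments are listed.

The background composition defaults to a SwissProt-like proteome
composition shipped as a plain-text table (`inst/extdata`); any
composition can be substituted. Natural logarithms are used everywhere so
the information gain and the score live on the same scale (nats).

## Pathogenicity weights

Weights are built by routing every variant of a labelled catalogue
through the same model selection used at prediction time and tallying,
per model, the cancer-associated and neutral variants that land on it
(`assignVariantsToModels()`, `computeWeightTable()`). "Relative
frequency" is read as *per-model count over the class total across all
models*, so each class's weights sum to 1; the raw-count alternative is
available as `weight_mode = "raw"` because the phrase does not pin the
normalization down. Duplicate catalogue records are counted once, and a
substitution carrying both labels is a validation error rather than being
arbitrated.

Two further conventions matter for reproducibility:

* The pseudo-count is applied at scoring time ($W + \delta$), never
  folded into the stored table, which therefore remains interpretable as
  frequencies.
* `excludeVariant()`/`includeVariant()` implement exact leave-one-out
  semantics: excluding a variant and rebuilding from scratch give
  field-identical tables, which the tests assert.

Models built ab initio from homologous-sequence alignments have no
curated domain boundaries; their weights aggregate over the member
proteins whose sequences built the model (`weightsForMembership()`),
normalized against the same catalogue-wide totals so the two weighting
routes share a scale. Running the homology search itself is out of scope;
the package starts from the membership table such a search produces.

## Evaluation protocol

`computeMetrics()` reports the six standard performance parameters.
Under the default *normalized* mode the confusion table is first reduced
to per-class rates, and the parameters are computed from the rates, so
accuracy is always the mean of sensitivity and specificity and no metric
depends on class imbalance. This interpretation is pinned down by a
discriminating fixture in the acceptance tests: on one published
driver-versus-passenger confusion table, normalized rates give a
precision of 0.88 where raw counts give 0.89, and only the former matches
the published value. Undefined ratios (zero denominators) propagate as
`NA` markers, never as silent zeros.

`cumulativeROC()` sweeps the threshold from most to least damaging and
accumulates true/false positives, processing tied scores as one block so
the curve is independent of input order; an optional cap truncates the
curve at a false-positive fraction (e.g. 1%) for the conservative-regime
view. Its trapezoidal area on the rate scale equals the Mann–Whitney
concordance, which the tests verify by brute force and against pROC.

`kfoldWeightsCV()` guards against circularity between weight construction
and evaluation: folds are label-stratified and seeded (fold membership is
keyed to a canonical variant ordering, so shuffling the input changes
nothing), each fold is scored against a weight table rebuilt from its
complement only, and `k = n` gives leave-one-out. Whether leave-one-out
should drop only the held-out variant's own count or the whole weight
row of every model it touches is a genuine design choice; we default to
single-variant exclusion and expose `exclusion = "model"` for the
stricter variant. `oddsRatio()` supports the comparison of weighting
schemes, with a flagged Haldane–Anscombe correction for zero cells.

## The synthetic benchmark

Everything above is testable without any external database through
`syntheticScenario()`/`generateScenario()`, which emulate the statistical
structure the method assumes rather than real protein families:

* Match-state emissions are symmetric-Dirichlet draws, half the columns
  with concentration 0.2 (conserved, as in domain models) and half with
  3.0 (diffuse).
* Each synthetic protein gets one significant full-length assignment and
  one insignificant decoy, exercising the e-value filter.
* Cancer variants are planted at conserved columns — wild-type at the
  consensus, mutant with emission $\le$ 0.02 — preferentially on the
  designated driver models (placement weight $1 +$ `cancer_enrichment`,
  default 3, against 1 elsewhere). Neutral variants sit at diffuse
  columns with both alleles at emission $\ge$ 0.04 and the mutant not
  rarer than the wild type.

The reference conditions are seed 7, 4 models of 100 match states, 24
proteins and 500 variants per class; the tests and the acceptance script
run at exactly these sizes (about a thousand predictions, a few seconds).
Each artifact type draws from its own stream derived from the master
seed, so bundles are byte-reproducible and regenerating one artifact does
not perturb the others.

What passing on these fixtures shows — and what it does not: the planted
emission gap makes classes cleanly separable, so end-to-end MCC and AUC
near 1 demonstrate that the plumbing (mapping, selection, weighting,
scoring, thresholding) is correct, not that real drivers are this easy.
Real catalogues add label noise, training/benchmark overlap, shared
domains between classes and recurrence structure, none of which the
generator simulates; published-scale performance is represented in the
package only through the printed confusion tables used as metric
fixtures.

## Numerical conventions and limitations

* Emissions are stored as probabilities; the HMMER3 ASCII reader converts
  the format's negative-natural-log scores, treats `*` (probability
  zero) as a validity error for match emissions, renormalizes the
  round-off left by 5-decimal score printing (deviations up to $10^{-3}$),
  and rejects anything larger. The package's own writer emits 12 decimals
  so fixtures round-trip within $10^{-9}$.
* Coordinates are 1-based and closed, following HMMER convention;
  alignment operation strings use M/I/D with their usual consumption
  semantics.
* Only the 20 standard amino acids are accepted; B/Z/X/U are rejected
  rather than redistributed.
* Scores are carried at full precision and rounded to 2 decimals only in
  report files.
* The package predicts from protein-level substitutions only: no
  transcript mapping, genome coordinates, or consensus with other
  predictors.
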