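---
title: "Network similarity: methods and design notes"
author: "homologNS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network similarity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Sequence similarity identifies homologs but not *functional analogs*:
after lineage-specific duplications, two species may each carry several
co-orthologous genes, and which copy participates in the same biological
process is invisible to alignment. `homologNS` scores functional analogy
from expression data alone, on the premise that genes working in the same
process are co-expressed with the same kinds of partners, and that gene
families provide a species-independent vocabulary ("meta-genes") in which
two species' co-expression neighborhoods can be compared.

# The model, stage by stage

## Bayesian integration into a functional network

Each expression dataset contributes evidence about every gene pair it
measures. Per dataset we compute Pearson correlation over
pairwise-complete samples (pairs with fewer than `minSamples = 3`
complete observations are omitted), Fisher-z transform, and cut the
values at their per-dataset quantiles into `nBins = 5` evidence bins.
Quantile binning makes datasets with very different correlation
distributions comparable; the z-transform spreads the right tail so the
top bins separate strong co-expression. When a dataset has fewer distinct
values than bins, binning degrades to the distinct boundaries available
(with a warning) rather than failing.

Against a gold standard of labeled pairs we estimate per-dataset
class-conditional tables P(bin | FR) and P(bin | not FR) with a Laplace
pseudocount (default 1), guaranteeing positive entries with minimal
distortion. The naive-Bayes posterior for a pair is computed in log
space; a pair measured by no dataset reports the prior, flagged
"no evidence". Posteriors are clipped to (1e-6, 1 - 1e-6) so downstream
log-odds and file round trips are safe. Log-space combination means that
stacking even a thousand uninformative datasets leaves the posterior at
the prior to 1e-9 (asserted in the tests).

The standard itself is built from annotations: positives are pairs
experimentally co-annotated to at least one biologically specific term,
with same-family pairs excluded so the standard cannot leak homology;
negatives are sampled without replacement, seeded, from pairs of genes
occurring in positives, until the positive fraction matches the prior
(default 0.05). If the co-annotation graph is too dense to reach the
prior, construction fails and reports the achievable prior rather than
silently under-sampling. Whether intra-family pairs should also be
barred from the negatives is genuinely open; we exclude only positives
by default and expose `excludeIntraFamily`.

Compendia can optionally be filtered to the datasets that best
recapitulate the standard on their own, scored by the area under the
precision-recall curve restricted to low recall (`recallFraction = 0.1`)
— the regime that matters when most pairs are unrelated. The curve is
evaluated at distinct-score cutoffs so tied scores (ubiquitous after
binning) are treated evenhandedly, and integrated by trapezoid. This
mirrors the practice of dropping datasets that would mostly add
violations of the independence assumption; it is off by default because
small compendia rarely profit, and because scoring selection on the
training standard is mildly optimistic (documented, not corrected).

## Neighborhoods and meta-gene signatures

A gene's neighborhood is every neighbor with posterior at or above
`hardCutoff = 0.5` — the natural probability threshold. Genes with few
confident neighbors would otherwise be unscorable, so a soft floor
(`softMin = 50`) admits the top 50 neighbors by probability (or the whole
degree, if smaller); `softMin = 0` disables it. The floor admits
arbitrarily low probabilities; the minimum admitted probability is
recorded on the object so users can judge. Ties at the boundary break
lexicographically by gene identifier, for determinism. Note the floor is
calibrated to genome-scale networks: on toy networks of under ~100 genes
it swallows most of the genome and saturates every signature, which is
why the package's small test fixtures set `softMin = 0`.

The signature of a neighborhood is the set of families of its retained
members — set semantics, so a family counts once however many members
appear, and genes excluded for multi-family membership or absent from
the family map are dropped (with a logged count).

## The NS score

For two genes from organisms A and B, signatures are restricted to the
organism-pair background: families containing at least one retained,
compendium-present gene in *each* organism. With background size N,
restricted signature sizes K and n, and overlap k, the score is the
exact upper-tail hypergeometric probability P(X ≥ k). An empty
restricted signature yields p = 1 with a "no informative neighborhood"
flag rather than an error, so genome-wide scans do not abort. The
K/n arguments are passed to the kernel in sorted order — the
distribution is symmetric in them, and a canonical order makes
score(a, b) and score(b, a) identical bit for bit.

Within-species scores use the same computation with both signatures from
one network and a single-organism background (families with a retained,
compendium-present gene in that organism). The pairwise rule is defined
only across species; this is our single-organism analog, used to place
paralogs on a common scale in family-wide clusterings, and should be
read as an extension.

Family-wide matrices report -log10 p and a display order from
average-linkage clustering of the similarity matrix converted to a
distance by subtracting from its maximum. No clustering method is
canonical here; average linkage on the transformed score is a
conventional, stable choice, not a claim.

## Evaluation

Homolog-pair standards keep only queries with at least one positive and
one negative candidate — otherwise a ranking is vacuous. Within each
query, candidate ranks are normalized linearly onto [0, 1] (best = 1,
worst = 0; tied scores share the mean of their positions, the unbiased
choice under exchangeability), then pooled across queries. The pooled
AUC is the Mann–Whitney probability that a positive outranks a negative;
significance uses the normal-approximation Mann–Whitney test with tie
correction, with a seeded label-permutation test as an alternative
(`method = "permutation"`). Normalized ranks are invariant to any
strictly monotone rescoring, so the evaluation compares rankings, not
score scales.

Sequence similarity is deliberately an *input* (a pair/score table) —
no single alignment-derived measure is canonical for this purpose, so
the package does not compute one. The combined score is simply the mean
of the two within-query normalized ranks; it can only use candidates
carrying both scores.

# The synthetic benchmark

The generator emulates exactly the structure the method assumes: two
species share 60 families; each gene belongs to one family and one of 6
co-expression modules; module assignments are mirrored across species so
every gene has a cross-species analog. Fifteen families have two members
per species placed in two *different* modules — the duplication pattern
(neuronal vs. broad, in the motivating family) that defeats sequence
comparison. Expression is a latent-profile model: per dataset each
module draws a condition profile, and a gene's value is
`signal * profile[module] + N(0, noiseSd)`, giving within-module
correlation signal² / (signal² + noiseSd²).

Defaults define the package's standard study conditions: 300 genes per
species, 8 datasets × 20 samples, signal 1, noiseSd 0.5 (within-module r
≈ 0.8 — strong but realistic for genes in one tightly co-regulated
process), annotation fraction 0.8, and 4 specific terms per module.
Terms are module-derived so that co-annotation mirrors module
co-membership; splitting each module into several terms keeps the
co-annotation graph sparse enough that the 0.05 standard prior is
achievable (with one term per module the achievable prior would be about
the reciprocal of the module count). Module labels double as binary
tissue attributes, so both the attribute-based and the GO-based
evaluation standards are exercised by one generator. An annotation-bias
corruptor concentrates records on one member per family, emulating the
literature's uneven study of close homologs, for robustness tests.

What the generator does **not** emulate: probe effects, batch structure,
heavy-tailed noise, varying module sizes per dataset, partially
overlapping gene coverage, or families whose members span only some
species. Passing the end-to-end tests therefore shows the machinery is
correct and well calibrated under the model's own assumptions — not that
any particular real compendium will reach the same accuracy.

Problem sizes in the test suite were chosen to exercise the defaults
honestly while keeping the suite quick: the end-to-end recovery check
runs the full default spec over 20 generator seeds; unit fixtures use a
2 × 90-gene spec (with `softMin = 0` and a 0.1 standard prior, as
explained above).

# Numerical and degenerate-input choices

- Hypergeometric tails come from the exact `phyper` upper tail (log-space
  capable); the test suite checks it against full enumeration of all
  draws for every parameter combination with N ≤ 12, to 1e-12.
- Edge files are canonical (lexicographically smaller gene first),
  probabilities written with full precision, so write/read is the
  identity.
- Missing expression values: "NA" and empty cells, plus any non-numeric
  cell, become missing; correlations use pairwise-complete samples.
- Gene identifiers are opaque, case-sensitive strings; joins across
  files are exact-match. No identifier mapping is attempted.
- All stochastic steps (negative sampling, permutation tests, the
  generator) take explicit seeds; a single base seed is fanned out to
  stage-specific child seeds so stages stay reproducible independently.
- Empty enrichment universes return empty result frames; terms with no
  annotated background family are skipped (the test is undefined).
  Ontology propagation is off by default — the specific-term slice is
  assumed already curated — and co-annotation is matched literally.

# Known limitations

- Naive Bayes ignores dataset dependence; the top-k selection mitigates
  but does not model it.
- The GO-derived evaluation inherits annotation bias: homologs studied
  unequally can make a correct ranking look wrong. The bias corruptor
  exists precisely to probe this.
- The within-species score and the clustering display are pragmatic
  extensions; only the cross-species score has the background rule's
  full justification.
- The soft cutoff trades calibration for coverage; scores produced under
  it (flagged on the object) sit on a slightly different scale than
  hard-cutoff scores.
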