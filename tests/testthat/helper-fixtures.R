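# Shared fixtures and independent oracles, built in code at test time.

# Brute-force upper-tail hypergeometric by enumerating all C(N, n) draws
# from an urn with K marked items; independent of stats::phyper.
enumHyperTail <- function(k, K, n, N) {
  draws <- combn(seq_len(N), n)
  mean(colSums(draws <= K) >= k)
}

# A small family map: two organisms, three families, one multi-family gene.
tinyFamilyMap <- function() {
  FamilyMap(
    gene = c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4"),
    organism = rep(c("orgA", "orgB"), each = 4),
    family = c("F1", "F1", "F2", "F3", "F1", "F2", "F2", "F3"))
}

# A hand-written network: star around the query plus extras.
starNetwork <- function(probs, query = "q", organism = "orgA",
                        prior = 0.05) {
  nb <- names(probs)
  FunctionalNetwork(gene1 = rep(query, length(probs)), gene2 = nb,
                    prob = unname(probs), organism = organism,
                    prior = prior)
}

# Uniform conditional tables: evidence carrying no information.
uniformCpt <- function(nBins = 5L, id = "d") {
  new("ConditionalTable", datasetId = id,
      pPos = rep(1 / nBins, nBins), pNeg = rep(1 / nBins, nBins),
      pseudocount = 0)
}

# Evidence placing a single pair in a given bin.
singlePairEvidence <- function(bin, nBins = 5L, id = "d",
                               pair = c("g1", "g2")) {
  new("DatasetEvidence", datasetId = id,
      pairs = data.frame(gene1 = min(pair), gene2 = max(pair),
                         bin = as.integer(bin), stringsAsFactors = FALSE),
      nBins = as.integer(nBins), breaks = numeric(),
      coverage = sort(pair))
}

# Conditional table with explicit likelihoods for that bin.
explicitCpt <- function(pPosBin, pNegBin, bin = 1L, nBins = 5L, id = "d") {
  pPos <- rep((1 - pPosBin) / (nBins - 1), nBins); pPos[bin] <- pPosBin
  pNeg <- rep((1 - pNegBin) / (nBins - 1), nBins); pNeg[bin] <- pNegBin
  new("ConditionalTable", datasetId = id, pPos = pPos, pNeg = pNeg,
      pseudocount = 0)
}

# Small synthetic spec for fast pipeline tests.
smallSpec <- function(seed = 1L, ...) {
  # at this scale the co-annotation graph is too dense for a 0.05 prior,
  # so small-fixture tests pair it with an integration prior of 0.1
  syntheticSpec(nGenes = 90L, nFamilies = 15L, nModules = 3L,
                nDuplicationFamilies = 3L, nDatasets = 4L, nSamples = 15L,
                termsPerModule = 12L, seed = seed, ...)
}
smallPrior <- 0.1

expect_silent_valid <- function(object) {
  expect_true(isTRUE(validObject(object, test = TRUE)))
}
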