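test_that("pairwise correlation matches the textbook formula", {
  mat <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 5, 9),
               g3 = c(1, 2, 3, 4), g4 = c(4, 3, 2, 1))
  ds <- ExpressionDataset(mat, "d")
  co <- correlateDataset(ds)
  lookup <- function(a, b)
    co$cor[co$gene1 == min(a, b) & co$gene2 == max(a, b)]
  # independent oracle: explicit sums
  x <- mat["g1", ]; y <- mat["g2", ]
  rOracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(lookup("g1", "g2"), rOracle, tolerance = 1e-12)
  expect_equal(rOracle, 11 / sqrt(130))
  expect_equal(lookup("g1", "g3"), 1)    # identical rows
  expect_equal(lookup("g1", "g4"), -1)   # anti-parallel rows

  expect_error(correlateDataset(ExpressionDataset(mat[, 1:2], "d2")),
               "samples")
})

test_that("pairs with too few complete observations are omitted", {
  mat <- rbind(g1 = c(1, 2, 3, 4, 5), g2 = c(2, 1, 4, NA, NA),
               g3 = c(NA, NA, NA, 1, 2))
  ds <- ExpressionDataset(mat, "d")
  co <- correlateDataset(ds, minSamples = 3L)
  keys <- paste(co$gene1, co$gene2)
  expect_true("g1 g2" %in% keys)    # 3 complete samples
  expect_false("g1 g3" %in% keys)   # only 2
  expect_false("g2 g3" %in% keys)   # 0 complete
})

test_that("quantile discretization fills bins evenly and degrades sanely", {
  pairFrame <- function(r) data.frame(
    gene1 = sprintf("a%03d", seq_along(r)),
    gene2 = sprintf("b%03d", seq_along(r)), cor = r)
  ev <- discretize(pairFrame(seq(-0.9, 0.9, length.out = 100)), nBins = 5)
  counts <- tabulate(ev@pairs$bin, 5)
  expect_true(all(abs(counts - 20) <= 1))

  # explicit median split of 0.1 ... 1.0 into 2 bins
  ev2 <- discretize(pairFrame(seq(0.1, 1.0, by = 0.1)), nBins = 2)
  expect_identical(ev2@pairs$bin[1:5], rep(1L, 5))
  expect_identical(ev2@pairs$bin[6:10], rep(2L, 5))

  expect_warning(evc <- discretize(pairFrame(rep(0.5, 10)), nBins = 5),
                 "single")
  expect_identical(unique(evc@pairs$bin), 1L)
  expect_identical(evc@nBins, 1L)

  expect_warning(discretize(pairFrame(rep(c(0.1, 0.9), 10)), nBins = 5),
                 "degraded")
})

test_that("conditional tables smooth counts as (c + pc) / (total + pc * B)", {
  ev <- new("DatasetEvidence", datasetId = "d",
            pairs = data.frame(gene1 = c("a", "c", "e", "g"),
                               gene2 = c("b", "d", "f", "h"),
                               bin = c(2L, 2L, 1L, 3L)),
            nBins = 3L, breaks = numeric(),
            coverage = letters[1:8])
  std <- new("PairStandard",
             positives = data.frame(gene1 = c("a", "c"),
                                    gene2 = c("b", "d")),
             negatives = data.frame(gene1 = c("e", "g"),
                                    gene2 = c("f", "h")),
             prior = 0.5)
  # no smoothing: positives all in bin 2 of 3
  cpt0 <- suppressWarnings(learnCpt(ev, std, pseudocount = 0))
  expect_equal(cpt0@pPos, c(0, 1, 0))
  # Laplace: counts (1, 0, 1) for negatives -> (2, 1, 2) / 5
  cpt1 <- learnCpt(ev, std, pseudocount = 1)
  expect_equal(cpt1@pNeg, c(2, 1, 2) / 5)
  expect_true(all(cpt1@pPos > 0))
  expect_equal(sum(cpt1@pPos), 1)

  # counts (1,1) over 2 bins with pseudocount 1 -> (0.5, 0.5)
  ev2 <- new("DatasetEvidence", datasetId = "d2",
             pairs = data.frame(gene1 = c("a", "c", "e"),
                                gene2 = c("b", "d", "f"),
                                bin = c(1L, 2L, 1L)),
             nBins = 2L, breaks = numeric(), coverage = letters[1:6])
  cpt2 <- learnCpt(ev2, std, pseudocount = 1)
  expect_equal(cpt2@pPos, c(0.5, 0.5))

  noOverlap <- new("PairStandard",
                   positives = data.frame(gene1 = "x", gene2 = "y"),
                   negatives = data.frame(gene1 = "x", gene2 = "z"),
                   prior = 0.5)
  expect_error(learnCpt(ev, noOverlap), "d")
})

test_that("naive-Bayes posterior reproduces hand-computed values", {
  prior <- 0.05
  # uninformative evidence: posterior == prior
  evs <- list(singlePairEvidence(3L))
  expect_equal(as.numeric(
    posteriorProbability(c("g1", "g2"), evs, list(uniformCpt()), prior)),
    prior, tolerance = 1e-12)

  # one dataset, P(b|+) = 0.6, P(b|-) = 0.2:
  # 0.05 * 0.6 / (0.05 * 0.6 + 0.95 * 0.2) = 0.1363636...
  cpt <- explicitCpt(0.6, 0.2, bin = 1L)
  ev <- singlePairEvidence(1L)
  expect_equal(as.numeric(
    posteriorProbability(c("g1", "g2"), list(ev), list(cpt), prior)),
    0.05 * 0.6 / (0.05 * 0.6 + 0.95 * 0.2), tolerance = 1e-9)

  # two identical datasets: squared likelihood ratio
  expect_equal(as.numeric(
    posteriorProbability(c("g1", "g2"), list(ev, ev), list(cpt, cpt),
                         prior)),
    0.05 * 0.36 / (0.05 * 0.36 + 0.95 * 0.04), tolerance = 1e-9)

  # uncovered pair: prior, flagged
  out <- posteriorProbability(c("u", "v"), list(ev), list(cpt), prior)
  expect_equal(as.numeric(out), prior)
  expect_true(attr(out, "noEvidence"))
})

test_that("posterior is order-invariant and monotone in a likelihood ratio", {
  prior <- 0.05
  cptA <- explicitCpt(0.5, 0.25, bin = 2L, id = "a")
  cptB <- explicitCpt(0.3, 0.15, bin = 4L, id = "b")
  evA <- singlePairEvidence(2L, id = "a")
  evB <- singlePairEvidence(4L, id = "b")
  p1 <- posteriorProbability(c("g1", "g2"), list(evA, evB),
                             list(cptA, cptB), prior)
  p2 <- posteriorProbability(c("g1", "g2"), list(evB, evA),
                             list(cptB, cptA), prior)
  expect_equal(as.numeric(p1), as.numeric(p2), tolerance = 1e-15)

  # raising one dataset's likelihood ratio raises the posterior
  ratios <- seq(0.1, 0.9, by = 0.1)
  post <- vapply(ratios, function(r) as.numeric(
    posteriorProbability(c("g1", "g2"), list(evA, evB),
                         list(explicitCpt(r, 0.2, bin = 2L), cptB),
                         prior)), 0)
  expect_true(all(diff(post) > 0))
})

test_that("log-space integration survives 1000 uninformative datasets", {
  prior <- 0.05
  evs <- rep(list(singlePairEvidence(1L)), 1000L)
  cpts <- rep(list(uniformCpt()), 1000L)
  p <- as.numeric(posteriorProbability(c("g1", "g2"), evs, cpts, prior))
  expect_equal(p, prior, tolerance = 1e-9)
})

test_that("dataset selection scores partial precision-recall area", {
  nPos <- 40L; nNeg <- 160L
  std <- new("PairStandard",
             positives = data.frame(gene1 = sprintf("p%03da", 1:nPos),
                                    gene2 = sprintf("p%03db", 1:nPos)),
             negatives = data.frame(gene1 = sprintf("n%03da", 1:nNeg),
                                    gene2 = sprintf("n%03db", 1:nNeg)),
             prior = 0.2)
  mkEvidence <- function(bins, id) {
    df <- rbind(positives(std), negatives(std))
    df$bin <- bins
    new("DatasetEvidence", datasetId = id, pairs = df, nBins = 2L,
        breaks = numeric(), coverage = unique(c(df$gene1, df$gene2)))
  }
  # perfectly separating dataset: all positives in the high-LR bin
  evPerfect <- mkEvidence(rep(c(2L, 1L), c(nPos, nNeg)), "perfect")
  cpt <- explicitCpt(0.9, 0.1, bin = 2L, nBins = 2L)
  selPerfect <- selectTopDatasets(list(evPerfect), list(cpt), std, k = 1,
                                  recallFraction = 0.1)
  expect_equal(unname(selPerfect$scores["perfect"]), 0.1,
               tolerance = 1e-12)

  # random dataset: precision ~ prior, partial area ~ prior * recallFraction
  set.seed(11)
  evRandom <- mkEvidence(sample(rep(c(2L, 1L), c(100L, 100L))), "random")
  selRandom <- selectTopDatasets(list(evRandom), list(cpt), std, k = 1,
                                 recallFraction = 0.5)
  expect_lt(abs(unname(selRandom$scores["random"]) - 0.2 * 0.5), 0.06)

  expect_warning(
    sel <- selectTopDatasets(list(evPerfect, evRandom), list(cpt, cpt),
                             std, k = 5),
    "fewer")
  expect_length(sel$selected, 2L)
  expect_identical(sel$selected[1L], 1L)  # perfect ranks first
})

test_that("uninformative data yields a network of near-prior posteriors", {
  # pure-noise expression: the learned class-conditional bin tables are
  # close to uniform, so no pair should earn a confident posterior
  set.seed(3)
  mat <- matrix(rnorm(30 * 12), 30, 12,
                dimnames = list(sprintf("g%02d", 1:30), NULL))
  ds <- ExpressionDataset(mat, "flat")
  genes <- rownames(mat)
  pos <- data.frame(gene1 = genes[1:10], gene2 = genes[11:20],
                    stringsAsFactors = FALSE)
  neg <- data.frame(gene1 = genes[1:10], gene2 = genes[21:30],
                    stringsAsFactors = FALSE)
  std <- new("PairStandard", positives = pos, negatives = neg,
             prior = 0.5)
  net <- integrateCompendium(list(ds), std, prior = 0.05)
  expect_lt(max(edges(net)$prob), 0.5)
  expect_lt(abs(median(edges(net)$prob) - 0.05), 0.05)

  expect_error(integrateCompendium(list(), std), "empty")
  # a standard that never overlaps the compendium fails during learning
  strayStd <- new("PairStandard",
                  positives = data.frame(gene1 = "x1", gene2 = "x2"),
                  negatives = data.frame(gene1 = "x1", gene2 = "x3"),
                  prior = 0.5)
  expect_error(integrateCompendium(list(ds), strayStd), "overlap")
})

test_that("planted modules separate within- from between-module posteriors", {
  data <- generateSynthetic(smallSpec(seed = 5))
  fm <- data$familyMap
  org <- "speciesA"
  std <- buildIntegrationStandard(data$annotations[[org]], fm,
                                  prior = smallPrior, seed = 99)
  net <- integrateCompendium(data$compendia[[org]], std, organism = org)
  e <- edges(net)
  mods <- data$groundTruth@modules
  same <- mods[e$gene1] == mods[e$gene2]
  expect_gt(mean(e$prob[same]), mean(e$prob[!same]))
  expect_gt(mean(e$prob[same]), 0.5)
  expect_lt(mean(e$prob[!same]), 0.1)
})
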