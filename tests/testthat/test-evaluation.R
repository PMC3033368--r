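test_that("within-query rank normalization maps scores onto [0, 1]", {
  expect_equal(normalizeQueryRanks(c(0.9, 0.1)), c(1, 0))
  expect_equal(normalizeQueryRanks(c(0.2, 0.9, 0.5)), c(0, 1, 0.5))
  # tied scores share the mean of their positions (mean of both orderings)
  expect_equal(normalizeQueryRanks(c(0.4, 0.4)), c(0.5, 0.5))
  expect_equal(normalizeQueryRanks(c(0.4, 0.4, 0.9)), c(0.25, 0.25, 1))
  expect_error(normalizeQueryRanks(0.5), "two candidates")
  # invariance to strictly monotone transforms
  set.seed(8)
  s <- rnorm(20)
  expect_equal(normalizeQueryRanks(s), normalizeQueryRanks(exp(s)))
  expect_equal(normalizeQueryRanks(s), normalizeQueryRanks(rank(s)))
})

test_that("pooled AUC separates perfect, inverted and mixed rankings", {
  rkCorrect <- HomologRanking("q1", c("c1", "c2"), c(0.9, 0.1),
                              c("positive", "negative"))
  rkInverted <- HomologRanking("q2", c("c3", "c4"), c(0.2, 0.7),
                               c("positive", "negative"))
  perfect <- pooledAuc(list(rkCorrect, rkCorrect))
  expect_equal(auc(perfect), 1)
  expect_lt(pValue(perfect), 0.2)

  # one correct + one inverted query: ranks pos {1, 0} vs neg {0, 1};
  # the U statistic counts 1 win, 1 loss, 2 ties -> AUC exactly 0.5
  mixed <- pooledAuc(list(rkCorrect, rkInverted))
  expect_identical(auc(mixed), 0.5)

  # AUC(reversed scores) = 1 - AUC(scores)
  flip <- function(rk) HomologRanking(rk@query, rk@candidates$gene,
                                      -rk@candidates$score,
                                      rk@candidates$label)
  rks <- list(rkCorrect, rkInverted, rkCorrect)
  expect_equal(auc(pooledAuc(lapply(rks, flip))),
               1 - auc(pooledAuc(rks)))

  expect_error(pooledAuc(list()), "no rankings")
})

test_that("pooled AUC is calibrated at 0.5 under label permutation", {
  set.seed(314)
  rankings <- lapply(seq_len(1000L), function(i) {
    m <- sample(2:5, 1L)
    labels <- c("positive", "negative",
                sample(c("positive", "negative"), m - 2L, replace = TRUE))
    HomologRanking(paste0("q", i), paste0("c", seq_len(m)), rnorm(m),
                   sample(labels))
  })
  res <- pooledAuc(rankings)
  expect_lt(abs(auc(res) - 0.5), 0.02)
  expect_gt(pValue(res), 0.01)

  # the seeded permutation null agrees
  resPerm <- pooledAuc(rankings[1:50], method = "permutation",
                       nPerm = 200L, seed = 5L)
  expect_gt(pValue(resPerm), 0.05)
  expect_identical(pValue(resPerm),
                   pValue(pooledAuc(rankings[1:50],
                                    method = "permutation",
                                    nPerm = 200L, seed = 5L)))
})

test_that("combined rank scores average the two normalized ranks", {
  ns <- c(c1 = 5, c2 = 3, c3 = 1)
  sq <- c(c1 = 100, c2 = 40, c3 = 70)
  comb <- combinedRankScore(ns, sq)
  expect_equal(unname(comb["c1"]), 1)          # best under both
  expect_equal(unname(comb["c2"]), 0.25)       # ranks 0.5 and 0
  expect_equal(unname(comb["c3"]), 0.25)       # ranks 0 and 0.5
  expect_warning(combinedRankScore(ns, sq[1:2]), "excluded")
})

test_that("complementary errors are rescued by the combined score", {
  # two queries; the network score misranks a decoy for q2, the sequence
  # score misranks a different decoy for q1; the average rank fixes both
  std <- new("HomologPairStandard", entries = data.frame(
    query = rep(c("q1", "q2"), each = 3),
    candidate = c("a", "b", "c", "d", "e", "f"),
    label = c("positive", "negative", "negative",
              "positive", "negative", "negative")),
    orgPair = c("orgA", "orgB"))
  netScores <- data.frame(query = rep(c("q1", "q2"), each = 3),
                          candidate = c("a", "b", "c", "d", "e", "f"),
                          score = c(0.9, 0.5, 0.1, 0.6, 0.9, 0.1))
  seqScores <- data.frame(query = rep(c("q1", "q2"), each = 3),
                          candidate = c("a", "b", "c", "d", "e", "f"),
                          score = c(0.6, 0.2, 0.9, 0.9, 0.2, 0.4))
  ev <- evaluateRanking(std, netScores, seqScores)
  aucOf <- function(src) ev$table$auc[ev$table$source == src]
  expect_gte(aucOf("combined"), max(aucOf("network"), aucOf("sequence")))
  expect_equal(aucOf("combined"), 1)
})

test_that("evaluation applies the one-positive-one-negative filter", {
  # q2 has no negative: dropped; an empty standard only warns
  std <- new("HomologPairStandard", entries = data.frame(
    query = c("q1", "q1", "q2", "q2"),
    candidate = c("a", "b", "c", "d"),
    label = c("positive", "negative", "positive", "negative")),
    orgPair = c("orgA", "orgB"))
  scores <- data.frame(query = c("q1", "q1", "q2"),
                       candidate = c("a", "b", "c"),
                       score = c(1, 0, 1))
  ev <- suppressWarnings(evaluateRanking(std, scores))
  expect_identical(ev$results$network@nQueries, 1L)
  expect_equal(ev$table$auc, 1)

  emptyStd <- new("HomologPairStandard",
                  entries = data.frame(query = character(),
                                       candidate = character(),
                                       label = character()),
                  orgPair = c("orgA", "orgB"))
  expect_warning(evEmpty <- evaluateRanking(emptyStd, scores), "empty")
  expect_identical(nrow(evEmpty$table), 0L)
})

test_that("a ground-truth scorer attains AUC 1 on the synthetic standard", {
  data <- generateSynthetic(smallSpec(seed = 2))
  std <- groundTruthStandard(data$groundTruth, data$spec)
  df <- standardEntries(std)
  oracle <- data.frame(query = df$query, candidate = df$candidate,
                       score = ifelse(df$label == "positive", 1, 0))
  ev <- evaluateRanking(std, oracle)
  expect_equal(ev$table$auc, 1)
})

test_that("noisier compendia never rank analogs better (trend over seeds)", {
  aucAt <- function(noise) {
    mean(vapply(1:2, function(s) {
      # hard cutoff only: at this scale a soft floor of 50 would swallow
      # most of the genome and saturate every signature
      b <- suppressWarnings(suppressMessages(runSyntheticBenchmark(
        smallSpec(seed = s, noiseSd = noise), prior = smallPrior,
        softMin = 0L)))
      auc(b$auc)
    }, 0))
  }
  low <- aucAt(0.3); high <- aucAt(3)
  expect_gt(low, high)
  expect_gt(low, 0.9)
})
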