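test_that("hypergeometric tail matches full enumeration for all N <= 12", {
  for (N in 2:12) {
    for (n in 1:N) {
      draws <- combn(seq_len(N), n)
      for (K in 0:N) {
        marked <- colSums(draws <= K)
        for (k in 0:min(K, n)) {
          expect_equal(hypergeomTail(k, K, n, N), mean(marked >= k),
                       tolerance = 1e-12,
                       label = sprintf("tail(k=%d,K=%d,n=%d,N=%d)",
                                       k, K, n, N))
        }
      }
    }
  }
})

test_that("hypergeometric tail worked case and edge cases", {
  # C(4,3)C(6,2) + C(4,4)C(6,1) over C(10,5) = 66/252
  expect_equal(hypergeomTail(3, 4, 5, 10), 66 / 252, tolerance = 1e-12)
  expect_equal(hypergeomTail(0, 4, 5, 10), 1)
  # containment forces maximal overlap
  expect_equal(hypergeomTail(3, 5, 3, 5), 1)
  expect_error(hypergeomTail(4, 3, 5, 10), "invalid")
  expect_error(hypergeomTail(2, 3, 5, 4), "invalid")
  # non-increasing in k for fixed (N, K, n)
  tails <- hypergeomTail(0:5, 7, 5, 20)
  expect_true(all(diff(tails) < 0))
  # log-space path agrees
  expect_equal(exp(hypergeomTail(3, 4, 5, 10, logP = TRUE)), 66 / 252,
               tolerance = 1e-12)
})

# Two-organism fixture with controllable neighborhood family content:
# each family Fxx has one gene per organism; the query genes a_q / b_q
# connect (p = 0.9) to exactly the member genes of the families we want
# in their signatures.
signatureFixture <- function(famsA, famsB, allFams) {
  fm <- FamilyMap(
    gene = c(paste0("a_", allFams), paste0("b_", allFams), "a_q", "b_q"),
    organism = rep(c("orgA", "orgB", "orgA", "orgB"),
                   c(length(allFams), length(allFams), 1L, 1L)),
    family = c(allFams, allFams, "FQA", "FQB"))
  netA <- starNetwork(setNames(rep(0.9, length(famsA)),
                               paste0("a_", famsA)), query = "a_q",
                      organism = "orgA")
  netB <- starNetwork(setNames(rep(0.9, length(famsB)),
                               paste0("b_", famsB)), query = "b_q",
                      organism = "orgB")
  bg <- new("BackgroundSet", orgPair = c("orgA", "orgB"),
            families = allFams)
  list(fm = fm, netA = netA, netB = netB, bg = bg)
}

test_that("NS score counts background-restricted signature overlap", {
  allFams <- sprintf("F%02d", 1:20)
  fx <- signatureFixture(allFams[1:8], allFams[5:12], allFams)
  res <- nsScore("a_q", "b_q", fx$netA, fx$netB, fx$fm, fx$bg,
                 softMin = 0)
  expect_identical(res@k, 4L)
  expect_identical(res@K, 8L)
  expect_identical(res@n, 8L)
  expect_identical(res@N, 20L)
  expect_identical(sharedFamilies(res), sprintf("F%02d", 5:8))
  expect_identical(res@onlyA, sprintf("F%02d", 1:4))
  expect_identical(res@onlyB, sprintf("F%02d", 9:12))
  expect_equal(pValue(res), hypergeomTail(4, 8, 8, 20))

  # disjoint signatures: k = 0, p = 1
  fxD <- signatureFixture(allFams[1:6], allFams[7:12], allFams)
  resD <- nsScore("a_q", "b_q", fxD$netA, fxD$netB, fxD$fm, fxD$bg,
                  softMin = 0)
  expect_identical(resD@k, 0L)
  expect_equal(pValue(resD), 1)

  # identical signatures: minimal p among overlaps with the same (K, n, N)
  fxI <- signatureFixture(allFams[1:8], allFams[1:8], allFams)
  resI <- nsScore("a_q", "b_q", fxI$netA, fxI$netB, fxI$fm, fxI$bg,
                  softMin = 0)
  expect_identical(resI@k, 8L)
  expect_lt(pValue(resI), pValue(res))
  ps <- hypergeomTail(0:8, 8, 8, 20)
  expect_equal(pValue(resI), min(ps))
})

test_that("NS score is exactly symmetric and flags empty signatures", {
  allFams <- sprintf("F%02d", 1:15)
  fx <- signatureFixture(allFams[1:9], allFams[4:11], allFams)
  ab <- nsScore("a_q", "b_q", fx$netA, fx$netB, fx$fm, fx$bg, softMin = 0)
  ba <- nsScore("b_q", "a_q", fx$netB, fx$netA, fx$fm, fx$bg, softMin = 0)
  expect_identical(pValue(ab), pValue(ba))
  expect_identical(ab@k, ba@k)

  # neighborhood entirely outside the background: flagged, p = 1
  bgSmall <- new("BackgroundSet", orgPair = c("orgA", "orgB"),
                 families = allFams[12:15])
  resE <- nsScore("a_q", "b_q", fx$netA, fx$netB, fx$fm, bgSmall,
                  softMin = 0)
  expect_true(resE@noInformative)
  expect_equal(pValue(resE), 1)
})

test_that("p is monotone in N for fixed overlap and signature sizes", {
  # while N <= K + n - k the overlap is forced and p stays 1; beyond that
  # the same overlap grows ever more surprising as the urn expands
  ps <- vapply(30:120, function(N) hypergeomTail(10, 20, 25, N), 0)
  expect_true(all(diff(ps) <= 0))
  expect_equal(ps[1:6], rep(1, 6))         # N <= 35 forces k >= 10
  strict <- vapply(36:120, function(N) hypergeomTail(10, 20, 25, N), 0)
  expect_true(all(diff(strict) < 0))
})

test_that("within-species NS treats a gene as its own perfect analog", {
  fams <- sprintf("F%02d", 1:12)
  fm <- FamilyMap(gene = c(paste0("a_", fams), "q1", "q2"),
                  organism = "orgA",
                  family = c(fams, "FQ1", "FQ2"))
  members <- setNames(rep(0.8, 6), paste0("a_", fams[1:6]))
  net <- FunctionalNetwork(
    gene1 = c(rep("q1", 6), rep("q2", 6)),
    gene2 = rep(names(members), 2),
    prob = rep(0.8, 12), organism = "orgA")
  bg <- new("BackgroundSet", orgPair = "orgA", families = fams)
  self <- withinSpeciesNs("q1", "q1", net, fm, bg, softMin = 0)
  expect_identical(self@k, self@K)
  expect_equal(pValue(self), hypergeomTail(6, 6, 6, 12))
  twin <- withinSpeciesNs("q1", "q2", net, fm, bg, softMin = 0)
  expect_identical(pValue(twin), pValue(self))
})

test_that("overlap decomposition partitions families with annotations", {
  allFams <- sprintf("F%02d", 1:20)
  # two queries overlapping disjoint regions of a third signature
  fx1 <- signatureFixture(allFams[1:10], allFams[1:5], allFams)
  fx2 <- signatureFixture(allFams[1:10], allFams[6:10], allFams)
  r1 <- nsScore("a_q", "b_q", fx1$netA, fx1$netB, fx1$fm, fx1$bg,
                softMin = 0)
  r2 <- nsScore("a_q", "b_q", fx2$netA, fx2$netB, fx2$fm, fx2$bg,
                softMin = 0)
  expect_length(intersect(sharedFamilies(r1), sharedFamilies(r2)), 0L)

  fa <- new("FamilyAnnotation",
            annotations = data.frame(family = c("F01", "F01", "F03"),
                                     term = c("T1", "T2", "T1")))
  dec <- overlapDecomposition(r1, fa)
  expect_setequal(dec$shared$family, allFams[1:5])
  expect_setequal(dec$onlyA$family, allFams[6:10])
  expect_identical(nrow(dec$onlyB), 0L)
  expect_identical(dec$shared$terms[dec$shared$family == "F01"], "T1,T2")

  # identical signatures leave nothing exclusive
  fxI <- signatureFixture(allFams[1:5], allFams[1:5], allFams)
  rI <- nsScore("a_q", "b_q", fxI$netA, fxI$netB, fxI$fm, fxI$bg,
                softMin = 0)
  decI <- overlapDecomposition(rI, fa)
  expect_identical(nrow(decI$onlyA), 0L)
  expect_identical(nrow(decI$onlyB), 0L)
})

test_that("family NS matrices are symmetric and errors name the gene", {
  allFams <- sprintf("F%02d", 1:20)
  fx <- signatureFixture(allFams[1:8], allFams[3:10], allFams)
  backgrounds <- list("orgA|orgB" = fx$bg,
                      orgA = new("BackgroundSet", orgPair = "orgA",
                                 families = allFams),
                      orgB = new("BackgroundSet", orgPair = "orgB",
                                 families = allFams))
  m <- familyNsMatrix(c("a_q", "b_q"), c("orgA", "orgB"),
                      list(orgA = fx$netA, orgB = fx$netB), fx$fm,
                      backgrounds, softMin = 0)
  s <- scoreMatrix(m)
  expect_identical(dim(s), c(2L, 2L))
  expect_equal(s["a_q", "b_q"], s["b_q", "a_q"])
  expect_equal(s["a_q", "b_q"],
               -log10(hypergeomTail(6, 8, 8, 20)))
  expect_true(all(is.na(diag(s))))

  expect_error(
    familyNsMatrix(c("a_q", "ghost"), c("orgA", "orgB"),
                   list(orgA = fx$netA, orgB = fx$netB), fx$fm,
                   backgrounds), "ghost")
})
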