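#' @include AllClasses.R utils.R neighborhoods.R
NULL

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` marked items when `n` items are drawn without replacement from
#' an urn of `N` items of which `K` are marked. Computed exactly (in log
#' space when `logP = TRUE`).
#'
#' @param k observed overlap, `0 <= k <= min(K, n)`.
#' @param K number of marked items.
#' @param n number of draws.
#' @param N urn size; `K <= N`, `n <= N`.
#' @param logP return the natural log of the tail probability.
#' @return the tail probability (vectorized over its arguments).
#' @export
hypergeomTail <- function(k, K, n, N, logP = FALSE) {
  bad <- k < 0 | K < 0 | n < 0 | K > N | n > N | k > pmin(K, n)
  if (any(bad))
    stop("invalid hypergeometric parameters: need 0 <= k <= min(K,n) and K,n <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = logP)
}

.nsFromSignatures <- function(geneA, geneB, sigA, sigB, background) {
  bg <- families(background)
  N <- length(bg)
  ra <- intersect(sigA, bg)
  rb <- intersect(sigB, bg)
  shared <- sort(intersect(ra, rb))
  noInf <- length(ra) == 0L || length(rb) == 0L
  # sorted (K, n) arguments: the hypergeometric is symmetric in them, and
  # a canonical order makes score(a, b) == score(b, a) bit-for-bit
  p <- if (noInf) 1 else hypergeomTail(length(shared),
                                       min(length(ra), length(rb)),
                                       max(length(ra), length(rb)), N)
  new("NSResult", geneA = geneA, geneB = geneB,
      k = length(shared), K = length(ra), n = length(rb), N = N,
      pValue = p, sharedFamilies = shared,
      onlyA = sort(setdiff(ra, rb)), onlyB = sort(setdiff(rb, ra)),
      noInformative = noInf)
}

#' Network-similarity score between two genes of different organisms
#'
#' Both genes' neighborhoods are projected onto meta-genes and restricted
#' to the organism-pair background; the score is the upper-tail
#' hypergeometric probability of the overlap between the two restricted
#' signatures. A gene with an empty restricted signature yields p = 1,
#' flagged as having no informative neighborhood.
#'
#' @param geneA,geneB query genes in `netA` and `netB` respectively.
#' @param netA,netB [FunctionalNetwork-class] objects for the two
#'   organisms.
#' @param fm a [FamilyMap-class].
#' @param background the organism-pair [BackgroundSet-class].
#' @param hardCutoff,softMin neighborhood parameters (defaults 0.5 / 50).
#' @return An [NSResult-class] carrying the shared and exclusive family
#'   sets for downstream decomposition.
#' @export
nsScore <- function(geneA, geneB, netA, netB, fm, background,
                    hardCutoff = 0.5, softMin = 50L) {
  sigA <- toMetagenes(getNeighborhood(netA, geneA, hardCutoff, softMin),
                      fm, background)
  sigB <- toMetagenes(getNeighborhood(netB, geneB, hardCutoff, softMin),
                      fm, background)
  .nsFromSignatures(geneA, geneB, restrictedFamilies(sigA),
                    restrictedFamilies(sigB), background)
}

#' Within-species network-similarity score
#'
#' Identical computation to [nsScore()] with both signatures drawn from one
#' network, against a within-species background (see [buildBackground()]
#' with a single organism). Used to place same-species paralogs on a common
#' scale with cross-species scores in family-wide clusterings.
#'
#' @param geneA,geneB same-species query genes.
#' @param net the species' [FunctionalNetwork-class].
#' @inheritParams nsScore
#' @return An [NSResult-class].
#' @export
withinSpeciesNs <- function(geneA, geneB, net, fm, background,
                            hardCutoff = 0.5, softMin = 50L) {
  nsScore(geneA, geneB, net, net, fm, background, hardCutoff, softMin)
}

#' Decompose an NS overlap into annotated shared and exclusive family sets
#'
#' The Venn-style partition behind an NS score: families shared by both
#' neighborhoods and those exclusive to either gene, each joined with
#' family-level annotations so the biological content of the overlap can be
#' inspected.
#'
#' @param res an [NSResult-class].
#' @param fa a [FamilyAnnotation-class] (see [familyAnnotations()]).
#' @return named list of data.frames (`shared`, `onlyA`, `onlyB`) with
#'   columns `family` and `terms` (comma-collapsed).
#' @export
overlapDecomposition <- function(res, fa) {
  ann <- familyTerms(fa)
  annotate <- function(fams) {
    terms <- vapply(fams, function(f)
      paste(sort(ann$term[ann$family == f]), collapse = ","), "")
    data.frame(family = fams, terms = unname(terms),
               stringsAsFactors = FALSE)
  }
  list(shared = annotate(res@sharedFamilies),
       onlyA = annotate(res@onlyA),
       onlyB = annotate(res@onlyB))
}

#' All pairwise NS scores among a set of genes, with a display clustering
#'
#' Cross-species pairs are scored with [nsScore()], same-species pairs with
#' [withinSpeciesNs()]; scores are reported as -log10 p. The display order
#' comes from average-linkage clustering of the similarity matrix
#' (converted to a distance by subtracting from its maximum), ties broken
#' by gene identifier.
#'
#' @param genes character vector of gene identifiers.
#' @param organisms organism of each gene (parallel to `genes`).
#' @param networks named list (by organism) of
#'   [FunctionalNetwork-class] objects.
#' @param fm a [FamilyMap-class].
#' @param backgrounds named list of [BackgroundSet-class] objects: one per
#'   unordered organism pair, named `"orgA|orgB"` with the two labels
#'   sorted, plus one per single organism named `"org"`.
#' @param hardCutoff,softMin neighborhood parameters.
#' @return An [NSMatrix-class].
#' @export
familyNsMatrix <- function(genes, organisms, networks, fm, backgrounds,
                           hardCutoff = 0.5, softMin = 50L) {
  stopifnot(length(genes) == length(organisms), length(genes) >= 2L)
  sigs <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    net <- networks[[organisms[i]]]
    if (is.null(net) || !genes[i] %in% networkGenes(net))
      stop("gene '", genes[i], "' is absent from the network of '",
           organisms[i], "'")
    sigs[[i]] <- families(toMetagenes(
      getNeighborhood(net, genes[i], hardCutoff, softMin), fm))
  }
  bgKey <- function(o1, o2) {
    if (o1 == o2) o1 else paste(sort(c(o1, o2)), collapse = "|")
  }
  m <- matrix(NA_real_, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (i in seq_len(length(genes) - 1L)) {
    for (j in seq(i + 1L, length(genes))) {
      bg <- backgrounds[[bgKey(organisms[i], organisms[j])]]
      if (is.null(bg))
        stop("no background supplied for organism pair ",
             bgKey(organisms[i], organisms[j]))
      res <- .nsFromSignatures(genes[i], genes[j], sigs[[i]], sigs[[j]], bg)
      m[i, j] <- m[j, i] <- -log10(pValue(res))
    }
  }
  sim <- m
  diag(sim) <- 0
  d <- stats::as.dist(max(sim) - sim)
  ord <- stats::hclust(d, method = "average")$order
  new("NSMatrix", genes = genes, organisms = organisms, scores = m,
      order = as.integer(ord))
}
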