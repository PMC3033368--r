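#' @include AllClasses.R utils.R
NULL

# All unordered co-annotation pairs: genes experimentally annotated to the
# same specific term. Returns a canonical pair frame.
.coAnnotatedPairs <- function(ann) {
  rec <- annotationRecords(ann)
  rec <- rec[rec$term %in% specificTerms(ann), , drop = FALSE]
  rec <- unique(rec[c("gene", "term")])
  bits <- lapply(split(rec$gene, rec$term), function(g) {
    g <- sort(unique(g))
    if (length(g) < 2L) return(NULL)
    m <- combn(g, 2L)
    data.frame(gene1 = m[1L, ], gene2 = m[2L, ], stringsAsFactors = FALSE)
  })
  bits <- bits[!vapply(bits, is.null, TRUE)]
  if (!length(bits)) return(.emptyPairFrame())
  canonicalPairs(do.call(rbind, bits))
}

#' Build a labeled gene-pair standard for Bayesian integration
#'
#' Positive pairs are genes experimentally co-annotated to at least one
#' specific term, with homologous pairs (same family under `fm`) excluded.
#' Negative pairs are sampled uniformly at random, without replacement, from
#' the unordered pairs of genes that occur in the positive set (excluding
#' the positives themselves) until the positive fraction matches `prior`.
#'
#' @param ann an [AnnotationSet-class] restricted to one organism.
#' @param fm a [FamilyMap-class]; used to exclude homologous positives.
#' @param prior target prior probability of functional interaction, in
#'   (0,1). Defaults to 0.05.
#' @param seed RNG seed for negative sampling (required: sampling must be
#'   reproducible).
#' @param excludeIntraFamily also forbid same-family pairs among the
#'   sampled negatives (default `FALSE`: only positives are excluded).
#' @return A [PairStandard-class].
#' @export
buildIntegrationStandard <- function(ann, fm, prior = 0.05, seed,
                                     excludeIntraFamily = FALSE) {
  stopifnot(prior > 0, prior < 1)
  if (missing(seed)) stop("a seed is required for negative sampling")
  pos <- .coAnnotatedPairs(ann)
  if (nrow(pos)) {
    f1 <- familyOf(fm, pos$gene1)
    f2 <- familyOf(fm, pos$gene2)
    homologous <- !is.na(f1) & !is.na(f2) & f1 == f2
    pos <- pos[!homologous, , drop = FALSE]
  }
  if (!nrow(pos))
    stop("no positive pairs: cannot build an integration standard")
  nNeg <- round(nrow(pos) * (1 - prior) / prior)
  genes <- sort(unique(c(pos$gene1, pos$gene2)))
  allPairs <- combn(genes, 2L)
  cand <- data.frame(gene1 = allPairs[1L, ], gene2 = allPairs[2L, ],
                     stringsAsFactors = FALSE)
  cand <- cand[!pairKey(cand$gene1, cand$gene2) %in%
                 pairKey(pos$gene1, pos$gene2), , drop = FALSE]
  if (excludeIntraFamily) {
    f1 <- familyOf(fm, cand$gene1); f2 <- familyOf(fm, cand$gene2)
    cand <- cand[is.na(f1) | is.na(f2) | f1 != f2, , drop = FALSE]
  }
  if (nrow(cand) < nNeg) {
    achievable <- nrow(pos) / (nrow(pos) + nrow(cand))
    stop(sprintf(
      "too few genes to reach prior %.4g: only %d candidate negatives for %d positives (achievable prior %.4g)",
      prior, nrow(cand), nrow(pos), achievable))
  }
  neg <- withSeed(seed, cand[sample.int(nrow(cand), nNeg), , drop = FALSE])
  rownames(neg) <- NULL
  new("PairStandard", positives = pos, negatives = canonicalPairs(neg),
      prior = prior)
}

# Same-family cross-organism (query, candidate) pairs under a family map.
.crossFamilyPairs <- function(fm, orgPair) {
  e <- familyEntries(fm)
  a <- e[e$organism == orgPair[1L], , drop = FALSE]
  b <- e[e$organism == orgPair[2L], , drop = FALSE]
  m <- merge(a[c("gene", "family")], b[c("gene", "family")],
             by = "family", suffixes = c(".q", ".c"))
  data.frame(query = m$gene.q, candidate = m$gene.c, family = m$family,
             stringsAsFactors = FALSE)
}

.finalizeHomologStandard <- function(df, orgPair) {
  if (nrow(df)) {
    npos <- tapply(df$label == "positive", df$query, sum)
    nneg <- tapply(df$label == "negative", df$query, sum)
    ok <- names(npos)[npos >= 1L & nneg >= 1L]
    df <- df[df$query %in% ok, , drop = FALSE]
    rownames(df) <- NULL
  }
  if (!nrow(df)) warning("empty homolog standard: no usable queries")
  new("HomologPairStandard",
      entries = df[c("query", "candidate", "label")], orgPair = orgPair)
}

#' Build a homolog-pair standard from a binary gene attribute
#'
#' For same-family cross-organism pairs whose query carries the attribute
#' (e.g. nervous-system expression): a candidate that also carries it is a
#' positive; a candidate assayed and lacking it is a negative; candidates
#' with unknown status are omitted. Queries without at least one positive
#' and one negative are dropped.
#'
#' @param attribute named character vector over genes with values `"has"`,
#'   `"lacks"` or `"unknown"`; genes not named are treated as unknown.
#' @param fm a [FamilyMap-class] (homology = family co-membership).
#' @param orgPair character(2): query organism, candidate organism.
#' @return A [HomologPairStandard-class].
#' @export
buildHomologStandard <- function(attribute, fm, orgPair) {
  pairs <- .crossFamilyPairs(fm, orgPair)
  qa <- unname(attribute[pairs$query])
  ca <- unname(attribute[pairs$candidate])
  qa[is.na(qa)] <- "unknown"; ca[is.na(ca)] <- "unknown"
  keep <- qa == "has" & ca %in% c("has", "lacks")
  df <- pairs[keep, , drop = FALSE]
  df$label <- ifelse(ca[keep] == "has", "positive", "negative")
  .finalizeHomologStandard(df, orgPair)
}

#' Build a homolog-pair standard from shared specific GO annotations
#'
#' Same-family cross-organism pairs in which both genes carry at least one
#' specific-term experimental annotation: sharing a term makes the pair
#' positive, sharing none makes it negative; pairs with an unannotated gene
#' are omitted.
#'
#' @param annQuery,annCandidate [AnnotationSet-class] objects for the query
#'   and candidate organisms (pre-filtered to experimental evidence).
#' @param fm a [FamilyMap-class].
#' @param orgPair character(2): query organism, candidate organism.
#' @return A [HomologPairStandard-class].
#' @export
buildGoHomologStandard <- function(annQuery, annCandidate, fm, orgPair) {
  termsOf <- function(ann) {
    rec <- annotationRecords(ann)
    rec <- rec[rec$term %in% specificTerms(ann), , drop = FALSE]
    lapply(split(rec$term, rec$gene), unique)
  }
  tq <- termsOf(annQuery); tc <- termsOf(annCandidate)
  pairs <- .crossFamilyPairs(fm, orgPair)
  keep <- pairs$query %in% names(tq) & pairs$candidate %in% names(tc)
  df <- pairs[keep, , drop = FALSE]
  if (nrow(df)) {
    shared <- mapply(function(q, c)
      length(intersect(tq[[q]], tc[[c]])) > 0L, df$query, df$candidate)
    df$label <- ifelse(shared, "positive", "negative")
  } else df$label <- character()
  .finalizeHomologStandard(df, orgPair)
}
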