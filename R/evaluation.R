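#' @include AllClasses.R utils.R
NULL

#' Normalize within-query candidate ranks onto the unit interval
#'
#' The best-scoring candidate receives rank 1, the worst rank 0, the rest
#' fall linearly in between: position r of m candidates (best = m-1) maps
#' to r/(m-1). Tied scores share the mean of their positions.
#'
#' @param scores numeric vector of candidate scores (higher = better).
#' @return numeric vector of normalized ranks, parallel to `scores`.
#' @export
normalizeQueryRanks <- function(scores) {
  m <- length(scores)
  if (m < 2L)
    stop("rank normalization needs at least two candidates")
  (rank(scores, ties.method = "average") - 1) / (m - 1)
}

#' Build a HomologRanking for one query
#'
#' @param query query gene.
#' @param gene,score,label parallel candidate vectors; labels are
#'   "positive"/"negative".
#' @param scoreSource provenance of the scores.
#' @return A [HomologRanking-class].
#' @export
HomologRanking <- function(query, gene, score, label,
                           scoreSource = "network") {
  new("HomologRanking", query = as.character(query),
      candidates = data.frame(gene = as.character(gene),
                              score = as.numeric(score),
                              label = as.character(label),
                              stringsAsFactors = FALSE),
      scoreSource = scoreSource)
}

#' Pooled normalized-rank AUC over all queries
#'
#' Every query's candidate scores are rescaled to normalized ranks, the
#' (rank, label) pairs are pooled across queries, and the AUC is the
#' Mann-Whitney probability that a positive outranks a negative (ties count
#' half). Significance is a two-sided Mann-Whitney test with normal
#' approximation and tie correction, or a seeded label-permutation test.
#'
#' @param rankings list of [HomologRanking-class] objects.
#' @param method significance method: `"mannwhitney"` (default) or
#'   `"permutation"`.
#' @param nPerm number of permutations for the permutation test.
#' @param seed RNG seed for the permutation test.
#' @return An [AUCResult-class].
#' @export
pooledAuc <- function(rankings, method = c("mannwhitney", "permutation"),
                      nPerm = 1000L, seed = 1L) {
  method <- match.arg(method)
  if (!length(rankings)) stop("no rankings to pool")
  nr <- unlist(lapply(rankings, function(rk) {
    validObject(rk)
    normalizeQueryRanks(rk@candidates$score)
  }), use.names = FALSE)
  lab <- unlist(lapply(rankings, function(rk) rk@candidates$label),
                use.names = FALSE)
  pos <- nr[lab == "positive"]
  neg <- nr[lab == "negative"]
  aucOf <- function(p, q) {
    r <- rank(c(p, q))
    (sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2) /
      (length(p) * length(q))
  }
  aucVal <- aucOf(pos, neg)
  if (method == "mannwhitney") {
    pv <- suppressWarnings(
      wilcox.test(pos, neg, exact = FALSE, correct = TRUE)$p.value)
  } else {
    obs <- abs(aucVal - 0.5)
    n1 <- length(pos)
    pv <- withSeed(seed, {
      hits <- 0L
      for (b in seq_len(nPerm)) {
        idx <- sample.int(length(nr), n1)
        if (abs(aucOf(nr[idx], nr[-idx]) - 0.5) >= obs - 1e-12)
          hits <- hits + 1L
      }
      (hits + 1) / (nPerm + 1)
    })
  }
  new("AUCResult", auc = aucVal, pValue = pv,
      nQueries = length(rankings), nPairs = length(nr),
      normalizedRanks = nr, labels = lab, method = method)
}

#' Combine network and sequence scores into a rank-average score
#'
#' Candidates are ranked separately under each score within the query; the
#' combined score is the mean of the two normalized ranks. Candidates
#' missing either score are excluded with a warning.
#'
#' @param nsScores,seqScores named numeric vectors of candidate scores
#'   (higher = better), names are candidate genes.
#' @return named numeric vector of combined scores.
#' @export
combinedRankScore <- function(nsScores, seqScores) {
  common <- intersect(names(nsScores), names(seqScores))
  dropped <- setdiff(union(names(nsScores), names(seqScores)), common)
  if (length(dropped))
    warning("candidate(s) missing a score excluded: ",
            paste(dropped, collapse = ", "))
  if (length(common) < 2L)
    stop("combined ranking needs at least two candidates with both scores")
  setNames((normalizeQueryRanks(nsScores[common]) +
              normalizeQueryRanks(seqScores[common])) / 2, common)
}

#' Score every pair of a homolog standard with the NS score
#'
#' Computes neighborhoods and meta-gene signatures once per gene, then the
#' background-restricted overlap p-value for each (query, candidate) pair.
#' Scores are returned as -log10 p so that higher means more similar.
#'
#' @param std a [HomologPairStandard-class].
#' @param netQuery,netCandidate networks of the query and candidate
#'   organisms.
#' @param fm a [FamilyMap-class].
#' @param background the organism-pair [BackgroundSet-class].
#' @param hardCutoff,softMin neighborhood parameters.
#' @return data.frame with columns `query`, `candidate`, `score`.
#' @export
scoreHomologStandard <- function(std, netQuery, netCandidate, fm,
                                 background, hardCutoff = 0.5,
                                 softMin = 50L) {
  df <- standardEntries(std)
  bg <- families(background)
  restrictedSig <- function(net, genes) {
    nbs <- allNeighborhoods(net, hardCutoff, softMin)
    out <- lapply(genes, function(g) {
      nb <- nbs[[g]]
      if (is.null(nb)) return(character())
      fams <- familyOf(fm, nb@members)
      intersect(unique(fams[!is.na(fams)]), bg)
    })
    names(out) <- genes
    out
  }
  qs <- restrictedSig(netQuery, unique(df$query))
  cs <- restrictedSig(netCandidate, unique(df$candidate))
  N <- length(bg)
  score <- mapply(function(q, c) {
    sq <- qs[[q]]; sc <- cs[[c]]
    if (!length(sq) || !length(sc)) return(0)
    k <- length(intersect(sq, sc))
    -hypergeomTail(k, length(sq), length(sc), N, logP = TRUE) / log(10)
  }, df$query, df$candidate)
  data.frame(query = df$query, candidate = df$candidate,
             score = unname(score), stringsAsFactors = FALSE)
}

#' Evaluate homolog ranking against a labeled standard
#'
#' Builds per-query rankings from the supplied score table(s), applies the
#' at-least-one-positive / at-least-one-negative filter, and reports the
#' pooled normalized-rank AUC with significance per score source
#' ("network", plus "sequence" and "combined" when sequence scores are
#' given).
#'
#' @param std a [HomologPairStandard-class].
#' @param networkScores data.frame `query`, `candidate`, `score` (e.g. from
#'   [scoreHomologStandard()]).
#' @param sequenceScores optional data.frame in the same shape.
#' @param method,nPerm,seed passed to [pooledAuc()].
#' @return list with `table` (data.frame: source, auc, p.value, n.queries,
#'   n.pairs) and `results` (named list of [AUCResult-class]).
#' @export
evaluateRanking <- function(std, networkScores, sequenceScores = NULL,
                            method = "mannwhitney", nPerm = 1000L,
                            seed = 1L) {
  df <- standardEntries(std)
  if (!nrow(df)) {
    warning("empty standard: nothing to evaluate")
    return(list(table = data.frame(), results = list()))
  }
  lookup <- function(scores) {
    setNames(scores$score, paste(scores$query, scores$candidate,
                                 sep = "\r"))
  }
  buildRankings <- function(scoreMap) {
    out <- list()
    for (q in unique(df$query)) {
      sub <- df[df$query == q, , drop = FALSE]
      s <- scoreMap[paste(sub$query, sub$candidate, sep = "\r")]
      keep <- !is.na(s)
      if (sum(keep) < nrow(sub))
        warning("query '", q, "': candidate(s) without a score excluded")
      sub <- sub[keep, , drop = FALSE]
      if (!any(sub$label == "positive") || !any(sub$label == "negative"))
        next
      out[[q]] <- HomologRanking(q, sub$candidate, s[keep], sub$label)
    }
    out
  }
  sources <- list(network = lookup(networkScores))
  if (!is.null(sequenceScores)) {
    seqMap <- lookup(sequenceScores)
    sources$sequence <- seqMap
    netMap <- sources$network
    comb <- unlist(lapply(unique(df$query), function(q) {
      sub <- df[df$query == q, , drop = FALSE]
      keys <- paste(sub$query, sub$candidate, sep = "\r")
      ns <- netMap[keys]; sq <- seqMap[keys]
      ok <- !is.na(ns) & !is.na(sq)
      if (sum(ok) < 2L) return(NULL)
      cs <- (normalizeQueryRanks(ns[ok]) + normalizeQueryRanks(sq[ok])) / 2
      setNames(cs, keys[ok])
    }))
    sources$combined <- comb
  }
  results <- list()
  rows <- list()
  for (src in names(sources)) {
    rks <- buildRankings(sources[[src]])
    if (!length(rks)) {
      warning("no usable queries for score source '", src, "'")
      next
    }
    res <- pooledAuc(rks, method = method, nPerm = nPerm, seed = seed)
    results[[src]] <- res
    rows[[src]] <- data.frame(source = src, auc = auc(res),
                              p.value = pValue(res),
                              n.queries = res@nQueries,
                              n.pairs = res@nPairs,
                              stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       results = results)
}
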