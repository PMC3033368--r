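#' @include AllClasses.R utils.R
NULL

#' Pairwise Pearson correlation within one expression dataset
#'
#' Correlations are computed over pairwise-complete samples; a gene pair is
#' reported only if at least `minSamples` complete observations support it.
#'
#' @param ds an [ExpressionDataset-class].
#' @param minSamples minimum number of pairwise-complete samples (>= 3).
#' @return data.frame with columns `gene1`, `gene2`, `cor` (canonical pair
#'   order).
#' @export
correlateDataset <- function(ds, minSamples = 3L) {
  stopifnot(minSamples >= 3L)
  mat <- exprsMatrix(ds)
  if (ncol(mat) < 3L)
    stop("dataset '", datasetId(ds), "' has fewer than 3 samples")
  r <- suppressWarnings(cor(t(mat), use = "pairwise.complete.obs"))
  obs <- !is.na(mat)
  counts <- tcrossprod(obs * 1)
  idx <- which(upper.tri(r) & counts >= minSamples & !is.na(r),
               arr.ind = TRUE)
  df <- data.frame(gene1 = rownames(mat)[idx[, 1L]],
                   gene2 = rownames(mat)[idx[, 2L]],
                   cor = r[idx], stringsAsFactors = FALSE)
  canonicalPairs(df)
}

#' Discretize correlations into quantile bins of the z-transformed values
#'
#' Correlations are Fisher z-transformed and cut at their per-dataset
#' quantiles so that every dataset contributes comparably populated
#' evidence bins regardless of its correlation distribution. When fewer
#' distinct quantile boundaries than requested exist, the binning degrades
#' gracefully (with a warning) to the distinct boundaries available.
#'
#' @param correlations data.frame with columns `gene1`, `gene2`, `cor`
#'   (output of [correlateDataset()]).
#' @param nBins requested number of bins (>= 2); default 5.
#' @param datasetId identifier stored on the evidence object.
#' @return A [DatasetEvidence-class] with 1-based bin indices.
#' @export
discretize <- function(correlations, nBins = 5L, datasetId = "dataset") {
  stopifnot(nBins >= 2L)
  z <- atanh(pmin(pmax(correlations$cor, -1 + 1e-15), 1 - 1e-15))
  breaks <- unique(as.numeric(quantile(z, seq(0, 1, length.out = nBins + 1L),
                                       na.rm = TRUE)))
  if (length(breaks) < 2L) {
    warning("all correlations equal in '", datasetId,
            "': a single occupied bin")
    breaks <- c(breaks - 0.5, breaks + 0.5)
  } else if (length(breaks) - 1L < nBins) {
    warning("fewer distinct values than bins in '", datasetId,
            "': degraded to ", length(breaks) - 1L, " bins")
  }
  bin <- .bincode(z, breaks, right = TRUE, include.lowest = TRUE)
  pairs <- data.frame(gene1 = correlations$gene1,
                      gene2 = correlations$gene2,
                      bin = as.integer(bin), stringsAsFactors = FALSE)
  new("DatasetEvidence", datasetId = as.character(datasetId),
      pairs = pairs, nBins = length(breaks) - 1L, breaks = breaks,
      coverage = sort(unique(c(pairs$gene1, pairs$gene2))))
}

#' Learn a per-dataset conditional probability table
#'
#' Estimates P(bin | positive) and P(bin | negative) from the standard
#' pairs present in the dataset's evidence, with Laplace smoothing:
#' `(count + pseudocount) / (total + pseudocount * nBins)`.
#'
#' @param ev a [DatasetEvidence-class].
#' @param std a [PairStandard-class].
#' @param pseudocount smoothing pseudocount; default 1 (Laplace).
#' @return A [ConditionalTable-class].
#' @export
learnCpt <- function(ev, std, pseudocount = 1) {
  key <- pairKey(ev@pairs$gene1, ev@pairs$gene2)
  posBins <- ev@pairs$bin[key %in% pairKey(positives(std)$gene1,
                                           positives(std)$gene2)]
  negBins <- ev@pairs$bin[key %in% pairKey(negatives(std)$gene1,
                                           negatives(std)$gene2)]
  if (!length(posBins) || !length(negBins))
    stop("dataset '", datasetId(ev),
         "' has no overlap with the standard's ",
         if (!length(posBins)) "positive" else "negative", " pairs")
  smooth <- function(bins) {
    cnt <- tabulate(bins, nbins = ev@nBins)
    (cnt + pseudocount) / (sum(cnt) + pseudocount * ev@nBins)
  }
  if (pseudocount <= 0 &&
      (any(tabulate(posBins, ev@nBins) == 0) ||
       any(tabulate(negBins, ev@nBins) == 0)))
    warning("zero pseudocount with empty bins: conditional table has zeros")
  new("ConditionalTable", datasetId = datasetId(ev),
      pPos = smooth(posBins), pNeg = smooth(negBins),
      pseudocount = pseudocount)
}

# Per-dataset log likelihood-ratio of the observed bin for a set of pair
# keys; NA where the dataset does not cover the pair.
.logLRForKeys <- function(keys, ev, cpt) {
  bin <- ev@pairs$bin[match(keys, pairKey(ev@pairs$gene1, ev@pairs$gene2))]
  log(cpt@pPos[bin]) - log(cpt@pNeg[bin])
}

#' Naive-Bayes posterior probability of functional relationship
#'
#' Combines per-dataset evidence in log space:
#' posterior = prior * prod(P(b|+)) / (prior * prod(P(b|+)) +
#' (1-prior) * prod(P(b|-))), the product running over the datasets that
#' cover the pair. A pair covered by no dataset returns the prior, flagged
#' with attribute `noEvidence = TRUE`.
#'
#' @param pair character(2): the two genes.
#' @param evidences list of [DatasetEvidence-class].
#' @param cpts list of [ConditionalTable-class], parallel to `evidences`.
#' @param prior prior probability of functional relationship.
#' @return posterior probability (numeric scalar).
#' @export
posteriorProbability <- function(pair, evidences, cpts, prior) {
  stopifnot(length(evidences) == length(cpts), prior > 0, prior < 1)
  key <- pairKey(pair[1L], pair[2L])
  llr <- vapply(seq_along(evidences), function(i)
    .logLRForKeys(key, evidences[[i]], cpts[[i]]), numeric(1L))
  if (all(is.na(llr))) {
    out <- prior
    attr(out, "noEvidence") <- TRUE
    return(out)
  }
  plogis(log(prior) - log1p(-prior) + sum(llr, na.rm = TRUE))
}

#' Rank datasets by how well they alone recapitulate the standard
#'
#' Each dataset's standard pairs are ranked by their single-dataset
#' posterior (equivalently, log likelihood-ratio) and scored by the area
#' under the precision-recall curve restricted to recall in
#' `[0, recallFraction]`. The `k` best-scoring datasets are returned, ties
#' broken by dataset identifier.
#'
#' @param evidences list of [DatasetEvidence-class].
#' @param cpts parallel list of [ConditionalTable-class].
#' @param std a [PairStandard-class].
#' @param k number of datasets to keep.
#' @param recallFraction recall ceiling for the partial area, in (0,1].
#' @return list with `selected` (indices into `evidences`) and `scores`
#'   (named partial-AUPRC vector).
#' @export
selectTopDatasets <- function(evidences, cpts, std, k,
                              recallFraction = 0.1) {
  stopifnot(k >= 1L, recallFraction > 0, recallFraction <= 1)
  posKey <- pairKey(positives(std)$gene1, positives(std)$gene2)
  negKey <- pairKey(negatives(std)$gene1, negatives(std)$gene2)
  stdKey <- c(posKey, negKey)
  label <- rep(c(TRUE, FALSE), c(length(posKey), length(negKey)))
  scores <- vapply(seq_along(evidences), function(i) {
    llr <- .logLRForKeys(stdKey, evidences[[i]], cpts[[i]])
    keep <- !is.na(llr)
    lab <- label[keep]
    if (!any(lab)) return(0)
    o <- order(-llr[keep])
    s <- llr[keep][o]
    lab <- lab[o]
    # precision-recall evaluated at distinct-score cutoffs (tie groups are
    # not split, so tied positives and negatives are treated evenhandedly),
    # integrated by trapezoid up to the recall ceiling
    ends <- cumsum(rle(s)$lengths)
    tp <- cumsum(lab)[ends]
    rec <- tp / sum(lab)
    prec <- tp / ends
    area <- 0
    r0 <- 0; p0 <- prec[1L]
    for (j in seq_along(ends)) {
      r1 <- rec[j]; p1 <- prec[j]
      if (r1 >= recallFraction) {
        # linear interpolation of precision at the ceiling
        pCeil <- if (r1 > r0) p0 + (p1 - p0) * (recallFraction - r0) /
          (r1 - r0) else p1
        area <- area + (recallFraction - r0) * (p0 + pCeil) / 2
        r0 <- recallFraction
        break
      }
      area <- area + (r1 - r0) * (p0 + p1) / 2
      r0 <- r1; p0 <- p1
    }
    area
  }, numeric(1L))
  ids <- vapply(evidences, datasetId, "")
  names(scores) <- ids
  if (length(evidences) < k) {
    warning("fewer datasets (", length(evidences), ") than requested k = ",
            k, ": keeping all")
    k <- length(evidences)
  }
  selected <- order(-scores, ids)[seq_len(k)]
  list(selected = selected, scores = scores)
}

#' Integrate an expression compendium into a functional network
#'
#' Full pipeline: per-dataset Pearson correlation over pairwise-complete
#' samples, Fisher-z quantile discretization, conditional-table learning
#' against the standard, optional top-k dataset selection, and naive-Bayes
#' posterior computation in log space over all covered pairs. Posteriors
#' are clipped to `(clip, 1 - clip)`.
#'
#' @param compendium list of [ExpressionDataset-class].
#' @param std a [PairStandard-class].
#' @param prior prior probability; defaults to the standard's prior.
#' @param nBins evidence bins per dataset (default 5).
#' @param pseudocount Laplace pseudocount (default 1).
#' @param minSamples minimum pairwise-complete samples per correlation.
#' @param topK if non-`NULL`, keep only the `topK` datasets best at
#'   recapitulating the standard (see [selectTopDatasets()]).
#' @param recallFraction recall ceiling for dataset selection.
#' @param organism organism label for the resulting network.
#' @param clip posterior clipping epsilon (default 1e-6).
#' @return A [FunctionalNetwork-class].
#' @export
integrateCompendium <- function(compendium, std, prior = priorOf(std),
                                nBins = 5L, pseudocount = 1,
                                minSamples = 3L, topK = NULL,
                                recallFraction = 0.1,
                                organism = "unknown", clip = 1e-6) {
  if (!length(compendium)) stop("empty compendium")
  if (!nrow(positives(std)) || !nrow(negatives(std)))
    stop("the integration standard must contain positives and negatives")
  evidences <- lapply(compendium, function(ds)
    discretize(correlateDataset(ds, minSamples), nBins = nBins,
               datasetId = datasetId(ds)))
  cpts <- lapply(evidences, learnCpt, std = std,
                 pseudocount = pseudocount)
  if (!is.null(topK)) {
    sel <- selectTopDatasets(evidences, cpts, std, k = topK,
                             recallFraction = recallFraction)$selected
    evidences <- evidences[sel]
    cpts <- cpts[sel]
  }
  keyList <- lapply(evidences, function(ev)
    pairKey(ev@pairs$gene1, ev@pairs$gene2))
  allKeys <- unique(unlist(keyList, use.names = FALSE))
  logOdds <- rep(log(prior) - log1p(-prior), length(allKeys))
  for (i in seq_along(evidences)) {
    m <- match(allKeys, keyList[[i]])
    bin <- evidences[[i]]@pairs$bin[m]
    llr <- log(cpts[[i]]@pPos[bin]) - log(cpts[[i]]@pNeg[bin])
    llr[is.na(llr)] <- 0
    logOdds <- logOdds + llr
  }
  post <- pmin(pmax(plogis(logOdds), clip), 1 - clip)
  gp <- strsplit(allKeys, "\r", fixed = TRUE)
  FunctionalNetwork(gene1 = vapply(gp, `[[`, "", 1L),
                    gene2 = vapply(gp, `[[`, "", 2L),
                    prob = post, organism = organism, prior = prior)
}
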