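#' @import methods
#' @importFrom stats cor quantile p.adjust phyper plogis rnorm runif setNames
#'   wilcox.test rbinom
#' @importFrom utils read.delim write.table head combn
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom S4Vectors metadata
NULL

.emptyPairFrame <- function() {
  data.frame(gene1 = character(), gene2 = character(),
             stringsAsFactors = FALSE)
}

#' ExpressionDataset: a processed expression matrix for one dataset
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' genes x samples matrix of (already normalized) expression values in the
#' `"exprs"` assay, plus a dataset identifier. Missing values are permitted;
#' correlation downstream is computed over pairwise-complete samples.
#'
#' @slot datasetId single string naming the dataset.
#' @export
setClass("ExpressionDataset",
         contains = "SummarizedExperiment",
         representation(datasetId = "character"))

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (length(object@datasetId) != 1L || is.na(object@datasetId) ||
      !nzchar(object@datasetId))
    msg <- c(msg, "datasetId must be a single non-empty string")
  if (ncol(object) < 2L)
    msg <- c(msg, "an expression dataset needs at least 2 samples")
  rn <- rownames(object)
  if (is.null(rn) || anyNA(rn) || any(!nzchar(rn)))
    msg <- c(msg, "all genes must have non-empty identifiers")
  else if (anyDuplicated(rn))
    msg <- c(msg, sprintf("duplicate gene identifier(s): %s",
                          paste(unique(rn[duplicated(rn)]), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset from a matrix
#'
#' @param mat numeric matrix, genes in rows (rownames required), samples in
#'   columns.
#' @param datasetId dataset identifier.
#' @return An [ExpressionDataset-class] object.
#' @export
ExpressionDataset <- function(mat, datasetId) {
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  new("ExpressionDataset",
      SummarizedExperiment(assays = list(exprs = mat)),
      datasetId = as.character(datasetId))
}

#' FamilyMap: gene -> (organism, family) with multi-family exclusion
#'
#' Genes listed under more than one family are removed from the map and
#' recorded in `excludedGenes`; every retained gene maps to exactly one
#' family.
#'
#' @slot entries data.frame with columns `gene`, `organism`, `family`.
#' @slot excludedGenes character vector of genes dropped for multi-family
#'   membership.
#' @export
setClass("FamilyMap",
         representation(entries = "data.frame", excludedGenes = "character"))

setValidity("FamilyMap", function(object) {
  msg <- character()
  need <- c("gene", "organism", "family")
  if (!all(need %in% names(object@entries)))
    msg <- c(msg, "entries must have columns gene, organism, family")
  else {
    if (anyDuplicated(object@entries$gene))
      msg <- c(msg, "a retained gene maps to more than one family")
    if (any(object@entries$gene %in% object@excludedGenes))
      msg <- c(msg, "excluded genes must not appear among retained entries")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FamilyMap from gene/organism/family assignments
#'
#' @param gene,organism,family parallel character vectors; a gene appearing
#'   with more than one distinct family is excluded.
#' @return A [FamilyMap-class] object.
#' @export
FamilyMap <- function(gene = character(), organism = character(),
                      family = character()) {
  df <- unique(data.frame(gene = as.character(gene),
                          organism = as.character(organism),
                          family = as.character(family),
                          stringsAsFactors = FALSE))
  nfam <- tapply(df$family, df$gene, function(x) length(unique(x)))
  bad <- if (length(nfam)) names(nfam)[nfam > 1L] else character(0)
  keep <- df[!df$gene %in% bad, , drop = FALSE]
  keep <- keep[!duplicated(keep$gene), , drop = FALSE]
  rownames(keep) <- NULL
  new("FamilyMap", entries = keep,
      excludedGenes = as.character(sort(bad)))
}

#' AnnotationSet: gene/term/evidence records plus the specific-term slice
#'
#' @slot records data.frame with columns `gene`, `term`, `evidence`.
#' @slot specificTerms character vector of term identifiers regarded as
#'   biologically specific (used for gold standards and enrichment).
#' @slot organism optional single organism label ("" if unspecified).
#' @export
setClass("AnnotationSet",
         representation(records = "data.frame", specificTerms = "character",
                        organism = "character"))

setValidity("AnnotationSet", function(object) {
  msg <- character()
  if (!all(c("gene", "term", "evidence") %in% names(object@records)))
    msg <- c(msg, "records must have columns gene, term, evidence")
  if (length(object@organism) != 1L)
    msg <- c(msg, "organism must be a single string (possibly \"\")")
  if (length(msg)) msg else TRUE
})

#' @rdname AnnotationSet-class
#' @param records data.frame with columns `gene`, `term`, `evidence`.
#' @param specificTerms character vector; empty means "all observed terms".
#' @param organism optional organism label.
#' @export
AnnotationSet <- function(records, specificTerms = character(),
                          organism = "") {
  records <- unique(as.data.frame(records, stringsAsFactors = FALSE))
  rownames(records) <- NULL
  if (length(specificTerms) == 0L && nrow(records) > 0L) {
    warning("no specific terms declared; treating all observed terms as specific")
    specificTerms <- sort(unique(records$term))
  }
  new("AnnotationSet", records = records,
      specificTerms = as.character(specificTerms),
      organism = as.character(organism))
}

#' PairStandard: labeled same-species gene pairs for Bayesian integration
#'
#' Positive pairs are co-annotated to at least one specific term (homologous
#' pairs excluded); negatives are sampled at random so that
#' positives / (positives + negatives) matches the requested prior.
#'
#' @slot positives,negatives data.frames with columns `gene1`, `gene2`
#'   (canonical order, `gene1 < gene2`).
#' @slot prior prior probability of functional interaction.
#' @export
setClass("PairStandard",
         representation(positives = "data.frame", negatives = "data.frame",
                        prior = "numeric"))

setValidity("PairStandard", function(object) {
  msg <- character()
  for (nm in c("positives", "negatives")) {
    df <- slot(object, nm)
    if (!all(c("gene1", "gene2") %in% names(df))) {
      msg <- c(msg, sprintf("%s needs columns gene1, gene2", nm))
      next
    }
    if (nrow(df) && any(df$gene1 == df$gene2))
      msg <- c(msg, sprintf("%s contains a self-pair", nm))
    if (nrow(df) && any(df$gene1 > df$gene2))
      msg <- c(msg, sprintf("%s not in canonical order", nm))
  }
  if (!length(msg)) {
    key <- function(df) paste(df$gene1, df$gene2, sep = "\r")
    if (length(intersect(key(object@positives), key(object@negatives))))
      msg <- c(msg, "positives and negatives overlap")
  }
  if (length(object@prior) != 1L || object@prior <= 0 || object@prior >= 1)
    msg <- c(msg, "prior must lie in (0,1)")
  else {
    np <- nrow(object@positives); nn <- nrow(object@negatives)
    if (np + nn > 0L) {
      # achieved prior must be within one pair of the requested value
      ach <- np / (np + nn)
      tol <- 1 / (np + nn)
      if (abs(ach - object@prior) > tol + 1e-12)
        msg <- c(msg, sprintf(
          "achieved prior %.4f differs from requested %.4f by more than one pair",
          ach, object@prior))
    }
  }
  if (length(msg)) msg else TRUE
})

#' HomologPairStandard: labeled cross-species homolog pairs for evaluation
#'
#' @slot entries data.frame with columns `query`, `candidate`, `label`
#'   (label is "positive" or "negative"); each usable query keeps at least
#'   one positive and one negative candidate.
#' @slot orgPair character(2), the organisms of query and candidate genes.
#' @export
setClass("HomologPairStandard",
         representation(entries = "data.frame", orgPair = "character"))

setValidity("HomologPairStandard", function(object) {
  msg <- character()
  df <- object@entries
  if (!all(c("query", "candidate", "label") %in% names(df)))
    return("entries needs columns query, candidate, label")
  if (nrow(df)) {
    if (!all(df$label %in% c("positive", "negative")))
      msg <- c(msg, "labels must be 'positive' or 'negative'")
    if (anyDuplicated(df[c("query", "candidate")]))
      msg <- c(msg, "duplicate (query, candidate) pair")
    npos <- tapply(df$label == "positive", df$query, sum)
    nneg <- tapply(df$label == "negative", df$query, sum)
    if (any(npos == 0L) || any(nneg == 0L))
      msg <- c(msg, "every query needs >=1 positive and >=1 negative")
  }
  if (length(object@orgPair) != 2L)
    msg <- c(msg, "orgPair must have length 2")
  if (length(msg)) msg else TRUE
})

#' FunctionalNetwork: per-species posterior probabilities of functional
#' relationship
#'
#' Edges are unordered gene pairs stored in canonical order
#' (lexicographically smaller gene first) with a posterior probability that
#' the two genes participate in the same biological process.
#'
#' @slot organism organism label.
#' @slot edges data.frame with columns `gene1`, `gene2`, `prob`.
#' @slot prior the prior probability used during integration.
#' @export
setClass("FunctionalNetwork",
         representation(organism = "character", edges = "data.frame",
                        prior = "numeric"))

setValidity("FunctionalNetwork", function(object) {
  msg <- character()
  df <- object@edges
  if (!all(c("gene1", "gene2", "prob") %in% names(df)))
    return("edges needs columns gene1, gene2, prob")
  if (nrow(df)) {
    if (any(df$gene1 >= df$gene2))
      msg <- c(msg, "edges must be canonical (gene1 < gene2), no self-edges")
    if (anyDuplicated(paste(df$gene1, df$gene2, sep = "\r")))
      msg <- c(msg, "duplicate edge")
    if (any(!is.finite(df$prob)) || any(df$prob < 0) || any(df$prob > 1))
      msg <- c(msg, "edge probabilities must lie in [0,1]")
  }
  if (length(object@prior) != 1L || object@prior <= 0 || object@prior >= 1)
    msg <- c(msg, "prior must lie in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Construct a FunctionalNetwork
#'
#' @param gene1,gene2 character vectors of gene pairs (any order; canonical
#'   order is enforced).
#' @param prob posterior probabilities in `[0,1]`.
#' @param organism organism label.
#' @param prior prior probability of functional interaction.
#' @export
FunctionalNetwork <- function(gene1, gene2, prob, organism = "unknown",
                              prior = 0.05) {
  df <- canonicalPairs(data.frame(gene1 = as.character(gene1),
                                  gene2 = as.character(gene2),
                                  prob = as.numeric(prob),
                                  stringsAsFactors = FALSE))
  new("FunctionalNetwork", organism = as.character(organism),
      edges = df, prior = prior)
}

#' DatasetEvidence: discretized correlation evidence from one dataset
#'
#' @slot datasetId dataset identifier.
#' @slot pairs data.frame with columns `gene1`, `gene2`, `bin` (1-based bin
#'   index).
#' @slot nBins number of bins actually used.
#' @slot breaks numeric bin boundaries on the z-transformed correlation
#'   scale (kept for reproducibility).
#' @slot coverage genes measured in the dataset.
#' @export
setClass("DatasetEvidence",
         representation(datasetId = "character", pairs = "data.frame",
                        nBins = "integer", breaks = "numeric",
                        coverage = "character"))

setValidity("DatasetEvidence", function(object) {
  msg <- character()
  df <- object@pairs
  if (!all(c("gene1", "gene2", "bin") %in% names(df)))
    return("pairs needs columns gene1, gene2, bin")
  if (nrow(df)) {
    if (any(df$bin < 1L) || any(df$bin > object@nBins))
      msg <- c(msg, "bin indices out of range")
    g <- unique(c(df$gene1, df$gene2))
    if (!all(g %in% object@coverage))
      msg <- c(msg, "pairs contain genes outside dataset coverage")
  }
  if (length(msg)) msg else TRUE
})

#' ConditionalTable: per-dataset naive-Bayes conditional bin probabilities
#'
#' @slot datasetId dataset identifier.
#' @slot pPos,pNeg probability of each bin given a positive / negative pair
#'   (Laplace-smoothed, each sums to 1, all entries > 0).
#' @slot pseudocount the smoothing pseudocount used.
#' @export
setClass("ConditionalTable",
         representation(datasetId = "character", pPos = "numeric",
                        pNeg = "numeric", pseudocount = "numeric"))

setValidity("ConditionalTable", function(object) {
  msg <- character()
  if (length(object@pPos) != length(object@pNeg))
    msg <- c(msg, "pPos and pNeg must have the same length")
  for (nm in c("pPos", "pNeg")) {
    v <- slot(object, nm)
    if (length(v)) {
      if (abs(sum(v) - 1) > 1e-9)
        msg <- c(msg, sprintf("%s must sum to 1", nm))
      if (any(v < 0))
        msg <- c(msg, sprintf("%s must be non-negative", nm))
      # zeros only arise when smoothing was explicitly disabled
      if (object@pseudocount > 0 && any(v == 0))
        msg <- c(msg, sprintf("%s must be strictly positive (smoothed)", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Neighborhood: the functional neighborhood of a query gene
#'
#' @slot query the query gene.
#' @slot members neighbor genes (never containing the query).
#' @slot probabilities edge probability for each member (parallel vector).
#' @slot cutoffUsed the hard probability cutoff applied.
#' @slot softApplied whether the soft minimum-size rule filled the
#'   neighborhood beyond the hard cutoff.
#' @slot minProbability smallest edge probability admitted (informative when
#'   the soft rule applied).
#' @export
setClass("Neighborhood",
         representation(query = "character", members = "character",
                        probabilities = "numeric", cutoffUsed = "numeric",
                        softApplied = "logical", minProbability = "numeric"))

setValidity("Neighborhood", function(object) {
  msg <- character()
  if (object@query %in% object@members)
    msg <- c(msg, "the query gene cannot be its own neighbor")
  if (length(object@members) != length(object@probabilities))
    msg <- c(msg, "members and probabilities lengths differ")
  if (anyDuplicated(object@members))
    msg <- c(msg, "duplicate neighbor")
  if (length(msg)) msg else TRUE
})

#' MetaGeneSignature: family identifiers represented in a neighborhood
#'
#' @slot query the query gene.
#' @slot families families of the (retained) neighbor genes.
#' @slot restrictedFamilies `families` intersected with an organism-pair
#'   background (equal to `families` when no background was supplied).
#' @export
setClass("MetaGeneSignature",
         representation(query = "character", families = "character",
                        restrictedFamilies = "character"))

setValidity("MetaGeneSignature", function(object) {
  if (!all(object@restrictedFamilies %in% object@families))
    "restrictedFamilies must be a subset of families" else TRUE
})

#' BackgroundSet: organism-pair-specific family background
#'
#' Families with at least one retained, compendium-present gene in each
#' organism of the pair (or in the single organism, for within-species use).
#'
#' @slot orgPair one or two organism labels.
#' @slot families the background family identifiers.
#' @export
setClass("BackgroundSet",
         representation(orgPair = "character", families = "character"))

#' NSResult: network-similarity score between two genes
#'
#' @slot geneA,geneB the two genes compared.
#' @slot k overlap size; number of shared background-restricted families.
#' @slot K,n sizes of the two background-restricted signatures.
#' @slot N background size.
#' @slot pValue upper-tail hypergeometric probability of the overlap.
#' @slot sharedFamilies,onlyA,onlyB the overlap decomposition.
#' @slot noInformative TRUE when either restricted signature was empty (the
#'   score is then 1 by convention).
#' @export
setClass("NSResult",
         representation(geneA = "character", geneB = "character",
                        k = "integer", K = "integer", n = "integer",
                        N = "integer", pValue = "numeric",
                        sharedFamilies = "character", onlyA = "character",
                        onlyB = "character", noInformative = "logical"))

setValidity("NSResult", function(object) {
  msg <- character()
  if (object@k != length(object@sharedFamilies))
    msg <- c(msg, "k must equal |sharedFamilies|")
  if (object@k > min(object@K, object@n))
    msg <- c(msg, "k cannot exceed min(K, n)")
  if (object@K > object@N || object@n > object@N)
    msg <- c(msg, "K and n cannot exceed N")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in (0,1]")
  if (length(msg)) msg else TRUE
})

#' NSMatrix: all pairwise NS scores among a set of genes
#'
#' @slot genes gene identifiers (rownames of `scores`).
#' @slot organisms organism of each gene.
#' @slot scores symmetric matrix of -log10 NS p-values (diagonal NA).
#' @slot order display order from average-linkage clustering.
#' @export
setClass("NSMatrix",
         representation(genes = "character", organisms = "character",
                        scores = "matrix", order = "integer"))

#' HomologRanking: scored and labeled candidate homologs for one query
#'
#' @slot query the query gene.
#' @slot candidates data.frame with columns `gene`, `score`, `label`.
#' @slot scoreSource one of "network", "sequence", "combined".
#' @export
setClass("HomologRanking",
         representation(query = "character", candidates = "data.frame",
                        scoreSource = "character"))

setValidity("HomologRanking", function(object) {
  df <- object@candidates
  msg <- character()
  if (!all(c("gene", "score", "label") %in% names(df)))
    return("candidates needs columns gene, score, label")
  if (nrow(df) < 2L)
    msg <- c(msg, "a ranking needs at least two candidates")
  if (!any(df$label == "positive") || !any(df$label == "negative"))
    msg <- c(msg, "a ranking needs >=1 positive and >=1 negative")
  if (length(msg)) msg else TRUE
})

#' AUCResult: pooled normalized-rank AUC with significance
#'
#' @slot auc area under the curve on pooled normalized ranks.
#' @slot pValue significance of the AUC against the null of random ranking.
#' @slot nQueries,nPairs numbers of queries and pooled pairs.
#' @slot normalizedRanks pooled per-pair normalized ranks in `[0,1]`.
#' @slot labels labels parallel to `normalizedRanks`.
#' @slot method significance method used.
#' @export
setClass("AUCResult",
         representation(auc = "numeric", pValue = "numeric",
                        nQueries = "integer", nPairs = "integer",
                        normalizedRanks = "numeric", labels = "character",
                        method = "character"))

#' SyntheticSpec: parameters of the two-species synthetic benchmark
#'
#' Defaults describe the package's standard benchmark: 2 organisms x 300
#' genes, 60 shared families (15 of them two-member, Snap25-style
#' duplication families), 6 co-expression modules, 8 datasets x 20 samples.
#'
#' @slot organisms two organism labels.
#' @slot nGenes genes per organism.
#' @slot nFamilies shared families.
#' @slot nModules planted co-expression modules.
#' @slot nDuplicationFamilies families with exactly two members per
#'   organism, placed in two different modules (lineage-specific-duplication
#'   style).
#' @slot nDatasets,nSamples compendium size per organism.
#' @slot signal module signal strength (latent profile loading).
#' @slot noiseSd standard deviation of additive Gaussian noise.
#' @slot annotationFraction fraction of genes receiving a module-derived
#'   term annotation.
#' @slot termsPerModule number of specific terms each module is split into.
#' @slot seed base RNG seed.
#' @export
setClass("SyntheticSpec",
         representation(organisms = "character", nGenes = "integer",
                        nFamilies = "integer", nModules = "integer",
                        nDuplicationFamilies = "integer",
                        nDatasets = "integer", nSamples = "integer",
                        signal = "numeric", noiseSd = "numeric",
                        annotationFraction = "numeric",
                        termsPerModule = "integer", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (length(object@organisms) != 2L ||
      anyDuplicated(object@organisms))
    msg <- c(msg, "exactly two distinct organisms required")
  if (object@nModules < 2L) msg <- c(msg, "need >=2 modules")
  if (object@nDuplicationFamilies > object@nFamilies)
    msg <- c(msg, "more duplication families than families")
  big <- object@nFamilies - object@nDuplicationFamilies
  rest <- object@nGenes - 2L * object@nDuplicationFamilies
  if (rest < big || (big > 0L && rest %% big != 0L))
    msg <- c(msg, sprintf(
      "nGenes - 2*nDuplicationFamilies (%d) must be a positive multiple of the %d non-duplication families",
      rest, big))
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@annotationFraction < 0 || object@annotationFraction > 1)
    msg <- c(msg, "annotationFraction must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: planted structure behind a synthetic benchmark
#'
#' @slot modules named integer vector: module index of every gene (both
#'   organisms).
#' @slot analogs data.frame of cross-species same-family, same-module pairs
#'   (columns `geneA`, `geneB`, `family`, `module`).
#' @slot decoys data.frame of cross-species same-family, different-module
#'   pairs (same columns plus `moduleB`).
#' @slot duplicationFamilies identifiers of the planted duplication
#'   families.
#' @slot moduleTerms list: for each module, its specific term identifiers.
#' @export
setClass("GroundTruth",
         representation(modules = "integer", analogs = "data.frame",
                        decoys = "data.frame",
                        duplicationFamilies = "character",
                        moduleTerms = "list"))

#' FamilyAnnotation: family-level term annotations (union over members)
#'
#' A family is annotated to a term if any retained member gene carries an
#' experimental annotation for that term, in any organism.
#'
#' @slot annotations data.frame with columns `family`, `term`.
#' @export
setClass("FamilyAnnotation",
         representation(annotations = "data.frame"))
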