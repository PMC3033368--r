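#' @include AllClasses.R
NULL

#' Accessors for homologNS classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("datasetId", function(object) standardGeneric("datasetId"))
#' @rdname accessors
#' @export
setMethod("datasetId", "ExpressionDataset", function(object) object@datasetId)
#' @rdname accessors
#' @export
setMethod("datasetId", "DatasetEvidence", function(object) object@datasetId)
#' @rdname accessors
#' @export
setMethod("datasetId", "ConditionalTable", function(object) object@datasetId)

#' @rdname accessors
#' @export
setGeneric("exprsMatrix", function(object) standardGeneric("exprsMatrix"))
#' @rdname accessors
#' @export
setMethod("exprsMatrix", "ExpressionDataset",
          function(object) assay(object, "exprs"))

#' @rdname accessors
#' @export
setGeneric("familyEntries", function(object) standardGeneric("familyEntries"))
#' @rdname accessors
#' @export
setMethod("familyEntries", "FamilyMap", function(object) object@entries)

#' @rdname accessors
#' @export
setGeneric("excludedGenes", function(object) standardGeneric("excludedGenes"))
#' @rdname accessors
#' @export
setMethod("excludedGenes", "FamilyMap", function(object) object@excludedGenes)

#' Family of each gene under a FamilyMap
#'
#' @param object a [FamilyMap-class].
#' @param genes character vector; genes not retained in the map yield `NA`.
#' @return named character vector of family identifiers.
#' @export
setGeneric("familyOf", function(object, genes) standardGeneric("familyOf"))
#' @rdname familyOf
#' @export
setMethod("familyOf", "FamilyMap", function(object, genes) {
  e <- object@entries
  setNames(e$family[match(genes, e$gene)], genes)
})

#' @rdname accessors
#' @export
setGeneric("annotationRecords",
           function(object) standardGeneric("annotationRecords"))
#' @rdname accessors
#' @export
setMethod("annotationRecords", "AnnotationSet",
          function(object) object@records)

#' @rdname accessors
#' @export
setGeneric("specificTerms", function(object) standardGeneric("specificTerms"))
#' @rdname accessors
#' @export
setMethod("specificTerms", "AnnotationSet",
          function(object) object@specificTerms)

#' @rdname accessors
#' @export
setGeneric("positives", function(object) standardGeneric("positives"))
#' @rdname accessors
#' @export
setMethod("positives", "PairStandard", function(object) object@positives)

#' @rdname accessors
#' @export
setGeneric("negatives", function(object) standardGeneric("negatives"))
#' @rdname accessors
#' @export
setMethod("negatives", "PairStandard", function(object) object@negatives)

#' @rdname accessors
#' @export
setGeneric("priorOf", function(object) standardGeneric("priorOf"))
#' @rdname accessors
#' @export
setMethod("priorOf", "PairStandard", function(object) object@prior)
#' @rdname accessors
#' @export
setMethod("priorOf", "FunctionalNetwork", function(object) object@prior)

#' @rdname accessors
#' @export
setGeneric("organismOf", function(object) standardGeneric("organismOf"))
#' @rdname accessors
#' @export
setMethod("organismOf", "FunctionalNetwork", function(object) object@organism)

#' @rdname accessors
#' @export
setGeneric("edges", function(object) standardGeneric("edges"))
#' @rdname accessors
#' @export
setMethod("edges", "FunctionalNetwork", function(object) object@edges)

#' Genes present in a network
#'
#' @param object a [FunctionalNetwork-class].
#' @export
setGeneric("networkGenes", function(object) standardGeneric("networkGenes"))
#' @rdname networkGenes
#' @export
setMethod("networkGenes", "FunctionalNetwork", function(object)
  sort(unique(c(object@edges$gene1, object@edges$gene2))))

#' @rdname accessors
#' @export
setGeneric("standardEntries",
           function(object) standardGeneric("standardEntries"))
#' @rdname accessors
#' @export
setMethod("standardEntries", "HomologPairStandard",
          function(object) object@entries)

#' @rdname accessors
#' @export
setGeneric("members", function(object) standardGeneric("members"))
#' @rdname accessors
#' @export
setMethod("members", "Neighborhood", function(object)
  setNames(object@probabilities, object@members))

#' @rdname accessors
#' @export
setGeneric("softApplied", function(object) standardGeneric("softApplied"))
#' @rdname accessors
#' @export
setMethod("softApplied", "Neighborhood", function(object) object@softApplied)

#' @rdname accessors
#' @export
setGeneric("families", function(object) standardGeneric("families"))
#' @rdname accessors
#' @export
setMethod("families", "MetaGeneSignature", function(object) object@families)
#' @rdname accessors
#' @export
setMethod("families", "BackgroundSet", function(object) object@families)

#' @rdname accessors
#' @export
setGeneric("restrictedFamilies",
           function(object) standardGeneric("restrictedFamilies"))
#' @rdname accessors
#' @export
setMethod("restrictedFamilies", "MetaGeneSignature",
          function(object) object@restrictedFamilies)

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setMethod("pValue", "NSResult", function(object) object@pValue)
#' @rdname accessors
#' @export
setMethod("pValue", "AUCResult", function(object) object@pValue)

#' @rdname accessors
#' @export
setGeneric("sharedFamilies",
           function(object) standardGeneric("sharedFamilies"))
#' @rdname accessors
#' @export
setMethod("sharedFamilies", "NSResult", function(object)
  object@sharedFamilies)

#' @rdname accessors
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))
#' @rdname accessors
#' @export
setMethod("auc", "AUCResult", function(object) object@auc)

#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(object) standardGeneric("scoreMatrix"))
#' @rdname accessors
#' @export
setMethod("scoreMatrix", "NSMatrix", function(object) object@scores)

#' @rdname accessors
#' @export
setGeneric("clusterOrder", function(object) standardGeneric("clusterOrder"))
#' @rdname accessors
#' @export
setMethod("clusterOrder", "NSMatrix", function(object) object@order)

#' @rdname accessors
#' @export
setGeneric("familyTerms", function(object) standardGeneric("familyTerms"))
#' @rdname accessors
#' @export
setMethod("familyTerms", "FamilyAnnotation",
          function(object) object@annotations)

setMethod("show", "FamilyMap", function(object) {
  cat(sprintf("FamilyMap: %d genes in %d families (%d excluded as multi-family)\n",
              nrow(object@entries), length(unique(object@entries$family)),
              length(object@excludedGenes)))
})

setMethod("show", "FunctionalNetwork", function(object) {
  cat(sprintf("FunctionalNetwork [%s]: %d genes, %d edges, prior %.3g\n",
              object@organism, length(networkGenes(object)),
              nrow(object@edges), object@prior))
})

setMethod("show", "PairStandard", function(object) {
  cat(sprintf("PairStandard: %d positives, %d negatives (prior %.4g)\n",
              nrow(object@positives), nrow(object@negatives), object@prior))
})

setMethod("show", "HomologPairStandard", function(object) {
  df <- object@entries
  cat(sprintf("HomologPairStandard [%s vs %s]: %d queries, %d pairs (%d+/%d-)\n",
              object@orgPair[1], object@orgPair[2],
              length(unique(df$query)), nrow(df),
              sum(df$label == "positive"), sum(df$label == "negative")))
})

setMethod("show", "Neighborhood", function(object) {
  cat(sprintf("Neighborhood of %s: %d members (cutoff %.2f%s)\n",
              object@query, length(object@members), object@cutoffUsed,
              if (object@softApplied) ", soft minimum applied" else ""))
})

setMethod("show", "NSResult", function(object) {
  cat(sprintf("NS score %s vs %s: overlap k=%d (K=%d, n=%d, N=%d), p = %.4g%s\n",
              object@geneA, object@geneB, object@k, object@K, object@n,
              object@N, object@pValue,
              if (object@noInformative) " [no informative neighborhood]" else ""))
})

setMethod("show", "AUCResult", function(object) {
  cat(sprintf("Pooled normalized-rank AUC = %.4f (p = %.3g; %d queries, %d pairs; %s)\n",
              object@auc, object@pValue, object@nQueries, object@nPairs,
              object@method))
})

setMethod("show", "NSMatrix", function(object) {
  cat(sprintf("NSMatrix: %d genes (-log10 p), clustering order: %s\n",
              length(object@genes),
              paste(object@genes[object@order], collapse = ", ")))
})
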