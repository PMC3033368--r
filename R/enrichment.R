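#' @include AllClasses.R utils.R nsScore.R
NULL

#' Family-level annotations from per-organism gene annotations
#'
#' A family is considered annotated to a term if any retained member gene
#' (in any organism) carries an experimental annotation for that term;
#' families with no annotated member are absent from the result.
#'
#' @param annotationSets list of [AnnotationSet-class] objects
#'   (pre-filtered to experimental evidence, as [readAnnotations()] does).
#' @param fm a [FamilyMap-class].
#' @return A [FamilyAnnotation-class].
#' @export
familyAnnotations <- function(annotationSets, fm) {
  if (is(annotationSets, "AnnotationSet"))
    annotationSets <- list(annotationSets)
  rec <- do.call(rbind, lapply(annotationSets, function(a)
    annotationRecords(a)[c("gene", "term")]))
  if (is.null(rec) || !nrow(rec))
    return(new("FamilyAnnotation",
               annotations = data.frame(family = character(),
                                        term = character(),
                                        stringsAsFactors = FALSE)))
  rec$family <- unname(familyOf(fm, rec$gene))
  rec <- rec[!is.na(rec$family), c("family", "term")]
  rec <- unique(rec)
  rec <- rec[order(rec$family, rec$term), , drop = FALSE]
  rownames(rec) <- NULL
  new("FamilyAnnotation", annotations = rec)
}

#' Term enrichment of a family set against an organism-pair background
#'
#' For each term with at least one annotated family in the background, the
#' upper-tail hypergeometric probability of the query set's annotated
#' count is computed with the background as the urn, then
#' Benjamini-Hochberg adjusted. Because the urn is the organism-pair
#' background, the same query set can yield different enrichments for
#' different organism pairs.
#'
#' @param queryFamilies character vector; must be a subset of the
#'   background families.
#' @param background a [BackgroundSet-class].
#' @param fa a [FamilyAnnotation-class].
#' @param fdr significance threshold on the adjusted values; default 0.05.
#' @return data.frame sorted by p with columns `term`, `k`, `K`, `n`, `N`,
#'   `p`, `q`, `significant`.
#' @export
enrichFamilies <- function(queryFamilies, background, fa, fdr = 0.05) {
  bg <- families(background)
  queryFamilies <- unique(queryFamilies)
  stray <- setdiff(queryFamilies, bg)
  if (length(stray))
    stop("query families outside the background: ",
         paste(stray, collapse = ", "))
  ann <- familyTerms(fa)
  ann <- ann[ann$family %in% bg, , drop = FALSE]
  if (!nrow(ann))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), significant = logical()))
  Ks <- tapply(ann$family, ann$term, function(f) length(unique(f)))
  inQuery <- ann[ann$family %in% queryFamilies, , drop = FALSE]
  ks <- tapply(inQuery$family, inQuery$term, function(f) length(unique(f)))
  terms <- names(Ks)
  k <- ifelse(terms %in% names(ks), ks[terms], 0L)
  res <- data.frame(term = terms, k = as.integer(k),
                    K = as.integer(Ks[terms]),
                    n = length(queryFamilies), N = length(bg),
                    stringsAsFactors = FALSE)
  res$p <- hypergeomTail(res$k, res$K, res$n, res$N)
  res$q <- p.adjust(res$p, method = "BH")
  res$significant <- res$q <= fdr
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
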