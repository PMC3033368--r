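#' @include AllClasses.R utils.R
NULL

.neighborProbs <- function(net, gene) {
  df <- edges(net)
  s1 <- df$gene1 == gene
  s2 <- df$gene2 == gene
  c(setNames(df$prob[s1], df$gene2[s1]), setNames(df$prob[s2], df$gene1[s2]))
}

.pickNeighborhood <- function(nb, query, hardCutoff, softMin) {
  hard <- nb[nb >= hardCutoff]
  softApplied <- FALSE
  if (softMin > 0L && length(hard) < softMin) {
    # soft minimum: take the top softMin neighbors by probability (or the
    # whole degree if smaller); ties at the boundary broken by gene id
    o <- order(-nb, names(nb))
    take <- min(softMin, length(nb))
    hard <- nb[o[seq_len(take)]]
    softApplied <- TRUE
  }
  new("Neighborhood", query = query, members = names(hard),
      probabilities = unname(hard), cutoffUsed = hardCutoff,
      softApplied = softApplied,
      minProbability = if (length(hard)) min(hard) else NA_real_)
}

#' Extract the functional neighborhood of a query gene
#'
#' The hard cutoff keeps every neighbor whose edge probability reaches
#' `hardCutoff` (0.5 by default, the natural probability threshold). When
#' fewer than `softMin` neighbors pass, the soft minimum-size rule admits
#' the top `softMin` neighbors by probability instead (or the gene's whole
#' degree if smaller); `softMin = 0` disables the floor.
#'
#' @param net a [FunctionalNetwork-class].
#' @param gene query gene (must be present in the network).
#' @param hardCutoff hard probability cutoff, default 0.5.
#' @param softMin soft minimum neighborhood size, default 50.
#' @return A [Neighborhood-class].
#' @export
getNeighborhood <- function(net, gene, hardCutoff = 0.5, softMin = 50L) {
  nb <- .neighborProbs(net, gene)
  if (!length(nb) && !gene %in% networkGenes(net))
    stop("gene '", gene, "' is absent from the network")
  .pickNeighborhood(nb, gene, hardCutoff, softMin)
}

#' Neighborhoods of every gene in a network
#'
#' Single pass over the edge list; equivalent to calling
#' [getNeighborhood()] per gene but much faster on whole networks.
#'
#' @inheritParams getNeighborhood
#' @return named list of [Neighborhood-class] objects.
#' @export
allNeighborhoods <- function(net, hardCutoff = 0.5, softMin = 50L) {
  df <- edges(net)
  gene <- c(df$gene1, df$gene2)
  other <- c(df$gene2, df$gene1)
  prob <- c(df$prob, df$prob)
  sp <- split(setNames(prob, other), gene)
  lapply(setNames(names(sp), names(sp)), function(g)
    .pickNeighborhood(sp[[g]], g, hardCutoff, softMin))
}

#' Project a neighborhood onto species-independent meta-genes
#'
#' The signature is the set of families of the neighborhood's retained
#' genes (a family counts as present if any member gene is present).
#' Neighbors that are unmapped or excluded for multi-family membership are
#' dropped with a logged count.
#'
#' @param nb a [Neighborhood-class].
#' @param fm a [FamilyMap-class].
#' @param background optional [BackgroundSet-class]; when supplied,
#'   `restrictedFamilies` is the signature intersected with it.
#' @return A [MetaGeneSignature-class].
#' @export
toMetagenes <- function(nb, fm, background = NULL) {
  fams <- familyOf(fm, nb@members)
  dropped <- sum(is.na(fams))
  if (dropped == length(fams) && length(fams))
    warning("all neighbors of '", nb@query, "' are unmapped: empty signature")
  else if (dropped > 0L)
    message(dropped, " unmapped neighbor(s) of '", nb@query, "' dropped")
  fams <- sort(unique(fams[!is.na(fams)]))
  restricted <- if (is.null(background)) fams
  else intersect(fams, families(background))
  new("MetaGeneSignature", query = nb@query, families = fams,
      restrictedFamilies = restricted)
}

#' Build the organism-pair-specific family background
#'
#' A family belongs to the background when each organism of the pair
#' contributes at least one retained gene that is also present in that
#' organism's expression compendium. With a single organism the analogous
#' within-species background is produced.
#'
#' @param fm a [FamilyMap-class].
#' @param compendiumGenes named list (by organism) of character vectors of
#'   compendium-present genes.
#' @param orgPair one or two organism labels (must name entries of
#'   `compendiumGenes`).
#' @return A [BackgroundSet-class].
#' @export
buildBackground <- function(fm, compendiumGenes, orgPair) {
  stopifnot(length(orgPair) %in% 1:2,
            all(orgPair %in% names(compendiumGenes)))
  e <- familyEntries(fm)
  famSets <- lapply(orgPair, function(org) {
    sub <- e[e$organism == org & e$gene %in% compendiumGenes[[org]], ,
             drop = FALSE]
    unique(sub$family)
  })
  fams <- sort(Reduce(intersect, famSets))
  if (!length(fams))
    stop("empty background for organism pair ",
         paste(orgPair, collapse = "/"), ": no scoring possible")
  new("BackgroundSet", orgPair = orgPair, families = fams)
}
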