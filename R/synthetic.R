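#' @include AllClasses.R utils.R goldStandard.R integration.R neighborhoods.R evaluation.R
NULL

#' Describe a two-species synthetic benchmark
#'
#' The generator emulates the structure the NS method assumes: two species
#' sharing a family structure, each with planted co-expression modules so
#' that functionally analogous genes (same family, same module) have
#' similar meta-gene neighborhoods. A subset of families are two-member
#' "duplication" families whose per-species duplicates sit in two different
#' modules, mimicking lineage-specific duplications with divergent
#' (e.g. neuronal vs. broad) expression.
#'
#' @param organisms two organism labels.
#' @param nGenes genes per organism (default 300).
#' @param nFamilies shared families (default 60).
#' @param nModules co-expression modules (default 6).
#' @param nDuplicationFamilies two-member duplication families (default
#'   15); the remaining genes are spread evenly over the other families.
#' @param nDatasets expression datasets per organism (default 8).
#' @param nSamples samples per dataset (default 20).
#' @param signal module signal strength (default 1).
#' @param noiseSd additive Gaussian noise standard deviation (default
#'   0.5, i.e. a within-module correlation of about 0.8).
#' @param annotationFraction fraction of genes receiving a module-derived
#'   specific-term annotation (default 0.8).
#' @param termsPerModule specific terms per module (default 4); annotation
#'   terms are module-derived so that co-annotation mirrors module
#'   co-membership while keeping the positive set sparse.
#' @param seed RNG seed.
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(organisms = c("speciesA", "speciesB"),
                          nGenes = 300L, nFamilies = 60L, nModules = 6L,
                          nDuplicationFamilies = 15L, nDatasets = 8L,
                          nSamples = 20L, signal = 1, noiseSd = 0.5,
                          annotationFraction = 0.8, termsPerModule = 4L,
                          seed = 1L) {
  new("SyntheticSpec", organisms = as.character(organisms),
      nGenes = as.integer(nGenes), nFamilies = as.integer(nFamilies),
      nModules = as.integer(nModules),
      nDuplicationFamilies = as.integer(nDuplicationFamilies),
      nDatasets = as.integer(nDatasets), nSamples = as.integer(nSamples),
      signal = as.numeric(signal), noiseSd = as.numeric(noiseSd),
      annotationFraction = as.numeric(annotationFraction),
      termsPerModule = as.integer(termsPerModule), seed = as.integer(seed))
}

#' Generate a synthetic two-species benchmark
#'
#' Produces per-organism expression compendia with planted module
#' structure, a shared family map (module assignments mirrored across
#' organisms so every analog has a counterpart), module-derived
#' experimental annotations, and the ground truth of analog (same family,
#' same module) and decoy (same family, different module) cross-species
#' pairs. Fixed seed implies byte-identical output.
#'
#' Expression model: per dataset each module draws a latent condition
#' profile; a gene's expression is `signal * profile[module] + N(0,
#' noiseSd)`.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with elements `spec`, `compendia` (named list per organism
#'   of [ExpressionDataset-class] lists), `familyMap`, `annotations`
#'   (named list of [AnnotationSet-class]), and `groundTruth`
#'   ([GroundTruth-class]).
#' @export
generateSynthetic <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    nDup <- spec@nDuplicationFamilies
    nBig <- spec@nFamilies - nDup
    bigSize <- (spec@nGenes - 2L * nDup) %/% max(nBig, 1L)
    famIds <- sprintf("F%03d", seq_len(spec@nFamilies))
    famSizes <- c(rep(2L, nDup), rep(bigSize, nBig))
    names(famSizes) <- famIds
    # mirrored module plan: slot j of family f has the same module in both
    # organisms; duplication families get two distinct modules
    slotModules <- lapply(seq_along(famIds), function(i) {
      if (i <= nDup) sample.int(spec@nModules, 2L)
      else sample.int(spec@nModules, famSizes[i], replace = TRUE)
    })
    famVec <- rep(famIds, famSizes)
    modVec <- unlist(slotModules, use.names = FALSE)
    geneIds <- lapply(spec@organisms, function(org)
      sprintf("%s_g%03d", org, seq_len(spec@nGenes)))
    names(geneIds) <- spec@organisms
    fm <- FamilyMap(gene = unlist(geneIds, use.names = FALSE),
                    organism = rep(spec@organisms, each = spec@nGenes),
                    family = rep(famVec, times = 2L))
    modules <- setNames(rep(modVec, times = 2L),
                        unlist(geneIds, use.names = FALSE))
    # ground truth: cross-species same-family pairs, split by module match
    crossIdx <- split(seq_len(spec@nGenes), famVec)
    pairRows <- lapply(famIds, function(f) {
      idx <- crossIdx[[f]]
      g <- expand.grid(a = idx, b = idx)
      data.frame(geneA = geneIds[[1L]][g$a], geneB = geneIds[[2L]][g$b],
                 family = f, module = modVec[g$a],
                 moduleB = modVec[g$b], stringsAsFactors = FALSE)
    })
    pairs <- do.call(rbind, pairRows)
    analogs <- pairs[pairs$module == pairs$moduleB,
                     c("geneA", "geneB", "family", "module")]
    decoys <- pairs[pairs$module != pairs$moduleB, ]
    rownames(analogs) <- rownames(decoys) <- NULL
    moduleTerms <- lapply(seq_len(spec@nModules), function(m)
      sprintf("M%d.%d", m, seq_len(spec@termsPerModule)))
    allTerms <- unlist(moduleTerms, use.names = FALSE)
    annotations <- lapply(spec@organisms, function(org) {
      g <- geneIds[[org]]
      keep <- runif(length(g)) < spec@annotationFraction
      mods <- modules[g[keep]]
      term <- vapply(mods, function(m)
        moduleTerms[[m]][sample.int(spec@termsPerModule, 1L)], "")
      suppressWarnings(AnnotationSet(
        data.frame(gene = g[keep], term = unname(term), evidence = "IDA",
                   stringsAsFactors = FALSE),
        specificTerms = allTerms, organism = org))
    })
    names(annotations) <- spec@organisms
    compendia <- lapply(spec@organisms, function(org) {
      lapply(seq_len(spec@nDatasets), function(d) {
        profile <- matrix(rnorm(spec@nModules * spec@nSamples),
                          spec@nModules, spec@nSamples)
        noise <- matrix(rnorm(spec@nGenes * spec@nSamples,
                              sd = spec@noiseSd),
                        spec@nGenes, spec@nSamples)
        mat <- spec@signal * profile[modules[geneIds[[org]]], ,
                                     drop = FALSE] + noise
        dimnames(mat) <- list(geneIds[[org]],
                              sprintf("s%02d", seq_len(spec@nSamples)))
        ExpressionDataset(mat, sprintf("%s_ds%02d", org, d))
      })
    })
    names(compendia) <- spec@organisms
    gt <- new("GroundTruth", modules = as.integer(modules),
              analogs = analogs, decoys = decoys,
              duplicationFamilies = famIds[seq_len(nDup)],
              moduleTerms = moduleTerms)
    names(gt@modules) <- names(modules)
    list(spec = spec, compendia = compendia, familyMap = fm,
         annotations = annotations, groundTruth = gt)
  })
}

#' Concentrate annotations on one member per family (annotation bias)
#'
#' Emulates the literature bias where one member of a homologous family is
#' studied far more thoroughly than the others: within each family the
#' most-annotated member (ties broken by gene id) is kept intact and each
#' annotation record of the other members is removed with probability
#' `biasFraction`.
#'
#' @param ann an [AnnotationSet-class].
#' @param biasFraction fraction of non-focal records removed, in `[0,1]`.
#' @param fm a [FamilyMap-class] defining the families.
#' @param seed RNG seed.
#' @return the corrupted [AnnotationSet-class].
#' @export
corruptAnnotations <- function(ann, biasFraction, fm, seed) {
  stopifnot(biasFraction >= 0, biasFraction <= 1)
  rec <- annotationRecords(ann)
  if (!nrow(rec)) return(ann)
  fam <- unname(familyOf(fm, rec$gene))
  counts <- table(rec$gene)
  focal <- tapply(seq_len(nrow(rec)), fam, function(idx) {
    g <- unique(rec$gene[idx])
    g[order(-as.integer(counts[g]), g)][1L]
  })
  isFocal <- rec$gene == unname(focal[fam]) | is.na(fam)
  keep <- withSeed(seed,
                   isFocal | runif(nrow(rec)) >= biasFraction)
  new("AnnotationSet", records = rec[keep, , drop = FALSE],
      specificTerms = specificTerms(ann), organism = ann@organism)
}

#' Homolog-pair standard from synthetic ground truth
#'
#' Analog pairs become positives, decoy pairs negatives; queries without at
#' least one of each are dropped.
#'
#' @param gt a [GroundTruth-class].
#' @param orgPair character(2): query organism first. When the query
#'   organism is the second species of the generator, pairs are transposed
#'   accordingly.
#' @param spec the [SyntheticSpec-class] the truth came from.
#' @return A [HomologPairStandard-class].
#' @export
groundTruthStandard <- function(gt, spec, orgPair = spec@organisms) {
  flip <- !identical(orgPair[1L], spec@organisms[1L])
  pick <- function(df, label) {
    if (!nrow(df)) return(NULL)
    data.frame(query = if (flip) df$geneB else df$geneA,
               candidate = if (flip) df$geneA else df$geneB,
               label = label, stringsAsFactors = FALSE)
  }
  df <- rbind(pick(gt@analogs, "positive"), pick(gt@decoys, "negative"))
  .finalizeHomologStandard(df, orgPair)
}

#' Run the full synthetic benchmark end to end
#'
#' Generates a two-species benchmark, builds each organism's integration
#' standard from the synthetic annotations, integrates each compendium
#' into a functional network, scores every ground-truth homolog pair with
#' the NS score, and evaluates analog recovery with the pooled
#' normalized-rank AUC.
#'
#' @param spec a [SyntheticSpec-class].
#' @param hardCutoff,softMin neighborhood parameters.
#' @param prior integration prior (default 0.05).
#' @param nBins,pseudocount integration parameters.
#' @return list with `auc` ([AUCResult-class]), `networks`, `background`,
#'   `standard`, `scores` and the generated `data`.
#' @export
runSyntheticBenchmark <- function(spec, hardCutoff = 0.5, softMin = 50L,
                                  prior = 0.05, nBins = 5L,
                                  pseudocount = 1) {
  data <- generateSynthetic(spec)
  fm <- data$familyMap
  networks <- lapply(seq_along(spec@organisms), function(i) {
    org <- spec@organisms[i]
    std <- buildIntegrationStandard(data$annotations[[org]], fm,
                                    prior = prior,
                                    seed = childSeed(spec@seed, i))
    integrateCompendium(data$compendia[[org]], std, prior = prior,
                        nBins = nBins, pseudocount = pseudocount,
                        organism = org)
  })
  names(networks) <- spec@organisms
  compendiumGenes <- lapply(data$compendia, function(cc)
    rownames(exprsMatrix(cc[[1L]])))
  background <- buildBackground(fm, compendiumGenes, spec@organisms)
  standard <- groundTruthStandard(data$groundTruth, spec)
  scores <- scoreHomologStandard(standard, networks[[1L]], networks[[2L]],
                                 fm, background, hardCutoff, softMin)
  eval <- evaluateRanking(standard, scores)
  list(auc = eval$results$network, networks = networks,
       background = background, standard = standard, scores = scores,
       data = data)
}
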