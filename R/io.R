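#' @include AllClasses.R utils.R
NULL

.readTsv <- function(path, ...) {
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE,
             na.strings = c("NA", ""), quote = "", ...)
}

.provenanceHeader <- function(con, what, config = list()) {
  cat(sprintf("# homologNS %s | %s\n", what,
              format(Sys.time(), "%Y-%m-%d")), file = con)
  if (length(config)) {
    kv <- paste(names(config), vapply(config, function(x)
      paste(format(x), collapse = ","), ""), sep = "=")
    cat(sprintf("# config: %s\n", paste(kv, collapse = " ")), file = con)
  }
}

#' Read an expression matrix
#'
#' Tab-delimited, first column gene identifiers, header row of sample
#' identifiers. Both `NA` and empty cells denote missing values; any other
#' non-numeric cell also becomes missing.
#'
#' @param path file path.
#' @param datasetId dataset identifier; defaults to the file name without
#'   extension.
#' @return An [ExpressionDataset-class].
#' @export
readExpressionMatrix <- function(path,
                                 datasetId = sub("\\.[^.]*$", "",
                                                 basename(path))) {
  df <- .readTsv(path, colClasses = "character")
  if (ncol(df) < 3L)
    stop("expression matrix '", path, "' needs >=2 sample columns")
  genes <- df[[1L]]
  if (anyNA(genes) || any(!nzchar(genes)))
    stop("expression matrix '", path, "' has an empty gene identifier")
  if (anyDuplicated(genes))
    stop("duplicate gene identifier(s) in '", path, "': ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  mat <- suppressWarnings(
    vapply(df[-1L], function(col) as.numeric(col), numeric(nrow(df))))
  mat <- matrix(mat, nrow = length(genes),
                dimnames = list(genes, names(df)[-1L]))
  ExpressionDataset(mat, datasetId)
}

#' Write an expression matrix
#'
#' @param ds an [ExpressionDataset-class].
#' @param path output file path.
#' @export
writeExpressionMatrix <- function(ds, path) {
  mat <- exprsMatrix(ds)
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-family map
#'
#' TSV with columns `gene_id`, `organism`, `family_id` (TreeFam-B style).
#' Genes appearing under more than one family are excluded from the map and
#' recorded, so that every retained gene maps to exactly one family.
#'
#' @param path file path.
#' @return A [FamilyMap-class].
#' @export
readFamilyMap <- function(path) {
  df <- .readTsv(path)
  need <- c("gene_id", "organism", "family_id")
  if (!all(need %in% names(df)))
    stop("family map '", path, "' must have columns ",
         paste(need, collapse = ", "))
  fm <- FamilyMap(df$gene_id, df$organism, df$family_id)
  if (length(excludedGenes(fm)))
    message(length(excludedGenes(fm)),
            " gene(s) excluded for multi-family membership")
  fm
}

#' Write a gene-family map
#'
#' Retained entries only; exclusion is therefore idempotent across a
#' write/read round trip.
#'
#' @param fm a [FamilyMap-class].
#' @param path output file path.
#' @export
writeFamilyMap <- function(fm, path) {
  e <- familyEntries(fm)
  out <- data.frame(gene_id = e$gene, organism = e$organism,
                    family_id = e$family, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.parseGaf <- function(lines, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 7L)
  if (length(bad))
    stop("unparseable line ", bad[1L], " in '", path,
         "': expected >=7 tab-separated columns")
  data.frame(gene = vapply(fields, `[[`, "", 2L),
             term = vapply(fields, `[[`, "", 5L),
             evidence = vapply(fields, `[[`, "", 7L),
             stringsAsFactors = FALSE)
}

#' Read gene annotations
#'
#' Accepts either GAF 2.x (columns 2, 5 and 7: object id, term, evidence)
#' or a 3-column TSV `gene<tab>term<tab>evidence`. Records whose evidence
#' code is not in `evidenceCodes` are dropped with a logged count.
#'
#' @param path file path.
#' @param specificTerms character vector of biologically specific term
#'   identifiers; empty means "treat all observed terms as specific" (a
#'   warning is emitted).
#' @param evidenceCodes accepted evidence vocabulary; defaults to the GO
#'   experimental codes, [experimentalEvidenceCodes()].
#' @param organism optional organism label attached to the set.
#' @return An [AnnotationSet-class].
#' @export
readAnnotations <- function(path, specificTerms = character(),
                            evidenceCodes = experimentalEvidenceCodes(),
                            organism = "") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & !startsWith(lines, "#") &
                   nzchar(lines)]
  if (!length(lines)) {
    rec <- data.frame(gene = character(), term = character(),
                      evidence = character(), stringsAsFactors = FALSE)
  } else {
    nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
    if (max(nfield) <= 3L) {
      hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
      if (identical(tolower(hdr[1:3]), c("gene", "term", "evidence")))
        lines <- lines[-1L]
      bad <- which(lengths(strsplit(lines, "\t", fixed = TRUE)) != 3L)
      if (length(bad))
        stop("unparseable line ", bad[1L], " in '", path,
             "': expected 3 tab-separated columns")
      parts <- strsplit(lines, "\t", fixed = TRUE)
      rec <- data.frame(gene = vapply(parts, `[[`, "", 1L),
                        term = vapply(parts, `[[`, "", 2L),
                        evidence = vapply(parts, `[[`, "", 3L),
                        stringsAsFactors = FALSE)
    } else {
      rec <- .parseGaf(lines, path)
    }
  }
  keep <- rec$evidence %in% evidenceCodes
  if (any(!keep))
    message(sum(!keep), " annotation record(s) dropped: non-experimental evidence")
  AnnotationSet(rec[keep, , drop = FALSE], specificTerms = specificTerms,
                organism = organism)
}

#' Write / read a functional network
#'
#' Networks are serialized as TSV `gene1<tab>gene2<tab>probability` with the
#' pair in canonical order (lexicographically smaller gene first) and the
#' probability printed with full precision. A provenance header records the
#' organism and prior; `readNetwork` restores both, so
#' `readNetwork(writeNetwork(net))` is the identity.
#'
#' @param net a [FunctionalNetwork-class].
#' @param path file path.
#' @return `writeNetwork` returns `path` invisibly; `readNetwork` a
#'   [FunctionalNetwork-class].
#' @export
writeNetwork <- function(net, path) {
  stopifnot(is(net, "FunctionalNetwork"))
  validObject(net)
  con <- file(path, "w")
  on.exit(close(con))
  .provenanceHeader(con, "network",
                    list(organism = organismOf(net), prior = priorOf(net)))
  cat(sprintf("# organism: %s\n# prior: %.17g\n", organismOf(net),
              priorOf(net)), file = con)
  df <- edges(net)
  cat("gene1\tgene2\tprobability\n", file = con)
  if (nrow(df))
    writeLines(sprintf("%s\t%s\t%.17g", df$gene1, df$gene2, df$prob), con)
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  organism <- sub("^# organism: ", "", grep("^# organism: ", hdr, value = TRUE))
  prior <- as.numeric(sub("^# prior: ", "", grep("^# prior: ", hdr,
                                                 value = TRUE)))
  if (!length(organism)) organism <- "unknown"
  if (!length(prior) || is.na(prior)) prior <- 0.05
  df <- .readTsv(path)
  if (!all(c("gene1", "gene2", "probability") %in% names(df)))
    stop("network file '", path,
         "' must have columns gene1, gene2, probability")
  if (nrow(df) && (any(!is.finite(df$probability)) ||
                   any(df$probability < 0) || any(df$probability > 1)))
    stop("network file '", path, "' contains a probability outside [0,1]")
  FunctionalNetwork(df$gene1, df$gene2, df$probability,
                    organism = organism[1L], prior = prior[1L])
}

#' Write / read a labeled pair standard
#'
#' Integration standards are serialized as `gene1<tab>gene2<tab>label` with
#' the prior recorded in the header; evaluation standards as
#' `query<tab>candidate<tab>label`.
#'
#' @param std a [PairStandard-class] or [HomologPairStandard-class].
#' @param path file path.
#' @export
writePairStandard <- function(std, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .provenanceHeader(con, "pair standard", list(prior = priorOf(std)))
  cat(sprintf("# prior: %.17g\n", priorOf(std)), file = con)
  cat("gene1\tgene2\tlabel\n", file = con)
  p <- positives(std); n <- negatives(std)
  if (nrow(p))
    writeLines(sprintf("%s\t%s\tpositive", p$gene1, p$gene2), con)
  if (nrow(n))
    writeLines(sprintf("%s\t%s\tnegative", n$gene1, n$gene2), con)
  invisible(path)
}

#' @rdname writePairStandard
#' @export
readPairStandard <- function(path) {
  lines <- readLines(path)
  prior <- as.numeric(sub("^# prior: ", "",
                          grep("^# prior: ", lines, value = TRUE)))
  if (!length(prior) || is.na(prior)) prior <- 0.05
  df <- .readTsv(path)
  if (!all(c("gene1", "gene2", "label") %in% names(df)))
    stop("standard file '", path, "' must have columns gene1, gene2, label")
  new("PairStandard",
      positives = canonicalPairs(df[df$label == "positive",
                                    c("gene1", "gene2"), drop = FALSE]),
      negatives = canonicalPairs(df[df$label == "negative",
                                    c("gene1", "gene2"), drop = FALSE]),
      prior = prior[1L])
}

#' @rdname writePairStandard
#' @export
writeHomologStandard <- function(std, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .provenanceHeader(con, "homolog standard",
                    list(orgPair = paste(std@orgPair, collapse = "/")))
  cat(sprintf("# organisms: %s\t%s\n", std@orgPair[1], std@orgPair[2]),
      file = con)
  cat("query\tcandidate\tlabel\n", file = con)
  df <- standardEntries(std)
  if (nrow(df))
    writeLines(sprintf("%s\t%s\t%s", df$query, df$candidate, df$label), con)
  invisible(path)
}

#' @rdname writePairStandard
#' @export
readHomologStandard <- function(path) {
  lines <- readLines(path)
  org <- grep("^# organisms: ", lines, value = TRUE)
  orgPair <- if (length(org))
    strsplit(sub("^# organisms: ", "", org[1L]), "\t", fixed = TRUE)[[1L]]
  else c("organismA", "organismB")
  df <- .readTsv(path)
  if (!all(c("query", "candidate", "label") %in% names(df)))
    stop("standard file '", path,
         "' must have columns query, candidate, label")
  new("HomologPairStandard", entries = df, orgPair = orgPair)
}

#' Read precomputed sequence-similarity scores for homolog pairs
#'
#' TSV with columns `query`, `candidate`, `score` (higher = more similar).
#'
#' @param path file path.
#' @return data.frame with those three columns.
#' @export
readSequenceScores <- function(path) {
  df <- .readTsv(path)
  if (!all(c("query", "candidate", "score") %in% names(df)))
    stop("sequence score file '", path,
         "' must have columns query, candidate, score")
  df$score <- as.numeric(df$score)
  df
}
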