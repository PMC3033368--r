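#' @include AllClasses.R
NULL

# Canonicalize an unordered pair frame: lexicographically smaller gene
# first, duplicates collapsed, self-pairs rejected by callers that care.
canonicalPairs <- function(df) {
  swap <- df$gene1 > df$gene2
  if (any(swap)) {
    tmp <- df$gene1[swap]
    df$gene1[swap] <- df$gene2[swap]
    df$gene2[swap] <- tmp
  }
  df <- df[!duplicated(paste(df$gene1, df$gene2, sep = "\r")), , drop = FALSE]
  rownames(df) <- NULL
  df
}

pairKey <- function(g1, g2) {
  swap <- g1 > g2
  k1 <- ifelse(swap, g2, g1)
  k2 <- ifelse(swap, g1, g2)
  paste(k1, k2, sep = "\r")
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stage-specific child seed from a base seed; keeps results
# reproducible while decoupling stages from one another.
childSeed <- function(seed, offset) {
  (as.integer(seed) * 1103L + as.integer(offset) * 12347L) %% 2147483587L
}

#' Experimental GO evidence codes
#'
#' The default vocabulary of evidence codes treated as "experimental" when
#' reading annotations: the GO experimental codes (EXP, IDA, IPI, IMP, IGI,
#' IEP) and their high-throughput counterparts.
#'
#' @return character vector of evidence codes.
#' @export
experimentalEvidenceCodes <- function() {
  c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP",
    "HTP", "HDA", "HMP", "HGI", "HEP")
}
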