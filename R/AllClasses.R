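#' @import methods
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment assay assayNames rowData
#' @importFrom stats rnorm rpois rbinom runif var cor sd lm coef vcov dnorm
#'   qnorm density complete.cases setNames pnorm
#' @importFrom utils read.delim write.table head tail
NULL

#' Container for dosage genotypes with site metadata
#'
#' `GenotypeData` extends [SummarizedExperiment::SummarizedExperiment] with a
#' mandatory `"dosage"` assay (sites in rows, individuals in columns; values
#' are alternate-allele counts in \[0, 2\] or `NA`, real-valued after
#' imputation) and site metadata columns `chrom`, `pos`, `ref`, `alt`.
#' Optional `"refDepth"`/`"altDepth"` assays carry per-site allele read
#' counts for shallow-sequenced individuals.
#'
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- NULL
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain", paste(need, collapse = ", ")))
  else {
    o <- order(as.character(rd$chrom), rd$pos)
    if (is.unsorted(o) && !identical(o, seq_len(nrow(rd))))
      msg <- c(msg, "sites must be ordered by chrom, pos")
  }
  d <- SummarizedExperiment::assay(object, "dosage")
  if (any(d < -1e-9 | d > 2 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "dosages must lie in [0, 2] or be NA")
  if (is.null(msg)) TRUE else msg
})

#' Phased diploid genomes for a set of individuals
#'
#' Alleles are stored as two haplotype matrices (individuals x sites, values
#' 0/1 counting the alternate allele). `originA`/`originB` track, for every
#' allele, the founder haplotype it descends from (odd/even integer ids),
#' which makes identity-by-descent and true-ancestry calculations exact.
#'
#' @slot hapA,hapB integer matrices, individuals x sites.
#' @slot originA,originB integer matrices of founder-haplotype ids.
#' @slot sites DataFrame with chrom, pos.
#' @slot config the `genomeConfig()` list used to simulate.
#' @export
setClass("PhasedGenomes", representation(
  hapA = "matrix", hapB = "matrix",
  originA = "matrix", originB = "matrix",
  sites = "DataFrame", config = "list"))

setValidity("PhasedGenomes", function(object) {
  dims <- list(dim(object@hapA), dim(object@hapB),
               dim(object@originA), dim(object@originB))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    return("haplotype and origin matrices must share dimensions")
  if (ncol(object@hapA) != nrow(object@sites))
    return("number of site columns must match sites metadata")
  TRUE
})

#' Grandparental-ancestry haplotype maps for a family
#'
#' Run-length segments per individual assigning stretches of the
#' informative-site axis to `homA` (both alleles from grandparent A), `het`,
#' `homB`, or `unassigned`. Segment coordinates are indices into the family's
#' informative marker set.
#'
#' @slot segments named list (one per individual) of data.frames with
#'   `chrom`, `start`, `end`, `state`.
#' @slot hetFraction named numeric: het sites / assigned sites.
#' @slot markers the `InformativeMarkerSet` the map was built on.
#' @export
setClass("HaplotypeMapSet", representation(
  segments = "list", hetFraction = "numeric", markers = "list"))

#' REML fit of a multi-kernel mixed model
#'
#' @slot varcomp data.frame with component, estimate, se, boundary flag.
#' @slot fixef named numeric of fixed-effect estimates.
#' @slot blup named list of per-kernel BLUP vectors (individual level).
#' @slot gebv numeric: the additive-kernel BLUP (GEBV) per individual.
#' @slot pev numeric: prediction error variance of the additive BLUP.
#' @slot reliability numeric in \[0,1\] per individual.
#' @slot loglik restricted log-likelihood at convergence.
#' @slot converged logical. @slot niter integer.
#' @slot details list: iteration trace, AI matrix, model matrices metadata.
#' @export
setClass("FitResult", representation(
  varcomp = "data.frame", fixef = "numeric", blup = "list",
  gebv = "numeric", pev = "numeric", reliability = "numeric",
  loglik = "numeric", converged = "logical", niter = "integer",
  details = "list"))

setMethod("show", "GenotypeData", function(object) {
  d <- SummarizedExperiment::assay(object, "dosage")
  cat("GenotypeData:", nrow(object), "sites x", ncol(object), "individuals\n")
  cat("  missing:", sprintf("%.1f%%", 100 * mean(is.na(d))),
      " assays:", paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
})

setMethod("show", "PhasedGenomes", function(object) {
  cat("PhasedGenomes:", nrow(object@hapA), "individuals x",
      ncol(object@hapA), "sites on",
      length(unique(object@sites$chrom)), "chromosome(s)\n")
})

setMethod("show", "HaplotypeMapSet", function(object) {
  cat("HaplotypeMapSet:", length(object@segments), "individuals,",
      length(object@markers$sites), "informative sites\n")
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult (", if (object@converged) "converged" else "NOT converged",
      ", ", object@niter, " iterations, logLik ", round(object@loglik, 3), ")\n", sep = "")
  print(object@varcomp, row.names = FALSE)
})
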