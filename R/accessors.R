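#' Accessors for winterGP data containers
#'
#' `dosages()` returns the sites x individuals dosage matrix; `siteInfo()`
#' the site metadata as a data.frame; `individuals()` the individual ids;
#' `varComp()`, `gebv()`, `pev()`, `reliabilities()` the corresponding
#' pieces of a [FitResult-class].
#'
#' @param x a `GenotypeData`, `PhasedGenomes`, `HaplotypeMapSet` or
#'   `FitResult` object.
#' @return See details per generic.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeData", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @rdname accessors
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))
#' @rdname accessors
#' @export
setMethod("siteInfo", "GenotypeData", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))
#' @rdname accessors
#' @export
setMethod("siteInfo", "PhasedGenomes", function(x) as.data.frame(x@sites))

#' @rdname accessors
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))
#' @rdname accessors
#' @export
setMethod("individuals", "GenotypeData", function(x) colnames(x))
#' @rdname accessors
#' @export
setMethod("individuals", "PhasedGenomes", function(x) rownames(x@hapA))
#' @rdname accessors
#' @export
setMethod("individuals", "HaplotypeMapSet", function(x) names(x@segments))

#' @rdname accessors
#' @export
setGeneric("varComp", function(x) standardGeneric("varComp"))
#' @rdname accessors
#' @export
setMethod("varComp", "FitResult", function(x) x@varcomp)

#' @rdname accessors
#' @export
setGeneric("gebv", function(x) standardGeneric("gebv"))
#' @rdname accessors
#' @export
setMethod("gebv", "FitResult", function(x) x@gebv)

#' @rdname accessors
#' @export
setGeneric("pev", function(x) standardGeneric("pev"))
#' @rdname accessors
#' @export
setMethod("pev", "FitResult", function(x) x@pev)

#' @rdname accessors
#' @export
setGeneric("reliabilities", function(x) standardGeneric("reliabilities"))
#' @rdname accessors
#' @export
setMethod("reliabilities", "FitResult", function(x) x@reliability)

#' @rdname accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @rdname accessors
#' @export
setMethod("segments", "HaplotypeMapSet", function(x) x@segments)

#' @rdname accessors
#' @export
setGeneric("hetFraction", function(x) standardGeneric("hetFraction"))
#' @rdname accessors
#' @export
setMethod("hetFraction", "HaplotypeMapSet", function(x) x@hetFraction)

#' Construct a GenotypeData object
#'
#' @param dosage numeric matrix, sites x individuals, values in \[0,2\] or NA.
#' @param chrom,pos,ref,alt site metadata vectors (recycled ref/alt allowed).
#' @param refDepth,altDepth optional read-count matrices matching `dosage`.
#' @return a [GenotypeData-class] object.
#' @export
GenotypeData <- function(dosage, chrom, pos, ref = "A", alt = "T",
                         refDepth = NULL, altDepth = NULL) {
  stopifnot(is.matrix(dosage), length(chrom) == nrow(dosage),
            length(pos) == nrow(dosage))
  rd <- S4Vectors::DataFrame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = rep_len(as.character(ref), nrow(dosage)),
    alt = rep_len(as.character(alt), nrow(dosage)))
  assays <- list(dosage = dosage)
  if (!is.null(refDepth)) assays$refDepth <- refDepth
  if (!is.null(altDepth)) assays$altDepth <- altDepth
  se <- SummarizedExperiment::SummarizedExperiment(assays = assays, rowData = rd)
  new("GenotypeData", se)
}
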