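#' Read-depth model for sequencing simulation
#'
#' Founders are deeply sequenced (default target 40 reads per site) while
#' descendants are shallow (per-individual target drawn uniformly from
#' `descendant_depth_range`, default 1-5 reads per site), matching the
#' study's sequencing design.
#'
#' @param founder_mean_depth mean reads per site for founders (>= 0).
#' @param descendant_depth_range length-2 range of per-individual mean depth
#'   for non-founders.
#' @param error_rate per-read miscall probability in \[0, 0.5).
#' @return a list of class `readDepthModel`.
#' @export
readDepthModel <- function(founder_mean_depth = 40,
                           descendant_depth_range = c(1, 5),
                           error_rate = 0.002) {
  stopifnot(founder_mean_depth >= 0, length(descendant_depth_range) == 2,
            all(descendant_depth_range >= 0))
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)")
  structure(list(founder_mean_depth = founder_mean_depth,
                 descendant_depth_range = sort(descendant_depth_range),
                 error_rate = error_rate),
            class = "readDepthModel")
}

#' Simulate sequencing reads and naive hard genotype calls
#'
#' Per-site depth is Poisson in the individual's target depth; each read
#' reports the alternate allele with probability dosage/2 adjusted by the
#' error rate. Hard calls: no reads -> missing; only reference reads -> 0;
#' only alternate reads -> 2; both -> 1 (a heterozygous site covered by a
#' single read is therefore always miscalled as a homozygote, the ambiguity
#' the haplotype-map module exists to rescue).
#'
#' @param genomes a [PhasedGenomes-class].
#' @param pedigree pedigree data.frame (to tell founders from descendants).
#' @param model a [readDepthModel()].
#' @param seed integer seed.
#' @return a [GenotypeData-class] with assays `dosage` (hard calls),
#'   `refDepth` and `altDepth`.
#' @export
simulateReads <- function(genomes, pedigree, model = readDepthModel(),
                          seed = 1L) {
  stopifnot(inherits(model, "readDepthModel"))
  set.seed(seed)
  M <- trueDosages(genomes)
  ids <- rownames(M)
  gen <- pedigree$generation[match(ids, pedigree$id)]
  target <- ifelse(gen == "founder", model$founder_mean_depth,
                   stats::runif(length(ids), model$descendant_depth_range[1],
                                model$descendant_depth_range[2]))
  n <- nrow(M); nsite <- ncol(M)
  depth <- matrix(stats::rpois(n * nsite, rep(target, nsite)), n, nsite)
  e <- model$error_rate
  p_alt <- (M / 2) * (1 - e) + (1 - M / 2) * e
  alt <- matrix(stats::rbinom(n * nsite, depth, p_alt), n, nsite)
  ref <- depth - alt
  call <- matrix(NA_real_, n, nsite)
  call[depth > 0 & alt == 0] <- 0
  call[depth > 0 & ref == 0] <- 2
  call[alt > 0 & ref > 0] <- 1
  st <- siteInfo(genomes)
  GenotypeData(dosage = t(call) |> `colnames<-`(ids),
               chrom = st$chrom, pos = st$pos,
               refDepth = t(ref) |> `colnames<-`(ids),
               altDepth = t(alt) |> `colnames<-`(ids))
}
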