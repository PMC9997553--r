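#' Variance-component recovery experiment
#'
#' Simulates replicate multi-generation pedigrees (default ~300 individuals:
#' 20 founders, four F1 families of 25, four sibling-mated pseudo-F2
#' families of 45) with ~2,000 markers and three years of winter-survivorship
#' records generated from the study's single-trait variance decomposition
#' (additive 12.52, dominance 0, epistatic 1.23, residual genotypic 7.44,
#' year residuals 25.52/22.16/20.5), then refits the four-kernel
#' (G + D + E + I) REML model with year-specific residuals to each replicate.
#'
#' Records are generated on the latent Gaussian scale (no censoring), since
#' the experiment measures recovery of the Gaussian model's own generating
#' parameters; censoring semantics are exercised elsewhere.
#'
#' @param n_reps number of replicate pedigrees.
#' @param seed master seed; replicate seeds are derived from it.
#' @param params a [traitSimParams()] holding the generating components.
#' @param cfg,design genome and pedigree configuration overrides.
#' @param n_years record years.
#' @return data.frame with one row per replicate: the four genetic-kernel
#'   estimates, the dominance boundary flag and the convergence flag.
#' @export
varianceRecoveryExperiment <- function(n_reps = 20L, seed = 1L,
                                       params = traitSimParams(),
                                       cfg = NULL, design = NULL,
                                       n_years = 3L) {
  if (is.null(cfg))
    cfg <- genomeConfig(n_chromosomes = 3, sites_per_chromosome = 667,
                        divergence = 0.15)
  if (is.null(design))
    design <- pedigreeDesign(n_founders = 20, n_tolerant = 2,
                             f1_sizes = rep(25L, 4), pf2_sizes = rep(45L, 4))
  rows <- lapply(seq_len(n_reps), function(r) {
    s <- (seed %% 10000L) * 100000L + r * 977L
    sim <- buildPedigree(cfg, design, seed = s)
    ph <- simulatePhenotypes(sim$pedigree, sim$genomes, params,
                             n_years = n_years, seed = s + 1L,
                             censor = FALSE)
    M <- trueDosages(sim$genomes)
    G <- additiveG(M)
    K <- list(G = G, D = dominanceD(M), E = epistaticE(G),
              I = identityKernelMatrix(rownames(M)))
    fit <- suppressWarnings(fitREML(ph$phenotypes, K, trait = "ws"))
    vc <- varComp(fit)
    data.frame(rep = r,
               additive = vc$estimate[vc$component == "G"],
               dominance = vc$estimate[vc$component == "D"],
               epistatic = vc$estimate[vc$component == "E"],
               residual_genotypic = vc$estimate[vc$component == "I"],
               dominance_at_boundary = vc$boundary[vc$component == "D"],
               converged = fit@converged)
  })
  do.call(rbind, rows)
}

#' Identity kernel over a set of individuals
#'
#' @param ids individual ids.
#' @return identity matrix with `ids` as dimnames.
#' @export
identityKernelMatrix <- function(ids) {
  I <- diag(length(ids))
  dimnames(I) <- list(ids, ids)
  I
}
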