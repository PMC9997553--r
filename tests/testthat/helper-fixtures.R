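# Shared simulated fixtures, built once per test run and cached.
.fx <- new.env()

# small multi-generation world with phenotypes (uncensored for clean math)
fxWorld <- function() {
  if (is.null(.fx$world)) {
    cfg <- genomeConfig(n_chromosomes = 2, sites_per_chromosome = 500,
                        divergence = 0.2)
    des <- pedigreeDesign(n_founders = 10, n_tolerant = 2,
                          f1_sizes = c(15L, 15L), pf2_sizes = c(20L, 20L))
    sim <- buildPedigree(cfg, des, seed = 42)
    ph <- simulatePhenotypes(sim$pedigree, sim$genomes, traitSimParams(),
                             n_years = 3, seed = 43, censor = FALSE)
    M <- trueDosages(sim$genomes)
    .fx$world <- list(cfg = cfg, des = des, sim = sim, ph = ph, M = M)
  }
  .fx$world
}

# dense-marker world for haplotype-map reconstruction
fxHapWorld <- function(seed = 3, depth = c(3, 5)) {
  key <- paste0("hap", seed, "_", depth[1], "_", depth[2])
  if (is.null(.fx[[key]])) {
    cfg <- genomeConfig(n_chromosomes = 2, sites_per_chromosome = 6000,
                        founder_af_beta = c(0.5, 0.5), divergence = 0.3)
    des <- pedigreeDesign(n_founders = 8, n_tolerant = 2,
                          f1_sizes = c(8L, 8L), pf2_sizes = c(12L, 12L))
    sim <- buildPedigree(cfg, des, seed = seed)
    gd <- simulateReads(sim$genomes, sim$pedigree,
                        readDepthModel(descendant_depth_range = depth),
                        seed = seed + 1L)
    .fx[[key]] <- list(cfg = cfg, sim = sim, gd = gd,
                       fam = unique(sim$pedigree$family[
                         sim$pedigree$generation == "pseudoF2"])[1])
  }
  .fx[[key]]
}

identityKernel <- function(ids) {
  I <- diag(length(ids))
  dimnames(I) <- list(ids, ids)
  I
}

# exact per-site ancestry states from the simulator's origin tracks:
# number of alleles descending from founder A -> homB / het / homA
trueAncestryStates <- function(sim, mk, id) {
  g <- sim$genomes
  hapsA <- c(2 * match(mk$founderA, sim$pedigree$id) - 1,
             2 * match(mk$founderA, sim$pedigree$id))
  i <- match(id, rownames(g@originA))
  nA <- (g@originA[i, mk$sites] %in% hapsA) +
    (g@originB[i, mk$sites] %in% hapsA)
  c("homB", "het", "homA")[nA + 1]
}

# states implied by a haplotype map's segments on the informative-site axis
mapStates <- function(maps, mk, id) {
  seg <- segments(maps)[[id]]
  called <- rep("unassigned", length(mk$sites))
  for (k in seq_len(nrow(seg)))
    called[seg$start[k]:seg$end[k]] <- seg$state[k]
  called
}

# GenotypeData wrapper for a plain individuals x sites matrix on one chrom
toyGD <- function(M, refDepth = NULL, altDepth = NULL) {
  GenotypeData(dosage = t(M), chrom = rep("Chr1", ncol(M)),
               pos = seq_len(ncol(M)) * 100L,
               refDepth = if (!is.null(refDepth)) t(refDepth),
               altDepth = if (!is.null(altDepth)) t(altDepth))
}
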