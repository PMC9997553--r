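#' Genome simulation configuration
#'
#' Describes the simulated coordinate frame: chromosome count, marker density,
#' genetic map length, the Beta model for ancestral reference-allele
#' frequencies, and an Fst-like divergence splitting founders into two
#' ancestry groups (the winter-tolerant donors vs the diverse southern pool).
#'
#' @param n_chromosomes number of chromosomes (>= 1).
#' @param sites_per_chromosome markers per chromosome (>= 1).
#' @param map_length genetic length per chromosome in Morgans (>= 0).
#' @param founder_af_beta length-2 shape parameters of the Beta distribution
#'   for per-site ancestral allele frequency.
#' @param divergence Fst-like scalar in \[0, 1) controlling how far the two
#'   founder subpopulations have drifted (Balding-Nichols model).
#' @return a list of class `genomeConfig`.
#' @export
genomeConfig <- function(n_chromosomes = 3L, sites_per_chromosome = 500L,
                         map_length = 1, founder_af_beta = c(0.8, 0.8),
                         divergence = 0.15) {
  stopifnot(n_chromosomes >= 1, sites_per_chromosome >= 1, map_length >= 0,
            length(founder_af_beta) == 2, all(founder_af_beta > 0))
  if (divergence < 0 || divergence >= 1)
    stop("divergence must lie in [0, 1)")
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 sites_per_chromosome = as.integer(sites_per_chromosome),
                 map_length = map_length,
                 founder_af_beta = founder_af_beta,
                 divergence = divergence),
            class = "genomeConfig")
}

.siteTable <- function(cfg) {
  S4Vectors::DataFrame(
    chrom = paste0("Chr", rep(seq_len(cfg$n_chromosomes),
                              each = cfg$sites_per_chromosome)),
    pos = rep(seq_len(cfg$sites_per_chromosome) * 1000L, cfg$n_chromosomes))
}

#' Simulate founder genomes
#'
#' Draws per-site ancestral allele frequencies from the configured Beta model,
#' perturbs them into two subpopulation frequency sets under the
#' Balding-Nichols model at the configured divergence, and samples phased
#' founder haplotypes. The first `n_tolerant` founders are tagged as the
#' winter-tolerant donors and belong to subpopulation 2; the remaining
#' founders represent the diverse southern pool (subpopulation 1).
#'
#' @param cfg a [genomeConfig()].
#' @param n_founders number of founders (>= 1).
#' @param n_tolerant number of tolerant founders (<= `n_founders`).
#' @param seed integer seed; all downstream randomness is reproducible.
#' @return list with `genomes` ([PhasedGenomes-class]) and `pedigree`
#'   (data.frame with id, parent1, parent2, generation, family, tolerant).
#' @export
simulateFounders <- function(cfg, n_founders = 20L, n_tolerant = 2L,
                             seed = 1L) {
  stopifnot(inherits(cfg, "genomeConfig"))
  if (n_founders < 1) stop("need at least one founder")
  if (n_tolerant > n_founders) stop("n_tolerant must be <= n_founders")
  set.seed(seed)
  nsite <- cfg$n_chromosomes * cfg$sites_per_chromosome
  p <- stats::rbeta(nsite, cfg$founder_af_beta[1], cfg$founder_af_beta[2])
  p <- pmin(pmax(p, 0.02), 0.98)   # keep sites segregating
  Fst <- cfg$divergence
  if (Fst > 0) {
    a <- p * (1 - Fst) / Fst
    b <- (1 - p) * (1 - Fst) / Fst
    p1 <- stats::rbeta(nsite, a, b)
    p2 <- stats::rbeta(nsite, a, b)
  } else {
    p1 <- p2 <- p
  }
  ids <- sprintf("FND%02d", seq_len(n_founders))
  tolerant <- seq_len(n_founders) <= n_tolerant
  hapA <- hapB <- matrix(0L, n_founders, nsite, dimnames = list(ids, NULL))
  for (i in seq_len(n_founders)) {
    pi <- if (tolerant[i]) p2 else p1
    hapA[i, ] <- stats::rbinom(nsite, 1L, pi)
    hapB[i, ] <- stats::rbinom(nsite, 1L, pi)
  }
  originA <- matrix(rep(2L * seq_len(n_founders) - 1L, nsite), n_founders,
                    nsite, dimnames = list(ids, NULL))
  originB <- originA + 1L
  cfg2 <- cfg
  cfg2$af <- list(ancestral = p, pop1 = p1, pop2 = p2)
  genomes <- new("PhasedGenomes", hapA = hapA, hapB = hapB,
                 originA = originA, originB = originB,
                 sites = .siteTable(cfg), config = unclass(cfg2))
  ped <- data.frame(id = ids, parent1 = NA_character_,
                    parent2 = NA_character_, generation = "founder",
                    family = NA_character_, tolerant = tolerant,
                    stringsAsFactors = FALSE)
  list(genomes = genomes, pedigree = ped)
}

# One meiosis for individual `ind`: Poisson(map_length) crossovers per
# chromosome, no interference, uniform map. Returns the transmitted allele
# and origin vectors plus the crossover count (the simulator's own log).
.gamete <- function(genomes, ind) {
  cfg <- genomes@config
  nchr <- cfg$n_chromosomes
  L <- cfg$sites_per_chromosome
  allele <- integer(nchr * L)
  origin <- integer(nchr * L)
  nco_total <- 0L
  hA <- genomes@hapA[ind, ]; hB <- genomes@hapB[ind, ]
  oA <- genomes@originA[ind, ]; oB <- genomes@originB[ind, ]
  for (c in seq_len(nchr)) {
    idx <- ((c - 1L) * L + 1L):(c * L)
    nco <- stats::rpois(1L, cfg$map_length)
    nco_total <- nco_total + nco
    # crossover positions on (0,1) of the chromosome; selector flips there
    sel <- rep(sample(c(1L, 2L), 1L), L)
    if (nco > 0) {
      cuts <- sort(ceiling(stats::runif(nco) * L))  # site index after which state flips
      for (cut in cuts) if (cut < L)
        sel[(cut + 1L):L] <- 3L - sel[(cut + 1L):L]
    }
    allele[idx] <- ifelse(sel == 1L, hA[idx], hB[idx])
    origin[idx] <- ifelse(sel == 1L, oA[idx], oB[idx])
  }
  list(allele = allele, origin = origin, crossovers = nco_total)
}

#' Cross two individuals
#'
#' Simulates one meiosis in each parent (crossover count per chromosome is
#' Poisson in the map length, no interference) and returns the offspring as a
#' one-individual [PhasedGenomes-class]. The realized crossover counts are
#' stored in `config$crossovers`.
#'
#' @param genomes a [PhasedGenomes-class] containing both parents.
#' @param parent1,parent2 individual ids (rows of `genomes`).
#' @param id id for the offspring.
#' @param seed optional seed.
#' @return a [PhasedGenomes-class] with a single individual.
#' @export
makeCross <- function(genomes, parent1, parent2, id = "offspring",
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(parent1 %in% individuals(genomes), parent2 %in% individuals(genomes))
  g1 <- .gamete(genomes, parent1)
  g2 <- .gamete(genomes, parent2)
  cfg <- genomes@config
  cfg$crossovers <- c(g1$crossovers, g2$crossovers)
  new("PhasedGenomes",
      hapA = matrix(g1$allele, 1, dimnames = list(id, NULL)),
      hapB = matrix(g2$allele, 1, dimnames = list(id, NULL)),
      originA = matrix(g1$origin, 1, dimnames = list(id, NULL)),
      originB = matrix(g2$origin, 1, dimnames = list(id, NULL)),
      sites = genomes@sites, config = cfg)
}

#' True genotype dosages from phased genomes
#'
#' @param genomes a [PhasedGenomes-class].
#' @return integer matrix, individuals x sites, of alternate-allele dosages.
#' @export
trueDosages <- function(genomes) genomes@hapA + genomes@hapB

#' Genome-wide inbreeding coefficients (identity by descent)
#'
#' Fraction of sites at which the two alleles descend from the same founder
#' haplotype, computed exactly from the origin tracks.
#'
#' @param genomes a [PhasedGenomes-class].
#' @return named numeric vector.
#' @export
inbreedingF <- function(genomes)
  rowMeans(genomes@originA == genomes@originB)
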