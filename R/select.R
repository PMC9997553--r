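#' Selection intensity for truncation selection
#'
#' The mean deviation, in phenotypic standard deviations, of the selected
#' upper fraction p of a normal distribution: i = phi(z_p) / p with z_p the
#' upper-p quantile (i = 1.755 for the top 10%, printed as 1.75).
#'
#' @param p selected proportion in (0, 1\].
#' @return the intensity i (0 when everyone is selected).
#' @export
selectionIntensity <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  ifelse(p == 1, 0, dnorm(qnorm(1 - p)) / p)
}

#' Breeder's equation
#'
#' Expected genetic gain per selection cycle, Delta G = sigma_a * i * r,
#' with sigma_a the additive standard deviation, i the selection intensity
#' and r the selection accuracy.
#'
#' @param sigma_a additive SD in trait units. @param i intensity.
#' @param r accuracy in \[0, 1\].
#' @return Delta G in trait units per cycle.
#' @export
breedersEquation <- function(sigma_a, i, r) {
  stopifnot(sigma_a >= 0, i >= 0, r >= 0, r <= 1)
  sigma_a * i * r
}

#' Expected gain from additive variance, selected fraction and heritability
#'
#' Convenience wrapper reproducing the study's worked calculation: the
#' narrow-sense (mid-parent regression) heritability enters as the squared
#' accuracy, so Delta G = sqrt(va) * i(p) * sqrt(h2). Do not square h2
#' again.
#'
#' @param va additive variance (trait units squared).
#' @param p selected proportion. @param h2 narrow-sense heritability.
#' @return expected gain per cycle in trait units.
#' @export
selectionGain <- function(va, p, h2)
  breedersEquation(sqrt(va), selectionIntensity(p), sqrt(h2))

#' Mid-parent regression heritability
#'
#' OLS slope of family offspring means on mid-parent values, overall and
#' within groups (generations); estimates narrow-sense heritability.
#'
#' @param midparent numeric vector of family mid-parent values.
#' @param offspring numeric vector of family offspring means.
#' @param group optional grouping factor (e.g. generation).
#' @return list with `overall` slope and `by_group` named vector (groups
#'   with fewer than 3 families give NA).
#' @export
midparentHeritability <- function(midparent, offspring, group = NULL) {
  ok <- complete.cases(midparent, offspring)
  if (sum(ok) < 3) stop("need at least 3 families")
  if (stats::var(midparent[ok]) == 0) stop("zero variance in mid-parent values")
  sl <- function(x, y) unname(coef(stats::lm(y ~ x))[2])
  out <- list(overall = sl(midparent[ok], offspring[ok]))
  if (!is.null(group)) {
    out$by_group <- vapply(split(seq_along(midparent)[ok], group[ok]),
                           function(ii) {
                             if (length(ii) < 3 ||
                                 stats::var(midparent[ii]) == 0)
                               return(NA_real_)
                             sl(midparent[ii], offspring[ii])
                           }, numeric(1))
  }
  out
}

#' Family mid-parent / offspring-mean table
#'
#' Builds, from a pedigree and per-individual trait values, one row per
#' full-sib family with both parents phenotyped: mid-parent value, offspring
#' mean, family size and generation.
#'
#' @param pedigree pedigree data.frame.
#' @param values named numeric vector of per-individual trait values.
#' @param min_n minimum offspring with values per family.
#' @return data.frame (family, generation, midparent, offspring_mean, n).
#' @export
familyMidparentTable <- function(pedigree, values, min_n = 3L) {
  fams <- unique(stats::na.omit(pedigree$family))
  rows <- list()
  for (f in fams) {
    kids <- pedigree[!is.na(pedigree$family) & pedigree$family == f, ]
    pars <- unique(c(kids$parent1, kids$parent2))
    pars <- pars[!is.na(pars)]
    if (length(pars) != 2) next
    if (!all(pars %in% names(values))) next
    kv <- values[intersect(kids$id, names(values))]
    kv <- kv[!is.na(kv)]
    if (length(kv) < min_n) next
    rows[[f]] <- data.frame(family = f, generation = kids$generation[1],
                            midparent = mean(values[pars]),
                            offspring_mean = mean(kv), n = length(kv),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean Z-scores across two traits
#'
#' Per-individual mean of the two traits' standardized values (survivorship
#' and heading date, both unflipped), as used to pick the progeny
#' validation sample.
#'
#' @param ws,hd named numeric vectors (shared names used).
#' @return named numeric vector of mean Z-scores.
#' @export
meanZScores <- function(ws, hd) {
  ids <- intersect(names(ws), names(hd))
  z <- cbind(scale(ws[ids]), scale(hd[ids]))
  stats::setNames(rowMeans(z), ids)
}

#' Inverted-density sampling
#'
#' Samples `n` individuals without replacement with inclusion weights
#' proportional to the reciprocal of a Gaussian kernel-density estimate
#' (Silverman bandwidth) of their mean Z-scores, capped at the
#' `cap_quantile` weight quantile — which deliberately oversamples the tails
#' of the trait distribution.
#'
#' @param z named numeric vector of mean Z-scores.
#' @param n sample size (<= length(z)).
#' @param seed integer seed.
#' @param cap_quantile weight cap (default 0.99); `Inf` disables capping.
#' @return list with `ids` (sampled names) and `weights` (normalized, full
#'   population).
#' @export
invertedDensitySample <- function(z, n, seed = 1L, cap_quantile = 0.99) {
  if (n > length(z)) stop("n exceeds the population size")
  set.seed(seed)
  f <- stats::density(z)
  fz <- stats::approx(f$x, f$y, xout = z, rule = 2)$y
  w <- 1 / pmax(fz, .Machine$double.eps)
  if (is.finite(cap_quantile))
    w <- pmin(w, stats::quantile(w, cap_quantile))
  w <- w / sum(w)
  ids <- sample(names(z), n, prob = w)
  list(ids = ids, weights = w)
}

#' Correlation-erosion simulation experiment
#'
#' Simulates the pedigree under a chosen trait-correlation mechanism and
#' reports the phenotypic correlation between winter survivorship and
#' heading date per generation, averaged over seeds. Under `"structure"`
#' (ancestry-aligned effects at distinct QTL, zero pleiotropy) the founder
#' correlation is strong and erodes across generations; under
#' `"pleiotropy"` (shared QTL) it persists; under `"none"` it is absent.
#'
#' The structure arm reproduces the conditions of the study's pedigree:
#' mixed tolerant-by-diverse and diverse-by-diverse crosses, survivorship
#' scores censored at the 0 floor with absorbing mortality, and directional
#' inbreeding depression (about -16 score units per unit F, the study's
#' observed F1-to-pseudo-F2 gap). Crossing smooths the binary founder
#' ancestry contrast, and mortality plus inbreeding depression truncate the
#' sibling-mated generation, so the between-trait correlation declines
#' monotonically. The pleiotropy arm runs in a mild, uncensored-like world:
#' persistence there isolates the recombination-proofness of shared QTL.
#'
#' @param mechanism `"structure"`, `"pleiotropy"` or `"none"`.
#' @param n_seeds number of replicate simulations.
#' @param cfg optional [genomeConfig()] override.
#' @param design optional [pedigreeDesign()] override.
#' @param n_years record years.
#' @param target_corr magnitude/sign of the generated correlation.
#' @return data.frame (generation, mean_r, se_r) ordered founder, F1,
#'   pseudo-F2 (and progeny when present), with attribute
#'   `monotone_decline` (logical: |r| non-increasing across generations).
#' @export
correlationErosionExperiment <- function(mechanism = c("structure",
                                                       "pleiotropy", "none"),
                                         n_seeds = 10L, cfg = NULL,
                                         design = NULL, n_years = 3L,
                                         target_corr = -0.6) {
  mechanism <- match.arg(mechanism)
  if (is.null(cfg))
    cfg <- genomeConfig(n_chromosomes = 3, sites_per_chromosome = 400,
                        divergence = if (mechanism == "none") 0 else 0.3)
  if (is.null(design)) {
    # the study's crossing mix: mostly tolerant x diverse, a few
    # diverse x diverse
    f1p <- list(c("FND01", "FND03"), c("FND02", "FND04"),
                c("FND01", "FND05"), c("FND02", "FND06"),
                c("FND07", "FND08"), c("FND09", "FND10"))
    design <- pedigreeDesign(n_founders = 20, n_tolerant = 2,
                             f1_sizes = rep(18L, 6), f1_parents = f1p,
                             pf2_sizes = rep(18L, 6), pf2_f1_family = 1:6)
  }
  ld <- sqrt(abs(target_corr)) * 1.18  # loading; |l| <= 1 after clamp
  ld <- min(ld, 0.97)
  params <- switch(mechanism,
    structure = traitSimParams(
      ws = list(additive_var = 12, dominance_var = 0, epistatic_var = 0,
                residual_genotypic_var = 1, year_residual_vars = 16,
                mean = 7, censor_bounds = c(0, 20), round = TRUE),
      hd = list(additive_var = 25, dominance_var = 0, epistatic_var = 0,
                residual_genotypic_var = 2, year_residual_vars = 8,
                mean = 227, censor_bounds = NULL, round = FALSE),
      pleiotropy_corr = 0,
      structure_effect = c(ld, sign(target_corr) * ld),
      inbreeding_depression = c(-16, 0),
      year_effects = list(ws = 0, hd = 0)),
    pleiotropy = traitSimParams(
      ws = list(additive_var = 12, dominance_var = 0, epistatic_var = 0,
                residual_genotypic_var = 1, year_residual_vars = 4,
                mean = 10, censor_bounds = c(0, 20), round = TRUE),
      hd = list(additive_var = 25, dominance_var = 0, epistatic_var = 0,
                residual_genotypic_var = 2, year_residual_vars = 8,
                mean = 227, censor_bounds = NULL, round = FALSE),
      pleiotropy_corr = target_corr, structure_effect = c(0, 0),
      year_effects = list(ws = 0, hd = 0)),
    none = traitSimParams(
      ws = list(additive_var = 12, dominance_var = 0, epistatic_var = 0,
                residual_genotypic_var = 1, year_residual_vars = 4,
                mean = 10, censor_bounds = c(0, 20), round = TRUE),
      hd = list(additive_var = 25, dominance_var = 0, epistatic_var = 0,
                residual_genotypic_var = 2, year_residual_vars = 8,
                mean = 227, censor_bounds = NULL, round = FALSE),
      pleiotropy_corr = 0, structure_effect = c(0, 0),
      year_effects = list(ws = 0, hd = 0)))
  gens <- c("founder", "F1", "pseudoF2")
  if (design$n_progeny > 0) gens <- c(gens, "progeny")
  rs <- matrix(NA_real_, n_seeds, length(gens),
               dimnames = list(NULL, gens))
  for (s in seq_len(n_seeds)) {
    sim <- buildPedigree(cfg, design, seed = s * 1000L + 17L)
    ph <- simulatePhenotypes(sim$pedigree, sim$genomes, params,
                             n_years = n_years, seed = s * 1000L + 18L)
    p <- ph$phenotypes
    wsm <- tapply(p$value[p$trait == "ws"], p$individual[p$trait == "ws"],
                  mean)
    hdm <- tapply(p$value[p$trait == "hd"], p$individual[p$trait == "hd"],
                  mean)
    for (g in gens) {
      ids <- sim$pedigree$id[sim$pedigree$generation == g]
      ids <- intersect(intersect(ids, names(wsm)), names(hdm))
      if (length(ids) >= 3 && stats::sd(wsm[ids]) > 0 &&
          stats::sd(hdm[ids]) > 0)
        rs[s, g] <- stats::cor(wsm[ids], hdm[ids])
    }
  }
  out <- data.frame(generation = gens,
                    mean_r = colMeans(rs, na.rm = TRUE),
                    se_r = apply(rs, 2, stats::sd, na.rm = TRUE) /
                      sqrt(colSums(!is.na(rs))),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "replicates") <- rs
  attr(out, "monotone_decline") <-
    all(diff(abs(out$mean_r)) <= 1e-8)
  out
}
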