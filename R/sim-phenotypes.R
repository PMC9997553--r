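#' Trait simulation parameters
#'
#' Generative parameters for the two traits: winter survivorship ("ws", a
#' 0-20 spring-vigor score, censored and integer-rounded, score 0 = dead) and
#' heading date ("hd", ordinal day of year, uncensored). Per-trait defaults
#' are the study's single-trait variance decomposition for each trait
#' (additive / dominance / epistatic / residual-genotypic components plus
#' year-specific residual variances), a survivorship mean placed mid-scale,
#' and a heading mean of 227 DOY whose implied phenotypic SD is ~10 d.
#'
#' Trait correlation can be generated by two distinct mechanisms:
#' `pleiotropy_corr` draws shared-QTL effects with the given correlation
#' (recombination-proof), while `structure_effect` loads a fraction of each
#' trait's additive effects onto the founder-subpopulation allele-frequency
#' axis (loading in \[-1, 1\] per trait; opposite signs give the antagonistic
#' founder correlation that erodes as recombination breaks cross-locus
#' ancestry LD).
#'
#' @param ws,hd per-trait parameter lists; see Defaults in the source.
#' @param n_qtl causal loci per trait.
#' @param pleiotropy_corr QTL-level genetic correlation in \[-1, 1\]; when
#'   nonzero the traits share one QTL set.
#' @param structure_effect length-2 loadings of (ws, hd) additive effects on
#'   the subpopulation-divergence axis.
#' @param year_effects list(ws=, hd=) of per-year fixed offsets (recycled).
#' @param fallvigor_effect slope of the survivorship score on (centered)
#'   fall vigor.
#' @param inbreeding_depression length-2 numeric: change in the (ws, hd)
#'   latent trait per unit of genome-wide inbreeding F (0 disables).
#'   Sibling-mated pseudo-F2s (F = 0.25) of the study scored roughly 4
#'   points lower than their F1 relatives, i.e. about -16 per unit F.
#' @param n_epi_pairs number of additive-by-additive QTL pairs.
#' @return a list of class `traitSimParams`.
#' @export
traitSimParams <- function(
    ws = list(additive_var = 12.52, dominance_var = 0, epistatic_var = 1.23,
              residual_genotypic_var = 7.44,
              year_residual_vars = c(25.52, 22.16, 20.5),
              mean = 10, censor_bounds = c(0, 20), round = TRUE),
    hd = list(additive_var = 25.38, dominance_var = 1.87, epistatic_var = 0,
              residual_genotypic_var = 14.12,
              year_residual_vars = c(50.91, 39.98),
              mean = 227, censor_bounds = NULL, round = FALSE),
    n_qtl = 200L, pleiotropy_corr = 0, structure_effect = c(0, 0),
    year_effects = list(ws = c(0, -3, 3), hd = c(0, -2)),
    fallvigor_effect = 1, inbreeding_depression = c(0, 0),
    n_epi_pairs = 100L) {
  for (tr in list(ws, hd)) {
    v <- unlist(tr[c("additive_var", "dominance_var", "epistatic_var",
                     "residual_genotypic_var", "year_residual_vars")])
    if (any(!is.finite(v)) || any(v < 0)) stop("variances must be finite and >= 0")
    if (!is.null(tr$censor_bounds) && tr$censor_bounds[1] >= tr$censor_bounds[2])
      stop("censor bounds must satisfy low < high")
  }
  if (abs(pleiotropy_corr) > 1) stop("pleiotropy_corr must lie in [-1, 1]")
  if (any(abs(structure_effect) > 1)) stop("structure loadings lie in [-1, 1]")
  structure(list(ws = ws, hd = hd, n_qtl = as.integer(n_qtl),
                 pleiotropy_corr = pleiotropy_corr,
                 structure_effect = structure_effect,
                 year_effects = year_effects,
                 fallvigor_effect = fallvigor_effect,
                 inbreeding_depression = rep_len(inbreeding_depression, 2),
                 n_epi_pairs = as.integer(n_epi_pairs)),
            class = "traitSimParams")
}

# Scale a genetic-value vector so its sample variance matches the target
# variance under the corresponding realized kernel K: the GBLUP prior
# u ~ N(0, K * sigma2) implies E[var(u)] = sigma2 * (mean(diag K) - mean(K)).
.calibrate <- function(u, sigma2, K) {
  if (sigma2 <= 0) return(u * 0)
  target <- sigma2 * (mean(diag(K)) - mean(K))
  v0 <- stats::var(u)
  if (v0 <= 0) return(u * 0)
  u * sqrt(target / v0)
}

#' Simulate multi-year phenotypes on a pedigree
#'
#' Latent genetic value per trait = QTL additive + dominance +
#' pairwise-epistatic effects + a residual genotypic effect, each calibrated
#' so that its realized variance matches the requested variance component
#' under the corresponding realized relationship matrix (so REML on the
#' simulated data is estimating its own generating parameters). Observed
#' records add year effects, a fall-vigor covariate effect (survivorship
#' only) and year-specific residuals; survivorship is censored to its bounds
#' and rounded, and a score of 0 (mortality) is absorbing: later records stay
#' 0 and heading date is unobserved from death onward.
#'
#' @param pedigree,genomes output of [buildPedigree()].
#' @param params a [traitSimParams()].
#' @param n_years number of survivorship record years.
#' @param seed integer seed.
#' @param censor if `FALSE`, the latent Gaussian records are returned
#'   uncensored and unrounded (used for clean parameter-recovery studies).
#' @return list with `phenotypes` (data.frame: individual, year, trait,
#'   value, fall_vigor) and `truth` (true genetic values, components and QTL
#'   indices per trait).
#' @export
simulatePhenotypes <- function(pedigree, genomes, params = traitSimParams(),
                               n_years = 3L, seed = 1L, censor = TRUE) {
  stopifnot(inherits(params, "traitSimParams"), n_years >= 1)
  set.seed(seed)
  M <- trueDosages(genomes)
  ids <- rownames(M)
  n <- nrow(M); nsite <- ncol(M)
  af <- genomes@config$af
  d <- if (!is.null(af)) af$pop2 - af$pop1 else rep(0, nsite)

  # QTL sets
  if (params$pleiotropy_corr != 0) {
    shared <- sample(nsite, params$n_qtl)
    qtl <- list(ws = shared, hd = shared)
  } else {
    # disjoint causal sets: any cross-trait correlation must come from
    # cross-locus LD (ancestry structure), never from shared loci
    # (n_qtl is capped at half the site count to keep the sets disjoint)
    nq <- min(params$n_qtl, nsite %/% 2L)
    both <- sample(nsite, 2L * nq)
    qtl <- list(ws = both[seq_len(nq)], hd = both[nq + seq_len(nq)])
  }
  # base (unaligned) effects, correlated across traits if pleiotropic
  nq <- length(qtl$ws)
  z1 <- stats::rnorm(nq)
  if (params$pleiotropy_corr != 0) {
    rho <- params$pleiotropy_corr
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(nq)
  } else z2 <- stats::rnorm(nq)
  zs <- list(ws = z1, hd = z2)

  # realized kernels for calibration (all sites)
  G <- additiveG(M, jitter = 0)
  D <- dominanceD(M, jitter = 0)
  E <- epistaticE(G, jitter = 0)

  truth <- list(qtl = qtl, genetic = NULL)
  gmat <- matrix(0, n, 2, dimnames = list(ids, c("ws", "hd")))
  bvmat <- matrix(0, n, 2, dimnames = list(ids, c("ws", "hd")))
  for (t in 1:2) {
    tn <- c("ws", "hd")[t]
    pt <- params[[tn]]
    idx <- qtl[[tn]]
    s <- params$structure_effect[t]
    a <- sqrt(max(0, 1 - s^2)) * zs[[tn]]
    if (s != 0) {
      dq <- d[idx]
      if (stats::sd(dq) > 0) a <- a + s * dq / stats::sd(dq)
      else warning("no subpopulation divergence; structure loading ignored")
    }
    W <- sweep(M[, idx, drop = FALSE], 2L, colMeans(M[, idx, drop = FALSE]))
    u_a <- .calibrate(drop(W %*% a), pt$additive_var, G)
    # dominance deviations at the QTL
    u_d <- 0
    if (pt$dominance_var > 0) {
      het <- (M[, idx, drop = FALSE] == 1) * 1
      u_d <- .calibrate(drop(sweep(het, 2L, colMeans(het)) %*%
                               stats::rnorm(length(idx))), pt$dominance_var, D)
    }
    # additive x additive pairs
    u_e <- 0
    if (pt$epistatic_var > 0) {
      pr <- matrix(sample(idx, 2L * params$n_epi_pairs, replace = TRUE), ncol = 2)
      pr <- pr[pr[, 1] != pr[, 2], , drop = FALSE]
      Wc <- sweep(M, 2L, colMeans(M))
      ee <- stats::rnorm(nrow(pr))
      u_e <- .calibrate(drop((Wc[, pr[, 1], drop = FALSE] *
                                Wc[, pr[, 2], drop = FALSE]) %*% ee),
                        pt$epistatic_var, E)
    }
    u_R <- stats::rnorm(n, 0, sqrt(pt$residual_genotypic_var))
    bvmat[, t] <- u_a
    gmat[, t] <- u_a + u_d + u_e + u_R
  }
  # directional inbreeding depression on the latent scale
  ibd <- params$inbreeding_depression
  if (is.null(ibd)) ibd <- c(0, 0)
  if (any(ibd != 0)) {
    Fi <- inbreedingF(genomes)
    gmat[, "ws"] <- gmat[, "ws"] + ibd[1] * Fi
    gmat[, "hd"] <- gmat[, "hd"] + ibd[2] * Fi
  }
  truth$bv <- bvmat
  truth$genetic <- gmat

  fall_vigor <- pmin(pmax(round(stats::rnorm(n, 3.5, 1)), 0), 5)
  names(fall_vigor) <- ids

  recs <- list()
  dead_at <- rep(Inf, n)  # first year with survivorship score 0
  yrs_ws <- seq_len(n_years)
  resid_ws <- rep_len(params$ws$year_residual_vars, n_years)
  yeff_ws <- rep_len(params$year_effects$ws, n_years)
  for (y in yrs_ws) {
    val <- params$ws$mean + gmat[, "ws"] + yeff_ws[y] +
      params$fallvigor_effect * (fall_vigor - 3.5) +
      stats::rnorm(n, 0, sqrt(resid_ws[y]))
    if (censor && !is.null(params$ws$censor_bounds)) {
      val <- pmin(pmax(val, params$ws$censor_bounds[1]),
                  params$ws$censor_bounds[2])
      if (isTRUE(params$ws$round)) val <- round(val)
      val[dead_at < y] <- params$ws$censor_bounds[1]
      dead_at[val <= params$ws$censor_bounds[1] & dead_at > y] <- y
    }
    recs[[length(recs) + 1L]] <- data.frame(
      individual = ids, year = y, trait = "ws", value = val,
      fall_vigor = fall_vigor, stringsAsFactors = FALSE)
  }
  n_years_hd <- min(n_years, length(params$hd$year_residual_vars))
  yeff_hd <- rep_len(params$year_effects$hd, n_years_hd)
  for (y in seq_len(n_years_hd)) {
    val <- params$hd$mean + gmat[, "hd"] + yeff_hd[y] +
      stats::rnorm(n, 0, sqrt(params$hd$year_residual_vars[y]))
    if (isTRUE(params$hd$round)) val <- round(val)
    val[dead_at <= y] <- NA_real_   # dead plants do not flower
    recs[[length(recs) + 1L]] <- data.frame(
      individual = ids, year = y, trait = "hd", value = val,
      fall_vigor = fall_vigor, stringsAsFactors = FALSE)
  }
  pheno <- do.call(rbind, recs)
  rownames(pheno) <- NULL
  pheno <- pheno[!is.na(pheno$value), , drop = FALSE]
  list(phenotypes = pheno, truth = truth)
}
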