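setupOneWay <- function(g = 10, r = 4, su = 4, se = 2, seed = 101) {
  set.seed(seed)
  ids <- sprintf("G%02d", 1:g)
  u <- rnorm(g, 0, sqrt(su))
  d <- data.frame(individual = rep(ids, each = r), year = 1,
                  trait = "ws", value = rep(u, each = r) +
                    rnorm(g * r, 0, sqrt(se)),
                  fall_vigor = 0, stringsAsFactors = FALSE)
  list(d = d, ids = ids)
}

test_that("REML on balanced one-way data matches the ANOVA estimators", {
  s <- setupOneWay()
  fit <- fitREML(s$d, list(I = identityKernel(s$ids)),
                 year_specific_residual = FALSE)
  # closed-form oracle: sigma_u = (MSA - MSE)/r, sigma_e = MSE
  a <- anova(lm(value ~ individual, data = s$d))
  msa <- a$`Mean Sq`[1]; mse <- a$`Mean Sq`[2]
  expect_equal(varComp(fit)$estimate[1], (msa - mse) / 4, tolerance = 1e-4)
  expect_equal(varComp(fit)$estimate[2], mse, tolerance = 1e-4)
  # accepted iterations never decrease the restricted likelihood
  expect_true(all(diff(fit@details$trace) > -1e-8))
})

test_that("duplicated kernels are flagged but their sum stays stable", {
  s <- setupOneWay(seed = 103)
  K <- identityKernel(s$ids)
  single <- fitREML(s$d, list(I = K), year_specific_residual = FALSE)
  expect_warning(
    dup <- fitREML(s$d, list(I = K, I2 = K), year_specific_residual = FALSE),
    "identified")
  expect_equal(sum(varComp(dup)$estimate[1:2]),
               varComp(single)$estimate[1], tolerance = 0.05)
})

test_that("GBLUP additive predictions equal the ridge marker solution", {
  w <- fxWorld()
  set.seed(11)
  ids <- individuals(w$sim$genomes)[1:30]
  M <- w$M[ids, ]
  M <- M[, colMeans(M) > 0 & colMeans(M) < 2][, 1:150]
  G <- additiveG(M)
  u <- w$ph$truth$bv[ids, "ws"]
  d <- data.frame(individual = ids, year = 1, trait = "ws",
                  value = u + rnorm(30, 0, 2), fall_vigor = 0,
                  stringsAsFactors = FALSE)
  fit <- fitREML(d, list(G = G), year_specific_residual = FALSE)
  th <- varComp(fit)$estimate
  # oracle: direct closed-form ridge regression on the marker matrix with
  # lambda implied by the fitted variances
  p <- colMeans(M) / 2
  cc <- 2 * sum(p * (1 - p))
  W <- sweep(M, 2, 2 * p)
  V <- th[1] * tcrossprod(W) / cc + diag(30) * th[2] +
    diag(30) * 1e-6 * th[1]           # kernel jitter as in additiveG
  mu <- sum(solve(V, d$value)) / sum(solve(V, rep(1, 30)))
  ahat <- (th[1] / cc) * crossprod(W, solve(V, d$value - mu))
  u_ridge <- drop(W %*% ahat)
  expect_equal(unname(gebv(fit)), unname(u_ridge), tolerance = 1e-5)
})

test_that("reliability equals the explicit mixed-model-equation inverse", {
  # 3 phenotyped individuals + 1 unphenotyped one with little relationship
  set.seed(41)
  M <- rbind(a = sample(0:2, 80, TRUE), b = sample(0:2, 80, TRUE),
             c = sample(0:2, 80, TRUE), d = sample(0:2, 80, TRUE))
  M[2, 1:40] <- M[1, 1:40]            # a and b share half their genome
  G <- additiveG(M)
  set.seed(5)
  d <- data.frame(individual = rep(c("a", "b", "c"), each = 3), year = 1,
                  trait = "ws",
                  value = rep(c(2, 1, -3), each = 3) + rnorm(9, 0, 1),
                  fall_vigor = 0, stringsAsFactors = FALSE)
  fit <- fitREML(d, list(G = G), year_specific_residual = FALSE)
  th <- varComp(fit)$estimate
  expect_gt(th[1], 0)
  # oracle: invert the MME coefficient matrix at the fitted variances
  X <- matrix(1, 9, 1)
  Z <- matrix(0, 9, 4); Z[cbind(1:9, rep(1:3, each = 3))] <- 1
  C <- rbind(cbind(crossprod(X) / th[2], crossprod(X, Z) / th[2]),
             cbind(crossprod(Z, X) / th[2],
                   crossprod(Z) / th[2] + solve(G) / th[1]))
  pev_mme <- as.numeric(diag(solve(C))[-1])
  expect_equal(unname(pev(fit)), pev_mme, tolerance = 1e-5)
  r2 <- reliability(fit, G)
  expect_equal(unname(r2), unname(pmin(pmax(
    1 - pev_mme / (diag(unclass(G)) * th[1]), 0), 1)), tolerance = 1e-5)
  # the unphenotyped, nearly unrelated individual has the lowest reliability
  expect_lt(r2["d"], min(r2[c("a", "b", "c")]))
  expect_lt(r2["d"], 0.3)
})

test_that("adding records for an individual does not reduce its reliability", {
  M <- rbind(a = c(0, 1, 2, 0, 1, 2), b = c(0, 1, 2, 2, 1, 0),
             c = c(2, 1, 0, 2, 1, 0))
  G <- additiveG(M)
  set.seed(6)
  base <- data.frame(individual = c("a", rep(c("b", "c"), each = 3)),
                     year = 1, trait = "ws",
                     value = c(2, rnorm(6, 0, 2)), fall_vigor = 0,
                     stringsAsFactors = FALSE)
  more <- rbind(base, data.frame(individual = "a", year = 1, trait = "ws",
                                 value = c(2.5, 1.5, 2.2), fall_vigor = 0))
  r1 <- reliabilities(fitREML(base, list(G = G),
                              year_specific_residual = FALSE))["a"]
  r2 <- reliabilities(fitREML(more, list(G = G),
                              year_specific_residual = FALSE))["a"]
  expect_gte(r2 + 1e-6, r1)
})

test_that("stage-one BLUEs reduce to genotype means and equal weights when balanced", {
  s <- setupOneWay(g = 6, r = 3, seed = 107)
  b <- fitBlues(s$d)
  mns <- tapply(s$d$value, s$d$individual, mean)
  expect_equal(b$blue, as.numeric(mns[b$individual]), tolerance = 1e-8)
  expect_equal(var(b$weight), 0)
})

test_that("unbalanced BLUEs match the normal-equation solution", {
  set.seed(109)
  d <- data.frame(
    individual = c("g1", "g1", "g2", "g2", "g3", "g4", "g4", "g4", "g5",
                   "g6", "g6"),
    year = c(1, 2, 1, 2, 1, 1, 2, 2, 2, 1, 2),
    trait = "ws", value = rnorm(11, 10, 3),
    fall_vigor = 0, stringsAsFactors = FALSE)
  b <- fitBlues(d)
  # oracle: explicit normal equations with the same parameterization
  gfac <- factor(d$individual)
  Xg <- model.matrix(~ 0 + gfac)
  xy <- (d$year == 2) * 2 - 1            # contr.sum column for 2 years
  X <- cbind(Xg, -xy)
  bb <- solve(crossprod(X), crossprod(X, d$value))
  expect_equal(b$blue, as.numeric(bb[1:6]), tolerance = 1e-8)
})

test_that("two-stage weighted prediction behaves as specified", {
  # pedigree-structured kinship (so the additive variance is identified)
  # plus genuine residual genotypic variance (so the individual-level noise
  # split is interior, where two-stage and joint fits coincide)
  w <- fxWorld()
  ids <- w$sim$pedigree$id[w$sim$pedigree$generation %in%
                             c("F1", "pseudoF2")][1:60]
  G <- additiveG(w$M[ids, ])
  set.seed(9)
  u <- w$ph$truth$bv[ids, "ws"] + rnorm(60, 0, 2)
  s <- list(ids = ids,
            d = data.frame(individual = rep(ids, each = 3), year = 1,
                           trait = "ws",
                           value = rep(u, each = 3) + rnorm(180, 0, 3),
                           fall_vigor = 0, stringsAsFactors = FALSE))
  blues <- fitBlues(s$d)
  # equal SEs: weighted fit identical to unweighted
  fitw <- suppressWarnings(twoStagePredict(blues, G))
  blues_nose <- blues; blues_nose$se <- NULL
  expect_warning(fitu <- twoStagePredict(blues_nose, G), "unweighted")
  expect_equal(gebv(fitw), gebv(fitu), tolerance = 1e-8)
  # an infinite-SE genotype loses its influence on its own GEBV
  # limit behavior, isolated from the I kernel (which is confounded with a
  # near-constant weighted residual): an enormous-SE genotype's BLUE has
  # vanishing influence on its own GEBV
  b2 <- blues; b2$se[1] <- 1e8
  b3 <- b2; b3$blue[1] <- b3$blue[1] + 50
  g2 <- gebv(suppressWarnings(twoStagePredict(b2, G,
                                              include_residual = FALSE)))
  g3 <- gebv(suppressWarnings(twoStagePredict(b3, G,
                                              include_residual = FALSE)))
  expect_lt(abs(g3[b2$individual[1]] - g2[b2$individual[1]]), 0.1)
  # balanced data: two-stage GEBVs match the joint single-stage fit
  joint <- suppressWarnings(
    fitREML(s$d, list(G = G, I = identityKernel(s$ids)),
            year_specific_residual = FALSE))
  twost <- suppressWarnings(twoStagePredict(blues, G))
  expect_gt(cor(gebv(twost)[s$ids], gebv(joint)[s$ids]), 0.9999)
  expect_lt(max(abs(gebv(twost)[s$ids] - gebv(joint)[s$ids])) /
              sd(gebv(joint)), 0.01)
})

test_that("multi-trait REML recovers the genetic covariance structure", {
  cfg <- genomeConfig(n_chromosomes = 2, sites_per_chromosome = 400,
                      divergence = 0.1)
  des <- pedigreeDesign(n_founders = 10, n_tolerant = 2,
                        f1_sizes = c(25L, 25L), pf2_sizes = c(25L, 25L))
  sim <- buildPedigree(cfg, des, seed = 301)
  prm <- traitSimParams(
    ws = list(additive_var = 10, dominance_var = 0, epistatic_var = 0,
              residual_genotypic_var = 2, year_residual_vars = c(8, 8),
              mean = 10, censor_bounds = NULL, round = FALSE),
    hd = list(additive_var = 10, dominance_var = 0, epistatic_var = 0,
              residual_genotypic_var = 2, year_residual_vars = c(8, 8),
              mean = 227, censor_bounds = NULL, round = FALSE),
    pleiotropy_corr = -0.5, year_effects = list(ws = c(0, 1), hd = c(0, 1)))
  ph <- simulatePhenotypes(sim$pedigree, sim$genomes, prm, n_years = 2,
                           seed = 302, censor = FALSE)
  ids <- sim$pedigree$id
  G <- additiveG(trueDosages(sim$genomes))
  fit <- fitMultitrait(ph$phenotypes, list(G = G, I = identityKernel(ids)))
  vc <- varComp(fit)
  cv <- vc$estimate[vc$component == "G:cov"]
  v1 <- vc$estimate[vc$component == "G:var_ws"]
  v2 <- vc$estimate[vc$component == "G:var_hd"]
  rg <- cv / sqrt(v1 * v2)
  expect_lt(rg, -0.2)                 # sign and rough magnitude recovered
  expect_equal(rg, -0.5, tolerance = 0.5)
  # with covariances fixed at 0 the fit decouples into single-trait fits
  fit0 <- fitMultitrait(ph$phenotypes, list(G = G, I = identityKernel(ids)),
                        fix_cov = TRUE)
  f_ws <- fitREML(ph$phenotypes, list(G = G, I = identityKernel(ids)),
                  trait = "ws")
  expect_gt(cor(fit0@blup$G[, "ws"], f_ws@blup$G), 0.9999)
  expect_equal(unname(fit0@blup$G[, "ws"]), unname(f_ws@blup$G),
               tolerance = 0.02)
})
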