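# brute-force application of the published filter rules, used as the oracle
.bruteFilter <- function(M, founders, cfg) {
  nsite <- ncol(M)
  drop <- rep(NA_character_, nsite)
  miss <- colMeans(is.na(M))
  drop[miss >= cfg$max_missing] <- "missing"
  af <- colMeans(M[founders, , drop = FALSE], na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af); maf[is.nan(maf)] <- 0
  drop[is.na(drop) & maf < cfg$min_maf] <- "maf"
  kept <- integer(0)
  for (j in which(is.na(drop))) {
    bad <- FALSE
    for (k in tail(kept, cfg$ld_window_sites)) {
      x <- M[founders, j]; y <- M[founders, k]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
      if (cor(x[ok], y[ok])^2 >= cfg$max_ld_r2) { bad <- TRUE; break }
    }
    if (bad) drop[j] <- "ld" else kept <- c(kept, j)
  }
  list(kept = kept, drop = drop)
}

test_that("site filters match exhaustive rule application on a toy matrix", {
  set.seed(17)
  n <- 12
  founders <- paste0("F", 1:6)
  ids <- c(founders, paste0("X", 1:6))
  M <- matrix(sample(0:2, n * 10, replace = TRUE), n, 10,
              dimnames = list(ids, NULL))
  M[1:3, 1] <- NA                      # 25% missing -> dropped
  M[, 2] <- c(rep(0, 11), 1)          # founder MAF 0 -> dropped
  M[founders, 3] <- c(0, 0, 0, 0, 0, 1)  # founder MAF 1/12 = 0.083 kept
  M[founders, 4] <- c(0, 0, 0, 0, 1, 0)  # founder MAF 0.083, r2=? vs site 3
  M[, 6] <- M[, 5]                     # identical -> LD-dropped
  cfg <- filterConfig(min_maf = 0.05)
  gd <- toyGD(M)
  out <- filterSites(gd, cfg, founders)
  oracle <- .bruteFilter(M, founders, cfg)
  expect_equal(nrow(out$gd), length(oracle$kept))
  expect_equal(siteInfo(out$gd)$pos, oracle$kept * 100L)
  got <- out$audit$rule[order(out$audit$site)]
  expect_equal(got, oracle$drop[!is.na(oracle$drop)])
  expect_true("missing" %in% got && "ld" %in% got && "maf" %in% got)

  # a site with founder MAF 0.04 at threshold 0.05 is dropped as "maf"
  M2 <- matrix(rep(c(0, 2), 25), 50, 4,
               dimnames = list(paste0("F", 1:50), NULL))
  M2[, 2] <- c(rep(2, 48), 1, 1)       # MAF = 2/100 = 0.02 < 0.05
  M2[, 3] <- sample(0:2, 50, TRUE)
  M2[, 4] <- sample(0:2, 50, TRUE)
  out2 <- filterSites(toyGD(M2), cfg, paste0("F", 1:50))
  expect_equal(out2$audit$rule[out2$audit$site == 2], "maf")

  # idempotence: re-filtering the survivors drops nothing
  out3 <- filterSites(out$gd, cfg, founders)
  expect_equal(nrow(out3$audit), 0)
  expect_equal(nrow(out3$gd), nrow(out$gd))
  expect_error(filterSites(gd, cfg, character(0)), "founder")
})

test_that("unambiguous parental assignment fills exactly the forced calls", {
  ped <- data.frame(id = c("P1", "P2", "K1"),
                    parent1 = c(NA, NA, "P1"), parent2 = c(NA, NA, "P2"),
                    generation = c("founder", "founder", "F1"),
                    family = c(NA, NA, "F1.1"), stringsAsFactors = FALSE)
  M <- rbind(P1 = c(0, 0, 2, 0, 1, NA),
             P2 = c(0, 2, 0, 2, 1, 2),
             K1 = c(NA, NA, NA, 1, NA, NA))
  out <- t(dosages(assignUnambiguous(toyGD(M), ped)))
  expect_equal(unname(out["K1", ]), c(0, 1, 1, 1, NA, NA))
  expect_equal(out[c("P1", "P2"), ], M[c("P1", "P2"), ])  # parents untouched
})

test_that("EM imputation is exact, conservative and beats site means", {
  w <- fxWorld()
  M <- w$M[1:40, 1:300] + 0   # double storage, as imputation returns
  gd <- GenotypeData(t(M), chrom = siteInfo(w$sim$genomes)$chrom[1:300],
                     pos = siteInfo(w$sim$genomes)$pos[1:300])
  expect_identical(dosages(imputeEM(gd)), dosages(gd))  # nothing missing

  # single missing entry, all other individuals dosage 2 -> imputed 2
  M1 <- matrix(2, 6, 4, dimnames = list(paste0("i", 1:6), NULL))
  M1[, 2] <- c(0, 1, 2, 0, 1, 2)   # keep matrix polymorphic
  M1[1, 1] <- NA
  out <- t(dosages(imputeEM(toyGD(M1))))
  expect_equal(unname(out[1, 1]), 2, tolerance = 1e-8)

  # masked-entry recovery: EM RMSE strictly below site-mean RMSE
  set.seed(7)
  mask <- which(matrix(runif(length(M)), nrow(M)) < 0.05)
  Mm <- M; Mm[mask] <- NA
  gdm <- GenotypeData(t(Mm), chrom = siteInfo(w$sim$genomes)$chrom[1:300],
                      pos = siteInfo(w$sim$genomes)$pos[1:300])
  imp <- t(dosages(imputeEM(gdm)))
  mu <- matrix(colMeans(Mm, na.rm = TRUE), nrow(M), ncol(M), byrow = TRUE)
  rmse_em <- sqrt(mean((imp[mask] - M[mask])^2))
  rmse_mu <- sqrt(mean((mu[mask] - M[mask])^2))
  expect_lt(rmse_em, rmse_mu)
  # observed entries preserved bit-exactly; deterministic
  expect_identical(imp[-mask], M[-mask])
  expect_identical(imp, t(dosages(imputeEM(gdm))))
  # a site with zero observed calls is rejected
  Mz <- M1; Mz[, 3] <- NA
  expect_error(imputeEM(toyGD(Mz)), "zero observed")
})

test_that("haplotype projection assigns dosages from segment states", {
  # founders with known dosages; one mapped individual with three segments
  ped <- .toyPedProj <- data.frame(
    id = c("A", "B", "P1", "P2", "C1"),
    parent1 = c(NA, NA, "A", "A", "P1"),
    parent2 = c(NA, NA, "B", "B", "P2"),
    generation = c("founder", "founder", "F1", "F1", "pseudoF2"),
    family = c(NA, NA, "F1.1", "PF2.1", "PF2.1"), stringsAsFactors = FALSE)
  M <- rbind(A = c(2, 2, 0, 2, 1, 0),
             B = c(0, 0, 2, 0, 1, 2),
             P1 = c(1, 1, 1, 1, 1, 1), P2 = c(1, 1, 1, 1, 1, 1),
             C1 = c(NA, NA, NA, NA, NA, NA))
  gd <- toyGD(M)
  mk <- structure(list(sites = 1:6, chrom = rep("Chr1", 6),
                       aAlleleIsAlt = rep(TRUE, 6), founderA = "A",
                       founderB = "B", f1Parents = c("P1", "P2"),
                       family = "PF2.1", members = "C1"),
                  class = "InformativeMarkerSet")
  states <- c("homA", "homA", "het", "het", "unassigned", "homB")
  maps <- buildHaplotypeMap(matrix(states, 1, dimnames = list("C1", NULL)),
                            chrom = mk$chrom, min_run_sites = 1, markers = mk)
  out <- t(dosages(projectHaplotypes(gd, maps)))
  expect_equal(unname(out["C1", ]), c(2, 2, 1, 1, NA, 2))
  # homA with founder dosage 2 -> 2; het with founders 2/0 -> 1  (above)
  # unmapped individuals are left unchanged, with a warning
  maps2 <- maps; maps2@segments <- list(); maps2@hetFraction <- numeric(0)
  expect_warning(projectHaplotypes(gd, maps2), "no haplotype map")
})

test_that("projection beats naive hard calls at shallow depth", {
  w <- fxHapWorld(seed = 5, depth = c(1, 2))
  hm <- familyHaplotypeMaps(w$gd, w$sim$pedigree, w$fam)
  ids <- individuals(hm$maps)
  truthM <- trueDosages(w$sim$genomes)[ids, , drop = FALSE]
  hard <- t(dosages(w$gd))[ids, , drop = FALSE]
  # complete founder calls, then project
  gd2 <- w$gd
  d <- dosages(gd2)
  fnd <- c(hm$markers$founderA, hm$markers$founderB)
  for (f in fnd) d[is.na(d[, f]), f] <- 1
  SummarizedExperiment::assay(gd2, "dosage") <- d
  proj <- t(dosages(projectHaplotypes(gd2, hm$maps)))[ids, , drop = FALSE]
  # the rescue target: truly heterozygous sites, which one or two reads
  # cannot call (homozygous sites are trivially right from a single read)
  het <- truthM == 1 & !is.na(hard) & !is.na(proj)
  acc_hard <- mean(abs(hard[het] - truthM[het]) < 0.5)
  acc_proj <- mean(abs(proj[het] - truthM[het]) < 0.5)
  expect_gt(acc_proj, acc_hard)
})

test_that("second round drops low-call sites then completes the matrix", {
  M <- rbind(A = c(0, 2, 1, 0), B = c(2, 0, 1, 2),
             m1 = c(0, NA, NA, 1), m2 = c(1, NA, 1, 0),
             m3 = c(0, NA, NA, 2), m4 = c(2, NA, NA, 1),
             m5 = c(1, NA, NA, 0), m6 = c(0, NA, NA, 1),
             m7 = c(1, NA, 0, 2), m8 = c(2, NA, NA, 1),
             m9 = c(0, NA, NA, 0), m10 = c(1, NA, NA, 2))
  gd <- toyGD(M)
  out <- secondRound(gd, mapped_ids = paste0("m", 1:10),
                     cfg = filterConfig())
  # site 2: 0% calls among mapped -> dropped; site 3: 30% >= 20% retained
  expect_equal(out$audit$site, 2L)
  expect_equal(nrow(out$gd), 3)
  expect_false(anyNA(dosages(out$gd)))
})
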