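# toy family: founders FND01/FND02, F1 parents P1/P2, pseudo-F2 children
.toyPed <- data.frame(
  id = c("FND01", "FND02", "P1", "P2", "C1", "C2"),
  parent1 = c(NA, NA, "FND01", "FND01", "P1", "P1"),
  parent2 = c(NA, NA, "FND02", "FND02", "P2", "P2"),
  generation = c("founder", "founder", "F1", "F1", "pseudoF2", "pseudoF2"),
  family = c(NA, NA, "F1.1", "F1.1", "PF2.1", "PF2.1"),
  stringsAsFactors = FALSE)

test_that("informative-marker selection applies both published criteria", {
  # rows: FND01 FND02 P1 P2 C1 C2; columns: 6 sites
  M <- rbind(FND01 = c(0, 0, 2, 0, 1, NA),
             FND02 = c(0, 2, 0, 2, 2, 2),
             P1    = c(1, 1, 1, 1, 1, 1),
             P2    = c(1, 1, 1, 1, 1, 1),
             C1    = c(0, 0, 2, 0, 1, 1),
             C2    = c(0, 2, 0, 2, 1, 1))
  dp <- matrix(3, 6, 6, dimnames = list(rownames(M), NULL))
  dp["P1", 4] <- 0; dp["P2", 4] <- 0     # site 4: no F1 parent depth
  gd <- toyGD(M, refDepth = dp, altDepth = dp * 0)
  mk <- selectInformativeMarkers(gd, .toyPed, "PF2.1", min_parent_depth = 4)
  # site1 matching homozygotes, site4 zero parent depth, site5 het parent,
  # site6 missing founder call -> only sites 2 and 3 retained
  expect_equal(mk$sites, c(2L, 3L))
  # orientation: grandparent A = FND01 (parent1 lineage)
  expect_equal(mk$founderA, "FND01")
  expect_equal(unname(mk$aAlleleIsAlt), c(FALSE, TRUE))
  expect_error(selectInformativeMarkers(gd, .toyPed, "nope"), "family")
})

test_that("windowed ancestry probability is the direct read ratio", {
  M <- rbind(FND01 = rep(0, 8), FND02 = rep(2, 8),
             P1 = rep(1, 8), P2 = rep(1, 8),
             C1 = rep(1, 8), C2 = rep(1, 8))
  # C1: ref (=A) reads only at sites 1-4; mixed 5,6; nothing at 7,8
  rd <- matrix(0, 6, 8, dimnames = list(rownames(M), NULL))
  ad <- rd
  rd["P1", ] <- 5; rd["P2", ] <- 5
  rd["C1", 1:4] <- 2
  rd["C1", 5] <- 5; ad["C1", 5] <- 5
  gd <- toyGD(M, refDepth = rd, altDepth = ad)
  mk <- selectInformativeMarkers(gd, .toyPed, "PF2.1")
  expect_equal(length(mk$sites), 8L)
  tr <- windowAncestryProbability(gd, mk, individuals = "C1",
                                  window_sites = 3)
  # oracle: direct ratio of A reads over total reads in the centered window
  aRead <- c(2, 2, 2, 2, 5, 0, 0, 0); tRead <- c(2, 2, 2, 2, 10, 0, 0, 0)
  phat_exp <- vapply(1:8, function(i) {
    win <- max(1, i - 1):min(8, i + 1)
    if (sum(tRead[win]) == 0) NA_real_ else sum(aRead[win]) / sum(tRead[win])
  }, numeric(1))
  expect_equal(unname(tr$phat["C1", ]), phat_exp)
  expect_error(windowAncestryProbability(gd, mk, window_sites = 0),
               "window_sites")
})

test_that("parental state thresholds match the published rule exactly", {
  p <- c(0.95, 0.5, 0.15, 0.05, 0.85, 1, 0, NA, 0.2, 0.75, 0.1, 0.9, 0.21,
         0.749)
  tr <- structure(list(phat = matrix(p, 1, dimnames = list("i", NULL))),
                  class = "AncestryProbTrack")
  st <- callParentalStates(tr)[1, ]
  expect_equal(unname(st),
               c("homA", "het", "unassigned", "homB", "unassigned", "homA",
                 "homB", "unassigned", "unassigned", "unassigned",
                 "unassigned", "unassigned", "het", "het"))
})

test_that("short heterozygous runs are dropped with exact boundary rules", {
  mkmap <- function(states) {
    maps <- buildHaplotypeMap(matrix(states, 1, dimnames = list("i", NULL)),
                              chrom = rep("Chr1", length(states)))
    segments(maps)[["i"]]
  }
  # het run of 99 between homozygous runs is absorbed (100 is not < 100)
  seg <- mkmap(rep(c("homA", "het", "homA"), c(200, 99, 200)))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$state, "homA")
  expect_equal(seg$end - seg$start + 1, 499)
  seg <- mkmap(rep(c("homA", "het", "homA"), c(200, 100, 200)))
  expect_equal(nrow(seg), 3)
  # discordant homozygous flanks: the short het run becomes unassigned
  seg <- mkmap(rep(c("homA", "het", "homB"), c(200, 50, 200)))
  expect_equal(seg$state, c("homA", "unassigned", "homB"))
  # chromosome end: not between two homozygous runs, retained
  seg <- mkmap(rep(c("homA", "het"), c(150, 50)))
  expect_equal(seg$state, c("homA", "het"))
  expect_error(buildHaplotypeMap(matrix(character(0), 1, 0), character(0)),
               "empty")
})

test_that("segments tile the informative-site axis without overlap", {
  w <- fxHapWorld()
  hm <- familyHaplotypeMaps(w$gd, w$sim$pedigree, w$fam)
  L <- length(hm$markers$sites)
  for (id in individuals(hm$maps)) {
    seg <- segments(hm$maps)[[id]]
    covered <- unlist(Map(seq, seg$start, seg$end))
    expect_equal(sort(covered), seq_len(L))  # full cover, no overlap
    expect_true(all(diff(seg$start) > 0))
  }
})

test_that("individual QC applies the heterozygosity and single-parent rules", {
  mk1 <- function(states) buildHaplotypeMap(
    matrix(states, 1, dimnames = list("i", NULL)),
    chrom = rep("Chr1", length(states)), min_run_sites = 1)
  hi_het <- mk1(rep(c("het", "homA"), c(90, 10)))
  expect_equal(qcFilterIndividuals(hi_het)$removed$reason,
               "excess heterozygosity")
  one_par <- mk1(rep(c("homA", "unassigned"), c(80, 20)))
  expect_equal(qcFilterIndividuals(one_par)$removed$reason,
               "single-parent haplotypes")
  ok <- mk1(rep(c("homA", "het", "homB"), c(30, 40, 30)))
  expect_equal(qcFilterIndividuals(ok)$retained, "i")
  # boundary: het fraction exactly 0.85 is kept (strictly greater removes)
  edge <- mk1(rep(c("het", "homA", "homB"), c(85, 10, 5)))
  expect_equal(qcFilterIndividuals(edge)$retained, "i")
})

test_that("reconstruction matches true ancestry blocks at >=3x depth", {
  accAt <- function(seed, depth) {
    w <- fxHapWorld(seed, depth)
    hm <- familyHaplotypeMaps(w$gd, w$sim$pedigree, w$fam)
    mean(vapply(individuals(hm$maps), function(id) {
      called <- mapStates(hm$maps, hm$markers, id)
      truest <- trueAncestryStates(w$sim, hm$markers, id)
      ass <- called != "unassigned"
      mean(called[ass] == truest[ass])
    }, numeric(1)))
  }
  acc35 <- mean(vapply(c(3, 13), accAt, numeric(1), depth = c(3, 5)))
  expect_gte(acc35, 0.95)
  # accuracy is monotone non-decreasing in read depth
  acc12 <- accAt(3, c(1, 2))
  acc8 <- accAt(3, c(8, 10))
  expect_gte(acc35 + 0.005, acc12)
  expect_gte(acc8 + 0.005, accAt(3, c(3, 5)))
})

test_that("pollen-contaminated individuals are flagged more often than true pseudo-F2s", {
  w <- fxHapWorld(seed = 3)
  sim <- w$sim
  fam_members <- sim$pedigree$id[!is.na(sim$pedigree$family) &
                                   sim$pedigree$family == w$fam]
  f1p <- unique(unlist(sim$pedigree[sim$pedigree$id %in% fam_members,
                                    c("parent1", "parent2")]))
  # contaminants: one true F1 parent crossed to an unrelated founder
  set.seed(99)
  g <- sim$genomes
  conts <- lapply(1:6, function(k)
    makeCross(g, f1p[1], "FND07", id = sprintf("CONT%02d", k)))
  g2 <- g
  for (cc in conts) {
    g2@hapA <- rbind(g2@hapA, cc@hapA); g2@hapB <- rbind(g2@hapB, cc@hapB)
    g2@originA <- rbind(g2@originA, cc@originA)
    g2@originB <- rbind(g2@originB, cc@originB)
  }
  ped2 <- rbind(sim$pedigree,
                data.frame(id = sprintf("CONT%02d", 1:6),
                           parent1 = f1p[1], parent2 = f1p[2],
                           generation = "pseudoF2", family = w$fam,
                           tolerant = FALSE))
  gd2 <- simulateReads(g2, ped2, readDepthModel(
    descendant_depth_range = c(3, 5)), seed = 101)
  hm <- familyHaplotypeMaps(gd2, ped2, w$fam)
  rem <- hm$qc$removed$id
  rate_cont <- mean(sprintf("CONT%02d", 1:6) %in% rem)
  rate_true <- mean(setdiff(fam_members, sprintf("CONT%02d", 1:6)) %in% rem)
  expect_gt(rate_cont, rate_true)
})
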