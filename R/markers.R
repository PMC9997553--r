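#' Marker filter configuration
#'
#' Thresholds follow the study's pipeline: keep sites with missingness below
#' `max_missing` (default 20%), founder minor-allele frequency at least
#' `min_maf` (0.05 for the primary marker set, 0.025 for the merged
#' progeny set), and squared correlation below `max_ld_r2` (0.90) with every
#' retained marker among the nearest `ld_window_sites` (15) variant sites,
#' MAF and LD both computed within the founders. `second_round_min_call` is
#' the minimum call rate within haplotype-mapped individuals for a site to
#' survive the second filtering round (20%).
#'
#' @param max_missing,min_maf,max_ld_r2,second_round_min_call proportions in
#'   \[0, 1\].
#' @param ld_window_sites window size of the LD scan, in variant sites.
#' @return a list of class `filterConfig`.
#' @export
filterConfig <- function(max_missing = 0.20, min_maf = 0.05,
                         max_ld_r2 = 0.90, ld_window_sites = 15L,
                         second_round_min_call = 0.20) {
  props <- c(max_missing, min_maf, max_ld_r2, second_round_min_call)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  structure(list(max_missing = max_missing, min_maf = min_maf,
                 max_ld_r2 = max_ld_r2,
                 ld_window_sites = as.integer(ld_window_sites),
                 second_round_min_call = second_round_min_call),
            class = "filterConfig")
}

#' Filter sites on missingness, founder MAF and founder LD
#'
#' Applies, in order: (1) drop sites with missingness (over all individuals)
#' of `max_missing` or more; (2) drop sites with founder minor-allele
#' frequency below `min_maf`; (3) greedy left-to-right LD pruning within
#' founders — a site is dropped when its squared correlation with any
#' already-retained site among the nearest `ld_window_sites` retained sites
#' on the same chromosome reaches `max_ld_r2` (earlier site kept on ties).
#'
#' @param gd a [GenotypeData-class].
#' @param cfg a [filterConfig()].
#' @param founder_ids individual ids used for the MAF and LD computations.
#' @return list with `gd` (filtered) and `audit` (data.frame: site index in
#'   the input, chrom, pos, rule that dropped it).
#' @export
filterSites <- function(gd, cfg = filterConfig(), founder_ids) {
  if (missing(founder_ids) || !length(founder_ids))
    stop("founder ids are required for MAF/LD filtering")
  dos <- dosages(gd)
  fd <- dos[, intersect(founder_ids, colnames(dos)), drop = FALSE]
  if (!ncol(fd)) stop("no founders found in genotype data")
  nsite <- nrow(dos)
  rule <- rep(NA_character_, nsite)

  miss <- rowMeans(is.na(dos))
  rule[miss >= cfg$max_missing] <- "missing"

  af <- rowMeans(fd, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  rule[is.na(rule) & maf < cfg$min_maf] <- "maf"

  chrom <- siteInfo(gd)$chrom
  keep_idx <- which(is.na(rule))
  retained <- integer(0)
  for (j in keep_idx) {
    prev <- retained[chrom[retained] == chrom[j]]
    prev <- tail(prev, cfg$ld_window_sites)
    dropped <- FALSE
    for (k in rev(prev)) {
      x <- fd[j, ]; y <- fd[k, ]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3) next
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      if (stats::cor(x[ok], y[ok])^2 >= cfg$max_ld_r2) { dropped <- TRUE; break }
    }
    if (dropped) rule[j] <- "ld" else retained <- c(retained, j)
  }
  audit <- data.frame(site = which(!is.na(rule)),
                      chrom = chrom[!is.na(rule)],
                      pos = siteInfo(gd)$pos[!is.na(rule)],
                      rule = rule[!is.na(rule)], stringsAsFactors = FALSE)
  list(gd = gd[retained, ], audit = audit)
}

#' Fill parentally unambiguous missing calls
#'
#' A missing call is filled only when the individual's two parents are both
#' genotyped at the site and are matching homozygotes (0/0 -> 0, 2/2 -> 2)
#' or contrasting homozygotes (0/2 -> 1); every other parental configuration
#' leaves the call missing.
#'
#' @param gd a [GenotypeData-class].
#' @param pedigree pedigree data.frame.
#' @return the [GenotypeData-class] with filled calls.
#' @export
assignUnambiguous <- function(gd, pedigree) {
  dos <- dosages(gd)
  for (i in seq_len(ncol(dos))) {
    id <- colnames(dos)[i]
    r <- match(id, pedigree$id)
    if (is.na(r)) next
    p1 <- pedigree$parent1[r]; p2 <- pedigree$parent2[r]
    if (is.na(p1) || is.na(p2)) next
    if (!p1 %in% colnames(dos) || !p2 %in% colnames(dos)) next
    g1 <- dos[, p1]; g2 <- dos[, p2]
    m <- is.na(dos[, i]) & !is.na(g1) & !is.na(g2)
    dos[m & g1 == 0 & g2 == 0, i] <- 0
    dos[m & g1 == 2 & g2 == 2, i] <- 2
    dos[m & ((g1 == 0 & g2 == 2) | (g1 == 2 & g2 == 0)), i] <- 1
  }
  SummarizedExperiment::assay(gd, "dosage") <- dos
  gd
}

#' Expectation-maximization dosage imputation
#'
#' Alternates between (E) predicting each missing dosage as the
#' relationship-weighted mean of the observed dosages at that site — weights
#' are the positive part of the current realized additive relationship to
#' the observed individuals — and (M) recomputing the relationship matrix
#' from the completed data, starting from site-mean fills, until the largest
#' absolute change in an imputed entry is below `tol` or `max_iter` is
#' reached. Observed entries are never altered; imputations are real-valued.
#'
#' @param gd a [GenotypeData-class].
#' @param max_iter,tol convergence controls (defaults 50, 1e-4).
#' @return the completed [GenotypeData-class].
#' @export
imputeEM <- function(gd, max_iter = 50L, tol = 1e-4) {
  M <- t(dosages(gd))           # individuals x sites
  obs <- !is.na(M)
  if (any(colSums(obs) == 0))
    stop("site(s) with zero observed calls; filter before imputing")
  if (all(obs)) return(gd)
  mu <- colSums(M * obs, na.rm = TRUE) / colSums(obs)
  Mf <- M
  Mf[!obs] <- matrix(rep(mu, each = nrow(M)), nrow(M))[!obs]
  M0 <- M; M0[!obs] <- 0
  for (it in seq_len(max_iter)) {
    G <- additiveG(Mf, jitter = 0)
    Wn <- pmax(unclass(G), 0)
    diag(Wn) <- 0
    num <- Wn %*% M0
    den <- Wn %*% obs
    pred <- ifelse(den > 0, num / den,
                   matrix(rep(mu, each = nrow(M)), nrow(M)))
    pred <- pmin(pmax(pred, 0), 2)
    delta <- max(abs(pred[!obs] - Mf[!obs]))
    Mf[!obs] <- pred[!obs]
    if (delta < tol) break
  }
  SummarizedExperiment::assay(gd, "dosage") <- t(Mf)
  gd
}

#' Project founder genotypes through haplotype maps
#'
#' Replaces each mapped pseudo-F2 individual's dosages with the values
#' implied by its ancestry segments: `homA` segments take founder A's
#' (imputed) dosage, `homB` founder B's, `het` the mean of the two;
#' `unassigned` segments leave the sites missing. Segment boundaries on the
#' informative-site axis are extended to genomic intervals by midpoint
#' between flanking informative markers. Individuals without a map are left
#' unchanged (with a warning listing them).
#'
#' @param gd a [GenotypeData-class] covering all individuals (founders
#'   imputed/complete).
#' @param maps a [HaplotypeMapSet-class] (QC-passed) whose `markers` field
#'   records the informative sites and founder ids.
#' @return the [GenotypeData-class] with projected dosages.
#' @export
projectHaplotypes <- function(gd, maps) {
  mk <- maps@markers
  dos <- dosages(gd)
  st <- siteInfo(gd)
  dA <- dos[, mk$founderA]; dB <- dos[, mk$founderB]
  if (anyNA(dA) || anyNA(dB))
    stop("founder genotypes must be complete before projection")
  pos_inf <- st$pos[mk$sites]; chr_inf <- mk$chrom
  mapped <- intersect(names(maps@segments), colnames(dos))
  unmapped <- setdiff(mk$members, mapped)
  if (length(unmapped))
    warning("no haplotype map for: ", paste(unmapped, collapse = ", "))
  for (id in mapped) {
    seg <- maps@segments[[id]]
    newdos <- rep(NA_real_, nrow(dos))
    for (ch in unique(seg$chrom)) {
      cseg <- seg[seg$chrom == ch, , drop = FALSE]
      gsites <- which(st$chrom == ch)
      if (!nrow(cseg) || !length(gsites)) next
      # genomic interval per segment: midpoints between flanking markers
      lo <- pos_inf[cseg$start]; hi <- pos_inf[cseg$end]
      nlo <- c(-Inf, (hi[-nrow(cseg)] + lo[-1]) / 2)
      nhi <- c((hi[-nrow(cseg)] + lo[-1]) / 2, Inf)
      for (k in seq_len(nrow(cseg))) {
        if (cseg$state[k] == "unassigned") next
        inseg <- gsites[st$pos[gsites] >= nlo[k] & st$pos[gsites] < nhi[k]]
        if (!length(inseg)) next
        newdos[inseg] <- switch(cseg$state[k],
                                homA = dA[inseg],
                                homB = dB[inseg],
                                het = (dA[inseg] + dB[inseg]) / 2)
      }
    }
    dos[, id] <- newdos
  }
  SummarizedExperiment::assay(gd, "dosage") <- dos
  gd
}

#' Second-round filtering and imputation
#'
#' Drops sites whose call rate within the haplotype-mapped individuals is
#' below `second_round_min_call`, then re-runs [imputeEM()] on the
#' remainder.
#'
#' @param gd a projected [GenotypeData-class].
#' @param mapped_ids ids of haplotype-mapped individuals.
#' @param cfg a [filterConfig()].
#' @return list with `gd` (final, complete) and `audit` (dropped sites).
#' @export
secondRound <- function(gd, mapped_ids, cfg = filterConfig()) {
  dos <- dosages(gd)
  mapped_ids <- intersect(mapped_ids, colnames(dos))
  if (!length(mapped_ids)) stop("no mapped individuals present")
  callrate <- rowMeans(!is.na(dos[, mapped_ids, drop = FALSE]))
  drop <- which(callrate < cfg$second_round_min_call)
  audit <- data.frame(site = drop,
                      chrom = siteInfo(gd)$chrom[drop],
                      pos = siteInfo(gd)$pos[drop],
                      rule = rep("second_round_call_rate", length(drop)),
                      stringsAsFactors = FALSE)
  keep <- setdiff(seq_len(nrow(dos)), drop)
  list(gd = imputeEM(gd[keep, ]), audit = audit)
}
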