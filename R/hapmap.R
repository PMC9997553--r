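#' Select family-informative markers
#'
#' For one pseudo-F2 family, retains the biallelic sites at which the two
#' founder grandparents carry contrasting homozygous calls (dosage 0 vs 2)
#' and at which the family's F1 parents have sufficient summed read depth.
#' The allele-to-grandparent orientation is recorded per site; grandparent A
#' is the founder listed as parent1 of the F1 family (pedigree order).
#'
#' @param gd a [GenotypeData-class] with `refDepth`/`altDepth` assays.
#' @param pedigree pedigree data.frame.
#' @param family a pseudo-F2 family id (value of `pedigree$family`).
#' @param min_parent_depth minimum summed read depth across the family's F1
#'   parents for a site to be retained (default 4).
#' @return a list of class `InformativeMarkerSet`: `sites` (row indices into
#'   `gd`), `chrom`, `aAlleleIsAlt` (TRUE when the alternate allele belongs
#'   to grandparent A), `founderA`, `founderB`, `f1Parents`, `family`,
#'   `members`. Zero informative sites is signalled by an empty `sites`
#'   vector with a warning.
#' @export
selectInformativeMarkers <- function(gd, pedigree, family,
                                     min_parent_depth = 4) {
  members <- pedigree$id[!is.na(pedigree$family) & pedigree$family == family]
  if (!length(members)) stop("unknown family: ", family)
  f1p <- unique(unlist(pedigree[pedigree$id %in% members,
                                c("parent1", "parent2")]))
  f1p <- f1p[!is.na(f1p)]
  grand <- unique(unlist(pedigree[pedigree$id %in% f1p,
                                  c("parent1", "parent2")]))
  grand <- grand[!is.na(grand)]
  if (length(grand) != 2)
    stop("family must have exactly 2 distinct founder grandparents, got ",
         length(grand))
  # grandparent A = parent1 of the F1 parents (consistent across siblings)
  founderA <- pedigree$parent1[match(f1p[1], pedigree$id)]
  founderB <- setdiff(grand, founderA)
  dos <- dosages(gd)
  gA <- dos[, founderA]; gB <- dos[, founderB]
  contrasting <- !is.na(gA) & !is.na(gB) &
    ((gA == 0 & gB == 2) | (gA == 2 & gB == 0))
  rd <- SummarizedExperiment::assay(gd, "refDepth")
  ad <- SummarizedExperiment::assay(gd, "altDepth")
  f1p_in <- intersect(f1p, colnames(gd))
  pdepth <- rowSums(rd[, f1p_in, drop = FALSE] + ad[, f1p_in, drop = FALSE])
  keep <- which(contrasting & pdepth >= min_parent_depth)
  if (!length(keep)) warning("no informative sites for family ", family)
  structure(list(sites = keep,
                 chrom = siteInfo(gd)$chrom[keep],
                 aAlleleIsAlt = dos[keep, founderA] == 2,
                 founderA = founderA, founderB = founderB,
                 f1Parents = f1p, family = family,
                 members = intersect(members, colnames(gd))),
            class = "InformativeMarkerSet")
}

#' Windowed grandparental ancestry probability
#'
#' Slides a centered window of `window_sites` informative sites (step 1,
#' truncated at chromosome ends) along each chromosome and computes, at each
#' site, p-hat = (reads matching grandparent A's allele in the window) /
#' (total informative reads in the window). Sites whose window holds no
#' reads get `NA`.
#'
#' @param gd a [GenotypeData-class] with read-count assays.
#' @param markers an `InformativeMarkerSet`.
#' @param individuals ids to compute tracks for (default: family members).
#' @param window_sites window width in informative sites (>= 1).
#' @return a list of class `AncestryProbTrack`: matrices `phat` and
#'   `support` (individuals x informative sites), `chrom`, and `markers`.
#' @export
windowAncestryProbability <- function(gd, markers,
                                      individuals = markers$members,
                                      window_sites = 100L) {
  if (window_sites < 1) stop("window_sites must be >= 1")
  idx <- markers$sites
  rd <- SummarizedExperiment::assay(gd, "refDepth")[idx, individuals, drop = FALSE]
  ad <- SummarizedExperiment::assay(gd, "altDepth")[idx, individuals, drop = FALSE]
  aReads <- ifelse(markers$aAlleleIsAlt, 1, 0) * ad +
    ifelse(markers$aAlleleIsAlt, 0, 1) * rd
  tReads <- rd + ad
  L <- length(idx)
  phat <- support <- matrix(NA_real_, length(individuals), L,
                            dimnames = list(individuals, NULL))
  half_lo <- floor((window_sites - 1) / 2)
  half_hi <- floor(window_sites / 2)
  for (ch in unique(markers$chrom)) {
    cidx <- which(markers$chrom == ch)
    m <- length(cidx)
    csumA <- rbind(0, apply(aReads[cidx, , drop = FALSE], 2, cumsum))
    csumT <- rbind(0, apply(tReads[cidx, , drop = FALSE], 2, cumsum))
    lo <- pmax(1L, seq_len(m) - half_lo)
    hi <- pmin(m, seq_len(m) + half_hi)
    wA <- csumA[hi + 1L, , drop = FALSE] - csumA[lo, , drop = FALSE]
    wT <- csumT[hi + 1L, , drop = FALSE] - csumT[lo, , drop = FALSE]
    p <- ifelse(wT > 0, wA / wT, NA_real_)
    phat[, cidx] <- t(p)
    support[, cidx] <- t(wT)
  }
  structure(list(phat = phat, support = support, chrom = markers$chrom,
                 markers = markers, window_sites = as.integer(window_sites)),
            class = "AncestryProbTrack")
}

#' Call per-site parental states from an ancestry track
#'
#' Thresholds exactly as in the study: p-hat > 0.9 is a grandparent-A
#' homozygote, p-hat < 0.1 a grandparent-B homozygote, 0.2 < p-hat < 0.75 a
#' heterozygote; p-hat in \[0.1, 0.2\], \[0.75, 0.9\] or undefined stays
#' unassigned (the published thresholds leave those intervals uncalled).
#'
#' @param track an `AncestryProbTrack`.
#' @return character matrix (individuals x sites) with values `"homA"`,
#'   `"het"`, `"homB"`, `"unassigned"`.
#' @export
callParentalStates <- function(track) {
  p <- track$phat
  st <- matrix("unassigned", nrow(p), ncol(p), dimnames = dimnames(p))
  st[!is.na(p) & p > 0.9] <- "homA"
  st[!is.na(p) & p < 0.1] <- "homB"
  st[!is.na(p) & p > 0.2 & p < 0.75] <- "het"
  st
}

# run-length encode one state vector into a segment data.frame
.rleSegments <- function(states, chrom) {
  out <- list()
  for (ch in unique(chrom)) {
    cidx <- which(chrom == ch)
    r <- rle(states[cidx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out[[ch]] <- data.frame(chrom = ch, start = cidx[starts],
                            end = cidx[ends], state = r$values,
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# drop het runs shorter than min_run lying between two homozygous runs
# (nearest non-unassigned neighbours); matching flanks absorb the sites,
# discordant flanks leave them unassigned
.dropShortHet <- function(states, chrom, min_run) {
  for (ch in unique(chrom)) {
    cidx <- which(chrom == ch)
    seg <- .rleSegments(states[cidx], rep("x", length(cidx)))
    assigned <- which(seg$state %in% c("homA", "homB", "het"))
    for (k in seq_len(nrow(seg))) {
      if (seg$state[k] != "het") next
      len <- seg$end[k] - seg$start[k] + 1L
      if (len >= min_run) next
      prv <- assigned[assigned < k]; nxt <- assigned[assigned > k]
      prv <- if (length(prv)) seg$state[max(prv)] else NA
      nxt <- if (length(nxt)) seg$state[min(nxt)] else NA
      if (is.na(prv) || is.na(nxt)) next
      if (!prv %in% c("homA", "homB") || !nxt %in% c("homA", "homB")) next
      repl <- if (prv == nxt) prv else "unassigned"
      states[cidx[seg$start[k]:seg$end[k]]] <- repl
    }
  }
  states
}

#' Build run-length haplotype maps
#'
#' Run-length encodes the called state sequences, drops heterozygous runs of
#' fewer than `min_run_sites` informative sites that lie between two
#' homozygous runs (flanking runs of matching state absorb the sites;
#' discordant flanks leave them unassigned), recomputes run lengths, and
#' reports the per-individual heterozygosity fraction (het sites / assigned
#' sites). The short-run pass is applied once by default; set
#' `iterate = TRUE` to repeat to a fixpoint.
#'
#' @param states character matrix from [callParentalStates()].
#' @param chrom chromosome of each informative site (from the marker set).
#' @param min_run_sites minimum run length retained (default 100).
#' @param markers the `InformativeMarkerSet` (stored for projection).
#' @param iterate repeat the dropping pass until stable.
#' @return a [HaplotypeMapSet-class].
#' @export
buildHaplotypeMap <- function(states, chrom, min_run_sites = 100L,
                              markers = list(), iterate = FALSE) {
  if (is.null(dim(states))) states <- matrix(states, 1,
                                             dimnames = list("ind1", NULL))
  if (ncol(states) == 0) stop("empty state sequence")
  segs <- list(); hetfr <- numeric(0)
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    repeat {
      s2 <- .dropShortHet(s, chrom, min_run_sites)
      if (identical(s2, s) || !iterate) { s <- s2; break }
      s <- s2
    }
    seg <- .rleSegments(s, chrom)
    segs[[rownames(states)[i]]] <- seg
    nhet <- sum(s == "het")
    nass <- sum(s != "unassigned")
    hetfr[rownames(states)[i]] <- if (nass > 0) nhet / nass else NA_real_
  }
  new("HaplotypeMapSet", segments = segs, hetFraction = hetfr,
      markers = if (inherits(markers, "InformativeMarkerSet"))
        unclass(markers) else markers)
}

#' QC filter individuals on their haplotype maps
#'
#' Removes individuals with heterozygosity fraction above `max_het`
#' (strictly greater, default 0.85) and individuals whose assigned segments
#' carry haplotypes of only one grandparent — both signatures of pollen
#' contamination in the study.
#'
#' @param maps a [HaplotypeMapSet-class].
#' @param max_het heterozygosity threshold.
#' @return list with `retained` (ids) and `removed` (data.frame id, reason).
#' @export
qcFilterIndividuals <- function(maps, max_het = 0.85) {
  removed <- list(); retained <- character(0)
  for (id in names(maps@segments)) {
    hf <- maps@hetFraction[[id]]
    seg <- maps@segments[[id]]
    st <- unique(seg$state[seg$state != "unassigned"])
    if (!length(st)) {
      removed[[id]] <- "no assigned segments"
    } else if (!is.na(hf) && hf > max_het) {
      removed[[id]] <- "excess heterozygosity"
    } else if (all(st %in% "homA") || all(st %in% "homB")) {
      removed[[id]] <- "single-parent haplotypes"
    } else retained <- c(retained, id)
  }
  list(retained = retained,
       removed = data.frame(id = names(removed),
                            reason = unlist(removed, use.names = FALSE),
                            stringsAsFactors = FALSE))
}

#' Reconstruct haplotype maps for one family end to end
#'
#' Convenience wrapper: marker selection, windowed ancestry, state calling,
#' run-length map construction and individual QC.
#'
#' @inheritParams selectInformativeMarkers
#' @inheritParams windowAncestryProbability
#' @inheritParams buildHaplotypeMap
#' @param max_het QC threshold passed to [qcFilterIndividuals()].
#' @return list with `maps` ([HaplotypeMapSet-class], QC-passed individuals
#'   only), `qc` (the full QC report) and `markers`.
#' @export
familyHaplotypeMaps <- function(gd, pedigree, family, min_parent_depth = 4,
                                window_sites = 100L, min_run_sites = 100L,
                                max_het = 0.85) {
  mk <- selectInformativeMarkers(gd, pedigree, family, min_parent_depth)
  if (!length(mk$sites))
    return(list(maps = NULL, qc = NULL, markers = mk))
  tr <- windowAncestryProbability(gd, mk, window_sites = window_sites)
  st <- callParentalStates(tr)
  maps <- buildHaplotypeMap(st, mk$chrom, min_run_sites, markers = mk)
  qc <- qcFilterIndividuals(maps, max_het)
  keep <- qc$retained
  maps@segments <- maps@segments[keep]
  maps@hetFraction <- maps@hetFraction[keep]
  list(maps = maps, qc = qc, markers = mk)
}
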