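#' Pedigree design for the multi-generation simulation
#'
#' Describes the crossing plan: founders (a few tolerant donors plus a
#' diverse pool), F1 families from tolerant x diverse crosses, pseudo-F2
#' families from matings of two full siblings within an F1 family, and an
#' open-pollinated progeny set whose seed parents are pseudo-F2 individuals.
#'
#' @param n_founders,n_tolerant founder counts.
#' @param f1_sizes integer vector: size of each F1 family. Family i crosses
#'   tolerant founder `((i-1) %% n_tolerant) + 1` with the i-th diverse
#'   founder unless `f1_parents` overrides the pairs.
#' @param f1_parents optional list of length-2 character vectors of founder
#'   ids, one per F1 family.
#' @param pf2_sizes integer vector: size of each pseudo-F2 family.
#' @param pf2_f1_family integer vector mapping each pseudo-F2 family to the
#'   F1 family its two sibling parents are drawn from (recycled).
#' @param n_progeny number of open-pollinated progeny (0 for none).
#' @param n_seed_parents number of pseudo-F2 individuals used as seed
#'   parents for the progeny set (the study used 8).
#' @return a list of class `pedigreeDesign`.
#' @export
pedigreeDesign <- function(n_founders = 20L, n_tolerant = 2L,
                           f1_sizes = c(30L, 30L, 20L, 20L),
                           f1_parents = NULL,
                           pf2_sizes = c(45L, 45L, 45L, 45L),
                           pf2_f1_family = seq_along(pf2_sizes),
                           n_progeny = 0L, n_seed_parents = 8L) {
  stopifnot(n_tolerant <= n_founders, all(f1_sizes >= 1))
  structure(list(n_founders = as.integer(n_founders),
                 n_tolerant = as.integer(n_tolerant),
                 f1_sizes = as.integer(f1_sizes), f1_parents = f1_parents,
                 pf2_sizes = as.integer(pf2_sizes),
                 pf2_f1_family = rep_len(as.integer(pf2_f1_family),
                                         length(pf2_sizes)),
                 n_progeny = as.integer(n_progeny),
                 n_seed_parents = as.integer(n_seed_parents)),
            class = "pedigreeDesign")
}

#' Simulate a full multi-generation pedigree with genomes
#'
#' Builds founders, F1 families, sibling-mated pseudo-F2 families and an
#' open-pollinated progeny generation (random pseudo-F2 pollen parent;
#' recorded seed parent only), simulating every meiosis.
#'
#' @param cfg a [genomeConfig()].
#' @param design a [pedigreeDesign()].
#' @param seed integer seed.
#' @return list with `pedigree` (data.frame: id, parent1, parent2,
#'   generation, family, tolerant) and `genomes` ([PhasedGenomes-class] over
#'   all individuals, in pedigree order).
#' @export
buildPedigree <- function(cfg, design = pedigreeDesign(), seed = 1L) {
  stopifnot(inherits(cfg, "genomeConfig"), inherits(design, "pedigreeDesign"))
  fnd <- simulateFounders(cfg, design$n_founders, design$n_tolerant,
                          seed = seed)
  genomes <- fnd$genomes
  ped <- fnd$pedigree
  tol_ids <- ped$id[ped$tolerant]
  div_ids <- ped$id[!ped$tolerant]

  nsite <- ncol(genomes@hapA)
  n_total <- design$n_founders + sum(design$f1_sizes) +
    sum(design$pf2_sizes) + design$n_progeny
  grow <- function(m) {
    out <- matrix(0L, n_total, nsite)
    out[seq_len(nrow(m)), ] <- m
    out
  }
  hapA <- grow(genomes@hapA); hapB <- grow(genomes@hapB)
  originA <- grow(genomes@originA); originB <- grow(genomes@originB)
  all_ids <- character(n_total)
  all_ids[seq_len(design$n_founders)] <- ped$id
  cursor <- design$n_founders

  emit <- function(p1_row, p2_row) {
    # meiosis against the currently accumulated matrices
    tmp <- new("PhasedGenomes",
               hapA = hapA[c(p1_row, p2_row), , drop = FALSE],
               hapB = hapB[c(p1_row, p2_row), , drop = FALSE],
               originA = originA[c(p1_row, p2_row), , drop = FALSE],
               originB = originB[c(p1_row, p2_row), , drop = FALSE],
               sites = genomes@sites, config = genomes@config)
    rownames(tmp@hapA) <- rownames(tmp@hapB) <- c("p1", "p2")
    rownames(tmp@originA) <- rownames(tmp@originB) <- c("p1", "p2")
    g1 <- .gamete(tmp, "p1"); g2 <- .gamete(tmp, "p2")
    list(hA = g1$allele, hB = g2$allele, oA = g1$origin, oB = g2$origin)
  }
  rowOf <- function(id) match(id, all_ids)

  newrows <- list()
  # F1 families
  f1_members <- list()
  for (f in seq_along(design$f1_sizes)) {
    if (is.null(design$f1_parents)) {
      p1 <- tol_ids[((f - 1L) %% design$n_tolerant) + 1L]
      if (f > length(div_ids))
        stop("more F1 families than diverse founders; give f1_parents")
      p2 <- div_ids[f]
    } else {
      pp <- design$f1_parents[[f]]
      p1 <- pp[1]; p2 <- pp[2]
    }
    fam <- sprintf("F1.%d", f)
    ids <- sprintf("F1_%02d_%03d", f, seq_len(design$f1_sizes[f]))
    f1_members[[f]] <- ids
    for (k in seq_along(ids)) {
      cursor <- cursor + 1L
      all_ids[cursor] <- ids[k]
      off <- emit(rowOf(p1), rowOf(p2))
      hapA[cursor, ] <- off$hA; hapB[cursor, ] <- off$hB
      originA[cursor, ] <- off$oA; originB[cursor, ] <- off$oB
      newrows[[length(newrows) + 1L]] <- data.frame(
        id = ids[k], parent1 = p1, parent2 = p2, generation = "F1",
        family = fam, tolerant = FALSE, stringsAsFactors = FALSE)
    }
  }
  # pseudo-F2 families: two distinct full siblings from one F1 family
  pf2_ids_all <- character(0)
  for (f in seq_along(design$pf2_sizes)) {
    src <- design$pf2_f1_family[f]
    sibs <- f1_members[[src]]
    if (length(sibs) < 2)
      stop("pseudo-F2 parents must be two distinct siblings of one F1 family")
    pp <- sample(sibs, 2L)
    fam <- sprintf("PF2.%d", f)
    ids <- sprintf("PF2_%02d_%03d", f, seq_len(design$pf2_sizes[f]))
    pf2_ids_all <- c(pf2_ids_all, ids)
    for (k in seq_along(ids)) {
      cursor <- cursor + 1L
      all_ids[cursor] <- ids[k]
      off <- emit(rowOf(pp[1]), rowOf(pp[2]))
      hapA[cursor, ] <- off$hA; hapB[cursor, ] <- off$hB
      originA[cursor, ] <- off$oA; originB[cursor, ] <- off$oB
      newrows[[length(newrows) + 1L]] <- data.frame(
        id = ids[k], parent1 = pp[1], parent2 = pp[2],
        generation = "pseudoF2", family = fam, tolerant = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  # open-pollinated progeny: recorded seed parent, random pollen parent
  if (design$n_progeny > 0) {
    seed_parents <- sample(pf2_ids_all,
                           min(design$n_seed_parents, length(pf2_ids_all)))
    for (k in seq_len(design$n_progeny)) {
      sp <- sample(seed_parents, 1L)
      pollen <- sample(setdiff(pf2_ids_all, sp), 1L)
      cursor <- cursor + 1L
      id <- sprintf("PRG%03d", k)
      all_ids[cursor] <- id
      off <- emit(rowOf(sp), rowOf(pollen))
      hapA[cursor, ] <- off$hA; hapB[cursor, ] <- off$hB
      originA[cursor, ] <- off$oA; originB[cursor, ] <- off$oB
      newrows[[length(newrows) + 1L]] <- data.frame(
        id = id, parent1 = sp, parent2 = NA_character_,
        generation = "progeny", family = "PRG", tolerant = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  ped <- rbind(ped, do.call(rbind, newrows))
  dimnames(hapA) <- dimnames(hapB) <- list(all_ids, NULL)
  dimnames(originA) <- dimnames(originB) <- list(all_ids, NULL)
  genomes <- new("PhasedGenomes", hapA = hapA, hapB = hapB,
                 originA = originA, originB = originB,
                 sites = genomes@sites, config = genomes@config)
  list(pedigree = ped, genomes = genomes)
}

#' Validate a pedigree table
#'
#' Checks that parents precede children, founders have no parents, and
#' generation labels are known.
#'
#' @param ped pedigree data.frame (id, parent1, parent2, generation, ...).
#' @param strict if TRUE, a child listed before a parent is an error;
#'   otherwise rows are reordered.
#' @return the (possibly reordered) pedigree, invisibly errors otherwise.
#' @export
validatePedigree <- function(ped, strict = FALSE) {
  need <- c("id", "parent1", "parent2", "generation")
  if (!all(need %in% names(ped)))
    stop("pedigree must contain columns ", paste(need, collapse = ", "))
  ok_gen <- c("founder", "F1", "pseudoF2", "progeny")
  bad <- which(!ped$generation %in% ok_gen)
  if (length(bad))
    stop("unknown generation label in row ", bad[1], ": ", ped$generation[bad[1]])
  if (anyDuplicated(ped$id)) stop("duplicated individual ids")
  fnd <- ped$generation == "founder"
  if (any(!is.na(ped$parent1[fnd]) | !is.na(ped$parent2[fnd])))
    stop("founders must not have parents")
  seen <- character(0)
  order_ok <- TRUE
  for (i in seq_len(nrow(ped))) {
    ps <- stats::na.omit(c(ped$parent1[i], ped$parent2[i]))
    if (!all(ps %in% seen)) order_ok <- FALSE
    seen <- c(seen, ped$id[i])
  }
  if (!order_ok) {
    if (strict) stop("child listed before parent")
    # topological reorder
    placed <- character(0); rows <- integer(0); left <- seq_len(nrow(ped))
    while (length(left)) {
      ready <- left[vapply(left, function(i) {
        ps <- stats::na.omit(c(ped$parent1[i], ped$parent2[i]))
        all(ps %in% placed)
      }, logical(1))]
      if (!length(ready)) stop("cyclic pedigree")
      placed <- c(placed, ped$id[ready]); rows <- c(rows, ready)
      left <- setdiff(left, ready)
    }
    ped <- ped[rows, , drop = FALSE]
  }
  invisible(ped)
}
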