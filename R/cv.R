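.bindCvRows <- function(rows) {
  if (!length(rows))
    return(data.frame(family = character(0), type = character(0),
                      n_masked = integer(0), ability = numeric(0),
                      bias = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Family- and generation-masked cross-validation
#'
#' Implements the study's three schemes. A full two-stage model (stage-one
#' BLUEs, then the weighted G+I GBLUP) provides reference BLUPs; target
#' phenotypes (never genotypes) are then masked, the model is refitted, and
#' predictive ability is the Pearson correlation between the reference BLUPs
#' and the masked-model GEBVs over the masked individuals. Bias is the OLS
#' slope of reference BLUP on GEBV (below 1 = shrunken predictions). Only
#' families larger than `min_family_size` phenotyped individuals are
#' eligible (the study used > 40); for `whole_generation` masking the
#' within-family ability (mean of per-family correlations) is also reported.
#'
#' @param pheno phenotype data.frame.
#' @param G additive relationship matrix over all individuals.
#' @param pedigree pedigree data.frame.
#' @param scheme `"half_family"`, `"whole_family"` or `"whole_generation"`.
#' @param trait trait to evaluate.
#' @param min_family_size eligibility threshold (strictly greater).
#' @param generation generation masked by `whole_generation` (default
#'   pseudo-F2).
#' @param reference `"blup"` correlates masked-model GEBVs with full-model
#'   BLUPs (the study's definition); `"phenotype"` correlates them with the
#'   masked individuals' own stage-one BLUEs instead. The BLUP reference
#'   shares training noise with the GEBVs through the kinship matrix and so
#'   retains some correlation even for a heritability-free trait; the
#'   phenotype reference does not.
#' @param seed seed for the random half-family split.
#' @return data.frame (family, type, n_masked, ability, bias) with
#'   attributes `overall` (ability/bias over all masked individuals pooled)
#'   and, for generation masking, `within_family` (mean per-family
#'   ability). Families below the size threshold are skipped and listed in
#'   attribute `skipped`.
#' @export
runCV <- function(pheno, G, pedigree,
                  scheme = c("half_family", "whole_family",
                             "whole_generation"),
                  trait = "ws", min_family_size = 40L,
                  generation = "pseudoF2",
                  reference = c("blup", "phenotype"), seed = 1L) {
  scheme <- match.arg(scheme)
  reference <- match.arg(reference)
  set.seed(seed)
  blues <- fitBlues(pheno, trait)
  blues <- blues[blues$individual %in% rownames(G), , drop = FALSE]
  if (reference == "blup") {
    full <- twoStagePredict(blues, G)
    ref <- gebv(full)
  } else ref <- stats::setNames(blues$blue, blues$individual)

  fam_of <- pedigree$family[match(blues$individual, pedigree$id)]
  gen_of <- pedigree$generation[match(blues$individual, pedigree$id)]
  fams <- table(fam_of[gen_of %in% c("F1", "pseudoF2")])
  eligible <- names(fams)[fams > min_family_size]
  skipped <- names(fams)[fams <= min_family_size]

  maskFit <- function(mask_ids) {
    fit <- twoStagePredict(blues[!blues$individual %in% mask_ids, ,
                                 drop = FALSE], G)
    g <- gebv(fit)[mask_ids]
    if (length(mask_ids) < 2 || stats::sd(g) == 0 ||
        stats::sd(ref[mask_ids]) == 0)
      return(c(ability = NA_real_, bias = NA_real_))
    c(ability = stats::cor(ref[mask_ids], g),
      bias = unname(coef(stats::lm(ref[mask_ids] ~ g))[2]))
  }

  rows <- list()
  if (scheme %in% c("half_family", "whole_family")) {
    frac <- if (scheme == "half_family") 0.5 else 1.0
    for (f in eligible) {
      members <- blues$individual[!is.na(fam_of) & fam_of == f]
      mask <- if (frac < 1)
        sample(members, floor(length(members) * frac)) else members
      st <- maskFit(mask)
      rows[[f]] <- data.frame(
        family = f, type = unique(gen_of[fam_of == f])[1],
        n_masked = length(mask), ability = st["ability"], bias = st["bias"],
        stringsAsFactors = FALSE)
    }
    out <- .bindCvRows(rows)
    attr(out, "overall") <- c(ability = mean(out$ability, na.rm = TRUE),
                              bias = mean(out$bias, na.rm = TRUE))
  } else {
    mask <- blues$individual[gen_of == generation]
    if (length(mask) < 2) stop("nothing to mask for generation ", generation)
    fit <- twoStagePredict(blues[!blues$individual %in% mask, ,
                                 drop = FALSE], G)
    g <- gebv(fit)[mask]
    overall <- c(ability = stats::cor(ref[mask], g),
                 bias = unname(coef(stats::lm(ref[mask] ~ g))[2]))
    for (f in intersect(eligible, unique(fam_of[gen_of == generation]))) {
      m <- intersect(mask, blues$individual[fam_of == f])
      ab <- if (length(m) >= 2 && stats::sd(g[m]) > 0)
        stats::cor(ref[m], g[m]) else NA_real_
      bi <- if (length(m) >= 2 && stats::sd(g[m]) > 0)
        unname(coef(stats::lm(ref[m] ~ g[m]))[2]) else NA_real_
      rows[[f]] <- data.frame(family = f, type = generation,
                              n_masked = length(m), ability = ab, bias = bi,
                              stringsAsFactors = FALSE)
    }
    out <- .bindCvRows(rows)
    attr(out, "overall") <- overall
    attr(out, "within_family") <- mean(out$ability, na.rm = TRUE)
  }
  attr(out, "skipped") <- skipped
  attr(out, "scheme") <- scheme
  out
}

#' Progeny genomic prediction
#'
#' Trains the two-stage model on all non-progeny phenotypes (optionally also
#' masking the pseudo-F2 generation, to measure the erosion of predictive
#' ability when training data are not updated), predicts GEBVs for the
#' progeny through the relationship matrix, and correlates them with the
#' progeny's own stage-one BLUEs. Additional kernels (epistatic for
#' survivorship, dominance for heading date) can be supplied.
#'
#' @param pheno phenotype data.frame containing progeny records.
#' @param G additive relationship matrix including the progeny.
#' @param pedigree pedigree data.frame.
#' @param trait trait to predict.
#' @param extra_kernels optional named list of additional kernels.
#' @param mask_pf2 also drop pseudo-F2 phenotypes from training.
#' @return list with `ability`, `bias`, `n`, `gebv` (progeny GEBVs) and
#'   `reference` (progeny BLUEs).
#' @export
predictProgeny <- function(pheno, G, pedigree, trait = "ws",
                           extra_kernels = NULL, mask_pf2 = FALSE) {
  prog <- pedigree$id[pedigree$generation == "progeny"]
  prog <- intersect(prog, rownames(G))
  if (!length(prog)) stop("no progeny present in the kernel")
  blues <- fitBlues(pheno, trait)
  blues <- blues[blues$individual %in% rownames(G), , drop = FALSE]
  train <- blues[!blues$individual %in% prog, , drop = FALSE]
  if (mask_pf2) {
    pf2 <- pedigree$id[pedigree$generation == "pseudoF2"]
    train <- train[!train$individual %in% pf2, , drop = FALSE]
  }
  fit <- twoStagePredict(train, G, extra_kernels = extra_kernels)
  g <- gebv(fit)[prog]
  refb <- blues[blues$individual %in% prog, , drop = FALSE]
  common <- intersect(prog, refb$individual)
  yref <- refb$blue[match(common, refb$individual)]
  list(ability = stats::cor(g[common], yref),
       bias = unname(coef(stats::lm(yref ~ g[common]))[2]),
       n = length(common), gebv = g,
       reference = stats::setNames(yref, common))
}

#' Genetic distance to the tolerant founders vs a trait
#'
#' Per-individual distance is 1 minus the correlation-normalized
#' relationship G_if / sqrt(G_ii G_ff), averaged over the tolerant founders;
#' the returned value is the Pearson correlation between that distance and
#' the supplied trait values (negative when relatedness to the tolerant
#' donors drives the trait).
#'
#' @param G additive relationship matrix.
#' @param tolerant_ids founder ids (must be in `G`).
#' @param trait_values named numeric vector.
#' @return list with `correlation` and the `distance` vector.
#' @export
founderDistanceDiagnostic <- function(G, tolerant_ids, trait_values) {
  if (!all(tolerant_ids %in% rownames(G)))
    stop("tolerant founders absent from the relationship matrix")
  ids <- intersect(names(trait_values), rownames(G))
  if (length(ids) < 3) stop("need at least 3 phenotyped individuals")
  dg <- diag(as.matrix(G))
  dist <- rowMeans(vapply(tolerant_ids, function(f)
    1 - G[ids, f] / sqrt(dg[ids] * dg[f]), numeric(length(ids))))
  list(correlation = stats::cor(dist, trait_values[ids]),
       distance = stats::setNames(dist, ids))
}
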