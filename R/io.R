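#' Read genotypes from a VCF file
#'
#' Loads a VCF 4.x through VariantAnnotation, keeps biallelic SNPs (others
#' are dropped), converts GT to alternate-allele dosage and, when an AD
#' field is present, carries the per-site allele read counts.
#'
#' @param path VCF file path (plain or bgzipped).
#' @return a [GenotypeData-class].
#' @export
readVcfGenotypes <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  if (anyDuplicated(colnames(vcf))) stop("duplicated sample ids in VCF")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  keep <- lengths(altl) == 1 & nchar(ref) == 1
  alt <- rep(NA_character_, length(ref))
  alt[keep] <- vapply(altl[keep], function(a) as.character(a[1]), "")
  keep <- keep & !is.na(alt) & nchar(alt) == 1
  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  gt2 <- gsub("|", "/", gt, fixed = TRUE)
  dos[gt2 %in% c("0/0")] <- 0
  dos[gt2 %in% c("0/1", "1/0")] <- 1
  dos[gt2 %in% c("1/1")] <- 2
  chrom <- as.character(GenomicRanges::seqnames(rr))[keep]
  pos <- GenomicRanges::start(rr)[keep]
  refD <- altD <- NULL
  if ("AD" %in% names(VariantAnnotation::geno(vcf))) {
    ad <- VariantAnnotation::geno(vcf)$AD[keep, , drop = FALSE]
    refD <- apply(ad, c(1, 2), function(x) as.integer(x[[1]][1]))
    altD <- apply(ad, c(1, 2), function(x) as.integer(x[[1]][2]))
  }
  GenotypeData(dosage = dos, chrom = chrom, pos = pos,
               ref = ref[keep], alt = alt[keep],
               refDepth = refD, altDepth = altD)
}

#' Write genotypes to a VCF 4.2 file
#'
#' Emits GT (and AD when read-count assays are present). Dosages are
#' hard-called: values are rounded to 0/1/2 (a warning is given if any
#' entry is non-integer) and missing becomes `./.`.
#'
#' @param gd a [GenotypeData-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVcfGenotypes <- function(gd, path) {
  dos <- dosages(gd)
  if (any(abs(dos - round(dos)) > 1e-8, na.rm = TRUE))
    warning("non-integer dosages rounded for VCF output")
  dos <- round(dos)
  st <- siteInfo(gd)
  gtmap <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(dos), ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- gtmap[dos[ok] + 1]
  hasAD <- all(c("refDepth", "altDepth") %in%
                 SummarizedExperiment::assayNames(gd))
  if (hasAD) {
    rd <- SummarizedExperiment::assay(gd, "refDepth")
    ad <- SummarizedExperiment::assay(gd, "altDepth")
    gt <- matrix(paste0(gt, ":", rd, ",", ad), nrow(gt))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=winterGP",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               if (hasAD)
                 '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(dos)), collapse = "\t")),
             con)
  fmt <- if (hasAD) "GT:AD" else "GT"
  body <- cbind(st$chrom, st$pos, ".", st$ref, st$alt, ".", "PASS", ".",
                fmt, gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read and write pedigree / phenotype tables
#'
#' Tab-separated files. The pedigree has columns id, parent1, parent2,
#' generation, family (empty string or NA for missing parents); phenotypes
#' have individual, year, trait, value, fall_vigor. `readTables()` checks
#' referential integrity: every phenotyped individual must appear in the
#' pedigree, and generation labels must be valid.
#'
#' @param pedigree_path,phenotype_path file paths.
#' @param strict passed to [validatePedigree()].
#' @return list with `pedigree` and `phenotypes` data.frames.
#' @export
readTables <- function(pedigree_path, phenotype_path, strict = FALSE) {
  ped <- read.delim(pedigree_path, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  ped <- validatePedigree(ped, strict = strict)
  ph <- read.delim(phenotype_path, stringsAsFactors = FALSE)
  need <- c("individual", "year", "trait", "value")
  if (!all(need %in% names(ph)))
    stop("phenotype table must contain ", paste(need, collapse = ", "))
  orphan <- setdiff(unique(ph$individual), ped$id)
  if (length(orphan))
    stop("phenotyped individuals missing from pedigree: ",
         paste(head(orphan, 5), collapse = ", "))
  list(pedigree = ped, phenotypes = ph)
}

#' @rdname readTables
#' @param pedigree,phenotypes data.frames to write.
#' @param path output path.
#' @export
writePedigree <- function(pedigree, path) {
  write.table(pedigree, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readTables
#' @export
writePhenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write haplotype segments as a BED-like table
#'
#' @param maps a [HaplotypeMapSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHaplotypeSegments <- function(maps, path) {
  rows <- do.call(rbind, lapply(names(maps@segments), function(id)
    cbind(individual = id, maps@segments[[id]])))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# tiny FNV-1a string hash; keeps the run report self-describing without
# adding a digest dependency
.configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' One structured object holding every stage's parameters; each published
#' threshold surfaces as a named field defaulting to the study's value.
#'
#' @param seed master seed for every stage.
#' @param genome a [genomeConfig()]. @param design a [pedigreeDesign()].
#' @param trait_params a [traitSimParams()]. @param depth a
#'   [readDepthModel()]. @param filter a [filterConfig()].
#' @param window_sites,min_run_sites,min_parent_depth,max_het haplotype-map
#'   parameters.
#' @param trait trait analyzed. @param n_years record years.
#' @param kernels character subset of c("G", "D", "E", "I").
#' @param cv_schemes cross-validation schemes to run (may be empty).
#' @param min_family_size CV eligibility threshold.
#' @param out_dir optional output directory for files and the JSON report.
#' @return a list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L,
                           genome = genomeConfig(n_chromosomes = 2,
                                                 sites_per_chromosome = 300),
                           design = pedigreeDesign(
                             n_founders = 12, n_tolerant = 2,
                             f1_sizes = c(12L, 12L), pf2_sizes = c(16L, 16L)),
                           trait_params = traitSimParams(),
                           depth = readDepthModel(),
                           filter = filterConfig(),
                           window_sites = 100L, min_run_sites = 100L,
                           min_parent_depth = 4, max_het = 0.85,
                           trait = "ws", n_years = 3L,
                           kernels = c("G", "I"),
                           cv_schemes = character(0),
                           min_family_size = 10L,
                           out_dir = NULL) {
  if (!length(kernels)) stop("at least one kernel is required")
  if (!all(kernels %in% c("G", "D", "E", "I")))
    stop("kernels must be a subset of G, D, E, I")
  structure(as.list(environment()), class = "pipelineConfig")
}

#' Run the full synthetic pipeline
#'
#' simulate -> sequence -> haplotype maps (+ QC) -> marker filtering ->
#' unambiguous parental assignment -> EM imputation -> haplotype projection
#' -> second-round filter/imputation -> kinship -> REML fit (-> optional
#' cross-validation), returning a machine-readable report whose filter
#' counts satisfy the conservation identity n_final = n_input - drops.
#'
#' @param config a [pipelineConfig()].
#' @return a report list (also written as JSON to `out_dir` when set).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  report <- list(seed = config$seed, config_hash = .configHash(
    config[setdiff(names(config), "out_dir")]))
  sim <- buildPedigree(config$genome, config$design, seed = config$seed)
  ph <- simulatePhenotypes(sim$pedigree, sim$genomes, config$trait_params,
                           n_years = config$n_years,
                           seed = config$seed + 1L)
  gd <- simulateReads(sim$genomes, sim$pedigree, config$depth,
                      seed = config$seed + 2L)
  report$counts <- list(individuals = ncol(gd), sites_input = nrow(gd))

  pf2fams <- unique(sim$pedigree$family[sim$pedigree$generation == "pseudoF2"])
  maps <- list(); qc_removed <- 0L
  for (f in pf2fams) {
    hm <- familyHaplotypeMaps(gd, sim$pedigree, f,
                              min_parent_depth = config$min_parent_depth,
                              window_sites = config$window_sites,
                              min_run_sites = config$min_run_sites,
                              max_het = config$max_het)
    if (!is.null(hm$maps)) {
      maps[[f]] <- hm
      qc_removed <- qc_removed + nrow(hm$qc$removed)
    }
  }
  report$counts$hapmap_qc_removed <- qc_removed

  founder_ids <- sim$pedigree$id[sim$pedigree$generation == "founder"]
  flt <- filterSites(gd, config$filter, founder_ids)
  report$counts$sites_dropped_round1 <- as.list(table(flt$audit$rule))
  gd2 <- assignUnambiguous(flt$gd, sim$pedigree)
  ok <- rowSums(!is.na(dosages(gd2))) > 0
  gd2 <- gd2[which(ok), ]
  gd2 <- imputeEM(gd2)
  mapped_ids <- character(0)
  for (f in names(maps)) {
    gd2 <- projectHaplotypes(gd2, maps[[f]]$maps)
    mapped_ids <- c(mapped_ids, individuals(maps[[f]]$maps))
  }
  if (length(mapped_ids)) {
    sr <- secondRound(gd2, mapped_ids, config$filter)
    gd2 <- sr$gd
    report$counts$sites_dropped_round2 <- nrow(sr$audit)
  } else report$counts$sites_dropped_round2 <- 0L
  report$counts$sites_final <- nrow(gd2)
  drops <- sum(unlist(report$counts$sites_dropped_round1)) +
    sum(!ok) + report$counts$sites_dropped_round2
  report$counts$conservation_ok <-
    report$counts$sites_final == report$counts$sites_input - drops

  K <- list()
  G <- additiveG(gd2)
  if ("G" %in% config$kernels) K$G <- G
  if ("D" %in% config$kernels) K$D <- dominanceD(gd2)
  if ("E" %in% config$kernels) K$E <- epistaticE(G)
  if ("I" %in% config$kernels)
    K$I <- diag(ncol(gd2)) |> `dimnames<-`(list(colnames(gd2), colnames(gd2)))
  fit <- fitREML(ph$phenotypes, K, trait = config$trait)
  report$variances <- varComp(fit)
  report$mean_reliability <- mean(reliabilities(fit))

  if (length(config$cv_schemes)) {
    report$cv <- list()
    for (sc in config$cv_schemes) {
      cv <- runCV(ph$phenotypes, G, sim$pedigree, scheme = sc,
                  trait = config$trait,
                  min_family_size = config$min_family_size,
                  seed = config$seed + 3L)
      report$cv[[sc]] <- list(table = cv, overall = attr(cv, "overall"))
    }
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    writeVcfGenotypes(gd, file.path(config$out_dir, "genotypes.vcf"))
    writePedigree(sim$pedigree, file.path(config$out_dir, "pedigree.tsv"))
    writePhenotypes(ph$phenotypes, file.path(config$out_dir, "phenotypes.tsv"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}
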