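#' Realized relationship matrices
#'
#' `additiveG()` builds the VanRaden method-1 additive matrix
#' G = WW' / (2 * sum(p_j q_j)) with W the column-centered dosage matrix;
#' `dominanceD()` the classical dominance matrix from the heterozygosity
#' covariate h = (-2p^2, 2pq, -2q^2) for dosages (0, 1, 2), normalized by
#' sum((2 p q)^2); `epistaticE()` the additive-by-additive epistatic matrix
#' as the Hadamard square of G, rescaled so its mean diagonal equals the mean
#' diagonal of G. Allele frequencies are taken from the analyzed individuals
#' unless `p` is supplied.
#'
#' @param gm a [GenotypeData-class] or a complete individuals x sites dosage
#'   matrix (no missing values).
#' @param p optional vector of alternate-allele frequencies per site.
#' @param jitter value added to the diagonal for numerical stability before
#'   REML (default 1e-6).
#' @return symmetric PSD matrix with individual ids as dimnames and
#'   attributes `kind` and `nMarkers`.
#' @name kinship
NULL

.indivMatrix <- function(gm) {
  if (is(gm, "GenotypeData")) t(dosages(gm)) else as.matrix(gm)
}

#' @rdname kinship
#' @export
additiveG <- function(gm, p = NULL, jitter = 1e-6) {
  M <- .indivMatrix(gm)
  if (anyNA(M)) stop("dosage matrix must be complete (impute first)")
  if (is.null(p)) p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic sites")
  M <- M[, poly, drop = FALSE]; p <- p[poly]
  W <- sweep(M, 2L, 2 * p)
  G <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  diag(G) <- diag(G) + jitter
  structure(G, kind = "G", nMarkers = sum(poly))
}

#' @rdname kinship
#' @export
dominanceD <- function(gm, p = NULL, jitter = 1e-6) {
  M <- .indivMatrix(gm)
  if (anyNA(M)) stop("dosage matrix must be complete (impute first)")
  if (is.null(p)) p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic sites")
  M <- M[, poly, drop = FALSE]; p <- p[poly]
  q <- 1 - p
  # classical parameterization; real-valued dosages are interpolated so that
  # hard calls 0/1/2 give exactly -2p^2 / 2pq / -2q^2
  H <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  for (j in seq_len(ncol(M))) {
    x <- M[, j]
    hj <- ifelse(x <= 1, -2 * p[j]^2 + x * (2 * p[j] * q[j] + 2 * p[j]^2),
                 2 * p[j] * q[j] + (x - 1) * (-2 * q[j]^2 - 2 * p[j] * q[j]))
    H[, j] <- hj
  }
  D <- tcrossprod(H) / sum((2 * p * q)^2)
  diag(D) <- diag(D) + jitter
  structure(D, kind = "D", nMarkers = sum(poly))
}

#' @rdname kinship
#' @export
epistaticE <- function(G, jitter = 1e-6) {
  E <- unclass(G) * unclass(G)
  E <- E * mean(diag(as.matrix(G))) / mean(diag(E))
  diag(E) <- diag(E) + jitter
  structure(E, kind = "E", nMarkers = attr(G, "nMarkers"))
}
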