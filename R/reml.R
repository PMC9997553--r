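# Average-information REML with EM fallback for linear covariance models
# V(theta) = sum_j theta_j * V_j. Variance parameters are boundary-
# constrained at `lower` (0); covariance parameters use lower = -Inf.
.remlEngine <- function(y, X, Vlist, lower = rep(0, length(Vlist)),
                        init = NULL, tol = 1e-6, max_iter = 200L) {
  n <- length(y)
  X <- as.matrix(X)
  X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]  # full rank
  p <- ncol(X)
  nv <- length(Vlist)
  vy <- stats::var(y)
  if (is.null(init)) init <- ifelse(is.finite(lower), vy / nv, 0)
  theta <- pmax(init, ifelse(is.finite(lower), 1e-8 * vy, -Inf))

  bigV <- function(th) {
    V <- matrix(0, n, n)
    for (j in seq_len(nv)) if (th[j] != 0) V <- V + th[j] * Vlist[[j]]
    V
  }
  crit <- function(th) {
    V <- bigV(th)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    XtVX <- crossprod(X, Vinv %*% X)
    ch2 <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(ch2)) return(NULL)
    VinvX <- Vinv %*% X
    P <- Vinv - VinvX %*% chol2inv(ch2) %*% t(VinvX)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(ch2))) +
                    sum(y * Py))
    list(ll = ll, P = P, Py = Py, Vinv = Vinv)
  }

  st <- crit(theta)
  if (is.null(st)) stop("model is singular at the starting values")
  frozen <- rep(FALSE, nv)
  trace <- numeric(0)
  converged <- FALSE
  AI <- NULL
  for (it in seq_len(max_iter)) {
    B <- vapply(Vlist, function(Vj) drop(Vj %*% st$Py), numeric(n))
    PB <- st$P %*% B
    score <- vapply(seq_len(nv), function(j)
      -0.5 * (sum(st$P * Vlist[[j]]) - sum(st$Py * B[, j])), numeric(1))
    AI <- 0.5 * crossprod(B, PB)
    # release boundary parameters whose gradient points inward
    frozen <- frozen & !(score > 0)
    free <- which(!frozen)
    delta <- rep(0, nv)
    sol <- tryCatch(solve(AI[free, free, drop = FALSE], score[free]),
                    error = function(e) NULL)
    ok <- FALSE
    if (!is.null(sol)) {
      step <- 1
      for (h in 1:12) {
        cand <- theta
        cand[free] <- theta[free] + step * sol
        hitlo <- is.finite(lower) & cand < lower
        cand[hitlo] <- lower[hitlo]
        stc <- crit(cand)
        if (!is.null(stc) && stc$ll >= st$ll - 1e-10) {
          theta <- cand; frozen <- frozen | hitlo
          stnew <- stc; ok <- TRUE
          break
        }
        step <- step / 2
      }
    }
    if (!ok) {  # EM-type fallback: multiplicative, keeps theta >= 0
      cand <- theta
      for (j in free) {
        trPV <- sum(st$P * Vlist[[j]])
        if (trPV > 0 && theta[j] > 0 && is.finite(lower[j]))
          cand[j] <- theta[j] * sum(st$Py * B[, j]) / trPV
      }
      stc <- crit(cand)
      if (!is.null(stc) && stc$ll >= st$ll - 1e-10) {
        theta <- cand; stnew <- stc
      } else stnew <- st   # no improvement possible
    }
    trace <- c(trace, stnew$ll)
    if (abs(stnew$ll - st$ll) < tol * (abs(st$ll) + 1)) {
      st <- stnew; converged <- TRUE; break
    }
    st <- stnew
  }
  # SEs from the inverse AI matrix at convergence
  se <- rep(NA_real_, nv)
  Ainv <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(Ainv)) {
    dg <- diag(Ainv)
    se[dg > 0] <- sqrt(dg[dg > 0])
  }
  if (is.null(Ainv) || kappa(AI) > 1e10)
    warning("variance components are weakly identified (flat likelihood); ",
            "estimates of overlapping kernels are only jointly determined")
  XtVX <- crossprod(X, st$Vinv %*% X)
  b <- drop(solve(XtVX, crossprod(X, st$Vinv %*% y)))
  names(b) <- colnames(X)
  list(theta = theta, se = se, loglik = st$ll, P = st$P, Py = st$Py,
       Vinv = st$Vinv, fixef = b, converged = converged,
       niter = length(trace), trace = trace, AI = AI,
       # a component within numerical tolerance of its constraint counts as
       # pinned to the boundary (reported as an exact 0 with a nonzero SE)
       boundary = is.finite(lower) & theta <= pmax(lower, 1e-4 * vy))
}

#' Multi-kernel single-trait REML
#'
#' Fits y = Xb + Z u_a + Z u_d + Z u_E + Z u_R + e by restricted maximum
#' likelihood (average-information updates with EM fallback), where the
#' random vectors follow N(0, K sigma2_k) for each supplied kernel (additive
#' G, dominance D, epistatic E, identity I for the residual genotypic
#' effect) and the residual has a year-specific variance. Fixed effects are
#' year, fall vigor and their interaction. Negative component updates are
#' constrained to the zero boundary; standard errors come from the inverse
#' average-information matrix.
#'
#' @param pheno phenotype data.frame (individual, year, trait, value,
#'   fall_vigor).
#' @param kernels named list of relationship matrices over a common
#'   individual set (e.g. `list(G = ..., I = diag(...))`); names are used in
#'   the variance-component table.
#' @param trait which trait to fit (default `"ws"`).
#' @param year_specific_residual one residual variance per year (default) or
#'   a single pooled residual.
#' @param tol,max_iter REML convergence controls.
#' @return a [FitResult-class]; `gebv()` returns the additive-kernel BLUP
#'   when a kernel named `"G"` is present.
#' @export
fitREML <- function(pheno, kernels, trait = "ws",
                    year_specific_residual = TRUE,
                    tol = 1e-6, max_iter = 200L) {
  stopifnot(length(kernels) >= 1)
  ids <- rownames(kernels[[1]])
  for (K in kernels)
    if (!identical(rownames(K), ids))
      stop("all kernels must be indexed by the same individuals")
  d <- pheno[pheno$trait == trait & pheno$individual %in% ids, , drop = FALSE]
  d <- d[!is.na(d$value), , drop = FALSE]
  if (!nrow(d)) stop("no records for trait ", trait)
  n <- nrow(d)
  yearf <- factor(d$year)
  fv <- d$fall_vigor
  if (nlevels(yearf) > 1 && stats::var(fv) > 0)
    X <- stats::model.matrix(~ yearf * fv)
  else if (nlevels(yearf) > 1) X <- stats::model.matrix(~ yearf)
  else if (stats::var(fv) > 0) X <- stats::model.matrix(~ fv)
  else X <- matrix(1, n, 1)
  Z <- matrix(0, n, length(ids))
  Z[cbind(seq_len(n), match(d$individual, ids))] <- 1
  colnames(Z) <- ids

  Vlist <- lapply(kernels, function(K) Z %*% K %*% t(Z))
  names(Vlist) <- names(kernels)
  if (year_specific_residual && nlevels(yearf) > 1) {
    for (lv in levels(yearf))
      Vlist[[paste0("residual:year", lv)]] <- diag((d$year == lv) * 1)
  } else Vlist[["residual"]] <- diag(n)
  res <- .remlEngine(d$value, X, Vlist, tol = tol, max_iter = max_iter)

  nk <- length(kernels)
  blup <- list()
  for (j in seq_len(nk))
    blup[[names(kernels)[j]]] <-
      drop(res$theta[j] * kernels[[j]] %*% crossprod(Z, res$Py)) |>
      stats::setNames(ids)
  gv <- if ("G" %in% names(kernels)) blup[["G"]] else blup[[1]]
  aname <- if ("G" %in% names(kernels)) "G" else names(kernels)[1]
  ja <- match(aname, names(kernels))
  Ka <- kernels[[ja]]; tha <- res$theta[ja]
  KZt <- Ka %*% t(Z)
  pevv <- pmax(diag(tha * Ka - tha^2 * KZt %*% res$P %*% t(KZt)), 0)
  rel <- if (tha > 0) pmin(pmax(1 - pevv / (diag(Ka) * tha), 0), 1)
  else rep(0, length(ids))
  varcomp <- data.frame(component = names(Vlist), estimate = res$theta,
                        se = res$se, boundary = res$boundary,
                        stringsAsFactors = FALSE)
  new("FitResult", varcomp = varcomp, fixef = res$fixef, blup = blup,
      gebv = gv, pev = stats::setNames(pevv, ids),
      reliability = stats::setNames(rel, ids),
      loglik = res$loglik, converged = res$converged,
      niter = as.integer(res$niter),
      details = list(trace = res$trace, AI = res$AI, ids = ids,
                     trait = trait, n_records = n))
}

#' Per-individual reliability of the additive BLUP
#'
#' r2_i = 1 - PEV_i / (G_ii * sigma2_a), clipped to \[0, 1\]: the squared
#' accuracy of the predicted breeding value on a genotype-difference basis.
#'
#' @param fit a [FitResult-class] with an additive kernel named `"G"`.
#' @param G the additive relationship matrix used in the fit.
#' @return named numeric vector.
#' @export
reliability <- function(fit, G) {
  va <- fit@varcomp$estimate[fit@varcomp$component == "G"]
  if (!length(va)) stop("fit has no additive kernel named 'G'")
  vg <- diag(as.matrix(G)) * va
  if (any(vg <= 0)) stop("zero genetic variance for some individuals")
  pmin(pmax(1 - fit@pev / vg, 0), 1)
}

#' Stage-one BLUEs with weights
#'
#' Ordinary least squares with genotype, year, fall vigor and the
#' year-by-fall-vigor interaction as fixed effects (sum-to-zero year
#' contrasts, so a genotype's BLUE is its year-averaged adjusted mean).
#' The weight attached to each BLUE is 1 / sqrt(SE).
#'
#' @param pheno phenotype data.frame.
#' @param trait trait to analyze.
#' @return data.frame of class `StageOneBLUEs`: individual, blue, se,
#'   weight. Aliased (inestimable) genotypes are dropped with a warning.
#' @export
fitBlues <- function(pheno, trait = "ws") {
  d <- pheno[pheno$trait == trait & !is.na(pheno$value), , drop = FALSE]
  d$individual <- factor(d$individual)
  d$yearf <- factor(d$year)
  form <- value ~ 0 + individual
  ctr <- list()
  if (nlevels(d$yearf) > 1 && stats::var(d$fall_vigor) > 0) {
    form <- value ~ 0 + individual + yearf * fall_vigor
    ctr <- list(yearf = "contr.sum")
  } else if (nlevels(d$yearf) > 1) {
    form <- value ~ 0 + individual + yearf
    ctr <- list(yearf = "contr.sum")
  } else if (stats::var(d$fall_vigor) > 0)
    form <- value ~ 0 + individual + fall_vigor
  fit <- stats::lm(form, data = d, contrasts = if (length(ctr)) ctr else NULL)
  cf <- coef(fit)
  keep <- grep("^individual", names(cf))
  est <- cf[keep]
  ses <- sqrt(diag(vcov(fit)))[names(cf)[keep][!is.na(est)]]
  ids <- sub("^individual", "", names(cf)[keep])
  if (anyNA(est))
    warning("aliased genotypes dropped: ",
            paste(ids[is.na(est)], collapse = ", "))
  ok <- !is.na(est)
  out <- data.frame(individual = ids[ok], blue = unname(est[ok]),
                    se = unname(ses), stringsAsFactors = FALSE)
  out$weight <- 1 / sqrt(out$se)
  class(out) <- c("StageOneBLUEs", "data.frame")
  out
}

#' Two-stage weighted genomic prediction
#'
#' Stage two of the study's prediction pipeline: genotype BLUEs are modelled
#' as mu + u_a + u_R + e with u_a ~ N(0, G sigma2_a), u_R ~ N(0, I sigma2_R)
#' and per-genotype residual variance proportional to the stage-one SE
#' (i.e. the weight 1/sqrt(SE) enters through the residual); `se_scaling =
#' "se2"` uses SE^2 instead. The GEBV is the additive BLUP; genotypes in `G`
#' without a BLUE are predicted through their relationships.
#'
#' @param blues a `StageOneBLUEs` data.frame (or any data.frame with
#'   individual, blue, se).
#' @param G additive relationship matrix (may include unphenotyped
#'   individuals).
#' @param include_residual include the I-kernel residual genotypic effect.
#' @param se_scaling `"se"` (literal reading) or `"se2"`.
#' @param extra_kernels optional named list of further relationship matrices
#'   (e.g. dominance or epistatic) over the same individuals.
#' @param tol,max_iter REML controls.
#' @return a [FitResult-class] indexed by the individuals of `G`.
#' @export
twoStagePredict <- function(blues, G, include_residual = TRUE,
                            se_scaling = c("se", "se2"),
                            extra_kernels = NULL,
                            tol = 1e-6, max_iter = 200L) {
  se_scaling <- match.arg(se_scaling)
  ids <- rownames(G)
  b <- blues[blues$individual %in% ids, , drop = FALSE]
  if (!nrow(b)) stop("no BLUEs match the kernel individuals")
  n <- nrow(b)
  y <- b$blue
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  Z <- matrix(0, n, length(ids))
  Z[cbind(seq_len(n), match(b$individual, ids))] <- 1
  Vlist <- list(G = Z %*% G %*% t(Z))
  if (include_residual) Vlist$I <- tcrossprod(Z)
  if (!is.null(extra_kernels))
    for (k in names(extra_kernels))
      Vlist[[k]] <- Z %*% extra_kernels[[k]] %*% t(Z)
  if (is.null(b$se) || anyNA(b$se)) {
    warning("missing stage-one SEs; fitting unweighted")
    Vlist$residual <- diag(n)
  } else {
    w <- if (se_scaling == "se") b$se else b$se^2
    # median normalization keeps the typical residual near theta_e even
    # when a few genotypes carry enormous stage-one SEs
    Vlist$residual <- diag(w / stats::median(w))
  }
  res <- .remlEngine(y, X, Vlist, tol = tol, max_iter = max_iter)
  ua <- drop(res$theta[1] * G %*% crossprod(Z, res$Py))
  names(ua) <- ids
  blup <- list(G = ua)
  if (include_residual)
    blup$I <- stats::setNames(drop(res$theta[2] * crossprod(Z, res$Py)), ids)
  KZt <- G %*% t(Z)
  pevv <- pmax(diag(res$theta[1] * G -
                      res$theta[1]^2 * KZt %*% res$P %*% t(KZt)), 0)
  rel <- if (res$theta[1] > 0)
    pmin(pmax(1 - pevv / (diag(as.matrix(G)) * res$theta[1]), 0), 1)
  else rep(0, length(ids))
  varcomp <- data.frame(component = names(Vlist), estimate = res$theta,
                        se = res$se, boundary = res$boundary,
                        stringsAsFactors = FALSE)
  new("FitResult", varcomp = varcomp, fixef = res$fixef, blup = blup,
      gebv = ua, pev = stats::setNames(pevv, ids),
      reliability = stats::setNames(rel, ids),
      loglik = res$loglik, converged = res$converged,
      niter = as.integer(res$niter),
      details = list(trace = res$trace, ids = ids, n_records = n,
                     weighted = !is.null(b$se)))
}

#' Two-trait REML with unstructured genetic covariance
#'
#' Stacks two traits and fits, for every supplied kernel, an unstructured
#' 2 x 2 trait covariance (variance per trait plus a covariance), with
#' year-specific residual variances per trait and no cross-trait residual
#' covariance. With `fix_cov = TRUE` the genetic covariances are fixed at 0
#' and the model decouples into the two single-trait fits.
#'
#' @param pheno phenotype data.frame with both traits.
#' @param kernels named list of relationship matrices.
#' @param traits length-2 character (default `c("ws", "hd")`).
#' @param fix_cov fix all genetic covariances at zero.
#' @param tol,max_iter REML controls.
#' @return a [FitResult-class]; `blup` holds one (individuals x 2) matrix
#'   per kernel, `gebv` the additive BLUP of the first trait. A singular fit
#'   stops with an error mentioning "singular".
#' @export
fitMultitrait <- function(pheno, kernels, traits = c("ws", "hd"),
                          fix_cov = FALSE, tol = 1e-6, max_iter = 200L) {
  stopifnot(length(traits) == 2)
  ids <- rownames(kernels[[1]])
  dl <- lapply(traits, function(tr) {
    d <- pheno[pheno$trait == tr & pheno$individual %in% ids &
                 !is.na(pheno$value), , drop = FALSE]
    if (!nrow(d)) stop("no records for trait ", tr)
    d
  })
  nrec <- vapply(dl, nrow, 0L)
  n <- sum(nrec)
  y <- c(dl[[1]]$value, dl[[2]]$value)
  # block-diagonal fixed design: per-trait intercept, year, fall vigor
  Xl <- lapply(dl, function(d) {
    yearf <- factor(d$year)
    if (nlevels(yearf) > 1 && stats::var(d$fall_vigor) > 0)
      stats::model.matrix(~ yearf * fall_vigor, data = d)
    else if (nlevels(yearf) > 1) stats::model.matrix(~ yearf, data = d)
    else matrix(1, nrow(d), 1)
  })
  X <- matrix(0, n, ncol(Xl[[1]]) + ncol(Xl[[2]]))
  X[seq_len(nrec[1]), seq_len(ncol(Xl[[1]]))] <- Xl[[1]]
  X[nrec[1] + seq_len(nrec[2]), ncol(Xl[[1]]) + seq_len(ncol(Xl[[2]]))] <- Xl[[2]]
  colnames(X) <- c(paste0(traits[1], ":", colnames(Xl[[1]])),
                   paste0(traits[2], ":", colnames(Xl[[2]])))
  Zl <- lapply(dl, function(d) {
    Z <- matrix(0, nrow(d), length(ids))
    Z[cbind(seq_len(nrow(d)), match(d$individual, ids))] <- 1
    Z
  })
  rows <- list(seq_len(nrec[1]), nrec[1] + seq_len(nrec[2]))

  Vlist <- list(); lower <- numeric(0)
  for (k in names(kernels)) {
    K <- kernels[[k]]
    for (t in 1:2) {
      Vt <- matrix(0, n, n)
      Vt[rows[[t]], rows[[t]]] <- Zl[[t]] %*% K %*% t(Zl[[t]])
      Vlist[[paste0(k, ":var_", traits[t])]] <- Vt
      lower <- c(lower, 0)
    }
    if (!fix_cov) {
      Vc <- matrix(0, n, n)
      C12 <- Zl[[1]] %*% K %*% t(Zl[[2]])
      Vc[rows[[1]], rows[[2]]] <- C12
      Vc[rows[[2]], rows[[1]]] <- t(C12)
      Vlist[[paste0(k, ":cov")]] <- Vc
      lower <- c(lower, -Inf)
    }
  }
  for (t in 1:2) {
    yearf <- factor(dl[[t]]$year)
    for (lv in levels(yearf)) {
      Vt <- matrix(0, n, n)
      diag(Vt)[rows[[t]]] <- (dl[[t]]$year == lv) * 1
      Vlist[[paste0("residual:", traits[t], ":year", lv)]] <- Vt
      lower <- c(lower, 0)
    }
  }
  res <- tryCatch(
    .remlEngine(y, X, Vlist, lower = lower, tol = tol, max_iter = max_iter),
    error = function(e) stop("singular multi-trait fit: ", conditionMessage(e)))

  blup <- list()
  for (k in names(kernels)) {
    K <- kernels[[k]]
    C <- matrix(0, 2, 2)
    C[1, 1] <- res$theta[match(paste0(k, ":var_", traits[1]), names(Vlist))]
    C[2, 2] <- res$theta[match(paste0(k, ":var_", traits[2]), names(Vlist))]
    if (!fix_cov)
      C[1, 2] <- C[2, 1] <- res$theta[match(paste0(k, ":cov"), names(Vlist))]
    U <- matrix(0, length(ids), 2, dimnames = list(ids, traits))
    for (t in 1:2) for (tp in 1:2)
      U[, t] <- U[, t] + C[t, tp] *
        drop(K %*% crossprod(Zl[[tp]], res$Py[rows[[tp]]]))
    blup[[k]] <- U
  }
  gv <- if ("G" %in% names(kernels)) blup[["G"]][, 1] else blup[[1]][, 1]
  varcomp <- data.frame(component = names(Vlist), estimate = res$theta,
                        se = res$se, boundary = res$boundary,
                        stringsAsFactors = FALSE)
  new("FitResult", varcomp = varcomp, fixef = res$fixef, blup = blup,
      gebv = gv, pev = numeric(0), reliability = numeric(0),
      loglik = res$loglik, converged = res$converged,
      niter = as.integer(res$niter),
      details = list(trace = res$trace, ids = ids, traits = traits))
}
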