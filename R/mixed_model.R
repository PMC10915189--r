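## Single-trait animal model: y = Xb + Za + e with a ~ N(0, sigma_a2 * H)
## (H = A for PBLUP).  Mixed-model equations, AI-REML with EM fallback.

#' Build design matrices for the animal model
#'
#' X is a full-rank 0/1 incidence matrix for the fixed factors
#' (intercept + treatment contrasts, one reference level dropped per
#' factor); Z maps phenotype records to pedigree animal slots.
#'
#' @param phen data.frame with columns `id`, the fixed factor columns and
#'   the trait column.
#' @param ped a [Pedigree-class] containing every phenotyped animal.
#' @param trait trait column name (default "trait").
#' @param fixed character vector of fixed factor column names
#'   (default c("hys", "sex")).
#' @return list with `y`, dense `X`, sparse `Z` (records x animals) and
#'   `animalIds` (pedigree order).
#' @export
buildDesign <- function(phen, ped, trait = "trait",
                        fixed = c("hys", "sex")) {
  stopifnot(is.data.frame(phen), is(ped, "Pedigree"),
            trait %in% names(phen), all(fixed %in% names(phen)))
  idx <- match(phen$id, animalIds(ped))
  if (anyNA(idx))
    stop("phenotyped animal(s) absent from pedigree: ",
         paste(head(phen$id[is.na(idx)], 5), collapse = ", "))
  y <- as.numeric(phen[[trait]])
  for (f in fixed) {
    tab <- table(phen[[f]])
    if (any(tab == 1))
      warning("fixed factor '", f, "' has level(s) with a single record: ",
              paste(head(names(tab)[tab == 1], 3), collapse = ", "))
  }
  fml <- stats::as.formula(paste("~", paste(
    sprintf("factor(%s)", fixed), collapse = " + ")))
  X <- model.matrix(fml, data = phen)
  ## drop aliased columns so X is full rank even with confounded levels
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  Z <- Matrix::sparseMatrix(i = seq_along(y), j = idx, x = 1,
                            dims = c(length(y), nAnimals(ped)),
                            dimnames = list(NULL, animalIds(ped)))
  list(y = y, X = X, Z = Z, animalIds = animalIds(ped))
}

#' Combined pedigree-genomic inverse relationship matrix
#'
#' H^-1 equals A^-1 everywhere except the genotyped block, where
#' Gstar^-1 - A22^-1 is added.
#'
#' @param aInv sparse A inverse over all pedigree animals.
#' @param a22Inv dense inverse of the genotyped block of A.
#' @param gStarInv dense inverse of the blended/tuned G.
#' @param genotypedIdx integer indices of the genotyped animals within the
#'   pedigree (order matching the rows of `gStarInv`/`a22Inv`).
#' @return sparse symmetric H inverse.
#' @export
hInverse <- function(aInv, a22Inv, gStarInv, genotypedIdx) {
  if (length(genotypedIdx) == 0L) return(aInv)
  stopifnot(nrow(a22Inv) == length(genotypedIdx),
            nrow(gStarInv) == length(genotypedIdx))
  if (!isSymmetric(unname(as.matrix(gStarInv)), tol = 1e-8) ||
      !isSymmetric(unname(as.matrix(a22Inv)), tol = 1e-8))
    stop("gStarInv and a22Inv must be symmetric")
  corr <- gStarInv - a22Inv
  nG <- length(genotypedIdx)
  Corr <- Matrix::sparseMatrix(i = rep(genotypedIdx, times = nG),
                               j = rep(genotypedIdx, each = nG),
                               x = as.vector(corr), dims = dim(aInv))
  H <- Matrix::forceSymmetric(aInv + Corr)
  dimnames(H) <- dimnames(aInv)
  H
}

## trace(S %*% B) for sparse symmetric S and dense B
.trSparseDense <- function(S, B) {
  TT <- as(as(S, "generalMatrix"), "TsparseMatrix")
  sum(TT@x * B[cbind(TT@i + 1L, TT@j + 1L)])
}

.buildC <- function(XtX, XtZ, ZtZ, HinvDense, lambda) {
  q <- nrow(HinvDense)
  p <- nrow(XtX)
  C <- matrix(0, p + q, p + q)
  C[seq_len(p), seq_len(p)] <- XtX
  C[seq_len(p), p + seq_len(q)] <- XtZ
  C[p + seq_len(q), seq_len(p)] <- t(XtZ)
  C[p + seq_len(q), p + seq_len(q)] <- ZtZ + lambda * HinvDense
  C
}

#' Solve the mixed-model equations
#'
#' Solves `[X'X, X'Z; Z'X, Z'Z + lambda * Hinv] [b; a] = [X'y; Z'y]` with
#' `lambda = sigmaE2 / sigmaA2`.  Small/desk-scale systems are factorised
#' densely when inverse blocks are requested (needed for prediction error
#' variances); otherwise a sparse Cholesky solve is used.
#'
#' @param y,X,Z from [buildDesign()].
#' @param Hinv sparse inverse relationship matrix ([aInverse()] for PBLUP,
#'   [hInverse()] for ssGBLUP).
#' @param sigmaA2,sigmaE2 variance components.
#' @param keepInverse return the dense inverse coefficient matrix blocks.
#' @param pevIdx animal indices whose prediction-error (co)variance block
#'   is wanted (implies `keepInverse` for that block).
#' @param maxDense guard for dense factorisation (default 6000 equations).
#' @return list of class `MMESolution`: `b`, `a` (GEBVs, named by animal),
#'   `fitted`, `residuals`, `lambda`, and when requested `Caa` (the
#'   animal-block of the inverse coefficient matrix; multiply by sigmaE2
#'   for PEV) restricted to `pevIdx`.
#' @export
solveMME <- function(y, X, Z, Hinv, sigmaA2, sigmaE2,
                     keepInverse = FALSE, pevIdx = NULL,
                     maxDense = 6000L) {
  stopifnot(sigmaA2 > 0, sigmaE2 > 0)
  lambda <- sigmaE2 / sigmaA2
  p <- ncol(X); q <- ncol(Z)
  XtX <- crossprod(X)
  XtZ <- as.matrix(Matrix::crossprod(X, Z))
  ZtZ <- Matrix::crossprod(Z)
  rhs <- c(crossprod(X, y), as.vector(Matrix::crossprod(Z, y)))
  wantInv <- keepInverse || !is.null(pevIdx)
  Caa <- NULL
  if (wantInv) {
    if (p + q > maxDense)
      stop("system too large for dense inverse blocks (", p + q,
           " equations > ", maxDense, ")")
    C <- .buildC(as.matrix(XtX), XtZ, as.matrix(ZtZ), as.matrix(Hinv),
                 lambda)
    ch <- tryCatch(chol(C), error = function(e)
      stop("singular mixed-model equations; check for confounded ",
           "fixed-effect levels"))
    Cinv <- chol2inv(ch)
    sol <- drop(Cinv %*% rhs)
    if (is.null(pevIdx)) pevIdx <- seq_len(q)
    Caa <- Cinv[p + pevIdx, p + pevIdx, drop = FALSE]
  } else {
    Csp <- rbind(
      cbind(Matrix::Matrix(XtX, sparse = TRUE), Matrix::Matrix(XtZ, sparse = TRUE)),
      cbind(Matrix::t(Matrix::Matrix(XtZ, sparse = TRUE)), ZtZ + lambda * Hinv))
    sol <- tryCatch(as.vector(Matrix::solve(Csp, rhs)),
                    error = function(e)
      stop("singular mixed-model equations; check for confounded ",
           "fixed-effect levels"))
  }
  b <- sol[seq_len(p)]
  names(b) <- colnames(X)
  a <- sol[p + seq_len(q)]
  names(a) <- colnames(Z)
  fitted <- drop(X %*% b) + as.vector(Z %*% a)
  structure(list(b = b, a = a, fitted = fitted, residuals = y - fitted,
                 lambda = lambda, Caa = Caa, pevIdx = pevIdx,
                 sigmaA2 = sigmaA2, sigmaE2 = sigmaE2),
            class = "MMESolution")
}

#' @export
print.MMESolution <- function(x, ...) {
  cat("MMESolution:", length(x$b), "fixed-effect levels,",
      length(x$a), "animals (lambda =", format(x$lambda, digits = 4), ")\n")
  invisible(x)
}

#' AI-REML variance components for the animal model
#'
#' Average-information REML on (sigma_a2, sigma_e2) with EM fallback
#' whenever an AI update would leave the parameter space.  First
#' derivatives and traces come from the mixed-model-equation identities
#' (Py = e_hat / sigma_e2; tr(P Z H Z') = (q - lambda * tr(Hinv Caa)) /
#' sigma_a2); the AI matrix is formed from the working variates
#' Za_hat/sigma_a2 and e_hat/sigma_e2.  The standard error of h2 comes
#' from the inverse AI matrix by the delta method.
#'
#' @param y,X,Z from [buildDesign()].
#' @param Hinv sparse inverse relationship matrix.
#' @param start optional c(sigmaA2, sigmaE2) start values; default is half
#'   the phenotypic variance each.
#' @param tol relative convergence tolerance (default 1e-8).
#' @param maxIter iteration cap (default 200); non-convergence returns the
#'   best estimates flagged `converged = FALSE`.
#' @param method `"ai"` (AI with EM fallback, default) or `"em"` (pure EM,
#'   mainly for diagnostics).
#' @param verbose print per-iteration estimates.
#' @return a [VarianceComponents-class].
#' @export
aiReml <- function(y, X, Z, Hinv, start = NULL, tol = 1e-8,
                   maxIter = 200L, method = c("ai", "em"),
                   verbose = FALSE) {
  method <- match.arg(method)
  n <- length(y); p <- ncol(X); q <- ncol(Z)
  if (n <= p) stop("more fixed-effect columns than records")
  vp <- var(y)
  if (is.null(start)) start <- c(vp / 2, vp / 2)
  theta <- start
  floorA <- 1e-10 * vp
  floorE <- 1e-10 * vp

  XtX <- as.matrix(crossprod(X))
  XtZ <- as.matrix(Matrix::crossprod(X, Z))
  ZtZd <- as.matrix(Matrix::crossprod(Z))
  HinvDense <- as.matrix(Hinv)
  Xty <- drop(crossprod(X, y))
  Zty <- as.vector(Matrix::crossprod(Z, y))
  yty <- sum(y * y)
  rhs <- c(Xty, Zty)

  history <- matrix(NA_real_, maxIter, 2L,
                    dimnames = list(NULL, c("sigmaA2", "sigmaE2")))
  converged <- FALSE
  AI <- NULL
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    sa <- theta[1L]; se <- theta[2L]
    lambda <- se / sa
    C <- .buildC(XtX, XtZ, ZtZd, HinvDense, lambda)
    ch <- chol(C)
    Cinv <- chol2inv(ch)
    sol <- drop(Cinv %*% rhs)
    b <- sol[seq_len(p)]
    a <- sol[p + seq_len(q)]
    ehat <- y - drop(X %*% b) - as.vector(Z %*% a)
    Caa <- Cinv[p + seq_len(q), p + seq_len(q)]
    trHC <- .trSparseDense(Hinv, Caa)
    aHa <- drop(crossprod(a, as.vector(Hinv %*% a)))

    ## scores
    tA <- (q - lambda * trHC) / sa            # tr(P Z H Z')
    trP <- (n - p - sa * tA) / se             # tr(P)
    scoreA <- -0.5 * (tA - aHa / sa^2)
    scoreE <- -0.5 * (trP - sum(ehat^2) / se^2)

    ## average information from working variates
    uA <- as.vector(Z %*% a) / sa
    uE <- ehat / se
    Pvec <- function(w) {
      rw <- c(drop(crossprod(X, w)), as.vector(Matrix::crossprod(Z, w)))
      sw <- drop(Cinv %*% rw)
      (w - drop(X %*% sw[seq_len(p)]) -
         as.vector(Z %*% sw[p + seq_len(q)])) / se
    }
    PuA <- Pvec(uA); PuE <- Pvec(uE)
    AI <- 0.5 * matrix(c(sum(uA * PuA), sum(uA * PuE),
                         sum(uA * PuE), sum(uE * PuE)), 2L, 2L)

    emStep <- function() {
      c((aHa + se * trHC) / q,
        (yty - sum(b * Xty) - sum(a * Zty)) / (n - p))
    }
    if (method == "em") {
      thetaNew <- emStep()
    } else {
      thetaNew <- tryCatch(theta + solve(AI, c(scoreA, scoreE)),
                           error = function(e) c(NA_real_, NA_real_))
      if (anyNA(thetaNew) || thetaNew[1L] < floorA || thetaNew[2L] < floorE)
        thetaNew <- emStep()
    }
    thetaNew[1L] <- max(thetaNew[1L], floorA)
    thetaNew[2L] <- max(thetaNew[2L], floorE)
    history[iter, ] <- thetaNew
    if (verbose)
      message(sprintf("iter %d: sigma_a2 = %.6g, sigma_e2 = %.6g",
                      iter, thetaNew[1L], thetaNew[2L]))
    rel <- abs(thetaNew - theta) / pmax(abs(theta), 1e-12)
    ## near the sigma_a2 = 0 boundary relative changes stall; accept once
    ## the component is negligible and sigma_e2 is stable
    atBoundary <- thetaNew[1L] / sum(thetaNew) < 1e-6 && rel[2L] < tol
    theta <- thetaNew
    if (all(rel < tol) || atBoundary) {
      converged <- TRUE
      break
    }
  }

  sa <- theta[1L]; se <- theta[2L]
  h2 <- sa / (sa + se)
  seH2 <- NA_real_
  vcov <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(vcov)) {
    gr <- c(se, -sa) / (sa + se)^2
    v <- drop(t(gr) %*% vcov %*% gr)
    if (is.finite(v) && v >= 0) seH2 <- sqrt(v)
  }
  new("VarianceComponents", sigmaA2 = sa, sigmaE2 = se, h2 = h2,
      seH2 = seH2, converged = converged, nIter = iter,
      method = "animal-model", history = history[seq_len(iter), , drop = FALSE])
}

#' Heritability from variance components
#'
#' h2 = sigma_a2 / (sigma_a2 + sigma_e2).  Rounding happens only at report
#' time.
#'
#' @param sigmaA2 additive variance, or a [VarianceComponents-class].
#' @param sigmaE2 residual variance (ignored when a VarianceComponents is
#'   given).
#' @return heritability in `[0, 1]`.
#' @examples
#' heritability(66.74, 67.31)  # 0.4979 -> reported as 0.50
#' @export
heritability <- function(sigmaA2, sigmaE2 = NULL) {
  if (is(sigmaA2, "VarianceComponents"))
    return(sigmaA2@h2)
  stopifnot(is.numeric(sigmaA2), is.numeric(sigmaE2))
  tot <- sigmaA2 + sigmaE2
  if (any(tot <= 0)) stop("sigmaA2 + sigmaE2 must be > 0")
  sigmaA2 / tot
}
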