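# shared builders for the test suite; everything is generated in code

trioPed <- function() {
  sortPedigree(data.frame(id = c("s", "d", "o"),
                          sire = c(0, 0, "s"), dam = c(0, 0, "d")))
}

fullSibMatingPed <- function() {
  sortPedigree(data.frame(id = c("s", "d", "a", "b", "x"),
                          sire = c(0, 0, "s", "s", "a"),
                          dam = c(0, 0, "d", "d", "b")))
}

# random valid pedigree: each non-founder gets two distinct earlier parents
randomPed <- function(n, nFounders = 10L, seed = 1L) {
  set.seed(seed)
  sire <- integer(n); dam <- integer(n)
  for (i in (nFounders + 1L):n) {
    p <- sample.int(i - 1L, 2L)
    sire[i] <- p[1L]; dam[i] <- p[2L]
  }
  new("Pedigree", id = sprintf("A%04d", seq_len(n)),
      sire = sire, dam = dam,
      sex = rep(NA_character_, n), generation = rep(NA_integer_, n))
}

# GenotypeData from a bare dosage matrix
makeGeno <- function(d, chrom = NULL, bp = NULL) {
  m <- ncol(d)
  if (is.null(chrom)) chrom <- rep(1, m)
  if (is.null(bp)) bp <- ave(seq_len(m), chrom, FUN = seq_along) * 1000
  map <- data.frame(chrom = chrom,
                    snp_id = sprintf("snp%03d", seq_len(m)),
                    cm = bp / 1e4, bp = bp,
                    allele1 = "A", allele2 = "B",
                    stringsAsFactors = FALSE)
  new("GenotypeData", dosages = d, map = map,
      animalIds = sprintf("an%03d", seq_len(nrow(d))), metadata = list())
}

# dense H from the textbook joint-distribution identity, for the blockwise
# H-inverse oracle
denseH <- function(A, Gstar, gIdx) {
  nIdx <- setdiff(seq_len(nrow(A)), gIdx)
  A11 <- A[nIdx, nIdx, drop = FALSE]; A12 <- A[nIdx, gIdx, drop = FALSE]
  A22 <- A[gIdx, gIdx, drop = FALSE]
  A22i <- solve(A22)
  H <- A
  H[nIdx, nIdx] <- A11 + A12 %*% A22i %*% (Gstar - A22) %*% A22i %*% t(A12)
  H[nIdx, gIdx] <- A12 %*% A22i %*% Gstar
  H[gIdx, nIdx] <- t(H[nIdx, gIdx])
  H[gIdx, gIdx] <- Gstar
  H
}

# explicit REML log-likelihood (dense V), the oracle for the AI-REML path
remlLogLik <- function(sa, se, y, X, ZAZ) {
  V <- sa * ZAZ + se * diag(length(y))
  cV <- chol(V)
  Vi <- chol2inv(cV)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX, crossprod(X, Vi))
  -0.5 * (2 * sum(log(diag(cV))) +
            as.numeric(determinant(XtViX)$modulus) +
            drop(t(y) %*% P %*% y))
}

# full-likelihood grid search over f_AB with marginals fixed at the sample
# allele frequencies (single free parameter), the EM oracle
gridSearchLD <- function(gi, gj, step = 1e-5) {
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  pA <- mean(gi) / 2; pB <- mean(gj) / 2
  cnt <- table(factor(gi, 0:2), factor(gj, 0:2))
  ll <- function(fAB) {
    f <- c(fAB, pA - fAB, pB - fAB, 1 - pA - pB + fAB)
    if (any(f < -1e-12)) return(-Inf)
    f <- pmax(f, 1e-300)
    pr <- matrix(0, 3, 3)
    pr[3, 3] <- f[1]^2;          pr[3, 2] <- 2 * f[1] * f[2]
    pr[3, 1] <- f[2]^2;          pr[2, 3] <- 2 * f[1] * f[3]
    pr[2, 2] <- 2 * (f[1] * f[4] + f[2] * f[3])
    pr[2, 1] <- 2 * f[2] * f[4]; pr[1, 3] <- f[3]^2
    pr[1, 2] <- 2 * f[3] * f[4]; pr[1, 1] <- f[4]^2
    sum(cnt[cnt > 0] * log(pr[cnt > 0]))
  }
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  grid <- seq(lo, hi, by = step)
  best <- grid[which.max(vapply(grid, ll, numeric(1)))]
  c(AB = best, Ab = pA - best, aB = pB - best, ab = 1 - pA - pB + best)
}

# genotype pairs sampled from known two-locus haplotype frequencies
simFromHapFreqs <- function(f, n, seed = 1L) {
  set.seed(seed)
  haps <- matrix(c(1, 1, 1, 0, 0, 1, 0, 0), 4, 2, byrow = TRUE)
  pick <- sample.int(4L, 2L * n, replace = TRUE, prob = f)
  h1 <- haps[pick[seq_len(n)], , drop = FALSE]
  h2 <- haps[pick[n + seq_len(n)], , drop = FALSE]
  list(gi = h1[, 1] + h2[, 1], gj = h1[, 2] + h2[, 2])
}

# exhaustive-enumeration hypergeometric upper tail: walk every possible
# drawn subset of the universe
enumHyperTail <- function(N, term, n, k) {
  subsets <- utils::combn(N, n)
  hits <- colSums(matrix(subsets %in% term, nrow = n))
  mean(hits >= k)
}

# the frozen acceptance-scale generator configuration (study conditions)
recoveryConfig <- function(seed) {
  simConfig(n_founders = 560, n_generations = 4, offspring_per_mating = 1,
            prop_genotyped = 0.5, n_chrom = 10, snps_per_chrom = 200,
            chrom_length_morgans = 1, sigma_a2 = 66.74, sigma_e2 = 67.31,
            n_qtl = 2000, qtl_var_prop = 1, n_hys_levels = 5,
            sex_effect = 3, seed = seed)
}

# one full ssGBLUP fit on a simulated dataset; returns the pieces tests need
fitSsgblup <- function(dat, sigmaA2 = NULL, sigmaE2 = NULL, reml = FALSE) {
  g <- imputeMean(qcFilter(dat$genotypes)$genotypes)
  vr <- vanRadenG(g)
  a22 <- a22Matrix(dat$pedigree, animalIds(g))
  bt <- blendTuneG(vr$G, a22$A22)
  Ai <- aInverse(dat$pedigree)
  gi <- match(animalIds(g), animalIds(dat$pedigree))
  Hi <- hInverse(Ai, a22$A22inv, bt$GstarInv, gi)
  des <- buildDesign(dat$phenotypes, dat$pedigree)
  vc <- NULL
  if (reml) {
    vc <- aiReml(des$y, des$X, des$Z, Hi)
    sigmaA2 <- vc@sigmaA2; sigmaE2 <- vc@sigmaE2
  }
  sol <- solveMME(des$y, des$X, des$Z, Hi, sigmaA2, sigmaE2, pevIdx = gi)
  bs <- backsolveSnpEffects(vr$W, bt$GstarInv, sol$a[gi], vr$k)
  tab <- snpEffectTable(bs, bt$Gstar, sol$Caa, sigmaA2, sigmaE2, markers(g))
  list(geno = g, vr = vr, bt = bt, Ainv = Ai, gIdx = gi, Hinv = Hi,
       design = des, vc = vc, sol = sol, backsolve = bs, table = tab)
}
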