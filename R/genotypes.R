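## Genotype input, quality control and the VanRaden genomic relationship
## matrix with A22 blending/tuning.

#' Read PLINK text genotypes (.ped / .map)
#'
#' The counted allele of each marker is the minor allele determined from
#' the data (ties broken towards the lexicographically smaller allele);
#' "0 0" allele pairs are missing calls.
#'
#' @param pedPath,mapPath paths to the PLINK text files.
#' @return a [GenotypeData-class].
#' @export
readPlinkText <- function(pedPath, mapPath) {
  map <- read.table(mapPath, header = FALSE, sep = "",
                    colClasses = c("character", "character",
                                   "numeric", "numeric"))
  names(map) <- c("chrom", "snp_id", "cm", "bp")
  m <- nrow(map)
  lines <- readLines(pedPath)
  lines <- lines[nzchar(trimws(lines))]
  nInd <- length(lines)
  ids <- character(nInd)
  alleles <- matrix("0", nInd, 2L * m)
  for (i in seq_len(nInd)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(tok) != 6L + 2L * m)
      stop(".ped line ", i, " has ", length(tok), " fields; expected ",
           6L + 2L * m, " for ", m, " markers")
    ids[i] <- tok[2L]
    alleles[i, ] <- tok[-(1:6)]
  }
  dos <- matrix(NA_real_, nInd, m)
  a1 <- character(m); a2 <- character(m)
  for (j in seq_len(m)) {
    x <- alleles[, 2L * j - 1L]
    y <- alleles[, 2L * j]
    ok <- x != "0" & y != "0"
    obs <- c(x[ok], y[ok])
    if (!length(obs)) {
      a1[j] <- a2[j] <- NA_character_
      next
    }
    tab <- sort(table(obs))
    als <- names(tab)
    if (length(als) == 1L) {
      minor <- als; major <- als
    } else {
      if (tab[1L] == tab[2L]) als <- sort(als) else als <- names(tab)
      minor <- als[1L]; major <- als[2L]
    }
    a1[j] <- minor; a2[j] <- major
    dos[ok, j] <- (x[ok] == minor) + (y[ok] == minor)
  }
  map$allele1 <- a1
  map$allele2 <- a2
  map$chrom <- suppressWarnings(
    if (all(!is.na(as.numeric(map$chrom)))) as.numeric(map$chrom)
    else map$chrom)
  ord <- order(map$chrom, map$bp)
  new("GenotypeData", dosages = dos[, ord, drop = FALSE],
      map = map[ord, , drop = FALSE], animalIds = ids,
      metadata = list())
}

#' Read a dosage matrix TSV
#'
#' Animals in rows (first column = animal id), SNP ids in the header.  A
#' matching marker map may be supplied; otherwise markers are placed on a
#' single dummy chromosome at consecutive positions.
#'
#' @param path TSV path.
#' @param map optional data.frame (chrom, snp_id, cm, bp).
#' @return a [GenotypeData-class].
#' @export
readDosageMatrix <- function(path, map = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(df[[1L]])
  d <- as.matrix(df[, -1L, drop = FALSE])
  snp <- colnames(d)
  if (is.null(map)) {
    map <- data.frame(chrom = 1, snp_id = snp, cm = seq_along(snp),
                      bp = seq_along(snp), allele1 = "A", allele2 = "B",
                      stringsAsFactors = FALSE)
  } else {
    map <- map[match(snp, map$snp_id), ]
    map$allele1 <- map$allele1 %||% "A"
    map$allele2 <- map$allele2 %||% "B"
  }
  ord <- order(map$chrom, map$bp)
  new("GenotypeData", dosages = d[, ord, drop = FALSE],
      map = map[ord, , drop = FALSE], animalIds = ids, metadata = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Allele frequencies of the counted allele
#'
#' p = mean dosage / 2 over non-missing calls; all-missing markers get NA
#' with a warning.
#'
#' @param g a [GenotypeData-class] or dosage matrix.
#' @return numeric vector of frequencies, one per marker.
#' @export
alleleFrequencies <- function(g) {
  d <- if (is(g, "GenotypeData")) g@dosages else g
  p <- colMeans(d, na.rm = TRUE) / 2
  if (anyNA(p) || any(!is.finite(p))) {
    p[!is.finite(p)] <- NA_real_
    warning("marker(s) with no called genotypes: frequency undefined")
  }
  unname(p)
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test on the heterozygote count given the allele
#' counts (Wigginton et al. style, as used by PLINK): the p-value is the
#' total probability of heterozygote configurations no more probable than
#' the observed one.
#'
#' @param nAA,nAa,naa genotype counts (AA = counted-allele homozygote).
#' @return two-sided exact p-value in (0, 1].
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n == 0) stop("no genotypes")
  nA <- 2L * nAA + nAa
  na <- 2L * naa + nAa
  rare <- min(nA, na)
  ## heterozygote counts share the parity of the rare allele count
  hetVals <- seq(rare %% 2L, rare, by = 2L)
  if (length(hetVals) == 0L) hetVals <- 0L
  ## probabilities by recurrence from the mid heterozygote count
  probs <- numeric(length(hetVals))
  mid <- which.min(abs(hetVals - rare * (nA + na - rare) / (nA + na)))
  probs[mid] <- 1
  ## P(h+2)/P(h) = 4 * nr(h) * nc(h) / ((h+2) * (h+1)) with nr, nc the
  ## homozygote counts of the rare and common allele at h hets
  homR <- function(h) (rare - h) / 2
  homC <- function(h) (n - h - homR(h))
  if (mid < length(hetVals)) {
    for (k in mid:(length(hetVals) - 1L)) {
      h <- hetVals[k]
      probs[k + 1L] <- probs[k] * 4 * homR(h) * homC(h) /
        ((h + 2) * (h + 1))
    }
  }
  if (mid > 1L) {
    for (k in mid:2L) {
      h <- hetVals[k]
      probs[k - 1L] <- probs[k] * h * (h - 1) /
        (4 * (homR(h) + 1) * (homC(h) + 1))
    }
  }
  probs <- probs / sum(probs)
  pObs <- probs[match(nAa, hetVals)]
  if (is.na(pObs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(probs[probs <= pObs * (1 + 1e-12)]))
}

#' Filter markers by call rate, MAF and Hardy-Weinberg equilibrium
#'
#' Markers are removed in the fixed order call rate < `callRate`, then
#' minor allele frequency < `maf`, then HWE exact p < `hweP`; each removed
#' marker is attributed to the first filter it fails.  Animals are never
#' removed.
#'
#' @param g a [GenotypeData-class].
#' @param callRate,maf,hweP thresholds (defaults 0.90, 0.01, 1e-6).
#' @return list with `genotypes` (filtered [GenotypeData-class]) and
#'   `report` (class `QCReport`).
#' @export
qcFilter <- function(g, callRate = 0.90, maf = 0.01, hweP = 1e-6) {
  stopifnot(is(g, "GenotypeData"))
  d <- g@dosages
  m <- ncol(d)
  cr <- colMeans(!is.na(d))
  p <- suppressWarnings(colMeans(d, na.rm = TRUE) / 2)
  mafs <- pmin(p, 1 - p)
  failCall <- cr < callRate | !is.finite(p)
  failMaf <- !failCall & mafs < maf
  hwe <- rep(NA_real_, m)
  candidates <- which(!failCall & !failMaf)
  for (j in candidates) {
    x <- d[, j]
    hwe[j] <- hweExactTest(sum(x == 2, na.rm = TRUE),
                           sum(x == 1, na.rm = TRUE),
                           sum(x == 0, na.rm = TRUE))
  }
  failHwe <- !failCall & !failMaf & !is.na(hwe) & hwe < hweP
  keep <- !(failCall | failMaf | failHwe)
  if (!any(keep)) stop("no markers survive QC")
  out <- new("GenotypeData",
             dosages = d[, keep, drop = FALSE],
             map = g@map[keep, , drop = FALSE],
             animalIds = g@animalIds,
             metadata = g@metadata)
  report <- structure(list(
    n_snps_before = m,
    n_snps_after = sum(keep),
    n_animals = nrow(d),
    removed = c(call_rate = sum(failCall), maf = sum(failMaf),
                hwe = sum(failHwe)),
    thresholds = c(call_rate = callRate, maf = maf, hwe_p = hweP)),
    class = "QCReport")
  list(genotypes = out, report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat("QC report:", x$n_snps_before, "->", x$n_snps_after, "SNPs (",
      x$n_animals, "animals, never filtered )\n")
  cat(sprintf("  removed: call_rate %d, maf %d, hwe %d\n",
              x$removed["call_rate"], x$removed["maf"], x$removed["hwe"]))
  cat(sprintf("  thresholds: call_rate %.2f, maf %.3g, hwe_p %.3g\n",
              x$thresholds["call_rate"], x$thresholds["maf"],
              x$thresholds["hwe_p"]))
  invisible(x)
}

#' Mean-impute missing dosages
#'
#' Missing calls are replaced by twice the counted-allele frequency of
#' their marker, which leaves every column mean unchanged.
#'
#' @param g a [GenotypeData-class].
#' @return a complete [GenotypeData-class].
#' @export
imputeMean <- function(g) {
  stopifnot(is(g, "GenotypeData"))
  d <- g@dosages
  if (anyNA(d)) {
    p <- colMeans(d, na.rm = TRUE) / 2
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- 2 * p[idx[, 2L]]
  }
  initialize(g, dosages = d)
}

#' VanRaden genomic relationship matrix
#'
#' G = W W' / (2 * sum p (1 - p)) with W the dosage matrix column-centred
#' at twice the allele frequencies (VanRaden method 1).
#'
#' @param g complete [GenotypeData-class] (see [imputeMean()]) or a
#'   complete dosage matrix.
#' @param p optional allele frequencies; computed from the data if absent.
#' @return list with `G` (dense symmetric), `W`, `p` and the scaling
#'   denominator `k = 2 * sum p (1 - p)`.
#' @export
vanRadenG <- function(g, p = NULL) {
  d <- if (is(g, "GenotypeData")) g@dosages else g
  if (anyNA(d)) stop("dosage matrix must be complete; run imputeMean()")
  if (is.null(p)) p <- colMeans(d) / 2
  k <- 2 * sum(p * (1 - p))
  if (k <= 0) stop("all markers monomorphic: VanRaden denominator is zero")
  W <- sweep(d, 2L, 2 * p, "-")
  G <- tcrossprod(W) / k
  ids <- if (is(g, "GenotypeData")) animalIds(g) else rownames(d)
  dimnames(G) <- list(ids, ids)
  list(G = G, W = W, p = p, k = k)
}

#' Blend and tune G towards A22
#'
#' First rescales G as `beta * G + alpha` so its mean diagonal and mean
#' off-diagonal match those of A22 (moment tuning), then blends:
#' `Gstar = blendW * Gtuned + (1 - blendW) * A22`, which restores full
#' rank for inversion inside H.
#'
#' @param G dense genomic relationship matrix.
#' @param A22 pedigree relationship block of the same animals, same order.
#' @param blendW blend weight in (0, 1], default 0.95.
#' @param tune apply moment tuning first (default TRUE).
#' @return list with `Gstar`, `GstarInv`, `alpha`, `beta`, `blendW`.
#' @export
blendTuneG <- function(G, A22, blendW = 0.95, tune = TRUE) {
  stopifnot(all(dim(G) == dim(A22)))
  if (blendW <= 0 || blendW > 1) stop("blendW must be in (0, 1]")
  n <- nrow(G)
  alpha <- 0; beta <- 1
  Gt <- G
  if (tune && n > 1) {
    mdG <- mean(diag(G)); mdA <- mean(diag(A22))
    moG <- (sum(G) - sum(diag(G))) / (n * (n - 1))
    moA <- (sum(A22) - sum(diag(A22))) / (n * (n - 1))
    if (abs(mdG - moG) < 1e-12)
      stop("cannot tune: G diagonal and off-diagonal means coincide")
    beta <- (mdA - moA) / (mdG - moG)
    alpha <- moA - beta * moG
    Gt <- beta * G + alpha
  }
  Gstar <- blendW * Gt + (1 - blendW) * A22
  ch <- tryCatch(chol(Gstar), error = function(e)
    stop("blended G is not positive definite; lower blendW or check input"))
  GstarInv <- chol2inv(ch)
  dimnames(Gstar) <- dimnames(G)
  dimnames(GstarInv) <- dimnames(G)
  list(Gstar = Gstar, GstarInv = GstarInv, alpha = alpha, beta = beta,
       blendW = blendW)
}
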