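## Pairwise linkage disequilibrium from unphased dosages: two-locus EM for
## haplotype frequencies, D / D' / r2, and strong-LD runs within a region.

#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood haplotype frequencies (AB, Ab, aB, ab) from unphased
#' dosage pairs.  Only double heterozygotes are phase-ambiguous; the EM
#' starts from allele-frequency products (linkage equilibrium) and splits
#' the double heterozygotes between cis and trans at each step.  The
#' multinomial log-likelihood is non-decreasing across iterations.
#'
#' @param gi,gj dosage vectors for the two markers (0/1/2, NA dropped
#'   pairwise); allele A/B = counted allele of each marker.
#' @param tol relative log-likelihood convergence tolerance (default 1e-9).
#' @param maxIter iteration cap (default 100).
#' @return named numeric (AB, Ab, aB, ab) with attributes `n` (informative
#'   pairs), `loglik` (trace), `monomorphic` and `ambiguous` flags.
#' @export
emHaplotypeFreqs <- function(gi, gj, tol = 1e-9, maxIter = 100L) {
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  n <- length(gi)
  if (n == 0) stop("no informative genotype pairs")
  cnt <- matrix(0, 3, 3)
  for (a in 0:2) for (b in 0:2) cnt[a + 1, b + 1] <- sum(gi == a & gj == b)
  pA <- mean(gi) / 2; pB <- mean(gj) / 2
  mono <- pA %in% c(0, 1) || pB %in% c(0, 1)
  ## unambiguous haplotype counts
  cAB <- 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3]
  cAb <- 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1]
  caB <- 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3]
  cab <- 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1]
  dh <- cnt[2, 2]                       # double heterozygotes

  f <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  f <- pmax(f, 1e-12); f <- f / sum(f)

  llFun <- function(f) {
    probs <- matrix(0, 3, 3)
    hap <- list(c(1, 0), c(1, 1), c(0, 0), c(0, 1))  # not used; direct below
    pAB <- f[1]; pAb <- f[2]; paB <- f[3]; pab <- f[4]
    probs[3, 3] <- pAB^2;        probs[3, 2] <- 2 * pAB * pAb
    probs[3, 1] <- pAb^2;        probs[2, 3] <- 2 * pAB * paB
    probs[2, 2] <- 2 * (pAB * pab + pAb * paB)
    probs[2, 1] <- 2 * pAb * pab; probs[1, 3] <- paB^2
    probs[1, 2] <- 2 * paB * pab; probs[1, 1] <- pab^2
    sum(cnt[cnt > 0] * log(pmax(probs[cnt > 0], 1e-300)))
  }
  ll <- llFun(f)
  llTrace <- ll
  for (it in seq_len(maxIter)) {
    denom <- f["AB"] * f["ab"] + f["Ab"] * f["aB"]
    pcis <- if (denom > 0) f["AB"] * f["ab"] / denom else 0.5
    newCounts <- c(cAB + dh * pcis, cAb + dh * (1 - pcis),
                   caB + dh * (1 - pcis), cab + dh * pcis)
    fNew <- newCounts / (2 * n)
    names(fNew) <- names(f)
    llNew <- llFun(fNew)
    llTrace <- c(llTrace, llNew)
    done <- abs(llNew - ll) <= tol * (abs(ll) + 1e-12)
    f <- fNew; ll <- llNew
    if (done) break
  }
  ## symmetric likelihood (cis/trans indistinguishable) -> flag ambiguity
  fSwap <- c(f["Ab"], f["AB"], f["ab"], f["aB"])
  names(fSwap) <- names(f)
  ambiguous <- dh > 0 && abs(llFun(fSwap) - ll) < 1e-9 &&
    max(abs(fSwap - f)) > 1e-6
  structure(f, n = n, loglik = llTrace, monomorphic = mono,
            ambiguous = ambiguous)
}

#' LD statistics from haplotype frequencies
#'
#' D = f_AB - p_A p_B; D' = |D| / D_max with D_max = min(p_A p_b, p_a p_B)
#' for D > 0 and min(p_A p_B, p_a p_b) otherwise; r2 = D^2 / (p_A p_a p_B
#' p_b).
#'
#' @param hapFreqs named numeric (AB, Ab, aB, ab), e.g. from
#'   [emHaplotypeFreqs()].
#' @return named numeric c(D, D_prime, r2); NA with a warning when a
#'   marginal frequency is 0.
#' @export
ldPairStats <- function(hapFreqs) {
  f <- hapFreqs
  stopifnot(length(f) == 4L, abs(sum(f) - 1) < 1e-6, all(f >= -1e-12))
  pA <- unname(f[1] + f[2]); pB <- unname(f[1] + f[3])
  pa <- 1 - pA; pb <- 1 - pB
  if (min(pA, pa, pB, pb) <= 0) {
    warning("monomorphic locus: LD undefined")
    return(c(D = NA_real_, D_prime = NA_real_, r2 = NA_real_))
  }
  D <- unname(f[1] - pA * pB)
  Dmax <- if (D > 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  c(D = D,
    D_prime = if (Dmax > 0) abs(D) / Dmax else 0,
    r2 = D^2 / (pA * pa * pB * pb))
}

#' Span (bp) of a marker run
#'
#' @param bp physical positions of the markers in the run.
#' @return max(bp) - min(bp).
#' @export
ldRegionSpan <- function(bp) {
  stopifnot(length(bp) >= 1, all(is.finite(bp)))
  max(bp) - min(bp)
}

#' Pairwise LD report for a marker region
#'
#' Computes all pairwise D'/r2 among the selected markers (one chromosome
#' only) and finds maximal runs of consecutive markers whose within-run
#' pairwise D' all reach the threshold (a simplified strong-LD-block
#' rule).
#'
#' @param geno a [GenotypeData-class].
#' @param snpIds marker ids to analyse, or NULL with `region`.
#' @param region string "chrom:start-end" (1-based inclusive).
#' @param dprimeThreshold strong-LD cutoff on D' (default 0.8).
#' @return list of class `LDRegionReport`: `markers` (map rows), `dprime`
#'   and `r2` matrices, `runs` (data.frame from, to, n_markers, span_bp),
#'   `threshold`.
#' @export
ldRegionReport <- function(geno, snpIds = NULL, region = NULL,
                           dprimeThreshold = 0.8) {
  stopifnot(is(geno, "GenotypeData"))
  map <- markers(geno)
  if (is.null(snpIds)) {
    if (is.null(region)) stop("supply snpIds or region")
    mm <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(mm) != 4L) stop("region must look like 'chrom:start-end'")
    sel <- map$chrom == ifelse(grepl("^[0-9.]+$", mm[2]),
                               as.numeric(mm[2]), mm[2]) &
      map$bp >= as.numeric(mm[3]) & map$bp <= as.numeric(mm[4])
    snpIds <- map$snp_id[sel]
  }
  idx <- match(snpIds, map$snp_id)
  if (anyNA(idx)) stop("unknown marker id(s): ",
                       paste(head(snpIds[is.na(idx)], 5), collapse = ", "))
  if (length(idx) < 2L) stop("need at least 2 markers")
  if (length(unique(map$chrom[idx])) > 1L)
    stop("markers must lie on a single chromosome")
  idx <- idx[order(map$bp[idx])]
  m <- length(idx)
  d <- geno@dosages[, idx, drop = FALSE]
  Dp <- matrix(NA_real_, m, m, dimnames = list(map$snp_id[idx], map$snp_id[idx]))
  R2 <- Dp
  diag(Dp) <- 1; diag(R2) <- 1
  for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    f <- emHaplotypeFreqs(d[, a], d[, b])
    st <- suppressWarnings(ldPairStats(f))
    Dp[a, b] <- Dp[b, a] <- st["D_prime"]
    R2[a, b] <- R2[b, a] <- st["r2"]
  }
  ## maximal runs of consecutive markers with all pairwise D' >= threshold
  runs <- list()
  a <- 1L
  while (a <= m) {
    b <- a
    while (b < m) {
      blk <- Dp[a:(b + 1L), a:(b + 1L)]
      if (all(blk[upper.tri(blk)] >= dprimeThreshold, na.rm = FALSE) &&
          !anyNA(blk[upper.tri(blk)])) b <- b + 1L else break
    }
    if (b > a)
      runs[[length(runs) + 1L]] <-
        data.frame(from = map$snp_id[idx[a]], to = map$snp_id[idx[b]],
                   n_markers = b - a + 1L,
                   span_bp = ldRegionSpan(map$bp[idx[a:b]]))
    a <- b + 1L
  }
  runs <- if (length(runs)) do.call(rbind, runs)
          else data.frame(from = character(), to = character(),
                          n_markers = integer(), span_bp = numeric())
  structure(list(markers = map[idx, , drop = FALSE], dprime = Dp, r2 = R2,
                 runs = runs, threshold = dprimeThreshold),
            class = "LDRegionReport")
}

#' @export
print.LDRegionReport <- function(x, ...) {
  cat("LD region report:", nrow(x$markers), "markers on chromosome",
      x$markers$chrom[1], "\n")
  cat("  strong-LD runs (all pairwise D' >=", x$threshold, "):",
      nrow(x$runs), "\n")
  if (nrow(x$runs)) print(x$runs)
  invisible(x)
}

#' Write (and optionally render) an LD heat map
#'
#' Always writes the full D' matrix as TSV; when `pngPath` is given, a
#' lower-triangle rendering with fixed colour bins at D' = 0.2, 0.4, 0.6,
#' 0.8 (deeper red = stronger LD) is produced.
#'
#' @param report an [ldRegionReport()] result.
#' @param tsvPath output TSV path.
#' @param pngPath optional PNG path.
#' @return invisibly, the TSV path.
#' @export
ldHeatmap <- function(report, tsvPath, pngPath = NULL) {
  stopifnot(inherits(report, "LDRegionReport"))
  write.table(report$dprime, tsvPath, sep = "\t", quote = FALSE,
              col.names = NA)
  if (!is.null(pngPath)) {
    m <- report$dprime
    m[upper.tri(m)] <- NA
    bins <- c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf)
    cols <- c("#fff5f0", "#fcbba1", "#fb6a4a", "#de2d26", "#a50f15")
    grDevices::png(pngPath, width = 700, height = 700)
    graphics::image(seq_len(nrow(m)), seq_len(ncol(m)),
                    matrix(as.integer(cut(m, bins)), nrow(m)),
                    col = cols, xlab = "", ylab = "", axes = FALSE,
                    main = "pairwise D'")
    graphics::axis(1, at = seq_len(nrow(m)), labels = rownames(m),
                   las = 2, cex.axis = 0.6)
    grDevices::dev.off()
  }
  invisible(tsvPath)
}
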