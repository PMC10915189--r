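## ssGWAS: back-solve per-SNP allele-substitution effects from GEBVs,
## attach sampling variances and p-values, classify against Bonferroni
## thresholds, and emit Manhattan-ready tables.

#' Back-solve SNP effects from GEBVs
#'
#' u_hat = lambda * D * W' * Gstar^-1 * a_hat with lambda = 1/k the
#' VanRaden scaling (k = 2 * sum p(1-p)) and D the per-SNP weight matrix
#' (identity by default: unweighted single-pass ssGWAS).  Using the same
#' blended/tuned Gstar as the mixed model keeps the back-solve consistent
#' with the fitted GEBVs: when Gstar = W D W' / k exactly, W u_hat
#' reconstructs a_hat.
#'
#' @param W centred dosage matrix (animals x SNPs) from [vanRadenG()].
#' @param gStarInv inverse of the blended/tuned G used in the MME.
#' @param aHat GEBVs of the genotyped animals, same order as rows of `W`.
#' @param k VanRaden denominator 2 * sum p(1-p) (from [vanRadenG()]).
#' @param D optional per-SNP weights (default uniform 1).
#' @return list with `u` (named SNP effects) and `T` (the back-solve
#'   operator, SNPs x animals, needed for sampling variances).
#' @export
backsolveSnpEffects <- function(W, gStarInv, aHat, k, D = NULL) {
  if (nrow(W) != length(aHat))
    stop("rows of W (", nrow(W), ") must match GEBVs (", length(aHat), ")")
  stopifnot(nrow(gStarInv) == nrow(W), k > 0)
  m <- ncol(W)
  if (is.null(D)) D <- rep(1, m)
  if (any(D <= 0)) stop("weights D must be positive")
  Tm <- (D / k) * crossprod(W, gStarInv)   # m x nG operator
  u <- drop(Tm %*% aHat)
  names(u) <- colnames(W)
  list(u = u, T = Tm)
}

#' SNP effect table with sampling variances and p-values
#'
#' Var(u_hat) is the back-solve operator applied to
#' Var(a_hat) = Gstar * sigma_a2 - PEC, where PEC = Caa * sigma_e2 is the
#' prediction-error covariance of the GEBVs from the inverse mixed-model
#' coefficient matrix.  z = u / sd(u); two-sided normal p-values.
#' Markers whose computed variance is not positive get p = 1 and are
#' flagged.
#'
#' @param backsolve result of [backsolveSnpEffects()].
#' @param gStar blended/tuned genomic relationship matrix.
#' @param Caa animal-block inverse of the MME coefficient matrix for the
#'   genotyped animals (from [solveMME()] with `pevIdx`).
#' @param sigmaA2,sigmaE2 variance components used in the MME.
#' @param map marker map (chrom, snp_id, bp) aligned with the SNPs.
#' @return data.frame of class `SnpEffectTable`: snp_id, chrom, bp,
#'   effect, var_u, z, p_value, var_flag.
#' @export
snpEffectTable <- function(backsolve, gStar, Caa, sigmaA2, sigmaE2, map) {
  Tm <- backsolve$T
  u <- backsolve$u
  stopifnot(nrow(map) == length(u), nrow(gStar) == ncol(Tm),
            nrow(Caa) == ncol(Tm))
  varA <- gStar * sigmaA2 - Caa * sigmaE2
  varU <- rowSums((Tm %*% varA) * Tm)
  bad <- !(varU > 0)
  if (any(bad))
    warning(sum(bad), " marker(s) with non-positive sampling variance; ",
            "p set to 1")
  z <- ifelse(bad, 0, u / sqrt(pmax(varU, .Machine$double.xmin)))
  p <- ifelse(bad, 1, 2 * pnorm(-abs(z)))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- data.frame(snp_id = map$snp_id, chrom = map$chrom, bp = map$bp,
                    effect = unname(u), var_u = unname(varU),
                    z = unname(z), p_value = unname(p),
                    var_flag = unname(bad), stringsAsFactors = FALSE)
  class(out) <- c("SnpEffectTable", "data.frame")
  out
}

#' Genome-wide significance thresholds
#'
#' Bonferroni significance 0.05 / m and suggestive 1 / m for m tested
#' markers; values are reported to 3 significant figures but carried
#' exactly for classification.
#'
#' @param m number of tested markers (>= 1).
#' @return list of class `Thresholds`: `m`, `bonferroni`, `suggestive`,
#'   plus `bonferroni3`/`suggestive3` rounded to 3 significant figures.
#' @examples
#' gwasThresholds(29732)  # 1.68e-06 and 3.36e-05
#' @export
gwasThresholds <- function(m) {
  stopifnot(m >= 1)
  b <- 0.05 / m
  s <- 1 / m
  structure(list(m = m, bonferroni = b, suggestive = s,
                 bonferroni3 = signif(b, 3), suggestive3 = signif(s, 3)),
            class = "Thresholds")
}

#' @export
print.Thresholds <- function(x, ...) {
  cat(sprintf("m = %d markers: Bonferroni %.3g, suggestive %.3g\n",
              x$m, x$bonferroni, x$suggestive))
  invisible(x)
}

#' Classify markers against significance thresholds
#'
#' Strict inequality at both cutoffs: significant when p < bonferroni,
#' suggestive when bonferroni <= p < suggestive, else ns.
#'
#' @param pValues numeric p-values, or a `SnpEffectTable`.
#' @param th a [gwasThresholds()] result.
#' @param chrom optional chromosome labels for per-chromosome counts
#'   (taken from the table when one is supplied).
#' @return list with `class` (factor per marker), `counts` (named totals)
#'   and `byChrom` (table or NULL).
#' @export
classifyAndCount <- function(pValues, th, chrom = NULL) {
  stopifnot(inherits(th, "Thresholds"))
  if (inherits(pValues, "SnpEffectTable")) {
    chrom <- pValues$chrom
    pValues <- pValues$p_value
  }
  cls <- ifelse(pValues < th$bonferroni, "significant",
                ifelse(pValues < th$suggestive, "suggestive", "ns"))
  cls <- factor(cls, levels = c("significant", "suggestive", "ns"))
  counts <- table(cls)
  byChrom <- if (!is.null(chrom)) table(chrom, cls) else NULL
  list(class = cls,
       counts = setNames(as.integer(counts), names(counts)),
       byChrom = byChrom)
}

#' Manhattan-plot-ready table
#'
#' Adds a genome-wide cumulative position and -log10(p); the thresholds
#' are attached as guide-line attributes and header metadata.
#'
#' @param table a `SnpEffectTable` (or data.frame with chrom, bp,
#'   p_value), sorted by chromosome then bp.
#' @param th optional [gwasThresholds()]; defaults to thresholds at the
#'   number of rows.
#' @return data.frame chrom, bp, cum_bp, p_value, neg_log10_p with
#'   attributes `bonferroni_line` and `suggestive_line` (-log10 scale).
#' @export
manhattanTable <- function(table, th = NULL) {
  stopifnot(all(c("chrom", "bp", "p_value") %in% names(table)))
  if (is.null(th)) th <- gwasThresholds(nrow(table))
  ord <- order(table$chrom, table$bp)
  tb <- table[ord, , drop = FALSE]
  offsets <- c(0, cumsum(tapply(tb$bp, factor(tb$chrom,
                                              levels = unique(tb$chrom)),
                                max)))
  chromIdx <- match(tb$chrom, unique(tb$chrom))
  out <- data.frame(snp_id = tb$snp_id %||% NA_character_,
                    chrom = tb$chrom, bp = tb$bp,
                    cum_bp = tb$bp + offsets[chromIdx],
                    p_value = tb$p_value,
                    neg_log10_p = -log10(tb$p_value),
                    stringsAsFactors = FALSE)
  attr(out, "bonferroni_line") <- -log10(th$bonferroni)
  attr(out, "suggestive_line") <- -log10(th$suggestive)
  out
}

#' Render a Manhattan plot to PNG
#'
#' Simple base-graphics rendering of a [manhattanTable()] with the two
#' guide lines.
#'
#' @param mt result of [manhattanTable()].
#' @param file PNG path.
#' @param width,height device size in pixels.
#' @return invisibly, `file`.
#' @export
plotManhattan <- function(mt, file, width = 1200, height = 500) {
  grDevices::png(file, width = width, height = height)
  on.exit(grDevices::dev.off())
  cols <- c("grey30", "steelblue")[1 + match(mt$chrom, unique(mt$chrom)) %% 2]
  graphics::plot(mt$cum_bp, mt$neg_log10_p, pch = 20, col = cols,
                 xlab = "cumulative position (bp)",
                 ylab = expression(-log[10](p)))
  graphics::abline(h = attr(mt, "bonferroni_line"), col = "red")
  graphics::abline(h = attr(mt, "suggestive_line"), col = "darkgreen")
  invisible(file)
}
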