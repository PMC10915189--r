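#' @import methods
#' @importFrom stats pnorm rnorm rbinom rpois runif var sd p.adjust phyper
#'   model.matrix setNames complete.cases aggregate
#' @importFrom utils read.table write.table head tail
NULL

#' Pedigree of animals with parent links
#'
#' An ordered pedigree: one record per animal, parents stored as integer
#' indices into the same object (0 = unknown).  Records are topologically
#' sorted so every parent precedes its offspring; this is enforced by the
#' validity method and is what the relationship-matrix code relies on.
#'
#' @slot id character vector of unique animal identifiers.
#' @slot sire,dam integer indices of the parents within `id` (0 = unknown).
#' @slot sex character `"M"`/`"F"` or `NA` when unknown.
#' @slot generation integer generation number (founders = 0) or `NA`.
#'
#' @seealso [sortPedigree()], [inbreeding()], [aMatrix()], [aInverse()]
#' @export
setClass("Pedigree",
  representation(
    id = "character",
    sire = "integer",
    dam = "integer",
    sex = "character",
    generation = "integer"
  )
)

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  msgs <- character()
  if (length(object@sire) != n || length(object@dam) != n)
    msgs <- c(msgs, "id, sire and dam must have equal length")
  if (anyDuplicated(object@id))
    msgs <- c(msgs, "animal ids must be unique")
  if (n > 0 && length(object@sire) == n) {
    idx <- seq_len(n)
    bad <- which(object@sire >= idx | object@dam >= idx)
    if (length(bad))
      msgs <- c(msgs, paste0("parents must precede offspring (record ",
                             bad[1L], ")"))
    if (any(object@sire < 0L) || any(object@dam < 0L))
      msgs <- c(msgs, "parent indices must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Genotypes for a set of animals with a marker map
#'
#' Allele dosages (0/1/2 copies of the counted allele, `NA` = missing) for
#' `nAnimals x nMarkers`, together with the marker map (chromosome, id,
#' genetic position in cM, physical position in bp, allele pair).  Markers
#' are stored sorted by chromosome then bp.
#'
#' @slot dosages numeric matrix, animals in rows, markers in columns.
#' @slot map data.frame with columns `chrom`, `snp_id`, `cm`, `bp`,
#'   `allele1` (counted), `allele2`.
#' @slot animalIds character, one per dosage row.
#' @slot metadata list of optional extras (e.g. the simulator stores the
#'   complete all-animal dosage matrix used to attach QTL effects).
#'
#' @seealso [readPlinkText()], [qcFilter()], [vanRadenG()]
#' @export
setClass("GenotypeData",
  representation(
    dosages = "matrix",
    map = "data.frame",
    animalIds = "character",
    metadata = "list"
  ),
  prototype(metadata = list())
)

setValidity("GenotypeData", function(object) {
  msgs <- character()
  d <- object@dosages
  if (nrow(d) != length(object@animalIds))
    msgs <- c(msgs, "one animal id per dosage row required")
  if (ncol(d) != nrow(object@map))
    msgs <- c(msgs, "one map row per dosage column required")
  need <- c("chrom", "snp_id", "cm", "bp", "allele1", "allele2")
  if (!all(need %in% names(object@map)))
    msgs <- c(msgs, paste("map must have columns:", paste(need, collapse = ", ")))
  if (length(d) && !all(d %in% c(0, 1, 2) | is.na(d)))
    msgs <- c(msgs, "dosages must be 0, 1, 2 or NA")
  if (all(need %in% names(object@map)) && nrow(object@map) > 1) {
    ord <- order(object@map$chrom, object@map$bp)
    if (!identical(ord, seq_len(nrow(object@map))))
      msgs <- c(msgs, "markers must be sorted by chromosome then bp")
    if (any(unlist(tapply(object@map$bp, object@map$chrom,
                          function(x) diff(x) <= 0))))
      msgs <- c(msgs, "bp must be strictly increasing within chromosome")
  }
  if (length(msgs)) msgs else TRUE
})

#' Variance components of the single-trait animal model
#'
#' Additive-genetic and residual variances with the derived heritability
#' h2 = sigmaA2 / (sigmaA2 + sigmaE2), its delta-method standard error, and
#' REML convergence information.
#'
#' @slot sigmaA2,sigmaE2 numeric, additive and residual variances (trait
#'   units squared).
#' @slot h2,seH2 numeric, heritability and its standard error.
#' @slot converged logical, did AI-REML converge.
#' @slot nIter integer, iterations used.
#' @slot method character, `"ssGBLUP"` or `"PBLUP"` (informational).
#' @slot history matrix of the (sigmaA2, sigmaE2) iterates, one row per
#'   iteration, for diagnostics.
#'
#' @seealso [aiReml()], [heritability()]
#' @export
setClass("VarianceComponents",
  representation(
    sigmaA2 = "numeric",
    sigmaE2 = "numeric",
    h2 = "numeric",
    seH2 = "numeric",
    converged = "logical",
    nIter = "integer",
    method = "character",
    history = "matrix"
  )
)

setValidity("VarianceComponents", function(object) {
  msgs <- character()
  if (object@sigmaA2 < 0) msgs <- c(msgs, "sigmaA2 must be >= 0")
  if (object@sigmaE2 <= 0) msgs <- c(msgs, "sigmaE2 must be > 0")
  h <- object@sigmaA2 / (object@sigmaA2 + object@sigmaE2)
  if (abs(h - object@h2) > 1e-12)
    msgs <- c(msgs, "h2 must equal sigmaA2/(sigmaA2+sigmaE2)")
  if (length(msgs)) msgs else TRUE
})
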