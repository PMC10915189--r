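#' Number of animals in an object
#' @param x a [Pedigree-class] or [GenotypeData-class].
#' @return integer count.
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))

#' Animal identifiers
#' @param x a [Pedigree-class] or [GenotypeData-class].
#' @return character vector of ids.
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' Marker map accessor
#' @param x a [GenotypeData-class].
#' @return data.frame with one row per marker.
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' Dosage matrix accessor
#' @param x a [GenotypeData-class].
#' @return numeric matrix, animals x markers.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Inbreeding coefficients
#'
#' Pedigree inbreeding coefficient F for every animal, computed with the
#' Meuwissen & Luo recursion (each animal's diagonal of the numerator
#' relationship matrix is accumulated over its ancestor paths, so no dense
#' matrix is ever formed).  Founders have F = 0; the offspring of parents s
#' and d has F = a(s, d) / 2.
#'
#' @param ped a sorted [Pedigree-class].
#' @return numeric vector of F, one per animal, named by id.
#' @examples
#' ped <- sortPedigree(data.frame(
#'   id = c("s", "d", "o1", "o2", "x"),
#'   sire = c(0, 0, "s", "s", "o1"),
#'   dam  = c(0, 0, "d", "d", "o2")))
#' inbreeding(ped)  # full-sib mating: x has F = 0.25
#' @export
setGeneric("inbreeding", function(ped) standardGeneric("inbreeding"))

#' @describeIn nAnimals number of pedigree records
#' @export
setMethod("nAnimals", "Pedigree", function(x) length(x@id))

#' @describeIn animalIds pedigree record ids
#' @export
setMethod("animalIds", "Pedigree", function(x) x@id)

#' @describeIn nAnimals number of genotyped animals
#' @export
setMethod("nAnimals", "GenotypeData", function(x) nrow(x@dosages))

#' @describeIn animalIds genotyped animal ids
#' @export
setMethod("animalIds", "GenotypeData", function(x) x@animalIds)

#' @describeIn markers marker map of a GenotypeData
#' @export
setMethod("markers", "GenotypeData", function(x) x@map)

#' @describeIn dosages dosage matrix of a GenotypeData
#' @export
setMethod("dosages", "GenotypeData", function(x) {
  d <- x@dosages
  dimnames(d) <- list(x@animalIds, x@map$snp_id)
  d
})

setMethod("show", "Pedigree", function(object) {
  n <- nAnimals(object)
  nf <- sum(object@sire == 0L & object@dam == 0L)
  cat("Pedigree with", n, "animals (", nf, "founders )\n")
  if (!all(is.na(object@generation)))
    cat("  generations:", paste(range(object@generation, na.rm = TRUE),
                                collapse = "-"), "\n")
  if (!all(is.na(object@sex)))
    cat("  sex: ", sum(object@sex == "M", na.rm = TRUE), "M /",
        sum(object@sex == "F", na.rm = TRUE), "F\n")
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@dosages), "animals x",
      ncol(object@dosages), "markers on",
      length(unique(object@map$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(object@dosages))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("VarianceComponents (%s): sigma_a2 = %.4g, sigma_e2 = %.4g\n",
              object@method, object@sigmaA2, object@sigmaE2))
  cat(sprintf("  h2 = %.4f (SE %.4f), %s in %d iterations\n",
              object@h2, object@seH2,
              if (object@converged) "converged" else "NOT converged",
              object@nIter))
})

#' Coerce a Pedigree to a data.frame
#'
#' @param x a [Pedigree-class].
#' @param ... ignored.
#' @return data.frame with columns id, sire, dam (ids, "0" = unknown),
#'   sex, generation.
#' @method as.data.frame Pedigree
#' @export
as.data.frame.Pedigree <- function(x, ...) {
  sid <- ifelse(x@sire == 0L, "0", x@id[pmax(x@sire, 1L)])
  did <- ifelse(x@dam == 0L, "0", x@id[pmax(x@dam, 1L)])
  data.frame(id = x@id, sire = sid, dam = did,
             sex = x@sex, generation = x@generation,
             stringsAsFactors = FALSE)
}

setMethod("as.data.frame", "Pedigree", as.data.frame.Pedigree)
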