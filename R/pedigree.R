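## Pedigree construction and numerator relationship matrices.
## A is built by the tabular method; A-inverse by Henderson's rules with
## inbreeding; F by the Meuwissen & Luo ancestor recursion.

.unknownParent <- function(x) {
  is.na(x) | x == "" | x == "0" | x == 0
}

#' Sort raw pedigree records into a valid Pedigree
#'
#' Reorders records so every parent precedes its offspring (a stable
#' topological sort), normalises unknown parents (`0`, `""`, `NA`) to the
#' internal sentinel, and checks for duplicate ids, missing parent records
#' and cycles.
#'
#' @param raw data.frame with columns `id`, `sire`, `dam` (any type
#'   coercible to character) and optionally `sex` and `generation`.
#' @return a [Pedigree-class].
#' @examples
#' sortPedigree(data.frame(id = c("c", "a", "b"),
#'                         sire = c("a", 0, 0), dam = c("b", 0, 0)))
#' @export
sortPedigree <- function(raw) {
  stopifnot(is.data.frame(raw), all(c("id", "sire", "dam") %in% names(raw)))
  id <- as.character(raw$id)
  if (anyDuplicated(id))
    stop("duplicate animal id: ", id[duplicated(id)][1L])
  sire <- as.character(raw$sire)
  dam <- as.character(raw$dam)
  sire[.unknownParent(sire)] <- NA
  dam[.unknownParent(dam)] <- NA
  known <- c(sire[!is.na(sire)], dam[!is.na(dam)])
  missing <- setdiff(known, id)
  if (length(missing))
    stop("parent id(s) not present in pedigree: ",
         paste(head(missing, 5), collapse = ", "))

  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  ## Kahn topological sort, stable in input order
  parents <- cbind(si, di)
  indeg <- rowSums(!is.na(parents) * 0)  # recomputed below via children lists
  children <- vector("list", n)
  indeg <- integer(n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        if (p == i) stop("pedigree cycle involving id: ", id[i])
        children[[p]] <- c(children[[p]], i)
        indeg[i] <- indeg[i] + 1L
      }
    }
  }
  ## stable order: always take the earliest input record whose parents are
  ## already placed, so an input that is already sorted passes through as-is
  order_out <- integer(n)
  used <- logical(n)
  for (k in seq_len(n)) {
    cand <- which(!used & indeg == 0L)
    if (!length(cand))
      stop("pedigree cycle involving id: ", id[which(!used)[1L]])
    v <- cand[1L]
    used[v] <- TRUE
    order_out[k] <- v
    for (ch in children[[v]]) indeg[ch] <- indeg[ch] - 1L
  }

  rank <- integer(n); rank[order_out] <- seq_len(n)
  so <- si[order_out]; do <- di[order_out]
  sireNew <- ifelse(is.na(so), 0L, rank[so])
  damNew <- ifelse(is.na(do), 0L, rank[do])
  new("Pedigree",
      id = id[order_out],
      sire = as.integer(sireNew),
      dam = as.integer(damNew),
      sex = if ("sex" %in% names(raw)) as.character(raw$sex)[order_out]
            else rep(NA_character_, n),
      generation = if ("generation" %in% names(raw))
                     as.integer(raw$generation)[order_out]
                   else rep(NA_integer_, n))
}

#' Read a pedigree CSV
#'
#' Expects columns id, sire, dam ("0", "" or NA meaning unknown); extra
#' columns `sex`/`generation` are kept.  Records are sorted on read.
#'
#' @param path file path.
#' @return a [Pedigree-class].
#' @export
readPedigree <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", colClasses = "character",
                   comment.char = "#")
  sortPedigree(df)
}

## Mendelian-sampling variance of animal i given parental inbreeding.
## Both parents known: 1/2 - (F_s + F_d)/4; one known: 3/4 - F_p/4;
## none: 1.
.mendelianVariance <- function(sire, dam, F) {
  n <- length(sire)
  d <- numeric(n)
  for (i in seq_len(n)) {
    s <- sire[i]; dd <- dam[i]
    if (s > 0L && dd > 0L) d[i] <- 0.5 - 0.25 * (F[s] + F[dd])
    else if (s > 0L) d[i] <- 0.75 - 0.25 * F[s]
    else if (dd > 0L) d[i] <- 0.75 - 0.25 * F[dd]
    else d[i] <- 1
  }
  d
}

#' @describeIn inbreeding Meuwissen & Luo recursion on a sorted pedigree
#' @export
setMethod("inbreeding", "Pedigree", function(ped) {
  n <- nAnimals(ped)
  sire <- ped@sire; dam <- ped@dam
  F <- numeric(n)
  d <- numeric(n)   # Mendelian-sampling variances, filled as we go
  v <- numeric(n)
  for (i in seq_len(n)) {
    s <- sire[i]; dd <- dam[i]
    d[i] <- if (s > 0L && dd > 0L) 0.5 - 0.25 * (F[s] + F[dd])
            else if (s > 0L) 0.75 - 0.25 * F[s]
            else if (dd > 0L) 0.75 - 0.25 * F[dd]
            else 1
    if (s == 0L || dd == 0L) { F[i] <- 0; next }
    ## a(i,i) = sum_j L_ij^2 d_j accumulated over ancestor paths
    v[i] <- 1
    aii <- 0
    for (j in i:1) {
      vj <- v[j]
      if (vj == 0) next
      aii <- aii + vj * vj * d[j]
      sj <- sire[j]; dj <- dam[j]
      if (sj > 0L) v[sj] <- v[sj] + 0.5 * vj
      if (dj > 0L) v[dj] <- v[dj] + 0.5 * vj
      v[j] <- 0
    }
    F[i] <- aii - 1
  }
  names(F) <- ped@id
  F
})

#' Numerator relationship matrix A (tabular method)
#'
#' Dense pedigree relationship matrix: a(i,i) = 1 + F(i) and
#' a(i,j) = (a(j, sire_i) + a(j, dam_i)) / 2 for j < i, with unknown
#' parents contributing 0.  Intended for test/desk scale; a size guard
#' protects against accidental huge allocations.
#'
#' @param ped sorted [Pedigree-class].
#' @param maxN dense-materialisation guard (default 20000).
#' @return dense symmetric matrix with dimnames = animal ids.
#' @export
aMatrix <- function(ped, maxN = 20000L) {
  n <- nAnimals(ped)
  if (n > maxN)
    stop("pedigree has ", n, " animals; dense A is guarded at ", maxN,
         ". Use aInverse() for large pedigrees.")
  sire <- ped@sire; dam <- ped@dam
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + A[j, s]
      if (d > 0L) row <- row + A[j, d]
      row <- row / 2
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(ped@id, ped@id)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules accounting for inbreeding: for each animal with
#' Mendelian-sampling variance d, add d^-1 * c(1, -1/2, -1/2) outer itself
#' over the (animal, sire, dam) entries that exist.
#'
#' @param ped sorted [Pedigree-class].
#' @param F optional precomputed inbreeding coefficients (from
#'   [inbreeding()]); computed if missing.
#' @return sparse symmetric `Matrix::dsCMatrix` with dimnames = ids.
#' @export
aInverse <- function(ped, F = NULL) {
  n <- nAnimals(ped)
  if (is.null(F)) F <- inbreeding(ped)
  sire <- ped@sire; dam <- ped@dam
  d <- .mendelianVariance(sire, dam, F)
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  pos <- 0L
  for (i in seq_len(n)) {
    trio <- c(i, sire[i], dam[i])
    coefs <- c(1, -0.5, -0.5)[trio > 0L]
    trio <- trio[trio > 0L]
    k <- length(trio)
    w <- 1 / d[i]
    for (a in seq_len(k)) for (b in seq_len(k)) {
      pos <- pos + 1L
      ii[pos] <- trio[a]; jj[pos] <- trio[b]
      xx[pos] <- w * coefs[a] * coefs[b]
    }
  }
  ii <- ii[seq_len(pos)]; jj <- jj[seq_len(pos)]; xx <- xx[seq_len(pos)]
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped@id, ped@id))
  Matrix::forceSymmetric(Ainv)
}

## indices of all ancestors of `idx` (inclusive), for pedigree pruning
.ancestorClosure <- function(ped, idx) {
  keep <- logical(nAnimals(ped))
  keep[idx] <- TRUE
  for (i in rev(seq_len(nAnimals(ped)))) {
    if (!keep[i]) next
    if (ped@sire[i] > 0L) keep[ped@sire[i]] <- TRUE
    if (ped@dam[i] > 0L) keep[ped@dam[i]] <- TRUE
  }
  which(keep)
}

#' Relationship matrix of the genotyped subset (A22) and its inverse
#'
#' Computes the block of A for the genotyped animals by evaluating the
#' tabular method on the pedigree pruned to the genotyped animals and their
#' ancestors, then slicing.  The inverse is obtained by Cholesky
#' factorisation of the dense block.
#'
#' @param ped sorted [Pedigree-class].
#' @param genotypedIds character ids of genotyped animals (subset of the
#'   pedigree ids).
#' @param computeInverse also return the dense inverse (default TRUE).
#' @return list with `A22` (dense, dimnames = genotyped ids in the order
#'   given) and `A22inv` (or NULL).
#' @export
a22Matrix <- function(ped, genotypedIds, computeInverse = TRUE) {
  idx <- match(genotypedIds, ped@id)
  if (anyNA(idx))
    stop("genotyped ids absent from pedigree: ",
         paste(head(genotypedIds[is.na(idx)], 5), collapse = ", "))
  keep <- .ancestorClosure(ped, idx)
  newIdx <- integer(nAnimals(ped))
  newIdx[keep] <- seq_along(keep)
  oldSire <- ped@sire[keep]; oldDam <- ped@dam[keep]
  sub <- new("Pedigree",
             id = ped@id[keep],
             sire = as.integer(ifelse(oldSire == 0L, 0L, newIdx[pmax(oldSire, 1L)])),
             dam = as.integer(ifelse(oldDam == 0L, 0L, newIdx[pmax(oldDam, 1L)])),
             sex = ped@sex[keep],
             generation = ped@generation[keep])
  Asub <- aMatrix(sub)
  A22 <- Asub[genotypedIds, genotypedIds, drop = FALSE]
  A22inv <- NULL
  if (computeInverse) {
    ch <- tryCatch(chol(A22), error = function(e) NULL)
    if (is.null(ch))
      stop("A22 is singular (identical animals?); consider removing ",
           "duplicates or adding a small diagonal jitter")
    A22inv <- chol2inv(ch)
    dimnames(A22inv) <- dimnames(A22)
  }
  list(A22 = A22, A22inv = A22inv)
}
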