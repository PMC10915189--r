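## Synthetic-data generator: multi-generation pedigree, gene-dropped
## genotypes with map-distance recombination (Haldane), and phenotypes
## obeying y = Xb + Za + e with known variance components.

#' Simulation configuration
#'
#' Collects and validates all generator parameters.  Defaults describe a
#' small closed nucleus-herd-like population: a founder cohort, discrete
#' generations produced by random hierarchical mating (every female of the
#' previous generation mated to one random male), ~17% male sex ratio, and
#' the youngest animals genotyped.
#'
#' @param n_founders founder cohort size (>= 2).
#' @param n_generations number of discrete offspring generations (>= 0).
#' @param offspring_per_mating offspring per dam per generation.
#' @param prop_genotyped fraction of animals genotyped, youngest first.
#' @param n_chrom,snps_per_chrom marker panel layout.
#' @param chrom_length_morgans genetic length of each chromosome (Morgans).
#' @param maf_range founder minor-allele-frequency interval, within (0, 0.5].
#' @param n_qtl number of markers given explicit trait effects (0 = purely
#'   polygenic).
#' @param qtl_var_prop fraction of `sigma_a2` carried by the explicit QTL
#'   in the founder population (ignored when `n_qtl = 0`).
#' @param sigma_a2,sigma_e2 additive-genetic and residual variances (trait
#'   units squared).
#' @param n_hys_levels number of herd-year-season contemporary groups.
#' @param sex_effect additive fixed effect of being male (trait units).
#' @param sex_ratio_male probability an animal is male.
#' @param seed integer master seed; every stochastic draw derives from it.
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(n_founders = 100L, n_generations = 3L,
                      offspring_per_mating = 1L, prop_genotyped = 0.5,
                      n_chrom = 3L, snps_per_chrom = 100L,
                      chrom_length_morgans = 1, maf_range = c(0.05, 0.5),
                      n_qtl = 0L, qtl_var_prop = 0.1,
                      sigma_a2 = 1, sigma_e2 = 1,
                      n_hys_levels = 4L, sex_effect = 1,
                      sex_ratio_male = 0.17, seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              offspring_per_mating = as.integer(offspring_per_mating),
              prop_genotyped = prop_genotyped,
              n_chrom = as.integer(n_chrom),
              snps_per_chrom = as.integer(snps_per_chrom),
              chrom_length_morgans = chrom_length_morgans,
              maf_range = maf_range, n_qtl = as.integer(n_qtl),
              qtl_var_prop = qtl_var_prop,
              sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
              n_hys_levels = as.integer(n_hys_levels),
              sex_effect = sex_effect, sex_ratio_male = sex_ratio_male,
              seed = as.integer(seed))
  stopifnot(cfg$n_founders >= 2L, cfg$n_generations >= 0L,
            cfg$offspring_per_mating >= 1L,
            cfg$prop_genotyped >= 0, cfg$prop_genotyped <= 1,
            cfg$n_chrom >= 1L, cfg$snps_per_chrom >= 1L,
            cfg$n_hys_levels >= 1L, cfg$n_qtl >= 0L,
            cfg$sigma_a2 >= 0, cfg$sigma_e2 > 0,
            cfg$qtl_var_prop >= 0, cfg$qtl_var_prop <= 1,
            length(cfg$maf_range) == 2L,
            cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
            cfg$maf_range[1] <= cfg$maf_range[2],
            cfg$sex_ratio_male > 0, cfg$sex_ratio_male < 1,
            abs(cfg$seed) < 2^31 - 10)
  class(cfg) <- "SimConfig"
  cfg
}

## at least one animal of each sex per cohort, else no matings are possible
.drawSexes <- function(n, pMale) {
  sex <- ifelse(runif(n) < pMale, "M", "F")
  if (!any(sex == "M")) sex[sample.int(n, 1L)] <- "M"
  if (!any(sex == "F")) sex[sample.int(n, 1L)] <- "F"
  sex
}

#' Simulate a multi-generation pedigree
#'
#' Founders form generation 0 with unknown parents.  Each later generation
#' is produced by mating every female of the previous generation to one
#' randomly chosen male of that generation (`offspring_per_mating`
#' offspring per dam).  Records come out topologically ordered.
#'
#' @param cfg a [simConfig()].
#' @return a [Pedigree-class] with sex and generation filled in.
#' @export
simulatePedigree <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (cfg$n_founders < 2L) stop("need at least 2 founders to mate")
  set.seed(cfg$seed)
  id <- sprintf("G0_%04d", seq_len(cfg$n_founders))
  sire <- integer(cfg$n_founders)
  dam <- integer(cfg$n_founders)
  sex <- .drawSexes(cfg$n_founders, cfg$sex_ratio_male)
  gen <- integer(cfg$n_founders)

  prevIdx <- seq_len(cfg$n_founders)
  for (g in seq_len(cfg$n_generations)) {
    dams <- prevIdx[sex[prevIdx] == "F"]
    sires <- prevIdx[sex[prevIdx] == "M"]
    nOff <- length(dams) * cfg$offspring_per_mating
    mateSire <- sires[sample.int(length(sires), length(dams), replace = TRUE)]
    offSire <- rep(mateSire, each = cfg$offspring_per_mating)
    offDam <- rep(dams, each = cfg$offspring_per_mating)
    offIdx <- length(id) + seq_len(nOff)
    id <- c(id, sprintf("G%d_%04d", g, seq_len(nOff)))
    sire <- c(sire, offSire)
    dam <- c(dam, offDam)
    sex <- c(sex, .drawSexes(nOff, cfg$sex_ratio_male))
    gen <- c(gen, rep(g, nOff))
    prevIdx <- offIdx
  }
  new("Pedigree", id = id, sire = as.integer(sire), dam = as.integer(dam),
      sex = sex, generation = as.integer(gen))
}

## one gamete: recombine the two parental haplotypes of one chromosome.
## gpos: marker positions in Morgans. Haldane: crossovers ~ Poisson(L),
## positions uniform on (0, L); starting haplotype chosen at random.
.gamete <- function(h1, h2, gpos, L) {
  k <- rpois(1L, L)
  phase <- if (k == 0L) 0L else findInterval(gpos, sort(runif(k, 0, L)))
  phase <- (phase + sample.int(2L, 1L) - 1L) %% 2L
  ifelse(phase == 0L, h1, h2)
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder haplotype alleles are drawn per marker at a frequency sampled
#' from `maf_range`; gametes are formed with Haldane-model recombination
#' (crossover count Poisson with mean equal to the chromosome map length).
#' Only the youngest `ceil(prop_genotyped * N)` animals carry genotypes in
#' the returned object; the complete all-animal dosage matrix is kept in
#' `metadata(x)$trueDosages` for the phenotype simulator.
#'
#' Dosages are recoded so the counted allele is the minor allele in the
#' genotyped subset (ties broken by allele label), matching the PLINK
#' reader convention, so written datasets round-trip exactly.
#'
#' @param ped a [Pedigree-class] from [simulatePedigree()].
#' @param cfg the same [simConfig()].
#' @return a [GenotypeData-class].
#' @export
simulateGenotypes <- function(ped, cfg) {
  stopifnot(is(ped, "Pedigree"), inherits(cfg, "SimConfig"))
  if (cfg$chrom_length_morgans <= 0)
    stop("chrom_length_morgans must be > 0")
  set.seed(cfg$seed + 1L)
  n <- nAnimals(ped)
  m <- cfg$n_chrom * cfg$snps_per_chrom
  mc <- cfg$snps_per_chrom
  L <- cfg$chrom_length_morgans
  gposChrom <- (seq_len(mc) - 0.5) / mc * L

  map <- data.frame(
    chrom = rep(seq_len(cfg$n_chrom), each = mc),
    snp_id = sprintf("SNP%d_%04d", rep(seq_len(cfg$n_chrom), each = mc),
                     rep(seq_len(mc), cfg$n_chrom)),
    cm = rep(gposChrom * 100, cfg$n_chrom),
    bp = rep(round(gposChrom / L * 1e8) + 1, cfg$n_chrom),
    allele1 = "A", allele2 = "B",
    stringsAsFactors = FALSE)

  p <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  founder <- ped@sire == 0L & ped@dam == 0L
  nf <- sum(founder)
  H1[founder, ] <- matrix(rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
  H2[founder, ] <- matrix(rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)

  cols <- split(seq_len(m), map$chrom)
  for (i in which(!founder)) {
    s <- ped@sire[i]; d <- ped@dam[i]
    for (cc in cols) {
      H1[i, cc] <- .gamete(H1[s, cc], H2[s, cc], gposChrom, L)
      H2[i, cc] <- .gamete(H1[d, cc], H2[d, cc], gposChrom, L)
    }
  }
  allDos <- H1 + H2

  nG <- ceiling(cfg$prop_genotyped * n)
  gIdx <- if (nG > 0) tail(seq_len(n), nG) else integer(0)
  dos <- allDos[gIdx, , drop = FALSE]
  storage.mode(dos) <- "double"

  ## recode to minor-allele coding based on the genotyped subset
  if (length(gIdx)) {
    freq <- colMeans(dos) / 2
    flip <- freq > 0.5
    if (any(flip)) {
      dos[, flip] <- 2 - dos[, flip]
      allDos[, flip] <- 2L - allDos[, flip]
      tmp <- map$allele1[flip]
      map$allele1[flip] <- map$allele2[flip]
      map$allele2[flip] <- tmp
    }
  }
  storage.mode(allDos) <- "double"
  new("GenotypeData", dosages = dos, map = map,
      animalIds = ped@id[gIdx],
      metadata = list(trueDosages = allDos, founderFreq = p))
}

#' Simulate phenotypes and true breeding values
#'
#' Breeding values are the sum of a polygenic term built by gene flow down
#' the pedigree (founders ~ N(0, sigma_poly); offspring = parent average +
#' Mendelian sampling with variance 0.5 * sigma_poly * (1 - (F_s + F_d)/2))
#' and, when `n_qtl > 0`, marker-dosage QTL effects rescaled so QTL +
#' polygenic variance equals `sigma_a2` in the founder cohort.  Phenotype =
#' herd-year-season effect + sex effect + breeding value + residual.
#'
#' @param ped a [Pedigree-class].
#' @param geno the matching [GenotypeData-class] (used for QTL dosages).
#' @param cfg the same [simConfig()].
#' @return list with `phenotypes` (data.frame id, hys, sex, trait) and
#'   `truth` (class `TrueValues`: breeding_values, qtl_positions,
#'   qtl_effects, realized_h2, hys_effects, residuals).
#' @export
simulatePhenotypes <- function(ped, geno, cfg) {
  stopifnot(is(ped, "Pedigree"), inherits(cfg, "SimConfig"))
  set.seed(cfg$seed + 2L)
  n <- nAnimals(ped)
  qtlProp <- if (cfg$n_qtl > 0L) cfg$qtl_var_prop else 0
  sigmaPoly <- cfg$sigma_a2 * (1 - qtlProp)

  ## QTL component from true all-animal dosages
  qtlPos <- integer(0); alpha <- numeric(0)
  qtlValue <- numeric(n)
  if (cfg$n_qtl > 0L) {
    stopifnot(is(geno, "GenotypeData"))
    trueDos <- geno@metadata$trueDosages
    m <- ncol(trueDos)
    if (cfg$n_qtl > m) stop("n_qtl exceeds the number of simulated markers")
    founder <- ped@sire == 0L & ped@dam == 0L
    qtlPos <- sort(sample.int(m, cfg$n_qtl))
    alpha <- rnorm(cfg$n_qtl)
    raw <- drop(trueDos[, qtlPos, drop = FALSE] %*% alpha)
    vf <- var(raw[founder])
    if (!is.finite(vf) || vf <= 0)
      stop("sampled QTL are monomorphic in founders; increase maf_range ",
           "or founder count")
    alpha <- alpha * sqrt(cfg$qtl_var_prop * cfg$sigma_a2 / vf)
    qtlValue <- drop(trueDos[, qtlPos, drop = FALSE] %*% alpha)
    qtlValue <- qtlValue - mean(qtlValue[founder])
  }

  F <- inbreeding(ped)
  poly <- numeric(n)
  for (i in seq_len(n)) {
    s <- ped@sire[i]; d <- ped@dam[i]
    if (s == 0L && d == 0L) {
      poly[i] <- rnorm(1L, 0, sqrt(sigmaPoly))
    } else {
      pa <- (if (s > 0L) poly[s] else 0) / 2 + (if (d > 0L) poly[d] else 0) / 2
      Fs <- if (s > 0L) F[s] else 0
      Fd <- if (d > 0L) F[d] else 0
      msv <- 0.5 * sigmaPoly * (1 - (Fs + Fd) / 2)
      ## unknown parents: the missing half-parental contribution goes back
      ## into the sampling term so Var(a_i) stays at sigmaPoly in the base
      if (s == 0L) msv <- msv + sigmaPoly / 4
      if (d == 0L) msv <- msv + sigmaPoly / 4
      poly[i] <- pa + rnorm(1L, 0, sqrt(msv))
    }
  }
  a <- poly + qtlValue

  hys <- sample.int(cfg$n_hys_levels, n, replace = TRUE)
  hysEff <- rnorm(cfg$n_hys_levels, 0,
                  0.5 * sqrt(cfg$sigma_a2 + cfg$sigma_e2))
  sexEff <- ifelse(ped@sex == "M", cfg$sex_effect, 0)
  e <- rnorm(n, 0, sqrt(cfg$sigma_e2))
  y <- hysEff[hys] + sexEff + a + e

  phen <- data.frame(id = ped@id, hys = hys, sex = ped@sex, trait = y,
                     stringsAsFactors = FALSE)
  va <- var(a); ve <- var(e)
  truth <- structure(list(
    breeding_values = setNames(a, ped@id),
    qtl_positions = qtlPos,
    qtl_effects = alpha,
    realized_h2 = if (va + ve > 0) va / (va + ve) else 0,
    hys_effects = hysEff,
    residuals = e), class = "TrueValues")
  list(phenotypes = phen, truth = truth)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper chaining [simulatePedigree()], [simulateGenotypes()]
#' and [simulatePhenotypes()].
#'
#' @param cfg a [simConfig()].
#' @return list with `pedigree`, `genotypes`, `phenotypes`, `truth`.
#' @export
simulateDataset <- function(cfg) {
  ped <- simulatePedigree(cfg)
  geno <- simulateGenotypes(ped, cfg)
  ph <- simulatePhenotypes(ped, geno, cfg)
  list(pedigree = ped, genotypes = geno,
       phenotypes = ph$phenotypes, truth = ph$truth)
}

#' Write a simulated dataset to disk
#'
#' Emits `pedigree.csv` (id, sire, dam; 0 = unknown), `phenotypes.csv`
#' (id, hys, sex, trait), PLINK text `genotypes.ped`/`genotypes.map`
#' (missing calls encoded "0 0") and, when truth is supplied, `truth.tsv`.
#' Genotypes are written in minor-allele coding so that
#' [readPlinkText()] recovers the dosage matrix exactly.
#'
#' @param ped [Pedigree-class].
#' @param geno [GenotypeData-class].
#' @param phen phenotype data.frame (id, hys, sex, trait).
#' @param dir output directory (created if needed).
#' @param truth optional `TrueValues` list.
#' @param overwrite refuse to clobber existing files unless TRUE.
#' @return invisibly, a named character vector of the files written.
#' @export
writeDataset <- function(ped, geno, phen, dir, truth = NULL,
                         overwrite = FALSE) {
  stopifnot(all(phen$id %in% animalIds(ped)),
            all(animalIds(geno) %in% animalIds(ped)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(pedigree = file.path(dir, "pedigree.csv"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             ped = file.path(dir, "genotypes.ped"),
             map = file.path(dir, "genotypes.map"),
             truth = file.path(dir, "truth.tsv"))
  if (is.null(truth)) files <- files[names(files) != "truth"]
  exists <- file.exists(files)
  if (any(exists) && !overwrite)
    stop("refusing to overwrite existing file(s): ",
         paste(basename(files[exists]), collapse = ", "),
         " (set overwrite = TRUE)")

  pd <- as.data.frame(ped)
  write.table(pd[, c("id", "sire", "dam")], files["pedigree"],
              sep = ",", row.names = FALSE, quote = FALSE)
  write.table(phen, files["phenotypes"], sep = ",", row.names = FALSE,
              quote = FALSE)

  map <- markers(geno)
  write.table(map[, c("chrom", "snp_id", "cm", "bp")], files["map"],
              sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  d <- geno@dosages
  sexCode <- c(M = 1L, F = 2L)[ped@sex[match(animalIds(geno), ped@id)]]
  sexCode[is.na(sexCode)] <- 0L
  con <- file(files["ped"], "w")
  on.exit(close(con))
  a1 <- map$allele1; a2 <- map$allele2
  for (i in seq_len(nrow(d))) {
    g <- d[i, ]
    first <- ifelse(is.na(g), "0", ifelse(g >= 1, a1, a2))
    second <- ifelse(is.na(g), "0", ifelse(g == 2, a1, a2))
    al <- character(2L * ncol(d))
    al[c(TRUE, FALSE)] <- first
    al[c(FALSE, TRUE)] <- second
    cat(animalIds(geno)[i], animalIds(geno)[i], "0", "0", sexCode[i], "-9",
        al, "\n", file = con, sep = " ")
  }
  if (!is.null(truth)) {
    tv <- data.frame(id = names(truth$breeding_values),
                     breeding_value = unname(truth$breeding_values))
    write.table(tv, files["truth"], sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  invisible(files)
}
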