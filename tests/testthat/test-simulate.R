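test_that("simulatePedigree honours counts, ordering and degenerate cases", {
  cfg <- simConfig(n_founders = 2, n_generations = 1,
                   offspring_per_mating = 3, seed = 5)
  ped <- simulatePedigree(cfg)
  expect_equal(nAnimals(ped), 5L)
  expect_equal(sum(ped@sire > 0 & ped@dam > 0), 3L)
  ## sires male, dams female, parents before offspring
  off <- which(ped@sire > 0)
  expect_true(all(ped@sex[ped@sire[off]] == "M"))
  expect_true(all(ped@sex[ped@dam[off]] == "F"))
  expect_true(all(ped@sire[off] < off & ped@dam[off] < off))

  ## founders only
  ped0 <- simulatePedigree(simConfig(n_founders = 10, n_generations = 0,
                                     seed = 1))
  expect_equal(nAnimals(ped0), 10L)
  expect_true(all(ped0@sire == 0 & ped0@dam == 0))

  expect_error(simConfig(n_founders = 1), "n_founders")
})

test_that("the whole dataset is reproducible from the seed", {
  cfg <- simConfig(n_founders = 30, n_generations = 2, prop_genotyped = 0.5,
                   n_chrom = 2, snps_per_chrom = 20, n_qtl = 3, seed = 99)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(as.data.frame(d1$pedigree), as.data.frame(d2$pedigree))
  expect_identical(d1$genotypes@dosages, d2$genotypes@dosages)
  expect_identical(d1$phenotypes, d2$phenotypes)
  expect_identical(d1$truth$breeding_values, d2$truth$breeding_values)
})

test_that("gene dropping respects founder frequencies and genotyped subset", {
  ## one SNP at founder frequency 0.5: mean dosage ~ 1 within 3 SE
  cfg <- simConfig(n_founders = 800, n_generations = 0, prop_genotyped = 1,
                   n_chrom = 1, snps_per_chrom = 1,
                   maf_range = c(0.5, 0.5), seed = 21)
  g <- simulateGenotypes(simulatePedigree(cfg), cfg)
  se3 <- 3 * sqrt(2 * 0.5 * 0.5 / 800)
  expect_lt(abs(mean(dosages(g)) - 1), se3)

  ## nobody genotyped: empty matrix, map retained
  cfg0 <- simConfig(n_founders = 20, n_generations = 1, prop_genotyped = 0,
                    n_chrom = 2, snps_per_chrom = 5, seed = 3)
  g0 <- simulateGenotypes(simulatePedigree(cfg0), cfg0)
  expect_equal(nrow(g0@dosages), 0L)
  expect_equal(nrow(markers(g0)), 10L)

  cfg0bad <- cfg0
  cfg0bad$chrom_length_morgans <- 0
  expect_error(simulateGenotypes(simulatePedigree(cfg0), cfg0bad),
               "chrom_length_morgans")

  ## genotyped subset = youngest animals first
  cfg2 <- simConfig(n_founders = 20, n_generations = 2, prop_genotyped = 0.3,
                    n_chrom = 1, snps_per_chrom = 5, seed = 4)
  ped2 <- simulatePedigree(cfg2)
  g2 <- simulateGenotypes(ped2, cfg2)
  nG <- ceiling(0.3 * nAnimals(ped2))
  expect_equal(animalIds(g2), tail(animalIds(ped2), nG))
})

test_that("phenotypes carry the configured variance components", {
  ## no genetics: breeding values all zero, variance ~ sigma_e2
  cfg <- simConfig(n_founders = 500, n_generations = 0, prop_genotyped = 0,
                   sigma_a2 = 0, sigma_e2 = 4, n_qtl = 0, seed = 8)
  ped <- simulatePedigree(cfg)
  r <- simulatePhenotypes(ped, NULL, cfg)
  expect_true(all(r$truth$breeding_values == 0))
  expect_lt(abs(var(r$truth$residuals) - 4), 3 * 4 * sqrt(2 / 499))

  ## productive-trait-scale variances: var(a + e) ~ 134.05 at n = 2000
  cfg2 <- simConfig(n_founders = 2000, n_generations = 0, prop_genotyped = 0,
                    sigma_a2 = 66.74, sigma_e2 = 67.31, n_qtl = 0, seed = 12)
  ped2 <- simulatePedigree(cfg2)
  r2 <- simulatePhenotypes(ped2, NULL, cfg2)
  ae <- r2$truth$breeding_values + r2$truth$residuals
  expect_lt(abs(var(ae) - 134.05), 3 * 134.05 * sqrt(2 / 1999))

  ## QTL count guard
  cfg3 <- simConfig(n_founders = 30, n_generations = 1, prop_genotyped = 1,
                    n_chrom = 1, snps_per_chrom = 5, n_qtl = 6, seed = 2)
  ped3 <- simulatePedigree(cfg3)
  g3 <- simulateGenotypes(ped3, cfg3)
  expect_error(simulatePhenotypes(ped3, g3, cfg3), "n_qtl")
})

test_that("offspring breeding values regress on parents with slope 1/2", {
  cfg <- simConfig(n_founders = 6000, n_generations = 1,
                   offspring_per_mating = 1, prop_genotyped = 0,
                   sigma_a2 = 1, sigma_e2 = 1, n_qtl = 0, seed = 31)
  ped <- simulatePedigree(cfg)
  r <- simulatePhenotypes(ped, NULL, cfg)
  a <- r$truth$breeding_values
  off <- which(ped@dam > 0)
  parent <- c(a[ped@sire[off]], a[ped@dam[off]])
  child <- c(a[off], a[off])
  slope <- coef(lm(child ~ parent))[2]
  expect_gt(length(child), 9000)           # ~10^4 parent-offspring pairs
  expect_lt(abs(slope - 0.5), 0.03)
})

test_that("founder additive variance approaches sigma_a2", {
  cfg <- simConfig(n_founders = 2000, n_generations = 0, prop_genotyped = 0,
                   sigma_a2 = 3, sigma_e2 = 1, n_qtl = 0, seed = 17)
  r <- simulatePhenotypes(simulatePedigree(cfg), NULL, cfg)
  se3 <- 3 * 3 * sqrt(2 / 1999)
  expect_lt(abs(var(r$truth$breeding_values) - 3), se3)
})

test_that("mean inbreeding rises across generations in a closed population", {
  meanF <- matrix(0, 10, 5)
  for (rep in 1:10) {
    cfg <- simConfig(n_founders = 16, n_generations = 4,
                     offspring_per_mating = 2, prop_genotyped = 0,
                     seed = 700 + rep)
    ped <- simulatePedigree(cfg)
    F <- inbreeding(ped)
    meanF[rep, ] <- tapply(F, ped@generation, mean)
  }
  avg <- colMeans(meanF)
  expect_true(all(diff(avg) >= -1e-9))
  expect_gt(avg[5], avg[1])
})

test_that("writeDataset round-trips through the package readers", {
  cfg <- simConfig(n_founders = 20, n_generations = 2, prop_genotyped = 0.6,
                   n_chrom = 2, snps_per_chrom = 8, seed = 44)
  dat <- simulateDataset(cfg)
  dir <- tempfile()
  writeDataset(dat$pedigree, dat$genotypes, dat$phenotypes, dir,
               truth = dat$truth)
  g2 <- readPlinkText(file.path(dir, "genotypes.ped"),
                      file.path(dir, "genotypes.map"))
  expect_equal(unname(dosages(g2)), unname(dosages(dat$genotypes)))
  expect_equal(animalIds(g2), animalIds(dat$genotypes))
  ped2 <- readPedigree(file.path(dir, "pedigree.csv"))
  expect_equal(animalIds(ped2), animalIds(dat$pedigree))
  ## refuses to clobber without the flag
  expect_error(writeDataset(dat$pedigree, dat$genotypes, dat$phenotypes,
                            dir), "overwrite")
  expect_silent(writeDataset(dat$pedigree, dat$genotypes, dat$phenotypes,
                             dir, overwrite = TRUE))
})

test_that("missing dosages are written as 0 0 and read back as NA", {
  d <- matrix(c(0, 1, 2, NA, 1, 0), 2, 3)
  g <- makeGeno(d)
  phen <- data.frame(id = animalIds(g), hys = 1, sex = "F", trait = 0)
  ped <- sortPedigree(data.frame(id = animalIds(g), sire = 0, dam = 0))
  dir <- tempfile()
  writeDataset(ped, g, phen, dir)
  line1 <- readLines(file.path(dir, "genotypes.ped"))[2]
  expect_match(line1, " 0 0")
  g2 <- readPlinkText(file.path(dir, "genotypes.ped"),
                      file.path(dir, "genotypes.map"))
  expect_true(is.na(dosages(g2)[2, 2]))
  ## empty genotype set still writes a valid pair of files
  g0 <- makeGeno(matrix(numeric(0), 0, 3))
  dir0 <- tempfile()
  writeDataset(ped, g0, phen, dir0)
  expect_equal(length(readLines(file.path(dir0, "genotypes.ped"))), 0L)
  expect_equal(nrow(read.table(file.path(dir0, "genotypes.map"))), 3L)
})
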