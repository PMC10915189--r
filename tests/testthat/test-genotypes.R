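test_that("readPlinkText applies the minor-allele counting convention", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("1\tm1\t0\t100"), file.path(dir, "t.map"))
  ## alleles A A / A G: A is the major allele (3 of 4), so G is counted;
  ## dosage of G = c(0, 1)
  writeLines(c("f1 i1 0 0 1 -9 A A",
               "f2 i2 0 0 2 -9 A G"), file.path(dir, "t.ped"))
  g <- readPlinkText(file.path(dir, "t.ped"), file.path(dir, "t.map"))
  expect_equal(unname(dosages(g)[, 1]), c(0, 1))
  expect_equal(markers(g)$allele1, "G")

  ## tie at 0.5: lexicographically smaller allele is counted
  writeLines(c("f1 i1 0 0 1 -9 A G",
               "f2 i2 0 0 2 -9 G A"), file.path(dir, "t.ped"))
  g2 <- readPlinkText(file.path(dir, "t.ped"), file.path(dir, "t.map"))
  expect_equal(markers(g2)$allele1, "A")
  expect_equal(unname(dosages(g2)[, 1]), c(1, 1))

  ## "0 0" is missing; ragged line is an error naming the line
  writeLines(c("f1 i1 0 0 1 -9 0 0",
               "f2 i2 0 0 2 -9 G G"), file.path(dir, "t.ped"))
  g3 <- readPlinkText(file.path(dir, "t.ped"), file.path(dir, "t.map"))
  expect_true(is.na(dosages(g3)[1, 1]))
  writeLines(c("f1 i1 0 0 1 -9 A"), file.path(dir, "t.ped"))
  expect_error(readPlinkText(file.path(dir, "t.ped"),
                             file.path(dir, "t.map")), "line 1")
})

test_that("alleleFrequencies handles missing and monomorphic markers", {
  g <- makeGeno(matrix(c(0, 1, 2, 2,
                         2, 2, 2, 2,
                         1, NA, 1, NA), 4, 3))
  p <- alleleFrequencies(g)
  expect_equal(p[1], 0.625)       # MAF 0.375
  expect_equal(p[2], 1)           # monomorphic, MAF 0
  expect_equal(p[3], 0.5)         # mean over non-missing
  gAllMiss <- makeGeno(matrix(NA_real_, 2, 1))
  expect_warning(pm <- alleleFrequencies(gAllMiss), "undefined")
  expect_true(is.na(pm))
})

test_that("hweExactTest matches enumeration and known cases", {
  ## two individuals, alleles 2+2: configurations {0, 2} hets
  expect_equal(hweExactTest(0, 2, 0), 1)
  ## monomorphic: single configuration
  expect_equal(hweExactTest(10, 0, 0), 1)
  ## direct-factorial enumeration oracle at (25, 50, 25)
  enumP <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    nA <- 2 * nAA + nAa
    hets <- seq(min(nA, 2 * n - nA) %% 2, min(nA, 2 * n - nA), by = 2)
    lp <- vapply(hets, function(h) {
      aa <- (nA - h) / 2
      lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) -
        lgamma(n - aa - h + 1) + h * log(2) +
        lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
    }, numeric(1))
    pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
    obs <- pr[match(nAa, hets)]
    sum(pr[pr <= obs * (1 + 1e-12)])
  }
  for (case in list(c(25, 50, 25), c(40, 20, 40), c(5, 60, 35),
                    c(1, 1, 98))) {
    expect_equal(hweExactTest(case[1], case[2], case[3]),
                 enumP(case[1], case[2], case[3]), tolerance = 1e-10,
                 info = paste(case, collapse = ","))
  }
})

test_that("HWE exact p-values are super-uniform under the null", {
  set.seed(202)
  nSim <- 10000
  n <- 100; p <- 0.3
  geno <- matrix(rbinom(nSim * n, 2, p), n, nSim)
  pv <- vapply(seq_len(nSim), function(j) {
    x <- geno[, j]
    hweExactTest(sum(x == 2), sum(x == 1), sum(x == 0))
  }, numeric(1))
  expect_true(all(pv >= 0 & pv <= 1))
  expect_lte(mean(pv < 0.05), 0.06)
})

test_that("qcFilter removes markers in the fixed order and is idempotent", {
  set.seed(9)
  n <- 60
  clean <- matrix(rbinom(n * 5, 2, 0.4), n, 5)
  lowCall <- c(rbinom(n - 12, 2, 0.4), rep(NA, 12))      # call rate 0.8
  lowMaf <- c(1, rep(0, n - 1))                          # MAF 1/120 < 0.01
  hweBad <- rep(1, n)                                    # all hets
  g <- makeGeno(cbind(clean, lowCall, lowMaf, hweBad))
  r <- qcFilter(g)
  expect_equal(unname(r$report$removed),
               c(1L, 1L, 1L))
  expect_equal(r$report$n_snps_after, 5L)
  expect_equal(r$report$n_snps_before - sum(r$report$removed),
               r$report$n_snps_after)
  ## animals never removed
  expect_equal(nAnimals(r$genotypes), n)
  ## idempotent
  r2 <- qcFilter(r$genotypes)
  expect_equal(unname(r2$report$removed), c(0L, 0L, 0L))
  expect_identical(r2$genotypes@dosages, r$genotypes@dosages)
  ## everything failing is an error
  expect_error(qcFilter(makeGeno(matrix(0, 10, 2))), "no markers")
})

test_that("imputeMean preserves column means exactly", {
  g <- makeGeno(matrix(c(0, NA, 2, 1, 1, 1), 3, 2))
  gi <- imputeMean(g)
  expect_equal(unname(dosages(gi)[, 1]), c(0, 1, 2))
  expect_false(anyNA(dosages(gi)))
  expect_equal(colMeans(dosages(gi)),
               colMeans(dosages(g), na.rm = TRUE), ignore_attr = TRUE)
  ## complete data passes through unchanged
  gc <- makeGeno(matrix(c(0, 1, 2, 0), 2, 2))
  expect_identical(dosages(imputeMean(gc)), dosages(gc))
})

test_that("vanRadenG matches hand algebra and expectation checks", {
  ## 1 SNP, p = 0.5, dosages 0/2: G = [[2,-2],[-2,2]]
  vr <- vanRadenG(matrix(c(0, 2), 2, 1))
  expect_equal(unname(vr$G), matrix(c(2, -2, -2, 2), 2))
  expect_equal(vr$k, 0.5)
  ## centred W has zero column sums (exact)
  set.seed(33)
  d <- matrix(rbinom(200 * 60, 2, runif(60, 0.1, 0.9)), 200, 60,
              byrow = TRUE)
  vr2 <- vanRadenG(d)
  expect_lt(max(abs(colSums(vr2$W))), 1e-10)
  ## HWE genotypes, many markers: mean diag(G) ~ 1
  set.seed(34)
  m <- 5000
  p <- runif(m, 0.1, 0.9)
  dh <- sapply(p, function(pp) rbinom(300, 2, pp))
  vr3 <- vanRadenG(dh)
  expect_lt(abs(mean(diag(vr3$G)) - 1), 0.05)
  ## duplicate animals give identical G rows
  ddup <- rbind(d[1, ], d[1, ], d[2, ])
  G <- vanRadenG(ddup)$G
  expect_equal(G[1, ], G[2, ], ignore_attr = TRUE)
  expect_error(vanRadenG(matrix(2, 3, 2)), "monomorphic")
})

test_that("blendTuneG is a fixed point at A22 and always positive definite", {
  set.seed(51)
  ped <- randomPed(120, nFounders = 15, seed = 51)
  ids <- tail(animalIds(ped), 40)
  A22 <- a22Matrix(ped, ids, computeInverse = FALSE)$A22
  ## G = A22: tuning is the identity and blending is convex
  r <- blendTuneG(A22, A22)
  expect_equal(r$Gstar, A22, tolerance = 1e-10)
  ## blendW = 1 with tuning off returns G unchanged
  d <- matrix(rbinom(40 * 300, 2, rep(runif(300, 0.1, 0.9), each = 40)),
              40, 300)
  G <- vanRadenG(d)$G
  r2 <- blendTuneG(G, A22, blendW = 1, tune = FALSE)
  expect_equal(r2$Gstar, G, ignore_attr = TRUE)
  ## random valid input: minimum eigenvalue > 0
  r3 <- blendTuneG(G, A22, blendW = 0.95)
  expect_gt(min(eigen(r3$Gstar, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  expect_error(blendTuneG(G, A22, blendW = 0), "blendW")
})
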