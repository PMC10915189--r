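test_that("buildDesign produces full-rank incidence matrices", {
  ped <- sortPedigree(data.frame(id = sprintf("a%d", 1:6), sire = 0, dam = 0))
  phen <- data.frame(id = sprintf("a%d", 1:6),
                     hys = rep(1:2, each = 3),
                     sex = rep(c("M", "F"), 3),
                     trait = rnorm(6))
  des <- buildDesign(phen, ped)
  ## intercept + 1 HYS contrast + 1 sex contrast
  expect_equal(ncol(des$X), 3L)
  expect_equal(qr(des$X)$rank, 3L)
  ## one record per animal: Z is row selection
  expect_equal(as.matrix(des$Z)[, 1:6],
               diag(6), ignore_attr = TRUE)
  ## repeated records duplicate the Z row
  phen2 <- rbind(phen, phen[1, ])
  des2 <- buildDesign(phen2, ped)
  expect_equal(as.matrix(des2$Z)[7, ], as.matrix(des2$Z)[1, ])
  ## unknown animal is an error listing the id
  phen3 <- phen; phen3$id[1] <- "ghost"
  expect_error(buildDesign(phen3, ped), "ghost")
})

test_that("hInverse reduces to A-inverse without genomic information", {
  ped <- randomPed(60, nFounders = 10, seed = 2)
  Ai <- aInverse(ped)
  expect_identical(hInverse(Ai, matrix(0, 0, 0), matrix(0, 0, 0),
                            integer(0)), Ai)
  ## Gstar = A22 makes the correction vanish
  ids <- tail(animalIds(ped), 20)
  a22 <- a22Matrix(ped, ids)
  gIdx <- match(ids, animalIds(ped))
  H0 <- hInverse(Ai, a22$A22inv, a22$A22inv, gIdx)
  expect_lt(max(abs(as.matrix(H0) - as.matrix(Ai))), 1e-10)
})

test_that("blockwise H-inverse matches the dense joint-distribution oracle", {
  set.seed(77)
  ped <- randomPed(100, nFounders = 15, seed = 77)
  ids <- tail(animalIds(ped), 30)
  gIdx <- match(ids, animalIds(ped))
  A <- aMatrix(ped)
  a22 <- a22Matrix(ped, ids)
  d <- matrix(rbinom(30 * 400, 2, rep(runif(400, 0.2, 0.8), each = 30)),
              30, 400)
  G <- vanRadenG(d)$G
  bt <- blendTuneG(G, a22$A22)
  Hi <- hInverse(aInverse(ped), a22$A22inv, bt$GstarInv, gIdx)
  Hdense <- denseH(A, bt$Gstar, gIdx)
  expect_lt(max(abs(as.matrix(Hi) - solve(Hdense))), 1e-6)
})

test_that("solveMME reproduces closed forms and the dense GLS oracle", {
  ## single animal, known zero mean: scalar shrinkage y * sa/(sa+se)
  ped1 <- sortPedigree(data.frame(id = "x", sire = 0, dam = 0))
  X0 <- matrix(nrow = 1, ncol = 0)
  Z1 <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 1))
  sol <- solveMME(2, X0, Z1, aInverse(ped1), sigmaA2 = 3, sigmaE2 = 1)
  expect_equal(unname(sol$a), 2 * 3 / (3 + 1))
  ## sigma_a2 -> 0: all GEBVs -> 0
  solSmall <- solveMME(2, X0, Z1, aInverse(ped1), 1e-9, 1)
  expect_lt(abs(solSmall$a), 1e-8)

  ## 300-animal simulated set vs dense GLS
  cfg <- simConfig(n_founders = 120, n_generations = 2,
                   offspring_per_mating = 1, prop_genotyped = 0,
                   sigma_a2 = 2, sigma_e2 = 3, seed = 61)
  dat <- simulateDataset(cfg)
  des <- buildDesign(dat$phenotypes, dat$pedigree)
  Ai <- aInverse(dat$pedigree)
  sol2 <- solveMME(des$y, des$X, des$Z, Ai, 2, 3)
  A <- aMatrix(dat$pedigree)
  Zm <- as.matrix(des$Z)
  V <- 2 * Zm %*% A %*% t(Zm) + 3 * diag(length(des$y))
  Vi <- solve(V)
  bGls <- solve(crossprod(des$X, Vi %*% des$X),
                crossprod(des$X, Vi %*% des$y))
  aGls <- 2 * A %*% t(Zm) %*% Vi %*% (des$y - des$X %*% bGls)
  expect_lt(max(abs(sol2$b - bGls)), 1e-6)
  expect_lt(max(abs(sol2$a - aGls)), 1e-6)
  ## first MME block: residuals orthogonal to the fixed-effect columns
  expect_lt(max(abs(crossprod(des$X, sol2$residuals))), 1e-6)
})

test_that("a record-less progeny-less animal gets the parent-average GEBV", {
  cfg <- simConfig(n_founders = 40, n_generations = 2, prop_genotyped = 0,
                   sigma_a2 = 2, sigma_e2 = 2, seed = 13)
  dat <- simulateDataset(cfg)
  ## append a phantom offspring of two phenotyped animals
  df <- as.data.frame(dat$pedigree)
  sire <- df$id[df$sex == "M"][1]
  dam <- df$id[df$sex == "F"][1]
  df2 <- rbind(df[, 1:3],
               data.frame(id = "phantom", sire = sire, dam = dam))
  ped <- sortPedigree(df2)
  des <- buildDesign(dat$phenotypes, ped)
  sol <- solveMME(des$y, des$X, des$Z, aInverse(ped), 2, 2)
  expect_equal(unname(sol$a["phantom"]),
               unname((sol$a[sire] + sol$a[dam]) / 2), tolerance = 1e-10)
})

test_that("aiReml agrees with direct REML likelihood maximisation", {
  cfg <- simConfig(n_founders = 50, n_generations = 2, prop_genotyped = 0,
                   sigma_a2 = 3, sigma_e2 = 2, seed = 11)
  dat <- simulateDataset(cfg)
  des <- buildDesign(dat$phenotypes, dat$pedigree)
  vc <- aiReml(des$y, des$X, des$Z, aInverse(dat$pedigree))
  expect_true(vc@converged)
  A <- aMatrix(dat$pedigree)
  ZAZ <- as.matrix(des$Z) %*% A %*% t(as.matrix(des$Z))
  o <- optim(log(c(1, 1)), function(par)
    -remlLogLik(exp(par[1]), exp(par[2]), des$y, des$X, ZAZ),
    method = "BFGS")
  expect_equal(vc@sigmaA2, exp(o$par[1]), tolerance = 1e-3)
  expect_equal(vc@sigmaE2, exp(o$par[2]), tolerance = 1e-3)
  ## h2 slot is exactly the ratio
  expect_equal(vc@h2, vc@sigmaA2 / (vc@sigmaA2 + vc@sigmaE2))
})

test_that("EM iterates never decrease the REML log-likelihood", {
  cfg <- simConfig(n_founders = 40, n_generations = 2, prop_genotyped = 0,
                   sigma_a2 = 1, sigma_e2 = 2, seed = 23)
  dat <- simulateDataset(cfg)
  des <- buildDesign(dat$phenotypes, dat$pedigree)
  vc <- aiReml(des$y, des$X, des$Z, aInverse(dat$pedigree), method = "em",
               tol = 1e-6, maxIter = 40)
  A <- aMatrix(dat$pedigree)
  ZAZ <- as.matrix(des$Z) %*% A %*% t(as.matrix(des$Z))
  ll <- apply(vc@history, 1, function(th)
    remlLogLik(th[1], th[2], des$y, des$X, ZAZ))
  expect_true(all(diff(ll) > -1e-8))
})

test_that("a null trait drives the additive variance to the boundary", {
  ## large full-sib families separate family from residual variance well,
  ## so sigma_a2 = 0 is recovered tightly
  cfg <- simConfig(n_founders = 100, n_generations = 2,
                   offspring_per_mating = 4, prop_genotyped = 0,
                   sigma_a2 = 0, sigma_e2 = 2, seed = 29)
  dat <- simulateDataset(cfg)
  des <- buildDesign(dat$phenotypes, dat$pedigree)
  vc <- aiReml(des$y, des$X, des$Z, aInverse(dat$pedigree))
  expect_lt(vc@h2, 0.05)
})

test_that("PBLUP and ssGBLUP coincide when nobody is genotyped", {
  cfg <- simConfig(n_founders = 60, n_generations = 2, prop_genotyped = 0,
                   sigma_a2 = 2, sigma_e2 = 2, seed = 37)
  dat <- simulateDataset(cfg)
  des <- buildDesign(dat$phenotypes, dat$pedigree)
  Ai <- aInverse(dat$pedigree)
  Hi <- hInverse(Ai, matrix(0, 0, 0), matrix(0, 0, 0), integer(0))
  vcA <- aiReml(des$y, des$X, des$Z, Ai)
  vcH <- aiReml(des$y, des$X, des$Z, Hi)
  expect_identical(vcA@sigmaA2, vcH@sigmaA2)
  expect_identical(vcA@sigmaE2, vcH@sigmaE2)
})

test_that("PBLUP recovers a 0.5 heritability across replicates", {
  h2 <- numeric(10)
  se <- numeric(10)
  for (r in 1:10) {
    cfg <- simConfig(n_founders = 250, n_generations = 2,
                     offspring_per_mating = 1, prop_genotyped = 0,
                     sigma_a2 = 2, sigma_e2 = 2, seed = 900 + r)
    dat <- simulateDataset(cfg)
    des <- buildDesign(dat$phenotypes, dat$pedigree)
    vc <- aiReml(des$y, des$X, des$Z, aInverse(dat$pedigree))
    h2[r] <- vc@h2
    se[r] <- vc@seH2
  }
  expect_lt(abs(mean(h2) - 0.5), 0.05)
  covered <- sum(abs(h2 - 0.5) <= 2 * se)
  expect_gte(covered, 8)
})

test_that("heritability reproduces the reported productive-trait values", {
  expect_equal(round(heritability(66.74, 67.31), 2), 0.50)
  expect_equal(round(heritability(59.24, 69.29), 2), 0.46)
  expect_equal(round(heritability(2.01, 6.62), 2), 0.23)
  expect_equal(heritability(0, 5), 0)
  vc <- new("VarianceComponents", sigmaA2 = 2, sigmaE2 = 6,
            h2 = 0.25, seH2 = 0.01, converged = TRUE, nIter = 1L,
            method = "test", history = matrix(numeric(0), 0, 2))
  expect_equal(heritability(vc), 0.25)
  expect_error(heritability(0, 0), "> 0")
})
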