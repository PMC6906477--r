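# Gibbs sampler for the four-distribution mixture model.

# small fixed design shared by several tests
gibbsToy <- function(n = 5, m = 2, seed = 81) {
  set.seed(seed)
  geno <- matrix(rbinom(n * m, 2, 0.5), n, m,
                 dimnames = list(seq_len(n), paste0("s", seq_len(m))))
  while (any(colMeans(geno) %in% c(0, 2))) {
    geno <- matrix(rbinom(n * m, 2, 0.5), n, m,
                   dimnames = list(seq_len(n), paste0("s", seq_len(m))))
  }
  geno
}

test_that("chain bookkeeping: saved-sample counts and determinism", {
  geno <- gibbsToy()
  drp <- makeDrp(1:5, c(1, -1, 2, 0, -2), rep(0.5, 5))
  ch <- ChainConfig(nIter = 120, burnIn = 100, thin = 20, seed = 5)
  expect_equal(nSavedSamples(ch), 1)
  fit <- runGibbs(drp, geno, chain = ch)
  expect_length(fit@mu, 1)

  ch2 <- ChainConfig(400, 100, 3, seed = 9)
  f1 <- runGibbs(drp, geno, chain = ch2)
  f2 <- runGibbs(drp, geno, chain = ch2)
  expect_identical(f1@mu, f2@mu)
  expect_identical(f1@components$ALL$effects, f2@components$ALL$effects)
  expect_error(ChainConfig(100, 100, 1), "burnIn")
})

test_that("no-signal data give near-zero effects and the constant mean", {
  geno <- gibbsToy(n = 30, m = 4, seed = 82)
  drp <- makeDrp(1:30, rep(3.5, 30), rep(0.5, 30))
  fit <- runGibbs(drp, geno, chain = ChainConfig(3000, 500, 5, seed = 1))
  eff <- fit@components$ALL$effects
  pm <- colMeans(eff)
  psd <- apply(eff, 2, sd)
  expect_true(all(abs(pm) <= 3 * pmax(psd, 1e-8)))
  expect_lt(abs(mean(fit@mu) - 3.5), 0.05)
})

test_that("pi draws stay on the simplex; class variances keep exact ratios", {
  geno <- gibbsToy(n = 20, m = 6, seed = 83)
  set.seed(84)
  drp <- makeDrp(1:20, rnorm(20), rep(0.5, 20))
  fit <- runGibbs(drp, geno, chain = ChainConfig(500, 100, 2, seed = 3))
  pis <- fit@components$ALL$pi
  expect_true(all(abs(rowSums(pis) - 1) < 1e-12))
  expect_true(all(pis >= 0))
  spec <- MixtureSpec()
  expect_identical(spec@ratios, c(1e-3, 1e-2, 1e-1, 1))
  expect_error(MixtureSpec(ratios = c(0.5, 1, 1, 1)), "fixed")
})

test_that("Dirichlet posterior update matches its analytic mean", {
  set.seed(85)
  draws <- dirichletPosteriorDraws(c(100, 0, 0, 0), n = 50000)
  m <- 225 / 256
  v <- 225 * 31 / (256^2 * 257)
  expect_lt(abs(mean(draws[, 1]) - m), 3 * sqrt(v / 50000))
})

test_that("posterior-mean effects match the conjugate class-enumeration
           oracle on a 5x2 instance", {
  geno <- gibbsToy()
  y <- c(1.2, -0.8, 2.1, 0.3, -1.6)
  d <- c(1, 0.5, 2, 1, 0.8)
  drp <- makeDrp(1:5, y, 1 / (1 + d))
  spec <- MixtureSpec()
  s4 <- 0.8; se <- 0.5
  fit <- runGibbs(drp, geno, spec,
                  ChainConfig(200000, 2000, 20, seed = 10),
                  fix = list(mu = 0, pi = spec@piInit, sigma4 = s4,
                             sigmaE = se))
  pm <- colMeans(fit@components$ALL$effects)

  # oracle: enumerate the 4x4 class grid; per class the model is Gaussian,
  # so the conditional posterior of the effects is available in closed form
  X <- sweep(geno, 2, colMeans(geno))
  D <- diag(d) * se
  num <- c(0, 0); den <- 0
  for (k1 in 1:4) for (k2 in 1:4) {
    Vg <- diag(s4 * spec@ratios[c(k1, k2)], 2)
    S <- X %*% Vg %*% t(X) + D
    logml <- log(spec@piInit[k1]) + log(spec@piInit[k2]) -
      0.5 * (determinant(S)$modulus + t(y) %*% solve(S, y))[1]
    w <- exp(logml)
    gmean <- Vg %*% t(X) %*% solve(S, y)
    num <- num + w * as.numeric(gmean)
    den <- den + w
  }
  oracle <- num / den
  expect_lt(max(abs(pm - oracle)), 0.02)
})

test_that("with classes forced to the largest variance the sampler matches
           the ridge posterior", {
  geno <- gibbsToy(n = 3, m = 2, seed = 86)
  y <- c(1, -2, 0.5)
  drp <- makeDrp(1:3, y, rep(0.5, 3))
  s4 <- 1.5; se <- 0.7
  fit <- runGibbs(drp, geno, MixtureSpec(),
                  ChainConfig(100000, 2000, 1, seed = 11),
                  fix = list(mu = 0, pi = c(0, 0, 0, 1), sigma4 = s4,
                             sigmaE = se))
  pm <- colMeans(fit@components$ALL$effects)
  X <- sweep(geno, 2, colMeans(geno))
  ridge <- solve(crossprod(X) / se + diag(2) / s4, crossprod(X, y) / se)
  expect_lt(max(abs(pm - as.numeric(ridge))), 0.01)
  expect_true(all(fit@components$ALL$classProb[, 4] == 1))
})

test_that("rescaling the data rescales the posterior effects", {
  geno <- gibbsToy(n = 25, m = 5, seed = 87)
  set.seed(88)
  y <- rnorm(25)
  ch <- ChainConfig(4000, 1000, 5, seed = 12)
  f1 <- runGibbs(makeDrp(1:25, y, rep(0.5, 25)), geno, chain = ch)
  f2 <- runGibbs(makeDrp(1:25, 3 * y, rep(0.5, 25)), geno, chain = ch)
  pm1 <- colMeans(f1@components$ALL$effects)
  pm2 <- colMeans(f2@components$ALL$effects)
  expect_equal(pm2, 3 * pm1, tolerance = 0.05)
})

test_that("posterior EBVs aggregate effects per component", {
  geno <- gibbsToy(n = 10, m = 3, seed = 89)
  set.seed(90)
  drp <- makeDrp(1:10, rnorm(10), rep(0.5, 10))
  fit <- runGibbs(drp, geno, chain = ChainConfig(300, 100, 2, seed = 13))
  ebv <- posteriorEBV(fit, geno)
  X <- sweep(geno, 2, fit@components$ALL$centers)
  expect_equal(unname(ebvTotal(ebv)),
               as.numeric(X %*% colMeans(fit@components$ALL$effects)))

  # a chain whose saved states are identical: EBV is exactly X g
  one <- fit
  one@mu <- one@mu[1]
  one@sigmaE <- one@sigmaE[1]
  one@components$ALL$effects <-
    one@components$ALL$effects[rep(1, 4), , drop = FALSE]
  g1 <- one@components$ALL$effects[1, ]
  expect_equal(unname(ebvTotal(posteriorEBV(one, geno))),
               as.numeric(X %*% g1))

  # all-zero effects give all-zero EBVs
  zero <- fit
  zero@components$ALL$effects[] <- 0
  expect_true(all(ebvTotal(posteriorEBV(zero, geno)) == 0))

  expect_error(posteriorEBV(fit, geno[, 1:2]), "SNPs")
})

test_that("a null second component leaves the total EBV to component one", {
  st <- smallStudy(seed = 91, nFounders = 20, nGenerations = 3,
                   siresPerGen = 3, offspringPerSire = 8,
                   nChip = 60, nDfs = 8, nFra = 10, nOverlap = 2)
  b2 <- fitBayes("B2", st$drp, st$panel,
                 chain = ChainConfig(400, 100, 3, seed = 14))
  comp <- ebvComponents(b2$ebv)
  z <- comp
  z[, "WGS"] <- 0
  fitz <- b2$fit
  fitz@components$WGS$effects[] <- 0
  geno <- genotypes(st$panel[, animalIds(b2$ebv)])
  gl <- list(K54 = geno[, panelSnpIds(st$panel, "CHIP")],
             WGS = geno[, panelSnpIds(st$panel, "WGS")])
  e0 <- posteriorEBV(fitz, gl)
  expect_equal(unname(ebvTotal(e0)), unname(comp[, "K54"]))
})

test_that("B2 on duplicated panels agrees with B1 on the pooled panel", {
  geno <- gibbsToy(n = 40, m = 8, seed = 92)
  set.seed(93)
  y <- as.numeric(sweep(geno, 2, colMeans(geno)) %*%
                    rnorm(8, sd = 0.4)) + rnorm(40, sd = 0.6)
  drp <- makeDrp(1:40, y, rep(0.5, 40))
  b1 <- runGibbs(drp, list(ALL = cbind(geno, geno)),
                 chain = ChainConfig(6000, 1000, 5, seed = 15))
  b2 <- runGibbs(drp, list(K54 = geno, WGS = geno),
                 chain = ChainConfig(6000, 1000, 5, seed = 16))
  e1 <- posteriorEBV(b1, list(ALL = cbind(geno, geno)))
  e2 <- posteriorEBV(b2, list(K54 = geno, WGS = geno))
  # exchangeable construction: totals statistically indistinguishable
  expect_gt(cor(ebvTotal(e1), ebvTotal(e2)), 0.98)
  expect_lt(mean(abs(ebvTotal(e1) - ebvTotal(e2))) / sd(ebvTotal(e1)), 0.2)
})

test_that("a major QTL is promoted into the heavy-tail classes", {
  ped <- simulatePedigree(400, 1, seed = 94)
  pan <- simulateGenotypes(ped, 1, 120, seed = 95)
  tr <- TraitSpec("milk", 0.39)
  qtl <- assignQTL(pan, tr, "major_qtl", nQtl = 40, seed = 96,
                   majorFrac = 0.35)
  erc <- rep(8, 400)
  drp <- simulateDRP(trueBreedingValues(qtl), tr, erc, seed = 97)
  b1 <- fitBayes("B1", drp, pan, chain = ChainConfig(3000, 500, 5, seed = 98))
  cp <- b1$fit@components$ALL$classProb
  heavy <- cp[, 3] + cp[, 4]
  eff <- qtlEffects(qtl)
  major <- causalIndices(qtl)[which.max(abs(eff))]
  expect_gt(heavy[major], mean(heavy))
})
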