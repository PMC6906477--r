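# Weighted mixed-model solver and REML variance components.

test_that("two-animal closed form and the no-genetic-variance limit", {
  drp <- makeDrp(1:2, c(2, -2), r2 = c(0.5, 0.5))  # weights exactly 1
  G <- RelationshipMatrix(diag(2), "G", ids = 1:2)
  vc <- VarianceComponents(c(ALL = 1), 1)
  ebv <- solveMME(drp, G, vc)
  expect_equal(ebvMu(ebv), 0)
  expect_equal(unname(ebvTotal(ebv)), c(1, -1))

  vc0 <- VarianceComponents(c(ALL = 1e-12), 1)
  expect_lt(max(abs(ebvTotal(solveMME(drp, G, vc0)))), 1e-10)
})

test_that("solver matches a dense GLS/BLUP oracle with two components and
           prediction-only animals", {
  st <- smallStudy(seed = 71, nFounders = 16, nGenerations = 3,
                   siresPerGen = 3, offspringPerSire = 7,
                   nChip = 60, nDfs = 8, nFra = 10, nOverlap = 2)
  ids <- animalIds(st$panel)[1:30]
  sub <- st$panel[, ids]
  gk <- computeGVanRaden(sub, "CHIP")
  gw <- computeGVanRaden(sub, "WGS")
  vc <- VarianceComponents(c(K54 = 0.4, WGS = 0.25), 0.6)
  recIds <- as.integer(ids)[1:22]                 # 8 prediction-only animals
  ebv <- solveMME(st$drp, list(gk, gw), vc, recordIds = recIds)

  # oracle: explicit GLS for mu, then the multivariate-normal conditional
  # mean of (a1, a2) given y, built from scratch
  recs <- drpRecords(st$drp)
  recs <- recs[recs$usable & recs$animal_id %in% recIds, ]
  ri <- match(as.character(recs$animal_id), ids)
  K1 <- relMatrix(gk); K2 <- relMatrix(gw)
  V <- 0.4 * K1[ri, ri] + 0.25 * K2[ri, ri] + 0.6 * diag(recs$weight_d)
  one <- rep(1, nrow(recs))
  mu <- solve(t(one) %*% solve(V, one), t(one) %*% solve(V, recs$drp))[1]
  r <- recs$drp - mu
  a1 <- 0.4 * K1[, ri] %*% solve(V, r)
  a2 <- 0.25 * K2[, ri] %*% solve(V, r)
  expect_lt(max(abs(ebvComponents(ebv)[, "K54"] - a1)), 1e-6)
  expect_lt(max(abs(ebvComponents(ebv)[, "WGS"] - a2)), 1e-6)
  expect_lt(abs(ebvMu(ebv) - mu), 1e-8)
  expect_equal(unname(ebvTotal(ebv)),
               unname(rowSums(ebvComponents(ebv))), tolerance = 1e-12)
})

test_that("doubling a record's residual weight shrinks its influence", {
  G <- RelationshipMatrix(diag(3), "G", ids = 1:3)
  vc <- VarianceComponents(c(ALL = 1), 1)
  pull <- function(w2) {
    drp <- makeDrp(1:3, c(3, 0, 0), r2 = c(1 / (1 + w2), 0.5, 0.5))
    unname(ebvTotal(solveMME(drp, G, vc))[1])
  }
  e <- vapply(c(0.5, 1, 2, 4), pull, numeric(1))
  expect_true(all(diff(e) < 0))   # heavier weight, weaker pull toward DRP
})

test_that("EBVs are shift-invariant apart from the fitted mean", {
  st <- smallStudy(seed = 72, nFounders = 20, nGenerations = 3,
                   siresPerGen = 3, offspringPerSire = 8,
                   nChip = 60, nDfs = 8, nFra = 10, nOverlap = 2)
  G <- computeGVanRaden(st$panel)
  vc <- VarianceComponents(c(ALL = 0.4), 0.6)
  e1 <- solveMME(st$drp, G, vc)
  recs <- drpRecords(st$drp); recs$drp <- recs$drp + 7
  e2 <- solveMME(DRPRecords(recs), G, vc)
  expect_equal(ebvMu(e2), ebvMu(e1) + 7, tolerance = 1e-8)
  expect_equal(ebvTotal(e2), ebvTotal(e1), tolerance = 1e-8)
})

test_that("two identical components collapse to one with summed variance", {
  st <- smallStudy(seed = 73, nFounders = 20, nGenerations = 3,
                   siresPerGen = 3, offspringPerSire = 8,
                   nChip = 60, nDfs = 8, nFra = 10, nOverlap = 2)
  G <- computeGVanRaden(st$panel)
  G2 <- RelationshipMatrix(relMatrix(G), "G", tag = "COPY",
                           ids = animalIds(G))
  v1 <- 0.3; v2 <- 0.2
  eTwo <- solveMME(st$drp, list(G, G2),
                   VarianceComponents(c(A = v1, B = v2), 0.5))
  eOne <- solveMME(st$drp, G, VarianceComponents(c(ALL = v1 + v2), 0.5))
  expect_lt(max(abs(ebvTotal(eTwo) - ebvTotal(eOne))), 1e-8)
})

test_that("PBLUP on founders equals GBLUP with an identity G", {
  ped <- simulatePedigree(25, 1, seed = 74)
  ids <- animalIds(ped)
  drp <- makeDrp(ids, rnorm(25), rep(0.7, 25))
  vc <- VarianceComponents(c(ALL = 0.5), 0.5)
  eA <- solveMME(drp, computeA(ped, ids), vc)
  eG <- solveMME(drp, RelationshipMatrix(diag(25), "G", ids = ids), vc)
  expect_equal(ebvTotal(eA), ebvTotal(eG), tolerance = 1e-10)
})

test_that("REML finds no heritability in pure noise", {
  h2hat <- vapply(1:5, function(s) {
    ped <- simulatePedigree(300, 1, seed = 75 + s)
    pan <- qcFilter(simulateGenotypes(ped, 2, 300, seed = 175 + s))$panel
    set.seed(275 + s)
    drp <- makeDrp(animalIds(ped), rnorm(300), rep(0.5, 300))
    impliedH2(remlEstimate(drp, computeGVanRaden(pan)))
  }, numeric(1))
  expect_lt(mean(h2hat), 0.05)
  expect_true(all(h2hat < 0.10))
})

test_that("the REML optimum dominates a grid over variance ratios", {
  st <- smallStudy(seed = 78, nFounders = 14, nGenerations = 3,
                   siresPerGen = 3, offspringPerSire = 6,
                   nChip = 60, nDfs = 8, nFra = 10, nOverlap = 2)
  ids <- animalIds(st$panel)[1:30]
  G <- computeGVanRaden(st$panel[, ids])
  vc <- remlEstimate(st$drp, G, tol = 1e-10, maxIter = 200)
  recs <- drpRecords(st$drp)
  recs <- recs[recs$usable & as.character(recs$animal_id) %in% ids, ]
  ri <- match(as.character(recs$animal_id), ids)
  K <- relMatrix(G)[ri, ri] + diag(1e-8, length(ri))
  llHat <- remlLoglik(recs$drp, recs$weight_d, list(K),
                      sigma2Additive(vc), sigma2Residual(vc))
  expect_equal(llHat, vc@loglik, tolerance = 1e-6)
  vy <- var(recs$drp)
  grid <- expand.grid(a = seq(0.05, 2, length.out = 20) * vy,
                      e = seq(0.05, 2, length.out = 20) * vy)
  llGrid <- mapply(function(a, e) remlLoglik(recs$drp, recs$weight_d,
                                             list(K), a, e),
                   grid$a, grid$e)
  expect_gte(llHat, max(llGrid) - 1e-6)
})

test_that("two-component REML recovers simulated variance shares", {
  # chip and selected-WGS panels tag disjoint causal sets with known shares
  nseeds <- 10
  shares <- numeric(nseeds)
  trueShare <- 0.4
  for (s in seq_len(nseeds)) {
    ped <- simulatePedigree(1000, 1, seed = 700 + s)
    pan <- simulateGenotypes(ped, 2, 400, seed = 720 + s)
    geno <- genotypes(pan)
    set.seed(740 + s)
    cset <- sample(800, 80)
    chipQtl <- cset[1:48]; wgsQtl <- cset[49:80]
    af <- alleleFreqs(pan)
    X <- sweep(geno[, cset], 2, 2 * af[cset])
    eff <- rnorm(80)
    tbvC <- X[, 1:48] %*% eff[1:48]
    tbvW <- X[, 49:80] %*% eff[49:80]
    tbvC <- tbvC / sd(tbvC) * sqrt((1 - trueShare) * 0.5)
    tbvW <- tbvW / sd(tbvW) * sqrt(trueShare * 0.5)
    y <- tbvC + tbvW + rnorm(1000, sd = sqrt(0.5))
    drp <- makeDrp(animalIds(ped), y, rep(0.5, 1000))
    rd <- snpInfo(pan)
    rowData(pan)$in_chip <- seq_len(800) %in% setdiff(seq_len(800), wgsQtl)
    rowData(pan)$in_dfs <- seq_len(800) %in% wgsQtl
    gk <- computeGVanRaden(pan, "CHIP")
    gw <- computeGVanRaden(pan, "WGS")
    vc <- remlEstimate(drp, list(gk, gw), tol = 1e-5)
    s2 <- sigma2Additive(vc)
    shares[s] <- s2["WGS"] / sum(s2)
  }
  expect_lt(abs(mean(shares) - trueShare), 0.10)
})

test_that("fitModel dispatches models and degenerate cases coherently", {
  st <- smallStudy(seed = 79, nFounders = 24, nGenerations = 3,
                   siresPerGen = 3, offspringPerSire = 10,
                   nChip = 80, nDfs = 10, nFra = 12, nOverlap = 2)
  # two identical-structure components with one variance pushed to zero
  # behave like the single-component fit on the chip SNPs
  g2 <- fitModel("G2", st$drp, st$panel,
                 varcomp = VarianceComponents(c(K54 = 0.4, WGS = 1e-12),
                                              0.6))
  g1 <- fitModel("G1", st$drp, st$panel, snpSubset = "CHIP",
                 varcomp = VarianceComponents(c(ALL = 0.4), 0.6))
  expect_lt(max(abs(ebvTotal(g2$ebv) - ebvTotal(g1$ebv))), 1e-4)

  pan <- st$panel
  rowData(pan)$in_dfs <- FALSE
  rowData(pan)$in_fra <- FALSE
  expect_error(fitModel("G2", st$drp, pan), "selected-WGS")
})
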