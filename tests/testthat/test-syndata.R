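# Synthetic-population generators: pedigree, gene dropping, QTL
# architectures, panels, ERC/DRP phenotypes.

test_that("founder-only pedigrees and half-sib family structure", {
  ped <- pedigreeTable(simulatePedigree(10, 1, seed = 1))
  expect_equal(nrow(ped), 10)
  expect_true(all(is.na(ped$sire_id)) && all(is.na(ped$dam_id)))

  ped2 <- pedigreeTable(simulatePedigree(30, 2, siresPerGen = 2,
                                         offspringPerSire = 5, seed = 2))
  g2 <- ped2[ped2$birth_cohort == 2, ]
  expect_equal(nrow(g2), 10)
  expect_equal(as.integer(sort(table(g2$sire_id), decreasing = TRUE)),
               c(5L, 5L))
  expect_error(simulatePedigree(0, 1), "counts")
})

test_that("pedigree simulation is deterministic and structurally valid", {
  a <- simulatePedigree(40, 3, 3, 8, seed = 99)
  b <- simulatePedigree(40, 3, 3, 8, seed = 99)
  expect_identical(pedigreeTable(a), pedigreeTable(b))
  expect_true(validObject(a))
  p <- pedigreeTable(a)
  sx <- setNames(p$sex, p$animal_id)
  expect_true(all(sx[as.character(na.omit(p$sire_id))] == "M"))
  expect_true(all(sx[as.character(na.omit(p$dam_id))] == "F"))
})

test_that("gene dropping is Mendelian-consistent and copies haplotypes at
           zero recombination", {
  ped <- simulatePedigree(40, 3, 4, 10, seed = 3)
  pan <- simulateGenotypes(ped, nChromosomes = 2, snpsPerChromosome = 50,
                           recombRate = 0, seed = 4)
  g <- genotypes(pan)
  pd <- pedigreeTable(ped)
  off <- pd[!is.na(pd$sire_id), ]
  for (i in seq_len(nrow(off))) {
    go <- g[as.character(off$animal_id[i]), ]
    gs <- g[as.character(off$sire_id[i]), ]
    gd <- g[as.character(off$dam_id[i]), ]
    # Mendelian bounds: offspring allele count within what parents can give
    expect_true(all(go >= (gs == 2) + (gd == 2)))
    expect_true(all(go <= (gs >= 1) + (gd >= 1)))
  }
  expect_identical(g, genotypes(simulateGenotypes(ped, 2, 50,
                                                  recombRate = 0, seed = 4)))
})

test_that("founder allele frequencies follow binomial sampling", {
  ped <- simulatePedigree(2000, 1, seed = 5)
  pan <- simulateGenotypes(ped, nChromosomes = 1, snpsPerChromosome = 40,
                           founderMafRange = c(0.3, 0.3), seed = 6)
  af <- alleleFreqs(pan)
  se <- sqrt(0.3 * 0.7 / (2 * 2000))
  expect_true(all(abs(af - 0.3) < 3.9 * se))   # 40 SNPs, allow a wide band
  expect_lt(mean(abs(af - 0.3) > 2 * se), 0.25)
})

test_that("parent-offspring genotype regression is one half", {
  ped <- simulatePedigree(1200, 2, siresPerGen = 20, offspringPerSire = 40,
                          seed = 7)
  pan <- simulateGenotypes(ped, nChromosomes = 1, snpsPerChromosome = 150,
                           seed = 8)
  g <- genotypes(pan)
  pd <- pedigreeTable(ped)
  off <- pd[!is.na(pd$sire_id), ]
  gs <- g[as.character(off$sire_id), , drop = FALSE]
  go <- g[as.character(off$animal_id), , drop = FALSE]
  founders <- g[as.character(pd$animal_id[is.na(pd$sire_id)]), ]
  ratio <- vapply(seq_len(ncol(g)), function(j)
    cov(gs[, j], go[, j]) / var(founders[, j]), numeric(1))
  expect_lt(abs(mean(ratio) - 0.5), 0.05)
})

test_that("simulator rejects half-known parentage", {
  ped <- pedigreeTable(simulatePedigree(10, 1, seed = 1))
  ped <- rbind(ped, data.frame(animal_id = 11L, sire_id = 1L,
                               dam_id = NA_integer_, birth_cohort = 2L,
                               sex = "F"))
  expect_error(simulateGenotypes(PedigreeTable(ped), 1, 10),
               "one known parent")
})

test_that("QTL architectures hit their target heritability", {
  ped <- simulatePedigree(2000, 1, seed = 9)
  pan <- simulateGenotypes(ped, nChromosomes = 2, snpsPerChromosome = 1000,
                           seed = 10)
  tr <- TraitSpec("milk", 0.39)
  qtl <- assignQTL(pan, tr, "polygenic", nQtl = 2000, seed = 11)
  tbv <- trueBreedingValues(qtl)
  h2hat <- var(tbv) / (var(tbv) + (1 - 0.39))
  expect_lt(abs(h2hat - 0.39), 0.02)

  # null heritability: no genetic signal at all
  qtl0 <- assignQTL(pan, tr, "polygenic", nQtl = 10, seed = 12,
                    targetH2 = 0)
  expect_true(all(trueBreedingValues(qtl0) == 0))
  expect_true(all(qtlEffects(qtl0) == 0))
  expect_error(assignQTL(pan, tr, "polygenic", nQtl = 0, seed = 1),
               "nQtl")
})

test_that("a major QTL carries its configured share of genetic variance", {
  ped <- simulatePedigree(1500, 1, seed = 13)
  pan <- simulateGenotypes(ped, nChromosomes = 1, snpsPerChromosome = 400,
                           seed = 14)
  tr <- TraitSpec("milk", 0.39)
  qtl <- assignQTL(pan, tr, "major_qtl", nQtl = 80, seed = 15,
                   majorFrac = 0.30, nMajor = 1)
  eff <- qtlEffects(qtl)
  major <- which.max(abs(eff))
  x <- genotypes(pan)[, causalIndices(qtl)[major]]
  share <- eff[major]^2 * var(x) / var(trueBreedingValues(qtl))
  expect_lt(abs(share - 0.30), 0.05)
})

test_that("DRP reliabilities, weights and the error model are consistent", {
  tr <- TraitSpec("milk", 0.39)
  lam <- lambdaShrink(tr)
  expect_equal(lam, (1 - 0.39) / 0.39)

  tbv <- setNames(rnorm(3), 1:3)
  d <- drpRecords(simulateDRP(tbv, tr, erc = c(10, lam, 0), seed = 1))
  expect_equal(d$r2_drp[1], 10 / (10 + lam))
  expect_equal(d$r2_drp[1], 0.8647, tolerance = 1e-4)
  expect_equal(d$weight_d[1], 0.1565, tolerance = 1e-3)
  expect_equal(d$r2_drp[2], 0.5)          # erc = lambda symmetry point
  expect_equal(d$weight_d[2], 1)
  expect_false(d$usable[3])               # erc = 0 flagged unusable
  expect_equal(d$r2_drp[3], 0)
  expect_error(simulateDRP(tbv, tr, erc = c(-1, 1, 1)), "non-negative")
})

test_that("squared DRP-TBV correlation matches the reliability by design", {
  tr <- TraitSpec("milk", 0.39)
  lam <- lambdaShrink(tr)
  for (r2 in c(0.3, 0.8)) {
    tbv <- setNames(rnorm(5000, sd = sqrt(0.39)), seq_len(5000))
    erc <- rep(r2 * lam / (1 - r2), 5000)
    d <- drpRecords(simulateDRP(tbv, tr, erc, seed = round(100 * r2)))
    emp <- cor(d$drp, tbv)^2
    mcse <- sqrt(2 / 5000)   # rough MC error of a squared correlation
    expect_lt(abs(emp - r2), 3 * mcse)
  }
})

test_that("sex-stratified ERC reproduces the bull >> cow reliability gap", {
  sex <- rep(c("M", "F"), each = 2000)
  erc <- simulateERC(sex, seed = 21)
  expect_lt(abs(mean(erc[sex == "M"]) - 40) / 40, 0.1)
  expect_lt(abs(mean(erc[sex == "F"]) - 2) / 2, 0.1)
  lam <- lambdaShrink(TraitSpec("milk", 0.39))
  r2 <- erc / (erc + lam)
  expect_gt(mean(r2[sex == "M"]), mean(r2[sex == "F"]) + 0.2)
})

test_that("panel labelling obeys the overlap accounting", {
  st <- smallStudy(seed = 31)
  rd <- snpInfo(st$panel)
  expect_equal(sum(rd$in_dfs), 16)
  expect_equal(sum(rd$in_fra), 24)
  expect_equal(sum(rd$in_dfs & rd$in_fra), 4)
  expect_equal(length(panelSnpIds(st$panel, "WGS")), 16 + 24 - 4)
  expect_false(any(rd$in_chip & (rd$in_dfs | rd$in_fra)))

  # disjoint panels when no overlap is requested
  pan0 <- simulateGenotypes(simulatePedigree(60, 1, seed = 1), 2, 80,
                            seed = 2)
  tr <- TraitSpec("milk", 0.39)
  qtl <- assignQTL(pan0, tr, "polygenic", nQtl = 20, seed = 3)
  p2 <- buildPanels(pan0, qtl, nChip = 60, nDfs = 8, nFra = 9,
                    nOverlap = 0, proximity = 2, seed = 4)
  rd2 <- snpInfo(p2)
  expect_equal(sum(rd2$in_dfs & rd2$in_fra), 0)
  expect_equal(length(panelSnpIds(p2, "WGS")), 17)

  # proximity 0: every selected-WGS SNP is itself causal
  p3 <- buildPanels(pan0, qtl, nChip = 60, nDfs = 5, nFra = 5,
                    nOverlap = 2, proximity = 0, seed = 5)
  rd3 <- snpInfo(p3)
  expect_true(all(rd3$is_causal[rd3$in_dfs | rd3$in_fra]))

  # infeasible requests name the shortfall
  expect_error(buildPanels(pan0, qtl, nChip = 60, nDfs = 100, nFra = 100,
                           nOverlap = 0, proximity = 0, seed = 6),
               "shortfall")
})
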