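# Shared in-code fixtures. Everything is generated at test time from seeds.

# DRP records built directly from reliabilities (erc back-computed so that
# r2 = erc/(erc + lambda) holds at lambda = 1)
makeDrp <- function(ids, drp, r2, trait = "toy") {
  w <- ifelse(r2 > 0, (1 - r2) / r2, Inf)
  DRPRecords(data.frame(animal_id = as.integer(ids), trait = trait,
                        drp = drp, erc = ifelse(r2 > 0, r2 / (1 - r2), 0),
                        r2_drp = r2, weight_d = w, usable = r2 > 0))
}

# named EBV vector convenience
namedEbv <- function(ids, values) setNames(values, as.character(ids))

# a small population with labelled panels and phenotypes, reused across tests
smallStudy <- function(seed = 11, nFounders = 80, nGenerations = 4,
                       siresPerGen = 5, offspringPerSire = 16,
                       nChromosomes = 3, snpsPerChromosome = 120,
                       architecture = "mixture", nQtl = 24, h2 = 0.39,
                       nChip = 180, nDfs = 16, nFra = 24, nOverlap = 4) {
  ped <- simulatePedigree(nFounders, nGenerations, siresPerGen,
                          offspringPerSire, seed = seed)
  panel <- simulateGenotypes(ped, nChromosomes, snpsPerChromosome,
                             seed = seed + 1)
  panel <- qcFilter(panel)$panel          # drop monomorphic drift losses
  trait <- TraitSpec("milk", h2)
  qtl <- assignQTL(panel, trait, architecture, nQtl = nQtl, seed = seed + 2)
  panel <- buildPanels(panel, qtl, nChip, nDfs, nFra, nOverlap,
                       proximity = 2, seed = seed + 3)
  erc <- simulateERC(pedigreeTable(ped)$sex, seed = seed + 4)
  drp <- simulateDRP(trueBreedingValues(qtl), trait, erc, seed = seed + 5)
  split <- splitReferenceValidation(ped, drp, birthCutoff = nGenerations,
                                    halfsibWindowStart = nGenerations - 1)
  list(ped = ped, panel = panel, trait = trait, qtl = qtl, drp = drp,
       split = split)
}

# restricted log-likelihood of the weighted single/multi-component model,
# computed densely and independently of the package's REML internals
remlLoglik <- function(y, d, Klist, sigma2, sigma2e) {
  n <- length(y)
  V <- diag(sigma2e * d)
  for (k in seq_along(Klist)) V <- V + sigma2[k] * Klist[[k]]
  ch <- chol(V)
  Vi <- chol2inv(ch)
  Vi1 <- Vi %*% rep(1, n)
  mu <- sum(Vi %*% y) / sum(Vi1)
  r <- y - mu
  -0.5 * (2 * sum(log(diag(ch))) + log(sum(Vi1)) +
            as.numeric(crossprod(r, Vi %*% r)))
}
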