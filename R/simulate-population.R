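## Population simulator: hierarchical half-sib pedigrees and gene-dropping
## genotypes. Family linkage disequilibrium arises from co-segregation in the
## pedigree; founders are simulated in linkage equilibrium.

#' Simulate a paternal half-sib structured pedigree
#'
#' Generates a discrete-generation pedigree resembling a dairy-cattle
#' population: a founder cohort, then each later cohort produced by a small
#' number of sires, each with a fixed number of offspring (paternal half-sib
#' families), dams drawn at random from the previous cohort's females.
#'
#' @param nFounders founder animals (cohort 1), half of each sex.
#' @param nGenerations total number of cohorts including the founders.
#' @param siresPerGen sires used per non-founder cohort.
#' @param offspringPerSire offspring per sire (the paternal half-sib family
#'   size by construction).
#' @param seed integer seed; the same seed reproduces the pedigree exactly.
#' @return a [PedigreeTable-class].
#' @examples
#' ped <- simulatePedigree(20, 3, siresPerGen = 2, offspringPerSire = 5,
#'                         seed = 1)
#' @export
simulatePedigree <- function(nFounders, nGenerations, siresPerGen = 4,
                             offspringPerSire = 10, seed = 1) {
  if (nFounders < 1 || nGenerations < 1 || siresPerGen < 1 ||
      offspringPerSire < 1)
    stop("all counts must be >= 1")
  set.seed(seed)
  sex <- rep(c("M", "F"), length.out = nFounders)
  ped <- data.frame(animal_id = seq_len(nFounders), sire_id = NA_integer_,
                    dam_id = NA_integer_, birth_cohort = 1L, sex = sex)
  nextId <- nFounders + 1L
  if (nGenerations > 1) {
    for (g in 2:nGenerations) {
      prev <- ped[ped$birth_cohort == g - 1L, ]
      males <- prev$animal_id[prev$sex == "M"]
      females <- prev$animal_id[prev$sex == "F"]
      if (length(males) < siresPerGen)
        stop("not enough males in cohort ", g - 1L, " to supply ",
             siresPerGen, " sires")
      if (length(females) < 1)
        stop("no females in cohort ", g - 1L)
      sires <- sample(males, siresPerGen)
      n_off <- siresPerGen * offspringPerSire
      off <- data.frame(
        animal_id = seq.int(nextId, length.out = n_off),
        sire_id = rep(sires, each = offspringPerSire),
        dam_id = sample(females, n_off, replace = TRUE),
        birth_cohort = g,
        sex = sample(c("M", "F"), n_off, replace = TRUE))
      nextId <- nextId + n_off
      ped <- rbind(ped, off)
    }
  }
  PedigreeTable(ped)
}

## One meiosis: recombine a parent's two chromosome-phased haplotypes.
## chromStarts/chromEnds are index ranges per chromosome; recombRate is the
## expected number of crossovers per chromosome per meiosis.
.gamete <- function(h1, h2, chromIdx, recombRate) {
  out <- integer(length(h1))
  for (ci in chromIdx) {
    L <- length(ci)
    src <- sample.int(2L, 1L)                      # starting haplotype
    take1 <- rep(src == 1L, L)
    if (recombRate > 0 && L > 1) {
      ncross <- rpois(1L, recombRate)
      ncross <- min(ncross, L - 1L)
      if (ncross > 0) {
        cuts <- sort(sample.int(L - 1L, ncross))   # crossover after cuts[k]
        seg <- findInterval(seq_len(L) - 1L, cuts) # 0,1,... segment index
        take1 <- (seg %% 2L == 0L) == (src == 1L)
      }
    }
    out[ci] <- ifelse(take1, h1[ci], h2[ci])
  }
  out
}

#' Gene-dropping genotype simulation over a pedigree
#'
#' Founder haplotypes are drawn independently per SNP at a frequency sampled
#' from `founderMafRange`; every descendant receives one recombined haplotype
#' from each parent (crossover counts Poisson with mean `recombRate` per
#' chromosome per meiosis). Genotypes are the haplotype sums, so all output is
#' Mendelian-consistent by construction. With `recombRate = 0` each inherited
#' chromosome is an exact copy of one parental haplotype.
#'
#' @param pedigree a [PedigreeTable-class]; every non-founder must have both
#'   parents recorded.
#' @param nChromosomes,snpsPerChromosome genome layout.
#' @param founderMafRange interval within (0, 0.5] from which per-SNP founder
#'   allele frequencies are drawn uniformly.
#' @param recombRate expected crossovers per chromosome per meiosis.
#' @param seed integer seed.
#' @return a [GenotypePanel-class] with all SNPs initially labelled CHIP.
#' @export
simulateGenotypes <- function(pedigree, nChromosomes = 5,
                              snpsPerChromosome = 200,
                              founderMafRange = c(0.05, 0.5),
                              recombRate = 1, seed = 1) {
  stopifnot(founderMafRange[1] > 0, founderMafRange[2] <= 0.5,
            founderMafRange[1] <= founderMafRange[2])
  ped <- pedigreeTable(pedigree)
  oneParent <- xor(is.na(ped$sire_id), is.na(ped$dam_id))
  if (any(oneParent))
    stop("animals with exactly one known parent are not supported: ",
         paste(ped$animal_id[oneParent], collapse = ", "))
  set.seed(seed)
  M <- nChromosomes * snpsPerChromosome
  chrom <- rep(seq_len(nChromosomes), each = snpsPerChromosome)
  chromIdx <- split(seq_len(M), chrom)
  p <- runif(M, founderMafRange[1], founderMafRange[2])

  ord <- order(ped$birth_cohort, ped$animal_id)
  ped <- ped[ord, ]
  n <- nrow(ped)
  H1 <- matrix(0L, n, M)                           # paternal haplotype
  H2 <- matrix(0L, n, M)                           # maternal haplotype
  row_of <- setNames(seq_len(n), ped$animal_id)
  for (i in seq_len(n)) {
    if (is.na(ped$sire_id[i])) {
      H1[i, ] <- rbinom(M, 1L, p)
      H2[i, ] <- rbinom(M, 1L, p)
    } else {
      s <- row_of[as.character(ped$sire_id[i])]
      d <- row_of[as.character(ped$dam_id[i])]
      H1[i, ] <- .gamete(H1[s, ], H2[s, ], chromIdx, recombRate)
      H2[i, ] <- .gamete(H1[d, ], H2[d, ], chromIdx, recombRate)
    }
  }
  geno <- H1 + H2
  rownames(geno) <- as.character(ped$animal_id)
  info <- data.frame(snp_id = sprintf("c%d_s%d", chrom,
                                      unlist(lapply(chromIdx, seq_along)) - 1L),
                     chrom = chrom,
                     pos_index = unlist(lapply(chromIdx, seq_along)) - 1L)
  GenotypePanel(geno, info, animalIds = ped$animal_id)
}
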