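## Trait architecture, true breeding values and deregressed-proof phenotypes.

#' Assign a QTL architecture and compute true breeding values
#'
#' Samples causal SNPs and allele-substitution effects under one of three
#' architectures, then rescales the effects so the realized additive variance
#' var(TBV) equals `targetH2` on a phenotypic scale of 1 (residual variance
#' `1 - targetH2`):
#' \describe{
#'   \item{polygenic}{i.i.d. normal effects at every causal SNP.}
#'   \item{major_qtl}{`nMajor` loci jointly explaining `majorFrac` of the
#'     genetic variance on top of a polygenic background.}
#'   \item{mixture}{effects drawn from four zero-mean normals with variance
#'     ratios 1/1000 : 1/100 : 1/10 : 1, mirroring the Bayesian mixture
#'     prior.}
#' }
#'
#' @param panel a [GenotypePanel-class].
#' @param trait a [TraitSpec-class]; its heritability is the default target.
#' @param architectureKind `"polygenic"`, `"major_qtl"` or `"mixture"`.
#' @param nQtl number of causal SNPs.
#' @param seed integer seed.
#' @param targetH2 heritability to rescale to (0 allowed: all effects zero).
#' @param majorFrac,nMajor major-QTL settings (used for `"major_qtl"` only).
#' @return a [QTLArchitecture-class] carrying effects and per-animal TBV.
#' @export
assignQTL <- function(panel, trait, architectureKind = c("polygenic",
                      "major_qtl", "mixture"), nQtl = 100, seed = 1,
                      targetH2 = heritability(trait), majorFrac = 0.3,
                      nMajor = 1) {
  architectureKind <- match.arg(architectureKind)
  geno <- genotypes(panel)
  M <- ncol(geno)
  if (nQtl > M) stop("nQtl exceeds the number of SNPs")
  if (nQtl == 0 && targetH2 > 0)
    stop("nQtl = 0 is inconsistent with a nonzero heritability")
  set.seed(seed)
  af <- alleleFreqs(panel)
  poly <- which(af > 0 & af < 1)
  if (length(poly) < nQtl) stop("not enough polymorphic SNPs for nQtl")
  causal <- sort(sample(poly, nQtl))
  X <- sweep(geno[, causal, drop = FALSE], 2, 2 * af[causal])

  if (targetH2 == 0) {
    eff <- numeric(nQtl)
    tbv <- setNames(numeric(nrow(geno)), rownames(geno))
  } else {
    eff <- switch(architectureKind,
      polygenic = rnorm(nQtl),
      major_qtl = {
        e <- rnorm(nQtl) * 0.1
        majors <- sample(nQtl, nMajor)
        vb <- var(as.vector(X[, -majors, drop = FALSE] %*% e[-majors]))
        vx <- apply(X[, majors, drop = FALSE], 2, var)
        # each major locus gets an equal share of majorFrac of the genetic var
        e[majors] <- sqrt((majorFrac / (1 - majorFrac)) * vb /
                            (nMajor * vx)) * sample(c(-1, 1), nMajor, TRUE)
        e
      },
      mixture = {
        cls <- sample.int(4L, nQtl, replace = TRUE,
                          prob = c(0.889, 0.1, 0.01, 0.001))
        rnorm(nQtl, sd = sqrt(c(1e-3, 1e-2, 1e-1, 1)[cls]))
      })
    tbv_raw <- as.vector(X %*% eff)
    sc <- sqrt(targetH2 / var(tbv_raw))
    eff <- eff * sc
    tbv <- setNames(tbv_raw * sc, rownames(geno))
  }
  new("QTLArchitecture", causal_idx = as.integer(causal), effects = eff,
      kind = architectureKind, target_h2 = targetH2, tbv = tbv)
}

#' True breeding values of a QTL architecture
#' @param x a [QTLArchitecture-class].
#' @export
trueBreedingValues <- function(x) x@tbv

#' @rdname trueBreedingValues
#' @export
causalIndices <- function(x) x@causal_idx

#' @rdname trueBreedingValues
#' @export
qtlEffects <- function(x) x@effects

#' Label chip and selected-WGS SNP panels
#'
#' Labels `nChip` evenly spaced non-causal SNPs as the chip background, and
#' draws the selected-WGS panels (DFS-like and FRA-like) from SNPs that are
#' causal or lie within `proximity` SNP-index positions of a causal SNP on the
#' same chromosome — emulating variants preselected near causative mutations.
#' Exactly `nOverlap` SNPs carry both selected-WGS labels, so the deduplicated
#' union has `nDfs + nFra - nOverlap` SNPs.
#'
#' @param panel a [GenotypePanel-class].
#' @param qtl a [QTLArchitecture-class] identifying the causal SNPs.
#' @param nChip,nDfs,nFra,nOverlap panel sizes; `nOverlap` is the number of
#'   dual-labelled SNPs.
#' @param proximity maximum SNP-index distance from a causal SNP for
#'   selected-WGS eligibility (0 = causal SNPs only).
#' @param seed integer seed.
#' @return a relabelled [GenotypePanel-class].
#' @export
buildPanels <- function(panel, qtl, nChip, nDfs, nFra, nOverlap = 0,
                        proximity = 2, seed = 1) {
  stopifnot(nOverlap <= min(nDfs, nFra))
  set.seed(seed)
  info <- snpInfo(panel)
  M <- nrow(info)
  causal <- causalIndices(qtl)
  isCausal <- seq_len(M) %in% causal

  nonCausal <- which(!isCausal)
  if (length(nonCausal) < nChip)
    stop("not enough non-causal SNPs for a chip of size ", nChip)
  chip <- nonCausal[unique(round(seq(1, length(nonCausal),
                                     length.out = nChip)))]
  if (length(chip) < nChip)    # rounding collisions at high density
    chip <- nonCausal[seq_len(nChip)]

  near <- rep(FALSE, M)
  for (j in causal) {
    same <- info$chrom == info$chrom[j] &
      abs(info$pos_index - info$pos_index[j]) <= proximity
    near <- near | same
  }
  cand <- setdiff(which(near), chip)
  nUnion <- nDfs + nFra - nOverlap
  if (length(cand) < nUnion)
    stop("selected-WGS shortfall: need ", nUnion, " SNPs near causal ",
         "variants but only ", length(cand), " are available")
  sel <- sample(cand, nUnion)
  both <- sel[seq_len(nOverlap)]
  dfsOnly <- sel[seq.int(nOverlap + 1, length.out = nDfs - nOverlap)]
  fraOnly <- setdiff(sel, c(both, dfsOnly))

  rowData(panel)$is_causal <- isCausal
  rowData(panel)$in_chip <- seq_len(M) %in% chip
  rowData(panel)$in_dfs <- seq_len(M) %in% c(both, dfsOnly)
  rowData(panel)$in_fra <- seq_len(M) %in% c(both, fraOnly)
  validObject(panel)
  panel
}

#' Simulate effective record contributions by sex
#'
#' ERC values are drawn log-normally with sex-specific means, reflecting that
#' progeny-tested bulls carry far more information than cows with own records
#' only. The log-scale location is set so the distribution mean equals the
#' requested mean.
#'
#' @param sex character vector of `"M"`/`"F"` per animal.
#' @param bullMean,cowMean target ERC means (defaults 40 and 2).
#' @param sdlog log-scale standard deviation.
#' @param seed integer seed.
#' @return numeric ERC vector aligned with `sex`.
#' @export
simulateERC <- function(sex, bullMean = 40, cowMean = 2, sdlog = 0.5,
                        seed = 1) {
  set.seed(seed)
  mu <- ifelse(sex == "M", log(bullMean), log(cowMean)) - sdlog^2 / 2
  rlnorm(length(sex), meanlog = mu, sdlog = sdlog)
}

#' Simulate deregressed proofs around true breeding values
#'
#' Each animal's DRP is its TBV plus independent noise with variance
#' `sigma2_a * d_i`, where `d_i = (1 - r2_i)/r2_i`, `r2_i = erc_i/(erc_i +
#' lambda)` and `sigma2_a` is the realized additive variance. Under this
#' error model the squared correlation between DRP and TBV equals the DRP
#' reliability. Animals with `erc = 0` get `r2 = 0`, an `NA` proof, and are
#' flagged unusable.
#'
#' @param tbv named numeric of true breeding values.
#' @param trait a [TraitSpec-class].
#' @param erc non-negative effective record contributions, aligned to `tbv`.
#' @param seed integer seed.
#' @return a [DRPRecords-class].
#' @export
simulateDRP <- function(tbv, trait, erc, seed = 1) {
  if (any(erc < 0)) stop("erc must be non-negative")
  stopifnot(length(erc) == length(tbv))
  set.seed(seed)
  lam <- lambdaShrink(trait)
  r2 <- erc / (erc + lam)
  d <- ifelse(r2 > 0, (1 - r2) / r2, Inf)
  s2a <- var(tbv)
  drp <- tbv + rnorm(length(tbv), sd = sqrt(s2a * ifelse(is.finite(d), d, 0)))
  drp[r2 == 0] <- NA_real_
  DRPRecords(data.frame(animal_id = as.integer(names(tbv)),
                        trait = traitName(trait), drp = drp, erc = erc,
                        r2_drp = r2, weight_d = d, usable = r2 > 0))
}
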