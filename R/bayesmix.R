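## Bayesian four-distribution mixture models (BayesR family): one genetic
## component pooling all SNPs (B1) or separate chip and selected-WGS
## components with zero covariance (B2). The single-site Gibbs sampler lives
## in C++; this file handles centering, initial values, and posterior
## summaries.

## centered genotype matrices per component; centering frequencies are the
## observed frequencies among the analyzed animals
.centeredComponents <- function(genoList) {
  lapply(genoList, function(geno) {
    p <- colMeans(geno) / 2
    if (any(p == 0 | p == 1))
      stop("constant-column SNPs in a genetic component; run qcFilter first")
    list(X = sweep(geno, 2, 2 * p), centers = 2 * p)
  })
}

#' Run the Gibbs sampler for the four-distribution mixture model
#'
#' For each SNP in turn the class indicator is sampled from the four
#' marginal-likelihood-weighted class probabilities and the effect from its
#' conditional normal; mixing proportions are then refreshed from
#' `Dirichlet(counts + class tallies)` per genetic component, the free class
#' variance from its scaled inverse chi-square conditional, the residual
#' variance from its weighted conditional, and the mean from its conditional.
#' Class likelihoods are evaluated in log space with max-subtraction. The
#' chain is deterministic given `chain@seed`.
#'
#' Individual updates can be frozen via `fix` — useful for validating the
#' sampler against closed-form posteriors.
#'
#' @param drp a [DRPRecords-class]; usable records of animals present in the
#'   genotype matrices are the data.
#' @param genoList named list of one or two 0/1/2 genotype matrices
#'   (individuals x SNPs, rownames = animal ids), one per genetic component.
#' @param spec a [MixtureSpec-class].
#' @param chain a [ChainConfig-class].
#' @param fix named list; any of `mu`, `pi`, `sigma4`, `sigmaE` set to a
#'   value freezes that update at the value.
#' @param recordIds optional restriction of the records used.
#' @param randomOrder update SNPs in a random order each iteration
#'   (default: fixed order, for reproducibility).
#' @return a [GibbsFit-class].
#' @export
runGibbs <- function(drp, genoList, spec = MixtureSpec(),
                     chain = ChainConfig(), fix = list(), recordIds = NULL,
                     randomOrder = FALSE) {
  if (is.matrix(genoList)) genoList <- list(ALL = genoList)
  if (is.null(names(genoList)))
    names(genoList) <- if (length(genoList) == 1) "ALL" else c("K54", "WGS")
  recs <- drpRecords(drp)
  recs <- recs[recs$usable, ]
  ids <- rownames(genoList[[1]])
  for (gm in genoList) if (!identical(rownames(gm), ids))
    stop("genotype matrices carry mismatched animals")
  recs <- recs[recs$animal_id %in% as.integer(ids), ]
  if (!is.null(recordIds))
    recs <- recs[recs$animal_id %in% as.integer(recordIds), ]
  if (nrow(recs) < 2) stop("need at least 2 usable records")

  cc <- .centeredComponents(genoList)
  ri <- match(as.character(recs$animal_id), ids)
  Xrec <- lapply(cc, function(z) z$X[ri, , drop = FALSE])
  y <- recs$drp
  w <- 1 / recs$weight_d
  vy <- max(var(y), 1e-8)   # constant y still needs proper priors

  sumVarX <- vapply(Xrec, function(X) sum(apply(X, 2, var)), numeric(1))
  meanRatio <- sum(spec@piInit * spec@ratios)
  s4init <- 0.5 * vy / (pmax(sumVarX, 1e-12) * meanRatio * length(Xrec))
  seInit <- 0.5 * vy
  piInit <- matrix(rep(spec@piInit, length(Xrec)), nrow = length(Xrec),
                   byrow = TRUE)
  if (!is.null(fix$pi)) piInit <- matrix(rep(fix$pi, length(Xrec)),
                                         nrow = length(Xrec), byrow = TRUE)
  if (!is.null(fix$sigma4)) s4init <- rep(fix$sigma4,
                                          length.out = length(Xrec))
  if (!is.null(fix$sigmaE)) seInit <- fix$sigmaE
  muInit <- if (!is.null(fix$mu)) fix$mu else sum(w * y) / sum(w)

  set.seed(chain@seed)
  raw <- .gibbs_mixture_cpp(y, w, unname(Xrec), spec@dirichlet, spec@ratios,
                            piInit, spec@dfSigma, s4init, s4init, seInit,
                            seInit, muInit, chain@nIter, chain@burnIn,
                            chain@thin, !is.null(fix$mu), !is.null(fix$pi),
                            !is.null(fix$sigma4), !is.null(fix$sigmaE),
                            randomOrder)
  comps <- raw$components
  names(comps) <- names(genoList)
  for (k in seq_along(comps)) {
    comps[[k]]$snp_ids <- colnames(genoList[[k]])
    comps[[k]]$centers <- cc[[k]]$centers
  }
  new("GibbsFit", mu = as.numeric(raw$mu), sigmaE = as.numeric(raw$sigma_e),
      components = comps, spec = spec, chain = chain, animalIds = ids)
}

#' Breeding values from saved mixture-model samples
#'
#' EBV per animal = centered genotype row times the posterior-mean effect
#' vector, summed over genetic components; component contributions are kept
#' separate in the result. Genotypes are centered with the frequencies used
#' during sampling.
#'
#' @param fit a [GibbsFit-class].
#' @param genoList genotype matrices matching the fit's components (possibly
#'   covering more animals than were sampled, e.g. validation animals);
#'   default `NULL` is an error — the genotypes must be supplied.
#' @return an [EBVSet-class].
#' @export
posteriorEBV <- function(fit, genoList) {
  if (is.matrix(genoList)) genoList <- list(genoList)
  if (length(genoList) != length(fit@components))
    stop("need one genotype matrix per fitted genetic component")
  ids <- rownames(genoList[[1]])
  comp <- matrix(0, length(ids), length(fit@components))
  colnames(comp) <- names(fit@components)
  for (k in seq_along(fit@components)) {
    ck <- fit@components[[k]]
    geno <- genoList[[k]]
    if (ncol(geno) != length(ck$centers))
      stop("genotype matrix for component ", names(fit@components)[k],
           " has ", ncol(geno), " SNPs; the fit used ", length(ck$centers))
    gbar <- colMeans(ck$effects)
    comp[, k] <- sweep(geno, 2, ck$centers) %*% gbar
  }
  EBVSet(ids, mean(fit@mu), comp)
}

#' Fit a one- or two-component Bayesian mixture model
#'
#' `"B1"` pools all SNPs of `snpSubset` into one genetic component with one
#' `(pi, sigma4)`; `"B2"` keeps separate chip and selected-WGS components
#' with their own `(pi, sigma4)` and zero covariance between components.
#'
#' @param modelName `"B1"` or `"B2"`.
#' @param drp a [DRPRecords-class].
#' @param panel a [GenotypePanel-class].
#' @param spec,chain prior and chain settings.
#' @param snpSubset SNP subset for B1 (default `"ALL"`).
#' @param referenceIds records used for fitting (remaining animals are
#'   prediction-only).
#' @param animals animals carried in the genotype matrices (default all
#'   animals in `drp` present in the panel).
#' @param ... passed to [runGibbs()].
#' @return list with `fit` (a [GibbsFit-class]), `ebv` (an
#'   [EBVSet-class] over `animals`) and `summary` (posterior means).
#' @export
fitBayes <- function(modelName = c("B1", "B2"), drp, panel,
                     spec = MixtureSpec(), chain = ChainConfig(),
                     snpSubset = "ALL", referenceIds = NULL, animals = NULL,
                     ...) {
  modelName <- match.arg(modelName)
  recs <- drpRecords(drp)
  if (is.null(animals))
    animals <- intersect(recs$animal_id, as.integer(animalIds(panel)))
  sub <- panel[, as.character(animals)]
  geno <- genotypes(sub)
  genoList <- if (modelName == "B1") {
    list(ALL = geno[, panelSnpIds(sub, snpSubset), drop = FALSE])
  } else {
    wgs <- panelSnpIds(sub, "WGS")
    if (!length(wgs)) stop("B2 requested but the selected-WGS panel is empty")
    list(K54 = geno[, panelSnpIds(sub, "CHIP"), drop = FALSE],
         WGS = geno[, wgs, drop = FALSE])
  }
  fit <- runGibbs(drp, genoList, spec, chain, recordIds = referenceIds, ...)
  ebv <- posteriorEBV(fit, genoList)
  summary <- list(
    mu = mean(fit@mu), sigma_e = mean(fit@sigmaE),
    pi = lapply(fit@components, function(c) colMeans(c$pi)),
    sigma4 = lapply(fit@components, function(c) mean(c$sigma4)),
    n_saved = length(fit@mu))
  list(fit = fit, ebv = ebv, summary = summary)
}

#' Draws from the Dirichlet posterior of the class probabilities
#'
#' The conditional update of the mixing proportions given class tallies is
#' `Dirichlet(counts + tallies)`; this helper draws from it (gamma
#' normalisation), e.g. to inspect the update in isolation.
#'
#' @param tallies integer class tallies (length 4).
#' @param counts Dirichlet pseudo-counts (default `c(125, 25, 5, 1)`).
#' @param n number of draws.
#' @return an `n x 4` matrix of simplex draws.
#' @export
dirichletPosteriorDraws <- function(tallies, counts = c(125, 25, 5, 1),
                                    n = 1) {
  alpha <- counts + tallies
  x <- matrix(rgamma(n * 4, shape = rep(alpha, each = n)), n, 4)
  x / rowSums(x)
}
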