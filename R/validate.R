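## Validation machinery for genomic prediction: reliability, dispersion bias,
## stability, paired bootstrap contrasts with Bonferroni control, the
## equal-SNP-count thinning control, and a scenario grid runner.

.alignValidation <- function(ebv, drp, ids = NULL) {
  ev <- if (is(ebv, "EBVSet")) ebvTotal(ebv) else ebv
  recs <- drpRecords(drp)
  recs <- recs[recs$usable, ]
  common <- intersect(names(ev), as.character(recs$animal_id))
  if (!is.null(ids)) common <- intersect(common, as.character(ids))
  if (length(common) < 2)
    stop("need at least 2 validation animals with both EBV and DRP")
  recs <- recs[match(common, as.character(recs$animal_id)), ]
  list(ebv = unname(ev[common]), drp = recs$drp, r2 = recs$r2_drp,
       ids = common)
}

#' Reliability of genomic prediction
#'
#' Squared correlation between EBV and DRP over the validation animals,
#' divided by their mean DRP reliability.
#'
#' @param ebv an [EBVSet-class] or named numeric of breeding values.
#' @param drp a [DRPRecords-class].
#' @param ids optional validation animal ids (default: all shared animals).
#' @return a single number (can exceed 1 when prediction is more accurate
#'   than the DRP itself).
#' @export
reliability <- function(ebv, drp, ids = NULL) {
  a <- .alignValidation(ebv, drp, ids)
  if (sd(a$ebv) == 0 || sd(a$drp) == 0)
    stop("zero variance in EBV or DRP over the validation animals")
  cor(a$ebv, a$drp)^2 / mean(a$r2)
}

#' Dispersion bias of genomic prediction
#'
#' Ordinary least-squares regression coefficient of DRP on EBV over the
#' validation animals; 1 indicates no dispersion bias, values below 1
#' inflated predictions.
#'
#' @inheritParams reliability
#' @export
biasSlope <- function(ebv, drp, ids = NULL) {
  a <- .alignValidation(ebv, drp, ids)
  if (sd(a$ebv) == 0) stop("constant EBV: slope undefined")
  cov(a$ebv, a$drp) / var(a$ebv)
}

#' Stability of genomic prediction
#'
#' Pearson correlation between breeding values estimated from the reduced
#' (reference-only) data and from the full data, over the same validation
#' animals.
#'
#' @param ebvReduced,ebvFull [EBVSet-class] objects (or named numerics).
#' @param ids validation animals; default: all ids shared by both sets,
#'   which must agree.
#' @export
stability <- function(ebvReduced, ebvFull, ids = NULL) {
  e1 <- if (is(ebvReduced, "EBVSet")) ebvTotal(ebvReduced) else ebvReduced
  e2 <- if (is(ebvFull, "EBVSet")) ebvTotal(ebvFull) else ebvFull
  if (is.null(ids)) {
    ids <- names(e1)
    if (!all(ids %in% names(e2)))
      stop("reduced and full EBV sets cover different animals")
  }
  ids <- as.character(ids)
  if (!all(ids %in% names(e1)) || !all(ids %in% names(e2)))
    stop("requested animals missing from an EBV set")
  cor(e1[ids], e2[ids])
}

#' @importFrom stats cov
NULL

#' Paired bootstrap comparison of two prediction scenarios
#'
#' Each bootstrap replicate resamples the validation animals with
#' replacement once and evaluates the metric for both scenarios on the same
#' resample (shared-resample pairing). The mean and standard deviation of
#' the replicate contrasts give the paired statistic: t = mean/SD, two-tailed
#' p from the t distribution with `nBoot - 1` degrees of freedom, and a
#' Bonferroni flag at `alpha / familySize`.
#'
#' @param metric `"reliability"`, `"bias"`, or a function
#'   `(ebvVec, drpVec, r2Vec) -> number`.
#' @param scenarioA,scenarioB lists with elements `ebv` (an
#'   [EBVSet-class] or named numeric) and `drp` (a [DRPRecords-class]);
#'   both scenarios must share the validation animals.
#' @param ids optional validation ids.
#' @param nBoot bootstrap replicates (default 10,000); fewer than 100 is
#'   refused unless `force = TRUE`.
#' @param alpha,familySize significance level and Bonferroni family size m
#'   (threshold `alpha/familySize`).
#' @param seed integer seed for the resampling.
#' @param force override the minimum-replicate refusal.
#' @return one-row data.frame: point estimates, mean contrast, bootstrap SE,
#'   t, p, Bonferroni flag, and an `identical` flag for degenerate
#'   self-comparisons.
#' @export
bootstrapCompare <- function(metric, scenarioA, scenarioB, ids = NULL,
                             nBoot = 10000, alpha = 0.05, familySize = 1,
                             seed = 1, force = FALSE) {
  if (nBoot < 100) {
    if (!force) stop("nBoot < 100 gives unstable standard errors; ",
                     "set force = TRUE to override")
    warning("nBoot < 100: standard errors will be unstable")
  }
  fn <- if (is.function(metric)) metric else switch(
    match.arg(metric, c("reliability", "bias")),
    reliability = function(e, y, r2) cor(e, y)^2 / mean(r2),
    bias = function(e, y, r2) cov(e, y) / var(e))
  metricName <- if (is.function(metric)) "custom" else metric
  a <- .alignValidation(scenarioA$ebv, scenarioA$drp, ids)
  b <- .alignValidation(scenarioB$ebv, scenarioB$drp, a$ids)
  if (!identical(a$ids, b$ids))
    stop("the two scenarios must share the validation animals")
  n <- length(a$ids)
  set.seed(seed)
  contrast <- numeric(nBoot)
  for (r in seq_len(nBoot)) {
    idx <- sample.int(n, n, replace = TRUE)
    contrast[r] <- fn(a$ebv[idx], a$drp[idx], a$r2[idx]) -
      fn(b$ebv[idx], b$drp[idx], b$r2[idx])
  }
  mc <- mean(contrast)
  sec <- sd(contrast)
  ident <- sec == 0 && all(contrast == 0)
  tstat <- if (ident) NA_real_ else mc / sec
  p <- if (ident) NA_real_ else 2 * pt(-abs(tstat), df = nBoot - 1)
  data.frame(metric = metricName,
             value_A = fn(a$ebv, a$drp, a$r2),
             value_B = fn(b$ebv, b$drp, b$r2),
             mean_contrast = mc, se_contrast = sec, t = tstat, p_value = p,
             significant_after_bonferroni = !ident && p < alpha / familySize,
             identical = ident, family_size = familySize,
             n_validation = n, n_boot = nBoot)
}

#' Equal-SNP-count thinning control
#'
#' Tests whether a gain from adding selected-WGS SNPs is attributable to SNP
#' density: per replicate, `nRemove` chip SNPs are removed at random, all
#' selected-WGS SNPs kept, the model refitted on the thinned union (whose
#' size equals the chip-only panel when `nRemove` equals the selected-WGS
#' union size), and the validation metrics recomputed.
#'
#' @param panel a [GenotypePanel-class] with chip and selected-WGS labels.
#' @param drp a [DRPRecords-class].
#' @param modelName `"G1"` or `"B1"`.
#' @param nRemove chip SNPs removed per replicate (typically the selected-WGS
#'   union size); must be below the chip count.
#' @param replicates number of replicates (default 5).
#' @param seed integer seed.
#' @param referenceIds,validationIds reference records and validation
#'   animals.
#' @param chain [ChainConfig-class] for `"B1"`.
#' @return list with `perReplicate` (data.frame of reliability/bias per
#'   replicate and its SNP count) and `mean` (their means).
#' @export
snpThinningExperiment <- function(panel, drp, modelName = c("G1", "B1"),
                                  nRemove, replicates = 5, seed = 1,
                                  referenceIds = NULL, validationIds = NULL,
                                  chain = ChainConfig()) {
  modelName <- match.arg(modelName)
  chip <- panelSnpIds(panel, "CHIP")
  wgs <- panelSnpIds(panel, "WGS")
  if (nRemove >= length(chip))
    stop("nRemove must be smaller than the chip SNP count (",
         length(chip), ")")
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max, replicates)
  rows <- lapply(seq_len(replicates), function(r) {
    set.seed(repSeeds[r])
    keepChip <- if (nRemove > 0) sample(chip, length(chip) - nRemove)
                else chip
    snps <- union(keepChip, wgs)
    ebv <- if (modelName == "G1") {
      fitModel("G1", drp, panel, snpSubset = snps,
               referenceIds = referenceIds)$ebv
    } else {
      sub <- panel[snps, ]
      fitBayes("B1", drp, sub, chain = ChainConfig(chain@nIter,
               chain@burnIn, chain@thin, seed = repSeeds[r]),
               referenceIds = referenceIds)$ebv
    }
    data.frame(replicate = r, n_snps = length(snps),
               reliability = reliability(ebv, drp, validationIds),
               bias = biasSlope(ebv, drp, validationIds))
  })
  per <- do.call(rbind, rows)
  list(perReplicate = per,
       mean = colMeans(per[, c("n_snps", "reliability", "bias")]))
}

## stable small-integer seed from a scenario key
.keySeed <- function(masterSeed, key) {
  (masterSeed + sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))) %%
    2147483647L
}

#' Run a grid of prediction scenarios with comparison families
#'
#' Executes every trait x reference-set x SNP-set x model cell (fit on the
#' reference records, evaluate on the validation animals) and then builds
#' the three comparison families: across SNP sets (fixed reference and
#' model), across reference sets (fixed SNP set and model), and across
#' models (fixed reference and SNP set). Bonferroni correction is applied
#' within each family (m = number of pairwise comparisons in the family).
#' Per-cell chain/bootstrap seeds are derived by stable hashing of the cell
#' key, so adding a scenario does not perturb the others.
#'
#' @param panel a [GenotypePanel-class].
#' @param drpList named list of [DRPRecords-class], one per trait.
#' @param referenceSets named list of reference animal-id vectors.
#' @param validationIds validation animals (shared across cells).
#' @param snpSets named character vector/list of panel labels (or id
#'   vectors) defining the SNP scenarios, e.g.
#'   `list(K54 = "CHIP", K54_WGS = "ALL")`.
#' @param models character subset of `c("PBLUP", "G1", "G2", "B1", "B2")`.
#' @param pedigree a [PedigreeTable-class], required when `"PBLUP"` is run.
#' @param chain [ChainConfig-class] template for Bayesian models (its seed
#'   is replaced per cell).
#' @param nBoot,alpha bootstrap settings for the comparisons.
#' @param seed master seed.
#' @return list with `results` (one row per cell) and `comparisons` (one row
#'   per within-family pair).
#' @export
runScenarioGrid <- function(panel, drpList, referenceSets, validationIds,
                            snpSets = list(K54 = "CHIP", K54_WGS = "ALL"),
                            models = "G1", pedigree = NULL,
                            chain = ChainConfig(), nBoot = 1000,
                            alpha = 0.05, seed = 1) {
  stopifnot(length(names(drpList)) == length(drpList),
            length(names(referenceSets)) == length(referenceSets))
  cells <- expand.grid(trait = names(drpList), ref = names(referenceSets),
                       snp = names(snpSets), model = models,
                       stringsAsFactors = FALSE)
  ## two-component models need a selected-WGS component: only sensible on
  ## scenarios that include it, and PBLUP ignores the SNP set (run once)
  cells <- cells[!(cells$model %in% c("G2", "B2") &
                     vapply(cells$snp, function(s)
                       identical(snpSets[[s]], "CHIP"), logical(1))), ]
  if ("PBLUP" %in% models)
    cells <- cells[!(cells$model == "PBLUP" &
                       cells$snp != names(snpSets)[1]), ]

  ebvs <- list()
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    key <- paste(cell$trait, cell$ref, cell$snp, cell$model, sep = "|")
    drp <- drpList[[cell$trait]]
    refIds <- referenceSets[[cell$ref]]
    ebv <- switch(as.character(cell$model),
      PBLUP = {
        if (is.null(pedigree)) stop("PBLUP requested without a pedigree")
        fitModel("PBLUP", drp, pedigree, referenceIds = refIds,
                 animals = union(refIds, validationIds))$ebv
      },
      G1 = fitModel("G1", drp, panel, snpSubset = snpSets[[cell$snp]],
                    referenceIds = refIds,
                    animals = union(refIds, validationIds))$ebv,
      G2 = fitModel("G2", drp, panel, referenceIds = refIds,
                    animals = union(refIds, validationIds))$ebv,
      B1 = fitBayes("B1", drp, panel,
                    snpSubset = if (is.character(snpSets[[cell$snp]]) &&
                                    length(snpSets[[cell$snp]]) == 1)
                      snpSets[[cell$snp]] else "ALL",
                    chain = ChainConfig(chain@nIter, chain@burnIn,
                                        chain@thin,
                                        seed = .keySeed(seed, key)),
                    referenceIds = refIds,
                    animals = union(refIds, validationIds))$ebv,
      B2 = fitBayes("B2", drp, panel,
                    chain = ChainConfig(chain@nIter, chain@burnIn,
                                        chain@thin,
                                        seed = .keySeed(seed, key)),
                    referenceIds = refIds,
                    animals = union(refIds, validationIds))$ebv)
    ebvs[[key]] <<- ebv
    data.frame(trait = cell$trait, reference_set = cell$ref,
               snp_set = cell$snp, model = cell$model,
               reliability = reliability(ebv, drp, validationIds),
               bias_slope = biasSlope(ebv, drp, validationIds),
               n_validation = length(validationIds))
  })
  results <- do.call(rbind, rows)

  comparisons <- list()
  families <- list(snp_set = c("trait", "reference_set", "model"),
                   reference_set = c("trait", "snp_set", "model"),
                   model = c("trait", "reference_set", "snp_set"))
  for (fam in names(families)) {
    fixed <- families[[fam]]
    groups <- split(seq_len(nrow(results)),
                    interaction(results[fixed], drop = TRUE))
    for (g in groups) {
      if (length(g) < 2) next
      m <- choose(length(g), 2)
      for (pair in utils::combn(g, 2, simplify = FALSE)) {
        rA <- results[pair[1], ]; rB <- results[pair[2], ]
        keyA <- paste(rA$trait, rA$reference_set, rA$snp_set, rA$model,
                      sep = "|")
        keyB <- paste(rB$trait, rB$reference_set, rB$snp_set, rB$model,
                      sep = "|")
        drp <- drpList[[rA$trait]]
        cmp <- bootstrapCompare("reliability",
                                list(ebv = ebvs[[keyA]], drp = drp),
                                list(ebv = ebvs[[keyB]], drp = drp),
                                ids = validationIds, nBoot = nBoot,
                                alpha = alpha, familySize = m,
                                seed = .keySeed(seed, paste(keyA, keyB)))
        cmp <- cbind(data.frame(family = fam, scenario_A = keyA,
                                scenario_B = keyB), cmp)
        comparisons[[length(comparisons) + 1L]] <- cmp
      }
    }
  }
  list(results = results,
       comparisons = if (length(comparisons))
         do.call(rbind, comparisons) else NULL,
       ebvs = ebvs)
}

#' Compact significance letters from a pairwise-significance matrix
#'
#' Greedy clique labelling: scenarios sharing a letter are not significantly
#' different. A presentation helper for grid results.
#'
#' @param sig logical symmetric matrix, `TRUE` where a pair differs
#'   significantly; dimnames label the scenarios.
#' @return named character vector of letter groups.
#' @export
significanceLetters <- function(sig) {
  n <- nrow(sig)
  labels <- rep("", n)
  letter <- 0L
  covered <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (covered[i]) next
    grp <- i
    for (j in seq_len(n)[-i])
      if (all(!sig[j, grp])) grp <- c(grp, j)
    letter <- letter + 1L
    labels[grp] <- paste0(labels[grp], letters[letter])
    covered[grp] <- TRUE
  }
  setNames(labels, rownames(sig))
}
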