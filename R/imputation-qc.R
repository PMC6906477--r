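## Imputation-error emulation and genotype quality control. Imputation itself
## is out of scope; only its error process and the downstream QC metrics
## (per-SNP correlation and concordance with the true genotypes) matter for
## the prediction analyses.

#' Inject imputation-like genotype errors
#'
#' Each genotype is independently replaced, with its SNP's error probability,
#' by a fresh draw from the SNP's Hardy-Weinberg genotype distribution (at
#' the observed allele frequency). Returns the corrupted panel together with
#' the per-SNP Pearson correlation and concordance rate between original and
#' corrupted 0/1/2 codes — the two metrics used for post-imputation QC.
#'
#' @param panel a [GenotypePanel-class].
#' @param snpErrorRates per-SNP error probabilities in \[0, 1\] (recycled if
#'   scalar).
#' @param seed integer seed.
#' @return list with `panel` (corrupted [GenotypePanel-class]) and `metrics`
#'   (data.frame `snp_id`, `correlation`, `concordance`).
#' @export
injectImputationErrors <- function(panel, snpErrorRates, seed = 1) {
  geno <- genotypes(panel)
  M <- ncol(geno)
  rates <- rep_len(snpErrorRates, M)
  if (any(rates < 0 | rates > 1)) stop("error rates must lie in [0, 1]")
  set.seed(seed)
  p <- alleleFreqs(panel)
  n <- nrow(geno)
  out <- geno
  for (j in seq_len(M)) {
    if (rates[j] == 0) next
    hit <- runif(n) < rates[j]
    if (any(hit)) {
      hw <- c((1 - p[j])^2, 2 * p[j] * (1 - p[j]), p[j]^2)
      out[hit, j] <- sample(0:2, sum(hit), replace = TRUE, prob = hw)
    }
  }
  corr <- vapply(seq_len(M), function(j) {
    if (sd(geno[, j]) == 0 || sd(out[, j]) == 0)
      return(if (all(geno[, j] == out[, j])) 1 else 0)
    cor(geno[, j], out[, j])
  }, numeric(1))
  conc <- colMeans(geno == out)
  corr[conc == 1] <- 1        # identical columns: exact, not cor()'s eps
  newPanel <- GenotypePanel(out, snpInfo(panel), animalIds = animalIds(panel))
  list(panel = newPanel,
       metrics = data.frame(snp_id = snpInfo(panel)$snp_id,
                            correlation = corr, concordance = conc))
}

#' Quality-control filter on MAF and imputation metrics
#'
#' Retains exactly the SNPs with minor allele frequency at or above `mafMin`
#' and — when metrics are supplied — imputation correlation and concordance
#' strictly greater than `metricMin`. The MAF rule is inclusive at the
#' boundary; the imputation rules are strict. Applying the filter twice is a
#' no-op.
#'
#' @param panel a [GenotypePanel-class].
#' @param imputationMetrics data.frame as returned by
#'   [injectImputationErrors()], aligned by `snp_id`; `NULL` skips the
#'   imputation-metric rules (e.g. for directly observed genotypes).
#' @param mafMin minimum minor allele frequency retained (default 0.01).
#' @param metricMin strict lower bound on both imputation metrics
#'   (default 0.8).
#' @return list with `panel` (filtered) and `report` (per-SNP pass/fail with
#'   reason codes among `"MAF"`, `"correlation"`, `"concordance"`).
#' @export
qcFilter <- function(panel, imputationMetrics = NULL, mafMin = 0.01,
                     metricMin = 0.8) {
  info <- snpInfo(panel)
  af <- alleleFreqs(panel)
  maf <- pmin(af, 1 - af)
  # a SNP with no genotypic variation has no segregating minor allele,
  # whatever its nominal frequency (e.g. an all-heterozygote column)
  maf[.colVars(genotypes(panel)) == 0] <- 0
  failMaf <- maf < mafMin
  if (!is.null(imputationMetrics)) {
    m <- imputationMetrics[match(info$snp_id, imputationMetrics$snp_id), ]
    if (anyNA(m$correlation))
      stop("imputation metrics are not aligned to the panel's SNPs")
    failCor <- !(m$correlation > metricMin)
    failConc <- !(m$concordance > metricMin)
  } else {
    failCor <- failConc <- rep(FALSE, nrow(info))
  }
  reason <- vapply(seq_len(nrow(info)), function(j) {
    paste(c("MAF", "correlation", "concordance")[
      c(failMaf[j], failCor[j], failConc[j])], collapse = ",")
  }, character(1))
  pass <- reason == ""
  if (!any(pass)) stop("no SNPs survive quality control")
  report <- data.frame(snp_id = info$snp_id, maf = unname(maf),
                       pass = pass, reason = reason)
  list(panel = panel[pass, ], report = report)
}
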