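## Accessors and show methods. Slots are never touched directly downstream.

#' @export
setGeneric("pedigreeTable", function(x) standardGeneric("pedigreeTable"))
#' Pedigree records as a data.frame
#' @param x a [PedigreeTable-class].
#' @export
setMethod("pedigreeTable", "PedigreeTable", function(x) x@ped)

#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))
#' @export
setMethod("animalIds", "PedigreeTable", function(x) x@ped$animal_id)
#' @export
setMethod("animalIds", "GenotypePanel", function(x) colnames(x))
#' @export
setMethod("animalIds", "EBVSet", function(x) x@ids)
#' @export
setMethod("animalIds", "RelationshipMatrix", function(x) x@ids)
#' @export
setMethod("animalIds", "GibbsFit", function(x) x@animalIds)

#' Genotype matrix in analysis orientation (individuals x SNPs)
#' @param x a [GenotypePanel-class].
#' @export
genotypes <- function(x) t(assay(x, "geno"))

#' Per-SNP metadata of a GenotypePanel
#' @param x a [GenotypePanel-class].
#' @export
snpInfo <- function(x) as.data.frame(rowData(x))

#' Observed allele frequencies (counted allele), one per SNP
#' @param x a [GenotypePanel-class].
#' @export
alleleFreqs <- function(x) setNames(rowData(x)$allele_freq, rowData(x)$snp_id)

#' SNP ids carrying a given panel label
#'
#' `"CHIP"`, `"DFS"`, `"FRA"` select single labels; `"WGS"` is the
#' deduplicated union of the DFS and FRA selected-WGS labels; `"ALL"` selects
#' every SNP.
#' @param x a [GenotypePanel-class].
#' @param label panel label.
#' @export
panelSnpIds <- function(x, label = c("ALL", "CHIP", "DFS", "FRA", "WGS")) {
  label <- match.arg(label)
  rd <- rowData(x)
  keep <- switch(label,
                 ALL = rep(TRUE, nrow(rd)),
                 CHIP = rd$in_chip,
                 DFS = rd$in_dfs,
                 FRA = rd$in_fra,
                 WGS = rd$in_dfs | rd$in_fra)
  rd$snp_id[keep]
}

#' Lambda shrinkage constant (1 - h2)/h2 of a trait
#' @param trait a [TraitSpec-class].
#' @export
lambdaShrink <- function(trait) (1 - trait@h2) / trait@h2

#' Heritability of a trait
#' @param trait a [TraitSpec-class].
#' @export
heritability <- function(trait) trait@h2

#' Trait name
#' @param trait a [TraitSpec-class].
#' @export
traitName <- function(trait) trait@name

#' DRP records as a data.frame
#' @param x a [DRPRecords-class].
#' @export
drpRecords <- function(x) x@recs

#' The relationship matrix itself
#' @param x a [RelationshipMatrix-class].
#' @export
relMatrix <- function(x) x@mat

#' @rdname relMatrix
#' @export
matrixKind <- function(x) x@kind

#' @rdname relMatrix
#' @export
componentTag <- function(x) x@tag

#' Additive variance components
#' @param x a [VarianceComponents-class].
#' @export
sigma2Additive <- function(x) x@sigma2

#' @rdname sigma2Additive
#' @export
sigma2Residual <- function(x) x@sigma2_e

#' Genomic heritability implied by a variance-component fit
#'
#' The residual variance of record j is `sigma2_e * d_j`, so on the scale of
#' a record with weight `meanWeight` the heritability is
#' `sum(sigma2) / (sum(sigma2) + sigma2_e * meanWeight)`. The default
#' `meanWeight = 1` corresponds to an unweighted record.
#' @param x a [VarianceComponents-class].
#' @param meanWeight residual weight d of the reference record scale.
#' @export
impliedH2 <- function(x, meanWeight = 1)
  sum(x@sigma2) / (sum(x@sigma2) + x@sigma2_e * meanWeight)

#' Total estimated breeding values (sum over genetic components)
#' @param x an [EBVSet-class].
#' @export
ebvTotal <- function(x) setNames(rowSums(x@components), x@ids)

#' @rdname ebvTotal
#' @export
ebvComponents <- function(x) x@components

#' @rdname ebvTotal
#' @export
ebvMu <- function(x) x@mu

#' Reference / validation / excluded ids of a split
#' @param x a [SplitResult-class].
#' @export
referenceIds <- function(x) x@reference_ids

#' @rdname referenceIds
#' @export
validationIds <- function(x) x@validation_ids

#' @rdname referenceIds
#' @export
excludedIds <- function(x) x@excluded

#' Number of posterior samples a chain configuration saves
#' @param chain a [ChainConfig-class].
#' @export
nSavedSamples <- function(chain) {
  (chain@nIter - chain@burnIn) %/% chain@thin
}

## show methods -------------------------------------------------------------

setMethod("show", "PedigreeTable", function(object) {
  p <- object@ped
  founders <- sum(is.na(p$sire_id) & is.na(p$dam_id))
  cat(sprintf("PedigreeTable: %d animals (%d founders), cohorts %d-%d\n",
              nrow(p), founders, min(p$birth_cohort), max(p$birth_cohort)))
})

setMethod("show", "GenotypePanel", function(object) {
  rd <- rowData(object)
  cat(sprintf(paste0("GenotypePanel: %d individuals x %d SNPs ",
                     "(CHIP %d, DFS %d, FRA %d, WGS-union %d, causal %d)\n"),
              ncol(object), nrow(object), sum(rd$in_chip), sum(rd$in_dfs),
              sum(rd$in_fra), sum(rd$in_dfs | rd$in_fra), sum(rd$is_causal)))
})

setMethod("show", "TraitSpec", function(object) {
  cat(sprintf("TraitSpec '%s': h2 = %.3f, lambda = %.4f\n",
              object@name, object@h2, lambdaShrink(object)))
})

setMethod("show", "DRPRecords", function(object) {
  r <- object@recs
  cat(sprintf("DRPRecords: %d records, %d usable, mean r2_DRP = %.3f\n",
              nrow(r), sum(r$usable), mean(r$r2_drp[r$usable])))
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat(sprintf("RelationshipMatrix %s[%s]: %d animals, mean diag = %.3f\n",
              object@kind, object@tag, length(object@ids),
              mean(diag(object@mat))))
})

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents:",
      paste(sprintf("sigma2[%s] = %.4g", names(object@sigma2), object@sigma2),
            collapse = ", "),
      sprintf(", sigma2_e = %.4g (h2 = %.3f)\n",
              object@sigma2_e, impliedH2(object)))
})

setMethod("show", "EBVSet", function(object) {
  cat(sprintf("EBVSet: %d animals, %d component(s), mu = %.4g\n",
              length(object@ids), ncol(object@components), object@mu))
})

setMethod("show", "SplitResult", function(object) {
  cat(sprintf("SplitResult: %d reference, %d validation, %d excluded\n",
              length(object@reference_ids), length(object@validation_ids),
              nrow(object@excluded)))
})

setMethod("show", "GibbsFit", function(object) {
  cat(sprintf("GibbsFit: %d saved samples, %d genetic component(s) [%s]\n",
              length(object@mu), length(object@components),
              paste(names(object@components), collapse = ", ")))
})
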