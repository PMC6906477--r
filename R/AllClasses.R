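#' @import methods
#' @importFrom stats cor var sd rnorm runif rbinom rpois rgamma rchisq rlnorm
#'   pt quantile lm coef setNames aggregate complete.cases
#' @importFrom S4Vectors DataFrame SimpleList metadata `metadata<-`
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom SummarizedExperiment `rowData<-`
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom Matrix nearPD
#' @useDynLib wgsblend, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## ---------------------------------------------------------------------------
## Pedigree
## ---------------------------------------------------------------------------

#' PedigreeTable: animal/sire/dam records with birth cohorts and sex
#'
#' A validated container for pedigree information. Each row is one animal with
#' integer identifiers for itself and its parents (`NA` for unknown), an
#' integer birth cohort (year-like index) and a sex code (`"M"`/`"F"`).
#' Validity enforces that the pedigree graph is acyclic (via the cohort
#' ordering), that sires are male and dams female, and that parents are born
#' strictly before their offspring.
#'
#' @slot ped a `data.frame` with columns `animal_id`, `sire_id`, `dam_id`,
#'   `birth_cohort`, `sex`.
#' @export
setClass("PedigreeTable", slots = c(ped = "data.frame"))

setValidity("PedigreeTable", function(object) {
  p <- object@ped
  need <- c("animal_id", "sire_id", "dam_id", "birth_cohort", "sex")
  if (!all(need %in% names(p)))
    return(paste("pedigree must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(p$animal_id)) return("duplicated animal_id")
  if (!all(p$sex %in% c("M", "F"))) return("sex must be 'M' or 'F'")
  sx <- setNames(p$sex, p$animal_id)
  co <- setNames(p$birth_cohort, p$animal_id)
  for (col in c("sire_id", "dam_id")) {
    par <- p[[col]]
    known <- !is.na(par)
    if (any(known & !(par %in% p$animal_id)))
      return(sprintf("%s refers to animals absent from the pedigree", col))
    if (any(par[known] == p$animal_id[known]))
      return("an animal cannot be its own parent")
    want <- if (col == "sire_id") "M" else "F"
    if (any(sx[as.character(par[known])] != want))
      return(sprintf("all %ss must have sex '%s'", sub("_id", "", col), want))
    if (any(co[as.character(par[known])] >= p$birth_cohort[known]))
      return("parents must have strictly earlier birth_cohort than offspring")
  }
  TRUE
})

#' @rdname PedigreeTable-class
#' @param ped data.frame of pedigree records.
#' @export
PedigreeTable <- function(ped) {
  ped$animal_id <- as.integer(ped$animal_id)
  ped$sire_id <- as.integer(ped$sire_id)
  ped$dam_id <- as.integer(ped$dam_id)
  ped$birth_cohort <- as.integer(ped$birth_cohort)
  ped$sex <- as.character(ped$sex)
  new("PedigreeTable", ped = ped)
}

## ---------------------------------------------------------------------------
## GenotypePanel: a SummarizedExperiment of 0/1/2 allele counts
## ---------------------------------------------------------------------------

#' GenotypePanel: genotypes with per-SNP panel labels
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with one assay
#' (`"geno"`, SNPs in rows, individuals in columns, allele counts in
#' \{0,1,2\}) and mandatory `rowData` columns: `snp_id`, `chrom`, `pos_index`
#' (0-based SNP index within chromosome), the panel-membership flags
#' `in_chip`, `in_dfs`, `in_fra` (a SNP may carry both selected-WGS labels),
#' `is_causal`, and `allele_freq` (observed frequency of the counted allele).
#'
#' @export
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  need <- c("snp_id", "chrom", "pos_index", "in_chip", "in_dfs", "in_fra",
            "is_causal", "allele_freq")
  if (!all(need %in% colnames(rowData(object))))
    return(paste("rowData must contain:", paste(need, collapse = ", ")))
  g <- assay(object, "geno")
  if (!all(g %in% 0:2)) return("genotype entries must be 0, 1 or 2")
  af <- rowData(object)$allele_freq
  recomputed <- rowMeans(g) / 2
  if (max(abs(af - recomputed)) > 1e-8)
    return("allele_freq must equal column-mean/2 of the genotypes")
  TRUE
})

#' Construct a GenotypePanel
#'
#' @param geno integer matrix, individuals x SNPs (the natural analysis
#'   orientation; stored transposed as the SE assay).
#' @param snpInfo data.frame with one row per SNP; missing label columns are
#'   filled with defaults (all-chip, non-causal).
#' @param animalIds identifiers for the rows of `geno`.
#' @return a [GenotypePanel-class].
#' @export
GenotypePanel <- function(geno, snpInfo = NULL, animalIds = rownames(geno)) {
  if (is.null(animalIds)) animalIds <- seq_len(nrow(geno))
  m <- ncol(geno)
  if (is.null(snpInfo)) snpInfo <- data.frame(snp_id = colnames(geno))
  if (is.null(snpInfo$snp_id)) snpInfo$snp_id <- paste0("snp", seq_len(m))
  if (is.null(snpInfo$chrom)) snpInfo$chrom <- 1L
  if (is.null(snpInfo$pos_index)) {
    snpInfo$pos_index <- unlist(lapply(split(seq_len(m), snpInfo$chrom),
                                       function(i) seq_along(i) - 1L),
                                use.names = FALSE)[order(order(snpInfo$chrom))]
  }
  for (flag in c("in_chip", "in_dfs", "in_fra", "is_causal"))
    if (is.null(snpInfo[[flag]])) snpInfo[[flag]] <- flag == "in_chip"
  snpInfo$allele_freq <- colMeans(geno) / 2
  gm <- t(geno)
  storage.mode(gm) <- "integer"
  dimnames(gm) <- list(snpInfo$snp_id, as.character(animalIds))
  rd <- DataFrame(snpInfo)
  rownames(rd) <- snpInfo$snp_id
  se <- SummarizedExperiment(assays = SimpleList(geno = gm), rowData = rd,
                             colData = DataFrame(row.names =
                                                   as.character(animalIds)))
  new("GenotypePanel", se)
}

## ---------------------------------------------------------------------------
## Trait and phenotype containers
## ---------------------------------------------------------------------------

#' TraitSpec: trait name and narrow-sense heritability
#'
#' The shrinkage constant lambda = (1 - h2)/h2 is derived, never stored, so it
#' can never drift out of step with `h2`.
#'
#' @slot name trait name.
#' @slot h2 narrow-sense heritability in (0, 1).
#' @export
setClass("TraitSpec", slots = c(name = "character", h2 = "numeric"))

setValidity("TraitSpec", function(object) {
  if (length(object@h2) != 1 || object@h2 <= 0 || object@h2 >= 1)
    return("h2 must be a single value in (0, 1)")
  TRUE
})

#' @rdname TraitSpec-class
#' @param name,h2 trait name and heritability.
#' @export
TraitSpec <- function(name, h2) new("TraitSpec", name = name, h2 = h2)

#' DRPRecords: deregressed proofs with reliabilities and residual weights
#'
#' Per animal-by-trait records of the pseudo-phenotype (DRP), the effective
#' record contribution (ERC) behind it, the implied DRP reliability
#' r2 = ERC/(ERC + lambda) and the residual weight d = (1 - r2)/r2 used on the
#' diagonal of the residual covariance. Records with ERC = 0 carry r2 = 0 and
#' are flagged unusable.
#'
#' @slot recs data.frame with columns `animal_id`, `trait`, `drp`, `erc`,
#'   `r2_drp`, `weight_d`, `usable`.
#' @export
setClass("DRPRecords", slots = c(recs = "data.frame"))

setValidity("DRPRecords", function(object) {
  r <- object@recs
  need <- c("animal_id", "trait", "drp", "erc", "r2_drp", "weight_d", "usable")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (any(r$erc < 0)) return("erc must be non-negative")
  if (any(r$r2_drp < 0 | r$r2_drp >= 1)) return("r2_drp must lie in [0, 1)")
  ok <- r$usable
  if (any(ok & r$weight_d <= 0)) return("usable records need weight_d > 0")
  TRUE
})

#' @rdname DRPRecords-class
#' @param recs data.frame of DRP records.
#' @export
DRPRecords <- function(recs) new("DRPRecords", recs = recs)

#' QTLArchitecture: simulated causal loci, effects and true breeding values
#'
#' @slot causal_idx column indices of causal SNPs in the generating panel.
#' @slot effects allele-substitution effects, one per causal SNP.
#' @slot kind one of `"polygenic"`, `"major_qtl"`, `"mixture"`.
#' @slot target_h2 heritability the effects were rescaled to.
#' @slot tbv named numeric of true breeding values per animal.
#' @export
setClass("QTLArchitecture",
         slots = c(causal_idx = "integer", effects = "numeric",
                   kind = "character", target_h2 = "numeric", tbv = "numeric"))

#' SplitResult: reference/validation partition of the genotyped animals
#'
#' @slot reference_ids,validation_ids integer animal identifiers.
#' @slot excluded data.frame (`animal_id`, `reason`) of animals dropped from
#'   both sets, with reason codes.
#' @export
setClass("SplitResult",
         slots = c(reference_ids = "integer", validation_ids = "integer",
                   excluded = "data.frame"))

setValidity("SplitResult", function(object) {
  if (length(intersect(object@reference_ids, object@validation_ids)))
    return("reference and validation sets overlap")
  if (length(intersect(object@excluded$animal_id,
                       c(object@reference_ids, object@validation_ids))))
    return("excluded animals must not appear in reference or validation")
  TRUE
})

## ---------------------------------------------------------------------------
## Relationship matrices and mixed-model results
## ---------------------------------------------------------------------------

#' RelationshipMatrix: pedigree (A) or genomic (G) covariance structure
#'
#' @slot mat symmetric n x n matrix.
#' @slot kind `"A"` (pedigree numerator relationship) or `"G"` (genomic).
#' @slot tag component tag: `"ALL"`, `"K54"` (chip) or `"WGS"` (selected WGS).
#' @slot ids animal identifiers aligned with rows/columns.
#' @export
setClass("RelationshipMatrix",
         slots = c(mat = "matrix", kind = "character", tag = "character",
                   ids = "character"))

setValidity("RelationshipMatrix", function(object) {
  m <- object@mat
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (nrow(m) != length(object@ids)) return("ids must match matrix dimension")
  if (max(abs(m - t(m))) > 1e-10) return("matrix must be symmetric (1e-10)")
  if (!object@kind %in% c("A", "G")) return("kind must be 'A' or 'G'")
  if (object@kind == "A" && any(diag(m) < 1 - 1e-10))
    return("A-matrix diagonal must be >= 1")
  TRUE
})

#' @rdname RelationshipMatrix-class
#' @param mat,kind,tag,ids slot values; ids default to the matrix rownames.
#' @export
RelationshipMatrix <- function(mat, kind, tag = "ALL", ids = rownames(mat)) {
  if (is.null(ids)) ids <- as.character(seq_len(nrow(mat)))
  dimnames(mat) <- list(ids, ids)
  new("RelationshipMatrix", mat = mat, kind = kind, tag = tag,
      ids = as.character(ids))
}

#' VarianceComponents: REML (or fixed) variance components
#'
#' @slot sigma2 named additive variances, one per random genetic component.
#' @slot sigma2_e residual variance (scale of the weighted residual).
#' @slot loglik restricted log-likelihood at the estimate (NA if not fitted).
#' @slot niter REML iterations used.
#' @slot converged logical.
#' @export
setClass("VarianceComponents",
         slots = c(sigma2 = "numeric", sigma2_e = "numeric",
                   loglik = "numeric", niter = "integer",
                   converged = "logical"))

setValidity("VarianceComponents", function(object) {
  if (any(object@sigma2 < 0) || object@sigma2_e < 0)
    return("variances must be non-negative")
  TRUE
})

#' @rdname VarianceComponents-class
#' @param sigma2,sigma2_e,loglik,niter,converged slot values; an unnamed
#'   single additive variance is tagged `"ALL"`, a pair `"K54"`/`"WGS"`.
#' @export
VarianceComponents <- function(sigma2, sigma2_e, loglik = NA_real_,
                               niter = 0L, converged = NA) {
  if (is.null(names(sigma2)))
    names(sigma2) <- if (length(sigma2) == 1) "ALL" else c("K54", "WGS")
  new("VarianceComponents", sigma2 = sigma2, sigma2_e = sigma2_e,
      loglik = loglik, niter = as.integer(niter), converged = converged)
}

#' EBVSet: estimated breeding values, total and per genetic component
#'
#' @slot ids animal identifiers.
#' @slot mu fitted overall mean.
#' @slot components matrix, animals x genetic components; the total EBV is
#'   the row sum (see [ebvTotal()]).
#' @export
setClass("EBVSet",
         slots = c(ids = "character", mu = "numeric", components = "matrix"))

setValidity("EBVSet", function(object) {
  if (nrow(object@components) != length(object@ids))
    return("component matrix rows must match ids")
  TRUE
})

#' @rdname EBVSet-class
#' @param ids,mu,components slot values.
#' @export
EBVSet <- function(ids, mu, components) {
  if (is.null(colnames(components)))
    colnames(components) <- paste0("comp", seq_len(ncol(components)))
  rownames(components) <- as.character(ids)
  new("EBVSet", ids = as.character(ids), mu = mu, components = components)
}

## ---------------------------------------------------------------------------
## Bayesian mixture model containers
## ---------------------------------------------------------------------------

#' MixtureSpec: prior of the four-distribution SNP-effect mixture
#'
#' SNP effects are a mixture of four zero-mean normals whose variances stand
#' in the fixed ratios 1/1000 : 1/100 : 1/10 : 1 of a single free variance per
#' genetic component; mixing proportions follow a Dirichlet prior. The free
#' variance carries a scaled inverse chi-square prior whose scale is set at
#' fit time from an initial genetic-variance guess.
#'
#' @slot dirichlet Dirichlet pseudo-counts, default `c(125, 25, 5, 1)`.
#' @slot piInit initial mixing proportions, default
#'   `c(0.889, 0.1, 0.01, 0.001)`.
#' @slot ratios class-variance ratios, fixed `c(1/1000, 1/100, 1/10, 1)`.
#' @slot dfSigma prior degrees of freedom of the free class variance
#'   (and of the residual variance), default 4.
#' @export
setClass("MixtureSpec",
         slots = c(dirichlet = "numeric", piInit = "numeric",
                   ratios = "numeric", dfSigma = "numeric"),
         prototype = prototype(dirichlet = c(125, 25, 5, 1),
                               piInit = c(0.889, 0.1, 0.01, 0.001),
                               ratios = c(1e-3, 1e-2, 1e-1, 1),
                               dfSigma = 4))

setValidity("MixtureSpec", function(object) {
  if (length(object@dirichlet) != 4 || any(object@dirichlet <= 0))
    return("dirichlet must be 4 strictly positive counts")
  if (!isTRUE(all.equal(object@ratios, c(1e-3, 1e-2, 1e-1, 1))))
    return("class-variance ratios are fixed at 1/1000, 1/100, 1/10, 1")
  if (abs(sum(object@piInit) - 1) > 1e-6) return("piInit must sum to 1")
  TRUE
})

#' @rdname MixtureSpec-class
#' @param ... slots to override.
#' @export
MixtureSpec <- function(...) new("MixtureSpec", ...)

#' ChainConfig: Gibbs chain length, burn-in, thinning and seed
#'
#' Defaults follow routine practice for this model family: 50,000 iterations,
#' the first 10,000 discarded, every 20th of the remainder saved (2,000
#' posterior samples).
#'
#' @slot nIter,burnIn,thin,seed integers.
#' @export
setClass("ChainConfig",
         slots = c(nIter = "integer", burnIn = "integer", thin = "integer",
                   seed = "integer"),
         prototype = prototype(nIter = 50000L, burnIn = 10000L, thin = 20L,
                               seed = 1L))

setValidity("ChainConfig", function(object) {
  if (object@burnIn >= object@nIter) return("burnIn must be < nIter")
  if (object@thin < 1) return("thin must be >= 1")
  TRUE
})

#' @rdname ChainConfig-class
#' @param nIter,burnIn,thin,seed chain settings.
#' @export
ChainConfig <- function(nIter = 50000L, burnIn = 10000L, thin = 20L,
                        seed = 1L) {
  new("ChainConfig", nIter = as.integer(nIter), burnIn = as.integer(burnIn),
      thin = as.integer(thin), seed = as.integer(seed))
}

#' GibbsFit: saved posterior samples of the four-distribution mixture model
#'
#' @slot mu saved overall-mean samples.
#' @slot sigmaE saved residual-variance samples.
#' @slot components per genetic component: list with `effects`
#'   (samples x SNPs), `pi` (samples x 4), `sigma4` (free-variance samples),
#'   `classProb` (SNPs x 4 posterior class-membership frequencies),
#'   `snp_ids`, `centers` (2p used for centering).
#' @slot spec,chain the [MixtureSpec-class] and [ChainConfig-class] used.
#' @slot animalIds animals the model was fitted to.
#' @export
setClass("GibbsFit",
         slots = c(mu = "numeric", sigmaE = "numeric", components = "list",
                   spec = "MixtureSpec", chain = "ChainConfig",
                   animalIds = "character"))
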