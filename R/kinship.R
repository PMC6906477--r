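## Relationship matrices: pedigree numerator matrix A by the tabular method
## (after tracing genotyped animals a fixed number of generations back) and
## genomic matrices G by VanRaden's first method.

#' Pedigree relationship matrix for a set of genotyped animals
#'
#' Truncates the pedigree to ancestors within `depth` generations of
#' `genotypedIds`, treats the truncation's founders as unrelated and
#' non-inbred, applies the tabular method, and returns the submatrix for the
#' requested animals (in the requested order).
#'
#' @param pedigree a [PedigreeTable-class].
#' @param genotypedIds animals to return the matrix for.
#' @param depth generations traced back from the genotyped animals
#'   (default 3).
#' @return a [RelationshipMatrix-class] of kind `"A"`.
#' @export
computeA <- function(pedigree, genotypedIds = animalIds(pedigree),
                     depth = 3) {
  ped <- pedigreeTable(pedigree)
  genotypedIds <- as.integer(genotypedIds)
  missing <- setdiff(genotypedIds, ped$animal_id)
  if (length(missing))
    stop("animals absent from the pedigree: ",
         paste(missing, collapse = ", "))

  keep <- genotypedIds
  frontier <- genotypedIds
  for (d in seq_len(depth)) {
    rows <- ped[ped$animal_id %in% frontier, ]
    parents <- unique(c(rows$sire_id, rows$dam_id))
    parents <- parents[!is.na(parents)]
    frontier <- setdiff(parents, keep)
    keep <- union(keep, frontier)
    if (!length(frontier)) break
  }
  sub <- ped[ped$animal_id %in% keep, ]
  sub <- sub[order(sub$birth_cohort, sub$animal_id), ]
  n <- nrow(sub)
  idx <- setNames(seq_len(n), sub$animal_id)
  si <- ifelse(is.na(sub$sire_id) | !(sub$sire_id %in% sub$animal_id),
               NA_integer_, idx[as.character(sub$sire_id)])
  di <- ifelse(is.na(sub$dam_id) | !(sub$dam_id %in% sub$animal_id),
               NA_integer_, idx[as.character(sub$dam_id)])

  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (is.na(s)) 0 else A[s, j]) +
                      (if (is.na(d)) 0 else A[d, j]))
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  dimnames(A) <- list(sub$animal_id, sub$animal_id)
  keepChr <- as.character(genotypedIds)
  RelationshipMatrix(A[keepChr, keepChr, drop = FALSE], kind = "A",
                     tag = "ALL", ids = keepChr)
}

#' Genomic relationship matrix, VanRaden method 1
#'
#' G = M M' / (2 sum_j p_j (1 - p_j)), where M is the allele-count matrix of
#' the selected SNPs centered by twice the allele frequency observed in the
#' analyzed individuals.
#'
#' @param panel a [GenotypePanel-class].
#' @param snpSubset a panel label (`"ALL"`, `"CHIP"`, `"DFS"`, `"FRA"`,
#'   `"WGS"` = DFS/FRA union) or an explicit vector of SNP ids.
#' @param tag component tag stored on the result; defaults to `"K54"` for the
#'   chip subset, `"WGS"` for the selected-WGS union, `"ALL"` otherwise.
#' @return a [RelationshipMatrix-class] of kind `"G"`.
#' @export
computeGVanRaden <- function(panel, snpSubset = "ALL", tag = NULL) {
  if (length(snpSubset) == 1 &&
      snpSubset %in% c("ALL", "CHIP", "DFS", "FRA", "WGS")) {
    ids <- panelSnpIds(panel, snpSubset)
    if (is.null(tag))
      tag <- switch(snpSubset, CHIP = "K54", WGS = "WGS", "ALL")
  } else {
    ids <- as.character(snpSubset)
    if (is.null(tag)) tag <- "ALL"
  }
  if (!length(ids)) stop("empty SNP subset")
  geno <- genotypes(panel)[, ids, drop = FALSE]
  p <- colMeans(geno) / 2
  mono <- p == 0 | p == 1 | .colVars(geno) == 0
  if (any(mono))
    stop("monomorphic SNPs in subset (run qcFilter first): ",
         paste(utils::head(ids[mono], 5), collapse = ", "),
         if (sum(mono) > 5) " ..." else "")
  M <- sweep(geno, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(M) / denom
  G <- (G + t(G)) / 2
  RelationshipMatrix(G, kind = "G", tag = tag, ids = rownames(geno))
}

## diagonal jitter making a (possibly rank-deficient) G usable in dense solves
.stabilize <- function(M, eps = 1e-8) M + diag(eps, nrow(M))

## column variances without an extra dependency
.colVars <- function(m) {
  mu <- colMeans(m)
  colMeans(m^2) - mu^2
}
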