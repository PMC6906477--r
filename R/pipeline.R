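## Orchestration and file interchange: PLINK .raw-style genotype I/O, a
## defaulted YAML-configurable end-to-end experiment, and a manifest that
## makes every run reproducible from (config, seed) alone.

#' Write genotypes in PLINK .raw style with a panel-label sidecar
#'
#' The main file is a whitespace table with header `FID IID <snp ids>` and
#' one 0/1/2 entry per SNP; panel labels, causal flags and positions go to
#' `<path>.panels.csv`.
#'
#' @param panel a [GenotypePanel-class].
#' @param path output path of the genotype table.
#' @export
writeGenotypes <- function(panel, path) {
  geno <- genotypes(panel)
  info <- snpInfo(panel)
  header <- paste(c("FID", "IID", info$snp_id), collapse = " ")
  body <- paste(1L, rownames(geno),
                apply(geno, 1, paste, collapse = " "))
  writeLines(c(header, body), path)
  utils::write.csv(info[, c("snp_id", "chrom", "pos_index", "in_chip",
                            "in_dfs", "in_fra", "is_causal")],
                   paste0(path, ".panels.csv"), row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a PLINK .raw-style table
#'
#' Entries outside \{0, 1, 2\} are rejected with the offending line number.
#' Missing entries (`NA`) are rejected unless `imputeToMean = TRUE`, which
#' replaces them by the rounded SNP mean with a warning. A
#' `<path>.panels.csv` sidecar, when present, restores panel labels.
#'
#' @param path genotype table path.
#' @param imputeToMean allow mean imputation of missing entries.
#' @return a [GenotypePanel-class].
#' @export
readGenotypes <- function(path, imputeToMean = FALSE) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty genotype file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  header <- fields[[1]]
  if (length(header) < 3 || header[1] != "FID" || header[2] != "IID")
    stop("malformed header: expected 'FID IID <snp ids>'")
  snps <- header[-(1:2)]
  nf <- length(header)
  rows <- fields[-1]
  bad <- which(lengths(rows) != nf)
  if (length(bad))
    stop("line ", bad[1] + 1L, ": expected ", nf, " fields, found ",
         lengths(rows)[bad[1]])
  ids <- vapply(rows, `[`, character(1), 2L)
  geno <- matrix(NA_integer_, length(rows), length(snps))
  for (i in seq_along(rows)) {
    v <- rows[[i]][-(1:2)]
    isNA <- v %in% c("NA", "na", ".")
    g <- suppressWarnings(as.integer(v))
    badEntry <- !isNA & (is.na(g) | g < 0L | g > 2L)
    if (any(badEntry))
      stop("line ", i + 1L, ": genotype entry '", v[which(badEntry)[1]],
           "' is not in {0, 1, 2}")
    if (any(isNA) && !imputeToMean)
      stop("line ", i + 1L, ": missing genotype; re-run with ",
           "imputeToMean = TRUE to replace by the rounded SNP mean")
    geno[i, ] <- g
  }
  if (anyNA(geno)) {
    warning("mean-imputing ", sum(is.na(geno)), " missing genotypes")
    for (j in which(colSums(is.na(geno)) > 0)) {
      m <- as.integer(round(mean(geno[, j], na.rm = TRUE)))
      geno[is.na(geno[, j]), j] <- m
    }
  }
  rownames(geno) <- ids
  colnames(geno) <- snps
  side <- paste0(path, ".panels.csv")
  info <- if (file.exists(side)) utils::read.csv(side)
          else data.frame(snp_id = snps)
  GenotypePanel(geno, info, animalIds = ids)
}

## ---------------------------------------------------------------------------
## Configuration
## ---------------------------------------------------------------------------

.defaultConfig <- function() list(
  seed = 1L,
  population = list(nFounders = 200L, nGenerations = 4L, siresPerGen = 8L,
                    offspringPerSire = 25L, nChromosomes = 5L,
                    snpsPerChromosome = 240L, recombRate = 1,
                    founderMafRange = c(0.05, 0.5)),
  trait = list(name = "milk", h2 = 0.39, architecture = "mixture",
               nQtl = 60L),
  panels = list(nChip = 800L, nDfs = 40L, nFra = 70L, nOverlap = 5L,
                proximity = 2L),
  drp = list(bullMeanERC = 40, cowMeanERC = 2, sdlog = 0.5,
             drp_set = "bc", bullErcInflation = 1.5),
  qc = list(chipErrorRate = 0.002, wgsErrorRate = 0.01, mafMin = 0.01,
            metricMin = 0.8),
  split = list(birthCutoff = 4L, halfsibWindowStart = 3L,
               familySizeCap = 500L, minValR2 = 0.20),
  models = "G1",
  snpSets = list(K54 = "CHIP", K54_DFS_FRA = "ALL"),
  chain = list(nIter = 3000L, burnIn = 1000L, thin = 4L),
  validation = list(nBoot = 1000L, alpha = 0.05))

.mergeConfig <- function(user, defaults, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults))
      stop("unknown config field: ", here)
    ## enumeration-like fields are replaced wholesale, sections merged
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
                          !nm %in% c("snpSets", "models"))
      .mergeConfig(user[[nm]], defaults[[nm]], here) else user[[nm]]
  }
  defaults
}

#' Resolve an experiment configuration against the defaults
#'
#' @param config a nested list, a YAML file path, or `NULL` for pure
#'   defaults. Unknown fields are schema errors naming the field path;
#'   unknown model names are rejected.
#' @return the fully resolved configuration list.
#' @export
resolveConfig <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  cfg <- .mergeConfig(config, .defaultConfig())
  bad <- setdiff(cfg$models, c("PBLUP", "G1", "G2", "B1", "B2"))
  if (length(bad))
    stop("models: unknown model name '", bad[1], "'")
  cfg
}

## ---------------------------------------------------------------------------
## End-to-end run
## ---------------------------------------------------------------------------

.checksum <- function(x) {
  v <- suppressWarnings(as.numeric(unlist(x, use.names = FALSE)))
  v <- v[is.finite(v)]
  sprintf("n%d_s%.8e", length(v), sum(v * (seq_along(v) %% 97 + 1)))
}

#' Run a full simulate-fit-validate experiment
#'
#' Simulates a half-sib population with chip and selected-WGS panels,
#' injects imputation errors and applies QC, simulates deregressed proofs,
#' splits reference/validation, runs the configured model x SNP-set grid,
#' and writes results, per-scenario EBVs and a manifest to `outDir`.
#' Rerunning with the same configuration and seed reproduces the outputs
#' exactly.
#'
#' @param config see [resolveConfig()].
#' @param outDir output directory (created; `NULL` skips writing).
#' @return invisible list: `config`, `panel`, `drp`, `split`, `grid`
#'   (results/comparisons/ebvs), `manifest`.
#' @export
runExperiment <- function(config = NULL, outDir = NULL) {
  cfg <- resolveConfig(config)
  po <- cfg$population
  ped <- simulatePedigree(po$nFounders, po$nGenerations, po$siresPerGen,
                          po$offspringPerSire, seed = cfg$seed)
  panel0 <- simulateGenotypes(ped, po$nChromosomes, po$snpsPerChromosome,
                              po$founderMafRange, po$recombRate,
                              seed = cfg$seed + 1L)
  trait <- TraitSpec(cfg$trait$name, cfg$trait$h2)
  qtl <- assignQTL(panel0, trait, cfg$trait$architecture, cfg$trait$nQtl,
                   seed = cfg$seed + 2L)
  panel1 <- buildPanels(panel0, qtl, cfg$panels$nChip, cfg$panels$nDfs,
                        cfg$panels$nFra, cfg$panels$nOverlap,
                        cfg$panels$proximity, seed = cfg$seed + 3L)
  rates <- ifelse(snpInfo(panel1)$in_dfs | snpInfo(panel1)$in_fra,
                  cfg$qc$wgsErrorRate, cfg$qc$chipErrorRate)
  imp <- injectImputationErrors(panel1, rates, seed = cfg$seed + 4L)
  qc <- qcFilter(imp$panel, imp$metrics, cfg$qc$mafMin, cfg$qc$metricMin)
  panel <- qc$panel

  pedDf <- pedigreeTable(ped)
  erc <- simulateERC(pedDf$sex, cfg$drp$bullMeanERC, cfg$drp$cowMeanERC,
                     cfg$drp$sdlog, seed = cfg$seed + 5L)
  if (identical(cfg$drp$drp_set, "b"))
    erc[pedDf$sex == "M"] <- erc[pedDf$sex == "M"] * cfg$drp$bullErcInflation
  tbv <- trueBreedingValues(qtl)[as.character(pedDf$animal_id)]
  drp <- simulateDRP(tbv, trait, erc, seed = cfg$seed + 6L)

  split <- splitReferenceValidation(ped, drp, cfg$split$birthCutoff,
                                    cfg$split$halfsibWindowStart,
                                    cfg$split$familySizeCap,
                                    cfg$split$minValR2)
  chain <- ChainConfig(cfg$chain$nIter, cfg$chain$burnIn, cfg$chain$thin,
                       seed = cfg$seed)
  drpList <- setNames(list(drp), traitName(trait))
  grid <- runScenarioGrid(panel, drpList,
                          referenceSets = list(REF = referenceIds(split)),
                          validationIds = validationIds(split),
                          snpSets = cfg$snpSets, models = cfg$models,
                          pedigree = ped, chain = chain,
                          nBoot = cfg$validation$nBoot,
                          alpha = cfg$validation$alpha, seed = cfg$seed)

  manifest <- list(config = cfg, seed = cfg$seed,
                   n_animals = nrow(pedDf), n_snps_postqc = ncol(genotypes(panel)),
                   n_reference = length(referenceIds(split)),
                   n_validation = length(validationIds(split)),
                   checksums = list(genotypes = .checksum(genotypes(panel)),
                                    drp = .checksum(drpRecords(drp)$drp),
                                    results = .checksum(grid$results[
                                      c("reliability", "bias_slope")])))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(grid$results, file.path(outDir, "results.csv"),
                     row.names = FALSE)
    if (!is.null(grid$comparisons))
      utils::write.csv(grid$comparisons,
                       file.path(outDir, "comparisons.csv"),
                       row.names = FALSE)
    for (key in names(grid$ebvs)) {
      e <- grid$ebvs[[key]]
      df <- data.frame(animal_id = animalIds(e), mu = ebvMu(e),
                       ebv_total = unname(ebvTotal(e)))
      df <- cbind(df, as.data.frame(ebvComponents(e)))
      utils::write.csv(df, file.path(outDir, paste0(
        "ebv_", gsub("[^A-Za-z0-9]+", "_", key), ".csv")),
        row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(config = cfg, panel = panel, drp = drp, split = split,
                 grid = grid, manifest = manifest))
}
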