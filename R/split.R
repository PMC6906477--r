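## Reference/validation partitioning mimicking routine dairy cross-validation:
## young cows (plus recent paternal half-sisters) predicted from an older
## reference, with leakage-prone relatives excluded from the reference.

#' Split animals into reference and validation populations
#'
#' Validation candidates are females born in or after `birthCutoff`, together
#' with their female paternal half-sibs born in or after
#' `halfsibWindowStart`. Paternal half-sib families whose candidate group
#' exceeds `familySizeCap` are returned to the reference (to avoid a large
#' loss of reference animals); candidates whose DRP reliability is at or
#' below `minValR2` are excluded. From the reference, the validation animals'
#' maternal half-sibs born in or after `halfsibWindowStart`, the progeny of
#' validation animals, and the sibs (full or half) of those progeny are
#' excluded. Only animals with usable DRP records enter either set.
#'
#' @param pedigree a [PedigreeTable-class].
#' @param drp a [DRPRecords-class] covering the pedigree's genotyped animals.
#' @param birthCutoff first cohort whose females seed the validation set.
#' @param halfsibWindowStart earliest cohort from which half-sibs join the
#'   validation set (and from which maternal half-sibs are excluded).
#' @param familySizeCap largest admissible validation half-sib family
#'   (default 500).
#' @param minValR2 strict lower bound on validation DRP reliability
#'   (default 0.20).
#' @return a [SplitResult-class].
#' @export
splitReferenceValidation <- function(pedigree, drp, birthCutoff,
                                     halfsibWindowStart = birthCutoff - 2,
                                     familySizeCap = 500, minValR2 = 0.20) {
  ped <- pedigreeTable(pedigree)
  recs <- drpRecords(drp)
  recs <- recs[recs$usable, ]
  ped <- ped[ped$animal_id %in% recs$animal_id, ]
  r2 <- setNames(recs$r2_drp, recs$animal_id)

  seedCows <- ped$animal_id[ped$sex == "F" & ped$birth_cohort >= birthCutoff]
  if (length(seedCows) == 0) stop("empty validation: no females born in or ",
                                  "after cohort ", birthCutoff)
  seedSires <- unique(ped$sire_id[ped$animal_id %in% seedCows])
  seedSires <- seedSires[!is.na(seedSires)]
  halfsibs <- ped$animal_id[!is.na(ped$sire_id) &
                              ped$sire_id %in% seedSires &
                              ped$sex == "F" &
                              ped$birth_cohort >= halfsibWindowStart]
  cand <- union(seedCows, halfsibs)

  excluded <- data.frame(animal_id = integer(), reason = character())
  ## family-size cap: oversized candidate families return to the reference
  sires <- setNames(ped$sire_id, ped$animal_id)
  famOf <- sires[as.character(cand)]
  famSize <- table(famOf, useNA = "no")
  big <- as.integer(names(famSize)[famSize > familySizeCap])
  capped <- cand[!is.na(famOf) & famOf %in% big]
  cand <- setdiff(cand, capped)

  lowr2 <- cand[r2[as.character(cand)] <= minValR2]
  cand <- setdiff(cand, lowr2)
  if (length(lowr2))
    excluded <- rbind(excluded, data.frame(animal_id = lowr2,
                                           reason = "low_r2"))
  if (length(cand) == 0) stop("empty validation after reliability and ",
                              "family-size rules")

  validation <- sort(cand)
  refPool <- setdiff(ped$animal_id, validation)

  ## leakage exclusions from the reference
  dams <- setNames(ped$dam_id, ped$animal_id)
  valDams <- unique(dams[as.character(validation)])
  valDams <- valDams[!is.na(valDams)]
  matHS <- ped$animal_id[!is.na(ped$dam_id) & ped$dam_id %in% valDams &
                           ped$birth_cohort >= halfsibWindowStart]
  matHS <- setdiff(matHS, validation)
  progeny <- ped$animal_id[(!is.na(ped$dam_id) & ped$dam_id %in% validation) |
                             (!is.na(ped$sire_id) &
                                ped$sire_id %in% validation)]
  progSires <- unique(sires[as.character(progeny)])
  progDams <- unique(dams[as.character(progeny)])
  progSibs <- ped$animal_id[(!is.na(ped$sire_id) &
                               ped$sire_id %in% progSires[!is.na(progSires)]) |
                              (!is.na(ped$dam_id) &
                                 ped$dam_id %in% progDams[!is.na(progDams)])]
  progSibs <- setdiff(progSibs, c(progeny, validation))

  drop <- list(maternal_halfsib = setdiff(matHS, c(progeny, progSibs)),
               progeny = progeny, progeny_sib = progSibs)
  for (why in names(drop)) {
    ids <- intersect(drop[[why]], refPool)
    if (length(ids))
      excluded <- rbind(excluded, data.frame(animal_id = ids, reason = why))
  }
  reference <- sort(setdiff(refPool, excluded$animal_id))
  new("SplitResult", reference_ids = as.integer(reference),
      validation_ids = as.integer(validation), excluded = excluded)
}
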