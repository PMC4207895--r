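#' Registered phenotype/GEBV trait pairings
#'
#' Each phenotypic trait is analysed in conjunction with its assigned GEBV
#' trait; scan traits recorded separately on bulls and heifers/steers map to
#' a single GEBV.  Synthetic traits pair \code{p.X} with \code{g.X}.
#'
#' @return named character vector, phenotypic trait -> GEBV trait.
#' @export
defaultTraitPairs <- function() {
  c(p.WW = "g.WW", p.YW = "g.YW", p.FW = "g.FW",
    p.BEMA = "g.SEMA", p.HEMA = "g.SEMA",
    p.BRIB = "g.SRIB", p.HRIB = "g.SRIB",
    p.BP8 = "g.SP8", p.HP8 = "g.SP8",
    p.CRIB = "g.CRIB", p.CP8 = "g.CP8", p.CIMF = "g.CIMF", p.CWT = "g.CWT",
    p.SIM = "g.SIM")
}

#' Traits fitted with maternal effects
#'
#' The early weight traits (200-, 400- and 600-day weight) carry maternal
#' genetic and maternal permanent environment effects in the bivariate
#' model; all other traits use the plain direct-genetic model.
#'
#' @return character vector of trait labels.
#' @export
maternalTraits <- function() c("p.WW", "p.YW", "p.FW")

.checkRecords <- function(records) {
  need <- c("animal_id", "trait", "value", "cg")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("phenotype records lack column(s): ", paste(miss, collapse = ", "))
  records
}

.known <- function(x) !is.na(x) & x != "0" & x != ""

#' Delete single-record contemporary groups
#'
#' Every surviving contemporary group (within trait) keeps at least two
#' records.
#'
#' @param records phenotype record data.frame (columns animal_id, trait,
#'   value, cg, ...).
#' @return the filtered records.
#' @export
dropSingleRecordGroups <- function(records) {
  .checkRecords(records)
  key <- paste(records$trait, records$cg)
  n <- table(key)
  out <- records[n[key] >= 2L, , drop = FALSE]
  if (!nrow(out) && nrow(records))
    warning("all contemporary groups had a single record; no records left")
  out
}

#' Weight-trait record exclusions
#'
#' For the early weight traits, a record is kept only if the sire, dam,
#' maternal grandsire and embryo-transfer recipient dam are all known; of
#' multiple records per animal and trait only the first (by
#' \code{record_index}) survives.  Other traits are untouched.
#'
#' @param records phenotype record data.frame; columns sire, dam, mgs,
#'   recipient_dam and record_index are consulted for the weight traits.
#' @param weightTraits trait labels the rule applies to.
#' @return the filtered records.
#' @export
filterWeightRecords <- function(records, weightTraits = maternalTraits()) {
  .checkRecords(records)
  w <- records$trait %in% weightTraits
  if (!any(w)) return(records)
  ok <- !w | (.known(records$sire) & .known(records$dam) &
              .known(records$mgs) & .known(records$recipient_dam))
  records <- records[ok, , drop = FALSE]
  w <- records$trait %in% weightTraits
  ri <- if ("record_index" %in% names(records)) records$record_index
        else seq_len(nrow(records))
  ord <- order(records$animal_id, records$trait, ri)
  dupSorted <- duplicated(paste(records$animal_id, records$trait)[ord])
  dup <- logical(nrow(records))
  dup[ord] <- dupSorted
  records[!(dup & w), , drop = FALSE]
}

#' Reduce records to those connected to the validation set
#'
#' Keeps a record iff the recorded animal is in the validation set, is a
#' direct progeny of a validation animal, or shares a contemporary group
#' with a record of an animal in one of those two groups.  The closure is
#' exactly one contemporary-group step - a CG-mate of a CG-mate is not
#' retained.
#'
#' @param records phenotype record data.frame.
#' @param validationIds character tokens of the validation animals.
#' @param ped a [Pedigree-class] for the progeny lookup.
#' @return the filtered records.
#' @export
reduceByConnection <- function(records, validationIds, ped) {
  .checkRecords(records)
  stopifnot(is(ped, "Pedigree"))
  if (!length(validationIds)) return(records[0, , drop = FALSE])
  tb <- pedigreeTable(ped)
  prog <- tb$animal[(!is.na(tb$sire) & tb$sire %in% validationIds) |
                    (!is.na(tb$dam) & tb$dam %in% validationIds)]
  core <- union(validationIds, prog)
  inCore <- records$animal_id %in% core
  keyCg <- paste(records$trait, records$cg)
  coreCgs <- unique(keyCg[inCore])
  records[inCore | keyCg %in% coreCgs, , drop = FALSE]
}

#' Run the full phenotype filtering pipeline
#'
#' Fixed stage order: weight-trait exclusions (including deduplication to
#' the first record), single-record contemporary-group deletion, then the
#' connection-based reduction (when a validation set is given).  Input and
#' output counts per stage are returned as the filter report.
#'
#' @param records raw phenotype record data.frame.
#' @param validationIds optional validation animal tokens (enables the
#'   connection reduction).
#' @param ped a [Pedigree-class], required with \code{validationIds}.
#' @param weightTraits see [filterWeightRecords()].
#' @return list with \code{records} (filtered) and \code{report}
#'   (data.frame of per-stage record counts).
#' @export
applyPhenotypeFilters <- function(records, validationIds = NULL, ped = NULL,
                                  weightTraits = maternalTraits()) {
  .checkRecords(records)
  report <- data.frame(stage = "input", n = nrow(records))
  rec <- filterWeightRecords(records, weightTraits)
  report <- rbind(report, data.frame(stage = "weight_exclusions", n = nrow(rec)))
  rec <- dropSingleRecordGroups(rec)
  report <- rbind(report, data.frame(stage = "single_record_groups", n = nrow(rec)))
  if (!is.null(validationIds)) {
    if (is.null(ped)) stop("connection reduction requires a pedigree")
    rec <- reduceByConnection(rec, validationIds, ped)
    report <- rbind(report, data.frame(stage = "connection_reduction", n = nrow(rec)))
  }
  list(records = rec, report = report)
}

#' Write a filter report as JSON
#'
#' @param report the \code{report} element of [applyPhenotypeFilters()].
#' @param path output path.
#' @export
writeFilterReport <- function(report, path) {
  jsonlite::write_json(stats::setNames(as.list(report$n), report$stage),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Assemble the bivariate observation vectors for one trait pairing
#'
#' Pairs the filtered phenotype records of one trait with the GEBV records
#' of its assigned GEBV trait and computes the overlap set (animals with
#' both observations), which controls whether a residual covariance is
#' estimable.
#'
#' @param records filtered phenotype record data.frame.
#' @param gebv GEBV table (columns animal_id, pe_label, gebv), already
#'   restricted to one prediction equation.
#' @param trait phenotypic trait label.
#' @param gebvTrait GEBV trait label; must be the registered partner of
#'   \code{trait}.
#' @param pairings named map phenotypic trait -> GEBV trait (default
#'   [defaultTraitPairs()]).
#' @return a [TraitDataset-class].
#' @export
assembleTraitDataset <- function(records, gebv, trait, gebvTrait,
                                 pairings = defaultTraitPairs()) {
  .checkRecords(records)
  if (!trait %in% names(pairings) || pairings[[trait]] != gebvTrait)
    stop("unregistered trait pairing ", trait, " / ", gebvTrait,
         "; valid pairs: ",
         paste(names(pairings), pairings, sep = "->", collapse = ", "))
  if (length(unique(gebv$pe_label)) > 1L)
    stop("GEBV table mixes prediction equations; subset to one pe_label")
  phen <- records[records$trait == trait, , drop = FALSE]
  if (anyDuplicated(phen$animal_id))
    stop("duplicate phenotype records per animal after filtering")
  gtab <- gebv[!duplicated(gebv$animal_id), c("animal_id", "gebv")]
  overlap <- intersect(phen$animal_id, gtab$animal_id)
  new("TraitDataset", phenotypes = phen, gebv = gtab, trait = trait,
      gebvTrait = gebvTrait, overlapIds = overlap)
}
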