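#' Define a synthetic across-breed validation study
#'
#' Describes the full design replicated by [runStudy()]: a multi-breed
#' population, prediction equations trained on named breed subsets (pooled,
#' single-breed, taurine-like subsets), and validation sets of sires plus
#' current-generation animals per validation breed - including, optionally,
#' a breed absent from every training subset.  The default scales the
#' original Angus/Limousin/Brahman design down to desk size: three
#' weakly diverged breeds plus one strongly diverged breed, with 100
#' validation animals per breed.
#'
#' @param breeds named numeric vector: breed label -> FST divergence from
#'   the common ancestral population.
#' @param trainingSubsets named list of breed-label vectors, one per
#'   prediction equation.
#' @param validationBreeds breed labels to validate in.
#' @param nReplicates number of independent replicate studies.
#' @param nFoundersPerBreed,offspringPerBreed,nGenerations population sizing
#'   per breed.
#' @param nSnps,nQtl,qtlSharing,hiddenQtl genetic architecture (see
#'   [simParams()]).
#' @param sigma2A,sigma2E trait variances (plain trait, no maternal
#'   effects).
#' @param cgCount,cgEffectSd contemporary-group structure.
#' @param nValidationSires,nCurrent validation set composition.
#' @param seed master seed.
#' @return list of class \code{studyDesign}.
#' @export
studyDesign <- function(breeds = c(ANG = 0.05, HER = 0.05, BRM = 0.25),
                        trainingSubsets = list(ALL = c("ANG", "HER", "BRM"),
                                               ANG = "ANG", BRM = "BRM"),
                        validationBreeds = c("ANG", "BRM"),
                        nReplicates = 10L,
                        nFoundersPerBreed = 60L, offspringPerBreed = 200L,
                        nGenerations = 2L, nSnps = 600L, nQtl = 60L,
                        qtlSharing = 0.5, hiddenQtl = FALSE,
                        sigma2A = 0.3, sigma2E = 0.7,
                        cgCount = 4L, cgEffectSd = 0.5,
                        nValidationSires = 25L, nCurrent = 75L,
                        seed = 1L) {
  if (is.null(names(breeds)) || anyDuplicated(names(breeds)))
    stop("breeds must be a named vector with unique labels")
  if (anyDuplicated(names(trainingSubsets)))
    stop("training subset names must be unique")
  bad <- setdiff(c(unlist(trainingSubsets), validationBreeds), names(breeds))
  if (length(bad)) stop("unknown breed label(s): ",
                        paste(unique(bad), collapse = ", "))
  out <- list(breeds = breeds, trainingSubsets = trainingSubsets,
              validationBreeds = validationBreeds,
              nReplicates = as.integer(nReplicates),
              nFoundersPerBreed = as.integer(nFoundersPerBreed),
              offspringPerBreed = as.integer(offspringPerBreed),
              nGenerations = as.integer(nGenerations),
              nSnps = as.integer(nSnps), nQtl = as.integer(nQtl),
              qtlSharing = qtlSharing, hiddenQtl = isTRUE(hiddenQtl),
              sigma2A = sigma2A, sigma2E = sigma2E,
              cgCount = as.integer(cgCount), cgEffectSd = cgEffectSd,
              nValidationSires = as.integer(nValidationSires),
              nCurrent = as.integer(nCurrent), seed = as.integer(seed))
  class(out) <- "studyDesign"
  out
}

# one replicate: simulate, train the PEs, validate per breed
.runReplicate <- function(design, rep) {
  labels <- names(design$breeds)
  cfg <- simParams(nBreeds = length(labels),
                   divergenceFst = unname(design$breeds),
                   nSnps = design$nSnps, nQtl = design$nQtl,
                   nFoundersPerBreed = design$nFoundersPerBreed,
                   nGenerations = design$nGenerations,
                   offspringPerBreed = design$offspringPerBreed,
                   sigma2A = design$sigma2A, sigma2E = design$sigma2E,
                   qtlSharing = design$qtlSharing,
                   hiddenQtl = design$hiddenQtl,
                   cgCount = design$cgCount, cgEffectSd = design$cgEffectSd,
                   seed = (design$seed * 977L + rep * 131L) %% 2147483647L)
  pop <- simulatePopulation(cfg)
  toB <- stats::setNames(paste0("B", seq_along(labels)), labels)
  h2 <- design$sigma2A / (design$sigma2A + design$sigma2E)

  # validation sets first; every training set excludes them all
  valSets <- lapply(design$validationBreeds, function(vb) {
    makeTrainingValidationSplit(
      pop, trainingBreeds = lapply(design$trainingSubsets,
                                   function(b) unname(toB[b])),
      validationBreed = unname(toB[vb]),
      nValidationSires = design$nValidationSires,
      nCurrent = design$nCurrent)$validation
  })
  names(valSets) <- design$validationBreeds
  allVal <- unique(unlist(valSets))

  phen <- pop@phenotypes
  pes <- lapply(names(design$trainingSubsets), function(lbl) {
    bs <- unname(toB[design$trainingSubsets[[lbl]]])
    ids <- intersect(phen$animal_id,
                     setdiff(names(pop@breedOf)[pop@breedOf %in% bs], allVal))
    Gtr <- computeAlleleFreqs(subsetGenotypes(pop@genotypes, ids = ids))
    y <- phen$value[match(ids, phen$animal_id)]
    trainSnpBlup(Gtr, y, h2Assumed = h2, label = lbl)
  })
  names(pes) <- names(design$trainingSubsets)

  rows <- list()
  for (vb in design$validationBreeds) {
    valIds <- valSets[[vb]]
    breedIds <- names(pop@breedOf)[pop@breedOf == toB[vb]]
    recs <- phen[phen$animal_id %in% breedIds, , drop = FALSE]
    filt <- applyPhenotypeFilters(recs, validationIds = valIds,
                                  ped = pop@pedigree)
    Gval <- subsetGenotypes(pop@genotypes, ids = valIds)
    anchors <- unique(c(filt$records$animal_id, valIds))
    ped3 <- pruneToGenerations(pop@pedigree, anchors, nGen = 3L)
    ainv <- aInverse(ped3)
    for (lbl in names(pes)) {
      gtab <- suppressWarnings(applyPE(pes[[lbl]], Gval))
      dsn <- assembleTraitDataset(filt$records, gtab, "p.SIM", "g.SIM")
      fit <- tryCatch(remlFit(dsn, ainv, maternal = FALSE),
                      error = function(e) e)
      failed <- inherits(fit, "error")
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = rep, validation_breed = vb, trait = "p.SIM",
        pe_label = lbl,
        rg = if (failed) NA_real_ else fit@rg,
        se_rg = if (failed) NA_real_ else fit@seRg,
        h2_gebv = if (failed) NA_real_ else fit@h2Gebv,
        se_h2 = if (failed) NA_real_ else fit@seH2Gebv,
        n_pheno = nrow(dsn@phenotypes), n_gebv = nrow(dsn@gebv),
        converged = if (failed) FALSE else fit@converged,
        error = if (failed) conditionMessage(fit) else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the replicated synthetic study
#'
#' Executes the full factorial (replicate x validation breed x prediction
#' equation): simulates the population, trains the prediction equations on
#' the designated subsets (validation animals excluded), applies them to
#' the validation genotypes, filters the phenotype records, and estimates
#' each GEBV's accuracy as the genetic correlation in the bivariate REML
#' model.  Per-cell failures are caught and flagged, never dropped.
#'
#' @param design a [studyDesign()].
#' @param verbose print a line per replicate.
#' @return the result grid: a data.frame with one row per cell (columns
#'   replicate, validation_breed, trait, pe_label, rg, se_rg, h2_gebv,
#'   se_h2, n_pheno, n_gebv, converged, error).
#' @export
runStudy <- function(design, verbose = FALSE) {
  stopifnot(inherits(design, "studyDesign"))
  out <- list()
  for (rep in seq_len(design$nReplicates)) {
    if (verbose) message("replicate ", rep, "/", design$nReplicates)
    out[[rep]] <- .runReplicate(design, rep)
  }
  grid <- do.call(rbind, out)
  attr(grid, "design") <- design
  grid
}

#' Summarize a study result grid
#'
#' Trait-averaged mean accuracy (genetic correlation) per validation breed
#' and prediction equation, over converged cells only; failed cells are
#' tallied separately.
#'
#' @param grid a result grid from [runStudy()].
#' @return list with \code{summary} (data.frame validation_breed, pe_label,
#'   mean_rg, mean_h2_gebv, n_cells, n_failed) and \code{markdown} (report
#'   lines).
#' @export
summarizeGrid <- function(grid) {
  if (!nrow(grid)) stop("empty result grid")
  key <- interaction(grid$validation_breed, grid$pe_label, drop = TRUE)
  rows <- lapply(split(grid, key), function(g) {
    ok <- g$converged & !is.na(g$rg)
    data.frame(validation_breed = g$validation_breed[1],
               pe_label = g$pe_label[1],
               mean_rg = if (any(ok)) mean(g$rg[ok]) else NA_real_,
               mean_h2_gebv = if (any(ok)) mean(g$h2_gebv[ok]) else NA_real_,
               n_cells = nrow(g), n_failed = sum(!ok),
               stringsAsFactors = FALSE)
  })
  s <- do.call(rbind, rows)
  s <- s[order(s$validation_breed, s$pe_label), ]
  rownames(s) <- NULL
  md <- c("| breed | PE | mean r_g | mean h2(GEBV) | cells | failed |",
          "|---|---|---|---|---|---|",
          sprintf("| %s | %s | %.3f | %.3f | %d | %d |",
                  s$validation_breed, s$pe_label, s$mean_rg,
                  s$mean_h2_gebv, s$n_cells, s$n_failed))
  list(summary = s, markdown = md)
}

#' Write a study grid and its summary
#'
#' @param grid result grid from [runStudy()].
#' @param dir output directory (created if needed); writes
#'   \code{grid.csv} and \code{summary.md}.
#' @return invisibly, the file paths.
#' @export
writeStudyResults <- function(grid, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f1 <- file.path(dir, "grid.csv")
  utils::write.csv(grid, f1, row.names = FALSE)
  f2 <- file.path(dir, "summary.md")
  writeLines(summarizeGrid(grid)$markdown, f2)
  invisible(c(f1, f2))
}
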