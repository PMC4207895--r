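#' Accessors
#'
#' Small accessor generics shared across the package's classes.
#'
#' @param x an object.
#' @return \code{animalIds}: character vector of animal tokens.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' @rdname accessors
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @describeIn Pedigree-class animal tokens in topological order.
#' @param x a Pedigree.
#' @export
setMethod("animalIds", "Pedigree", function(x) x@id)

#' @describeIn Pedigree-class number of animals.
#' @export
setMethod("nAnimals", "Pedigree", function(x) length(x@id))

#' @describeIn RelationshipMatrix-class row/column tokens.
#' @param x a RelationshipMatrix.
#' @export
setMethod("animalIds", "RelationshipMatrix", function(x) x@ids)

#' @describeIn SparseInverse-class row/column tokens.
#' @param x a SparseInverse.
#' @export
setMethod("animalIds", "SparseInverse", function(x) x@ids)

#' @describeIn GenotypeMatrix-class animal tokens (rows).
#' @param x a GenotypeMatrix.
#' @export
setMethod("animalIds", "GenotypeMatrix", function(x) x@ids)

#' @describeIn GenotypeMatrix-class number of genotyped animals.
#' @export
setMethod("nAnimals", "GenotypeMatrix", function(x) length(x@ids))

#' @describeIn GenotypeMatrix-class SNP tokens (columns).
#' @export
setMethod("snpIds", "GenotypeMatrix", function(x) x@snpIds)

#' @describeIn PredictionEquation-class SNP tokens the effects refer to.
#' @param x a PredictionEquation.
#' @export
setMethod("snpIds", "PredictionEquation", function(x) x@snpIds)

#' @describeIn Pedigree-class tabular view (animal, sire, dam tokens,
#'   generation index); unknown parents are \code{NA}.
#' @param object a Pedigree.
#' @export
pedigreeTable <- function(object) {
  stopifnot(is(object, "Pedigree"))
  tok <- function(i) ifelse(i == 0L, NA_character_, object@id[pmax(i, 1L)])
  data.frame(animal = object@id, sire = tok(object@sire),
             dam = tok(object@dam), generation = object@generation,
             stringsAsFactors = FALSE)
}

#' @describeIn Pedigree-class generation index per animal (founders are 0).
#' @export
generationIndex <- function(object) {
  stopifnot(is(object, "Pedigree"))
  stats::setNames(object@generation, object@id)
}

setMethod("show", "Pedigree", function(object) {
  n <- length(object@id)
  nf <- sum(object@sire == 0L & object@dam == 0L)
  cat("Pedigree with", n, "animals (", nf, "founders ),",
      "max generation", if (n) max(object@generation) else 0, "\n")
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat("RelationshipMatrix:", length(object@ids), "animals, mean diagonal",
      format(mean(diag(object@values)), digits = 4), "\n")
})

setMethod("show", "SparseInverse", function(object) {
  cat("SparseInverse (A^-1):", length(object@ids), "animals,",
      length(object@mat@x), "stored entries, logdet(A) =",
      format(object@logdet, digits = 6), "\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", length(object@ids), "animals x",
      length(object@snpIds), "SNPs\n")
})

setMethod("show", "PredictionEquation", function(object) {
  m <- object@trainingMeta
  cat("PredictionEquation:", length(object@effects), "SNP effects,",
      "intercept", format(object@intercept, digits = 4))
  if (!is.null(m$label)) cat(", training set", m$label)
  if (!is.null(m$n)) cat(" (n =", m$n, ")")
  cat("\n")
})

setMethod("show", "TraitDataset", function(object) {
  cat("TraitDataset:", object@trait, "vs", object@gebvTrait, "-",
      nrow(object@phenotypes), "phenotype records,",
      nrow(object@gebv), "GEBV records,",
      length(object@overlapIds), "overlap animals\n")
})

setMethod("show", "REMLResult", function(object) {
  cat("REMLResult (", object@model, "model ): logL =",
      format(object@loglik, digits = 8),
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  cat("  r_g =", format(object@rg, digits = 3), "+/-",
      format(object@seRg, digits = 3),
      " h2_GEBV =", format(object@h2Gebv, digits = 3), "+/-",
      format(object@seH2Gebv, digits = 3), "\n")
  est <- rbind(estimate = object@estimates, se = object@se)
  print(round(est, 4))
})

setMethod("show", "SimulatedPopulation", function(object) {
  cat("SimulatedPopulation:", nAnimals(object@pedigree), "animals,",
      length(unique(object@breedOf)), "breeds,",
      length(snpIds(object@genotypes)), "marker SNPs,",
      nrow(object@phenotypes), "phenotype records\n")
})
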