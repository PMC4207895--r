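#' @import methods
#' @import Matrix
NULL

#' Pedigree of a seed-stock population
#'
#' Stores animal/sire/dam triples in topological order (every parent precedes
#' all of its offspring).  Unknown parents are coded internally as index
#' \code{0L} and treated as unrelated founders.  IDs are opaque tokens mapped
#' to dense integer indices; the mapping is the \code{id} slot.
#'
#' @slot id character vector of animal tokens, in topological order.
#' @slot sire,dam integer vectors of parent indices into \code{id}
#'   (\code{0L} means unknown).
#' @slot generation integer generation index per animal: 0 for animals with
#'   both parents unknown, otherwise 1 + max(parental generation).
#'
#' @seealso [readPedigree()], [additiveRelationshipMatrix()], [aInverse()]
#' @export
setClass("Pedigree",
  representation(id = "character", sire = "integer", dam = "integer",
                 generation = "integer"))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (length(object@sire) != n || length(object@dam) != n ||
      length(object@generation) != n)
    return("id, sire, dam and generation must have equal length")
  if (anyDuplicated(object@id))
    return("duplicate animal ids")
  idx <- seq_len(n)
  if (any(object@sire < 0L) || any(object@dam < 0L) ||
      any(object@sire > n) || any(object@dam > n))
    return("parent indices out of range")
  # topological order: parents strictly precede offspring
  if (any(object@sire >= idx) || any(object@dam >= idx))
    return("pedigree not topologically ordered (a parent does not precede its offspring)")
  TRUE
})

#' Numerator relationship matrix
#'
#' Dense symmetric matrix of additive relationships among a set of animals.
#' For a pedigree-derived matrix the diagonal elements are \eqn{1 + F_i}
#' with \eqn{F_i} the inbreeding coefficient; the class also holds genomic
#' relationship matrices, whose diagonal averages 1 but may drop below it.
#'
#' @slot ids ordered animal tokens (row/column labels).
#' @slot values symmetric numeric matrix.
#' @export
setClass("RelationshipMatrix",
  representation(ids = "character", values = "matrix"))

setValidity("RelationshipMatrix", function(object) {
  v <- object@values
  if (nrow(v) != length(object@ids) || ncol(v) != length(object@ids))
    return("matrix dimension does not match ids")
  if (nrow(v) && max(abs(v - t(v))) > 1e-8)
    return("relationship matrix not symmetric")
  if (nrow(v) && any(diag(v) <= 0))
    return("diagonal elements must be positive")
  TRUE
})

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembled directly from the pedigree by Henderson's rules with
#' Mendelian-sampling variances from parental inbreeding, so the dense
#' inverse is never formed.
#'
#' @slot ids ordered animal tokens.
#' @slot mat sparse symmetric matrix (\code{Matrix} package) holding
#'   \eqn{A^{-1}}.
#' @slot logdet log-determinant of \eqn{A} (not of the inverse), a by-product
#'   of the Mendelian-sampling variances, reused by the REML likelihood.
#' @export
setClass("SparseInverse",
  representation(ids = "character", mat = "Matrix", logdet = "numeric"))

#' Genotype matrix (allele dosages)
#'
#' Animals by SNPs matrix of alternate-allele counts 0/1/2 (NA for missing),
#' together with per-SNP reference allele frequencies (computed on a training
#' set or supplied).
#'
#' @slot ids animal tokens (rows).
#' @slot snpIds SNP tokens (columns).
#' @slot dosages numeric matrix, entries in \{0, 1, 2, NA\}.
#' @slot alleleFreqs per-SNP allele frequency in (0, 1); may be NA before
#'   [computeAlleleFreqs()] is called.
#' @export
setClass("GenotypeMatrix",
  representation(ids = "character", snpIds = "character",
                 dosages = "matrix", alleleFreqs = "numeric"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  if (nrow(d) != length(object@ids)) return("row count != length(ids)")
  if (ncol(d) != length(object@snpIds)) return("column count != length(snpIds)")
  if (length(object@alleleFreqs) != ncol(d))
    return("alleleFreqs length != SNP count")
  dd <- d[!is.na(d)]
  if (length(dd) && !all(dd %in% c(0, 1, 2)))
    return("dosages must be 0, 1, 2 or NA")
  TRUE
})

#' Prediction equation (per-SNP allele substitution effects)
#'
#' A GEBV is the pure linear function
#' \eqn{\hat g_i = \mu + \sum_k x_{ik}\alpha_k} of an animal's allele
#' dosages \eqn{x_{ik}}.
#'
#' @slot snpIds SNP tokens the effects refer to.
#' @slot effects allele substitution effects, trait units per allele copy.
#' @slot intercept trait units.
#' @slot trainingMeta named list: training subset label, n, lambda, assumed
#'   h2, training allele frequencies (used to impute missing dosages).
#' @export
setClass("PredictionEquation",
  representation(snpIds = "character", effects = "numeric",
                 intercept = "numeric", trainingMeta = "list"))

setValidity("PredictionEquation", function(object) {
  if (length(object@effects) != length(object@snpIds))
    return("effects length != snpIds length")
  if (length(object@intercept) != 1L) return("intercept must be scalar")
  TRUE
})

#' Analysis-ready trait dataset
#'
#' The observation vectors of the bivariate model: filtered phenotype records
#' of one trait plus the GEBV records of its assigned GEBV trait, aligned by
#' animal.  \code{overlapIds} are the animals observed on both; only those
#' carry a residual covariance.
#'
#' @slot phenotypes data.frame with columns animal_id, value, cg, sire, dam
#'   (dam required when a maternal model is fitted).
#' @slot gebv data.frame with columns animal_id, gebv.
#' @slot trait,gebvTrait trait labels.
#' @slot overlapIds animals with both a phenotype and a GEBV record.
#' @export
setClass("TraitDataset",
  representation(phenotypes = "data.frame", gebv = "data.frame",
                 trait = "character", gebvTrait = "character",
                 overlapIds = "character"))

#' Result of a REML fit
#'
#' @slot estimates named numeric vector of variance components (trait
#'   units squared).
#' @slot se named numeric vector of standard errors (same names), from the
#'   inverse average-information matrix.
#' @slot vcov covariance matrix of the estimated components.
#' @slot loglik restricted log-likelihood at the optimum.
#' @slot converged logical convergence flag.
#' @slot iterations function evaluations used by the optimizer.
#' @slot h2Gebv,seH2Gebv heritability of the GEBV and its SE.
#' @slot rg,seRg genetic correlation between phenotypic trait and GEBV
#'   (the GEBV accuracy) and its SE.
#' @slot model "maternal" or "plain" (and "univariate" variants).
#' @export
setClass("REMLResult",
  representation(estimates = "numeric", se = "numeric", vcov = "matrix",
                 loglik = "numeric", converged = "logical",
                 iterations = "integer", h2Gebv = "numeric",
                 seH2Gebv = "numeric", rg = "numeric", seRg = "numeric",
                 model = "character"))

#' Simulated multi-breed population with known truth
#'
#' @slot pedigree a [Pedigree-class].
#' @slot genotypes a [GenotypeMatrix-class] (marker panel; excludes QTL when
#'   the hidden-QTL mode is on).
#' @slot breedOf named character vector, breed per animal.
#' @slot trueBvDirect,trueBvMaternal named numeric vectors of true breeding
#'   values (trait units).
#' @slot phenotypes data.frame of simulated records (animal_id, trait, value,
#'   cg, sire, dam, mgs, recipient_dam, record_index).
#' @slot truth list: the generating configuration, realized QTL effects,
#'   QTL dosages, per-breed allele frequencies.
#' @export
setClass("SimulatedPopulation",
  representation(pedigree = "Pedigree", genotypes = "GenotypeMatrix",
                 breedOf = "character", trueBvDirect = "numeric",
                 trueBvMaternal = "numeric", phenotypes = "data.frame",
                 truth = "list"))
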