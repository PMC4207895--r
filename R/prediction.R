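#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix of allele counts 0/1/2 (NA = missing);
#'   row names are animal ids and column names SNP ids unless given
#'   explicitly.
#' @param ids,snps optional explicit tokens.
#' @param alleleFreqs optional per-SNP frequencies; left NA otherwise (see
#'   [computeAlleleFreqs()]).
#' @return a [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(dosages, ids = rownames(dosages),
                           snps = colnames(dosages), alleleFreqs = NULL) {
  if (is.null(ids)) ids <- paste0("id", seq_len(nrow(dosages)))
  if (is.null(snps)) snps <- paste0("SNP", seq_len(ncol(dosages)))
  if (is.null(alleleFreqs)) alleleFreqs <- rep(NA_real_, ncol(dosages))
  dimnames(dosages) <- list(ids, snps)
  new("GenotypeMatrix", ids = as.character(ids), snpIds = as.character(snps),
      dosages = dosages, alleleFreqs = alleleFreqs)
}

#' @describeIn GenotypeMatrix observed allele frequencies (half the mean
#'   dosage, missing values skipped) stored into the object.
#' @param G a GenotypeMatrix.
#' @export
computeAlleleFreqs <- function(G) {
  stopifnot(is(G, "GenotypeMatrix"))
  G@alleleFreqs <- colMeans(G@dosages, na.rm = TRUE) / 2
  G
}

#' @describeIn GenotypeMatrix subset by animals and/or SNPs (tokens).
#' @param ids,snps tokens to keep (NULL = all).
#' @export
subsetGenotypes <- function(G, ids = NULL, snps = NULL) {
  stopifnot(is(G, "GenotypeMatrix"))
  ri <- if (is.null(ids)) seq_along(G@ids) else match(ids, G@ids)
  ci <- if (is.null(snps)) seq_along(G@snpIds) else match(snps, G@snpIds)
  if (anyNA(ri)) stop("unknown animal id(s) in subset")
  if (anyNA(ci)) stop("unknown SNP id(s) in subset")
  new("GenotypeMatrix", ids = G@ids[ri], snpIds = G@snpIds[ci],
      dosages = G@dosages[ri, ci, drop = FALSE],
      alleleFreqs = G@alleleFreqs[ci])
}

#' Read / write genotype dosage tables
#'
#' Tab-separated text with a header of SNP ids and a leading \code{id}
#' column, one row per animal (PLINK-RAW-like allele counts).
#'
#' @param path file path.
#' @return \code{readGenotypes}: a [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  GenotypeMatrix(m, ids = ids, snps = colnames(df)[-1])
}

#' @rdname readGenotypes
#' @param G a [GenotypeMatrix-class].
#' @export
writeGenotypes <- function(G, path) {
  df <- data.frame(id = G@ids, G@dosages, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

# centered dosage matrix: missing -> 2p (i.e. 0 after centering);
# returns list(Z, freqs, keep) with monomorphic SNPs dropped
.centeredDosages <- function(G, freqs = NULL, dropMono = TRUE) {
  d <- G@dosages
  if (is.null(freqs)) {
    freqs <- G@alleleFreqs
    if (anyNA(freqs)) freqs <- colMeans(d, na.rm = TRUE) / 2
  }
  keep <- seq_len(ncol(d))
  if (dropMono) {
    keep <- which(freqs > 0 & freqs < 1)
    if (length(keep) < ncol(d))
      message(ncol(d) - length(keep), " monomorphic SNP(s) dropped")
  }
  Z <- sweep(d[, keep, drop = FALSE], 2, 2 * freqs[keep])
  Z[is.na(Z)] <- 0
  list(Z = Z, freqs = freqs[keep], keep = keep)
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' \eqn{G = ZZ^\top / (2\sum_k p_k(1-p_k))} with Z the dosages centered by
#' twice the allele frequency; monomorphic SNPs are dropped with a message
#' and missing dosages are mean-imputed.
#'
#' @param G a [GenotypeMatrix-class].
#' @param freqs optional reference allele frequencies (defaults to the
#'   frequencies stored in \code{G}, or observed ones).
#' @return a [RelationshipMatrix-class].
#' @export
buildGRM <- function(G, freqs = NULL) {
  stopifnot(is(G, "GenotypeMatrix"))
  cd <- .centeredDosages(G, freqs)
  denom <- 2 * sum(cd$freqs * (1 - cd$freqs))
  if (denom <= 0) stop("no polymorphic SNPs to build a GRM from")
  grm <- tcrossprod(cd$Z) / denom
  dimnames(grm) <- list(G@ids, G@ids)
  new("RelationshipMatrix", ids = G@ids, values = grm)
}

#' Train a SNP-BLUP prediction equation
#'
#' Ridge solution for the allele substitution effects,
#' \eqn{\hat\alpha = (Z^\top Z + \lambda I)^{-1} Z^\top (y - \bar y)} with
#' \eqn{\lambda = 2\sum_k p_k(1-p_k)\,(1-h^2)/h^2}, which makes the implied
#' GEBV identical to GBLUP breeding values from the VanRaden GRM.  Solved
#' through the n-by-n dual system when the marker count exceeds the animal
#' count.  The intercept absorbs the centering so that
#' GEBV = intercept + raw dosages times effects.
#'
#' @param G training [GenotypeMatrix-class].
#' @param y response vector (one record per training animal, same order).
#' @param h2Assumed assumed heritability in (0, 1) driving the shrinkage.
#' @param label training-subset label stored in the metadata.
#' @param lambda optional explicit ridge parameter overriding the h2 rule.
#' @return a [PredictionEquation-class].
#' @export
trainSnpBlup <- function(G, y, h2Assumed = 0.3, label = "TRAIN",
                         lambda = NULL) {
  stopifnot(is(G, "GenotypeMatrix"), length(y) == length(G@ids))
  if (is.null(lambda)) {
    if (!is.numeric(h2Assumed) || h2Assumed <= 0 || h2Assumed >= 1)
      stop("h2Assumed must be in (0, 1)")
  }
  cd <- .centeredDosages(G)
  Z <- cd$Z
  n <- nrow(Z)
  m <- ncol(Z)
  sumpq <- sum(cd$freqs * (1 - cd$freqs))
  if (is.null(lambda)) lambda <- 2 * sumpq * (1 - h2Assumed) / h2Assumed
  yc <- y - mean(y)
  if (m > n) {
    K <- tcrossprod(Z)
    alpha <- drop(crossprod(Z, solve(K + diag(lambda, n), yc)))
  } else {
    alpha <- drop(solve(crossprod(Z) + diag(lambda, m), crossprod(Z, yc)))
  }
  intercept <- mean(y) - sum(2 * cd$freqs * alpha)
  new("PredictionEquation", snpIds = G@snpIds[cd$keep], effects = alpha,
      intercept = intercept,
      trainingMeta = list(label = label, n = n, lambda = lambda,
                          h2Assumed = if (is.null(h2Assumed)) NA else h2Assumed,
                          freqs = cd$freqs))
}

#' Apply a prediction equation to genotypes
#'
#' \eqn{\hat g_i = \mu + \sum_k x_{ik} \alpha_k} over the intersection of
#' the equation's SNPs with the genotype panel; missing dosages are imputed
#' with twice the training allele frequency.
#'
#' @param pe a [PredictionEquation-class].
#' @param G a [GenotypeMatrix-class].
#' @param label value for the \code{pe_label} column (defaults to the
#'   training label).
#' @return a GEBV table: data.frame with columns
#'   \code{animal_id, pe_label, gebv}.
#' @export
applyPE <- function(pe, G, label = pe@trainingMeta$label) {
  stopifnot(is(pe, "PredictionEquation"), is(G, "GenotypeMatrix"))
  common <- intersect(pe@snpIds, G@snpIds)
  if (!length(common)) stop("no SNPs shared between equation and genotypes")
  if (length(common) < 0.5 * length(pe@snpIds))
    warning("only ", length(common), " of ", length(pe@snpIds),
            " equation SNPs present in the genotypes")
  k <- match(common, pe@snpIds)
  X <- G@dosages[, match(common, G@snpIds), drop = FALSE]
  if (anyNA(X)) {
    f2 <- if (is.null(pe@trainingMeta$freqs)) colMeans(X, na.rm = TRUE)
          else 2 * pe@trainingMeta$freqs[k]
    for (j in seq_along(common)) {
      miss <- is.na(X[, j])
      if (any(miss)) X[miss, j] <- f2[j]
    }
  }
  gebv <- pe@intercept + drop(X %*% pe@effects[k])
  data.frame(animal_id = G@ids, pe_label = if (is.null(label)) "PE" else label,
             gebv = gebv, stringsAsFactors = FALSE)
}

#' Cross-validated accuracy of a prediction equation
#'
#' k-fold cross-validation of SNP-BLUP on one genotype/response set: for
#' each fold the equation is trained on the remainder and the product-moment
#' correlation between predicted GEBV and the held-out responses is
#' reported.  Folds are animal-wise random, or family-aware when
#' \code{groups} is given (whole groups, e.g. sire families, are held out
#' together; relatedness between training and holdout otherwise inflates
#' the apparent accuracy).
#'
#' @param G a [GenotypeMatrix-class].
#' @param y response vector.
#' @param kFolds number of folds (default 5).
#' @param h2Assumed shrinkage heritability passed to [trainSnpBlup()].
#' @param seed fold-assignment seed.
#' @param groups optional factor of family labels (one per animal).
#' @return list with \code{perFold} correlations and their \code{mean}.
#' @export
crossvalidatePE <- function(G, y, kFolds = 5L, h2Assumed = 0.3, seed = 1L,
                            groups = NULL) {
  stopifnot(is(G, "GenotypeMatrix"), length(y) == length(G@ids), kFolds >= 2L)
  set.seed(seed)
  n <- length(y)
  if (is.null(groups)) {
    fold <- sample(rep_len(seq_len(kFolds), n))
  } else {
    g <- as.factor(groups)
    gf <- sample(rep_len(seq_len(kFolds), nlevels(g)))
    fold <- gf[as.integer(g)]
  }
  acc <- numeric(kFolds)
  for (f in seq_len(kFolds)) {
    hold <- which(fold == f)
    if (length(hold) < 10L)
      warning("fold ", f, " has fewer than 10 animals")
    Gtr <- subsetGenotypes(G, ids = G@ids[-hold])
    pe <- trainSnpBlup(Gtr, y[-hold], h2Assumed = h2Assumed,
                       label = paste0("fold", f))
    pred <- applyPE(pe, subsetGenotypes(G, ids = G@ids[hold]))
    acc[f] <- stats::cor(pred$gebv, y[hold])
  }
  list(perFold = acc, mean = mean(acc))
}

#' Naive inner-product accuracy estimate
#'
#' The plain product-moment correlation between a GEBV vector and a response
#' vector - the usual cross-validation style accuracy estimator.  Its
#' expectation rests on inner products of random vectors whose covariance is
#' a relationship matrix times a scalar; when the mean diagonal of that
#' matrix exceeds 1 (inbreeding, genomic relationships), the estimated
#' covariance and hence the accuracy is inflated.  Supplying \code{K}
#' attaches the mean diagonal as attribute \code{meanKDiag} as the
#' inflation diagnostic.
#'
#' @param gebv,response equal-length numeric vectors.
#' @param K optional [RelationshipMatrix-class] of the animals involved.
#' @param center subtract sample means first (the plain correlation,
#'   default).  \code{center = FALSE} uses raw inner products of the
#'   vectors, treating them as having expectation zero - the form whose
#'   expectation is the trace argument above, and the one that exposes the
#'   inflation (sample centering partially hides it and additionally
#'   absorbs any genetic trend).
#' @return the correlation (scalar), with attribute \code{meanKDiag} when
#'   \code{K} is supplied.
#' @export
innerProductAccuracy <- function(gebv, response, K = NULL, center = TRUE) {
  if (length(gebv) != length(response)) stop("unequal vector lengths")
  if (stats::sd(gebv) == 0 || stats::sd(response) == 0)
    stop("zero variance: correlation undefined")
  r <- if (center) stats::cor(gebv, response)
       else sum(gebv * response) / sqrt(sum(gebv^2) * sum(response^2))
  if (!is.null(K)) {
    stopifnot(is(K, "RelationshipMatrix"))
    attr(r, "meanKDiag") <- mean(diag(K@values))
  }
  r
}

#' Read / write prediction-equation files
#'
#' Tab-separated \code{snp_id, effect} rows preceded by \code{# key=value}
#' comment lines carrying the intercept and training metadata.
#'
#' @param pe a [PredictionEquation-class].
#' @param path file path.
#' @export
writePE <- function(pe, path) {
  meta <- pe@trainingMeta
  hdr <- c(paste0("# intercept=", format(pe@intercept, digits = 17)),
           paste0("# label=", meta$label %||% "PE"),
           paste0("# n=", meta$n %||% NA),
           paste0("# lambda=", format(meta$lambda %||% NA, digits = 17)))
  writeLines(c(hdr, "snp_id\teffect",
               paste(pe@snpIds, format(pe@effects, digits = 17), sep = "\t")),
             path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname writePE
#' @return \code{readPE}: a [PredictionEquation-class] (training allele
#'   frequencies are not persisted; missing-dosage imputation then falls
#'   back to the target panel's own frequencies).
#' @export
readPE <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  kv <- do.call(rbind, strsplit(sub("^#\\s*", "", meta), "="))
  vals <- stats::setNames(kv[, 2], kv[, 1])
  body <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                            header = TRUE)
  new("PredictionEquation", snpIds = as.character(body$snp_id),
      effects = as.numeric(body$effect),
      intercept = as.numeric(vals[["intercept"]]),
      trainingMeta = list(label = unname(vals["label"]),
                          n = as.integer(vals["n"]),
                          lambda = as.numeric(vals["lambda"]),
                          freqs = NULL))
}
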