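#' Simulation parameters for a multi-breed population
#'
#' Bundles and validates the generating parameters of the synthetic
#' populations used for parameter-recovery testing.  Defaults describe a
#' beef-weight-like trait on the phenotypic-variance scale 1: direct
#' heritability 0.3, maternal heritability 0.1, a mildly antagonistic
#' direct-maternal covariance, and a modest maternal permanent environment,
#' with moderate breed divergence (FST 0.1).
#'
#' @param nBreeds number of breeds.
#' @param divergenceFst Wright's FST of each breed from the common ancestral
#'   population; scalar or one value per breed.  0 is allowed (breeds
#'   identical).
#' @param nSnps marker panel size.
#' @param nQtl number of trait loci.  By default QTL are a random subset of
#'   the markers (effects sit on observed SNPs); with
#'   \code{hiddenQtl = TRUE} the QTL are extra unobserved loci so markers tag
#'   the trait only through relatedness.
#' @param nFoundersPerBreed founders per breed (half of each sex).
#' @param nGenerations number of offspring generations after the founders.
#' @param offspringPerBreed offspring produced per breed per generation.
#' @param sireFraction fraction of available males sampled as sires each
#'   generation (small values give large paternal half-sib families).
#' @param sigma2A,sigma2M,sigmaAM direct genetic variance, maternal genetic
#'   variance and their covariance (trait units squared).
#' @param sigma2Pe maternal permanent environment variance.
#' @param sigma2E residual variance.
#' @param qtlSharing fraction of QTL segregating in every breed; the rest
#'   are breed-specific (fixed for the reference allele elsewhere).
#' @param cgCount contemporary groups per breed-generation cohort.
#' @param cgEffectSd SD of the contemporary-group fixed effects.
#' @param hiddenQtl see \code{nQtl}.
#' @param seed master seed; all randomness flows from it through named
#'   substreams.
#' @return a validated list of class \code{simParams}.
#' @export
simParams <- function(nBreeds = 3L, divergenceFst = 0.1, nSnps = 1000L,
                      nQtl = 100L, nFoundersPerBreed = 50L,
                      nGenerations = 2L, offspringPerBreed = 200L,
                      sireFraction = 0.1, sigma2A = 0.3, sigma2M = 0,
                      sigmaAM = 0, sigma2Pe = 0, sigma2E = 0.7,
                      qtlSharing = 1, cgCount = 5L, cgEffectSd = 0.5,
                      hiddenQtl = FALSE, seed = 1L) {
  cfg <- list(nBreeds = as.integer(nBreeds), divergenceFst = divergenceFst,
              nSnps = as.integer(nSnps), nQtl = as.integer(nQtl),
              nFoundersPerBreed = as.integer(nFoundersPerBreed),
              nGenerations = as.integer(nGenerations),
              offspringPerBreed = as.integer(offspringPerBreed),
              sireFraction = sireFraction, sigma2A = sigma2A,
              sigma2M = sigma2M, sigmaAM = sigmaAM, sigma2Pe = sigma2Pe,
              sigma2E = sigma2E, qtlSharing = qtlSharing,
              cgCount = as.integer(cgCount), cgEffectSd = cgEffectSd,
              hiddenQtl = isTRUE(hiddenQtl), seed = as.integer(seed))
  with(cfg, {
    stopifnot(nBreeds >= 1L, nSnps >= 1L, nQtl >= 1L, nQtl <= nSnps,
              nFoundersPerBreed >= 2L, nGenerations >= 0L,
              sigma2A >= 0, sigma2M >= 0, sigma2Pe >= 0, sigma2E >= 0,
              qtlSharing >= 0, qtlSharing <= 1,
              sireFraction > 0, sireFraction <= 1)
    if (abs(sigmaAM) > sqrt(sigma2A * sigma2M) + 1e-12)
      stop("sigmaAM violates |sigmaAM| <= sqrt(sigma2A * sigma2M)")
    fst <- rep_len(divergenceFst, nBreeds)
    if (nBreeds > 1L && any(fst < 0 | fst >= 1))
      stop("divergenceFst must be in [0, 1) for multi-breed simulations")
  })
  class(cfg) <- "simParams"
  cfg
}

# named substream: deterministic function of master seed and stream label
.setSubstream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  set.seed((as.integer(seed) %% 1000003L) * 2011L + (h %% 104729L))
}

#' Per-breed allele frequencies under Balding-Nichols divergence
#'
#' Ancestral frequencies are drawn Uniform(0.05, 0.95) per locus; each
#' breed's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) with F the breed's FST.
#' F = 0 gives frequencies identical to the ancestral draw.
#'
#' @param cfg a [simParams()] list.
#' @return list with \code{ancestral} (length nLoci) and \code{freqs}
#'   (nBreeds x nLoci matrix); nLoci is \code{nSnps} plus \code{nQtl} extra
#'   loci in hidden-QTL mode.
#' @export
simulateBreedFrequencies <- function(cfg) {
  stopifnot(inherits(cfg, "simParams"))
  nLoci <- cfg$nSnps + if (cfg$hiddenQtl) cfg$nQtl else 0L
  .setSubstream(cfg$seed, "frequencies")
  anc <- stats::runif(nLoci, 0.05, 0.95)
  fst <- rep_len(cfg$divergenceFst, cfg$nBreeds)
  freqs <- matrix(NA_real_, cfg$nBreeds, nLoci)
  for (b in seq_len(cfg$nBreeds)) {
    f <- fst[b]
    if (f <= 0) {
      freqs[b, ] <- anc
    } else {
      freqs[b, ] <- stats::rbeta(nLoci, anc * (1 - f) / f,
                                 (1 - anc) * (1 - f) / f)
    }
  }
  rownames(freqs) <- paste0("B", seq_len(cfg$nBreeds))
  list(ancestral = anc, freqs = freqs)
}

# drop one gamete per parent per locus: transmitted allele ~ Bernoulli(dose/2)
.dropGamete <- function(parentDose) {
  stats::rbinom(length(parentDose), 1L, parentDose / 2)
}

#' Simulate a multi-breed pedigreed population with known truth
#'
#' Gene-dropping through a pedigree of \code{nGenerations} discrete
#' generations per breed (unlinked loci).  QTL effects are drawn
#' \eqn{N(0, \sigma^2_a / (2\sum_k p_k q_k))} (jointly with maternal effects
#' when \code{sigma2M > 0}, with correlation implied by \code{sigmaAM});
#' true breeding values are linear in QTL dosages.  Phenotypes follow
#' \deqn{y_i = cg_i + u_{d,i} + u_{m,dam(i)} + pe_{dam(i)} + e_i,}
#' maternal terms applying only to animals with a recorded dam.
#'
#' @param cfg a [simParams()] list.
#' @return a [SimulatedPopulation-class].
#' @export
simulatePopulation <- function(cfg) {
  stopifnot(inherits(cfg, "simParams"))
  fr <- simulateBreedFrequencies(cfg)
  nLoci <- ncol(fr$freqs)
  lociIds <- paste0("SNP", seq_len(nLoci))

  # -- QTL placement and effects ------------------------------------------
  .setSubstream(cfg$seed, "qtl")
  if (cfg$hiddenQtl) {
    qtl <- (cfg$nSnps + 1L):nLoci           # unobserved extra loci
  } else {
    qtl <- sort(sample.int(nLoci, cfg$nQtl))
  }
  nShared <- round(cfg$qtlSharing * cfg$nQtl)
  sharedQtl <- if (nShared > 0) qtl[seq_len(nShared)] else integer(0)
  specificQtl <- setdiff(qtl, sharedQtl)
  # breed-specific QTL: fixed (freq 0) in every other breed
  ownerOf <- integer(0)
  if (length(specificQtl)) {
    ownerOf <- rep_len(seq_len(cfg$nBreeds), length(specificQtl))
    for (k in seq_along(specificQtl)) {
      others <- setdiff(seq_len(cfg$nBreeds), ownerOf[k])
      fr$freqs[others, specificQtl[k]] <- 0
    }
  }
  pbar <- colMeans(fr$freqs[, qtl, drop = FALSE])
  vBase <- 2 * sum(pbar * (1 - pbar))
  Sg <- matrix(c(cfg$sigma2A, cfg$sigmaAM, cfg$sigmaAM,
                 max(cfg$sigma2M, 1e-12)), 2, 2) / vBase
  Lg <- chol(Sg)
  eff <- matrix(stats::rnorm(2L * cfg$nQtl), ncol = 2) %*% Lg
  alphaD <- eff[, 1]
  alphaM <- if (cfg$sigma2M > 0) eff[, 2] else rep(0, cfg$nQtl)

  # -- pedigree + gene dropping -------------------------------------------
  .setSubstream(cfg$seed, "pedigree")
  ids <- character(0); sire <- character(0); dam <- character(0)
  sex <- character(0); breed <- character(0); gen <- integer(0)
  dosList <- list()
  for (b in seq_len(cfg$nBreeds)) {
    bn <- paste0("B", b)
    nf <- cfg$nFoundersPerBreed
    fid <- sprintf("%s_G0_%04d", bn, seq_len(nf))
    fsex <- rep(c("M", "F"), length.out = nf)
    fdos <- matrix(stats::rbinom(nf * nLoci, 2L,
                                 rep(fr$freqs[b, ], each = nf)),
                   nrow = nf)
    ids <- c(ids, fid); sire <- c(sire, rep(NA, nf)); dam <- c(dam, rep(NA, nf))
    sex <- c(sex, fsex); breed <- c(breed, rep(bn, nf)); gen <- c(gen, rep(0L, nf))
    dosList[[length(dosList) + 1L]] <- fdos
    prevIds <- fid; prevSex <- fsex; prevDos <- fdos
    for (g in seq_len(cfg$nGenerations)) {
      males <- which(prevSex == "M"); females <- which(prevSex == "F")
      nSires <- max(1L, ceiling(cfg$sireFraction * length(males)))
      sires <- males[sample.int(length(males), nSires)]
      no <- cfg$offspringPerBreed
      oid <- sprintf("%s_G%d_%04d", bn, g, seq_len(no))
      osire <- sires[sample.int(length(sires), no, replace = TRUE)]
      odam <- females[sample.int(length(females), no, replace = TRUE)]
      # dam reuse above creates full-sib families and repeated dams (PE)
      odos <- matrix(0L, no, nLoci)
      for (k in seq_len(no)) {
        odos[k, ] <- .dropGamete(prevDos[osire[k], ]) +
          .dropGamete(prevDos[odam[k], ])
      }
      ids <- c(ids, oid)
      sire <- c(sire, prevIds[osire]); dam <- c(dam, prevIds[odam])
      sex <- c(sex, sample(c("M", "F"), no, replace = TRUE))
      breed <- c(breed, rep(bn, no)); gen <- c(gen, rep(g, no))
      dosList[[length(dosList) + 1L]] <- odos
      prevIds <- oid; prevSex <- sex[(length(sex) - no + 1L):length(sex)]
      prevDos <- odos
    }
  }
  dos <- do.call(rbind, dosList)
  rownames(dos) <- ids
  colnames(dos) <- lociIds
  ped <- Pedigree(ids, sire, dam)
  names(sex) <- names(breed) <- ids

  # -- true breeding values ------------------------------------------------
  qd <- sweep(dos[, qtl, drop = FALSE], 2, 2 * pbar)
  ubvD <- drop(qd %*% alphaD)
  ubvM <- drop(qd %*% alphaM)
  names(ubvD) <- names(ubvM) <- ids

  # -- phenotypes ----------------------------------------------------------
  .setSubstream(cfg$seed, "phenotypes")
  hasDam <- !is.na(dam)
  rec <- which(hasDam)                     # records require a recorded dam
  damTok <- dam
  sireTok <- sire
  pe <- stats::rnorm(length(ids), 0, sqrt(cfg$sigma2Pe))
  names(pe) <- ids
  cgTok <- character(length(ids))
  cgEff <- numeric(0)
  for (coh in split(seq_along(ids), paste(breed, gen))) {
    k <- min(cfg$cgCount, max(1L, length(coh)))
    grp <- sample(rep_len(seq_len(k), length(coh)))
    cgTok[coh] <- paste0(breed[coh], "_G", gen[coh], "_CG", grp)
  }
  uCg <- unique(cgTok[rec])
  cgEff <- stats::setNames(stats::rnorm(length(uCg), 0, cfg$cgEffectSd), uCg)
  e <- stats::rnorm(length(ids), 0, sqrt(cfg$sigma2E))
  y <- cgEff[cgTok] + ubvD + ubvM[damTok] + pe[damTok] + e
  mgs <- sireTok[match(damTok, ids)]       # maternal grandsire
  phen <- data.frame(animal_id = ids[rec], trait = "p.SIM",
                     value = unname(y[rec]), cg = cgTok[rec],
                     sire = sireTok[rec], dam = damTok[rec],
                     mgs = mgs[rec], recipient_dam = damTok[rec],
                     record_index = 1L, stringsAsFactors = FALSE)

  markers <- seq_len(cfg$nSnps)            # hidden QTL are dropped here
  geno <- new("GenotypeMatrix", ids = ids, snpIds = lociIds[markers],
              dosages = dos[, markers, drop = FALSE] * 1.0,
              alleleFreqs = rep(NA_real_, length(markers)))

  new("SimulatedPopulation",
      pedigree = ped, genotypes = geno, breedOf = breed,
      trueBvDirect = ubvD, trueBvMaternal = ubvM, phenotypes = phen,
      truth = list(config = cfg, qtlLoci = lociIds[qtl], alphaD = alphaD,
                   alphaM = alphaM, qtlMeanFreq = pbar,
                   breedFreqs = fr$freqs, ancestralFreqs = fr$ancestral,
                   sex = sex, generation = stats::setNames(gen, ids),
                   cgEffects = cgEff))
}

#' Training/validation split mirroring the across-breed study design
#'
#' Produces named training index sets (pooled, single-breed, subset designs)
#' and a validation set of widely used sires plus current-generation animals
#' of one breed.  Validation animals are excluded from every training set;
#' the validation breed may itself be absent from all training breeds (the
#' "no pure-breed representation in training" situation).
#'
#' @param pop a [SimulatedPopulation-class].
#' @param trainingBreeds named list of breed-label vectors, one per
#'   prediction-equation training subset (e.g.
#'   \code{list(ALL = c("B1","B2","B3"), B1 = "B1")}).
#' @param validationBreed single breed label.
#' @param nValidationSires,nCurrent validation set composition: sires with
#'   recorded progeny, and animals of the last generation.  Honored exactly
#'   when available.
#' @return list with elements \code{training} (named list of animal id
#'   vectors), \code{validation} (ids), \code{sires}, \code{current},
#'   \code{validationBreed} and \code{absentFromTraining}.
#' @export
makeTrainingValidationSplit <- function(pop, trainingBreeds, validationBreed,
                                        nValidationSires = 25L,
                                        nCurrent = 75L) {
  stopifnot(is(pop, "SimulatedPopulation"))
  breed <- pop@breedOf
  gen <- pop@truth$generation
  ids <- names(breed)
  inBreed <- ids[breed == validationBreed]
  if (!length(inBreed)) stop("unknown validation breed: ", validationBreed)
  maxG <- max(gen[inBreed])
  tb <- pedigreeTable(pop@pedigree)
  nProg <- table(tb$sire[!is.na(tb$sire)])
  sirePool <- intersect(names(nProg), inBreed)
  sirePool <- sirePool[order(-as.vector(nProg[sirePool]))]
  sires <- utils::head(sirePool, nValidationSires)
  current <- inBreed[gen[inBreed] == maxG]
  .setSubstream(pop@truth$config$seed, "split")
  if (length(current) > nCurrent) current <- sample(current, nCurrent)
  validation <- union(sires, current)
  training <- lapply(trainingBreeds, function(bs) {
    setdiff(ids[breed %in% bs], validation)
  })
  for (nm in names(training)) {
    if (length(intersect(training[[nm]], validation)))
      stop("training set ", nm, " overlaps the validation set")
  }
  list(training = training, validation = validation, sires = sires,
       current = current, validationBreed = validationBreed,
       absentFromTraining =
         !validationBreed %in% unlist(trainingBreeds, use.names = FALSE))
}

#' Write a simulated population to plain-text files
#'
#' Emits \code{pedigree.csv}, \code{phenotypes.csv}, \code{genotypes.tsv}
#' (animal id column + one column per SNP, header row of SNP ids) and
#' \code{truth.json}.
#'
#' @param pop a [SimulatedPopulation-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
writeSimulatedPopulation <- function(pop, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pPed <- file.path(dir, "pedigree.csv")
  writePedigree(pop@pedigree, pPed)
  pPhen <- file.path(dir, "phenotypes.csv")
  utils::write.csv(pop@phenotypes, pPhen, row.names = FALSE, quote = FALSE)
  pGeno <- file.path(dir, "genotypes.tsv")
  writeGenotypes(pop@genotypes, pGeno)
  pTruth <- file.path(dir, "truth.json")
  tr <- pop@truth
  jsonlite::write_json(
    list(config = unclass(tr$config), qtlLoci = tr$qtlLoci,
         alphaD = tr$alphaD, alphaM = tr$alphaM,
         trueBvDirect = as.list(pop@trueBvDirect),
         trueBvMaternal = as.list(pop@trueBvMaternal)),
    pTruth, auto_unbox = TRUE, digits = NA)
  invisible(c(pPed, pPhen, pGeno, pTruth))
}

#' Nested-family pedigree for model-based simulations
#'
#' Unrelated sires and dams (nested within sires) with \code{nRecords}
#' offspring assigned random parents - the balanced one-generation design
#' used by the parameter-recovery studies.
#'
#' @param nRecords number of offspring (split evenly across generations).
#' @param nSires,damsPerSire founder family structure.
#' @param generations offspring generations; with 2, second-generation
#'   animals have first-generation parents (so dams have records and known
#'   sires - needed to separate direct from maternal effects).
#' @param seed RNG seed.
#' @return a [Pedigree-class]; offspring tokens are \code{O<g>_<i>}.
#' @export
nestedFamilyPedigree <- function(nRecords, nSires = 30L, damsPerSire = 4L,
                                 generations = 1L, seed = 1L) {
  set.seed(seed)
  nd <- nSires * damsPerSire
  id <- c(paste0("S", seq_len(nSires)), paste0("D", seq_len(nd)))
  sire <- dam <- rep(NA_character_, nSires + nd)
  per <- ceiling(nRecords / generations)
  prevM <- paste0("S", seq_len(nSires))
  prevF <- paste0("D", seq_len(nd))
  made <- 0L
  for (g in seq_len(generations)) {
    no <- min(per, nRecords - made)
    oid <- paste0("O", g, "_", seq_len(no))
    id <- c(id, oid)
    sire <- c(sire, sample(prevM, no, TRUE))
    dam <- c(dam, sample(prevF, no, TRUE))
    sx <- rep(c("M", "F"), length.out = no)
    prevM <- utils::head(oid[sx == "M"], max(nSires, 1L))
    prevF <- oid[sx == "F"]
    made <- made + no
  }
  Pedigree(id, sire, dam)
}

#' Closed-population drift pedigree (accumulating inbreeding)
#'
#' A small closed population mated at random for several generations; drift
#' in the small parent pool accumulates inbreeding, pushing the mean
#' diagonal of the numerator relationship matrix well above 1 in the later
#' generations.
#'
#' @param nFounders founder count.
#' @param perGeneration offspring per generation.
#' @param nGenerations generations after the founders.
#' @param nBreeders parents actually used per generation (small pools give
#'   fast inbreeding; default: everyone breeds).
#' @param seed RNG seed.
#' @return a [Pedigree-class]; final-generation tokens are
#'   \code{G<nGenerations>_<i>}.
#' @export
driftPedigree <- function(nFounders = 10L, perGeneration = 80L,
                          nGenerations = 4L, nBreeders = NULL, seed = 1L) {
  set.seed(seed)
  id <- paste0("G0_", seq_len(nFounders))
  sire <- dam <- rep(NA_character_, nFounders)
  sex <- rep(c("M", "F"), length.out = nFounders)
  prev <- id; prevSex <- sex
  for (g in seq_len(nGenerations)) {
    males <- prev[prevSex == "M"]; females <- prev[prevSex == "F"]
    if (!is.null(nBreeders)) {
      males <- utils::head(males, ceiling(nBreeders / 2))
      females <- utils::head(females, ceiling(nBreeders / 2))
    }
    oid <- paste0("G", g, "_", seq_len(perGeneration))
    id <- c(id, oid)
    sire <- c(sire, sample(males, perGeneration, TRUE))
    dam <- c(dam, sample(females, perGeneration, TRUE))
    prevSex <- sample(c("M", "F"), perGeneration, TRUE)
    prev <- oid
  }
  Pedigree(id, sire, dam)
}

#' Simulate records directly under the bivariate animal model
#'
#' Draws breeding values from
#' \eqn{N(0, \Sigma_g \otimes A)} over a pedigree and builds phenotype and
#' GEBV records with contemporary-group effects and (optionally correlated)
#' residuals - the generating process the bivariate REML fit assumes, with
#' every parameter known.  Used for parameter-recovery studies: the true
#' GEBV accuracy is \eqn{r_g = \sigma_{a,g}/\sqrt{\sigma^2_a\sigma^2_g}}.
#'
#' @param vc named list/vector of true components: sigma2_a, sigma_ag,
#'   sigma2_g, sigma2_ep, sigma2_eg always; sigma_epg optional; sigma_am,
#'   sigma_gm, sigma2_m, sigma2_p enable the maternal model.
#' @param nRecords number of recorded animals (ignored when \code{pedigree}
#'   is supplied).
#' @param pedigree optional [Pedigree-class]; records are generated for the
#'   animals named by \code{recordIds} (default: all non-founders).
#' @param recordIds see \code{pedigree}.
#' @param nSires,damsPerSire,generations structure of the default
#'   nested-family pedigree (use \code{generations = 2} for maternal-model
#'   recovery studies).
#' @param nCg contemporary groups; \code{cgSd} their effect SD.
#' @param gebvMean fixed mean of the GEBV channel.
#' @param overlap fraction of recorded animals carrying both a phenotype
#'   and a GEBV record (1 = full overlap; 0 = disjoint halves).
#' @param seed RNG seed.
#' @return list: \code{dataset} (a [TraitDataset-class]), \code{ainv} (a
#'   [SparseInverse-class] of the pedigree), \code{pedigree}, \code{truth}
#'   (the generating components plus true r_g and GEBV h2).
#' @export
simulateBivariateData <- function(vc, nRecords = 600L, pedigree = NULL,
                                  recordIds = NULL, nSires = 30L,
                                  damsPerSire = 4L, generations = 1L,
                                  nCg = 10L, cgSd = 0.5,
                                  gebvMean = 0, overlap = 1, seed = 1L) {
  vc <- as.list(vc)
  maternal <- !is.null(vc$sigma2_m) && vc$sigma2_m > 0
  if (is.null(pedigree))
    pedigree <- nestedFamilyPedigree(nRecords, nSires, damsPerSire,
                                     generations = generations, seed = seed)
  set.seed(seed + 7L)
  tb <- pedigreeTable(pedigree)
  if (is.null(recordIds))
    recordIds <- tb$animal[!is.na(tb$sire) & !is.na(tb$dam)]
  n <- length(recordIds)
  aid <- animalIds(pedigree)
  A <- additiveRelationshipMatrix(pedigree)@values
  L <- t(chol(A + diag(1e-10, nrow(A))))
  k <- if (maternal) 3L else 2L
  Sg <- matrix(0, k, k)
  Sg[1, 1] <- vc$sigma2_a; Sg[2, 2] <- vc$sigma2_g
  Sg[1, 2] <- Sg[2, 1] <- vc$sigma_ag %||% 0
  if (maternal) {
    Sg[3, 3] <- vc$sigma2_m
    Sg[1, 3] <- Sg[3, 1] <- vc$sigma_am %||% 0
    Sg[2, 3] <- Sg[3, 2] <- vc$sigma_gm %||% 0
  }
  U <- L %*% matrix(stats::rnorm(k * length(aid)), ncol = k) %*%
    chol(Sg + diag(1e-12, k))
  rownames(U) <- aid

  cg <- sample(sprintf("cg%02d", seq_len(nCg)), n, TRUE)
  cgEff <- stats::setNames(stats::rnorm(nCg, 0, cgSd),
                           sprintf("cg%02d", seq_len(nCg)))
  damOf <- stats::setNames(tb$dam, tb$animal)
  sireOf <- stats::setNames(tb$sire, tb$animal)

  # residuals: correlated for overlap animals
  s2ep <- vc$sigma2_ep; s2eg <- vc$sigma2_eg; sepg <- vc$sigma_epg %||% 0
  Re <- matrix(c(s2ep, sepg, sepg, s2eg), 2, 2)
  E <- matrix(stats::rnorm(2 * n), ncol = 2) %*% chol(Re + diag(1e-12, 2))

  pe <- if (maternal)
    stats::setNames(stats::rnorm(length(aid), 0, sqrt(vc$sigma2_p %||% 0)),
                    aid)
  else NULL
  yP <- cgEff[cg] + U[recordIds, 1] + E[, 1]
  if (maternal)
    yP <- yP + U[damOf[recordIds], 3] + pe[damOf[recordIds]]
  yG <- gebvMean + U[recordIds, 2] + E[, 2]

  if (overlap >= 1) {
    pIds <- gIds <- recordIds
  } else if (overlap <= 0) {
    half <- floor(n / 2)
    pIds <- recordIds[seq_len(half)]
    gIds <- recordIds[(half + 1L):n]
  } else {
    nOv <- round(overlap * n)
    pIds <- recordIds[seq_len(floor((n + nOv) / 2))]
    gIds <- recordIds[(length(pIds) - nOv + 1L):n]
  }
  phen <- data.frame(animal_id = pIds, trait = "p.SIM",
                     value = unname(yP[match(pIds, recordIds)]),
                     cg = cg[match(pIds, recordIds)],
                     sire = sireOf[pIds], dam = damOf[pIds],
                     mgs = sireOf[damOf[pIds]],
                     recipient_dam = damOf[pIds], record_index = 1L,
                     stringsAsFactors = FALSE)
  gtab <- data.frame(animal_id = gIds,
                     gebv = unname(yG[match(gIds, recordIds)]),
                     stringsAsFactors = FALSE)
  dsn <- new("TraitDataset", phenotypes = phen, gebv = gtab,
             trait = "p.SIM", gebvTrait = "g.SIM",
             overlapIds = intersect(pIds, gIds))
  rgTrue <- (vc$sigma_ag %||% 0) / sqrt(vc$sigma2_a * vc$sigma2_g)
  list(dataset = dsn, ainv = aInverse(pedigree), pedigree = pedigree,
       truth = c(vc, list(rg = rgTrue,
                          h2Gebv = vc$sigma2_g / (vc$sigma2_g + vc$sigma2_eg),
                          h2 = vc$sigma2_a /
                            (vc$sigma2_a + (vc$sigma2_m %||% 0) +
                             (vc$sigma2_p %||% 0) + vc$sigma2_ep))))
}
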