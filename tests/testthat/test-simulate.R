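test_that("simulation configs are validated", {
  expect_s3_class(simParams(), "simParams")
  expect_error(simParams(nBreeds = 3, divergenceFst = 1.2), "divergenceFst")
  expect_error(simParams(nBreeds = 2, divergenceFst = -0.1), "divergenceFst")
  expect_error(simParams(sigma2A = 0.3, sigma2M = 0.1, sigmaAM = 0.5),
               "sigmaAM")
  expect_error(simParams(qtlSharing = 1.5))
  # fst = 0 with several breeds is allowed (identical breeds)
  expect_silent(simParams(nBreeds = 2, divergenceFst = 0))
})

test_that("breed frequencies follow the divergence model", {
  # fst -> 0: breeds equal the ancestral draw
  cfg0 <- simParams(nBreeds = 2, divergenceFst = 0, nSnps = 200, seed = 3)
  fr0 <- simulateBreedFrequencies(cfg0)
  expect_equal(fr0$freqs[1, ], fr0$ancestral, ignore_attr = TRUE)
  expect_equal(fr0$freqs[2, ], fr0$ancestral, ignore_attr = TRUE)

  # single breed: one Balding-Nichols draw around the ancestral values
  cfg1 <- simParams(nBreeds = 1, divergenceFst = 0.1, nSnps = 500, seed = 4)
  fr1 <- simulateBreedFrequencies(cfg1)
  expect_equal(dim(fr1$freqs), c(1L, 500L))
  expect_true(all(fr1$freqs >= 0 & fr1$freqs <= 1))

  # realized FST (Hudson estimator, 2 breeds) near the target
  cfg <- simParams(nBreeds = 2, divergenceFst = 0.1, nSnps = 10000, seed = 5)
  fr <- simulateBreedFrequencies(cfg)
  p1 <- fr$freqs[1, ]; p2 <- fr$freqs[2, ]
  num <- (p1 - p2)^2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fstHat <- mean(num) / mean(den)
  expect_lt(abs(fstHat - 0.1), 0.02)
})

test_that("gene dropping is Mendelian-consistent and deterministic", {
  cfg <- simParams(nBreeds = 2, nSnps = 40, nQtl = 10,
                   nFoundersPerBreed = 8, nGenerations = 2,
                   offspringPerBreed = 12, seed = 9)
  pop <- simulatePopulation(cfg)
  tb <- pedigreeTable(pop@pedigree)
  d <- pop@genotypes@dosages
  ok <- TRUE
  for (i in which(!is.na(tb$sire))) {
    oz <- d[tb$animal[i], ]
    sz <- d[tb$sire[i], ]
    dz <- d[tb$dam[i], ]
    # transmitted allele from a parent with dosage 0/2 is forced
    lo <- (sz == 2) + (dz == 2)
    hi <- 2 - ((sz == 0) + (dz == 0))
    ok <- ok && all(oz >= lo & oz <= hi)
  }
  expect_true(ok)

  pop2 <- simulatePopulation(cfg)
  expect_identical(pop@genotypes@dosages, pop2@genotypes@dosages)
  expect_identical(pop@phenotypes, pop2@phenotypes)
  expect_identical(pop@trueBvDirect, pop2@trueBvDirect)
})

test_that("phenotypes collapse to true breeding values without noise", {
  cfg <- simParams(nBreeds = 1, nSnps = 100, nQtl = 30,
                   nFoundersPerBreed = 10, nGenerations = 1,
                   offspringPerBreed = 30, sigma2A = 0.4, sigma2E = 0,
                   sigma2M = 0, sigma2Pe = 0, cgEffectSd = 0, seed = 12)
  pop <- simulatePopulation(cfg)
  ph <- pop@phenotypes
  expect_equal(ph$value, unname(pop@trueBvDirect[ph$animal_id]),
               tolerance = 1e-12)
})

test_that("realized genetic variance and inheritance match the parameters", {
  # var of true BV across a large founder-rich population
  vs <- sapply(1:5, function(s) {
    cfg <- simParams(nBreeds = 1, nSnps = 400, nQtl = 100,
                     nFoundersPerBreed = 400, nGenerations = 1,
                     offspringPerBreed = 1200, sigma2A = 0.5, seed = 100 + s)
    pop <- simulatePopulation(cfg)
    var(pop@trueBvDirect)
  })
  expect_lt(abs(mean(vs) / 0.5 - 1), 0.1)

  # regression of offspring BV on mid-parent BV ~ 1
  cfg <- simParams(nBreeds = 1, nSnps = 400, nQtl = 100,
                   nFoundersPerBreed = 200, nGenerations = 1,
                   offspringPerBreed = 1500, sigma2A = 0.5, seed = 77)
  pop <- simulatePopulation(cfg)
  tb <- pedigreeTable(pop@pedigree)
  off <- tb$animal[!is.na(tb$sire)]
  mid <- (pop@trueBvDirect[tb$sire[match(off, tb$animal)]] +
            pop@trueBvDirect[tb$dam[match(off, tb$animal)]]) / 2
  b <- coef(lm(pop@trueBvDirect[off] ~ mid))[2]
  expect_lt(abs(b - 1), 0.1)
})

test_that("training/validation splits honor sizes and disjointness", {
  cfg <- simParams(nBreeds = 3, nSnps = 50, nQtl = 10,
                   nFoundersPerBreed = 20, nGenerations = 2,
                   offspringPerBreed = 40, sireFraction = 0.6, seed = 21)
  pop <- simulatePopulation(cfg)
  sp <- makeTrainingValidationSplit(
    pop, trainingBreeds = list(ALL = c("B1", "B2", "B3"), B1 = "B1"),
    validationBreed = "B1", nValidationSires = 5, nCurrent = 20)
  expect_length(sp$sires, 5)
  expect_length(sp$current, 20)
  for (tr in sp$training)
    expect_length(intersect(tr, sp$validation), 0)
  expect_false(sp$absentFromTraining)

  # validation breed entirely absent from training breeds
  sp2 <- makeTrainingValidationSplit(
    pop, trainingBreeds = list(OTHERS = c("B2", "B3")),
    validationBreed = "B1", nValidationSires = 5, nCurrent = 10)
  expect_true(sp2$absentFromTraining)
  expect_length(intersect(sp2$training$OTHERS, sp2$validation), 0)
})

test_that("population files round-trip through the plain-text writers", {
  cfg <- simParams(nBreeds = 1, nSnps = 30, nQtl = 5, nFoundersPerBreed = 6,
                   nGenerations = 1, offspringPerBreed = 10, seed = 33)
  pop <- simulatePopulation(cfg)
  dir <- tempfile()
  writeSimulatedPopulation(pop, dir)
  g <- readGenotypes(file.path(dir, "genotypes.tsv"))
  expect_equal(g@dosages, pop@genotypes@dosages, ignore_attr = TRUE)
  ped <- readPedigree(file.path(dir, "pedigree.csv"))
  expect_setequal(animalIds(ped), animalIds(pop@pedigree))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(truth$alphaD), cfg$nQtl)
})

test_that("model-based bivariate simulator reproduces its own truth", {
  vc <- list(sigma2_a = 0.3, sigma_ag = 0.2, sigma2_g = 0.8,
             sigma2_ep = 0.7, sigma_epg = 0, sigma2_eg = 0.2)
  sim <- simulateBivariateData(vc, nRecords = 300, seed = 8)
  expect_s4_class(sim$dataset, "TraitDataset")
  expect_equal(sim$truth$rg, 0.2 / sqrt(0.3 * 0.8))
  expect_equal(sim$truth$h2Gebv, 0.8)
  expect_length(sim$dataset@overlapIds, 300)

  # disjoint-channel variant
  sim0 <- simulateBivariateData(vc, nRecords = 300, overlap = 0, seed = 8)
  expect_length(sim0$dataset@overlapIds, 0)

  # drift pedigree accumulates inbreeding
  ped <- driftPedigree(nFounders = 10, perGeneration = 50,
                       nGenerations = 4, nBreeders = 8, seed = 2)
  A <- additiveRelationshipMatrix(ped)
  last <- grep("^G4", animalIds(ped), value = TRUE)
  expect_gt(mean(diag(A@values)[match(last, animalIds(A))]), 1.1)
})
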