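toyDataset <- function(inst) {
  new("TraitDataset", phenotypes = inst$phen, gebv = inst$gtab,
      trait = "p.SIM", gebvTrait = "g.SIM",
      overlapIds = intersect(inst$phen$animal_id, inst$gtab$animal_id))
}

test_that("design matrices have the documented block structure", {
  ped <- Pedigree(paste0("A", 1:6), rep("0", 6), rep("0", 6))
  ai <- aInverse(ped)
  phen <- data.frame(animal_id = paste0("A", 1:4), trait = "p.SIM",
                     value = rnorm(4), cg = c("c1", "c1", "c2", "c2"),
                     dam = NA, stringsAsFactors = FALSE)
  gtab <- data.frame(animal_id = paste0("A", 3:6), gebv = rnorm(4))
  dsn <- new("TraitDataset", phenotypes = phen, gebv = gtab,
             trait = "p.SIM", gebvTrait = "g.SIM",
             overlapIds = c("A3", "A4"))
  ds <- buildDesign(dsn, ai, maternal = FALSE)
  W <- as.matrix(ds$W)
  # fixed part: 2 CG columns over phenotype rows, each row sum 1
  expect_equal(ds$p, 3L)
  expect_equal(rowSums(W[1:4, 1:2]), rep(1, 4))
  # GEBV fixed part is a single column of 1s on the GEBV rows
  expect_equal(W[5:8, 3], rep(1, 4))
  expect_equal(W[1:4, 3], rep(0, 4))
  # plain model carries no maternal or permanent environment columns
  expect_null(ds$cols$m)
  expect_null(ds$cols$pe)
  expect_equal(ds$q, 3L + 2L * 6L)
  expect_equal(ds$nOv, 2L)

  # maternal model requires known dams
  expect_error(buildDesign(dsn, ai, maternal = TRUE), "known dam")
})

test_that("restricted likelihood matches the dense oracle on toys", {
  for (s in 1:6) {
    maternal <- s > 3
    inst <- randomToyInstance(100 + s, maternal = maternal,
                              overlap = s %% 2 == 0)
    ds <- buildDesign(toyDataset(inst), aInverse(inst$ped),
                      maternal = maternal)
    ll <- restrictedLogLik(inst$vc, ds)
    ll0 <- oracleREML(inst$phen, inst$gtab, inst$ped, inst$vc,
                      maternal = maternal)
    expect_equal(ll, ll0, tolerance = 1e-9)
  }
})

test_that("likelihood collapses to iid residuals without genetic variance", {
  inst <- randomToyInstance(42)
  ds <- buildDesign(toyDataset(inst), aInverse(inst$ped), maternal = FALSE)
  vc <- c(sigma2_a = 1e-7, sigma_ag = 0, sigma2_g = 1e-7,
          sigma2_ep = 1.5, sigma_epg = 0, sigma2_eg = 0.7)
  ll <- restrictedLogLik(vc, ds)
  ll0 <- oracleREML(inst$phen, inst$gtab, inst$ped, vc)
  expect_equal(ll, ll0, tolerance = 1e-7)
  # and the genetic terms are negligible: doubling A-structured variance
  # from 1e-7 barely moves the likelihood
  vc2 <- vc; vc2[c("sigma2_a", "sigma2_g")] <- 2e-7
  expect_lt(abs(restrictedLogLik(vc2, ds) - ll), 0.01)
})

test_that("residual covariance is structural: zero overlap pins it to zero", {
  vcT <- list(sigma2_a = 0.4, sigma_ag = 0.25, sigma2_g = 0.8,
              sigma2_ep = 0.6, sigma_epg = 0, sigma2_eg = 0.2)
  sim <- simulateBivariateData(vcT, nRecords = 240, overlap = 0, seed = 31)
  ds <- buildDesign(sim$dataset, sim$ainv, maternal = FALSE)
  expect_false(ds$fitResidualCov)
  v1 <- c(sigma2_a = .4, sigma_ag = .2, sigma2_g = .8,
          sigma2_ep = .6, sigma_epg = 0, sigma2_eg = .2)
  v2 <- v1; v2["sigma_epg"] <- 0.31
  expect_identical(restrictedLogLik(v1, ds), restrictedLogLik(v2, ds))

  fit <- remlFit(sim$dataset, sim$ainv, maternal = FALSE)
  expect_equal(unname(fit@estimates["sigma_epg"]), 0)
  expect_true(is.na(fit@se["sigma_epg"]))
})

test_that("derived parameters and their delta SEs have closed-form limits", {
  vc <- c(sigma2_a = 0.5, sigma_ag = 0, sigma2_g = 0.8, sigma2_eg = 0.2)
  expect_equal(unname(geneticCorrelation(vc)["rg"]), 0)
  vc["sigma_ag"] <- sqrt(0.5 * 0.8)
  expect_equal(unname(geneticCorrelation(vc)["rg"]), 1)
  expect_error(geneticCorrelation(c(sigma2_a = 0, sigma_ag = 0,
                                    sigma2_g = 1)), "undefined")

  expect_equal(unname(gebvHeritability(c(sigma2_g = 0.8,
                                         sigma2_eg = 0))["h2"]), 1)
  expect_equal(unname(gebvHeritability(c(sigma2_g = 0.3,
                                         sigma2_eg = 0.3))["h2"]), 0.5)

  # delta SE against an analytic check on a diagonal covariance
  V <- diag(c(0.01, 0.02, 0.03))
  dimnames(V) <- list(c("sigma_ag", "sigma2_a", "sigma2_g"),
                      c("sigma_ag", "sigma2_a", "sigma2_g"))
  vc2 <- c(sigma2_a = 0.5, sigma_ag = 0.2, sigma2_g = 0.8)
  gc <- geneticCorrelation(vc2, V)
  rg <- 0.2 / sqrt(0.4)
  grad <- c(1 / sqrt(0.4), -rg / 1, -rg / 1.6)
  expect_equal(unname(gc["se"]), sqrt(sum(grad^2 * c(0.01, 0.02, 0.03))))
})

test_that("bivariate fit recovers the generating parameters", {
  vcT <- list(sigma2_a = 0.3, sigma_ag = 0.5 * sqrt(0.3 * 0.8),
              sigma2_g = 0.8, sigma2_ep = 0.7, sigma_epg = 0.1,
              sigma2_eg = 0.2)
  sim <- simulateBivariateData(vcT, nRecords = 700, nSires = 35, seed = 3)
  fit <- remlFit(sim$dataset, sim$ainv, maternal = FALSE)
  expect_true(fit@converged)
  expect_lt(abs(fit@rg - 0.5), 3 * fit@seRg)
  expect_gte(fit@rg, -1); expect_lte(fit@rg, 1)
  expect_true(all(fit@se[c("sigma2_a", "sigma2_g")] > 0, na.rm = TRUE))
  # genetic block of the estimates is PSD (Cholesky parameterization)
  Sg <- matrix(c(fit@estimates["sigma2_a"], fit@estimates["sigma_ag"],
                 fit@estimates["sigma_ag"], fit@estimates["sigma2_g"]), 2)
  expect_gte(min(eigen(Sg, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
})

test_that("null phenotype gives a genetic correlation within 2 SE of zero", {
  vcT <- list(sigma2_a = 0.3, sigma_ag = 0, sigma2_g = 0.8,
              sigma2_ep = 0.7, sigma_epg = 0, sigma2_eg = 0.2)
  sim <- simulateBivariateData(vcT, nRecords = 700, nSires = 35, seed = 11)
  fit <- remlFit(sim$dataset, sim$ainv, maternal = FALSE)
  expect_lt(abs(fit@rg), 2 * fit@seRg)
})

test_that("univariate and bivariate GEBV heritabilities agree", {
  vcT <- list(sigma2_a = 0.3, sigma_ag = 0.25, sigma2_g = 0.8,
              sigma2_ep = 0.7, sigma_epg = 0, sigma2_eg = 0.2)
  sim <- simulateBivariateData(vcT, nRecords = 600, seed = 17)
  fitB <- remlFit(sim$dataset, sim$ainv, maternal = FALSE)
  fitU <- univariateFit(sim$dataset, sim$ainv, channel = "gebv")
  seJoint <- sqrt(fitB@seH2Gebv^2 + fitU@seH2Gebv^2)
  expect_lt(abs(fitB@h2Gebv - fitU@h2Gebv), 2 * seJoint)
})

test_that("delta-method SEs agree with a parametric bootstrap", {
  vcT <- list(sigma2_g = 0.8, sigma2_eg = 0.25)
  h2T <- 0.8 / 1.05
  fits <- sapply(1:120, function(r) {
    ped <- nestedFamilyPedigree(320, nSires = 16, damsPerSire = 4,
                                seed = 900 + r)
    tb <- pedigreeTable(ped)
    rec <- tb$animal[!is.na(tb$sire)]
    A <- additiveRelationshipMatrix(ped)@values
    set.seed(900 + r)
    u <- drop(t(chol(A)) %*% rnorm(nrow(A))) * sqrt(0.8)
    names(u) <- animalIds(ped)
    g <- data.frame(animal_id = rec,
                    gebv = u[rec] + rnorm(length(rec), 0, sqrt(0.25)))
    dsn <- new("TraitDataset", phenotypes = data.frame(), gebv = g,
               trait = "p.SIM", gebvTrait = "g.SIM",
               overlapIds = character(0))
    fit <- univariateFit(dsn, aInverse(ped), channel = "gebv")
    c(fit@h2Gebv, fit@seH2Gebv)
  })
  empSE <- sd(fits[1, ])
  deltaSE <- mean(fits[2, ], na.rm = TRUE)
  expect_lt(abs(mean(fits[1, ]) - h2T), 0.05)
  expect_lt(abs(deltaSE / empSE - 1), 0.15)
})

test_that("degenerate responses pin the variances to the floor", {
  ped <- nestedFamilyPedigree(120, nSires = 10, seed = 5)
  tb <- pedigreeTable(ped)
  rec <- tb$animal[!is.na(tb$sire)]
  g <- data.frame(animal_id = rec, gebv = rep(2.5, length(rec)))
  dsn <- new("TraitDataset", phenotypes = data.frame(), gebv = g,
             trait = "p.SIM", gebvTrait = "g.SIM", overlapIds = character(0))
  fit <- univariateFit(dsn, aInverse(ped), channel = "gebv")
  expect_lt(fit@estimates["sigma2_g"], 1e-6)
  expect_lt(fit@estimates["sigma2_eg"], 1e-6)
})

test_that("ignoring a real maternal effect inflates the direct heritability", {
  vcT <- list(sigma2_a = 0.25, sigma_ag = 0.2, sigma2_g = 0.8,
              sigma_am = 0, sigma_gm = 0, sigma2_m = 0.25, sigma2_p = 0.1,
              sigma2_ep = 0.45, sigma_epg = 0, sigma2_eg = 0.2)
  sim <- simulateBivariateData(vcT, nRecords = 900, nSires = 30,
                               generations = 2, seed = 23)
  fitM <- remlFit(sim$dataset, sim$ainv, maternal = TRUE, fixGm = TRUE)
  fit3 <- remlFit(sim$dataset, sim$ainv, maternal = FALSE)
  h2 <- function(f) {
    e <- f@estimates
    tot <- sum(e[c("sigma2_a", "sigma2_m", "sigma2_p", "sigma2_ep")],
               na.rm = TRUE)
    unname(e["sigma2_a"]) / tot
  }
  expect_gt(h2(fit3), h2(fitM))

  # with fixGm the GEBV-maternal covariance is structurally zero
  expect_equal(unname(fitM@estimates["sigma_gm"]), 0)
  expect_true(is.na(fitM@se["sigma_gm"]))
})

test_that("REML results serialize to JSON, CSV and Markdown", {
  vcT <- list(sigma2_a = 0.4, sigma_ag = 0.3, sigma2_g = 0.8,
              sigma2_ep = 0.6, sigma_epg = 0, sigma2_eg = 0.2)
  sim <- simulateBivariateData(vcT, nRecords = 200, seed = 41)
  fit <- remlFit(sim$dataset, sim$ainv, maternal = FALSE)
  pre <- tempfile()
  writeREMLResult(fit, pre)
  js <- jsonlite::read_json(paste0(pre, ".json"))
  expect_equal(js$rg, fit@rg, tolerance = 1e-12)
  tab <- read.csv(paste0(pre, ".csv"))
  expect_setequal(tab$component, names(fit@estimates))
  expect_true(any(grepl("\\|", readLines(paste0(pre, ".md")))))
})
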