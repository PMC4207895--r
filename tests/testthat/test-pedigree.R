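test_that("pedigree construction validates, sorts and reports conflicts", {
  ped <- Pedigree(c("A", "B", "C"), c("0", "0", "0"), c("0", "0", "0"))
  expect_equal(nAnimals(ped), 3L)
  expect_equal(unname(generationIndex(ped)), c(0L, 0L, 0L))

  ped2 <- Pedigree(c("A", "B", "C"), c("0", "0", "A"), c("0", "0", "B"))
  expect_equal(animalIds(ped2)[3], "C")

  # parent listed after its offspring gets reordered ahead of it
  ped3 <- Pedigree(c("A", "C"), c("C", "0"), c("0", "0"))
  ids <- animalIds(ped3)
  expect_lt(which(ids == "C"), which(ids == "A"))

  expect_error(Pedigree(c("A", "A"), c("0", "0"), c("0", "0")), "duplicate")
  expect_error(Pedigree(c("A", "B"), c("B", "A"), c("0", "0")), "cycle")
  expect_error(Pedigree("A", "A", "0"), "own parent")
  expect_warning(Pedigree(c("X", "A", "B"), c("0", "X", "0"), c("0", "0", "X")),
                 "both sire and dam")
  expect_error(suppressWarnings(
    Pedigree(c("X", "A", "B"), c("0", "X", "0"), c("0", "0", "X"),
             strict = TRUE)), "both sire and dam")

  # referenced parents without a row become founders
  ped4 <- Pedigree("A", "S", "D")
  expect_setequal(animalIds(ped4), c("A", "S", "D"))
})

test_that("pedigree CSV round trip preserves structure", {
  ped <- Pedigree(c("S", "D", "O"), c("0", "0", "S"), c("0", "0", "D"))
  f <- tempfile(fileext = ".csv")
  writePedigree(ped, f)
  ped2 <- readPedigree(f)
  expect_identical(pedigreeTable(ped), pedigreeTable(ped2))
  expect_error(readPedigree(textConnection("a,b\n1,2")), "3 columns")
})

test_that("pruning keeps exactly the requested ancestor generations", {
  # chain of 5 generations: F0 -> F1 -> F2 -> F3 -> F4
  id <- paste0("F", 0:4)
  ped <- Pedigree(id, c("0", id[1:4]), rep("0", 5))
  pr <- pruneToGenerations(ped, "F4", nGen = 3)
  expect_setequal(animalIds(pr), c("F4", "F3", "F2", "F1"))
  tb <- pedigreeTable(pr)
  expect_true(is.na(tb$sire[tb$animal == "F1"]))  # beyond horizon cut

  pr0 <- pruneToGenerations(ped, "F4", nGen = 0)
  expect_equal(animalIds(pr0), "F4")
  expect_true(all(is.na(pedigreeTable(pr0)$sire)))

  # idempotence and anchor-all identity
  prAll <- pruneToGenerations(ped, id, nGen = 10)
  expect_identical(pedigreeTable(prAll), pedigreeTable(ped))
  expect_identical(pedigreeTable(pruneToGenerations(pr, animalIds(pr), 3)),
                   pedigreeTable(pr))

  expect_error(pruneToGenerations(ped, "nope", 3), "unknown anchor")
})

test_that("pruning matches the exhaustive ancestor walk and is monotone", {
  for (s in 1:5) {
    ped <- randomPedigree(60, seed = s)
    anchor <- sample(animalIds(ped), 1)
    for (g in 1:3) {
      pr <- pruneToGenerations(ped, anchor, nGen = g)
      expect_setequal(animalIds(pr),
                      union(anchor, oracleAncestors(ped, anchor, g)))
    }
    # monotone: larger horizon contains the smaller
    a2 <- sample(animalIds(ped), 3)
    expect_true(all(animalIds(pruneToGenerations(ped, a2, 1)) %in%
                    animalIds(pruneToGenerations(ped, a2, 2))))
  }
})

test_that("tabular A matches closed forms", {
  ped <- Pedigree(c("X", "Y", "Z"), rep("0", 3), rep("0", 3))
  expect_equal(additiveRelationshipMatrix(ped)@values, diag(3),
               ignore_attr = TRUE)

  trio <- Pedigree(c("S", "D", "O"), c("0", "0", "S"), c("0", "0", "D"))
  A <- additiveRelationshipMatrix(trio)@values
  expect_equal(A["S", "O"], 0.5)
  expect_equal(A["O", "O"], 1)

  # parents are full sibs (a = 0.5) -> offspring F = 0.25
  fs <- Pedigree(c("S", "D", "A", "B", "O"),
                 c("0", "0", "S", "S", "A"), c("0", "0", "D", "D", "B"))
  Af <- additiveRelationshipMatrix(fs)@values
  expect_equal(Af["A", "B"], 0.5)
  expect_equal(Af["O", "O"], 1.25)
})

test_that("sparse A-inverse follows Henderson's rules and inverts tabular A", {
  founders <- Pedigree(c("X", "Y"), c("0", "0"), c("0", "0"))
  expect_equal(as.matrix(aInverse(founders)@mat), diag(2),
               ignore_attr = TRUE)

  trio <- Pedigree(c("S", "D", "O"), c("0", "0", "S"), c("0", "0", "D"))
  Ai <- as.matrix(aInverse(trio)@mat)
  dimnames(Ai) <- list(animalIds(trio), animalIds(trio))
  expect_equal(Ai["O", "O"], 2)
  expect_equal(Ai["S", "O"], -1)
  expect_equal(Ai["S", "D"], 0.5)

  for (s in 1:4) {
    ped <- randomPedigree(200, seed = 10 + s)
    A <- oracleA(ped)
    ai <- aInverse(ped)
    expect_lt(max(abs(as.matrix(ai@mat) %*% A - diag(nrow(A)))), 1e-8)
    expect_equal(ai@logdet, as.numeric(determinant(A)$modulus),
                 tolerance = 1e-8)
  }
})

test_that("A-inverse without inbreeding uses the classical constants", {
  # O (sire-daughter offspring) is inbred; its child P then has an inbred
  # parent, which is where the Mendelian-sampling variances differ
  ped <- Pedigree(c("S", "D", "A", "O", "E", "P"),
                  c("0", "0", "S", "S", "0", "O"),
                  c("0", "0", "D", "A", "0", "E"))
  ai1 <- aInverse(ped, withInbreeding = TRUE)
  ai0 <- aInverse(ped, withInbreeding = FALSE)
  expect_false(isTRUE(all.equal(as.matrix(ai1@mat), as.matrix(ai0@mat))))
  # on a non-inbred pedigree the two agree
  trio <- Pedigree(c("S", "D", "O"), c("0", "0", "S"), c("0", "0", "D"))
  expect_equal(as.matrix(aInverse(trio, TRUE)@mat),
               as.matrix(aInverse(trio, FALSE)@mat))
})

test_that("inbreeding coefficients match the tabular diagonal", {
  ped <- Pedigree(c("X", "Y"), c("0", "0"), c("0", "0"))
  expect_equal(unname(inbreedingCoefficients(ped)), c(0, 0))

  fs <- Pedigree(c("S", "D", "A", "B", "O"),
                 c("0", "0", "S", "S", "A"), c("0", "0", "D", "D", "B"))
  expect_equal(unname(inbreedingCoefficients(fs)["O"]), 0.25)

  # sire-daughter mating
  sd <- Pedigree(c("S", "D", "A", "O"),
                 c("0", "0", "S", "S"), c("0", "0", "D", "A"))
  expect_equal(unname(inbreedingCoefficients(sd)["O"]), 0.25)

  for (s in 1:5) {
    ped <- randomPedigree(150, seed = 20 + s)
    expect_equal(unname(inbreedingCoefficients(ped)),
                 unname(diag(oracleA(ped)) - 1), tolerance = 1e-10)
  }
})

test_that("relationship summaries cover the documented cases", {
  # two breeds without shared ancestors: all cross relationships are 0
  ped <- Pedigree(c("A1", "A2", "A3", "B1", "B2", "B3"),
                  c("0", "0", "A1", "0", "0", "B1"),
                  c("0", "0", "A2", "0", "0", "B2"))
  A <- additiveRelationshipMatrix(ped)
  expect_equal(unname(relationshipSummary(A, c("A1", "A2", "A3"),
                                          c("B1", "B2", "B3"))),
               c(0, 0, 0))

  trio <- additiveRelationshipMatrix(
    Pedigree(c("S", "D", "O"), c("0", "0", "S"), c("0", "0", "D")))
  expect_equal(unname(relationshipSummary(trio, "S", "O")), c(0.5, 0.5, 0.5))

  # brute-force pair enumeration on a random split
  ped <- randomPedigree(60, seed = 31)
  A <- additiveRelationshipMatrix(ped)
  ids <- animalIds(ped)
  s1 <- sample(ids, 20); s2 <- sample(ids, 25)
  vals <- c()
  for (i in s1) for (j in s2)
    if (i != j) vals <- c(vals, A@values[i, j])
  expect_equal(unname(relationshipSummary(A, s1, s2)),
               c(mean(vals), min(vals), max(vals)))

  expect_error(relationshipSummary(A, character(0), s2), "empty")
})

test_that("A is positive semi-definite on random pedigrees", {
  for (s in 1:5) {
    A <- additiveRelationshipMatrix(randomPedigree(120, seed = 40 + s))
    expect_gt(min(eigen(A@values, symmetric = TRUE,
                        only.values = TRUE)$values), -1e-9)
  }
})

test_that("A-inverse triplet export is readable and consistent", {
  ped <- randomPedigree(40, seed = 50)
  ai <- aInverse(ped)
  pre <- tempfile()
  writeAInverse(ai, pre)
  tri <- read.delim(paste0(pre, ".triplets"))
  ids <- read.delim(paste0(pre, ".ids"))
  expect_equal(ids$id, animalIds(ped))
  M <- matrix(0, 40, 40)
  M[cbind(tri$i, tri$j)] <- tri$value
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  expect_equal(M, as.matrix(ai@mat), ignore_attr = TRUE, tolerance = 1e-12)
})
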