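# Independent dense-algebra oracles used across the test files.  Everything
# here is written from first principles (base R only) so that it never
# shares code paths with the package internals it checks.

# random valid pedigree: founders first, then animals with parents drawn
# from earlier animals
randomPedigree <- function(n, nFounders = max(5L, n %/% 5L), seed = 1L) {
  set.seed(seed)
  id <- paste0("P", seq_len(n))
  sire <- dam <- rep("0", n)
  for (i in (nFounders + 1L):n) {
    sire[i] <- id[sample.int(i - 1L, 1L)]
    dam[i] <- id[sample.int(i - 1L, 1L)]
  }
  suppressWarnings(Pedigree(id, sire, dam))
}

# tabular A computed independently (row-wise recursion over a token table)
oracleA <- function(ped) {
  tb <- pedigreeTable(ped)
  n <- nrow(tb)
  si <- match(tb$sire, tb$animal)
  di <- match(tb$dam, tb$animal)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      a1 <- if (is.na(si[j])) 0 else A[i, si[j]]
      a2 <- if (is.na(di[j])) 0 else A[i, di[j]]
      A[i, j] <- A[j, i] <- 0.5 * (a1 + a2)
    }
    A[j, j] <- 1 + if (!is.na(si[j]) && !is.na(di[j])) 0.5 * A[si[j], di[j]] else 0
  }
  dimnames(A) <- list(tb$animal, tb$animal)
  A
}

# exhaustive ancestor walk with a generation budget
oracleAncestors <- function(ped, anchor, nGen) {
  tb <- pedigreeTable(ped)
  out <- character(0)
  frontier <- anchor
  for (g in seq_len(nGen)) {
    if (!length(frontier)) break
    par <- c(tb$sire[match(frontier, tb$animal)],
             tb$dam[match(frontier, tb$animal)])
    frontier <- unique(par[!is.na(par)])
    out <- union(out, frontier)
  }
  out
}

# dense brute-force restricted log-likelihood of the bivariate model,
# built directly from the record tables (never from the package design)
oracleREML <- function(phen, gtab, ped, vc, maternal = FALSE) {
  A <- oracleA(ped)
  aid <- rownames(A)
  np <- nrow(phen); ng <- nrow(gtab); n <- np + ng
  y <- c(phen$value, gtab$gebv)
  cg <- factor(phen$cg)
  p <- nlevels(cg) + 1L
  X <- matrix(0, n, p)
  if (np) X[cbind(seq_len(np), as.integer(cg))] <- 1
  X[np + seq_len(ng), p] <- 1
  Zrow <- function(ids, rows) {
    Z <- matrix(0, n, length(aid))
    Z[cbind(rows, match(ids, aid))] <- 1
    Z
  }
  Zd <- Zrow(phen$animal_id, seq_len(np))
  Zg <- Zrow(gtab$animal_id, np + seq_len(ng))
  V <- vc[["sigma2_a"]] * Zd %*% A %*% t(Zd) +
    vc[["sigma2_g"]] * Zg %*% A %*% t(Zg) +
    vc[["sigma_ag"]] * (Zd %*% A %*% t(Zg) + Zg %*% A %*% t(Zd))
  if (maternal) {
    Zm <- Zrow(phen$dam, seq_len(np))
    dams <- unique(phen$dam)
    Zp <- matrix(0, n, length(dams))
    Zp[cbind(seq_len(np), match(phen$dam, dams))] <- 1
    V <- V + vc[["sigma2_m"]] * Zm %*% A %*% t(Zm) +
      vc[["sigma_am"]] * (Zd %*% A %*% t(Zm) + Zm %*% A %*% t(Zd)) +
      vc[["sigma_gm"]] * (Zg %*% A %*% t(Zm) + Zm %*% A %*% t(Zg)) +
      vc[["sigma2_p"]] * Zp %*% t(Zp)
  }
  R <- matrix(0, n, n)
  if (np) diag(R)[seq_len(np)] <- vc[["sigma2_ep"]]
  diag(R)[np + seq_len(ng)] <- vc[["sigma2_eg"]]
  sepg <- if ("sigma_epg" %in% names(vc)) vc[["sigma_epg"]] else 0
  for (a in intersect(phen$animal_id, gtab$animal_id)) {
    i <- match(a, phen$animal_id)
    j <- np + match(a, gtab$animal_id)
    R[i, j] <- R[j, i] <- sepg
  }
  V <- V + R
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  -0.5 * ((n - p) * log(2 * pi) +
            as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XVX)$modulus) +
            drop(t(y) %*% P %*% y))
}

# random toy record set over a random pedigree (for likelihood oracles)
randomToyInstance <- function(seed, maternal = FALSE, overlap = TRUE) {
  set.seed(seed)
  n <- sample(12:18, 1)
  ped <- randomPedigree(n, nFounders = 6L, seed = seed + 500L)
  tb <- pedigreeTable(ped)
  nonF <- tb$animal[!is.na(tb$sire) & !is.na(tb$dam)]
  pool <- if (maternal) nonF else tb$animal
  np <- min(length(pool), sample(6:10, 1))
  pan <- sample(pool, np)
  gan <- if (overlap) sample(tb$animal, 8) else sample(setdiff(tb$animal, pan),
                                                       min(6, n - np))
  phen <- data.frame(animal_id = pan, trait = "p.SIM",
                     value = rnorm(np, 10, 2),
                     cg = sample(c("c1", "c2"), np, TRUE),
                     dam = tb$dam[match(pan, tb$animal)],
                     stringsAsFactors = FALSE)
  gtab <- data.frame(animal_id = gan, gebv = rnorm(length(gan)),
                     stringsAsFactors = FALSE)
  vc <- c(sigma2_a = runif(1, .5, 2), sigma_ag = runif(1, -.3, .6),
          sigma2_g = runif(1, .5, 2), sigma2_ep = runif(1, .5, 2),
          sigma_epg = runif(1, -.2, .4), sigma2_eg = runif(1, .3, 1))
  if (maternal)
    vc <- c(vc, sigma_am = runif(1, -.2, .2), sigma_gm = runif(1, -.2, .2),
            sigma2_m = runif(1, .3, 1), sigma2_p = runif(1, .1, .5))
  # keep the genetic block safely PD
  k <- if (maternal) 3 else 2
  Sg <- diag(c(vc["sigma2_a"], vc["sigma2_g"], if (maternal) vc["sigma2_m"]),
             k)
  Sg[1, 2] <- Sg[2, 1] <- vc["sigma_ag"]
  if (maternal) {
    Sg[1, 3] <- Sg[3, 1] <- vc["sigma_am"]
    Sg[2, 3] <- Sg[3, 2] <- vc["sigma_gm"]
  }
  if (min(eigen(Sg, symmetric = TRUE, only.values = TRUE)$values) < 0.05)
    vc["sigma_ag"] <- vc["sigma_am"] <- vc["sigma_gm"] <- 0
  list(ped = ped, phen = phen, gtab = gtab, vc = vc)
}
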