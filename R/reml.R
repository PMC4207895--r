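## Bivariate animal-model REML.
##
## The observation vector stacks the phenotype records of one trait over the
## GEBV records of its assigned GEBV trait.  Fixed effects: contemporary
## group for the phenotype, a single mean for the GEBV.  Random effects:
## direct genetic for both traits (and maternal genetic + maternal permanent
## environment for the early weight traits), all genetic effects covarying
## through the numerator relationship matrix A; residuals are correlated
## only for animals observed on both traits.
##
## The restricted log-likelihood is evaluated through the mixed-model
## equations identity  -2 logL = (n-p) log 2pi + log|R| + log|G| + log|C|
## + y'Py, with a single sparse Cholesky factorization (CHOLMOD) per
## evaluation whose symbolic analysis is reused across evaluations.

# ---- design -------------------------------------------------------------

#' Build the bivariate (or univariate) REML design
#'
#' Precomputes the sparse incidence matrix, its crossproduct pieces, the
#' assembled-coefficient pattern and the factorization template used by
#' [restrictedLogLik()] and [remlFit()].
#'
#' @param dataset a [TraitDataset-class] (use \code{channels} to restrict to
#'   one trait for univariate analyses).
#' @param ainv a [SparseInverse-class] covering every record animal (and
#'   every dam for maternal models); typically from [aInverse()] on a
#'   pedigree pruned with [pruneToGenerations()].
#' @param maternal fit maternal genetic and maternal permanent environment
#'   effects for the phenotypic trait ("auto" switches them on for the
#'   early weight traits).
#' @param fitResidualCov fit the phenotype/GEBV residual covariance.  NULL
#'   (default) fits it exactly when some animals carry both observations;
#'   with no overlap it is structurally zero and any supplied value is
#'   ignored.
#' @param channels which record channels to include:
#'   \code{c("phenotype", "gebv")} (default, bivariate) or a single one.
#' @return an opaque design object (class \code{remlDesign}).
#' @export
buildDesign <- function(dataset, ainv, maternal = "auto",
                        fitResidualCov = NULL,
                        channels = c("phenotype", "gebv")) {
  stopifnot(is(dataset, "TraitDataset"), is(ainv, "SparseInverse"))
  channels <- match.arg(channels, c("phenotype", "gebv"),
                        several.ok = TRUE)
  if (identical(maternal, "auto"))
    maternal <- dataset@trait %in% maternalTraits()
  hasP <- "phenotype" %in% channels && nrow(dataset@phenotypes) > 0
  hasG <- "gebv" %in% channels && nrow(dataset@gebv) > 0
  if (!hasP && !hasG) stop("no records in the requested channels")
  maternal <- maternal && hasP
  aids <- ainv@ids
  nA <- length(aids)

  phen <- if (hasP) dataset@phenotypes else NULL
  gtab <- if (hasG) dataset@gebv else NULL
  if (hasP) {
    ia <- match(phen$animal_id, aids)
    if (anyNA(ia)) stop("phenotyped animal(s) missing from the A-inverse: ",
                        paste(utils::head(phen$animal_id[is.na(ia)], 5),
                              collapse = ", "))
    if (maternal) {
      if (!"dam" %in% names(phen) || any(!.known(phen$dam)))
        stop("maternal model requires a known dam for every phenotype record")
      idam <- match(phen$dam, aids)
      if (anyNA(idam)) stop("dam(s) missing from the A-inverse")
    }
  }
  if (hasG) {
    ig <- match(gtab$animal_id, aids)
    if (anyNA(ig)) stop("GEBV animal(s) missing from the A-inverse")
  }

  np <- if (hasP) nrow(phen) else 0L
  ng <- if (hasG) nrow(gtab) else 0L
  n <- np + ng

  # overlap pairs (phenotype row, gebv row) for the residual covariance
  if (hasP && hasG) {
    ov <- intersect(phen$animal_id, gtab$animal_id)
    oP <- match(ov, phen$animal_id)
    oG <- np + match(ov, gtab$animal_id)
  } else {
    ov <- character(0); oP <- integer(0); oG <- integer(0)
  }
  if (is.null(fitResidualCov)) fitResidualCov <- length(ov) > 0
  fitResidualCov <- fitResidualCov && length(ov) > 0

  # ---- columns ----
  effects <- c(if (hasP) "d", if (hasG) "g", if (maternal) "m")
  nEff <- length(effects)
  cgLev <- if (hasP) sort(unique(phen$cg)) else character(0)
  nCG <- length(cgLev)
  pFix <- nCG + as.integer(hasG)
  cols <- list()
  off <- pFix
  for (e in effects) { cols[[e]] <- off + seq_len(nA); off <- off + nA }
  damLev <- if (maternal) sort(unique(phen$dam)) else character(0)
  nDam <- length(damLev)
  if (maternal) { cols[["pe"]] <- off + seq_len(nDam); off <- off + nDam }
  q <- off

  # ---- sparse incidence ----
  ti <- list(); tj <- list(); tx <- list()
  addT <- function(i, j) {
    ti[[length(ti) + 1L]] <<- i; tj[[length(tj) + 1L]] <<- j
    tx[[length(tx) + 1L]] <<- rep(1, length(i))
  }
  if (hasP) {
    rp <- seq_len(np)
    addT(rp, match(phen$cg, cgLev))
    addT(rp, cols$d[ia])
    if (maternal) {
      addT(rp, cols$m[idam])
      addT(rp, cols$pe[match(phen$dam, damLev)])
    }
  }
  if (hasG) {
    rg <- np + seq_len(ng)
    addT(rg, rep(nCG + 1L, ng))       # GEBV mean column
    addT(rg, cols$g[ig])
  }
  W <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(n, q))
  y <- c(if (hasP) phen$value else numeric(0),
         if (hasG) gtab$gebv else numeric(0))

  # ---- crossproduct pieces, grouped by residual weight class ----
  rowsP <- if (hasP) seq_len(np) else integer(0)
  rowsG <- if (hasG) np + seq_len(ng) else integer(0)
  noP <- setdiff(rowsP, oP)
  noG <- setdiff(rowsG, oG)
  gen <- function(m) as(as(drop0(m), "generalMatrix"), "CsparseMatrix")
  xp <- function(rows) gen(Matrix::crossprod(W[rows, , drop = FALSE]))
  pieces <- list(); coefName <- character(0)
  addPiece <- function(mat, nm) {
    pieces[[length(pieces) + 1L]] <<- mat
    coefName[length(coefName) + 1L] <<- nm
  }
  if (length(noP)) addPiece(xp(noP), "wPno")
  if (length(noG)) addPiece(xp(noG), "wGno")
  if (length(ov)) {
    addPiece(xp(oP), "wPo")
    addPiece(xp(oG), "wGo")
    M <- Matrix::crossprod(W[oP, , drop = FALSE], W[oG, , drop = FALSE])
    addPiece(gen(M + Matrix::t(M)), "wPGo")
  }
  # genetic G-inverse blocks: kron(Sigma^-1, Ainv) laid out by effect order
  At <- as(as(ainv@mat, "generalMatrix"), "TsparseMatrix")
  embed <- function(a, b) {
    i <- c(cols[[a]][At@i + 1L], if (a != b) cols[[b]][At@i + 1L])
    j <- c(cols[[b]][At@j + 1L], if (a != b) cols[[a]][At@j + 1L])
    Matrix::sparseMatrix(i = i, j = j, x = rep(At@x, if (a == b) 1 else 2),
                         dims = c(q, q))
  }
  for (a in seq_len(nEff)) for (b in a:nEff)
    addPiece(gen(embed(effects[a], effects[b])),
             paste0("K_", effects[a], effects[b]))
  if (maternal)
    addPiece(gen(Matrix::sparseMatrix(i = cols$pe, j = cols$pe,
                                      x = rep(1, nDam), dims = c(q, q))),
             "Dpe")

  # union pattern and index maps (fixed across evaluations)
  pat <- lapply(pieces, function(m) { m@x[] <- 1; m })
  U <- Reduce(`+`, pat)
  keyOf <- function(m) {
    mi <- m@i + 1
    mj <- rep(seq_len(ncol(m)), diff(m@p))
    mi + (mj - 1) * as.numeric(q)
  }
  uKey <- keyOf(U)
  pieceIdx <- lapply(pieces, function(m) match(keyOf(m), uKey))
  pieceX <- lapply(pieces, function(m) m@x)

  # rhs / quadratic pieces
  v <- function(rows) if (length(rows))
    drop(as.matrix(Matrix::crossprod(W[rows, , drop = FALSE], y[rows])))
    else numeric(q)
  vec <- list(bPno = v(noP), bGno = v(noG))
  if (length(ov)) {
    vec$bPo <- v(oP); vec$bGo <- v(oG)
    vec$aPG <- if (length(oP))
      drop(as.matrix(Matrix::crossprod(W[oP, , drop = FALSE], y[oG])))
      else numeric(q)
    vec$aGP <- drop(as.matrix(Matrix::crossprod(W[oG, , drop = FALSE], y[oP])))
  }
  sq <- list(sPno = sum(y[noP]^2), sGno = sum(y[noG]^2),
             sPo = sum(y[oP]^2), sGo = sum(y[oG]^2),
             sPG = sum(y[oP] * y[oG]))

  ds <- list(q = q, n = n, p = pFix, nA = nA, nEff = nEff,
             effects = effects, nDam = nDam, maternal = maternal,
             hasP = hasP, hasG = hasG,
             fitResidualCov = fitResidualCov,
             nPno = length(noP), nGno = length(noG), nOv = length(ov),
             rowsP = rowsP, rowsG = rowsG, oP = oP, oG = oG,
             noP = noP, noG = noG, cols = cols, cgLev = cgLev,
             W = W, y = y,
             pieceIdx = pieceIdx, pieceX = pieceX, coefName = coefName,
             nnzU = length(uKey),
             Ctmp = U, vec = vec, sq = sq,
             logdetA = ainv@logdet, ainv = ainv@mat,
             varP = if (hasP) stats::var(phen$value) else NA_real_,
             varG = if (hasG) stats::var(gtab$gebv) else NA_real_,
             env = new.env(parent = emptyenv()))
  class(ds) <- "remlDesign"
  ds
}

#' @export
print.remlDesign <- function(x, ...) {
  cat("remlDesign:", x$n, "records (", length(x$rowsP), "phenotype /",
      length(x$rowsG), "GEBV ),", x$q, "equations,",
      x$nOv, "overlap animals,",
      if (x$maternal) "maternal model" else "plain model", "\n")
  invisible(x)
}

# variance components as matrices from a named vector
.vcMatrices <- function(ds, vc) {
  e <- ds$effects
  k <- length(e)
  nm2 <- function(a, b) {
    lab <- c(d = "a", g = "g", m = "m")
    if (a == b) paste0("sigma2_", lab[a])
    else {
      pr <- sort(c(lab[a], lab[b]))
      paste0("sigma_", pr[1], pr[2])
    }
  }
  Sg <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in a:k) {
    val <- vc[[nm2(e[a], e[b])]]
    if (is.null(val) || is.na(val)) val <- 0
    Sg[a, b] <- Sg[b, a] <- val
  }
  ep <- if (ds$hasP) vc[["sigma2_ep"]] else NA_real_
  eg <- if (ds$hasG) vc[["sigma2_eg"]] else NA_real_
  epg <- if (ds$fitResidualCov) {
    v <- vc[["sigma_epg"]]; if (is.null(v) || is.na(v)) 0 else v
  } else 0
  s2p <- if (ds$maternal) vc[["sigma2_p"]] else NA_real_
  list(Sg = Sg, ep = ep, eg = eg, epg = epg, s2p = s2p)
}

# coefficient of every precomputed piece for a given component set
.pieceCoefs <- function(ds, m) {
  iEP <- if (ds$hasP) 1 / m$ep else 0
  iEG <- if (ds$hasG) 1 / m$eg else 0
  if (ds$nOv) {
    det2 <- m$ep * m$eg - m$epg^2
    o11 <- m$eg / det2; o22 <- m$ep / det2; o12 <- -m$epg / det2
  } else { o11 <- o22 <- o12 <- 0 }
  Si <- solve(m$Sg)
  cf <- numeric(length(ds$coefName))
  names(cf) <- ds$coefName
  for (nm in ds$coefName) {
    cf[nm] <- switch(substr(nm, 1, 2),
      "wP" = switch(nm, wPno = iEP, wPo = o11, wPGo = o12),
      "wG" = switch(nm, wGno = iEG, wGo = o22),
      "K_" = {
        ab <- substring(nm, 3)
        a <- match(substr(ab, 1, 1), ds$effects)
        b <- match(substr(ab, 2, 2), ds$effects)
        Si[a, b]
      },
      "Dp" = 1 / m$s2p)
  }
  list(cf = cf, o = c(o11, o22, o12), iEP = iEP, iEG = iEG, Si = Si)
}

# log-determinant of the matrix factored in a CHMfactor
.logdetChol <- function(ch) {
  2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
}

# assemble C, factor it (reusing the symbolic analysis), and return the
# REML log-likelihood plus the MME solution
.remlCore <- function(ds, vc, wantSolution = FALSE) {
  if (!all(is.finite(unlist(vc)))) return(list(loglik = -Inf))
  m <- .vcMatrices(ds, vc)
  ev <- min(eigen(m$Sg, symmetric = TRUE, only.values = TRUE)$values)
  detR2 <- if (ds$nOv) m$ep * m$eg - m$epg^2 else 1
  # relative floors: tiny variances make the determinant/quadratic terms
  # cancel catastrophically in the MME identity
  fl <- 1e-9
  if (!is.finite(ev) || ev <= 1e-10 * max(abs(diag(m$Sg))) ||
      (ds$hasP && m$ep < fl * ds$varP) ||
      (ds$hasG && m$eg < fl * ds$varG) ||
      (ds$maternal && m$s2p < fl * ds$varP) ||
      detR2 <= fl^2 * max(1, ds$varP * ds$varG, na.rm = TRUE))
    return(list(loglik = -Inf))
  pc <- tryCatch(.pieceCoefs(ds, m), error = function(e) NULL)
  if (is.null(pc)) return(list(loglik = -Inf))
  xv <- numeric(ds$nnzU)
  for (k in seq_along(ds$pieceIdx)) {
    idx <- ds$pieceIdx[[k]]
    xv[idx] <- xv[idx] + pc$cf[k] * ds$pieceX[[k]]
  }
  C <- ds$Ctmp
  C@x <- xv
  Cs <- Matrix::forceSymmetric(C)
  ch <- ds$env$chol
  ok <- TRUE
  ch <- withCallingHandlers(
    tryCatch(if (is.null(ch)) Matrix::Cholesky(Cs, LDL = FALSE, super = TRUE,
                                               perm = TRUE)
             else Matrix::update(ch, Cs),
             error = function(e) NULL),
    warning = function(w) {
      ok <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (is.null(ch) || !ok) {
    ds$env$chol <- NULL                 # force a fresh symbolic analysis
    return(list(loglik = -Inf))
  }
  ds$env$chol <- ch

  v <- ds$vec
  rhs <- pc$iEP * v$bPno + pc$iEG * v$bGno
  if (ds$nOv)
    rhs <- rhs + pc$o[1] * v$bPo + pc$o[2] * v$bGo +
      pc$o[3] * (v$aPG + v$aGP)
  sol <- tryCatch(Matrix::solve(ch, rhs, system = "A"),
                  error = function(e) NULL)
  if (is.null(sol)) return(list(loglik = -Inf))
  sol <- drop(as.matrix(sol))

  yRy <- pc$iEP * ds$sq$sPno + pc$iEG * ds$sq$sGno
  if (ds$nOv)
    yRy <- yRy + pc$o[1] * ds$sq$sPo + pc$o[2] * ds$sq$sGo +
      2 * pc$o[3] * ds$sq$sPG
  yPy <- yRy - sum(rhs * sol)
  # y'Py is a PSD quadratic form; a clearly negative value flags a
  # numerically failed solve
  if (!is.finite(yPy) || yPy < -1e-6 * max(1, abs(yRy)))
    return(list(loglik = -Inf))
  yPy <- max(yPy, 0)

  logdetR <- (if (ds$hasP) ds$nPno * log(m$ep) else 0) +
    (if (ds$hasG) ds$nGno * log(m$eg) else 0) +
    ds$nOv * log(detR2)
  logdetG <- ds$nA * as.numeric(determinant(m$Sg, logarithm = TRUE)$modulus) +
    ds$nEff * ds$logdetA +
    if (ds$maternal) ds$nDam * log(m$s2p) else 0
  logdetC <- .logdetChol(ch)
  ll <- -0.5 * ((ds$n - ds$p) * log(2 * pi) + logdetR + logdetG +
                logdetC + yPy)
  out <- list(loglik = ll, m = m, pc = pc)
  if (wantSolution) { out$sol <- sol; out$chol <- ch }
  out
}

#' Restricted log-likelihood of the bivariate animal model
#'
#' Exact REML log-likelihood (constants included) for a given set of
#' variance components, evaluated through the mixed-model equations with a
#' sparse Cholesky factorization.  When the design has no phenotype/GEBV
#' overlap the residual covariance is structurally zero and any supplied
#' \code{sigma_epg} is ignored.
#'
#' @param vc named numeric vector of components; names among
#'   \code{sigma2_a, sigma_ag, sigma2_g, sigma_am, sigma_gm, sigma2_m,
#'   sigma2_p, sigma2_ep, sigma_epg, sigma2_eg} as applicable to the design.
#' @param design a design from [buildDesign()].
#' @return the restricted log-likelihood (scalar; \code{-Inf} outside the
#'   admissible parameter space).
#' @export
restrictedLogLik <- function(vc, design) {
  stopifnot(inherits(design, "remlDesign"))
  .remlCore(design, as.list(vc))$loglik
}

# ---- parameterization ---------------------------------------------------

# Unconstrained parameter vector <-> component list.
# Genetic block: Cholesky of Sigma permuted to put the GEBV effect first so
# that fixing sigma_gm = 0 is a single zeroed factor entry.
.makeParamMap <- function(ds, fixGm = FALSE, scaleP = 1, scaleG = 1) {
  e <- ds$effects
  k <- length(e)
  perm <- order(match(e, c("g", "d", "m")))   # g first, then d, then m
  lab <- c(d = "a", g = "g", m = "m")
  nmOf <- function(a, b) {
    if (a == b) paste0("sigma2_", lab[a]) else {
      pr <- sort(c(lab[a], lab[b])); paste0("sigma_", pr[1], pr[2])
    }
  }
  sc <- c(d = scaleP, g = scaleG, m = scaleP)
  fixPos <- if (fixGm && k == 3) c(3L, 1L) else NULL
  freeL <- which(lower.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  if (!is.null(fixPos))
    freeL <- freeL[!(freeL[, 1] == fixPos[1] & freeL[, 2] == fixPos[2]), ,
                   drop = FALSE]
  nGenPar <- nrow(freeL)
  hasRcov <- ds$fitResidualCov
  nResPar <- (ds$hasP + ds$hasG) + as.integer(hasRcov)
  nPar <- nGenPar + as.integer(ds$maternal) + nResPar

  toVc <- function(theta) {
    L <- matrix(0, k, k)
    for (r in seq_len(nGenPar)) {
      i <- freeL[r, 1]; j <- freeL[r, 2]
      L[i, j] <- if (i == j) exp(theta[r]) else theta[r]
    }
    Sstar <- L %*% t(L)
    inv <- order(perm)
    Sg <- Sstar[inv, inv, drop = FALSE]
    vc <- list()
    for (a in seq_len(k)) for (b in a:k)
      vc[[nmOf(e[a], e[b])]] <- Sg[a, b] * sc[e[a]] * sc[e[b]]
    pos <- nGenPar
    if (ds$maternal) {
      pos <- pos + 1L
      vc$sigma2_p <- exp(theta[pos]) * scaleP^2
    }
    if (hasRcov) {
      r11 <- exp(theta[pos + 1L]); r21 <- theta[pos + 2L]
      r22 <- exp(theta[pos + 3L])
      vc$sigma2_ep <- r11^2 * scaleP^2
      vc$sigma_epg <- r11 * r21 * scaleP * scaleG
      vc$sigma2_eg <- (r21^2 + r22^2) * scaleG^2
    } else {
      if (ds$hasP) { pos <- pos + 1L; vc$sigma2_ep <- exp(theta[pos]) * scaleP^2 }
      if (ds$hasG) { pos <- pos + 1L; vc$sigma2_eg <- exp(theta[pos]) * scaleG^2 }
    }
    vc
  }

  fromVc <- function(vc) {
    Sg <- matrix(0, k, k)
    for (a in seq_len(k)) for (b in a:k)
      Sg[a, b] <- Sg[b, a] <- (vc[[nmOf(e[a], e[b])]] %||% 0) /
        (sc[e[a]] * sc[e[b]])
    Sstar <- Sg[perm, perm, drop = FALSE]
    L <- t(chol(Sstar + diag(1e-10, k)))
    theta <- numeric(0)
    for (r in seq_len(nGenPar)) {
      i <- freeL[r, 1]; j <- freeL[r, 2]
      theta <- c(theta, if (i == j) log(L[i, j]) else L[i, j])
    }
    if (ds$maternal) theta <- c(theta, log(vc$sigma2_p / scaleP^2))
    if (hasRcov) {
      R2 <- matrix(c(vc$sigma2_ep / scaleP^2,
                     (vc$sigma_epg %||% 0) / (scaleP * scaleG),
                     (vc$sigma_epg %||% 0) / (scaleP * scaleG),
                     vc$sigma2_eg / scaleG^2), 2, 2)
      Lr <- t(chol(R2 + diag(1e-10, 2)))
      theta <- c(theta, log(Lr[1, 1]), Lr[2, 1], log(Lr[2, 2]))
    } else {
      if (ds$hasP) theta <- c(theta, log(vc$sigma2_ep / scaleP^2))
      if (ds$hasG) theta <- c(theta, log(vc$sigma2_eg / scaleG^2))
    }
    theta
  }

  # free component names (estimated, not structurally fixed)
  freeVc <- character(0)
  for (a in seq_len(k)) for (b in a:k) {
    nm <- nmOf(e[a], e[b])
    if (!(fixGm && nm == "sigma_gm")) freeVc <- c(freeVc, nm)
  }
  if (ds$maternal) freeVc <- c(freeVc, "sigma2_p")
  if (ds$hasP) freeVc <- c(freeVc, "sigma2_ep")
  if (hasRcov) freeVc <- c(freeVc, "sigma_epg")
  if (ds$hasG) freeVc <- c(freeVc, "sigma2_eg")

  list(nPar = nPar, toVc = toVc, fromVc = fromVc, freeVc = freeVc,
       fixGm = fixGm)
}

# ---- average information ------------------------------------------------

# R^{-1} v given the residual components
.rinv <- function(ds, m, v) {
  out <- numeric(ds$n)
  if (length(ds$noP)) out[ds$noP] <- v[ds$noP] / m$ep
  if (length(ds$noG)) out[ds$noG] <- v[ds$noG] / m$eg
  if (ds$nOv) {
    det2 <- m$ep * m$eg - m$epg^2
    vp <- v[ds$oP]; vg <- v[ds$oG]
    out[ds$oP] <- (m$eg * vp - m$epg * vg) / det2
    out[ds$oG] <- (m$ep * vg - m$epg * vp) / det2
  }
  out
}

# average-information matrix over the free components, at the solution
.aiMatrix <- function(ds, vc, core, freeVc) {
  m <- core$m
  W <- ds$W
  resid <- ds$y - drop(as.matrix(W %*% core$sol))
  t0 <- .rinv(ds, m, resid)                       # P y
  if (is.null(ds$env$achol))
    ds$env$achol <- Matrix::Cholesky(Matrix::forceSymmetric(ds$ainv),
                                     LDL = FALSE, perm = TRUE)
  Amult <- function(v)
    drop(as.matrix(Matrix::solve(ds$env$achol, v, system = "A")))
  e <- ds$effects
  lab <- c(d = "a", g = "g", m = "m")
  wOf <- function(nm) {
    if (nm == "sigma2_p") {
      Zp <- W[, ds$cols$pe, drop = FALSE]
      return(drop(as.matrix(Zp %*% Matrix::crossprod(Zp, t0))))
    }
    if (nm == "sigma2_ep") { w <- numeric(ds$n); w[ds$rowsP] <- t0[ds$rowsP]; return(w) }
    if (nm == "sigma2_eg") { w <- numeric(ds$n); w[ds$rowsG] <- t0[ds$rowsG]; return(w) }
    if (nm == "sigma_epg") {
      w <- numeric(ds$n); w[ds$oP] <- t0[ds$oG]; w[ds$oG] <- t0[ds$oP]
      return(w)
    }
    # genetic sigma_ab
    pair <- sub("^sigma2?_", "", nm)
    ab <- if (grepl("^sigma2_", nm)) c(pair, pair)
          else strsplit(pair, "")[[1]]
    key <- c(a = "d", g = "g", m = "m")
    a <- key[ab[1]]; b <- key[ab[2]]
    Za <- W[, ds$cols[[a]], drop = FALSE]
    Zb <- W[, ds$cols[[b]], drop = FALSE]
    w <- drop(as.matrix(Za %*% Amult(drop(as.matrix(Matrix::crossprod(Zb, t0))))))
    if (a != b)
      w <- w + drop(as.matrix(Zb %*% Amult(drop(as.matrix(Matrix::crossprod(Za, t0))))))
    w
  }
  ws <- lapply(freeVc, wOf)
  Pw <- lapply(ws, function(w) {
    u <- .rinv(ds, m, w)
    s <- Matrix::solve(core$chol, drop(as.matrix(Matrix::crossprod(W, u))),
                       system = "A")
    u - .rinv(ds, m, drop(as.matrix(W %*% s)))
  })
  kf <- length(freeVc)
  AI <- matrix(0, kf, kf, dimnames = list(freeVc, freeVc))
  for (i in seq_len(kf)) for (j in i:kf)
    AI[i, j] <- AI[j, i] <- 0.5 * sum(ws[[i]] * Pw[[j]])
  AI
}

# ---- fitting ------------------------------------------------------------

#' Fit the bivariate animal model by REML
#'
#' Maximizes the restricted log-likelihood over an unconstrained Cholesky
#' parameterization of the genetic and residual covariance blocks (which
#' guarantees positive semi-definite estimates at every iterate), then
#' derives standard errors from the inverse of the average-information
#' matrix at the optimum and reports the genetic correlation between the
#' phenotypic trait and the GEBV (its accuracy) and the heritability of the
#' GEBV with delta-method standard errors.
#'
#' @param dataset a [TraitDataset-class].
#' @param ainv a [SparseInverse-class] (see [buildDesign()]).
#' @param maternal "auto" (maternal effects for the early weight traits),
#'   TRUE or FALSE.
#' @param fixGm fix the GEBV/maternal genetic covariance at zero (an
#'   identifiability guard on small datasets).
#' @param fitResidualCov see [buildDesign()].
#' @param init optional named list/vector of starting components (original
#'   data scale).
#' @param control list: \code{maxit} (default 400), \code{reltol}
#'   (default 1e-10 on the log-likelihood).
#' @return a [REMLResult-class].
#' @export
remlFit <- function(dataset, ainv, maternal = "auto", fixGm = FALSE,
                    fitResidualCov = NULL, init = NULL, control = list()) {
  ds <- buildDesign(dataset, ainv, maternal = maternal,
                    fitResidualCov = fitResidualCov)
  .fitCore(ds, fixGm = fixGm, init = init, control = control,
           modelLabel = if (ds$maternal) "maternal" else "plain")
}

#' Univariate REML fit for one channel
#'
#' Same machinery restricted to a single trait: the GEBV channel yields the
#' heritability of the GEBV, the phenotype channel the heritability of the
#' phenotypic trait (with maternal effects when requested).
#'
#' @param dataset a [TraitDataset-class].
#' @param ainv a [SparseInverse-class].
#' @param channel "gebv" or "phenotype".
#' @inheritParams remlFit
#' @return a [REMLResult-class] (the genetic correlation slots are NA).
#' @export
univariateFit <- function(dataset, ainv, channel = c("gebv", "phenotype"),
                          maternal = FALSE, init = NULL, control = list()) {
  channel <- match.arg(channel)
  ds <- buildDesign(dataset, ainv, maternal = maternal, channels = channel)
  .fitCore(ds, fixGm = FALSE, init = init, control = control,
           modelLabel = paste0("univariate-", channel))
}

.fitCore <- function(ds, fixGm = FALSE, init = NULL, control = list(),
                     modelLabel = "plain") {
  maxit <- control$maxit %||% 400L
  reltol <- control$reltol %||% 1e-10
  scaleP <- if (ds$hasP) stats::sd(ds$y[ds$rowsP]) else 1
  scaleG <- if (ds$hasG) stats::sd(ds$y[ds$rowsG]) else 1
  if (!is.finite(scaleP) || scaleP <= 0) scaleP <- 1
  if (!is.finite(scaleG) || scaleG <= 0) scaleG <- 1
  pm <- .makeParamMap(ds, fixGm = fixGm, scaleP = scaleP, scaleG = scaleG)

  if (is.null(init)) {
    # phenotypic-variance partition on the unit scale
    init0 <- list(sigma2_a = 0.3, sigma_ag = 0, sigma2_g = 0.8,
                  sigma_am = 0, sigma_gm = 0, sigma2_m = 0.1,
                  sigma2_p = 0.05, sigma2_ep = 0.55, sigma_epg = 0,
                  sigma2_eg = 0.2)
    sc <- c(sigma2_a = scaleP^2, sigma_ag = scaleP * scaleG,
            sigma2_g = scaleG^2, sigma_am = scaleP^2,
            sigma_gm = scaleP * scaleG, sigma2_m = scaleP^2,
            sigma2_p = scaleP^2, sigma2_ep = scaleP^2,
            sigma_epg = scaleP * scaleG, sigma2_eg = scaleG^2)
    init <- lapply(names(init0), function(nm) init0[[nm]] * sc[[nm]])
    names(init) <- names(init0)
  } else init <- as.list(init)
  theta0 <- pm$fromVc(init)

  nEval <- 0L
  negll <- function(theta) {
    nEval <<- nEval + 1L
    ll <- .remlCore(ds, pm$toVc(theta))$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- stats::optim(theta0, negll, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  converged <- opt$convergence == 0L
  vc <- pm$toVc(opt$par)
  core <- .remlCore(ds, vc, wantSolution = TRUE)

  freeVc <- pm$freeVc
  AI <- tryCatch(.aiMatrix(ds, vc, core, freeVc), error = function(e) NULL)
  covM <- NULL
  if (!is.null(AI)) {
    covM <- tryCatch(solve(AI), error = function(e) NULL)
    if (is.null(covM)) covM <- pracma::pinv(AI)
    dimnames(covM) <- dimnames(AI)
  }
  if (is.null(covM)) covM <- matrix(NA_real_, length(freeVc), length(freeVc),
                                    dimnames = list(freeVc, freeVc))

  allNames <- unique(c(freeVc,
                       if (fixGm && "m" %in% ds$effects) "sigma_gm",
                       if (ds$hasP && ds$hasG && !ds$fitResidualCov)
                         "sigma_epg"))
  est <- vapply(allNames, function(nm) vc[[nm]] %||% 0, numeric(1))
  se <- vapply(allNames, function(nm) {
    if (nm %in% freeVc && is.finite(covM[nm, nm]) && covM[nm, nm] >= 0)
      sqrt(covM[nm, nm]) else NA_real_
  }, numeric(1))

  rg <- seRg <- NA_real_
  if (all(c("sigma2_a", "sigma2_g", "sigma_ag") %in% names(est))) {
    gc <- geneticCorrelation(est, covM)
    rg <- gc[["rg"]]; seRg <- gc[["se"]]
  }
  h2g <- seH2g <- NA_real_
  if (all(c("sigma2_g", "sigma2_eg") %in% names(est))) {
    hh <- gebvHeritability(est, covM)
    h2g <- hh[["h2"]]; seH2g <- hh[["se"]]
  }

  new("REMLResult", estimates = est, se = se, vcov = covM,
      loglik = core$loglik, converged = converged,
      iterations = nEval, h2Gebv = h2g, seH2Gebv = seH2g,
      rg = rg, seRg = seRg, model = modelLabel)
}

# ---- derived parameters -------------------------------------------------

#' Genetic correlation between the phenotypic trait and the GEBV
#'
#' \eqn{r_g = \sigma_{a,g} / \sqrt{\sigma^2_a \sigma^2_g}}; this is the
#' accuracy of the GEBV in the validation population.  The standard error
#' is by the delta method from the covariance matrix of the estimates.
#'
#' @param vc named vector (or [REMLResult-class]) containing
#'   \code{sigma2_a}, \code{sigma_ag}, \code{sigma2_g}.
#' @param vcov covariance matrix of the components (rows/columns named);
#'   may be NULL for a point estimate only.
#' @return named vector \code{c(rg, se)}.
#' @export
geneticCorrelation <- function(vc, vcov = NULL) {
  if (is(vc, "REMLResult")) { vcov <- vc@vcov; vc <- vc@estimates }
  va <- vc[["sigma2_a"]]; vg <- vc[["sigma2_g"]]; cag <- vc[["sigma_ag"]]
  if (!is.finite(va) || !is.finite(vg) || va <= 0 || vg <= 0)
    stop("genetic correlation undefined: a genetic variance is zero")
  rg <- cag / sqrt(va * vg)
  se <- NA_real_
  nm <- c("sigma_ag", "sigma2_a", "sigma2_g")
  if (!is.null(vcov) && all(nm %in% rownames(vcov)) &&
      all(is.finite(vcov[nm, nm]))) {
    grad <- c(1 / sqrt(va * vg), -rg / (2 * va), -rg / (2 * vg))
    v <- drop(t(grad) %*% vcov[nm, nm] %*% grad)
    if (is.finite(v) && v >= 0) se <- sqrt(v)
  }
  c(rg = rg, se = se)
}

#' Heritability of the GEBV
#'
#' \eqn{h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{e_g})}; near 1 when the
#' GEBV are error-free linear functions of the genotypes, lower under
#' genotyping/imputation error.  Delta-method standard error.
#'
#' @inheritParams geneticCorrelation
#' @return named vector \code{c(h2, se)}.
#' @export
gebvHeritability <- function(vc, vcov = NULL) {
  if (is(vc, "REMLResult")) { vcov <- vc@vcov; vc <- vc@estimates }
  vg <- vc[["sigma2_g"]]; veg <- vc[["sigma2_eg"]]
  s <- vg + veg
  if (!is.finite(s) || s <= 0) stop("total GEBV variance is zero")
  h2 <- vg / s
  se <- NA_real_
  nm <- c("sigma2_g", "sigma2_eg")
  if (!is.null(vcov) && all(nm %in% rownames(vcov)) &&
      all(is.finite(vcov[nm, nm]))) {
    grad <- c(veg / s^2, -vg / s^2)
    v <- drop(t(grad) %*% vcov[nm, nm] %*% grad)
    if (is.finite(v) && v >= 0) se <- sqrt(v)
  }
  c(h2 = h2, se = se)
}

#' Write a REML result to JSON and CSV
#'
#' \code{<prefix>.json} holds estimates, SEs, derived parameters, logL and
#' convergence; \code{<prefix>.csv} the component table; and
#' \code{<prefix>.md} a small "estimate|se" Markdown table.
#'
#' @param fit a [REMLResult-class].
#' @param prefix output path prefix.
#' @return invisibly, the file paths.
#' @export
writeREMLResult <- function(fit, prefix) {
  stopifnot(is(fit, "REMLResult"))
  js <- list(estimates = as.list(fit@estimates), se = as.list(fit@se),
             rg = fit@rg, se_rg = fit@seRg, h2_gebv = fit@h2Gebv,
             se_h2_gebv = fit@seH2Gebv, loglik = fit@loglik,
             converged = fit@converged, iterations = fit@iterations,
             model = fit@model)
  f1 <- paste0(prefix, ".json")
  jsonlite::write_json(js, f1, auto_unbox = TRUE, digits = NA, na = "null")
  df <- data.frame(component = names(fit@estimates),
                   estimate = unname(fit@estimates), se = unname(fit@se))
  f2 <- paste0(prefix, ".csv")
  utils::write.csv(df, f2, row.names = FALSE)
  md <- c("| parameter | estimate|se |", "|---|---|",
          sprintf("| r_g | %.2f|%.2f |", fit@rg, fit@seRg),
          sprintf("| h2_GEBV | %.2f|%.2f |", fit@h2Gebv, fit@seH2Gebv),
          sprintf("| %s | %.4g|%.3g |", names(fit@estimates),
                  fit@estimates, fit@se))
  f3 <- paste0(prefix, ".md")
  writeLines(md, f3)
  invisible(c(f1, f2, f3))
}
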