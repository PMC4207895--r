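#' Build a Pedigree from animal/sire/dam tokens
#'
#' Validates and topologically sorts raw pedigree triples.  Parents that are
#' referenced but have no own row are appended as founders so that every
#' listed sire/dam appears as an animal.  Cycles (an animal being its own
#' ancestor) are a hard error; a token used both as a sire and as a dam is a
#' warning by default and an error under \code{strict = TRUE}.
#'
#' @param animal,sire,dam character vectors of tokens.
#' @param unknown tokens coded as "parent unknown" (default \code{"0"},
#'   \code{""}, \code{"NA"}; \code{NA} is always unknown).
#' @param strict escalate the parent sex conflict warning to an error.
#' @return a [Pedigree-class], topologically sorted.
#' @examples
#' ped <- Pedigree(c("A", "B", "C"), c("0", "0", "A"), c("0", "0", "B"))
#' pedigreeTable(ped)
#' @export
Pedigree <- function(animal, sire, dam, unknown = c("0", "", "NA"),
                     strict = FALSE) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (length(sire) != length(animal) || length(dam) != length(animal))
    stop("animal, sire and dam must have the same length")
  if (anyDuplicated(animal)) {
    dup <- unique(animal[duplicated(animal)])
    stop("duplicate animal rows: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  sire[is.na(sire) | sire %in% unknown] <- NA_character_
  dam[is.na(dam) | dam %in% unknown] <- NA_character_

  # parents without their own row become founders
  missingParents <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(missingParents)) {
    animal <- c(animal, missingParents)
    sire <- c(sire, rep(NA_character_, length(missingParents)))
    dam <- c(dam, rep(NA_character_, length(missingParents)))
  }

  conflict <- intersect(stats::na.omit(sire), stats::na.omit(dam))
  if (length(conflict)) {
    msg <- paste0("token(s) used as both sire and dam: ",
                  paste(utils::head(conflict, 5), collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }

  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L
  if (any(si == seq_len(n)) || any(di == seq_len(n)))
    stop("animal listed as its own parent: ",
         animal[which(si == seq_len(n) | di == seq_len(n))[1]])

  ord <- .topoSort(si, di, animal)
  rk <- integer(n)
  rk[ord] <- seq_len(n)
  remap <- function(p) {
    v <- p[ord]
    out <- integer(n)
    out[v > 0L] <- rk[v[v > 0L]]
    out
  }
  s2 <- remap(si)
  d2 <- remap(di)
  gen <- integer(n)
  for (i in seq_len(n)) {
    gs <- if (s2[i] > 0L) gen[s2[i]] + 1L else 0L
    gd <- if (d2[i] > 0L) gen[d2[i]] + 1L else 0L
    gen[i] <- max(gs, gd)
  }
  new("Pedigree", id = animal[ord], sire = as.integer(s2),
      dam = as.integer(d2), generation = gen)
}

# Kahn topological sort over parent -> offspring edges; names a cycle on
# failure.
.topoSort <- function(si, di, labels) {
  n <- length(si)
  nParents <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (si[i] > 0L) children[[si[i]]] <- c(children[[si[i]]], i)
    if (di[i] > 0L) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  ord <- integer(n)
  queue <- which(nParents == 0L)
  k <- 0L
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    k <- k + 1L
    ord[k] <- v
    for (ch in children[[v]]) {
      nParents[ch] <- nParents[ch] - 1L
      if (nParents[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (k < n) {
    left <- which(nParents > 0L)
    # walk parents among the leftover set until a repeat names the cycle
    cyc <- left[1L]
    seen <- integer(0)
    repeat {
      seen <- c(seen, cyc)
      nxt <- if (si[cyc] %in% left) si[cyc] else di[cyc]
      if (nxt %in% seen) {
        cycle <- c(seen[which(seen == nxt):length(seen)], nxt)
        stop("pedigree cycle detected: ",
             paste(labels[cycle], collapse = " -> "))
      }
      cyc <- nxt
    }
  }
  ord
}

#' Read a pedigree CSV
#'
#' Expects a header and at least three columns (animal, sire, dam; extra
#' columns are ignored).
#'
#' @param path CSV file path.
#' @param unknown,strict see [Pedigree()].
#' @return a [Pedigree-class].
#' @export
readPedigree <- function(path, unknown = c("0", "", "NA"), strict = FALSE) {
  df <- utils::read.csv(path, header = TRUE, colClasses = "character")
  if (ncol(df) < 3L)
    stop("pedigree file must have at least 3 columns (animal, sire, dam)")
  Pedigree(df[[1]], df[[2]], df[[3]], unknown = unknown, strict = strict)
}

#' Write a pedigree CSV
#'
#' @param ped a [Pedigree-class].
#' @param path output file; unknown parents are written as "0".
#' @export
writePedigree <- function(ped, path) {
  tb <- pedigreeTable(ped)[, c("animal", "sire", "dam")]
  tb$sire[is.na(tb$sire)] <- "0"
  tb$dam[is.na(tb$dam)] <- "0"
  utils::write.csv(tb, path, row.names = FALSE, quote = FALSE)
}

#' Prune a pedigree to n generations of ancestors of anchor animals
#'
#' Keeps every anchor and its ancestors up to \code{nGen} generations back
#' (parents, grandparents, ... ; fewer when unavailable).  Parents beyond the
#' horizon are set unknown.  The default of three generations back mirrors
#' the usual requirement that every recorded animal has at least three
#' generations of ancestors in the pedigree where available.
#'
#' @param ped a [Pedigree-class].
#' @param anchors character tokens; must all be in the pedigree.
#' @param nGen non-negative integer horizon (default 3).
#' @return the pruned [Pedigree-class].
#' @export
pruneToGenerations <- function(ped, anchors, nGen = 3L) {
  stopifnot(is(ped, "Pedigree"), nGen >= 0L)
  anchors <- unique(as.character(anchors))
  bad <- setdiff(anchors, ped@id)
  if (length(bad))
    stop("unknown anchor token(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  n <- nAnimals(ped)
  budget <- rep(-1L, n)                 # -1 = not kept
  budget[match(anchors, ped@id)] <- as.integer(nGen)
  # propagate remaining depth to parents, offspring-before-parents
  for (i in rev(seq_len(n))) {
    b <- budget[i]
    if (b > 0L) {
      for (p in c(ped@sire[i], ped@dam[i])) {
        if (p > 0L && budget[p] < b - 1L) budget[p] <- b - 1L
      }
    }
  }
  keep <- which(budget >= 0L)
  s <- ped@sire[keep]
  d <- ped@dam[keep]
  cut <- budget[keep] == 0L
  s[cut] <- 0L
  d[cut] <- 0L
  tok <- function(p) ifelse(p == 0L | !(p %in% keep), NA_character_,
                            ped@id[pmax(p, 1L)])
  # the input Pedigree already passed validation; do not re-warn here
  suppressWarnings(Pedigree(ped@id[keep], tok(s), tok(d)))
}

#' Numerator relationship matrix by the tabular (recursive) method
#'
#' For animals ordered parents-before-offspring,
#' \eqn{a_{ij} = (a_{i,s(j)} + a_{i,d(j)})/2} for \eqn{i < j} and
#' \eqn{a_{jj} = 1 + a_{s(j),d(j)}/2}; unknown parents contribute 0.
#'
#' @param ped a [Pedigree-class].
#' @return a [RelationshipMatrix-class].
#' @export
additiveRelationshipMatrix <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  n <- nAnimals(ped)
  A <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  for (j in seq_len(n)) {
    s <- ped@sire[j]
    d <- ped@dam[j]
    if (j > 1L) {
      i <- seq_len(j - 1L)
      as_ <- if (s > 0L) A[i, s] else 0
      ad_ <- if (d > 0L) A[i, d] else 0
      v <- 0.5 * (as_ + ad_)
      A[i, j] <- v
      A[j, i] <- v
    }
    A[j, j] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  new("RelationshipMatrix", ids = ped@id, values = A)
}

# Meuwissen-Luo recursion: inbreeding coefficients and Mendelian-sampling
# variances d_i in one pass, never forming A.
.meuwissenLuo <- function(ped) {
  n <- nAnimals(ped)
  s <- ped@sire
  d <- ped@dam
  Fc <- numeric(n)
  dii <- numeric(n)
  Fpar <- function(p) if (p == 0L) -1 else Fc[p]
  for (i in seq_len(n)) {
    dii[i] <- 0.5 - 0.25 * (Fpar(s[i]) + Fpar(d[i]))
    if (s[i] == 0L || d[i] == 0L) next   # F = 0
    # collect ancestors of i (including i), then one decreasing-index sweep
    mark <- logical(i)
    stack <- i
    anc <- integer(0)
    while (length(stack)) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (mark[j]) next
      mark[j] <- TRUE
      anc <- c(anc, j)
      if (s[j] > 0L) stack <- c(stack, s[j])
      if (d[j] > 0L) stack <- c(stack, d[j])
    }
    anc <- sort(anc, decreasing = TRUE)
    L <- numeric(i)
    L[i] <- 1
    Fi <- -1
    for (j in anc) {
      lj <- L[j]
      if (lj == 0) next
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * lj
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * lj
      Fi <- Fi + lj * lj * dii[j]
    }
    Fc[i] <- Fi
  }
  list(F = Fc, d = dii)
}

#' Inbreeding coefficients
#'
#' \eqn{F_i = a_{ii} - 1}, computed by the Meuwissen-Luo recursion (no dense
#' matrix is formed); founders and animals with an unknown parent have
#' \eqn{F = 0}.
#'
#' @param ped a [Pedigree-class].
#' @return named numeric vector of F per animal.
#' @export
inbreedingCoefficients <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  stats::setNames(.meuwissenLuo(ped)$F, ped@id)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembled from per-animal contributions (Henderson's rules) with
#' Mendelian-sampling variances \eqn{d_i} from parental inbreeding
#' (Meuwissen-Luo); with \code{withInbreeding = FALSE} the classical
#' constants 1, 3/4, 1/2 are used instead.
#'
#' @param ped a [Pedigree-class].
#' @param withInbreeding account for parental inbreeding in \eqn{d_i}
#'   (default TRUE).
#' @return a [SparseInverse-class]; its \code{logdet} slot holds
#'   \eqn{\log|A| = \sum_i \log d_i}.
#' @export
aInverse <- function(ped, withInbreeding = TRUE) {
  stopifnot(is(ped, "Pedigree"))
  n <- nAnimals(ped)
  s <- ped@sire
  d <- ped@dam
  if (withInbreeding) {
    dii <- .meuwissenLuo(ped)$d
  } else {
    dii <- 1 - 0.25 * (s > 0L) - 0.25 * (d > 0L)
  }
  alpha <- 1 / dii
  ii <- jj <- xx <- list()
  add <- function(i, j, x) {
    ii[[length(ii) + 1L]] <<- i
    jj[[length(jj) + 1L]] <<- j
    xx[[length(xx) + 1L]] <<- x
  }
  idx <- seq_len(n)
  add(idx, idx, alpha)
  hs <- s > 0L
  hd <- d > 0L
  if (any(hs)) {
    add(idx[hs], s[hs], -alpha[hs] / 2)
    add(s[hs], idx[hs], -alpha[hs] / 2)
    add(s[hs], s[hs], alpha[hs] / 4)
  }
  if (any(hd)) {
    add(idx[hd], d[hd], -alpha[hd] / 2)
    add(d[hd], idx[hd], -alpha[hd] / 2)
    add(d[hd], d[hd], alpha[hd] / 4)
  }
  both <- hs & hd
  if (any(both)) {
    add(s[both], d[both], alpha[both] / 4)
    add(d[both], s[both], alpha[both] / 4)
  }
  m <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  new("SparseInverse", ids = ped@id, mat = Matrix::forceSymmetric(m),
      logdet = sum(log(dii)))
}

#' Export a sparse A-inverse as coordinate triplets
#'
#' Writes two plain-text files: \code{<prefix>.triplets} with 1-based
#' \code{i j value} rows (lower triangle) and \code{<prefix>.ids} mapping
#' indices to animal tokens.
#'
#' @param ainv a [SparseInverse-class].
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
writeAInverse <- function(ainv, prefix) {
  stopifnot(is(ainv, "SparseInverse"))
  tri <- as(Matrix::tril(ainv@mat), "TsparseMatrix")
  df <- data.frame(i = tri@i + 1L, j = tri@j + 1L, value = tri@x)
  df <- df[order(df$i, df$j), ]
  f1 <- paste0(prefix, ".triplets")
  f2 <- paste0(prefix, ".ids")
  utils::write.table(df, f1, row.names = FALSE, col.names = TRUE,
                     quote = FALSE, sep = "\t")
  utils::write.table(data.frame(index = seq_along(ainv@ids), id = ainv@ids),
                     f2, row.names = FALSE, col.names = TRUE, quote = FALSE,
                     sep = "\t")
  invisible(c(f1, f2))
}

#' Summarize relationships between two animal sets
#'
#' Mean, minimum and maximum of \eqn{a_{ij}} over all cross pairs
#' (i in set1, j in set2, i != j); the diagonal is never included even when
#' the sets overlap.
#'
#' @param A a [RelationshipMatrix-class].
#' @param set1,set2 character tokens (non-empty, subsets of the matrix ids).
#' @return named numeric vector \code{c(mean, min, max)}.
#' @export
relationshipSummary <- function(A, set1, set2) {
  stopifnot(is(A, "RelationshipMatrix"))
  if (!length(set1) || !length(set2)) stop("empty animal set")
  i1 <- match(unique(set1), A@ids)
  i2 <- match(unique(set2), A@ids)
  if (anyNA(i1) || anyNA(i2))
    stop("set contains tokens absent from the relationship matrix")
  sub <- A@values[i1, i2, drop = FALSE]
  same <- outer(i1, i2, "==")
  vals <- sub[!same]
  if (!length(vals)) stop("no cross pairs between the two sets")
  c(mean = mean(vals), min = min(vals), max = max(vals))
}
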