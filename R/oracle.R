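## Exhaustive enumeration oracle: the ground truth for every equivalence
## test of the DP engine and the ensemble metrics.  Enumerates the full
## structure space (pseudoknot-free, triple-free, allowed pairs, hairpin gap
## > theta), scores each structure independently of the DP recurrences by
## loop decomposition, and evaluates the weighted ensemble by direct
## summation.

#' Enumerate all secondary structures of a short sequence
#'
#' Every pseudoknot-free, triple-free structure over Watson-Crick/GU pairs
#' with hairpin gap j - i > theta, each exactly once.  Intended as a test
#' oracle; refuses sequences longer than \code{limit}.
#'
#' @param seq ACGU string.
#' @param params an \code{EnergyParams} (theta and pairing rules).
#' @param limit maximum sequence length (default 20).
#' @return list of \code{SecondaryStructure} objects.
#' @export
enumerateStructures <- function(seq, params, limit = 20L) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  if (n > limit)
    stop(sprintf("sequence length %d exceeds enumeration limit %d", n, limit))
  theta <- params@theta
  can <- allowedPairMatrix(res, theta)
  memo <- new.env(parent = emptyenv())
  # returns list of pair matrices (2 columns), possibly with 0 rows
  rec <- function(i, j) {
    if (j - i < theta + 1L) return(list(matrix(0L, 0, 2)))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- rec(i, j - 1L)                       # j unpaired
    for (k in i:(j - theta - 1L)) {
      if (!can[k, j]) next
      left <- rec(i, k - 1L)
      inner <- rec(k + 1L, j - 1L)
      for (A in left) for (B in inner)
        out[[length(out) + 1L]] <- rbind(A, B, c(k, j))
    }
    memo[[key]] <- out
    out
  }
  lapply(rec(1L, n), function(bp) {
    pt <- integer(n)
    if (nrow(bp)) { pt[bp[, 1]] <- bp[, 2]; pt[bp[, 2]] <- bp[, 1] }
    secondaryStructure(pt)
  })
}

#' Count secondary structures by the standard counting recursion
#'
#' Independent of the enumerator's code path: N(i,j) = N(i,j-1) +
#' sum_k N(i,k-1) * N(k+1,j-1) over allowed pairs (k,j).
#'
#' @param seq ACGU string.
#' @param params an \code{EnergyParams}.
#' @return numeric count.
#' @export
countStructures <- function(seq, params) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  theta <- params@theta
  can <- allowedPairMatrix(res, theta)
  N <- matrix(1, n + 1L, n + 1L)  # N[i, j+1]; empty/short intervals = 1
  if (n - 1L < theta + 1L) return(1)
  for (d in (theta + 1L):(n - 1L)) {
    for (i in seq_len(n - d)) {
      j <- i + d
      acc <- N[i, j]  # j unpaired: interval (i, j-1)
      for (k in i:(j - theta - 1L)) {
        if (!can[k, j]) next
        left <- if (k == i) 1 else N[i, k]
        acc <- acc + left * N[k + 1L, j]
      }
      N[i, j + 1L] <- acc
    }
  }
  N[1, n + 1L]
}

#' Free energy of a single structure by loop decomposition
#'
#' Scores a structure directly: hairpin energy for childless pairs, two-pair
#' loop energy (stack/bulge/internal) for pairs with one nested helix, the
#' affine multiloop a + b*k + c*u otherwise; the exterior loop is free.
#' With \code{pseudo} supplied (Deigan comparison mode), every stacked pair
#' context — pair (i,j) whose inner neighbor (i+1, j-1) is also a pair —
#' additionally contributes pseudo[i] + pseudo[j] + pseudo[i+1] +
#' pseudo[j-1], so interior helix positions are counted twice and isolated
#' pairs contribute nothing.
#'
#' This evaluator is the per-structure route used by the oracle; it shares
#' only the elementary loop-energy functions with the DP engine, not its
#' recurrences.
#'
#' @param seq ACGU string.
#' @param structure a \code{SecondaryStructure}.
#' @param params an \code{EnergyParams}.
#' @param pseudo optional per-position stacking pseudo-energies.
#' @return kcal/mol (+Inf if any loop is forbidden under the model).
#' @export
energyOfStructure <- function(seq, structure, params, pseudo = NULL) {
  res <- strsplit(seq, "")[[1]]
  pt <- pairTable(structure)
  n <- length(pt)
  if (length(res) != n) stop("sequence and structure lengths differ")
  # top-level children of the interval (i+1, j-1)
  childrenOf <- function(i, j) {
    kids <- matrix(0L, 0, 2)
    p <- i + 1L
    while (p <= j - 1L) {
      if (pt[p] > p) { kids <- rbind(kids, c(p, pt[p])); p <- pt[p] + 1L }
      else p <- p + 1L
    }
    kids
  }
  e <- 0
  bp <- basePairs(structure)
  for (r in seq_len(nrow(bp))) {
    i <- bp[r, 1]; j <- bp[r, 2]
    kids <- childrenOf(i, j)
    nk <- nrow(kids)
    if (nk == 0L) {
      e <- e + hairpinEnergy(res, i, j, params)
    } else if (nk == 1L) {
      e <- e + internalEnergy(res, i, j, kids[1, 1], kids[1, 2], params)
    } else {
      unp <- (j - i - 1L) - sum(kids[, 2] - kids[, 1] + 1L)
      e <- e + multiloopEnergy(nk + 1L, unp, params)
    }
    if (!is.null(pseudo) && pt[i + 1L] == j - 1L && j - 1L > i + 1L)
      e <- e + pseudo[i] + pseudo[j] + pseudo[i + 1L] + pseudo[j - 1L]
  }
  e
}

#' Brute-force weighted Boltzmann ensemble
#'
#' Direct evaluation over the enumerated structure space: per-structure
#' weights w(S) = exp(-beta d(S,q) / RT), weighted partition function
#' Z' = sum_S exp(-E(S)/RT) w(S), weighted probabilities P'(S), marginal
#' pair probabilities, expected distance and the minimizer of
#' E(S) + beta d(S,q).  Ground truth for all DP equivalence tests.
#'
#' @param seq ACGU string.
#' @param q complete unpaired-probability vector (or NULL with beta = 0).
#' @param beta scaling parameter, kcal/mol.
#' @param params an \code{EnergyParams}.
#' @param pseudo optional per-position stacking pseudo-energies (scored per
#'   structure as in \code{\link{energyOfStructure}}).
#' @param limit enumeration length limit.
#' @return list: \code{structures}, \code{energies}, \code{distances},
#'   \code{Z} (weighted), \code{logZ}, \code{probs} (P'(S)), \code{bpp},
#'   \code{unpaired}, \code{ED}, \code{mfeIndex}, \code{mfeScore}.
#' @export
bruteForceEnsemble <- function(seq, q, beta, params, pseudo = NULL,
                               limit = 20L) {
  n <- nchar(seq)
  if (is.null(q)) q <- rep(0, n)
  structs <- enumerateStructures(seq, params, limit)
  E <- vapply(structs, function(s) energyOfStructure(seq, s, params, pseudo),
    numeric(1))
  dists <- vapply(structs, function(s) structureDistance(s, q), numeric(1))
  terms <- exp(-E / params@RT) * exp(-beta * dists / params@RT)
  Z <- sum(terms)
  probs <- terms / Z
  bpp <- matrix(0, n, n)
  for (s in seq_along(structs)) {
    bp <- basePairs(structs[[s]])
    for (r in seq_len(nrow(bp))) {
      bpp[bp[r, 1], bp[r, 2]] <- bpp[bp[r, 1], bp[r, 2]] + probs[s]
      bpp[bp[r, 2], bp[r, 1]] <- bpp[bp[r, 2], bp[r, 1]] + probs[s]
    }
  }
  scores <- E + beta * dists
  list(structures = structs, energies = E, distances = dists, Z = Z,
    logZ = log(Z), probs = probs, bpp = bpp, unpaired = 1 - rowSums(bpp),
    ED = sum(probs * dists), mfeIndex = which.min(scores),
    mfeScore = min(scores))
}
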