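## Diagnostic quantities over the (weighted) Boltzmann ensemble.

#' L1 distance between a structure and probing data
#'
#' d(S, q) = sum_i |x_i - q_i| with x the unpaired indicator (1 = unpaired).
#' An unnormalized sum over positions, so values are of order n.
#'
#' @param structure a \code{SecondaryStructure}.
#' @param q numeric vector, same length.
#' @return numeric scalar in [0, n].
#' @export
structureDistance <- function(structure, q) {
  x <- unpairedIndicator(structure)
  if (length(x) != length(q)) stop("structure and q lengths differ")
  sum(abs(x - q))
}

#' Expected distance of the ensemble to the probing data
#'
#' ED = sum_i [ u_i (1 - q_i) + (1 - u_i) q_i ], where u_i is the ensemble
#' probability that position i is unpaired.  Equals the ensemble average of
#' d(S, q) — the quadratic-time form of the exponential-size sum over
#' structures, since the average of |x_i - q_i| over the ensemble is
#' u_i|1 - q_i| + (1 - u_i)|0 - q_i|.  The same formula with raw
#' reactivities s_i in place of q_i gives the unnormalized-data variant used
#' in the comparison mode.
#'
#' @param x either a base-pair probability matrix (symmetric) or a numeric
#'   vector of unpaired probabilities u.
#' @param q numeric vector of (normalized or raw) reactivities.
#' @return numeric scalar.
#' @export
expectedDistance <- function(x, q) {
  u <- if (is.matrix(x)) 1 - rowSums(x) else x
  if (length(u) != length(q)) stop("length mismatch")
  sum(u * (1 - q) + (1 - u) * q)
}

#' Critical distance of the weighted ensemble
#'
#' d* = (RT / beta) * ln(Z / Z').  Structures closer to the probing data
#' than d* gain probability under weighting, farther ones lose it:
#' P'(S) > P(S) iff d(S, q) < d*.  (From the definitions: P'(S)/P(S) =
#' exp(-beta d / RT) * Z/Z', which exceeds 1 iff d < (RT/beta) ln(Z/Z').)
#' As beta -> 0+ the ratio ln(Z/Z')/beta tends to ED/RT, so the limit of d*
#' is the unweighted expected distance; at beta = 0 that limit is returned
#' and requires \code{ed0}.
#'
#' @param logZ log of the plain partition function.
#' @param logZWeighted log of the weighted partition function.
#' @param beta scaling parameter, kcal/mol.
#' @param RT thermal energy, kcal/mol.
#' @param ed0 unweighted expected distance, used only for the beta = 0
#'   limit.
#' @return numeric scalar.
#' @export
criticalDistance <- function(logZ, logZWeighted, beta,
                             RT = GAS_CONSTANT * 310.15, ed0 = NULL) {
  if (beta == 0) {
    if (is.null(ed0))
      stop("beta = 0: supply ed0 (the unweighted expected distance limit)")
    return(ed0)
  }
  (RT / beta) * (logZ - logZWeighted)
}

#' Pointwise entropy of the pairing-outcome distribution
#'
#' For mode "full", position i's outcomes are its possible partners j
#' (probability p_ij) plus "unpaired" (u_i); H_i = -sum p ln p in nats.  For
#' mode "binary" only the paired/unpaired dichotomy is used:
#' H_i = -[u ln u + (1-u) ln(1-u)] — the uncertainty a probing experiment
#' can report on.  0 ln 0 is taken as 0.
#'
#' @param bpp symmetric base-pair probability matrix.
#' @param mode "full" or "binary".
#' @return list with \code{H} (numeric vector, nats) and \code{average}.
#' @export
pointwiseEntropy <- function(bpp, mode = c("full", "binary")) {
  mode <- match.arg(mode)
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  u <- 1 - rowSums(bpp)
  u <- pmin(pmax(u, 0), 1)
  H <- if (mode == "full") {
    -(rowSums(xlogx(bpp)) + xlogx(u))
  } else {
    -(xlogx(u) + xlogx(1 - u))
  }
  list(H = H, average = mean(H))
}

#' Morgan-Higgs structural diversity
#'
#' D = 2 * sum_{i<j} p_ij (1 - p_ij): the expected base-pair (symmetric
#' difference) distance between two independent draws from the ensemble,
#' since a pair present with probability p differs between the two draws
#' with probability 2p(1-p).
#'
#' @param bpp symmetric base-pair probability matrix.
#' @return numeric scalar >= 0.
#' @export
morganHiggsDiversity <- function(bpp) {
  p <- bpp[upper.tri(bpp)]
  2 * sum(p * (1 - p))
}
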