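## Accuracy against reference structures, probing-data discrepancy
## analysis, and the beta grid search.

#' Sensitivity and PPV of a predicted structure
#'
#' Exact pair matching only — a predicted pair counts as correct only if the
#' identical (i, j) pair is in the reference; no one-position slippage is
#' allowed.  Undefined ratios (0/0) are reported as NA, never as 0 or 1, so
#' empty predictions cannot silently inflate a benchmark.
#'
#' @param predicted,reference \code{SecondaryStructure}s of equal length.
#' @return list: \code{tp}, \code{fp}, \code{fn}, \code{sensitivity}
#'   (TP/(TP+FN)), \code{ppv} (TP/(TP+FP)); NA for 0/0.
#' @export
structureAccuracy <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("predicted and reference lengths differ")
  keyOf <- function(s) {
    bp <- basePairs(s)
    paste(bp[, 1], bp[, 2])
  }
  pk <- keyOf(predicted); rk <- keyOf(reference)
  tp <- sum(pk %in% rk)
  fp <- length(pk) - tp
  fn <- length(rk) - tp
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  list(tp = tp, fp = fp, fn = fn,
    sensitivity = ratio(tp, tp + fn), ppv = ratio(tp, tp + fp))
}

#' Probing-data discrepancies against a reference structure
#'
#' Positions where the normalized reactivity disagrees with the reference
#' pairing status by more than \code{threshold}: |q_i - x_i| > 0.5 flags a
#' confidently "unpaired" signal at a paired position or vice versa.
#' Missing-data positions (NA in q) are excluded from both the flags and
#' the rate denominator.
#'
#' @param q numeric vector of normalized unpaired probabilities, NA =
#'   missing.
#' @param reference a \code{SecondaryStructure}.
#' @param threshold discrepancy threshold (default 0.5).
#' @return list: \code{positions} (integer vector), \code{rate}
#'   (flagged / assessable), \code{assessable}.
#' @export
discrepancyPositions <- function(q, reference, threshold = 0.5) {
  x <- unpairedIndicator(reference)
  if (length(q) != length(x)) stop("q and reference lengths differ")
  ok <- !is.na(q)
  flagged <- which(ok & abs(q - x) > threshold)
  list(positions = flagged,
    rate = if (sum(ok)) length(flagged) / sum(ok) else NA_real_,
    assessable = sum(ok))
}

#' Grid search for the soft-constraint scaling parameter beta
#'
#' Folds at every beta on the grid, scores the weighted MFE structure
#' against the reference, and returns the beta optimizing the chosen
#' objective (default sensitivity + PPV).  Ties break toward smaller beta.
#' An undefined PPV (no predicted pairs) contributes 0 to the objective.
#'
#' @param seq ACGU string.
#' @param q complete unpaired-probability vector.
#' @param reference a \code{SecondaryStructure}.
#' @param params an \code{EnergyParams}.
#' @param grid numeric vector of beta values (default 0 to 3 by 0.1).
#' @param objective "sum" (default), "product" or "min" of sensitivity and
#'   PPV.
#' @return list: \code{beta} (optimum), \code{profile} (data.frame with
#'   beta, sensitivity, ppv, objective).
#' @export
betaGridSearch <- function(seq, q, reference, params,
                           grid = seq(0, 3, by = 0.1),
                           objective = c("sum", "product", "min")) {
  objective <- match.arg(objective)
  if (!length(grid)) stop("empty beta grid")
  rows <- lapply(grid, function(beta) {
    mfe <- weightedMFE(seq, q, beta, params)
    acc <- structureAccuracy(mfe$structure, reference)
    sens <- if (is.na(acc$sensitivity)) 0 else acc$sensitivity
    ppv <- if (is.na(acc$ppv)) 0 else acc$ppv
    obj <- switch(objective, sum = sens + ppv, product = sens * ppv,
      min = min(sens, ppv))
    data.frame(beta = beta, sensitivity = acc$sensitivity, ppv = acc$ppv,
      objective = obj)
  })
  profile <- do.call(rbind, rows)
  best <- which.max(profile$objective)  # first maximum = smallest beta
  list(beta = profile$beta[best], profile = profile)
}
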