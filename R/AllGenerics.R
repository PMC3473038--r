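#' Pair table accessor
#'
#' @param x a \code{SecondaryStructure}.
#' @return integer vector; entry i is the partner of position i (0 =
#'   unpaired).
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname pairTable
#' @export
setMethod("pairTable", "SecondaryStructure", function(x) x@pairTable)

#' Unpaired indicator vector
#'
#' The binary vector x with x[i] = 1 when position i is unpaired and 0 when
#' paired — the representation whose L1 distance to the normalized probing
#' probabilities q defines the structure-to-data distance.
#'
#' @param x a \code{SecondaryStructure}.
#' @return numeric vector of 0/1.
#' @export
setGeneric("unpairedIndicator", function(x) standardGeneric("unpairedIndicator"))

#' @rdname unpairedIndicator
#' @export
setMethod("unpairedIndicator", "SecondaryStructure",
  function(x) as.numeric(x@pairTable == 0L))

#' Base pairs of a structure
#'
#' @param x a \code{SecondaryStructure}.
#' @return two-column integer matrix of pairs (i, j) with i < j, ordered by i.
#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))

#' @rdname basePairs
#' @export
setMethod("basePairs", "SecondaryStructure", function(x) {
  pt <- x@pairTable
  i <- which(pt > seq_along(pt))
  cbind(i = i, j = pt[i])
})

setMethod("length", "SecondaryStructure", function(x) length(x@pairTable))

setMethod("show", "SecondaryStructure", function(object) {
  n <- length(object)
  cat(sprintf("SecondaryStructure of length %d with %d pairs\n",
    n, nrow(basePairs(object))))
  if (n <= 120) cat(" ", writeDotBracket(object), "\n")
})

#' Raw reactivity accessor
#' @param x a \code{ReactivityProfile}.
#' @return numeric vector (NA = missing).
#' @export
setGeneric("rawReactivity", function(x) standardGeneric("rawReactivity"))

#' @rdname rawReactivity
#' @export
setMethod("rawReactivity", "ReactivityProfile", function(x) x@raw)

#' Normalized unpaired probabilities accessor
#' @param x a \code{ReactivityProfile}.
#' @return numeric vector in [0,1] (NA at unresolved missing positions), or
#'   empty if normalization has not been run.
#' @export
setGeneric("unpairedProbs", function(x) standardGeneric("unpairedProbs"))

#' @rdname unpairedProbs
#' @export
setMethod("unpairedProbs", "ReactivityProfile", function(x) x@normalized)

#' Probing chemistry of a profile
#' @param x a \code{ReactivityProfile}.
#' @return "shape" or "inline".
#' @export
setGeneric("probingKind", function(x) standardGeneric("probingKind"))

#' @rdname probingKind
#' @export
setMethod("probingKind", "ReactivityProfile", function(x) x@kind)

setMethod("length", "ReactivityProfile", function(x) length(x@raw))

setMethod("show", "ReactivityProfile", function(object) {
  n <- length(object)
  miss <- sum(is.na(object@raw))
  cat(sprintf("ReactivityProfile (%s): %d positions, %d missing%s\n",
    object@kind, n, miss,
    if (length(object@normalized)) ", normalized" else ""))
})

setMethod("show", "EnergyParams", function(object) {
  cat(sprintf(paste0("EnergyParams: theta=%d, T=%.2f K, RT=%.4f kcal/mol, ",
    "multiloop (a,b,c)=(%.2f, %.2f, %.2f)\n"),
    object@theta, object@temperature, object@RT,
    object@multiloop[1], object@multiloop[2], object@multiloop[3]))
})

setMethod("show", "FoldResult", function(object) {
  cat(sprintf("FoldResult (mode=%s, beta=%.3g) for %d nt\n",
    object@mode, object@beta, nchar(object@sequence)))
  cat(sprintf("  MFE: %s  score=%.4f (Turner energy %.4f)\n",
    writeDotBracket(object@mfeStructure), object@mfeScore, object@mfeEnergy))
  cat(sprintf("  logZ=%.6f  logZ'=%.6f\n", object@logZ, object@logZWeighted))
  if (length(object@metrics))
    cat(sprintf("  ED'=%.4f  ED=%.4f  d*=%.4f  diversity=%.4f\n",
      object@metrics$ED_weighted, object@metrics$ED_unweighted,
      object@metrics$d_star, object@metrics$diversity))
})

#' MFE structure accessor
#' @param x a \code{FoldResult}.
#' @return the \code{SecondaryStructure} minimizing the fold objective.
#' @export
setGeneric("mfeStructure", function(x) standardGeneric("mfeStructure"))

#' @rdname mfeStructure
#' @export
setMethod("mfeStructure", "FoldResult", function(x) x@mfeStructure)

#' Base-pair probability matrix accessor
#' @param x a \code{FoldResult}.
#' @param weighted logical; weighted (default) or plain matrix.
#' @return numeric n x n matrix, symmetric upper/lower filled.
#' @export
setGeneric("pairProbs", function(x, weighted = TRUE) standardGeneric("pairProbs"))

#' @rdname pairProbs
#' @export
setMethod("pairProbs", "FoldResult",
  function(x, weighted = TRUE) if (weighted) x@bpp else x@bppUnweighted)

#' Ensemble diagnostics accessor
#' @param x a \code{FoldResult}.
#' @return named list: ED_weighted, ED_unweighted, d_star, entropy vectors
#'   and averages, diversity, logZ, logZ_weighted.
#' @export
setGeneric("ensembleMetrics", function(x) standardGeneric("ensembleMetrics"))

#' @rdname ensembleMetrics
#' @export
setMethod("ensembleMetrics", "FoldResult", function(x) x@metrics)
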