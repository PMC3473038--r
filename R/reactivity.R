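## Conversion of raw probing reactivities into per-nucleotide unpaired
## probabilities q in [0,1].  High reactivity (SHAPE acylation, in-line
## cleavage) indicates backbone flexibility, i.e. an unpaired nucleotide.

#' Default normalization configuration
#'
#' The SHAPE map is piecewise linear through configurable breakpoints; the
#' defaults anchor the map at the published moderate (0.3) and high (0.7)
#' reactivity thresholds, map raw [0, 0.25] to [0, 0.35] so that very low
#' reactivities are not over-interpreted as confidently paired, and clamp
#' reactivities above 2.2 to q = 1.  In-line data, whose signal is more
#' diffuse, is normalized by clipping at symmetric outlier quantiles
#' (defaults 2.5% / 97.5%) and mapping the rest linearly to [0,1].  The
#' exact breakpoint values are configuration, not constants: this list is
#' the single source of truth.
#'
#' @return named list with elements \code{shapeBreaksRaw},
#'   \code{shapeBreaksTarget}, \code{shapeCap}, \code{inlineQuantiles}
#'   (percent), \code{missingFill}.
#' @export
defaultNormalizationConfig <- function() {
  list(
    shapeBreaksRaw = c(0, 0.25, 0.3, 0.7, 2.2),
    shapeBreaksTarget = c(0, 0.35, 0.55, 0.85, 1.0),
    shapeCap = 2.2,
    inlineQuantiles = c(2.5, 97.5),
    missingFill = 0.5
  )
}

checkNormConfig <- function(config) {
  br <- config$shapeBreaksRaw; bt <- config$shapeBreaksTarget
  if (length(br) != length(bt) || length(br) < 2L)
    stop("breakpoint vectors must have equal length >= 2")
  if (any(diff(br) <= 0) || any(diff(bt) <= 0))
    stop("normalization breakpoints must be strictly increasing")
  if (bt[1] != 0 || bt[length(bt)] != 1)
    stop("target breakpoints must start at 0 and end at 1")
  qs <- config$inlineQuantiles
  if (length(qs) != 2L || qs[1] < 0 || qs[2] > 100 || qs[1] >= qs[2])
    stop("inline quantiles must satisfy 0 <= low < high <= 100")
  invisible(config)
}

#' Normalize SHAPE reactivities to unpaired probabilities
#'
#' Continuous piecewise-linear map through the configured breakpoints.
#' Negative raw values are clamped to 0 first (background-subtracted SHAPE
#' can dip below zero; the signal is "paired", same as 0).  Values at or
#' above the cap map to 1.  Missing values (NA) propagate.
#'
#' @param raw numeric vector of raw SHAPE reactivities (NA = missing).
#' @param config list as from \code{\link{defaultNormalizationConfig}}.
#' @return numeric vector q in [0,1] with NA preserved.
#' @export
normalizeShape <- function(raw, config = defaultNormalizationConfig()) {
  checkNormConfig(config)
  x <- pmax(raw, 0)
  x <- pmin(x, config$shapeCap)
  q <- stats::approx(config$shapeBreaksRaw, config$shapeBreaksTarget,
    xout = x, rule = 2)$y
  q[is.na(raw)] <- NA_real_
  q
}

#' Normalize in-line probing reactivities to unpaired probabilities
#'
#' Values at or below the low outlier quantile map to 0, at or above the
#' high quantile to 1, linearly in between (quantiles by linear
#' interpolation of order statistics, \code{stats::quantile} type 7).  A
#' degenerate scale (all observed values identical) returns 0.5 everywhere
#' with a warning.
#'
#' @param raw numeric vector of raw in-line reactivities (NA = missing).
#' @param config list as from \code{\link{defaultNormalizationConfig}}.
#' @return numeric vector q in [0,1] with NA preserved.
#' @export
normalizeInline <- function(raw, config = defaultNormalizationConfig()) {
  checkNormConfig(config)
  obs <- raw[!is.na(raw)]
  if (length(obs) < 2L) stop("need at least 2 observed values to normalize")
  lim <- stats::quantile(obs, config$inlineQuantiles / 100, names = FALSE,
    type = 7)
  if (lim[2] <= lim[1]) {
    warning("degenerate reactivity scale; returning q = 0.5 everywhere")
    q <- rep(0.5, length(raw))
  } else {
    q <- (raw - lim[1]) / (lim[2] - lim[1])
    q <- pmin(pmax(q, 0), 1)
  }
  q[is.na(raw)] <- NA_real_
  q
}

#' Replace missing unpaired probabilities
#'
#' The default fill of 0.5 encodes "no information": with the Boltzmann
#' position weights exp(-beta*|x - q|/RT), q = 0.5 gives the paired and
#' unpaired states of that position identical weight.
#'
#' @param q numeric vector in [0,1] with NA for missing.
#' @param fill probability in [0,1] (default 0.5).
#' @return complete numeric vector; idempotent on complete inputs.
#' @export
resolveMissing <- function(q, fill = 0.5) {
  if (length(fill) != 1L || is.na(fill) || fill < 0 || fill > 1)
    stop("fill must be a probability in [0,1]")
  q[is.na(q)] <- fill
  q
}

#' Normalize a ReactivityProfile in place
#'
#' Dispatches on the profile's probing chemistry and stores the normalized
#' q vector (missing values still NA; see \code{\link{resolveMissing}}).
#'
#' @param profile a \code{\linkS4class{ReactivityProfile}}.
#' @param config list as from \code{\link{defaultNormalizationConfig}}.
#' @return the profile with its \code{normalized} slot filled.
#' @export
normalizeProfile <- function(profile, config = defaultNormalizationConfig()) {
  q <- switch(probingKind(profile),
    shape = normalizeShape(rawReactivity(profile), config),
    inline = normalizeInline(rawReactivity(profile), config))
  initialize(profile, normalized = q)
}
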