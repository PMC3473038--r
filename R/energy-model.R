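## Nearest-neighbor thermodynamic model (Turner-style).  The bundled
## "turner-min" set covers stacks for all 6 allowed pair types,
## length-tabulated hairpin/bulge/internal initiations with
## Jacobson-Stockmayer long-loop extrapolation, an asymmetry penalty and the
## affine multiloop model.  Deliberately excluded, matching the scope of a
## standalone per-nucleotide reweighting engine: dangles, coaxial stacking,
## tetraloop bonuses, 1x1/2x2 special internal tables.

GAS_CONSTANT <- 0.0019872  # kcal/(mol K)
JS_COEF <- 1.75            # Jacobson-Stockmayer ln coefficient

PAIR_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")
PAIR_INDEX <- stats::setNames(seq_along(PAIR_TYPES), PAIR_TYPES)

#' Load a nearest-neighbor parameter set
#'
#' Reads the plain-text table format documented in the bundled
#' \code{turner-min.txt} (see
#' \code{system.file("extdata/params/turner-min.txt", package =
#' "shapefold")}).  Validates completeness: the stack table must cover all
#' 36 ordered combinations of the 6 allowed pair types, and each loop table
#' must be contiguous from its smallest size.
#'
#' @param name built-in set name (currently \code{"turner-min"}) or a path
#'   to a parameter file.
#' @param temperature optional override in Kelvin; RT is recomputed as
#'   R * temperature (the tabulated free energies are not rescaled).
#' @param theta optional override of the minimum hairpin gap.
#' @return an \code{\linkS4class{EnergyParams}}.
#' @export
loadEnergyParams <- function(name = "turner-min", temperature = NULL,
                             theta = NULL) {
  path <- if (file.exists(name)) name
    else system.file("extdata", "params", paste0(name, ".txt"),
      package = "shapefold")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown parameter set or missing file: ", name)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  hairpin <- c(); bulge <- c(); internal <- c()
  for (ln in lines) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    key <- f[1]
    if (key == "stack") {
      if (!(f[2] %in% PAIR_TYPES) || !(f[3] %in% PAIR_TYPES))
        stop("stack row with disallowed pair type: '", ln, "'")
      stack[f[2], f[3]] <- as.numeric(f[4])
    } else if (key %in% c("hairpin", "bulge", "internal")) {
      v <- as.numeric(f[3]); names(v) <- f[2]
      if (key == "hairpin") hairpin <- c(hairpin, v)
      else if (key == "bulge") bulge <- c(bulge, v)
      else internal <- c(internal, v)
    } else kv[[key]] <- as.numeric(f[2])
  }
  if (any(is.na(stack))) {
    miss <- which(is.na(stack), arr.ind = TRUE)[1, ]
    stop(sprintf("missing stack entry for context %s on %s",
      PAIR_TYPES[miss[2]], PAIR_TYPES[miss[1]]))
  }
  for (tab in list(hairpin = hairpin, bulge = bulge, internal = internal))
    if (!length(tab)) stop("parameter file lacks a loop table")
  temp <- if (!is.null(temperature)) temperature else kv$temperature
  th <- if (!is.null(theta)) as.integer(theta) else as.integer(kv$theta)
  new("EnergyParams", stack = stack,
    hairpinInit = hairpin, bulgeInit = bulge, internalInit = internal,
    asymmetryCoef = kv$asymmetry_coef, asymmetryMax = kv$asymmetry_max,
    multiloop = c(kv$multiloop_a, kv$multiloop_b, kv$multiloop_c),
    maxInternal = as.integer(kv$max_internal),
    theta = th, temperature = temp, RT = GAS_CONSTANT * temp)
}

## Pair-type index of residues a,b; 0 if not an allowed pair.
pairTypeIndex <- function(a, b) {
  p <- PAIR_INDEX[paste0(a, b)]
  ifelse(is.na(p), 0L, p)
}

## n x n logical matrix: canPair[i,j] TRUE when (i,j) is an allowed pair
## with hairpin gap j - i > theta.  Residues as character vector.
allowedPairMatrix <- function(res, theta) {
  n <- length(res)
  m <- matrix(FALSE, n, n)
  if (n >= theta + 2) {
    for (i in seq_len(n - theta - 1L)) {
      j <- (i + theta + 1L):n
      m[i, j] <- paste0(res[i], res[j]) %in% PAIR_TYPES
    }
  }
  m
}

## Tabulated initiation with Jacobson-Stockmayer extrapolation.
loopInit <- function(table, size, RT) {
  sizes <- as.integer(names(table))
  if (size < min(sizes)) return(Inf)
  if (size <= max(sizes)) return(unname(table[as.character(size)]))
  mx <- max(sizes)
  unname(table[as.character(mx)]) + JS_COEF * RT * log(size / mx)
}

#' Hairpin loop free energy
#'
#' @param seq ACGU string (or character vector of residues).
#' @param i,j 1-based closing pair positions, i < j.
#' @param params an \code{EnergyParams}.
#' @return kcal/mol; +Inf when (i,j) is not an allowed pair or the loop is
#'   shorter than theta.  Loops longer than the tabulated maximum use the
#'   Jacobson-Stockmayer extrapolation E(max) + 1.75*RT*ln(u/max).
#' @export
hairpinEnergy <- function(seq, i, j, params) {
  res <- if (length(seq) == 1L) strsplit(seq, "")[[1]] else seq
  if (pairTypeIndex(res[i], res[j]) == 0L) return(Inf)
  u <- j - i - 1L
  if (u < params@theta) return(Inf)
  loopInit(params@hairpinInit, u, params@RT)
}

#' Internal loop / bulge / stack free energy
#'
#' Combines the three two-pair loop cases closed by outer pair (i,j) with
#' inner pair (k,l), i < k < l < j: both sides empty is a stacked pair
#' (table lookup); exactly one side empty is a bulge (size-1 bulges keep the
#' helix stack on top of the initiation, larger bulges are initiation only);
#' both sides non-empty is an internal loop (initiation by total size plus a
#' capped asymmetry penalty).  Total loop sizes beyond \code{maxInternal}
#' (default 30) are forbidden.
#'
#' @param seq ACGU string or residue vector.
#' @param i,j outer pair; \code{k,l} inner pair.
#' @param k,l inner pair positions.
#' @param params an \code{EnergyParams}.
#' @return kcal/mol; +Inf for disallowed pairs or oversize loops.
#' @export
internalEnergy <- function(seq, i, j, k, l, params) {
  res <- if (length(seq) == 1L) strsplit(seq, "")[[1]] else seq
  p1 <- pairTypeIndex(res[i], res[j])
  p2 <- pairTypeIndex(res[k], res[l])
  if (p1 == 0L || p2 == 0L) return(Inf)
  n1 <- k - i - 1L
  n2 <- j - l - 1L
  if (n1 < 0L || n2 < 0L) return(Inf)
  size <- n1 + n2
  if (size > params@maxInternal) return(Inf)
  if (size == 0L) return(params@stack[p1, p2])
  if (n1 == 0L || n2 == 0L) {
    e <- loopInit(params@bulgeInit, size, params@RT)
    if (size == 1L) e <- e + params@stack[p1, p2]  # helix continues across
    return(e)
  }
  loopInit(params@internalInit, size, params@RT) +
    min(params@asymmetryMax, params@asymmetryCoef * abs(n1 - n2))
}

#' Affine multiloop free energy
#'
#' a + b*k + c*u for a multiloop containing k base pairs (closing pair
#' included) and u unpaired bases.
#'
#' @param branches k, number of base pairs in the loop (closing included).
#' @param unpaired u, number of unpaired bases in the loop.
#' @param params an \code{EnergyParams}.
#' @return kcal/mol.
#' @export
multiloopEnergy <- function(branches, unpaired, params) {
  params@multiloop[1] + params@multiloop[2] * branches +
    params@multiloop[3] * unpaired
}
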