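#' @import methods
NULL

#' SecondaryStructure: a pseudoknot-free RNA secondary structure
#'
#' Represents a secondary structure as a 1-based pair table: position i holds
#' the index of its pairing partner, or 0 when unpaired.  Validity enforces
#' the defining constraints of the structure space: the pair relation is an
#' involution (no base triples, since each position stores at most one
#' partner) and contains no pseudoknots (no crossing pairs i < k < j < l with
#' (i,j) and (k,l) both present).  Sequence-dependent constraints (allowed
#' pair alphabet, minimum hairpin gap theta) are checked at the parsing and
#' folding boundaries, not here, because reference structures from crystals
#' may legitimately contain non-canonical pairs.
#'
#' @slot pairTable integer vector; \code{pairTable[i]} is the partner of
#'   position i, 0 if unpaired.
#' @export
setClass("SecondaryStructure",
  representation(pairTable = "integer"),
  validity = function(object) {
    pt <- object@pairTable
    n <- length(pt)
    msgs <- character(0)
    if (any(is.na(pt)) || any(pt < 0L) || any(pt > n))
      msgs <- c(msgs, "pair table entries must lie in [0, n]")
    paired <- which(pt > 0L)
    if (length(paired)) {
      if (any(pt[paired] == paired))
        msgs <- c(msgs, "a position cannot pair with itself")
      else if (any(pt[pt[paired]] != paired))
        msgs <- c(msgs, "pair table is not an involution")
      else {
        # pseudoknot check on the half-pairs (i < j)
        ii <- paired[paired < pt[paired]]
        jj <- pt[ii]
        if (length(ii) > 1L) {
          o <- order(ii)
          ii <- ii[o]; jj <- jj[o]
          for (a in seq_len(length(ii) - 1L)) {
            b <- which(ii > ii[a] & ii < jj[a] & jj > jj[a])
            if (length(b)) {
              msgs <- c(msgs, "structure contains a pseudoknot")
              break
            }
          }
        }
      }
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' ReactivityProfile: raw probing data and normalized unpaired probabilities
#'
#' Holds per-nucleotide probing reactivities (SHAPE or in-line), with NA for
#' missing observations, together with the normalized unpaired probabilities
#' q in [0,1] once normalization has been applied.  Slot \code{normalized}
#' may still contain NA at missing positions until
#' \code{\link{resolveMissing}} fills them.
#'
#' @slot raw numeric vector of raw reactivities; NA = missing.
#' @slot kind character, \code{"shape"} or \code{"inline"}.
#' @slot normalized numeric vector of unpaired probabilities in [0,1]
#'   (NA allowed until missing values are resolved); length 0 until
#'   normalization is run.
#' @export
setClass("ReactivityProfile",
  representation(raw = "numeric", kind = "character", normalized = "numeric"),
  prototype(kind = "shape", normalized = numeric(0)),
  validity = function(object) {
    msgs <- character(0)
    if (length(object@kind) != 1L || !object@kind %in% c("shape", "inline"))
      msgs <- c(msgs, "kind must be 'shape' or 'inline'")
    nz <- object@normalized
    if (length(nz) && length(nz) != length(object@raw))
      msgs <- c(msgs, "normalized must match raw in length (or be empty)")
    if (length(nz)) {
      ok <- is.na(nz) | (nz >= 0 & nz <= 1)
      if (!all(ok)) msgs <- c(msgs, "normalized values must lie in [0,1]")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' EnergyParams: nearest-neighbor thermodynamic parameters
#'
#' A Turner-style nearest-neighbor parameter set: stacking free energies for
#' all ordered combinations of allowed pairs, length-tabulated hairpin /
#' bulge / internal loop initiations with Jacobson-Stockmayer long-loop
#' extrapolation, an affine multiloop model a + b*k + c*u, the minimum
#' hairpin gap theta and the thermodynamic temperature.  All energies are in
#' kcal/mol at the stated temperature.
#'
#' @slot stack numeric matrix, rownames/colnames the 6 allowed pair types
#'   ("AU","UA","CG","GC","GU","UG"); \code{stack[p1, p2]} is the free energy
#'   of inner pair p2 = (i+1, j-1) stacked on outer pair p1 = (i, j).
#' @slot hairpinInit named numeric, initiation by loop length.
#' @slot bulgeInit named numeric, initiation by bulge size.
#' @slot internalInit named numeric, initiation by total internal loop size.
#' @slot asymmetryCoef numeric, kcal/mol per unit loop asymmetry.
#' @slot asymmetryMax numeric, cap on the asymmetry penalty.
#' @slot multiloop numeric length 3, c(a, b, c): closing, per-branch,
#'   per-unpaired.
#' @slot maxInternal integer, internal/bulge loops larger than this are
#'   forbidden (+Inf).
#' @slot theta integer, minimum unpaired bases enclosed by a hairpin.
#' @slot temperature numeric, Kelvin.
#' @slot RT numeric, kcal/mol (R = 0.0019872 kcal/(mol K)).
#' @export
setClass("EnergyParams",
  representation(stack = "matrix", hairpinInit = "numeric",
    bulgeInit = "numeric", internalInit = "numeric",
    asymmetryCoef = "numeric", asymmetryMax = "numeric",
    multiloop = "numeric", maxInternal = "integer",
    theta = "integer", temperature = "numeric", RT = "numeric"),
  validity = function(object) {
    msgs <- character(0)
    pt <- c("AU", "UA", "CG", "GC", "GU", "UG")
    if (!identical(rownames(object@stack), pt) ||
        !identical(colnames(object@stack), pt))
      msgs <- c(msgs, "stack matrix must be 6x6 over AU,UA,CG,GC,GU,UG")
    else if (any(!is.finite(object@stack)))
      msgs <- c(msgs, "stack matrix must be complete (finite)")
    if (object@theta < 1L) msgs <- c(msgs, "theta must be >= 1")
    if (length(object@multiloop) != 3L)
      msgs <- c(msgs, "multiloop must be c(a, b, c)")
    if (abs(object@RT - 0.0019872 * object@temperature) > 1e-9)
      msgs <- c(msgs, "RT must equal R * temperature")
    if (length(msgs)) msgs else TRUE
  }
)

#' FoldResult: output of a soft-constraint (or plain / pseudo-energy) fold
#'
#' Container for everything a fold produces: the minimum free energy
#' structure under the chosen objective, the weighted and unweighted
#' base-pair probability matrices, log partition functions, and the ensemble
#' diagnostics (expected distance, critical distance, entropies, diversity).
#'
#' @slot sequence character, the folded RNA sequence (ACGU).
#' @slot mode character: "soft", "deigan" or "plain".
#' @slot beta numeric, soft-constraint scaling parameter (kcal/mol).
#' @slot q numeric, normalized unpaired probabilities used (empty in plain
#'   mode).
#' @slot mfeStructure SecondaryStructure minimizing the mode's objective.
#' @slot mfeScore numeric, minimized objective (E + beta*d in soft mode).
#' @slot mfeEnergy numeric, Turner-energy component of the MFE structure.
#' @slot bpp numeric matrix of weighted base-pair probabilities p'_ij.
#' @slot bppUnweighted numeric matrix of plain probabilities p_ij.
#' @slot unpaired numeric, weighted unpaired probabilities u'_i.
#' @slot logZ numeric, log of the plain partition function.
#' @slot logZWeighted numeric, log of the weighted partition function.
#' @slot metrics list of ensemble diagnostics (see
#'   \code{\link{ensembleMetrics}}).
#' @export
setClass("FoldResult",
  representation(sequence = "character", mode = "character", beta = "numeric",
    q = "numeric", mfeStructure = "SecondaryStructure", mfeScore = "numeric",
    mfeEnergy = "numeric", bpp = "matrix", bppUnweighted = "matrix",
    unpaired = "numeric", logZ = "numeric", logZWeighted = "numeric",
    metrics = "list"))
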