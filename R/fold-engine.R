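## Weighted McCaskill partition function with per-nucleotide soft
## constraints, inside-outside base-pair probabilities, weighted MFE by
## min-sum transform, and the stacking pseudo-energy comparison mode.
##
## The defining contract of the weighted recurrences: every structure's term
## in Z' carries exactly one weight factor per position — w1[i] when i is
## unpaired, w0[i] when paired — so that the per-structure factor equals
## exp(-beta * d(S,q) / RT) with d the L1 distance between the structure's
## unpaired indicator and the probing probabilities q.

#' Boltzmann position weights
#'
#' Computes w(i, x) = exp(-beta * |x - q_i| / RT) for both pairing states of
#' every position: \code{w1} for unpaired (x = 1, matching q =
#' Pr(unpaired)), \code{w0} for paired (x = 0).  beta = 0 gives all weights
#' 1 (plain fold); q = 0.5 gives equal paired/unpaired weight.
#'
#' @param q complete numeric vector of unpaired probabilities in [0,1].
#' @param beta scaling parameter in kcal/mol, >= 0.
#' @param RT thermal energy in kcal/mol (default 37 C).
#' @return list with numeric vectors \code{w0} and \code{w1}.
#' @export
buildWeights <- function(q, beta, RT = GAS_CONSTANT * 310.15) {
  if (beta < 0) stop("beta must be >= 0")
  if (any(is.na(q)) || any(q < 0 | q > 1))
    stop("q must be complete and in [0,1]; resolve missing values first")
  list(w0 = exp(-beta * q / RT), w1 = exp(-beta * (1 - q) / RT))
}

#' Loop weight: product of unpaired weights over an interval
#'
#' Omega(i, j) = prod of w1[k] for k in i..j; the empty interval (i > j) has
#' weight 1.
#'
#' @param weights list from \code{\link{buildWeights}}.
#' @param i,j 1-based interval bounds.
#' @return numeric scalar.
#' @export
loopWeight <- function(weights, i, j) {
  if (i > j) 1 else prod(weights$w1[i:j])
}

## Precomputed engine context shared by the PF and MFE routines.
## pseudo: per-position stacking pseudo-energies (Deigan mode), or NULL.
engineContext <- function(seq, params, pseudo = NULL) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  theta <- params@theta
  can <- allowedPairMatrix(res, theta)
  ptype <- matrix(0L, n, n)
  idx <- which(can, arr.ind = TRUE)
  if (nrow(idx))
    ptype[idx] <- unname(PAIR_INDEX[paste0(res[idx[, 1]], res[idx[, 2]])])
  eH <- matrix(Inf, n, n)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    eH[i, j] <- hairpinEnergy(res, i, j, params)
  }
  maxI <- params@maxInternal
  bulgeE <- vapply(seq_len(maxI), function(s) loopInit(params@bulgeInit, s,
    params@RT), numeric(1))
  internE <- vapply(seq_len(maxI), function(s) loopInit(params@internalInit,
    s, params@RT), numeric(1))
  if (is.null(pseudo)) pseudo <- numeric(n)
  list(res = res, n = n, theta = theta, can = can, ptype = ptype, eH = eH,
    bulgeE = bulgeE, internE = internE, maxI = maxI,
    acoef = params@asymmetryCoef, amax = params@asymmetryMax,
    a = params@multiloop[1], b = params@multiloop[2], c = params@multiloop[3],
    RT = params@RT, stack = params@stack, pseudo = pseudo)
}

## Two-pair loop energy within a context; includes the Deigan stacking
## pseudo-energy when (k,l) = (i+1, j-1).
ctxInternalEnergy <- function(ctx, i, j, k, l) {
  n1 <- k - i - 1L; n2 <- j - l - 1L
  size <- n1 + n2
  if (size > ctx$maxI) return(Inf)
  if (size == 0L) {
    e <- ctx$stack[ctx$ptype[i, j], ctx$ptype[k, l]]
    return(e + ctx$pseudo[i] + ctx$pseudo[j] + ctx$pseudo[k] + ctx$pseudo[l])
  }
  if (n1 == 0L || n2 == 0L) {
    e <- ctx$bulgeE[size]
    if (size == 1L) e <- e + ctx$stack[ctx$ptype[i, j], ctx$ptype[k, l]]
    return(e)
  }
  ctx$internE[size] + min(ctx$amax, ctx$acoef * abs(n1 - n2))
}

#' Weighted inside partition tables
#'
#' Fills the triangular tables of the weighted McCaskill recursion:
#' \code{Z(i,j)} over all structures of the interval, \code{ZB(i,j)} over
#' structures containing pair (i,j), \code{ZM}/\code{ZM1} for multiloop
#' parts with >= 1 / exactly 1 component.  The total weighted partition
#' function is \code{Z[1, n]} (times the documented rescaling factor; see
#' \code{scale}).
#'
#' @param seq ACGU string.
#' @param weights list from \code{\link{buildWeights}}.
#' @param params an \code{EnergyParams}.
#' @param pseudo optional per-position stacking pseudo-energies (Deigan
#'   comparison mode); NULL for none.
#' @param scale per-position rescaling factor applied to every weight to
#'   prevent overflow on long sequences (default 1; see
#'   \code{\link{foldRna}} which chooses it from the plain MFE).  All
#'   returned tables are scaled by scale^(interval length);
#'   \code{log(Z[1,n]) - n*log(scale)} recovers log Z'.
#' @return list with matrices \code{Z}, \code{ZB}, \code{ZM}, \code{ZM1},
#'   the scaled weight vectors, \code{logScale} and the context.
#' @export
insidePartition <- function(seq, weights, params, pseudo = NULL, scale = 1) {
  ctx <- engineContext(seq, params, pseudo)
  n <- ctx$n; theta <- ctx$theta; RT <- ctx$RT
  w0 <- weights$w0 * scale
  w1 <- weights$w1 * scale
  # Omega(i,j) via log-cumsum; exact enough (<< 1e-9 relative at test sizes)
  lw1 <- c(0, cumsum(log(w1)))
  Om <- function(i, j) if (i > j) 1 else exp(lw1[j + 1L] - lw1[i])
  bML <- exp(-(ctx$a + ctx$b) / RT)
  bB <- exp(-ctx$b / RT)
  bC <- exp(-ctx$c / RT)
  Z <- matrix(0, n, n); ZB <- matrix(0, n, n)
  ZM <- matrix(0, n, n); ZM1 <- matrix(0, n, n)
  for (d in 0:(n - 1L)) for (i in seq_len(n - d)) {
    j <- i + d
    if (d > theta && ctx$can[i, j]) {
      acc <- if (is.finite(ctx$eH[i, j]))
        exp(-ctx$eH[i, j] / RT) * Om(i + 1L, j - 1L) else 0
      # internal loops / bulges / stacks: inner pair (k,l)
      kmax <- min(j - theta - 2L, i + 1L + ctx$maxI)
      if (kmax >= i + 1L) for (k in (i + 1L):kmax) {
        n1 <- k - i - 1L
        lmin <- max(k + theta + 1L, j - 1L - (ctx$maxI - n1))
        if (lmin > j - 1L) next
        for (l in lmin:(j - 1L)) {
          if (!ctx$can[k, l]) next
          e <- ctxInternalEnergy(ctx, i, j, k, l)
          if (is.finite(e))
            acc <- acc + exp(-e / RT) * Om(i + 1L, k - 1L) *
              Om(l + 1L, j - 1L) * ZB[k, l]
        }
      }
      # multiloop: >= 2 components inside, last starting at h
      if (j - 2L >= i + 2L) {
        hs <- (i + 2L):(j - 2L)
        acc <- acc + bML * sum(ZM[i + 1L, hs - 1L] * ZM1[hs, j - 1L])
      }
      ZB[i, j] <- w0[i] * w0[j] * acc
    }
    # ZM1: exactly one component, i paired with l in [i, j]
    if (d > theta) {
      ls <- (i + theta + 1L):j
      ls <- ls[ZB[i, ls] > 0]
      if (length(ls))
        ZM1[i, j] <- sum(ZB[i, ls] * bB * bC^(j - ls) *
          exp(lw1[j + 1L] - lw1[ls + 1L]))
      # ZM: last component starts at k
      ks <- i:(j - theta - 1L)
      first <- bC^(ks - i) * exp(lw1[ks] - lw1[i])  # Om(i, k-1) * c-penalty
      rest <- c(0, ZM[i, ks[-1L] - 1L])
      ZM[i, j] <- sum((first + rest) * ZM1[ks, j])
    }
    # Z: j unpaired, or j paired with k
    zleft <- if (d == 0L) 1 else Z[i, j - 1L]
    acc <- zleft * w1[j]
    if (d > theta) {
      ks <- i:(j - theta - 1L)
      zl <- c(1, Z[i, ks[-1L] - 1L])
      acc <- acc + sum(zl * ZB[ks, j])
    }
    Z[i, j] <- acc
  }
  list(Z = Z, ZB = ZB, ZM = ZM, ZM1 = ZM1, w0 = w0, w1 = w1,
    logScale = log(scale), ctx = ctx, lw1 = lw1)
}

#' Weighted base-pair probabilities (inside-outside)
#'
#' Outside pass mirroring every inside recurrence, then
#' p'(i,j) = ZB(i,j) * ZBhat(i,j) / Z'.  The per-position unpaired
#' probability is u'(i) = 1 - sum_j p'(i,j).
#'
#' @param tables result of \code{\link{insidePartition}}.
#' @return list with \code{bpp} (symmetric n x n matrix), \code{unpaired}
#'   (numeric vector) and \code{logZ} (log of the weighted partition
#'   function, rescaling undone).
#' @export
pairProbabilities <- function(tables) {
  ctx <- tables$ctx
  n <- ctx$n; theta <- ctx$theta; RT <- ctx$RT
  Z <- tables$Z; ZB <- tables$ZB; ZM <- tables$ZM; ZM1 <- tables$ZM1
  w0 <- tables$w0; w1 <- tables$w1; lw1 <- tables$lw1
  Om <- function(i, j) if (i > j) 1 else exp(lw1[j + 1L] - lw1[i])
  bML <- exp(-(ctx$a + ctx$b) / RT)
  bB <- exp(-ctx$b / RT)
  bC <- exp(-ctx$c / RT)
  hZ <- matrix(0, n, n); hZB <- matrix(0, n, n)
  hZM <- matrix(0, n, n); hZM1 <- matrix(0, n, n)
  hZ[1, n] <- 1
  for (d in (n - 1L):0) for (i in seq_len(n - d)) {
    j <- i + d
    # --- push from hZ(i,j)
    v <- hZ[i, j]
    if (v != 0) {
      if (j - 1L >= i) hZ[i, j - 1L] <- hZ[i, j - 1L] + v * w1[j]
      if (d > theta) {
        ks <- i:(j - theta - 1L)
        for (k in ks) {
          if (ZB[k, j] == 0 && k > i) next
          zl <- if (k == i) 1 else Z[i, k - 1L]
          if (k - 1L >= i) hZ[i, k - 1L] <- hZ[i, k - 1L] + v * ZB[k, j]
          hZB[k, j] <- hZB[k, j] + v * zl
        }
      }
    }
    # --- push from hZM(i,j)
    v <- hZM[i, j]
    if (v != 0 && d > theta) {
      ks <- i:(j - theta - 1L)
      for (k in ks) {
        first <- bC^(k - i) * exp(lw1[k] - lw1[i])
        rest <- if (k == i) 0 else ZM[i, k - 1L]
        hZM1[k, j] <- hZM1[k, j] + v * (first + rest)
        if (k - 1L >= i) hZM[i, k - 1L] <- hZM[i, k - 1L] + v * ZM1[k, j]
      }
    }
    # --- push from hZM1(i,j)
    v <- hZM1[i, j]
    if (v != 0 && d > theta) {
      ls <- (i + theta + 1L):j
      for (l in ls) {
        if (ZB[i, l] == 0) next
        hZB[i, l] <- hZB[i, l] + v * bB * bC^(j - l) *
          exp(lw1[j + 1L] - lw1[l + 1L])
      }
    }
    # --- push from hZB(i,j) in its role as an outer pair
    v <- hZB[i, j]
    if (v != 0 && ctx$can[i, j]) {
      vw <- v * w0[i] * w0[j]
      kmax <- min(j - theta - 2L, i + 1L + ctx$maxI)
      if (kmax >= i + 1L) for (k in (i + 1L):kmax) {
        n1 <- k - i - 1L
        lmin <- max(k + theta + 1L, j - 1L - (ctx$maxI - n1))
        if (lmin > j - 1L) next
        for (l in lmin:(j - 1L)) {
          if (!ctx$can[k, l]) next
          e <- ctxInternalEnergy(ctx, i, j, k, l)
          if (is.finite(e))
            hZB[k, l] <- hZB[k, l] + vw * exp(-e / RT) *
              Om(i + 1L, k - 1L) * Om(l + 1L, j - 1L)
        }
      }
      if (j - 2L >= i + 2L) for (h in (i + 2L):(j - 2L)) {
        zm1 <- ZM1[h, j - 1L]
        zm <- ZM[i + 1L, h - 1L]
        if (zm1 != 0)
          hZM[i + 1L, h - 1L] <- hZM[i + 1L, h - 1L] + vw * bML * zm1
        if (zm != 0)
          hZM1[h, j - 1L] <- hZM1[h, j - 1L] + vw * bML * zm
      }
    }
  }
  Ztot <- Z[1, n]
  bpp <- ZB * hZB / Ztot
  bpp <- bpp + t(bpp)
  unpaired <- 1 - rowSums(bpp)
  list(bpp = bpp, unpaired = unpaired,
    logZ = log(Ztot) - n * tables$logScale)
}

#' Weighted minimum free energy structure
#'
#' Min-sum transform of the weighted partition recursion: minimizes
#' E(S) + beta * d(S, q), where d(S,q) = sum_i |x_i - q_i| is the L1
#' distance between the structure's unpaired indicator and the probing
#' probabilities.  beta = 0 yields the plain Turner MFE.  Traceback is
#' deterministic: at ties the unpaired extension is preferred, then pair
#' candidates in increasing position order.
#'
#' @param seq ACGU string.
#' @param q complete unpaired-probability vector (ignored when beta = 0; may
#'   be NULL then).
#' @param beta scaling parameter in kcal/mol, >= 0.
#' @param params an \code{EnergyParams}.
#' @param pseudo optional per-position stacking pseudo-energies (Deigan
#'   mode).
#' @return list with \code{structure} (a \code{SecondaryStructure}),
#'   \code{score} (minimized objective, kcal/mol) and \code{energy} (its
#'   Turner-energy component, pseudo-energy included in Deigan mode).
#' @export
weightedMFE <- function(seq, q, beta, params, pseudo = NULL) {
  if (beta < 0) stop("beta must be >= 0")
  ctx <- engineContext(seq, params, pseudo)
  n <- ctx$n; theta <- ctx$theta
  if (beta == 0 || is.null(q)) q <- rep(0, n)  # costs vanish at beta = 0
  v0 <- beta * q          # cost of pairing position i
  v1 <- beta * (1 - q)    # cost of leaving it unpaired
  cs <- c(0, cumsum(v1))
  V <- function(i, j) if (i > j) 0 else cs[j + 1L] - cs[i]
  a <- ctx$a; b <- ctx$b; cc <- ctx$c
  BIG <- Inf
  Fm <- matrix(0, n, n); FB <- matrix(BIG, n, n)
  FM <- matrix(BIG, n, n); FM1 <- matrix(BIG, n, n)
  # traceback choices
  cF <- matrix(0L, n, n)                   # 0 = j unpaired, else pair start k
  cFBkind <- matrix(0L, n, n)              # 1 hairpin, 2 internal, 3 multi
  cFBk <- matrix(0L, n, n); cFBl <- matrix(0L, n, n)
  cFM <- matrix(0L, n, n); cFMfirst <- matrix(FALSE, n, n)
  cFM1 <- matrix(0L, n, n)
  for (d in 0:(n - 1L)) for (i in seq_len(n - d)) {
    j <- i + d
    if (d > theta && ctx$can[i, j]) {
      best <- ctx$eH[i, j] + V(i + 1L, j - 1L)
      kind <- 1L; bk <- 0L; bl <- 0L
      kmax <- min(j - theta - 2L, i + 1L + ctx$maxI)
      if (kmax >= i + 1L) for (k in (i + 1L):kmax) {
        n1 <- k - i - 1L
        lmin <- max(k + theta + 1L, j - 1L - (ctx$maxI - n1))
        if (lmin > j - 1L) next
        for (l in lmin:(j - 1L)) {
          if (!ctx$can[k, l] || !is.finite(FB[k, l])) next
          e <- ctxInternalEnergy(ctx, i, j, k, l)
          cand <- e + V(i + 1L, k - 1L) + V(l + 1L, j - 1L) + FB[k, l]
          if (cand < best) { best <- cand; kind <- 2L; bk <- k; bl <- l }
        }
      }
      if (j - 2L >= i + 2L) for (h in (i + 2L):(j - 2L)) {
        if (!is.finite(FM[i + 1L, h - 1L]) || !is.finite(FM1[h, j - 1L]))
          next
        cand <- a + b + FM[i + 1L, h - 1L] + FM1[h, j - 1L]
        if (cand < best) { best <- cand; kind <- 3L; bk <- h }
      }
      FB[i, j] <- v0[i] + v0[j] + best
      cFBkind[i, j] <- kind; cFBk[i, j] <- bk; cFBl[i, j] <- bl
    }
    if (d > theta) {
      best <- BIG; bl <- 0L
      for (l in (i + theta + 1L):j) {
        if (!is.finite(FB[i, l])) next
        cand <- FB[i, l] + b + cc * (j - l) + V(l + 1L, j)
        if (cand < best) { best <- cand; bl <- l }
      }
      FM1[i, j] <- best; cFM1[i, j] <- bl
      best <- BIG; bk <- 0L; bfirst <- TRUE
      for (k in i:(j - theta - 1L)) {
        if (!is.finite(FM1[k, j])) next
        firstCost <- cc * (k - i) + V(i, k - 1L)
        restCost <- if (k == i) BIG else FM[i, k - 1L]
        if (firstCost + FM1[k, j] < best) {
          best <- firstCost + FM1[k, j]; bk <- k; bfirst <- TRUE
        }
        if (restCost + FM1[k, j] < best) {
          best <- restCost + FM1[k, j]; bk <- k; bfirst <- FALSE
        }
      }
      FM[i, j] <- best; cFM[i, j] <- bk; cFMfirst[i, j] <- bfirst
    }
    fleft <- if (d == 0L) 0 else Fm[i, j - 1L]
    best <- fleft + v1[j]; bk <- 0L
    if (d > theta) for (k in i:(j - theta - 1L)) {
      if (!is.finite(FB[k, j])) next
      fl <- if (k == i) 0 else Fm[i, k - 1L]
      if (fl + FB[k, j] < best) { best <- fl + FB[k, j]; bk <- k }
    }
    Fm[i, j] <- best; cF[i, j] <- bk
  }
  # traceback
  pt <- integer(n)
  stack <- list(c(1L, 1L, n))  # (table: 1=F, 2=FB, 3=FM, 4=FM1), i, j
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    tb <- top[1]; i <- top[2]; j <- top[3]
    if (j < i) next
    if (tb == 1L) {
      k <- cF[i, j]
      if (k == 0L) {
        if (j - 1L >= i) stack[[length(stack) + 1L]] <- c(1L, i, j - 1L)
      } else {
        stack[[length(stack) + 1L]] <- c(2L, k, j)
        if (k - 1L >= i) stack[[length(stack) + 1L]] <- c(1L, i, k - 1L)
      }
    } else if (tb == 2L) {
      pt[i] <- j; pt[j] <- i
      kind <- cFBkind[i, j]
      if (kind == 2L) {
        stack[[length(stack) + 1L]] <- c(2L, cFBk[i, j], cFBl[i, j])
      } else if (kind == 3L) {
        h <- cFBk[i, j]
        stack[[length(stack) + 1L]] <- c(3L, i + 1L, h - 1L)
        stack[[length(stack) + 1L]] <- c(4L, h, j - 1L)
      }
    } else if (tb == 3L) {
      k <- cFM[i, j]
      stack[[length(stack) + 1L]] <- c(4L, k, j)
      if (!cFMfirst[i, j] && k - 1L >= i)
        stack[[length(stack) + 1L]] <- c(3L, i, k - 1L)
    } else {
      l <- cFM1[i, j]
      stack[[length(stack) + 1L]] <- c(2L, i, l)
    }
  }
  s <- secondaryStructure(pt)
  list(structure = s, score = Fm[1, n],
    energy = energyOfStructure(seq, s, params, pseudo = pseudo))
}

#' Stacking pseudo free energy of a raw reactivity
#'
#' m * ln(s + 1) + b; missing reactivities contribute no term (0).  Default
#' slope and intercept are the published values m = 2.6, b = -0.8 kcal/mol.
#'
#' @param s raw (unnormalized) reactivity, >= 0 or NA.
#' @param m slope, kcal/mol.
#' @param b intercept, kcal/mol.
#' @return kcal/mol.
#' @export
deiganPseudoEnergy <- function(s, m = 2.6, b = -0.8) {
  out <- m * log(s + 1) + b
  out[is.na(s)] <- 0
  out
}

#' Fold with the stacking pseudo-energy comparison mode
#'
#' The comparison method: the pseudo free energy m*ln(s+1)+b of a position
#' enters only through base-pair stacks.  Operationally the pseudo-energies
#' of all four positions are added to every stack term (the two-pair loop
#' with no unpaired bases), so an interior pair of a helix is counted twice,
#' a helix-terminal pair once, and an isolated pair not at all.  Weights are
#' all 1 (no per-nucleotide soft constraints).
#'
#' @param seq ACGU string.
#' @param raw numeric vector of raw reactivities (NA = missing).
#' @param params an \code{EnergyParams}.
#' @param m,b Deigan slope and intercept, kcal/mol.
#' @param scale per-position rescaling factor (see
#'   \code{\link{insidePartition}}).
#' @return list with \code{structure}, \code{score}, \code{energy} (MFE
#'   under the pseudo-energy objective) and \code{tables} (inside tables of
#'   the pseudo-energy partition function).
#' @export
foldDeigan <- function(seq, raw, params, m = 2.6, b = -0.8, scale = 1) {
  n <- nchar(seq)
  pseudo <- deiganPseudoEnergy(raw, m, b)
  ones <- list(w0 = rep(1, n), w1 = rep(1, n))
  mfe <- weightedMFE(seq, NULL, 0, params, pseudo = pseudo)
  tables <- insidePartition(seq, ones, params, pseudo = pseudo,
    scale = scale)
  c(mfe, list(tables = tables))
}
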