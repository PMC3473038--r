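## High-level folding interface, end-to-end run configuration, and
## deterministic fixture generation.

#' Fold an RNA with probing-data soft constraints
#'
#' The full engine pipeline on in-memory data: builds position weights,
#' computes the weighted and unweighted partition functions and base-pair
#' probabilities, the mode's MFE structure, and all ensemble diagnostics.
#'
#' Modes: \code{"soft"} applies the per-nucleotide Boltzmann weights
#' exp(-beta|x - q|/RT); \code{"plain"} ignores the data (classic McCaskill
#' + Turner MFE, identical to soft at beta = 0); \code{"deigan"} applies
#' the stacking pseudo-energy m ln(s+1) + b to raw reactivities instead of
#' soft weights.
#'
#' Numeric safety: for sequences longer than 60 nt every position weight is
#' rescaled by a factor derived from the plain MFE (the classic partition
#' function scaling trick), which keeps the DP in double range for
#' sequences up to several thousand nt at 37 C; log Z values are reported
#' with the rescaling undone.  Probabilities are scale-invariant.
#'
#' @param seq ACGU string (use \code{\link{readFastaRna}} for files).
#' @param q normalized unpaired probabilities (complete; run
#'   \code{\link{resolveMissing}} first), or NULL in plain mode.
#' @param beta scaling parameter, kcal/mol (default 1).
#' @param params an \code{EnergyParams} (default the bundled turner-min).
#' @param mode "soft", "plain" or "deigan".
#' @param raw raw reactivities (NA = missing), required in deigan mode.
#' @param m,b Deigan slope/intercept, kcal/mol.
#' @return a \code{\linkS4class{FoldResult}}.
#' @export
foldRna <- function(seq, q = NULL, beta = 1, params = loadEnergyParams(),
                    mode = c("soft", "plain", "deigan"), raw = NULL,
                    m = 2.6, b = -0.8) {
  mode <- match.arg(mode)
  n <- nchar(seq)
  if (mode == "soft") {
    if (is.null(q)) stop("soft mode requires normalized reactivities q")
    if (any(is.na(q))) stop("q has missing values; run resolveMissing()")
  }
  if (mode == "deigan" && is.null(raw))
    stop("deigan mode requires raw reactivities")
  if (mode == "plain") beta <- 0
  RT <- params@RT
  plainMfe <- weightedMFE(seq, NULL, 0, params)
  scale <- if (n > 60)
    exp(1.07 * plainMfe$energy / (RT * n)) else 1
  ones <- list(w0 = rep(1, n), w1 = rep(1, n))
  inPlain <- insidePartition(seq, ones, params, scale = scale)
  ppPlain <- pairProbabilities(inPlain)
  if (mode == "deigan") {
    pseudo <- deiganPseudoEnergy(raw, m, b)
    mfe <- weightedMFE(seq, NULL, 0, params, pseudo = pseudo)
    inW <- insidePartition(seq, ones, params, pseudo = pseudo,
      scale = scale)
    qeff <- rep(NA_real_, 0)
  } else {
    qeff <- if (is.null(q)) rep(0.5, n) else q
    weights <- buildWeights(qeff, beta, RT)
    mfe <- if (mode == "plain") plainMfe else
      weightedMFE(seq, qeff, beta, params)
    inW <- insidePartition(seq, weights, params, scale = scale)
  }
  ppW <- pairProbabilities(inW)
  qMetric <- if (mode == "deigan") raw else qeff
  edW <- if (mode == "deigan" && any(is.na(qMetric))) {
    okq <- !is.na(qMetric)
    sum(ppW$unpaired[okq] * (1 - qMetric[okq]) +
        (1 - ppW$unpaired[okq]) * qMetric[okq])
  } else expectedDistance(ppW$unpaired, qMetric)
  ed0 <- if (mode == "deigan" && any(is.na(qMetric))) {
    okq <- !is.na(qMetric)
    sum(ppPlain$unpaired[okq] * (1 - qMetric[okq]) +
        (1 - ppPlain$unpaired[okq]) * qMetric[okq])
  } else expectedDistance(ppPlain$unpaired, qMetric)
  entF <- pointwiseEntropy(ppW$bpp, "full")
  entB <- pointwiseEntropy(ppW$bpp, "binary")
  dstar <- if (mode == "soft" && beta > 0)
    criticalDistance(ppPlain$logZ, ppW$logZ, beta, RT) else ed0
  metrics <- list(
    ED_weighted = edW, ED_unweighted = ed0, d_star = dstar,
    avg_entropy_full = entF$average, avg_entropy_binary = entB$average,
    diversity = morganHiggsDiversity(ppW$bpp),
    logZ = ppPlain$logZ, logZ_weighted = ppW$logZ,
    entropy_full = entF$H, entropy_binary = entB$H,
    unpaired_weighted = ppW$unpaired, unpaired_unweighted = ppPlain$unpaired)
  new("FoldResult", sequence = seq, mode = mode, beta = beta, q = qeff,
    mfeStructure = mfe$structure, mfeScore = mfe$score,
    mfeEnergy = mfe$energy, bpp = ppW$bpp, bppUnweighted = ppPlain$bpp,
    unpaired = ppW$unpaired, logZ = ppPlain$logZ,
    logZWeighted = ppW$logZ, metrics = metrics)
}

#' Run a fold end-to-end from files
#'
#' Reads the inputs named in \code{config}, normalizes, folds, computes the
#' metrics and writes every requested output.  \code{config} is a named
#' list with elements:
#' \describe{
#'   \item{fasta}{input FASTA path (required).}
#'   \item{shape}{reactivity file path (required unless mode = "plain").}
#'   \item{kind}{"shape" (default) or "inline".}
#'   \item{mode}{"soft" (default), "deigan" or "plain".}
#'   \item{beta}{scaling parameter (default 1).}
#'   \item{params}{parameter set name or file (default "turner-min").}
#'   \item{normalization}{list overriding
#'     \code{\link{defaultNormalizationConfig}} entries.}
#'   \item{m, b}{Deigan slope/intercept.}
#'   \item{outCt, outDb, outBpp, outMetrics}{output paths (each optional).}
#' }
#'
#' @param config named list, see Details.
#' @return the \code{FoldResult}, invisibly.
#' @export
runFold <- function(config) {
  mode <- if (is.null(config$mode)) "soft" else config$mode
  beta <- if (is.null(config$beta)) 1 else config$beta
  if (is.null(config$fasta)) stop("config$fasta is required")
  fa <- readFastaRna(config$fasta)
  n <- nchar(fa$seq)
  params <- loadEnergyParams(
    if (is.null(config$params)) "turner-min" else config$params)
  nc <- defaultNormalizationConfig()
  if (!is.null(config$normalization))
    nc[names(config$normalization)] <- config$normalization
  q <- NULL; raw <- NULL
  if (mode != "plain") {
    if (is.null(config$shape))
      stop("mode '", mode, "' requires a reactivity file (config$shape)")
    kind <- if (is.null(config$kind)) "shape" else config$kind
    prof <- readReactivity(config$shape, n, kind)
    raw <- rawReactivity(prof)
    if (mode == "soft") {
      prof <- normalizeProfile(prof, nc)
      q <- resolveMissing(unpairedProbs(prof), nc$missingFill)
    }
  }
  result <- foldRna(fa$seq, q = q, beta = beta, params = params,
    mode = mode, raw = raw,
    m = if (is.null(config$m)) 2.6 else config$m,
    b = if (is.null(config$b)) -0.8 else config$b)
  message(sprintf(
    "fold: %s | mode=%s beta=%.3g | logZ=%.4f logZ'=%.4f | ED %.4f -> %.4f",
    fa$id, mode, result@beta, result@logZ, result@logZWeighted,
    result@metrics$ED_unweighted, result@metrics$ED_weighted))
  if (!is.null(config$outCt))
    writeCT(fa$seq, mfeStructure(result), config$outCt,
      energy = result@mfeEnergy, title = fa$id)
  if (!is.null(config$outDb))
    writeLines(c(paste0(">", fa$id), fa$seq,
      writeDotBracket(mfeStructure(result))), config$outDb)
  if (!is.null(config$outBpp))
    writeBppTriples(pairProbs(result), config$outBpp)
  if (!is.null(config$outMetrics))
    writeMetricsJson(ensembleMetrics(result), config$outMetrics)
  invisible(result)
}

#' Generate deterministic test fixtures
#'
#' Writes, under \code{dir}: random valid RNA sequences (lengths 8-16), a
#' reference structure for each drawn from the exhaustive enumeration,
#' synthetic reactivity profiles built from the reference structure
#' (q = x +/- uniform noise of the requested level, clipped to [0,1], with
#' zero-noise profiles replacing the reference by the minimum-energy
#' structure sharing its pairing indicator so that the profile has a unique
#' best explanation), and malformed-file negatives for I/O tests.  The same
#' seed yields byte-identical output.
#'
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @param nseq number of sequence/structure/profile triples (default 5).
#' @param noise uniform noise half-width on q (default 0.2).
#' @param params an \code{EnergyParams}.
#' @return list of per-fixture metadata, invisibly.
#' @export
makeFixtures <- function(seed, dir, nseq = 5, noise = 0.2,
                         params = loadEnergyParams()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  out <- vector("list", nseq)
  for (f in seq_len(nseq)) {
    n <- sample(8:16, 1)
    seq <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
      prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
    structs <- enumerateStructures(seq, params)
    s <- structs[[sample(length(structs), 1)]]
    # canonical representative: min-energy structure with this indicator
    x <- unpairedIndicator(s)
    same <- Filter(function(t) identical(unpairedIndicator(t), x), structs)
    es <- vapply(same, function(t) energyOfStructure(seq, t, params),
      numeric(1))
    s <- same[[which.min(es)]]
    q <- pmin(pmax(x + stats::runif(n, -noise, noise), 0), 1)
    base <- file.path(dir, sprintf("fix%02d", f))
    writeLines(c(sprintf(">fix%02d", f), seq), paste0(base, ".fa"))
    writeLines(sprintf("%d %.4f", seq_len(n), q), paste0(base, ".shape"))
    writeLines(writeDotBracket(s), paste0(base, ".db"))
    writeCT(seq, s, paste0(base, ".ct"), title = sprintf("fix%02d", f))
    out[[f]] <- list(seq = seq, structure = s, q = q)
  }
  # malformed negatives
  writeLines(c(">bad", "ACGN"), file.path(dir, "bad-residue.fa"))
  writeLines(c("1 0.2", "1 0.3"), file.path(dir, "dup-position.shape"))
  writeLines("((..", file.path(dir, "unbalanced.db"))
  writeLines(c("4 bad-ct", "1 G 0 2 5 1", "2 A 1 3 0 2", "3 A 2 4 0 3",
    "4 C 3 0 0 4"), file.path(dir, "bad-partner.ct"))
  invisible(out)
}
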