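## Readers/writers for every external representation the tool touches.
## All file coordinates are 1-based inclusive (CT / .shape conventions).

#' Construct a SecondaryStructure from a pair table
#'
#' @param pairTable integer vector; entry i is the partner of position i,
#'   0 if unpaired.
#' @return a validated \code{\linkS4class{SecondaryStructure}}.
#' @examples
#' secondaryStructure(c(5L, 0L, 0L, 0L, 1L))
#' @export
secondaryStructure <- function(pairTable) {
  new("SecondaryStructure", pairTable = as.integer(pairTable))
}

#' Empty structure of a given length
#' @param n positive integer.
#' @return a \code{SecondaryStructure} with no pairs.
#' @export
emptyStructure <- function(n) secondaryStructure(integer(n))

#' Read the first RNA record of a FASTA file
#'
#' Uses Biostrings for the FASTA parsing, then normalizes to an RNA alphabet:
#' lowercase is uppercased and T is converted to U.  Any residue outside
#' \{A,C,G,U,T\} is a hard error naming the offending position.  If the file
#' contains more than one record the first is used and a warning is emitted
#' (the tool is single-sequence).
#'
#' @param path path to a FASTA file.
#' @return list with elements \code{id} (record identifier) and
#'   \code{seq} (character, ACGU).
#' @export
readFastaRna <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  if (length(recs) > 1L)
    warning(sprintf("FASTA file %s has %d records; using the first ('%s')",
      path, length(recs), names(recs)[1]))
  id <- names(recs)[1]
  seq <- normalizeRnaString(as.character(recs[[1]]))
  list(id = id, seq = seq)
}

## Uppercase, T->U, validate alphabet; shared by FASTA and CT readers.
normalizeRnaString <- function(s) {
  s <- chartr("acgut", "ACGUU", s)
  s <- gsub("T", "U", s, fixed = TRUE)
  bad <- regexpr("[^ACGU]", s)
  if (bad > 0)
    stop(sprintf("invalid residue '%s' at position %d",
      substr(s, bad, bad), bad))
  if (nchar(s) < 1L) stop("sequence is empty")
  s
}

#' Read a two-column reactivity file
#'
#' Parses the RNAstructure \code{.shape} dialect: whitespace-separated lines
#' "position value", 1-based positions, with -999 as the missing-data
#' sentinel.  Positions absent from the file and positions with value -999
#' are both reported as NA (missing).
#'
#' @param path path to the reactivity file.
#' @param n sequence length; positions must lie in [1, n].
#' @param kind "shape" (default) or "inline".
#' @return a \code{\linkS4class{ReactivityProfile}} of length \code{n}
#'   (not yet normalized).
#' @export
readReactivity <- function(path, n, kind = c("shape", "inline")) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  raw <- rep(NA_real_, n)
  seen <- logical(n)
  for (ln in lines) {
    fields <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(fields) < 2L)
      stop("malformed reactivity line: '", ln, "'")
    pos <- suppressWarnings(as.integer(fields[1]))
    val <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(pos) || is.na(val))
      stop("non-numeric reactivity line: '", ln, "'")
    if (pos < 1L || pos > n)
      stop(sprintf("reactivity position %d out of range [1, %d]", pos, n))
    if (seen[pos])
      stop(sprintf("duplicate reactivity position %d", pos))
    seen[pos] <- TRUE
    raw[pos] <- if (val == -999) NA_real_ else val
  }
  new("ReactivityProfile", raw = raw, kind = kind)
}

#' Parse a dot-bracket string
#'
#' Characters '.' (unpaired), '(' and ')' (pair opening/closing).  When a
#' sequence and/or parameters are supplied the pairs are checked against the
#' allowed-pair alphabet (Watson-Crick + GU) and the minimum hairpin gap
#' theta.  Validation severity is configurable: reference structures from
#' crystallography may contain non-canonical pairs, so the default keeps the
#' pair and warns; the folding engine itself always rejects.
#'
#' @param text dot-bracket string.
#' @param sequence optional ACGU string for pair-alphabet checking.
#' @param theta minimum hairpin gap used for validation (default 3).
#' @param validate "warn" (default), "error" or "none".
#' @return a \code{\linkS4class{SecondaryStructure}}.
#' @export
parseDotBracket <- function(text, sequence = NULL, theta = 3L,
                            validate = c("warn", "error", "none")) {
  validate <- match.arg(validate)
  chars <- strsplit(text, "")[[1]]
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad))
    stop(sprintf("invalid dot-bracket character '%s' at position %d",
      chars[bad[1]], bad[1]))
  n <- length(chars)
  pt <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket: unmatched ')' at ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack))
    stop("unbalanced dot-bracket: unmatched '(' at ", stack[1])
  s <- secondaryStructure(pt)
  if (validate != "none") {
    complain <- if (validate == "error") stop else warning
    bp <- basePairs(s)
    if (nrow(bp)) {
      gaps <- bp[, 2] - bp[, 1]
      if (any(gaps <= theta))
        complain(sprintf("pair (%d,%d) violates the hairpin constraint (gap %d <= theta %d)",
          bp[which.min(gaps), 1], bp[which.min(gaps), 2], min(gaps), theta))
      if (!is.null(sequence)) {
        res <- strsplit(sequence, "")[[1]]
        ok <- paste0(res[bp[, 1]], res[bp[, 2]]) %in% names(PAIR_INDEX)
        if (!all(ok)) {
          k <- which(!ok)[1]
          complain(sprintf("pair (%d,%d) = %s-%s is not Watson-Crick or GU",
            bp[k, 1], bp[k, 2], res[bp[k, 1]], res[bp[k, 2]]))
        }
      }
    }
  }
  s
}

#' Write a structure as a dot-bracket string
#'
#' Inverse of \code{\link{parseDotBracket}}: round-trip identity holds for
#' every valid (pseudoknot-free) structure.
#'
#' @param structure a \code{SecondaryStructure}.
#' @return dot-bracket character string.
#' @export
writeDotBracket <- function(structure) {
  pt <- pairTable(structure)
  chars <- rep(".", length(pt))
  chars[pt > seq_along(pt)] <- "("
  chars[pt > 0L & pt < seq_along(pt)] <- ")"
  paste(chars, collapse = "")
}

#' Read a CT (connectivity table) file
#'
#' Standard 6-column CT body: index, base, i-1, i+1, partner, index.  The
#' header line starts with the sequence length and may carry a free energy
#' and a title.  Partner columns are checked for involution consistency.
#'
#' @param path path to a CT file.
#' @return list with \code{seq} (ACGU string), \code{structure}
#'   (\code{SecondaryStructure}), \code{energy} (numeric or NA) and
#'   \code{title}.
#' @export
readCT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty CT file: ", path)
  hdr <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  n <- suppressWarnings(as.integer(hdr[1]))
  if (is.na(n) || n < 1L) stop("malformed CT header: '", lines[1], "'")
  energy <- NA_real_
  em <- regmatches(lines[1],
    regexpr("(?i)energy\\s*=?\\s*(-?[0-9.]+)", lines[1], perl = TRUE))
  if (length(em))
    energy <- as.numeric(sub("(?i)energy\\s*=?\\s*", "", em, perl = TRUE))
  if (length(lines) - 1L != n)
    stop(sprintf("CT row count %d does not match header length %d",
      length(lines) - 1L, n))
  bases <- character(n); pt <- integer(n)
  for (r in seq_len(n)) {
    f <- strsplit(trimws(lines[r + 1L]), "[[:space:]]+")[[1]]
    if (length(f) < 6L) stop("malformed CT row ", r)
    idx <- as.integer(f[1])
    if (idx != r) stop(sprintf("CT row %d has index %d", r, idx))
    bases[r] <- f[2]
    pt[r] <- as.integer(f[5])
  }
  paired <- which(pt > 0L)
  if (any(pt[paired] < 1L | pt[paired] > n) || any(pt[pt[paired]] != paired))
    stop("inconsistent partner columns in CT file (involution violated)")
  seq <- normalizeRnaString(paste(bases, collapse = ""))
  list(seq = seq, structure = secondaryStructure(pt), energy = energy,
    title = paste(hdr[-1], collapse = " "))
}

#' Write a CT file
#'
#' @param seq ACGU string.
#' @param structure a \code{SecondaryStructure} of the same length.
#' @param path output path.
#' @param energy optional free energy for the header (kcal/mol).
#' @param title optional title (default "shapefold").
#' @export
writeCT <- function(seq, structure, path, energy = NA, title = "shapefold") {
  n <- nchar(seq)
  pt <- pairTable(structure)
  if (length(pt) != n) stop("sequence and structure lengths differ")
  hdr <- if (is.na(energy)) sprintf("%d %s", n, title)
    else sprintf("%d ENERGY = %.2f %s", n, energy, title)
  res <- strsplit(seq, "")[[1]]
  rows <- sprintf("%d %s %d %d %d %d", seq_len(n), res,
    seq_len(n) - 1L, ifelse(seq_len(n) == n, 0L, seq_len(n) + 1L),
    pt, seq_len(n))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write base-pair probabilities as "i j p" triples
#'
#' 1-based positions, probability to 6 decimals; pairs with probability
#' below \code{minProb} are omitted.
#'
#' @param bpp numeric matrix of pair probabilities.
#' @param path output path.
#' @param minProb smallest probability written (default 1e-6).
#' @export
writeBppTriples <- function(bpp, path, minProb = 1e-6) {
  n <- nrow(bpp)
  idx <- which(upper.tri(bpp) & bpp >= minProb, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  writeLines(sprintf("%d %d %.6f", idx[, 1], idx[, 2],
    bpp[idx, drop = FALSE]), path)
  invisible(path)
}

#' Write the ensemble metrics report as JSON
#'
#' @param metrics named list (as in \code{\link{ensembleMetrics}}).
#' @param path output path.
#' @export
writeMetricsJson <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
    na = "null", pretty = TRUE)
  invisible(path)
}
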