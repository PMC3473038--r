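# Shared helpers: parameter set, random instances, random valid structures.

tmParams <- loadEnergyParams()

randomSeq <- function(n, gc = 0.6) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)), collapse = "")
}

randomInstance <- function(nmin = 8, nmax = 14) {
  n <- sample(nmin:nmax, 1)
  list(seq = randomSeq(n), q = runif(n), n = n)
}

# random valid structure over a random sequence, via the enumerator
randomStructure <- function(nmin = 8, nmax = 14) {
  s <- randomSeq(sample(nmin:nmax, 1))
  structs <- enumerateStructures(s, tmParams)
  list(seq = s, structure = structs[[sample(length(structs), 1)]])
}

unitWeights <- function(n) list(w0 = rep(1, n), w1 = rep(1, n))
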