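# Builders and brute-force oracles shared across the test files.

# A minimal repertoire from a count vector; keys are distinct nucleotide
# sequences (in-frame, stop-free) with matching amino acids.
makeRep <- function(counts, tissue = NA_character_, patientId = "",
                    sampleId = "test") {
  n <- length(counts)
  codons <- c("TGT", "GCC", "AGC", "GGG", "TTT", "CAT", "AAA", "GAA")
  aa <- c("C", "A", "S", "G", "F", "H", "K", "E")
  k <- max(1, ceiling(log(n, 8)) + 1)
  idx <- arrayInd(seq_len(n), rep(8, k))
  nt <- do.call(paste0, lapply(seq_len(k), function(j) codons[idx[, j]]))
  aas <- do.call(paste0, lapply(seq_len(k), function(j) aa[idx[, j]]))
  Repertoire(data.frame(cdr3_nt = nt, cdr3_aa = aas,
                        v_segment = "TRBV20-1", j_segment = "TRBJ2-1",
                        count = counts, stringsAsFactors = FALSE),
             sampleId = sampleId, patientId = patientId, tissue = tissue)
}

# Random repertoire with heavy-ish tail, distinct keys.
randomRep <- function(n, maxCount = 50, ...) {
  makeRep(sample.int(maxCount, n, replace = TRUE), ...)
}

# Brute-force two-tailed signed-rank p by enumerating all 2^n sign vectors.
bruteSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.numeric(signs %*% r)
  w <- sum(r[d > 0])
  min(1, 2 * min(mean(W <= w + 1e-9), mean(W >= w - 1e-9)))
}

# Brute-force two-tailed Mann-Whitney p by enumerating all group labelings.
bruteMannWhitneyP <- function(a, b) {
  x <- c(a, b)
  N <- length(x); nA <- length(a)
  r <- rank(x)
  U <- apply(utils::combn(N, nA), 2, function(i)
    sum(r[i]) - nA * (nA + 1) / 2)
  u <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  min(1, 2 * min(mean(U <= u + 1e-9), mean(U >= u - 1e-9)))
}

# Small, fast synthetic-cohort configuration for structural tests.
smallConfig <- function(...) {
  syntheticCohortConfig(nPatients = 3, clonesTumor = 400,
                        clonesNormal = 400, readsPerSample = 4000, ...)
}
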