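# Independent plain-R reference implementation of the affine-gap local
# aligner contract: full Gotoh dynamic programming over complete score
# matrices (M = column ends in a substitution, GQ = gap consuming the query,
# GS = gap consuming the subject), gap of length L costing open + L * extend,
# and the documented deterministic tie rules (first score-maximal end cell in
# query-major order; traceback prefers substitution > query-consuming gap >
# subject-consuming gap, extension over restart at zero ties). Row-vectorized
# for speed but structurally independent of the compiled implementation.
oracle_align <- function(q, s, match = 2, mismatch = 3, gap_open = 5,
                         gap_extend = 2, min_score = 20) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  go <- gap_open + gap_extend; ge <- gap_extend
  M <- matrix(-Inf, n + 1, m + 1); M[1, ] <- 0; M[, 1] <- 0
  GQ <- matrix(-Inf, n + 1, m + 1)
  GS <- matrix(-Inf, n + 1, m + 1)
  tbM <- matrix(0L, n, m); tbQ <- matrix(0L, n, m); tbS <- matrix(0L, n, m)
  for (i in 1:n) {
    subv <- ifelse(qc[i] == sc & qc[i] != "N", match, -mismatch)
    # substitution state
    if (i == 1) {
      prev <- rep(0, m); pm <- rep(0L, m)
    } else {
      pM <- M[i, 1:m]; pQ <- GQ[i, 1:m]; pS <- GS[i, 1:m]
      prev <- pM; pm <- rep(1L, m)
      sel <- pQ > prev; prev[sel] <- pQ[sel]; pm[sel] <- 2L
      sel <- pS > prev; prev[sel] <- pS[sel]; pm[sel] <- 3L
      sel <- prev < 0; prev[sel] <- 0; pm[sel] <- 0L
      prev[1] <- 0; pm[1] <- 0L  # j == 1 border: start fresh
    }
    Mrow <- prev + subv
    # gap consuming the query (from previous row, same column)
    vq <- M[i, 2:(m + 1)] - go; pq <- rep(1L, m)
    sel <- GQ[i, 2:(m + 1)] - ge > vq; vq[sel] <- (GQ[i, 2:(m + 1)] - ge)[sel]; pq[sel] <- 2L
    sel <- GS[i, 2:(m + 1)] - go > vq; vq[sel] <- (GS[i, 2:(m + 1)] - go)[sel]; pq[sel] <- 3L
    # gap consuming the subject (same row, previous column) via cummax chain
    A <- pmax(c(0, Mrow), c(-Inf, vq))           # column indices 0..m
    B <- A + ge * (0:m)
    vs <- cummax(B)[1:m] - ge * (1:m) - go + ge  # value at columns 1..m
    # predecessor for GS, tested in preference order
    ps <- rep(3L, m)
    fromM <- c(-Inf, Mrow[-m]) - go == vs
    fromQ <- !fromM & (c(-Inf, vq[-m]) - go == vs)
    ps[fromQ] <- 2L; ps[fromM] <- 1L
    M[i + 1, 2:(m + 1)] <- Mrow
    GQ[i + 1, 2:(m + 1)] <- vq
    GS[i + 1, 2:(m + 1)] <- vs
    tbM[i, ] <- pm; tbQ[i, ] <- pq; tbS[i, ] <- ps
  }
  core <- M[-1, -1, drop = FALSE]
  best <- max(core)
  if (best < min_score) return(NULL)
  bi <- which(apply(core, 1, max) == best)[1]
  bj <- which(core[bi, ] == best)[1]
  i <- bi; j <- bj; state <- 1L
  nident <- 0L; nmis <- 0L; ngap <- 0L; alnlen <- 0L
  qstart <- bi; sstart <- bj
  repeat {
    if (state == 1L) {
      if (qc[i] == sc[j] && qc[i] != "N") nident <- nident + 1L else nmis <- nmis + 1L
      alnlen <- alnlen + 1L; qstart <- i; sstart <- j
      p <- tbM[i, j]; i <- i - 1L; j <- j - 1L
      if (p == 0L) break
      state <- p
    } else if (state == 2L) {
      ngap <- ngap + 1L; alnlen <- alnlen + 1L
      state <- tbQ[i, j]; i <- i - 1L
    } else {
      ngap <- ngap + 1L; alnlen <- alnlen + 1L
      state <- tbS[i, j]; j <- j - 1L
    }
  }
  list(score = best, nident = nident, mismatch = nmis, gaps = ngap,
       alnlen = alnlen, pident = round(100 * nident / alnlen, 3),
       qstart = qstart, qend = bi, sstart = sstart, send = bj)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# a related pair: a random sequence and a substitution/indel-mutated copy
related_pair <- function(n, sub_rate = 0.05, indel_rate = 0.01) {
  a <- random_dna(n)
  b <- mutate_sequence(a, sub_rate, indel_rate, 2)
  c(a, b)
}

# closed-form ARI from a contingency table, written directly from the
# definition as an independent check on adjusted_rand_index()
ari_closed_form <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  ni <- rowSums(tab); nj <- colSums(tab)
  index <- sum(tab * (tab - 1) / 2)
  ei <- sum(ni * (ni - 1) / 2); ej <- sum(nj * (nj - 1) / 2)
  expected <- ei * ej / (n * (n - 1) / 2)
  maxi <- (ei + ej) / 2
  if (maxi == expected) return(1.0)
  (index - expected) / (maxi - expected)
}

small_plasmid_set <- function(seqs, prefix = "TST") {
  plasmid_set(sprintf("%s%03d.1", prefix, seq_along(seqs)), seqs)
}
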