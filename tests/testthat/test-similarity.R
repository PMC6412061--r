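test_that("self-alignment is perfect and a single substitution scores as expected", {
  set.seed(11)
  x <- list(accession = "X", sequence = random_dna(80))
  hit <- align_pair(x, x)
  expect_equal(hit$pident, 100)
  expect_equal(hit$qcov, 100)
  expect_equal(hit$mismatch, 0L)
  expect_equal(hit$gaps, 0L)

  a <- list(accession = "A", sequence = "ACGTACGTAC")
  bseq <- "ACGTCCGTAC"  # substitution at position 5
  b <- list(accession = "B", sequence = bseq)
  hit <- align_pair(a, b, alignment_params(min_score = 5))
  orc <- oracle_align(a$sequence, bseq, min_score = 5)
  expect_equal(hit$nident, 9L)
  expect_equal(hit$length, 10L)
  expect_equal(hit$pident, 90)
  expect_equal(hit$nident, orc$nident)
  expect_equal(hit$length, orc$alnlen)
})

test_that("unrelated random sequences never look like cognates", {
  set.seed(23)
  a <- list(accession = "A", sequence = random_dna(1000))
  b <- list(accession = "B", sequence = random_dna(1000))
  hit <- align_pair(a, b)
  orc <- oracle_align(a$sequence, b$sequence)
  if (is.null(hit)) {
    expect_null(orc)
  } else {
    expect_lt(hit$qcov, 40)
    expect_equal(hit$nident, orc$nident)
  }
})

test_that("compiled aligner matches the dynamic-programming oracle exactly", {
  set.seed(7)
  params <- alignment_params(min_score = 12)
  n_checked <- 0L
  for (k in 1:70) {
    if (k %% 4 == 0) {
      q <- random_dna(sample(40:300, 1)); s <- random_dna(sample(40:300, 1))
    } else {
      p <- related_pair(sample(60:300, 1), sub_rate = 0.08, indel_rate = 0.02)
      q <- p[1]; s <- p[2]
    }
    hit <- align_pair(list(accession = "q", sequence = q),
                      list(accession = "s", sequence = s), params)
    orc <- oracle_align(q, s, min_score = 12)
    if (is.null(hit)) {
      expect_null(orc)
    } else {
      n_checked <- n_checked + 1L
      expect_identical(hit$nident, orc$nident)
      expect_identical(hit$length, orc$alnlen)
      expect_identical(hit$pident, orc$pident)
      expect_identical(hit$mismatch, orc$mismatch)
      expect_identical(hit$gaps, orc$gaps)
    }
  }
  expect_gte(n_checked, 50L)
})

test_that("optimal local score agrees with an established aligner", {
  set.seed(31)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  for (k in 1:10) {
    p <- related_pair(sample(60:200, 1), sub_rate = 0.1, indel_rate = 0.02)
    hit <- align_pair(list(accession = "q", sequence = p[1]),
                      list(accession = "s", sequence = p[2]),
                      alignment_params(min_score = 1))
    ref <- Biostrings::pairwiseAlignment(p[1], p[2], type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2,
                                         scoreOnly = TRUE)
    expect_false(is.null(hit))
    orc <- oracle_align(p[1], p[2], min_score = 1)
    expect_equal(orc$score, ref)
  }
})

test_that("every emitted hit satisfies the column-accounting invariant", {
  set.seed(5)
  for (k in 1:20) {
    p <- related_pair(sample(50:250, 1), sub_rate = 0.1, indel_rate = 0.03)
    hit <- align_pair(list(accession = "q", sequence = p[1]),
                      list(accession = "s", sequence = p[2]),
                      alignment_params(min_score = 10))
    if (is.null(hit)) next
    expect_identical(hit$nident + hit$mismatch + hit$gaps, hit$length)
    expect_equal(hit$pident, round(100 * hit$nident / hit$length, 3))
    expect_lte(hit$qcov, 100)
  }
})

test_that("hits tables parse, validate and round-trip", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Q1\tS1\t1000\t900\t950\t92.0\t828\t60\t1e-50\t90.0\t12", tf)
  hits <- parse_hits_table(tf)
  expect_equal(hits$nident, 828L)
  expect_equal(hits$gaps, 12L)
  expect_equal(hits$qcov, 90.0)

  writeLines("Q1\tS1\t1000\t900\t950\t92.0\t828\t60\t1e-50\t90.0", tf)
  expect_error(parse_hits_table(tf), "11.*column.*1|line.*1")

  writeLines(character(0), tf)
  expect_equal(nrow(parse_hits_table(tf)), 0L)

  # invariant violation: nident + mismatch + gaps != length
  writeLines("Q1\tS1\t1000\t900\t950\t92.0\t828\t60\t1e-50\t90.0\t13", tf)
  expect_error(parse_hits_table(tf), "invariant")

  set.seed(3)
  p <- related_pair(150, 0.05, 0.01)
  hit <- align_pair(list(accession = "q", sequence = p[1]),
                    list(accession = "s", sequence = p[2]))
  write_hits_table(hit, tf)
  back <- parse_hits_table(tf)
  expect_equal(back$nident, hit$nident)
  expect_equal(back$pident, hit$pident)
  expect_equal(back$qcov, hit$qcov)
  write_hits_table(back, tf)
  expect_equal(parse_hits_table(tf), back)
})

test_that("length ratio is symmetric, bounded and errors on zero", {
  expect_equal(length_ratio(1000, 800), 0.80)
  expect_equal(length_ratio(800, 1000), 0.80)
  expect_equal(length_ratio(500, 500), 1.0)
  expect_error(length_ratio(0, 10), "positive")
})

test_that("the cognate filter applies strict coverage and inclusive length rules", {
  mk <- function(qcov, qlen, slen, pident = 95) {
    nident <- round(pident); data.frame(
      qseqid = "Q", sseqid = "S", qlen = qlen, length = 100L, slen = slen,
      pident = pident, nident = nident, mismatch = 100L - nident,
      evalue = 0, qcov = qcov, gaps = 0L)
  }
  expect_true(is_cognate_hit(mk(85, 1000, 900)))
  expect_false(is_cognate_hit(mk(80.0, 1000, 900)))   # strictly greater than 80
  expect_false(is_cognate_hit(mk(95, 1000, 700)))     # ratio 0.70 < 0.80
  expect_true(is_cognate_hit(mk(95, 1000, 800)))      # ratio 0.80 inclusive
  expect_true(is_cognate_hit(mk(80.0, 1000, 900),
                             cognate_criteria(qcov_strict = FALSE)))
  # self-hits always fail
  h <- mk(95, 1000, 1000); h$sseqid <- "Q"
  expect_false(is_cognate_hit(h))
  # ratio criterion symmetric under role swap
  expect_equal(is_cognate_hit(mk(95, 800, 1000)), is_cognate_hit(mk(95, 1000, 800)))
  # optional identity criterion
  expect_false(is_cognate_hit(mk(95, 1000, 900, pident = 70),
                              cognate_criteria(pident_min = 75)))
})

test_that("tightening filter thresholds never admits more hits", {
  set.seed(19)
  for (rep_i in 1:5) {
    n <- 200
    qlen <- sample(500:5000, n, replace = TRUE)
    slen <- sample(500:5000, n, replace = TRUE)
    alnlen <- pmin(qlen, slen)
    nident <- round(alnlen * runif(n, 0.5, 1))
    hits <- data.frame(
      qseqid = sprintf("Q%03d", 1:n), sseqid = sprintf("S%03d", 1:n),
      qlen = qlen, length = alnlen, slen = slen,
      pident = round(100 * nident / alnlen, 3), nident = nident,
      mismatch = alnlen - nident, evalue = 0,
      qcov = round(runif(n, 0, 100), 1), gaps = 0L)
    base <- sum(is_cognate_hit(hits, cognate_criteria(70, 0.7)))
    for (qc in c(75, 80, 90)) {
      expect_lte(sum(is_cognate_hit(hits, cognate_criteria(qc, 0.7))), base)
    }
    for (lr in c(0.8, 0.9, 0.99)) {
      expect_lte(sum(is_cognate_hit(hits, cognate_criteria(70, lr))), base)
    }
    expect_lte(sum(is_cognate_hit(hits, cognate_criteria(70, 0.7, pident_min = 80))),
               base)
  }
})

test_that("all-vs-all reports one ordered hit per pair and no self-pairs", {
  set.seed(13)
  seqs <- rep(random_dna(300), 3)
  rec <- small_plasmid_set(seqs)
  hits <- all_vs_all(rec, engine = "exact")
  expect_equal(nrow(hits), 6L)
  expect_true(all(hits$pident == 100))
  expect_true(all(hits$qseqid != hits$sseqid))
  expect_equal(anyDuplicated(paste(hits$qseqid, hits$sseqid)), 0L)

  one <- all_vs_all(small_plasmid_set(random_dna(200)), engine = "exact")
  expect_equal(nrow(one), 0L)

  two <- small_plasmid_set(c(random_dna(1000), random_dna(1000)))
  h2 <- all_vs_all(two, engine = "exact")
  expect_equal(sum(is_cognate_hit(h2)), 0L)
})

test_that("the blast engine agrees with the exact engine on the cognate graph", {
  set.seed(91)
  anc1 <- random_dna(1500); anc2 <- random_dna(1800)
  seqs <- c(mutate_sequence(anc1, 0.03), mutate_sequence(anc1, 0.03),
            mutate_sequence(anc2, 0.02), mutate_sequence(anc2, 0.02),
            random_dna(1600), random_dna(1700))
  rec <- small_plasmid_set(seqs)
  edge_key <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "~"))
  }
  g_exact <- build_cognate_graph(rec, all_vs_all(rec, engine = "exact"))
  g_blast <- build_cognate_graph(rec, all_vs_all(rec, engine = "blast"))
  expect_equal(edge_key(g_blast), edge_key(g_exact))
})
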