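#' Alignment parameters
#'
#' Scoring and seeding parameters for pairwise local nucleotide alignment.
#' Defaults mirror the classic nucleotide-search settings (match +2,
#' mismatch -3, gap open 5, gap extend 2, seed word size 11); a gap of length
#' L costs `gap_open + L * gap_extend`.
#'
#' @param match Match reward (positive integer).
#' @param mismatch Mismatch penalty (positive integer, subtracted).
#' @param gap_open Gap-opening penalty (positive integer).
#' @param gap_extend Gap-extension penalty, `gap_open >= gap_extend >= 0`.
#' @param word_size Seed word size used by the heuristic (blast) engine; the
#'   exact engine performs full dynamic programming and ignores it.
#' @param min_score Minimum alignment score for a hit to be reported at all.
#' @param topology `"linear"` (default) or `"circular"`; circular doubles the
#'   subject before alignment and caps the alignment length at the subject
#'   length.
#' @return An `alignment_params` list.
#' @export
alignment_params <- function(match = 2L, mismatch = 3L, gap_open = 5L,
                             gap_extend = 2L, word_size = 11L, min_score = 20L,
                             topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(match > 0, mismatch >= 0, gap_open >= gap_extend, gap_extend >= 0,
            word_size >= 4)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
                 word_size = as.integer(word_size), min_score = as.integer(min_score),
                 topology = topology),
            class = "alignment_params")
}

empty_hits <- function() {
  data.frame(qseqid = character(), sseqid = character(), qlen = integer(),
             length = integer(), slen = integer(), pident = numeric(),
             nident = integer(), mismatch = integer(), evalue = numeric(),
             qcov = numeric(), gaps = integer(), stringsAsFactors = FALSE)
}

# Raw-score-based surrogate for an expectation value; monotone decreasing in
# the score and never used by any filter in this package.
score_evalue <- function(score, qlen, slen) {
  pmin(1e6, as.numeric(qlen) * as.numeric(slen) * 2^(-0.5 * score))
}

#' Align one plasmid pair and report the best local hit
#'
#' Computes the optimal affine-gap local alignment (the single best HSP)
#' between a query and a subject sequence by full dynamic programming, and
#' reports it in the 11-column hit layout. Query coverage is the aligned span
#' on the query (gap columns in the query excluded) over the query length.
#' Co-optimal alignments are resolved deterministically: the end cell is the
#' first score-maximal cell scanning query-major, and traceback prefers a
#' substitution over a query-consuming gap over a subject-consuming gap,
#' extending rather than restarting on score ties.
#'
#' @param a,b Single rows of a `plasmid_set` (query and subject), or lists
#'   with `accession`, `sequence` and `length` fields.
#' @param params An [alignment_params()] object.
#' @return A one-row hit data.frame, or `NULL` when no alignment reaches
#'   `params$min_score`.
#' @export
align_pair <- function(a, b, params = alignment_params()) {
  qseq <- a$sequence[[1]]; sseq <- b$sequence[[1]]
  stopifnot(nzchar(qseq), nzchar(sseq))
  qlen <- nchar(qseq); slen <- nchar(sseq)
  subj <- if (params$topology == "circular" && slen > 1)
    paste0(sseq, sseq) else sseq
  if (as.double(qlen) * nchar(subj) > 6e8) {
    stop("pair too long for the exact aligner (", qlen, " x ", slen,
         "); use all_vs_all(engine = \"blast\") for collection-scale input")
  }
  res <- .sw_align_cpp(qseq, subj, params$match, params$mismatch,
                       params$gap_open, params$gap_extend, params$min_score)
  if (is.null(res)) return(NULL)
  alnlen <- res$alnlen
  if (params$topology == "circular" && alnlen > slen) alnlen <- slen
  qspan <- res$qend - res$qstart + 1L
  data.frame(qseqid = a$accession[[1]], sseqid = b$accession[[1]],
             qlen = qlen, length = alnlen, slen = slen,
             pident = round(100 * res$nident / alnlen, 3),
             nident = res$nident, mismatch = res$mismatch,
             evalue = score_evalue(res$score, qlen, slen),
             qcov = round(100 * qspan / qlen, 3), gaps = res$gaps,
             stringsAsFactors = FALSE)
}

validate_hits <- function(hits, where = "hits table") {
  n <- nrow(hits)
  if (n == 0) return(hits)
  bad_sum <- hits$nident + hits$mismatch + hits$gaps != hits$length
  bad_pid <- abs(hits$pident - 100 * hits$nident / hits$length) > 0.01 + 1e-9
  bad_rng <- hits$qcov > 100 + 1e-9 | hits$pident > 100 + 1e-9 |
    hits$length > hits$qlen + hits$slen | hits$qlen <= 0 | hits$slen <= 0
  bad <- bad_sum | bad_pid | bad_rng
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    stop("rows violating hit invariants in ", where, ": ",
         paste(which(bad), collapse = ", "))
  }
  hits
}

#' Parse a tabular similarity-hits file
#'
#' Reads tab-separated rows in the fixed 11-column order `qseqid, sseqid,
#' qlen, length, slen, pident, nident, mismatch, evalue, qcov, gaps`
#' (an optional header line starting with `qseqid` is skipped). Rows
#' violating the hit invariants (`nident + mismatch + gaps == length`,
#' `pident` consistent with `nident/length` within 0.01, percentages in
#' range) are rejected with their row numbers.
#'
#' @param path Path to the hits TSV.
#' @return A hits data.frame with the 11 canonical columns.
#' @export
parse_hits_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0 && grepl("^qseqid\\b", lines[1])) lines <- lines[-1]
  if (length(lines) == 0) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 11L)) {
    stop("expected 11 tab-separated columns; offending line(s): ",
         paste(which(nfield != 11L), collapse = ", "))
  }
  m <- matrix(unlist(parts), ncol = 11L, byrow = TRUE)
  hits <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                     qlen = as.integer(m[, 3]), length = as.integer(m[, 4]),
                     slen = as.integer(m[, 5]), pident = as.numeric(m[, 6]),
                     nident = as.integer(m[, 7]), mismatch = as.integer(m[, 8]),
                     evalue = as.numeric(m[, 9]), qcov = as.numeric(m[, 10]),
                     gaps = as.integer(m[, 11]), stringsAsFactors = FALSE)
  validate_hits(hits, where = path)
}

#' Write similarity hits in the 11-column tabular layout
#'
#' Round-trips with [parse_hits_table()] (parse -> write -> parse is the
#' identity).
#'
#' @param hits A hits data.frame.
#' @param path Output path.
#' @param header Write the column-name header line (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_hits_table <- function(hits, path, header = TRUE) {
  hits <- hits[, HIT_COLUMNS, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines(paste(HIT_COLUMNS, collapse = "\t"), con)
  if (nrow(hits) > 0) {
    fmt <- vapply(seq_len(nrow(hits)), function(i) paste(
      hits$qseqid[i], hits$sseqid[i], hits$qlen[i], hits$length[i],
      hits$slen[i], format(hits$pident[i], scientific = FALSE, trim = TRUE),
      hits$nident[i], hits$mismatch[i],
      format(hits$evalue[i], digits = 6, trim = TRUE),
      format(hits$qcov[i], scientific = FALSE, trim = TRUE), hits$gaps[i],
      sep = "\t"), "")
    writeLines(fmt, con)
  }
  invisible(path)
}

#' Length-similarity ratio of a sequence pair
#'
#' `min(qlen, slen) / max(qlen, slen)`; symmetric in its arguments. A pair of
#' "similar length within 80%" has ratio >= 0.80.
#'
#' @param qlen,slen Positive lengths (vectorized).
#' @return Ratio(s) in (0, 1].
#' @export
length_ratio <- function(qlen, slen) {
  if (any(qlen <= 0 | slen <= 0)) stop("lengths must be positive")
  pmin(qlen, slen) / pmax(qlen, slen)
}

#' Cognate-filter criteria
#'
#' The cognate filter keeps a hit when query coverage exceeds `qcov_min`
#' (strictly, by default: "greater than 80%"), the two sequence lengths are
#' within `length_ratio_min` of each other (inclusive), and, if set,
#' percent identity reaches `pident_min` (inclusive). A second profile with
#' `qcov_strict = FALSE` (at least 80% coverage) suits secondary screening of
#' hits against an external nucleotide collection.
#'
#' @param qcov_min Query-coverage threshold in percent (default 80).
#' @param length_ratio_min Minimum min/max length ratio (default 0.80).
#' @param pident_min Optional percent-identity threshold (default unset;
#'   high identity is an observed consequence of the other two criteria, not
#'   a rule).
#' @param qcov_strict Strict (`>`) vs inclusive (`>=`) coverage comparison.
#' @return A `cognate_criteria` list.
#' @export
cognate_criteria <- function(qcov_min = 80, length_ratio_min = 0.80,
                             pident_min = NULL, qcov_strict = TRUE) {
  stopifnot(qcov_min >= 0, qcov_min <= 100,
            length_ratio_min > 0, length_ratio_min <= 1,
            is.null(pident_min) || (pident_min >= 0 && pident_min <= 100))
  structure(list(qcov_min = qcov_min, length_ratio_min = length_ratio_min,
                 pident_min = pident_min, qcov_strict = isTRUE(qcov_strict)),
            class = "cognate_criteria")
}

#' Does a hit qualify as a cognate link?
#'
#' Vectorized over the rows of `hits`. Self-hits (`qseqid == sseqid`) are
#' always `FALSE`.
#'
#' @param hits A hits data.frame.
#' @param criteria A [cognate_criteria()] object.
#' @return Logical vector, one element per hit.
#' @export
is_cognate_hit <- function(hits, criteria = cognate_criteria()) {
  if (nrow(hits) == 0) return(logical(0))
  cov_ok <- if (criteria$qcov_strict) hits$qcov > criteria$qcov_min
            else hits$qcov >= criteria$qcov_min
  len_ok <- length_ratio(hits$qlen, hits$slen) >= criteria$length_ratio_min
  pid_ok <- if (is.null(criteria$pident_min)) TRUE
            else hits$pident >= criteria$pident_min
  cov_ok & len_ok & pid_ok & hits$qseqid != hits$sseqid
}

blast_available <- function() {
  nzchar(Sys.which("blastn")) && nzchar(Sys.which("makeblastdb"))
}

all_vs_all_blast <- function(records, params) {
  if (!blast_available()) {
    stop("blastn/makeblastdb not found on PATH; use engine = \"exact\"")
  }
  dir <- tempfile("avablast")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  fa <- file.path(dir, "collection.fasta")
  write_plasmid_fasta(records, fa)
  db <- file.path(dir, "db")
  out <- file.path(dir, "hits.tsv")
  st <- system2("makeblastdb", c("-in", fa, "-dbtype", "nucl", "-out", db),
                stdout = FALSE, stderr = FALSE)
  if (st != 0) stop("makeblastdb failed")
  st <- system2("blastn", c(
    "-task", "blastn", "-query", fa, "-db", db,
    "-word_size", params$word_size, "-reward", params$match,
    "-penalty", -params$mismatch, "-gapopen", params$gap_open,
    "-gapextend", params$gap_extend, "-dust", "no", "-max_hsps", "1",
    "-max_target_seqs", max(10L, nrow(records) + 5L),
    "-outfmt", shQuote(paste("6", paste(sub("^qcov$", "qcovhsp", HIT_COLUMNS),
                                        collapse = " "))),
    "-out", out), stdout = FALSE, stderr = FALSE)
  if (st != 0) stop("blastn failed")
  hits <- if (file.size(out) > 0) {
    h <- read.delim(out, header = FALSE, col.names = HIT_COLUMNS,
                    stringsAsFactors = FALSE)
    h[h$qseqid != h$sseqid, , drop = FALSE]
  } else empty_hits()
  rownames(hits) <- NULL
  hits
}

#' All-vs-all pairwise similarity search
#'
#' For every ordered pair of distinct records, reports at most one hit (the
#' best HSP). Two engines are available: `"exact"` runs the full
#' dynamic-programming aligner of [align_pair()] on every pair (quadratic in
#' both collection and sequence size; intended for modest inputs and as the
#' reference), while `"blast"` shells out to the standard `blastn` search
#' tool with the same scoring parameters and one HSP per pair — the
#' practitioner's choice for collection-scale databases. `"auto"` picks blast
#' when it is installed and the total alignment work is large.
#'
#' @param records A `plasmid_set`, internally deduplicated.
#' @param params An [alignment_params()] object.
#' @param engine `"auto"`, `"exact"` or `"blast"`.
#' @return A hits data.frame (11 canonical columns), ordered by query then
#'   subject accession.
#' @export
all_vs_all <- function(records, params = alignment_params(),
                       engine = c("auto", "exact", "blast")) {
  engine <- match.arg(engine)
  stopifnot(!anyDuplicated(records$accession))
  n <- nrow(records)
  if (engine == "auto") {
    work <- (sum(as.double(records$length)))^2
    engine <- if (work > 1e13 && blast_available()) "blast" else "exact"
  }
  hits <- if (engine == "blast") {
    all_vs_all_blast(records, params)
  } else {
    if (n < 2) return(empty_hits())
    rows <- vector("list", n * (n - 1L))
    k <- 0L
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      res <- align_pair(records[i, ], records[j, ], params)
      if (!is.null(res)) { k <- k + 1L; rows[[k]] <- res }
    }
    if (k == 0) empty_hits() else do.call(rbind, rows[seq_len(k)])
  }
  hits <- hits[order(hits$qseqid, hits$sseqid), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
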