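#' Read a marker reference set from FASTA
#'
#' Headers follow the convention `marker_id|type_label description`; when no
#' `|` is present the marker id doubles as its type label (the incompatibility
#' group or MOB family the marker diagnoses).
#'
#' @param path FASTA path.
#' @param scheme `"rep"` (replicon) or `"mob"` (relaxase) typing scheme.
#' @return A `marker_set` data.frame with `marker_id`, `type_label`,
#'   `sequence`, `length`, `scheme`.
#' @export
read_marker_fasta <- function(path, scheme = c("rep", "mob")) {
  scheme <- match.arg(scheme)
  seqs <- Biostrings::readBStringSet(path)
  header <- sub("\\s.*$", "", names(seqs))
  marker_id <- sub("\\|.*$", "", header)
  type_label <- ifelse(grepl("|", header, fixed = TRUE),
                       sub("^[^|]*\\|", "", header), header)
  marker_set(marker_id, type_label, toupper(as.character(seqs)), scheme)
}

#' Construct a marker reference set in memory
#'
#' @param marker_id,type_label,sequence Parallel character vectors.
#' @param scheme `"rep"` or `"mob"`.
#' @return A `marker_set` data.frame.
#' @export
marker_set <- function(marker_id, type_label, sequence, scheme = c("rep", "mob")) {
  scheme <- match.arg(scheme)
  stopifnot(all(nzchar(sequence)), !anyDuplicated(marker_id))
  out <- data.frame(marker_id = marker_id, type_label = type_label,
                    sequence = toupper(sequence), length = nchar(sequence),
                    scheme = scheme, stringsAsFactors = FALSE)
  class(out) <- c("marker_set", "data.frame")
  out
}

#' Typing thresholds
#'
#' Inclusive cutoffs on the best marker hit: percent identity and coverage of
#' the *marker* sequence (the replicon/relaxase reference gene), following the
#' replicon-typing convention that the short reference gene — not the long
#' plasmid — must be covered. Defaults: 80% identity, 60% marker coverage.
#'
#' @param pident_min Percent-identity cutoff (inclusive).
#' @param cov_min Marker-coverage cutoff in percent (inclusive).
#' @return A `typing_criteria` list.
#' @export
typing_criteria <- function(pident_min = 80, cov_min = 60) {
  stopifnot(pident_min >= 0, pident_min <= 100, cov_min >= 0, cov_min <= 100)
  structure(list(pident_min = pident_min, cov_min = cov_min),
            class = "typing_criteria")
}

#' Type one plasmid against a marker reference set
#'
#' Each marker is aligned as the query against the plasmid; a hit qualifies
#' when `pident >= pident_min` and marker coverage (aligned marker span /
#' marker length) `>= cov_min`. The best qualifying hit wins, ranked by
#' `pident * coverage`, ties by higher `pident`, then lexicographic
#' `type_label` — giving a deterministic single label per plasmid, or
#' untyped (`NA`) when no hit qualifies.
#'
#' @param record One row of a `plasmid_set`.
#' @param refs A `marker_set` (all one scheme; empty set is an error).
#' @param criteria A [typing_criteria()] object.
#' @param params An [alignment_params()] object.
#' @return A one-row data.frame: `accession`, `scheme`, `type_label`
#'   (`NA` = untyped), `marker_id`, `pident`, `coverage`.
#' @export
type_plasmid <- function(record, refs, criteria = typing_criteria(),
                         params = alignment_params()) {
  if (nrow(refs) == 0) stop("empty marker reference set")
  if (length(unique(refs$scheme)) != 1L) stop("marker set mixes typing schemes")
  untyped <- data.frame(accession = record$accession[[1]], scheme = refs$scheme[1],
                        type_label = NA_character_, marker_id = NA_character_,
                        pident = NA_real_, coverage = NA_real_,
                        stringsAsFactors = FALSE)
  best <- NULL
  for (i in seq_len(nrow(refs))) {
    marker <- list(accession = refs$marker_id[i], sequence = refs$sequence[i])
    hit <- align_pair(marker, record, params)
    if (is.null(hit)) next
    coverage <- hit$qcov  # marker is the query
    if (hit$pident < criteria$pident_min || coverage < criteria$cov_min) next
    cand <- list(score = hit$pident * coverage, pident = hit$pident,
                 coverage = coverage, marker_id = refs$marker_id[i],
                 type_label = refs$type_label[i])
    if (is.null(best) ||
        cand$score > best$score ||
        (cand$score == best$score && cand$pident > best$pident) ||
        (cand$score == best$score && cand$pident == best$pident &&
         cand$type_label < best$type_label)) {
      best <- cand
    }
  }
  if (is.null(best)) return(untyped)
  data.frame(accession = record$accession[[1]], scheme = refs$scheme[1],
             type_label = best$type_label, marker_id = best$marker_id,
             pident = best$pident, coverage = best$coverage,
             stringsAsFactors = FALSE)
}

#' Type a plasmid collection under one or both schemes
#'
#' One replicon result and one MOB result per record (when the corresponding
#' reference set is supplied); output order follows the record order within
#' scheme and is independent of it in content.
#'
#' @param records A `plasmid_set`.
#' @param rep_refs,mob_refs `marker_set`s (either may be `NULL`).
#' @param criteria_rep,criteria_mob Per-scheme [typing_criteria()].
#' @param params An [alignment_params()] object.
#' @return A data.frame of typing results (possibly zero rows).
#' @export
type_collection <- function(records, rep_refs = NULL, mob_refs = NULL,
                            criteria_rep = typing_criteria(),
                            criteria_mob = typing_criteria(),
                            params = alignment_params()) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    if (!is.null(rep_refs)) {
      out[[length(out) + 1L]] <- type_plasmid(records[i, ], rep_refs,
                                              criteria_rep, params)
    }
    if (!is.null(mob_refs)) {
      out[[length(out) + 1L]] <- type_plasmid(records[i, ], mob_refs,
                                              criteria_mob, params)
    }
  }
  if (length(out) == 0) {
    return(data.frame(accession = character(), scheme = character(),
                      type_label = character(), marker_id = character(),
                      pident = numeric(), coverage = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write typing results as TSV
#'
#' Untyped plasmids are written with the literal label `untyped`.
#'
#' @param results From [type_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_typing_table <- function(results, path) {
  results$type_label[is.na(results$type_label)] <- "untyped"
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
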