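empty_lineage <- function(n = 1) {
  out <- data.frame(taxid = rep(NA_character_, n))
  for (r in RANKS) out[[r]] <- rep(NA_character_, n)
  out
}

#' Read a plasmid collection from a multi-FASTA file
#'
#' Each header is split into an accession (the first whitespace-delimited
#' token, `>` stripped) and a free-text title (the remainder). Sequences are
#' uppercased and characters outside `A/C/G/T/N` are replaced by `N` (the
#' replacement count is reported via a warning), so downstream alignment works
#' over a defined alphabet. Taxonomy columns are left unassigned until
#' [load_metadata()] is applied.
#'
#' @param path Path to a FASTA file.
#' @param source Provenance label for every record, one of
#'   `"plasmid_release"`, `"genome_extract"` or `"synthetic"`.
#' @return A `plasmid_set`: a data.frame with one row per record and columns
#'   `accession`, `title`, `sequence`, `length`, `source`, `taxid` and the six
#'   taxonomic ranks `species`..`phylum` (all `NA` until metadata is loaded).
#' @export
parse_plasmid_fasta <- function(path, source = c("plasmid_release", "genome_extract", "synthetic")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  sequence <- toupper(as.character(seqs))
  accession <- sub("\\s.*$", "", headers)
  title <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  empty <- nchar(sequence) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty sequence entr",
            if (sum(empty) == 1L) "y" else "ies", ": ",
            paste(accession[empty], collapse = ", "))
  }
  bad <- gsub("[ACGTN]", "", sequence)
  n_bad <- sum(nchar(bad))
  if (n_bad > 0) {
    warning(n_bad, " characters outside {A,C,G,T,N} replaced by N")
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  out <- data.frame(accession = accession, title = title, sequence = sequence,
                    length = nchar(sequence),
                    source = rep_len(source, length(accession)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, empty_lineage(nrow(out)))
  out <- out[!empty, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("plasmid_set", "data.frame")
  out
}

#' Construct a plasmid set from in-memory vectors
#'
#' Convenience constructor used by the synthetic generator and tests; applies
#' the same alphabet normalization as [parse_plasmid_fasta()].
#'
#' @param accession,sequence Character vectors of equal length.
#' @param title Optional titles (defaults to empty strings).
#' @param source Provenance label (see [parse_plasmid_fasta()]).
#' @return A `plasmid_set` data.frame.
#' @export
plasmid_set <- function(accession, sequence, title = "",
                        source = c("synthetic", "plasmid_release", "genome_extract")) {
  source <- match.arg(source)
  sequence <- gsub("[^ACGTN]", "N", toupper(sequence))
  out <- data.frame(accession = accession, title = rep_len(title, length(accession)),
                    sequence = sequence, length = nchar(sequence),
                    source = rep_len(source, length(accession)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, empty_lineage(nrow(out)))
  class(out) <- c("plasmid_set", "data.frame")
  out
}

#' Write a plasmid set to multi-FASTA
#'
#' Headers are `accession title`; sequence lines wrap at 60 columns.
#'
#' @param records A `plasmid_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plasmid_fasta <- function(records, path) {
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- ifelse(nzchar(records$title),
                     paste(records$accession, records$title),
                     records$accession)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Attach taxonomy metadata to plasmid records
#'
#' Joins a tab-separated metadata table onto the records by versioned
#' accession. Records without a metadata row keep an all-missing lineage and
#' are reported in a message. An optional logical `assembly_complete` column
#' is carried through for use by [screen_titles()].
#'
#' @param records A `plasmid_set`.
#' @param table Path to a TSV with header columns `accession`, `taxid`,
#'   `species`, `genus`, `family`, `order`, `class`, `phylum` (extra columns
#'   ignored), or an equivalent data.frame.
#' @return The records with lineage columns populated.
#' @export
load_metadata <- function(records, table) {
  meta <- if (is.data.frame(table)) table else
    read.delim(table, stringsAsFactors = FALSE, colClasses = "character",
               check.names = FALSE)
  if (!"accession" %in% names(meta)) stop("metadata table lacks an 'accession' column")
  dup <- meta$accession[duplicated(meta$accession)]
  if (length(dup) > 0) {
    stop("duplicate accession rows in metadata table: ",
         paste(unique(dup), collapse = ", "))
  }
  idx <- match(records$accession, meta$accession)
  unmatched <- records$accession[is.na(idx)]
  if (length(unmatched) > 0) {
    message(length(unmatched), " record(s) without metadata keep an unassigned lineage: ",
            paste(utils::head(unmatched, 5), collapse = ", "),
            if (length(unmatched) > 5) ", ..." else "")
  }
  for (col in c("taxid", RANKS)) {
    if (col %in% names(meta)) {
      v <- trimws(meta[[col]][idx])
      v[!is.na(v) & !nzchar(v)] <- NA_character_
      records[[col]] <- v
    }
  }
  if ("assembly_complete" %in% names(meta)) {
    records$assembly_complete <- as.logical(meta$assembly_complete[idx])
  }
  records
}

#' Default title-screening rule set
#'
#' Case-insensitive keyword lists marking records whose titles indicate a
#' partial plasmid or a single gene, and records describing phages. The
#' defaults are a starting point; the categories matter, the exact keyword
#' lists are configurable.
#'
#' @param partial_keywords Keywords marking partial/gene-only entries.
#' @param phage_keywords Keywords marking phage entries.
#' @return A `screening_rules` list.
#' @export
screening_rules <- function(partial_keywords = c("partial", " gene,", " gene "),
                            phage_keywords = c("phage", "bacteriophage")) {
  structure(list(partial_keywords = partial_keywords,
                 phage_keywords = phage_keywords),
            class = "screening_rules")
}

new_screen_report <- function(n_input) {
  list(n_input = n_input, n_kept = 0L, n_dropped_partial = 0L,
       n_dropped_incomplete_assembly = 0L, n_dropped_phage = 0L,
       n_dropped_duplicate = 0L,
       dropped = data.frame(accession = character(), reason = character(),
                            stringsAsFactors = FALSE))
}

title_matches <- function(titles, keywords) {
  if (length(keywords) == 0) return(rep(FALSE, length(titles)))
  pat <- paste(vapply(keywords, function(k)
    gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", k), ""), collapse = "|")
  grepl(pat, titles, ignore.case = TRUE)
}

#' Screen plasmid records for complete, non-phage entries
#'
#' Applies the completeness screen: records whose titles indicate a partial
#' plasmid or a lone gene are dropped (reason `"partial"`); records described
#' as phages are dropped (reason `"phage"`); if an `assembly_complete` column
#' is present, records flagged `FALSE` are dropped (reason
#' `"incomplete_assembly"`). Screening is total (never errors) and idempotent.
#'
#' @param records A `plasmid_set`.
#' @param rules A [screening_rules()] object.
#' @return A list with `kept` (the surviving `plasmid_set`) and `report`
#'   (screen counters plus a per-accession drop table; counters always sum to
#'   the input size).
#' @export
screen_titles <- function(records, rules = screening_rules()) {
  report <- new_screen_report(nrow(records))
  drop_partial <- title_matches(records$title, rules$partial_keywords)
  drop_phage <- !drop_partial & title_matches(records$title, rules$phage_keywords)
  drop_asm <- rep(FALSE, nrow(records))
  if ("assembly_complete" %in% names(records)) {
    drop_asm <- !drop_partial & !drop_phage &
      !is.na(records$assembly_complete) & !records$assembly_complete
  }
  reason <- rep(NA_character_, nrow(records))
  reason[drop_partial] <- "partial"
  reason[drop_phage] <- "phage"
  reason[drop_asm] <- "incomplete_assembly"
  keep <- is.na(reason)
  report$n_kept <- sum(keep)
  report$n_dropped_partial <- sum(drop_partial)
  report$n_dropped_phage <- sum(drop_phage)
  report$n_dropped_incomplete_assembly <- sum(drop_asm)
  report$dropped <- data.frame(accession = records$accession[!keep],
                               reason = reason[!keep], stringsAsFactors = FALSE)
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, report = report)
}

#' Merge two plasmid sources without duplicates
#'
#' Union keyed on the full versioned accession. When both sources contain an
#' accession the primary-source record is kept and the secondary copy is
#' counted as a duplicate; a duplicate whose sequence differs from the
#' primary copy is additionally reported as a conflict.
#'
#' @param primary,secondary `plasmid_set` objects, each internally
#'   deduplicated.
#' @return A list with `merged` (primary records followed by
#'   secondary-only records) and `report` (a screen report whose
#'   `n_dropped_duplicate` counts secondary records discarded; `n_input` is
#'   the total over both sources).
#' @export
merge_sources <- function(primary, secondary) {
  stopifnot(!anyDuplicated(primary$accession), !anyDuplicated(secondary$accession))
  dup <- secondary$accession %in% primary$accession
  if (any(dup)) {
    pseq <- setNames(primary$sequence, primary$accession)
    conflict <- secondary$accession[dup][secondary$sequence[dup] !=
                                           pseq[secondary$accession[dup]]]
    if (length(conflict) > 0) {
      warning("accession(s) present in both sources with different sequence; ",
              "primary copy kept: ", paste(conflict, collapse = ", "))
    }
  }
  merged <- rbind(primary, secondary[!dup, , drop = FALSE])
  rownames(merged) <- NULL
  class(merged) <- c("plasmid_set", "data.frame")
  report <- new_screen_report(nrow(primary) + nrow(secondary))
  report$n_kept <- nrow(merged)
  report$n_dropped_duplicate <- sum(dup)
  report$dropped <- data.frame(accession = secondary$accession[dup],
                               reason = rep("duplicate", sum(dup)),
                               stringsAsFactors = FALSE)
  list(merged = merged, report = report)
}

#' Serialize a screen report as JSON
#'
#' @param report A report from [screen_titles()] or [merge_sources()].
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_screen_report <- function(report, path = NULL) {
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
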