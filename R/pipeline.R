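#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the contingency table in closed form. When the correction
#' denominator is zero (e.g. both partitions all-singletons, or a single
#' item) the partitions are identical up to relabeling and the index is
#' defined as 1.
#'
#' @param a,b Equal-length label vectors.
#' @return A number <= 1 (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n <= 1) return(1.0)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1.0)
  (sum_ij - expected) / denom
}

#' Score recovery of planted cognate groups
#'
#' Compares the recovered grouping against the generator's ground truth.
#' Decoys form singleton classes of their own in the planted partition.
#'
#' @param groups Groups from [cognate_components()] (classification optional).
#' @param truth Truth table from [generate_dataset()] (`accession`,
#'   `group_id` with `"decoy"` for decoys).
#' @return A list: `ari` (adjusted Rand index), `exact` (`TRUE` when the
#'   partitions coincide), `n_recovered_groups` / `n_planted_groups`
#'   (multi-member only), and `confusion` (recovered group vs planted group
#'   contingency table, multi-member recovered groups only).
#' @export
evaluate_recovery <- function(groups, truth) {
  rec <- data.frame(accession = unlist(groups$members),
                    recovered = rep(groups$group_id, groups$n_members),
                    stringsAsFactors = FALSE)
  if (!setequal(rec$accession, truth$accession) ||
      nrow(rec) != nrow(truth)) {
    stop("recovered groups and truth table cover different accession sets")
  }
  idx <- match(rec$accession, truth$accession)
  planted <- truth$group_id[idx]
  planted[planted == "decoy"] <- paste0("decoy_", rec$accession[planted == "decoy"])
  ari <- adjusted_rand_index(rec$recovered, planted)
  exact <- isTRUE(all.equal(ari, 1.0, tolerance = 1e-12)) &&
    length(unique(rec$recovered)) == length(unique(planted))
  multi <- groups$n_members > 1L
  truth_counts <- table(truth$group_id[truth$group_id != "decoy"])
  conf <- table(recovered = rec$recovered, planted = planted)
  conf <- conf[rownames(conf) %in% groups$group_id[multi], , drop = FALSE]
  conf <- conf[, colSums(conf) > 0, drop = FALSE]
  list(ari = ari, exact = exact,
       n_recovered_groups = sum(multi),
       n_planted_groups = sum(truth_counts > 1),
       confusion = conf)
}

#' Tally coding-sequence functional categories
#'
#' Counts single-letter functional (COG) category assignments per plasmid and
#' converts them to percentages. Missing or empty categories are mapped to
#' `"S"` (unknown function). Malformed rows (missing accession or cds id) are
#' skipped and counted in a warning.
#'
#' @param annotations A data.frame (or TSV path) with columns `accession`,
#'   `cds_id`, `category`.
#' @return A data.frame with `accession`, `category`, `count`, `percent`;
#'   per-accession percentages sum to 100 (up to rounding to one decimal).
#'   Plasmids absent from the table simply yield no rows.
#' @export
tally_categories <- function(annotations) {
  ann <- if (is.data.frame(annotations)) annotations else
    read.delim(annotations, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(ann) == 0) {
    return(data.frame(accession = character(), category = character(),
                      count = integer(), percent = numeric(),
                      stringsAsFactors = FALSE))
  }
  bad <- is.na(ann$accession) | !nzchar(ann$accession) |
    is.na(ann$cds_id) | !nzchar(ann$cds_id)
  if (any(bad)) {
    warning(sum(bad), " malformed annotation row(s) skipped")
    ann <- ann[!bad, , drop = FALSE]
  }
  ann$category[is.na(ann$category) | !nzchar(ann$category)] <- "S"
  ann$category <- substr(trimws(ann$category), 1L, 1L)
  tab <- as.data.frame(table(accession = ann$accession, category = ann$category),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  names(tab)[3] <- "count"
  totals <- tapply(tab$count, tab$accession, sum)
  tab$percent <- round(100 * tab$count / as.numeric(totals[tab$accession]), 1)
  tab <- tab[order(tab$accession, tab$category), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Run the full cognate / host-range pipeline
#'
#' Screen -> similarity (computed or imported) -> cognate filter -> network
#' components -> host-range classification -> optional typing and functional
#' tallies -> summary. Exactly one of "compute alignments" and "import a hits
#' table" is active: supply `hits` (a data.frame or TSV path) to import.
#' All artifacts are written under `out_dir` with fixed names (`hits.tsv`,
#' `edges.tsv`, `groups.tsv`, `typing.tsv`, `summary.json`, and
#' `truth_eval.json` when a truth table is given).
#'
#' @param records A `plasmid_set` (lineages loaded) or FASTA path.
#' @param metadata Metadata TSV path or data.frame (required when `records`
#'   is a path; ignored when lineages are already attached).
#' @param hits Optional precomputed hits (data.frame or 11-column TSV path);
#'   when `NULL` alignments are computed.
#' @param rep_refs,mob_refs Optional `marker_set`s (or FASTA paths).
#' @param truth Optional truth table for recovery scoring.
#' @param criteria A [cognate_criteria()] object.
#' @param criteria_rep,criteria_mob Per-scheme [typing_criteria()].
#' @param params An [alignment_params()] object.
#' @param engine Alignment engine for [all_vs_all()].
#' @param rules A [screening_rules()] object.
#' @param out_dir Optional output directory for artifacts.
#' @param annotations Optional coding-sequence annotation table (or path) for
#'   [tally_categories()].
#' @param verbose Emit per-stage record counts via `message()`.
#' @return A list: `records` (screened), `screen_report`, `hits`, `graph`,
#'   `groups` (classified), `summary`, and, when applicable, `typing`,
#'   `tallies`, `recovery`.
#' @export
run_pipeline <- function(records, metadata = NULL, hits = NULL,
                         rep_refs = NULL, mob_refs = NULL, truth = NULL,
                         criteria = cognate_criteria(),
                         criteria_rep = typing_criteria(),
                         criteria_mob = typing_criteria(),
                         params = alignment_params(),
                         engine = c("auto", "exact", "blast"),
                         rules = screening_rules(),
                         out_dir = NULL, annotations = NULL, verbose = FALSE) {
  engine <- match.arg(engine)
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(records)) records <- parse_plasmid_fasta(records)
  if (!is.null(metadata)) records <- load_metadata(records, metadata)
  say("input: %d records", nrow(records))

  scr <- screen_titles(records, rules)
  records <- scr$kept
  say("screened: %d kept, %d dropped", scr$report$n_kept,
      scr$report$n_input - scr$report$n_kept)

  if (is.character(rep_refs)) rep_refs <- read_marker_fasta(rep_refs, "rep")
  if (is.character(mob_refs)) mob_refs <- read_marker_fasta(mob_refs, "mob")

  if (is.null(hits)) {
    hits <- all_vs_all(records, params, engine)
  } else {
    if (is.character(hits)) hits <- parse_hits_table(hits)
    unknown <- setdiff(unique(c(hits$qseqid, hits$sseqid)), records$accession)
    if (length(unknown) > 0) {
      stop("imported hits reference accession(s) outside the screened set: ",
           paste(unknown, collapse = ", "))
    }
  }
  say("similarity: %d hits, %d passing the cognate filter", nrow(hits),
      sum(is_cognate_hit(hits, criteria)))

  graph <- build_cognate_graph(records, hits, criteria)
  groups <- cognate_components(graph)
  groups <- classify_groups(groups, records)
  summary <- summarize_groups(groups)
  say("network: %d plasmids with cognates in %d groups, %d singletons",
      summary$n_with_cognates, summary$n_groups, summary$n_without_cognates)

  out <- list(records = records, screen_report = scr$report, hits = hits,
              graph = graph, groups = groups, summary = summary)

  if (!is.null(rep_refs) || !is.null(mob_refs)) {
    out$typing <- type_collection(records, rep_refs, mob_refs,
                                  criteria_rep, criteria_mob, params)
    say("typing: %d of %d results typed", sum(!is.na(out$typing$type_label)),
        nrow(out$typing))
  }
  if (!is.null(annotations)) out$tallies <- tally_categories(annotations)
  if (!is.null(truth)) out$recovery <- evaluate_recovery(groups, truth)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_hits_table(hits, file.path(out_dir, "hits.tsv"))
    export_network(graph, groups, file.path(out_dir, "edges.tsv"),
                   file.path(out_dir, "groups.tsv"))
    if (!is.null(out$typing)) {
      write_typing_table(out$typing, file.path(out_dir, "typing.tsv"))
    }
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
               file.path(out_dir, "summary.json"))
    if (!is.null(out$recovery)) {
      rec <- out$recovery[c("ari", "exact", "n_recovered_groups", "n_planted_groups")]
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, pretty = TRUE,
                                  digits = NA),
                 file.path(out_dir, "truth_eval.json"))
    }
  }
  out
}
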