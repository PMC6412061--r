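#' Build the cognate network
#'
#' Every record becomes a vertex (isolates included); an undirected edge
#' `{q, s}` is added when at least one direction's hit passes the cognate
#' filter (or both directions, under the stricter reciprocal rule).
#'
#' @param records A `plasmid_set`.
#' @param hits A hits data.frame; hits referencing accessions absent from
#'   `records` raise an error naming them.
#' @param criteria A [cognate_criteria()] object.
#' @param reciprocal Require both directions to pass before drawing the edge
#'   (default `FALSE`: coverage is asymmetric for unequal lengths and a
#'   qualifying hit in either direction suffices).
#' @return An undirected [igraph::graph] with vertex names set to accessions.
#' @export
build_cognate_graph <- function(records, hits, criteria = cognate_criteria(),
                                reciprocal = FALSE) {
  accs <- records$accession
  unknown <- setdiff(unique(c(hits$qseqid, hits$sseqid)), accs)
  if (length(unknown) > 0) {
    stop("hit(s) reference accession(s) not in the record set: ",
         paste(unknown, collapse = ", "))
  }
  pass <- hits[is_cognate_hit(hits, criteria), c("qseqid", "sseqid"), drop = FALSE]
  if (nrow(pass) > 0) {
    a <- pmin(pass$qseqid, pass$sseqid)
    b <- pmax(pass$qseqid, pass$sseqid)
    key <- paste(a, b, sep = "\r")
    if (reciprocal) {
      dirkey <- paste(pass$qseqid, pass$sseqid, sep = "\r")
      tab <- table(key[!duplicated(dirkey)])
      keep <- names(tab)[tab >= 2L]
      sel <- match(keep, key)
    } else {
      sel <- which(!duplicated(key))
    }
    edges <- cbind(a[sel], b[sel])
  } else {
    edges <- matrix(character(0), ncol = 2)
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(accs), name = accs)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  g
}

#' Extract cognate groups as connected components
#'
#' Partitions the vertex set; singleton components are plasmids with no
#' cognates. Groups are ordered (and identified) by their smallest member
#' accession, so the output is deterministic.
#'
#' @param graph A graph from [build_cognate_graph()].
#' @return A data.frame with one row per group: `group_id` (`G0001`, ... in
#'   order of smallest member accession), `n_members`, and a list-column
#'   `members` of sorted accession vectors.
#' @export
cognate_components <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) {
    return(data.frame(group_id = character(), n_members = integer(),
                      members = I(list()), stringsAsFactors = FALSE))
  }
  comp <- igraph::components(graph)
  members <- split(igraph::V(graph)$name, comp$membership)
  members <- lapply(members, function(x) sort(x))
  members <- members[order(vapply(members, `[`, "", 1L))]
  data.frame(group_id = sprintf("G%04d", seq_along(members)),
             n_members = lengths(members), members = I(unname(members)),
             stringsAsFactors = FALSE)
}

normalize_taxon <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  x
}

#' Classify the host range of one cognate group
#'
#' A singleton group is `"singleton"`. Otherwise the class is `inter_R`
#' where R is the broadest rank (species < genus < family < order < class <
#' phylum) at which at least two members carry *different assigned* taxon
#' names; missing ranks never count as differing. If all assigned names agree
#' at every rank the group is `"intra_species"`; if no rank has two or more
#' assigned names the group is `"unclassifiable"`. Taxon names are compared
#' by string equality after whitespace normalization.
#'
#' @param members Character vector of member accessions.
#' @param lineages A data.frame with an `accession` column and the six rank
#'   columns (`species`..`phylum`), e.g. a `plasmid_set` after
#'   [load_metadata()].
#' @return A single host-range class string (one of
#'   `r paste(HOST_RANGE_LEVELS, collapse = ", ")`).
#' @export
classify_host_range <- function(members, lineages) {
  idx <- match(members, lineages$accession)
  if (anyNA(idx)) {
    stop("no lineage entry for member(s): ",
         paste(members[is.na(idx)], collapse = ", "))
  }
  if (length(members) == 1L) return("singleton")
  any_comparable <- FALSE
  for (rank in RANKS_BROAD_FIRST) {
    names_at_rank <- normalize_taxon(lineages[[rank]][idx])
    assigned <- names_at_rank[!is.na(names_at_rank)]
    if (length(assigned) >= 2L) {
      any_comparable <- TRUE
      if (length(unique(assigned)) >= 2L) return(paste0("inter_", sub("^class$", "class", rank)))
    }
  }
  if (any_comparable) "intra_species" else "unclassifiable"
}

#' Classify every cognate group
#'
#' @param groups Output of [cognate_components()].
#' @param lineages Lineage table (see [classify_host_range()]).
#' @return `groups` with a `host_range` column and per-rank taxon-set
#'   list-columns (`species_seen`, ..., `phylum_seen`).
#' @export
classify_groups <- function(groups, lineages) {
  groups$host_range <- vapply(groups$members, classify_host_range, "",
                              lineages = lineages)
  for (rank in RANKS) {
    groups[[paste0(rank, "_seen")]] <- I(lapply(groups$members, function(mm) {
      v <- normalize_taxon(lineages[[rank]][match(mm, lineages$accession)])
      sort(unique(v[!is.na(v)]))
    }))
  }
  groups
}

host_range_at_least <- function(host_range, level) {
  ord <- match(host_range, HOST_RANGE_LEVELS)
  ref <- match(level, HOST_RANGE_LEVELS)
  !is.na(ord) & host_range != "unclassifiable" & ord >= ref
}

#' Summarize cognate groups and host-range counts
#'
#' Produces the funnel and nested counts for a classified grouping: total
#' plasmids, how many have cognates (belong to a multi-member group) versus
#' none, the number of multi-member groups, and *cumulative* counts of groups
#' at or broader than each host-range class ("different species" includes
#' every group spanning different genera, families, and so on, so the counts
#' are nested: species >= genera >= families >= ...).
#'
#' @param groups Classified groups from [classify_groups()].
#' @return A list of counts (see Details), serializable as JSON.
#' @export
summarize_groups <- function(groups) {
  multi <- groups$n_members > 1L
  list(
    n_plasmids = sum(groups$n_members),
    n_with_cognates = sum(groups$n_members[multi]),
    n_without_cognates = sum(!multi),
    n_groups = sum(multi),
    n_groups_diff_species = sum(host_range_at_least(groups$host_range, "inter_species")),
    n_groups_diff_genera = sum(host_range_at_least(groups$host_range, "inter_genus")),
    n_groups_diff_families = sum(host_range_at_least(groups$host_range, "inter_family")),
    n_groups_diff_orders = sum(host_range_at_least(groups$host_range, "inter_order")),
    n_groups_diff_classes = sum(host_range_at_least(groups$host_range, "inter_class")),
    n_groups_diff_phyla = sum(host_range_at_least(groups$host_range, "inter_phylum")),
    n_groups_unclassifiable = sum(groups$host_range == "unclassifiable")
  )
}

#' Export the cognate network and groups as TSV
#'
#' @param graph Graph from [build_cognate_graph()].
#' @param groups Classified groups.
#' @param edges_path,groups_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a list of the paths written.
#' @export
export_network <- function(graph, groups, edges_path = NULL, groups_path = NULL) {
  if (!is.null(edges_path)) {
    el <- igraph::as_edgelist(graph)
    write.table(data.frame(a = el[, 1], b = el[, 2]), edges_path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = c("accession_a", "accession_b"))
  }
  if (!is.null(groups_path)) {
    flat <- data.frame(
      group_id = groups$group_id, n_members = groups$n_members,
      host_range = if ("host_range" %in% names(groups)) groups$host_range else NA,
      members = vapply(groups$members, paste, "", collapse = ","),
      stringsAsFactors = FALSE)
    for (rank in RANKS) {
      col <- paste0(rank, "_seen")
      if (col %in% names(groups)) {
        flat[[col]] <- vapply(groups[[col]], paste, "", collapse = ",")
      }
    }
    write.table(flat, groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(edges = edges_path, groups = groups_path))
}
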