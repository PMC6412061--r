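#' Curated broad-host-range candidate plasmid groups
#'
#' Ships with the package: the ten published candidate cognate-plasmid
#' groups whose members were recovered from bacterial isolates of different
#' families, encoded as their NCBI accessions with the species, family and
#' phylum assignments as reported (genus, order and class are not reported
#' and stay unassigned). Useful as a small real-world input for the
#' host-range classifier.
#'
#' @return A list: `groups` (a membership data.frame in the
#'   [cognate_components()] layout, `group_id` = published plasmid-group
#'   name) and `lineages` (accession-keyed lineage table).
#' @export
bhr_candidate_groups <- function() {
  path <- system.file("extdata", "bhr_candidate_groups.tsv",
                      package = "plasmidrange", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("taxid", RANKS)) tab[[col]][!nzchar(tab[[col]])] <- NA_character_
  members <- split(tab$accession, tab$group_id)
  members <- members[unique(tab$group_id)]  # keep file order
  groups <- data.frame(group_id = names(members),
                       n_members = lengths(members),
                       members = I(unname(lapply(members, sort))),
                       stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  list(groups = groups, lineages = tab[, c("accession", "taxid", RANKS)])
}
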