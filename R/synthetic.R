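#' Configuration for the synthetic plasmid population generator
#'
#' The defaults describe the benchmark population used throughout the
#' package's validation: 20 planted cognate groups of 4 members each, drawn
#' from random 20–40 kb ancestors, members diverged by 3% per-site
#' substitutions with no indels or truncation, plus 150 unrelated decoy
#' sequences — a population in which the cognate filter (coverage > 80%,
#' length ratio >= 0.80) should recover the planted partition exactly.
#'
#' @param seed Integer RNG seed; every generated byte is a deterministic
#'   function of the config including this seed.
#' @param n_groups Number of planted cognate groups.
#' @param members_per_group Length-2 integer range (inclusive) of members per
#'   group.
#' @param ancestor_length Length-2 range of ancestor lengths in bases.
#' @param substitution_rate Per-site substitution probability (to one of the
#'   three other bases, uniformly).
#' @param indel_rate Per-site probability of starting an indel.
#' @param indel_length_mean Mean indel length (geometric lengths >= 1).
#' @param truncation_fraction Fraction of the sequence removed (as a
#'   contiguous suffix, mimicking an incomplete assembly) from truncated
#'   members.
#' @param truncate_members Number of members per group to truncate (0 = none).
#' @param n_decoys Number of unrelated decoy sequences, length-matched to the
#'   ancestor range.
#' @param taxonomy_spec Character vector of target host-range classes, one
#'   per group (recycled); each group's lineages are constructed to realize
#'   its target class exactly. Default cycles through all classes from
#'   intra-species to inter-phylum.
#' @param marker_spec Optional data.frame with columns `type_label`,
#'   `length`, `carrier_fraction`, `scheme` describing typing markers to
#'   embed verbatim in randomly chosen records.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_groups = 20L,
                             members_per_group = c(4L, 4L),
                             ancestor_length = c(20000L, 40000L),
                             substitution_rate = 0.03, indel_rate = 0,
                             indel_length_mean = 3,
                             truncation_fraction = 0, truncate_members = 0L,
                             n_decoys = 150L,
                             taxonomy_spec = NULL, marker_spec = NULL) {
  if (length(members_per_group) == 1L) members_per_group <- rep(members_per_group, 2)
  if (length(ancestor_length) == 1L) ancestor_length <- rep(ancestor_length, 2)
  stopifnot(substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1,
            truncation_fraction >= 0, truncation_fraction < 1,
            members_per_group[1] <= members_per_group[2],
            ancestor_length[1] <= ancestor_length[2], ancestor_length[1] >= 1,
            n_groups >= 0, n_decoys >= 0, indel_length_mean > 0)
  if (is.null(taxonomy_spec)) {
    taxonomy_spec <- rep(c("intra_species", "inter_species", "inter_genus",
                           "inter_family", "inter_order", "inter_class",
                           "inter_phylum"), length.out = max(1L, n_groups))
  }
  stopifnot(all(taxonomy_spec %in% HOST_RANGE_LEVELS))
  structure(list(seed = as.integer(seed), n_groups = as.integer(n_groups),
                 members_per_group = as.integer(members_per_group),
                 ancestor_length = as.integer(ancestor_length),
                 substitution_rate = substitution_rate, indel_rate = indel_rate,
                 indel_length_mean = indel_length_mean,
                 truncation_fraction = truncation_fraction,
                 truncate_members = as.integer(truncate_members),
                 n_decoys = as.integer(n_decoys),
                 taxonomy_spec = rep(taxonomy_spec, length.out = max(1L, n_groups)),
                 marker_spec = marker_spec),
            class = "synthetic_config")
}

random_sequence <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# uniform draw from an inclusive integer range; safe for degenerate ranges
# (base sample() would treat a scalar as 1:x)
sample_range <- function(lo, hi, n = 1L) {
  if (lo == hi) rep.int(lo, n) else sample(seq.int(lo, hi), n, replace = TRUE)
}

#' Mutate a sequence under a substitution + indel model
#'
#' Substitutions hit each site independently and always change the base
#' (uniform over the three alternatives). Indels start at each site
#' independently with `indel_rate`; each is an insertion or deletion with
#' equal probability and has geometric length with the given mean.
#' Deterministic given the R RNG state (seed it with [set.seed()] before
#' calling).
#'
#' @param seq A nucleotide string.
#' @param substitution_rate,indel_rate Per-site rates in \[0, 1).
#' @param indel_length_mean Mean indel length (>= 1).
#' @return The mutated sequence string.
#' @export
mutate_sequence <- function(seq, substitution_rate, indel_rate = 0,
                            indel_length_mean = 3) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0) return(seq)
  if (substitution_rate > 0) {
    hit <- which(stats::runif(n) < substitution_rate)
    if (length(hit) > 0) {
      # draw a uniform alternative base != current
      cur <- match(chars[hit], BASES)
      shift <- sample.int(3L, length(hit), replace = TRUE)
      idx <- ((ifelse(is.na(cur), sample.int(4L, length(hit), replace = TRUE), cur) - 1L +
                 shift) %% 4L) + 1L
      chars[hit] <- BASES[idx]
    }
  }
  if (indel_rate > 0) {
    sites <- which(stats::runif(n) < indel_rate)
    if (length(sites) > 0) {
      is_ins <- stats::runif(length(sites)) < 0.5
      p <- min(1, 1 / indel_length_mean)
      lens <- stats::rgeom(length(sites), p) + 1L
      pieces <- as.list(chars)
      for (k in seq_along(sites)) {
        s <- sites[k]
        if (is_ins[k]) {
          pieces[[s]] <- c(chars[s], sample(BASES, lens[k], replace = TRUE))
        } else {
          del_to <- min(n, s + lens[k] - 1L)
          for (d in s:del_to) pieces[[d]] <- character(0)
        }
      }
      chars <- unlist(pieces)
    }
  }
  paste(chars, collapse = "")
}

# Lineages realizing a target host-range class for one group: ranks broader
# than the target rank are shared, the target rank carries >= 2 distinct
# names, narrower ranks follow nested naming (so they differ whenever any
# broader rank differs, as in real taxonomy).
group_lineages <- function(group_index, n_members, target) {
  gid <- sprintf("g%02d", group_index)
  target_rank <- switch(target,
    intra_species = NA_character_, singleton = NA_character_,
    unclassifiable = "unclassifiable",
    sub("^inter_", "", target))
  ranks_narrow_first <- RANKS  # species .. phylum
  out <- empty_lineage(n_members)
  out$taxid <- sprintf("tax_%s_m%02d", gid, seq_len(n_members))
  if (identical(target_rank, "unclassifiable")) return(out)  # all ranks missing
  target_pos <- if (is.na(target_rank)) 0L else match(target_rank, ranks_narrow_first)
  for (r in seq_along(ranks_narrow_first)) {
    rank <- ranks_narrow_first[r]
    if (r > target_pos) {
      # broader than (or no) target: shared name
      out[[rank]] <- sprintf("%s_%s_shared", rank, gid)
    } else {
      # at or below the target rank: alternate between two clades so the
      # broadest differing rank is exactly the target
      clade <- (seq_len(n_members) - 1L) %% 2L + 1L
      out[[rank]] <- sprintf("%s_%s_c%d", rank, gid, clade)
    }
  }
  out
}

#' Build the taxonomy plan for a synthetic config
#'
#' Constructs one lineage per planned record so that running
#' [classify_host_range()] on each planted group returns exactly its target
#' class; decoys get unique lineages of their own.
#'
#' @param config A [synthetic_config()].
#' @param members Integer vector of member counts per group (as drawn by
#'   [generate_dataset()]).
#' @return A data.frame of accession, taxid and the six ranks.
#' @export
generate_taxonomy <- function(config, members = NULL) {
  if (is.null(members)) members <- rep(config$members_per_group[1], config$n_groups)
  stopifnot(length(members) == config$n_groups)
  plans <- list()
  for (g in seq_len(config$n_groups)) {
    target <- config$taxonomy_spec[g]
    if (members[g] < 2 && !target %in% c("singleton", "intra_species")) {
      stop("group ", g, " has ", members[g],
           " member(s); cannot realize target class ", target)
    }
    lin <- group_lineages(g, members[g], target)
    lin <- cbind(accession = sprintf("SYNg%02dm%02d.1", g, seq_len(members[g])), lin)
    plans[[g]] <- lin
  }
  if (config$n_decoys > 0) {
    dl <- empty_lineage(config$n_decoys)
    dl$taxid <- sprintf("tax_dec%03d", seq_len(config$n_decoys))
    for (rank in RANKS) dl[[rank]] <- sprintf("%s_dec%03d", rank, seq_len(config$n_decoys))
    plans[[length(plans) + 1L]] <- cbind(accession = sprintf("SYNDEC%03d.1",
                                                             seq_len(config$n_decoys)), dl)
  }
  out <- do.call(rbind, plans)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic plasmid population with planted ground truth
#'
#' Draws `n_groups` random ancestors, derives each group's members by
#' mutation (and optional suffix truncation), adds unrelated decoys, builds
#' lineages realizing each group's target host-range class, embeds any
#' configured typing markers verbatim at random positions, and emits the
#' ground-truth table. Byte-reproducible from the config (including seed).
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory; when given, writes
#'   `population.fasta`, `metadata.tsv`, `markers.fasta` (if any) and
#'   `truth.tsv` there.
#' @return A list: `records` (`plasmid_set` with lineages attached),
#'   `metadata` (lineage table), `markers` (`marker_set` or `NULL`), `truth`
#'   (data.frame `accession`, `group_id` (`"decoy"` for decoys),
#'   `host_range`, `markers`), and `paths` when `dir` was given.
#' @export
generate_dataset <- function(config = synthetic_config(), dir = NULL) {
  set.seed(config$seed)
  n_groups <- config$n_groups
  members <- if (n_groups > 0) {
    sample_range(config$members_per_group[1], config$members_per_group[2], n_groups)
  } else integer(0)
  taxonomy <- generate_taxonomy(config, members)

  accession <- character(0); sequence <- character(0)
  truth_group <- character(0); truth_range <- character(0)
  for (g in seq_len(n_groups)) {
    anc_len <- sample_range(config$ancestor_length[1], config$ancestor_length[2])
    ancestor <- random_sequence(anc_len)
    trunc_idx <- if (config$truncate_members > 0)
      seq_len(min(config$truncate_members, members[g])) else integer(0)
    for (m in seq_len(members[g])) {
      seqm <- mutate_sequence(ancestor, config$substitution_rate,
                              config$indel_rate, config$indel_length_mean)
      if (m %in% trunc_idx && config$truncation_fraction > 0) {
        keep <- floor(nchar(seqm) * (1 - config$truncation_fraction))
        seqm <- substr(seqm, 1L, max(1L, keep))
      }
      accession <- c(accession, sprintf("SYNg%02dm%02d.1", g, m))
      sequence <- c(sequence, seqm)
      truth_group <- c(truth_group, sprintf("g%02d", g))
      truth_range <- c(truth_range,
                       if (members[g] == 1L) "singleton" else config$taxonomy_spec[g])
    }
  }
  for (d in seq_len(config$n_decoys)) {
    len <- sample_range(config$ancestor_length[1], config$ancestor_length[2])
    accession <- c(accession, sprintf("SYNDEC%03d.1", d))
    sequence <- c(sequence, random_sequence(len))
    truth_group <- c(truth_group, "decoy")
    truth_range <- c(truth_range, "singleton")
  }

  # markers: random sequences embedded verbatim in sampled carriers
  markers <- NULL
  carried <- rep("", length(accession))
  if (!is.null(config$marker_spec) && nrow(config$marker_spec) > 0) {
    ms <- config$marker_spec
    if (is.null(ms$scheme)) ms$scheme <- "rep"
    mseq <- vapply(ms$length, random_sequence, "")
    markers <- do.call(rbind, lapply(split(seq_len(nrow(ms)), ms$scheme), function(ii) {
      marker_set(sprintf("MRK%02d", ii), ms$type_label[ii], mseq[ii],
                 scheme = ms$scheme[ii][1])
    }))
    rownames(markers) <- NULL
    class(markers) <- c("marker_set", "data.frame")
    for (i in seq_len(nrow(ms))) {
      n_carriers <- round(ms$carrier_fraction[i] * length(accession))
      if (n_carriers < 1) next
      carriers <- sample(length(accession), n_carriers)
      for (cr in carriers) {
        pos <- sample.int(nchar(sequence[cr]), 1L)
        sequence[cr] <- paste0(substr(sequence[cr], 1, pos), mseq[i],
                               substr(sequence[cr], pos + 1L, nchar(sequence[cr])))
        carried[cr] <- if (nzchar(carried[cr]))
          paste(carried[cr], ms$type_label[i], sep = ",") else ms$type_label[i]
      }
    }
  }

  records <- plasmid_set(accession, sequence,
                         title = paste("synthetic plasmid", accession,
                                       "complete sequence"),
                         source = "synthetic")
  records <- load_metadata(records, taxonomy)
  truth <- data.frame(accession = accession, group_id = truth_group,
                      host_range = truth_range, markers = carried,
                      stringsAsFactors = FALSE)
  out <- list(records = records, metadata = taxonomy, markers = markers,
              truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "population.fasta"),
                  metadata = file.path(dir, "metadata.tsv"),
                  truth = file.path(dir, "truth.tsv"))
    write_plasmid_fasta(records, paths$fasta)
    write.table(taxonomy, paths$metadata, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(markers)) {
      paths$markers <- file.path(dir, "markers.fasta")
      x <- Biostrings::DNAStringSet(markers$sequence)
      names(x) <- paste0(markers$marker_id, "|", markers$type_label)
      Biostrings::writeXStringSet(x, paths$markers, width = 60L)
    }
    out$paths <- paths
  }
  out
}
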