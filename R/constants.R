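#' @useDynLib plasmidrange, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom utils read.delim write.table
#' @importFrom stats setNames
NULL

# taxonomic ranks, narrowest first; "class" is the R-facing column name
RANKS <- c("species", "genus", "family", "order", "class", "phylum")
RANKS_BROAD_FIRST <- rev(RANKS)

# host-range classes, narrowest to broadest; unclassifiable sits outside the
# ordering and is excluded from cumulative counts
HOST_RANGE_LEVELS <- c("singleton", "intra_species", "inter_species",
                       "inter_genus", "inter_family", "inter_order",
                       "inter_class", "inter_phylum", "unclassifiable")

# fixed 11-column tabular hit layout
HIT_COLUMNS <- c("qseqid", "sseqid", "qlen", "length", "slen", "pident",
                 "nident", "mismatch", "evalue", "qcov", "gaps")

BASES <- c("A", "C", "G", "T")
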