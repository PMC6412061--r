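mk_hit <- function(q, s, qcov = 95, qlen = 1000, slen = 1000, pident = 98) {
  nident <- round(pident * 10)
  data.frame(qseqid = q, sseqid = s, qlen = qlen, length = 1000L, slen = slen,
             pident = pident, nident = nident, mismatch = 1000L - nident,
             evalue = 0, qcov = qcov, gaps = 0L, stringsAsFactors = FALSE)
}

mk_records <- function(accs) plasmid_set(accs, rep("ACGT", length(accs)))

lineage_table <- function(accs, ...) {
  tab <- data.frame(accession = accs, taxid = NA_character_,
                    species = NA_character_, genus = NA_character_,
                    family = NA_character_, order = NA_character_,
                    class = NA_character_, phylum = NA_character_,
                    stringsAsFactors = FALSE)
  for (nm in names(list(...))) tab[[nm]] <- list(...)[[nm]]
  tab
}

test_that("an edge needs only one passing direction, and unknowns are fatal", {
  rec <- mk_records(c("A", "B", "C"))
  hits <- rbind(mk_hit("A", "B", qcov = 90),      # passes
                mk_hit("B", "A", qcov = 50),      # fails
                mk_hit("B", "C", qcov = 10),      # fails
                mk_hit("C", "B", qcov = 20))      # fails
  g <- build_cognate_graph(rec, hits)
  expect_equal(igraph::ecount(g), 1L)
  expect_true(igraph::are_adjacent(g, "A", "B"))
  expect_equal(igraph::vcount(g), 3L)

  g2 <- build_cognate_graph(rec, hits, reciprocal = TRUE)
  expect_equal(igraph::ecount(g2), 0L)

  both <- rbind(mk_hit("A", "B"), mk_hit("B", "A"))
  expect_equal(igraph::ecount(build_cognate_graph(rec, both, reciprocal = TRUE)), 1L)

  expect_error(build_cognate_graph(rec, mk_hit("A", "ZZZ")), "ZZZ")
})

test_that("no passing hits leaves every record an isolated vertex", {
  rec <- mk_records(c("A", "B", "C"))
  g <- build_cognate_graph(rec, mk_hit("A", "B", qcov = 10))
  expect_equal(igraph::ecount(g), 0L)
  comp <- cognate_components(g)
  expect_equal(nrow(comp), 3L)
  expect_true(all(comp$n_members == 1L))
})

test_that("edges come only from hits: a chain stays a chain", {
  rec <- mk_records(c("A", "B", "C"))
  g <- build_cognate_graph(rec, rbind(mk_hit("A", "B"), mk_hit("B", "C")))
  expect_equal(igraph::ecount(g), 2L)
  expect_false(igraph::are_adjacent(g, "A", "C"))
})

test_that("components partition the vertex set deterministically", {
  rec <- mk_records(c("D", "C", "B", "A"))
  g <- build_cognate_graph(rec, rbind(mk_hit("A", "B"), mk_hit("B", "C")))
  comp <- cognate_components(g)
  expect_equal(comp$members[[1]], c("A", "B", "C"))
  expect_equal(comp$members[[2]], "D")
  expect_equal(comp$group_id, c("G0001", "G0002"))
  expect_equal(sort(unlist(comp$members)), sort(rec$accession))
  expect_equal(sum(comp$n_members), igraph::vcount(g))

  tri <- build_cognate_graph(mk_records(c("A", "B", "C")),
                             rbind(mk_hit("A", "B"), mk_hit("B", "C"),
                                   mk_hit("A", "C")))
  expect_equal(cognate_components(tri)$n_members, 3L)

  empty <- cognate_components(build_cognate_graph(mk_records(character(0)),
                                                  mk_hit("A", "B")[0, ]))
  expect_equal(nrow(empty), 0L)
})

test_that("graph construction is symmetric under query/subject role reversal", {
  rec <- mk_records(c("A", "B", "C", "D"))
  hits <- rbind(mk_hit("A", "B", qcov = 90, qlen = 1000, slen = 900),
                mk_hit("C", "D", qcov = 85, qlen = 2000, slen = 1900),
                mk_hit("A", "C", qcov = 30))
  rev_hits <- hits
  rev_hits[, c("qseqid", "sseqid", "qlen", "slen")] <-
    hits[, c("sseqid", "qseqid", "slen", "qlen")]
  both <- rbind(hits, rev_hits)
  g1 <- build_cognate_graph(rec, both)
  swapped <- both
  swapped[, c("qseqid", "sseqid", "qlen", "slen")] <-
    both[, c("sseqid", "qseqid", "slen", "qlen")]
  g2 <- build_cognate_graph(rec, swapped)
  el <- function(g) {
    e <- igraph::as_edgelist(g)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_equal(el(g1), el(g2))
})

test_that("host range is the broadest rank with two differing assigned names", {
  accs <- c("P1", "P2")
  # different families, same phylum, class/order unassigned: inter_family
  lin <- lineage_table(accs, species = c("Burkholderia ambifaria", "Dickeya solani"),
                       family = c("Burkholderiaceae", "Pectobacteriaceae"),
                       phylum = c("Proteobacteria", "Proteobacteria"))
  expect_equal(classify_host_range(accs, lin), "inter_family")

  # identical species throughout
  lin2 <- lineage_table(c("P1", "P2", "P3"),
                        species = rep("Escherichia coli", 3),
                        genus = rep("Escherichia", 3),
                        family = rep("Enterobacteriaceae", 3))
  expect_equal(classify_host_range(c("P1", "P2", "P3"), lin2), "intra_species")

  # genus differs, family shared
  lin3 <- lineage_table(accs, species = c("Escherichia coli", "Klebsiella pneumoniae"),
                        genus = c("Escherichia", "Klebsiella"),
                        family = rep("Enterobacteriaceae", 2))
  expect_equal(classify_host_range(accs, lin3), "inter_genus")

  # singleton
  expect_equal(classify_host_range("P1", lin), "singleton")

  # all ranks missing on every member
  expect_equal(classify_host_range(accs, lineage_table(accs)), "unclassifiable")

  # missing ranks never count as differing
  lin4 <- lineage_table(accs, family = c("Enterobacteriaceae", NA),
                        species = c("Escherichia coli", "Escherichia coli"))
  expect_equal(classify_host_range(accs, lin4), "intra_species")

  expect_error(classify_host_range(c("P1", "NOPE"), lin), "NOPE")
})

test_that("adding a member never narrows the host-range class", {
  set.seed(77)
  lv <- c("singleton", "intra_species", "inter_species", "inter_genus",
          "inter_family", "inter_order", "inter_class", "inter_phylum")
  pool <- sprintf("M%02d", 1:8)
  taxa <- expand.grid(sp = c("s1", "s2"), ge = c("g1", "g2"), fa = c("f1", "f2"),
                      stringsAsFactors = FALSE)[1:8, ]
  lin <- lineage_table(pool, species = taxa$sp, genus = taxa$ge, family = taxa$fa,
                       order = rep("o1", 8), class = rep("c1", 8),
                       phylum = rep("p1", 8))
  for (rep_i in 1:20) {
    members <- sample(pool, sample(1:7, 1))
    extra <- sample(setdiff(pool, members), 1)
    before <- classify_host_range(members, lin)
    after <- classify_host_range(c(members, extra), lin)
    expect_gte(match(after, lv), match(before, lv))
  }
})

test_that("summary counts are cumulative over host-range classes", {
  groups <- data.frame(group_id = c("G1", "G2", "G3", "G4"),
                       n_members = c(3L, 2L, 2L, 1L),
                       stringsAsFactors = FALSE)
  groups$members <- I(list(c("A", "B", "C"), c("D", "E"), c("F", "G"), "H"))
  groups$host_range <- c("inter_family", "inter_genus", "intra_species", "singleton")
  s <- summarize_groups(groups)
  expect_equal(s$n_plasmids, 8L)
  expect_equal(s$n_with_cognates, 7L)
  expect_equal(s$n_without_cognates, 1L)
  expect_equal(s$n_groups, 3L)
  expect_equal(s$n_groups_diff_families, 1L)
  expect_equal(s$n_groups_diff_genera, 2L)
  expect_equal(s$n_groups_diff_species, 2L)
  # nested counts on randomized class assignments
  set.seed(8)
  lv <- c("intra_species", "inter_species", "inter_genus", "inter_family",
          "inter_order", "inter_class", "inter_phylum", "unclassifiable")
  for (rep_i in 1:10) {
    g <- data.frame(group_id = sprintf("G%02d", 1:30), n_members = 2L)
    g$members <- I(replicate(30, c("x", "y"), simplify = FALSE))
    g$host_range <- sample(lv, 30, replace = TRUE)
    s <- summarize_groups(g)
    expect_gte(s$n_groups_diff_species, s$n_groups_diff_genera)
    expect_gte(s$n_groups_diff_genera, s$n_groups_diff_families)
    expect_gte(s$n_groups_diff_families, s$n_groups_diff_orders)
    expect_gte(s$n_groups_diff_orders, s$n_groups_diff_classes)
    expect_gte(s$n_groups_diff_classes, s$n_groups_diff_phyla)
  }
  # all singletons: every cumulative count zero
  solo <- data.frame(group_id = c("G1", "G2"), n_members = 1L)
  solo$members <- I(list("A", "B"))
  solo$host_range <- "singleton"
  s0 <- summarize_groups(solo)
  expect_equal(s0$n_groups_diff_species, 0L)
  expect_equal(s0$n_groups, 0L)
})

test_that("network export writes edge and group tables", {
  rec <- mk_records(c("A", "B", "C"))
  g <- build_cognate_graph(rec, mk_hit("A", "B"))
  groups <- classify_groups(cognate_components(g), lineage_table(c("A", "B", "C"),
    species = c("s1", "s2", "s3"), genus = c("g1", "g1", "g2")))
  ed <- withr::local_tempfile(fileext = ".tsv")
  gr <- withr::local_tempfile(fileext = ".tsv")
  export_network(g, groups, ed, gr)
  edges <- read.delim(ed)
  expect_equal(nrow(edges), 1L)
  gtab <- read.delim(gr)
  expect_equal(nrow(gtab), 2L)
  expect_equal(gtab$host_range[1], "inter_species")
  expect_equal(gtab$members[1], "A,B")
})
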