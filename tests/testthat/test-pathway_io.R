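test_that("reaction tables parse, trim and validate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "pathway_id\treaction_id\tgene_ids\tsubstrate_ids\tproduct_ids\treversible",
    "path1\tR1\tG1; G2\tC1\tC2\t0",
    "path1\tR2\tG3\tC2\tC3\t1"), path)
  rt <- read_reaction_table(path)
  expect_s3_class(rt, "reaction_table")
  expect_equal(nrow(rt), 2)
  expect_equal(rt$gene_ids[[1]], c("G1", "G2"))
  expect_equal(rt$substrate_ids[[1]], "C1")
  expect_equal(rt$product_ids[[1]], "C2")
  expect_false(rt$reversible[1])
  expect_true(rt$reversible[2])

  # header only -> zero rows
  writeLines(paste("pathway_id", "reaction_id", "gene_ids", "substrate_ids",
                   "product_ids", "reversible", sep = "\t"), path)
  expect_equal(nrow(read_reaction_table(path)), 0)

  # missing column is named in the error
  writeLines(c("pathway_id\treaction_id\tgene_ids\tsubstrate_ids\treversible",
               "p\tR\tG\tC\t0"), path)
  expect_error(read_reaction_table(path), "product_ids")

  # empty identifier cell reports the line
  writeLines(c(
    "pathway_id\treaction_id\tgene_ids\tsubstrate_ids\tproduct_ids\treversible",
    "p\tR\t\tC1\tC2\t0"), path)
  expect_error(read_reaction_table(path), "gene_ids.*row 1")
  expect_error(read_reaction_table("/nonexistent/file.tsv"), "not found")
})

test_that("reaction record invariants are enforced", {
  expect_error(reaction_table("p", "r", list(c("G1", "G1")), list("C1"),
                              list("C2"), FALSE), "duplicated")
  expect_error(reaction_table("", "r", list("G1"), list("C1"),
                              list("C2"), FALSE), "pathway_id")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("pathway_id", "reaction_id", "gene_ids",
                     "substrate_ids", "product_ids", "reversible",
                     sep = "\t"),
               "p\tR\tG1\tC1\tC2\t2"), f)
  expect_error(read_reaction_table(f), "reversible")
})

test_that("pathway graph construction follows reaction directionality", {
  rt <- reaction_table("p", "R1", list("G1"), list("C1"), list("C2"), FALSE)
  g <- build_pathway_graph(rt)
  expect_setequal(edge_set(g), c("C1->G1", "G1->C2"))
  expect_setequal(igraph::V(g)$name[igraph::V(g)$kind == "gene"], "G1")

  rt_rev <- reaction_table("p", "R1", list("G1"), list("C1"), list("C2"),
                           TRUE)
  g_rev <- build_pathway_graph(rt_rev)
  expect_setequal(edge_set(g_rev),
                  c("C1->G1", "G1->C1", "G1->C2", "C2->G1"))
  # reversible edge set is a superset of the irreversible one
  expect_true(all(edge_set(g) %in% edge_set(g_rev)))

  # multi-gene enzymes duplicate connectivity exactly
  rt2 <- reaction_table("p", "R1", list(c("G1", "G2")), list("C1"),
                        list("C2"), FALSE)
  g2 <- build_pathway_graph(rt2)
  nb <- function(gr, v, mode) {
    sort(igraph::V(gr)$name[igraph::neighbors(gr, v, mode = mode)])
  }
  expect_equal(nb(g2, "G1", "in"), nb(g2, "G2", "in"))
  expect_equal(nb(g2, "G1", "out"), nb(g2, "G2", "out"))

  # id used both as gene and compound is a construction error
  bad <- reaction_table("p", "R1", list("X"), list("X2"), list("X"), FALSE)
  expect_error(build_pathway_graph(bad), "both as gene and compound")
  # records of different pathways are rejected
  expect_error(build_pathway_graph(toy_reactions()), "single pathway")
})

test_that("pathway graphs are bipartite and order-invariant", {
  rt <- toy_reactions()
  rt_a <- rt[rt$pathway_id == "pwA", ]
  g <- build_pathway_graph(rt_a)
  el <- igraph::as_edgelist(g, names = TRUE)
  kind <- setNames(igraph::V(g)$kind, igraph::V(g)$name)
  expect_true(all(kind[el[, 1]] != kind[el[, 2]]))

  g_flip <- build_pathway_graph(rt_a[rev(seq_len(nrow(rt_a))), ])
  expect_setequal(edge_set(g), edge_set(g_flip))
  expect_equal(sort(igraph::V(g)$name), sort(igraph::V(g_flip)$name))
})

test_that("gene-gene contraction links producers to consumers", {
  rt <- reaction_table(c("p", "p"), c("R1", "R2"), list("G1", "G2"),
                       list("C1", "C2"), list("C2", "C3"), c(FALSE, FALSE))
  g <- build_gene_gene_graph(rt)
  expect_equal(edge_set(g), "G1->G2")
  expect_setequal(igraph::V(g)$name, c("G1", "G2"))
  expect_true(all(igraph::V(g)$kind == "gene"))

  # single reaction: gene nodes, no edges
  g1 <- build_gene_gene_graph(rt[1, ])
  expect_equal(igraph::ecount(g1), 0)
  expect_setequal(igraph::V(g1)$name, "G1")

  # reversible chain yields both directions
  rt_rev <- reaction_table(c("p", "p"), c("R1", "R2"), list("G1", "G2"),
                           list("C1", "C2"), list("C2", "C3"),
                           c(TRUE, TRUE))
  expect_setequal(edge_set(build_gene_gene_graph(rt_rev)),
                  c("G1->G2", "G2->G1"))
})

test_that("graphs round-trip through GraphML", {
  rt <- toy_reactions()
  g <- build_pathway_graph(rt[rt$pathway_id == "pwA", ])
  path <- withr::local_tempfile(fileext = ".graphml")
  write_pathway_graphml(g, path)
  g2 <- read_pathway_graphml(path)
  expect_setequal(edge_set(g), edge_set(g2))
  expect_equal(sort(igraph::V(g)$name), sort(igraph::V(g2)$name))
  k1 <- setNames(igraph::V(g)$kind, igraph::V(g)$name)
  k2 <- setNames(igraph::V(g2)$kind, igraph::V(g2)$name)
  expect_equal(k1[sort(names(k1))], k2[sort(names(k2))])

  # global graph keeps its pathway membership index
  gg <- toy_graph()
  write_pathway_graphml(gg, path)
  gg2 <- read_pathway_graphml(path)
  expect_equal(pathway_members(gg2), pathway_members(gg))

  # empty graph round-trips
  ge <- igraph::make_empty_graph(directed = TRUE)
  write_pathway_graphml(ge, path)
  expect_equal(igraph::vcount(read_pathway_graphml(path)), 0)
  expect_error(read_pathway_graphml("/nonexistent.graphml"), "not found")
})

test_that("compound filtering drops compounds and emptied reactions", {
  rt <- toy_reactions()
  filtered <- filter_compounds(rt, "C3")
  expect_equal(nrow(filtered), 1)  # r2 and r3 both lose a side
  expect_equal(filtered$reaction_id, "r1")
  expect_identical(filter_compounds(rt, character(0)), rt)
})

test_that("the reduced KGML reader maps onto reaction records", {
  kgml <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<pathway name="path:test01" org="hsa" number="00001">',
    '  <entry id="1" name="hsa:10 hsa:11" type="gene" reaction="rn:R001"/>',
    '  <entry id="2" name="hsa:20" type="gene" reaction="rn:R002"/>',
    '  <entry id="3" name="cpd:C01" type="compound"/>',
    '  <reaction id="1" name="rn:R001" type="irreversible">',
    '    <substrate id="3" name="cpd:C01"/>',
    '    <product id="4" name="cpd:C02"/>',
    '  </reaction>',
    '  <reaction id="2" name="rn:R002" type="reversible">',
    '    <substrate id="4" name="cpd:C02"/>',
    '    <product id="5" name="cpd:C03"/>',
    '  </reaction>',
    '  <reaction id="3" name="rn:R999" type="irreversible">',
    '    <substrate id="4" name="cpd:C02"/>',
    '    <product id="5" name="cpd:C03"/>',
    '  </reaction>',
    '</pathway>'), kgml)
  rt <- read_kgml(kgml)
  expect_equal(nrow(rt), 2)  # R999 has no gene annotation
  expect_equal(rt$pathway_id, rep("path:test01", 2))
  expect_setequal(rt$gene_ids[[1]], c("hsa:10", "hsa:11"))
  expect_equal(rt$substrate_ids[[2]], "cpd:C02")
  expect_true(rt$reversible[2])
  expect_false(rt$reversible[1])
  g <- build_pathway_graph(rt)
  expect_true("cpd:C02->hsa:20" %in% edge_set(g))
})
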