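# KGML parsing, omics-to-pathway mapping, set comparison and the
# shared-entity pathway network.

fixture <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "kgml-fixture")
      make_pathway_fixture(dir)
    }
    list(dir = dir,
         kgml = list.files(dir, pattern = "^map.*xml$", full.names = TRUE),
         gene_list = file.path(dir, "gene_list.tsv"),
         gene_map = file.path(dir, "gene_map.tsv"),
         panel = file.path(dir, "panel.tsv"))
  }
})

test_that("the KGML reader parses the fixture and validates references", {
  fx <- fixture()
  recs <- parse_kgml(fx$kgml)
  expect_length(recs, nrow(pathway_membership_reference()))
  ids <- vapply(recs, `[[`, "", "pathway_id")
  expect_setequal(ids, pathway_membership_reference()$pathway_id)

  # reaction participants are subsets of the declared entity sets
  for (r in recs) {
    for (rx in r$reactions) {
      expect_true(all(c(rx$substrates, rx$products) %in% r$compounds))
      expect_true(all(rx$enzyme %in% r$enzymes))
    }
  }

  # an empty pathway parses to empty sets without error
  f <- tempfile(fileext = ".xml")
  writeLines('<pathway name="path:map99999" title="Empty"></pathway>', f)
  empty <- parse_kgml(f)[[1]]
  expect_length(empty$compounds, 0)
  expect_length(empty$reactions, 0)

  # undeclared reaction compounds are a validation error naming the ID
  f2 <- tempfile(fileext = ".xml")
  writeLines(c('<pathway name="path:map99998" title="Bad">',
               '  <entry id="1" name="cpd:C00001" type="compound"/>',
               '  <reaction id="2" name="rn:R00001" enzyme="">',
               '    <substrate name="cpd:C00002"/><product name="cpd:C00001"/>',
               '  </reaction>', '</pathway>'), f2)
  expect_error(parse_kgml(f2), "C00002", class = "hypoxiaNMR_undeclared_compound")

  # malformed XML is reported with the offending file
  f3 <- tempfile(fileext = ".xml")
  writeLines("<pathway name='path:map1'><entry", f3)
  expect_error(parse_kgml(f3), class = "hypoxiaNMR_malformed_xml")
})

test_that("metabolite mapping hits exactly the metabolome pathway set", {
  fx <- fixture()
  recs <- parse_kgml(fx$kgml)
  hits <- map_metabolites(read.delim(fx$panel), recs)
  expect_length(unique(hits$pathway_id), 14)

  # a single-compound panel hits only pathways declaring that compound
  taur <- map_metabolites(data.frame(metabolite = "taurine", compound_id = "C00245"), recs)
  expect_identical(unique(taur$pathway_id), "map00430")
  none <- map_metabolites(data.frame(metabolite = "x", compound_id = "C99999"), recs)
  expect_identical(nrow(none), 0L)
})

test_that("gene mapping converts, warns on unmapped, hits the transcriptome set", {
  fx <- fixture()
  recs <- parse_kgml(fx$kgml)
  gmap <- read_gene_map(fx$gene_map)
  genes <- readLines(fx$gene_list)
  expect_warning(expect_warning(
    hits <- map_genes(genes, gmap, recs),
    "no enzyme mapping"), "not found in any pathway")
  expect_length(unique(hits$pathway_id), 11)
  expect_length(attr(hits, "unmapped_genes"), 55)
  # empty gene list: no hits
  expect_identical(nrow(map_genes(character(0), gmap, recs)), 0L)
})

test_that("set comparison reproduces the published membership partition", {
  fx <- fixture()
  recs <- parse_kgml(fx$kgml)
  met <- unique(map_metabolites(read.delim(fx$panel), recs)$pathway_id)
  trans <- unique(suppressWarnings(
    map_genes(readLines(fx$gene_list), read_gene_map(fx$gene_map), recs))$pathway_id)
  cmp <- compare_sets(met, trans)
  expect_length(cmp$common, 4)
  expect_length(cmp$metabolome_only, 10)
  expect_setequal(cmp$common, c("map00010", "map00230", "map00330", "map00620"))
  expect_equal(length(cmp$common) + length(cmp$metabolome_only), length(met))

  # identical inputs leave both *_only partitions empty
  same <- compare_sets(met, met)
  expect_length(same$metabolome_only, 0)
  expect_length(same$transcriptome_only, 0)
})

test_that("inclusion-exclusion holds on random pathway sets", {
  set.seed(11)
  for (i in 1:50) {
    M <- sample(letters, sample(0:15, 1))
    T_ <- sample(letters, sample(0:15, 1))
    cmp <- compare_sets(M, T_)
    expect_equal(length(union(M, T_)),
                 length(M) + length(T_) - length(cmp$common))
    expect_equal(length(cmp$common) + length(cmp$metabolome_only), length(unique(M)))
  }
})

test_that("edge weights equal brute-force shared-entity counts", {
  fx <- fixture()
  recs <- parse_kgml(fx$kgml)
  met_hits <- map_metabolites(read.delim(fx$panel), recs)
  trans_hits <- suppressWarnings(
    map_genes(readLines(fx$gene_list), read_gene_map(fx$gene_map), recs))
  g <- build_graph(recs, met_hits, trans_hits)
  expect_equal(igraph::vcount(g), 21)
  expect_false(any(igraph::which_loop(g)))
  expect_true(all(igraph::E(g)$weight >= 1))

  # O(n^2) brute-force oracle over mapped entities
  ids <- vapply(recs, `[[`, "", "pathway_id")
  mapped_c <- unique(met_hits$compound)
  mapped_e <- unique(trans_hits$enzyme)
  nodes <- igraph::V(g)$name
  for (i in seq_len(length(nodes) - 1)) {
    for (j in (i + 1):length(nodes)) {
      ri <- recs[[match(nodes[i], ids)]]
      rj <- recs[[match(nodes[j], ids)]]
      w <- length(intersect(intersect(ri$compounds, mapped_c),
                            intersect(rj$compounds, mapped_c))) +
        length(intersect(intersect(ri$enzymes, mapped_e),
                         intersect(rj$enzymes, mapped_e)))
      eid <- igraph::get_edge_ids(g, c(nodes[i], nodes[j]))
      got <- if (eid == 0) 0 else igraph::E(g)$weight[eid]
      expect_equal(got, w)
    }
  }
})

test_that("toy graphs behave: single shared compound, disjoint pathways", {
  mk <- function(id, compounds) {
    structure(list(pathway_id = id, name = id, compounds = compounds,
                   enzymes = character(0), reactions = list()),
              class = "pathway_record")
  }
  recs <- list(mk("p1", c("C00022", "C00001")), mk("p2", c("C00022", "C00002")),
               mk("p3", "C00099"))
  met_hits <- data.frame(pathway_id = c("p1", "p2", "p3"),
                         compound = c("C00022", "C00022", "C00099"),
                         metabolite = c("pyruvate", "pyruvate", "x"))
  trans_hits <- data.frame(pathway_id = character(0), enzyme = character(0))
  g <- build_graph(recs, met_hits, trans_hits)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 1)   # p1-p2 share exactly pyruvate
})

test_that("graph export round-trips GraphML and counts SIF lines", {
  fx <- fixture()
  recs <- parse_kgml(fx$kgml)
  met_hits <- map_metabolites(read.delim(fx$panel), recs)
  trans_hits <- suppressWarnings(
    map_genes(readLines(fx$gene_list), read_gene_map(fx$gene_map), recs))
  g <- build_graph(recs, met_hits, trans_hits)

  f <- tempfile(fileext = ".graphml")
  export_graph(g, f, "graphml")
  g2 <- read_graphml(f)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  expect_identical(igraph::V(g2)$source[match(igraph::V(g)$name, igraph::V(g2)$name)],
                   igraph::V(g)$source)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  # weights agree edge by edge
  el <- igraph::as_edgelist(g)
  for (k in seq_len(nrow(el))) {
    expect_equal(igraph::E(g2)$weight[igraph::get_edge_ids(g2, el[k, ])],
                 igraph::E(g)$weight[k])
  }

  fs <- tempfile(fileext = ".sif")
  export_graph(g, fs, "sif")
  expect_length(readLines(fs), igraph::ecount(g))

  # empty graph exports a valid zero-edge file
  g0 <- build_graph(recs, met_hits[0, ], trans_hits[0, ])
  f0 <- tempfile(fileext = ".graphml")
  export_graph(g0, f0, "graphml")
  expect_equal(igraph::ecount(read_graphml(f0)), 0)
  expect_error(export_graph(g, tempfile(), "gexf"), class = "hypoxiaNMR_unknown_format")
})
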