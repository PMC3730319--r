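#!/usr/bin/env Rscript
# Step 6 -- metabolome vs transcriptome pathway network.
#
# Emits the KGML-subset fixture (pathways, 66-entry up-regulated gene list,
# gene-to-enzyme map), maps the metabolite panel and the gene list onto
# pathways, compares the two pathway sets, and builds the shared-entity
# pathway network for Cytoscape-style tooling.

library(hypoxiaNMR)

outdir <- "results/06_pathways"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

fx <- make_pathway_fixture(file.path(outdir, "kgml"))
recs <- parse_kgml(fx$kgml_files)
panel <- read.delim(fx$panel)
met_hits <- map_metabolites(panel, recs)
trans_hits <- suppressWarnings(
  map_genes(readLines(fx$gene_list), read_gene_map(fx$gene_map), recs))

met <- unique(met_hits$pathway_id)
trans <- unique(trans_hits$pathway_id)
cmp <- compare_sets(met, trans)
write_comparison(recs, met, trans, file.path(outdir, "pathway_comparison.tsv"))

g <- build_graph(recs, met_hits, trans_hits)
export_graph(g, file.path(outdir, "pathway_network.graphml"), "graphml")
export_graph(g, file.path(outdir, "pathway_network.sif"), "sif")

ids <- vapply(recs, `[[`, "", "pathway_id")
nms <- vapply(recs, `[[`, "", "name")
cat(sprintf("metabolome: %d pathways; transcriptome: %d pathways\n",
            length(met), length(trans)))
cat(sprintf("common (%d): %s\n", length(cmp$common),
            paste(nms[match(cmp$common, ids)], collapse = "; ")))
cat(sprintf("metabolome-only: %d pathways not covered by the transcriptome set\n",
            length(cmp$metabolome_only)))
cat(sprintf("network: %d nodes, %d edges; strongest link weight %d (%s)\n",
            igraph::vcount(g), igraph::ecount(g), max(igraph::E(g)$weight),
            paste(igraph::as_edgelist(g)[which.max(igraph::E(g)$weight), ],
                  collapse = " -- ")))
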