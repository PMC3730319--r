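## KGML-subset parsing, gene/metabolite-to-pathway mapping, metabolome vs
## transcriptome pathway comparison, and the shared-entity pathway network.

strip_kegg_prefix <- function(x) sub("^[a-z]+:", "", x)

#' Parse KGML-subset pathway files
#'
#' Reads one pathway per XML file. The consumed subset is: the `pathway`
#' root (attributes `name`, `title`), `entry` elements with `id`, `name`,
#' `type` (`compound`, `enzyme`, `gene`, `ortholog`), and `reaction`
#' elements with an optional `enzyme` attribute and `substrate`/`product`
#' children (attribute `name`). Real KEGG KGML files parse through the same
#' reader (elements outside the subset are ignored with a warning).
#' Accession prefixes (`cpd:`, `ec:`, `path:`) are stripped.
#'
#' @param files Character vector of KGML file paths.
#' @return List of `pathway_record` objects: `pathway_id`, `name`,
#'   `compounds`, `enzymes`, `reactions` (list of
#'   (substrates, products, enzyme)).
#' @export
parse_kgml <- function(files) {
  lapply(files, function(f) {
    doc <- tryCatch(xml2::read_xml(f), error = function(e) {
      abort("MALFORMED_XML", sprintf("%s: %s", f, conditionMessage(e)))
    })
    root <- xml2::xml_name(doc)
    if (root != "pathway") {
      abort("MALFORMED_XML", sprintf("%s: root element is <%s>, expected <pathway>", f, root))
    }
    pid <- strip_kegg_prefix(xml2::xml_attr(doc, "name"))
    title <- xml2::xml_attr(doc, "title")
    compounds <- character(0); enzymes <- character(0)
    reactions <- list()
    for (node in xml2::xml_children(doc)) {
      nm <- xml2::xml_name(node)
      if (nm == "entry") {
        type <- xml2::xml_attr(node, "type")
        id <- strip_kegg_prefix(xml2::xml_attr(node, "name"))
        if (identical(type, "compound")) {
          compounds <- c(compounds, id)
        } else if (type %in% c("enzyme", "gene", "ortholog")) {
          enzymes <- c(enzymes, id)
        } else {
          warning(sprintf("%s: ignoring entry of unknown type '%s'", f, type))
        }
      } else if (nm == "reaction") {
        subs <- strip_kegg_prefix(xml2::xml_attr(xml2::xml_find_all(node, "./substrate"), "name"))
        prods <- strip_kegg_prefix(xml2::xml_attr(xml2::xml_find_all(node, "./product"), "name"))
        enz <- xml2::xml_attr(node, "enzyme")
        enz <- if (is.na(enz)) character(0) else strip_kegg_prefix(enz)
        reactions[[length(reactions) + 1]] <-
          list(substrates = subs, products = prods, enzyme = enz,
               name = strip_kegg_prefix(xml2::xml_attr(node, "name")))
      } else {
        warning(sprintf("%s: ignoring unknown element <%s>", f, nm))
      }
    }
    rec <- structure(list(pathway_id = pid, name = title,
                          compounds = unique(compounds), enzymes = unique(enzymes),
                          reactions = reactions),
                     class = "pathway_record")
    validate_pathway_record(rec, file = f)
  })
}

#' @noRd
validate_pathway_record <- function(rec, file = rec$pathway_id) {
  if (is.na(rec$pathway_id) || !nzchar(rec$pathway_id)) {
    abort("MALFORMED_XML", sprintf("%s: pathway id missing", file))
  }
  for (rx in rec$reactions) {
    bad_c <- setdiff(c(rx$substrates, rx$products), rec$compounds)
    if (length(bad_c)) {
      abort("UNDECLARED_COMPOUND",
            sprintf("%s: reaction references undeclared compound(s): %s",
                    file, paste(bad_c, collapse = ", ")))
    }
    bad_e <- setdiff(rx$enzyme, rec$enzymes)
    if (length(bad_e)) {
      abort("UNDECLARED_ENZYME",
            sprintf("%s: reaction references undeclared enzyme(s): %s",
                    file, paste(bad_e, collapse = ", ")))
    }
  }
  rec
}

#' @export
print.pathway_record <- function(x, ...) {
  cat(sprintf("<pathway_record> %s (%s): %d compounds, %d enzymes, %d reactions\n",
              x$pathway_id, x$name, length(x$compounds), length(x$enzymes),
              length(x$reactions)))
  invisible(x)
}

#' Read a gene-to-enzyme map table
#'
#' A local, versioned stand-in for an online ID-conversion service: a TSV
#' with columns `input_id`, `entrez_id`, `enzyme`.
#'
#' @param path TSV path.
#' @return data.frame (duplicated (input, enzyme) rows dropped).
#' @export
read_gene_map <- function(path) {
  gm <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("input_id", "entrez_id", "enzyme") %in% names(gm)))
  gm[!duplicated(gm[, c("input_id", "enzyme")]), ]
}

#' Map up-regulated genes onto pathways via their enzymes
#'
#' Genes are converted to enzyme identifiers through the gene map, then
#' matched against each pathway's enzyme set. Genes without a map entry,
#' and enzymes absent from every pathway, are reported via warnings but are
#' not fatal.
#'
#' @param genes Character vector of input gene IDs.
#' @param gmap Gene map (see [read_gene_map()]).
#' @param pathways List of `pathway_record`s.
#' @return data.frame of hits (`pathway_id`, `enzyme`), with attribute
#'   `unmapped_genes`.
#' @export
map_genes <- function(genes, gmap, pathways) {
  rows <- gmap[gmap$input_id %in% genes, ]
  unmapped <- setdiff(genes, gmap$input_id)
  if (length(unmapped)) {
    warning(sprintf("%d gene(s) have no enzyme mapping", length(unmapped)))
  }
  enzymes <- unique(rows$enzyme)
  hits <- list()
  for (p in pathways) {
    found <- intersect(enzymes, p$enzymes)
    if (length(found)) {
      hits[[length(hits) + 1]] <- data.frame(pathway_id = p$pathway_id, enzyme = found)
    }
  }
  lost <- setdiff(enzymes, unlist(lapply(pathways, `[[`, "enzymes")))
  if (length(lost)) {
    warning(sprintf("enzyme(s) not found in any pathway: %s", paste(lost, collapse = ", ")))
  }
  out <- if (length(hits)) do.call(rbind, hits) else data.frame(pathway_id = character(0), enzyme = character(0))
  attr(out, "unmapped_genes") <- unmapped
  out
}

#' Map the metabolite panel onto pathways via compound IDs
#'
#' @param panel data.frame with columns `metabolite`, `compound_id` (see
#'   [panel_compounds()]).
#' @param pathways List of `pathway_record`s.
#' @return data.frame of hits (`pathway_id`, `compound`, `metabolite`).
#' @export
map_metabolites <- function(panel, pathways) {
  hits <- list()
  for (p in pathways) {
    found <- intersect(panel$compound_id, p$compounds)
    if (length(found)) {
      hits[[length(hits) + 1]] <- data.frame(
        pathway_id = p$pathway_id, compound = found,
        metabolite = panel$metabolite[match(found, panel$compound_id)])
    }
  }
  if (length(hits)) do.call(rbind, hits) else {
    data.frame(pathway_id = character(0), compound = character(0), metabolite = character(0))
  }
}

#' Partition metabolome and transcriptome pathway sets
#'
#' @param met_pathways,trans_pathways Character vectors of pathway IDs.
#' @return list with sorted `common`, `metabolome_only`,
#'   `transcriptome_only`.
#' @export
compare_sets <- function(met_pathways, trans_pathways) {
  met <- unique(met_pathways); trans <- unique(trans_pathways)
  list(common = sort(intersect(met, trans)),
       metabolome_only = sort(setdiff(met, trans)),
       transcriptome_only = sort(setdiff(trans, met)))
}

#' Write the two-column membership comparison as TSV
#' @param records Parsed `pathway_record`s (for display names).
#' @param met_pathways,trans_pathways Pathway ID vectors.
#' @param path Output path.
#' @return The comparison data.frame, invisibly.
#' @export
write_comparison <- function(records, met_pathways, trans_pathways, path) {
  ids <- vapply(records, `[[`, "", "pathway_id")
  nms <- vapply(records, `[[`, "", "name")
  keep <- ids %in% union(met_pathways, trans_pathways)
  df <- data.frame(pathway_id = ids[keep], pathway = nms[keep],
                   metabolome = ifelse(ids[keep] %in% met_pathways, "V", ""),
                   transcriptome = ifelse(ids[keep] %in% trans_pathways, "V", ""))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Build the pathway-pathway shared-entity network
#'
#' One node per hit pathway, tagged by omics source (`metabolome`,
#' `transcriptome` or `both`). An edge joins two pathways when they share at
#' least one mapped entity; the weight is the number of shared mapped
#' compounds plus shared mapped enzymes. By default the count is restricted
#' to entities that were themselves hits (panel compounds and gene-mapped
#' enzymes); `mapped_only = FALSE` counts over all KGML entities instead.
#'
#' @param records List of `pathway_record`s.
#' @param met_hits Output of [map_metabolites()].
#' @param trans_hits Output of [map_genes()].
#' @param mapped_only Restrict shared-entity counting to mapped entities.
#' @return An undirected weighted [igraph][igraph::graph] with vertex
#'   attribute `source` and edge attribute `weight`.
#' @export
build_graph <- function(records, met_hits, trans_hits, mapped_only = TRUE) {
  ids <- vapply(records, `[[`, "", "pathway_id")
  met_set <- unique(met_hits$pathway_id)
  trans_set <- unique(trans_hits$pathway_id)
  nodes <- union(met_set, trans_set)
  src <- ifelse(nodes %in% met_set & nodes %in% trans_set, "both",
                ifelse(nodes %in% met_set, "metabolome", "transcriptome"))
  mapped_c <- unique(met_hits$compound)
  mapped_e <- unique(trans_hits$enzyme)
  ent <- lapply(nodes, function(p) {
    rec <- records[[match(p, ids)]]
    cs <- rec$compounds; es <- rec$enzymes
    if (mapped_only) { cs <- intersect(cs, mapped_c); es <- intersect(es, mapped_e) }
    list(compounds = cs, enzymes = es)
  })
  names(ent) <- nodes
  edges <- list()
  if (length(nodes) >= 2) {
    for (i in seq_len(length(nodes) - 1)) {
      for (j in (i + 1):length(nodes)) {
        w <- length(intersect(ent[[i]]$compounds, ent[[j]]$compounds)) +
          length(intersect(ent[[i]]$enzymes, ent[[j]]$enzymes))
        if (w >= 1) {
          edges[[length(edges) + 1]] <- data.frame(from = nodes[i], to = nodes[j], weight = w)
        }
      }
    }
  }
  edf <- if (length(edges)) do.call(rbind, edges) else data.frame(from = character(0), to = character(0), weight = numeric(0))
  g <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                     vertices = data.frame(name = nodes, source = src))
  g
}

#' Export a pathway graph
#'
#' `graphml` round-trips nodes, source tags and weights losslessly. `sif`
#' is the simple Cytoscape interaction format: one `A shared_with B` line
#' per edge (weights and isolated nodes are not representable in SIF).
#'
#' @param g Graph from [build_graph()].
#' @param path Output file path.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("graphml", "sif")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort("UNKNOWN_FORMAT", sprintf("unknown graph format '%s'", format[1])))
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ends <- igraph::as_edgelist(g)
    lines <- if (nrow(ends)) sprintf("%s shared_with %s", ends[, 1], ends[, 2]) else character(0)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read back a GraphML pathway graph
#' @param path GraphML file.
#' @return An igraph object.
#' @export
read_graphml <- function(path) igraph::read_graph(path, format = "graphml")
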