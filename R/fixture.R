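## Synthetic KGML pathway fixture: a reduced, self-consistent pathway set
## whose membership structure reproduces the published metabolome vs
## transcriptome comparison (14 metabolome pathways, 11 transcriptome
## pathways, 4 in common). All files are labelled synthetic: compound and
## enzyme accessions are real KEGG-style identifiers, but each pathway file
## contains only the reduced entity subset this analysis consumes.

#' Reference pathway membership structure
#'
#' The ground truth the fixture is built from: 21 pathways flagged by
#' whether the metabolite panel (metabolome) and the up-regulated gene set
#' (transcriptome) map onto them. 14 metabolome pathways, 11 transcriptome
#' pathways, 4 common.
#'
#' @return data.frame with columns `pathway_id`, `name`, `metabolome`,
#'   `transcriptome` (logical).
#' @export
pathway_membership_reference <- function() {
  df <- data.frame(
    pathway_id = c("map00010", "map00230", "map00330", "map00620",
                   "map00040", "map00053", "map00250", "map00260", "map00270",
                   "map00290", "map00430", "map00471", "map00480", "map00910",
                   "map00051", "map00072", "map00590", "map00591", "map00830",
                   "map00980", "map00982"),
    name = c("Glycolysis / Gluconeogenesis", "Purine metabolism",
             "Arginine and proline metabolism", "Pyruvate metabolism",
             "Pentose and glucuronate interconversions",
             "Ascorbate and aldarate metabolism",
             "Alanine, aspartate and glutamate metabolism",
             "Glycine, serine and threonine metabolism",
             "Cysteine and methionine metabolism",
             "Valine, leucine and isoleucine biosynthesis",
             "Taurine and hypotaurine metabolism",
             "D-Glutamine and D-glutamate metabolism",
             "Glutathione metabolism", "Nitrogen metabolism",
             "Fructose and mannose metabolism",
             "Synthesis and degradation of ketone bodies",
             "Arachidonic acid metabolism", "Linoleic acid metabolism",
             "Retinol metabolism",
             "Metabolism of xenobiotics by cytochrome P450",
             "Drug metabolism - cytochrome P450"),
    metabolome = c(rep(TRUE, 14), rep(FALSE, 7)),
    transcriptome = c(rep(TRUE, 4), rep(FALSE, 10), rep(TRUE, 7))
  )
  df
}

#' Fixture pathway definitions
#' @noRd
fixture_pathways <- function() {
  rx <- function(s, p, e, name) list(substrates = s, products = p, enzyme = e, name = name)
  list(
    map00010 = list(
      compounds = c("C00031", "C00022", "C00186", "C00469", "C00033", "C00074", "C00084"),
      enzymes = c("2.7.1.40", "1.1.1.27", "1.1.1.1", "2.7.2.3", "2.7.1.1"),
      reactions = list(rx("C00074", "C00022", "2.7.1.40", "R00200"),
                       rx("C00022", "C00186", "1.1.1.27", "R00703"),
                       rx("C00084", "C00469", "1.1.1.1", "R00754"))),
    map00230 = list(
      compounds = c("C00064", "C00037", "C00002", "C00144"),
      enzymes = c("2.7.1.40", "6.3.4.13"),
      reactions = list(rx(c("C00002", "C00037"), "C00144", "6.3.4.13", "R04144"))),
    map00330 = list(
      compounds = c("C00148", "C00025", "C00300", "C02305", "C00062"),
      enzymes = c("1.14.11.2", "2.7.3.2"),
      reactions = list(rx("C00300", "C02305", "2.7.3.2", "R01881"),
                       rx("C00148", "C00025", "1.14.11.2", "R00708"))),
    map00620 = list(
      compounds = c("C00022", "C00186", "C00033", "C00024"),
      enzymes = c("2.7.1.40", "1.1.1.27", "6.2.1.1"),
      reactions = list(rx("C00022", "C00186", "1.1.1.27", "R00703"),
                       rx("C00033", "C00024", "6.2.1.1", "R00235"))),
    map00040 = list(
      compounds = c("C00137", "C00191", "C00181"),
      enzymes = "1.1.1.19",
      reactions = list(rx("C00191", "C00137", "1.1.1.19", "R01183"))),
    map00053 = list(
      compounds = c("C00137", "C00072", "C00818"),
      enzymes = "1.13.99.1",
      reactions = list(rx("C00137", "C00818", "1.13.99.1", "R01184"))),
    map00250 = list(
      compounds = c("C00041", "C00025", "C00064", "C00022", "C00049"),
      enzymes = c("2.6.1.2", "6.3.1.2"),
      reactions = list(rx("C00041", "C00022", "2.6.1.2", "R00258"),
                       rx("C00025", "C00064", "6.3.1.2", "R00253"))),
    map00260 = list(
      compounds = c("C00037", "C00300", "C00065", "C00188"),
      enzymes = c("2.1.1.2", "2.6.1.52"),
      reactions = list(rx("C00065", "C00037", "2.6.1.52", "R00945"))),
    map00270 = list(
      compounds = c("C00073", "C00022", "C00021", "C00097"),
      enzymes = c("2.5.1.6", "4.4.1.1"),
      reactions = list(rx("C00073", "C00021", "2.5.1.6", "R00177"))),
    map00290 = list(
      compounds = c("C00183", "C00123", "C00407", "C00141"),
      enzymes = "2.6.1.42",
      reactions = list(rx("C00141", "C00183", "2.6.1.42", "R01214"))),
    map00430 = list(
      compounds = c("C00245", "C00519", "C00606"),
      enzymes = "1.8.1.3",
      reactions = list(rx("C00519", "C00245", "1.8.1.3", "R01682"))),
    map00471 = list(
      compounds = c("C00064", "C00025", "C00819"),
      enzymes = "5.1.1.3",
      reactions = list(rx("C00025", "C00819", "5.1.1.3", "R00260"))),
    map00480 = list(
      compounds = c("C00025", "C00037", "C00051", "C00097"),
      enzymes = c("6.3.2.2", "6.3.2.3"),
      reactions = list(rx(c("C00025", "C00097"), "C00051", "6.3.2.2", "R00894"))),
    map00910 = list(
      compounds = c("C00064", "C00025", "C00014", "C00088"),
      enzymes = "6.3.1.2",
      reactions = list(rx(c("C00025", "C00014"), "C00064", "6.3.1.2", "R00253"))),
    map00051 = list(
      compounds = c("C00095", "C00159", "C05345"),
      enzymes = c("2.7.1.105", "5.3.1.8"),
      reactions = list(rx("C00159", "C00095", "5.3.1.8", "R00772"))),
    map00072 = list(
      compounds = c("C00164", "C01089", "C00207"),
      enzymes = "1.1.1.30",
      reactions = list(rx("C00164", "C01089", "1.1.1.30", "R01361"))),
    map00590 = list(
      compounds = c("C00219", "C00584", "C14748"),
      enzymes = c("3.1.1.4", "1.14.99.1"),
      reactions = list(rx("C00219", "C00584", "1.14.99.1", "R00073"))),
    map00591 = list(
      compounds = c("C01595", "C14762", "C04717"),
      enzymes = "3.1.1.4",
      reactions = list(rx("C01595", "C14762", "3.1.1.4", "R07861"))),
    map00830 = list(
      compounds = c("C00473", "C00376", "C02588"),
      enzymes = c("1.1.1.1", "1.14.14.1"),
      reactions = list(rx("C00473", "C00376", "1.1.1.1", "R01041"))),
    map00980 = list(
      compounds = c("C07535", "C14039", "C00051"),
      enzymes = c("2.5.1.18", "1.14.14.1"),
      reactions = list(rx("C07535", "C14039", "1.14.14.1", "R09404"))),
    map00982 = list(
      compounds = c("C07047", "C16844", "C00051"),
      enzymes = c("2.5.1.18", "1.14.14.1", "1.1.1.1"),
      reactions = list(rx("C07047", "C16844", "1.14.14.1", "R08359")))
  )
}

#' Mock up-regulated gene list and gene-to-enzyme map
#'
#' 66 up-regulated gene symbols (a hypoxia-flavoured synthetic list). Ten
#' carry gene-map rows pointing at enzymes present in the fixture pathways;
#' one maps to an enzyme absent from every fixture pathway (exercising the
#' zero-hit warning path); the rest have no map entry.
#' @noRd
fixture_genes <- function() {
  mapped <- data.frame(
    input_id = c("PKM2", "LDHA", "PGK1", "P4HA1", "PFKFB3", "BDH1",
                 "PLA2G4A", "ADH7", "GSTP1", "CYP1A1", "ALDOC"),
    entrez_id = c(5315L, 3939L, 5230L, 5033L, 5209L, 622L,
                  5321L, 131L, 2950L, 1543L, 230L),
    enzyme = c("2.7.1.40", "1.1.1.27", "2.7.2.3", "1.14.11.2", "2.7.1.105",
               "1.1.1.30", "3.1.1.4", "1.1.1.1", "2.5.1.18", "1.14.14.1",
               "4.1.2.13")   # 4.1.2.13 absent from every fixture pathway
  )
  filler <- c("VEGFA", "SLC2A1", "CA9", "ADM", "NDRG1", "EGLN3", "BNIP3",
              "ANKRD37", "DDIT4", "P4HB", "ANGPTL4", "PLOD2", "STC2",
              "AK3L1", "MXI1", "WSB1", "KDM3A", "RORA", "BHLHE40", "PPFIA4",
              "ENO2P", "INSIG2", "GPI1P", "PDK1L", "FAM162A", "KCTD11",
              "PGM1L", "TPI1P", "DDX41L", "RBPJL", "HERPUD1", "SERTAD1",
              "JMJD6L", "TMEM45A", "C4orf3", "GBE1L", "IRS2L", "CCNG2L",
              "VLDLRL", "PFKPL", "SLC16A3", "LOXL2", "CITED2", "KLF10",
              "BNIP3L", "PIM1L", "NOL3L", "RRAGDL", "GYS1L", "HK2L",
              "ERO1A", "PPP1R3C", "CXCR4L", "MAFFL", "ZNF395")
  list(genes = c(mapped$input_id, filler), gene_map = mapped)
}

#' Write the KGML-subset pathway fixture
#'
#' Emits one KGML-subset XML file per pathway of the reference membership
#' table (compound and enzyme entries plus consistent reactions), the mock
#' 66-entry up-regulated gene list (`gene_list.tsv`), the gene-to-enzyme
#' map (`gene_map.tsv`) and the metabolite panel (`panel.tsv`). Running
#' [parse_kgml()], [map_metabolites()] and [map_genes()] on the fixture
#' reproduces the reference membership exactly. Shared IDs across files
#' denote the same entity.
#'
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `kgml_files`, `gene_list`, `gene_map`,
#'   `panel` paths.
#' @export
make_pathway_fixture <- function(outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir) || file.access(outdir, 2) != 0) {
    abort("UNWRITABLE", sprintf("cannot write to '%s'", outdir))
  }
  ref <- pathway_membership_reference()
  defs <- fixture_pathways()
  kgml_files <- character(0)
  for (pid in names(defs)) {
    d <- defs[[pid]]
    title <- ref$name[match(pid, ref$pathway_id)]
    lines <- c(sprintf('<?xml version="1.0"?>'),
               sprintf('<!-- synthetic KGML-subset fixture: reduced entity set for %s -->', pid),
               sprintf('<pathway name="path:%s" org="map" number="%s" title="%s">',
                       pid, sub("^map", "", pid), title))
    id <- 0
    for (cpd in d$compounds) {
      id <- id + 1
      lines <- c(lines, sprintf('  <entry id="%d" name="cpd:%s" type="compound"/>', id, cpd))
    }
    for (enz in d$enzymes) {
      id <- id + 1
      lines <- c(lines, sprintf('  <entry id="%d" name="ec:%s" type="enzyme"/>', id, enz))
    }
    for (r in d$reactions) {
      id <- id + 1
      lines <- c(lines, sprintf('  <reaction id="%d" name="rn:%s" type="irreversible" enzyme="ec:%s">',
                                id, r$name, r$enzyme))
      lines <- c(lines, sprintf('    <substrate name="cpd:%s"/>', r$substrates),
                 sprintf('    <product name="cpd:%s"/>', r$products),
                 '  </reaction>')
    }
    lines <- c(lines, '</pathway>')
    f <- file.path(outdir, paste0(pid, ".xml"))
    writeLines(lines, f)
    kgml_files <- c(kgml_files, f)
  }
  gg <- fixture_genes()
  gene_list <- file.path(outdir, "gene_list.tsv")
  writeLines(gg$genes, gene_list)
  gene_map <- file.path(outdir, "gene_map.tsv")
  utils::write.table(gg$gene_map, gene_map, sep = "\t", row.names = FALSE, quote = FALSE)
  panel <- file.path(outdir, "panel.tsv")
  utils::write.table(panel_compounds(), panel, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(kgml_files = kgml_files, gene_list = gene_list,
                 gene_map = gene_map, panel = panel))
}
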