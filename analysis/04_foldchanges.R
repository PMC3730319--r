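#!/usr/bin/env Rscript
# Step 4 -- targeted quantification and fold changes.
#
# Quantifies the 17-metabolite panel in every preprocessed spectrum by
# non-negative least squares on the template library, normalizes each
# sample to its total concentration, and computes signed median fold
# changes (hypoxia / normoxia) per metabolite and time point.

library(hypoxiaNMR)

outdir <- "results/04_foldchanges"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

spectra <- lapply(list.files("results/01_simulate/spectra", full.names = TRUE),
                  read_spectrum)
prep <- lapply(spectra, preprocess_spectrum)
conc <- normalize_total(quantify_study(prep))
write.csv(conc, file.path(outdir, "concentrations.csv"), row.names = FALSE)

fc <- fold_changes(conc)
write_fold_changes(fc, file.path(outdir, "fold_changes.tsv"))
hm <- heatmap_matrix(fc)
write_heatmap_matrix(hm, file.path(outdir, "heatmap_matrix.csv"))

f48 <- fc[fc$time_point == "48h" & !fc$missing, ]
up <- f48[order(-f48$signed_ratio), ][1:3, ]
dn <- f48[order(f48$signed_ratio), ][1:3, ]
cat("48 h fold changes (signed ratio, hypoxia vs normoxia):\n")
cat(sprintf("  strongest increases: %s\n",
            paste(sprintf("%s %+.2f", up$metabolite, up$signed_ratio), collapse = ", ")))
cat(sprintf("  strongest decreases: %s\n",
            paste(sprintf("%s %+.2f", dn$metabolite, dn$signed_ratio), collapse = ", ")))
cat(sprintf("  masked (below detection): %s\n",
            paste(fc$metabolite[fc$missing], fc$time_point[fc$missing],
                  collapse = "; ")))
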