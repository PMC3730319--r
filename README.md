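# hypoxiaNMR

An R package and analysis workflow for ¹H-NMR metabolomics of tumour
hypoxia. It re-implements, end to end and with tests, a time-course study
of MDA-MB-231 breast cancer cells under hypoxia (0.5% O₂) versus normoxia
(4, 24, 48 h; 9 replicates per condition per time point, 54 samples): from
spectra to discriminating metabolites, fold changes, classifiers, and a
metabolome–transcriptome pathway network. Because the original raw spectra
were never deposited, the package includes a first-class synthetic-data
generator that emulates the study design and its reported effect sizes, so
every stage of the pipeline is testable offline.

It is aimed at metabolomics and systems-biology researchers who want a
reproducible, scriptable version of this analysis pattern: spectral
post-processing → chemometric feature selection → targeted quantification
→ classification → pathway integration.

## The methods at the core

* **Spectral post-processing.** Each spectrum is aligned to the α-glucose
  anomeric doublet at 5.223 ppm (TMSP at 0 ppm as fallback), scaled to the
  TMSP peak intensity, stripped of the 4.5–5.0 ppm water region, baseline
  corrected by asymmetric least squares
  (min Σᵢ wᵢ(yᵢ−zᵢ)² + λΣ(Δ²zᵢ)²), normalized by the 5–95% trimmed mean of
  the 0.2–4.4 ppm window, and binned into 420 bins of 0.01 ppm.
* **Selection.** Mean-centered PCA on the binned matrix; per bin the
  loading distance dⱼ = √(p²ⱼ₁ + p²ⱼ₂) ranks contribution to the PC1/PC2
  plane; bins above the 90th-percentile threshold merge into regions,
  confirmed by paired t-tests (α = 0.05) across hypoxia/normoxia replicate
  pairs, then mapped to metabolites via a peak-template library.
* **Fold changes.** Per metabolite and time point, the ratio of group
  medians r = med(hypoxia)/med(normoxia), reported as a signed ratio (+r
  if r ≥ 1, else −1/r) and as log₂ r; below-detection groups yield masked
  cells.
* **Classification.** Per time point, a stratified 2/3 split (6+6 train,
  3+3 test), linear SVM with the cost tuned by leave-one-out
  cross-validation maximizing balanced accuracy BAC =
  (specificity + sensitivity)/2, hypoxia positive.
* **Pathway network.** A KGML-subset reader maps the 17-metabolite panel
  (via KEGG compound IDs) and a 66-entry up-regulated gene list (via a
  local gene→enzyme table) onto pathways; pathways become nodes and edges
  are weighted by the number of shared mapped metabolites plus enzymes.

## Worked example

The numbered scripts under `analysis/` run the whole study and write their
tables under `results/`. Running them in order prints, among other things:

```
$ Rscript analysis/01_simulate.R
simulated 54 spectra (9 per condition x time point)
planted 48 h effects span -4.29 (myo-inositol) to +3.00 (glutamine/valine/leucine);
glucose is below detection at 48 h, pyruvate at 4 h

$ Rscript analysis/03_select.R
  4h: PC1 25%, PC2 18% of variance; condition silhouette -0.01
 24h: PC1 93%, PC2 1% of variance; condition silhouette 0.89  (clear separation)
 48h: PC1 96%, PC2 1% of variance; condition silhouette 0.92  (clear separation)
48 h selection: 29 regions above the loading-distance threshold, 29 significant (paired t, alpha = 0.05)
selected metabolites (17): lactate, alanine, valine, leucine, methionine, glutamine,
glutamate, pyruvate, acetate, ethanol, glycine, taurine, myo-inositol, creatine,
creatine phosphate, proline, glucose

$ Rscript analysis/05_classify.R
test-set performance (hypoxia positive):
    4h: BAC  66.7%  accuracy  66.7%  specificity  66.7%  sensitivity  66.7%
   24h: BAC 100.0%  accuracy 100.0%  specificity 100.0%  sensitivity 100.0%
   48h: BAC 100.0%  accuracy 100.0%  specificity 100.0%  sensitivity 100.0%

$ Rscript analysis/06_pathways.R
metabolome: 14 pathways; transcriptome: 11 pathways
common (4): Glycolysis / Gluconeogenesis; Purine metabolism; Arginine and proline
metabolism; Pyruvate metabolism
metabolome-only: 10 pathways not covered by the transcriptome set
network: 21 nodes, 32 edges; strongest link weight 5 (map00010 -- map00620)
```

Read: at 4 h the hypoxia and normoxia score clusters overlap (silhouette
≈ 0, classification near chance), while by 48 h they separate completely —
the metabolic response to hypoxia emerges between 24 and 48 h. The
selection procedure recovers exactly the 17-metabolite panel planted by
the generator, glucose included (it is implicated through the crowded
3.2–3.9 ppm carbohydrate region although itself depleted at 48 h). Of the
14 pathways hit by the metabolite panel, 4 are shared with the
transcriptome-derived set and 10 are metabolome-only.

`run_all(pipeline_config(seed = 1, outdir = "results/run"))` executes the
same six stages in one call with a validated config and a config hash
stamped into every artifact.

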