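#' The 17-metabolite peak-template library
#'
#' Returns the fixed template library used both to render synthetic spectra
#' and to identify/quantify metabolites in preprocessed spectra. Each template
#' carries the metabolite name, its KEGG compound accession, and a set of
#' Lorentzian peaks given as (center ppm, relative area, full-width at
#' half-maximum in ppm). Relative areas sum to 1 per metabolite, so the total
#' spectral area contributed by a metabolite equals its concentration (in the
#' simulator's arbitrary relative units).
#'
#' Chemical shifts are literature values for metabolites in aqueous cell
#' extracts, rounded to 3 decimals; they are fixture constants of this
#' package. The alpha-glucose anomeric doublet at 5.223 ppm doubles as the
#' chemical-shift alignment reference.
#'
#' @param linewidth Default full-width at half-maximum in ppm for all peaks.
#' @return A named list of `metabolite_template` objects with fields
#'   `name`, `kegg_compound_id` and `peaks` (data.frame with columns
#'   `center`, `relative_area`, `linewidth`).
#' @export
#' @examples
#' lib <- metabolite_library()
#' names(lib)
#' lib$lactate$peaks
metabolite_library <- function(linewidth = 0.004) {
  spec <- list(
    ## name, KEGG compound, peak centers, relative areas
    lactate          = list("C00186", c(1.326, 4.114),                       c(0.75, 0.25)),
    alanine          = list("C00041", c(1.477, 3.782),                       c(0.75, 0.25)),
    valine           = list("C00183", c(0.988, 1.035, 2.274),                c(0.40, 0.40, 0.20)),
    leucine          = list("C00123", c(0.961, 1.712),                       c(0.70, 0.30)),
    methionine       = list("C00073", c(2.134, 2.642),                       c(0.60, 0.40)),
    glutamine        = list("C00064", c(2.446, 2.135),                       c(0.60, 0.40)),
    glutamate        = list("C00025", c(2.344, 2.082),                       c(0.70, 0.30)),
    pyruvate         = list("C00022", 2.368,                                 1.00),
    acetate          = list("C00033", 1.918,                                 1.00),
    ethanol          = list("C00469", c(1.176, 3.656),                       c(0.70, 0.30)),
    glycine          = list("C00037", 3.562,                                 1.00),
    taurine          = list("C00245", c(3.258, 3.424),                       c(0.50, 0.50)),
    `myo-inositol`   = list("C00137", c(3.284, 3.528, 3.618, 4.062),         c(0.20, 0.40, 0.20, 0.20)),
    creatine         = list("C00300", c(3.028, 3.926),                       c(0.60, 0.40)),
    `creatine phosphate` = list("C02305", c(3.048, 3.946),                   c(0.60, 0.40)),
    proline          = list("C00148", c(2.008, 3.338, 4.124),                c(0.35, 0.40, 0.25)),
    glucose          = list("C00031", c(3.246, 3.412, 3.474, 3.736, 3.886, 5.223),
                                      c(0.15, 0.15, 0.15, 0.25, 0.15, 0.15))
  )
  lib <- lapply(names(spec), function(nm) {
    x <- spec[[nm]]
    new_metabolite_template(
      name = nm,
      kegg_compound_id = x[[1]],
      peaks = data.frame(center = x[[2]], relative_area = x[[3]], linewidth = linewidth)
    )
  })
  names(lib) <- names(spec)
  lib
}

#' Construct and validate a metabolite template
#'
#' @param name Metabolite identifier, unique within a library.
#' @param kegg_compound_id KEGG compound accession (e.g. `"C00186"`).
#' @param peaks data.frame with columns `center` (ppm), `relative_area`
#'   (positive, summing to 1) and `linewidth` (FWHM, ppm).
#' @return A `metabolite_template` object.
#' @export
new_metabolite_template <- function(name, kegg_compound_id, peaks) {
  stopifnot(is.character(name), nzchar(name),
            is.data.frame(peaks),
            all(c("center", "relative_area", "linewidth") %in% names(peaks)))
  if (any(peaks$center < 0 | peaks$center > 10)) {
    abort("BAD_TEMPLATE", sprintf("template '%s': peak centers must lie in 0-10 ppm", name))
  }
  if (any(peaks$relative_area <= 0) || abs(sum(peaks$relative_area) - 1) > 1e-8) {
    abort("BAD_TEMPLATE", sprintf("template '%s': relative areas must be positive and sum to 1", name))
  }
  structure(list(name = name, kegg_compound_id = kegg_compound_id, peaks = peaks),
            class = "metabolite_template")
}

#' @export
print.metabolite_template <- function(x, ...) {
  cat(sprintf("<metabolite_template> %s (%s), %d peak(s)\n",
              x$name, x$kegg_compound_id, nrow(x$peaks)))
  print(x$peaks)
  invisible(x)
}

#' Names of the 17-metabolite hypoxia panel
#' @return Character vector of metabolite names in the fixed display order.
#' @export
panel_metabolites <- function() names(metabolite_library())

#' Panel metabolites with their KEGG compound accessions
#' @return data.frame with columns `metabolite` and `compound_id`.
#' @export
panel_compounds <- function() {
  lib <- metabolite_library()
  data.frame(metabolite = vapply(lib, `[[`, "", "name"),
             compound_id = vapply(lib, `[[`, "", "kegg_compound_id"),
             row.names = NULL)
}
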