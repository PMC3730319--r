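#' Study design for the hypoxia time-course
#'
#' Two conditions (hypoxia, normoxia) at three treatment durations with equal
#' group sizes; the default reproduces the 54-sample design (9 samples per
#' condition per time point).
#'
#' @param n_per_group Samples per condition per time point.
#' @param time_points Ordered treatment durations.
#' @param seed Integer seed attached to the design.
#' @return A `study_design` object.
#' @export
study_design <- function(n_per_group = 9, time_points = TIME_POINTS, seed = 1L) {
  stopifnot(n_per_group >= 1, length(time_points) >= 1)
  structure(list(n_per_group = as.integer(n_per_group),
                 time_points = time_points,
                 conditions = CONDITIONS,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Samples-by-metabolites layout for a design
#' @noRd
design_samples <- function(design) {
  g <- expand.grid(replicate = seq_len(design$n_per_group),
                   condition = design$conditions,
                   time_point = design$time_points,
                   stringsAsFactors = FALSE)
  g$sample_id <- sprintf("%s_%s_r%d", g$condition, g$time_point, g$replicate)
  g[, c("sample_id", "condition", "time_point", "replicate")]
}

#' Simulate a metabolite concentration table
#'
#' Per sample, concentration = baseline level x hypoxia effect (signed fold
#' ratio applied to hypoxia samples only: ratio r > 0 multiplies by r, r < 0
#' by 1/|r|) x multiplicative lognormal noise with the given coefficient of
#' variation. Entries marked below-detection (`NA` in the effect table) are
#' drawn near `below_dl_level` in both groups and flagged missing.
#'
#' @param design A [study_design()].
#' @param effects An `effect_table` (see [default_effect_table()]).
#' @param cv Coefficient of variation of the multiplicative lognormal noise
#'   (0 = noise-free).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param baseline Baseline concentration level(s): scalar or vector named by
#'   metabolite. Must be positive.
#' @param detection_limit Concentrations below this value are flagged missing.
#' @param below_dl_level Level at which undetectable entries are simulated.
#' @return A `concentration_table`: data.frame with metadata columns
#'   (`sample_id`, `condition`, `time_point`, `replicate`) and one column per
#'   panel metabolite; attributes `detection_limit` and `missing_mask`
#'   (samples x metabolites logical matrix).
#' @export
#' @examples
#' tab <- simulate_concentrations(study_design(), default_effect_table(),
#'                                cv = 0, seed = 1)
#' ## noise-free hypoxia/normoxia ratio for lactate at 48 h is exactly 1.99
simulate_concentrations <- function(design, effects, cv = 0.1, seed = NULL,
                                    baseline = 1, detection_limit = 0.05,
                                    below_dl_level = 0.01) {
  stopifnot(inherits(design, "study_design"), cv >= 0)
  mets <- effects$metabolite
  base <- if (length(baseline) == 1) stats::setNames(rep(baseline, length(mets)), mets) else baseline[mets]
  if (any(!is.finite(base)) || any(base <= 0)) {
    abort("BAD_BASELINE", "baseline levels must be positive and finite")
  }
  samples <- design_samples(design)
  if (any(!samples$time_point %in% names(effects))) {
    abort("BAD_DESIGN", "design time points missing from the effect table")
  }
  with_seed(seed, {
    sdlog <- sqrt(log(1 + cv^2))
    n <- nrow(samples)
    vals <- matrix(NA_real_, n, length(mets), dimnames = list(samples$sample_id, mets))
    for (j in seq_along(mets)) {
      for (i in seq_len(n)) {
        r <- effects[[samples$time_point[i]]][j]
        level <- if (is.na(r)) {
          below_dl_level
        } else if (samples$condition[i] == "hypoxia") {
          base[j] * (if (r >= 0) r else 1 / abs(r))
        } else {
          base[j]
        }
        noise <- if (cv > 0) stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
        vals[i, j] <- level * noise
      }
    }
    out <- cbind(samples, as.data.frame(vals, check.names = FALSE))
    attr(out, "detection_limit") <- detection_limit
    attr(out, "missing_mask") <- vals < detection_limit
    class(out) <- c("concentration_table", "data.frame")
    out
  })
}

#' Extract the numeric concentration matrix from a table
#' @param tab A `concentration_table`.
#' @return Numeric samples x metabolites matrix.
#' @export
conc_values <- function(tab) {
  meta <- c("sample_id", "condition", "time_point", "replicate")
  m <- as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE])
  rownames(m) <- tab$sample_id
  m
}

#' Rendering settings for synthetic spectra
#'
#' @param axis Descending uniform ppm axis (see [default_ppm_axis()]).
#' @param tmsp_area Area of the TMSP reference singlet at 0.00 ppm.
#' @param tmsp_linewidth FWHM of the TMSP singlet (ppm).
#' @param water_center,water_sd,water_area Broad Gaussian water artifact
#'   (centered in the 4.5-5.0 ppm removal window).
#' @param drift_amplitude Amplitude of the smooth cubic baseline drift.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param gain Global detector gain multiplying the whole trace (signal,
#'   drift and noise alike).
#' @param shift Rigid chemical-shift calibration error (ppm) applied to all
#'   features.
#' @return A list of class `render_params`.
#' @export
render_params <- function(axis = default_ppm_axis(), tmsp_area = 0.3,
                          tmsp_linewidth = 0.003, water_center = 4.75,
                          water_sd = 0.07, water_area = 20,
                          drift_amplitude = 2, noise_sd = 0.2, gain = 1,
                          shift = 0) {
  structure(list(axis = axis, tmsp_area = tmsp_area,
                 tmsp_linewidth = tmsp_linewidth, water_center = water_center,
                 water_sd = water_sd, water_area = water_area,
                 drift_amplitude = drift_amplitude, noise_sd = noise_sd,
                 gain = gain, shift = shift),
            class = "render_params")
}

#' Lorentzian line shape with unit area
#' @noRd
lorentz <- function(x, center, fwhm) {
  (2 / (pi * fwhm)) / (1 + (2 * (x - center) / fwhm)^2)
}

#' Render a synthetic 1H-NMR spectrum from metabolite concentrations
#'
#' The spectrum is the sum over metabolites of concentration-scaled
#' Lorentzian peaks from the template library, plus a TMSP reference singlet
#' of fixed area at 0.00 ppm, a broad Gaussian water artifact inside the
#' 4.5-5.0 ppm region, a smooth low-order polynomial baseline drift, and
#' additive Gaussian noise. The total area contributed by a metabolite is
#' proportional to its concentration.
#'
#' @param concentrations Named numeric vector of metabolite concentrations
#'   (names must match templates in `library`).
#' @param library Template library from [metabolite_library()].
#' @param params Render settings from [render_params()].
#' @param seed Integer seed for drift and noise; `NULL` uses the current RNG
#'   stream.
#' @param sample_id,condition,time_point,replicate Metadata for the result.
#' @return An `nmr_spectrum`.
#' @export
render_spectrum <- function(concentrations, library = metabolite_library(),
                            params = render_params(), seed = NULL,
                            sample_id = "sample", condition = NA_character_,
                            time_point = NA_character_, replicate = NA_integer_) {
  x <- params$axis
  if (length(x) < 3 || any(diff(x) >= 0)) {
    abort("BAD_AXIS", "ppm axis must be strictly descending")
  }
  steps <- diff(x)
  if (max(abs(steps - steps[1])) > 1e-9) {
    abort("BAD_AXIS", "ppm axis must be uniformly spaced")
  }
  if (min(x) > 0.2 || max(x) < 4.4) {
    abort("BAD_AXIS", "ppm axis must cover the 0.2-4.4 ppm analysis window")
  }
  if (any(!names(concentrations) %in% names(library))) {
    missing_t <- setdiff(names(concentrations), names(library))
    abort("NO_TEMPLATE", paste("no template for metabolite(s):", paste(missing_t, collapse = ", ")))
  }
  d <- params$shift
  y <- numeric(length(x))
  for (nm in names(concentrations)) {
    conc <- concentrations[[nm]]
    if (is.na(conc) || conc == 0) next
    pk <- library[[nm]]$peaks
    for (i in seq_len(nrow(pk))) {
      y <- y + conc * pk$relative_area[i] * lorentz(x, pk$center[i] + d, pk$linewidth[i])
    }
  }
  y <- y + params$tmsp_area * lorentz(x, 0 + d, params$tmsp_linewidth)
  y <- y + params$water_area * stats::dnorm(x, params$water_center + d, params$water_sd)
  with_seed(seed, {
    if (params$drift_amplitude != 0) {
      u <- (x - min(x)) / diff(range(x))
      cf <- stats::runif(4, -1, 1)
      y <- y + params$drift_amplitude * (cf[1] + cf[2] * u + cf[3] * u^2 + cf[4] * u^3)
    }
    if (params$noise_sd > 0) {
      y <- y + stats::rnorm(length(x), 0, params$noise_sd)
    }
    new_spectrum(x, params$gain * y, sample_id = sample_id, condition = condition,
                 time_point = time_point, replicate = replicate)
  })
}

#' Generate the full synthetic hypoxia study
#'
#' Simulates the ground-truth concentration table for the default 54-sample
#' design (9 hypoxia + 9 normoxia at 4, 24 and 48 h), then renders one
#' spectrum per sample, each with its own small random chemical-shift
#' calibration error so the alignment step has real work to do.
#'
#' @param seed Integer seed; the whole study is a pure function of it.
#' @param design Study design (default: the 54-sample design).
#' @param effects Effect table (default: [default_effect_table()]).
#' @param cv Concentration noise coefficient of variation.
#' @param params Render settings shared by all samples.
#' @param library Template library.
#' @param shift_sd Standard deviation (ppm) of the per-sample calibration
#'   shift.
#' @param ... Passed to [simulate_concentrations()].
#' @return An `nmr_study`: list with `spectra` (list of 54 `nmr_spectrum`)
#'   and `truth` (the ground-truth `concentration_table`).
#' @export
make_study <- function(seed = 1L, design = study_design(seed = seed),
                       effects = default_effect_table(), cv = 0.1,
                       params = render_params(), library = metabolite_library(),
                       shift_sd = 0.004, ...) {
  with_seed(seed, {
    truth <- simulate_concentrations(design, effects, cv = cv, seed = NULL, ...)
    vals <- conc_values(truth)
    spectra <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      p <- params
      p$shift <- stats::rnorm(1, 0, shift_sd)
      spectra[[i]] <- render_spectrum(
        vals[i, ], library = library, params = p, seed = NULL,
        sample_id = truth$sample_id[i], condition = truth$condition[i],
        time_point = truth$time_point[i], replicate = truth$replicate[i]
      )
    }
    names(spectra) <- truth$sample_id
    structure(list(spectra = spectra, truth = truth, seed = seed),
              class = "nmr_study")
  })
}

#' @export
print.nmr_study <- function(x, ...) {
  cat(sprintf("<nmr_study> %d spectra, seed %d\n", length(x$spectra), x$seed))
  print(table(condition = x$truth$condition, time_point = x$truth$time_point))
  invisible(x)
}
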