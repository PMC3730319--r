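## Spectral post-processing: alignment, TMSP scaling, water removal,
## baseline correction, robust-mean normalization and fixed-width binning.
## Pipeline order: align -> scale -> water removal -> baseline -> normalize
## -> bin.

#' Locate a reference peak near a nominal position
#'
#' Searches `nominal +/- window` for the apex and refines it by quadratic
#' interpolation through the apex and its two neighbours (sub-pixel
#' position). The apex must rise above the local median by at least
#' `snr_min` times the robust noise estimate, otherwise the peak is deemed
#' absent.
#'
#' @return list(center, height) or NULL when no qualifying peak exists.
#' @noRd
find_reference_peak <- function(s, nominal, window = 0.1, snr_min = 5) {
  idx <- which(s$ppm >= nominal - window & s$ppm <= nominal + window)
  if (length(idx) < 5) return(NULL)
  y <- s$intensity[idx]
  noise <- estimate_noise(s$intensity)
  if (!is.finite(noise) || noise <= 0) noise <- stats::sd(y) * 1e-3 + 1e-12
  k <- which.max(y)
  prominence <- y[k] - stats::median(y)
  if (prominence < snr_min * noise) return(NULL)
  i <- idx[k]
  center <- s$ppm[i]
  if (i > 1 && i < length(s$ppm)) {
    y0 <- s$intensity[i - 1]; y1 <- s$intensity[i]; y2 <- s$intensity[i + 1]
    denom <- y0 - 2 * y1 + y2
    if (is.finite(denom) && abs(denom) > 0) {
      frac <- 0.5 * (y0 - y2) / denom          # offset in index units
      frac <- max(-0.5, min(0.5, frac))
      step <- s$ppm[i + 1] - s$ppm[i]          # negative (descending axis)
      center <- s$ppm[i] + frac * step
    }
  }
  list(center = center, height = max(y))
}

#' Align a spectrum to a chemical-shift reference
#'
#' Rigidly shifts the ppm axis so that the detected reference feature (the
#' alpha-glucose anomeric doublet at 5.223 ppm, or the TMSP singlet at
#' 0 ppm) sits at its nominal position. Intensities are unchanged. When
#' glucose is depleted below detection (48 h samples) the glucose reference
#' is absent; [align_spectrum()] falls back to TMSP in that case.
#'
#' @param s An `nmr_spectrum`.
#' @param mode Reference feature: `"glucose_5.223"` or `"tmsp_0"`.
#' @param window Half-width (ppm) of the search window around the nominal
#'   position.
#' @param snr_min Minimum apex prominence in units of the robust noise level.
#' @return The aligned spectrum, with attribute `shift_applied` (ppm).
#' @export
align_to_reference <- function(s, mode = c("glucose_5.223", "tmsp_0"),
                               window = 0.1, snr_min = 5) {
  mode <- match.arg(mode)
  nominal <- if (mode == "glucose_5.223") 5.223 else 0
  pk <- find_reference_peak(s, nominal, window = window, snr_min = snr_min)
  if (is.null(pk)) {
    abort("REFERENCE_NOT_FOUND",
          sprintf("no reference peak found within %.3f +/- %.2f ppm", nominal, window))
  }
  shift <- nominal - pk$center
  out <- s
  out$ppm <- s$ppm + shift
  attr(out, "shift_applied") <- shift
  out
}

#' Align with glucose reference and TMSP fallback
#'
#' Tries the alpha-glucose anomeric doublet first; when it is not detectable
#' (e.g. glucose depleted after 48 h of treatment) falls back to the TMSP
#' singlet at 0 ppm and records the fallback in attribute `align_mode`.
#'
#' @inheritParams align_to_reference
#' @param quiet Suppress the fallback message.
#' @return Aligned spectrum with attributes `shift_applied` and `align_mode`.
#' @export
align_spectrum <- function(s, window = 0.1, snr_min = 5, quiet = TRUE) {
  out <- tryCatch(align_to_reference(s, "glucose_5.223", window, snr_min),
                  hypoxiaNMR_reference_not_found = function(e) NULL)
  mode <- "glucose_5.223"
  if (is.null(out)) {
    if (!quiet) message(sprintf("%s: glucose reference not found, falling back to TMSP", s$sample_id))
    out <- align_to_reference(s, "tmsp_0", window, snr_min)
    mode <- "tmsp_0"
  }
  attr(out, "align_mode") <- mode
  out
}

#' Scale spectral intensities to the TMSP reference
#'
#' Divides all intensities by the maximum intensity of the TMSP peak near
#' 0 ppm, so the TMSP apex becomes 1. Removes dependence on detector gain.
#'
#' @param s An `nmr_spectrum` (aligned).
#' @param window Half-width (ppm) of the TMSP search window.
#' @param snr_min Minimum apex prominence in noise units.
#' @return The scaled spectrum.
#' @export
scale_to_tmsp <- function(s, window = 0.05, snr_min = 5) {
  pk <- find_reference_peak(s, 0, window = window, snr_min = snr_min)
  if (is.null(pk) || pk$height <= 0) {
    abort("REFERENCE_NOT_FOUND", "TMSP peak not detectable near 0 ppm")
  }
  out <- s
  out$intensity <- s$intensity / pk$height
  out
}

#' Excise the residual water region
#'
#' Removes all points with `lo <= ppm <= hi` from both the axis and the
#' intensity vector (default 4.5-5.0 ppm). Points are excised, not zeroed,
#' so later stages never see the artifact.
#'
#' @param s An `nmr_spectrum`.
#' @param lo,hi Closed excision interval (ppm), `lo < hi`.
#' @return The spectrum without the water region.
#' @export
remove_water <- function(s, lo = 4.5, hi = 5.0) {
  stopifnot(lo < hi)
  keep <- s$ppm < lo | s$ppm > hi
  out <- s
  out$ppm <- s$ppm[keep]
  out$intensity <- s$intensity[keep]
  out
}

#' Asymmetric-least-squares baseline correction
#'
#' Estimates a slowly varying baseline by iteratively reweighted penalized
#' least squares: the baseline z minimizes
#' `sum_i w_i (y_i - z_i)^2 + smoothness * sum_i (delta^2 z_i)^2`,
#' with asymmetric weights (`asymmetry` for points above the baseline, `1 -
#' asymmetry` below), so peaks are ignored while the smooth background is
#' tracked. The estimated baseline is subtracted.
#'
#' @param s An `nmr_spectrum` with at least 100 points.
#' @param smoothness Second-difference penalty (larger = stiffer baseline).
#' @param asymmetry Weight given to points above the baseline (0 < p < 0.5).
#' @param iterations Reweighting iterations.
#' @return Baseline-corrected spectrum, with the estimate in attribute
#'   `baseline`.
#' @export
baseline_correct <- function(s, smoothness = 1e8, asymmetry = 0.001,
                             iterations = 10) {
  n <- length(s$intensity)
  if (n < 100) abort("TOO_SHORT", "baseline correction needs at least 100 points")
  y <- s$intensity
  z <- .als_baseline(y, smoothness, asymmetry, as.integer(iterations))
  out <- s
  out$intensity <- y - z
  attr(out, "baseline") <- z
  out
}

#' Robust-mean normalization
#'
#' Divides all intensities by the trimmed mean (central 90% by default) of
#' the intensities inside the analysis window, so that statistic equals 1
#' after normalization. Scale-invariant and idempotent.
#'
#' @param s An `nmr_spectrum`.
#' @param lo,hi Analysis window (ppm).
#' @param trim Fraction trimmed from each tail (0.05 keeps the central 90%).
#' @return The normalized spectrum.
#' @export
robust_mean_normalize <- function(s, lo = 0.2, hi = 4.4, trim = 0.05) {
  win <- s$intensity[s$ppm >= lo & s$ppm <= hi]
  if (length(win) == 0) abort("DEGENERATE_SPECTRUM", "no points in the analysis window")
  m <- mean(win, trim = trim)
  if (!is.finite(m) || m <= 0) {
    abort("DEGENERATE_SPECTRUM", "trimmed mean of the analysis window is not positive")
  }
  out <- s
  out$intensity <- s$intensity / m
  out
}

#' Bin a spectrum into fixed-width chemical-shift bins
#'
#' Aggregates intensities into `(hi - lo)/width` bins over the analysis
#' window (default: 420 bins of 0.01 ppm over 0.2-4.4 ppm). A point falls in
#' bin j when `lo + width*(j-1) <= ppm < lo + width*j` (half-open on the
#' ascending-ppm axis); the boundary point at `hi` is kept in the last bin.
#' Bin values are sums, so total in-range intensity is conserved.
#'
#' @param s An `nmr_spectrum` covering `[lo, hi]`.
#' @param lo,hi Analysis window (ppm).
#' @param width Bin width (ppm); `(hi - lo)/width` must be integral.
#' @return Named numeric vector of bin values (names = bin-center ppm to 3
#'   decimals), with attribute `bin_edges` (ascending, length nbins + 1).
#' @export
bin_spectrum <- function(s, lo = 0.2, hi = 4.4, width = 0.01) {
  nbins_f <- (hi - lo) / width
  nbins <- round(nbins_f)
  if (abs(nbins_f - nbins) > 1e-8) {
    abort("BAD_BINS", "(hi - lo) / width must be an integer number of bins")
  }
  if (min(s$ppm) > lo + 1e-9 || max(s$ppm) < hi - 1e-9) {
    abort("COVERAGE", sprintf("spectrum does not span the %.2f-%.2f ppm window", lo, hi))
  }
  edges <- lo + width * (0:nbins)
  inr <- s$ppm >= lo & s$ppm <= hi
  p <- s$ppm[inr]
  y <- s$intensity[inr]
  ## half-open [edge_j, edge_{j+1}) against the edges themselves; the point
  ## at hi is kept in the last bin
  j <- findInterval(p, edges, rightmost.closed = TRUE)
  vals <- numeric(nbins)
  acc <- rowsum(y, j)
  vals[as.integer(rownames(acc))] <- acc[, 1]
  names(vals) <- sprintf("ppm_%.3f", edges[-length(edges)] + width / 2)
  attr(vals, "bin_edges") <- edges
  vals
}

#' Run the full post-processing chain on one spectrum
#'
#' Order: reference alignment (glucose with TMSP fallback), TMSP intensity
#' scaling, water-region excision, asymmetric-least-squares baseline
#' correction, robust-mean normalization.
#'
#' @param s A raw `nmr_spectrum`.
#' @param water Excision interval, `c(lo, hi)` in ppm.
#' @param smoothness,asymmetry Baseline parameters (see
#'   [baseline_correct()]).
#' @param trim Trimmed-mean fraction for normalization.
#' @return The preprocessed spectrum.
#' @export
preprocess_spectrum <- function(s, water = c(4.5, 5.0), smoothness = 1e8,
                                asymmetry = 0.001, trim = 0.05) {
  s <- align_spectrum(s)
  s <- scale_to_tmsp(s)
  s <- remove_water(s, water[1], water[2])
  s <- baseline_correct(s, smoothness = smoothness, asymmetry = asymmetry)
  robust_mean_normalize(s, trim = trim)
}

#' Preprocess and bin a set of spectra into a BinnedMatrix
#'
#' @param spectra List of raw `nmr_spectrum` objects.
#' @param lo,hi,width Binning parameters (defaults give 420 bins of
#'   0.01 ppm over 0.2-4.4 ppm).
#' @param preprocess Apply [preprocess_spectrum()] first (set `FALSE` when
#'   the spectra are already preprocessed).
#' @param ... Passed to [preprocess_spectrum()].
#' @return A `binned_matrix`: list with `values` (samples x bins matrix),
#'   `bin_edges`, and `meta` (data.frame with sample_id, condition,
#'   time_point, replicate).
#' @export
bin_spectra <- function(spectra, lo = 0.2, hi = 4.4, width = 0.01,
                        preprocess = TRUE, ...) {
  rows <- lapply(spectra, function(s) {
    if (preprocess) s <- preprocess_spectrum(s, ...)
    bin_spectrum(s, lo = lo, hi = hi, width = width)
  })
  values <- do.call(rbind, rows)
  rownames(values) <- vapply(spectra, `[[`, "", "sample_id")
  meta <- data.frame(
    sample_id = vapply(spectra, `[[`, "", "sample_id"),
    condition = vapply(spectra, `[[`, "", "condition"),
    time_point = vapply(spectra, `[[`, "", "time_point"),
    replicate = vapply(spectra, function(s) as.integer(s$replicate), 1L),
    row.names = NULL
  )
  structure(list(values = values, bin_edges = attr(rows[[1]], "bin_edges"),
                 meta = meta),
            class = "binned_matrix")
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat(sprintf("<binned_matrix> %d samples x %d bins (%.2f-%.2f ppm)\n",
              nrow(x$values), ncol(x$values),
              min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' Subset a binned matrix by sample metadata
#' @param m A `binned_matrix`.
#' @param time_point,condition Optional filters.
#' @return A `binned_matrix` with the matching samples.
#' @export
subset_binned <- function(m, time_point = NULL, condition = NULL) {
  keep <- rep(TRUE, nrow(m$meta))
  if (!is.null(time_point)) keep <- keep & m$meta$time_point %in% time_point
  if (!is.null(condition)) keep <- keep & m$meta$condition %in% condition
  structure(list(values = m$values[keep, , drop = FALSE],
                 bin_edges = m$bin_edges, meta = m$meta[keep, , drop = FALSE]),
            class = "binned_matrix")
}

#' Write a binned matrix as CSV
#'
#' First column `sample_id`, then one column per bin labeled by bin-center
#' ppm to 3 decimals, in fixed ascending order.
#'
#' @param m A `binned_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_binned_matrix <- function(m, path) {
  df <- data.frame(sample_id = m$meta$sample_id, m$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
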