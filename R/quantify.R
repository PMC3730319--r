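## Targeted metabolite quantification from preprocessed spectra,
## total-concentration normalization, and signed median fold changes.

#' Quantify panel metabolites in one preprocessed spectrum
#'
#' Fits the template peak shapes to the spectrum by non-negative least
#' squares over the analysis window: the design matrix holds one column per
#' metabolite (its unit-concentration Lorentzian comb evaluated on the
#' observed axis) and the fitted coefficients are relative concentrations.
#' Metabolites whose fitted peak height falls below `detection_sigma` times
#' the residual noise level are flagged below the detection limit.
#'
#' @param s A preprocessed `nmr_spectrum` (see [preprocess_spectrum()]).
#' @param library Template library.
#' @param window Analysis window (ppm) used for the fit.
#' @param detection_sigma Detection limit in residual-noise standard
#'   deviations (default 3).
#' @return Named numeric vector of concentrations (one table row), with
#'   attributes `below_dl` (logical), `noise_sd` and `residual` (fit
#'   residual vector).
#' @export
quantify_targeted <- function(s, library = metabolite_library(),
                              window = c(0.2, 4.4), detection_sigma = 3) {
  inr <- s$ppm >= window[1] & s$ppm <= window[2]
  x <- s$ppm[inr]
  y <- s$intensity[inr]
  A <- vapply(library, function(tmpl) {
    col <- numeric(length(x))
    for (i in seq_len(nrow(tmpl$peaks))) {
      col <- col + tmpl$peaks$relative_area[i] *
        lorentz(x, tmpl$peaks$center[i], tmpl$peaks$linewidth[i])
    }
    col
  }, numeric(length(x)))

  ## overlap guard: near-collinear template pairs make the fit rank-deficient
  cc <- suppressWarnings(stats::cor(A))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 0
  if (any(cc > 0.999)) {
    ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    abort("ILL_CONDITIONED",
          sprintf("templates '%s' and '%s' are nearly collinear on this axis",
                  colnames(A)[ij[1]], colnames(A)[ij[2]]))
  }

  fit <- pracma::lsqnonneg(A, y)
  coefs <- stats::setNames(fit$x, names(library))
  resid <- y - as.numeric(A %*% fit$x)
  noise <- max(estimate_noise(resid), 1e-12)
  heights <- coefs * apply(A, 2, max)
  below <- heights < detection_sigma * noise
  attr(coefs, "below_dl") <- below
  attr(coefs, "noise_sd") <- noise
  attr(coefs, "residual") <- resid
  coefs
}

#' Quantify a list of preprocessed spectra into a concentration table
#'
#' @param spectra List of preprocessed `nmr_spectrum` objects.
#' @param library Template library.
#' @param ... Passed to [quantify_targeted()].
#' @return A `concentration_table` with attribute `missing_mask`.
#' @export
quantify_study <- function(spectra, library = metabolite_library(), ...) {
  rows <- lapply(spectra, quantify_targeted, library = library, ...)
  vals <- do.call(rbind, rows)
  mask <- do.call(rbind, lapply(rows, attr, "below_dl"))
  meta <- data.frame(
    sample_id = vapply(spectra, `[[`, "", "sample_id"),
    condition = vapply(spectra, `[[`, "", "condition"),
    time_point = vapply(spectra, `[[`, "", "time_point"),
    replicate = vapply(spectra, function(s) as.integer(s$replicate), 1L),
    row.names = NULL
  )
  out <- cbind(meta, as.data.frame(vals, check.names = FALSE))
  rownames(mask) <- meta$sample_id
  attr(out, "missing_mask") <- mask
  class(out) <- c("concentration_table", "data.frame")
  out
}

#' Normalize each sample to its total concentration
#'
#' Divides each sample's values by the sum of its non-missing
#' concentrations, so non-missing values sum to 1 per sample. The missing
#' mask is carried through unchanged.
#'
#' @param tab A `concentration_table`.
#' @return The normalized table.
#' @export
normalize_total <- function(tab) {
  vals <- conc_values(tab)
  mask <- attr(tab, "missing_mask")
  if (is.null(mask)) mask <- matrix(FALSE, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  out <- tab
  for (i in seq_len(nrow(vals))) {
    tot <- sum(vals[i, !mask[i, ]])
    if (!is.finite(tot) || tot <= 0) {
      abort("DEGENERATE_SAMPLE",
            sprintf("sample '%s' has no positive non-missing concentration", tab$sample_id[i]))
    }
    vals[i, ] <- vals[i, ] / tot
  }
  out[, colnames(vals)] <- vals
  attr(out, "missing_mask") <- mask
  attr(out, "normalized") <- TRUE
  out
}

#' Signed median fold changes per metabolite and time point
#'
#' The fold ratio is the median hypoxia concentration over the median
#' normoxia concentration. It is reported with the signed convention
#' (ratio >= 1 -> +ratio, ratio < 1 -> -1/ratio; positive = higher under
#' hypoxia) together with the log2 value `log2(ratio)`. A group whose
#' majority of values lies below the detection limit yields a missing
#' record (black cells of the fold-change heatmap).
#'
#' @param tab A `concentration_table` (normalized or raw; the estimator is
#'   scale-invariant within a time point).
#' @return data.frame with columns `metabolite`, `time_point`,
#'   `signed_ratio`, `log2_value`, `missing`.
#' @export
fold_changes <- function(tab) {
  vals <- conc_values(tab)
  mask <- attr(tab, "missing_mask")
  if (is.null(mask)) mask <- matrix(FALSE, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  tps <- unique(tab$time_point)
  mets <- colnames(vals)
  out <- list()
  for (tp in tps) {
    hyp <- tab$time_point == tp & tab$condition == "hypoxia"
    nor <- tab$time_point == tp & tab$condition == "normoxia"
    if (!any(hyp) || !any(nor)) {
      abort("BAD_DESIGN", sprintf("both groups must be present at time point '%s'", tp))
    }
    for (met in mets) {
      miss <- mean(mask[hyp, met]) > 0.5 || mean(mask[nor, met]) > 0.5
      if (miss) {
        out[[length(out) + 1]] <- data.frame(metabolite = met, time_point = tp,
                                             signed_ratio = NA_real_,
                                             log2_value = NA_real_, missing = TRUE)
        next
      }
      mh <- stats::median(vals[hyp, met])
      mn <- stats::median(vals[nor, met])
      if (mh == 0 || mn == 0) {
        abort("ZERO_MEDIAN", sprintf("zero group median for '%s' at %s", met, tp))
      }
      ratio <- mh / mn
      signed <- if (ratio >= 1) ratio else -1 / ratio
      out[[length(out) + 1]] <- data.frame(metabolite = met, time_point = tp,
                                           signed_ratio = signed,
                                           log2_value = log2(ratio),
                                           missing = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Metabolite-by-time matrix of log2 fold changes
#'
#' @param records Output of [fold_changes()].
#' @param metabolite_order Row order (default: the fixed panel order).
#' @param time_order Column order.
#' @return Numeric matrix of log2 values with `NA` for missing cells and a
#'   logical attribute `missing_mask`.
#' @export
heatmap_matrix <- function(records, metabolite_order = panel_metabolites(),
                           time_order = TIME_POINTS) {
  mets <- intersect(metabolite_order, unique(records$metabolite))
  tps <- intersect(time_order, unique(records$time_point))
  m <- matrix(NA_real_, length(mets), length(tps), dimnames = list(mets, tps))
  mask <- matrix(FALSE, length(mets), length(tps), dimnames = list(mets, tps))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (!r$metabolite %in% mets || !r$time_point %in% tps) next
    if (isTRUE(r$missing)) {
      mask[r$metabolite, r$time_point] <- TRUE
    } else {
      m[r$metabolite, r$time_point] <- r$log2_value
    }
  }
  attr(m, "missing_mask") <- mask
  m
}

#' Write/read a heatmap matrix as CSV (lossless for values and mask)
#'
#' Missing (masked) cells are serialized as the string `"NA"`.
#' @param m Matrix from [heatmap_matrix()].
#' @param path CSV path.
#' @return `path` / the matrix.
#' @export
write_heatmap_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_heatmap_matrix
#' @export
read_heatmap_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  attr(m, "missing_mask") <- is.na(m)
  m
}

#' Write the fold-change report as TSV
#' @param records Output of [fold_changes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fold_changes <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
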