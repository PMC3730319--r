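## Mean-centered PCA on binned spectra, loading-distance region selection
## and paired-t confirmation.

#' Fit mean-centered PCA on a binned matrix
#'
#' Columns are mean-centered (no scaling) before the decomposition, matching
#' the usual treatment of binned NMR intensities. Component signs are fixed
#' by convention: the largest-magnitude loading of each component is
#' positive.
#'
#' @param m A `binned_matrix` (or plain samples x bins matrix).
#' @param k Number of components to retain.
#' @return A `pca_model`: list with `scores` (samples x k), `loadings`
#'   (bins x k, orthonormal), `explained_variance_fraction` (length k),
#'   `center` (bin means), `meta` (sample metadata when available).
#' @export
fit_pca <- function(m, k = 2) {
  X <- if (inherits(m, "binned_matrix")) m$values else as.matrix(m)
  meta <- if (inherits(m, "binned_matrix")) m$meta else NULL
  n <- nrow(X); p <- ncol(X)
  if (n < 2) abort("BAD_INPUT", "PCA needs at least 2 samples")
  if (k > min(n - 1, p)) {
    abort("RANK", sprintf("k = %d exceeds the maximum rank min(n - 1, p) = %d", k, min(n - 1, p)))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (ev[k] <= max(ev) * 1e-12) {
    abort("RANK", sprintf("k = %d exceeds the numerical rank of the data", k))
  }
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {   # sign convention: largest-magnitude loading positive
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = (ev / sum(ev))[seq_len(k)],
                 center = pc$center, meta = meta,
                 bin_edges = if (inherits(m, "binned_matrix")) m$bin_edges else NULL),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d samples, %d bins, %d component(s)\n",
              nrow(x$scores), nrow(x$loadings), ncol(x$scores)))
  cat("explained variance fraction:",
      paste(sprintf("%.3f", x$explained_variance_fraction), collapse = ", "), "\n")
  invisible(x)
}

#' Per-bin Euclidean distance of PC1 and PC2 loadings
#'
#' `d_j = sqrt(loading_j1^2 + loading_j2^2)`: the contribution of bin j to
#' the first two components, used to rank spectral regions.
#'
#' @param model A `pca_model` with at least 2 components.
#' @return Numeric vector of per-bin distances.
#' @export
loading_distance <- function(model) {
  if (ncol(model$loadings) < 2) abort("BAD_INPUT", "loading_distance needs k >= 2 components")
  sqrt(model$loadings[, 1]^2 + model$loadings[, 2]^2)
}

#' Select discriminating spectral regions and map them to metabolites
#'
#' Bins whose loading distance reaches the given quantile threshold are
#' merged into contiguous regions; each region is integrated (summed) per
#' sample and confirmed by a paired t-test across hypoxia/normoxia pairs
#' matched by replicate index. Surviving regions are mapped to metabolites
#' whose template peaks fall inside the region (within `tol` ppm).
#'
#' @param m The `binned_matrix` the model was fitted on (one time point:
#'   samples must form hypoxia/normoxia pairs matched by replicate).
#' @param model The fitted `pca_model`.
#' @param threshold Loading-distance quantile above which bins are marked
#'   (default 0.9 = top decile).
#' @param alpha Significance level of the confirmation test.
#' @param library Template library for the region-to-metabolite mapping.
#' @param tol Mapping tolerance (ppm) added on both sides of a region.
#' @param paired Use the paired t-test (default); `FALSE` gives Welch.
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()] (default `"none"`, matching a fixed per-region
#'   alpha; `"BH"` available).
#' @return A `selection_result`: list with `regions` (data.frame: ppm_lo,
#'   ppm_hi, n_bins, distance, statistic, p_value, significant,
#'   metabolites), `selected_metabolites` (deduplicated names from
#'   significant regions), `threshold_value`, `alpha`.
#' @export
select_regions <- function(m, model, threshold = 0.9, alpha = 0.05,
                           library = metabolite_library(), tol = 0.01,
                           paired = TRUE, p_adjust = "none") {
  stopifnot(inherits(m, "binned_matrix"))
  d <- loading_distance(model)
  thr <- stats::quantile(d, threshold)
  mask <- d >= thr
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  if (length(keep) == 0) {
    return(structure(list(regions = data.frame(), selected_metabolites = character(0),
                          threshold_value = unname(thr), alpha = alpha),
                     class = "selection_result"))
  }

  hyp <- m$meta$condition == "hypoxia"
  nor <- m$meta$condition == "normoxia"
  if (paired) {
    key_h <- paste(m$meta$time_point[hyp], m$meta$replicate[hyp])
    key_n <- paste(m$meta$time_point[nor], m$meta$replicate[nor])
    if (sum(hyp) == 0 || sum(hyp) != sum(nor) ||
        !setequal(key_h, key_n) || anyDuplicated(key_h) || anyDuplicated(key_n)) {
      abort("UNPAIRED", "samples do not form hypoxia/normoxia pairs matched by (time point, replicate)")
    }
    ord_h <- which(hyp)[order(key_h)]
    ord_n <- which(nor)[order(key_n)]
  }

  edges <- m$bin_edges
  rows <- lapply(keep, function(r) {
    bins <- starts[r]:ends[r]
    integral <- rowSums(m$values[, bins, drop = FALSE])
    tt <- if (paired) {
      stats::t.test(integral[ord_h], integral[ord_n], paired = TRUE)
    } else {
      stats::t.test(integral[hyp], integral[nor])
    }
    data.frame(ppm_lo = edges[bins[1]], ppm_hi = edges[bins[length(bins)] + 1],
               n_bins = length(bins), distance = max(d[bins]),
               statistic = unname(tt$statistic), p_value = tt$p.value)
  })
  regions <- do.call(rbind, rows)
  regions$p_value <- stats::p.adjust(regions$p_value, method = p_adjust)
  regions$significant <- regions$p_value <= alpha
  regions$metabolites <- vapply(seq_len(nrow(regions)), function(i) {
    hits <- vapply(library, function(tmpl) {
      any(tmpl$peaks$center >= regions$ppm_lo[i] - tol &
          tmpl$peaks$center <= regions$ppm_hi[i] + tol)
    }, TRUE)
    paste(names(library)[hits], collapse = ";")
  }, "")

  sel <- unlist(strsplit(regions$metabolites[regions$significant], ";", fixed = TRUE))
  sel <- unique(sel[nzchar(sel)])
  structure(list(regions = regions,
                 selected_metabolites = sel[order(match(sel, names(library)))],
                 threshold_value = unname(thr), alpha = alpha),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d region(s), %d significant, %d metabolite(s)\n",
              nrow(x$regions), sum(x$regions$significant),
              length(x$selected_metabolites)))
  if (length(x$selected_metabolites)) {
    cat("selected:", paste(x$selected_metabolites, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a selection report as TSV
#' @param sel A `selection_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  utils::write.table(sel$regions, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mean silhouette width of group labels on the first two score dimensions
#'
#' Standard silhouette over Euclidean distances in the PC1/PC2 plane; used
#' to quantify how clearly the hypoxia and normoxia score clusters separate
#' at a given time point.
#'
#' @param scores Samples x >=2 score matrix.
#' @param labels Group labels (two or more groups).
#' @return Mean silhouette width in \[-1, 1\].
#' @export
silhouette_mean <- function(scores, labels) {
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  labels <- as.character(labels)
  dm <- as.matrix(stats::dist(scores))
  n <- nrow(dm)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(dm[i, own & seq_len(n) != i])
    b <- min(vapply(unique(labels[!own]), function(g) mean(dm[i, labels == g]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
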