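# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# the default 54-sample study at seed 1
get_study1 <- function() cached("study1", make_study(seed = 1))

# its preprocessed, binned matrix
get_binned1 <- function() cached("binned1", bin_spectra(get_study1()$spectra))

# a quick noise-free render of one concentration vector
quiet_params <- function(...) render_params(noise_sd = 0, drift_amplitude = 0, ...)

# paired 48 h binned-matrix stand-in built directly from noise (no spectra);
# used for null-rate properties where only the matrix structure matters
noise_binned <- function(n_pairs = 9, n_bins = 60, sd = 1) {
  values <- matrix(stats::rnorm(2 * n_pairs * n_bins, sd = sd), 2 * n_pairs, n_bins)
  meta <- data.frame(
    sample_id = sprintf("s%02d", seq_len(2 * n_pairs)),
    condition = rep(c("hypoxia", "normoxia"), each = n_pairs),
    time_point = "48h",
    replicate = rep(seq_len(n_pairs), 2)
  )
  edges <- 0.2 + 0.01 * (0:n_bins)
  rownames(values) <- meta$sample_id
  structure(list(values = values, bin_edges = edges, meta = meta),
            class = "binned_matrix")
}
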