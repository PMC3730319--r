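#' Construct a 1D NMR spectrum object
#'
#' A frequency-domain proton spectrum: a strictly descending ppm axis, an
#' intensity vector of the same length, and sample metadata.
#'
#' @param ppm Numeric chemical-shift axis, strictly descending (ppm).
#' @param intensity Numeric intensities, same length as `ppm`.
#' @param sample_id Sample identifier string.
#' @param condition `"hypoxia"` or `"normoxia"` (or `NA` for fixtures).
#' @param time_point `"4h"`, `"24h"` or `"48h"` (or `NA`).
#' @param replicate Integer replicate index within (condition, time point).
#' @return An `nmr_spectrum` object.
#' @export
new_spectrum <- function(ppm, intensity, sample_id = "sample",
                         condition = NA_character_, time_point = NA_character_,
                         replicate = NA_integer_) {
  if (length(ppm) != length(intensity)) {
    abort("BAD_SPECTRUM", "ppm and intensity must have the same length")
  }
  if (length(ppm) >= 2 && any(diff(ppm) >= 0)) {
    abort("BAD_SPECTRUM", "ppm axis must be strictly descending")
  }
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 sample_id = sample_id, condition = condition,
                 time_point = time_point, replicate = replicate),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s (%s, %s): %d points, %.3f to %.3f ppm\n",
              x$sample_id, x$condition, x$time_point, length(x$ppm),
              max(x$ppm), min(x$ppm)))
  invisible(x)
}

#' Write a spectrum as two-column text with a metadata header
#'
#' The format is `# key: value` header lines followed by whitespace-separated
#' `ppm intensity` rows, readable by [read_spectrum()].
#'
#' @param s An `nmr_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  hdr <- c(sprintf("# sample_id: %s", s$sample_id),
           sprintf("# condition: %s", s$condition),
           sprintf("# time_point: %s", s$time_point),
           sprintf("# replicate: %s", s$replicate))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(data.frame(ppm = s$ppm, intensity = s$intensity),
                     con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#' @param path File path.
#' @return An `nmr_spectrum`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines)], col.names = c("ppm", "intensity"))
  rep_ <- suppressWarnings(as.integer(meta$replicate))
  new_spectrum(dat$ppm, dat$intensity,
               sample_id = meta$sample_id %||% "sample",
               condition = meta$condition %||% NA_character_,
               time_point = meta$time_point %||% NA_character_,
               replicate = rep_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default simulated acquisition axis
#'
#' Descending uniform ppm axis covering 10 to -0.5 ppm, wide enough for the
#' TMSP reference at 0 ppm, the water region and the full analysis window.
#'
#' @param from,to Axis end points (ppm), `from > to`.
#' @param by Spacing (ppm).
#' @return Numeric descending axis.
#' @export
default_ppm_axis <- function(from = 10, to = -0.5, by = 0.001) {
  seq(from, to, by = -abs(by))
}
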