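# Coverage: sliding-window per-base depth, mapped-read scaling
# normalization, and display smoothing.

#' Construct a coverage track
#'
#' Windows tile each chromosome with the stated step; the number of windows
#' per chromosome is `floor((length - window) / step) + 1` (trailing partial
#' windows are dropped).
#' @param chroms data.frame name/length (extra columns ignored).
#' @param window,step window geometry in bp.
#' @param values named list of per-window numeric vectors.
#' @param norm normalization record.
#' @export
coverage_track <- function(chroms, window, step, values, norm = NULL) {
  expected <- pmax(0, floor((chroms$length - window) / step) + 1)
  got <- vapply(values[chroms$name], length, integer(1))
  if (!all(got == expected)) stopf("window count does not tile the genome")
  structure(list(chroms = chroms[, c("name", "length")],
                 window = window, step = step, values = values,
                 norm = norm %||% list(factor = 1, reference = NA)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d chromosomes, window %d bp, step %d bp, factor %.4g\n",
              nrow(x$chroms), x$window, x$step, x$norm$factor))
  invisible(x)
}

.same_geometry <- function(a, b) {
  identical(a$chroms, b$chroms) && a$window == b$window && a$step == b$step
}

#' Sliding-window mean per-base depth of an alignment set
#'
#' Each window's value is the mean per-base read depth within the window
#' (reads counted over their full aligned span).
#' @param aln data.frame chrom/start/end (0-based half-open).
#' @param genome an `annotated_genome` (or any object with a
#'   `$chromosomes` name/length table).
#' @param window window size bp (>= step).
#' @param step window increment bp.
#' @return a `coverage_track`.
#' @export
window_coverage <- function(aln, genome, window = 100, step = 50) {
  if (window < step) stopf("window must be >= step")
  ch <- genome$chromosomes
  if (nrow(aln) && !all(aln$chrom %in% ch$name))
    stopf("alignment on unknown chromosome")
  values <- list()
  for (i in seq_len(nrow(ch))) {
    len <- ch$length[i]
    n_win <- floor((len - window) / step) + 1
    if (n_win < 1) { values[[ch$name[i]]] <- numeric(0); next }
    idx <- which(aln$chrom == ch$name[i])
    s0 <- aln$start[idx]
    e0 <- aln$end[idx]
    if (length(idx) && (any(s0 < 0) || any(e0 > len)))
      stopf("alignment beyond chromosome bounds on %s", ch$name[i])
    if (length(idx) == 0) {
      values[[ch$name[i]]] <- numeric(n_win)
      next
    }
    delta <- tabulate(s0 + 1, nbins = len + 1) -
      tabulate(e0 + 1, nbins = len + 1)
    depth <- cumsum(delta)[seq_len(len)]
    cs <- c(0, cumsum(depth))
    s <- (seq_len(n_win) - 1) * step
    values[[ch$name[i]]] <- (cs[s + window + 1] - cs[s + 1]) / window
  }
  coverage_track(ch, window, step, values)
}

#' Depth scaling factor between two samples
#'
#' The factor is the ratio of total mapped reads in the sample relative to
#' the reference; [normalize_track()] divides the sample's values by it.
#' @param sample_mapped_reads,reference_mapped_reads mapped-read totals.
#' @export
scaling_factor <- function(sample_mapped_reads, reference_mapped_reads) {
  if (reference_mapped_reads <= 0) stopf("zero reference read count")
  if (sample_mapped_reads <= 0) stopf("zero sample read count")
  sample_mapped_reads / reference_mapped_reads
}

#' Apply a scaling factor to a track
#' @param track a `coverage_track`.
#' @param factor scaling factor from [scaling_factor()].
#' @param reference reference sample id recorded in the track.
#' @export
normalize_track <- function(track, factor, reference = "reference") {
  track$values <- lapply(track$values, function(v) v / factor)
  track$norm <- list(factor = factor, reference = reference)
  track
}

#' Moving-average display smoothing
#'
#' Averages window values over a display window (e.g. 350 or 500 bp),
#' keeping the native step. Edge windows average over the available
#' neighbours only, so total signal is conserved up to edge effects.
#' @param track a `coverage_track`.
#' @param display_window display window bp (>= the track's native window;
#'   multiple of the step).
#' @export
smooth_track <- function(track, display_window) {
  if (display_window < track$window)
    stopf("display window smaller than native window")
  k <- round(display_window / track$step)
  l <- floor((k - 1) / 2)
  r <- k - 1 - l
  track$values <- lapply(track$values, function(v) {
    n <- length(v)
    if (n == 0) return(v)
    cs <- c(0, cumsum(v))
    i <- seq_len(n)
    lo <- pmax(1, i - l)
    hi <- pmin(n, i + r)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  })
  track$display_window <- display_window
  track
}

#' Total signal mass of a track (sum of values times step)
#' @param track a `coverage_track`.
#' @export
track_mass <- function(track) {
  sum(vapply(track$values, sum, numeric(1))) * track$step
}
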