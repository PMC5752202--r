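# Telomere repeat arrays: detect maximal exact tandem runs of the
# telomeric hexamer on either strand, and classify arrays as terminal or
# interstitial.

#' Length in bp of an n-unit telomere repeat array
#' @param n repeat count (>= 0).
#' @export
array_length_bp <- function(n) {
  if (any(n < 0)) stopf("negative repeat count")
  6 * n
}

#' Find telomere repeat arrays in a sequence
#'
#' Maximal exact tandem runs of the hexamer (TTAGGG on "+", its reverse
#' complement CCCTAA on "-") of at least `min_n` units. Partial trailing
#' units are not counted.
#' @param sequence character DNA sequence (A/C/G/T/N).
#' @param min_n minimum repeat count reported.
#' @return data.frame start/end/n/strand (0-based half-open).
#' @export
find_repeat_arrays <- function(sequence, min_n = 1L) {
  scan1 <- function(unit, strand) {
    m <- gregexpr(paste0("(?:", unit, ")+"), sequence)[[1]]
    if (m[1] == -1)
      return(data.frame(start = numeric(), end = numeric(), n = integer(),
                        strand = character(), stringsAsFactors = FALSE))
    len <- attr(m, "match.length")
    n <- len %/% 6L
    keep <- n >= min_n
    data.frame(start = as.numeric(m[keep] - 1),
               end = as.numeric(m[keep] - 1 + 6 * n[keep]),
               n = n[keep], strand = rep(strand, sum(keep)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(scan1(TEL_UNIT, "+"), scan1(TEL_UNIT_RC, "-"))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find repeat arrays on every chromosome of a sequence genome
#' @param genome sequence-mode `annotated_genome`.
#' @param min_n minimum repeat count.
#' @return data.frame chrom/start/end/n/strand.
#' @export
find_genome_repeat_arrays <- function(genome, min_n = 1L) {
  if (is.null(genome$sequences)) stopf("genome has no sequences")
  out <- lapply(genome$chromosomes$name, function(nm) {
    a <- find_repeat_arrays(genome$sequences[[nm]], min_n)
    if (nrow(a)) cbind(data.frame(chrom = nm, stringsAsFactors = FALSE), a)
    else NULL
  })
  out <- do.call(rbind, out) %||%
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n = integer(), strand = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify repeat arrays as terminal or interstitial
#'
#' Terminal arrays lie within `terminal_zone` of an end of a linear
#' chromosome; all arrays on circular chromosomes are interstitial.
#' @param arrays data.frame chrom/start/end (as from
#'   [find_genome_repeat_arrays()]).
#' @param genome the `annotated_genome` locating the arrays.
#' @param terminal_zone bp from a chromosome end.
#' @return `arrays` with a logical `terminal` column.
#' @export
classify_arrays <- function(arrays, genome, terminal_zone = 1000) {
  if (nrow(arrays) == 0) { arrays$terminal <- logical(0); return(arrays) }
  lens <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  circ <- stats::setNames(genome$chromosomes$circular, genome$chromosomes$name)
  arrays$terminal <- !circ[arrays$chrom] &
    (arrays$start <= terminal_zone |
     lens[arrays$chrom] - arrays$end <= terminal_zone)
  rownames(arrays) <- NULL
  arrays
}
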