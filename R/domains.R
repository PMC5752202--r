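# Domain calling and differential classification: threshold the
# chip/input enrichment ratio, merge seed runs, and compare call sets
# across strains through the liftover (gained / lost / invariant).

#' Call methylation domains from chip and input tracks
#'
#' Windows whose enrichment ratio `chip / max(input, floor)` reaches the
#' threshold seed domains; adjacent or near-adjacent (<= merge gap) seed
#' runs merge; runs shorter than the minimum size are dropped. The input
#' denominator is floored at its genome-wide 5th percentile to avoid
#' division blow-ups in low-coverage windows.
#'
#' @param chip,input `coverage_track`s with identical geometry.
#' @param T enrichment threshold.
#' @param G merge gap bp.
#' @param S minimum domain size bp.
#' @return a `domain_calls` data.frame chrom/start/end/mean_enrichment with
#'   the caller parameters attached.
#' @export
call_domains <- function(chip, input, T = 2.0, G = 10e3, S = 500) {
  if (!.same_geometry(chip, input)) stopf("mismatched track geometry")
  allv <- unlist(input$values, use.names = FALSE)
  if (length(allv) == 0 || mean(allv) <= 0)
    stopf("input track has zero genome-wide mean")
  floor_v <- max(stats::quantile(allv, 0.05, names = FALSE), 1e-9)
  out <- list()
  for (nm in names(chip$values)) {
    cv <- chip$values[[nm]]
    iv <- input$values[[nm]]
    if (length(cv) == 0) next
    enr <- cv / pmax(iv, floor_v)
    seed <- enr >= T
    if (!any(seed)) next
    r <- rle(seed)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- data.frame(chrom = nm,
                       start = (starts[r$values] - 1) * chip$step,
                       end = (ends[r$values] - 1) * chip$step + chip$window)
    runs <- merge_intervals(runs, gap = G)
    runs <- runs[runs$end - runs$start >= S, , drop = FALSE]
    if (nrow(runs) == 0) next
    runs$mean_enrichment <- vapply(seq_len(nrow(runs)), function(i) {
      lo <- floor(runs$start[i] / chip$step) + 1
      hi <- floor((runs$end[i] - chip$window) / chip$step) + 1
      lo <- max(1, lo); hi <- min(length(enr), hi)
      if (hi < lo) NA_real_ else mean(enr[lo:hi])
    }, numeric(1))
    out[[nm]] <- runs
  }
  calls <- do.call(rbind, out) %||%
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               mean_enrichment = numeric(), stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  attr(calls, "params") <- list(T = T, G = G, S = S)
  class(calls) <- c("domain_calls", class(calls))
  calls
}

#' Classify domains as gained, lost or invariant across a rearrangement
#'
#' Reference calls are lifted through the map onto the derived genome. An
#' alternative call overlapping a lifted reference call by at least
#' `min_overlap` of both lengths (reciprocal rule) is invariant; alt calls
#' with no qualifying partner are gained; lifted reference calls with no
#' qualifying partner are lost.
#'
#' @param ref_calls calls on the source genome.
#' @param alt_calls calls on the derived genome.
#' @param map `liftover_map` from source to derived genome.
#' @param min_overlap reciprocal overlap fraction for invariance.
#' @return data.frame chrom/start/end/label (coordinates on the derived
#'   genome; lost intervals are the lifted reference footprints).
#' @export
classify_differential <- function(ref_calls, alt_calls, map, min_overlap = 0.5) {
  if (nrow(ref_calls) && !all(ref_calls$chrom %in% map$src_chroms$name))
    stopf("reference calls not on the map's source genome")
  if (nrow(alt_calls) && !all(alt_calls$chrom %in% map$tgt_chroms$name))
    stopf("alt calls not on the map's target genome")
  nref <- nrow(ref_calls)
  nalt <- nrow(alt_calls)
  lv <- lift_many(map, ref_calls)
  lifted_len <- numeric(nref)
  if (nrow(lv)) {
    agg <- tapply(lv$end - lv$start, lv$idx, sum)
    lifted_len[as.integer(names(agg))] <- agg
  }
  alt_len <- if (nalt) alt_calls$end - alt_calls$start else numeric(0)
  ref_matched <- logical(nref)
  alt_matched <- logical(nalt)
  if (nrow(lv) && nalt) {
    ov <- interval_overlaps(lv, alt_calls)
    if (nrow(ov)) {
      key <- paste(lv$idx[ov$qi], ov$si)
      tot <- tapply(ov$overlap_bp, key, sum)
      ij <- do.call(rbind, strsplit(names(tot), " "))
      i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
      hit <- tot >= min_overlap * alt_len[j] & tot >= min_overlap * lifted_len[i]
      ref_matched[unique(i[hit])] <- TRUE
      alt_matched[unique(j[hit])] <- TRUE
    }
  }
  rows <- list()
  if (nalt) {
    lab <- ifelse(alt_matched, "invariant", "gained")
    rows$alt <- data.frame(chrom = alt_calls$chrom, start = alt_calls$start,
                           end = alt_calls$end, label = lab,
                           stringsAsFactors = FALSE)
  }
  lost_i <- which(!ref_matched & lifted_len > 0)
  if (length(lost_i)) {
    lvl <- lv[lv$idx %in% lost_i, , drop = FALSE]
    rows$lost <- data.frame(chrom = lvl$chrom, start = lvl$start,
                            end = lvl$end, label = "lost",
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               label = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Extension of the end-anchored domain run into a chromosome
#'
#' Calls within the merge gap of each other join into runs; the run whose
#' edge lies within the gap of the chromosome end is the end-anchored run,
#' and the extension is the distance from the end to its farthest interior
#' edge. Returns 0 when no call lies within the gap of the end.
#'
#' @param calls domain calls on one chromosome (chrom/start/end).
#' @param chrom chromosome name.
#' @param side which end, "L" or "R".
#' @param chrom_length chromosome length bp.
#' @param G merge gap bp.
#' @return extension in bp.
#' @export
subtelomeric_extension <- function(calls, chrom, side, chrom_length, G = 10e3) {
  cc <- calls[calls$chrom == chrom, , drop = FALSE]
  if (nrow(cc) == 0) return(0)
  runs <- merge_intervals(cc, gap = G)
  if (side == "L") {
    anchored <- runs[runs$start <= G, , drop = FALSE]
    if (nrow(anchored) == 0) return(0)
    max(anchored$end)
  } else {
    anchored <- runs[chrom_length - runs$end <= G, , drop = FALSE]
    if (nrow(anchored) == 0) return(0)
    chrom_length - min(anchored$start)
  }
}

#' Span, farthest peak and gene content of an anchor-connected domain run
#'
#' Merges calls across gaps up to `G`, finds the run containing (or within
#' `G` of) the anchor position, and reports the run's span, the farthest
#' distance of any member call edge from the anchor, and the number of
#' genes fully inside the run.
#'
#' @param calls domain calls (chrom/start/end).
#' @param chrom chromosome of the anchor.
#' @param anchor_pos anchor position (e.g. a repeat insertion site).
#' @param genes gene table (chrom/start/end/...).
#' @param G merge gap bp.
#' @return list(span_bp, farthest_bp, n_genes).
#' @export
anchored_span_and_genes <- function(calls, chrom, anchor_pos, genes, G = 10e3) {
  cc <- calls[calls$chrom == chrom, , drop = FALSE]
  empty <- list(span_bp = 0, farthest_bp = 0, n_genes = 0L)
  if (nrow(cc) == 0) return(empty)
  runs <- merge_intervals(cc, gap = G)
  d <- pmax(0, pmax(runs$start - anchor_pos, anchor_pos - runs$end))
  i <- which.min(d)
  if (d[i] > G) return(empty)
  run <- runs[i, ]
  members <- cc[cc$end > run$start - 1 & cc$start < run$end + 1, , drop = FALSE]
  farthest <- max(abs(c(members$start, members$end) - anchor_pos))
  gg <- genes[genes$chrom == chrom & genes$start >= run$start &
              genes$end <= run$end, , drop = FALSE]
  list(span_bp = run$end - run$start, farthest_bp = farthest,
       n_genes = nrow(gg))
}
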