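# Breakpoint detection from discordant pairs and split reads, plus the
# outward-primer fusion test for circularized chromosomes. A deliberate
# simplification of probabilistic SV callers: evidence is clustered by
# single linkage on both loci and calls below a weight threshold are
# discarded.

#' Collect discordant-pair and split-read evidence
#'
#' Pairs are discordant when inter-chromosomal, oriented other than
#' forward-reverse, or when the implied insert lies outside
#' `mean +/- 4 sd`. Split reads contribute base-pair-resolution junction
#' evidence.
#' @param aln alignment data.frame from [pairs_to_source_alignments()]
#'   (columns qname/mate/chrom/start/end/strand and split columns).
#' @param insert_mean,insert_sd fragment length distribution.
#' @return evidence data.frame chrom1/pos1/dir1/chrom2/pos2/dir2/type.
#' @export
collect_evidence <- function(aln, insert_mean, insert_sd) {
  if (is.null(aln$mate) || anyNA(aln$mate)) stopf("missing mate information")
  empty <- data.frame(chrom1 = character(), pos1 = numeric(), dir1 = character(),
                      chrom2 = character(), pos2 = numeric(), dir2 = character(),
                      type = character(), stringsAsFactors = FALSE)
  ev <- list()

  ## split reads: exact junction coordinates
  sp <- aln[!is.na(aln$split_chrom), , drop = FALSE]
  if (nrow(sp)) {
    ev$split <- data.frame(chrom1 = sp$chrom, pos1 = sp$junc_pos, dir1 = sp$strand,
                           chrom2 = sp$split_chrom, pos2 = sp$junc_pos2,
                           dir2 = sp$split_strand, type = "split",
                           stringsAsFactors = FALSE)
  }

  ## discordant pairs (primary alignments)
  m1 <- aln[aln$mate == 1L, , drop = FALSE]
  m2 <- aln[aln$mate == 2L, , drop = FALSE]
  common <- intersect(m1$qname, m2$qname)
  m1 <- m1[match(common, m1$qname), , drop = FALSE]
  m2 <- m2[match(common, m2$qname), , drop = FALSE]
  if (nrow(m1)) {
    same <- m1$chrom == m2$chrom
    left_is_1 <- m1$start <= m2$start
    lo_strand <- ifelse(left_is_1, m1$strand, m2$strand)
    hi_strand <- ifelse(left_is_1, m2$strand, m1$strand)
    insert <- pmax(m1$end, m2$end) - pmin(m1$start, m2$start)
    proper <- same & lo_strand == "+" & hi_strand == "-" &
      insert >= insert_mean - 4 * insert_sd &
      insert <= insert_mean + 4 * insert_sd
    disc <- which(!proper)
    if (length(disc)) {
      inner <- function(d) {
        ifelse(d$strand == "+", d$end, d$start)
      }
      ev$pairs <- data.frame(chrom1 = m1$chrom[disc], pos1 = inner(m1)[disc],
                             dir1 = m1$strand[disc],
                             chrom2 = m2$chrom[disc], pos2 = inner(m2)[disc],
                             dir2 = m2$strand[disc], type = "pair",
                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, ev) %||% empty
  if (nrow(out)) {
    ## canonical locus order: (chrom, pos) lexicographic
    swap <- out$chrom1 > out$chrom2 |
      (out$chrom1 == out$chrom2 & out$pos1 > out$pos2)
    if (any(swap)) {
      tmp <- out[swap, c("chrom1", "pos1", "dir1")]
      out[swap, c("chrom1", "pos1", "dir1")] <- out[swap, c("chrom2", "pos2", "dir2")]
      out[swap, c("chrom2", "pos2", "dir2")] <- tmp
    }
  }
  rownames(out) <- NULL
  out
}

#' Cluster evidence and call breakpoints
#'
#' Single-linkage clustering of evidence whose two loci each fall within
#' `cluster_dist`; the call position per side is the median of split-read
#' junction positions when available, else the boundary of the
#' discordant-pair support. Calls with weight below `min_weight`, or whose
#' support spreads over more than `10 * cluster_dist`, are discarded.
#' @param evidence from [collect_evidence()].
#' @param cluster_dist bp linkage distance.
#' @param min_weight minimum supporting evidence count.
#' @return data.frame chrom1/pos1/chrom2/pos2/weight/n_split/n_pair.
#' @export
cluster_and_call <- function(evidence, cluster_dist = 500, min_weight = 5) {
  empty <- data.frame(chrom1 = character(), pos1 = numeric(),
                      chrom2 = character(), pos2 = numeric(),
                      weight = integer(), n_split = integer(),
                      n_pair = integer(), stringsAsFactors = FALSE)
  if (nrow(evidence) == 0) return(empty)
  ev <- evidence[order(evidence$chrom1, evidence$chrom2, evidence$pos1), ,
                 drop = FALSE]
  key <- paste(ev$chrom1, ev$chrom2)
  calls <- list()
  for (k in unique(key)) {
    e <- ev[key == k, , drop = FALSE]
    ## linkage on locus 1
    grp1 <- cumsum(c(TRUE, diff(e$pos1) > cluster_dist))
    for (g1 in unique(grp1)) {
      e1 <- e[grp1 == g1, , drop = FALSE]
      e1 <- e1[order(e1$pos2), , drop = FALSE]
      grp2 <- cumsum(c(TRUE, diff(e1$pos2) > cluster_dist))
      for (g2 in unique(grp2)) {
        e2 <- e1[grp2 == g2, , drop = FALSE]
        if (nrow(e2) < min_weight) next
        if (diff(range(e2$pos1)) > 10 * cluster_dist ||
            diff(range(e2$pos2)) > 10 * cluster_dist) next
        sp <- e2[e2$type == "split", , drop = FALSE]
        if (nrow(sp)) {
          p1 <- stats::median(sp$pos1)
          p2 <- stats::median(sp$pos2)
        } else {
          # support boundary: reads approach the junction from the side
          # their orientation points to
          p1 <- if (sum(e2$dir1 == "+") >= sum(e2$dir1 == "-"))
            max(e2$pos1) else min(e2$pos1)
          p2 <- if (sum(e2$dir2 == "+") >= sum(e2$dir2 == "-"))
            max(e2$pos2) else min(e2$pos2)
        }
        calls[[length(calls) + 1]] <- data.frame(
          chrom1 = e2$chrom1[1], pos1 = p1, chrom2 = e2$chrom2[1], pos2 = p2,
          weight = nrow(e2), n_split = nrow(sp),
          n_pair = sum(e2$type == "pair"), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, calls) %||% empty
  rownames(out) <- NULL
  out[order(out$chrom1, out$pos1), , drop = FALSE]
}

#' Outward-primer fusion test for circularized chromosomes
#'
#' Primers are placed `primer_offset` bp from each end of the
#' pre-circularization chromosome, pointing outward. On a circularized
#' chromosome the two primers face each other across the fusion junction;
#' the test is positive when the implied amplicon (junction-spanning
#' distance, after telomere trimming) is at most `max_amplicon`.
#' @param genome_state the (possibly circularized) `annotated_genome`;
#'   fusion junctions recorded at circularization are used.
#' @param primer_offset bp from the former chromosome ends.
#' @param max_amplicon largest amplifiable product (bp).
#' @param primer_pairs optional explicit data.frame chrom/left_offset/
#'   right_offset overriding auto placement.
#' @return named logical vector, one entry per chromosome.
#' @export
fusion_junction_test <- function(genome_state, primer_offset = 1000,
                                 max_amplicon = 5000, primer_pairs = NULL) {
  ch <- genome_state$chromosomes
  res <- stats::setNames(logical(nrow(ch)), ch$name)
  for (i in seq_len(nrow(ch))) {
    nm <- ch$name[i]
    off_l <- primer_offset
    off_r <- primer_offset
    if (!is.null(primer_pairs)) {
      j <- which(primer_pairs$chrom == nm)
      if (length(j)) {
        off_l <- primer_pairs$left_offset[j[1]]
        off_r <- primer_pairs$right_offset[j[1]]
      }
    }
    if (off_l < 0 || off_r < 0 || off_l + off_r > ch$length[i])
      stopf("primer off chromosome %s", nm)
    if (!ch$circular[i]) { res[nm] <- FALSE; next }
    jn <- genome_state$junctions[genome_state$junctions$chrom == nm, ,
                                 drop = FALSE]
    if (nrow(jn) == 0) { res[nm] <- FALSE; next }
    amp <- (off_l - jn$trimmed_left[1]) + (off_r - jn$trimmed_right[1])
    res[nm] <- amp > 0 && amp <= max_amplicon
  }
  res
}
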