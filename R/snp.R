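# Allele-specific read partitioning ("SNP parsing"): trim reads to a fixed
# length, assign each read to a parent by exact full-length matching
# against SNP flanking contexts, scale the two allele files to the smaller
# one, and build per-allele coverage profiles.

#' Trim reads to a fixed length and drop shorter reads
#'
#' Keeps the first `L` bases (5' end) of each read; reads shorter than `L`
#' are removed. Alignment coordinates, when present, are adjusted to the
#' retained span.
#' @param reads data.frame with a `seq` column (optionally
#'   chrom/start/end/strand).
#' @param L retained length (default 70).
#' @export
trim_filter_reads <- function(reads, L = 70L) {
  if (L <= 0) stopf("trim length must be positive")
  keep <- nchar(reads$seq) >= L
  out <- reads[keep, , drop = FALSE]
  if (nrow(out) == 0) { rownames(out) <- NULL; return(out) }
  trimmed <- nchar(out$seq) > L
  out$seq <- substr(out$seq, 1, L)
  if (!is.null(out$start) && !is.null(out$strand) && any(trimmed)) {
    plus <- out$strand == "+"
    out$end[trimmed & plus] <- out$start[trimmed & plus] + L
    out$start[trimmed & !plus] <- out$end[trimmed & !plus] - L
  }
  rownames(out) <- NULL
  out
}

#' Build an exact-match index over SNP flank contexts
#'
#' For each SNP and parent, every read-length window of the flanking
#' context that covers the SNP position is indexed (both strands). A read
#' equal to any indexed window matches that SNP under that parent.
#' @param snpome SNPome data.frame (chrom/pos/allele_a/allele_b/flank_a/
#'   flank_b) with a `flank` attribute.
#' @return an index for [assign_reads()].
#' @export
snp_index <- function(snpome) {
  f <- attr(snpome, "flank") %||% 70L
  L <- f
  build <- function(ctx) {
    # context has length 2f+1 with the SNP at 0-based index f; windows
    # [i, i+L) covering the SNP have i in [f-L+1, f] => 1..L for L == f
    n <- nrow(snpome)
    if (n == 0) return(character(0))
    starts <- seq.int(f - L + 2, f + 1)   # 1-based substring starts
    keys <- as.vector(vapply(starts, function(s0)
      substring(ctx, s0, s0 + L - 1), character(n)))
    keys
  }
  keys_a <- build(snpome$flank_a)
  keys_b <- build(snpome$flank_b)
  keys <- c(keys_a, revcomp(keys_a), keys_b, revcomp(keys_b))
  lab <- rep(c("A", "A", "B", "B"), each = length(keys_a))
  # collapse duplicate keys; cross-parent coincidences become "conflicted"
  first <- !duplicated(keys)
  key_first <- keys[first]
  lab_first <- lab[first]
  ref <- lab_first[match(keys, key_first)]
  bad <- unique(keys[ref != lab])
  if (length(bad)) lab_first[key_first %in% bad] <- "conflicted"
  probes <- list(
    a = substring(snpome$flank_a, f - 9, f + 11),
    b = substring(snpome$flank_b, f - 9, f + 11))
  structure(list(keys = key_first, labels = lab_first, L = L,
                 probes = probes, n_snps = nrow(snpome)),
            class = "snp_index")
}

#' Assign reads to a parent of origin
#'
#' A read that matches (exact, full length, either strand) the flank
#' context of at least one SNP under exactly one parental allele is
#' assigned to that parent. Reads covering no informative SNP, or with no
#' exact match under either parent, are unassigned. Reads matching
#' different parents at different overlapped SNPs (chimeras) are
#' conflicted.
#' @param reads data.frame with a `seq` column, trimmed to the index's
#'   read length.
#' @param index from [snp_index()] (a SNPome data.frame is also accepted).
#' @return character vector of labels: parent_A / parent_B / unassigned /
#'   conflicted.
#' @export
assign_reads <- function(reads, index) {
  if (!inherits(index, "snp_index")) index <- snp_index(index)
  if (any(nchar(reads$seq) != index$L))
    stopf("read length differs from the SNPome flank convention (%d)", index$L)
  hit <- index$labels[match(reads$seq, index$keys)]
  hit_rc <- index$labels[match(revcomp(reads$seq), index$keys)]
  lab <- ifelse(!is.na(hit), hit, hit_rc)
  both <- !is.na(hit) & !is.na(hit_rc) & hit != hit_rc
  lab[both] <- "conflicted"
  out <- ifelse(is.na(lab), "unassigned",
                ifelse(lab == "A", "parent_A",
                       ifelse(lab == "B", "parent_B", "conflicted")))
  ## chimera detection among unmatched reads: 21-mer probes centered on
  ## each SNP under each parent; reads carrying probes of both parents are
  ## chimeric junction reads
  un <- which(out == "unassigned")
  if (length(un) && index$n_snps > 0) {
    pa <- unique(c(index$probes$a, revcomp(index$probes$a)))
    pb <- unique(c(index$probes$b, revcomp(index$probes$b)))
    w <- nchar(index$probes$a[1])
    nk <- index$L - w + 1L
    if (nk > 0) {
      seqs <- reads$seq[un]
      km <- vapply(seq_len(nk), function(i) substring(seqs, i, i + w - 1L),
                   character(length(un)))
      km <- matrix(km, nrow = length(un))
      va <- rowSums(matrix(km %in% pa, nrow = length(un))) > 0
      vb <- rowSums(matrix(km %in% pb, nrow = length(un))) > 0
      out[un[va & vb]] <- "conflicted"
    }
  }
  out
}

#' Assign a single read
#' @param read character read sequence.
#' @param index from [snp_index()].
#' @export
assign_read <- function(read, index) {
  assign_reads(data.frame(seq = read, stringsAsFactors = FALSE), index)
}

#' Scaling factors for two allele-parsed read files
#'
#' The factor for each file is the ratio of its alignment count to the
#' smaller file's count (so the smaller file's factor is 1); per-allele
#' tracks are divided by their factor.
#' @param count_a,count_b alignment counts of the two parsed files.
#' @return c(factor_a, factor_b).
#' @export
allele_scaling <- function(count_a, count_b) {
  if (count_a <= 0 || count_b <= 0) stopf("zero count in a SNP-parsed file")
  m <- min(count_a, count_b)
  c(factor_a = count_a / m, factor_b = count_b / m)
}

#' Allele-specific coverage profiles
#'
#' The full SNP-parsing pipeline: trim and filter reads, assign each to a
#' parent, partition, compute per-parent window coverage in the shared
#' coordinate frame of `genome`, and apply smallest-file scaling.
#' Conflicted reads are excluded and counted.
#' @param reads data.frame with seq and chrom/start/end/strand in the
#'   profiling frame.
#' @param snpome SNPome data.frame (or [snp_index()]).
#' @param genome genome (or chromosome table holder) defining the frame.
#' @param window,step coverage window geometry.
#' @param L trim length.
#' @return list(track_a, track_b, counts, factors).
#' @export
snp_parsed_profiles <- function(reads, snpome, genome, window = 100,
                                step = 50, L = 70L) {
  index <- if (inherits(snpome, "snp_index")) snpome else snp_index(snpome)
  reads <- trim_filter_reads(reads, L)
  lab <- assign_reads(reads, index)
  counts <- c(parent_A = sum(lab == "parent_A"),
              parent_B = sum(lab == "parent_B"),
              unassigned = sum(lab == "unassigned"),
              conflicted = sum(lab == "conflicted"))
  a <- reads[lab == "parent_A", , drop = FALSE]
  b <- reads[lab == "parent_B", , drop = FALSE]
  track_a <- window_coverage(a, genome, window, step)
  track_b <- window_coverage(b, genome, window, step)
  fac <- allele_scaling(max(counts["parent_A"], 1), max(counts["parent_B"], 1))
  track_a <- normalize_track(track_a, fac[1], reference = "smallest_file")
  track_b <- normalize_track(track_b, fac[2], reference = "smallest_file")
  list(track_a = track_a, track_b = track_b, counts = counts, factors = fac)
}

#' Extract duplication-scenario reads in the segment frame
#'
#' Maps truth alignments on the derived genome of a segmental duplication
#' scenario into the shared segment coordinate frame (native copy and
#' duplicate copy overlaid) and attaches read sequences.
#' @param scenario a `segmental_duplication` [build_scenario()] result.
#' @param aln truth alignments on the scenario's derived genome.
#' @return data.frame chrom("segment")/start/end/strand/seq.
#' @export
segdup_frame_reads <- function(scenario, aln) {
  tr <- scenario$truth
  a1 <- tr$segment[1]; a2 <- tr$segment[2]
  segL <- a2 - a1
  don <- tr$segment_chrom
  acc <- tr$dup_chrom
  p <- tr$dup_start
  native <- aln$chrom == don & aln$start >= a1 & aln$end <= a2
  dup <- aln$chrom == acc & aln$start >= p & aln$end <= p + segL
  out <- aln[native | dup, , drop = FALSE]
  out <- reads_with_sequences(scenario$genome, out)
  shift <- ifelse(out$chrom == don, a1, p)
  out$start <- out$start - shift
  out$end <- out$end - shift
  out$chrom <- "segment"
  rownames(out) <- NULL
  out
}
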