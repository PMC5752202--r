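# Read simulation: ChIP/input single-end read sampling with domain
# enrichment, paired-end fragment sampling with liftover-aware mapping back
# to the source genome (the raw material of breakpoint detection), SNPome
# generation and negative-binomial RNA counts.

#' Parameters of the read simulators
#'
#' @param read_length read length in bp (single-end 75 by default).
#' @param paired simulate read pairs.
#' @param frag_mean,frag_sd fragment length distribution for paired mode.
#' @param depth target mean per-base coverage.
#' @param enrichment relative sampling rate of read starts inside
#'   methylation domains for the ChIP channel.
#' @param error_rate per-base substitution rate (0 disables errors).
#' @param seed integer seed.
#' @export
read_sim_params <- function(read_length = 75L, paired = FALSE,
                            frag_mean = 350, frag_sd = 50, depth = 20,
                            enrichment = 8, error_rate = 0, seed = 1L) {
  stopifnot(read_length > 0, frag_mean > 0, frag_sd >= 0, depth >= 0,
            enrichment > 0, error_rate >= 0, error_rate < 1)
  list(read_length = as.integer(read_length), paired = paired,
       frag_mean = frag_mean, frag_sd = frag_sd, depth = depth,
       enrichment = enrichment, error_rate = error_rate,
       seed = as.integer(seed))
}

# sample n integer positions uniformly from the union of intervals
# (data.frame start/end, half-open)
.sample_in_intervals <- function(iv, n) {
  if (n == 0 || nrow(iv) == 0) return(numeric(0))
  w <- iv$end - iv$start
  pick <- sample.int(nrow(iv), n, replace = TRUE, prob = w)
  iv$start[pick] + floor(stats::runif(n) * w[pick])
}

#' Simulate ChIP or input reads as truth alignments
#'
#' Read start positions are sampled uniformly for the input channel; for the
#' ChIP channel starts inside truth methylation domains are sampled with
#' relative rate `enrichment` versus 1 outside. Emitted read count is
#' `round(depth * genome_bp / read_length)` over the selected chromosomes.
#'
#' @param genome an `annotated_genome` (or scenario truth genome).
#' @param rsp see [read_sim_params()].
#' @param channel "chip" or "input".
#' @param domains truth domains to enrich (default `genome$domains`).
#' @param chroms restrict simulation to these chromosomes (the statistic of
#'   interest is often on one chromosome; restricting keeps runtime small
#'   and leaves per-chromosome coverage unchanged).
#' @return data.frame chrom/start/end/strand/name, sorted by position.
#' @export
simulate_chip_reads <- function(genome, rsp, channel = c("chip", "input"),
                                domains = NULL, chroms = NULL) {
  channel <- match.arg(channel)
  domains <- domains %||% genome$domains
  L <- rsp$read_length
  e <- if (channel == "chip") rsp$enrichment else 1
  ch <- genome$chromosomes
  if (!is.null(chroms)) ch <- ch[ch$name %in% chroms, , drop = FALSE]
  ch <- ch[ch$length > L, , drop = FALSE]
  if (rsp$depth <= 0) stopf("depth must be positive")
  n_total <- round(rsp$depth * sum(ch$length) / L)

  with_seed(derive_seed(rsp$seed, "reads", channel), {
    per <- vector("list", nrow(ch))
    # start-position space on each chromosome and its enriched portion
    dom_iv <- vector("list", nrow(ch))
    bg_iv <- vector("list", nrow(ch))
    w <- numeric(nrow(ch))
    for (i in seq_len(nrow(ch))) {
      len <- ch$length[i]
      space <- data.frame(chrom = ch$name[i], start = 0, end = len - L + 1)
      d <- domains[domains$chrom == ch$name[i], , drop = FALSE]
      d <- if (nrow(d)) merge_intervals(d) else d
      if (nrow(d)) {
        d$end <- pmin(d$end, len - L + 1)
        d <- d[d$end > d$start, , drop = FALSE]
      }
      dom_iv[[i]] <- d
      bg_iv[[i]] <- if (nrow(d)) interval_setdiff(space, d) else space
      A <- if (nrow(d)) sum(d$end - d$start) else 0
      w[i] <- (len - L + 1 - A) + e * A
    }
    alloc <- as.vector(stats::rmultinom(1, n_total, w))
    for (i in seq_len(nrow(ch))) {
      n_c <- alloc[i]
      if (n_c == 0) next
      A <- if (nrow(dom_iv[[i]])) sum(dom_iv[[i]]$end - dom_iv[[i]]$start) else 0
      p_dom <- e * A / w[i]
      n_dom <- stats::rbinom(1, n_c, p_dom)
      s <- c(.sample_in_intervals(dom_iv[[i]], n_dom),
             .sample_in_intervals(bg_iv[[i]], n_c - n_dom))
      per[[i]] <- data.frame(
        chrom = ch$name[i], start = s, end = s + L,
        strand = sample(c("+", "-"), n_c, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, per)
    if (is.null(out))
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), strand = character(),
                        stringsAsFactors = FALSE))
    rownames(out) <- NULL
    out
  })
}

#' Attach sequences to truth alignments
#'
#' Extracts each read's sequence from the genome (reverse-complemented for
#' minus-strand reads) and optionally applies uniform substitution errors.
#' @param genome sequence-mode `annotated_genome`.
#' @param aln alignment data.frame from [simulate_chip_reads()].
#' @param error_rate per-base substitution probability.
#' @param seed seed for the error process.
#' @return `aln` with a `seq` column.
#' @export
reads_with_sequences <- function(genome, aln, error_rate = 0, seed = 1L) {
  if (is.null(genome$sequences)) stopf("genome has no sequences")
  seqs <- character(nrow(aln))
  for (nm in unique(aln$chrom)) {
    i <- which(aln$chrom == nm)
    seqs[i] <- substring(genome$sequences[[nm]], aln$start[i] + 1, aln$end[i])
  }
  neg <- aln$strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  if (error_rate > 0) {
    seqs <- with_seed(derive_seed(seed, "readerr"), {
      L <- nchar(seqs)
      n_err <- stats::rbinom(length(seqs), L, error_rate)
      for (i in which(n_err > 0)) {
        pos <- sample.int(L[i], n_err[i])
        for (p in pos) {
          old <- substr(seqs[i], p, p)
          substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
        }
      }
      seqs
    })
  }
  aln$seq <- seqs
  aln
}

#' Simulate paired-end fragments on a (derived) genome
#'
#' Fragments are uniform (input DNA); lengths are normal with the configured
#' mean/sd, clamped to at least two read lengths.
#' @param genome the genome fragments are drawn from.
#' @param rsp see [read_sim_params()].
#' @param chroms restrict to these chromosomes.
#' @return data.frame chrom/start/end/frag_id.
#' @export
simulate_paired_fragments <- function(genome, rsp, chroms = NULL) {
  L <- rsp$read_length
  ch <- genome$chromosomes
  if (!is.null(chroms)) ch <- ch[ch$name %in% chroms, , drop = FALSE]
  n_frag <- round(rsp$depth * sum(ch$length) / (2 * L))
  with_seed(derive_seed(rsp$seed, "frags"), {
    ci <- sample.int(nrow(ch), n_frag, replace = TRUE, prob = ch$length)
    fl <- pmax(2 * L, round(stats::rnorm(n_frag, rsp$frag_mean, rsp$frag_sd)))
    fl <- pmin(fl, ch$length[ci])
    s <- floor(stats::runif(n_frag) * (ch$length[ci] - fl + 1))
    data.frame(chrom = ch$name[ci], start = s, end = s + fl,
               frag_id = seq_len(n_frag), stringsAsFactors = FALSE)
  })
}

#' Map derived-genome read pairs to source-genome alignments
#'
#' Emulates aligning reads from a rearranged genome against the source
#' reference: each read interval is pushed through the inverse liftover.
#' Reads spanning a junction become split alignments with exact junction
#' coordinates; reads entirely within novel (unmapped) material are dropped.
#'
#' @param frags fragments from [simulate_paired_fragments()] (on the
#'   derived genome).
#' @param map `liftover_map` from source to derived genome.
#' @param read_length read length in bp.
#' @return alignment data.frame with columns qname/mate/chrom/start/end/
#'   strand plus split-locus columns (split_chrom/split_start/split_end/
#'   split_strand/junc_pos/junc_pos2) for junction-spanning reads.
#' @export
pairs_to_source_alignments <- function(frags, map, read_length) {
  L <- read_length
  reads <- rbind(
    data.frame(qname = frags$frag_id, mate = 1L, chrom = frags$chrom,
               start = frags$start, end = frags$start + L, strand = "+",
               stringsAsFactors = FALSE),
    data.frame(qname = frags$frag_id, mate = 2L, chrom = frags$chrom,
               start = frags$end - L, end = frags$end, strand = "-",
               stringsAsFactors = FALSE))
  inv <- invert_liftover(map)
  b <- inv$blocks
  pieces <- list()
  for (i in seq_len(nrow(b))) {
    idx <- which(reads$chrom == b$src_chrom[i] & reads$start < b$src_end[i] &
                 reads$end > b$src_start[i])
    if (length(idx) == 0) next
    s <- pmax(reads$start[idx], b$src_start[i])
    e <- pmin(reads$end[idx], b$src_end[i])
    o1 <- s - b$src_start[i]
    o2 <- e - b$src_start[i]
    ts <- if (b$strand[i] == 1L) b$tgt_start[i] + o1 else b$tgt_end[i] - o2
    te <- if (b$strand[i] == 1L) b$tgt_start[i] + o2 else b$tgt_end[i] - o1
    pieces[[length(pieces) + 1]] <- data.frame(
      ridx = idx, dstart = s, m_chrom = b$tgt_chrom[i], m_start = ts,
      m_end = te, m_bstrand = b$strand[i], stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0) return(NULL)
  pc <- do.call(rbind, pieces)
  pc <- pc[order(pc$ridx, pc$dstart), ]
  cnt <- table(pc$ridx)
  first <- !duplicated(pc$ridx)

  res <- reads[pc$ridx[first], c("qname", "mate")]
  p1 <- pc[first, ]
  n <- nrow(res)
  res$chrom <- p1$m_chrom
  res$start <- p1$m_start
  res$end <- p1$m_end
  rs <- reads$strand[pc$ridx[first]]
  res$strand <- ifelse((rs == "+") == (p1$m_bstrand == 1L), "+", "-")
  res$split_chrom <- NA_character_
  res$split_start <- NA_real_
  res$split_end <- NA_real_
  res$split_strand <- NA_character_
  res$junc_pos <- NA_real_
  res$junc_pos2 <- NA_real_

  multi <- names(cnt)[cnt >= 2]
  if (length(multi)) {
    # take the second piece (reads cross at most a couple of junctions;
    # pieces are ordered along the read)
    idx2 <- which(duplicated(pc$ridx))
    idx2 <- idx2[!duplicated(pc$ridx[idx2])]   # first duplicate per read
    m <- match(pc$ridx[idx2], pc$ridx[first])
    p2 <- pc[idx2, ]
    res$split_chrom[m] <- p2$m_chrom
    res$split_start[m] <- p2$m_start
    res$split_end[m] <- p2$m_end
    rs2 <- reads$strand[p2$ridx]
    res$split_strand[m] <- ifelse((rs2 == "+") == (p2$m_bstrand == 1L), "+", "-")
    # junction coordinates: derived-right edge of piece1, derived-left of piece2
    pp1 <- pc[first, ][m, ]
    res$junc_pos[m] <- ifelse(pp1$m_bstrand == 1L, pp1$m_end, pp1$m_start)
    res$junc_pos2[m] <- ifelse(p2$m_bstrand == 1L, p2$m_start, p2$m_end)
  }
  rownames(res) <- NULL
  res
}

#' Generate a SNPome and the corresponding variant genome
#'
#' Biallelic substitutions at positions sampled per-base with probability
#' `snp_rate`; the SNPome records both alleles and the flanking context
#' (+/- `flank` bp) under each parent, with neighbouring SNPs applied, so
#' exact read matching against either context reproduces "100% alignment to
#' either genome".
#'
#' @param genome sequence-mode `annotated_genome`.
#' @param snp_rate per-bp substitution probability, in (0, 0.05].
#' @param seed integer seed.
#' @param flank context half-width (use the post-trim read length).
#' @return list(snpome = data.frame, variant = `annotated_genome` carrying
#'   the alternate alleles).
#' @export
generate_snpome <- function(genome, snp_rate, seed = 1L, flank = 70L) {
  if (is.null(genome$sequences)) stopf("genome has no sequences")
  if (snp_rate <= 0 || snp_rate > 0.05) stopf("snp_rate must be in (0, 0.05]")
  rows <- list()
  var_seqs <- genome$sequences
  for (nm in genome$chromosomes$name) {
    s <- genome$sequences[[nm]]
    len <- nchar(s)
    if (len < 2 * flank + 2) next
    snp <- with_seed(derive_seed(seed, "snpome", nm), {
      cnt <- stats::rbinom(1, len - 2 * flank, snp_rate)
      pos <- sort(sample(seq.int(flank, len - flank - 1), cnt))
      ref <- substring(s, pos + 1, pos + 1)
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      list(pos = pos, ref = ref, alt = unname(alt))
    })
    if (length(snp$pos) == 0) next
    v <- s
    for (i in seq_along(snp$pos))
      substr(v, snp$pos[i] + 1, snp$pos[i] + 1) <- snp$alt[i]
    var_seqs[[nm]] <- v
    rows[[nm]] <- data.frame(
      chrom = nm, pos = snp$pos, allele_a = snp$ref, allele_b = snp$alt,
      flank_a = substring(s, snp$pos - flank + 1, snp$pos + flank + 1),
      flank_b = substring(v, snp$pos - flank + 1, snp$pos + flank + 1),
      stringsAsFactors = FALSE)
  }
  snpome <- do.call(rbind, rows) %||%
    data.frame(chrom = character(), pos = numeric(), allele_a = character(),
               allele_b = character(), flank_a = character(),
               flank_b = character(), stringsAsFactors = FALSE)
  rownames(snpome) <- NULL
  attr(snpome, "flank") <- flank
  variant <- genome
  variant$sequences <- var_seqs
  list(snpome = snpome, variant = variant)
}

#' Simulate RNA-seq counts with methylation-dependent repression
#'
#' Per-gene counts are negative binomial. A gene fully covered by a truth
#' methylation domain has its mean multiplied by the repression factor
#' `rho`; partial overlap interpolates linearly in the covered fraction.
#'
#' @param genome an `annotated_genome` with genes.
#' @param domains truth domains (default `genome$domains`).
#' @param base_mean expected count of an unmethylated gene.
#' @param dispersion negative-binomial dispersion (1/size).
#' @param rho repression factor in (0, 1]; must be > 0.
#' @param seed integer seed.
#' @return data.frame gene_id/chrom/start/end/covered_fraction/count.
#' @export
simulate_rna_counts <- function(genome, domains = NULL, base_mean = 200,
                                dispersion = 0.2, rho = 0.1, seed = 1L) {
  if (rho <= 0) stopf("repression factor rho must be > 0")
  domains <- domains %||% genome$domains
  genes <- genome$genes
  if (nrow(genes) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      covered_fraction = numeric(), count = numeric(),
                      stringsAsFactors = FALSE))
  dm <- if (nrow(domains)) merge_intervals(domains) else domains
  f <- numeric(nrow(genes))
  if (nrow(dm)) {
    ov <- interval_overlaps(genes, dm)
    if (nrow(ov)) {
      agg <- tapply(ov$overlap_bp, ov$qi, sum)
      f[as.integer(names(agg))] <- agg / (genes$end - genes$start)[as.integer(names(agg))]
    }
  }
  mu <- base_mean * (1 - f + f * rho)
  counts <- with_seed(derive_seed(seed, "rna"), {
    stats::rnbinom(nrow(genes), mu = mu, size = 1 / dispersion)
  })
  data.frame(gene_id = genes$id, chrom = genes$chrom, start = genes$start,
             end = genes$end, covered_fraction = f, count = counts,
             stringsAsFactors = FALSE)
}

#' Noise-free coverage tracks from truth domains
#'
#' Builds the idealized ChIP and input tracks implied by the enrichment
#' model (rate `e` inside truth domains, 1 outside; input constant 1),
#' windowed like real tracks. Used for caller/classifier correctness tests.
#' @param genome an `annotated_genome`.
#' @param window,step window geometry in bp.
#' @param e domain enrichment.
#' @param domains truth domains (default `genome$domains`).
#' @return list(chip = `coverage_track`, input = `coverage_track`).
#' @export
noise_free_tracks <- function(genome, window = 100, step = 50, e = 8,
                              domains = NULL) {
  domains <- domains %||% genome$domains
  ch <- genome$chromosomes
  chip <- list(); input <- list()
  for (i in seq_len(nrow(ch))) {
    len <- ch$length[i]
    n_win <- floor((len - window) / step) + 1
    if (n_win < 1) { chip[[ch$name[i]]] <- numeric(0); input[[ch$name[i]]] <- numeric(0); next }
    d <- merge_intervals(domains[domains$chrom == ch$name[i], , drop = FALSE])
    delta <- numeric(len + 1)
    if (nrow(d)) {
      delta[d$start + 1] <- delta[d$start + 1] + 1
      delta[d$end + 1] <- delta[d$end + 1] - 1
    }
    occ <- cumsum(delta)[seq_len(len)]
    cs <- c(0, cumsum(occ))
    s <- (seq_len(n_win) - 1) * step
    frac <- (cs[s + window + 1] - cs[s + 1]) / window
    chip[[ch$name[i]]] <- 1 + (e - 1) * frac
    input[[ch$name[i]]] <- rep(1, n_win)
  }
  list(chip = coverage_track(ch, window, step, chip),
       input = coverage_track(ch, window, step, input))
}
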