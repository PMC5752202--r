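# Strain scenarios: abstracted rearrangement classes with ground truth.
# Each scenario draws rearrangement coordinates (seeded) under clearance
# constraints that keep truth domains resolvable, applies the rearrangement
# through the genome model, reevaluates the methylation ground truth, and
# records per-domain fates (kept / lost), de-novo domains and new ends.

SCENARIO_NAMES <- c("insertional", "reciprocal", "quasiterminal",
                    "insertional_to_mid", "terminal_shift", "tert",
                    "segmental_duplication")

# no truth domain overlaps [start, end) on chrom
.domain_free <- function(genome, chrom, start, end) {
  d <- genome$domains
  !any(d$chrom == chrom & d$end > start & d$start < end)
}

# a breakpoint within [len-lo, len-hi] of the right end whose distal side
# is domain-free (placed just distal of the nearest zone domain); NULL if
# the near-end region is fully occupied
.distal_clear_point <- function(genome, chrom, len, lo = 40e3, hi = 8e3) {
  d <- genome$domains
  d <- d[d$chrom == chrom & d$end > len - lo, , drop = FALSE]
  floor_pos <- if (nrow(d)) max(len - lo, max(d$end) + 2e3) else len - lo
  ceil_pos <- len - hi
  if (floor_pos >= ceil_pos) return(NULL)
  floor(stats::runif(1, floor_pos, ceil_pos))
}

# position-dependent domains within `zone` of the right end of each chrom
.right_zone_domains <- function(genome, zone = 100e3) {
  d <- genome$domains
  res <- list()
  for (i in seq_len(nrow(genome$chromosomes))) {
    nm <- genome$chromosomes$name[i]
    len <- genome$chromosomes$length[i]
    dd <- d[d$chrom == nm & d$class == "position_dependent" &
            d$end > len - zone - TEL_LEN * 40, , drop = FALSE]
    if (nrow(dd)) res[[nm]] <- dd
  }
  res
}

#' Build a strain scenario with ground truth
#'
#' Known scenario classes: `insertional` (interior donor segment inserted at
#' a distal acceptor position, displacing the old subtelomere),
#' `reciprocal` (arm exchange with one near-terminal breakpoint),
#' `quasiterminal` (distal donor segment fused to an acceptor end),
#' `insertional_to_mid` (distal donor segment moved to an internal acceptor
#' position), `terminal_shift` (a ~600 kb donor end segment fused onto an
#' acceptor end, shifting the acceptor subtelomere inward), `tert`
#' (telomere loss: all chromosomes circularize), `telomere_insertion_<k>`
#' (`(TTAGGG)_k` replacing an interior 2 kb locus), and
#' `segmental_duplication` (a distal segment present both at its native
#' subtelomeric position and as an internal copy, with a dense SNPome
#' distinguishing the copies when sequences are available).
#'
#' @param name scenario class (see above).
#' @param genome wild-type `annotated_genome`.
#' @param seed integer seed for the scenario draws and truth samplers.
#' @param reeval methylation ground-truth parameters
#'   ([reevaluation_params()]); its seed defaults to one derived from
#'   `seed`.
#' @param dup_snp_rate SNP density used for the segmental duplication
#'   SNPome (per bp).
#' @return object of class `strain_scenario`.
#' @export
build_scenario <- function(name, genome, seed = 1L, reeval = NULL,
                           dup_snp_rate = 0.005) {
  reeval <- reeval %||% reevaluation_params(seed = derive_seed(seed, "reeval", name))
  k_ins <- NULL
  if (grepl("^telomere_insertion_\\d+$", name)) {
    k_ins <- as.integer(sub("^telomere_insertion_", "", name))
  } else if (!name %in% SCENARIO_NAMES) {
    stopf("unknown scenario '%s'", name)
  }
  zone <- 100e3
  clear <- 265e3          # de-novo reach (D_tel) + caller merge gap + margin
  ch <- genome$chromosomes
  lens <- stats::setNames(ch$length, ch$name)
  draw_seed <- derive_seed(seed, "scenario", name)

  extras <- list()
  rlist <- NULL
  special <- NULL   # for segmental_duplication: list(genome, map)

  if (!is.null(k_ins)) {
    pick <- with_seed(draw_seed, {
      p <- NULL
      cc <- NULL
      for (try in 1:500) {
        cc <- sample(ch$name, 1, prob = ch$length)
        len <- lens[cc]
        if (len < 2 * (350e3 + reeval$D_tel)) next
        cand <- floor(stats::runif(1, reeval$D_tel + 350e3,
                                   len - reeval$D_tel - 350e3))
        if (.domain_free(genome, cc, cand - 320e3, cand + 320e3)) {
          p <- cand
          break
        }
      }
      if (is.null(p)) stopf("could not place a telomere insertion")
      list(chrom = cc, p = p)
    })
    rlist <- list(rearrangement("insertion_at_locus", chrom = pick$chrom,
                                insertion_point = pick$p,
                                replace = c(pick$p, pick$p + 2000),
                                novel_repeats = k_ins))
    extras$anchor_chrom <- pick$chrom
    extras$anchor_pos <- pick$p
  } else if (name == "tert") {
    rlist <- lapply(ch$name, function(cc) rearrangement("circularize", chrom = cc))
  } else if (name == "insertional") {
    pick <- with_seed(draw_seed, {
      zs <- .right_zone_domains(genome, zone)
      acc_opts <- sample(names(zs))
      res <- NULL
      for (acc in acc_opts) {
        len <- lens[acc]
        dmax <- max(zs[[acc]]$end)
        lo_p <- dmax + 2e3
        hi_p <- len - TEL_LEN * telomere_n(genome, acc, "R") - 1e3
        if (hi_p <= lo_p) next
        for (try in 1:200) {
          p <- floor(stats::runif(1, lo_p, hi_p))
          don <- sample(setdiff(ch$name, acc), 1)
          sl <- floor(stats::runif(1, 1.6e6, 2.1e6))
          if (lens[don] < sl + 700e3) next
          s <- floor(stats::runif(1, 350e3, lens[don] - 350e3 - sl))
          e <- s + sl
          ok <- .domain_free(genome, don, s - 5e3, s + 5e3) &&
            .domain_free(genome, don, e - clear, e + 5e3) &&
            .domain_free(genome, acc, p - 2e3, len)
          if (ok) { res <- list(don = don, acc = acc, s = s, e = e, p = p); break }
        }
        if (!is.null(res)) break
      }
      if (is.null(res)) stopf("could not draw an insertional scenario")
      res
    })
    rlist <- list(rearrangement("insertional_translocation", donor = pick$don,
                                acceptor = pick$acc,
                                segment = c(pick$s, pick$e),
                                insertion_point = pick$p))
  } else if (name == "reciprocal") {
    pick <- with_seed(draw_seed, {
      res <- NULL
      for (margin in c(clear, 150e3, 60e3)) {
        for (try in 1:300) {
          don <- sample(ch$name, 1)
          acc <- sample(setdiff(ch$name, don), 1)
          la <- lens[acc]
          a <- floor(stats::runif(1, min(400e3, lens[don] / 4),
                                  lens[don] - min(400e3, lens[don] / 4)))
          b <- .distal_clear_point(genome, acc, la, lo = 40e3, hi = 8e3)
          ok <- !is.null(b) && .domain_free(genome, don, a - margin, a + 5e3)
          if (ok) { res <- list(don = don, acc = acc, a = a, b = b); break }
        }
        if (!is.null(res)) break
      }
      if (is.null(res)) stopf("could not draw a reciprocal scenario")
      res
    })
    rlist <- list(rearrangement("reciprocal_translocation", donor = pick$don,
                                acceptor = pick$acc,
                                breakpoint_donor = pick$a,
                                breakpoint_acceptor = pick$b))
  } else if (name %in% c("quasiterminal", "terminal_shift")) {
    seg_range <- if (name == "quasiterminal") c(0.4e6, 1.2e6) else c(0.5e6, 0.7e6)
    pick <- with_seed(draw_seed, {
      zs <- .right_zone_domains(genome, zone)
      res <- NULL
      for (margin in c(clear, 150e3, 60e3)) {
        for (try in 1:300) {
          acc <- sample(names(zs), 1)        # acceptor loses its subtelomere
          don <- sample(setdiff(ch$name, acc), 1)
          if (name == "quasiterminal" && !don %in% names(zs) &&
              margin == clear) next
          ld <- lens[don]
          sl <- floor(stats::runif(1, seg_range[1], seg_range[2]))
          a <- ld - sl
          if (a < min(400e3, ld / 4)) next
          if (.domain_free(genome, don, a - margin, a + 5e3))
            { res <- list(don = don, acc = acc, a = a); break }
        }
        if (!is.null(res)) break
      }
      if (is.null(res)) stopf("could not draw a %s scenario", name)
      res
    })
    rlist <- list(rearrangement("quasiterminal_translocation",
                                donor = pick$don, acceptor = pick$acc,
                                breakpoint_donor = pick$a))
  } else if (name == "insertional_to_mid") {
    pick <- with_seed(draw_seed, {
      zs <- .right_zone_domains(genome, zone)
      res <- NULL
      for (try in 1:500) {
        don <- sample(names(zs), 1)
        acc <- sample(setdiff(ch$name, don), 1)
        ld <- lens[don]; la <- lens[acc]
        sl <- floor(stats::runif(1, 0.8e6, 1.3e6))
        a <- ld - TEL_LEN * telomere_n(genome, don, "R") - sl
        if (a < 400e3) next
        if (la < 2 * (reeval$D_tel + 300e3)) next
        p <- floor(stats::runif(1, reeval$D_tel + 300e3,
                                la - reeval$D_tel - 300e3))
        ok <- .domain_free(genome, don, a - clear, a + 5e3) &&
          .domain_free(genome, acc, p - 20e3, p + 20e3)
        if (ok) { res <- list(don = don, acc = acc, a = a, p = p); break }
      }
      if (is.null(res)) stopf("could not draw an insertional_to_mid scenario")
      res
    })
    e <- lens[pick$don] - TEL_LEN * telomere_n(genome, pick$don, "R")
    rlist <- list(rearrangement("insertional_translocation", donor = pick$don,
                                acceptor = pick$acc,
                                segment = c(pick$a, unname(e)),
                                insertion_point = pick$p))
  } else if (name == "segmental_duplication") {
    special <- .build_duplication(genome, seed, reeval, zone, dup_snp_rate)
    extras <- special$extras
  }

  if (!is.null(special)) {
    derived0 <- special$genome
    map <- special$map
    rlist <- special$rlist
  } else {
    res <- apply_rearrangements(genome, rlist, context_window = reeval$D_tel)
    derived0 <- res$genome
    map <- res$map
  }

  truth_genome <- reevaluate_genome(derived0, reeval)

  ## per-domain fates of the base genome's domains
  fates <- NULL
  lifted_all <- .empty_iv()[c("chrom", "start", "end")]
  if (nrow(genome$domains)) {
    fates <- genome$domains
    fates$fate <- "kept"
    lv <- lift_many(map, genome$domains)
    fates$lifted <- split(lv[, c("chrom", "start", "end", "strand")],
                          factor(lv$idx, levels = seq_len(nrow(fates))))
    llen <- vapply(fates$lifted, function(x) sum(x$end - x$start), numeric(1))
    cov <- numeric(nrow(fates))
    if (nrow(lv)) {
      ov <- interval_overlaps(lv, truth_genome$domains)
      if (nrow(ov)) {
        agg <- tapply(ov$overlap_bp, lv$idx[ov$qi], sum)
        cov[as.integer(names(agg))] <- agg
      }
    }
    fates$fate[llen == 0] <- "deleted"
    fates$fate[llen > 0 & cov < 0.5 * llen] <- "lost"
    if (nrow(lv)) lifted_all <- lv[, c("chrom", "start", "end")]
  }
  de_novo <- interval_setdiff(truth_genome$domains[, c("chrom", "start", "end")],
                              lifted_all)
  de_novo <- de_novo[de_novo$end - de_novo$start >= 1000, , drop = FALSE]

  new_ends <- truth_genome$telomeres[0, c("chrom", "side")]
  tl <- derived0$telomeres
  if (nrow(tl))
    new_ends <- tl[tl$nascent & tl$n > 0, c("chrom", "side"), drop = FALSE]

  structure(list(
    name = name, base = genome, genome = truth_genome, map = map,
    rearrangements = rlist, seed = seed, reeval = reeval,
    truth = c(list(domains = truth_genome$domains, fates = fates,
                   de_novo = de_novo, new_ends = new_ends,
                   breakpoints = map$breakpoints), extras)),
    class = "strain_scenario")
}

#' @export
print.strain_scenario <- function(x, ...) {
  cat(sprintf("strain_scenario '%s': %d truth domains, %d new end(s), %d breakpoint(s)\n",
              x$name, nrow(x$truth$domains), nrow(x$truth$new_ends),
              if (is.null(x$truth$breakpoints)) 0L else nrow(x$truth$breakpoints)))
  invisible(x)
}

# Segmental duplication: native distal segment stays; an extra copy is
# inserted internally on another chromosome. The liftover maps native
# coordinates (the duplicate copy is unmapped-from-source); a separate
# dup_map places segment-frame coordinates onto the duplicate copy.
.build_duplication <- function(genome, seed, reeval, zone, dup_snp_rate) {
  ch <- genome$chromosomes
  lens <- stats::setNames(ch$length, ch$name)
  pick <- with_seed(derive_seed(seed, "scenario", "segdup"), {
    zs <- .right_zone_domains(genome, zone)
    res <- NULL
    for (try in 1:500) {
      don <- sample(names(zs), 1)
      dom <- zs[[don]]
      a2 <- lens[don] - TEL_LEN * telomere_n(genome, don, "R")
      a1 <- min(dom$start) - 10e3
      if (a1 < 200e3) next
      acc <- sample(setdiff(ch$name, don), 1)
      la <- lens[acc]
      if (la < 2 * (reeval$D_tel + 300e3)) next
      p <- floor(stats::runif(1, reeval$D_tel + 300e3, la - reeval$D_tel - 300e3))
      if (.domain_free(genome, acc, p - 20e3, p + 20e3))
        { res <- list(don = don, acc = acc, a1 = unname(a1), a2 = unname(a2),
                      p = p); break }
    }
    if (is.null(res)) stopf("could not draw a segmental duplication")
    res
  })
  segL <- pick$a2 - pick$a1
  acc <- pick$acc; don <- pick$don
  la <- lens[acc]

  ## derived genome: identical to base except acceptor gains the copy
  tgt_chroms <- ch
  tgt_chroms$length[tgt_chroms$name == acc] <- la + segL
  blocks <- data.frame(src_chrom = ch$name, src_start = 0, src_end = ch$length,
                       tgt_chrom = ch$name, tgt_start = 0, tgt_end = ch$length,
                       strand = 1L, stringsAsFactors = FALSE)
  i <- which(blocks$src_chrom == acc)
  blocks <- rbind(blocks[-i, ],
                  data.frame(src_chrom = acc, src_start = 0, src_end = pick$p,
                             tgt_chrom = acc, tgt_start = 0, tgt_end = pick$p,
                             strand = 1L),
                  data.frame(src_chrom = acc, src_start = pick$p, src_end = la,
                             tgt_chrom = acc, tgt_start = pick$p + segL,
                             tgt_end = la + segL, strand = 1L))
  map <- liftover_map(blocks, ch[, c("name", "length")],
                      tgt_chroms[, c("name", "length")])

  ## duplicate-copy annotations at acceptor [p, p+segL)
  shift <- pick$p - pick$a1
  in_seg <- function(df) df[df$chrom == don & df$start >= pick$a1 &
                            df$end <= pick$a2, , drop = FALSE]
  dup_genes <- in_seg(genome$genes)
  if (nrow(dup_genes)) {
    dup_genes$chrom <- acc
    dup_genes$start <- dup_genes$start + shift
    dup_genes$end <- dup_genes$end + shift
    dup_genes$id <- paste0(dup_genes$id, "_dup")
  }
  dup_dom <- in_seg(genome$domains)
  if (nrow(dup_dom)) {
    dup_dom$chrom <- acc
    dup_dom$start <- dup_dom$start + shift
    dup_dom$end <- dup_dom$end + shift
  }
  lift_df <- function(df) {
    if (nrow(df) == 0) return(df)
    ii <- df$chrom == acc & df$start >= pick$p
    df$start[ii] <- df$start[ii] + segL
    df$end[ii] <- df$end[ii] + segL
    df
  }
  genes <- rbind(lift_df(genome$genes), dup_genes)
  domains <- rbind(lift_df(genome$domains), dup_dom)
  domains <- domains[order(domains$chrom, domains$start), ]

  sequences <- NULL
  snpome <- NULL
  if (!is.null(genome$sequences)) {
    seg_seq <- substr(genome$sequences[[don]], pick$a1 + 1, pick$a2)
    flank <- 70L
    snp <- with_seed(derive_seed(seed, "segdup_snps"), {
      cnt <- stats::rbinom(1, segL - 2 * flank, dup_snp_rate)
      pos <- sort(sample(seq.int(flank, segL - flank - 1), cnt))
      ref <- substring(seg_seq, pos + 1, pos + 1)
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      list(pos = pos, ref = ref, alt = unname(alt))
    })
    dup_seq <- seg_seq
    for (i in seq_along(snp$pos))
      substr(dup_seq, snp$pos[i] + 1, snp$pos[i] + 1) <- snp$alt[i]
    sequences <- genome$sequences
    sequences[[acc]] <- paste0(substr(sequences[[acc]], 1, pick$p), dup_seq,
                               substr(sequences[[acc]], pick$p + 1, la))
    ## SNPome on the segment frame; parent A = native (MV), B = duplicate (OR)
    ctx <- function(s, pos) substring(s, pos - flank + 1, pos + flank + 1)
    snpome <- data.frame(chrom = "segment", pos = snp$pos,
                         allele_a = snp$ref, allele_b = snp$alt,
                         flank_a = ctx(seg_seq, snp$pos),
                         flank_b = ctx(dup_seq, snp$pos),
                         stringsAsFactors = FALSE)
    attr(snpome, "parents") <- c("MV", "OR")
    attr(snpome, "flank") <- flank
  }

  derived <- annotated_genome(
    chromosomes = tgt_chroms, telomeres = genome$telomeres, genes = genes,
    domains = domains, arrays = genome$arrays, sequences = sequences,
    junctions = genome$junctions)

  dup_map <- liftover_map(
    data.frame(src_chrom = "segment", src_start = 0, src_end = segL,
               tgt_chrom = acc, tgt_start = pick$p, tgt_end = pick$p + segL,
               strand = 1L, stringsAsFactors = FALSE),
    data.frame(name = "segment", length = segL),
    tgt_chroms[, c("name", "length")])

  list(genome = derived, map = map, rlist = list(),
       extras = list(segment = c(pick$a1, pick$a2), segment_chrom = don,
                     dup_chrom = acc, dup_start = pick$p, dup_map = dup_map,
                     snpome = snpome))
}
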