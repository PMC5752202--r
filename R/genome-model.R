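# Core data model: annotated genomes, chromosomal rearrangements, coordinate
# liftover, telomere distance, and the ground-truth rule for where
# facultative heterochromatin (H3K27me2/3) can exist.
#
# Coordinates are 0-based, half-open throughout.

TEL_UNIT <- "TTAGGG"
TEL_UNIT_RC <- "CCCTAA"
TEL_LEN <- 6L

DOMAIN_CLASSES <- c("position_dependent", "position_independent")

.empty_genes <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             strand = character(), id = character(), stringsAsFactors = FALSE)
}
.empty_domains <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             class = character(), stringsAsFactors = FALSE)
}
.empty_telomeres <- function() {
  data.frame(chrom = character(), side = character(), n = integer(),
             nascent = logical(), stringsAsFactors = FALSE)
}
.empty_arrays <- function() {
  data.frame(chrom = character(), start = numeric(), n = integer(),
             nascent = logical(), stringsAsFactors = FALSE)
}
.empty_junctions <- function() {
  data.frame(chrom = character(), pos = numeric(), trimmed_left = numeric(),
             trimmed_right = numeric(), stringsAsFactors = FALSE)
}

#' Construct an annotated genome
#'
#' An annotated genome bundles chromosome sizes and circularity, telomere
#' repeat arrays at chromosome ends, interstitial telomere repeat arrays,
#' gene intervals, ground-truth methylation domains (each tagged
#' `position_dependent` or `position_independent`), and (optionally)
#' chromosome sequences.
#'
#' @param chromosomes data.frame with columns name, length, circular.
#' @param telomeres data.frame chrom/side("L","R")/n/nascent; repeat counts of
#'   the telomeric hexamer at each end of each linear chromosome.
#' @param genes data.frame chrom/start/end/strand/id.
#' @param domains data.frame chrom/start/end/class.
#' @param arrays interstitial repeat arrays: data.frame chrom/start/n/nascent.
#' @param sequences named character vector of chromosome sequences (optional;
#'   "lengths-only" genomes omit it).
#' @param junctions circularization fusion junctions (bookkeeping for the
#'   outward-primer fusion test).
#' @return object of class `annotated_genome`.
#' @export
annotated_genome <- function(chromosomes, telomeres = NULL, genes = NULL,
                             domains = NULL, arrays = NULL, sequences = NULL,
                             junctions = NULL) {
  stopifnot(all(c("name", "length") %in% names(chromosomes)))
  if (is.null(chromosomes$circular)) chromosomes$circular <- FALSE
  g <- structure(list(
    chromosomes = chromosomes[, c("name", "length", "circular")],
    telomeres = telomeres %||% .empty_telomeres(),
    genes = genes %||% .empty_genes(),
    domains = domains %||% .empty_domains(),
    arrays = arrays %||% .empty_arrays(),
    sequences = sequences,
    junctions = junctions %||% .empty_junctions()
  ), class = "annotated_genome")
  validate_genome(g)
  g
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated_genome: %d chromosomes, %.2f Mb%s\n",
              nrow(x$chromosomes), genome_length(x) / 1e6,
              if (is.null(x$sequences)) " (lengths-only)" else ""))
  cat(sprintf("  genes: %d, methylation domains: %d (%.2f%% of genome)\n",
              nrow(x$genes), nrow(x$domains), 100 * methylated_fraction(x)))
  invisible(x)
}

#' Validate annotated-genome invariants
#' @param g an `annotated_genome`.
#' @return invisible TRUE; errors on violation.
#' @export
validate_genome <- function(g) {
  ch <- g$chromosomes
  if (anyDuplicated(ch$name)) stopf("duplicated chromosome names")
  len <- stats::setNames(ch$length, ch$name)
  check_iv <- function(df, what) {
    if (nrow(df) == 0) return()
    if (!all(df$chrom %in% ch$name)) stopf("%s on unknown chromosome", what)
    if (any(df$start < 0) || any(df$end > len[df$chrom]))
      stopf("%s interval outside [0, length)", what)
    if (any(df$end < df$start)) stopf("%s has end < start", what)
  }
  check_iv(g$genes, "gene")
  check_iv(g$domains, "domain")
  if (nrow(g$domains)) {
    if (!all(g$domains$class %in% DOMAIN_CLASSES))
      stopf("domain class must be one of %s", paste(DOMAIN_CLASSES, collapse = ", "))
    if (any(g$domains$end <= g$domains$start)) stopf("domain with end <= start")
    m <- merge_intervals(g$domains)
    if (sum(m$end - m$start) != covered_bp(g$domains)) stopf("impossible")
  }
  if (nrow(g$telomeres)) {
    if (!all(g$telomeres$side %in% c("L", "R"))) stopf("telomere side must be L/R")
    circ <- ch$name[ch$circular]
    if (any(g$telomeres$chrom %in% circ & g$telomeres$n > 0))
      stopf("circular chromosome cannot carry a terminal telomere array")
  }
  if (!is.null(g$sequences)) {
    if (!all(ch$name %in% names(g$sequences))) stopf("missing sequences")
    if (!all(nchar(g$sequences[ch$name]) == ch$length))
      stopf("sequence length disagrees with chromosome length")
  }
  invisible(TRUE)
}

#' @export
genome_length <- function(g) sum(g$chromosomes$length)

#' Fraction of the genome covered by methylation domains
#' @param g an `annotated_genome`.
#' @export
methylated_fraction <- function(g) covered_bp(g$domains) / genome_length(g)

chrom_length <- function(g, chrom) {
  i <- match(chrom, g$chromosomes$name)
  if (is.na(i)) stopf("unknown chromosome '%s'", chrom)
  g$chromosomes$length[i]
}

is_circular <- function(g, chrom) {
  i <- match(chrom, g$chromosomes$name)
  if (is.na(i)) stopf("unknown chromosome '%s'", chrom)
  g$chromosomes$circular[i]
}

telomere_n <- function(g, chrom, side) {
  i <- which(g$telomeres$chrom == chrom & g$telomeres$side == side)
  if (length(i) == 0) 0L else g$telomeres$n[i[1]]
}

telomere_nascent <- function(g, chrom, side) {
  i <- which(g$telomeres$chrom == chrom & g$telomeres$side == side)
  if (length(i) == 0) FALSE else isTRUE(g$telomeres$nascent[i[1]])
}

# interval occupied by a terminal repeat array (may be empty)
array_span <- function(g, chrom, side) {
  n <- telomere_n(g, chrom, side)
  len <- chrom_length(g, chrom)
  if (side == "L") c(0, TEL_LEN * n) else c(len - TEL_LEN * n, len)
}

# reverse-complement of plain character sequences
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

## ---------------------------------------------------------------------------
## Rearrangements
## ---------------------------------------------------------------------------

REARRANGEMENT_KINDS <- c("insertional_translocation", "reciprocal_translocation",
                         "quasiterminal_translocation", "deletion",
                         "insertion_at_locus", "circularize")

#' Describe a chromosomal rearrangement
#'
#' @param kind one of `r toString(REARRANGEMENT_KINDS)`.
#' @param donor,acceptor chromosome names (donor also serves as the single
#'   chromosome for deletion/insertion/circularize via `chrom`).
#' @param chrom chromosome for single-chromosome kinds.
#' @param segment numeric c(start, end) of the moved/deleted donor segment.
#' @param insertion_point position on the acceptor (or `chrom`).
#' @param orientation +1 or -1 for the moved segment.
#' @param breakpoint_donor,breakpoint_acceptor breakpoints for reciprocal /
#'   quasiterminal translocations.
#' @param replace interval replaced by the inserted material
#'   (insertion_at_locus).
#' @param novel_repeats number of telomeric hexamer units inserted
#'   (insertion_at_locus); the novel sequence is `(TTAGGG)_n`.
#' @param novel_seq explicit novel sequence (insertion_at_locus).
#' @return object of class `rearrangement`.
#' @export
rearrangement <- function(kind, donor = NULL, acceptor = NULL, chrom = NULL,
                          segment = NULL, insertion_point = NULL,
                          orientation = 1L, breakpoint_donor = NULL,
                          breakpoint_acceptor = NULL, replace = NULL,
                          novel_repeats = 0L, novel_seq = NULL) {
  kind <- match.arg(kind, REARRANGEMENT_KINDS)
  if (!orientation %in% c(1L, -1L)) stopf("orientation must be +1 or -1")
  structure(list(kind = kind, donor = donor, acceptor = acceptor,
                 chrom = chrom, segment = segment,
                 insertion_point = insertion_point,
                 orientation = as.integer(orientation),
                 breakpoint_donor = breakpoint_donor,
                 breakpoint_acceptor = breakpoint_acceptor,
                 replace = replace, novel_repeats = as.integer(novel_repeats),
                 novel_seq = novel_seq),
            class = "rearrangement")
}

.piece <- function(src = NA_character_, s = 0, e = 0, strand = 1L,
                   novel_n = 0L, novel_seq = NA_character_) {
  data.frame(src = src, s = s, e = e, strand = as.integer(strand),
             novel_n = as.integer(novel_n), novel_seq = novel_seq,
             stringsAsFactors = FALSE)
}

.piece_len <- function(p) {
  ifelse(!is.na(p$src), p$e - p$s,
         ifelse(p$novel_n > 0, TEL_LEN * p$novel_n, nchar(p$novel_seq)))
}

.identity_layouts <- function(g) {
  lapply(stats::setNames(seq_len(nrow(g$chromosomes)), g$chromosomes$name),
         function(i) .piece(g$chromosomes$name[i], 0, g$chromosomes$length[i]))
}

#' Apply a rearrangement to a genome
#'
#' Produces the derived genome (segments moved and oriented, telomere arrays
#' travelling with chromosome ends, genes and domains lifted through the
#' coordinate map) together with the invertible liftover map. Chromosome
#' ends whose surrounding chromatin changed within `context_window` are
#' flagged nascent; [reevaluate_methylation()] nucleates de-novo domains
#' there.
#'
#' @param genome an `annotated_genome`.
#' @param r a [rearrangement()].
#' @param context_window bp of terminal context compared against the source
#'   genome when deciding whether an end is "new" (default 250 kb).
#' @return list(genome = derived `annotated_genome`, map = `liftover_map`).
#' @export
apply_rearrangement <- function(genome, r, context_window = 250e3) {
  stopifnot(inherits(r, "rearrangement"))
  layouts <- .identity_layouts(genome)
  circular <- stats::setNames(genome$chromosomes$circular, genome$chromosomes$name)
  junctions <- .empty_junctions()
  breakpoints <- data.frame(chrom1 = character(), pos1 = numeric(),
                            chrom2 = character(), pos2 = numeric(),
                            stringsAsFactors = FALSE)
  bp_add <- function(c1, p1, c2, p2) {
    breakpoints[nrow(breakpoints) + 1L, ] <<- list(c1, p1, c2, p2)
  }

  if (r$kind == "insertional_translocation") {
    d <- r$donor; a <- r$acceptor
    s <- r$segment[1]; e <- r$segment[2]; p <- r$insertion_point
    ld <- chrom_length(genome, d); la <- chrom_length(genome, a)
    if (s < 0 || e > ld || s > e) stopf("segment out of bounds")
    if (p < 0 || p > la) stopf("insertion point out of bounds")
    if (d == a && p > s && p < e) stopf("insertion point inside the moved segment")
    if (e > s) {
      if (d == a) {
        layouts[[d]] <- if (p <= s) {
          rbind(.piece(d, 0, p), .piece(d, s, e, r$orientation),
                .piece(d, p, s), .piece(d, e, ld))
        } else {
          rbind(.piece(d, 0, s), .piece(d, e, p),
                .piece(d, s, e, r$orientation), .piece(d, p, ld))
        }
      } else {
        layouts[[d]] <- rbind(.piece(d, 0, s), .piece(d, e, ld))
        layouts[[a]] <- rbind(.piece(a, 0, p), .piece(d, s, e, r$orientation),
                              .piece(a, p, la))
      }
      bp_add(a, p, d, if (r$orientation == 1L) s else e)
      bp_add(d, if (r$orientation == 1L) e else s, a, p)
    }
  } else if (r$kind %in% c("reciprocal_translocation", "quasiterminal_translocation")) {
    d <- r$donor; a <- r$acceptor
    if (identical(d, a)) stopf("reciprocal exchange needs two chromosomes")
    ld <- chrom_length(genome, d); la <- chrom_length(genome, a)
    bd <- r$breakpoint_donor
    ba <- r$breakpoint_acceptor %||%
      (if (r$kind == "quasiterminal_translocation")
        la - TEL_LEN * telomere_n(genome, a, "R") else NULL)
    if (is.null(bd) || is.null(ba)) stopf("breakpoints required")
    if (bd <= 0 || bd >= ld || ba <= 0 || ba >= la) stopf("segment out of bounds")
    layouts[[d]] <- rbind(.piece(d, 0, bd), .piece(a, ba, la))
    layouts[[a]] <- rbind(.piece(a, 0, ba), .piece(d, bd, ld))
    bp_add(d, bd, a, ba)
  } else if (r$kind == "deletion") {
    cc <- r$chrom %||% r$donor
    s <- r$segment[1]; e <- r$segment[2]
    len <- chrom_length(genome, cc)
    if (s < 0 || e > len || s > e) stopf("segment out of bounds")
    if (e > s) {
      layouts[[cc]] <- rbind(.piece(cc, 0, s), .piece(cc, e, len))
      bp_add(cc, s, cc, e)
    }
  } else if (r$kind == "insertion_at_locus") {
    cc <- r$chrom %||% r$donor
    len <- chrom_length(genome, cc)
    p <- r$insertion_point
    repl <- r$replace %||% c(p, p)
    if (repl[1] < 0 || repl[2] > len || repl[1] > repl[2])
      stopf("segment out of bounds")
    novel_len <- if (r$novel_repeats > 0) TEL_LEN * r$novel_repeats
                 else nchar(r$novel_seq %||% "")
    if (novel_len > 0 || repl[2] > repl[1]) {
      novel <- if (novel_len > 0) {
        .piece(NA, 0, 0, 1L, r$novel_repeats,
               if (r$novel_repeats > 0) NA_character_ else r$novel_seq)
      } else NULL
      layouts[[cc]] <- rbind(.piece(cc, 0, repl[1]), novel,
                             .piece(cc, repl[2], len))
      bp_add(cc, repl[1], cc, repl[2])
    }
  } else if (r$kind == "circularize") {
    cc <- r$chrom %||% r$donor
    if (is_circular(genome, cc)) stopf("chromosome '%s' is already circular", cc)
    len <- chrom_length(genome, cc)
    tl <- TEL_LEN * telomere_n(genome, cc, "L")
    tr <- TEL_LEN * telomere_n(genome, cc, "R")
    layouts[[cc]] <- .piece(cc, tl, len - tr)
    circular[cc] <- TRUE
    junctions[nrow(junctions) + 1L, ] <- list(cc, 0, tl, tr)
    bp_add(cc, tl, cc, len - tr)
  }

  .assemble_derived(genome, layouts, circular, junctions, breakpoints,
                    context_window)
}

#' Apply an ordered series of rearrangements, composing the liftover
#' @inheritParams apply_rearrangement
#' @param rlist list of [rearrangement()] objects, applied in order.
#' @export
apply_rearrangements <- function(genome, rlist, context_window = 250e3) {
  g <- genome
  map <- NULL
  for (r in rlist) {
    res <- apply_rearrangement(g, r, context_window)
    map <- if (is.null(map)) res$map else compose_liftover(map, res$map)
    g <- res$genome
  }
  if (is.null(map)) map <- identity_liftover(genome)
  list(genome = g, map = map)
}

.assemble_derived <- function(genome, layouts, circular, junctions,
                              breakpoints, context_window) {
  tgt_names <- names(layouts)
  tgt_len <- vapply(layouts, function(p) sum(.piece_len(p)), numeric(1))
  blocks <- list()
  for (nm in tgt_names) {
    p <- layouts[[nm]]
    lens <- .piece_len(p)
    off <- cumsum(c(0, lens))[seq_len(nrow(p))]
    src_rows <- which(!is.na(p$src) & lens > 0)
    if (length(src_rows))
      blocks[[nm]] <- data.frame(
        src_chrom = p$src[src_rows], src_start = p$s[src_rows],
        src_end = p$e[src_rows], tgt_chrom = nm,
        tgt_start = off[src_rows], tgt_end = off[src_rows] + lens[src_rows],
        strand = p$strand[src_rows], stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, blocks)
  rownames(blocks) <- NULL

  src_chroms <- genome$chromosomes[, c("name", "length")]
  tgt_chroms <- data.frame(name = tgt_names, length = unname(tgt_len),
                           stringsAsFactors = FALSE)
  map <- liftover_map(blocks, src_chroms, tgt_chroms,
                      junctions = junctions, breakpoints = breakpoints)

  ## genes
  genes <- .empty_genes()
  if (nrow(genome$genes)) {
    lv <- lift_many(map, genome$genes)
    if (nrow(lv)) {
      n_pieces <- table(lv$idx)
      split_idx <- as.integer(names(n_pieces)[n_pieces > 1])
      suffix <- integer(nrow(lv))
      if (length(split_idx)) {
        in_split <- lv$idx %in% split_idx
        suffix[in_split] <- stats::ave(rep(1L, sum(in_split)),
                                       lv$idx[in_split], FUN = seq_along)
      }
      g0 <- genome$genes[lv$idx, ]
      genes <- data.frame(
        chrom = lv$chrom, start = lv$start, end = lv$end,
        strand = ifelse(lv$strand == 1L, g0$strand,
                        ifelse(g0$strand == "+", "-", "+")),
        id = ifelse(suffix > 0, paste0(g0$id, ".", suffix), g0$id),
        stringsAsFactors = FALSE)
    }
  }

  ## domains (lift, then merge per class)
  domains <- .empty_domains()
  if (nrow(genome$domains)) {
    lv <- lift_many(map, genome$domains)
    dl <- if (nrow(lv)) {
      data.frame(chrom = lv$chrom, start = lv$start, end = lv$end,
                 class = genome$domains$class[lv$idx],
                 stringsAsFactors = FALSE)
    } else NULL
    if (!is.null(dl) && nrow(dl)) {
      per_class <- lapply(split(dl, dl$class), function(d) {
        m <- merge_intervals(d)
        m$class <- d$class[1]
        m
      })
      domains <- do.call(rbind, per_class)
      rownames(domains) <- NULL
      domains <- domains[order(domains$chrom, domains$start), ]
    }
  }

  ## interstitial arrays: lift existing, find displaced terminal arrays,
  ## register novel internal repeat pieces
  arrays <- .empty_arrays()
  add_array <- function(chrom, start, n, nascent) {
    arrays[nrow(arrays) + 1L, ] <<- list(chrom, start, as.integer(n), nascent)
  }
  if (nrow(genome$arrays)) {
    for (i in seq_len(nrow(genome$arrays))) {
      ar <- genome$arrays[i, ]
      lv <- lift_interval(map, ar$chrom, ar$start, ar$start + TEL_LEN * ar$n)
      if (nrow(lv)) add_array(lv$chrom[1], lv$start[1], ar$n, ar$nascent)
    }
  }

  ## telomeres at derived ends + displaced terminal arrays
  telomeres <- .empty_telomeres()
  tel_add <- function(chrom, side, n, nascent) {
    telomeres[nrow(telomeres) + 1L, ] <<- list(chrom, side, as.integer(n), nascent)
  }
  seen_terminal <- character()  # "chrom/side" of source arrays placed at ends
  for (nm in tgt_names) {
    if (circular[nm]) next
    p <- layouts[[nm]]
    lens <- .piece_len(p)
    p <- p[lens > 0, , drop = FALSE]
    lens <- lens[lens > 0]
    if (nrow(p) == 0) { tel_add(nm, "L", 0L, FALSE); tel_add(nm, "R", 0L, FALSE); next }
    for (side in c("L", "R")) {
      i <- if (side == "L") 1L else nrow(p)
      pc <- p[i, ]
      n <- 0L; nascent <- FALSE; src_key <- NULL
      if (is.na(pc$src)) {
        if (pc$novel_n > 0) { n <- pc$novel_n; nascent <- TRUE }
      } else {
        flush_fwd <- (pc$strand == 1L) &&
          ((side == "L" && pc$s == 0) || (side == "R" && pc$e == chrom_length(genome, pc$src)))
        flush_rev <- (pc$strand == -1L) &&
          ((side == "L" && pc$e == chrom_length(genome, pc$src)) || (side == "R" && pc$s == 0))
        if (flush_fwd || flush_rev) {
          src_side <- if (flush_fwd) side else (if (side == "L") "R" else "L")
          n <- telomere_n(genome, pc$src, src_side)
          if (n > 0) {
            src_key <- paste(pc$src, src_side, sep = "/")
            est <- flush_fwd &&
              (pc$e - pc$s) >= min(context_window, tgt_len[nm]) &&
              !telomere_nascent(genome, pc$src, src_side)
            nascent <- !est
          }
        }
      }
      tel_add(nm, side, n, nascent)
      if (!is.null(src_key)) seen_terminal <- c(seen_terminal, src_key)
    }
  }
  # source terminal arrays that were moved somewhere internal
  if (nrow(genome$telomeres)) {
    for (i in seq_len(nrow(genome$telomeres))) {
      tl <- genome$telomeres[i, ]
      if (tl$n == 0) next
      if (paste(tl$chrom, tl$side, sep = "/") %in% seen_terminal) next
      sp <- array_span(genome, tl$chrom, tl$side)
      lv <- lift_interval(map, tl$chrom, sp[1], sp[2])
      if (nrow(lv) == 0) next
      full <- sum(lv$end - lv$start) == sp[2] - sp[1]
      if (!full) next   # partially deleted arrays (e.g. trimming) vanish
      at_end <- (lv$start[1] == 0) ||
        (lv$end[nrow(lv)] == tgt_len[lv$chrom[1]])
      if (!at_end && !circular[lv$chrom[1]])
        add_array(lv$chrom[1], lv$start[1], tl$n, TRUE)
    }
  }

  ## novel internal repeat pieces become interstitial arrays
  for (nm in tgt_names) {
    p <- layouts[[nm]]
    lens <- .piece_len(p)
    off <- cumsum(c(0, lens))[seq_len(nrow(p))]
    for (i in seq_len(nrow(p))) {
      if (!is.na(p$src[i]) || p$novel_n[i] == 0) next
      terminal <- !circular[nm] && (off[i] == 0 || off[i] + lens[i] == tgt_len[nm])
      if (!terminal) add_array(nm, off[i], p$novel_n[i], TRUE)
    }
  }

  ## sequences
  sequences <- NULL
  if (!is.null(genome$sequences)) {
    sequences <- vapply(tgt_names, function(nm) {
      p <- layouts[[nm]]
      parts <- vapply(seq_len(nrow(p)), function(i) {
        if (!is.na(p$src[i])) {
          s <- substr(genome$sequences[[p$src[i]]], p$s[i] + 1, p$e[i])
          if (p$strand[i] == -1L) revcomp(s) else s
        } else if (p$novel_n[i] > 0) {
          strrep(TEL_UNIT, p$novel_n[i])
        } else p$novel_seq[i] %||% ""
      }, character(1))
      paste(parts, collapse = "")
    }, character(1))
  }

  ## carry over prior junctions still on the genome
  junc <- rbind(genome$junctions, junctions)

  derived <- annotated_genome(
    chromosomes = data.frame(name = tgt_names, length = unname(tgt_len),
                             circular = unname(circular[tgt_names]),
                             stringsAsFactors = FALSE),
    telomeres = telomeres, genes = genes, domains = domains, arrays = arrays,
    sequences = sequences, junctions = junc)
  list(genome = derived, map = map)
}

## ---------------------------------------------------------------------------
## Liftover maps
## ---------------------------------------------------------------------------

#' Build a liftover map from alignment blocks
#'
#' Blocks are equal-length source/target interval pairs with an orientation;
#' deleted source intervals are derived as the complement of the block
#' coverage.
#'
#' @param blocks data.frame src_chrom/src_start/src_end/tgt_chrom/tgt_start/
#'   tgt_end/strand.
#' @param src_chroms,tgt_chroms data.frame name/length.
#' @param junctions,breakpoints optional bookkeeping tables.
#' @return object of class `liftover_map`.
#' @export
liftover_map <- function(blocks, src_chroms, tgt_chroms, junctions = NULL,
                         breakpoints = NULL) {
  if (is.null(blocks) || nrow(blocks) == 0) {
    blocks <- data.frame(src_chrom = character(), src_start = numeric(),
                         src_end = numeric(), tgt_chrom = character(),
                         tgt_start = numeric(), tgt_end = numeric(),
                         strand = integer(), stringsAsFactors = FALSE)
  }
  if (any(blocks$src_end - blocks$src_start != blocks$tgt_end - blocks$tgt_start))
    stopf("liftover block with unequal source/target lengths")
  src_iv <- data.frame(chrom = blocks$src_chrom, start = blocks$src_start,
                       end = blocks$src_end)
  deleted <- interval_complement(src_iv, stats::setNames(src_chroms, c("name", "length")))
  structure(list(blocks = blocks, deleted = deleted, src_chroms = src_chroms,
                 tgt_chroms = tgt_chroms,
                 junctions = junctions %||% .empty_junctions(),
                 breakpoints = breakpoints),
            class = "liftover_map")
}

#' Identity liftover for a genome
#' @param g an `annotated_genome`.
#' @export
identity_liftover <- function(g) {
  ch <- g$chromosomes
  liftover_map(data.frame(src_chrom = ch$name, src_start = 0, src_end = ch$length,
                          tgt_chrom = ch$name, tgt_start = 0, tgt_end = ch$length,
                          strand = 1L, stringsAsFactors = FALSE),
               ch[, c("name", "length")], ch[, c("name", "length")])
}

#' Lift a source interval through a liftover map
#'
#' @param map a `liftover_map`.
#' @param chrom,start,end source interval (0-based half-open).
#' @return data.frame chrom/start/end/strand of target pieces, ordered along
#'   the source interval; empty when the interval is entirely deleted.
#' @export
lift_interval <- function(map, chrom, start, end) {
  if (!chrom %in% map$src_chroms$name) stopf("unknown chromosome '%s'", chrom)
  b <- map$blocks[map$blocks$src_chrom == chrom &
                  map$blocks$src_end > start & map$blocks$src_start < end, ,
                  drop = FALSE]
  if (nrow(b) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = integer(), stringsAsFactors = FALSE))
  b <- b[order(b$src_start), , drop = FALSE]
  s <- pmax(b$src_start, start)
  e <- pmin(b$src_end, end)
  o1 <- s - b$src_start
  o2 <- e - b$src_start
  ts <- ifelse(b$strand == 1L, b$tgt_start + o1, b$tgt_end - o2)
  te <- ifelse(b$strand == 1L, b$tgt_start + o2, b$tgt_end - o1)
  data.frame(chrom = b$tgt_chrom, start = ts, end = te, strand = b$strand,
             stringsAsFactors = FALSE)
}

# Vectorized liftover of many intervals; returns pieces tagged with the
# row index of the query interval, ordered along each source interval.
lift_many <- function(map, df) {
  b <- map$blocks
  pieces <- list()
  for (i in seq_len(nrow(b))) {
    idx <- which(df$chrom == b$src_chrom[i] & df$start < b$src_end[i] &
                 df$end > b$src_start[i])
    if (length(idx) == 0) next
    s <- pmax(df$start[idx], b$src_start[i])
    e <- pmin(df$end[idx], b$src_end[i])
    o1 <- s - b$src_start[i]
    o2 <- e - b$src_start[i]
    ts <- if (b$strand[i] == 1L) b$tgt_start[i] + o1 else b$tgt_end[i] - o2
    te <- if (b$strand[i] == 1L) b$tgt_start[i] + o2 else b$tgt_end[i] - o1
    pieces[[length(pieces) + 1]] <- data.frame(
      idx = idx, src_start = s, chrom = b$tgt_chrom[i], start = ts, end = te,
      strand = b$strand[i], stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0)
    return(data.frame(idx = integer(), src_start = numeric(),
                      chrom = character(), start = numeric(), end = numeric(),
                      strand = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, pieces)
  out <- out[order(out$idx, out$src_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Lift a single position; NA if deleted
#' @inheritParams lift_interval
#' @param pos 0-based source position.
#' @return list(chrom, pos, strand) or NULL if deleted.
#' @export
lift_point <- function(map, chrom, pos) {
  lv <- lift_interval(map, chrom, pos, pos + 1)
  if (nrow(lv) == 0) return(NULL)
  list(chrom = lv$chrom[1],
       pos = if (lv$strand[1] == 1L) lv$start[1] else lv$end[1] - 1,
       strand = lv$strand[1])
}

#' Invert a liftover map
#' @param map a `liftover_map`.
#' @export
invert_liftover <- function(map) {
  b <- map$blocks
  liftover_map(data.frame(src_chrom = b$tgt_chrom, src_start = b$tgt_start,
                          src_end = b$tgt_end, tgt_chrom = b$src_chrom,
                          tgt_start = b$src_start, tgt_end = b$src_end,
                          strand = b$strand, stringsAsFactors = FALSE),
               map$tgt_chroms, map$src_chroms)
}

#' Compose two liftover maps (src -> mid, mid -> tgt)
#' @param m1,m2 `liftover_map` objects where `m1`'s target genome is `m2`'s
#'   source genome.
#' @export
compose_liftover <- function(m1, m2) {
  out <- list()
  for (i in seq_len(nrow(m1$blocks))) {
    b <- m1$blocks[i, ]
    lv <- lift_interval(m2, b$tgt_chrom, b$tgt_start, b$tgt_end)
    if (nrow(lv) == 0) next
    # recover, for each mid piece, the corresponding source subinterval
    mid <- m2$blocks[m2$blocks$src_chrom == b$tgt_chrom &
                     m2$blocks$src_end > b$tgt_start &
                     m2$blocks$src_start < b$tgt_end, , drop = FALSE]
    mid <- mid[order(mid$src_start), , drop = FALSE]
    ps <- pmax(mid$src_start, b$tgt_start)
    pe <- pmin(mid$src_end, b$tgt_end)
    ss <- if (b$strand == 1L) b$src_start + (ps - b$tgt_start) else
      b$src_start + (b$tgt_end - pe)
    se <- ss + (pe - ps)
    out[[length(out) + 1]] <- data.frame(
      src_chrom = b$src_chrom, src_start = ss, src_end = se,
      tgt_chrom = lv$chrom, tgt_start = lv$start, tgt_end = lv$end,
      strand = b$strand * lv$strand, stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, out)
  # junctions of m1 lifted onto the final genome, plus m2's own
  j1 <- m1$junctions
  if (nrow(j1)) {
    keep <- logical(nrow(j1))
    for (i in seq_len(nrow(j1))) {
      lp <- lift_point(m2, j1$chrom[i], j1$pos[i])
      if (!is.null(lp)) { j1$chrom[i] <- lp$chrom; j1$pos[i] <- lp$pos; keep[i] <- TRUE }
    }
    j1 <- j1[keep, , drop = FALSE]
  }
  liftover_map(blocks, m1$src_chroms, m2$tgt_chroms,
               junctions = rbind(j1, m2$junctions),
               breakpoints = rbind(m1$breakpoints, m2$breakpoints))
}

## ---------------------------------------------------------------------------
## Telomere distance and the methylation ground-truth rule
## ---------------------------------------------------------------------------

#' Distance from a position to the nearest repeat-capped chromosome end
#'
#' @param genome an `annotated_genome`.
#' @param chrom chromosome name.
#' @param pos 0-based position.
#' @return bp to the nearest end carrying a telomere repeat array; `Inf` for
#'   circular chromosomes or when neither end is capped.
#' @export
distance_to_repeat_capped_end <- function(genome, chrom, pos) {
  len <- chrom_length(genome, chrom)
  if (pos < 0 || pos >= len) stopf("position outside chromosome")
  if (is_circular(genome, chrom)) return(Inf)
  d <- Inf
  if (telomere_n(genome, chrom, "L") > 0) d <- min(d, pos)
  if (telomere_n(genome, chrom, "R") > 0) d <- min(d, len - 1 - pos)
  d
}

# distance from a domain (closest edge) to the nearest capped end
.domain_end_distance <- function(genome, chrom, start, end) {
  min(distance_to_repeat_capped_end(genome, chrom, start),
      distance_to_repeat_capped_end(genome, chrom, end - 1))
}

#' Parameters of the methylation ground-truth rule
#'
#' @param D_tel telomere influence distance (bp): position-dependent domains
#'   farther than this from a repeat-capped end are lost.
#' @param min_inducing_repeats smallest interstitial repeat array that can
#'   nucleate a domain.
#' @param ext_mean,ext_sd,ext_min de-novo extension at new ends: normal with
#'   this mean/sd, truncated to [ext_min, D_tel].
#' @param span_mean_long,span_sd_long induced-domain total span for arrays of
#'   >= `long_k` repeats.
#' @param span_mean_short,span_sd_short induced span for shorter arrays.
#' @param span_split fraction of the induced span on the long side of the
#'   array.
#' @param long_k repeat count from which the long-span regime applies.
#' @param seed seed of the (deterministic, per-site) extension sampler.
#' @export
reevaluation_params <- function(D_tel = 250e3, min_inducing_repeats = 5L,
                                ext_mean = 180e3, ext_sd = 40e3, ext_min = 30e3,
                                span_mean_long = 225e3, span_sd_long = 25e3,
                                span_mean_short = 20e3, span_sd_short = 5e3,
                                span_split = 0.75, long_k = 10L, seed = 1L) {
  list(D_tel = D_tel, min_inducing_repeats = as.integer(min_inducing_repeats),
       ext_mean = ext_mean, ext_sd = ext_sd, ext_min = ext_min,
       span_mean_long = span_mean_long, span_sd_long = span_sd_long,
       span_mean_short = span_mean_short, span_sd_short = span_sd_short,
       span_split = span_split, long_k = as.integer(long_k),
       seed = as.integer(seed))
}

#' Ground-truth methylation domains after a rearrangement
#'
#' Implements the position rule for facultative heterochromatin:
#' position-dependent domains survive only within `D_tel` of a repeat-capped
#' end (or an interstitial array of at least `min_inducing_repeats`);
#' position-independent domains survive anywhere; each nascent repeat-capped
#' end nucleates a de-novo position-dependent domain extending inward by a
#' sampled extension; nascent interstitial arrays of sufficient size induce a
#' domain split asymmetrically around the array; circular chromosomes carry
#' no telomere-proximal domains.
#'
#' @param genome an `annotated_genome` (typically a derived genome whose
#'   nascent flags were set by [apply_rearrangement()]).
#' @param params see [reevaluation_params()].
#' @return data.frame of domains (chrom/start/end/class).
#' @export
reevaluate_methylation <- function(genome, params = reevaluation_params()) {
  dom <- genome$domains
  if (nrow(dom) && (anyNA(dom$class) || !all(dom$class %in% DOMAIN_CLASSES)))
    stopf("missing or invalid domain class tags")
  inducing <- genome$arrays[genome$arrays$n >= params$min_inducing_repeats, ,
                            drop = FALSE]
  inducing_iv <- if (nrow(inducing)) {
    data.frame(chrom = inducing$chrom, start = inducing$start,
               end = inducing$start + TEL_LEN * inducing$n)
  } else .empty_iv()[c("chrom", "start", "end")]

  keep <- logical(nrow(dom))
  for (i in seq_len(nrow(dom))) {
    if (dom$class[i] == "position_independent") { keep[i] <- TRUE; next }
    d <- .domain_end_distance(genome, dom$chrom[i], dom$start[i], dom$end[i])
    anchored <- d <= params$D_tel
    if (!anchored && nrow(inducing_iv)) {
      ov <- inducing_iv[inducing_iv$chrom == dom$chrom[i] &
                        inducing_iv$end > dom$start[i] &
                        inducing_iv$start < dom$end[i], ]
      anchored <- nrow(ov) > 0
    }
    keep[i] <- anchored
  }
  out <- dom[keep, , drop = FALSE]

  ## de-novo nucleation at nascent repeat-capped ends
  tel <- genome$telomeres
  for (i in seq_len(nrow(tel))) {
    if (tel$n[i] == 0 || !isTRUE(tel$nascent[i])) next
    len <- chrom_length(genome, tel$chrom[i])
    ext <- with_seed(derive_seed(params$seed, "telext", tel$chrom[i], tel$side[i]),
                     rtrunc_norm(1, params$ext_mean, params$ext_sd,
                                 params$ext_min, params$D_tel))
    ext <- round(ext) + TEL_LEN * tel$n[i]   # measured inward from the end
    iv <- if (tel$side[i] == "L") c(0, min(ext, len)) else c(max(0, len - ext), len)
    out <- rbind(out, data.frame(chrom = tel$chrom[i], start = iv[1],
                                 end = iv[2], class = "position_dependent",
                                 stringsAsFactors = FALSE))
  }

  ## induction at nascent interstitial arrays
  for (i in seq_len(nrow(inducing))) {
    if (!isTRUE(inducing$nascent[i])) next
    long <- inducing$n[i] >= params$long_k
    mu <- if (long) params$span_mean_long else params$span_mean_short
    sdv <- if (long) params$span_sd_long else params$span_sd_short
    sd_i <- derive_seed(params$seed, "arr", inducing$chrom[i], inducing$start[i])
    span <- with_seed(sd_i, {
      s <- rtrunc_norm(1, mu, sdv, max(mu - 4 * sdv, TEL_LEN * inducing$n[i] + 2e3),
                       mu + 4 * sdv)
      list(span = round(s), side = sample(c(1, -1), 1))
    })
    p <- inducing$start[i]
    len <- chrom_length(genome, inducing$chrom[i])
    f <- params$span_split
    iv <- if (span$side == 1) c(p - (1 - f) * span$span, p + f * span$span)
          else c(p - f * span$span, p + (1 - f) * span$span)
    iv <- round(pmin(pmax(iv, 0), len))
    out <- rbind(out, data.frame(chrom = inducing$chrom[i], start = iv[1],
                                 end = iv[2], class = "position_dependent",
                                 stringsAsFactors = FALSE))
  }

  if (nrow(out) == 0) return(.empty_domains())
  ## resolve: merge within class; position-independent wins overlaps
  pi_iv <- out[out$class == "position_independent", , drop = FALSE]
  pd_iv <- out[out$class == "position_dependent", , drop = FALSE]
  res <- list()
  if (nrow(pi_iv)) {
    m <- merge_intervals(pi_iv); m$class <- "position_independent"
    res$pi <- m
  }
  if (nrow(pd_iv)) {
    m <- merge_intervals(pd_iv)
    if (nrow(pi_iv)) m <- interval_setdiff(m, merge_intervals(pi_iv))
    if (nrow(m)) { m$class <- "position_dependent"; res$pd <- m }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out <- out[out$end > out$start, c("chrom", "start", "end", "class")]
  out[order(out$chrom, out$start), ]
}

#' Replace a genome's domains with the reevaluated ground truth
#'
#' Clears nascent flags so the operation is idempotent.
#' @inheritParams reevaluate_methylation
#' @return the updated `annotated_genome`.
#' @export
reevaluate_genome <- function(genome, params = reevaluation_params()) {
  genome$domains <- reevaluate_methylation(genome, params)
  if (nrow(genome$telomeres)) genome$telomeres$nascent <- FALSE
  if (nrow(genome$arrays)) genome$arrays$nascent <- FALSE
  rownames(genome$domains) <- NULL
  genome
}

#' Restrict a genome to a subset of chromosomes
#' @param g an `annotated_genome`.
#' @param chroms chromosome names to keep.
#' @export
subset_genome <- function(g, chroms) {
  keep <- g$chromosomes$name %in% chroms
  if (!all(chroms %in% g$chromosomes$name)) stopf("unknown chromosome")
  annotated_genome(
    chromosomes = g$chromosomes[keep, , drop = FALSE],
    telomeres = g$telomeres[g$telomeres$chrom %in% chroms, , drop = FALSE],
    genes = g$genes[g$genes$chrom %in% chroms, , drop = FALSE],
    domains = g$domains[g$domains$chrom %in% chroms, , drop = FALSE],
    arrays = g$arrays[g$arrays$chrom %in% chroms, , drop = FALSE],
    sequences = if (is.null(g$sequences)) NULL else g$sequences[chroms],
    junctions = g$junctions[g$junctions$chrom %in% chroms, , drop = FALSE])
}
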