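# Wild-type genome generator: multi-chromosome genomes with telomere repeat
# arrays at every end, genes at roughly one per 7.5 kb, and >200 facultative
# heterochromatin domains (0.5-107 kb) covering ~7% of the genome, enriched
# at subtelomeres. Everything is a pure function of (params, seed).

#' Parameters of the wild-type genome generator
#'
#' Defaults encode the genome statistics the analysis assumes: 7 chromosomes
#' of 4-10 Mb, 20 telomeric hexamer repeats per end, one 1-3 kb gene per
#' 7.5 kb, 230 methylation domains drawn log-uniform on 0.5-107 kb and
#' rescaled to cover 7% of the genome, with 35% of domains placed within
#' 100 kb of a chromosome end. Subtelomeric domains are tagged
#' position-dependent, internal domains position-independent.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_range uniform range of chromosome lengths (bp).
#' @param telomere_repeats hexamer repeat count at each linear end.
#' @param gene_density genes per bp.
#' @param gene_length_range uniform range of gene lengths (bp).
#' @param domain_count target number of methylation domains.
#' @param domain_size_range domain size bounds (bp); sizes are log-uniform.
#' @param methylated_fraction target fraction of the genome covered.
#' @param subtel_weight probability a domain is placed subtelomerically.
#' @param subtel_zone bp from an end within which placement counts as
#'   subtelomeric.
#' @param min_domain_gap minimum separation between distinct truth domains
#'   (kept above the caller's merge gap so truth domains stay resolvable).
#' @param frac_subtel_pd fraction of subtelomeric domains tagged
#'   position_dependent.
#' @param frac_internal_pi fraction of internal domains tagged
#'   position_independent.
#' @param with_sequence generate chromosome sequences (order-3 Markov
#'   background with telomere repeats embedded at the ends).
#' @param seed integer seed; same params + seed give byte-identical genomes.
#' @export
generator_params <- function(n_chromosomes = 7L,
                             chrom_length_range = c(4e6, 10e6),
                             telomere_repeats = 20L,
                             gene_density = 1 / 7500,
                             gene_length_range = c(1000, 3000),
                             domain_count = 230L,
                             domain_size_range = c(500, 107000),
                             methylated_fraction = 0.07,
                             subtel_weight = 0.35,
                             subtel_zone = 100e3,
                             min_domain_gap = 15e3,
                             frac_subtel_pd = 1.0,
                             frac_internal_pi = 1.0,
                             with_sequence = FALSE,
                             seed = 1L) {
  p <- list(n_chromosomes = as.integer(n_chromosomes),
            chrom_length_range = chrom_length_range,
            telomere_repeats = as.integer(telomere_repeats),
            gene_density = gene_density,
            gene_length_range = gene_length_range,
            domain_count = as.integer(domain_count),
            domain_size_range = domain_size_range,
            methylated_fraction = methylated_fraction,
            subtel_weight = subtel_weight, subtel_zone = subtel_zone,
            min_domain_gap = min_domain_gap,
            frac_subtel_pd = frac_subtel_pd,
            frac_internal_pi = frac_internal_pi,
            with_sequence = with_sequence, seed = as.integer(seed))
  stopifnot(p$methylated_fraction >= 0, p$methylated_fraction <= 1,
            p$subtel_weight >= 0, p$subtel_weight <= 1,
            p$frac_subtel_pd >= 0, p$frac_subtel_pd <= 1,
            p$frac_internal_pi >= 0, p$frac_internal_pi <= 1,
            all(p$domain_size_range > 0), all(p$chrom_length_range > 0))
  p
}

# order-k Markov DNA with random (seeded) transition probabilities
markov_sequence <- function(len, seed, order = 3) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    k <- 4^order
    P <- matrix(stats::rgamma(k * 4, 1), k, 4)
    P <- P / rowSums(P)
    cp1 <- P[, 1]
    cp2 <- P[, 1] + P[, 2]
    cp3 <- cp2 + P[, 3]
    out <- integer(len)
    state <- sample.int(k, 1) - 1L
    u <- stats::runif(len)
    modk <- as.integer(4^(order - 1))
    for (i in seq_len(len)) {
      si <- state + 1L
      b <- 1L + (u[i] > cp1[si]) + (u[i] > cp2[si]) + (u[i] > cp3[si])
      out[i] <- b
      state <- (state %% modk) * 4L + (b - 1L)
    }
    paste(bases[out], collapse = "")
  })
}

#' Generate a wild-type annotated genome
#'
#' @param params see [generator_params()].
#' @return an `annotated_genome` with a `manifest` attribute recording the
#'   params, seed and realized statistics (domain count, size range,
#'   methylated fraction).
#' @export
generate_wt_genome <- function(params = generator_params()) {
  p <- params
  tel_bp <- TEL_LEN * p$telomere_repeats

  lens <- with_seed(derive_seed(p$seed, "wtlen"), {
    round(stats::runif(p$n_chromosomes, p$chrom_length_range[1],
                       p$chrom_length_range[2]))
  })
  names <- paste0("chr", seq_len(p$n_chromosomes))
  G <- sum(lens)

  ## domain sizes: log-uniform on the stated range, rescaled by a common
  ## factor to meet the coverage target, clamped back into range
  lo <- p$domain_size_range[1]; hi <- p$domain_size_range[2]
  if (p$domain_count > 0 && p$methylated_fraction * G > p$domain_count * hi)
    stopf("infeasible targets: %.1f%% of %.0f bp unreachable with %d domains <= %d bp",
          100 * p$methylated_fraction, G, p$domain_count, hi)
  sizes <- numeric(0)
  if (p$domain_count > 0 && p$methylated_fraction > 0) {
    sizes <- with_seed(derive_seed(p$seed, "wtsizes"), {
      s <- exp(stats::runif(p$domain_count, log(lo), log(hi)))
      f <- p$methylated_fraction * G / sum(s)
      pmin(pmax(round(s * f), lo), hi)
    })
  }

  ## placement: two-component mixture, rejection against prior placements
  domains <- .empty_domains()
  if (length(sizes)) {
    domains <- with_seed(derive_seed(p$seed, "wtplace"), {
      occupied <- lapply(stats::setNames(vector("list", length(names)), names),
                        function(x) data.frame(start = numeric(), end = numeric()))
      rows <- vector("list", length(sizes))
      ord <- order(sizes, decreasing = TRUE)
      for (j in ord) {
        size <- sizes[j]
        placed <- FALSE
        for (try in 1:200) {
          subtel <- stats::runif(1) < p$subtel_weight
          if (subtel) {
            ei <- sample.int(2 * length(lens), 1)
            ci <- (ei + 1) %/% 2
            side <- if (ei %% 2 == 1) "L" else "R"
            len <- lens[ci]
            if (side == "L") {
              s <- tel_bp + floor(stats::runif(1, 0, p$subtel_zone))
              e <- s + size
              if (e > len - tel_bp) next
            } else {
              e <- len - tel_bp - floor(stats::runif(1, 0, p$subtel_zone))
              s <- e - size
              if (s < tel_bp) next
            }
          } else {
            ci <- sample.int(length(lens), 1, prob = lens)
            len <- lens[ci]
            if (len - 2 * tel_bp - size <= 0) next
            s <- tel_bp + floor(stats::runif(1, 0, len - 2 * tel_bp - size))
            e <- s + size
          }
          occ <- occupied[[names[ci]]]
          if (nrow(occ) && any(occ$end + p$min_domain_gap > s &
                               occ$start - p$min_domain_gap < e)) next
          occupied[[names[ci]]] <- rbind(occ, data.frame(start = s, end = e))
          cls <- if (subtel) {
            if (stats::runif(1) < p$frac_subtel_pd) "position_dependent"
            else "position_independent"
          } else {
            if (stats::runif(1) < p$frac_internal_pi) "position_independent"
            else "position_dependent"
          }
          rows[[j]] <- data.frame(chrom = names[ci], start = s, end = e,
                                  class = cls, stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed) warning("could not place a domain after 200 tries")
      }
      out <- do.call(rbind, rows)
      out[order(out$chrom, out$start), ]
    })
    rownames(domains) <- NULL
  }

  ## genes
  genes <- with_seed(derive_seed(p$seed, "wtgenes"), {
    out <- vector("list", length(lens))
    for (i in seq_along(lens)) {
      n <- round(lens[i] * p$gene_density)
      if (n == 0) next
      gl <- round(stats::runif(n, p$gene_length_range[1], p$gene_length_range[2]))
      s <- floor(stats::runif(n, tel_bp, lens[i] - tel_bp - gl))
      ord <- order(s)
      out[[i]] <- data.frame(chrom = names[i], start = s[ord],
                             end = s[ord] + gl[ord],
                             strand = sample(c("+", "-"), n, replace = TRUE),
                             id = sprintf("g_%s_%05d", names[i], seq_len(n)),
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out) %||% .empty_genes()
  })
  rownames(genes) <- NULL

  telomeres <- data.frame(
    chrom = rep(names, each = 2), side = rep(c("L", "R"), length(names)),
    n = p$telomere_repeats, nascent = FALSE, stringsAsFactors = FALSE)

  sequences <- NULL
  if (p$with_sequence) {
    sequences <- vapply(seq_along(lens), function(i) {
      s <- markov_sequence(lens[i], derive_seed(p$seed, "wtseq", names[i]))
      # embed telomere arrays: G-rich strand points 5'->3' toward each end
      s <- paste0(strrep(TEL_UNIT_RC, p$telomere_repeats),
                  substr(s, tel_bp + 1, lens[i] - tel_bp),
                  strrep(TEL_UNIT, p$telomere_repeats))
      s
    }, character(1))
    names(sequences) <- names
  }

  g <- annotated_genome(
    chromosomes = data.frame(name = names, length = lens, circular = FALSE,
                             stringsAsFactors = FALSE),
    telomeres = telomeres, genes = genes, domains = domains,
    sequences = sequences)
  attr(g, "manifest") <- list(
    params = p, seed = p$seed,
    realized = list(domain_count = nrow(domains),
                    domain_size_range = if (nrow(domains))
                      range(domains$end - domains$start) else c(NA, NA),
                    methylated_fraction = methylated_fraction(g)))
  g
}
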