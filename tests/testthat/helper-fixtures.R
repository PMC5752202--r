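# Shared fixtures and independent oracles. Oracles are deliberately naive
# (per-base loops, exhaustive scans) and independent of the package's
# vectorized implementations.

# A labeled-base toy genome: every base carries a unique integer id, so any
# rearrangement can be checked by locating ids in manually built derived
# sequences.
toy_ids <- function(lens) {
  offs <- cumsum(c(0, lens))[seq_along(lens)]
  stats::setNames(lapply(seq_along(lens), function(i)
    offs[i] + seq_len(lens[i])), names(lens))
}

toy_genome <- function(lens = c(chrA = 10000, chrB = 20000), tel_n = 0L,
                       genes = NULL, domains = NULL) {
  nm <- names(lens)
  annotated_genome(
    chromosomes = data.frame(name = nm, length = unname(lens),
                             circular = FALSE, stringsAsFactors = FALSE),
    telomeres = data.frame(chrom = rep(nm, each = 2),
                           side = rep(c("L", "R"), length(nm)),
                           n = as.integer(tel_n), nascent = FALSE,
                           stringsAsFactors = FALSE),
    genes = genes, domains = domains)
}

# locate a source interval's bases inside a manually built derived id vector
oracle_locate <- function(derived_ids, src_ids) {
  pos <- match(src_ids, derived_ids)
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0) return(data.frame(start = numeric(), end = numeric()))
  pos <- sort(pos)
  brk <- c(TRUE, diff(pos) != 1)
  grp <- cumsum(brk)
  data.frame(start = tapply(pos, grp, min) - 1,
             end = tapply(pos, grp, max))
}

# brute-force per-base window coverage oracle
oracle_window_coverage <- function(starts, ends, len, window = 100, step = 50) {
  depth <- numeric(len)
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1):ends[i]
    depth[idx] <- depth[idx] + 1
  }
  n_win <- floor((len - window) / step) + 1
  vapply(seq_len(n_win), function(w) {
    s <- (w - 1) * step
    mean(depth[(s + 1):(s + window)])
  }, numeric(1))
}

# exhaustive threshold-merge-filter caller oracle over window values
oracle_call_domains <- function(enr, window, step, T, G, S) {
  seeds <- which(enr >= T)
  if (length(seeds) == 0)
    return(data.frame(start = numeric(), end = numeric()))
  iv <- data.frame(start = (seeds - 1) * step, end = (seeds - 1) * step + window)
  merged <- list(iv[1, ])
  for (i in seq_len(nrow(iv))[-1]) {
    last <- merged[[length(merged)]]
    if (iv$start[i] - last$end <= G) {
      merged[[length(merged)]]$end <- max(last$end, iv$end[i])
    } else merged[[length(merged) + 1]] <- iv[i, ]
  }
  out <- do.call(rbind, merged)
  out[out$end - out$start >= S, , drop = FALSE]
}

# exhaustive repeat-array scan oracle
oracle_repeat_arrays <- function(s, unit, min_n = 1) {
  n <- nchar(s)
  u <- nchar(unit)
  hits <- integer(0)
  for (i in seq_len(max(0, n - u + 1)))
    if (substr(s, i, i + u - 1) == unit) hits <- c(hits, i)
  runs <- list()
  i <- 1
  while (i <= length(hits)) {
    start <- hits[i]
    cnt <- 1
    while (TRUE) {
      nxt <- start + cnt * u
      if (nxt %in% hits) cnt <- cnt + 1 else break
    }
    if (cnt >= min_n) runs[[length(runs) + 1]] <- c(start - 1, cnt)
    # skip past this maximal run (drop shifted sub-runs inside it)
    i <- which(hits > start + cnt * u - u)[1]
    if (is.na(i)) break
  }
  if (length(runs) == 0)
    return(data.frame(start = numeric(), n = integer()))
  m <- do.call(rbind, runs)
  data.frame(start = m[, 1], n = m[, 2])
}

# small sequence-mode genome for SNP / repeat tests
small_seq_genome <- function(seed = 7, n_chrom = 2, len_range = c(60e3, 90e3),
                             domain_count = 4) {
  generate_wt_genome(generator_params(
    n_chromosomes = n_chrom, chrom_length_range = len_range,
    domain_count = domain_count, domain_size_range = c(2000, 15000),
    methylated_fraction = 0.10, min_domain_gap = 12e3,
    with_sequence = TRUE, seed = seed))
}

# medium lengths-only genome (fast scenario tests)
medium_genome <- function(seed = 5) {
  generate_wt_genome(generator_params(seed = seed))
}
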