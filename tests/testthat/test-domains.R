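# Domain calling, differential classification, end-anchored measurements.

test_that("caller calls nothing when chip equals input", {
  g <- annotated_genome(data.frame(name = "c1", length = 2e6, circular = FALSE),
                        domains = data.frame(chrom = "c1", start = 5e5,
                                             end = 6e5,
                                             class = "position_independent"))
  tr <- noise_free_tracks(g, e = 1)
  calls <- call_domains(tr$chip, tr$input)
  expect_equal(nrow(calls), 0)
})

test_that("caller recovers a 47 kb domain within one window", {
  g <- annotated_genome(data.frame(name = "c1", length = 1e6, circular = FALSE),
                        domains = data.frame(chrom = "c1", start = 5e5,
                                             end = 5.47e5,
                                             class = "position_dependent"))
  tr <- noise_free_tracks(g, e = 8)
  calls <- call_domains(tr$chip, tr$input)
  expect_equal(nrow(calls), 1)
  expect_lte(abs(calls$start - 5e5), 50)
  expect_lte(abs(calls$end - 5.47e5), 50)
})

test_that("caller equals the exhaustive threshold-merge oracle", {
  set.seed(17)
  for (rep in 1:20) {
    n_win <- 400
    enr <- ifelse(stats::runif(n_win) < 0.2, stats::runif(n_win, 2, 8),
                  stats::runif(n_win, 0, 1.9))
    len <- (n_win - 1) * 50 + 100
    chroms <- data.frame(name = "c1", length = len, circular = FALSE)
    chip <- coverage_track(chroms, 100, 50, list(c1 = enr))
    input <- coverage_track(chroms, 100, 50, list(c1 = rep(1, n_win)))
    G <- sample(c(0, 200, 1000), 1)
    S <- sample(c(500, 2000), 1)
    got <- call_domains(chip, input, T = 2, G = G, S = S)
    exp <- oracle_call_domains(enr, 100, 50, T = 2, G = G, S = S)
    expect_equal(nrow(got), nrow(exp))
    if (nrow(exp)) {
      expect_equal(got$start, exp$start)
      expect_equal(got$end, exp$end)
    }
  }
})

test_that("caller is monotone in T and S", {
  set.seed(18)
  n_win <- 500
  enr <- stats::rgamma(n_win, 1.2)
  chroms <- data.frame(name = "c1", length = (n_win - 1) * 50 + 100,
                       circular = FALSE)
  chip <- coverage_track(chroms, 100, 50, list(c1 = enr))
  input <- coverage_track(chroms, 100, 50, list(c1 = rep(1, n_win)))
  lo <- call_domains(chip, input, T = 1.5, G = 500, S = 500)
  hi <- call_domains(chip, input, T = 2.5, G = 500, S = 500)
  # every hi call is contained in some lo call
  for (i in seq_len(nrow(hi))) {
    expect_true(any(lo$start <= hi$start[i] & lo$end >= hi$end[i]))
  }
  # lowering S never removes a call
  s_lo <- call_domains(chip, input, T = 2, G = 500, S = 300)
  s_hi <- call_domains(chip, input, T = 2, G = 500, S = 1500)
  expect_true(all(paste(s_hi$start, s_hi$end) %in%
                  paste(s_lo$start, s_lo$end)))
})

test_that("identity differential labels everything invariant", {
  g <- toy_genome()
  calls <- data.frame(chrom = c("chrA", "chrB"), start = c(1000, 5000),
                      end = c(3000, 9000))
  diff <- classify_differential(calls, calls, identity_liftover(g))
  expect_true(all(diff$label == "invariant"))
  expect_equal(nrow(diff), 2)
})

test_that("differential labels match an exhaustive pairwise oracle", {
  set.seed(19)
  g <- toy_genome(c(chrA = 50000))
  idm <- identity_liftover(g)
  for (rep in 1:15) {
    mk <- function(n) {
      s <- sort(sample.int(45000, n))
      data.frame(chrom = "chrA", start = s,
                 end = s + sample(500:3000, n, replace = TRUE))
    }
    ref <- merge_intervals(mk(6))
    alt <- merge_intervals(mk(6))
    got <- classify_differential(ref, alt, idm, min_overlap = 0.5)
    # oracle: brute-force reciprocal overlap
    for (j in seq_len(nrow(alt))) {
      ov <- pmin(alt$end[j], ref$end) - pmax(alt$start[j], ref$start)
      q <- any(ov >= 0.5 * (alt$end[j] - alt$start[j]) &
               ov >= 0.5 * (ref$end - ref$start))
      lab <- got$label[got$start == alt$start[j] & got$label != "lost"]
      expect_equal(lab, if (q) "invariant" else "gained")
    }
    for (i in seq_len(nrow(ref))) {
      ov <- pmin(ref$end[i], alt$end) - pmax(ref$start[i], alt$start)
      q <- any(ov >= 0.5 * (alt$end - alt$start) &
               ov >= 0.5 * (ref$end[i] - ref$start[i]))
      lost <- any(got$label == "lost" & got$start == ref$start[i])
      expect_equal(lost, !q)
    }
    # labels partition: every interval labelled exactly once
    expect_equal(nrow(got), nrow(alt) + sum(got$label == "lost"))
  }
})

test_that("quasiterminal scenario: moved domain invariant, displaced lost", {
  g <- medium_genome(seed = 30)
  sc <- build_scenario("quasiterminal", g, seed = 12)
  wt <- noise_free_tracks(g, e = 8)
  alt <- noise_free_tracks(sc$genome, e = 8)
  ref_calls <- call_domains(wt$chip, wt$input)
  alt_calls <- call_domains(alt$chip, alt$input)
  diff <- classify_differential(ref_calls, alt_calls, sc$map)
  fates <- sc$truth$fates
  cover_by <- function(iv, lab) {
    dd <- diff[diff$label == lab & diff$chrom == iv$chrom, , drop = FALSE]
    if (nrow(dd) == 0) return(0)
    sum(pmax(0, pmin(dd$end, iv$end) - pmax(dd$start, iv$start))) /
      (iv$end - iv$start)
  }
  for (i in which(fates$fate == "lost")) {
    lv <- fates$lifted[[i]]
    cov <- sum(vapply(seq_len(nrow(lv)), function(k)
      cover_by(lv[k, ], "lost") * (lv$end[k] - lv$start[k]), numeric(1)))
    expect_gt(cov / sum(lv$end - lv$start), 0.8)
  }
  # the donor's travelled subtelomeric domain is invariant
  don <- sc$rearrangements[[1]]$donor
  kept <- fates[fates$fate == "kept" & fates$chrom == don &
                fates$class == "position_dependent", ]
  expect_gt(nrow(kept), 0)
  for (i in seq_len(nrow(kept))) {
    lv <- kept$lifted[[i]][1, ]
    expect_gt(cover_by(lv, "invariant"), 0.8)
  }
  # the de-novo domain at the donor's new end is gained
  dn <- sc$truth$de_novo[1, ]
  expect_gt(cover_by(dn, "gained"), 0.8)
})

test_that("noise-free truth recovery has Jaccard >= 0.95 at e >= 4", {
  g <- generate_wt_genome(generator_params(
    n_chromosomes = 2, chrom_length_range = c(3e6, 4e6),
    domain_count = 30, domain_size_range = c(5000, 60000),
    methylated_fraction = 0.1, seed = 31))
  tr <- noise_free_tracks(g, e = 4)
  calls <- call_domains(tr$chip, tr$input)
  for (i in seq_len(nrow(g$domains))) {
    d <- g$domains[i, ]
    cc <- calls[calls$chrom == d$chrom, , drop = FALSE]
    ov <- pmax(0, pmin(cc$end, d$end) - pmax(cc$start, d$start))
    j <- which.max(ov)
    jac <- ov[j] / (max(cc$end[j], d$end) - min(cc$start[j], d$start))
    expect_gte(jac, 0.95)
  }
})

test_that("subtelomeric extension measures the end-anchored run", {
  calls <- data.frame(chrom = character(), start = numeric(), end = numeric())
  expect_equal(subtelomeric_extension(calls, "c1", "L", 1e6), 0)
  calls <- data.frame(chrom = "c1", start = 0, end = 180000)
  expect_equal(subtelomeric_extension(calls, "c1", "L", 1e6), 180000)
  # semi-continuous run with sub-gap holes, measured from the right end
  calls <- data.frame(chrom = "c1", start = c(9.0e5, 9.3e5, 9.8e5),
                      end = c(9.25e5, 9.7e5, 1e6))
  expect_equal(subtelomeric_extension(calls, "c1", "R", 1e6, G = 10e3), 1e5)
  # a gap larger than G breaks the anchor
  calls <- data.frame(chrom = "c1", start = c(9.0e5, 9.8e5),
                      end = c(9.2e5, 1e6))
  expect_equal(subtelomeric_extension(calls, "c1", "R", 1e6, G = 10e3), 2e4)
})

test_that("anchored span, farthest peak and gene count", {
  genes <- data.frame(chrom = "c1",
                      start = seq(1e5, 3e5, by = 1e4),
                      end = seq(1e5, 3e5, by = 1e4) + 2000,
                      strand = "+", id = paste0("g", 1:21))
  a <- 2e5
  calls <- data.frame(chrom = "c1", start = a - 50000, end = a + 50000)
  res <- anchored_span_and_genes(calls, "c1", a, genes)
  expect_equal(res$span_bp, 1e5)
  expect_equal(res$farthest_bp, 5e4)
  expect_equal(res$n_genes, sum(genes$start >= a - 50000 &
                                genes$end <= a + 50000))
  # no call near the anchor
  far <- data.frame(chrom = "c1", start = 5e5, end = 5.2e5)
  res <- anchored_span_and_genes(far, "c1", a, genes)
  expect_equal(unlist(res), c(span_bp = 0, farthest_bp = 0, n_genes = 0))
  # semi-continuous run merged across gaps < G
  calls <- data.frame(chrom = "c1", start = c(a - 60000, a + 2000),
                      end = c(a - 2000, a + 80000))
  res <- anchored_span_and_genes(calls, "c1", a, genes, G = 10e3)
  expect_equal(res$span_bp, 140000)
  expect_equal(res$farthest_bp, 80000)
})
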