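# Generators: genome fidelity, scenario truths, read samplers, SNPome, RNA.

test_that("default wild-type genomes meet the stated statistics", {
  g <- generate_wt_genome(generator_params(seed = 11))
  validate_genome(g)
  frac <- methylated_fraction(g)
  expect_gt(frac, 0.06)
  expect_lt(frac, 0.08)
  expect_gt(nrow(g$domains), 200)
  sizes <- g$domains$end - g$domains$start
  expect_true(all(sizes >= 500 & sizes <= 107000))
  expect_true(all(g$telomeres$n == 20L))
  # subtelomeric domains are position-dependent, internal are independent
  expect_true(all(g$domains$class %in%
                  c("position_dependent", "position_independent")))
  # truth domains stay resolvable: distinct domains separated by > 10 kb
  d <- g$domains[order(g$domains$chrom, g$domains$start), ]
  gaps <- unlist(lapply(split(d, d$chrom), function(x)
    if (nrow(x) > 1) x$start[-1] - x$end[-nrow(x)] else numeric(0)))
  expect_true(all(gaps > 10e3))
})

test_that("generator is a pure function of (params, seed)", {
  p <- generator_params(seed = 33)
  g1 <- generate_wt_genome(p)
  g2 <- generate_wt_genome(p)
  expect_identical(object_digest(g1), object_digest(g2))
  g3 <- generate_wt_genome(generator_params(seed = 34))
  expect_false(identical(object_digest(g1), object_digest(g3)))
})

test_that("domain count target 0 gives a domain-free genome", {
  g <- generate_wt_genome(generator_params(domain_count = 0, seed = 2))
  expect_equal(nrow(g$domains), 0)
})

test_that("scenario truths match their class semantics", {
  g <- medium_genome(seed = 8)
  # 17 repeats: one new internal domain spanning the insertion point
  sc <- build_scenario("telomere_insertion_17", g, seed = 3)
  expect_equal(nrow(sc$truth$de_novo), 1)
  dn <- sc$truth$de_novo
  expect_equal(dn$chrom, sc$truth$anchor_chrom)
  expect_lte(dn$start, sc$truth$anchor_pos)
  expect_gte(dn$end, sc$truth$anchor_pos)
  span <- dn$end - dn$start
  expect_gt(span, 120e3)   # long-array regime, ~225 kb
  expect_lt(span, 330e3)
  # the interstitial array is recorded with 17 units
  ar <- sc$genome$arrays
  expect_equal(ar$n, 17L)
  # short arrays induce short local methylation
  sc8 <- build_scenario("telomere_insertion_8", g, seed = 3)
  s8 <- sc8$truth$de_novo$end - sc8$truth$de_novo$start
  expect_lt(s8, 50e3)
  # below the inducing minimum: no induction
  sc4 <- build_scenario("telomere_insertion_4", g, seed = 3)
  expect_equal(nrow(sc4$truth$de_novo), 0)
})

test_that("segmental duplication truth: one copy keeps, one loses", {
  g <- medium_genome(seed = 9)
  sc <- build_scenario("segmental_duplication", g, seed = 6)
  tr <- sc$truth
  seg <- tr$segment
  don <- tr$segment_chrom
  # native copy domains still present at original coordinates
  native <- tr$domains[tr$domains$chrom == don &
                       tr$domains$start >= seg[1], , drop = FALSE]
  expect_gt(nrow(native), 0)
  # duplicate copy region carries no methylation
  segL <- seg[2] - seg[1]
  dup <- tr$domains[tr$domains$chrom == tr$dup_chrom &
                    tr$domains$end > tr$dup_start &
                    tr$domains$start < tr$dup_start + segL, , drop = FALSE]
  expect_equal(nrow(dup), 0)
})

test_that("chip read sampler conserves depth and respects enrichment", {
  g <- annotated_genome(
    chromosomes = data.frame(name = "c1", length = 6e5, circular = FALSE),
    domains = data.frame(chrom = "c1", start = c(1e5, 4e5),
                         end = c(1.5e5, 4.4e5), class = "position_dependent"))
  rsp <- read_sim_params(depth = 50, enrichment = 8, seed = 5)
  chip <- simulate_chip_reads(g, rsp, "chip")
  expect_equal(nrow(chip), round(50 * 6e5 / 75))

  # e = 8: in-domain / out-domain mean coverage ratio within 10% of 8
  tr <- window_coverage(chip, g)
  v <- tr$values$c1
  centers <- (seq_along(v) - 1) * 50 + 50
  in_dom <- (centers > 1e5 & centers < 1.5e5) | (centers > 4e5 & centers < 4.4e5)
  out_dom <- !((centers > 0.95e5 & centers < 1.55e5) |
               (centers > 3.95e5 & centers < 4.45e5))
  ratio <- mean(v[in_dom]) / mean(v[out_dom])
  expect_lt(abs(ratio - 8) / 8, 0.1)

  # e = 1 is indistinguishable from input (KS at alpha = 0.01)
  rsp1 <- read_sim_params(depth = 20, enrichment = 1, seed = 6)
  chip1 <- simulate_chip_reads(g, rsp1, "chip")
  input1 <- simulate_chip_reads(g, rsp1, "input")
  v1 <- window_coverage(chip1, g)$values$c1
  v2 <- window_coverage(input1, g)$values$c1
  ks <- suppressWarnings(stats::ks.test(v1, v2))
  expect_gt(ks$p.value, 0.01)

  # fixed seed: identical alignments
  expect_identical(object_digest(simulate_chip_reads(g, rsp, "chip")),
                   object_digest(chip))
})

test_that("SNPome generation is binomial, exact and deterministic", {
  g <- small_seq_genome(seed = 12)
  res <- generate_snpome(g, snp_rate = 0.002, seed = 4)
  len_eff <- sum(g$chromosomes$length - 140)
  n_exp <- 0.002 * len_eff
  sd_exp <- sqrt(len_eff * 0.002 * 0.998)
  expect_lt(abs(nrow(res$snpome) - n_exp), 3 * sd_exp)
  expect_true(all(res$snpome$allele_a != res$snpome$allele_b))

  # variant genome differs exactly at SNP positions
  for (nm in g$chromosomes$name) {
    s1 <- strsplit(g$sequences[[nm]], "")[[1]]
    s2 <- strsplit(res$variant$sequences[[nm]], "")[[1]]
    diff_pos <- which(s1 != s2) - 1
    expect_equal(diff_pos, res$snpome$pos[res$snpome$chrom == nm])
  }
  res2 <- generate_snpome(g, snp_rate = 0.002, seed = 4)
  expect_identical(object_digest(res2$snpome), object_digest(res$snpome))
  expect_error(generate_snpome(medium_genome(), 0.002), "no sequences")
  expect_error(generate_snpome(g, 0.2), "snp_rate")
})

test_that("RNA counts follow the repression model", {
  g <- generate_wt_genome(generator_params(
    n_chromosomes = 2, chrom_length_range = c(4e6, 5e6),
    domain_count = 60, domain_size_range = c(20e3, 80e3),
    methylated_fraction = 0.25, seed = 13))
  # rho = 1: methylated and unmethylated genes indistinguishable
  t1 <- simulate_rna_counts(g, rho = 1, seed = 1)
  meth <- t1$covered_fraction == 1
  expect_gt(sum(meth), 100)
  w <- stats::wilcox.test(t1$count[meth], t1$count[!meth])
  expect_gt(w$p.value, 0.01)
  # rho = 0.1: mean ratio within 20% of 0.1
  t2 <- simulate_rna_counts(g, rho = 0.1, seed = 2)
  unmeth <- t2$covered_fraction == 0
  ratio <- mean(t2$count[t2$covered_fraction == 1]) / mean(t2$count[unmeth])
  expect_lt(abs(ratio - 0.1) / 0.1, 0.2)
  # zero genes -> empty table; invalid rho errors
  g0 <- toy_genome()
  expect_equal(nrow(simulate_rna_counts(g0, seed = 1)), 0)
  expect_error(simulate_rna_counts(g, rho = 0), "rho")
})
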