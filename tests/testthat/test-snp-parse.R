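# Allele-specific read partitioning: trimming, exact assignment, scaling,
# and the duplication cis/trans profiles.

test_that("trimming keeps the first 70 nt and filters short reads", {
  reads <- data.frame(
    chrom = "c1", start = c(100, 300, 500), end = c(175, 360, 570),
    strand = c("+", "-", "+"),
    seq = c(strrep("A", 75), strrep("C", 60), strrep("G", 70)),
    stringsAsFactors = FALSE)
  tr <- trim_filter_reads(reads, 70)
  expect_equal(nrow(tr), 2)
  expect_equal(nchar(tr$seq), c(70, 70))
  # plus-strand read trimmed at the 3' (right) coordinate side
  expect_equal(tr$end[1] - tr$start[1], 70)
  # minus-strand read: the 5' end is the right coordinate edge
  expect_equal(tr$start[2], 500)
  # all reads exactly L: unchanged
  expect_identical(trim_filter_reads(tr, 70)$seq, tr$seq)
  expect_error(trim_filter_reads(reads, 0), "positive")
})

test_that("error-free reads assign to their parent with zero misassignment", {
  g <- small_seq_genome(seed = 61)
  sn <- generate_snpome(g, snp_rate = 0.001, seed = 62)
  idx <- snp_index(sn$snpome)
  set.seed(63)
  draw_reads <- function(genome) {
    n <- 10000
    pick <- sample.int(nrow(sn$snpome), n, replace = TRUE)
    off <- sample.int(70, n, replace = TRUE) - 1
    s <- sn$snpome$pos[pick] - off
    seqs <- substring(genome$sequences[sn$snpome$chrom[pick]], s + 1, s + 70)
    rc <- sample(c(TRUE, FALSE), n, replace = TRUE)
    seqs[rc] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[rc])))
    seqs
  }
  lab_a <- assign_reads(data.frame(seq = draw_reads(g)), idx)
  expect_true(all(lab_a == "parent_A"))
  lab_b <- assign_reads(data.frame(seq = draw_reads(sn$variant)), idx)
  expect_true(all(lab_b == "parent_B"))

  # a read covering no SNP is unassigned
  far <- setdiff(seq(100, 5000, by = 70), unlist(lapply(sn$snpome$pos,
    function(p) (p - 80):(p + 80))))
  read0 <- substring(g$sequences[[1]], far[1] + 1, far[1] + 70)
  expect_equal(assign_read(read0, idx), "unassigned")

  # wrong read length errors
  expect_error(assign_reads(data.frame(seq = strrep("A", 60)), idx),
               "flank convention")
})

test_that("chimeric reads joining the two parents are conflicted", {
  g <- small_seq_genome(seed = 64)
  sn <- generate_snpome(g, snp_rate = 0.004, seed = 65)
  s <- sn$snpome[sn$snpome$chrom == sn$snpome$chrom[1], ]
  # fuse an A-allele window of one SNP (SNP + 10 bases context each side)
  # with a B-allele window of another
  i <- 1; j <- 2
  left <- substring(s$flank_a[i], 47, 81)    # covers SNP i at offset 25
  right <- substring(s$flank_b[j], 61, 95)   # covers SNP j at offset 11
  chimera <- paste0(left, right)
  expect_equal(nchar(chimera), 70)
  idx <- snp_index(sn$snpome)
  expect_equal(assign_read(chimera, idx), "conflicted")
})

test_that("allele scaling follows the smallest-file rule", {
  expect_equal(unname(allele_scaling(150, 100)), c(1.5, 1.0))
  expect_equal(unname(allele_scaling(100, 100)), c(1.0, 1.0))
  expect_error(allele_scaling(0, 10), "zero count")

  # 2:1 depths agree within 2% after scaling
  g <- annotated_genome(data.frame(name = "c1", length = 4e5,
                                   circular = FALSE))
  r1 <- simulate_chip_reads(g, read_sim_params(depth = 30, seed = 1), "input")
  r2 <- simulate_chip_reads(g, read_sim_params(depth = 15, seed = 2), "input")
  f <- allele_scaling(nrow(r1), nrow(r2))
  t1 <- normalize_track(window_coverage(r1, g), f[1])
  t2 <- normalize_track(window_coverage(r2, g), f[2])
  expect_lt(abs(mean(t1$values$c1) - mean(t2$values$c1)) /
            mean(t2$values$c1), 0.02)
})

test_that("duplication scenario yields distinct per-allele profiles", {
  sc <- dup_scenario()
  rsp <- read_sim_params(depth = 25, enrichment = 8, seed = 73)
  aln <- simulate_chip_reads(sc$genome, rsp, "chip")
  fr <- segdup_frame_reads(sc, aln)
  # 1 kb windows: per-allele coverage is informative only near SNPs, so
  # windows must be wide enough to contain a few SNPs each
  prof <- snp_parsed_profiles(fr, sc$truth$snpome, segment_frame(sc),
                              window = 1000, step = 500)

  # partition completeness
  expect_equal(sum(prof$counts), nrow(trim_filter_reads(fr, 70)))
  # zero misassignment at error rate 0 is checked above; here both files
  # must be populated and conflicts rare
  expect_gt(prof$counts[["parent_A"]], 100)
  expect_gt(prof$counts[["parent_B"]], 100)
  expect_lt(prof$counts[["conflicted"]] / sum(prof$counts), 0.01)

  # the native (parent A) copy retains the domain, the duplicate lost it:
  # A/B enrichment ratio >= 2 on >= 80% of domain windows
  dom <- segment_frame_domains(sc)
  dom <- dom[dom$class == "position_dependent", , drop = FALSE]
  expect_gt(nrow(dom), 0)
  va <- prof$track_a$values$segment
  vb <- prof$track_b$values$segment
  win_start <- (seq_along(va) - 1) * prof$track_a$step
  in_dom <- rep(FALSE, length(va))
  for (i in seq_len(nrow(dom)))
    in_dom <- in_dom | (win_start >= dom$start[i] &
                        win_start + prof$track_a$window <= dom$end[i])
  floor_v <- max(stats::quantile(vb[vb > 0], 0.05), 1e-9)
  ratio <- va[in_dom] / pmax(vb[in_dom], floor_v)
  expect_gte(mean(ratio >= 2), 0.8)
  # outside the domain the duplicate copy is not depleted
  out_ratio <- stats::median(va[!in_dom] / pmax(vb[!in_dom], floor_v))
  expect_lt(out_ratio, 2)

  # strand symmetry: reverse-complementing reads preserves labels
  sub <- trim_filter_reads(fr[1:200, ], 70)
  lab1 <- assign_reads(sub, sc$truth$snpome)
  sub$seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sub$seq)))
  lab2 <- assign_reads(sub, sc$truth$snpome)
  expect_equal(lab1, lab2)
})
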