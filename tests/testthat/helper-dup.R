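# Cached sequence-mode duplication scenario (built once per test run;
# reused by the module tests and the acceptance suite).
.fixture_cache <- new.env()

dup_scenario <- function() {
  if (is.null(.fixture_cache$dup)) {
    g <- generate_wt_genome(generator_params(
      n_chromosomes = 2, chrom_length_range = c(1.3e6, 1.6e6),
      domain_count = 12, domain_size_range = c(8e3, 30e3),
      methylated_fraction = 0.10, subtel_weight = 0.5,
      with_sequence = TRUE, seed = 71))
    .fixture_cache$dup <- build_scenario("segmental_duplication", g, seed = 72)
  }
  .fixture_cache$dup
}

segment_frame <- function(sc) {
  list(chromosomes = data.frame(name = "segment",
                                length = diff(sc$truth$segment),
                                circular = FALSE))
}

# truth methylation of the native copy, in segment-frame coordinates
segment_frame_domains <- function(sc) {
  seg <- sc$truth$segment
  d <- sc$base$domains
  d <- d[d$chrom == sc$truth$segment_chrom & d$start >= seg[1] &
         d$end <= seg[2], , drop = FALSE]
  d$start <- d$start - seg[1]
  d$end <- d$end - seg[1]
  d$chrom <- "segment"
  d
}
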