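---
title: "Position effects on facultative heterochromatin: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position effects on facultative heterochromatin: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(telodomains)
```

## The scientific problem

In many fungi, repressive H3K27me2/3 (facultative heterochromatin) blankets
large subtelomeric domains. Chromosomal rearrangements show that much of
this methylation is a *position effect*: domains moved away from a
repeat-capped chromosome end lose the mark, chromatin newly placed next to
a telomere gains it, and short interstitial arrays of the telomeric
hexamer (TTAGGG) suffice to nucleate a large domain. Other domains are
position-independent and travel with their sequence. `telodomains`
implements this model as an explicit, testable simulation plus the ChIP-seq
analysis pipeline needed to measure it: sliding-window coverage, scaling
normalization, a thresholding domain caller, differential
(gained/lost/invariant) classification through an exact coordinate
liftover, allele-specific (SNP-parsed) profiling, discordant-pair /
split-read breakpoint calling, telomere repeat detection, and
expression-by-domain-class statistics.

## The ground-truth methylation model

Every genome carries truth domains tagged `position_dependent` or
`position_independent`. After a rearrangement, `reevaluate_methylation()`
applies the position rule:

* a position-dependent domain survives only if its nearest edge lies within
  `D_tel` of a repeat-capped chromosome end, or if it overlaps an
  interstitial telomere-repeat array of at least `min_inducing_repeats`
  units (the second clause makes the rule idempotent: induced domains
  remain anchored by their array);
* position-independent domains survive anywhere;
* each *nascent* repeat-capped end nucleates a de-novo position-dependent
  domain extending inward by a draw from Normal(180 kb, 40 kb) truncated to
  [30 kb, `D_tel`];
* a nascent interstitial array of `k >= 5` units induces a domain whose
  total span is drawn from Normal(225 kb, 25 kb) for `k >= 10` and
  Normal(20 kb, 5 kb) for `5 <= k < 10`, split 0.75/0.25 around the array
  (the side of the long arm is drawn at random);
* circular chromosomes (telomerase-loss survivors) have no capped ends, so
  every position-dependent subtelomeric domain is lost and nothing is
  induced.

`D_tel` defaults to 250 kb. The literature quantifies induced effects out
to roughly 170-225 kb from repeats but does not report a threshold; we
model a sharp cutoff with margin above those observations rather than a
graded decay, because nothing in the available observations constrains the
shape of the decay. The de-novo extension sampler's mean (180 kb) matches
the average extension reported for novel subtelomeres; its SD (40 kb) is a
free choice. All extension draws are seeded per site (chromosome x end, or
array position), which makes reevaluation a pure function of the genome
and parameters.

"Nascent" ends are identified structurally, not by bookkeeping: an end is
established only if its terminal 250 kb maps through the liftover as a
single forward-strand block flush with a source chromosome end that itself
carried an established array. A quasiterminal translocation that moves a
telomere *with* its neighborhood therefore keeps it established (the moved
domain is invariant), while a broken end capped by a transferred array is
nascent and nucleates de-novo methylation.

## The synthetic world

`generate_wt_genome()` draws 7 linear chromosomes of 4-10 Mb, each capped
by 20 telomeric hexamer units; genes at one per 7.5 kb (1-3 kb long); and
230 methylation domains covering ~7% of the genome. Domain sizes are drawn
log-uniform on [0.5, 107] kb. These three published statistics (count >
200, size range, 7% coverage) are mutually inconsistent for a ~49 Mb
genome under a log-uniform size law (expected coverage would be ~9%), so
the generator rescales the drawn sizes by a common factor to meet the
coverage target and clamps them back into the stated range. Placement is a
two-component mixture: with probability 0.35 a domain starts within 100 kb
of an end (these are tagged position-dependent), otherwise uniformly in
the interior (tagged position-independent). The subtelomeric weight is a
free default; no published fraction exists. Distinct truth domains keep a
minimum 15 kb separation — above the caller's 10 kb merge gap — so that
truth domains remain individually resolvable by the caller; real genomes
are not obliged to be this polite, which is one reason a green recovery
test does not certify performance on real data.

Sequence mode (needed by the SNP, repeat-detection and raw-read paths)
generates an order-3 Markov background with seeded random transition
probabilities and embeds the telomere arrays in the sequence (CCCTAA
repeats at left ends, TTAGGG at right ends, i.e. the G-rich strand runs
5'-3' toward each end). Lengths-only mode omits sequence for speed.

Scenario classes (`build_scenario()`) abstract the rearrangement families
studied with real strains: `insertional` (interior segment inserted
distally, displacing the old subtelomere), `reciprocal` (arm exchange with
one near-terminal breakpoint, creating one new subtelomere),
`quasiterminal` (distal segment fused to another end; the travelling
domain stays, the displaced acceptor subtelomere is lost, the donor's
broken end gains), `insertional_to_mid` and `terminal_shift` (variations
moving subtelomeric chromatin internal), `tert` (all chromosomes
circularize after telomere trimming; the fusion junction and trimmed array
lengths are recorded for the outward-primer test),
`telomere_insertion_<k>` ((TTAGGG)_k replaces an interior 2 kb locus), and
`segmental_duplication` (a distal segment present both natively and as an
internal copy carrying dense alternate alleles — the cis/trans test).
Scenario coordinates are drawn under clearance constraints (breakpoints
outside domains, de-novo landing zones domain-free) so that each truth
domain has an unambiguous fate; the drawn world is deliberately clean in
this respect.

Read simulation: ChIP read starts are sampled with relative rate `e`
(default 8) inside truth domains and 1 outside; input is uniform; emitted
read count is exactly `round(depth x genome / read_length)`. Paired
fragments are Normal(350, 50) in length; reads from a derived genome are
mapped back to source coordinates through the inverse liftover, which
yields discordant pairs and base-pair-exact split reads at junctions — an
idealization of an aligner with zero mapping error. RNA counts are
negative binomial (dispersion 0.2) with the mean multiplied by `rho`
(default 0.1) for genes fully inside a methylated domain, interpolated
linearly for partial overlap.

## Analysis stages and numerical choices

* **Coverage** (`window_coverage`): mean per-base depth in 100 bp windows
  every 50 bp; trailing partial windows are dropped (window count is
  `floor((L - window)/step) + 1`). Reads count over their full aligned
  span. Display smoothing (`smooth_track`, 350/500 bp) is a moving average
  with partial-edge renormalization, conserving mass up to edge effects.
* **Normalization** (`scaling_factor`): the sample/reference mapped-read
  ratio; tracks are divided by it. Allele-parsed files use the
  smallest-file convention instead (`allele_scaling`).
* **Caller** (`call_domains`): windows with `chip / max(input, floor)` at
  least `T = 2` seed domains; the input floor is its genome-wide 5th
  percentile (avoids ratio blow-ups in empty windows); seed runs merge
  across gaps up to `G = 10 kb` (the published induced domain is
  "semi-continuous", so a merge rule is required but its width is ours);
  runs under `S = 500 bp` (the smallest reported domain) are dropped.
* **Differential labels** (`classify_differential`): reference calls are
  lifted to the derived genome; a reciprocal 50% overlap with an
  alternative call makes both invariant; unmatched alternative calls are
  gained, unmatched lifted reference calls are lost. The published
  gain/loss assignment appears to have been visual; this classifier is a
  formalization, not a reconstruction.
* **SNP parsing** (`assign_reads`): reads trimmed to their first 70 bases
  (the published trim length; which end was kept is unstated — we keep the
  5' end and say so), then matched exactly, full-length, on either strand
  against indexed windows of each SNP's flanking context under each
  allele. Reads covering no SNP, or matching neither context exactly, are
  unassigned; reads carrying both parents' alleles (chimeras) are
  conflicted, excluded and counted.
* **Breakpoints** (`collect_evidence`/`cluster_and_call`): pairs are
  discordant when inter-chromosomal, mis-oriented, or with implied insert
  outside mean +/- 4 SD; single-linkage clustering on both loci within
  500 bp; call position is the median of split-read junctions when
  available; calls need weight >= 5 (the published threshold). The
  published secondary "evidence set score" filter has no stated
  definition, so it is replaced by an explicit support-span sanity filter.
* **qPCR summaries** (`qpcr_summary`): mean, sample SD, and
  `M +/- 1.96 SD/sqrt(n)`. The normal-approximation z is a reproduction
  choice: it matches the published intervals at n = 3 where a t-quantile
  does not. The published bounds themselves are internally inconsistent at
  ~2e-4 (interval centers differ from the printed means), so agreement is
  asserted to 1e-3, not 5 decimals. The t-test variants behind the
  published p-values cannot be identified from the text; `two_sample_t`
  exposes pooled/Welch and one/two tails and no published p-value is
  targeted.

## What the acceptance experiments establish (and what they do not)

The acceptance suite checks that the pipeline *recovers the quantities the
generator encodes* — coverage fraction and domain count of the wild-type
world, the ~225 kb induced span / ~170 kb farthest peak / ~30 genes of the
17-repeat insertion, the ~180 kb mean de-novo extension across
end-creating translocations — and that the statistics code reproduces
published worked-example numbers. Runs simulate reads only on the
chromosomes carrying the measured features: chip and input are sampled at
the same depth, so the scaling factor and the per-chromosome statistics
are unchanged by the restriction, and the experiments stay desk-scale.
Green tests establish internal consistency of model + pipeline at stated
noise levels; they do not establish performance on real ChIP-seq, which
has mappability structure, duplicate artifacts, uneven input and no clean
truth.

## Known limitations

* The sharp `D_tel` threshold is a modeling choice; graded decay is
  untested.
* No sequencing-error model beyond uniform substitution; no adapters,
  qualities, duplicates or mappability.
* The SV caller is intentionally minimal: no probabilistic scoring, no
  genotyping, no inversion-within-translocation grammar; the rDNA array is
  not modeled.
* Expression analysis stops at per-class log2 ratios; no dispersion
  estimation or shrinkage.
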