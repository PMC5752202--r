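# Expression statistics: library-size normalization, log2 ratios by
# differential-domain class, qPCR-style summaries and t tests.

#' Build an expression table
#' @param counts data.frame with gene_id column and one numeric column per
#'   sample.
#' @param meta optional data.frame sample/strain/replicate.
#' @export
expression_table <- function(counts, meta = NULL) {
  stopifnot("gene_id" %in% names(counts))
  structure(counts, meta = meta, class = c("expression_table", "data.frame"))
}

.sample_cols <- function(table) setdiff(names(table), "gene_id")

#' Library-size normalization (counts-per-million convention)
#'
#' Scales every sample to a common library total so strains are
#' comparable; displayed values elsewhere are counts/1000 of the
#' normalized library.
#' @param table expression data.frame (gene_id + sample columns).
#' @export
normalize_counts <- function(table) {
  for (s in .sample_cols(table)) {
    tot <- sum(table[[s]])
    if (tot <= 0) stopf("zero-total sample '%s'", s)
    table[[s]] <- table[[s]] / tot * 1e6
  }
  table
}

#' Per-gene log2 expression ratios by differential-domain class
#'
#' Genes fully inside a gained or lost interval form those classes; genes
#' overlapping no changed interval form the control class. Values are
#' `log2((strain + pc) / (wt + pc))` on library-normalized counts.
#' @param table expression data.frame (gene_id + sample columns).
#' @param strain,wt sample column names.
#' @param class_intervals data.frame chrom/start/end/label with labels
#'   gained/lost (e.g. from [classify_differential()]).
#' @param genes gene table (chrom/start/end/id) on the same genome as
#'   `class_intervals`.
#' @param pseudocount added before the ratio.
#' @return list(values = list(gained, lost, control), summary =
#'   five-number summaries per class).
#' @export
log2_ratio_by_class <- function(table, strain, wt, class_intervals, genes,
                                pseudocount = 1) {
  if (!all(c(strain, wt) %in% names(table)))
    stopf("strain or wt sample missing from the table")
  tab <- normalize_counts(table)
  lfc <- stats::setNames(
    log2((tab[[strain]] + pseudocount) / (tab[[wt]] + pseudocount)),
    tab$gene_id)
  changed <- class_intervals[class_intervals$label %in% c("gained", "lost"), ,
                             drop = FALSE]
  values <- list()
  for (lb in c("gained", "lost")) {
    iv <- changed[changed$label == lb, , drop = FALSE]
    ids <- character(0)
    if (nrow(iv)) {
      keep <- vapply(seq_len(nrow(genes)), function(i) {
        any(iv$chrom == genes$chrom[i] & iv$start <= genes$start[i] &
            iv$end >= genes$end[i])
      }, logical(1))
      ids <- genes$id[keep]
    }
    values[[lb]] <- unname(lfc[ids[ids %in% names(lfc)]])
  }
  overl <- rep(FALSE, nrow(genes))
  if (nrow(changed)) {
    ov <- interval_overlaps(genes, changed)
    overl[unique(ov$qi)] <- TRUE
  }
  ids <- genes$id[!overl]
  values$control <- unname(lfc[ids[ids %in% names(lfc)]])

  summary <- lapply(values, function(v) {
    if (length(v) == 0) return(stats::setNames(rep(NA_real_, 5),
      c("min", "q1", "median", "q3", "max")))
    stats::setNames(stats::fivenum(v), c("min", "q1", "median", "q3", "max"))
  })
  list(values = values, summary = summary)
}

#' qPCR-style summary: mean, SD and normal-approximation 95% CI
#'
#' The confidence interval is `M +/- 1.96 * SD / sqrt(n)` (normal
#' approximation with the sample SD; this reproduces published qPCR
#' intervals computed at small n, and is a reproduction choice rather than
#' an endorsement).
#' @param values numeric replicate values (n >= 2).
#' @return list(M, SD, n, ci = c(lo, hi)).
#' @export
qpcr_summary <- function(values) {
  n <- length(values)
  if (n < 2) stopf("need at least two replicates")
  M <- mean(values)
  SD <- stats::sd(values)
  list(M = M, SD = SD, n = n, ci = qpcr_ci(M, SD, n))
}

#' Normal-approximation confidence interval from summary statistics
#' @param M mean.
#' @param SD sample standard deviation.
#' @param n replicate count.
#' @param z normal quantile (1.96 for 95%).
#' @return c(lo, hi).
#' @export
qpcr_ci <- function(M, SD, n, z = 1.96) {
  half <- z * SD / sqrt(n)
  c(lo = M - half, hi = M + half)
}

#' Two-sample t test (pooled or Welch, one- or two-tailed)
#'
#' @param groupA,groupB numeric samples (each n >= 2).
#' @param variant "pooled" (equal variances) or "welch".
#' @param tail "two" or "one" (one-tailed p is for the observed direction).
#' @return list(t, df, p).
#' @export
two_sample_t <- function(groupA, groupB, variant = c("pooled", "welch"),
                         tail = c("two", "one")) {
  variant <- match.arg(variant)
  tail <- match.arg(tail)
  n1 <- length(groupA); n2 <- length(groupB)
  if (n1 < 2 || n2 < 2) stopf("each group needs n >= 2")
  v1 <- stats::var(groupA); v2 <- stats::var(groupB)
  m1 <- mean(groupA); m2 <- mean(groupB)
  if (v1 == 0 && v2 == 0 && m1 == m2)
    return(list(t = 0, df = n1 + n2 - 2, p = 1))
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- if (tail == "two") 2 * stats::pt(-abs(t), df) else stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
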