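# Interval helpers. All coordinates in this package are 0-based, half-open
# [start, end). IRanges (1-based, closed) is used internally for overlap
# machinery; conversion happens only inside these helpers.

.empty_iv <- function(extra = character()) {
  base <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     stringsAsFactors = FALSE)
  for (col in extra) base[[col]] <- character()
  base
}

.as_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1, end = x$end)
}

#' Merge intervals closer than a gap
#'
#' @param x data.frame with chrom/start/end (0-based half-open).
#' @param gap intervals on the same chromosome separated by `<= gap` bp are
#'   merged (gap = 0 merges only overlapping/abutting intervals).
#' @return merged data.frame sorted by chrom, start.
#' @export
merge_intervals <- function(x, gap = 0) {
  if (nrow(x) == 0) return(.empty_iv()[c("chrom", "start", "end")])
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  out <- lapply(split(x, x$chrom), function(d) {
    e <- cummax(d$end)
    new_run <- d$start > c(-Inf, e[-length(e)]) + gap
    grp <- cumsum(new_run)
    data.frame(chrom = d$chrom[1],
               start = tapply(d$start, grp, min),
               end = tapply(e, grp, max),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Pairwise overlaps between two interval sets.
# Returns data.frame(qi, si, overlap_bp) of overlapping pairs.
interval_overlaps <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(qi = integer(), si = integer(), overlap_bp = numeric()))
  res <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    hits <- IRanges::findOverlaps(.as_iranges(a[ai, ]), .as_iranges(b[bi, ]))
    if (length(hits) == 0) next
    qa <- ai[S4Vectors_from(hits)]
    sb <- bi[S4Vectors_to(hits)]
    ov <- pmin(a$end[qa], b$end[sb]) - pmax(a$start[qa], b$start[sb])
    res[[ch]] <- data.frame(qi = qa, si = sb, overlap_bp = ov)
  }
  if (length(res) == 0)
    return(data.frame(qi = integer(), si = integer(), overlap_bp = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# thin wrappers so IRanges accessors stay in one place
S4Vectors_from <- function(h) as.integer(S4Vectors::from(h))
S4Vectors_to <- function(h) as.integer(S4Vectors::to(h))

# Subtract interval set b from a (per chromosome), keeping extra columns of a.
interval_setdiff <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  pieces <- list()
  for (i in seq_len(nrow(a))) {
    cur <- data.frame(start = a$start[i], end = a$end[i])
    bb <- b[b$chrom == a$chrom[i] & b$end > a$start[i] & b$start < a$end[i], ,
            drop = FALSE]
    if (nrow(bb)) {
      bb <- merge_intervals(bb)
      for (j in seq_len(nrow(bb))) {
        nxt <- list()
        for (k in seq_len(nrow(cur))) {
          s <- cur$start[k]; e <- cur$end[k]
          if (bb$end[j] <= s || bb$start[j] >= e) {
            nxt[[length(nxt) + 1]] <- c(s, e)
          } else {
            if (bb$start[j] > s) nxt[[length(nxt) + 1]] <- c(s, bb$start[j])
            if (bb$end[j] < e) nxt[[length(nxt) + 1]] <- c(bb$end[j], e)
          }
        }
        cur <- if (length(nxt)) {
          m <- do.call(rbind, nxt)
          data.frame(start = m[, 1], end = m[, 2])
        } else data.frame(start = numeric(), end = numeric())
        if (nrow(cur) == 0) break
      }
    }
    if (nrow(cur)) {
      row <- a[rep(i, nrow(cur)), , drop = FALSE]
      row$start <- cur$start
      row$end <- cur$end
      pieces[[length(pieces) + 1]] <- row
    }
  }
  if (length(pieces) == 0) return(a[0, , drop = FALSE])
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# total bp of the union of an interval set
covered_bp <- function(x) {
  if (nrow(x) == 0) return(0)
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

# complement of interval set x within chromosomes df(name, length)
interval_complement <- function(x, chroms) {
  res <- list()
  for (i in seq_len(nrow(chroms))) {
    nm <- chroms$name[i]
    len <- chroms$length[i]
    xx <- merge_intervals(x[x$chrom == nm, , drop = FALSE])
    bounds <- c(0, as.vector(rbind(xx$start, xx$end)), len)
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ends > starts
    if (any(keep))
      res[[nm]] <- data.frame(chrom = nm, start = starts[keep],
                              end = ends[keep], stringsAsFactors = FALSE)
  }
  if (length(res) == 0) return(.empty_iv()[c("chrom", "start", "end")])
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
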