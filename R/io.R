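# Readers/writers for the plain-text interchange formats the pipeline
# speaks: FASTA, FASTQ, BED6, bedGraph, GFF3, a minimal SAM dialect
# (header + the 11 mandatory columns), SNPome TSV/paired-FASTA, and the
# JSON genome sidecar. Internal coordinates are 0-based half-open; BED and
# bedGraph are emitted as-is, GFF3 converts to 1-based inclusive, SAM POS
# is 1-based.

#' Write sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path input file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write intervals as BED6
#' @param df data.frame chrom/start/end plus optional name/score/strand.
#' @param path output file.
#' @export
write_bed6 <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = format(df$start, scientific = FALSE, trim = TRUE),
                    end = format(df$end, scientific = FALSE, trim = TRUE),
                    name = df$name %||% ".", score = df$score %||% 0,
                    strand = df$strand %||% ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#' @param path input file.
#' @export
read_bed6 <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand")[1:6])
  df
}

#' Write genes as GFF3 (1-based inclusive coordinates)
#' @param genes data.frame chrom/start/end/strand/id (0-based half-open).
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    lines <- sprintf("%s\ttelodomains\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, as.integer(genes$start + 1),
                     as.integer(genes$end), genes$strand, genes$id)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a GFF3 gene file back to 0-based half-open intervals
#' @param path input file.
#' @export
read_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (length(ln) == 0) return(.empty_genes())
  f <- strsplit(ln, "\t", fixed = TRUE)
  data.frame(chrom = vapply(f, `[`, "", 1),
             start = as.numeric(vapply(f, `[`, "", 4)) - 1,
             end = as.numeric(vapply(f, `[`, "", 5)),
             strand = vapply(f, `[`, "", 7),
             id = sub("^ID=", "", vapply(f, `[`, "", 9)),
             stringsAsFactors = FALSE)
}

#' Write a coverage track as bedGraph
#'
#' Window values are emitted at step resolution (each line covers one step,
#' carrying the value of the window starting there), so lines do not overlap.
#' @param track a `coverage_track`.
#' @param path output file.
#' @param track_line include a bedGraph track header line.
#' @export
write_bedgraph <- function(track, path, track_line = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (track_line) writeLines("track type=bedGraph", con)
  for (nm in names(track$values)) {
    v <- track$values[[nm]]
    if (length(v) == 0) next
    s <- (seq_along(v) - 1) * track$step
    writeLines(sprintf("%s\t%d\t%d\t%.6g", nm, as.integer(s),
                       as.integer(s + track$step), v), con)
  }
  invisible(path)
}

#' Read a bedGraph file
#' @param path input file.
#' @return data.frame chrom/start/end/value.
#' @export
read_bedgraph <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "track") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  data.frame(chrom = vapply(f, `[`, "", 1),
             start = as.numeric(vapply(f, `[`, "", 2)),
             end = as.numeric(vapply(f, `[`, "", 3)),
             value = as.numeric(vapply(f, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Write alignments as minimal SAM
#'
#' Header (@HD/@SQ) plus the 11 mandatory columns. Pairing flags are set
#' when a `mate` column (1/2) is present; sequence is written when a `seq`
#' column is present, else "*".
#' @param aln data.frame chrom/start/end/strand with optional name/mate/seq.
#' @param chroms data.frame name/length.
#' @param path output file.
#' @export
write_sam <- function(aln, chroms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", chroms$name, as.integer(chroms$length)), con)
  if (nrow(aln)) {
    qname <- aln$name %||% sprintf("r%07d", seq_len(nrow(aln)))
    flag <- ifelse(aln$strand %in% c("-", "-1"), 16L, 0L)
    if (!is.null(aln$mate))
      flag <- flag + 1L + ifelse(aln$mate == 1, 64L, 128L)
    seq <- aln$seq %||% rep("*", nrow(aln))
    cigar <- sprintf("%dM", as.integer(aln$end - aln$start))
    writeLines(paste(qname, flag, aln$chrom, as.integer(aln$start + 1), 60L,
                     cigar, "*", 0L, 0L, seq, "*", sep = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal SAM file
#' @param path input file.
#' @return data.frame chrom/start/end/strand/name/mate/seq.
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (length(ln) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), name = character(),
                      mate = integer(), seq = character(),
                      stringsAsFactors = FALSE))
  f <- strsplit(ln, "\t", fixed = TRUE)
  flag <- as.integer(vapply(f, `[`, "", 2))
  start <- as.numeric(vapply(f, `[`, "", 4)) - 1
  m <- regmatches(vapply(f, `[`, "", 6),
                  regexpr("^[0-9]+", vapply(f, `[`, "", 6)))
  len <- as.numeric(m)
  data.frame(chrom = vapply(f, `[`, "", 3), start = start, end = start + len,
             strand = ifelse(bitwAnd(flag, 16L) > 0, "-", "+"),
             name = vapply(f, `[`, "", 1),
             mate = ifelse(bitwAnd(flag, 64L) > 0, 1L,
                           ifelse(bitwAnd(flag, 128L) > 0, 2L, NA_integer_)),
             seq = vapply(f, `[`, "", 10), stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#' @param reads data.frame with name and seq columns.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(paste0("@", reads$name, "\n", reads$seq, "\n+\n",
                      strrep("I", nchar(reads$seq))), con)
  invisible(path)
}

#' Read a FASTQ file
#' @param path input file.
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  if (length(ln) == 0)
    return(data.frame(name = character(), seq = character(),
                      stringsAsFactors = FALSE))
  data.frame(name = sub("^@", "", ln[seq(1, length(ln), by = 4)]),
             seq = ln[seq(2, length(ln), by = 4)], stringsAsFactors = FALSE)
}

#' Serialize a genome to files (FASTA + JSON sidecar + GFF3 + BED6)
#'
#' The sidecar JSON carries chromosome table, telomere arrays, interstitial
#' arrays, domain truth and junctions; FASTA is written only for sequence
#' genomes ("lengths-only" mode skips it).
#' @param genome an `annotated_genome`.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return named character vector of written paths.
#' @export
genome_to_files <- function(genome, dir, prefix = "genome") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(sidecar = file.path(dir, paste0(prefix, ".json")),
             genes_gff = file.path(dir, paste0(prefix, "_genes.gff3")),
             genes_bed = file.path(dir, paste0(prefix, "_genes.bed")),
             domains_bed = file.path(dir, paste0(prefix, "_domains.bed")))
  side <- list(chromosomes = genome$chromosomes, telomeres = genome$telomeres,
               arrays = genome$arrays, domains = genome$domains,
               junctions = genome$junctions)
  jsonlite::write_json(side, paths["sidecar"], dataframe = "columns",
                       digits = NA, pretty = TRUE)
  write_gff3(genome$genes, paths["genes_gff"])
  g <- genome$genes
  write_bed6(data.frame(chrom = g$chrom, start = g$start, end = g$end,
                        name = g$id, score = 0, strand = g$strand),
             paths["genes_bed"])
  d <- genome$domains
  write_bed6(data.frame(chrom = d$chrom, start = d$start, end = d$end,
                        name = d$class, score = 0, strand = "."),
             paths["domains_bed"])
  if (!is.null(genome$sequences)) {
    paths["fasta"] <- file.path(dir, paste0(prefix, ".fasta"))
    write_fasta(genome$sequences, paths["fasta"])
  }
  paths
}

#' Load a genome serialized by [genome_to_files()]
#' @param dir directory holding the files.
#' @param prefix file name prefix used when writing.
#' @export
genome_from_files <- function(dir, prefix = "genome") {
  side <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                              simplifyVector = TRUE)
  fix <- function(df, template) {
    if (is.null(df) || length(df) == 0 || (is.data.frame(df) && nrow(df) == 0))
      return(template)
    as.data.frame(df, stringsAsFactors = FALSE)
  }
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  annotated_genome(
    chromosomes = as.data.frame(side$chromosomes, stringsAsFactors = FALSE),
    telomeres = fix(side$telomeres, .empty_telomeres()),
    genes = read_gff3(file.path(dir, paste0(prefix, "_genes.gff3"))),
    domains = fix(side$domains, .empty_domains()),
    arrays = fix(side$arrays, .empty_arrays()),
    sequences = if (file.exists(fasta)) read_fasta(fasta) else NULL,
    junctions = fix(side$junctions, .empty_junctions()))
}

#' Write a SNPome as TSV
#' @param snpome data.frame chrom/pos/allele_a/allele_b/flank_a/flank_b.
#' @param path output file.
#' @export
write_snpome_tsv <- function(snpome, path) {
  utils::write.table(snpome, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNPome TSV
#' @param path input file.
#' @export
read_snpome_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' Write a SNPome as a paired FASTA (both versions of each SNP)
#'
#' Each SNP contributes two records carrying the flanking context under each
#' parental allele.
#' @param snpome SNPome data.frame.
#' @param path output file.
#' @param parents labels of the two parents.
#' @export
write_snpome_fasta <- function(snpome, path, parents = c("A", "B")) {
  seqs <- c(stats::setNames(snpome$flank_a,
                            sprintf("%s_%s_%s", snpome$chrom, snpome$pos, parents[1])),
            stats::setNames(snpome$flank_b,
                            sprintf("%s_%s_%s", snpome$chrom, snpome$pos, parents[2])))
  write_fasta(seqs, path)
}

#' Write an expression table as TSV
#' @param table expression data.frame (gene_id + one column per sample).
#' @param path output file.
#' @export
write_expression_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression table TSV
#' @param path input file.
#' @export
read_expression_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
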