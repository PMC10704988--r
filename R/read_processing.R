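# Read-level filters, PCR-duplicate removal, coverage and FPKM.

#' Filter raw reads on ambiguous-base count and length
#'
#' Keeps reads with at most two ambiguous bases (`N`/`n`) and a length of at
#' least 16 nt; input order is preserved.
#'
#' @param reads Character vector of read sequences, or a data frame with a
#'   `sequence` column.
#' @param max_n Maximum allowed ambiguous bases (default 2).
#' @param min_length Minimum read length in nt (default 16).
#' @return The kept reads, same type as the input.
#' @export
filter_reads <- function(reads, max_n = 2L, min_length = 16L) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  stopifnot(is.character(seqs))
  n_count <- nchar(seqs) - nchar(gsub("[Nn]", "", seqs))
  keep <- n_count <= max_n & nchar(seqs) >= min_length
  if (is.data.frame(reads)) reads[keep, , drop = FALSE] else reads[keep]
}

#' Remove PCR-duplicate read placements
#'
#' At most one placement is retained per (chrom, start, end, strand) key;
#' the first occurrence wins.
#'
#' @param placements Interval table of read placements (optionally with a
#'   `name`/read-id column, which plays no part in the key).
#' @return The deduplicated placements, original order preserved.
#' @export
dedup_placements <- function(placements) {
  validate_intervals(placements)
  strand <- if ("strand" %in% names(placements)) placements$strand else "."
  key <- paste(placements$chrom, placements$start, placements$end, strand,
               sep = "\r")
  placements[!duplicated(key), , drop = FALSE]
}

#' Per-base read coverage over a region
#'
#' `depth[i]` is the number of placements covering base `region$start + i - 1`;
#' placements extending past the region are clipped, placements elsewhere
#' ignored.  Strands are pooled unless `strand` is given.
#'
#' @param placements Interval table of read placements.
#' @param region Single-row interval table.
#' @param strand Optional `"+"`/`"-"` to restrict to one strand.
#' @return A `coverage_track`: list with `chrom`, `start`, `end` and integer
#'   `depth` of length `end - start`.
#' @export
compute_coverage <- function(placements, region, strand = NULL) {
  stopifnot(nrow(region) == 1L)
  validate_intervals(region)
  L <- region$end - region$start
  p <- placements[placements$chrom == region$chrom, , drop = FALSE]
  if (!is.null(strand)) p <- p[p$strand == strand, , drop = FALSE]
  s <- pmax(p$start, region$start) - region$start
  e <- pmin(p$end, region$end) - region$start
  ok <- s < e
  s <- s[ok]; e <- e[ok]
  delta <- tabulate(s + 1L, nbins = L + 1L) - tabulate(e + 1L, nbins = L + 1L)
  depth <- cumsum(delta)[seq_len(L)]
  structure(list(chrom = region$chrom, start = region$start, end = region$end,
                 depth = as.integer(depth)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track %s:%d-%d (%d bp), depth range [%d, %d]\n",
              x$chrom, x$start, x$end, x$end - x$start,
              min(x$depth), max(x$depth)))
  invisible(x)
}

#' FPKM from a count matrix
#'
#' `FPKM[g, s] = counts[g, s] * 1e9 / (length[g] * library_size[s])`:
#' fragments per kilobase of transcript per million mapped fragments.  Gene
#' length defaults to the longest annotated transcript when derived from an
#' annotation (see [gene_lengths()]).
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames =
#'   gene ids), samples in columns.
#' @param transcript_lengths Named numeric vector of per-gene lengths (bp),
#'   covering every row of `counts`.
#' @param library_sizes Named (or positionally matched) numeric vector of
#'   total mapped fragments per sample; defaults to `colSums(counts)`.
#' @return Numeric matrix of FPKM values, same dimnames as `counts`.
#' @export
fpkm <- function(counts, transcript_lengths, library_sizes = colSums(counts)) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  missing <- setdiff(rownames(counts), names(transcript_lengths))
  if (length(missing))
    stop("no transcript length for gene(s): ", paste(missing, collapse = ", "))
  len <- transcript_lengths[rownames(counts)]
  stopifnot(all(len > 0), all(library_sizes > 0))
  sweep(sweep(counts * 1e9, 1, len, "/"), 2, library_sizes, "/")
}

#' Per-gene transcript length from an annotation
#'
#' Length of the longest annotated transcript of each gene (exon-sum bp),
#' the default length used by [fpkm()].
#'
#' @param annotation A `gene_annotation`.
#' @return Named integer vector, one entry per gene with transcripts.
#' @export
gene_lengths <- function(annotation) {
  t <- annotation$transcripts
  if (!nrow(t)) return(stats::setNames(integer(0), character(0)))
  tapply(t$length, t$gene_id, max)
}

#' Read aligned read placements from SAM/BAM
#'
#' Imports uniquely-mapped primary alignments (mapping quality at or above
#' `min_mapq`) as an interval table in the internal 0-based convention.
#' SAM text files are converted on the fly through \pkg{Rsamtools}.
#'
#' @param path Path to a SAM or BAM file.
#' @param min_mapq Minimum mapping quality (default 20), the uniquely-mapped
#'   filter.
#' @return Interval table with `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_sam_placements <- function(path, min_mapq = 20L) {
  stopifnot(file.exists(path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- tempfile(fileext = ".bam")
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    Rsamtools::asBam(path, sub("\\.bam$", "", bam), overwrite = TRUE,
                     indexDestination = TRUE)
  }
  param <- Rsamtools::ScanBamParam(
    what = "qname",
    mapqFilter = min_mapq,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  data.frame(chrom = as.character(GenomicAlignments::seqnames(aln)),
             start = GenomicAlignments::start(aln) - 1L,
             end = GenomicAlignments::end(aln),
             name = S4Vectors::mcols(aln)$qname,
             strand = as.character(GenomicAlignments::strand(aln)),
             stringsAsFactors = FALSE)
}

#' Write read placements as a minimal SAM file
#'
#' Emits unpaired single-end records (CIGAR `<len>M`, MAPQ 60, sequence and
#' qualities omitted) over an `@SQ` header derived from `chrom_sizes`.
#' Provided so the SAM reading path can be exercised on generated data.
#'
#' @param placements Interval table with `chrom`, `start`, `end`, `name`,
#'   `strand`.
#' @param path Output path (`.sam`).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return The path, invisibly.
#' @export
write_sam <- function(placements, path, chrom_sizes) {
  validate_intervals(placements)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                   as.integer(chrom_sizes)))
  flag <- ifelse(placements$strand == "-", 16L, 0L)
  len <- placements$end - placements$start
  rec <- paste(placements$name, flag, placements$chrom,
               placements$start + 1L, 60L, paste0(len, "M"),
               "*", 0L, 0L, "*", "*", sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}
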