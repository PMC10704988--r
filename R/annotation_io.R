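# GTF / BED input-output and the gene-model container.

#' Read gene models from a GTF file
#'
#' Parses an Ensembl-dialect GTF (via \pkg{rtracklayer}) into a
#' `gene_annotation` object: three data frames (`genes`, `transcripts`,
#' `exons`) in the package-internal 0-based half-open convention.  Records
#' without a `gene_id` attribute are skipped with a warning; structurally
#' malformed lines raise an error naming the first offending line.
#'
#' @param path Path to a GTF file.
#' @return An object of class `gene_annotation`, a list with elements
#'   `genes` (`gene_id`, `chrom`, `start`, `end`, `strand`, `biotype`),
#'   `transcripts` (`transcript_id`, `gene_id`, coordinates, `length` = sum
#'   of exon lengths) and `exons` (`transcript_id`, `gene_id`, coordinates).
#'   Biotypes are collapsed to `coding` / `noncoding` / `unknown`.
#' @export
read_gtf <- function(path) {
  stopifnot(file.exists(path))
  raw <- readLines(path)
  body <- which(!grepl("^#", raw) & nzchar(raw))
  if (length(body) == 0) return(empty_annotation())
  nf <- lengths(strsplit(raw[body], "\t", fixed = TRUE))
  if (any(nf < 9))
    stop("malformed GTF line ", body[which(nf < 9)[1]], " in ", path,
         ": expected 9 tab-separated fields")
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  no_gene <- is.na(meta$gene_id)
  if (any(no_gene)) {
    warning(sum(no_gene), " GTF record(s) without gene_id skipped")
    gr <- gr[!no_gene]
    meta <- S4Vectors::mcols(gr)
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
                   end = GenomicRanges::end(gr),
                   strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
                   type = as.character(meta$type),
                   gene_id = as.character(meta$gene_id),
                   stringsAsFactors = FALSE)
  df$transcript_id <- if ("transcript_id" %in% names(meta))
    as.character(meta$transcript_id) else NA_character_
  df$biotype <- if ("gene_biotype" %in% names(meta))
    as.character(meta$gene_biotype) else NA_character_

  exons <- df[df$type == "exon" & !is.na(df$transcript_id),
              c("transcript_id", "gene_id", "chrom", "start", "end", "strand")]
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  tx <- df[df$type == "transcript" & !is.na(df$transcript_id), , drop = FALSE]
  if (nrow(tx) == 0 && nrow(exons) > 0) {  # derive transcripts from exons
    tx <- data.frame(transcript_id = unique(exons$transcript_id))
    tx <- merge(tx, exons[!duplicated(exons$transcript_id),
                          c("transcript_id", "gene_id", "chrom", "strand")])
    rng <- tapply(seq_len(nrow(exons)), exons$transcript_id, function(i)
      c(min(exons$start[i]), max(exons$end[i])))
    tx$start <- vapply(rng[tx$transcript_id], `[`, numeric(1), 1)
    tx$end <- vapply(rng[tx$transcript_id], `[`, numeric(1), 2)
  }
  exon_len <- if (nrow(exons)) tapply(exons$end - exons$start, exons$transcript_id, sum)
              else integer(0)
  transcripts <- data.frame(
    transcript_id = tx$transcript_id, gene_id = tx$gene_id, chrom = tx$chrom,
    start = as.integer(tx$start), end = as.integer(tx$end), strand = tx$strand,
    length = as.integer(exon_len[tx$transcript_id]),
    stringsAsFactors = FALSE)
  rownames(transcripts) <- NULL

  gn <- df[df$type == "gene", , drop = FALSE]
  if (nrow(gn) == 0 && nrow(transcripts) > 0) {  # derive genes from transcripts
    gid <- unique(transcripts$gene_id)
    gn <- do.call(rbind, lapply(gid, function(g) {
      t <- transcripts[transcripts$gene_id == g, ]
      data.frame(gene_id = g, chrom = t$chrom[1], start = min(t$start),
                 end = max(t$end), strand = t$strand[1],
                 biotype = NA_character_, stringsAsFactors = FALSE)
    }))
  } else {
    gn <- gn[, c("gene_id", "chrom", "start", "end", "strand", "biotype")]
  }
  if (anyDuplicated(gn$gene_id))
    stop("duplicate gene_id in annotation: ",
         paste(unique(gn$gene_id[duplicated(gn$gene_id)]), collapse = ", "))
  gn$biotype <- collapse_biotype(gn$biotype)
  rownames(gn) <- NULL
  gene_annotation(gn, transcripts, exons)
}

collapse_biotype <- function(x) {
  out <- rep("unknown", length(x))
  out[!is.na(x) & x %in% c("protein_coding", "coding")] <- "coding"
  out[!is.na(x) & x %in% c("lncRNA", "lincRNA", "noncoding", "ncRNA")] <- "noncoding"
  out
}

empty_annotation <- function() {
  gene_annotation(
    data.frame(gene_id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), biotype = character()),
    data.frame(transcript_id = character(), gene_id = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), length = integer()),
    data.frame(transcript_id = character(), gene_id = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character()))
}

gene_annotation <- function(genes, transcripts, exons) {
  if (nrow(genes)) validate_intervals(genes)
  if (nrow(transcripts)) {
    validate_intervals(transcripts)
    m <- match(transcripts$gene_id, genes$gene_id)
    if (any(is.na(m)))
      stop("transcript(s) reference unknown gene_id: ",
           paste(unique(transcripts$gene_id[is.na(m)]), collapse = ", "))
    inside <- transcripts$start >= genes$start[m] & transcripts$end <= genes$end[m]
    if (!all(inside))
      stop("transcript interval outside its gene for: ",
           paste(transcripts$transcript_id[!inside], collapse = ", "))
  }
  structure(list(genes = genes, transcripts = transcripts, exons = exons),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exons on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Write a gene annotation as GTF
#'
#' Emits gene/transcript/exon lines in the Ensembl GTF dialect (1-based
#' closed coordinates), the inverse of [read_gtf()].
#'
#' @param annotation A `gene_annotation` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  fmt <- function(chrom, type, start0, end0, strand, attrs) {
    paste(chrom, "rbpscan", type, start0 + 1L, end0, ".", strand, ".", attrs,
          sep = "\t")
  }
  g <- annotation$genes; t <- annotation$transcripts; e <- annotation$exons
  bt <- ifelse(g$biotype == "coding", "protein_coding",
               ifelse(g$biotype == "noncoding", "lncRNA", "misc_RNA"))
  lines <- character(0)
  if (nrow(g))
    lines <- c(lines, fmt(g$chrom, "gene", g$start, g$end, g$strand,
                          sprintf('gene_id "%s"; gene_biotype "%s";', g$gene_id, bt)))
  if (nrow(t))
    lines <- c(lines, fmt(t$chrom, "transcript", t$start, t$end, t$strand,
                          sprintf('gene_id "%s"; transcript_id "%s";',
                                  t$gene_id, t$transcript_id)))
  if (nrow(e))
    lines <- c(lines, fmt(e$chrom, "exon", e$start, e$end, e$strand,
                          sprintf('gene_id "%s"; transcript_id "%s";',
                                  e$gene_id, e$transcript_id)))
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals or peaks as BED6
#'
#' Standard BED6 (0-based half-open, matching the internal convention):
#' columns chrom, start, end, name, score, strand.  For peak tables the
#' score column is the maximum per-base depth; a generic interval table gets
#' score 0.  No header is written by default.
#'
#' @param x Interval table; optional columns `name` (else `name_prefix_i`)
#'   and `score` (for peaks, pass `max_depth`).
#' @param path Output file path.
#' @param name_prefix Prefix used when `x` lacks a `name` column.
#' @return The path, invisibly.
#' @export
write_bed <- function(x, path, name_prefix = "region") {
  validate_intervals(x)
  name <- if ("name" %in% names(x)) x$name else
    if (nrow(x)) paste0(name_prefix, "_", seq_len(nrow(x))) else character(0)
  score <- if ("score" %in% names(x)) x$score else
    if ("max_depth" %in% names(x)) x$max_depth else rep(0L, nrow(x))
  strand <- if ("strand" %in% names(x)) x$strand else rep(".", nrow(x))
  bed <- data.frame(x$chrom, x$start, x$end, name, score, strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' Inverse of [write_bed()]; also reads the package's BED dialect of read
#' placements (name column = read id).
#'
#' @param path Path to a BED file (3-6 columns, no header).
#' @return Interval data frame with `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` (missing trailing columns filled with defaults).
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character()))
  x <- fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- cols[seq_len(ncol(x))]
  if (!"name" %in% names(x)) x$name <- paste0("region_", seq_len(nrow(x)))
  if (!"score" %in% names(x)) x$score <- 0
  if (!"strand" %in% names(x)) x$strand <- "."
  x$chrom <- as.character(x$chrom)
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  validate_intervals(x)
  x[, cols]
}
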