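# Genomic interval arithmetic.
#
# All coordinates in this package are 0-based, half-open [start, end):
# GTF input (1-based, closed) is converted on read, BED is written natively.
# A single internal convention removes every off-by-one at module borders.

#' Construct a table of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`,
#' `strand` (0-based half-open).  This constructor validates the invariants
#' shared by every coordinate-carrying table in the package.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start,end Integer vectors, `0 <= start < end`, half-open.
#' @param strand Character vector in `{"+", "-", "."}` (recycled).
#' @return A `data.frame` with the four columns, validated.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.integer(start),
                  end = as.integer(end),
                  strand = rep_len(as.character(strand), length(chrom)),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

validate_intervals <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop("interval chrom must be a non-empty string")
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stop("invalid interval(s) at row(s) ", paste(head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  if ("strand" %in% names(x) && any(!x$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(x)
}

#' Test whether two genomic intervals overlap
#'
#' Half-open semantics: `[100,200)` and `[200,300)` are adjacent, not
#' overlapping.  Strand is ignored; intervals on different chromosomes never
#' overlap.  Vectorised over rows.
#'
#' @param a,b Interval tables (or single rows) as from [genomic_intervals()].
#' @return Logical vector.
#' @export
overlaps <- function(a, b) {
  a$chrom == b$chrom & pmax(a$start, b$start) < pmin(a$end, b$end)
}

# Gap in bp between two intervals on the same chromosome: 0 if they overlap
# or touch, otherwise the distance between the nearer ends.  Vectorised.
interval_gap <- function(a, b) {
  pmax(pmax(a$start, b$start) - pmin(a$end, b$end), 0L)
}

#' Distance from an interval to the nearest gene
#'
#' The gap (bp) to the closest gene on the same chromosome; 0 when the
#' interval overlaps or touches a gene; `Inf` when no gene shares the
#' chromosome (including an empty gene set).
#'
#' @param x A single-row interval table.
#' @param genes A gene table with `chrom`, `start`, `end` columns (e.g.
#'   `annotation$genes`), possibly empty.
#' @return A numeric scalar (bp, or `Inf`).
#' @export
distance_to_nearest_gene <- function(x, genes) {
  stopifnot(nrow(x) == 1L)
  g <- genes[genes$chrom == x$chrom, , drop = FALSE]
  if (nrow(g) == 0) return(Inf)
  min(pmax(pmax(g$start, x$start) - pmin(g$end, x$end), 0L))
}
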