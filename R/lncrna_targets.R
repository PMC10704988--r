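# lncRNA candidate filtering and the cis-target co-location/co-expression
# screen.

PREDICTORS <- c("cpc2", "lgc", "cnci", "cpat")

#' Filter credible lncRNA candidates
#'
#' A candidate transcript is kept only when (i) all four coding-potential
#' predictors (CPC2, LGC, CNCI, CPAT) vote noncoding, (ii) it is at least
#' 200 bp long (199 bp is removed, 200 kept), (iii) it does not overlap any
#' known coding gene, and (iv) it lies at least 1,000 bp from the nearest
#' coding gene.  Transcripts with incomplete votes are rejected with reason
#' `incomplete_votes`.
#'
#' @param candidates Data frame with `transcript_id`, `chrom`, `start`,
#'   `end`, optional `strand` and `length` (exonic length; the interval
#'   length is used when absent), and one column per predictor in
#'   `c("cpc2","lgc","cnci","cpat")` holding `"noncoding"`/`"coding"` (or
#'   logical, `TRUE` = noncoding).
#' @param coding_genes Gene table (`chrom`, `start`, `end`) of known coding
#'   genes, e.g. `annotation$genes[annotation$genes$biotype == "coding", ]`.
#' @param min_length Minimum transcript length in bp (default 200, kept at
#'   the boundary).
#' @param min_gene_distance Minimum distance to the nearest coding gene in
#'   bp (default 1000, kept at the boundary).
#' @return `candidates` with added `overlaps_coding`,
#'   `nearest_gene_distance`, logical `kept` and a `reason` column (empty
#'   string when kept).
#' @export
filter_lncrna_candidates <- function(candidates, coding_genes,
                                     min_length = 200L,
                                     min_gene_distance = 1000L) {
  validate_intervals(candidates)
  votes <- sapply(PREDICTORS, function(p) {
    if (!p %in% names(candidates)) return(rep(NA, nrow(candidates)))
    v <- candidates[[p]]
    if (is.logical(v)) v else ifelse(is.na(v), NA, v == "noncoding")
  })
  votes <- matrix(votes, nrow = nrow(candidates), dimnames = list(NULL, PREDICTORS))
  complete <- rowSums(is.na(votes)) == 0
  all_noncoding <- complete & rowSums(votes, na.rm = TRUE) == length(PREDICTORS)
  len <- if ("length" %in% names(candidates)) candidates$length else
    candidates$end - candidates$start
  candidates$overlaps_coding <- vapply(seq_len(nrow(candidates)), function(i) {
    any(coding_genes$chrom == candidates$chrom[i] &
          pmax(coding_genes$start, candidates$start[i]) <
          pmin(coding_genes$end, candidates$end[i]))
  }, logical(1))
  candidates$nearest_gene_distance <- vapply(seq_len(nrow(candidates)),
    function(i) distance_to_nearest_gene(candidates[i, , drop = FALSE],
                                         coding_genes), numeric(1))
  reason <- character(nrow(candidates))
  reason[candidates$nearest_gene_distance < min_gene_distance] <- "near_gene"
  reason[candidates$overlaps_coding] <- "overlaps_coding"
  reason[len < min_length] <- "short"
  reason[complete & !all_noncoding] <- "coding_vote"
  reason[!complete] <- "incomplete_votes"
  if (any(!complete))
    log_msg(sum(!complete), " candidate(s) rejected: incomplete votes")
  candidates$kept <- reason == ""
  candidates$reason <- reason
  candidates
}

#' Co-located lncRNA-gene candidate pairs
#'
#' All (lncRNA, gene) pairs on the same chromosome whose gap is at most
#' `window` bp (100 kb by default, inclusive; overlap counts as distance 0).
#' Distance is measured between interval boundaries, strand-agnostic.
#'
#' @param lncrnas Interval table with an id column (`transcript_id` or
#'   `gene_id`, whichever is present first).
#' @param genes Gene table with `gene_id`.
#' @param window Maximum gap in bp (default 100000, inclusive).
#' @return Data frame of candidate pairs: `lncrna_id`, `gene_id`,
#'   `genomic_distance`.
#' @export
colocated_pairs <- function(lncrnas, genes, window = 100000L) {
  validate_intervals(lncrnas); validate_intervals(genes)
  idcol <- intersect(c("transcript_id", "gene_id", "name"), names(lncrnas))[1]
  stopifnot(!is.na(idcol))
  out <- lapply(seq_len(nrow(lncrnas)), function(i) {
    same <- genes$chrom == lncrnas$chrom[i] &
      genes$gene_id != lncrnas[[idcol]][i]
    g <- genes[same, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    gap <- pmax(pmax(g$start, lncrnas$start[i]) - pmin(g$end, lncrnas$end[i]), 0L)
    keep <- gap <= window
    if (!any(keep)) return(NULL)
    data.frame(lncrna_id = lncrnas[[idcol]][i], gene_id = g$gene_id[keep],
               genomic_distance = gap[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(lncrna_id = character(), gene_id = character(),
                      genomic_distance = integer())
  rownames(out) <- NULL
  out
}

#' Co-expression screen of lncRNA-gene pairs
#'
#' Pearson correlation across samples with the exact two-sided t-transform
#' p-value (`t = r * sqrt(n-2) / sqrt(1-r^2)`, n-2 degrees of freedom, as in
#' [stats::cor.test()]).  A pair passes when `|r| > r_cut` (strict) and
#' `p <= p_cut` (inclusive).  Zero-variance expression makes the pair fail
#' with reason `zero_variance`.
#'
#' @param pairs Data frame with `lncrna_id`, `gene_id` (e.g. from
#'   [colocated_pairs()]).
#' @param expr Expression matrix (FPKM), genes in rows (rownames = ids),
#'   at least 3 samples in columns; both pair members must be present.
#' @param r_cut Absolute-correlation cutoff (default 0.6, strict).
#' @param p_cut P-value cutoff (default 0.01, inclusive).
#' @param adjust_p Apply Benjamini-Hochberg across pairs before the p
#'   cutoff (off by default).
#' @return `pairs` with `pearson_r`, `p_value`, logical `passes` and a
#'   `reason` column.
#' @export
coexpression_screen <- function(pairs, expr, r_cut = 0.6, p_cut = 0.01,
                                adjust_p = FALSE) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3)
  missing <- setdiff(unique(c(pairs$lncrna_id, pairs$gene_id)), rownames(expr))
  if (length(missing))
    stop("pair member(s) absent from expression matrix: ",
         paste(head(missing, 5), collapse = ", "))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- expr[pairs$lncrna_id[i], ]; y <- expr[pairs$gene_id[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(list(r = NA_real_, p = NA_real_, reason = "zero_variance"))
    ct <- cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, reason = "")
  })
  pairs$pearson_r <- vapply(res, function(r) r$r, numeric(1))
  pairs$p_value <- vapply(res, function(r) r$p, numeric(1))
  pairs$reason <- vapply(res, function(r) r$reason, character(1))
  p <- if (adjust_p) bh_fdr(pairs$p_value) else pairs$p_value
  pairs$passes <- !is.na(pairs$pearson_r) & abs(pairs$pearson_r) > r_cut &
    !is.na(p) & p <= p_cut
  n_zv <- sum(pairs$reason == "zero_variance")
  if (n_zv) log_msg(n_zv, " pair(s) failed: zero-variance expression")
  pairs
}

#' Final cis targets: intersection of the two screens
#'
#' A pair is a cis target when it passed co-location and co-expression.
#'
#' @param colocated Output of [colocated_pairs()] (every row passed the
#'   distance screen).
#' @param coexpressed Output of [coexpression_screen()] (its `passes`
#'   column is honoured).
#' @return Data frame of final pairs with distance, correlation and p.
#' @export
cis_targets <- function(colocated, coexpressed) {
  co <- coexpressed[coexpressed$passes, , drop = FALSE]
  out <- merge(colocated, co[, c("lncrna_id", "gene_id", "pearson_r", "p_value")],
               by = c("lncrna_id", "gene_id"))
  out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
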