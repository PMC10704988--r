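# DEG threshold filtering, set overlaps and hypergeometric term enrichment.

#' Threshold filter for differentially expressed genes
#'
#' Strict boundaries exactly as printed in standard practice: up-regulated
#' when `p < alpha` and `fold_change > fc_hi`; down-regulated when
#' `p < alpha` and `fold_change < fc_lo`; everything else `none`.  Fold
#' changes are linear knockdown/control ratios (`log2_input = TRUE`
#' converts from log2).
#'
#' @param table Data frame with `gene_id`, `fold_change`, `p_value`.
#' @param fc_hi,fc_lo Fold-change cutoffs (defaults 2 and 0.5, strict).
#' @param alpha P-value cutoff (default 0.05, strict).
#' @param log2_input Treat `fold_change` as log2 and convert first.
#' @param adjust_p Apply Benjamini-Hochberg to `p_value` before filtering.
#' @return The table with a `direction` factor column (`up`/`down`/`none`).
#' @export
deg_filter <- function(table, fc_hi = 2, fc_lo = 0.5, alpha = 0.05,
                       log2_input = FALSE, adjust_p = FALSE) {
  stopifnot(all(c("gene_id", "fold_change", "p_value") %in% names(table)))
  fc <- if (log2_input) 2^table$fold_change else table$fold_change
  bad <- which(!is.na(fc) & fc <= 0)
  if (length(bad))
    stop("non-positive fold change at row(s): ", paste(bad, collapse = ", "))
  p <- table$p_value
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p_value outside [0, 1]")
  if (adjust_p) p <- bh_fdr(p)
  sig <- !is.na(p) & p < alpha & !is.na(fc)
  direction <- rep("none", nrow(table))
  direction[sig & fc > fc_hi] <- "up"
  direction[sig & fc < fc_lo] <- "down"
  table$fold_change <- fc
  table$direction <- factor(direction, levels = c("up", "down", "none"))
  table
}

#' Overlaps of named gene sets (Venn regions)
#'
#' Exact region cardinalities and memberships for two or three sets.
#'
#' @param sets Named list of 2-3 character vectors (gene ids; duplicates
#'   are dropped).
#' @return List with `regions` (data frame: `region`, `count`) and
#'   `members` (named list of the gene ids in each exclusive region and in
#'   each pairwise/global intersection).
#' @export
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, length(sets) <= 3,
            !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, ncol = length(sets),
                   dimnames = list(universe, nm))
  pattern <- apply(member, 1, function(r) paste(nm[r], collapse = "&"))
  exclusive <- split(universe, pattern)
  members <- exclusive
  # pairwise and (for 3 sets) global intersections, inclusive
  combs <- utils::combn(nm, 2, simplify = FALSE)
  if (length(nm) == 3) combs <- c(combs, list(nm))
  for (cm in combs) {
    members[[paste(cm, collapse = "&")]] <-
      Reduce(intersect, sets[cm])
  }
  regions <- data.frame(region = names(members),
                        count = lengths(members),
                        stringsAsFactors = FALSE)
  rownames(regions) <- NULL
  list(regions = regions, members = members)
}

#' Hypergeometric gene-set term enrichment
#'
#' Per term: upper-tail hypergeometric probability of drawing at least the
#' observed overlap, with population = background, successes = term genes
#' in the background, draws = query size; Benjamini-Hochberg adjustment
#' across tested terms.  Query genes absent from the background are dropped
#' with a warning.
#'
#' @param query Character vector of gene ids.
#' @param annotation Data frame with `gene_id`, `term_id` columns
#'   (GO/KEGG-style flat file).
#' @param background Character vector: the gene universe (e.g. all genes
#'   expressed in the experiment).
#' @return Data frame per term: `term_id`, `term_size`, `overlap`,
#'   `p_value`, `bh_p`, sorted by `p_value`.
#' @export
hypergeom_enrichment <- function(query, annotation, background) {
  stopifnot(all(c("gene_id", "term_id") %in% names(annotation)))
  query <- unique(query); background <- unique(background)
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) absent from background dropped: ",
            paste(head(outside, 5), collapse = ", "))
    query <- intersect(query, background)
  }
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  terms <- split(unique(ann[c("gene_id", "term_id")])$gene_id,
                 unique(ann[c("gene_id", "term_id")])$term_id)
  N <- length(background); n <- length(query)
  res <- lapply(names(terms), function(tm) {
    K <- length(terms[[tm]])
    ov <- length(intersect(terms[[tm]], query))
    data.frame(term_id = tm, term_size = K, overlap = ov,
               p_value = phyper(ov - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(term_id = character(), term_size = integer(),
                      overlap = integer(), p_value = numeric(), bh_p = numeric()))
  out$bh_p <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment with monotonicity enforcement; input order
#' preserved.  Thin validated wrapper over [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed,
#'   propagated).
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}
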