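# Permutation null by within-gene read redistribution, empirical p-values,
# and the significance and IP/input enrichment screens.

#' Redistribute a gene's reads uniformly at random
#'
#' Each permutation re-places every read at an independent uniform random
#' start within `[gene_start, gene_end - read_length]`, preserving read
#' lengths.  A read longer than the gene is pinned to the gene start with a
#' warning.  Deterministic given `seed`.
#'
#' @param gene Single-row interval table (the gene).
#' @param placements Read placements within the gene.
#' @param n Number of permutations.
#' @param seed Integer seed.
#' @return List of `n` `coverage_track` objects over the gene.
#' @export
permute_reads <- function(gene, placements, n, seed) {
  stopifnot(nrow(gene) == 1L, n >= 1)
  lens <- placements$end - placements$start
  L <- gene$end - gene$start
  if (any(lens > L)) {
    warning(sum(lens > L), " read(s) longer than gene ",
            if (!is.null(gene$gene_id)) gene$gene_id else "", "; placed at gene start")
  }
  with_seed(seed, lapply(seq_len(n), function(i) {
    npos <- pmax(L - lens + 1L, 1L)
    s <- gene$start + floor(runif(length(lens)) * npos)
    compute_coverage(
      data.frame(chrom = gene$chrom, start = as.integer(s),
                 end = as.integer(pmin(s + lens, gene$end)),
                 strand = "."),
      gene)
  }))
}

# Vectorised null statistics for one gene: for each of n permutations,
# the maximum base depth either gene-wide (scope "gene") or within each
# target interval (scope "peak").  Returns a matrix
# (length(target_starts) x n) for scope "peak", else a length-n vector.
# Uses the same placement model and seed policy as permute_reads.
null_max_depths <- function(gene, read_lengths, n, seed,
                            scope = c("gene", "peak"),
                            target_starts = NULL, target_ends = NULL) {
  scope <- match.arg(scope)
  L <- gene$end - gene$start
  R <- length(read_lengths)
  lens <- pmin(read_lengths, L)
  npos <- pmax(L - lens + 1L, 1L)
  # all n*R uniform draws up front (read-major per permutation), so the
  # null is a pure function of (seed, gene, read lengths)
  u <- with_seed(seed, runif(n * R))
  s_all <- floor(u * rep(npos, n))
  n_stat <- if (scope == "gene") 1L else length(target_starts)
  out <- matrix(0, nrow = n_stat, ncol = n)
  for (j in seq_len(n)) {
    s <- s_all[((j - 1L) * R + 1L):(j * R)]
    e <- pmin(s + lens, L)
    cov <- cumsum(tabulate(s + 1L, nbins = L + 1L) -
                    tabulate(e + 1L, nbins = L + 1L))
    if (scope == "gene") {
      out[1L, j] <- max(cov[seq_len(L)])
    } else {
      for (i in seq_len(n_stat)) {
        rows <- (target_starts[i] - gene$start + 1L):(target_ends[i] - gene$start)
        out[i, j] <- max(cov[rows])
      }
    }
  }
  if (scope == "gene") out[1L, ] else out
}

#' Empirical p-value from a permutation null
#'
#' Add-one estimator: `p = (1 + #{null >= observed}) / (1 + n)`.  Ties count
#' against the observation and p can never be exactly zero.
#'
#' @param observed_max_depth Observed statistic.
#' @param null Numeric vector of null statistics (length = number of
#'   permutations).
#' @return A probability in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed_max_depth, null) {
  stopifnot(length(null) >= 1)
  (1 + sum(null >= observed_max_depth)) / (1 + length(null))
}

#' Significance screen on called peaks
#'
#' A peak is significant when its empirical p-value is below `perm_alpha`
#' OR its maximum base depth reaches `min_max_depth` (the depth disjunct can
#' be disabled by setting `min_max_depth = Inf` in the params).
#'
#' @param peaks Peak table with `empirical_p` and `max_depth` columns.
#' @param params A `peak_params`.
#' @return `peaks` with a logical `significant` column.
#' @export
significance_screen <- function(peaks, params = peak_params()) {
  peaks$significant <- (!is.na(peaks$empirical_p) &
                          peaks$empirical_p < params$perm_alpha) |
    peaks$max_depth >= params$min_max_depth
  peaks
}

#' IP-versus-input enrichment screen
#'
#' Peak abundance in each library is the mean per-base depth within the
#' peak plus a pseudocount of 1, normalised per million mapped reads; the
#' fold change is the IP abundance over the input abundance and the peak
#' passes when the fold exceeds `ip_input_fc` (strict).  With no input
#' track the fold is `NA` and the peak passes by default with a warning.
#'
#' @param peaks Peak table.
#' @param ip_track,input_track `coverage_track`s of the enclosing region for
#'   the IP and input libraries (`input_track` may be `NULL`).
#' @param ip_libsize,input_libsize Total mapped reads of each library.
#' @param params A `peak_params`.
#' @return `peaks` with `ip_input_fold` and logical `input_pass` columns.
#' @export
ip_input_screen <- function(peaks, ip_track, input_track,
                            ip_libsize, input_libsize, params = peak_params()) {
  stopifnot(ip_libsize > 0)
  mean_depth <- function(track, s, e) {
    cs <- c(0, cumsum(as.numeric(track$depth)))
    a <- s - track$start; b <- e - track$start
    (cs[b + 1L] - cs[a + 1L]) / (b - a)
  }
  if (is.null(input_track)) {
    if (nrow(peaks)) warning("no input track: IP/input screen passes by default")
    peaks$ip_input_fold <- NA_real_
    peaks$input_pass <- TRUE
    return(peaks)
  }
  stopifnot(input_libsize > 0)
  ip_ab <- (mean_depth(ip_track, peaks$start, peaks$end) + 1) * 1e6 / ip_libsize
  in_ab <- (mean_depth(input_track, peaks$start, peaks$end) + 1) * 1e6 / input_libsize
  peaks$ip_input_fold <- if (nrow(peaks)) ip_ab / in_ab else numeric(0)
  peaks$input_pass <- peaks$ip_input_fold > params$ip_input_fc
  peaks
}

#' Full per-gene peak-calling pipeline over an annotation
#'
#' For every gene: IP coverage, baseline (gene mean depth floored at 1),
#' window-scan peak calling, read-redistribution permutation null and
#' empirical p-values, significance screen, and IP/input enrichment screen.
#' `final_pass` requires both screens.  Per-gene permutation seeds are
#' derived from `seed` by hashing the gene id ([stable_seed()]), so results
#' do not depend on gene order.
#'
#' @param ip_placements,input_placements Read-placement tables (input may be
#'   `NULL`).  PCR duplicates should already be removed (see
#'   [dedup_placements()]).
#' @param annotation A `gene_annotation`.
#' @param params A `peak_params`.
#' @param seed Integer base seed for the permutation null.
#' @return Peak table: `peak_id`, `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `max_depth`, `median_depth`, `read_count`, `empirical_p`,
#'   `ip_input_fold`, `significant`, `input_pass`, `final_pass`.
#' @export
call_peaks_genes <- function(ip_placements, input_placements, annotation,
                             params = peak_params(), seed = 1L) {
  genes <- annotation$genes
  ip_libsize <- nrow(ip_placements)
  input_libsize <- if (is.null(input_placements)) NA else nrow(input_placements)
  res <- lapply(seq_len(nrow(genes)), function(gi) {
    gene <- genes[gi, , drop = FALSE]
    ip_g <- ip_placements[ip_placements$chrom == gene$chrom &
                            ip_placements$start < gene$end &
                            ip_placements$end > gene$start, , drop = FALSE]
    if (!nrow(ip_g)) return(NULL)
    track <- compute_coverage(ip_g, gene)
    baseline <- max(1, mean(track$depth))
    pk <- call_peaks(track, baseline, params)
    if (!nrow(pk)) return(NULL)
    pk$strand <- gene$strand
    pk$gene_id <- gene$gene_id
    pk$read_count <- vapply(seq_len(nrow(pk)), function(i)
      sum(ip_g$start < pk$end[i] & ip_g$end > pk$start[i]), integer(1))
    null <- null_max_depths(gene, ip_g$end - ip_g$start, params$perm_n,
                            stable_seed(seed, gene$gene_id),
                            scope = params$null_scope,
                            target_starts = pk$start, target_ends = pk$end)
    pk$empirical_p <- if (params$null_scope == "gene")
      vapply(pk$max_depth, empirical_pvalue, numeric(1), null = null)
    else
      vapply(seq_len(nrow(pk)), function(i)
        empirical_pvalue(pk$max_depth[i], null[i, ]), numeric(1))
    pk <- significance_screen(pk, params)
    input_track <- if (is.null(input_placements)) NULL else
      compute_coverage(input_placements, gene)
    pk <- ip_input_screen(pk, track, input_track, ip_libsize, input_libsize,
                          params)
    pk
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), max_depth = numeric(),
                      median_depth = numeric(), open_rule = character(),
                      gene_id = character(), read_count = integer(),
                      empirical_p = numeric(), significant = logical(),
                      ip_input_fold = numeric(), input_pass = logical())
  out$final_pass <- out$significant & out$input_pass
  out$peak_id <- if (nrow(out)) paste0("peak_", seq_len(nrow(out))) else character(0)
  rownames(out) <- NULL
  out[, c("peak_id", "gene_id", "chrom", "start", "end", "strand",
          "max_depth", "median_depth", "read_count", "empirical_p",
          "ip_input_fold", "significant", "input_pass", "final_pass",
          "open_rule")]
}
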