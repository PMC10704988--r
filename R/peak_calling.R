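# Sliding-window peak calling.
#
# The caller scans a per-gene coverage track with fixed-width windows and
# runs a three-state automaton: a peak OPENS at the first window of a run of
# `consec_windows` windows that are all at least `start_ratio` times the
# baseline depth, or of a run whose median window depth exceeds
# `median_start`; it EXTENDS window by window while tracking the running
# maximum window depth; it CLOSES immediately before the first window of a
# run of `consec_windows` windows all below `end_fraction` of that running
# maximum (or at the end of the track).  Scanning resumes after the closing
# run, so peaks are disjoint by construction.

#' Parameters of the sliding-window peak caller
#'
#' @param window_size Window width in bp (default 5).
#' @param step Scan step in bp (default 5; the genome is tiled).
#' @param start_ratio Opening threshold as a multiple of the baseline depth
#'   (default 2.5).
#' @param consec_windows Run length (windows) required by both the opening
#'   and the closing rule (default 8).
#' @param median_start Alternative opening rule: a candidate run whose
#'   median window depth exceeds this value opens a peak regardless of the
#'   baseline (default 50).
#' @param end_fraction Closing threshold as a fraction of the running
#'   maximum window depth (default 0.04).
#' @param min_max_depth Peaks reaching this maximum base depth are kept as
#'   significant regardless of the permutation p-value (default 10).
#' @param perm_n Number of read-redistribution permutations (default 500).
#' @param perm_alpha Empirical p-value threshold (default 0.05).
#' @param ip_input_fc Required IP/input abundance fold change (default 4,
#'   exclusive).
#' @param null_scope Statistic of the permutation null: `"gene"` (default;
#'   maximum base depth anywhere in the gene per permutation, a scan-aware
#'   null) or `"peak"` (maximum depth within the observed peak interval).
#' @return A validated list of class `peak_params`.
#' @export
peak_params <- function(window_size = 5L, step = 5L, start_ratio = 2.5,
                        consec_windows = 8L, median_start = 50,
                        end_fraction = 0.04, min_max_depth = 10,
                        perm_n = 500L, perm_alpha = 0.05, ip_input_fc = 4,
                        null_scope = c("gene", "peak")) {
  p <- list(window_size = as.integer(window_size), step = as.integer(step),
            start_ratio = start_ratio, consec_windows = as.integer(consec_windows),
            median_start = median_start, end_fraction = end_fraction,
            min_max_depth = min_max_depth, perm_n = as.integer(perm_n),
            perm_alpha = perm_alpha, ip_input_fc = ip_input_fc,
            null_scope = match.arg(null_scope))
  stopifnot(p$window_size > 0, p$step > 0, p$start_ratio > 0,
            p$consec_windows > 0, p$median_start > 0, p$end_fraction > 0,
            p$end_fraction < 1, p$min_max_depth > 0, p$perm_n >= 1,
            p$perm_alpha > 0, p$perm_alpha < 1, p$ip_input_fc > 0)
  class(p) <- "peak_params"
  p
}

#' Mean depth per scan window of a coverage track
#'
#' Windows tile the track from its first base at `step` bp intervals; a
#' trailing partial window is included with its actual length.  A track
#' shorter than one window yields no windows.
#'
#' @param track A `coverage_track`.
#' @param params A `peak_params`.
#' @return Data frame with `start`, `end` (absolute, half-open) and `depth`
#'   (mean per-base depth of the window).
#' @export
window_depths <- function(track, params = peak_params()) {
  L <- track$end - track$start
  if (L < params$window_size)
    return(data.frame(start = integer(), end = integer(), depth = numeric()))
  s <- seq.int(0L, L - 1L, by = params$step)
  e <- pmin(s + params$window_size, L)
  cs <- c(0, cumsum(as.numeric(track$depth)))
  data.frame(start = track$start + s, end = track$start + e,
             depth = (cs[e + 1L] - cs[s + 1L]) / (e - s))
}

# TRUE at positions starting a run of k consecutive TRUEs.
run_start <- function(x, k) {
  n <- length(x)
  if (n < k) return(logical(n))
  cs <- c(0L, cumsum(as.integer(x)))
  out <- logical(n)
  i <- seq_len(n - k + 1L)
  out[i] <- (cs[i + k] - cs[i]) == k
  out
}

#' Call peaks on a coverage track
#'
#' Runs the window-scan automaton described in the package vignette.  Peak
#' boundaries snap to window edges; `max_depth` and `median_depth` are then
#' recomputed at base resolution from the track.
#'
#' @param track A `coverage_track` (typically one gene).
#' @param baseline Reference depth for the opening rule, `> 0`.  The
#'   per-gene pipeline uses the gene's mean per-base depth floored at 1.
#' @param params A `peak_params`.
#' @return Data frame of peaks: `chrom`, `start`, `end`, `strand`,
#'   `max_depth`, `median_depth`, `open_rule` (`"ratio"` or `"median"`).
#' @export
call_peaks <- function(track, baseline, params = peak_params()) {
  stopifnot(baseline > 0)
  wd <- window_depths(track, params)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), max_depth = numeric(),
                      median_depth = numeric(), open_rule = character())
  n <- nrow(wd)
  if (n == 0) return(empty)
  k <- params$consec_windows
  d <- wd$depth
  above <- d >= params$start_ratio * baseline
  open_ratio <- run_start(above, k)
  open_median <- logical(n)
  if (n >= k) {
    i <- seq_len(n - k + 1L)
    # median(run) > m needs at least half the run above m; compute the
    # exact run median only where that cheap condition holds
    cs <- c(0L, cumsum(as.integer(d > params$median_start)))
    cand <- i[(cs[i + k] - cs[i]) >= k %/% 2L]
    open_median[cand] <- vapply(cand, function(j)
      median(d[j:(j + k - 1L)]), numeric(1)) > params$median_start
  }
  peaks <- list()
  i <- 1L
  while (i <= n) {
    if (!(open_ratio[i] || open_median[i])) { i <- i + 1L; next }
    rule <- if (open_ratio[i]) "ratio" else "median"
    runmax <- d[i]
    j <- i + 1L
    close_at <- NA_integer_
    while (j <= n) {
      if (j + k - 1L <= n &&
          all(d[j:(j + k - 1L)] < params$end_fraction * runmax)) {
        close_at <- j
        break
      }
      runmax <- max(runmax, d[j])
      j <- j + 1L
    }
    last <- if (is.na(close_at)) n else close_at - 1L
    rel_s <- wd$start[i] - track$start
    rel_e <- wd$end[last] - track$start
    base_depths <- track$depth[(rel_s + 1L):rel_e]
    peaks[[length(peaks) + 1L]] <- data.frame(
      chrom = track$chrom, start = wd$start[i], end = wd$end[last],
      strand = ".", max_depth = max(base_depths),
      median_depth = median(base_depths), open_rule = rule,
      stringsAsFactors = FALSE)
    i <- if (is.na(close_at)) n + 1L else close_at + k
  }
  if (!length(peaks)) return(empty)
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out
}

#' Depth and read-count statistics of a peak interval
#'
#' @param interval Single-row interval table, contained in `track`.
#' @param track The `coverage_track` the peak was called on.
#' @param placements Read placements (for the overlap count).
#' @return List with `max_depth`, `median_depth`, `read_count`.
#' @export
peak_stats <- function(interval, track, placements) {
  stopifnot(nrow(interval) == 1L)
  if (interval$start < track$start || interval$end > track$end ||
      interval$chrom != track$chrom)
    stop("peak interval lies outside the coverage track")
  rel <- (interval$start - track$start + 1L):(interval$end - track$start)
  depths <- track$depth[rel]
  ov <- placements$chrom == interval$chrom &
    pmax(placements$start, interval$start) < pmin(placements$end, interval$end)
  list(max_depth = max(depths), median_depth = median(depths),
       read_count = sum(ov))
}
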