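# Independent reference implementations used as oracles.  These are written
# as plain, slow, straight-line code and share no helpers with the package.

# Per-base coverage by explicit counting.
ref_coverage <- function(placements, region) {
  depth <- integer(region$end - region$start)
  for (i in seq_len(region$end - region$start)) {
    pos <- region$start + i - 1L
    depth[i] <- sum(placements$chrom == region$chrom &
                      placements$start <= pos & placements$end > pos)
  }
  depth
}

# Window means by explicit slicing.
ref_window_means <- function(depth, window, step) {
  L <- length(depth)
  if (L < window) return(data.frame(start = integer(), depth = numeric()))
  starts <- seq(1L, L, by = step)
  data.frame(start = starts - 1L,
             depth = vapply(starts, function(s)
               mean(depth[s:min(s + window - 1L, L)]), numeric(1)))
}

# Straight-line transcription of the scan automaton, operating on a raw
# depth vector with 0-based output offsets.  Kept deliberately verbose and
# independent of the package implementation.
ref_call_peaks <- function(depth, baseline, window = 5L, step = 5L,
                           start_ratio = 2.5, consec = 8L,
                           median_start = 50, end_fraction = 0.04) {
  L <- length(depth)
  if (L < window) return(data.frame(start = integer(), end = integer(),
                                    max_depth = numeric()))
  w_start <- seq(0L, L - 1L, by = step)
  w_end <- pmin(w_start + window, L)
  nw <- length(w_start)
  wdep <- numeric(nw)
  for (i in seq_len(nw)) wdep[i] <- mean(depth[(w_start[i] + 1L):w_end[i]])
  peaks <- data.frame(start = integer(), end = integer(), max_depth = numeric())
  i <- 1L
  while (i <= nw) {
    opens <- FALSE
    if (i + consec - 1L <= nw) {
      run <- wdep[i:(i + consec - 1L)]
      if (all(run >= start_ratio * baseline)) opens <- TRUE
      if (median(run) > median_start) opens <- TRUE
    }
    if (!opens) { i <- i + 1L; next }
    running_max <- wdep[i]
    j <- i + 1L
    closed <- FALSE
    while (j <= nw) {
      if (j + consec - 1L <= nw) {
        nxt <- wdep[j:(j + consec - 1L)]
        if (all(nxt < end_fraction * running_max)) { closed <- TRUE; break }
      }
      running_max <- max(running_max, wdep[j])
      j <- j + 1L
    }
    last <- if (closed) j - 1L else nw
    pk_s <- w_start[i]; pk_e <- w_end[last]
    peaks <- rbind(peaks, data.frame(
      start = pk_s, end = pk_e,
      max_depth = max(depth[(pk_s + 1L):pk_e])))
    i <- if (closed) j + consec else nw + 1L
  }
  peaks
}

# Brute-force Benjamini-Hochberg step-up with monotonicity enforcement.
ref_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) adj[i] <- sorted[i] * m / i
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact upper-tail hypergeometric probability by enumeration.
ref_hyper_upper <- function(ov, K, N, n) {
  total <- choose(N, n)
  sum(vapply(ov:min(K, n), function(k)
    choose(K, k) * choose(N - K, n - k), numeric(1))) / total
}

# Two-pass Pearson correlation and its t-transform p-value.
ref_pearson <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Small random interval table on one chromosome.
random_intervals <- function(n, chrom = "chr1", max_pos = 10000L,
                             max_len = 500L) {
  s <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = chrom, start = s,
             end = s + sample.int(max_len, n, replace = TRUE),
             name = paste0("iv_", seq_len(n)), score = 0L,
             strand = sample(c("+", "-", "."), n, replace = TRUE),
             stringsAsFactors = FALSE)
}
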