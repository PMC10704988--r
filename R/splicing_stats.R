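# Splicing-ratio computation and differential testing of alternative
# splicing events between condition groups.

# Closed vocabulary of alternative-splicing event types.
AS_EVENT_TYPES <- c("cassetteExon", "ES", "MXE", "A5SS", "A3SS",
                    "A5SS&ES", "A3SS&ES", "5pMXE", "3pMXE")

#' Junction-based splicing ratio
#'
#' `alt / (alt + model)`: the fraction of junction reads supporting the
#' alternative isoform.  Event-samples with fewer than `min_total` total
#' junction reads are masked (`NA`) as too shallow to quantify.
#'
#' @param alt,model Non-negative junction read counts (vectorised).
#' @param min_total Minimum `alt + model` to report a ratio (default 10).
#' @return Numeric vector of ratios in `[0, 1]`, `NA` where masked.
#' @export
splicing_ratio <- function(alt, model, min_total = 10L) {
  stopifnot(all(alt >= 0, na.rm = TRUE), all(model >= 0, na.rm = TRUE))
  total <- alt + model
  ifelse(total >= min_total, alt / total, NA_real_)
}

# Equal-variance two-sample t-test that tolerates zero within-group
# variance: identical constant groups give t = 0 / p = 1, separated
# constant groups give t = +-Inf / p = 0.
.t_test_safe <- function(x, y, var_equal = TRUE) {
  tryCatch({
    tt <- t.test(x, y, var.equal = var_equal)
    list(t = unname(tt$statistic), p = tt$p.value)
  }, error = function(e) {
    # degenerate (essentially constant) data
    if (isTRUE(all.equal(mean(x), mean(y)))) list(t = 0, p = 1)
    else list(t = sign(mean(x) - mean(y)) * Inf, p = 0)
  })
}

#' Differential test of alternative-splicing events
#'
#' Per event, an unpaired two-tailed Student t-test (equal variance by
#' default) on per-sample splicing ratios, knockdown minus control, so a
#' positive t-value means the alternative isoform is more used in the
#' knockdown group.  Benjamini-Hochberg adjustment across all testable
#' events; significant when adjusted p <= `alpha_fdr`.  An event needs at
#' least two unmasked samples per group to be testable; untestable events
#' are reported with `NA` statistics.
#'
#' @param events Data frame with `event_id`, `gene_id`, `event_type` and
#'   per-sample count columns `model_<sample>` and `alt_<sample>`.
#' @param groups Named character vector mapping sample id to `"control"` or
#'   `"knockdown"`.
#' @param alpha_fdr FDR level (default 0.05).
#' @param min_total Masking threshold passed to [splicing_ratio()].
#' @param var_equal Classical Student test when `TRUE` (default); Welch
#'   otherwise.
#' @return Data frame with per-event `mean_ratio_control`,
#'   `mean_ratio_knockdown`, `t_value`, `p_value`, `bh_p`, `significant`.
#'   The implied raw-p cutoff (largest p among significant events) is
#'   attached as attribute `p_cutoff`.
#' @export
differential_asevents <- function(events, groups, alpha_fdr = 0.05,
                                  min_total = 10L, var_equal = TRUE) {
  stopifnot(all(groups %in% c("control", "knockdown")))
  bad_type <- setdiff(unique(events$event_type), AS_EVENT_TYPES)
  if (length(bad_type))
    stop("unknown event_type(s): ", paste(bad_type, collapse = ", "))
  samples <- names(groups)
  mcol <- paste0("model_", samples); acol <- paste0("alt_", samples)
  missing <- setdiff(c(mcol, acol), names(events))
  if (length(missing))
    stop("missing count column(s): ", paste(missing, collapse = ", "))
  ratios <- sapply(seq_along(samples), function(j)
    splicing_ratio(events[[acol[j]]], events[[mcol[j]]], min_total))
  ratios <- matrix(ratios, nrow = nrow(events))
  is_kd <- groups == "knockdown"
  res <- lapply(seq_len(nrow(events)), function(i) {
    kd <- ratios[i, is_kd]; ct <- ratios[i, !is_kd]
    kd <- kd[!is.na(kd)]; ct <- ct[!is.na(ct)]
    if (length(kd) < 2 || length(ct) < 2)
      return(list(mc = mean(ct), mk = mean(kd), t = NA_real_, p = NA_real_))
    tt <- .t_test_safe(kd, ct, var_equal)
    list(mc = mean(ct), mk = mean(kd), t = tt$t, p = tt$p)
  })
  out <- data.frame(
    event_id = events$event_id, gene_id = events$gene_id,
    event_type = events$event_type,
    mean_ratio_control = vapply(res, function(r) r$mc, numeric(1)),
    mean_ratio_knockdown = vapply(res, function(r) r$mk, numeric(1)),
    t_value = vapply(res, function(r) r$t, numeric(1)),
    p_value = vapply(res, function(r) r$p, numeric(1)),
    stringsAsFactors = FALSE)
  out$bh_p <- NA_real_
  testable <- !is.na(out$p_value)
  out$bh_p[testable] <- bh_fdr(out$p_value[testable])
  out$significant <- !is.na(out$bh_p) & out$bh_p <= alpha_fdr
  attr(out, "p_cutoff") <- if (any(out$significant))
    max(out$p_value[out$significant]) else NA_real_
  out
}

#' Tabulate significant events by type and direction of change
#'
#' Partitions significant events by the sign of the t-value: `increased`
#' (alternative isoform more used after knockdown, t > 0) versus
#' `decreased` (t < 0), per event type.
#'
#' @param results Output of [differential_asevents()].
#' @return Data frame with one row per event type in the vocabulary and
#'   integer columns `increased`, `decreased`.
#' @export
classify_event_direction <- function(results) {
  sig <- results[results$significant & !is.na(results$t_value), , drop = FALSE]
  out <- data.frame(event_type = AS_EVENT_TYPES,
                    increased = 0L, decreased = 0L, stringsAsFactors = FALSE)
  if (nrow(sig)) {
    up <- table(factor(sig$event_type[sig$t_value > 0], levels = AS_EVENT_TYPES))
    dn <- table(factor(sig$event_type[sig$t_value < 0], levels = AS_EVENT_TYPES))
    out$increased <- as.integer(up)
    out$decreased <- as.integer(dn)
  }
  out
}
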