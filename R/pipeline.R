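# Pipeline orchestration: differential-expression testing, stage wrappers,
# ground-truth evaluation and the one-shot end-to-end run.

#' Differential-expression test on a count matrix
#'
#' Fits the standard \pkg{DESeq2} negative-binomial model (knockdown versus
#' control) and returns the flat result table the downstream threshold
#' filter consumes.  Only the output table is used further; the filtering
#' semantics live in [deg_filter()].
#'
#' @param counts Integer matrix, genes x samples.
#' @param groups Named vector mapping sample id to `"control"`/`"knockdown"`.
#' @return Data frame: `gene_id`, `base_mean`, `fold_change` (linear,
#'   knockdown/control), `p_value`, `adj_p`.
#' @export
deg_test_counts <- function(counts, groups) {
  stopifnot(all(colnames(counts) %in% names(groups)))
  cond <- factor(groups[colnames(counts)], levels = c("control", "knockdown"))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = counts,
    colData = S4Vectors::DataFrame(condition = cond),
    design = ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds, contrast = c("condition", "knockdown", "control"))
  data.frame(gene_id = rownames(res), base_mean = res$baseMean,
             fold_change = 2^res$log2FoldChange, p_value = res$pvalue,
             adj_p = res$padj, stringsAsFactors = FALSE)
}

#' Match called peaks against planted truth
#'
#' A called peak and a truth peak match when their overlap covers at least
#' `min_reciprocal` of both intervals (reciprocal-overlap rule).
#'
#' @param called Peak table (rows with `chrom`, `start`, `end`).
#' @param truth Truth peak table.
#' @param min_reciprocal Reciprocal-overlap fraction (default 0.5).
#' @return List: `recall`, `precision`, logical vectors `truth_matched`
#'   and `called_matched`.
#' @export
match_peaks <- function(called, truth, min_reciprocal = 0.5) {
  match_one <- function(a_s, a_e, a_c, b) {
    ov <- pmin(a_e, b$end) - pmax(a_s, b$start)
    ok <- b$chrom == a_c & ov >= min_reciprocal * (a_e - a_s) &
      ov >= min_reciprocal * (b$end - b$start)
    any(ok)
  }
  tm <- vapply(seq_len(nrow(truth)), function(i)
    nrow(called) > 0 && match_one(truth$start[i], truth$end[i],
                                  truth$chrom[i], called), logical(1))
  cm <- vapply(seq_len(nrow(called)), function(i)
    nrow(truth) > 0 && match_one(called$start[i], called$end[i],
                                 called$chrom[i], truth), logical(1))
  list(recall = if (nrow(truth)) mean(tm) else NA_real_,
       precision = if (nrow(called)) mean(cm) else NA_real_,
       truth_matched = tm, called_matched = cm)
}

#' Peak-calling stage over files
#'
#' Reads IP/input placements (BED dialect or SAM) and a GTF, removes PCR
#' duplicates, runs [call_peaks_genes()] and writes the peak table (TSV)
#' plus a BED6 of final peaks.
#'
#' @param reads_ip,reads_input Paths (BED or SAM; input may be `NULL`).
#' @param gtf Path to the annotation.
#' @param outdir Output directory.
#' @param params A `peak_params`.
#' @param seed Base seed for the permutation null.
#' @return The peak table, invisibly; writes `peaks.tsv` and
#'   `peaks_final.bed` into `outdir`.
#' @export
run_callpeaks <- function(reads_ip, reads_input, gtf, outdir,
                          params = peak_params(), seed = 1L) {
  if (!file.exists(gtf)) stop("annotation not found: ", gtf)
  read_placements <- function(p) {
    if (grepl("\\.(sam|bam)$", p, ignore.case = TRUE)) read_sam_placements(p)
    else read_bed(p)
  }
  ip <- dedup_placements(read_placements(reads_ip))
  input <- if (is.null(reads_input)) NULL else
    dedup_placements(read_placements(reads_input))
  ann <- read_gtf(gtf)
  peaks <- call_peaks_genes(ip, input, ann, params, seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(peaks, file.path(outdir, "peaks.tsv"),
            list(rbpscan = as.character(utils::packageVersion("rbpscan")),
                 seed = seed))
  final <- peaks[peaks$final_pass, , drop = FALSE]
  final$name <- final$peak_id; final$score <- final$max_depth
  write_bed(final, file.path(outdir, "peaks_final.bed"))
  invisible(peaks)
}

#' Gene-set integration stage
#'
#' Computes the pairwise overlaps the study's Venn analyses describe:
#' differentially expressed genes against peak genes, regulated-splicing
#' genes against peak genes, and DEGs against regulated-splicing genes.
#' Warns when two non-empty sets share nothing (likely mismatched gene-id
#' namespaces).
#'
#' @param deg_genes,rasg_genes,peak_genes Character vectors of gene ids.
#' @param outdir Optional directory; when given, writes `venn_regions.tsv`
#'   and `venn_members.tsv`.
#' @return List of the three [overlap_sets()] results
#'   (`deg_peak`, `rasg_peak`, `deg_rasg`).
#' @export
run_integrate <- function(deg_genes, rasg_genes, peak_genes, outdir = NULL) {
  pairs <- list(
    deg_peak = list(DEG = deg_genes, peak = peak_genes),
    rasg_peak = list(RASG = rasg_genes, peak = peak_genes),
    deg_rasg = list(DEG = deg_genes, RASG = rasg_genes))
  out <- lapply(pairs, function(p) {
    if (all(lengths(p) > 0) &&
        length(intersect(p[[1]], p[[2]])) == 0)
      warning("zero overlap between non-empty sets ",
              paste(names(p), collapse = " and "),
              ": check gene-id namespaces")
    overlap_sets(p)
  })
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    regions <- do.call(rbind, lapply(names(out), function(nm)
      cbind(comparison = nm, out[[nm]]$regions)))
    write_tsv(regions, file.path(outdir, "venn_regions.tsv"))
    members <- do.call(rbind, lapply(names(out), function(nm) {
      m <- out[[nm]]$members
      if (!length(m)) return(NULL)
      data.frame(comparison = nm,
                 region = rep(names(m), lengths(m)),
                 gene_id = unlist(m, use.names = FALSE))
    }))
    if (is.null(members))
      members <- data.frame(comparison = character(), region = character(),
                            gene_id = character())
    write_tsv(members, file.path(outdir, "venn_members.tsv"))
  }
  out
}

#' One-shot end-to-end run on synthetic data
#'
#' Generates the synthetic dataset, reads every input back from disk, and
#' runs all stages: duplicate removal, peak calling with permutation and
#' IP/input screens, differential splicing, DESeq2 + threshold DEG
#' filtering, lncRNA candidate filtering, the cis-target screen, and the
#' gene-set overlaps.  All result tables are written under
#' `outdir/results` with provenance headers; the run is byte-reproducible
#' from (config, params).
#'
#' @param outdir Output directory (`inputs/` and `results/` are created).
#' @param config A `simulation_config`.
#' @param params A `peak_params`.
#' @param force Overwrite non-empty `outdir/inputs`.
#' @return Invisibly, a list with all stage results (`peaks`, `as_results`,
#'   `as_direction`, `deg_table`, `degs`, `lnc_filtered`, `colocated`,
#'   `coexpressed`, `cis`, `venn`), the `truth` tables, and `metrics`
#'   (peak recall/precision, AS power and empirical FDR, DEG recovery,
#'   cis recall).
#' @export
run_all <- function(outdir, config = simulation_config(),
                    params = peak_params(), force = FALSE) {
  inp <- file.path(outdir, "inputs"); resdir <- file.path(outdir, "results")
  sim <- simulate_dataset(config, inp, force = force)
  prov <- list(rbpscan = as.character(utils::packageVersion("rbpscan")),
               seed = config$seed)

  # ---- read everything back from disk (exercises the format readers)
  ann <- read_gtf(file.path(inp, "annotation.gtf"))
  ip <- read_bed(file.path(inp, "reads_ip.bed"))
  input <- read_bed(file.path(inp, "reads_input.bed"))
  counts_df <- read_tsv(file.path(inp, "counts.tsv"))
  counts <- as.matrix(counts_df[, -1]); rownames(counts) <- counts_df$gene_id
  fpkm_df <- read_tsv(file.path(inp, "fpkm.tsv"))
  fpkm_mat <- as.matrix(fpkm_df[, -1]); rownames(fpkm_mat) <- fpkm_df$gene_id
  smp <- read_tsv(file.path(inp, "samples.tsv"))
  groups <- stats::setNames(smp$group, smp$sample_id)
  events <- read_tsv(file.path(inp, "as_events.tsv"))
  votes <- read_tsv(file.path(inp, "lncrna_votes.tsv"))
  truth <- list(
    peaks = read_tsv(file.path(inp, "truth_peaks.tsv")),
    degs = read_tsv(file.path(inp, "truth_degs.tsv")),
    as = read_tsv(file.path(inp, "truth_as.tsv")),
    cis = read_tsv(file.path(inp, "truth_cis.tsv")))
  dir.create(resdir, showWarnings = FALSE, recursive = TRUE)

  # ---- peaks
  ip <- dedup_placements(ip); input <- dedup_placements(input)
  peaks <- call_peaks_genes(ip, input, ann, params, seed = config$seed)
  write_tsv(peaks, file.path(resdir, "peaks.tsv"), prov)
  final <- peaks[peaks$final_pass, , drop = FALSE]
  final$name <- final$peak_id; final$score <- round(final$max_depth)
  write_bed(final, file.path(resdir, "peaks_final.bed"))

  # ---- differential splicing
  as_res <- differential_asevents(events, groups)
  write_tsv(as_res, file.path(resdir, "as_results.tsv"), prov)
  as_dir <- classify_event_direction(as_res)
  write_tsv(as_dir, file.path(resdir, "as_direction.tsv"), prov)

  # ---- differential expression
  deg_table <- deg_test_counts(counts, groups)
  write_tsv(deg_table, file.path(resdir, "deg_table.tsv"), prov)
  degs <- deg_filter(deg_table)
  write_tsv(degs[degs$direction != "none", ],
            file.path(resdir, "deg_hits.tsv"), prov)

  # ---- lncRNA candidates and cis targets
  coding <- ann$genes[ann$genes$biotype == "coding", , drop = FALSE]
  lnc_filtered <- filter_lncrna_candidates(votes, coding)
  write_tsv(lnc_filtered, file.path(resdir, "lncrna_filtered.tsv"), prov)
  kept <- lnc_filtered[lnc_filtered$kept, , drop = FALSE]
  lnc_iv <- data.frame(gene_id = kept$gene_id, chrom = kept$chrom,
                       start = kept$start, end = kept$end,
                       stringsAsFactors = FALSE)
  colocated <- colocated_pairs(lnc_iv, coding)
  logexpr <- log2(fpkm_mat + 1)
  coexpressed <- if (nrow(colocated))
    coexpression_screen(colocated, logexpr) else
    cbind(colocated, pearson_r = numeric(0), p_value = numeric(0),
          reason = character(0), passes = logical(0))
  cis <- cis_targets(colocated, coexpressed)
  write_tsv(cis, file.path(resdir, "cis_pairs.tsv"), prov)

  # ---- integration
  deg_set <- degs$gene_id[degs$direction != "none"]
  rasg_set <- unique(as_res$gene_id[as_res$significant])
  peak_set <- unique(final$gene_id)
  venn <- run_integrate(deg_set, rasg_set, peak_set, resdir)

  # ---- metrics against the manifest
  pm <- match_peaks(final, truth$peaks)
  shifted <- truth$as$event_id
  declared <- as_res$event_id[as_res$significant]
  deg_rec <- if (nrow(truth$degs))
    mean(truth$degs$gene_id %in% deg_set) else NA_real_
  cis_rec <- if (nrow(truth$cis))
    mean(paste(truth$cis$lncrna_id, truth$cis$gene_id) %in%
           paste(cis$lncrna_id, cis$gene_id)) else NA_real_
  metrics <- list(
    peak_recall = pm$recall, peak_precision = pm$precision,
    n_final_peaks = nrow(final),
    as_power = if (length(shifted)) mean(shifted %in% declared) else NA_real_,
    as_fdr = if (length(declared)) mean(!declared %in% shifted) else 0,
    n_sig_events = length(declared),
    deg_recovery = deg_rec, n_deg = length(deg_set),
    cis_recall = cis_rec, n_cis = nrow(cis))
  invisible(list(peaks = peaks, final_peaks = final, as_results = as_res,
                 as_direction = as_dir, deg_table = deg_table, degs = degs,
                 lnc_filtered = lnc_filtered, colocated = colocated,
                 coexpressed = coexpressed, cis = cis, venn = venn,
                 truth = truth, metrics = metrics, outdir = outdir))
}
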