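# The synthetic-data generator and its ground-truth manifest.

test_that("generated datasets are byte-identical across runs with one seed", {
  cfg <- simulation_config(seed = 29, n_genes = 15, n_planted_peaks = 4,
                           n_lncrnas = 3, n_cis_pairs = 1,
                           n_as_events = 40, n_shifted_events = 8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1, force = TRUE, emit_sam = TRUE)
  simulate_dataset(cfg, d2, force = TRUE, emit_sam = TRUE)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # refusal to overwrite without force
  expect_error(simulate_dataset(cfg, d1), "force")
})

test_that("the annotation generator respects the config", {
  expect_equal(nrow(simulate_annotation(simulation_config(n_genes = 0,
                                                          n_planted_peaks = 0,
                                                          n_lncrnas = 0,
                                                          n_cis_pairs = 0))$genes),
               0L)
  cfg <- simulation_config(seed = 43, n_genes = 25, n_planted_peaks = 5,
                           n_lncrnas = 5, n_cis_pairs = 2)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$genes), 25L)
  expect_equal(sum(ann$genes$biotype == "noncoding"), 5L)
  # genes non-overlapping within each chromosome
  for (ch in unique(ann$genes$chrom)) {
    g <- ann$genes[ann$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  # gene count read back from the emitted GTF matches
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, f)
  expect_equal(nrow(read_gtf(f)$genes), 25L)
  # infeasible packing is an error
  expect_error(simulate_annotation(simulation_config(
    seed = 1, n_genes = 30, chrom_length = 50000L,
    n_lncrnas = 2, n_cis_pairs = 0, n_planted_peaks = 0)), "packing")
})

test_that("planted peaks carry the configured enrichment", {
  cfg <- simulation_config(seed = 47, n_genes = 1, n_planted_peaks = 1,
                           n_lncrnas = 0, n_cis_pairs = 0,
                           background_reads_per_kb = 60,
                           duplicate_fraction = 0)
  ann <- simulate_annotation(cfg)
  rip <- simulate_rip_reads(cfg, ann)
  expect_equal(nrow(rip$truth_peaks), 1L)
  g <- ann$genes[1, , drop = FALSE]
  tr_ip <- compute_coverage(rip$ip, g)
  tr_in <- compute_coverage(rip$input, g)
  sel <- (rip$truth_peaks$start - g$start + 1):(rip$truth_peaks$end - g$start)
  ratio <- mean(tr_ip$depth[sel]) / mean(tr_in$depth[sel])
  # expected depth ratio 1 + enrichment; required within 25% of the
  # configured concentration multiplier
  expect_lt(abs(ratio - cfg$peak_enrichment) / cfg$peak_enrichment, 0.25)
  # with enrichment "1x planted" the manifest still drives read placement,
  # and peak and background densities are exchangeable
  cfg0 <- simulation_config(seed = 47, n_genes = 1, n_planted_peaks = 1,
                            n_lncrnas = 0, n_cis_pairs = 0,
                            peak_enrichment = 1e-9,
                            background_reads_per_kb = 60,
                            duplicate_fraction = 0)
  rip0 <- simulate_rip_reads(cfg0, simulate_annotation(cfg0))
  g0 <- simulate_annotation(cfg0)$genes[1, , drop = FALSE]
  d0 <- compute_coverage(rip0$ip, g0)$depth
  sel0 <- (rip0$truth_peaks$start - g0$start + 1):(rip0$truth_peaks$end - g0$start)
  expect_lt(abs(mean(d0[sel0]) - mean(d0[-sel0])), 3)
  # manifest peak count equals the config
  cfg2 <- simulation_config(seed = 3, n_genes = 12, n_planted_peaks = 7,
                            n_lncrnas = 2, n_cis_pairs = 0)
  expect_equal(nrow(simulate_rip_reads(cfg2, simulate_annotation(cfg2))$truth_peaks),
               7L)
})

test_that("near-zero dispersion recovers the planted expression folds", {
  cfg <- simulation_config(seed = 53, n_genes = 40, dispersion = 0,
                           n_deg_up = 5, n_deg_down = 5,
                           n_lncrnas = 4, n_cis_pairs = 0)
  ann <- simulate_annotation(cfg)
  ex <- simulate_expression(cfg, ann)
  kd <- names(ex$groups)[ex$groups == "knockdown"]
  ct <- names(ex$groups)[ex$groups == "control"]
  for (i in seq_len(nrow(ex$truth_degs))) {
    g <- ex$truth_degs$gene_id[i]
    obs <- mean(ex$counts[g, kd]) / mean(ex$counts[g, ct])
    want <- if (ex$truth_degs$direction[i] == "up") cfg$deg_fold
            else 1 / cfg$deg_fold
    expect_lt(abs(obs - want) / want, 0.05)
  }
})

test_that("junction-count panels respect depth, masking and planted shifts", {
  cfg0 <- simulation_config(seed = 59, n_as_events = 30, n_shifted_events = 5,
                            junction_depth = 0)
  ase0 <- simulate_asevents(cfg0)
  groups <- setNames(rep(c("control", "knockdown"), each = 3),
                     c(paste0("ctrl_", 1:3), paste0("kd_", 1:3)))
  res0 <- differential_asevents(ase0$events, groups)
  expect_true(all(is.na(res0$p_value)))       # depth 0 masks everything
  # group ratio difference of shifted events tracks the planted delta
  cfg <- simulation_config(seed = 61, n_as_events = 100, n_shifted_events = 20,
                           junction_depth = 2000)
  ase <- simulate_asevents(cfg)
  res <- differential_asevents(ase$events, groups)
  m <- merge(res, ase$truth_shifted, by = "event_id")
  expect_equal(m$mean_ratio_knockdown - m$mean_ratio_control, m$delta,
               tolerance = 0.1)
  # infeasible shift is a config error at generation time
  expect_error(simulation_config(ratio_shift = 0.9), "ratio_shift")
})

test_that("every manifest id exists in the emitted files (cross-reference check)", {
  cfg <- simulation_config(seed = 67, n_genes = 20, n_planted_peaks = 5,
                           n_lncrnas = 4, n_cis_pairs = 2,
                           n_as_events = 50, n_shifted_events = 10)
  d <- withr::local_tempdir()
  out <- simulate_dataset(cfg, d, force = TRUE)
  ann <- read_gtf(file.path(d, "annotation.gtf"))
  peaks <- rbpscan:::read_tsv(file.path(d, "truth_peaks.tsv"))
  expect_true(all(peaks$gene_id %in% ann$genes$gene_id))
  degs <- rbpscan:::read_tsv(file.path(d, "truth_degs.tsv"))
  counts <- rbpscan:::read_tsv(file.path(d, "counts.tsv"))
  expect_true(all(degs$gene_id %in% counts$gene_id))
  tas <- rbpscan:::read_tsv(file.path(d, "truth_as.tsv"))
  events <- rbpscan:::read_tsv(file.path(d, "as_events.tsv"))
  expect_true(all(tas$event_id %in% events$event_id))
  cis <- rbpscan:::read_tsv(file.path(d, "truth_cis.tsv"))
  expect_true(all(c(cis$lncrna_id, cis$gene_id) %in% counts$gene_id))
  votes <- rbpscan:::read_tsv(file.path(d, "lncrna_votes.tsv"))
  expect_true(all(cis$lncrna_id %in% votes$gene_id))
  dup <- rbpscan:::read_tsv(file.path(d, "truth_duplicates.tsv"))
  reads <- rbind(read_bed(file.path(d, "reads_ip.bed")),
                 read_bed(file.path(d, "reads_input.bed")))
  expect_true(all(dup$read_id %in% reads$name))
})
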