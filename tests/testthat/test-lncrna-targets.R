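# lncRNA candidate filtering and the cis-target screens.

coding <- data.frame(gene_id = c("c1", "c2"), chrom = "chr1",
                     start = c(10000L, 50000L), end = c(12000L, 52000L))

mk_cand <- function(id, start, end, votes = rep("noncoding", 4), len = NULL) {
  d <- data.frame(transcript_id = id, chrom = "chr1", start = start, end = end,
                  stringsAsFactors = FALSE)
  if (!is.null(len)) d$length <- len
  d[c("cpc2", "lgc", "cnci", "cpat")] <- as.list(votes)
  d
}

test_that("lncRNA filter enforces every removal rule and its boundaries", {
  cand <- rbind(
    mk_cand("keep", 20000, 20500),                       # all rules pass
    mk_cand("short", 20000, 20199),                      # 199 bp -> removed
    mk_cand("edge200", 30000, 30200),                    # 200 bp -> kept
    mk_cand("vote", 20000, 20500, c("noncoding", "noncoding", "noncoding",
                                    "coding")),          # 3/4 -> removed
    mk_cand("overlap", 11000, 11500),                    # inside c1 -> removed
    mk_cand("near", 12500, 12999),                       # gap 500 -> removed
    mk_cand("edge1kb", 13000, 13400))                    # gap 1000 -> kept
  out <- filter_lncrna_candidates(cand, coding)
  expect_equal(out$transcript_id[out$kept], c("keep", "edge200", "edge1kb"))
  expect_equal(out$reason[out$transcript_id == "short"], "short")
  expect_equal(out$reason[out$transcript_id == "vote"], "coding_vote")
  expect_equal(out$reason[out$transcript_id == "overlap"], "overlaps_coding")
  expect_equal(out$reason[out$transcript_id == "near"], "near_gene")
  # incomplete votes are rejected with their own reason
  cand2 <- mk_cand("nav", 20000, 20500)
  cand2$cpat <- NA
  out2 <- filter_lncrna_candidates(cand2, coding)
  expect_false(out2$kept)
  expect_equal(out2$reason, "incomplete_votes")
  # exonic length overrides the interval span when provided
  cand3 <- mk_cand("spliced", 20000, 25000, len = 150L)
  expect_false(filter_lncrna_candidates(cand3, coding)$kept)
})

test_that("the filter result is invariant to candidate order", {
  set.seed(19)
  cand <- do.call(rbind, lapply(1:20, function(i)
    mk_cand(paste0("t", i), 15000 + 700 * i, 15000 + 700 * i + sample(150:600, 1),
            sample(c("noncoding", "coding"), 4, replace = TRUE,
                   prob = c(0.8, 0.2)))))
  a <- filter_lncrna_candidates(cand, coding)
  perm <- sample(nrow(cand))
  b <- filter_lncrna_candidates(cand[perm, ], coding)
  expect_equal(b$kept, a$kept[perm])
  expect_equal(b$reason, a$reason[perm])
})

test_that("co-location respects the inclusive 100-kb boundary", {
  lnc <- data.frame(gene_id = "L", chrom = "chr1",
                    start = 200000L, end = 201000L)
  exact <- data.frame(gene_id = "gA", chrom = "chr1",
                      start = 301000L, end = 302000L)   # gap exactly 100000
  over <- data.frame(gene_id = "gB", chrom = "chr1",
                     start = 301001L, end = 302000L)    # gap 100001
  expect_equal(colocated_pairs(lnc, exact)$gene_id, "gA")
  expect_equal(nrow(colocated_pairs(lnc, over)), 0L)
  expect_equal(colocated_pairs(lnc, exact)$genomic_distance, 100000L)
})

test_that("co-located pairs equal the brute-force all-pairs oracle", {
  set.seed(23)
  lnc <- random_intervals(50, max_pos = 5e6, max_len = 2000)
  names(lnc)[names(lnc) == "name"] <- "gene_id"
  lnc$chrom <- sample(c("chr1", "chr2"), 50, replace = TRUE)
  genes <- random_intervals(200, max_pos = 5e6, max_len = 20000)
  names(genes)[names(genes) == "name"] <- "gene_id"
  genes$gene_id <- paste0("g_", seq_len(200))
  genes$chrom <- sample(c("chr1", "chr2"), 200, replace = TRUE)
  got <- colocated_pairs(lnc, genes, window = 100000L)
  want <- 0L
  for (i in 1:50) for (j in 1:200) {
    if (lnc$chrom[i] != genes$chrom[j]) next
    gap <- max(max(lnc$start[i], genes$start[j]) -
                 min(lnc$end[i], genes$end[j]), 0)
    if (gap <= 100000) want <- want + 1L
  }
  expect_equal(nrow(got), want)
  # tightening the window never grows the output
  expect_lte(nrow(colocated_pairs(lnc, genes, window = 10000L)), nrow(got))
})

test_that("co-expression screen matches the textbook t-transform", {
  expr <- rbind(L = c(2.1, 3.9, 6.2, 7.8, 10.1, 12.2),
                G = c(1.0, 2.2, 2.9, 4.1, 5.2, 5.8),
                F = c(5.0, 5.0, 5.0, 5.0, 5.0, 5.0),
                O = c(1, -1, 1, -1, 1, -1))
  colnames(expr) <- paste0("s", 1:6)
  pairs <- data.frame(lncrna_id = "L", gene_id = c("G", "F", "O"))
  out <- coexpression_screen(pairs, expr)
  ref <- ref_pearson(expr["L", ], expr["G", ])
  expect_equal(out$pearson_r[1], ref$r, tolerance = 1e-10)
  expect_equal(out$p_value[1], ref$p, tolerance = 1e-6)
  expect_true(out$passes[1])
  expect_equal(out$reason[2], "zero_variance")       # flat partner fails
  expect_false(out$passes[2])
  expect_false(out$passes[3])                        # |r| ~ 0
  # identical vectors: r = 1, passes
  expr2 <- rbind(A = 1:6, B = 1:6); colnames(expr2) <- paste0("s", 1:6)
  out2 <- coexpression_screen(data.frame(lncrna_id = "A", gene_id = "B"), expr2)
  expect_equal(out2$pearson_r, 1)
  expect_true(out2$passes)
  # r computed here equals the two-pass formula on random vectors
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    e <- rbind(a = x, b = y); colnames(e) <- paste0("s", 1:8)
    o <- coexpression_screen(data.frame(lncrna_id = "a", gene_id = "b"), e)
    expect_equal(o$pearson_r, ref_pearson(x, y)$r, tolerance = 1e-10)
  }
})

test_that("cis targets are the intersection of both screens", {
  colocated <- data.frame(lncrna_id = c("L1", "L2"), gene_id = c("g1", "g2"),
                          genomic_distance = c(500L, 900L))
  coexpr <- data.frame(lncrna_id = c("L1", "L3"), gene_id = c("g1", "g3"),
                       pearson_r = c(0.95, 0.99), p_value = c(0.001, 0.0001),
                       passes = c(TRUE, TRUE))
  out <- cis_targets(colocated, coexpr)
  expect_equal(out$lncrna_id, "L1")    # L2 fails correlation, L3 distance
  expect_equal(out$genomic_distance, 500L)
  # tightening r_cut never grows the passing set
  expr <- matrix(rnorm(60), nrow = 10,
                 dimnames = list(paste0("m", 1:10), paste0("s", 1:6)))
  prs <- data.frame(lncrna_id = rep("m1", 9), gene_id = paste0("m", 2:10))
  loose <- coexpression_screen(prs, expr, r_cut = 0.3)
  tight <- coexpression_screen(prs, expr, r_cut = 0.8)
  expect_true(all(which(tight$passes) %in% which(loose$passes)))
})

test_that("planted cis pairs are recovered from a strongly correlated fixture", {
  cfg <- simulation_config(seed = 41, n_genes = 80, n_lncrnas = 12,
                           n_cis_pairs = 10, cis_correlation = 0.99,
                           n_deg_up = 0, n_deg_down = 0)
  ann <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, ann)
  expect_equal(nrow(expr$truth_cis), 10L)
  coding_g <- ann$genes[ann$genes$biotype == "coding", ]
  lnc <- ann$genes[ann$genes$biotype == "noncoding",
                   c("gene_id", "chrom", "start", "end")]
  coloc <- colocated_pairs(lnc, coding_g)
  coex <- coexpression_screen(coloc, log2(expr$fpkm + 1))
  cis <- cis_targets(coloc, coex)
  truth_key <- paste(expr$truth_cis$lncrna_id, expr$truth_cis$gene_id)
  got_key <- paste(cis$lncrna_id, cis$gene_id)
  expect_gte(mean(truth_key %in% got_key), 0.9)
})
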