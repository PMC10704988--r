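# Synthetic-data generator: every input the pipeline consumes, with a
# machine-readable ground-truth manifest.
#
# The generator emulates the study design the pipeline was built for:
# an IP library with localised read enrichment over a sparse genic
# background plus a matched input library; 3-versus-3 replicate expression
# with planted fold changes and planted lncRNA-mRNA co-expression; and
# replicate junction counts with planted splicing-ratio shifts.  All
# randomness flows from one seed; identical config + seed give
# byte-identical files.

#' Configuration of the synthetic-data generator
#'
#' Defaults describe the standard simulated experiment: paired 150-nt
#' reads, three biological replicates per group, eight-fold IP enrichment
#' over planted binding sites, four-fold planted expression changes and a
#' 0.3 planted splicing-ratio shift.
#'
#' @param seed Integer master seed.
#' @param n_genes Number of genes in the annotation.
#' @param gene_length_range Min/max gene length in bp.
#' @param n_chroms Number of synthetic chromosomes (1-3).
#' @param chrom_length Optional fixed chromosome length in bp; an error is
#'   raised if the genes do not fit.  `NULL` (default) sizes chromosomes to
#'   their content.
#' @param n_planted_peaks Number of genes carrying one planted binding site
#'   each.
#' @param peak_enrichment Fold concentration of IP reads within a planted
#'   peak relative to the local background (default 8).
#' @param peak_length Planted peak length in bp (default 1500,
#'   window-alignable).
#' @param background_reads_per_kb Genic background read density per library
#'   (default 15, about 2.2x per-base depth: sparse, punctate coverage as
#'   in an IP library).
#' @param read_length Read length in bp (default 150).
#' @param duplicate_fraction Fraction of reads duplicated in place to plant
#'   PCR duplicates (default 0.05).
#' @param n_replicates_per_group Biological replicates per group (default 3).
#' @param n_deg_up,n_deg_down Planted up-/down-regulated genes.
#' @param deg_fold Planted expression fold change (default 4).
#' @param dispersion Negative-binomial dispersion of simulated counts
#'   (default 0.05).
#' @param n_as_events Total alternative-splicing events.
#' @param n_shifted_events Events with a planted ratio shift in the
#'   knockdown group.
#' @param ratio_shift Planted splicing-ratio shift (default 0.3; signs
#'   alternate between events).
#' @param junction_depth Total junction reads per event and sample
#'   (default 100).
#' @param n_lncrnas Noncoding genes in the annotation.
#' @param n_cis_pairs Planted lncRNA-mRNA cis pairs (co-located and
#'   co-expressed).
#' @param cis_correlation Target Pearson correlation of planted cis pairs
#'   on the log-expression scale (default 0.9).
#' @param vote_error_rate Probability that a coding-potential predictor
#'   vote contradicts the true label (default 0).
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_genes = 150L,
                              gene_length_range = c(9000L, 11000L),
                              n_chroms = 2L, chrom_length = NULL,
                              n_planted_peaks = 20L, peak_enrichment = 8,
                              peak_length = 1500L,
                              background_reads_per_kb = 15,
                              read_length = 150L,
                              duplicate_fraction = 0.05,
                              n_replicates_per_group = 3L,
                              n_deg_up = 8L, n_deg_down = 8L, deg_fold = 4,
                              dispersion = 0.05,
                              n_as_events = 1000L, n_shifted_events = 100L,
                              ratio_shift = 0.3, junction_depth = 100L,
                              n_lncrnas = 8L, n_cis_pairs = 4L,
                              cis_correlation = 0.9,
                              vote_error_rate = 0) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 0, length(cfg$gene_length_range) == 2,
            cfg$gene_length_range[1] > 0,
            cfg$gene_length_range[1] <= cfg$gene_length_range[2],
            cfg$n_chroms >= 1, cfg$n_chroms <= 3,
            cfg$n_planted_peaks >= 0, cfg$n_planted_peaks <= cfg$n_genes,
            cfg$peak_enrichment > 0, cfg$peak_length > 0,
            cfg$background_reads_per_kb > 0, cfg$read_length > 0,
            cfg$duplicate_fraction >= 0, cfg$duplicate_fraction < 1,
            cfg$n_replicates_per_group >= 2,
            cfg$n_deg_up >= 0, cfg$n_deg_down >= 0, cfg$deg_fold > 1,
            cfg$dispersion >= 0, cfg$n_as_events >= 0,
            cfg$n_shifted_events <= cfg$n_as_events,
            cfg$junction_depth >= 0,
            cfg$n_lncrnas >= 0, cfg$n_lncrnas < max(cfg$n_genes, 1),
            cfg$n_cis_pairs <= cfg$n_lncrnas,
            cfg$cis_correlation > 0, cfg$cis_correlation < 1,
            cfg$vote_error_rate >= 0, cfg$vote_error_rate <= 1)
  if (cfg$ratio_shift < 0 || cfg$ratio_shift > 0.8)
    stop("ratio_shift must lie in [0, 0.8] to keep ratios inside [0, 1]")
  if (cfg$peak_length > cfg$gene_length_range[1] / 2)
    stop("peak_length must be at most half the shortest gene")
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a gene annotation
#'
#' Places non-overlapping genes on 1-3 synthetic chromosomes.  Inter-gene
#' gaps are drawn from a mixture spanning both sides of the 1-kb
#' nearest-gene and 100-kb co-location thresholds.  `n_lncrnas` genes are
#' noncoding; the first `n_cis_pairs` of them are guaranteed a coding
#' neighbour between 2 kb and 60 kb away (so they survive the
#' nearest-gene filter and are co-location candidates), and two decoy
#' lncRNAs are placed closer than 1 kb to a coding gene.
#'
#' @param config A `simulation_config`.
#' @return A `gene_annotation`; the lncRNA layout is attached as attribute
#'   `lnc_info` (data frame: `gene_id`, `category`).
#' @export
simulate_annotation <- function(config) {
  if (config$n_genes == 0) return(empty_annotation())
  with_seed(sub_seed(config$seed, 1L), {
    n <- config$n_genes
    # lengths on a 5-bp grid so terminal planted peaks stay window-aligned
    len_pool <- seq(config$gene_length_range[1], config$gene_length_range[2],
                    by = 5L)
    lens <- len_pool[sample.int(length(len_pool), n, replace = TRUE)]
    # lncRNA slots: interior, pairwise non-adjacent
    n_lnc <- config$n_lncrnas
    lnc_idx <- integer(0)
    if (n_lnc > 0) {
      cand <- seq(2L, n - 1L, by = 2L)
      lnc_idx <- sort(cand[sample.int(length(cand), n_lnc)])
    }
    category <- rep("coding", n)
    category[lnc_idx] <- "lnc_far"
    if (config$n_cis_pairs > 0)
      category[lnc_idx[seq_len(config$n_cis_pairs)]] <- "lnc_cis"
    n_decoy <- min(2L, n_lnc - config$n_cis_pairs)
    if (n_decoy > 0)
      category[rev(lnc_idx)[seq_len(n_decoy)]] <- "lnc_near"

    # preceding gap per gene, by category of the gene (and of its predecessor)
    draw_gap <- function(cat) {
      switch(cat,
             lnc_cis = sample(2000:60000, 1),
             lnc_near = sample(100:900, 1),
             lnc_far = sample(c(sample(1500:5000, 1), sample(20000:90000, 1),
                                sample(110000:200000, 1)), 1),
             # coding: mixture crossing the 1-kb and 100-kb thresholds
             sample(c(sample(200:900, 1), sample(2000:9000, 1),
                      sample(30000:90000, 1), sample(110000:180000, 1)),
                    1, prob = c(0.1, 0.5, 0.3, 0.1)))
    }
    chrom_of <- sort(rep_len(paste0("chr", seq_len(config$n_chroms)), n))
    start <- integer(n); end <- integer(n)
    pos <- stats::setNames(rep(0L, config$n_chroms),
                           paste0("chr", seq_len(config$n_chroms)))
    for (i in seq_len(n)) {
      gap <- draw_gap(category[i])
      # an lncRNA's category controls its preceding gap; keep the
      # following gap from undercutting it (min of the two gaps is what
      # the nearest-gene filter sees)
      if (i > 1 && chrom_of[i] == chrom_of[i - 1] &&
          category[i - 1] %in% c("lnc_cis", "lnc_far"))
        gap <- max(gap, 2000L)
      start[i] <- pos[chrom_of[i]] + gap
      end[i] <- start[i] + lens[i]
      pos[chrom_of[i]] <- end[i]
    }
    if (!is.null(config$chrom_length) && any(pos > config$chrom_length))
      stop("infeasible packing: genes exceed chrom_length on ",
           paste(names(pos)[pos > config$chrom_length], collapse = ", "))
    gene_id <- sprintf("gene_%03d", seq_len(n))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    biotype <- ifelse(startsWith(category, "lnc"), "noncoding", "coding")
    genes <- data.frame(gene_id = gene_id, chrom = chrom_of, start = start,
                        end = end, strand = strand, biotype = biotype,
                        stringsAsFactors = FALSE)
    # one or two transcripts per gene, 1-3 exons spanning the gene
    tx_list <- list(); ex_list <- list()
    for (i in seq_len(n)) {
      n_tx <- sample(1:2, 1)
      for (t in seq_len(n_tx)) {
        tid <- sprintf("%s_t%d", gene_id[i], t)
        n_ex <- sample(1:3, 1)
        if (n_ex == 1) {
          ex_s <- start[i]; ex_e <- end[i]
        } else {
          cuts <- sort(sample(seq(start[i] + 200L, end[i] - 200L, by = 50L),
                              2L * (n_ex - 1L)))
          ex_s <- c(start[i], cuts[seq(2, length(cuts), by = 2)])
          ex_e <- c(cuts[seq(1, length(cuts), by = 2)], end[i])
        }
        tx_list[[length(tx_list) + 1L]] <- data.frame(
          transcript_id = tid, gene_id = gene_id[i], chrom = chrom_of[i],
          start = start[i], end = end[i], strand = strand[i],
          length = as.integer(sum(ex_e - ex_s)), stringsAsFactors = FALSE)
        ex_list[[length(ex_list) + 1L]] <- data.frame(
          transcript_id = tid, gene_id = gene_id[i], chrom = chrom_of[i],
          start = as.integer(ex_s), end = as.integer(ex_e),
          strand = strand[i], stringsAsFactors = FALSE)
      }
    }
    ann <- gene_annotation(genes, do.call(rbind, tx_list), do.call(rbind, ex_list))
    attr(ann, "lnc_info") <- data.frame(gene_id = gene_id[lnc_idx],
                                        category = category[lnc_idx],
                                        stringsAsFactors = FALSE)
    ann
  })
}

#' Simulate IP and input read placements with planted peaks
#'
#' Input reads are uniform within each gene at `background_reads_per_kb`;
#' IP reads are an independent draw of the same background plus
#' `peak_enrichment`-fold concentrated reads uniform within each planted
#' peak, so the expected IP/input depth ratio inside a peak is
#' `1 + peak_enrichment`.  One peak is planted per selected gene, occupying
#' the terminal `peak_length` bp of the transcription unit (emulating the
#' terminal-exon/3'UTR bias of many RBP binding sites, and giving the
#' ground truth an unambiguous downstream boundary); gene lengths are
#' 5-bp-gridded, so peaks are window-aligned.  A `duplicate_fraction` of
#' reads is duplicated in place to plant PCR duplicates.
#'
#' @param config A `simulation_config`.
#' @param annotation A `gene_annotation` from [simulate_annotation()].
#' @return List: `ip`, `input` (placement tables with `name` read ids),
#'   `truth_peaks` (`gene_id`, `chrom`, `start`, `end`), `duplicates`
#'   (read ids planted as duplicates in either library).
#' @export
simulate_rip_reads <- function(config, annotation) {
  genes <- annotation$genes
  with_seed(sub_seed(config$seed, 2L), {
    peak_genes <- if (config$n_planted_peaks > 0)
      sort(sample(genes$gene_id, config$n_planted_peaks)) else character(0)
    truth <- lapply(peak_genes, function(g) {
      gr <- genes[genes$gene_id == g, ]
      data.frame(gene_id = g, chrom = gr$chrom,
                 start = gr$end - config$peak_length, end = gr$end,
                 stringsAsFactors = FALSE)
    })
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(gene_id = character(), chrom = character(),
                 start = integer(), end = integer())
    place_uniform <- function(n, lo, hi_start, chrom, strand, prefix) {
      if (n == 0) return(NULL)
      s <- lo + floor(runif(n) * (hi_start - lo + 1L))
      data.frame(chrom = chrom, start = as.integer(s),
                 end = as.integer(s + config$read_length),
                 name = sprintf("%s_r%04d", prefix, seq_len(n)),
                 score = 0L, strand = strand, stringsAsFactors = FALSE)
    }
    sim_library <- function(lib) {
      out <- lapply(seq_len(nrow(genes)), function(i) {
        g <- genes[i, ]
        L <- g$end - g$start
        if (L < config$read_length) return(NULL)
        n_bg <- rpois(1, config$background_reads_per_kb * L / 1000)
        bg <- place_uniform(n_bg, g$start, g$end - config$read_length,
                            g$chrom, g$strand,
                            paste0(lib, "_", g$gene_id, "_bg"))
        pk <- NULL
        if (lib == "ip" && g$gene_id %in% truth$gene_id) {
          tr <- truth[truth$gene_id == g$gene_id, ]
          n_pk <- rpois(1, config$peak_enrichment *
                          config$background_reads_per_kb *
                          config$peak_length / 1000)
          pk <- place_uniform(n_pk, tr$start,
                              tr$end - config$read_length,
                              g$chrom, g$strand,
                              paste0(lib, "_", g$gene_id, "_pk"))
        }
        rbind(bg, pk)
      })
      do.call(rbind, out)
    }
    ip <- sim_library("ip")
    input <- sim_library("input")
    plant_dups <- function(x) {
      n_dup <- floor(config$duplicate_fraction * nrow(x))
      if (n_dup == 0) return(list(x = x, ids = character(0)))
      pick <- sample(nrow(x), n_dup)
      dup <- x[pick, , drop = FALSE]
      dup$name <- paste0(dup$name, "_dup")
      list(x = rbind(x, dup), ids = dup$name)
    }
    dip <- plant_dups(ip); dinput <- plant_dups(input)
    rownames(dip$x) <- rownames(dinput$x) <- NULL
    list(ip = dip$x, input = dinput$x, truth_peaks = truth,
         duplicates = c(dip$ids, dinput$ids))
  })
}

#' Simulate replicate expression with planted fold changes and cis pairs
#'
#' Negative-binomial counts over lognormal baseline means for
#' `2 * n_replicates_per_group` samples (control then knockdown).  Planted
#' up-/down-regulated genes have their knockdown mean multiplied/divided by
#' `deg_fold`.  Each planted cis pair (a cis-compatible lncRNA and its
#' nearest coding gene within 100 kb) shares a per-sample latent factor
#' scaled so the log-expression correlation targets `cis_correlation`.
#'
#' @param config A `simulation_config`.
#' @param annotation Annotation from [simulate_annotation()] (its
#'   `lnc_info` attribute selects the cis-compatible lncRNAs).
#' @return List: `counts` and `fpkm` matrices (genes x samples), `groups`
#'   (named vector control/knockdown), `truth_degs` (`gene_id`,
#'   `direction`, `fold`), `truth_cis` (`lncrna_id`, `gene_id`).
#' @export
simulate_expression <- function(config, annotation) {
  genes <- annotation$genes
  n <- nrow(genes)
  reps <- config$n_replicates_per_group
  samples <- c(paste0("ctrl_", seq_len(reps)), paste0("kd_", seq_len(reps)))
  groups <- stats::setNames(rep(c("control", "knockdown"), each = reps), samples)
  lnc_info <- attr(annotation, "lnc_info")
  with_seed(sub_seed(config$seed, 3L), {
    base <- rlnorm(n, meanlog = log(300), sdlog = 0.7)
    names(base) <- genes$gene_id
    # planted cis pairs: cis-compatible lncRNA + nearest coding gene <= 100 kb
    cis <- NULL
    if (!is.null(lnc_info) && any(lnc_info$category == "lnc_cis")) {
      for (lg in lnc_info$gene_id[lnc_info$category == "lnc_cis"]) {
        li <- genes[genes$gene_id == lg, ]
        coding <- genes[genes$biotype == "coding" & genes$chrom == li$chrom, ]
        gap <- pmax(pmax(coding$start, li$start) - pmin(coding$end, li$end), 0L)
        ok <- which(gap <= 100000L)
        if (!length(ok)) next
        cis <- rbind(cis, data.frame(lncrna_id = lg,
                                     gene_id = coding$gene_id[ok[which.min(gap[ok])]],
                                     stringsAsFactors = FALSE))
      }
    }
    if (is.null(cis))
      cis <- data.frame(lncrna_id = character(), gene_id = character())
    # planted DEGs among coding genes not in a cis pair
    pool <- setdiff(genes$gene_id[genes$biotype == "coding"], cis$gene_id)
    deg_ids <- sample(pool, min(config$n_deg_up + config$n_deg_down, length(pool)))
    up_ids <- head(deg_ids, config$n_deg_up)
    down_ids <- setdiff(deg_ids, up_ids)
    truth_degs <- data.frame(
      gene_id = c(up_ids, down_ids),
      direction = rep(c("up", "down"), c(length(up_ids), length(down_ids))),
      fold = rep(config$deg_fold, length(up_ids) + length(down_ids)),
      stringsAsFactors = FALSE)
    # per-sample mean matrix
    mu <- matrix(base, nrow = n, ncol = length(samples),
                 dimnames = list(genes$gene_id, samples))
    kd <- groups == "knockdown"
    mu[up_ids, kd] <- mu[up_ids, kd] * config$deg_fold
    mu[down_ids, kd] <- mu[down_ids, kd] / config$deg_fold
    # latent factor per cis pair: var chosen so log-scale r ~ cis_correlation
    noise_var <- config$dispersion + 1 / mean(base)
    sd_z <- sqrt(config$cis_correlation / (1 - config$cis_correlation) * noise_var)
    for (i in seq_len(nrow(cis))) {
      z <- rnorm(length(samples), 0, sd_z)
      f <- exp(z - sd_z^2 / 2)
      mu[cis$lncrna_id[i], ] <- mu[cis$lncrna_id[i], ] * f
      mu[cis$gene_id[i], ] <- mu[cis$gene_id[i], ] * f
    }
    counts <- if (config$dispersion > 0)
      matrix(rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
             nrow = n, dimnames = dimnames(mu))
    else  # degenerate limit: counts equal their means exactly
      round(mu)
    lens <- gene_lengths(annotation)
    fpkm_mat <- fpkm(counts, lens, pmax(colSums(counts), 1))
    list(counts = counts, fpkm = fpkm_mat, groups = groups,
         truth_degs = truth_degs, truth_cis = cis)
  })
}

#' Simulate replicate junction counts with planted splicing shifts
#'
#' Per event and sample, alternative-isoform junction reads are
#' `Binomial(junction_depth, ratio)` and model reads make up the rest.
#' Null events share one ratio across groups; shifted events add
#' `ratio_shift` (alternating sign) in the knockdown group.  Event types
#' are drawn from the nine-type vocabulary.
#'
#' @param config A `simulation_config`.
#' @param annotation Optional annotation supplying gene ids (synthetic ids
#'   otherwise).
#' @return List: `events` (table with `model_*`/`alt_*` columns),
#'   `truth_shifted` (`event_id`, `delta`).
#' @export
simulate_asevents <- function(config, annotation = NULL) {
  reps <- config$n_replicates_per_group
  samples <- c(paste0("ctrl_", seq_len(reps)), paste0("kd_", seq_len(reps)))
  m <- config$n_as_events
  with_seed(sub_seed(config$seed, 4L), {
    event_id <- sprintf("ase_%04d", seq_len(m))
    gene_pool <- if (!is.null(annotation) && nrow(annotation$genes))
      annotation$genes$gene_id else sprintf("gene_%03d", seq_len(max(m, 1)))
    gene_id <- sample(gene_pool, m, replace = TRUE)
    event_type <- sample(AS_EVENT_TYPES, m, replace = TRUE)
    shifted <- sample(m, config$n_shifted_events)
    delta <- numeric(m)
    if (length(shifted))
      delta[shifted] <- config$ratio_shift *
        rep_len(c(1, -1), length(shifted))
    base <- runif(m, 0.15, 0.55)
    base[delta < 0] <- runif(sum(delta < 0), 0.35, 0.55)
    if (any(base + delta < 0 | base + delta > 1))
      stop("ratio + shift escapes [0, 1]; lower ratio_shift")
    kd_ratio <- base + delta
    counts <- lapply(samples, function(s) {
      r <- if (startsWith(s, "kd")) kd_ratio else base
      alt <- rbinom(m, config$junction_depth, r)
      data.frame(model = config$junction_depth - alt, alt = alt)
    })
    events <- data.frame(event_id = event_id, gene_id = gene_id,
                         event_type = event_type, stringsAsFactors = FALSE)
    for (j in seq_along(samples)) {
      events[[paste0("model_", samples[j])]] <- counts[[j]]$model
      events[[paste0("alt_", samples[j])]] <- counts[[j]]$alt
    }
    list(events = events,
         truth_shifted = data.frame(event_id = event_id[shifted],
                                    delta = delta[shifted],
                                    stringsAsFactors = FALSE))
  })
}

#' Coding-potential predictor votes for annotation transcripts
#'
#' One row per transcript of a noncoding gene (the lncRNA candidates),
#' with CPC2/LGC/CNCI/CPAT votes derived from the generator's labels;
#' each vote flips with probability `vote_error_rate`.
#'
#' @param config A `simulation_config`.
#' @param annotation A `gene_annotation` from [simulate_annotation()].
#' @return Data frame: `transcript_id`, coordinates, `length`, four
#'   predictor vote columns (`"noncoding"`/`"coding"`).
#' @export
simulate_lncrna_votes <- function(config, annotation) {
  tx <- annotation$transcripts
  lnc <- annotation$genes$gene_id[annotation$genes$biotype == "noncoding"]
  cand <- tx[tx$gene_id %in% lnc & !duplicated(tx$gene_id), , drop = FALSE]
  with_seed(sub_seed(config$seed, 5L), {
    for (p in PREDICTORS) {
      flip <- runif(nrow(cand)) < config$vote_error_rate
      cand[[p]] <- ifelse(flip, "coding", "noncoding")
    }
    rownames(cand) <- NULL
    cand
  })
}

#' Generate and write the full synthetic dataset
#'
#' Runs every generator stage and writes all pipeline inputs plus the
#' ground-truth manifest to `outdir`: `annotation.gtf`, `reads_ip.bed`,
#' `reads_input.bed`, `counts.tsv`, `fpkm.tsv`, `samples.tsv`,
#' `as_events.tsv`, `lncrna_votes.tsv` and `truth_*.tsv`.  Every TSV
#' carries a provenance header recording the package version and seed.
#' Files are byte-identical across runs with the same config.
#'
#' @param config A `simulation_config`.
#' @param outdir Output directory (created; must be empty or absent unless
#'   `force`).
#' @param force Overwrite a non-empty directory.
#' @param emit_sam Also write `reads_ip.sam` / `reads_input.sam`.
#' @return Invisibly, a list with the in-memory objects (`annotation`,
#'   `rip`, `expression`, `asevents`, `votes`) and `dir`.
#' @export
simulate_dataset <- function(config, outdir, force = FALSE, emit_sam = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) && !force)
    stop("output directory ", outdir, " is not empty (use force = TRUE)")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(rbpscan = as.character(utils::packageVersion("rbpscan")),
               seed = config$seed)
  ann <- simulate_annotation(config)
  rip <- simulate_rip_reads(config, ann)
  expr <- simulate_expression(config, ann)
  ase <- simulate_asevents(config, ann)
  votes <- simulate_lncrna_votes(config, ann)
  path <- function(f) file.path(outdir, f)
  write_gtf(ann, path("annotation.gtf"))
  write_bed(rip$ip, path("reads_ip.bed"))
  write_bed(rip$input, path("reads_input.bed"))
  if (emit_sam) {
    sizes <- tapply(ann$genes$end + 1000L, ann$genes$chrom, max)
    write_sam(rip$ip, path("reads_ip.sam"), sizes)
    write_sam(rip$input, path("reads_input.sam"), sizes)
  }
  cnt <- data.frame(gene_id = rownames(expr$counts), expr$counts,
                    check.names = FALSE)
  write_tsv(cnt, path("counts.tsv"), prov)
  fp <- data.frame(gene_id = rownames(expr$fpkm),
                   signif(expr$fpkm, 8), check.names = FALSE)
  write_tsv(fp, path("fpkm.tsv"), prov)
  write_tsv(data.frame(sample_id = names(expr$groups),
                       group = unname(expr$groups)),
            path("samples.tsv"), prov)
  write_tsv(ase$events, path("as_events.tsv"), prov)
  write_tsv(votes, path("lncrna_votes.tsv"), prov)
  write_tsv(rip$truth_peaks, path("truth_peaks.tsv"), prov)
  write_tsv(expr$truth_degs, path("truth_degs.tsv"), prov)
  write_tsv(ase$truth_shifted, path("truth_as.tsv"), prov)
  write_tsv(expr$truth_cis, path("truth_cis.tsv"), prov)
  write_tsv(data.frame(read_id = rip$duplicates), path("truth_duplicates.tsv"),
            prov)
  invisible(list(annotation = ann, rip = rip, expression = expr,
                 asevents = ase, votes = votes, dir = outdir))
}
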