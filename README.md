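# rbpscan

Peak calling and downstream screens for RNA-binding protein (RBP) studies
that pair an iRIP-seq experiment (immunoprecipitation of the RBP, sequenced
against a whole-lysate input control) with knockdown RNA-seq (3 control vs
3 knockdown replicates). The package answers the two questions such designs
ask — *where does the protein bind* and *what changes when it is removed* —
and integrates the answers into the gene sets a study reports.

## What it computes

**Binding sites.** Per-gene coverage is scanned with 5-bp windows in 5-bp
steps. A peak opens at a run of 8 windows all ≥ 2.5× the gene's baseline
depth (or a run whose median window depth exceeds 50), extends while
tracking its running maximum, and closes before a run of 8 windows below 4%
of that maximum. Significance comes from a within-gene permutation null —
the gene's reads are uniformly redistributed 500 times and the empirical
p-value is

&nbsp;&nbsp;&nbsp;&nbsp;*p* = (1 + #{null max depth ≥ observed max depth}) / (1 + 500),

with peaks kept when *p* < 0.05 or max depth ≥ 10, and finally screened for
IP/input abundance fold change > 4 (abundances per million mapped reads,
pseudocount 1).

**Differential splicing.** Per event and sample, the splicing ratio
alt/(alt+model) over junction reads (masked below 10 reads); unpaired
two-tailed Student *t* on the ratios, signed knockdown − control;
Benjamini–Hochberg control at 5% FDR.

**Expression and integration.** DESeq2 supplies the differential-expression
table; `deg_filter()` applies the strict printed cutoffs (*p* < 0.05 and
fold > 2 or < 0.5); exact Venn overlaps between DEG, regulated-splicing and
peak gene sets; hypergeometric term enrichment with BH control.

**lncRNA cis targets.** Credible lncRNAs = noncoding by all four predictor
votes (CPC2/LGC/CNCI/CPAT), ≥ 200 bp, no coding-gene overlap, ≥ 1 kb from
the nearest gene; cis pairs = co-location within 100 kb ∩ co-expression
with |Pearson r| > 0.6 and *p* ≤ 0.01 (t-transform, n−2 df).

**Synthetic data.** `simulate_dataset()` generates every input the pipeline
consumes — annotation, IP/input read placements with planted 8× binding
sites, replicate counts with planted 4-fold changes and planted
lncRNA–mRNA correlations, junction counts with planted ratio shifts of
0.3 — plus a ground-truth manifest, so the whole pipeline is testable
without any external data.

## Worked example

```r
library(rbpscan)

res <- run_all("demo_run", simulation_config(seed = 1))
head(res$final_peaks[, c("peak_id", "gene_id", "chrom", "start", "end",
                         "max_depth", "empirical_p", "ip_input_fold")], 5)
#>  peak_id  gene_id chrom   start     end max_depth empirical_p ip_input_fold
#>   peak_4 gene_003  chr1  177337  178802        29       0.002          7.29
#>   peak_6 gene_006  chr1  217903  219353        28       0.002          6.52
#>  peak_24 gene_018  chr1  754702  756137        27       0.002          6.61
#>  peak_50 gene_030  chr1 1282184 1283649        29       0.002          5.94
#>  peak_54 gene_035  chr1 1515228 1516668        28       0.002          5.83

str(res$metrics)
#> List of 10
#>  $ peak_recall   : num 1
#>  $ peak_precision: num 1
#>  $ n_final_peaks : int 20
#>  $ as_power      : num 0.94
#>  $ as_fdr        : num 0.06
#>  $ n_sig_events  : int 100
#>  $ deg_recovery  : num 1
#>  $ n_deg         : int 17
#>  $ cis_recall    : num 0.25
#>  $ n_cis         : int 1
```

Each final peak is a called binding site: `empirical_p = 0.002` is the
smallest value the 500-permutation null can report (the observed depth beat
every permutation), and `ip_input_fold` is the library-normalised IP/input
abundance ratio that cleared the > 4 screen. The metrics compare every
stage against the generator's manifest: all 20 planted sites recovered with
no false positives, 94% of planted splicing shifts declared at an empirical
FDR of 6%, and all planted 4-fold expression changes recovered. The low
`cis_recall` is expected behaviour, not a defect: with 6 samples, *p* ≤ 0.01
requires a sample correlation ≥ 0.917, so planted pairs at true r = 0.9 are
only sometimes recovered (see the methods vignette).

Result tables land in `demo_run/results/` (`peaks.tsv`, `as_results.tsv`,
`deg_table.tsv`, `cis_pairs.tsv`, `venn_regions.tsv`, …), each with a
provenance header recording the package version and seed; identical
configurations reproduce them byte for byte.

A thin command-line wrapper with the same stages as subcommands ships in
`inst/cli/rbpscan.R`:

```sh
Rscript inst/cli/rbpscan.R simulate --out ds --seed 7
Rscript inst/cli/rbpscan.R callpeaks --ip ds/reads_ip.bed --input ds/reads_input.bed \
    --gtf ds/annotation.gtf --out peaks
```

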