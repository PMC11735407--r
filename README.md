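# cocoprom — convergent co-regulated promoter analysis

Promoters can sit back-to-back. In the *divergent* arrangement a
minus-strand TSS a few hundred bp upstream of a plus-strand TSS produces
an upstream antisense RNA alongside the mRNA. In the *convergent*
arrangement a downstream antisense TSS — often inside the host gene's
first intron — transcribes back toward and across the host TSS, producing
a downstream antisense RNA (daRNA). Converging transcription has long been
expected to *interfere*; quantifying whether convergent promoter pairs are
instead *co-regulated* across conditions requires mapping them precisely
and comparing their fold changes. That is what this package does, from
strand-specific 5'-end (CAGE-like), 3'-end (QuantSeq-like) and RNA-seq
coverage tracks.

The core object is the four-TSS constellation

```
   TSS1(-)   TSS2(+)            TSS3(-)   TSS4(+)
     <---      --->               <---      --->
    uaRNA     host RNA           daRNA     dsRNA
```

with TSS1/TSS2 and TSS3/TSS4 divergent pairs and the inner TSS2/TSS3 pair
convergent. The pipeline:

1. **call-tss** — strand-specific seed/extend peak calling on pooled
   end-count tracks (Poisson background test, 50 bp peak merging), summits
   by local maxima → CTSS and QTTS site calls;
2. **detect-core** — mutual-nearest divergent pairing within 400 bp,
   joining of consecutive divergent pairs whose inner gap is ≤ 2,500 bp,
   expression-based labeling (most expressed TSS = TSS2 = host), filtering
   on annotated-TSS overlap;
3. **detect-extended** — direct convergent pairing of + and − CTSSs within
   2,500 bp, host assignment by annotation overlap then expression;
4. **annotate-darna** — daRNA transcript bodies by a 100 bp sliding-window
   walk over antisense RNA-seq coverage (mean ≥ 10 reads/bp), termination
   at CAGE-supported annotated TSSs, 3' ends from QTTSs, ranking by QTTS
   expression (`HOST-da1` is the dominant daRNA), host-TSS traversal;
5. **quantify** — per-sample 5'-end counts in peaks, median-of-ratios size
   factors `s_j = median_i (k_ij / (prod_j k_ij)^(1/m))`, pseudocounted
   fold changes `log2((mean_T + 1)/(mean_C + 1))`;
6. **correlate** — Spearman rho with two-sided significance of TSS2 vs
   TSS3 log2FC, OLS fit with 95% band, sign discordance, expression- and
   distance-tertile groups. Tau tissue-specificity
   (`sum(1 - x_i/x_max)/(n-1)`), Wilcoxon rank-sum comparisons, BH
   adjustment and scale-adjusted metaprofiles are available for summary
   analyses.

A first-class synthetic-data module (`sim_config()`, `plant_loci()`,
`simulate_tracks()`) plants quadruples, divergent-only and isolated
promoters with negative-binomial replicate noise, geometric 5'-end jitter,
Poisson background and bivariate-normal treatment effects of configurable
correlation between TSS2 and TSS3 — so the whole pipeline is validated
end-to-end against known truth without any external download.

## Worked example

```r
library(cocoprom)

cfg   <- sim_config(n_quadruples = 20, n_divergent_only = 5, n_isolated = 5,
                    effect_rho = 0.6, seed = 42)
truth <- plant_loci(cfg)
sim   <- simulate_tracks(truth, cfg)
res   <- run_sim_analysis(truth, sim)

res$core[1:3, .(chrom, tss2_pos, tss3_pos, host_gene_id, distance_2_3)]
#>     chrom tss2_pos tss3_pos host_gene_id distance_2_3
#> 1:  chrS1    12271    12636     SIMG0001          365
#> 2:  chrS1    28999    29480     SIMG0002          481
#> 3:  chrS1    49106    50002     SIMG0003          896

unlist(evaluate_quadruple_recovery(truth, res$core))
#>      n_planted     n_detected         recall      precision label_accuracy
#>             20             20              1              1              1

res$report
#>     group     n       rho            p     slope  intercept sign_discordance
#> 1:    all    20 0.8075188 1.672633e-05 0.7845253 -0.2323434              0.1
```

All 20 planted quadruples are recovered at their exact summits with the
correct host labels; the detected TSS2/TSS3 fold changes correlate
strongly (planted correlation 0.6; at only 20 loci the estimate is noisy),
and only 10% of pairs change in opposite directions. The dominant daRNAs
(one per locus here) have their 3' ends on the planted termini and all
traverse their host TSS, as expected for bodies longer than the promoter
spacing.

The same stages run from files: `simulate_dataset(cfg, dir)` writes
per-sample bedGraphs, a truth table and a host-gene GTF;
`run_pipeline(pipeline_config(dir, file.path(dir, "annotation.gtf")))`
writes one TSV per stage plus a JSON manifest. A thin command-line
wrapper lives at `inst/cli/cocoprom`:

```sh
Rscript inst/cli/cocoprom simulate --outdir sim --seed 1
Rscript inst/cli/cocoprom run --config pipeline.yaml
```

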