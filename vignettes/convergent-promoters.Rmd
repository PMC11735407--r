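---
title: "Detecting and quantifying convergent co-regulated promoters"
author: "cocoprom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying convergent co-regulated promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocoprom)
library(data.table)
set.seed(1)
```

## The biological question and the data model

Mammalian promoters rarely fire in isolation. A well-studied arrangement is
the *divergent* promoter, where a minus-strand TSS a few hundred base pairs
upstream of a plus-strand TSS produces an upstream antisense RNA (uaRNA /
PROMPT) alongside the mRNA, and the two are co-regulated. A second,
less-charted arrangement is the *convergent* promoter: a downstream
antisense TSS, often inside the first intron of the host gene, transcribing
back toward and across the host TSS, producing a downstream antisense RNA
(daRNA). Whether two promoters pointed at each other interfere (converging
polymerases colliding, one promoter occluded) or are instead co-regulated
is the question this package's analysis is built to quantify.

The full architecture is a constellation of four TSSs on a genome axis:

```
   TSS1(-)   TSS2(+)            TSS3(-)   TSS4(+)
     <---      --->               <---      --->
    uaRNA     host RNA           daRNA     dsRNA
```

TSS1/TSS2 form a divergent pair, TSS3/TSS4 a second divergent pair, and the
inner TSS2/TSS3 pair is convergent. By convention the most expressed TSS is
TSS2 and defines the host gene and the orientation; the mirrored layout on
the other strand is handled by relabeling under strand symmetry.

Three strand-specific signal classes drive the analysis:

* **5'-end tags** (CAGE-like): per-base counts of capped RNA 5' ends.
  Summits of 5'-end peaks are CTSSs.
* **3'-end tags** (QuantSeq-like): per-base counts of polyadenylated 3'
  ends. Summits are QTTSs and mark transcript termini.
* **RNA-seq coverage**: per-base read depth, used to walk out daRNA
  transcript bodies on the antisense strand.

All coordinates are internally 0-based, half-open (BED convention); GTF is
converted at the read/write boundary. Strand-specific tracks are one
bedGraph per strand, named `{sample}.{signal}.{plus|minus}.bedgraph`.

## The detection procedure

**Site calling.** Tracks are pooled across all samples (detection power
comes from the union of conditions; condition-specific quantification
happens later on the pooled peak coordinates). A position seeds a peak when
its pooled count is at least `min_seed_count` (default 5) *and* its Poisson
upper-tail probability under the genome-wide mean rate per bp is at most
`background_alpha` (default 1e-3). Peaks extend over contiguous signal
tolerating up to `max_internal_gap` (10 bp) of zeros, and peaks within
`merge_gap` (50 bp) are merged transitively. The summit — the CTSS or QTTS
— is the position of the maximum pooled count, ties resolved to the
smallest coordinate so the call is deterministic. This caller is
deliberately simple and fully specified: the downstream pairing logic is
caller-agnostic, and every step is checked against an exhaustive
position-scan oracle in the tests.

**Core set (quadruples).** Minus-strand CTSSs are paired with downstream
plus-strand CTSSs within `divergent_window` (400 bp, the established
bidirectional-promoter threshold) using mutual-nearest one-to-one matching:
a pair forms only when each summit is the other's closest eligible partner.
This prevents one TSS from joining two pairs and hence prevents overlapping
quadruples; the rule is exercised against a brute-force enumeration oracle.
Consecutive divergent pairs are then joined into a quadruple when the gap
between the inner convergent summits lies in `[min_gap,
convergent_window]` (1–2,500 bp). The most expressed of the four TSSs
becomes TSS2; its divergent partner is TSS1, the convergent counterpart
TSS3, TSS3's partner TSS4 (mirrored when the dominant TSS is on the minus
strand). A quadruple is kept only when an annotated transcript TSS on
TSS2's strand falls inside TSS2's peak, which sets the host gene.

Two cases the procedure must decide and documents here: (i) when the
expression maximum falls on an *outer* TSS (TSS1/TSS4 position), no
labeling satisfies both "TSS2 is the maximum" and "TSS2 is one of the inner
convergent pair", and the candidate is rejected rather than mislabeled;
(ii) expression ties resolve toward the annotated TSS, then leftmost.
Distances are summit-to-summit, matching how TSS2–TSS3 distances are
reported downstream.

**Extended set.** A more sensitive search pairs plus-strand CTSSs directly
with downstream minus-strand CTSSs within 2,500 bp (again mutual-nearest),
keeping pairs where at least one member's peak overlaps an annotated
same-strand TSS. The overlapping member is the host; if both overlap, the
more expressed one. The core set projects into the extended set (a
property test verifies this on simulated data).

## daRNA annotation

A daTSS with no annotated gene start at its position seeds a transcript
body walk: windows of `window_len` (100 bp) advance in the transcription
direction while the window passes the coverage threshold. The stated
threshold of ten reads is interpreted as **mean per-base coverage ≥ 10**
within the window (`mode = "mean"`; a raw 10-read window sum over 100 bp
would pass at 0.1x coverage, which cannot be what a coverage threshold
means). Coverage is the *total* across samples, as from merged libraries.
Windows are non-overlapping by default (`step = window_len`), the simplest
reading of a length-100 sliding window; both choices are exposed as
parameters. Within each step the termination check precedes the coverage
check: an annotated same-strand TSS supported by a CAGE peak truncates the
body at that TSS even under continuous coverage, so daRNA bodies do not
silently absorb downstream genes.

The walk quantizes the 3' boundary to the window grid. Because the QTTS is
the direct measurement of the terminus, a QTTS lying within one window
beyond the walked edge snaps the body to it. Each QTTS inside the body
defines one transcript (`{host}-da1`, `-da2`, ... by descending QTTS
count; count ties break toward the longer transcript, then daTSS
expression). A body without any QTTS still yields one transcript ending at
the body end with an explicit missing terminus, keeping length statistics
well defined. The dominant daRNA is the rank-1 transcript. Host-TSS
traversal is half-open containment of the host summit in the transcript
interval, so a transcript ending exactly at the host TSS does not traverse
it. A daTSS that never accumulates a passing window keeps a minimal 1-bp
body (the containment invariant holds) and is effectively unannotated.

## Quantification and statistics

Per-sample 5'-end tags are counted in the pooled peak intervals,
normalized by **median-of-ratios** size factors (each sample's factor is
the median, over features positive in every sample, of the ratio of its
count to the feature's geometric mean across samples; total-count scaling
is the fallback when no such feature exists), and summarized as
`log2((mean normalized treated + 1) / (mean normalized control + 1))`
plus a base mean. No dispersion model or per-feature test is fitted: the
co-regulation analyses consume fold changes, not feature-level p values.
One normalization subtlety worth stating precisely: because the
median-of-ratios reference is the per-feature geometric mean, scaling one
sample by *c* moves its factor relative to every other sample by exactly
*c* (the absolute factor absorbs c^(1/m)); fold changes of normalized
means are exactly invariant at pseudocount 0 and invariant to ~0.001 at
the default pseudocount for realistic depths. The tests assert the exact
forms.

Co-regulation of the convergent pair is the Spearman correlation of
TSS2 vs TSS3 log2 fold changes (exact p for n ≤ 10 without ties, t
approximation otherwise), with an OLS fit and 95% confidence band for
display, the sign-discordance fraction (share of pairs with strictly
opposite-signed fold changes; zeros count as concordant — the package's
operationalization of "proportion with a negative correlation", which the
source analyses leave undefined), grouping by rank tertiles of host
expression or TSS2–TSS3 distance (ties to the lower group), Wilcoxon
rank-sum comparisons, and Benjamini–Hochberg adjustment where families of
tests arise. Tissue specificity uses the Tau index
`sum(1 - x_i/max(x)) / (n - 1)` on non-negative expression vectors.
Metaprofiles average signal over regions either rescaled to a common
number of bins (so TSS2/TSS3 anchors align across loci of different
lengths; minus-strand regions are reversed so bin 1 is always 5') or over
fixed windows around an anchor; regions shorter than the bin count
contribute by fractional overlap.

## What the simulator emulates — and what it does not

`sim_config()` / `plant_loci()` / `simulate_tracks()` generate the study
conditions end-to-end:

* **Geometry.** Quadruples with TSS1–TSS2 and TSS3–TSS4 gaps uniform in
  60–300 bp and TSS2–TSS3 gaps uniform in 2–2,300 bp, matching the
  observed distance range of convergent pairs; divergent-only and
  isolated loci as negative structure; at least 5,000 bp between locus
  bounding boxes so no cross-locus pairing is possible under the 2,500 bp
  window and the truth is unambiguous.
* **Expression.** Baselines log-uniform in 20–200 expected tags per
  replicate (the empirical distribution of real libraries is not known to
  the generator, so a scale-spanning log-uniform is used); TSS2 exceeds
  the strongest other TSS of its quadruple by at least the 2x dominance
  margin. Counts are negative binomial with `variance = mu + 0.05 mu^2`
  per replicate, jittered around the TSS with geometric(0.5) offsets
  capped at 10 bp so the planted position is the unique mode.
* **Treatment effects.** TSS2/TSS3 log2 fold changes are bivariate normal
  with SD 1 and configurable correlation (`effect_rho`); TSS1 and TSS4
  copy their divergent partners, since divergent co-regulation is the
  accepted baseline.
* **Transcripts.** Host bodies (3–8 kb, plus strand) and daRNA bodies
  (2–12 kb, minus strand, hence usually traversing the host TSS) carry
  RNA-seq coverage at NB-drawn depth around 15x per sample and a 3'-end
  pile at the planted terminus. uaRNA/dsRNA classes are simulated as
  5'-end signal only: PROMPT-class RNAs are exosome-degraded and depleted
  in polyA-selected RNA-seq and 3'-end libraries, and this choice also
  keeps the planted antisense 3' boundaries unambiguous.
* **Background.** Poisson tags at `background_rate` (default 0.01/bp) per
  strand and sample on the end-count tracks.

Not emulated: sequence content (no FASTA/FASTQ, no alignment or
mappability artifacts), splicing, PCR duplicates, chained constellations
of more than four TSSs, and annotation errors. Passing recovery tests on
this generator therefore demonstrates the correctness of the geometric and
statistical pipeline under its stated model, not robustness to every
artifact of real libraries.

## Validation at the study scale

The acceptance suite (and `scripts/acceptance.R`, which recomputes the
same quantities from scratch) runs three simulation studies sized to
finish in minutes on one CPU:

1. **Structure recovery** — 200 quadruples + 200 divergent-only + 200
   isolated loci at background 0.01: recall and precision of the core
   detection ≥ 0.95 and TSS2 label accuracy ≥ 0.98 at a 10 bp matching
   tolerance.
2. **Co-regulation recovery** — 1,000 quadruples, `effect_rho = 0.6`, 3
   replicates per condition: the end-to-end Spearman rho of detected
   TSS2 vs TSS3 fold changes lands in [0.5, 0.7] (estimation noise
   attenuates the planted 0.6 by roughly the factor
   `1/(1 + var_noise/var_effect)`), and a null run at `effect_rho = 0`
   stays within ±0.1.
3. **daRNA boundaries** — 500 planted bodies at 15x coverage, zero
   background: ≥ 99% of inferred 3' boundaries within one window (100 bp)
   of the planted end, and the dominant transcript carries the planted
   strongest QTTS.

Operation-level correctness is established separately by exhaustive
brute-force oracles (pairing, assembly, merging, summits, body extension,
size factors, Spearman, BH, Tau, metaprofiles; 200 randomized instances
each) and closed-form identities (Tau at 0/1, the BH step-up on
(0.01, 0.02, 0.03), the pseudocounted fold-change arithmetic, the 50 bp
merge boundary).

## A small worked example

```{r example}
cfg <- sim_config(n_quadruples = 20, n_divergent_only = 5, n_isolated = 5,
                  effect_rho = 0.6, seed = 42)
truth <- plant_loci(cfg)
sim <- simulate_tracks(truth, cfg)
res <- run_sim_analysis(truth, sim)
res$core[1:3, .(chrom, tss2_pos, tss3_pos, host_gene_id, distance_2_3)]
evaluate_quadruple_recovery(truth, res$core)[c("recall", "precision")]
res$report
```

The same analysis runs from files: `simulate_dataset(cfg, dir)` writes
bedGraphs, truth tables and a host-gene GTF, and `run_pipeline()` (or the
`inst/cli/cocoprom` script) executes call-tss, detect-core,
detect-extended, annotate-darna, quantify and correlate with a JSON
manifest whose parameter hash changes exactly when a parameter does.

## Numerical choices and known limitations

* The external peak caller used upstream in the original analyses is not
  reproducible from its description; the seed/extend/Poisson stand-in here
  is deterministic and oracle-testable, and the detection logic is
  caller-agnostic. Whether the 400/2,500 bp windows apply to summits or
  peak edges is likewise not stated; summit-to-summit is implemented.
* How multi-candidate pairings were resolved is not stated;
  mutual-nearest matching is the documented choice.
* The daRNA coverage rule (`mean` vs `sum`, step size) is exposed because
  the textual description underdetermines it; defaults are the readings
  defended above.
* Sub-sampling noise at low baselines attenuates fold-change correlations
  (regression dilution); recovered rho is therefore expected slightly
  below the planted value, which the acceptance band accounts for.
* No feature-level differential testing, no FDR beyond BH, no
  conservation or chromatin layers: those analyses consume external data
  outside this package's scope.
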