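# ciliaprof

Time-course expression profiling of ciliogenesis induction.

When the green alga *Chlamydomonas reinhardtii* is deflagellated, it rebuilds
its flagella within the hour, and the transcriptome responds in minutes.
`ciliaprof` implements the analysis of a five-point FPKM time course sampled
at the pre-deflagellation baseline and at 3, 10, 30 and 60 minutes into
regrowth: it finds the genes induced during ciliogenesis, groups their
induction kinetics into recurring expression shapes, and compares the induced
set against external evidence such as flagellar proteomes. It is aimed at
anyone analysing short, densely sampled induction time courses where a full
differential-expression model is neither available (no replicates) nor the
point — the object of interest is the *shape* of the response.

## The method

For gene *g* with baseline FPKM *x*₀ and FPKM *x*ₜ at time *t* ∈ {3, 10, 30,
60} min, the fold ratio is

    r_t = (x_t + c) / (x_0 + c)

with pseudocount *c* (default 0.1; *c* = 0 reproduces printed fold-change
tables exactly). Genes are partitioned by threshold rules:

* **not expressed** — FPKM < 3 at every time point, baseline included;
* **up-regulated** — max *r*ₜ ≥ 2.5 (this takes precedence even if the gene
  also drops below 1/2.5 at another time point);
* **down-regulated** — min *r*ₜ ≤ 1/2.5 among the remaining expressed genes;
* **unchanged** — everything else.

The up-regulated profiles (log2 ratios by default) are then clustered:

1. rank by profile variance and keep the top 75%;
2. fuzzy k-means (k = 30, fuzziness m = 2) with distance 1 − Pearson *r*,
   giving each gene a membership probability in every cluster;
3. choose the membership cutoff adaptively so that the *average* gene is
   assigned to one cluster (multi-cluster membership stays possible);
4. build a single-linkage tree over the Pearson correlations between cluster
   mean profiles and merge branches with *r* > 0.9;
5. re-assign **every** up-regulated gene (including the 25% held out of
   clustering) to the merged cluster whose mean profile it correlates with
   best, provided *r* > 0.85; the rest are outliers.

Each final cluster mean is classified into one of sixteen principal
induction patterns in five groups — Arch (rise, peak at 10 min, decline),
Stag (a burst at 3/10/30/60 min sustained thereafter), Pulse (one-time-point
burst), Hump (two consecutive time points) and Up-Tick (up–down–up) — and
member genes inherit the label.

Because the processed expression matrix behind the original study is not
deposited anywhere, the package ships a synthetic generator
(`generate_dataset()`) that emulates it — archetype-driven induced genes,
repressed / flat / silent backgrounds, log-normal baselines, multiplicative
noise — with full ground-truth labels, so the whole pipeline is testable end
to end.

## Worked example

The four genes of the study's knockdown panel, from their printed FPKM
values:

```r
library(ciliaprof)
fpkm <- time_course_matrix(rbind(
  GLOD4   = c(3.55, 8.10, 12.50, 15.05, 11.58),
  NXN     = c(4.22, 16.29, 88.76, 190.26, 246.42),
  SPATA4  = c(11.99, 94.49, 163.70, 111.98, 28.03),
  ZMYND10 = c(4.08, 36.79, 117.92, 34.19, 0.71)))
prof <- compute_fold_ratios(fpkm, pseudocount = 0)
round(prof$ratios, 2)
#>           r3   r10   r30   r60
#> GLOD4   2.28  3.52  4.24  3.26
#> NXN     3.86 21.03 45.09 58.39
#> SPATA4  7.88 13.65  9.34  2.34
#> ZMYND10 9.02 28.90  8.38  0.17
```

ZMYND10 peaks at ~29-fold at 10 min and has collapsed below baseline by
60 min; NXN is still climbing at 58-fold at 60 min. All four genes clear
both the 3-FPKM expression floor and the 2.5-fold induction threshold:

```r
calls <- classify_regulation(fpkm, prof, ciliaprof_config(pseudocount = 0))
summarize_categories(calls)
#>            up         down     unchanged not_expressed         total
#>             4             0             0             0             4
classify_pattern(prof$ratios["ZMYND10", ])   # "Arch2"  (up 3-30 min, down at 60)
classify_pattern(prof$ratios["NXN", ])       # "Stag3"  (sustained from 3 min on)
```

A full pipeline run on a synthetic study-scale data set:

```r
sim <- generate_dataset(simulation_config(seed = 1))   # 15,210 genes
res <- run_pipeline(sim$matrix, ciliaprof_config(seed = 1))
res
#> ciliaprof pipeline run
#>   categories: up 1500, down 3560, unchanged 3690, not_expressed 6460, total 15210
#>   clusters: 30 before merge, 13 final; cutoff 0.379
#>   assigned 1495 gene(s), 5 outlier(s)
score_recovery(sim$truth, res$calls, res$cluster_set, res$labels)$group_recovery
#> [1] 0.9546667
```

i.e. 95.5% of the simulated induced genes are placed in a cluster labelled
with their true pattern group despite sd-0.25 noise on every log2 ratio.

A thin command-line front end wraps the same functions
(`inst/exec/ciliaprof`): `ciliaprof run --fpkm <tsv> --out <dir>`,
`ciliaprof simulate`, `ciliaprof overlap --up <list> --ref name=path`.

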