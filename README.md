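# repcycle

Cell-cycle-regulated transcription and DNA replication timing.

## The problem

Eukaryotic genomes replicate on a reproducible temporal program: each locus
has a characteristic time of replication within S phase (T\_rep). What sets
this program — in particular the firing order of late origins of replication
(ORIs) — is largely unknown. One informative observable is the relationship
between T\_rep and *when in the cell cycle* a gene is transcribed: if genes
whose transcripts peak after S phase (i.e. genes actively transcribed
*during* S) replicate systematically early, and the effect concentrates near
late-firing ORIs, that pattern points at S-phase transcription influencing
origin firing rather than the reverse.

`repcycle` implements this analysis as a reusable, tested pipeline for
anyone with (a) a replication-timing profile, (b) gene annotations, (c) an
ORI catalogue, (d) a cell-cycle-synchronized expression time course, and
(e) asynchronous expression levels. It also ships a fully truth-tracked
synthetic-data generator so that every stage can be validated without any
external download.

## The statistic at its core

For each timepoint *t* of a synchronized time course, the **oscillation
profile** is the Pearson correlation across genes

> r(t) = cor( e\_g(t), T\_rep(g) )

where e\_g(t) is gene *g*'s log2 expression ratio relative to asynchronous
cells and T\_rep(g) is its replication time, obtained by linear
interpolation of the timing profile to the gene's midpoint. Positive r(t)
means genes up-regulated at *t* replicate late; negative r(t) means they
replicate early. Each timepoint carries an analytic significance threshold
obtained by inverting the correlation t-test,
t = r·sqrt((n−2)/(1−r²)) with df = n−2
(e.g. |r| > 0.107 at n = 800 and |r| > 0.177 at n = 292, both two-tailed
P < 0.0025). The profile is recomputed within strata — early vs late
replication (cutoff halfway through S phase) and ORI-proximal vs ORI-distal
(5' end within a distance cutoff of the nearest confirmed/likely ORI) — and
strata are compared by their oscillation **amplitude** (max r − min r).

Supporting analyses: mean T\_rep of the most-induced vs most-repressed
expression decile (two-tailed Student's t), the T\_rep moving average along
the peak-expression-time ordering, median expression by T\_rep decile,
the k highest- vs lowest-expressed genes by asynchronous level with an
optional replication copy-number correction, and early-replicating peak
calling with ORI activation for low-resolution (human-style) profiles.

## Worked example

Simulate the default synthetic study (2 × 2 Mb genome, 400 cell-cycle-
regulated genes, 40 origins, coupling of S-phase transcription to
late-origin firing) and run the association analysis:

```r
library(repcycle)
library(dplyr)

params <- sim_params(seed = 42)
ds <- simulate_dataset(params)

gene_trep <- ds$genes |>
  interpolate_trep(ds$profile) |>
  classify_early_late(ds$profile) |>
  nearest_ori_distance(filter(ds$oris, status %in% c("confirmed", "likely"))) |>
  classify_ori_proximity(35000)

osc <- oscillation_profile(ds$expression, gene_trep, alpha = 0.0025)
osc
#> # A tibble: 9 × 6
#>    time phase        r n_pairs critical_r significant
#>   <dbl> <chr>    <dbl>   <int>      <dbl> <lgl>
#> 1     0 M/G1   0.369       400      0.151 TRUE
#> 2    20 G1     0.368       400      0.151 TRUE
#> 3    40 S     -0.310       400      0.151 TRUE
#> 4    60 G2    -0.422       400      0.151 TRUE
#> 5    80 M      0.157       400      0.151 TRUE
#> 6   100 M/G1   0.415       400      0.151 TRUE
#> 7   120 S      0.00425     400      0.151 FALSE
#> 8   140 G2    -0.417       400      0.151 TRUE
#> 9   160 M     -0.218       400      0.151 TRUE
```

The correlation oscillates with cell-cycle phase: genes highly expressed at
the G2 timepoints (whose transcription peaks during S phase) replicate
early (r = −0.42 at 60 min, well past the |r| > 0.151 threshold for
n = 400 at P < 0.0025), while genes expressed at M/G1 replicate late
(r = +0.42 at 100 min). `glance()` summarizes a profile in one row, and
`autoplot(osc)` draws it with its significance band.

Stratifying the same statistic shows where the signal lives:

```r
for (f in c("late", "early", "proximal", "distal")) {
  a <- oscillation_amplitude(oscillation_profile(ds$expression, gene_trep, gene_filter = f))
  cat(sprintf("%-9s amplitude: %.3f\n", f, a))
}
#> late      amplitude: 0.847
#> early     amplitude: 0.135
#> proximal  amplitude: 0.385
#> distal    amplitude: 0.234
```

The oscillation is carried by late-replicating, ORI-proximal genes — the
synthetic ground truth couples firing-time advances to S-phase
transcription only at late origins, and the stratified analysis recovers
exactly that structure.

The whole analysis is also available as a three-stage pipeline
(`cmd_simulate()`, `cmd_associate()`, `cmd_report()`, or the
`inst/exec/repcycle` script) that writes `oscillation_profile.tsv`,
`moving_average.tsv`, `decile_table.tsv`, `comparisons.tsv` and a JSON
manifest with the configuration, seed and input hashes.

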