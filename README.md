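# polwave

Analysis of DRB-release nascent-transcription time courses — and a
stochastic Pol II kinetic simulator that makes every analysis stage
verifiable by parameter recovery.

## The problem

DRB arrests RNA polymerase II at promoter-proximal pause sites; washing
it out at *t* = 0 releases the synchronized pool, and 4sU labeling plus
sequencing of the labeled fraction (TT-seq/Bru-seq) shows a wave of
nascent signal advancing into gene bodies. Two kinetic quantities hide
in such data and can *dissociate*:

- **elongation speed** *v* (kb/min): the slope of the wave position
  regressed on time after release,
  *x*(t) = *x*₀ + *v·t*;
- **processivity**: whether released polymerases stay template-engaged
  to the gene end, read from Pol II ChIP occupancy across gene bodies
  over the time course, with premature termination modeled as survival
  *S(d)* = e^(−λ·d) per distance travelled.

A mutant can be *faster yet less processive* — moving further by 10 min
while producing fewer transcripts and losing gene-body Pol II. `polwave`
is for genomics analysts who want that readout as a tested, seeded,
end-to-end pipeline: transcript filtering (> 30 kb, non-overlapping
units), TSS-anchored strand-oriented matrices (−2 kb … +30 kb nascent,
−2 kb … +15 kb Pol II), per-million normalization, metagene profiles,
smoothing-spline wave localization, rate regression (metagene-level and
per-gene), and a distal/proximal occupancy index.

## Worked example

Simulate a 50-gene cohort in two conditions — WT (*v* = 2.0 kb/min,
hazard 0.01/kb) versus a KO-like condition (*v* = 2.6 kb/min, hazard
0.05/kb) — and run the whole pipeline:

```r
library(polwave)
res <- run_all(list(seed = 1, outdir = "demo_out",
                    simulate = list(n_genes = 50,
                                    conditions = c("wt", "ko")),
                    wave = list(timepoints_min = c(0, 10))))
res$rates$wt$metagene
#> elongation rate: 1.887 kb/min (wave front, t = 0, 10 min)
res$rates$ko$metagene
#> elongation rate: 2.341 kb/min (wave front, t = 0, 10 min)
res$comparison
#> condition comparison: ko vs wt
#>   rate            ko>wt
#>   nascent_total   ko<wt
#>   body_occupancy  ko<wt
#>  timepoint_min    d_body    d_pause excluded
#>              0     0.000    0.00000    FALSE
#>              5 -1049.750 1111.05205    FALSE
#>             10 -1673.999  -35.48603    FALSE
res$indices$wt[["10"]]
#> processivity index (distal/proximal occupancy): 8.8889  [wt, t=10 min]
res$indices$ko[["10"]]
#> processivity index (distal/proximal occupancy): 1.7500  [ko, t=10 min]
```

Reading the output: the KO wave front advances faster (2.34 vs
1.89 kb/min; the true simulated speeds are 2.6 vs 2.0 — exponential
pause release biases front-based estimates slightly down, identically
in both conditions), yet KO makes less labeled RNA by 10 min
(`nascent_total ko<wt`), and its gene-body Pol II occupancy collapses
between 5 and 10 min (`d_body` increasingly negative, processivity
index 1.75 vs 8.89): faster but less processive. `demo_out/` holds the
matrices' metagene TSVs, `rates.tsv`, `timecourse.tsv`, `indices.tsv`,
`verdict.json`, metagene PDFs, and a `manifest.json` recording seed and
parameters.

The same pipeline runs on real data by replacing `simulate` with an
`inputs` block (annotation BED/GTF, chrom.sizes, bedGraph/bigWig/BED
tracks per condition/assay/timepoint); see `?validate_config`. A CLI
wrapper is installed at `inst/cli/polwave`
(`polwave {simulate,filter,run-all,...}`).

## Scope

Input is aligned coverage or intervals: read QC/trimming/alignment are
upstream, BAM processing and sequence-level read simulation are out of
scope, as are intron signal, GC bias, and replicate-level statistics.
See `vignettes/wave-kinetics.Rmd` for the model, parameter defaults,
and what a green parameter-recovery test does and does not establish.
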