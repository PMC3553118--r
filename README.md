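# taiseg

Genomic instability in tumour copy-number profiles: exact piecewise-constant
segmentation, the Total Aberration Index, and its association with clinical
outcome.

## What it does, and for whom

High-grade serous ovarian cancers (and many other solid tumours) carry broad
somatic copy-number aberrations rather than recurrent point mutations. For a
cohort profiled on a copy-number array (log2 tumour/normal ratios per probe),
`taiseg` provides the complete analysis chain a cancer-genomics group needs
to ask "do patients with more genomic disorganisation fare differently?":

1. **Segmentation** — each chromosome of each sample is fitted by exact
   penalized least-squares piecewise-constant fitting (PCF):

   minimise  Σ<sub>segments</sub> Σ<sub>j∈seg</sub> (y<sub>j</sub> − ȳ<sub>seg</sub>)² + γ·(k − 1),

   over segmentations into k segments of ≥ 3 probes, solved exactly by an
   O(n²) dynamic program (no heuristics).

2. **Total Aberration Index (TAI)** — per sample, the length-weighted mean
   absolute segment log2 ratio:

   TAI = Σ<sub>i</sub> L<sub>i</sub>·|ȳ<sub>i</sub>| / Σ<sub>i</sub> L<sub>i</sub>,

   with L<sub>i</sub> the genomic span (bp) of segment i — the absolute
   deviation from the diploid state averaged over covered genomic locations.

3. **Cohort statistics** — median split into TAI-low/high groups;
   gain/loss frequency tracks and fixed 1-Mb-grid cohort averages;
   Fisher exact and grouped Mann–Whitney comparisons of clinicopathological
   characteristics between TAI groups; Kaplan–Meier curves, log-rank tests,
   and Cox proportional-hazards models with TAI entered per SD (univariate
   and adjusted for age, stage, grade).

4. **Synthetic cohorts** — a generator with segment-level ground truth,
   tumour-purity dilution (log2(tf·2^level + 1 − tf)) and outcomes linked to
   true TAI, so every stage is testable without array downloads.

See `vignettes/tai-methods.Rmd` for the model, conventions and design
decisions.

## Worked example

```r
library(taiseg)

co  <- simulate_cohort(sim_params(n_samples = 40, seed = 1))
seg <- segment_profiles(co$cn, pipeline_config())
tai <- tai_table(seg)
tai
#> TAI table: 40 samples, median TAI 0.05494 (20 low / 20 high)
#>    sample_id        tai group            z
#> 1     SIM001 0.03915215   low -0.735596791
#> 2     SIM002 0.12527468  high  1.554060652
#> 3     SIM003 0.02907082   low -1.003619557
#> ...

build_table2(co$clinical, tai)
#> PFS: n = 40, events = 35 | log-rank p = 0.04254 | HR/SD = 0.571 [0.383, 0.850], p = 0.00581
#> OS:  n = 40, events = 29 | log-rank p = 0.1167  | HR/SD = 0.615 [0.401, 0.944], p = 0.02616
```

Each sample's TAI is its genome-wide aberration burden; the cohort is split
at the median TAI (20 low / 20 high). This simulated cohort was generated
with a protective instability effect (log-hazard −0.5 per SD of true TAI),
and the fitted models recover it: the hazard ratio per SD of estimated TAI
is 0.62 for overall survival (0.57 for progression-free survival), i.e.
higher TAI, longer survival — the direction reported for high-grade serous
disease.

A full run (`run_pipeline(pipeline_config(), "probes.tsv", "clinical.csv",
"out/")`) writes the segment table (BED-like TSV), the TAI table, frequency
and grid tracks, the group-comparison and survival summaries, and a YAML
manifest. A thin command-line wrapper with `simulate`, `segment`, `tai`,
`freq`, `stats`, `survival` and `run` subcommands is installed at
`inst/cli/taiseg.R`.

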