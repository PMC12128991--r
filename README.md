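# plaqueclone

Somatic clonal architecture of atherosclerotic plaques from multi-segment,
deep whole-exome variant calls with a patient-matched buffy-coat reference.

Atherosclerotic plaques harbour locally expanded somatic clones, and
expanded blood clones (CHIP — clonal hematopoiesis of indeterminate
potential) can infiltrate plaque tissue. Given ~700x candidate variant
calls from several segments cut along a plaque, sequenced in two
independent rounds, plus matched blood, `plaqueclone` answers:

* which calls are genuine tissue-confined somatic mutations,
* what fraction of cells in each segment carries each mutation and how far
  each clone physically extends along the plaque, and
* which CHIP mutations are present in blood and at what cell fractions they
  infiltrate the plaque.

The package is aimed at analysts of multi-region deep-sequencing
experiments (vascular somatic mosaicism in particular) who consume variant
calls and annotations and need a reproducible, tested path from calls to
clonal architecture.

## The model in brief

A variant is accepted per sample and sequencing round when
`alt >= 5`, `VAF >= 1%`, mean base quality `>= 25`, and the matched buffy
coat shows VAF `< 0.01%`; a mutation is validated when it passes in two
independent rounds, is not ~50% VAF in every covered sample (germline),
and is unique to one patient. Under diploidy and heterozygosity the clonal
cell frequency is

    f = 2 * VAF        (autosomes; chrX in females)
    f = VAF            (chrX/chrY in males)

with rounds pooled by read weighting, `sum(alt)/sum(total)`. Mutations
detected in the same samples with relative frequency differences <= 0.5 in
every shared sample are grouped into putative clones (connected
components); a clone positive in segments `[a1, a2)` and `[b1, b2)` has
physical extent at least `b1 - a2` (nearest edges) and at most `b2 - a1`
(farthest edges). CHIP screening keeps buffy variants in a 78-gene list
with depth `>= 20`, gnomAD MAF `< 1%` and damaging evidence (ClinVar,
loss of function, CADD `> 23`, or 4/5 dbNSFP votes), then force-calls
every site in every sample of every patient.

A binomial read-count simulator (`sim_config()`, `simulate_dataset()`)
generates cohorts with planted clones, germline variants, CHIP clones,
sequencing error and Poisson depth, and writes standard VCF/TSV/JSON
datasets, so the whole pipeline is testable with no external data.

## Worked example

```r
library(plaqueclone)

cfg <- sim_config(n_patients = 3, seed = 42)   # study-design defaults
sim <- simulate_dataset(cfg)
fit <- plaque_clonality(sim$obs, sim$truth$meta, sim$truth$annotations)
fit
#> Plaque clonal architecture: 3 patient(s), 12 plaque segment(s)
#>   validated somatic mutations: 32 (3/3 patients positive)
#>   clonal cell frequencies: 2.3%-33.2% (median 12.4%)
#>   putative clone groups: 15
#>   CHIP: 6 mutation(s) in 3/3 carrier(s)
```

32 planted somatic mutations survive the matched filter cascade; their
clonal cell frequencies (2 x pooled VAF) span 2.3%–33.2% of sample cells,
and the co-occurrence/similarity rule condenses them into 15 putative
clone groups with physical-extent bounds. Per-patient tables:

```r
summary(fit)$patient[, 1:4]
#>   patient n_mutations n_detections median_ccf
#> 1     P01          10           21 0.09898108
#> 2     P02          10           22 0.16486287
#> 3     P03          12           27 0.11223022
```

The frequency conversion itself is one call — for example the buffy-coat
CHIP VAFs 1.3%, 17% and 3.7% convert to cell fractions of 2.6%, 34% and
7.4%:

```r
vaf_to_ccf(c(0.013, 0.17, 0.037), "chr2", "female")
#> [1] 0.026 0.340 0.074
```

`plot(fit)` draws one patient's mutation frequencies along the plaque
axis; `write_report(fit, dir)` saves all tables (including CHIP carriers,
force-calls and infiltration) as TSV/JSON. Datasets round-trip through
disk with `write_dataset()` / `read_dataset()`, and
`inst/cli/plaqueclone.R` wraps simulate/run/report for shell use.

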