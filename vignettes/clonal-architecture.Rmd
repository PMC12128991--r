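---
title: "Methods: somatic clonal architecture from multi-segment plaque sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic clonal architecture from multi-segment plaque sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaqueclone)
```

## The problem

Atherosclerotic plaques contain locally expanded somatic clones. Deep
whole-exome sequencing (~700x) of several segments cut along a plaque,
together with the patient's buffy coat (blood leukocytes) as a matched
germline reference, makes three questions tractable:

1. Which variant calls are genuine tissue-confined somatic mutations?
2. What fraction of cells in each segment carries each mutation, and how far
   along the plaque does each clone physically extend?
3. Do expanded blood clones (CHIP, clonal hematopoiesis of indeterminate
   potential) infiltrate the plaque, and at what cell fractions?

`plaqueclone` implements this analysis path end to end, plus a read-count
simulator with planted ground truth so every stage can be validated without
patient data.

## The somatic filter cascade

A candidate variant is accepted in one sample and one sequencing round when

* it has at least 5 alternate reads (`min_alt_reads = 5`),
* its VAF is at least 1% (`min_vaf = 0.01`),
* its mean base quality is at least 25 (`min_base_quality = 25`), and
* the patient's buffy coat shows no or very low signal: buffy VAF
  strictly below 0.01% (`max_buffy_vaf = 1e-4`). At 700x this effectively
  demands zero alternate reads in blood; a variant absent from the buffy
  calls counts as VAF 0.

A mutation is **validated** for a patient when it passes this full per-round
filter in at least two *independent* sequencing rounds (libraries prepared
from raw DNA separately) in at least one sample. We deliberately adopt the
stricter of the two possible readings of the two-round rule — each round
must pass every threshold, not merely show nonzero reads — because it is
reproducible and conservative; `require_rounds` and all thresholds are
configurable.

Two clean-up stages follow. *Germline removal* drops variants whose
round-pooled VAF lies in `[0.40, 0.60]` in **every** covered sample of the
patient, including blood — the operational meaning of "approximately 50%
everywhere"; samples without coverage do not veto the rule.
*Cross-patient exclusion* removes any substitution validated in more than
one patient: independent somatic hits at the same base in two patients are
vastly less likely than a platform artifact.

Each stage only removes variants, so the cascade is monotone, and every
stage is idempotent on its own output; both properties are tested.

## From VAF to clonal cell frequency

Assuming diploid cells and mutation heterozygosity, a mutation carried by a
fraction *f* of cells sits on one of two copies, so its expected VAF is
*f*/2 and

> clonal cell frequency = 2 x VAF,

except on the X chromosome in males (single copy): multiplier 1. Female
chrX variants convert like autosomes (one of two X's; we do not model
X-inactivation because DNA read counts are unaffected by it). chrY in
females is rejected as an input error, and the sex of the patient is
mandatory whenever a sex-chromosome variant is converted — there is no
silent default. Frequencies are capped at 1 after doubling; the uncapped
value is kept in a diagnostic column (`ccf_uncapped`) because a sum of
capped values is the quantity used downstream.

Rounds are pooled by read-weighting, `sum(alt) / sum(total)`, which always
lies between the per-round VAFs and reduces to their mean at equal depths.

After patient-level validation, a mutation is quantified in *all* samples
of the patient; per-sample presence reuses the discovery thresholds
(pooled alt reads >= 5 and pooled VAF >= 1%). There is no established
convention for the presence threshold used at re-quantification; reusing
the discovery thresholds is our choice — it keeps a single detection floor
throughout.
Sample cell counts are estimated from DNA yield at 6.6 pg per diploid cell.

## Spatial clone mapping

Each plaque is a 1-D axis; frozen segments are disjoint half-open intervals
`[start_mm, end_mm)` separated by unsequenced gaps (alternate segments go
to histology). For one patient we build the mutation-by-sample frequency
matrix with columns ordered by segment start.

**Extent bounds.** A mutation positive in several segments must belong to a
clone bridging the gaps between them. We report two bounds from the
outermost positive segments: the *lower* bound is the distance between
their nearest edges (0 for a single segment) — a clone spanning two
segments must at least bridge the gap — and the *upper-consistent* bound is
the distance between their farthest edges. Reported clonal extents
rarely come with an explicit edge convention, so we always report both
bounds and treat nearest-edge as the headline number.

**Grouping into putative clones.** Mutations carried by the same clone
must appear in the same samples with similar magnitudes and similar
intersample differences. We operationalize this as: two mutations are
linkable iff (i) their nonzero columns are identical and (ii) in every
shared positive column the relative difference
`|f1 - f2| / max(f1, f2)` is at most `rel_tol` (default 0.5). Putative
clones are the connected components of this relation — single linkage with
no tie-breaking, hence deterministic and invariant to row permutation. The
representative profile is the column-wise median of members. The default
`rel_tol = 0.5` links the frequency profiles co-travelling mutations show
in practice (e.g. 5%/31%/10% against 5%/30%/10%) while remaining a single
interpretable dial; because bulk data
cannot prove co-occurrence in the same cells, groups are labelled
hypotheses, never ground truth. A `gap_tolerant` mode links patterns
differing in one interior column (tolerating a single sampling dropout);
it is off by default because it weakens rule (i).

**Multi-mutation flags.** When a sample's clonal cell frequencies summed
over mutations exceed 100%, distinct cells cannot carry them all: some
clones must carry more than one mutation. The flag is a per-sample column
sum > 1.

## CHIP screening and infiltration

Buffy-coat calls are screened tumor-only against a 78-gene CHIP driver
list (an editable text file shipped in `extdata`; supply your own via
`chip_params(gene_list=)`). A variant is kept when it lies in a listed
gene, is covered by at least 20 reads, has VAF >= 1%, has gnomAD MAF < 1%,
and carries damaging evidence. The damaging criteria combine with OR —
ClinVar pathogenic, loss-of-function consequence, CADD Phred > 23, or >= 4
of 5 dbNSFP predictors — because they are alternative lines of evidence
for "known or predicted damaging". A gnomAD MAF that is *missing* passes
the MAF filter: absence from a database of >140,000 genomes implies
rarity; this assumption is logged here deliberately. A residual germline
check (~50% VAF in every covered sample) backs up the MAF filter.

The 1% VAF floor matches the somatic limit of detection used everywhere
else in the pipeline; a separate blood-specific limit would add a second
dial without evidence to set it.

Screened mutations are then force-called: read support is reported at every
CHIP site in every sample of every patient, with *no coverage* recorded
explicitly and never conflated with zero alternate reads. CHIP variants
screened in more than one patient are excluded from all patients before
quantification (the same recurrence argument as in the somatic cascade).
Infiltration is quantified per (mutation, plaque sample) as pooled VAF and
clonal cell frequency with a detection flag (alt >= 5, VAF >= 1%), and per
carrier as the fraction of covered plaque samples positive.

## The simulator

`sim_config()` defaults encode the study conditions: 13 patients; 4 frozen
segments per plaque, 2-5 mm wide, spaced 4-10 mm apart; 700x mean depth;
two independent rounds; per-base miscall rate 1e-3; somatic clones with
cell fractions uniform on [0.01, 0.31] carrying 1-4 mutations each;
heterozygous germline variants at 50% VAF in every sample; CHIP clones in
6 of 13 patients with blood cell fractions uniform on [0.026, 0.34]
(buffy VAFs 1.3%-17%) and independent per-segment tissue infiltration —
independent because observed tissue fractions do not track blood fractions.

Choices not dictated by the study design, fixed once here:

* **Depth model**: per-site depth ~ Poisson(700) truncated at >= 1 (a
  constant-depth mode exists); the assay specifies target coverage only.
* **Error model**: symmetric per-base miscall; at a site with expected VAF
  v the alternate-read probability is `v + (1 - v) * error`. Error reads
  at a variant site therefore add to the alternate count.
* **Base quality**: per-variant mean base quality ~ Normal(35, 2),
  truncated to [2, 60] — a typical post-UMI Illumina mean well clear of
  the 25 acceptance threshold.
* **Spatial model**: a clone occupies a contiguous run of segments with
  one uniform fraction per sample (fractions drawn independently per
  sample); no within-sample gradient, no clone nesting. Multi-mutation
  clones (identical per-sample fractions across members) already reproduce
  the frequency-sums-above-100% phenomenon that nesting would also create.
* **Feasibility**: fractions of disjoint clones sharing a sample must sum
  to <= 1; random draws are re-drawn (up to 200 attempts), explicit clone
  specifications fail hard.
* **The buffy coat** carries germline, CHIP and designated error-only
  sites, but never tissue-restricted somatic sites. The upstream pipeline
  the simulator emulates collapses UMIs with error correction, suppressing
  sub-0.1% noise in the matched reference; emitting raw 1e-3 noise at
  somatic sites in blood would instead veto roughly half of all true
  somatic variants through the strict <0.01% buffy rule, which is not the
  behaviour of the error-corrected assay.

What the simulator does **not** emulate — and what passing tests therefore
cannot show about real data: mapping and alignment artifacts, UMI
collapsing itself, strand bias, copy-number variation, indels (point
substitutions only), within-segment spatial gradients, and contamination
between neighbouring segments. The filter thresholds this package tests
were designed against exactly such artifacts; here they are exercised only
against binomial sampling and symmetric miscalls.

Everything is deterministic given the config seed (truth uses `seed`,
reads use `seed + 1` so the same truth can be re-sequenced).

## Numerical and testing choices

Validation runs in the test suite use desk-scale problem sizes chosen to
make binomial expectations sharp: 1e5 error-only sites for specificity
(zero validated calls expected; at error 1e-3 the chance of >= 7 errors in
700 reads twice independently is ~1e-11 per site); 100 four-segment
plaques with clones of 4%-30% for sensitivity (>= 95% of clones validated;
mean absolute frequency error <= 2 percentage points); 100 replicate
plaques with three 3-mutation clones >= 5% for grouping recovery (mean
Rand index >= 0.9 against planted labels); exhaustive enumeration of all
63 presence patterns over 6 segments for extent bounds; and 300 planted
blood clones at the 4% floor for CHIP detection (>= 99%), with
Clopper-Pearson 95% intervals covering planted infiltration VAFs in >= 90%
of (mutation, sample) pairs. Grouping is cross-checked against a
brute-force pairwise oracle with components computed by igraph,
independently of the package's BFS.

Degenerate inputs are errors, not defaults: missing buffy coats, unknown
sex with sex-chromosome variants, chrY in females, single-round data under
a two-round rule, zero DNA yield, overlapping segment intervals, and
malformed annotation rows (reported with their row number).

## Known limitations

* Grouping cannot separate clones that genuinely occupy the same segments
  at similar fractions; bulk data admits multiple architectures and the
  output is a hypothesis.
* No copy-number correction: the 2xVAF rule overestimates frequencies in
  amplified regions and underestimates in deletions.
* Extent bounds assume the 1-D segment geometry is exact and clones are
  contiguous; a fragmented clone would be reported as one long clone.
* The per-sample presence floor (5 reads, 1%) is a detection limit, not a
  biological zero; absence below it is recorded as frequency 0.
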