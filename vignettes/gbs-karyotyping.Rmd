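---
title: "Karyotyping allopolyploids from GBS bin counts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyotyping allopolyploids from GBS bin counts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbskaryo)
library(dplyr)
```

## The problem

Newly synthesized wheat × rye amphidiploids (AABBDDRR, 2n = 56) are
genomically unstable: whole chromosomes, single arms, and sub-arm segments
are gained or lost during tissue culture and the first sexual generations.
Tracking these events matters because specific loci — notably the
incompatibility alleles *Eml-A1* (long arm of wheat 6A) and *Eml-R1b*
(long arm of rye 6R) — decide whether a plant is fertile at all, and
because the somatic chromosome number 2n summarizes how far a line has
drifted from the euploid complement.

Genotyping-by-sequencing (GBS) gives a cheap readout: reads pile up at
restriction-site-associated targets, so coverage along the genome is
uneven but highly reproducible between samples. Relative coverage in
genomic bins therefore measures DNA dosage. `gbskaryo` turns per-bin read
counts into an explicit, reproducible karyotype call chain:

1. **normalize** — counts-per-million per sample, then per-bin log2 ratios
   against the mean of euploid control samples;
2. **segment** — penalized least-squares changepoint detection per
   chromosome;
3. **assign** — integer copy number 0–4 per segment;
4. **classify** — the karyotype vocabulary (nullisomic … tetrasomic,
   mono-/ditelosomic, terminal/interstitial/pericentric deletions);
5. **report** — per-plant 2n, subgenome tallies, locus dosages.

A synthetic-cohort generator with planted events and an emitted truth set
makes every stage testable without any sequencing data.

## Data model

A *genome model* lists chromosomes with subgenome label (A/B/D/R), length
and centromere position. All coordinates are 0-based, half-open BED
convention. Bins tile each chromosome at a fixed width (1 Mb by default);
the final bin of a chromosome is kept even when shorter — dropping it
would blind the caller to terminal deletions, one of the key event
classes. Counting and calling happen on the 1 Mb grid; genome-wide plots
re-bin to 5 Mb for legibility only.

The bundled `default_genome()` is deliberately synthetic: 28 chromosomes
(21 wheat + 7 rye) of 20–60 Mb, not assembly-scale, so a full cohort
simulates and calls in seconds. Assembly-scale models load through
`read_genome()` and change nothing downstream.

## The count simulator

`simulate_cohort()` draws the count of bin $b$ in sample $s$ as

$$K_{sb} \sim \mathrm{NB}\!\left(\mu_{sb},\ \phi\right),\qquad
\mu_{sb} = L_s\, d_b\, \frac{w_b}{w}\,
\max\!\left(\frac{c_{sb}}{2},\ f\right)$$

with $L_s$ the library size (log-normal across samples), $d_b$ a per-bin
target density shared by **all** samples (log-normal multipliers,
normalized so the euploid expectation sums to $L_s$), $w_b/w$ the length
fraction of a possibly truncated terminal bin, $c_{sb}$ the planted copy
number (0–4), $f$ a cross-mapping floor, and $\phi$ the negative-binomial
dispersion ($\mathrm{Var} = \mu + \phi\mu^2$; $\phi = 0$ falls back to
Poisson for analytic checks).

Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| density sigma | 0.7 | strong but reproducible target unevenness, the defining feature of GBS coverage |
| library size | 2e5 reads (sigma 0.2) | ≈180 reads per 1 Mb bin on the default genome — enough that dosage classes separate cleanly, small enough for second-scale runs; no per-library totals are published for this system, so this is a desk-scale choice |
| dispersion | 0.05 | mild overdispersion typical of count re-sequencing data |
| cross-mapping floor | 0.02 | nullisomic regions in allopolyploids rarely read exactly zero because homeologous reads mis-map at low rate |

Per-genotype RNG substreams are keyed by *(seed, genotype name)*, so a
cohort can be extended — or its genotype list reordered — without changing
any existing sample's counts, and the same config + seed is bit-for-bit
reproducible. Event-free genotypes are written into the sample sheet as
controls.

What the simulator does **not** model: GC/fragment-length biases,
mappability structure, restriction-site polymorphism between subgenomes,
read-level errors, or translocations (which preserve dosage and are
invisible to coverage anyway). Passing tests on simulated cohorts
therefore demonstrate the statistical machinery, not robustness to every
artefact of real libraries.

## Normalization

Two steps, in this order: each sample's counts are divided by the sample
total and multiplied by 1e6 (CPM), then each bin's log2 ratio is taken
against the arithmetic mean of the control samples' CPM at that bin. The
control mean is computed on scaled values, matching the step order.

Zero-count bins need care: nullisomic regions genuinely produce zeros, so
ratios use a pseudocount (default 0.5 CPM on both numerator and
denominator — it cancels exactly when sample equals control) and are
floored at −5, which keeps nullisomy finite and plot-friendly. Bins whose
control mean falls below 1 CPM (GBS target deserts) are masked outright
and carry an explicit flag, never a silent zero. Partial terminal bins
need no length correction in the ratio because numerator and control share
the bin.

## Segmentation and copy number

Per chromosome, the unmasked log2-ratio series is segmented by exact
dynamic programming minimizing

$$\sum_{\text{segments}} \mathrm{SSE} + \beta \times (\#\text{segments} - 1)$$

subject to a minimum segment length of 3 bins (smaller events are below
the method's resolution and outside the "major rearrangement" scope).
Ties break toward fewer segments, then leftmost breakpoints; the
implementation is verified against an exhaustive-search oracle on
thousands of short series.

The penalty default is $\beta = 10\hat\sigma^2$, with $\hat\sigma^2$ the
per-bin noise variance estimated robustly as half the squared MAD of
within-chromosome lag-1 differences — differences cancel piecewise-
constant signal, so real events do not inflate the estimate. The estimate
is taken on test samples when any exist: a control's residual against a
reference mean that includes itself systematically understates the noise
a test sample sees.

Before segmentation each sample's series is recentred on its dominant
dosage state (an iterated trimmed median, ±0.5 window). This guards
against the compositional artefact of CPM scaling: a plant that has lost,
say, its whole rye subgenome redistributes those reads across the
remaining bins, shifting every wheat log2 ratio up by
$\log_2(1/0.75) \approx +0.41$ — enough to fake trisomies. A plain median
is not sufficient here because the floored bins of the eliminated
subgenome drag it off the euploid mode. The recentring assumes most of
the genome sits at baseline dosage, the standard read-depth caller
assumption; a genome more than ~half aberrant would defeat it.

Segment means map to copy numbers as the nearest integer to
$2 \times 2^{\bar r}$, clipped to 0–4 (tetrasomy is the largest state the
vocabulary needs); class boundaries sit at log2 ratios −2.000, −0.415,
+0.322, +0.807, and exact boundary values round toward fewer copies.

## Classification conventions

Several conventions are stated explicitly because the underlying biology
does not force a unique choice; they are applied consistently by the
caller, the simulator truth, and the 2n accounting:

* **Arm boundary.** The bin containing the centromere belongs to the
  short arm; the arm boundary is that bin's end.
* **Arm copy number** is the length-weighted *mode* of segment copy
  numbers on the arm — a mean would let a terminal deletion drag the
  whole arm down. Ties (a deletion covering exactly half an arm) resolve
  toward the euploid state, then toward fewer copies.
* **Labels.** Equal arms give whole-chromosome states (disomic emits no
  event). Unequal arms give telosomic calls named for the retained arm
  (`ditelosomic:S` = both homologs kept only the short arm); mixed states
  like (2,1) are labelled monotelosomic with the arm copy context
  recorded, since whole-homolog versus telosome configurations are
  cytologically ambiguous from coverage alone. Segments below their arm's
  copy number are `terminal` if they touch a chromosome end, `pericentric`
  if they overlap or abut the centromere bin (an abut rule is a
  convention, not a biological claim), else `interstitial`. Segmental
  *gains* above the arm baseline are reflected in segment copy numbers
  but receive no event label — the vocabulary covers losses, which is
  what this system produces.
* **2n counts chromosome bodies**: each chromosome contributes
  $\max(\mathrm{CN}_S, \mathrm{CN}_L)$, so telocentrics count as bodies
  and a ditelosomic plant still reports 2n = 56. Unequal-arm states
  contribute the larger arm's count by the same rule.

Locus dosage is the minimum copy number over segments overlapping the
locus interval; `present` means copy number ≥ 1. The caller makes no
hypothesis test for "structurally parental" chromosomes — segment mean
log2 ratios are reported so users can apply their own test; defining one
would go beyond what coverage alone supports at these bin counts.

## Numerical and degenerate cases

* A series shorter than two minimum segments is one segment; a whole
  short chromosome may thus be a single sub-minimum segment.
* Chromosomes fully masked for a sample abort the call with an error
  rather than silently reporting nothing.
* A sample with zero total counts is an error naming the sample.
* Floored (−5) segment means map to copy number 0 through the same
  rounding rule; `-Inf` is tolerated for robustness.
* All randomness flows from the config seed through named substreams;
  re-running any stage is bit-identical.

## Problem sizes

The test-suite and demonstration cohorts use the default 28-chromosome,
~1 120-bin genome with 30 genotypes (6 controls) at ≈180 reads per bin:
large enough that whole-chromosome and arm events separate by many
standard errors, small enough that the entire suite — including a
500-case segmentation-oracle battery and a full cohort recovery run —
completes in a few minutes. Null distributions and dosage means are
additionally checked on single-chromosome Poisson cohorts of ≥200 bins
where closed-form means and standard errors exist.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(
  genotypes = list(
    ctrl1 = NULL, ctrl2 = NULL, ctrl3 = NULL,
    dt6A  = dosage_event("6A", "arm:L", 0),     # ditelosomic 6AS
    gbs59 = dplyr::bind_rows(lapply(paste0(1:7, "R"), function(ch)
      dosage_event(ch, "whole_chromosome", 0)))  # whole rye genome lost
  ),
  seed = 1)

res <- run_pipeline(cfg, out_dir = tempfile(), plots = 1)
glance(res$report)      # per-plant 2n, subgenome tallies, status
tidy(res$calls)         # per-segment copy numbers
res$report$loci         # Eml-A1 / Eml-R1b presence
```

The ditelosomic plant reports 2n = 56 (the telosome still counts as a
body) with *Eml-A1* absent; the rye-free plant reports 2n = 42 with
*Eml-R1b* absent.

## Known limitations

* Coverage sees dosage only: balanced translocations, inversions and
  allele-specific composition are invisible.
* Sub-bin breakpoints are not refined; event bounds are bin-aligned.
* The euploid-majority assumption behind recentring fails for genomes
  more than about half aberrant.
* Control quality is the user's responsibility: a control carrying a real
  event biases the reference at its bins.
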