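---
title: "Sizing repeat expansions from optical genome mapping molecules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing repeat expansions from optical genome mapping molecules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogmstr)
```

## The measurement problem

Optical genome mapping (OGM) images ultra-long (hundreds of kb) DNA
molecules whose CTTAAG motif sites are fluorescently labelled (the DLE-1
chemistry). No base-level sequence is read: all structure is inferred from
inter-label distances. That makes OGM blind to small variants but uniquely
suited to very large short-tandem-repeat expansions, which PCR-based assays
cannot traverse, and — because each molecule is a single DNA fragment from a
single cell — to *somatic mosaicism*: the cell-to-cell spread of repeat
tract lengths.

`ogmstr` implements this measurement for a repeat locus bracketed by two
label sites, exemplified throughout by the CTG18.1 CTG repeat in *TCF4*
intron 3 (chr18), whose expansion beyond 50 repeats is the major genetic
risk factor for Fuchs endothelial corneal dystrophy (FECD). The hg38
reference carries 24 CTG units at this locus.

## The corrected reference distance

The locus sits between label site 10,414 (chr18:55,584,360) and site
10,415 (chr18:55,594,648), 10,288 bp apart. Site 10,416 (chr18:55,595,438)
lies only 790 bp beyond 10,415 — below the ~1 kb imaging resolution — so a
molecule shows *one* spot for the pair, randomly at either position. The
reference must therefore be compared at the *average* of the two positions,
giving a companion-averaged distance of 10,683 bp; measuring against the
average makes the random-survivor error (±395 bp) symmetric around zero
instead of a one-sided bias. Subtracting the reference's own 24 x 3 bp of
repeat leaves the corrected reference distance

> d_ref = mean(55,594,648, 55,595,438) − 55,584,360 − 72 = **10,611 bp**,

so that a molecule's expansion size

> expansion = d_obs − d_ref

equals its *full* repeat tract length in bp, and `expansion / 3` its CTG
repeat count. A molecule observed at 24,111 bp between the markers carries
13,500 bp ≈ 4500 repeats. Negative expansion sizes are possible (sizing
noise on short alleles) and are deliberately retained in histograms and
means; removing them would bias every summary upward.

`build_locus()` performs this arithmetic for any marker pair;
`effective_positions()` applies the same sub-resolution averaging to whole
maps (greedy left-to-right on consecutive gaps, means rounded half-up —
half-up is the rule that reproduces the published averaged position
exactly; inputs differing at 0.5 bp could legitimately round either way,
which we note as an interface caveat rather than hide).

## The synthetic molecule generator

Real OGM molecule data for a locus are bulky and vendor-aligned; the
package therefore ships a generator that emulates the *structure* of such
data at desk scale, with ground truth, so the pipeline and its statistics
are testable end to end. What it emulates, and the defaults:

* **Region** (`simulate_region()`): a 1 Mb contig with the three CTG18.1
  markers at their true relative offsets and background labels from a
  hard-core renewal process (minimum spacing 1.2 kb, density 16.3/100 kb).
  Coverage is expressed as molecule count over this fixed region rather
  than genome-wide depth. The hard-core spacing keeps sub-resolution
  collapse confined to the marker pair that motivates the averaging
  correction.
* **Molecule lengths**: log-normal with sdlog 0.55, parameterised by the
  target N50 (default 180 kb; for a log-normal the length-weighted median
  is exp(mu + sigma^2)). This meets the assay's N50 >= 150 kb QC with a
  realistic heavy tail.
* **Alleles** (`allele_model()`): diploid, unphased, fair-coin sampling.
  Mosaicism laws: `point` (none), `truncnorm` (low instability),
  `lognormal` (extreme instability, parameterised by its mode).
* **Tissue profiles**: `leukocyte_profile()` uses a truncated normal whose
  sd grows exponentially with progenitor size (sd0 = 1 repeat, k = 0.025
  per repeat), matching the qualitative observation that blood instability
  accelerates with the inherited allele; `cec_profile()` uses a log-normal
  mode in the 3,900–6,400 repeat range with sigma 0.25, the broad clusters
  seen in diseased corneal endothelium; `f35t_profile()` models the
  immortalised corneal endothelial control line (21-repeat STR-detectable
  allele plus a ~4500-repeat expansion) with sigma 0.02 — a tight cluster,
  consistent with a clonal line whose expansion is stable by Southern
  blot, and tight enough that the truth mode occupies a well-defined
  200 bp histogram bin.
* **Noise** (`noise_model()`): per-label dropout 0.10; spurious labels 0.8
  per 100 kb; Gaussian interval sizing error with sd = max(250 bp, 2% of
  the interval), the 250 bp floor corresponding to the assay's ±500 bp
  lower detection limit; molecule labels within 1 kb collapse to a single
  site with a uniformly random survivor. At these defaults simulated
  molecules carry 14–17 labels/100 kb, the vendor QC window.

What the generator does *not* emulate: optical point-spread imaging,
chimeric molecules, fragile sites, two-channel labelling, and
length-dependent capture bias (real OGM under-samples the longest
molecules; no functional form for this bias is established, so we omit it
rather than invent one — per-sample molecule counts for extreme expansions
should therefore be read as optimistic). Passing tests on synthetic data
show the *pipeline arithmetic and statistics* are correct under the stated
noise structure, not that the noise structure captures every failure mode
of real chips.

## Alignment

Real studies align molecules with the vendor tools and hand this package
the XMAP/CMAP output (`read_xmap()`, `read_cmap()`). For synthetic data the
package includes `align_molecule()`, a deliberately simplified
restriction-map-style dynamic programme over monotone label pairings:
matched pairs earn a bonus (default 5), skipped labels cost 3 per label on
either sequence, and each matched interval pays `1e-5 * (ref gap − qry
gap)^2` — except the declared locus interval, which is size-cost free so
that arbitrarily expanded molecules still align. Ends are free; ties break
toward more pairs, then the leftmost reference placement; both orientations
are tried. Alignments need at least 3 matched labels on each locus flank;
molecules with fewer than 5 labels are rejected. On small instances the DP
is verified against exhaustive enumeration of all monotone pairings.

A consequence worth knowing: when a marker label drops out *and* a spurious
label lands at a coincidentally compatible position, the aligner can anchor
the locus on the impostor, producing an isolated molecule far outside the
allele clusters (ca. 0.3–1% of molecules at default noise). Real OGM shows
exactly this class of single non-clustering artifact molecules, attributed
to misalignment of long repetitive regions with sparse labels. Following
that practice the pipeline retains them by default;
`summarize_sample(min_cluster_support = k, cluster_bin_width = w)` offers
the optional filter (drop molecules with fewer than k neighbours in their
w-bp bin) for analyses, like cluster-exclusivity questions, where isolated
artifacts are not evidence.

## Sizing and summaries

`select_spanning()` keeps alignments covering the upstream marker and at
least one of the downstream/companion pair — only such molecules bracket
the repeat. `size_molecule()` measures the molecule-frame distance from the
upstream site to the downstream representative (the mean of both sites when
both resolved), subtracts d_ref, and reports bp and repeats.
`histogram_sizes()` uses half-open 200 bp bins (negative bins allowed);
`summarize_sample()` reports molecule count, mean and maximum expansion —
both alleles pooled, since OGM molecules here cannot be phased — and the
fraction of molecules above a configurable 2000 bp "expanded" threshold,
used descriptively: expanded-allele clusters above it appear only in
expansion-positive affected tissue.

## The statistical layer

The downstream instability statistics operate on per-sample summaries
joined with subject metadata (`subject_records()`; expansion-positive is
defined as a progenitor allele >= 50 repeats):

* `anderson_darling()` — composite normality (via `nortest`), the check
  that motivates non-parametric and log-scale analyses downstream.
* `spearman_ci()` — midrank correlation with a percentile bootstrap CI
  (default 2,000 resamples) that resamples *subjects*, not molecules, when
  molecule-level observations are clustered within subjects. The bootstrap
  design is our choice; the original report does not state its CI
  construction.
* `mann_whitney()` / `wilcoxon_paired()` — two-sided throughout, exact
  null distributions at small n (pooled n <= 12, resp. <= 15 tie-free
  non-zero pairs; zeros dropped), normal approximation with tie correction
  otherwise. Nine paired samples that all shift the same way give the
  smallest attainable exact two-sided p, 2/2^9 ≈ 0.0039 — the
  configuration a fully consistent tissue contrast produces.
* `fit_log_linear()` — OLS on log mean molecule size with mean-centred
  progenitor size, age, and their interaction. Centring is applied before
  forming the product so the main effect and interaction decorrelate; the
  fit reports that correlation before and after centring. No
  multiple-testing correction is applied, and ancestry and sex are not
  modelled. Cohort-level coefficients from any particular study depend on
  its raw cohort data; the package validates this layer by parameter
  recovery on `simulate_cohort()` draws instead.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use a 1 Mb region, 2,000
molecules per profile for noiseless end-to-end checks (~300 spanning),
~1,800 molecules for the F35T-like fixture (~250 spanning, matching the
per-sample locus-molecule counts real 400X runs deliver), and 800 per
sample for the nine-subject tissue contrast — sizes chosen so each check
constrains what it claims while the whole suite stays desk-scale.
Positions are integers bp internally; BNX/CMAP/XMAP positions are written
with one decimal as in the wild and round-trip losslessly at that
precision. Averaged positions round half-up. RNG seeds parameterise every
stochastic entry point; identical seeds give byte-identical BNX output.

## Known limitations

* The built-in aligner is for synthetic data; it makes no attempt to
  reproduce vendor confidence scores.
* No allele phasing and no mixture-model allele deconvolution: histogram
  clusters are reported descriptively. A per-allele decomposition would
  need either phasing information or a mixture fit whose component count
  is not identifiable for heavily mosaic tissues.
* Expansions are assumed to change only the inter-marker interval;
  interruptions, flanking rearrangements and repeat motifs containing
  label sites are out of scope.
* Only label channel 1 and single-enzyme maps are supported.
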