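---
title: "Models and methods behind panelvaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind panelvaf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelvaf)
```

## The problem

Clinical tumor specimens sequenced on deep targeted panels routinely
carry actionable mutations at low variant allele fraction (VAF).
Two mechanisms push VAFs down: low tumor purity (a biopsy that is 20%
tumor cells halves a 40% clonal VAF to 8% before sequencing ever sees
it) and treatment-induced resistance clones, which are subclonal by
construction. Whether a panel assay can see a 2--5% variant is then a
question about sequencing depth, the error model, and the calling
pipeline jointly — which is exactly what a *limit of detection* (LOD)
calibration quantifies: the lowest VAF detected with at least 95%
sensitivity at a given depth, or equivalently the depth at which a
given VAF reaches 95% sensitivity.

`panelvaf` implements that calibration and the surrounding pipeline:
synthetic panel pileups, a reference SNV detection model, germline and
artifact filtering, purity inference, purity-adjusted copy number
calls, split-read fusion calls, and digital PCR concordance summaries.
Every stochastic stage takes an explicit seed and every pipeline run
writes a manifest, so results are reproducible bit for bit.

## The synthetic-data generator

The unit of simulation is the *deduplicated pileup*: per-site depth,
variant-supporting read count, stranded counts, and the 0-based offsets
of the variant base within its supporting reads. No read-level
FASTQ/BAM is synthesized.

* **Depth** is negative-binomial around `depth_mean` (panel capture is
  overdispersed; a Poisson model would understate coverage
  unevenness), thinned binomially by `dedup_fraction`. The default
  nominal depth of 1000x with `dedup_fraction = 0.8` reflects the
  common situation in FFPE libraries where roughly a fifth of nominal
  coverage is lost to duplicate removal (~800x effective against a
  ~1000x target).
* **Variant reads** are binomial at the expected VAF implied by purity
  `P`, clone fraction `c` and tumor copy state (`Y` variant copies of
  `X` total): `(P c Y) / (P c X + 2 P (1 - c) + 2 (1 - P))`.
* **Errors** occur at rate 0.001 per base, split uniformly over the
  three non-reference bases; only the designated alternative base
  counts toward `alt_count`. A single global error rate is assumed —
  real platforms have context-dependent error profiles, which the
  generator deliberately does not model.
* **Read offsets** are uniform on `[0, 99]` (100 bp reads).

The generator emulates the statistical structure the downstream
analyses assume — binomial allele sampling, overdispersed coverage,
purity dilution. It does not emulate alignment artifacts, FFPE damage
chemistry, GC tracks, or error-rate heterogeneity, so green tests here
say the *algorithms* are correct under their stated model, not that
the model exhausts real panel data.

## The reference detection model

Production pipelines for this problem combine multiple callers with
post-hoc filters. `panelvaf` instead declares a transparent reference
model with three exposed knobs (`detection_model()`): a site is called
when

1. `alt_count >= min_alt_reads` (default 4),
2. the upper-tail binomial probability of that many reads arising from
   error alone — rate `error_rate / 3` for one specific alternative
   base — is below `alpha` (default `1e-6`), and
3. the VAF clears `min_vaf`, if set.

The defaults are deliberately config-exposed: the depth a real assay
needs at a given VAF depends on the composite behavior of its actual
callers and filters, and a single binomial test is more permissive at
low VAF than a multi-caller consensus constrained to high positive
predictive value. The calibration depths this package computes for its
reference model are therefore expected to sit *below* what an
assay-grade pipeline requires at 2--5% VAF, and the package makes no
claim otherwise; the model is a reference point, not a caller.

## LOD calibration by in silico dilution

`run_dilution_grid()` implements the dilution assay. Heterozygous
substrate SNPs (the calibration default is 222 sites at ~1500x) are
diluted to each target VAF by converting each variant read to
reference with probability `1 - target / observed`, using the site's
*observed* VAF as the denominator — manual dilutions suffer from the
realized concentration differing from the intended one, and the in
silico assay removes exactly that nuisance. Trials are then binned by
*realized* VAF with a relative half-width of 20%, so a nominal 2% cell
only contains trials whose diluted VAF landed in 1.6--2.4%.

Each diluted site is thinned to a grid of depths. Two thinning modes
exist:

* `"pool"` (default): every read is kept independently with
  probability `d / depth`, emulating down-sampling a sequencing pool
  at a fraction; realized depths vary binomially.
* `"fixed"`: exactly `d` reads are drawn without replacement
  (hypergeometric). This pins the depth and is the design matched by
  the exact binomial oracle below.

The distinction matters at small depths: under pool thinning the
realized depth is approximately Poisson, and for the single-read rule
at 40% VAF the 95%-sensitivity depth shifts by over 20% relative to
the fixed-depth answer. The package tests therefore validate the
probit machinery in fixed mode and run the headline calibration in
pool mode.

Sensitivity per cell is `n_detected / n_trials`; `fit_probit()` fits a
maximum-likelihood probit of detection on `log10(depth)`,

$$\mathrm{sens}(d) = \Phi(a + b \log_{10} d),$$

and `depth_for_sensitivity()` inverts it in closed form,
`10^((qnorm(s) - a) / b)` with `s = 0.95` by default (the conventional
"consistently detected with >=95% sensitivity" definition). The
covariate is `log10(depth)` because calibrations span nearly two
orders of magnitude of depth; a linear-depth probit would be dominated
by the deep end of the grid.

Numerical choices: bins with zero trials are dropped before fitting;
complete or quasi-complete separation (every depth bin fully detected
or fully missed, a warning from the fitter, or an implausibly steep
slope) triggers a bias-reduced refit with Jeffreys-type pseudo-counts
— half a success and half a failure added per bin — and the fit is
flagged. `lod_at_depth()` reports, for a query depth, the smallest
calibrated VAF whose 95% depth is at or below it, flagging queries
outside the calibrated range instead of silently extrapolating, and
`lod_report()` annotates whole position lists this way, marking
zero-depth positions "no power" and positions whose best attainable
LOD exceeds a configurable ceiling "insufficient power". Reporting LOD
per position is more informative than reporting depth alone: it folds
the error model and pipeline behavior into the number a clinician
actually needs when a variant is *not* called.

`detection_rate_by_downsampling()` is the companion patient-data
analysis: sites detected at full depth are hypergeometrically
downsampled (10 iterations per depth by default) and the mean
detection rate per depth is reported with its standard error.

## Purity from clustered SNP allele fractions

For a germline heterozygous SNP in a mixed specimen where the tumor
clone (cell proportion `P`) carries `Y` alternative copies of `X`
total, the expected alternative allele frequency is

$$A = \frac{P Y + (1 - P)}{P X + 2 (1 - P)},$$

with normal cells contributing one alternative and two total alleles.
Copy-neutral heterozygous sites (`X = 2, Y = 1`) give `A = 1/2` for
every `P` and carry no information; informative sites are those under
copy gain or loss. The inversion is closed-form,
`P = (2A - 1) / (Y - 1 - A (X - 2))`, clipped to `[0, 1]`;
configurations with a vanishing denominator are skipped.

`find_copy_state_regions()` locates the copy-neutral baseline: among
SNPs with near-balanced allele fractions (0.4--0.6), the most
prominent peak of the coverage density is taken as the diploid depth —
resting on the observation that tumors tetraploid across the *entire*
genome are rare, so the dominant coverage mode is diploid. Contiguous
panel segments (gaps over 100 kb start a new segment) are labeled gain
or loss when their mean coverage ratio against that baseline exceeds
1.15 or falls below 0.85.

Within a segment, each SNP's alternative allele sits on an arbitrary
haplotype, so the observed AAFs split into two mirror branches with
`A_upper + A_lower = 1`. The estimator folds each SNP to
`max(A, 1 - A)` and pools the folded counts depth-weighted; the full
`(X, Y)` hypothesis grid `{(1,0), (1,1), (2,2), (3,1), (3,2), (4,1),
(4,3)}` is still enumerated per label, and lower-branch hypotheses
eliminate themselves through the residual screen (absolute model-AAF
residual above 0.05 discards a solution). Among surviving hypotheses
the one whose implied coverage ratio `(P X + 2 (1 - P)) / 2` best
matches the observed segment ratio wins.

Two identifiability limits are worth stating plainly. First, `(3, 2)`
at purity `P` and `(4, 3)` at purity `P/2` generate *identical*
expected AAF and coverage ratio, so panel data cannot separate them;
ties break toward the smaller total copy number. Second, below ~30%
purity a one-copy gain or loss moves segment coverage by under 15% and
tends to be labeled neutral — one concrete reason purity estimates
below the 0.30 reliability floor are flagged and not annotated.
Specimen purity is the *maximum* of the per-cluster clone proportions,
on the reasoning that the largest clone best represents the tumor
fraction; subclones only pull individual clusters down.

## Filtering and classification

Without matched normals, germline variants are removed by rules, each
an independent flag (so filter order cannot matter):

* VAF at or above 97% at a non-hotspot position (ties removed; the
  rule applies to raw VAF, before any purity consideration);
* population allele frequency strictly above 3% in a panel-of-normals
  cohort (computed as carrier-allele fraction, dosage sum over `2N`;
  positions absent from the cohort count as frequency 0);
* membership in a curated blacklist of recurrent artifact positions;
* a logistic-regression artifact score above its ROC-selected
  threshold.

The regression filter uses four features: an indel within 25 bp, the
count of other candidates within 50 bp, strand bias as `-log10` of the
two-sided Fisher exact p-value on the stranded 2x2 table, and read
position clustering as `1 - sd(offsets) / sd_uniform` clipped to
`[0, 1]` (a site whose variant base always appears at the same read
offset scores near 1; fewer than two supporting reads score 0 since a
single read cannot exhibit clustering). The windows are package
choices, exposed as arguments. Training labels — in practice, low-VAF
calls in normal samples enriched for positions with aberrant
transition/transversion behavior — are supplied by the caller; the
package does not hard-code a label rule because no principled cutoff
for "aberrant" exists, and the decision threshold is chosen on the
training ROC by maximal Youden index, with a cross-validated AUC
reported. Perfectly separable training data are refit with a small
ridge penalty and flagged.

Tier classification is positional: actionable list membership gives
Tier 1, COSMIC membership Tier 2, everything else Tier 3; fusions with
a known partner gene are Tier 1 and novel partners Tier 2.

## Copy number and fusions

Exon depths are normalized by the sample's overall target coverage,
then standardized by the per-exon median of similarly normalized
depths across at least three normal samples — per-exon
standardization absorbs capture-efficiency and GC effects without an
explicit GC regression. The standardized ratio `R` is inverted for
tumor copy number through the purity mixture `R = (P C + 2 (1 - P)) /
2`, floored at `C = 0`, and expressed as `log2(C / 2)`; "log scale" is
read as log2, the copy-number convention. Genes aggregate exon
amplitudes by the median, and calls use *strict* inequalities at
+/-1 log2 units (an amplitude of exactly 1 stays neutral). Per-sample
mean normalization assumes the panel is dominated by copy-neutral
territory; a panel where one amplified gene is a large share of the
target would bias `R` downward everywhere else.

Fusion calling consumes split-read records over tiled introns:
records agreeing within 10 bp on both sides of a breakpoint cluster
into a candidate, counting both primary and secondary alignments. A
candidate is called when, after read filters (mapping quality >= 20,
matched segment >= 20 bp — package choices for filter features whose
thresholds are not standardized), it keeps at least 4 split reads
with at least 2 per side and at least 80% strand-orientation
concordance. Breakpoints are the modal supported position, ties to
the smaller coordinate. Discordant-pair evidence and assembly are out
of scope: with ~180 bp fragments and 100 bp reads, most fragments are
fully sequenced and split reads are the dominant evidence class.

## Digital PCR

Droplet counts convert to mean copies per droplet via the Poisson
zero term, `lambda = -ln(1 - n_positive / n_total)`; saturated wells
are an error rather than an estimate. VAF is
`lambda_mut / (lambda_mut + lambda_wt)`. The default droplet volume
(0.85 nL) feeds only absolute concentration, never VAF. Concordance
between panel and dPCR VAFs is a plain Pearson correlation with an
optional stratification by sequencing depth, and cohort VAF summaries
count calls *strictly* below each threshold (ties at a threshold are
not "below" it).

## Problem sizes and determinism

The test suite runs its simulations at sizes chosen to keep Monte
Carlo error well inside the asserted tolerances while staying quick:
dilution grids use 200--300 substrate sites with 8--12 replicates per
cell (about 2,000--3,000 Bernoulli trials per grid cell), purity
recovery uses 210 SNPs over five segments per purity level, and the
CNV end-to-end check uses 100 seeded replicates of a 20-gene panel.
The LOD acceptance calibration itself uses 222 substrate sites at
~1500x, five target VAFs, a 12-point log-spaced depth grid and 10
replicates per cell. All generators are bit-reproducible given a
configuration and seed.

## Known limitations

* The reference detection model is a declared stand-in; its 95%
  depths at 2--5% VAF are lower than a production multi-caller
  pipeline with a positive-predictive-value constraint would need.
  Treat the calibration as a property of the model you configure.
* The purity estimator resolves neither the `(3,2)`-vs-`(4,3)`
  degeneracy nor sub-30% purity, by construction.
* A single global base error rate; no FFPE damage or alignment
  artifact model.
* No indel calling, no functional annotation, no segmentation across
  genes, no allele-specific copy number.
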