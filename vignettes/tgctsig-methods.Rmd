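---
title: "Methods: mutation and copy-number signature analysis in tgctsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation and copy-number signature analysis in tgctsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tgctsig` reimplements, as a tested pipeline, the computational procedures of
a multi-cohort testicular germ-cell tumour (TGCT) genomics analysis: somatic
variant harmonisation, mutation burden and clonality, SNV and copy-number
(CN) signatures, aneuploidy scoring, covariate-adjusted association testing,
and longitudinal force-calling with CN phylogenies. Because the real cohorts
are controlled-access, the package ships a synthetic cohort generator that
plants every statistical structure the downstream stages assume, with ground
truth, so that each stage can be validated by parameter recovery. This
vignette records the models, the tunable parameters, and the design decisions
taken where the underlying procedures left choices open.

## Variant filtering

Calls are retained when made by at least 2 of 3 callers; read evidence must
show at least one alternative read per strand, mean base quality >= 26 and
mean mapping quality >= 50; SNVs need >= 5 (indels >= 10) supporting reads and
VAF >= 0.05. All thresholds are inclusive on the stated side ("or more", "or
greater", "at least"). Calls failing the read-support filter are rescued by a
knowledge-base driver flag, a catalogue count >= 50, or by the identical
variant passing in a second tumour of the same case; rescue applies only to
read-support failures, never to consensus failures (a flag exposes the
alternative). A variant rescued via tumour B re-enters tumour A's call set.
The cross-dataset artifact rule removes genes and variants at >= 10% case
frequency in one dataset and < 1% in every other; it runs at both gene and
variant granularity and the union is removed. Capture intersection uses
half-open 0-based coordinates internally (BED native), 1-based positions at
the VCF/MAF boundary; the intersect size in bases is carried forward as the
burden denominator. The oxidation-artifact strand filter is applied to all
variants by default; `oxog_only_ca = TRUE` restricts it to C>A/G>T candidates
(whether the original procedure restricted it is not documented).

## Mutation burden and clonality

TMB is mutations divided by intersect bases, per megabase, reported for all
mutations and the nonsynonymous subset. Multiplicity uses
`m = VAF (p CNt + 2(1-p)) / p` with local total copy number taken from the
overlapping CN segment; where no segment overlaps, ploidy rounded to the
nearest integer is substituted and the substitution is recorded per variant.
`m > 0.8` (strict) flags a clonal mutation. Driver triage takes the two
significance algorithms' p/q values as *inputs* (their internals are out of
scope): Definitive = q < 0.05 in both, Likely = q < 0.05 in exactly one,
Putative = nominal p < 0.05 in at least one AND >= 95th centile of recurrent
driver-variant counts AND > 50% known driver variants — the three Putative
criteria are required jointly (they read as a conjunction); `putative_any`
switches to any-of. Pathway assignment uses fixed, mutually exclusive gene
sets (RAS/RAF, PI3K/MTOR, WNT/CTNNB1, DNA repair, chromatin modification).

## SNV signatures

Spectra are 96-channel trinucleotide counts in the pyrimidine-reference
convention; the channel order is fixed (substitution class outer, 5' flank
middle, 3' flank inner) and purine-reference calls are reverse-complemented.
Fitting is iterative forward selection: at each step the signature whose
inclusion (weights refit by non-negative least squares on the normalised
spectrum) most reduces the sum of squared differences is added, until the
improvement falls below `tol`; fitted weights below 0.06 (the conventional
minimum-weight cutoff of signature-refitting tools; configurable) are zeroed
and the rest refit; weights plus the unexplained residual sum to 1. The
error metric is SSE on the normalised 96-vector, with cosine distance as an
option; exome-vs-genome trinucleotide renormalisation is off by default.
Samples are fit individually only at >= 50 SNVs; group-level fits pool
spectra by element-wise summation first. The bundled 30-signature reference
(`synthetic_snv_signatures()`) is **synthetic** — a deterministic sparse
stand-in with well-separated rows, because the real catalogue is third-party
data; `read_signature_matrix()` loads a real catalogue TSV.

## Copy-number features, encoding and signatures

Six features are computed per sample from the segmented absolute CN profile:
segment size (Mb), breakpoints per 10 Mb window, absolute CN change at
adjacent-segment junctions, segment CN (non-integer values retained
throughout), breakpoints per scored chromosome arm, and lengths of maximal
chains of segments alternating between two integer-rounded CN states
(chains of >= 3 segments). Decisions the feature definitions leave open,
resolved here: 10 Mb windows are non-overlapping tiles from each chromosome
start (a deterministic special case of sliding windows); windows and arms
with zero breakpoints are reported (zero counts are informative for
low-breakpoint signatures); a breakpoint is a junction whose *rounded* total
CN differs across it, while change-points use the raw difference at every
junction. The genome model is a bundled build-37 autosome table (22
chromosomes, approximate centromere midpoints, 5 acrocentrics, 39 scored
arms); the X chromosome is excluded from all analyses.

Each feature observation is scored against a 36-component mixture model
(Gaussian for size/change-point/CN, Poisson for the three count features;
default split 10/3/7/8/5/3) and the posterior probabilities are summed,
giving a 36-entry sum-of-posteriors encoding whose per-feature block totals
equal the observation counts. The bundled component model is synthetic (the
reference model fitted on an external cohort is not redistributable);
`fit_component_model()` refits one by EM, selecting per-feature component
counts by lowest BIC when not fixed. Gaussian mixtures delegate to `mclust`;
the Poisson EM is implemented in the package. Samples with purity < 0.40 are
excluded before encoding.

NMF uses multiplicative updates under the KL objective by default (Frobenius
available), best of `n_restarts` random initialisations, with mandatory
seeds; after fitting, signature rows are normalised to sum to 1 and exposures
carry the scale. Rank selection surveys candidate ranks on the observed
matrix and on column-permuted replicates, recording cophenetic correlation
and dispersion of the restart consensus matrix, consensus silhouette, and
best-fit RSS from a chained warm-start sweep (each rank is also initialised
from the previous rank's best factors, making the RSS sequence monotone —
random-restart noise otherwise inflates apparent improvements at high
ranks). The codified decision rule: a rank qualifies when its cophenetic
correlation and dispersion exceed the permuted null's 95th percentile, its
*relative* RSS improvement over the previous rank exceeds both the null's
95th percentile and its mean plus three standard deviations (the relative
scale makes observed and null comparable; the dual threshold compensates for
the sampling noise of a quantile estimated from a modest number of
permutations), and the *next* rank's relative improvement does not — i.e.
the rank at which detectable structure is exhausted. The chosen rank is the
largest qualifying one; the survey range should extend one rank beyond the
largest plausible rank (the top of the range can never be chosen), and all
raw measures are reported so users can override. Signature matching maximises
total Pearson correlation over one-to-one assignments by exhaustive search
(global, not greedy, since greedy can mis-pair correlated signatures).
Exposure presence uses strict `> 0.05` on row-normalised exposures,
normalised before thresholding.

## Aneuploidy

The aneuploid genome fraction is the base count in segments whose rounded
total CN differs from rounded ploidy, over all segment bases. Arm events are
called from the segment-length-weighted mean of `log2(CN / round(ploidy))`
per scored arm at threshold |0.1| (strict); this documented arm-caller
replaces an external peak-calling tool, and operates on the ploidy-corrected
scale for consistency with the fraction metric. The aneuploidy score counts
non-neutral arms among the 39 scored arms (p and q of non-acrocentric
autosomes; q only of 13, 14, 15, 21, 22). Group comparisons use two-sided
Fisher's exact tests per arm with nominal hits flagged for follow-up
covariate-adjusted regression.

## Association machinery

Logistic (logit link) and linear models are fit by IRLS on complete cases
with dropped-row counts reported; separation is flagged. Backward stepwise
elimination removes the covariate with the largest Wald p until all remaining
p-values are below `alpha`; the exposure of interest can be protected from
removal (on by default in the analysis scripts — otherwise a reported
association could eliminate itself). Likelihood-ratio tests use the
chi-squared distribution on twice the log-likelihood difference. The
permutation linear model permutes the outcome and reports
`p = (1 + #{perm >= obs}) / (1 + n_perm)`. Group comparisons use two-sided
Wilcoxon *rank-sum* tests with Benjamini-Hochberg adjustment: the compared
groups are unpaired, so the rank-sum form is implemented even though
signed-rank is sometimes named for this comparison in descriptions of the
procedure; the discrepancy is noted here.

## Longitudinal analyses

Force-calling: present at >= 2 supporting bases; absent at < 2 supporting
bases and >= 50x depth; otherwise indeterminate (insufficient coverage to
assert absence). Sharing classes: truncal = present in all tumours of a
case; primary-/metastasis-only = confined to that compartment; indeterminate
sites are excluded from the denominator by default, with a strict mode that
makes any indeterminate site unclassifiable. Jaccard concordance is reported
as a percentage, 0 when both sets are empty.

The CN phylogeny distance is a minimum-event count: per chromosome and
allele (copy numbers rounded and capped at 4), the minimum number of
contiguous +/-1 segmental events transforming one profile into the other,
computed in closed form from the increments of the positive and negative
parts of the difference profile; an allele lost to zero copies cannot be
regained (infinite distance), consistent with the irreversibility semantics
of event-based CN phylogeny tools whose full finite-state-transducer distance
this deliberately simplifies. The closed form is verified in the test suite
against an exhaustive breadth-first-search oracle over the operation
semantics. Profiles are re-segmented to the union breakpoint grid
(`align_profiles()`), a diploid pseudo-sample is appended, distances are
symmetrised by the maximum of the two directions, and neighbour joining
(via `ape`) builds the topology, rooted at the diploid outgroup, with taxa
sorted by id for deterministic tie-breaking.

## The synthetic cohort generator

The generator's defaults are the study conditions assumed throughout the
tests: 39% platinum-resistant cases, 33% seminomas, 7.5% extragonadal
primaries, four datasets of unequal size (fresh-tissue vs FFPE material tied
to dataset), purity ~ Beta(7, 3), ploidy ~ N(3.0, 0.6) truncated to
[1.5, 4.8] so that ~80% of samples are hyperploid (> 2.5), mean depth 130x
(Poisson), a 30 Mb capture intersect, nonsynonymous burden 0.33/Mb with a
planted +0.35/Mb shift in resistant cases and 0.10/Mb synonymous, per-case
CN-signature exposures Dirichlet(1) over five signatures (implying each
signature present at > 5% exposure in ~81% of samples), 60 CN events per
sample, truncal fraction 0.5 for both variants and CN events, caller
sensitivities 0.97/0.95/0.90 with 0.5 false positives per caller per sample,
85% clonal variants, and one extra metastatic CN event per month since
diagnosis (months uniform on 6-48). VAFs follow the multiplicity model with
binomial read sampling; trinucleotide spectra are drawn from group-specific
reference-signature mixtures in which the deamination-clock signature is
absent from platinum-sensitive seminomas and the HR-deficiency signature is
reduced in resistant disease.

Copy-number profiles are generated at two levels of realism, and the
distinction matters for what passing tests demonstrate:

* `generate_cn_profile()` realises an actual segmentation: events drawn per
  signature (sizes and copy numbers from the signature's mixture blocks,
  placement clustered over arms to match the signature's breakpoint-per-arm
  mean, oscillating trains for signatures weighted on long oscillation
  components) are overlaid on a ploidy background. The event count per
  profile is fixed (allocation across signatures is multinomial in the
  exposures), because exposures are defined as event-count shares and a
  fixed total keeps them identifiable. Features re-extracted from such a
  profile include interactions — overlapping events create hybrid
  change-points, count histograms respond nonlinearly — so encodings are
  only approximately linear in exposures, as with real data.
* `sample_cn_features()` draws feature values directly from the
  exposure-blended mixtures (the generative inverse of the posterior
  encoding). Expected encodings are then exactly linear in exposures, which
  is the regime in which factorisation rank is well defined; the rank-
  recovery validation uses this path, while round-trip and exposure-recovery
  checks also use the full profile path. Neither path emulates real-data
  segmentation artifacts (wavy baselines, purity mis-estimation, FFPE
  degradation), so passing tests validate the pipeline's statistical
  machinery, not robustness to platform noise.

The five bundled generative CN signatures are synthetic, with nearly
disjoint component usage (whole-arm exchanges; LOH-like single-copy changes;
intermediate-state events; chromothripsis-like clustered small segments with
oscillation; focal high-amplitude amplification). Their component-space
profiles — what a factorisation can recover, baseline included — are
computed by Monte Carlo (`reference_encodings()` for the profile path,
`expected_encodings()` for the direct sampler) rather than asserted, and
matching of fitted signatures is always against these.

## Numerical choices and degenerate inputs

Mixture EM stops at a relative log-likelihood change of 1e-8 (Poisson) and
uses `mclust` defaults (Gaussian); observations with zero density under all
of a feature's components get a uniform posterior with a warning. NMF
updates stop when the objective change falls below 1e-9 relative (1e-7 inside the
rank survey's consensus runs); zero rows/columns are guarded by an epsilon of
1e-12. Empty variant sets, empty groups, single-tumour cases, zero spectra,
constant covariates, non-nested models and mismatched segment grids raise
explicit errors or warnings rather than propagating NaNs. Ties in neighbour
joining are broken by sorting taxa by id. The problem sizes used by the test
suite and the acceptance script (cohorts of 150-300 cases, 200-sample
signature cohorts, 10-seed rank-recovery studies, 1000-replicate GLM
calibration) were chosen as the smallest sizes at which the planted effects
are comfortably identifiable.

## Known limitations

The bundled SNV and CN references are synthetic stand-ins; conclusions about
real catalogues require loading the real matrices. The arm-caller is a
documented replacement for an external tool and agrees with it only at the
whole-arm level it is validated for. The minimum-event distance simplifies
the full transducer algebra (no separate whole-chromosome events, no
duplication-specific costs). Rank selection beyond the linear-encoding
regime is conservative: on full segmentation-derived cohorts the encoding
carries genuine interaction structure above the planted rank, and the survey
reports all measures so the user can judge. De novo signature extraction,
indel/doublet signatures, focal-peak deconvolution and subclonal
reconstruction are out of scope.
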