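---
title: "Models and methods: somatic evolution in normal tissue from duplex sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(duplexsoma)
```

# The problem

Duplex sequencing reads both strands of each original DNA molecule and only
reports bases on which the two strands agree, pushing the error rate far below
the ~10^-3 of standard short-read sequencing. At 30,000x duplex depth over a
small targeted panel, somatic mutations present in single cells of a
histologically normal biopsy become detectable: most calls sit at variant
allele frequencies (VAF) around 3 x 10^-5 to 1 x 10^-4, i.e. in clones of a
handful of cells. This package implements the downstream analysis of such
data: post-consensus variant filtering, contamination QC from germline SNP
B-allele frequencies, per-cell mutation burden, mutational-signature exposure
refitting with per-mutation attribution, dose-response estimation for
exposures (ageing, smoking, alcohol, platinum chemotherapy, alkylating
agents), and coverage-adjusted dN/dS selection inference. A synthetic cohort
generator with complete truth records makes every stage testable without
access-controlled patient data.

# Per-cell mutation burden

With N sequenced molecules at a site, a heterozygous mutation carried by a
fraction f of cells is seen at VAF approximately f/2. Summing over all
mutations j in a sample and dividing by the effectively sequenced megabases
L gives the mutations per Mb carried by an average cell:

    beta = 2 * sum_j VAF_j / L_Mb

`estimateBurden()` implements this identity; the genome-scale value multiplies
by a configurable haploid genome size (default 3,000 Mb — the factor 2 for
diploidy is already inside beta). The estimator is linear in the VAFs and
unbiased under the generator's observation model (see below). Burden is
computed per variant type (SBS, DBS, indel); per-signature components multiply
the SBS burden by fitted exposure fractions.

# The variant filter cascade

`runFilterCascade()` evaluates five independent rule families; because rules
are independent, the set of failed rules per variant does not depend on
evaluation order.

* **Basic quality.** Point mutations fail when mean mismatches in supporting
  reads exceed 4, when the no-consensus (N) fraction exceeds 0.05, or when
  duplex depth falls below the sample median minus three depth standard
  deviations; indels use an N-fraction bound of 0.10, the same coverage rule,
  and a microsatellite-length bound of 5. All bounds are strict inequalities.
* **Read-position artefacts.** Recurrent artefacts concentrate the mutant
  base at a fixed offset within reads. Positions are pooled across all
  occurrences of a distinct variant and tested against the uniform
  distribution on the read span with a one-sample Kolmogorov–Smirnov test
  (the uniform null is the standard artefact model; the span is treated as
  continuous on [0.5, read_length + 0.5] so integer positions sit at cell
  centres). Benjamini–Hochberg correction is applied within this family and
  q < 0.05 flags the variant. At least five pooled positions are required;
  smaller groups are recorded as untested. Pooling across occurrences (rather
  than testing per sample) is a design choice: artefacts recur, so pooling
  maximises power exactly where it matters.
* **Germline SNPs.** Within a patient, a variant with VAF > 0.95 in every
  sample is a homozygous SNP; one present in every sample with VAF in
  [0.01, 0.85] is heterozygous. Single-sample patients degenerate to that one
  sample.
* **Cohort contamination.** Each variant observed in more than 20 calls
  cohort-wide is tested under a global binomial model: p = P(X >= total alt
  molecules | Binomial(total molecules across occurrences, r)) with r the
  cohort mean per-call VAF. BH within the family, q < 0.05 removes the
  variant unless it is a curated driver hotspot. The global-rate reading of
  the binomial parameterisation is isolated in one function so it can be
  swapped.
* **Blood-like classification.** With a blood sample: variants found in blood
  and in strictly more than 25% of non-blood samples are blood-like (curated
  EGFR/PIK3CA/KRAS hotspots become "suspicious" instead); variants absent
  from blood but in more than 50% of non-blood samples are suspicious.
  Without blood, more than 50% of samples makes a variant blood-like.
  Blood-like calls are real mutations of the blood: they are removed from
  non-blood samples (infiltration) and from selection analyses but retained
  in the blood sample's own somatic set, so blood burden is not deflated.

Sites failing any family except the KS test alone form the blacklist used by
the selection stage (KS failures are read-level artefacts, not unreliable
sites).

# Sample-level QC from B-allele frequencies

Heterozygous SNPs should sit at BAF 0.5; copy-number change or cross-sample
contamination shifts them coherently. `assessAllelicImbalance()` applies
exact two-sided binomial tests per SNP against 0.5 and against the per-locus
median across the patient's samples, and flags a sample when the fraction of
deviating SNPs exceeds three times the fraction expected under the null at
alpha = 0.05 (the source analyses give no numeric cut-off; this multiplier is
exposed in `qcConfig()`). The binomial p-value is computed with tail sums and
a binary search rather than a full support scan, which matters at duplex
depths of 30,000; it reproduces `binom.test` to 10^-12.

`sharedImbalanceTest()` detects contamination against a sequenced tumour:
tumour-imbalanced SNPs (binomial p < 0.05, uncorrected, as in the source
design) are split into "high" and "low" by whether the tumour BAF exceeds its
median; under contamination the normal sample inherits the direction, so a
one-sided Mann–Whitney test (exact at small n) compares its BAFs between the
two groups. "One-way Wilcoxon" is interpreted as this one-sided Mann–Whitney
with the high group expected higher — the only reading under which the test
detects directional inheritance.

`bafCosineClustering()` mean-centres the BAF vectors (removing the trivial
0.5 baseline that would make all samples similar), computes pairwise cosine
similarity, clusters with average linkage and cuts at similarity 0.5; samples
sharing a cluster with a tumour are excluded. The threshold and linkage are
package choices exposed in the configuration, since the source names neither.

# Signature refitting and attribution

De novo signature extraction (hierarchical Dirichlet processes) is out of
scope by design; the package refits exposures of a fixed catalogue. For a
sample with channel counts n_c and catalogue S (channels x signatures), the
exposures e maximise the multinomial likelihood sum_c n_c log(sum_k e_k
S_kc), by EM from a uniform start to a log-likelihood tolerance of 10^-8
(cap 10,000 iterations; the likelihood is asserted non-decreasing). In the
large-count limit this is equivalent to non-negative least squares on
frequencies. Identical catalogue columns are flagged non-identifiable.

Maximum-likelihood refitting of a large catalogue against a few hundred
mutations leaks a few percent of exposure onto absent signatures (the
boundary constraint only cuts one side). `fitExposuresRestricted()` therefore
pools counts within a group (typically a tissue), drops signatures below 1%
pooled exposure, refits each sample on the restricted set, and finally prunes
per-sample exposures below 2% whose removal a likelihood-ratio test cannot
reject. This mirrors the practice of refitting against the signatures
actually extracted for a tissue and removes both the absent-signature leak
and the positive floor on truly-zero exposures; both thresholds are exposed
as arguments.

Per-mutation attribution is the posterior P(k | c, s) = e_sk S_kc / sum_j
e_sj S_jc; attribution vectors sum to one, and their per-signature sums equal
exposure times mutation count at the MLE. Driver fractions sum these
posteriors over putative driver mutations; the count is reported both
unrounded and rounded half-up (integer numerators are conventional in
figures). Catalogue matching uses cosine similarity with the strict > 0.9
rule; unmatched profiles receive the next free alphabetical name.

The bundled catalogue is fully synthetic: deterministic profiles with the
qualitative shapes of the processes they emulate (flat clock-like SBS5,
C>A-dominated smoking SBS4, C>T-dominated platinum SBS31, a T>C blood
signature SBS-A, and so on), constructed to be mutually separable (pairwise
cosine < 0.5). The pipeline treats the catalogue as an input and works
unchanged with a real one.

# Dose-response fits and relative effects

Per-signature genome-scale burdens are regressed on exposure covariates with
a Huber M-estimator (tuning constant 1.345, 95% Gaussian efficiency), taking
per-patient medians before fitting, with min/max retained for display. The
default 95% interval is a seeded patient-resampling bootstrap (percentile,
400 replicates): the burden noise from exposure refitting is heteroscedastic
— larger at higher exposures — and the asymptotic M-estimation covariance
undercovers there, while case resampling does not. The asymptotic interval
remains available via `ci_method = "asymptotic"`.

Pack years are packs per day times years smoked; a drink year is 14 units of
alcohol a week for a year, and when drinking history is unknown the duration
defaults to age minus 18. Alcohol trends across ordered consumption
categories use the Jonckheere–Terpstra test: the statistic sums pairwise
Mann–Whitney counts over ordered group pairs (ties one half), with an exact
p by full enumeration of index assignments when the total n is at most 10, a
tie-corrected normal approximation above that, and an optional seeded
permutation p.

Ageing equivalents divide a process slope times a reference exposure by the
tissue's clock-like slope; the reference exposures are 40 pack years, 6
platinum cycles and 50 drink years. For treatments without an estimable
slope, the treatment-attributed mutation count divided by the treatment
duration gives a rate, and division by the clock-like slope gives the
equivalent years. The package reports the formula value and does not
reconcile rounded narrative statements derived from it.

# Coverage-adjusted selection inference

Every coding site contributes its three possible substitutions, classified by
codon translation into synonymous / missense / nonsense and assigned to one
of 192 strand-specific trinucleotide channels read on the coding strand.
Opportunities are weighted by the median duplex coverage of the channel's
sites within the gene, normalised by the overall median depth — a relative
normalisation, chosen so that scaling all coverage leaves every estimate
unchanged. Blacklisted sites carry zero coverage; a fully blacklisted gene
has zero opportunity.

Channel rates and the global dN/dS are estimated jointly: profiling each
channel rate as (S_c + N_c) / (Lsyn_c + w Lnon_c) inside the Poisson
likelihood and maximising over w. Estimating rates from synonymous counts
alone is a trap this package deliberately avoids: many strand-specific
channels carry little or no synonymous opportunity, and a synonymous-only
plug-in rate of zero there systematically understates nonsynonymous
expectations (we measured ~15% at this panel's size, enough to miscall a
quarter of neutral genes). Per gene, expected counts are rate times
opportunity; w is observed/expected with a profile-likelihood 95% CI and a
one-sided exact Poisson tail test against w = 1 (positive selection), BH-
corrected per family across genes (exact tails, not the halved chi-squared,
which is liberal at the expectations a 300-bp gene produces). Indels use a single panel-wide rate
against coverage-weighted gene length. Driver genes require global q < 0.1 or
substitution q < 0.05 or indel q < 0.05; putative driver mutations are those
in driver genes that are truncating or missense with a pathogenicity score
strictly above 0.56. The full negative-binomial dNdScv machinery (gene-level
random effects, covariates) is deliberately simplified to this Poisson model;
the neutral-calibration simulations are the guard-rail for that choice.

Reporting filters (not estimation filters) suppress gene:sample dN/dS values
backed by too few events: missense values with fewer than 4 expected and 3
observed missense or fewer than 2 total observed variants; nonsense values
with fewer than 2 expected and observed, or a combined synonymous+nonsense
expectation below 3 with fewer than 2 events.

# The synthetic cohort generator

`generateCohort()` draws a toy genome and panel (default 30 named cancer
genes of 1.5 kb plus 25 neutral regions of 1.5 kb — 82.5 kb total), germline
SNP loci per patient, and per-sample somatic mutations from a sum of
dose-response processes: each process has a covariate (age, pack years, drink
years, platinum cycles, alkylating treatment days), per-tissue slopes in
mutations per cell per unit, and a signature mixture. The calibrated defaults
use the rates the study conditions state — clock-like 43/year in lung,
24/year in blood, 21/year in brain; smoking 20 mutations per pack year in
lung and ~5 in heart and liver; platinum 89 per cycle in blood and 32 in
lung — plus package-chosen values where no rate is printed (liver clock 50
per year and alcohol 25 per drink year, set so liver lands near 1.8 mutations
per Mb per cell with roughly 40% exogenous contribution; kidney, spleen,
heart, pituitary values in `defaultProcesses()`).

Mutation counts are Poisson with mean (burden/genome Mb) x panel Mb /
(2 x E[VAF]); VAFs are log-uniform on [1e-5, 1e-3] (half the clone cell
fraction); depth is negative-binomial around a per-sample median near 30,000;
alt counts are binomial. Detection is thinning — a mutation whose draw falls
below the minimum alt count is dropped, not redrawn — because thinning keeps
E[sum of observed VAFs] equal to the true clone-fraction sum and hence the
burden estimator exactly unbiased, which truncation would not. Channels are
drawn from the mixture and placed uniformly over panel sites with the
matching pyrimidine-collapsed context; the median VAF implied by the default
log-uniform range (1e-4) sits above the study's reported median
(~3.2e-5) — the real VAF distribution's shape is unknown beyond summary
statistics, and the range is kept as specified.

Positive selection inflates nonsynonymous counts in selected genes by a
factor w: the excess is Poisson with mean (w-1) times the *expected* neutral
count of the class in the gene (computed from the placement model and the
sample's detected total), drawn conditional on detection. Drawing against
the expected rather than realised neutral count matters: scaling the realised
count would hand the excess w times the gene's neutral Poisson noise and
destroy the coverage of the dN/dS confidence interval.

Artefacts recur across samples with supporting-read positions at a fixed
per-artefact offset (probability = skew); blood infiltration plants a
configurable fraction of blood mutations in a fixed fraction of the patient's
non-blood samples; contamination adds a tumour sample with allelically
imbalanced het SNPs and shifts a chosen normal's BAF profile toward it
deterministically (new alt = round(depth x ((1-f) baf + f tumour BAF))), so
identity at f = 0 and monotonicity in f hold exactly. SNP loci are kept
disjoint from somatic and artefact placement: a variant caller would fold a
somatic call at a germline allele into the genotype, and a single such
collision otherwise leaks a VAF-0.5 row into the somatic set and corrupts the
burden by orders of magnitude.

What the generator does *not* emulate: lineage structure (mutations get
independent VAFs; no phylogeny), UMI/consensus error models, mapping
artefacts beyond the read-position family, cell-type composition, and any
correlation between clone size and mutation age. Passing tests therefore
demonstrate the estimators' correctness under the stated statistical
structure, not robustness to every failure mode of real duplex data.

# Problem sizes and numerical choices

The shipped simulations use a 22-patient, five-tissue calibrated cohort
(~40k variants) for the end-to-end checks; 20-patient two-tissue cohorts over
100 seeds for dose-response coverage; and 500-gene cohorts (one gene at
w_mis = 5, ~30 expected missense events) over 50 seeds for selection
recovery, with 50 fully neutral seeds at a smaller (26-sample) cohort for
interval calibration — calibration does not depend on cohort size, and the
extra replicates sharpen the Monte-Carlo estimate of the coverage rate. These sizes were
chosen to give the binomial acceptance bounds (90%/95% rates) reasonable
resolution while keeping a full run on a single CPU comfortable. EM tolerance
is 1e-8 on the log-likelihood; profile-likelihood bounds use uniroot to 1e-8;
the global dN/dS optimiser runs to 1e-8 on w. Ties in EM are broken by
catalogue order; degenerate inputs (zero counts, zero-depth SNPs, empty
groups, fraction-zero contamination) are exact no-ops or explicit errors, as
documented on each function.

# Known limitations

* Exposure refitting at a few hundred mutations per sample retains a small
  attenuation (a few percent) for signatures whose profiles overlap; the
  bootstrap dose-response intervals absorb this in coverage terms, but point
  slopes can sit slightly below truth.
* The Poisson selection model ignores gene-level rate heterogeneity beyond
  the 192 channels; on real data with covariate-driven rate variation the
  neutral calibration would need the negative-binomial extension.
* The cohort contamination filter's global-rate binomial is one of several
  defensible readings of a tersely described procedure; it is isolated in
  `cohortContaminationFilter()`.
* Splice impact is carried in the data model but unused: toy gene models are
  contiguous CDS without introns.
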