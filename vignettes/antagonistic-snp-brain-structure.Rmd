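---
title: "Characterizing antagonistic cross-disorder SNPs at the brain-structural level"
author: "antagmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing antagonistic cross-disorder SNPs at the brain-structural level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antagmap)
```

## The problem

Antagonistic SNPs are variants whose same allele raises risk for one
neuropsychiatric disorder while protecting against another. A natural
hypothesis is that such a variant acts through brain structure: the allele
shifts a regional measure (cortical surface area, thickness, or a
subcortical volume), and that shift is risk-conferring for one disorder and
protective for the other. `antagmap` operationalizes this hypothesis as a
summary-statistics pipeline: no individual-level genotypes or images are
required for the first four stages, only published GWAS and case-control
tables.

## Stage 1: the association grid and its FDR convention

Each target SNP is looked up in one summary-statistics table per
image-derived phenotype (IDP). Records are harmonized so the signed effect
refers to the target's risk allele: if the table's effect allele is the
*other* allele, alleles are swapped and the sign negated; p-values are
untouched. Harmonization is an involution (flipping twice restores the
record) and never changes |effect| or p — both are tested properties.

Strand-ambiguous pairs (A/T, C/G) cannot be resolved without allele
frequencies, which summary tables in this setting do not reliably carry.
The default policy is to warn and accept them as-is, because the target set
is small and curated; `ambiguous = "exclude"` is available for automated
use. SNPs absent from a source are routed through an LD proxy when one is
configured with r² at or above 0.8 (a deliberately permissive floor; the
shipped fixture's only proxy has r² = 1).

The Benjamini–Hochberg step-up adjustment is applied across the whole grid:
`p_FDR(i) = min_{j ≥ i} min(1, m·p(j)/j)` on sorted p-values. The number of
tests `m` deserves care. The bundled published-scan fixture uses a grid of
11 SNPs × 79 IDP columns = 869 cells: 34 SA + 34 CT Desikan–Killiany
regions, total SA, mean CT, eight subcortical volumes, and hippocampal
volume *counted twice* because it is present both in the subcortical-volume
GWAS and in a dedicated hippocampal-volume GWAS. The printed adjusted
p-values of the source table are arithmetically consistent only with
m = 869, although the accompanying text speaks of 78 IDPs (which would give
m = 858); the package defaults `m` to the number of cells actually
attempted and lets the caller pin it explicitly, so this discrepancy is
surfaced rather than silently resolved. Missing cells are excluded from `m`
by default (`count_missing = TRUE` switches the convention), since the
reference analysis substituted a proxy rather than dropping a SNP.

Two numerical notes. First, step-up propagation matters in practice: in the
fixture, the raw p-value 1.64×10⁻⁵ at rank 4 receives the rank-6 quotient
2.16×10⁻⁵·869/6 = 3.13×10⁻³, not its own 3.56×10⁻³. Second, report
rounding is presentation-only: p-values are carried at full precision
internally and rounded to 3 significant figures on output, and the test
suite accepts either round-to-nearest or truncation when comparing against
printed 3-digit values, because published tables are not consistent about
which they use.

## Stage 2: the bootstrap enrichment null

Whether the antagonistic set is *collectively* unusual is tested by
resampling: draw B sets of eleven SNPs from a pool (all SNPs in the same
summary statistics, or only SNPs with cross-disorder association
p ≤ 10⁻⁶), rebuild the association grid for each drawn set with the
identical BH convention, and count significant cells. The empirical p-value
is the add-one upper-tail estimator (1 + #{counts ≥ observed})/(1 + B),
which never returns zero and has granularity 1/(B+1); B defaults to 10,000
so the smallest attainable p is ~10⁻⁴. Each replicate derives its RNG
substream deterministically from (seed, replicate index), making results
independent of evaluation order. Sampling is without replacement within a
set and independent across replicates; no MAF or LD matching is applied,
matching the plain "randomly sampled sets" design (the exact pool
construction of the reference analysis is not public, so these defaults are
explicit stand-ins recorded in every report).

The test suite verifies calibration (under an exchangeable global null the
rejection rate at 0.05 stays within its binomial band over 200 outer
repetitions) and power (with 8 of 11 SNPs carrying 5-SE effects on three
IDPs each, p < 0.05 in ≥ 95 of 100 repetitions at B = 500).

## Stage 3: effect-direction concordance

For each significant (SNP, IDP) pair the package triangulates three signs:
the risk-allele IDP effect, the allele's disorder directions, and the
published patient-versus-control Cohen's d for the same region and measure.
The classification rule is symmetric in the disorder pair: the expected
patient alteration is +sign(SNP effect) for the risk disorder and
−sign(SNP effect) for the protective disorder (patients with the protected
disorder are depleted of the allele). `opposed_idp` — both disorders
significantly altered in opposite directions — takes precedence;
`consistent_mediation` requires every significantly altered disorder to
match its expected sign; any mismatch is `inconsistent`; and
`indeterminate` covers the no-significant-data cases, including ANO and TS,
for which no large-scale case-control imaging tables exist
(reason `"no-case-control-data"`). Symmetry makes the call invariant to
re-harmonizing the SNP to its other allele (which negates the effect and
swaps the disorder roles) — an asymmetric risk-disorder-only rule would
not be, which is why the symmetric rule was chosen; the invariance is
tested.

Case-control tables are reported per hemisphere while the IDP grid uses
hemisphere-averaged measures, so hemispheres are merged first. The default
`both-required` policy calls a merged effect significant only when both
hemispheres are individually significant with agreeing sign, taking the
mean d — conservative, and consistent with the worked example
(d_left = −0.196, d_right = −0.195 for superior temporal SA in
schizophrenia, merged −0.1955). The `either` policy is available for
sparser tables. Disorder-specific subphenotypes (e.g. recurrence or subtype
strata) are excluded at ingestion. Significance is taken from the published
adjusted p at 0.05 with no re-correction across disorders, since each
consortium table carries its own multiplicity correction.

## Stage 4: annotation filters

The eQTL filter computes the Bonferroni threshold exactly:
α/(n_SNPs · n_tissues) = 0.05/128 = 3.90625×10⁻⁴ for 8 SNPs and 16 brain
tissues. A rounded published threshold (4.0×10⁻⁴) admits records the exact
correction would reject, so the exact value is the default and any
pre-rounded threshold must be imposed explicitly via `threshold`. The SNP
denominator is likewise a required explicit argument — it cannot be safely
inferred from the table, because the set of SNPs actually queried may be
larger than the set with any eQTL record. Pseudogene eQTLs are removed
before thresholding by a case-insensitive substring match on the HGNC locus
type, which has several pseudogene subtypes. The trait filter keeps
genome-wide-significant associations (p < 5×10⁻⁸) and removes traits
matching a shipped, user-extensible synonym table for the eight disorders.

## The voxel-wise stage

Beyond atlas-derived IDPs, `fit_voxelwise_glm()` regresses voxel-wise
gray-matter volume on allele dosage with covariates (age, sex, diagnosis,
total intracranial volume, scanner, ancestry components — whatever the
covariate table carries; categorical columns are dummy-coded). The fit is
computed by Frisch–Waugh partialling, which is algebraically identical to
full OLS and verified against an explicit normal-equations oracle to 1e-8.
Rank-deficient designs abort with the names of the collinear columns.

Clusters form at a one-sided uncorrected p < 0.001 in each direction
(positive and negative contrasts are run separately, never combined
two-sided) and survive at extent k > 10, i.e. k ≥ 11 — the strict
inequality is tested. Connectivity defaults to 18 (faces + edges, the
common neuroimaging convention) and is configurable to 6 or 26; component
labeling is validated against an independent flood-fill oracle.

Peak-level family-wise error is controlled by permutation rather than
random-field theory: RFT's smoothness estimation is out of scope here, and
permutation provides exact-level control under exchangeability. The scheme
is Freedman–Lane: volumes and dosage are residualized on the nuisance
covariates, dosage residuals are permuted, the t-map is rebuilt per
permutation, and the global max-|t| over the mask forms the null; each
peak's p_FWE is the add-one tail probability of its |t|. Because the
mechanism differs from RFT, published RFT-based p_FWE values are not
reproduction targets for this engine; its guarantees are instead
established by simulation (family-wise error within the binomial band of
0.05 over 200 null cohorts; planted 2-SD effects recovered within ±25%
and detected at p_FWE < 0.05). Peaks are annotated by mapping world
coordinates through a supplied label volume's inverse affine with
nearest-voxel rounding; label 0 or out-of-grid coordinates return
"unlabeled".

## The synthetic-data generators

Every stage's inputs can be generated with known truth, which is what the
test suite and the acceptance script run on.

* `gen_sumstats()` simulates on the standardized (effect/SE) scale: the
  observed z of a cell is Normal(planted z, 1), the SE is 1/sqrt(n) with
  per-source sample sizes defaulting to the discovery cohorts of the real
  IDP GWAS (33,281 cortical; 37,741 subcortical; 26,814 hippocampal), raw
  effects are z·SE, p-values two-sided normal tails. Downstream logic
  consumes only p and sign, so raw-β scaling is presentational. Optional
  block equicorrelation across IDPs within a SNP probes FDR behavior under
  the positive dependence brain measures exhibit (BH remains valid under
  PRDS). Alleles are drawn from non-ambiguous pairs.
* `gen_imaging_cohort()` builds desk-scale cohorts: 16³ grids of Gaussian
  noise smoothed with a unit-L2 Gaussian kernel (FWHM 3 voxels) so voxel
  SD is ~1 and effect sizes are in noise-SD units; covariates mimic a
  mixed patient–control sample (age 35.4 ± 13.1 y, 64% female, ~47%
  patients, TIV, a two-level scanner factor, three ancestry components)
  with modest true contributions so adjustment genuinely matters; a
  binomial dosage at allele frequency 0.3; and an optional planted dosage
  effect in a voxel region. It does not emulate image biophysics, spatial
  covariate gradients, or LD — so passing tests demonstrate the
  statistical engine's correctness and calibration, not robustness to
  registration error or realistic anatomy.
* `table1_fixture()` reconstructs the published scan's input grid: the 27
  significant (SNP, IDP, raw p, effect) cells plus 842 filler cells at
  p = 1, with target annotations and the proxy routing
  (rs1933802 → rs314280, r² = 1). Three of the eleven targets are not
  identifiable from the available listing and appear as clearly synthetic
  placeholders so the m = 869 arithmetic is preserved. Where the listing
  assigns one SNP two protective disorders, the first is retained.

## Problem sizes and numerical choices

The simulation experiments use 200 outer repetitions at B = 200 for
bootstrap calibration, 100 repetitions at B = 500 for power, 200 null
cohorts (16³, n = 40, 200 permutations) for family-wise error, and 50
cohorts (n = 60) for effect recovery — sizes chosen to keep Monte-Carlo
bands tight enough to be meaningful while remaining desk-scale. Ties in the
BH ranks share one adjusted value; degenerate inputs (empty p-vectors,
empty cluster sets, empty filter results) return empty, typed results
rather than errors, because an empty finding is a reportable scientific
outcome. RNG substreams are derived per replicate from (seed, index) via a
fixed linear map kept below 2³¹.

## Limitations

The pipeline consumes pre-extracted tables; it performs no remote queries,
no VCF parsing, no genome-build liftover, no image preprocessing, and no
formal mediation analysis — the concordance stage triangulates directions
of separately estimated effects and cannot establish a causal chain.
Bootstrap pool construction and the hemisphere-merge policy are explicit
configurable stand-ins where the reference methodology is underspecified;
both are recorded in every run manifest.
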