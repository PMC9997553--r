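---
title: "Models and methods behind winterGP"
author: "winterGP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind winterGP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(winterGP)
```

# Scope

winterGP analyzes winter survivorship (a 0–20 spring-vigor score; 0 = dead)
and heading date (ordinal day of year) in a multi-generation lowland
switchgrass pedigree: a handful of winter-tolerant founders crossed to a
diverse southern pool, F1 families, sibling-mated pseudo-F2 families, and an
open-pollinated progeny set. It covers the genomic side of such a program:
reconstructing grandparental ancestry of shallow-sequenced pseudo-F2s,
marker QC and imputation, realized-relationship kinship, multi-kernel REML,
cross-validated and progeny genomic prediction, and selection-response
arithmetic. A full synthetic-data generator makes every stage testable
without any external download; it is first-class, tested code, not a
fixture.

# The synthetic world

## Genomes and pedigree

Founder haplotypes are drawn per site from Beta-distributed ancestral allele
frequencies perturbed into two subpopulation frequency sets under the
Balding–Nichols model at an Fst-like `divergence`. The tolerant founders
belong to subpopulation 2. Meiosis places a Poisson(`map_length`) number of
crossovers uniformly per chromosome, without interference — the simplest
model adequate for ancestry-block statistics. Every allele carries a
founder-haplotype origin label, so identity-by-descent, inbreeding and true
local ancestry are exact bookkeeping, not estimates; these origin tracks are
the oracle for the haplotype-caller tests. Offspring of a full-sib mating
have expected F = 0.25 (the kinship of full sibs), which the origin tracks
confirm.

Lowland switchgrass is tetraploid, but the markers analyzed here are
diploid biallelic dosages, so the simulator is diploid/disomic throughout —
it matches the marker representation actually analyzed, not the karyotype.

## Traits

The latent genetic value per trait is a sum of QTL additive effects,
dominance deviations, additive-by-additive pairs, and an individual-level
residual genotypic effect. Each component is rescaled so that its realized
sample variance equals the requested variance component times
(mean diag K − mean K) for the corresponding realized kernel K — i.e. the
generated data are consistent with the GBLUP prior `u ~ N(0, K sigma2)`
whose parameters the REML stage estimates. Default winter-survivorship
components are additive 12.52, dominance 0, epistatic 1.23, residual
genotypic 7.44, with year residuals 25.52/22.16/20.5; heading date uses
25.38/1.87/0/14.12 with year residuals 50.91/39.98, mean 227 DOY, which
implies a phenotypic SD of about 10 days.

Records add year effects, a fall-vigor covariate effect (survivorship
only; fall vigor emulates establishment damage unrelated to winter), and
year-specific Gaussian residuals. Survivorship is censored to \[0, 20\] and
rounded; a score of 0 is absorbing (dead plants stay dead, and produce no
heading-date record). The absorbing choice is ours — the source program
never states how mortality was re-scored — and is flagged, not asserted as
the field protocol.

Two mechanisms generate between-trait correlation, and they are deliberately
distinct:

* `pleiotropy_corr` draws shared-QTL effects with the given correlation —
  recombination-proof by construction;
* `structure_effect` loads a fraction of each trait's additive effects onto
  the subpopulation allele-frequency axis at *disjoint* QTL sets, so any
  cross-trait correlation is cross-locus ancestry LD.

## What a green test does and does not establish

The generator emulates the statistical structure the analysis assumes —
pedigree nesting, depth-dependent genotype quality, variance components,
censoring. It does not emulate sequence-level artifacts (alignment error,
allele-specific bias), tetrasomic inheritance, spatial field trends, or
genotype-by-year interaction beyond year-specific residual scale. Green
tests establish the implementation is faithful to its stated model, not that
the model captures every feature of real switchgrass data.

# Haplotype reconstruction

Within one pseudo-F2 family, informative markers are sites where the two
founder grandparents are contrasting homozygotes and the family's F1
parents have at least `min_parent_depth` (default 4) summed reads — the
source text gives no number, so the default is configurable. A centered
window of 100 informative sites (step 1, truncated at chromosome ends)
yields p̂ = A-reads / total reads. Calls use strict inequalities exactly as
published: p̂ > 0.9 and < 0.1 are the two homozygotes, 0.2 < p̂ < 0.75 is
heterozygous, and p̂ in \[0.1, 0.2\] ∪ \[0.75, 0.9\] — the gap the published
thresholds leave — stays unassigned rather than being invented. Window reads
are pooled across the two F1-derived haplotypes; run lengths are counted in
informative-site space (both unstated in the source; both flagged).
Heterozygous runs shorter than 100 sites between two homozygous runs are
dropped in a single pass (matching flanks absorb the sites, discordant
flanks leave them unassigned), with `iterate = TRUE` available. Individuals
with > 85% heterozygosity or single-grandparent maps are removed as likely
pollen contamination.

# Markers

Filters read the published thresholds the only internally consistent way:
keep missingness < 20% (over all individuals), drop founder MAF < 0.05
(0.025 for the progeny-merged set), drop r² ≥ 0.90 against any retained
site among the nearest 15 variant sites within founders, scanning greedily
left-to-right in genome order (earlier site kept). Unambiguous parental
assignment fills a missing call only for matching (0/0, 2/2) or contrasting
(0/2) homozygous parents. EM imputation alternates site-mean fills,
realized-relationship computation, and relationship-weighted re-prediction
of missing entries (tol 1e-4, 50 iterations); imputed dosages stay
real-valued for kinship, with observed entries untouched. Projection assigns
pseudo-F2 dosages from segment states (homA → founder A's dosage, het →
the mean of the two founders), extending segment boundaries to genomic
midpoints between informative markers; unassigned segments leave sites
missing. A second round drops sites called in < 20% of mapped individuals
and re-imputes.

One measured caveat: at 1–2x depth, projected dosages beat naive hard calls
at truly heterozygous sites (which one read can never call) by a wide
margin, but not in overall per-site accuracy, because homozygous sites are
trivially right from a single read while projection pays for ancestry-state
errors. The tests assert the heterozygous-site comparison — the ambiguity
the map exists to rescue.

# Kinship and REML

Kinship uses VanRaden method 1 for G, the classical dominance covariate
(−2p², 2pq, −2q²) for D, and the Hadamard square G∘G rescaled to G's mean
diagonal for E; the source delegates these to a mixed-model package without
formulas, so each form is unit-tested against its written formula, never
against another package. Allele frequencies come from the analyzed set
(flag available); a 1e-6 diagonal jitter precedes REML.

The single-trait model is y = Xb + Zu_a + Zu_d + Zu_E + Zu_R + e with year,
fall vigor and their interaction fixed; u ~ N(0, K sigma²) per kernel and
year-specific residual variances. Estimation is average-information REML
with step-halving and an EM-type multiplicative fallback, tolerance 1e-6 on
the restricted log-likelihood, 200 iterations; negative updates are
constrained to the zero boundary, and a component within 1e-4·var(y) of the
constraint is reported as a boundary zero with its AI standard error —
matching the reported exact-0-with-SE convention. The likelihood never
decreases across accepted iterations (tested). PEV is computed via
sigma² K − sigma²K Z'PZK sigma², identical to the C22 block of the inverse
mixed-model equations (tested against explicit inversion), and reliability
is r²ᵢ = 1 − PEVᵢ/(Gᵢᵢ sigma_a²) — the additive-variance-scaled form; the
unscaled alternative is dimensionally inconsistent.

Two-stage prediction fits genotype BLUEs (OLS with sum-to-zero year
contrasts) in a G + I model whose residual is proportional to each BLUE's
stage-one SE — the literal reading of weighting by 1/sqrt(SE); SE²
scaling is a flag. Weights are median-normalized for conditioning. Where
the variance components are identified and interior, two-stage GEBVs match
the joint single-stage fit (max relative deviation below 1%, tested); at
boundaries or with near-identity kinship the REML ridge is flat and the
correspondence degrades — a property of the model, not the optimizer. The
multi-trait fit estimates an unstructured 2×2 covariance per kernel with
per-trait year-specific residuals and no cross-trait residual covariance;
fixing the covariances at 0 decouples it into the single-trait fits.

Genomic-prediction models default to additive + residual-genotypic kernels
only; dominance/epistatic kernels are opt-in, mirroring the progeny
prediction variants.

# Cross-validation and progeny prediction

Masking hides phenotypes, never genotypes. Predictive ability is the
correlation between full-model BLUPs and masked-model GEBVs over the masked
individuals; bias is the OLS slope of reference BLUP on GEBV, so shrinkage
reads as slope < 1. Half-family masking takes an unstratified random half.
One leakage is worth knowing: because the reference BLUPs and the masked
GEBVs share training noise through the same kinship matrix, this ability
definition stays positive (≈0.3–0.4 in our simulations) even for a
zero-heritability trait. The `reference = "phenotype"` flag, which
correlates GEBVs with the masked individuals' own BLUEs instead, goes to
zero as it should, and is what the no-signal property test uses. Progeny
ability correlates progeny GEBVs with stage-one BLUEs of the progeny's own
single-year records — the source never states its reference; BLUEs are the
defensible choice for a one-year, unreplicated set.

# Selection response and sampling

Selection intensity is i = phi(z_p)/p; the gain helper computes
ΔG = sqrt(va) · i · sqrt(h2), taking the mid-parent heritability as the
*squared* accuracy exactly as the source's worked example does — do not
square it again. Inverted-density sampling weights individuals by the
reciprocal of a Gaussian-kernel density (Silverman bandwidth, weights
capped at the 99th percentile — none of this is specified in the source)
of their mean trait Z-scores, unflipped for both traits.

# The correlation-erosion experiment

In a neutral additive world, sibling mating preserves between-family
ancestry LD, so the pooled phenotypic correlation does *not* decline from
F1 to pseudo-F2 — we measured it flat. The decline reported in the field
materializes once the experiment carries the conditions the pedigree
actually experienced: a crossing mix of tolerant-by-diverse and
diverse-by-diverse families (smoothing the binary founder contrast),
survivorship censored at the 0 floor with absorbing mortality, and
directional inbreeding depression of about −16 score units per unit F (the
observed F1 vs pseudo-F2 gap at F = 0.25). With those, the structure arm
declines monotonically (≈ −0.76 → −0.53 → −0.42 in 10-seed means) while the
pleiotropy arm, run in a mild world to isolate recombination-proofness,
persists. `inbreeding_depression` defaults to 0 everywhere else.

# Parameter-recovery calibration

The variance-recovery experiment (`varianceRecoveryExperiment()`) simulates
~300-individual pedigrees with ~2,000 markers and three record years from
the winter-survivorship components above and refits the 4-kernel model. It
generates records on the latent Gaussian scale: the generating components
are parameters of the Gaussian REML model, and censoring the response would
build attenuation into the recovery target. At this scale the four genetic
kernels are strongly confounded: replicate estimates trade variance between
G and E (total genetic variance is conserved) and the additive mean sits
within a few percent of its generating value, well inside two replicate
SDs. Dominance, generated at zero, pins to the boundary in most replicates.

# Numerical choices and degenerate inputs

* Internal site indices are 1-based over the simulated map; VCF positions
  are 1-based and preserved on round trip.
* REML: diagonal jitter 1e-6 on kernels; residual components floored at
  1e-8·var(y); singular fits stop with an explicit "singular" error; a flat
  AI matrix triggers a weak-identification warning (duplicated kernels are
  the canonical case — their sum remains stable).
* `imputeEM` requires every site to have at least one observed call; sites
  failing that must be filtered first.
* Zero informative sites in a family is an explicit empty-set signal, not
  an error; QC reasons are logged per removed individual.
* Progeny seed parents are a random subset of pseudo-F2s (default 8):
  survivorship cannot be conditioned on at pedigree-construction time
  because phenotypes are simulated downstream.
* The pipeline configuration is an R list (JSON-serializable); every
  published threshold surfaces as a named field defaulting to the
  published value.

# Known limitations

Diploid only; no HMM ancestry caller (the window caller is the method under
study); no genotype-likelihood imputation; no Bulmer-effect or multi-trait
selection indices; CV reproduces the design's orderings, not the real
data's table entries, which depend on the actual population.
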