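---
title: "Methods: CHIP annotation and cohort association in chipcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CHIP annotation and cohort association in chipcohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipcohort)
```

# Scope and model

`chipcohort` covers the full path from candidate somatic calls (or raw
array intensities) to cohort-level effect estimates for clonal
hematopoiesis of indeterminate potential (CHIP). Three annotation routes
are implemented — exome filtering, deep targeted-panel filtering, and
array-intensity hotspot calling — followed by endpoint harmonization and
logistic/Cox association models. Because the registry cohorts this kind
of analysis runs on are access-restricted, the package ships a seeded
generator that emulates all three input types with known ground truth;
every empirical claim in this vignette is one the test suite or the
acceptance script computes itself.

# The filtering cascades

All rules are conjunctive, evaluated per variant, and every failed rule
is reported (no short-circuiting), which is what makes per-rule decoy
fixtures possible. Thresholds live in parameter objects
(`chip_rule_params()`, `panel_rule_params()`, `lymphoid_rule_params()`),
so monotonicity — relaxing a threshold can only grow the pass set — is a
testable property rather than an assumption.

Points worth calling out:

* **Hotspot exemptions.** The population-frequency rule (gnomAD max AF
  ≤ 0.1%) would delete the two most recurrent CHIP hotspots, JAK2 V617F
  and DNMT3A codon 882, which reach appreciable frequency in population
  databases precisely because CHIP is common. Exemptions are supplied
  with the gene panel, not hard-coded; a codon-style exemption (`"R882"`)
  covers every substitution at the codon, an exact one (`"V617F"`) only
  that change.
* **Cohort frameshift frequency.** Recurrent frameshift alleles in
  blood-derived exomes are overwhelmingly alignment artifacts, hence the
  0.05%-of-samples cap (strictly above fails). The denominator is the
  number of samples in the run, not the number of variant rows, and the
  carrier count for an allele is taken over all rows sharing
  (chrom, pos, ref, alt). One consequence for small runs: a singleton
  frameshift in a cohort of under 2,000 samples already exceeds 0.05%,
  which is faithful to the rule but surprises on toy inputs — pass the
  real cohort size as `n_samples`.
* **Frameshift-cluster collapse.** Nearby frameshift calls are usually
  alternative alignments of one indel. Clustering is per sample and per
  chromosome by transitive closure of the 5-bp rule; cohort-wide
  clustering would merge independent clones from different people, which
  is why the per-sample scope was chosen. Ties on VAF break by smaller
  position, then lexicographic alternate allele — an arbitrary but fixed
  order that keeps runs deterministic.
* **No VAF floor in exome mode.** Clone-size is left uncensored in WES
  (the read-support rules impose a de-facto ~2% detection limit at 48×
  anyway); the targeted panel, with its germline-contamination risk at
  high VAF and deep coverage at low VAF, uses an explicit [2%, 40%]
  window. A WES floor can be switched on via `vaf_floor` but is off by
  default.
* **Splice variants without a boundary distance fail conservatively**:
  an unannotated splice distance cannot demonstrate compliance with the
  2-bp rule.

# The array hotspot caller

The published procedure was human curation of intensity plots; that is
not reproducible, so the package substitutes a robust-outlier caller
with the same geometry. At a hotspot the non-carriers form one cluster
in θ = y/(x+y); its center and scale are estimated by median and
1.4826·MAD with a single trimmed refit (trim at 4 scale units). The MAD
is floored (default 0.005) so tie-degenerate loci cannot produce
infinite z-scores. A carrier must clear both a robust-z threshold
(default 5) and a relative-BAF floor (default 0.05): the z-rule controls
false positives near the cluster, the BAF floor removes "significant"
but biologically meaningless sub-percent displacements.

The defaults were chosen a priori from the cluster-noise model (Gaussian
θ noise, default sd 0.01): five scale units put the per-sample false
positive probability well below 10⁻³, while a clone at VAF 0.10 sits ten
scale units out and is essentially always detected. The design target —
at least 80% detection at VAF ≥ 10% under default simulator noise —
mirrors the detection likelihood reported for manual curation of the
canonical hotspots, but it is a property of the simulator's stated
world, not a claim about any real array.

Locus qualification re-implements the published screening heuristic on
computed summaries: cohort prevalence under 10× the reference
(sequencing-derived) prevalence plus positive univariate age
(p < 0.1) and hematologic-malignancy (p < 0.05) associations, with one
association sufficing under a 2× ratio. "Positive association" is read
as coefficient > 0 with a two-sided p below the cutoff; a one-sided
variant would halve the p-values and is deliberately not the default.
The univariate tests are logistic regressions (the original screen's
test is unstated; logistic is the natural choice for a binary carrier
outcome). The decision rule is exposed separately
(`locus_confidence_rule()`) so its truth table can be tested without
fitting anything.

# Endpoints and association models

Prevalent means first mapped code on or before the DNA sampling date
(ties prevalent by default; `strict_prevalent` flips the boundary).
RA serotype uses seropositive dominance: one seropositive code anywhere
in the record overrides any number of seronegative codes, reflecting how
registry seronegative labels are provisional.

Logistic models (odds ratios) and Cox models (hazard ratios) share the
biobank conventions: adjustment for age, sex, smoking ever/never and 10
ancestry PCs; complete-case handling with every dropped row logged and
`n` defined as input minus logged exclusions; prevalent hematologic
malignancy excluded from co-occurrence models and incident hematologic
malignancy right-censoring survival (`build_survival()` makes the
censoring auditable: planting an incident malignancy before a death
converts exactly that death into a censoring). All p-values are
two-sided; intervals are Wald at 95%. Complete separation in the
logistic model is flagged on the estimate, not raised, because a
screening loop over many exposures must survive a degenerate cell.

The DAS28 24-month AUC is the trapezoidal integral of serial disease
activity scores, interpolated at and truncated to the horizon; a series
ending early integrates to its last visit rather than extrapolating.
Age-binned prevalence uses Wilson score intervals, which behave sensibly
at zero counts where Wald intervals collapse.

# The synthetic stated world

The generator's defaults are fixed, documented choices, not tuning
knobs:

* ages uniform on 25–74 (the population-survey recruitment window);
* CHIP by an age-logistic with intercept −6.045 and slope 0.055/yr,
  calibrated so prevalence is ≈ 7.8% at age 65 (the published 60–69
  figure) and ≈ 4% overall;
* driver genes DNMT3A 40%, TET2 20%, ASXL1 10%, JAK2 5%, other 25% —
  the qualitative spectrum of population CHIP;
* clone sizes Beta(1.5, 8) truncated to [0.02, 0.45] (right-skewed, most
  clones small);
* read evidence: depth Poisson at 48× (exome) or 1700× (panel),
  alternate reads binomial at the true VAF, per-strand splits binomial
  1/2. Clean draws are re-sampled until the read-support rules pass, so
  "planted truth" means *detectable* truth — the end-to-end recovery
  test asserts exact equality of the pass set and the clean set, which
  would be impossible if truth included clones below the detection
  limit;
* decoy variants violate exactly one rule each by construction;
* array θ noise Gaussian with sd 0.01 around a reference center of
  0.03; carriers displaced by their VAF. The σ default is a free
  parameter of the simulator, not a claim about any probe chemistry;
* prevalent RA at 1.2% baseline with a true OR of 2.06 on CHIP (plus
  mild age and female-sex effects); mortality exponential with an
  age-loglinear baseline and a true HR of 1.92 for CHIP-and-RA;
  the dedicated survival-recovery generator uses exposure prevalence
  0.22 (the CHIP fraction observed in newly diagnosed RA patients) and
  a 30% unexposed event rate over 15 years.

What a green test does **not** establish: the generator has no linkage
or haplotype structure, no longitudinal clone growth, no batch effects
in intensities, no miscoded registry events, and clone-to-BAF mapping
assumes autosomal heterozygous variants (no CN-LOH amplification). The
published cohort estimates themselves are computed on access-restricted
data and are used here only as parameter-recovery targets on synthetic
cohorts.

# Numerical choices and degenerate inputs

* Robust scale floored at 0.005; reference-cluster fits require ≥ 50
  usable samples; zero-intensity samples are excluded and counted,
  never imputed.
* Cohort-frequency comparisons are strict (`>` fails) to match the
  "more than" phrasing of the rules.
* Zero called carriers make a locus "not qualifiable" (flagged) rather
  than an error; an empty sequencing truth set yields a flagged, empty
  concordance report.
* Derived seeds in the acceptance script stay below 2³¹; all
  randomness flows from R's default Mersenne-Twister under `set.seed`.

# Known limitations

No competing-risks estimator (cumulative incidence is 1 − KM with death
treated as censoring); no ICD ontology beyond exact code-set matching;
no genome-wide mosaic chromosomal alteration calling; no read-level
simulation; the VCF reader apportions site-level strand counts to
decomposed alleles proportionally because exact per-allele strand
counts are not representable in a single site-level field.
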