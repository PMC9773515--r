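---
title: "MAVE-calibrated variant classification: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MAVE-calibrated variant classification: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maveclass)
```

# The problem

Lynch syndrome arises from germline inactivation of the DNA mismatch-repair
(MMR) genes *MSH2*, *MLH1*, *MSH6* and *PMS2*. Panel testing discovers many
missense variants whose clinical meaning is uncertain (VUS). A deep
mutational scan of MSH2 provides a per-variant loss-of-function (LoF)
score — a unitless enrichment measure in which higher values mean more
functional damage — and a sequence-based splice predictor provides a
deltaMax probability of splice disruption in [0, 1]. This package turns
those two scores into calibrated clinical evidence, applies it through a
point-based ACMG/AMP engine, and propagates the same functional annotation
into cohort-level association and tumor two-hit analyses.

# Functional tiering

`assign_tier()` bands each variant:

* **deleterious (splice)**: deltaMax ≥ 0.5 — checked first, so a variant
  disrupting splicing is attributed to the splice mechanism regardless of
  its protein score;
* **deleterious (protein)**: LoF ≥ 0.4;
* **intermediate**: LoF ∈ [0, 0.4) or deltaMax ∈ [0.2, 0.5);
* **neutral**: only when both measures are normal (LoF < 0 and
  deltaMax < 0.2);
* **unscored**: neither score available; such variants are excluded from
  all score-based analyses with a logged count.

Thresholds are inclusive on the deleterious side and exclusive on the
neutral side, so LoF exactly 0 is intermediate. When the two scores
disagree the more severe band wins: a variant is never called functionally
normal unless both measures are normal. In particular a variant with
LoF < 0 but deltaMax ∈ [0.2, 0.5) is banded intermediate — the tallying of
that corner case is genuinely ambiguous in practice, and we prefer the
conservative (non-neutral) reading. All four cutoffs are configuration
(`tier_cutoffs()`), not constants.

# OddsPath calibration

Controls are previously classified P/LP or B/LB variants whose
classification used *no* prior functional evidence (`curate_controls()`),
avoiding the circularity of validating one functional assay with another.
With prior $P_1$ = proportion pathogenic among all scored controls and
posterior $P_2$ = proportion pathogenic among controls scoring in a given
direction,

$$\mathrm{OddsPath} = \frac{P_2 (1 - P_1)}{(1 - P_2)\, P_1}.$$

Choices that matter:

* **Intermediate controls stay in the prior** but enter neither posterior:
  the prior describes the curated set before functional scoring. With 22
  P/LP + 26 B/LB and one pathogenic intermediate this gives
  $P_1 = 22/48$, corrected $P_2 = 21/22$ and $1/27$, hence OddsPath
  $546/22 \approx 24.8$ and $1/22 \approx 0.045$. Alternative bookkeeping
  (dropping the intermediate from the prior) moves these numbers by a few
  percent; `compute_oddspath()` therefore exposes every count and
  correction flag so either convention can be audited.
* **Zero-discordant-cell correction**: when a direction's discordant cell
  is empty, the posterior is recomputed as if one additional inconsistent
  variant were present (denominator + 1, discordant cell = 1), applied per
  direction and flagged.
* **Strength thresholds** 2.08 / 4.33 / 18.7 / 350 (reciprocals on the
  benign side) come from the established Bayesian points framework; the
  mapping (`map_strength()`) is a monotone, mirror-symmetric step function.

# The ACMG/AMP point engine

Evidence codes are parsed from the clinical shorthand (`PS3`, `PM2_P`,
`PS4_M`, …), carry supporting/moderate/strong/very-strong points
(1/2/4/8, negated for benign codes), and sum to a category:
P ≥ 10, LP 6–9, VUS 0–5, LB −6…−1, B ≤ −7. Each base code may apply at
most once; duplicates are validation errors. Points and category
thresholds are configuration so alternative published scales can be
swapped in. Only PS3/BS3 are *generated* by this package (from the
calibrated tiers); every other code is an input, since criteria such as
PM2 or PP1 require population or pedigree data out of scope here.

Functional-evidence rules (`functional_evidence_code()`,
`reclassify_catalog()`):

* LoF ≥ 1.7 (the lowest score among the pathogenic validation variants):
  PS3 at strong.
* LoF ∈ [0.4, 1.7): PS3-moderate-*eligible*, reported but conservatively
  not auto-applied — these variants score below every control used to
  establish the calibration (`apply_ps3_moderate = TRUE` overrides).
* Functionally normal by both measures: BS3 at strong.
* Splice-predicted and intermediate variants receive nothing: the assay is
  cDNA-based and blind to splicing, so splice predictions are
  computational evidence upstream, not assay evidence.

# Exact tests and association models

`fisher_two_sided()` enumerates the hypergeometric distribution over all
tables with the observed margins; `binomial_two_sided()` enumerates
binomial outcomes. Both sum the probabilities of outcomes no more likely
than the one observed (the "method of small p-values") with relative
tolerance $1 + 10^{-7}$ on ties, matching the convention of mainstream
scientific stacks; `central` (doubled tail) and `midp` variants are
available for sensitivity analysis, since published two-sided binomial
p-values do not always state their convention. Point masses come from R's
`dhyper`/`dbinom`, which work in log space, so totals of order $10^4$ are
safe. Degenerate tables (a zero margin) carry no information and return
p = 1.

`fit_cancer_association()` fits a maximum-likelihood logistic regression
of cancer diagnosis on six 0/1 carrier features (MSH2 missense with
deleterious score, MSH2 missense with neutral score, MSH2 other P/LP, and
any P/LP in MLH1 / MSH6 / PMS2), with Wald 95% intervals on the odds-ratio
scale — consistent with how such cohort odds ratios are conventionally
reported. Exclusion rules run first: carriers of a P/LP variant in a
non-Lynch gene are dropped from the missense-VUS analysis, and an
individual with both an MSH2 missense VUS and a P/LP in another Lynch gene
counts for that gene only. Two deliberate choices:

* **Sex is a covariate in the colorectal model by default.** Baseline
  colorectal rates differ several-fold by sex in screening cohorts (and in
  our generator: 8.9% female, 38.3% male). Omitting sex would report a
  marginal odds ratio attenuated by non-collapsibility even with features
  independent of sex; the conditional odds ratio is the generator's
  parameter and the natural estimand. `include_sex = FALSE` restores the
  marginal fit. The uterine/endometrial model is female-only by
  construction and takes no sex term.
* **Complete separation is flagged, never silent**: affected terms carry a
  `separation` flag, and empty feature columns are dropped with a warning.
* No multiple-testing correction is applied anywhere; raw p-values are
  reported.

# Paired tumor–normal analyses

Under the two-hit model, an inherited loss-of-function allele plus a
somatic second hit inactivates MSH2. `second_hit_analysis()` counts, among
individuals whose sole germline finding is one MSH2 missense variant, a
somatic MSH2 P/LP mutation, a somatic MSH2 LOH event (included by default,
`include_loh = FALSE` to restrict to point mutations), or an EPCAM
structural variant (which silences the downstream MSH2 copy) as second
hits, and Fisher-tests the deleterious-versus-neutral germline split.
`msi_analysis()` cross-tabulates microsatellite status (MSI-high or
MSI-low = unstable) after excluding MLH1-promoter-hypermethylated tumors,
because that epigenetic event causes MMR deficiency independently of MSH2.
`somatic_coincidence_analysis()` compares tumors whose somatic MSH2
missense burden is functionally disruptive against those where it is
exclusively neutral (and no other somatic MSH2 P/LP exists): in the latter
the MMR deficiency must be explained elsewhere, so somatic mutations in
the other MMR genes and MLH1 hypermethylation should be enriched. Cases
with two or more somatic MSH2 hits, at least one deleterious, and no
deleterious germline variant are flagged as sporadic ("Lynch-like")
candidates in the audit output.

Intermediate or unscored germline tiers, unassayed MSI, and unassayed
methylation are excluded from the respective tables with logged counts.
We report exact fractions rather than reproducing any particular rounding
of them.

# What the generator emulates — and what it does not

`simulation_config()` centralizes every parameter; a fixed seed gives
byte-identical output, with one RNG stream per sub-generator split
deterministically from the master seed.

* **Scores.** LoF scores are a two-component normal mixture. The
  deleterious component is Normal(2.5, 1.0). The neutral component is
  Normal(−0.3, 0.15): since the neutral band requires LoF < 0, a neutral
  component centred at 0 would place half its mass in the intermediate
  band, grossly inflating the intermediate fraction relative to the few
  percent seen in real score maps and breaking the truth-label round trip;
  centring just below zero reproduces a realistic tier mix. deltaMax puts
  a configurable mass (default 53/5130) uniformly above 0.5, the rest in a
  thin-tailed Beta mostly below 0.2. The real assay's score distribution
  is not reproduced; downstream analyses depend only on tier counts, not
  distribution shape.
* **Catalog.** Default 2000 variants (a desk-scale stand-in for the
  ~17,000 possible missense changes); 90% VUS; classified variants are
  score-concordant except for configurable injected discordants; VUS carry
  sampled prior evidence-code profiles (population-rarity evidence common,
  phenotype/computational evidence rarer and correlated with true
  deleteriousness) so that adding PS3 can actually complete a P/LP case.
  The generating component is echoed per record (`truth_component`) for
  recovery testing.
* **Controls.** The control draw reproduces the calibration conditions
  exactly: 22 pathogenic (one forced into the intermediate band) and 26
  benign score-concordant variants, labelled in the control table.
* **Carriers.** Default 20,000 individuals, 84% female; one feature
  category per carrier; outcomes drawn from the logistic model with
  configured odds ratios (colorectal defaults 2.53 / 8.10 / 14.4 for
  MSH2-deleterious-missense / MSH2-other-P/LP / MLH1; uterine-endometrial
  5.56 / 11.9 / 13.2 for MSH2-deleterious-missense / MSH2-other-P/LP /
  MSH6; the remaining defaults are plausible lesser effects, chosen once).
  Uterine/endometrial outcomes are structurally female-only.
* **Paired cohort.** Default 1604 cases; second-hit rates 0.92 / 0.17 by
  germline tier; MSI conditional on whether a biallelic MSH2 explanation
  exists; MLH1 hypermethylation injected only among unexplained tumors;
  somatic MSH2 missense variants drawn from the catalog by tier.

Not emulated: per-variant carrier recurrence and family structure
(carriers are independent), sequence context and mutational signatures,
realistic HGVS nomenclature (placeholders only), and assay noise beyond
the mixture overlap. Consequently, passing recovery tests demonstrates
correctness of the estimators under the stated generative model — not
robustness to pedigree correlation or ascertainment quirks of real
clinical databases.

# Numerical and degenerate-input choices

* Tie tolerance $1+10^{-7}$ in both exact tests; zero-margin tables give
  p = 1; zero cells in `odds_ratio_2x2()` trigger a flagged
  Haldane–Anscombe 0.5 correction.
* TSV round trips serialize numerics at full double precision
  (`%.17g`); empty string encodes missing; validation errors name the
  offending row.
* Reports are deterministic: run manifests embed the command, package
  version, seed, configuration hash and input digests, while timestamps
  go only to the log stream, so identical inputs give byte-identical
  report files.
* Classification conservation is asserted at run time: previously
  classified + newly P/LP + newly B/LB + remaining VUS must equal the
  catalog size.

# Problem sizes in the test suite

The suite exercises exhaustive Fisher enumeration for all 2×2 tables with
total count up to 30, Wald-interval coverage over 1000 null replicates,
odds-ratio recovery over 200 simulated cohorts of 50,000 carriers, and
null calibration of the second-hit test over 500 simulated paired cohorts
of 2000 cases — sizes chosen to make Monte-Carlo error small relative to
the tolerances being checked while keeping a full run at desk scale.

# Known limitations

* PS3/BS3 are the only evidence codes generated; the engine classifies
  from whatever other codes are supplied and does not validate their
  provenance.
* OddsPath uncertainty is not quantified (no bootstrap); the printed
  odds are point estimates over small control sets.
* The splice-disruption score is an input prediction, not a measurement;
  splice-predicted variants are deliberately denied PS3.
* HGVS strings are opaque identifiers: no transcript mapping, liftover or
  VCF parsing is provided.
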