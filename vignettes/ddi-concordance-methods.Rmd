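---
title: "Scoring and agreement methods for DDI compendia concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and agreement methods for DDI compendia concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddiconcord)
```

`ddiconcord` measures how well drug-information compendia agree about
potential drug–drug interactions. This vignette is the package's
account of the methods: the endpoint definitions, the statistical
machinery, the synthetic data model, and the places where the design
was genuinely open and a choice had to be made.

## The evidence matrix

The unit of analysis is the (drug pair, resource) record. A pair is
one psychotropic drug combined with one COVID-19 medication (never
psychotropic–psychotropic or COVID–COVID); the default universe
crosses 37 psychotropics — SSRIs, SNRIs, TCAs, MAOIs, other
antidepressants, antipsychotics, mood stabilizers, anxiolytics — with
9 COVID-19 medications. Each record carries a presence flag, five
documentation-component flags, and the resource's native severity and
course-of-action labels. Two modelling conventions are baked into the
container:

- **Absence is a finding, not missingness.** A (pair, resource)
  combination without a CSV row is materialized as `present = FALSE`:
  the resource was consulted and had no entry, which is exactly what
  the scope endpoint measures. Nothing is imputed.
- **`unrated` is reserved.** A standardized severity or action of
  `unrated` appears only when the entry is absent or the component is
  undocumented. `validate_matrix()` enforces this, along with
  one-record-per-combination uniqueness, and reports every violation
  with its coordinates.

## Vocabulary harmonization

Each resource grades severity on its own scale (PEPID's numeric 3/4/5,
UpToDate's letter codes C/D/X, verbal labels elsewhere). These are
mapped onto three informative categories — `minor`, `moderate`,
`major_contraindicated` — plus `unrated`. The shipped map collapses
each resource's major/contraindicated tier into one category (the
two-level risk collapse used when assembling moderate-to-
contraindicated study samples) while keeping `minor` distinct, because
the consistency rule below treats minor specially. Sub-moderate
vocabulary (PEPID 1–2, UpToDate A/B, a generic "Minor" elsewhere) is a
package extension: a moderate-and-above study sample never exercises
those labels, but the mapper must be total over data that includes
them. Course-of-action labels share one cross-resource map onto
`no_action`, `monitor`, `modify_dosage`, `avoid`.

Matching is exact after whitespace trimming, case folding, and
normalizing curly apostrophes. There is deliberately no fuzzy
matching: an unknown label raises an error naming the label, resource,
and pair, because a silently mis-mapped severity is worse than a halt.
Standardization is idempotent — the standardized columns are always
recomputed from the raw ones.

## Endpoints

**Scope** is the percentage of the full pair sample with an entry. The
denominator is always the sample size, never the resource's own entry
count.

**Completeness** gives an entry one point per documented component
(mechanism, clinical effects, severity, level of documentation, course
of action; 0–5 total). Component percentages are out of the resource's
entries. The overall distribution is summarized by median and
quartiles; a resource with zero entries is flagged with a warning and
`NA` rather than a silent `NaN`.

**Consistency** compares each resource's standardized rating to the
majority across resources for the same pair, separately for severity
and course of action (a pair can be eligible for one component and not
the other, since the rating components are documented independently).

Three rules define the majority:

- *Strict plurality*, not absolute majority, of the cast ratings. The
  choice was open; plurality is the weaker requirement and keeps more
  pairs eligible, and an absolute-majority mode
  (`mode = "absolute"`) is available for sensitivity analysis.
- *Ties yield no majority* and the pair is ineligible. Scoring all
  raters inconsistent on a tie was the alternative; a tie defines no
  reference standard, so refusing to score is the defensible reading.
- *A rater floor* (`min_raters`, default 3): pairs rated by two or
  fewer resources are excluded, matching the usual practice of not
  assessing consistency on sparsely covered pairs.

The `minor` rule: a minor severity rating still participates in the
vote tally, but the resource that cast it is always scored
inconsistent — even if minor wins the plurality — because a
moderate-to-contraindicated study frame by construction contains no
pair whose true severity is minor. The conservative reading is the
default and is switchable (`minor_inconsistent = FALSE`).

## Statistical machinery

**Fleiss' kappa.** For the subjects × categories count table with
`n_ij` raters assigning pair *i* to category *j* and `n_i = Σ_j n_ij`:

```
P_i  = [Σ_j n_ij (n_ij − 1)] / [n_i (n_i − 1)]
P̄ₑ  = Σ_j p_j²,   p_j = Σ_i n_ij / Σ_i n_i
κ    = (P̄ − P̄ₑ) / (1 − P̄ₑ)
```

Because compendia cover different pairs, the default mode keeps every
pair with at least two ratings and uses the per-subject `n_i`
generalization; `complete_case` restricts to pairs rated by the full
panel. Neither is canonically "right" for unbalanced panels, so both
are exposed. The standard error is the Fleiss (1971) fixed-marginal
null variance, with the mean rater count substituted for the panel
size when rater counts vary — an auditable, stated convention rather
than a claim of optimality; the z test is of κ = 0 and the CI is
κ ± z·SE. A table whose ratings all fall in one category has P̄ₑ = 1
and raises a degeneracy error instead of returning 0/0. Verbal
interpretation uses Landis–Koch bands with right-closed intervals:
κ ≤ 0.20 poor, (0.20, 0.40] fair, (0.40, 0.60] moderate, (0.60, 0.80]
substantial, above 0.80 almost perfect.

**McNemar's test** on paired coverage uses only the discordant counts
*b* (covered by the first resource only) and *c* (second only). The
exact p doubles the binomial(b+c, ½) tail at min(b, c), capped at 1;
the asymptotic version is the continuity-corrected
(|b−c|−1)²/(b+c) chi-square. `auto` switches to exact below
b + c = 25. b + c = 0 returns p = 1 with a degeneracy flag.

**Wilcoxon signed-rank** on paired completeness scores drops zero
differences, assigns average ranks to ties, and — because completeness
scores are small integers, so ties are the rule — computes the exact
two-sided p by enumerating all 2ⁿ sign assignments of the observed
rank vector whenever n ≤ 15 (the null distribution is symmetric about
Σr/2, so the two-sided region is |W⁺ − Σr/2| at least as extreme).
Beyond that, a normal approximation with tie-exact variance Σr²/4 and
a 0.5 continuity correction is used. Pairing is restricted to pairs
covered by both resources: an absent entry has no completeness score,
and imputing one would conflate the scope and completeness endpoints.

No multiplicity correction is applied across the 15 pairwise
comparisons by default — each is reported at its nominal level, which
mirrors how such comparisons are conventionally reported in this
literature; `holm = TRUE` adds adjusted p-values for users who want
family-wise control.

**Tiers.** Resources are sorted by median (then Q1, Q3, then name) and
grouped greedily: a resource joins the current tier iff its signed-rank
p against every member is ≥ α, else it opens a new tier. This is a
reporting convention — a readable ranking — not a simultaneous
inference procedure, and is documented as such.

## Numerical conventions

- **Truncation, not rounding.** Printed percentages truncate to the
  reported decimals (115/181 → 63.53; 85/181 → 46.9). This is the
  only convention consistent with the published scope column this
  package reproduces, and it is applied uniformly
  (`format_percent()`, `truncate_percent()`), with a 1e-9 epsilon
  inside `floor()` to protect exact ratios from float error.
- **Quartiles** are Tukey-inclusive (median of each half, median
  shared by both halves at odd n). No rule is canonical for 0–5
  integer scores; the inclusive rule is stated and used consistently,
  and the test oracles implement it independently.
- **Exactness thresholds** (McNemar exact below 25 discordant pairs,
  Wilcoxon enumeration to n = 15) keep the exact paths cheap
  (2¹⁵ subset sums) while covering the sample sizes where the
  asymptotics are least trustworthy.

## The synthetic generator

`generate_matrix()` draws matrices with the statistical structure the
analysis assumes, so every stage is testable without the commercial
databases:

- pairs sampled without replacement from the drug-pair cross-product;
  a request beyond the universe errors (custom drug lists can enlarge
  the universe, e.g. for large-n convergence checks);
- entry presence Bernoulli(π_r) per resource, independently across
  resources; component flags Bernoulli per component given presence;
- a latent true severity per pair (default masses 0.05 / 0.55 / 0.40
  on minor / moderate / major-contraindicated — a convention loosely
  reflecting a moderate-to-severe sample, with the small minor mass
  exercising the minor-exclusion rule);
- a single agreement parameter α: with probability α the resource
  reports the latent severity, otherwise a uniform draw over all
  three categories. α = 0 therefore gives independent uniform
  ratings (κ ≈ 0) and α = 1 unanimity (κ = 1), and estimated kappa is
  monotone in between — the property that makes α a usable
  one-dimensional agreement dial. A miss drawn only from the *other*
  categories was considered and rejected: it makes raters agree on
  avoiding the truth at low α, breaking monotonicity. The course of
  action is the deterministic image of the latent severity
  (minor → no action, moderate → monitor, major → avoid) perturbed the
  same way over the four actions. The default α = 0.8 sits in the
  moderate-agreement regime typical of severity ratings across
  compendia.
- `reference_marginal_config()` sets π_r and the documentation
  probabilities to the published per-resource marginal proportions of
  the 181-pair six-resource survey (e.g. π = 143/181 for PEPID;
  clinical-effects documentation 23/115 for Drugs.com).

Raw labels are emitted in each resource's native vocabulary, so
generated data exercises the harmonization stage end to end. One root
seed drives all draws via a single RNG stream, the caller's RNG state
is left untouched, and identical (config, seed) gives byte-identical
matrices and reports.

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: coverage is independent across
resources, whereas real compendia overlap non-randomly (the joint
dependence is not identifiable from published marginals);
documentation flags are independent across resources given presence,
so component-flag kappas sit at chance by construction; there is one
global α rather than per-resource reporting quality; and drug
identities carry no pharmacology — pair names are opaque labels.
Consistency denominators and kappa values of any particular real
survey are deliberately not targets: only the marginal structure and
the arithmetic downstream of it are.

## Problem sizes and determinism in the test suite

The suite exercises the 181 × 6 study geometry throughout: marginal
fidelity is checked by averaging scope over 60 seeded replicates
(tolerance 2 percentage points), large-sample convergence on a
5000-pair synthetic universe (tolerance 0.02), kappa monotonicity over
α ∈ {0, 0.3, 0.6, 0.9} averaged over 50 seeds per level, the McNemar
null level and the Wilcoxon power comparison over 200 replicates each,
and exhaustive oracle comparisons (all discordant splits to b + c =
20; all 2-rater 4-subject kappa tables over two and three categories;
full sign enumeration to n = 12). All stochastic tests fix their
seeds.

## Known limitations

- The endpoint definitions treat a resource's documentation flags as
  given; extracting them from monographs (and the judgment calls that
  entails) is upstream of this package.
- The variable-rater kappa SE uses a mean-rater-count plug-in; for
  severely unbalanced panels a resampling interval would be more
  defensible than the closed form.
- The tier procedure's greedy grouping depends on the sort order when
  medians tie; it is a presentation device, not an inference.
- Drug names are opaque: no RxNorm/ATC normalization, no detection of
  the same ingredient under two names.
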