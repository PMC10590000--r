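---
title: "Temporal disease and death trajectories of MAFLD: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal disease and death trajectories of MAFLD: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mafldtraj)
```

# The problem

Metabolic dysfunction-associated fatty liver disease (MAFLD) — hepatic
steatosis plus metabolic dysfunction — is associated with disease across
essentially every organ system. The question this package addresses is not
*whether* MAFLD raises risks, but *in what temporal order* the subsequent
conditions arrive: which diseases sit at the origin of the cascade, which
mediate, and which terminate it, including death by specific cause.
`mafldtraj` implements that trajectory analysis as a reusable, tested
pipeline over two inputs every EHR-backed biobank provides: a baseline
participant table and a table of first hospital diagnoses coded in ICD-10.

Because the real cohorts behind this design are access-restricted, the
package carries a first-class synthetic-cohort generator with planted,
known effects. Every stage of the pipeline is verified against that known
truth or against independent oracles (closed forms, brute-force
enumeration); nothing in the test suite depends on restricted data.

# Phenotyping

**Steatosis** is proxied by the fatty liver index,

$$\mathrm{FLI} = 100\,\sigma\!\left(0.953\ln \mathrm{TG} + 0.139\,\mathrm{BMI}
 + 0.718\ln \mathrm{GGT} + 0.053\,\mathrm{WC} - 15.745\right),$$

with TG in mg/dL, GGT in U/L, waist in cm, and $\sigma$ the logistic
function; FLI $\ge 60$ flags steatosis. The package's canonical
triglyceride unit is mmol/L (the unit of the metabolic criteria);
conversion by 88.57 happens inside `compute_fli()` so callers never mix
units.

**MAFLD** is steatosis plus any of: type-2 diabetes; BMI $\ge 25$; or at
least two of five metabolic abnormalities (prediabetes, low HDL,
TG $\ge 1.7$ mmol/L, blood pressure $\ge 130/85$ or medication, raised
waist). Insulin resistance would be a sixth abnormality but requires serum
insulin, which the target biobank does not collect, so the menu has five
usable items plus diabetes/BMI gates. Missing fields yield a three-valued
`NA` ("undetermined") only when the decision actually depends on them;
undetermined participants are excluded before matching, mirroring the
source design. One deliberate reading: the hypertension criterion
"$\ge 130/85$" is implemented as (SBP $\ge 130$ **or** DBP $\ge 85$) —
the conventional either-component reading — and is configurable only by
editing the classifier, since no data-driven resolution exists.

**Fibrosis.** The NAFLD fibrosis score is the printed linear formula
(intercept $-1.675$; age, BMI, diabetes, AST/ALT, platelets, albumin
terms); scores strictly above $-1.455$ flag advanced-fibrosis risk. The
boundary is exclusive by default because the source states a "cutoff"
without inclusivity; `flag_advanced_fibrosis(inclusive = TRUE)` flips it.

**Genetics.** The polygenic risk score over MBOAT7, GCKR, TM6SF2 and
PNPLA3 risk-allele dosages is normalized by $n_{\mathrm{SNP}}/\sum\beta$ so
its attainable range is exactly $[0, 2\,n_{\mathrm{SNP}}] = [0, 8]$
regardless of the weights. Tertile cutoffs 0.76 / 2.35 are the source
cohort's and are the default; synthetic cohorts should use
`prs_tertile(method = "empirical")` because their PRS distribution need not
match the source cohort's. Boundary semantics: low $< 0.76$, intermediate
$0.76$–$2.35$ inclusive, high $> 2.35$.

# Matching

Exposed and unexposed participants are matched 1:1 by greedy
nearest-neighbor on the logit propensity (additive logistic model of
exposure on age, sex and Townsend deprivation), without replacement, in an
order randomized by the seed. Design choices the source leaves open, fixed
here and logged with every run:

* **Sex is matched exactly** (stratified matching); continuous covariates
  act through the propensity.
* **Caliper** defaults to 0.2 SD of the logit propensity — the common
  default — and can be disabled (`caliper = "none"`) or set absolutely.
* Unmatched exposed participants are dropped with a logged count.
* Perfect separation in the propensity model is surfaced as a classed
  warning recommending exact matching, and the fitted 0/1 values are
  returned rather than erroring, since the fitted values are still
  well-defined for matching within strata.

Greedy matching is not globally optimal; the test suite checks it against
a brute-force assignment oracle only on configurations where the two
coincide, and checks the balance contract (post-match SMD never worse than
pre-match) across seeds rather than any optimality claim.

# PheWAS stage

One Cox proportional-hazards fit per outcome category (Efron ties), with
time-on-study from the assessment date; death and study end censor disease
outcomes. Attained age is *not* the time axis: the matched design already
balances age, and follow-up is reported from enrolment. Per-outcome
subcohorts exclude participants with the outcome at baseline; an event
dated exactly on the assessment date counts as prevalent (a boundary that
must be fixed somewhere; the conservative side was chosen). Outcomes must
occur in more than `min_case_fraction` (default 1%) of exposed
participants — `floor(0.01 × 163,303) = 1633` in the source cohort — and
significance is the conjunction HR $> 1$ and $p < \alpha/n$ with $n$ the
*total* category count by default (the source's "number of disease
categories"), configurable to the number actually tested. The Cox model is
exposure-only: matching is the confounding control. An adjusted mode
exists (`adjust` arguments) but is off by default because the source
states no adjustment.

# Pair inference

Ordered pairs of PheWAS-significant categories ($n(n-1)$ of them) pass
three gates:

1. **Co-occurrence**: more than `floor(0.005 × n_exposed)` exposed
   participants hold both diagnoses (816 in the source cohort).
2. **Direction**: among co-affected participants, the fraction with D2
   strictly later than D1 must exceed 1/2, with exact one-sided binomial
   $p$ below $\alpha$ divided by the number of pairs that passed gate 1.
   Same-day D1/D2 diagnoses carry no direction evidence (hospital episodes
   often code both at once) and are removed from the trial count. The
   exact tail is accumulated by the binomial-coefficient recurrence rather
   than a distribution-function call, so the unit tests' brute-force
   enumeration of all $2^n$ orderings is a genuinely independent check; a
   continuity-corrected normal approximation is available for counts
   above 500.
3. **Association**: a univariate logistic regression of incident D2 on D1
   among exposed participants free of D2 at baseline. OR $> 1$ and $p$
   below $\alpha$ divided by the number of pairs that passed gate 2.
   Without covariates the OR equals the 2×2 cross-product ratio, which the
   tests assert. Zero cells are non-estimable — no continuity correction
   is applied, matching the "confirm or drop" role of this stage.

   The exposure here is D1 *ever diagnosed during follow-up*
   (`anchoring = "ever"`), i.e. this gate tests plain association, with
   temporal order already enforced by gate 2. The seemingly stricter
   alternative — requiring D1 before D2 for cases but only before the end
   of follow-up for non-cases — was implemented and measured on planted
   amplified pairs: it gives cases a systematically shorter exposure
   window than non-cases, an immortal-time-style bias that pushes the OR
   of a *genuinely* amplified pair to 1 or below, so the stage would veto
   pairs the direction gate confirms at $p < 10^{-19}$. That variant is
   retained as `logistic_pair_test(anchoring = "temporal")` for
   sensitivity analysis only.

The sequential Bonferroni denominators (gate-1 survivors for gate 2,
gate-2 survivors for gate 3) mirror the staged flowchart of the source
design; both denominators are logged.

# Trajectory graph

Confirmed pairs form a directed graph; nodes carry the PheWAS HR, edges
the OR and pair count. The tree view deletes shortcut edges: D1→D3 is
pruned whenever D1→D2→D3 exists. On an acyclic graph this is exactly the
transitive reduction and preserves reachability — verified against a
reachability-matrix oracle on random DAGs. Two deliberate departures from
a naive implementation:

* **Cycles are never silently resolved.** Edges inside a directed cycle
  (possible when tie patterns differ between orientations) are exempt from
  pruning, labelled, and reported.
* **Pruned edges are retained** in the TSV export with a `pruned` flag;
  the source says the shortcut "could be" deleted, and analysts may want
  both views.

Node layers: sources are "original" diseases, sinks "terminal", the rest
"intermediary". Because "mediated downstream diseases" tallies can be read
as direct successors or all descendants, both counts are emitted
(`n_direct`, `n_descendants`).

# Death and genetic workflows

The death variant matches decedents to survivors *within the exposed
group* (1:1 by default on the same covariates; the ratio is configurable
because the source's printed counts imply an unstated, larger ratio),
sweeps the 16 chapter-level causes of death (primary and secondary
certificate codes both count), then treats each disease as exposure and
cause-specific death as outcome. The disease→death model is Cox on
time-to-death with the disease as a baseline-anchored binary exposure; a
logistic fallback is provided because the source flowchart does not name
the model. Pair inference then runs restricted to each cause's decedents
and the per-cause graph terminates in a synthetic `death:<cause>` node.
The 16-category scheme itself is a chapter-level grouping shipped as an
editable TSV, since the source names the categories but not the full code
ranges.

The genetic workflow is the identical pipeline with exposure = highest
versus lowest PRS tertile (middle dropped), used as a
confounding-resistant replication of the phenotype-defined trajectory.

# The synthetic world

`simulate_cohort()` draws the stated world once; its defaults are not
tuned to any test outcome:

* **Cohort**: default follow-up 12.9 years (the source cohort's mean),
  assessment dates spread over a 4-year recruitment window from a fixed
  synthetic study start (2006-01-01), ages 40–69, 50% male, Townsend-like
  deprivation score.
* **Steatosis**: a latent Bernoulli state with prevalence given by one
  knob (default 0.5, matching a matched-cohort design of half exposed).
  The FLI linear predictor is drawn on the correct side of the FLI = 60
  boundary given the state and *decomposed exactly* into BMI, waist, GGT
  and TG, so the emitted biomarkers reproduce the intended steatosis
  status and the FLI ≥ 60 fraction equals the knob up to binomial noise.
  Other biomarkers shift moderately with the latent state. Exposure truth
  is the MAFLD classification computed from the emitted biomarkers.
* **Events**: competing piecewise-exponential processes in continuous
  days. Category hazards are baseline × planted exposure HR (for exposed)
  × $\prod\psi$ over already-diagnosed amplifiers × optional genetic
  modifier $\mathrm{hr}^{\mathrm{PRS}/8}$. Default baseline rates
  (0.002–0.012/year over 26 common-condition categories) give realistic
  10–15% cumulative incidences over the follow-up. Amplification applies
  from the day after the amplifier's diagnosis, so planted directions are
  strictly ordered. Death is a competing cause-specific process that
  truncates further diagnoses.
* **Codes**: diagnoses are emitted as 4-character children of the
  category's 3-character stem so the truncation path is always exercised.
  The bundled code mapping (~70 codes → 31 categories) and the
  16-category death scheme are synthetic stand-ins for the study-scale
  files, in the same dialect.

What a green test does **not** establish: the generator has no genotype
linkage disequilibrium, no seasonality, no recall error in alcohol intake
(treated as a plain g/day value), no correlation between deprivation and
disease, and marginals are not calibrated to any real cohort. Recovery
tests therefore validate the *inference machinery*, not epidemiological
realism.

# Numerical choices and degenerate inputs

* Wald CIs and p-values throughout (matching standard PheWAS practice);
  non-convergence or monotone likelihood (SE > 50 on the log scale) flags
  a result non-estimable rather than erroring the sweep.
* Thresholds are strict: occurrence filters use $>$ floor(fraction × n);
  the direction gate needs fraction $> 0.5$; significance needs strict
  inequalities on HR, OR and $p$.
* Zero-participant simulations produce empty tables, not errors; zero
  baseline hazards produce empty event tables; an all-tied pair is
  "non-testable"; an empty PRS tertile under the genetic exposure is a
  hard error (the contrast is undefined).
* All randomness flows from one master seed through deterministic
  per-stream child seeds (`child_seed()`), so partial reruns and full
  reruns agree byte-for-byte.

# Known limitations

Greedy 1:1 matching can leave attainable balance on the table compared to
optimal matching; the disease→death exposure anchoring ignores
immortal-time subtleties (as does the source design); competing risks are
handled by censoring, not cause-specific cumulative-incidence models; and
the pair logistic stage conditions on surviving to co-occurrence. These
mirror the source method's scope and are deliberately not "fixed" here.
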