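---
title: "Simulating and auditing a web-RDS study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and auditing a web-RDS study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(webrds)
```

## The problem

Respondent-driven sampling (RDS) recruits hidden populations through their
own social ties: seeds receive a fixed number of single-use invitation
codes, pass them to eligible peers, and the referral chains grow wave by
wave. When degree — the number of eligible peers a participant reports
knowing — is recorded, selection probabilities can be approximated as
proportional to degree, which underpins reciprocal-degree (RDS-II)
weighting. The web variant moves everything online, trading interviewer
control for speed and reach, and thereby exposing the study to ineligible
participation, duplicate attempts, and self-recruitment driven by the
participation incentive.

This package treats the entire operational loop as an object of study. A
synthetic population and recruitment simulator generate raw intake data
with known ground truth; the cleaning funnel, degree-imputation rule and
diagnostics are then validated against that truth, and against a
deterministic reference fixture that reproduces a published
implementation study's headline counts (508 attempts, 156 invalid, 22
incomplete, 330 valid, 6 consistency exclusions, 324 analyzed; recruiter
productivity 75/60/39 over 174; 21 waves; degree mode 5, maximum 99).

## The synthetic population

`generate_population()` draws, for each of `n_total` persons, eligibility
(Bernoulli at `prevalence_eligible`), demographic traits from configurable
marginals, a device-use history (nonempty exactly for eligible members),
and a unique synthetic email and date of birth. Eligible members are
joined by a simple undirected graph:

- **Degree family.** Degrees are negative binomial truncated to
  `[1, degree_max]` (default cap 99, the largest value the two-question
  instrument accepts). The *truncated* mean is calibrated by root-finding
  so the realized mean matches `mean_degree`; the dispersion default (1.5)
  gives the right-skewed shape typical of self-reported contact networks.
  The true degree distribution of any real hidden population is
  unobserved — only heaped reports are — so the family is a modeling
  choice, exposed in the configuration.
- **Wiring.** A configuration model (igraph), simplified to remove loops
  and multi-edges (about a 1% loss in mean degree at the default sizes),
  then optionally rewired by trait-biased double-edge swaps towards a
  within-group edge share of `base + h (1 - base)` for homophily
  coefficient `h`, where `base` is the proportionate-mixing expectation.
  At `h = 0` the graph's trait assortativity is zero up to sampling noise.
- **Degree heaping.** `apply_degree_heaping()` reports degrees of 5 or
  less exactly and, with probability `heap_prob` (default 0.5 — the
  tendency is documented but unquantified), rounds larger degrees to the
  nearest multiple of 5, capped at 99. Heaping is why the reported-degree
  mode sits at 5.
- **Identity separability.** Emails are unique *after* the cleaning
  stage's normalization, and dates of birth are pairwise at least 2 days
  apart (sampled on a per-age-band grid; very large populations overflow
  the grid and degrade to plain uniqueness). This idealization makes the
  exact-DOB automatic block and the ±1-day proximity heuristic pure fraud
  signals. Real populations share birthdays, so a deployed system pays a
  false-positive cost this simulation deliberately excludes; passing
  tests therefore certify the *pipeline logic*, not the field
  false-positive rate.

## The recruitment simulator

`run_recruitment()` advances in discrete days. Seeds (chosen by
`select_seeds()`, which spreads seeds across trait strata and prefers
well-connected members, mirroring formative-phase practice) enroll on day
0 and receive `coupons_per_participant` codes (default 3, 8-character
collision-checked alphanumerics). Each held coupon is spent with daily
hazard `p_spend`; its *fate* is drawn once at issuance:

- **genuine** (the remainder): offered to a uniformly chosen not-yet-
  enrolled eligible neighbor;
- **ineligible contact** (`p_ineligible_use`, default 0.24): the attempt
  fails the screen and the code is invalidated;
- **duplicate** (`p_duplicate_attempt`, default 0.05): an already-enrolled
  neighbor re-attempts under a mutated email (token inversion, digit
  suffix, separator toggle) and a same-or-adjacent date of birth;
- **self-recruitment** (`p_self_recruit`, default 0.02): the recruiter
  spends their own code under a fresh email but their own date of birth.

Every taker is motivated by the incentive: under incentive level `low`
(before `incentive_switch_day`) or `high`, the spend proceeds with
probability `participation_prob[level]` and is otherwise retried later.
Setting the low-incentive probability to zero therefore reproduces a total
stall — not a single non-seed attempt before the switch — matching the
observed pattern that recruitment only gained momentum after the incentive
was raised. Drawing the fate at issuance (rather than re-rolling on each
retry) keeps the realized invalid share equal to the configured rates
(≈ 31% at the defaults), which would otherwise be inflated by the slower
consumption of declined genuine offers.

Accepted genuine offers abandon the questionnaire with `p_incomplete`
(default 0.06; the identity is then in the system and the code is spent)
and otherwise enroll: the participant answers the two network-size
questions (the operative second answer is the heaped true degree), has
all-negative device fields injected with `p_inconsistent` (default 0.018),
receives 3 codes, and joins the recruitment forest. Enrollment closes at
the end of the first day on which the valid completed count reaches
`target_n` (default 330). Defaults throughout are set to the rates the
reference study reports; where the study reports no number (for example
`p_spend`), values were chosen once for plausible chain dynamics and are
ordinary configuration knobs.

Because recruitment ties are real network ties, a participant's
recruitment-tree degree never exceeds their true degree, and heaping of
any degree above 5 lands on 5 or more — at least the largest possible tree
degree (one recruiter plus three recruits). Uncorrupted simulator output
therefore requires *zero* imputations, which the test suite asserts
exactly; implausible responses for testing are injected by
`corrupt_degree_records()`.

## The cleaning funnel

`intake_funnel()` applies five stages in the order the verification
process describes, each with first-arrival-wins semantics and a reason
code per removal:

1. **Automatic blocks** (`block_automatic()`): an attempt is removed if
   its coupon code was already used by any earlier attempt, or its
   lowercased email or exact date of birth matches an earlier *kept*
   attempt. Malformed identities are quarantined, never silently dropped.
2. **Manual patterns** (`flag_manual_patterns()`): emails are normalized
   in a fixed order — lowercase, strip `+tag`, tokenize the local part on
   `.`/`_`, strip trailing digits per token. Removal when (a) the sorted
   token key equals a kept attempt's (token inversions, numeric variants,
   separator toggles); (b) the normalized local-part edit distance is at
   most `similarity_threshold` (default 0.2, a knob — the source describes
   patterns, not a metric) *and* the date of birth is within ±1 day; or
   (c) the date of birth equals the recruiting participant's own (looked
   up through the coupon ledger) under a different email —
   self-recruitment. Ties resolve to the earliest kept attempt.
3. **Eligibility screen**: all three answers affirmative; missing counts
   as ineligible; the spent code is invalidated in the ledger.
4. **Completeness**: unfinished questionnaires are removed.
5. **Device consistency** (`check_consistency()`): completed records with
   no affirmative device field are excluded from analysis but retained in
   the recruitment forest, since their ties are real.

Two behaviors deserve explicit statement. First, self-recruitment under
the recruiter's exact date of birth is already caught by the automatic DOB
block whenever `dob` is among the automatic keys, so in the default
pipeline such attempts are attributed to the automatic stage; the manual
rule matters when the automatic key set is narrowed. Second, the
first-arrival-wins contract makes the *number* of kept rows order-free
only when duplicate groups do not chain across identifiers (same email to
one row, same DOB to another); with chained groups, which rows survive —
and in contrived cases how many — depends on arrival order. Percentages in
the funnel report use half-up rounding to one decimal, matching how such
tables are conventionally printed (156/508 → 30.7).

## Network size and imputation

The operative degree is the second question's answer (eligible peers aged
15+). A report is implausible when it is zero or below the participant's
recruitment-tree degree (`compute_tree_degree()`: recruiter plus
recruits — directly observed ties). `impute_degrees()` applies the
two-rule deterministic repair: substitute the first question's answer if
it passes the same plausibility test; otherwise substitute the half-up
rounded mean of the network sizes that needed no repair. The anchor mean
is frozen before any substitution, making the repair a pure function of
`(q1, q2, tree_degree, valid_mean)` and independent of record order. Two
conventions are ours, because the source does not state them: the anchor
mean is computed over operative (`q2`) values, and the mean substitute is
rounded half-up because degree is a count. The final degree is floored at
`max(tree_degree, 1)` so reciprocal-degree weights stay finite and no
imputation can produce a value the recruitment tree contradicts.

## Diagnostics, weighting and design effect

- `wave_statistics()`, `recruiter_productivity()` (counting, by default,
  recruits in the analysis set — the convention under which the reference
  study's 174 = 75 + 60 + 39 recruiters and its funnel are simultaneously
  consistent) and `coupon_exhaustion()` (denominator: participants with at
  least one issued code consumed, used or invalidated).
- `convergence_trace()` computes cumulative sample proportions (or means)
  in enrollment order and declares convergence when every value in the
  final `window_frac` of enrollments (default 0.25) deviates from the
  final value by less than `tol` (default 0.02). The published diagnostic
  is visual; these defaults are documented conventions, not reported
  values. A two-cluster bottleneck — two seed groups confined to opposite
  categories — produces plateaus that the detector correctly refuses to
  call converged.
- `recruitment_homophily()` reports, per category, the share of
  recruitments by category members landing on the same category, divided
  by the category's sample share (1 = proportionate mixing).
- `rds2_estimate()` implements reciprocal-degree weighting. The reference
  study deliberately applied no estimator to its own data; the estimator
  is provided for the simulator's validation loop, behind a small
  interface (seeds included by default, excludable). Weighted category
  shares always sum to 1.
- `chain_bootstrap_deff()` resamples whole seed-rooted chains with
  replacement — the chain, not the individual, being the approximately
  independent unit — and reports the ratio of the bootstrap variance to
  the simple-random-sampling benchmark `p(1-p)/n`. Independent
  single-member chains give a design effect near 1; chains homogeneous in
  the trait inflate it, which is the phenomenon behind the design-effect
  2.5 used in `sample_size()`.

## What the tests do and do not show

The property tests run at desk scale, chosen to keep the full suite within
a few minutes on one CPU: populations of roughly 1,000–6,000 persons,
recruitment targets of 100–500, 100 replicates for the parameter-recovery
check at n = 500 (where the mean RDS-II estimate recovers a known
prevalence of 0.30 within ±0.05 and is strictly less biased than the
unweighted mean when degree and trait are correlated), 50 replicate
rosters for fraud recall/precision, and 12-replicate grids for the
error-versus-sample-size trend. The simulator emulates the statistical
shape of a real web-RDS intake stream — funnel proportions, productivity,
heaping, stall-and-momentum dynamics — but not free-text answers,
device/browser fingerprints, shared birthdays, email providers' aliasing
conventions, or strategic fraud that adapts to the detection rules.
Passing tests certify the pipeline's logic and the estimator's behavior
under the stated model, not field performance against adaptive adversaries.

## Numerical conventions and degenerate inputs

Percentages round half away from zero to one decimal. Configuration-model
degree sequences with an odd sum have one unit removed from the largest
degree. A population whose expected (or realized) eligible count is below
2 is rejected: no network is possible. An attempt roster in which stage
counts fail to sum to the attempt total is a hard error (pipeline bug,
never silently absorbed). Stalled recruitment (no non-seed enrollment by
the horizon) raises a classed warning rather than failing, so stall
experiments remain inspectable. All randomness flows from explicit integer
seeds: identical seeds give byte-identical populations, rosters, ledgers
and forests, which the suite asserts.
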