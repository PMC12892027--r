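# webrds

Tools for designing, simulating and auditing **web-based respondent-driven
sampling (web-RDS)** studies of hidden populations — built around the use
case of recruiting users of electronic nicotine delivery systems (ENDS:
e-cigarettes, heated tobacco, vaporizers) in a large city where such
devices are banned and users are rare, stigmatized, and unreachable by
household surveys.

In RDS, researcher-selected *seeds* complete a questionnaire and receive a
small number of single-use invitation codes (*coupons*) to pass to eligible
peers; recruits in turn receive coupons, and the chains grow wave by wave.
Because each participant reports their personal network size *d_i* (the
number of eligible peers they know), selection probabilities can be
approximated as proportional to degree, giving the RDS-II
(Volz–Heckathorn) estimator for the population share of a category *c*:

```
p̂_c = Σ_{i : x_i = c} (1/d_i) / Σ_i (1/d_i)
```

Web-RDS moves recruitment and the questionnaire online, which is cheap and
fast but invites fraud: ineligible participation, duplicate attempts under
mutated emails, and self-recruitment for the secondary incentive. The
package implements the full operational loop needed to study and redeploy
such a design without access to any real survey data:

- **Synthetic population** (`population_config()`, `generate_population()`):
  a city population with a hidden, networked eligible subpopulation;
  truncated negative-binomial degrees, configurable trait homophily,
  unique synthetic identities, and multiple-of-5 degree heaping
  (`apply_degree_heaping()`).
- **Recruitment simulator** (`simulation_config()`, `select_seeds()`,
  `run_recruitment()`): discrete-day coupon dynamics with
  incentive-dependent participation, ineligible coupon use, duplicate and
  self-recruitment injection, and questionnaire dropout — emitting the raw
  attempt roster, coupon ledger and recruitment forest exactly as an
  intake system would see them.
- **Intake cleaning funnel** (`intake_funnel()` and its stages
  `block_automatic()`, `flag_manual_patterns()`, `screen_eligibility()`,
  `check_consistency()`): automatic blocking of repeated codes/emails/DOBs,
  email-similarity and self-recruitment heuristics, eligibility and
  device-consistency screens, with a machine-readable removal audit trail
  and a funnel report.
- **Network-size instrument** (`degree_records()`, `impute_degrees()`,
  `degree_summary()`): the two-question degree measure and the
  deterministic two-rule imputation for implausible self-reports, floored
  at the observed recruitment-tree degree.
- **Design and diagnostics** (`sample_size()`, `wave_statistics()`,
  `recruiter_productivity()`, `coupon_exhaustion()`,
  `convergence_trace()`, `recruitment_homophily()`, `rds2_estimate()`,
  `chain_bootstrap_deff()`), with `tidy()`/`glance()` methods and
  `autoplot()` displays.
- **Reference fixture** (`make_paper_fixture()`): a deterministic attempt
  roster, ledger and forest reproducing a published web-RDS
  implementation study's headline results end to end.

## Worked example

```r
library(webrds)

# How large must the sample be? Conservative p = 50%, SE 0.05,
# design effect 2.5, 20% anticipated loss:
sample_size(0.5, 0.05, 2.5, 0.2)
#>   n_unadjusted n_minimum n_target
#> 1          100       250      300

# The packaged reference study, run through the cleaning funnel:
fx <- make_paper_fixture()
funnel <- intake_funnel(fx$roster, fx$ledger)
funnel$report
#> <funnel report>
#>   attempts                   508
#>   invalid / ineligible       156  (30.7%)
#>     automatic blocks          12
#>     manual patterns           24
#>     failed screen            120
#>   incomplete                  22  (4.3%)
#>   valid participants         330
#>   consistency exclusions       6  (1.8%)
#>   analyzed                   324

# Operative network sizes, after the deterministic imputation rule:
degrees <- impute_degrees(degree_records(funnel$analysis, fx$forest))
degree_summary(degrees)
#> <degree summary>  n = 324
#>   degree <= 5 : 154 (47.5%)
#>   degree > 10 : 83 (25.6%)
#>   max reported: 99
#>   imputed     : 0 (0.0%)  [q1: 0, mean: 0]

# RDS-II weighted composition of the analyzed sample:
analysis <- funnel$analysis |>
  dplyr::left_join(dplyr::select(fx$forest, coupon_code, person_id),
                   by = "coupon_code") |>
  dplyr::left_join(dplyr::select(degrees, person_id, degree_final),
                   by = "person_id")
tidy(rds2_estimate(analysis, sex))
#> # A tibble: 2 × 4
#>   category     n prop_unweighted estimate
#>   <chr>    <int>           <dbl>    <dbl>
#> 1 female     127           0.392    0.379
#> 2 male       197           0.608    0.621
```

Here 154/324 = 47.5% of analyzed participants report knowing at most 5
eligible peers and the largest reported network is 99; the weighted share
for `male` (0.621) is above the raw share (0.608) because male
participants in this fixture report slightly smaller networks, so each
record carries more weight under reciprocal-degree weighting.

A fully simulated study — population, recruitment, cleaning, imputation,
diagnostics and a markdown report — is one call:

```r
study <- run_study(population_config(3000, 0.5, 6, rng_seed = 1),
                   simulation_config(target_n = 330, rng_seed = 2))
writeLines(render_report(study))
```

A thin command-line wrapper with `power`, `fixture`, `simulate`, `clean`,
`impute` and `run-all` subcommands ships in `inst/scripts/webrds.R`.

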