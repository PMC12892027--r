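## End-to-end pipeline: simulate -> clean -> impute -> analyze, with a
## reproducibility manifest and a plain-markdown study report whose every
## number recomputes from the intermediate tables.

#' Run a complete simulated web-RDS study
#'
#' Generates (or accepts) a population, simulates recruitment, runs the
#' intake-cleaning funnel, assembles and imputes degree records, and
#' computes the standard diagnostics (waves, productivity, coupon
#' exhaustion, degree summary, convergence, RDS-II estimates).
#'
#' @param pop_config A [population_config()] (ignored when `population` is
#'   given).
#' @param sim_config A [simulation_config()].
#' @param population Optional pre-built `webrds_population`.
#' @param trace_vars Character vector of roster columns to trace for
#'   convergence.
#' @param estimate_vars Character vector of roster columns to estimate with
#'   RDS-II weights.
#' @return A `webrds_study` list: `run`, `funnel`, `degrees`, `diagnostics`,
#'   `manifest`.
#' @export
run_study <- function(pop_config = NULL, sim_config = simulation_config(),
                      population = NULL,
                      trace_vars = c("age_group", "sex"),
                      estimate_vars = c("age_group", "sex")) {
  if (is.null(population)) {
    if (is.null(pop_config)) abort("supply `pop_config` or `population`.")
    population <- generate_population(pop_config)
  }
  run <- run_recruitment(population, sim_config)
  funnel <- intake_funnel(run$roster, run$ledger)
  degrees <- impute_degrees(degree_records(funnel$analysis, run$forest))
  analysis <- funnel$analysis %>%
    left_join(select(run$forest, "coupon_code", "person_id", "wave",
                     "seed_id"),
              by = "coupon_code") %>%
    left_join(select(degrees, "person_id", "degree_final"),
              by = "person_id") %>%
    arrange(.data$day, .data$attempt_id)
  diagnostics <- list(
    waves = wave_statistics(run$forest),
    productivity = recruiter_productivity(run$forest),
    exhaustion = coupon_exhaustion(funnel$ledger %||% run$ledger),
    degree_summary = degree_summary(degrees),
    convergence = lapply(
      setNames(trace_vars, trace_vars),
      function(v) convergence_trace(analysis, v)
    ),
    estimates = lapply(
      setNames(estimate_vars, estimate_vars),
      function(v) rds2_estimate(analysis, v)
    )
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("webrds")),
    rng_seed = sim_config$rng_seed,
    pop_hash = rlang::hash(population),
    sim_config_hash = rlang::hash(unclass(sim_config)),
    n_attempts = nrow(run$roster),
    n_analysis = nrow(analysis),
    table_hashes = list(
      roster = rlang::hash(run$roster),
      ledger = rlang::hash(run$ledger),
      forest = rlang::hash(run$forest)
    )
  )
  structure(list(run = run, funnel = funnel, degrees = degrees,
                 analysis = analysis, diagnostics = diagnostics,
                 manifest = manifest),
            class = "webrds_study")
}

#' Render a study report
#'
#' Markdown report with the cleaning funnel, recruiter productivity, degree
#' summary, wave statistics, convergence verdicts and (when present) RDS-II
#' estimates. Every figure is recomputed from the study object's tables.
#'
#' @param study A `webrds_study` from [run_study()], or a list with at least
#'   `funnel` and `run`.
#' @return Character vector of markdown lines.
#' @export
render_report <- function(study) {
  rp <- study$funnel$report
  dg <- study$diagnostics
  lines <- c(
    "# Web-RDS study report",
    "",
    "## Cleaning funnel",
    "",
    sprintf("- access attempts: %d", rp$n_attempts),
    sprintf("- invalid or ineligible: %d (%.1f%%) [automatic %d, manual %d, screen %d]",
            rp$n_invalid_total, rp$pct_invalid_total, rp$n_blocked_auto,
            rp$n_invalid_manual, rp$n_ineligible),
    sprintf("- incomplete questionnaires: %d (%.1f%%)", rp$n_incomplete,
            rp$pct_incomplete),
    sprintf("- valid participants: %d", rp$n_valid),
    sprintf("- consistency exclusions: %d (%.1f%%)", rp$n_inconsistent,
            rp$pct_inconsistent),
    sprintf("- analyzed: %d", rp$n_analysis),
    "",
    "## Recruitment",
    "",
    sprintf("- seeds: %d (%d unproductive)", dg$waves$n_seeds,
            dg$waves$n_unproductive_seeds),
    sprintf("- maximum wave depth: %d", dg$waves$max_wave),
    paste0("- productivity: ",
           paste(sprintf("%d recruiter(s) with %d recruit(s) (%.1f%%)",
                         dg$productivity$n_recruiters,
                         dg$productivity$n_recruits,
                         dg$productivity$share_pct), collapse = "; ")),
    sprintf("- coupon exhaustion: %d/%d (%.1f%%) used all invitations",
            dg$exhaustion$n_all_used, dg$exhaustion$n_any_used,
            dg$exhaustion$share_all_pct),
    "",
    "## Network size",
    "",
    sprintf("- degree <= 5: %d (%.1f%%); degree > 10: %d (%.1f%%); max %d",
            dg$degree_summary$n_le5, dg$degree_summary$pct_le5,
            dg$degree_summary$n_gt10, dg$degree_summary$pct_gt10,
            dg$degree_summary$max_degree),
    sprintf("- imputed: %d (%.1f%%) [q1-substituted %d, mean-substituted %d]",
            dg$degree_summary$n_imputed, dg$degree_summary$pct_imputed,
            dg$degree_summary$n_q1_substituted,
            dg$degree_summary$n_mean_substituted),
    "",
    "## Convergence",
    ""
  )
  for (v in names(dg$convergence)) {
    cv <- dg$convergence[[v]]
    lines <- c(lines, sprintf("- %s: %s", v,
                              if (cv$all_converged) "converged"
                              else "NOT converged"))
  }
  if (length(dg$estimates)) {
    lines <- c(lines, "", "## RDS-II estimates", "")
    for (v in names(dg$estimates)) {
      est <- dg$estimates[[v]]$estimates
      lines <- c(lines, paste0("- ", v, ": ",
                               paste(sprintf("%s %.3f", est$category,
                                             est$estimate),
                                     collapse = ", ")))
    }
  }
  lines
}

#' Write the observed data bundle to CSV
#'
#' Writes `attempt_roster.csv`, `coupon_ledger.csv` and `forest_edges.csv`;
#' the ground-truth table, when present, goes to `truth_table.csv` and is
#' not part of the observed bundle.
#'
#' @param run A `webrds_run` or `webrds_fixture`.
#' @param dir Output directory (created if needed).
#' @param include_truth Also write the ground-truth labels.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(run, dir, include_truth = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$roster, file.path(dir, "attempt_roster.csv"))
  readr::write_csv(run$ledger, file.path(dir, "coupon_ledger.csv"))
  readr::write_csv(run$forest, file.path(dir, "forest_edges.csv"))
  if (include_truth && !is.null(run$truth)) {
    readr::write_csv(run$truth, file.path(dir, "truth_table.csv"))
  }
  invisible(dir)
}

#' Read an observed data bundle from CSV
#'
#' @param dir Directory written by [write_bundle()].
#' @return List with `roster`, `ledger`, `forest` tibbles.
#' @export
read_bundle <- function(dir) {
  list(
    roster = readr::read_csv(file.path(dir, "attempt_roster.csv"),
                             show_col_types = FALSE),
    ledger = readr::read_csv(file.path(dir, "coupon_ledger.csv"),
                             show_col_types = FALSE),
    forest = readr::read_csv(file.path(dir, "forest_edges.csv"),
                             show_col_types = FALSE)
  )
}
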