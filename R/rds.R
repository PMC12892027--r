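## RDS design and analysis: sample-size calculation, recruitment-forest
## diagnostics, convergence traces, recruitment homophily, RDS-II weighting,
## and a seed-chain bootstrap for the design effect.

#' Design-effect sample-size calculation
#'
#' Standard proportion-based calculation for a chain-referral survey:
#' `n_unadjusted = ceil(p(1-p)/se^2)` for a simple random sample, inflated
#' by the design effect, then by the anticipated loss rate. With the
#' conservative `p = 0.5`, `se = 0.05`, `deff = 2.5` and 20% loss this gives
#' 100, 250 and 300.
#'
#' @param p Anticipated proportion, in (0, 1).
#' @param se Target standard error (> 0).
#' @param deff Design effect (>= 1).
#' @param loss_rate Anticipated loss fraction (>= 0).
#' @return One-row tibble: `n_unadjusted`, `n_minimum`, `n_target`.
#' @examples
#' sample_size(0.5, 0.05, 2.5, 0.2)
#' @export
sample_size <- function(p = 0.5, se = 0.05, deff = 2.5, loss_rate = 0.2) {
  if (!is.numeric(p) || p <= 0 || p >= 1) abort("`p` must be in (0, 1).")
  if (!is.numeric(se) || se <= 0) abort("`se` must be positive.")
  if (!is.numeric(deff) || deff < 1) abort("`deff` must be >= 1.")
  if (!is.numeric(loss_rate) || loss_rate < 0) abort("`loss_rate` must be >= 0.")
  n0 <- ceiling(p * (1 - p) / se^2)
  n_min <- ceiling(n0 * deff)
  n_target <- ceiling(n_min * (1 + loss_rate))
  tibble(n_unadjusted = as.integer(n0), n_minimum = as.integer(n_min),
         n_target = as.integer(n_target))
}

#' Wave statistics of a recruitment forest
#'
#' @param forest Recruitment forest tibble (`person_id`, `recruiter_id`,
#'   `wave`).
#' @return List: `max_wave`, `wave_counts` (tibble, one row per wave),
#'   `n_seeds`, `n_unproductive_seeds` (seeds with no recruits at all).
#' @export
wave_statistics <- function(forest) {
  seeds <- forest$person_id[is.na(forest$recruiter_id)]
  recruiters <- unique(forest$recruiter_id[!is.na(forest$recruiter_id)])
  list(
    max_wave = if (nrow(forest)) max(forest$wave) else NA_integer_,
    wave_counts = count(forest, .data$wave, name = "n"),
    n_seeds = length(seeds),
    n_unproductive_seeds = sum(!seeds %in% recruiters)
  )
}

#' Cumulative-proportion convergence trace
#'
#' Computes the running sample proportion (or mean, for numeric variables)
#' of a variable in enrollment order — the standard visual diagnostic for
#' whether the sample composition has stabilized away from the seeds.
#' The trace is declared converged when every value in the final
#' `window_frac` of enrollments deviates from the final value by less than
#' `tol`.
#'
#' @param data Analysis roster ordered by enrollment.
#' @param variable Column to trace (bare name or string). Categorical
#'   variables give one trace per category.
#' @param window_frac Fraction of final enrollments inspected (default
#'   0.25).
#' @param tol Maximum allowed deviation from the final value (default 0.02).
#' @return A `webrds_convergence` object; `tidy()` returns the trace tibble
#'   (`index`, `category`, `value`), and `autoplot()` draws it.
#' @export
convergence_trace <- function(data, variable, window_frac = 0.25, tol = 0.02) {
  x <- dplyr::pull(data, {{ variable }})
  var_name <- tryCatch(as_name(enquo(variable)), error = function(e) "variable")
  n <- length(x)
  if (!n) abort("no observations to trace.")
  if (is.numeric(x) && !is.factor(x)) {
    traces <- list(mean = cumsum(x) / seq_len(n))
  } else {
    lev <- sort(unique(as.character(x)))
    traces <- lapply(lev, function(l) cumsum(x == l) / seq_len(n))
    names(traces) <- lev
  }
  win <- seq.int(max(1L, n - ceiling(window_frac * n) + 1L), n)
  converged <- vapply(traces, function(tr) {
    all(abs(tr[win] - tr[n]) < tol)
  }, logical(1))
  trace_tbl <- bind_rows(lapply(names(traces), function(nm) {
    tibble(index = seq_len(n), category = nm, value = traces[[nm]])
  }))
  structure(
    list(variable = var_name, trace = trace_tbl, converged = converged,
         all_converged = all(converged), window_frac = window_frac,
         tol = tol, n = n),
    class = "webrds_convergence"
  )
}

#' @export
print.webrds_convergence <- function(x, ...) {
  cat("<convergence trace>", x$variable, " n =", x$n, "\n")
  for (nm in names(x$converged)) {
    cat(sprintf("  %-12s final %.3f  %s\n", nm,
                x$trace$value[x$trace$category == nm][x$n],
                if (x$converged[[nm]]) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' @export
tidy.webrds_convergence <- function(x, ...) x$trace

#' @export
glance.webrds_convergence <- function(x, ...) {
  tibble(variable = x$variable, n = x$n, window_frac = x$window_frac,
         tol = x$tol, all_converged = x$all_converged)
}

#' Recruitment homophily index
#'
#' For each category `c` of a trait, the share of recruitments made by
#' category-`c` recruiters that landed on category-`c` recruits, divided by
#' the sample share of `c`. An index of 1 indicates proportionate mixing; 2
#' with a 50% category share indicates perfect assortativity; 0 means no
#' within-group recruitment. Categories with zero sample share get `NA`.
#'
#' @param forest Recruitment forest.
#' @param traits Tibble mapping `person_id` to trait columns.
#' @param trait Trait column name (string).
#' @return Tibble (`category`, `n_edges`, `within_share`, `sample_share`,
#'   `index`).
#' @export
recruitment_homophily <- function(forest, traits, trait) {
  if (!trait %in% names(traits)) abort(paste0("trait not found: ", trait))
  tr <- setNames(as.character(traits[[trait]]), traits$person_id)
  members <- tr[forest$person_id]
  sample_share <- table(members) / length(members)
  edges <- forest[!is.na(forest$recruiter_id), , drop = FALSE]
  rec_tr <- tr[edges$recruiter_id]
  rct_tr <- tr[edges$person_id]
  cats <- sort(unique(as.character(members)))
  out <- lapply(cats, function(c0) {
    ed <- which(rec_tr == c0)
    ws <- if (length(ed)) mean(rct_tr[ed] == c0) else NA_real_
    ss <- as.numeric(sample_share[c0])
    tibble(category = c0, n_edges = length(ed), within_share = ws,
           sample_share = ss,
           index = if (!is.na(ss) && ss > 0) ws / ss else NA_real_)
  })
  bind_rows(out)
}

#' RDS-II (reciprocal-degree) estimator
#'
#' Volz–Heckathorn weighting: each participant's selection probability is
#' taken proportional to their network degree, so estimates weight each
#' record by `1/degree`. For a category `c`,
#' `estimate = sum_{i: x_i = c} (1/d_i) / sum_i (1/d_i)`. Estimates over all
#' categories of a variable sum to 1.
#'
#' @param data Tibble with the variable and a positive degree column.
#' @param variable Variable to estimate (bare name or string).
#' @param degree Degree column (bare name or string; default
#'   `degree_final`).
#' @param include_seeds Keep seed rows (wave 0) in the estimate; requires a
#'   `wave` column to exclude them.
#' @return A `webrds_rds2` object; `tidy()` gives per-category estimates,
#'   `glance()` the fit summary.
#' @examples
#' d <- tibble::tibble(x = c(1, 0, 1), degree_final = c(1, 2, 2))
#' tidy(rds2_estimate(d, x)) # weighted share of x = 1 is 0.75
#' @export
rds2_estimate <- function(data, variable, degree = "degree_final",
                          include_seeds = TRUE) {
  if (!include_seeds) {
    if (!"wave" %in% names(data)) {
      abort("excluding seeds requires a `wave` column.")
    }
    data <- data[data$wave > 0, , drop = FALSE]
  }
  x <- dplyr::pull(data, {{ variable }})
  d <- dplyr::pull(data, {{ degree }})
  var_name <- tryCatch(as_name(enquo(variable)), error = function(e) "variable")
  if (any(is.na(d)) || any(d <= 0)) {
    abort("all degrees must be positive; run imputation first.")
  }
  w <- (1 / d) / sum(1 / d)
  xf <- as.character(x)
  cats <- sort(unique(xf))
  est <- unname(vapply(cats, function(c0) sum(w[xf == c0]), numeric(1)))
  unw <- unname(vapply(cats, function(c0) mean(xf == c0), numeric(1)))
  structure(
    list(
      variable = var_name,
      estimates = tibble(category = cats, n = as.integer(table(xf)[cats]),
                         prop_unweighted = unw, estimate = unname(est)),
      weights = w, n = length(x),
      mean_degree = mean(d),
      include_seeds = include_seeds
    ),
    class = "webrds_rds2"
  )
}

#' @export
print.webrds_rds2 <- function(x, ...) {
  cat("<RDS-II estimate>", x$variable, " n =", x$n, "\n")
  print(x$estimates)
  invisible(x)
}

#' @export
tidy.webrds_rds2 <- function(x, ...) x$estimates

#' @export
glance.webrds_rds2 <- function(x, ...) {
  tibble(variable = x$variable, n = x$n, n_categories = nrow(x$estimates),
         mean_degree = x$mean_degree, include_seeds = x$include_seeds,
         estimate_total = sum(x$estimates$estimate))
}

#' Seed-chain bootstrap design effect
#'
#' Resamples whole seed-rooted recruitment chains with replacement (the
#' chain, not the individual, is the approximately independent unit in
#' chain-referral data), recomputes the RDS-II estimate for the chosen
#' category in each replicate, and reports
#' `deff = bootstrap variance / (p(1-p)/n)` against the simple-random-
#' sampling benchmark at the same size.
#'
#' @param data Analysis tibble with `person_id`, the variable, and a degree
#'   column.
#' @param forest Recruitment forest with `person_id` and `seed_id`.
#' @param variable Variable (bare name or string).
#' @param category Category whose proportion is bootstrapped (default: the
#'   largest weighted category).
#' @param degree Degree column (default `degree_final`).
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param rng_seed Seed for reproducible resampling.
#' @return A list: `deff`, `boot_var`, `srs_var`, `estimate`, `n_boot`,
#'   `n_seeds`.
#' @export
chain_bootstrap_deff <- function(data, forest, variable, category = NULL,
                                 degree = "degree_final", n_boot = 500,
                                 rng_seed = 1L) {
  if (!is.numeric(n_boot) || n_boot < 100) {
    abort("`n_boot` must be at least 100.")
  }
  dat <- left_join(data, select(forest, "person_id", "seed_id"),
                   by = "person_id")
  if (any(is.na(dat$seed_id))) abort("every record must map to a seed chain.")
  seeds <- unique(dat$seed_id)
  if (length(seeds) < 2) abort("need at least 2 seed chains to bootstrap.")
  x <- as.character(dplyr::pull(dat, {{ variable }}))
  d <- dplyr::pull(dat, {{ degree }})
  if (is.null(category)) {
    full <- rds2_estimate(dat, {{ variable }}, degree = {{ degree }})
    category <- full$estimates$category[which.max(full$estimates$estimate)]
  }
  chains <- split(seq_len(nrow(dat)), dat$seed_id)
  est_of <- function(idx) {
    w <- 1 / d[idx]
    sum(w[x[idx] == category]) / sum(w)
  }
  p_hat <- est_of(seq_len(nrow(dat)))
  withr::with_seed(rng_seed, {
    boots <- vapply(seq_len(n_boot), function(b) {
      take <- sample(names(chains), length(chains), replace = TRUE)
      est_of(unlist(chains[take], use.names = FALSE))
    }, numeric(1))
  })
  srs_var <- p_hat * (1 - p_hat) / nrow(dat)
  list(deff = var(boots) / srs_var, boot_var = var(boots),
       srs_var = srs_var, estimate = p_hat, category = category,
       n_boot = as.integer(n_boot), n_seeds = length(seeds))
}
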