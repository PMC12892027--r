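## Network-size instrument: the two-question degree measure, the recruitment-
## tree plausibility floor, and the deterministic imputation rule for
## implausible self-reports.

#' Recruitment-tree degree
#'
#' The number of individuals verifiably connected to a participant in the
#' recruitment tree: their recruiter (if any) plus their recruits. A
#' self-reported network size below this value is implausible, because
#' these ties are directly observed.
#'
#' @param forest Recruitment forest tibble (`person_id`, `recruiter_id`).
#' @param person_id Optional single id; when given, returns one integer and
#'   errors if the person is not enrolled.
#' @return Tibble (`person_id`, `tree_degree`) or a single integer.
#' @export
compute_tree_degree <- function(forest, person_id = NULL) {
  kids <- table(forest$recruiter_id[!is.na(forest$recruiter_id)])
  td <- tibble(
    person_id = forest$person_id,
    tree_degree = as.integer(!is.na(forest$recruiter_id)) +
      as.integer(ifelse(is.na(match(forest$person_id, names(kids))), 0,
                        kids[forest$person_id]))
  )
  if (!is.null(person_id)) {
    i <- match(person_id, td$person_id)
    if (is.na(i)) abort(paste0("unknown person: ", person_id))
    return(td$tree_degree[i])
  }
  td
}

#' Assemble degree records from a cleaned roster and forest
#'
#' Joins the two network-size questions (`q1_network`: known ENDS users in
#' the city over the past 12 months; `q2_network`: the subset aged >= 15,
#' the operative degree for weighting) to the recruitment tree through the
#' invitation code each participant enrolled with.
#'
#' @param roster Valid or analysis roster containing `coupon_code`,
#'   `q1_network`, `q2_network`.
#' @param forest Recruitment forest with `coupon_code`, `person_id`,
#'   `recruiter_id`.
#' @return Tibble (`person_id`, `q1`, `q2`, `tree_degree`) — one row per
#'   matched participant.
#' @export
degree_records <- function(roster, forest) {
  td <- compute_tree_degree(forest)
  forest %>%
    select("person_id", "coupon_code") %>%
    dplyr::inner_join(
      select(roster, "coupon_code", q1 = "q1_network", q2 = "q2_network"),
      by = "coupon_code"
    ) %>%
    left_join(td, by = "person_id") %>%
    select("person_id", "q1", "q2", "tree_degree")
}

plausible_q <- function(q, tree_degree) {
  !is.na(q) & q > 0 & q >= tree_degree
}

#' Deterministic degree imputation
#'
#' Applies the published two-rule repair for implausible operative network
#' sizes. A reported `q2` of zero, or smaller than the participant's
#' recruitment-tree degree, is implausible; the value of `q1` is then
#' substituted, provided `q1` itself passes the same plausibility test.
#' When `q1` also fails, the record receives the rounded (half-up) mean of
#' the network sizes that required no imputation. The final degree is never
#' allowed below the tree degree nor below 1, so weights stay finite and
#' conservative.
#'
#' Flags are determined against a `valid_mean` frozen before any
#' substitution, so the result is a pure function of
#' `(q1, q2, tree_degree, valid_mean)` and independent of record order.
#'
#' @param records Tibble from [degree_records()] (`q1`, `q2`, `tree_degree`).
#' @param valid_mean Optional anchor mean; by default the mean of `q2` over
#'   records needing no imputation.
#' @return `records` with `degree_final` and `imputation_flag`
#'   (`none`, `q1_substituted`, `mean_substituted`).
#' @export
impute_degrees <- function(records, valid_mean = NULL) {
  ok2 <- plausible_q(records$q2, records$tree_degree)
  if (is.null(valid_mean)) {
    if (!any(ok2)) abort("no valid records to anchor the imputation mean.")
    valid_mean <- mean(records$q2[ok2])
  }
  if (!is.numeric(valid_mean) || valid_mean <= 0) {
    abort("`valid_mean` must be positive.")
  }
  ok1 <- plausible_q(records$q1, records$tree_degree)
  flag <- ifelse(ok2, "none",
                 ifelse(ok1, "q1_substituted", "mean_substituted"))
  final <- ifelse(ok2, records$q2,
                  ifelse(ok1, records$q1, round_half_up(valid_mean)))
  final <- pmax(as.integer(final), records$tree_degree, 1L)
  records$degree_final <- final
  records$imputation_flag <- flag
  attr(records, "valid_mean") <- valid_mean
  records
}

#' Impute a single degree record
#'
#' Scalar form of [impute_degrees()]; a pure function of its four arguments.
#'
#' @param q1,q2 The two reported network sizes.
#' @param tree_degree Observed recruitment-tree degree.
#' @param valid_mean Anchor mean of valid network sizes (> 0).
#' @return List with `degree_final` and `imputation_flag`.
#' @examples
#' impute_degree(q1 = 8, q2 = 0, tree_degree = 2, valid_mean = 9.4)
#' @export
impute_degree <- function(q1, q2, tree_degree, valid_mean) {
  rec <- impute_degrees(tibble(q1 = q1, q2 = q2, tree_degree = tree_degree),
                        valid_mean = valid_mean)
  list(degree_final = rec$degree_final[1],
       imputation_flag = rec$imputation_flag[1])
}

#' Summarize the degree distribution
#'
#' Counts and shares of small (<= 5) and large (> 10) operative network
#' sizes, the maximum, and the imputation tally — the headline facts of the
#' reported-degree distribution.
#'
#' @param records Imputed degree records (`degree_final`,
#'   `imputation_flag`).
#' @return A `webrds_degree_summary` list; `tidy()` gives the histogram
#'   series (one row per degree value).
#' @export
degree_summary <- function(records) {
  d <- records$degree_final
  n <- length(d)
  fl <- table(factor(records$imputation_flag,
                     levels = c("none", "q1_substituted", "mean_substituted")))
  structure(
    list(
      n = n,
      n_le5 = sum(d <= 5), pct_le5 = pct1(sum(d <= 5), n),
      n_gt10 = sum(d > 10), pct_gt10 = pct1(sum(d > 10), n),
      max_degree = if (n) max(d) else NA_integer_,
      n_q1_substituted = as.integer(fl[["q1_substituted"]]),
      n_mean_substituted = as.integer(fl[["mean_substituted"]]),
      n_imputed = as.integer(fl[["q1_substituted"]] + fl[["mean_substituted"]]),
      pct_imputed = pct1(fl[["q1_substituted"]] + fl[["mean_substituted"]], n),
      histogram = count(tibble(degree = d), .data$degree, name = "n")
    ),
    class = "webrds_degree_summary"
  )
}

#' @export
print.webrds_degree_summary <- function(x, ...) {
  cat("<degree summary>  n =", x$n, "\n")
  cat(sprintf("  degree <= 5 : %d (%.1f%%)\n", x$n_le5, x$pct_le5))
  cat(sprintf("  degree > 10 : %d (%.1f%%)\n", x$n_gt10, x$pct_gt10))
  cat(sprintf("  max reported: %d\n", x$max_degree))
  cat(sprintf("  imputed     : %d (%.1f%%)  [q1: %d, mean: %d]\n",
              x$n_imputed, x$pct_imputed,
              x$n_q1_substituted, x$n_mean_substituted))
  invisible(x)
}

#' @export
tidy.webrds_degree_summary <- function(x, ...) x$histogram

#' Inject implausible network-size responses
#'
#' Test/validation helper that corrupts clean degree records with a known
#' number of rule-1 cases (`q2` zeroed while `q1` stays plausible — repaired
#' by q1 substitution) and rule-2 cases (both questions zeroed — repaired by
#' the mean), so the imputation tally can be checked against ground truth.
#'
#' @param records Clean degree records.
#' @param n_rule1,n_rule2 Number of corruptions of each kind.
#' @param rng_seed Seed for choosing which records are corrupted.
#' @return The corrupted records.
#' @export
corrupt_degree_records <- function(records, n_rule1 = 13, n_rule2 = 7,
                                   rng_seed = 1L) {
  elig1 <- which(plausible_q(records$q1, records$tree_degree) &
                   records$tree_degree >= 1)
  elig2 <- which(records$tree_degree >= 1)
  withr::with_seed(rng_seed, {
    if (length(elig1) < n_rule1 + n_rule2) {
      abort("not enough records with observed ties to corrupt.")
    }
    pick1 <- sample(elig1, n_rule1)
    pick2 <- sample(setdiff(elig2, pick1), n_rule2)
    records$q2[pick1] <- 0L
    records$q1[pick2] <- 0L
    records$q2[pick2] <- 0L
    records
  })
}
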