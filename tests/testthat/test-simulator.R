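test_that("seed selection is diverse, degree-greedy, and deterministic", {
  pop <- small_population(seed = 2, n = 1000, prev = 0.5)
  seeds <- select_seeds(pop, 12)
  expect_equal(nrow(seeds), 12)
  expect_true(all(seeds$eligible))
  expect_gte(length(unique(seeds$zone)), 3)
  expect_identical(seeds, select_seeds(pop, 12))
  # degenerate stratification: the single seed is the top-degree member
  one <- select_seeds(pop, 1)
  expect_equal(one$true_degree,
               max(pop$nodes$true_degree[pop$nodes$eligible]))
  expect_error(select_seeds(pop, sum(pop$nodes$eligible) + 1), "exceeds")
})

test_that("recruitment runs are reproducible and structurally sound", {
  pop <- small_population(seed = 4, n = 1500, prev = 0.6, mean_degree = 6)
  cfg <- quick_sim_config(seed = 9, target_n = 120)
  run1 <- run_recruitment(pop, cfg)
  run2 <- run_recruitment(pop, cfg)
  expect_identical(run1, run2)

  forest <- run1$forest
  expect_equal(anyDuplicated(forest$person_id), 0L)
  # every non-seed has exactly one recruiter who enrolled earlier
  nonseed <- forest[!is.na(forest$recruiter_id), ]
  ri <- match(nonseed$recruiter_id, forest$person_id)
  expect_false(any(is.na(ri)))
  expect_equal(nonseed$wave, forest$wave[ri] + 1L)
  expect_true(all(nonseed$day >= forest$day[ri]))
  # every used coupon traces to an issued coupon
  used <- run1$roster$coupon_code
  expect_true(all(used %in% run1$ledger$code))
  # coupon statuses are within the contract and used codes are unique
  expect_true(all(run1$ledger$status %in% c("unused", "used", "invalidated")))
  expect_equal(anyDuplicated(run1$ledger$code), 0L)
})

test_that("the no-fraud limit yields a roster equal to the forest", {
  pop <- small_population(seed = 6, n = 1500, prev = 0.6)
  run <- run_recruitment(pop, clean_sim_config(seed = 2, target_n = 120))
  expect_equal(nrow(run$roster), nrow(run$forest))
  expect_true(all(run$truth$truth_kind %in% c("seed", "valid")))
})

test_that("forests respect the coupon quota and acyclicity everywhere", {
  for (k in 1:60) {
    cpp <- 1L + (k %% 3L)
    pop <- small_population(seed = 700 + k, n = 400, prev = 0.6,
                            mean_degree = 5)
    cfg <- quick_sim_config(seed = k, target_n = 60,
                            coupons_per_participant = cpp,
                            p_incomplete = 0.05 * (k %% 2))
    run <- suppressWarnings(run_recruitment(pop, cfg))
    forest <- run$forest
    if (nrow(forest) == 0) next
    out <- table(forest$recruiter_id[!is.na(forest$recruiter_id)])
    if (length(out)) expect_lte(max(out), cpp)
    # acyclic: wave strictly increases along every edge
    nonseed <- forest[!is.na(forest$recruiter_id), ]
    ri <- match(nonseed$recruiter_id, forest$person_id)
    expect_true(all(nonseed$wave == forest$wave[ri] + 1L))
    expect_lte(max(forest$wave), max(forest$day))
  }
})

test_that("zero low-incentive participation stalls recruitment exactly", {
  pop <- small_population(seed = 8, n = 1200, prev = 0.6)
  cfg <- simulation_config(target_n = 100,
                           participation_prob = c(low = 0, high = 0.6),
                           incentive_switch_day = 45, horizon_days = 150,
                           rng_seed = 3)
  run <- run_recruitment(pop, cfg)
  nonseed <- run$forest[!is.na(run$forest$recruiter_id), ]
  expect_gt(nrow(nonseed), 0)
  expect_gte(min(nonseed$day), 45)
  # the enrollment curve is flat before the switch, rising after
  expect_equal(sum(run$forest$day < 45), 12)
})

test_that("invalid and duplicate attempts arise at the configured rate", {
  shares <- vapply(1:50, function(s) {
    pop <- small_population(seed = 3000 + s, n = 1200, prev = 0.6,
                            mean_degree = 6)
    run <- run_recruitment(pop, quick_sim_config(seed = s, target_n = 120))
    mean(run$truth$truth_kind %in% c("ineligible", "duplicate",
                                     "self_recruit"))
  }, numeric(1))
  # p_ineligible_use + p_duplicate_attempt + p_self_recruit = 0.31,
  # slightly diluted by the seed rows
  expect_lt(abs(mean(shares) - 0.31), 0.03)
})

test_that("recruiter productivity matches a brute-force edge tally", {
  # forced example: one seed with three recruits
  f <- tibble::tibble(
    person_id = c("S1", "A", "B", "C"),
    recruiter_id = c(NA, "S1", "S1", "S1"),
    wave = c(0L, 1L, 1L, 1L), analysis = TRUE
  )
  prod <- recruiter_productivity(f)
  expect_equal(prod$n_recruits, 3L)
  expect_equal(prod$n_recruiters, 1L)

  for (s in 1:25) {
    forest <- random_forest(seed = s, n = 60 + s)
    prod <- recruiter_productivity(forest)
    oracle <- table(table(forest$recruiter_id[!is.na(forest$recruiter_id)]))
    expect_equal(setNames(prod$n_recruiters, prod$n_recruits),
                 setNames(as.integer(oracle), names(oracle)))
    expect_equal(sum(prod$n_recruiters * prod$n_recruits),
                 sum(!is.na(forest$recruiter_id)))
  }

  empty <- recruiter_productivity(tibble::tibble(
    person_id = "S1", recruiter_id = NA_character_, wave = 0L,
    analysis = TRUE))
  expect_equal(nrow(empty), 0)
})
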