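test_that("sample-size calculation matches the design formula", {
  expect_equal(unlist(sample_size(0.5, 0.05, 2.5, 0.2)),
               c(n_unadjusted = 100L, n_minimum = 250L, n_target = 300L))
  expect_equal(unlist(sample_size(0.5, 0.05, 1.0, 0)),
               c(n_unadjusted = 100L, n_minimum = 100L, n_target = 100L))
  expect_equal(unlist(sample_size(0.3, 0.02, 2.0, 0.1)),
               c(n_unadjusted = 525L, n_minimum = 1050L, n_target = 1155L))
  expect_error(sample_size(0, 0.05), "in \\(0, 1\\)")
  expect_error(sample_size(0.5, 0), "positive")
})

test_that("wave statistics agree with parent-pointer traversal", {
  chain <- tibble::tibble(
    person_id = c("S1", "A", "B", "C", "D"),
    recruiter_id = c(NA, "S1", "A", "B", "C"),
    wave = 0:4
  )
  ws <- wave_statistics(chain)
  expect_equal(ws$max_wave, 4L)
  expect_equal(ws$n_seeds, 1L)
  expect_equal(ws$n_unproductive_seeds, 0L)

  for (s in 1:30) {
    forest <- random_forest(seed = 200 + s, n = 50 + 2 * s)
    ws <- wave_statistics(forest)
    expect_equal(ws$max_wave, oracle_max_depth(forest))
    expect_equal(sum(ws$wave_counts$n), nrow(forest))
    seeds <- forest$person_id[is.na(forest$recruiter_id)]
    expect_equal(ws$n_unproductive_seeds,
                 sum(!seeds %in% forest$recruiter_id))
  }
})

test_that("convergence detection matches closed-form traces", {
  # constant variable: flat trace, converged immediately
  d <- tibble::tibble(x = rep("a", 40))
  cv <- convergence_trace(d, x)
  expect_true(cv$all_converged)
  expect_true(all(cv$trace$value == 1))

  # alternating 0/1: cumulative mean oscillates towards 0.5
  d2 <- tibble::tibble(x = rep(0:1, 50))
  cv2 <- convergence_trace(d2, x, window_frac = 0.25, tol = 0.05)
  expect_true(cv2$all_converged)
  expected <- cumsum(d2$x) / seq_len(100)
  expect_equal(cv2$trace$value[cv2$trace$category == "mean"], expected)

  # two isolated clusters: plateaus differ by more than the tolerance
  d3 <- tibble::tibble(x = c(rep(1, 100), rep(0, 100)))
  cv3 <- convergence_trace(d3, x, window_frac = 0.25, tol = 0.05)
  expect_false(cv3$all_converged)

  expect_error(convergence_trace(d3, nope), "nope")
})

test_that("recruitment homophily indexes mixing against sample shares", {
  # perfectly assortative, 50/50 shares -> index 2
  f <- tibble::tibble(
    person_id = sprintf("P%d", 1:8),
    recruiter_id = c(NA, "P1", "P2", NA, "P4", "P5", "P6", "P7"),
    wave = c(0, 1, 2, 0, 1, 2, 3, 4)
  )
  tr <- tibble::tibble(person_id = f$person_id,
                       grp = c("a", "a", "a", "b", "b", "b", "b", "b"))
  hi <- recruitment_homophily(f, tr, "grp")
  expect_equal(hi$index[hi$category == "a"], 1 / (3 / 8))
  # zero within-group edges -> index 0
  f2 <- tibble::tibble(person_id = c("P1", "P2"),
                       recruiter_id = c(NA, "P1"), wave = 0:1)
  tr2 <- tibble::tibble(person_id = c("P1", "P2"), grp = c("a", "b"))
  hi2 <- recruitment_homophily(f2, tr2, "grp")
  expect_equal(hi2$index[hi2$category == "a"], 0)
})

test_that("homophily indexes are near one under proportionate mixing", {
  idx <- vapply(1:50, function(s) {
    forest <- random_forest(seed = 900 + s, n = 120, n_seeds = 6)
    grp <- withr::with_seed(s, sample(c("u", "v"), 120, replace = TRUE))
    tr <- tibble::tibble(person_id = forest$person_id, grp = grp)
    hi <- recruitment_homophily(forest, tr, "grp")
    hi$index[hi$category == "u"]
  }, numeric(1))
  expect_lt(abs(mean(idx, na.rm = TRUE) - 1), 0.05)
})

test_that("RDS-II weighting reduces to hand arithmetic", {
  d <- tibble::tibble(x = c(1, 0, 1), degree_final = c(1, 2, 2))
  est <- tidy(rds2_estimate(d, x))
  expect_equal(est$estimate[est$category == "1"], 0.75)
  # equal degrees: weights cancel
  d2 <- tibble::tibble(x = c("a", "a", "b", "c"), degree_final = rep(4, 4))
  est2 <- tidy(rds2_estimate(d2, x))
  expect_equal(est2$estimate, est2$prop_unweighted)
  # categories always sum to one
  for (s in 1:10) {
    d3 <- withr::with_seed(s, tibble::tibble(
      x = sample(letters[1:4], 60, replace = TRUE),
      degree_final = sample(1:30, 60, replace = TRUE)
    ))
    expect_equal(sum(tidy(rds2_estimate(d3, x))$estimate), 1,
                 tolerance = 1e-9)
  }
  expect_error(rds2_estimate(tibble::tibble(x = 1, degree_final = 0), x),
               "positive")
  g <- glance(rds2_estimate(d, x))
  expect_equal(g$estimate_total, 1)
})

test_that("seed exclusion drops wave-zero rows from the estimate", {
  d <- tibble::tibble(x = c("a", "b", "b"), degree_final = c(2, 2, 2),
                      wave = c(0L, 1L, 2L))
  est <- tidy(rds2_estimate(d, x, include_seeds = FALSE))
  expect_equal(est$estimate[est$category == "b"], 1)
})

test_that("chain bootstrap approaches one for independent equal chains", {
  n_seed <- 150
  d <- withr::with_seed(7, tibble::tibble(
    person_id = sprintf("P%03d", 1:n_seed),
    x = sample(c("y", "n"), n_seed, replace = TRUE, prob = c(0.4, 0.6)),
    degree_final = 5
  ))
  forest <- tibble::tibble(person_id = d$person_id,
                           recruiter_id = NA_character_,
                           seed_id = d$person_id, wave = 0L)
  out <- chain_bootstrap_deff(d, forest, x, category = "y", n_boot = 600,
                              rng_seed = 3)
  expect_gt(out$deff, 0.7)
  expect_lt(out$deff, 1.4)
})

test_that("clustered chains inflate the design effect", {
  # 12 chains, trait constant within chain: variance far above SRS
  above <- vapply(1:20, function(s) {
    chain_x <- rep(c("y", "n"), c(4, 8))
    d <- tibble::tibble(
      person_id = sprintf("P%03d", 1:240),
      x = rep(chain_x, each = 20),
      degree_final = 5,
      seed_chain = rep(sprintf("S%02d", 1:12), each = 20)
    )
    forest <- tibble::tibble(person_id = d$person_id,
                             recruiter_id = NA_character_,
                             seed_id = d$seed_chain, wave = 0L)
    chain_bootstrap_deff(d, forest, x, category = "y", n_boot = 200,
                         rng_seed = s)$deff > 1
  }, logical(1))
  expect_gte(mean(above), 0.95)
})

test_that("bootstrap preconditions are enforced", {
  d <- tibble::tibble(person_id = c("A", "B"), x = c("y", "n"),
                      degree_final = 2)
  forest <- tibble::tibble(person_id = c("A", "B"),
                           recruiter_id = NA_character_,
                           seed_id = c("A", "B"), wave = 0L)
  expect_error(chain_bootstrap_deff(d, forest, x, n_boot = 0), "at least 100")
  one <- tibble::tibble(person_id = "A", x = "y", degree_final = 2)
  fone <- tibble::tibble(person_id = "A", recruiter_id = NA_character_,
                         seed_id = "A", wave = 0L)
  expect_error(chain_bootstrap_deff(one, fone, x, n_boot = 200), "2 seed")
})

test_that("RDS-II error shrinks with sample size on simulated studies", {
  mae_at <- function(target) {
    errs <- vapply(1:12, function(s) {
      pop <- generate_population(population_config(4000, 0.85, 8,
                                                   rng_seed = 100 + s))
      pop <- withr::with_seed(s, add_degree_linked_trait(pop,
                                                         prevalence = 0.3,
                                                         strength = 1))
      truth <- mean(pop$nodes$trait[pop$nodes$eligible])
      run <- run_recruitment(pop, clean_sim_config(seed = s,
                                                   target_n = target,
                                                   horizon_days = 400))
      an <- run$forest
      tr <- pop$nodes$trait[match(an$person_id, pop$nodes$person_id)]
      q2 <- run$roster$q2_network[match(an$coupon_code,
                                        run$roster$coupon_code)]
      d <- tibble::tibble(x = tr, degree_final = pmax(q2, 1))
      est <- tidy(rds2_estimate(d, x))
      abs(est$estimate[est$category == "TRUE"] - truth)
    }, numeric(1))
    mean(errs)
  }
  maes <- vapply(c(100L, 250L, 500L), mae_at, numeric(1))
  expect_lt(max(maes), 0.08) # bias bounded throughout
  expect_lt(maes[3], maes[1]) # and shrinking with n
  expect_lte(maes[2], maes[1])
})
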