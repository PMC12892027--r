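mini_roster <- function(...) {
  rows <- list(...)
  tibble::tibble(
    attempt_id = seq_along(rows),
    coupon_code = vapply(rows, `[[`, "", 1),
    email = vapply(rows, `[[`, "", 2),
    dob = as.Date(vapply(rows, `[[`, "", 3)),
    used_ends_12mo = TRUE, age_ok = TRUE, resident = TRUE, completed = TRUE,
    device_ecig = TRUE, device_htp = FALSE, device_vape = FALSE,
    q1_network = 5L, q2_network = 5L
  )
}

test_that("automatic blocking removes repeats and keeps first arrivals", {
  r <- mini_roster(
    c("C1", "ana@x.test", "1990-01-01"),
    c("C1", "bia@x.test", "1991-05-05"),     # repeated coupon
    c("C2", "ana@x.test", "1992-02-02"),     # repeated email
    c("C3", "carla@x.test", "1990-01-01"),   # repeated DOB
    c("C4", "dani@x.test", "1993-03-03")
  )
  out <- block_automatic(r)
  expect_equal(out$kept$attempt_id, c(1L, 5L))
  expect_equal(out$removed$reason,
               c("repeated_coupon", "repeated_email", "repeated_dob"))
  # identity case: all distinct -> all kept
  r2 <- mini_roster(
    c("C1", "a@x.test", "1990-01-01"),
    c("C2", "b@x.test", "1991-01-01"),
    c("C3", "c@x.test", "1992-01-01")
  )
  expect_equal(nrow(block_automatic(r2)$kept), 3)
})

test_that("malformed identities are quarantined, not dropped silently", {
  r <- mini_roster(
    c("C1", "a@x.test", "1990-01-01"),
    c("C2", "not-an-email", "1991-01-01")
  )
  r$dob[1] <- r$dob[1] # keep valid
  out <- block_automatic(r)
  expect_equal(out$quarantined$attempt_id, 2L)
  expect_equal(nrow(out$kept), 1)
})

test_that("automatic blocking equals the quadratic-scan oracle", {
  for (s in c(1, 2, 3)) {
    r <- random_roster(400, seed = s)
    out <- block_automatic(r)
    oracle <- oracle_block(r)
    expect_equal(out$kept$attempt_id, oracle$kept)
    expect_equal(out$removed$attempt_id, oracle$removed)
    expect_equal(out$quarantined$attempt_id, oracle$quarantined)
  }
})

test_that("permuting a roster changes which duplicate wins, not how many", {
  # collisions on one identifier at a time: when duplicate groups do not
  # chain across keys, the number kept is an order-free invariant (one
  # survivor per duplicate group), though which row survives is not
  r <- withr::with_seed(4, tibble::tibble(
    attempt_id = 1:300,
    coupon_code = sprintf("C%04d", 1:300),
    email = sprintf("user%03d@x.test", sample(120, 300, replace = TRUE)),
    dob = as.Date("1990-01-01") + 3L * (1:300),
    used_ends_12mo = TRUE, age_ok = TRUE, resident = TRUE, completed = TRUE,
    device_ecig = TRUE, device_htp = FALSE, device_vape = FALSE,
    q1_network = 5L, q2_network = 5L
  ))
  base <- block_automatic(r)
  expect_equal(nrow(base$kept), length(unique(r$email)))
  for (s in 1:5) {
    perm <- withr::with_seed(s, r[sample.int(nrow(r)), ])
    perm$attempt_id <- seq_len(nrow(perm))
    out <- block_automatic(perm)
    expect_equal(nrow(out$kept), nrow(base$kept))
  }
})

test_that("manual patterns catch inversions, variants, and similarity", {
  r <- mini_roster(
    c("C1", "ana.silva@x.test", "1990-01-01"),
    c("C2", "silva.ana@x.test", "1991-06-06"),    # token inversion
    c("C3", "joao@x.test", "1992-02-02"),
    c("C4", "joao2@x.test", "1992-02-08"),        # numeric variant
    c("C5", "marcos.lima@x.test", "1993-03-03"),
    c("C6", "marcos.limas@x.test", "1993-03-04"), # similar + adjacent DOB
    c("C7", "bia_souza@x.test", "1994-04-04"),
    c("C8", "biasouza@x.test", "1995-05-05")      # separator toggle
  )
  out <- flag_manual_patterns(r)
  expect_equal(out$removed$attempt_id, c(2L, 4L, 6L, 8L))
  expect_equal(out$removed$reason,
               c("token_inversion", "numeric_variant", "similar_email_dob",
                 "numeric_variant"))
  expect_equal(out$removed$matched_attempt[1:2], c(1L, 3L))
})

test_that("self-recruitment is detected through the coupon ledger", {
  r <- mini_roster(
    c("SEED01", "recruiter@x.test", "1990-01-01"),
    c("K1", "someone.else@x.test", "1990-01-01") # recruiter's own DOB
  )
  ledger <- tibble::tibble(
    code = c("SEED01", "K1"), issuer_id = c("STUDY", "P1"),
    issuer_dob = as.Date(c(NA, "1990-01-01")), status = "used"
  )
  out <- flag_manual_patterns(r, ledger = ledger)
  expect_equal(out$removed$attempt_id, 2L)
  expect_equal(out$removed$reason, "self_recruit")
  # without the ledger the DOB coincidence alone is not evidence
  expect_equal(nrow(flag_manual_patterns(r)$removed), 0)
})

test_that("the eligibility screen is conservative and invalidates codes", {
  r <- mini_roster(
    c("C1", "a@x.test", "1990-01-01"),
    c("C2", "b@x.test", "1991-01-01"),
    c("C3", "c@x.test", "1992-01-01")
  )
  r$used_ends_12mo[2] <- FALSE
  r$resident[3] <- NA
  ledger <- tibble::tibble(code = c("C1", "C2", "C3"), issuer_id = "P1",
                           issuer_dob = as.Date("1970-01-01"),
                           status = "used")
  out <- screen_eligibility(r, ledger)
  expect_equal(out$eligible$attempt_id, 1L)
  expect_equal(out$ineligible$reason, c("failed_screen", "missing_screen"))
  expect_equal(out$ledger$status, c("used", "invalidated", "invalidated"))
})

test_that("device consistency excludes contradictory records only", {
  r <- mini_roster(
    c("C1", "a@x.test", "1990-01-01"),
    c("C2", "b@x.test", "1991-01-01")
  )
  r$device_ecig[2] <- FALSE
  out <- check_consistency(r)
  expect_equal(out$analysis$attempt_id, 1L)
  expect_equal(out$excluded$attempt_id, 2L)
})

test_that("the funnel is idempotent on its own output", {
  fx <- make_paper_fixture()
  first <- intake_funnel(fx$roster, fx$ledger)
  again <- intake_funnel(
    dplyr::mutate(first$analysis, attempt_id = dplyr::row_number())
  )
  expect_equal(nrow(again$removals), 0)
  expect_equal(again$report$n_analysis, first$report$n_analysis)
})

test_that("funnel reports enforce their accounting identities", {
  expect_error(build_funnel_report(n_attempts = 10, n_valid = 5),
               "pipeline bug")
  rp <- build_funnel_report(n_attempts = 508, n_blocked_auto = 12,
                            n_invalid_manual = 24, n_ineligible = 120,
                            n_incomplete = 22, n_valid = 330,
                            n_inconsistent = 6)
  expect_equal(rp$n_analysis, 324)
  expect_equal(rp$pct_invalid_total, round_half_up(100 * 156 / 508, 1))
  expect_equal(rp$pct_inconsistent, round_half_up(100 * 6 / 330, 1))
  td <- tidy(rp)
  expect_equal(td$n[td$stage == "analysis"], 324)
})

test_that("fraud detection has high recall and almost no false positives", {
  res <- vapply(1:50, function(s) {
    pop <- small_population(seed = 5000 + s, n = 1600, prev = 0.6,
                            mean_degree = 6)
    run <- run_recruitment(pop, quick_sim_config(
      seed = s, target_n = 250, p_duplicate_attempt = 0.08,
      p_self_recruit = 0.03
    ))
    fun <- intake_funnel(run$roster, run$ledger)
    dup_ids <- run$truth$attempt_id[run$truth$truth_kind %in%
                                      c("duplicate", "self_recruit")]
    removed_dupes <- fun$removals$attempt_id[fun$removals$stage %in%
                                               c("automatic", "manual")]
    legit <- run$truth$attempt_id[run$truth$truth_kind %in% c("seed", "valid")]
    c(recall = mean(dup_ids %in% removed_dupes),
      fp = mean(legit %in% removed_dupes))
  }, numeric(2))
  expect_gte(mean(res["recall", ]), 0.95)
  expect_lte(mean(res["fp", ]), 0.01)
})
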