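# Shared fixtures and independent oracles for the test suite.

small_population <- function(seed = 1, n = 1200, prev = 0.5, mean_degree = 5,
                             homophily = c(zone = 0)) {
  generate_population(population_config(
    n_total = n, prevalence_eligible = prev, mean_degree = mean_degree,
    homophily = homophily, rng_seed = seed
  ))
}

quick_sim_config <- function(seed = 1, target_n = 150, ...) {
  simulation_config(target_n = target_n, incentive_switch_day = 0,
                    participation_prob = c(low = 0.05, high = 0.6),
                    rng_seed = seed, ...)
}

clean_sim_config <- function(seed = 1, target_n = 150, ...) {
  quick_sim_config(seed = seed, target_n = target_n,
                   p_ineligible_use = 0, p_duplicate_attempt = 0,
                   p_self_recruit = 0, p_incomplete = 0, p_inconsistent = 0,
                   ...)
}

# Independent O(n^2) oracle for the automatic blocking stage: pairwise scan
# against every earlier attempt (coupon: any earlier occurrence; email/DOB:
# earlier *kept* attempts), first arrival wins.
oracle_block <- function(roster, keys = c("coupon", "email", "dob")) {
  n <- nrow(roster)
  ok_row <- grepl("^[^@[:space:]]+@[^@[:space:]]+$", roster$email) &
    !is.na(roster$email) & !is.na(roster$dob)
  emails <- tolower(trimws(roster$email))
  kept <- logical(n)
  removed <- logical(n)
  for (i in seq_len(n)) {
    if (!ok_row[i]) next # quarantined
    hit <- FALSE
    if ("coupon" %in% keys && i > 1) {
      for (j in seq_len(i - 1)) {
        if (ok_row[j] && roster$coupon_code[j] == roster$coupon_code[i]) {
          hit <- TRUE
          break
        }
      }
    }
    if (!hit && i > 1) {
      for (j in seq_len(i - 1)) {
        if (!kept[j]) next
        if (("email" %in% keys && emails[j] == emails[i]) ||
            ("dob" %in% keys && roster$dob[j] == roster$dob[i])) {
          hit <- TRUE
          break
        }
      }
    }
    if (hit) removed[i] <- TRUE else kept[i] <- TRUE
  }
  list(kept = which(kept), removed = which(removed),
       quarantined = which(!ok_row))
}

# Random raw roster with forced identifier collisions.
random_roster <- function(n, seed, p_malformed = 0.01) {
  withr::with_seed(seed, {
    codes <- sprintf("C%04d", sample(ceiling(n * 0.8), n, replace = TRUE))
    emails <- sprintf("user%03d@x.test", sample(ceiling(n * 0.7), n,
                                                replace = TRUE))
    dobs <- as.Date("1990-01-01") + sample(ceiling(n * 0.9), n,
                                           replace = TRUE)
    bad <- runif(n) < p_malformed
    emails[bad] <- "not-an-email"
    tibble::tibble(
      attempt_id = seq_len(n), coupon_code = codes, email = emails,
      dob = dobs, used_ends_12mo = TRUE, age_ok = TRUE, resident = TRUE,
      completed = TRUE, device_ecig = TRUE, device_htp = FALSE,
      device_vape = FALSE, q1_network = 5L, q2_network = 5L
    )
  })
}

# Random recruitment forest (valid structure) for brute-force comparisons.
random_forest <- function(seed, n = 80, n_seeds = 5, max_out = 3) {
  withr::with_seed(seed, {
    pid <- sprintf("P%03d", seq_len(n))
    recruiter <- rep(NA_character_, n)
    wave <- integer(n)
    kids <- integer(n)
    for (i in (n_seeds + 1):n) {
      open <- which(kids[seq_len(i - 1)] < max_out)
      p <- open[sample.int(length(open), 1)]
      recruiter[i] <- pid[p]
      wave[i] <- wave[p] + 1L
      kids[p] <- kids[p] + 1L
    }
    seed_of <- pid
    for (i in seq_len(n)) {
      if (!is.na(recruiter[i])) seed_of[i] <- seed_of[match(recruiter[i], pid)]
    }
    tibble::tibble(person_id = pid, recruiter_id = recruiter,
                   coupon_code = sprintf("K%05d", seq_len(n)),
                   day = wave * 2L, wave = wave, seed_id = seed_of,
                   analysis = TRUE)
  })
}

# Brute-force max depth by following parent pointers.
oracle_max_depth <- function(forest) {
  depth <- vapply(forest$person_id, function(p) {
    d <- 0L
    while (TRUE) {
      r <- forest$recruiter_id[match(p, forest$person_id)]
      if (is.na(r)) return(d)
      d <- d + 1L
      p <- r
    }
  }, integer(1))
  max(depth)
}
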