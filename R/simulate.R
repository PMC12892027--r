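#' Configuration for a web-RDS recruitment simulation
#'
#' Parameterizes the coupon-based chain-referral process: seed count,
#' invitation quota, incentive-dependent participation, and the rates at
#' which fraudulent, ineligible or incomplete access attempts reach the
#' data-collection system.
#'
#' @param n_seeds Number of valid seeds (default 12).
#' @param coupons_per_participant Invitation codes issued per enrollee
#'   (default 3).
#' @param participation_prob Named vector `c(low = , high = )`: per-offer
#'   probability that an invited peer participates under each incentive
#'   level.
#' @param incentive_switch_day Day index at which the incentive moves from
#'   `low` to `high` (0 means high from the start).
#' @param horizon_days Last simulated day.
#' @param p_spend Daily hazard that a held coupon is passed on.
#' @param p_ineligible_use Probability a spent coupon goes to an ineligible
#'   contact (the code is then invalidated).
#' @param p_duplicate_attempt Probability a spent coupon is consumed by an
#'   already-enrolled person re-attempting under a mutated email.
#' @param p_self_recruit Probability a recruiter spends their own coupon
#'   under a fake email but their own date of birth.
#' @param p_incomplete Probability an accepted eligible attempt abandons the
#'   questionnaire.
#' @param p_inconsistent Probability a completed eligible record carries
#'   contradictory (all-negative) device-use fields.
#' @param heap_prob Degree-heaping probability passed to
#'   [apply_degree_heaping()].
#' @param target_n Enrollment target; the system closes at the end of the
#'   first day on which the count of valid completed participants reaches it.
#' @param rng_seed Integer seed; identical seeds give identical outputs.
#' @return A `webrds_sim_config` list.
#' @export
simulation_config <- function(n_seeds = 12L,
                              coupons_per_participant = 3L,
                              participation_prob = c(low = 0.05, high = 0.55),
                              incentive_switch_day = 60L,
                              horizon_days = 270L,
                              p_spend = 0.15,
                              p_ineligible_use = 0.24,
                              p_duplicate_attempt = 0.05,
                              p_self_recruit = 0.02,
                              p_incomplete = 0.06,
                              p_inconsistent = 0.018,
                              heap_prob = 0.5,
                              target_n = 330L,
                              rng_seed = 1L) {
  if (n_seeds < 1) abort("`n_seeds` must be >= 1.")
  if (coupons_per_participant < 1) abort("`coupons_per_participant` must be >= 1.")
  if (!all(c("low", "high") %in% names(participation_prob))) {
    abort("`participation_prob` needs named entries `low` and `high`.")
  }
  for (nm in c("p_spend", "p_ineligible_use", "p_duplicate_attempt",
               "p_self_recruit", "p_incomplete", "p_inconsistent",
               "heap_prob")) {
    assert_prob(get(nm), nm)
  }
  assert_prob(unname(participation_prob), "participation_prob")
  if (sum(p_ineligible_use, p_duplicate_attempt, p_self_recruit) >= 1) {
    abort("fraud/ineligible probabilities must sum to < 1.")
  }
  structure(
    list(n_seeds = as.integer(n_seeds),
         coupons_per_participant = as.integer(coupons_per_participant),
         participation_prob = participation_prob,
         incentive_switch_day = as.integer(incentive_switch_day),
         horizon_days = as.integer(horizon_days),
         p_spend = p_spend,
         p_ineligible_use = p_ineligible_use,
         p_duplicate_attempt = p_duplicate_attempt,
         p_self_recruit = p_self_recruit,
         p_incomplete = p_incomplete,
         p_inconsistent = p_inconsistent,
         heap_prob = heap_prob,
         target_n = as.integer(target_n),
         rng_seed = as.integer(rng_seed)),
    class = "webrds_sim_config"
  )
}

#' Select diverse seeds from a population
#'
#' Chooses eligible, well-connected seeds spread across the requested trait
#' strata as evenly as availability permits, mirroring the practice of
#' seeding chains in different city zones and age groups to dilute
#' homophily. Selection is deterministic: at each step the stratum with the
#' fewest seeds selected so far receives the highest-degree remaining
#' candidate (global ties broken by degree, then person id).
#'
#' @param population A `webrds_population`.
#' @param n_seeds Number of seeds.
#' @param diversity_traits Character vector of trait columns to stratify on.
#' @param strict Error if some trait-level combination present in the
#'   population has no eligible candidate.
#' @return Tibble of seed rows from `population$nodes`.
#' @export
select_seeds <- function(population, n_seeds = 12L,
                         diversity_traits = c("zone", "age_group"),
                         strict = FALSE) {
  nodes <- population$nodes
  cand <- nodes[nodes$eligible, , drop = FALSE]
  if (nrow(cand) < n_seeds) {
    abort("`n_seeds` exceeds the number of eligible members.")
  }
  stratum_of <- function(df) {
    do.call(paste, c(lapply(diversity_traits, function(tr) df[[tr]]),
                     sep = "/"))
  }
  if (strict) {
    all_strata <- unique(stratum_of(nodes))
    missing <- setdiff(all_strata, unique(stratum_of(cand)))
    if (length(missing)) {
      abort(paste("strata without eligible candidates:",
                  paste(missing, collapse = ", ")))
    }
  }
  cand$.stratum <- stratum_of(cand)
  cand <- cand[order(-cand$true_degree, cand$person_id), ]
  chosen <- integer(0)
  sel_count <- setNames(rep(0L, length(unique(cand$.stratum))),
                        unique(cand$.stratum))
  avail <- rep(TRUE, nrow(cand))
  for (k in seq_len(n_seeds)) {
    strata_avail <- unique(cand$.stratum[avail])
    mins <- min(sel_count[strata_avail])
    pool_strata <- strata_avail[sel_count[strata_avail] == mins]
    idx <- which(avail & cand$.stratum %in% pool_strata)[1] # highest degree
    chosen <- c(chosen, idx)
    avail[idx] <- FALSE
    s <- cand$.stratum[idx]
    sel_count[s] <- sel_count[s] + 1L
  }
  out <- cand[chosen, ]
  out$.stratum <- NULL
  out
}

# 8-character uppercase alphanumeric coupon codes, collision-checked.
gen_codes <- function(n, registry) {
  alphabet <- c(LETTERS, 0:9)
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      code <- paste(sample(alphabet, 8, replace = TRUE), collapse = "")
      if (is.null(registry[[code]])) {
        assign(code, TRUE, envir = registry)
        out[i] <- code
        break
      }
    }
  }
  out
}

# Email mutation operators used by duplicate attempts: token inversion,
# digit suffixes, separator toggling -- exactly the patterns the manual
# review stage is built to detect.
mutate_email <- function(email) {
  local <- sub("@.*$", "", email)
  domain <- sub("^[^@]*@", "", email)
  toks <- strsplit(local, "[._]")[[1]]
  op <- sample(3L, 1L)
  if (op == 1L && length(toks) >= 2) {
    local <- paste(rev(toks), collapse = ".")
  } else if (op == 2L) {
    local <- paste0(local, sample(1:99, 1))
  } else {
    sep <- sample(c("_", ""), 1)
    local <- paste(toks, collapse = sep)
  }
  paste0(local, "@", domain)
}

#' Simulate a web-RDS recruitment process
#'
#' Runs a discrete-day simulation of coupon-based peer recruitment on the
#' eligible subnetwork: seeds enroll on day 0 and receive invitation codes;
#' held codes are passed on with a daily hazard; each spend is consumed by a
#' genuine eligible peer (who participates with an incentive-dependent
#' probability and may abandon the questionnaire), by an ineligible contact
#' (code invalidated), by a duplicate re-attempt under a mutated email, or by
#' the recruiter under a fake email with their own date of birth. Enrollment
#' closes at the end of the first day on which the valid completed count
#' reaches `target_n`.
#'
#' @param population A `webrds_population`.
#' @param config A [simulation_config()].
#' @param seeds Optional tibble of seed rows (defaults to
#'   [select_seeds()] with `config$n_seeds`).
#' @return A `webrds_run` list: `roster` (the observed attempt roster, one
#'   row per access attempt), `ledger` (coupon issuance/usage), `forest`
#'   (recruiter-recruit edges with waves and seed ids), and `truth`
#'   (ground-truth labels per attempt, never part of the observed bundle).
#' @export
run_recruitment <- function(population, config, seeds = NULL) {
  if (!inherits(config, "webrds_sim_config")) {
    abort("`config` must come from simulation_config().")
  }
  nodes <- population$nodes
  elig_idx <- which(nodes$eligible)
  m <- length(elig_idx)
  if (m < config$n_seeds) abort("population has fewer eligible members than seeds.")
  pos <- match(nodes$person_id, nodes$person_id) # identity; for clarity below
  elig_pos <- setNames(seq_len(m), nodes$person_id[elig_idx])
  # neighbor lists in eligible-index space
  ef <- unname(elig_pos[population$edges$from])
  et <- unname(elig_pos[population$edges$to])
  nbr <- vector("list", m)
  if (length(ef)) {
    o <- order(ef); spl <- split(et[o], ef[o])
    nbr[as.integer(names(spl))] <- spl
    o <- order(et); spl <- split(ef[o], et[o])
    for (k in names(spl)) nbr[[as.integer(k)]] <- c(nbr[[as.integer(k)]], spl[[k]])
  }

  withr::with_seed(config$rng_seed, {
    if (is.null(seeds)) seeds <- select_seeds(population, config$n_seeds)
    seed_eidx <- unname(elig_pos[seeds$person_id])

    level_of <- function(day) {
      if (day < config$incentive_switch_day) "low" else "high"
    }

    # growable state --------------------------------------------------------
    cap_r <- config$target_n * 3L + 200L
    roster <- list(
      attempt_id = integer(cap_r), coupon_code = character(cap_r),
      email = character(cap_r), dob = rep(as.Date(NA), cap_r),
      day = integer(cap_r),
      used_ends_12mo = rep(NA, cap_r), age_ok = rep(NA, cap_r),
      resident = rep(NA, cap_r), completed = rep(NA, cap_r),
      device_ecig = rep(NA, cap_r), device_htp = rep(NA, cap_r),
      device_vape = rep(NA, cap_r),
      q1_network = rep(NA_integer_, cap_r), q2_network = rep(NA_integer_, cap_r),
      age_group = rep(NA_character_, cap_r), sex = rep(NA_character_, cap_r),
      zone = rep(NA_character_, cap_r), ever_cigarette = rep(NA, cap_r)
    )
    truth <- list(attempt_id = integer(cap_r),
                  truth_person_id = rep(NA_character_, cap_r),
                  truth_kind = character(cap_r))
    n_rows <- 0L
    grow_roster <- function() {
      cap_new <- length(roster$attempt_id) * 2L
      for (nm in names(roster)) roster[[nm]] <<- c(roster[[nm]], rep(roster[[nm]][NA_integer_], cap_new - length(roster[[nm]])))
      for (nm in names(truth)) truth[[nm]] <<- c(truth[[nm]], rep(truth[[nm]][NA_integer_], cap_new - length(truth[[nm]])))
    }

    cap_c <- config$target_n * (config$coupons_per_participant + 1L) + 100L
    cp <- list(code = character(cap_c), issuer = integer(cap_c), # eligible idx, 0 = STUDY
               status = character(cap_c), issued_day = integer(cap_c),
               spend_day = numeric(cap_c), used_day = rep(NA_integer_, cap_c),
               used_by = rep(NA_integer_, cap_c),
               destiny = character(cap_c))
    n_cp <- 0L
    code_registry <- new.env(hash = TRUE)

    enrolled <- rep(FALSE, m)
    consumed_identity <- rep(FALSE, m) # incomplete attempts: identity in system
    wave <- rep(NA_integer_, m)
    seed_of <- rep(NA_character_, m)
    forest <- list(person_id = character(0), recruiter_id = character(0),
                   coupon_code = character(0), day = integer(0),
                   wave = integer(0), seed_id = character(0),
                   analysis = logical(0))
    inel_pool <- sample(which(!nodes$eligible))
    inel_ptr <- 0L
    fake_ptr <- 0L
    n_valid <- 0L

    add_row <- function(code, email, dob, day, screen, completed, devices,
                        q1, q2, traits, person_id, kind) {
      if (n_rows + 1L > length(roster$attempt_id)) grow_roster()
      n_rows <<- n_rows + 1L
      i <- n_rows
      roster$attempt_id[i] <<- i
      roster$coupon_code[i] <<- code
      roster$email[i] <<- email
      roster$dob[i] <<- dob
      roster$day[i] <<- day
      roster$used_ends_12mo[i] <<- screen[1]
      roster$age_ok[i] <<- screen[2]
      roster$resident[i] <<- screen[3]
      roster$completed[i] <<- completed
      roster$device_ecig[i] <<- devices[1]
      roster$device_htp[i] <<- devices[2]
      roster$device_vape[i] <<- devices[3]
      roster$q1_network[i] <<- q1
      roster$q2_network[i] <<- q2
      roster$age_group[i] <<- traits[1]
      roster$sex[i] <<- traits[2]
      roster$zone[i] <<- traits[3]
      roster$ever_cigarette[i] <<- as.logical(traits[4])
      truth$attempt_id[i] <<- i
      truth$truth_person_id[i] <<- person_id
      truth$truth_kind[i] <<- kind
      i
    }

    # Each coupon's fate (genuine offer, ineligible contact, duplicate
    # re-attempt, self-recruitment) is drawn once at issuance: the stated
    # rates are per spent coupon, and a declined genuine offer is retried
    # rather than re-rolled.
    issue_coupons <- function(issuer_eidx, day) {
      k <- config$coupons_per_participant
      codes <- gen_codes(k, code_registry)
      for (j in seq_len(k)) {
        n_cp <<- n_cp + 1L
        i <- n_cp
        cp$code[i] <<- codes[j]
        cp$issuer[i] <<- issuer_eidx
        cp$status[i] <<- "unused"
        cp$issued_day[i] <<- day
        cp$spend_day[i] <<- day + 1 + rgeom(1, config$p_spend)
        u <- runif(1)
        cp$destiny[i] <<- if (u < config$p_self_recruit) {
          "self"
        } else if (u < config$p_self_recruit + config$p_duplicate_attempt) {
          "duplicate"
        } else if (u < config$p_self_recruit + config$p_duplicate_attempt +
                   config$p_ineligible_use) {
          "ineligible"
        } else {
          "genuine"
        }
      }
    }

    questionnaire <- function(gi, inconsistent) {
      ni <- elig_idx[gi]
      q2 <- apply_degree_heaping(nodes$true_degree[ni], config$heap_prob)
      q2 <- max(q2, 1L) # an enrolled person knows at least their recruiter
      q1 <- min(q2 + rpois(1, 0.8), 99L)
      dev <- c(nodes$device_ecig[ni], nodes$device_htp[ni], nodes$device_vape[ni])
      if (inconsistent) dev <- c(FALSE, FALSE, FALSE)
      list(q1 = as.integer(q1), q2 = as.integer(q2), devices = dev)
    }

    enroll <- function(gi, recruiter_gi, code, day) {
      ni <- elig_idx[gi]
      inconsistent <- if (is.na(recruiter_gi)) FALSE else runif(1) < config$p_inconsistent
      qq <- questionnaire(gi, inconsistent)
      add_row(code, nodes$email[ni], nodes$dob[ni], day,
              c(TRUE, TRUE, TRUE), TRUE, qq$devices, qq$q1, qq$q2,
              c(nodes$age_group[ni], nodes$sex[ni], nodes$zone[ni],
                nodes$ever_cigarette[ni]),
              nodes$person_id[ni], if (is.na(recruiter_gi)) "seed" else "valid")
      enrolled[gi] <<- TRUE
      wave[gi] <<- if (is.na(recruiter_gi)) 0L else wave[recruiter_gi] + 1L
      seed_of[gi] <<- if (is.na(recruiter_gi)) nodes$person_id[ni] else seed_of[recruiter_gi]
      forest$person_id <<- c(forest$person_id, nodes$person_id[ni])
      forest$recruiter_id <<- c(forest$recruiter_id,
                                if (is.na(recruiter_gi)) NA_character_
                                else nodes$person_id[elig_idx[recruiter_gi]])
      forest$coupon_code <<- c(forest$coupon_code, code)
      forest$day <<- c(forest$day, day)
      forest$wave <<- c(forest$wave, wave[gi])
      forest$seed_id <<- c(forest$seed_id, seed_of[gi])
      forest$analysis <<- c(forest$analysis, !inconsistent)
      n_valid <<- n_valid + 1L
      issue_coupons(gi, day)
    }

    # day 0: seeds enroll with study-issued codes
    seed_codes <- sprintf("SEED%02d", seq_along(seed_eidx))
    for (s in seq_along(seed_eidx)) {
      assign(seed_codes[s], TRUE, envir = code_registry)
      enroll(seed_eidx[s], NA_integer_, seed_codes[s], 0L)
    }

    for (day in seq_len(config$horizon_days)) {
      due <- which(cp$status[seq_len(n_cp)] == "unused" &
                     cp$spend_day[seq_len(n_cp)] <= day)
      for (i in due) {
        issuer <- cp$issuer[i]
        # every taker — genuine peer, ineligible contact, or fraudster — is
        # motivated by the participation incentive: under a low incentive
        # the coupon is simply held and retried later
        if (runif(1) >= config$participation_prob[[level_of(day)]]) {
          cp$spend_day[i] <- day + 1 + rgeom(1, config$p_spend)
          next
        }
        if (cp$destiny[i] == "self") {
          fake_ptr <- fake_ptr + 1L
          ni <- elig_idx[issuer]
          aid <- add_row(cp$code[i],
                         sprintf("novo.usuario%03d@mail.test", fake_ptr),
                         nodes$dob[ni], day, c(TRUE, TRUE, TRUE), TRUE,
                         c(TRUE, FALSE, FALSE), 3L, 2L,
                         c(nodes$age_group[ni], nodes$sex[ni], nodes$zone[ni],
                           nodes$ever_cigarette[ni]),
                         nodes$person_id[ni], "self_recruit")
          cp$status[i] <- "used"; cp$used_day[i] <- day; cp$used_by[i] <- aid
        } else if (cp$destiny[i] == "duplicate") {
          cands <- nbr[[issuer]]
          cands <- cands[enrolled[cands]]
          dup <- if (length(cands)) cands[sample.int(length(cands), 1)] else issuer
          ni <- elig_idx[dup]
          dob <- nodes$dob[ni] + sample(c(0L, -1L, 1L), 1, prob = c(.5, .25, .25))
          qq <- questionnaire(dup, FALSE)
          aid <- add_row(cp$code[i], mutate_email(nodes$email[ni]), dob, day,
                         c(TRUE, TRUE, TRUE), TRUE, qq$devices, qq$q1, qq$q2,
                         c(nodes$age_group[ni], nodes$sex[ni], nodes$zone[ni],
                           nodes$ever_cigarette[ni]),
                         nodes$person_id[ni], "duplicate")
          cp$status[i] <- "used"; cp$used_day[i] <- day; cp$used_by[i] <- aid
        } else if (cp$destiny[i] == "ineligible") {
          inel_ptr <- inel_ptr + 1L
          if (inel_ptr <= length(inel_pool)) {
            ni <- inel_pool[inel_ptr]
            email <- nodes$email[ni]; dob <- nodes$dob[ni]
            traits <- c(nodes$age_group[ni], nodes$sex[ni], nodes$zone[ni],
                        nodes$ever_cigarette[ni])
            pid <- nodes$person_id[ni]
          } else {
            email <- sprintf("convidado%05d@example.test", inel_ptr)
            dob <- as.Date("1900-06-15") + inel_ptr * 7L
            traits <- c("25-34", "male", "north", FALSE)
            pid <- NA_character_
          }
          fail <- sample(3L, 1L, prob = c(.7, .1, .2))
          screen <- c(fail != 1L, fail != 2L, fail != 3L)
          aid <- add_row(cp$code[i], email, dob, day, screen, FALSE,
                         c(NA, NA, NA), NA_integer_, NA_integer_,
                         traits, pid, "ineligible")
          cp$status[i] <- "invalidated"; cp$used_day[i] <- day; cp$used_by[i] <- aid
        } else {
          cands <- nbr[[issuer]]
          cands <- cands[!enrolled[cands] & !consumed_identity[cands]]
          if (!length(cands)) {
            cp$spend_day[i] <- Inf # nobody left to invite
            next
          }
          target <- cands[sample.int(length(cands), 1)]
          if (runif(1) < config$p_incomplete) {
            ni <- elig_idx[target]
            aid <- add_row(cp$code[i], nodes$email[ni], nodes$dob[ni], day,
                           c(TRUE, TRUE, TRUE), FALSE, c(NA, NA, NA),
                           NA_integer_, NA_integer_,
                           c(NA_character_, NA_character_, NA_character_, NA),
                           nodes$person_id[ni], "incomplete")
            consumed_identity[target] <- TRUE
            cp$status[i] <- "used"; cp$used_day[i] <- day; cp$used_by[i] <- aid
          } else {
            enroll(target, issuer, cp$code[i], day)
            cp$status[i] <- "used"; cp$used_day[i] <- day
            cp$used_by[i] <- n_rows
          }
        }
      }
      if (n_valid >= config$target_n) break
      active <- any(cp$status[seq_len(n_cp)] == "unused" &
                      is.finite(cp$spend_day[seq_len(n_cp)]))
      if (!active) break
    }

    if (n_valid <= length(seed_eidx)) {
      warn("recruitment stalled: no non-seed enrollments before the horizon",
           class = "webrds_stall")
    }

    keep <- seq_len(n_rows)
    roster_tbl <- as_tibble(lapply(roster, function(v) v[keep]))
    truth_tbl <- as_tibble(lapply(truth, function(v) v[keep]))
    kc <- seq_len(n_cp)
    issuer_gid <- ifelse(cp$issuer[kc] == 0L, "STUDY",
                         nodes$person_id[elig_idx[pmax(cp$issuer[kc], 1L)]])
    ledger <- tibble(
      code = cp$code[kc],
      issuer_id = issuer_gid,
      issuer_dob = as.Date(ifelse(cp$issuer[kc] == 0L, NA,
                                  nodes$dob[elig_idx[pmax(cp$issuer[kc], 1L)]]),
                           origin = "1970-01-01"),
      status = cp$status[kc],
      issued_day = cp$issued_day[kc],
      used_day = cp$used_day[kc],
      used_by = cp$used_by[kc]
    )
    seed_ledger <- tibble(
      code = seed_codes, issuer_id = "STUDY",
      issuer_dob = as.Date(NA), status = "used",
      issued_day = 0L, used_day = 0L,
      used_by = match(seed_codes, roster_tbl$coupon_code)
    )
    structure(
      list(roster = roster_tbl,
           ledger = bind_rows(seed_ledger, ledger),
           forest = as_tibble(forest),
           truth = truth_tbl,
           seeds = seeds,
           config = config),
      class = "webrds_run"
    )
  })
}

#' @export
print.webrds_run <- function(x, ...) {
  cat("<webrds_run>\n")
  cat("  attempts:", nrow(x$roster),
      " enrolled:", nrow(x$forest),
      " max wave:", max(x$forest$wave), "\n")
  invisible(x)
}

#' Recruiter productivity
#'
#' Tabulates, among participants who enrolled at least one recruit, how many
#' enrolled exactly 1, 2, 3, ... recruits. By default only recruits in the
#' analysis set are counted (records excluded for device-field inconsistency
#' stay in the recruitment network but do not count towards productivity).
#'
#' @param forest Recruitment forest tibble (`person_id`, `recruiter_id`,
#'   `wave`, optionally `analysis`).
#' @param analysis_only Count only recruits flagged `analysis` (default TRUE
#'   when the column is present).
#' @return Tibble with `n_recruits`, `n_recruiters`, `share_pct` (half-up,
#'   one decimal, of productive recruiters).
#' @export
recruiter_productivity <- function(forest, analysis_only = TRUE) {
  rows <- forest[!is.na(forest$recruiter_id), , drop = FALSE]
  if (analysis_only && "analysis" %in% names(forest)) {
    rows <- rows[rows$analysis, , drop = FALSE]
  }
  if (!nrow(rows)) {
    return(tibble(n_recruits = integer(0), n_recruiters = integer(0),
                  share_pct = numeric(0)))
  }
  tab <- table(table(rows$recruiter_id))
  total <- sum(tab)
  tibble(
    n_recruits = as.integer(names(tab)),
    n_recruiters = as.integer(tab),
    share_pct = pct1(as.integer(tab), total)
  )
}

#' Coupon exhaustion summary
#'
#' Share of enrolled participants, among those with at least one of their
#' issued invitation codes consumed (used or invalidated), whose codes were
#' all consumed. The denominator convention — participants who used at least
#' one invitation, counting every consumption regardless of the recruit's
#' eventual validity — is the one under which the fixture reproduces the
#' published 113/218 split.
#'
#' @param ledger Coupon ledger tibble (`code`, `issuer_id`, `status`).
#' @return One-row tibble: `n_any_used`, `n_all_used`, `share_all_pct`.
#' @export
coupon_exhaustion <- function(ledger) {
  led <- ledger[ledger$issuer_id != "STUDY", , drop = FALSE]
  per <- led %>%
    group_by(.data$issuer_id) %>%
    summarise(n_issued = n(),
              n_consumed = sum(.data$status != "unused"),
              .groups = "drop")
  n_any <- sum(per$n_consumed >= 1)
  n_all <- sum(per$n_consumed == per$n_issued & per$n_issued > 0)
  tibble(n_any_used = n_any, n_all_used = n_all,
         share_all_pct = pct1(n_all, n_any))
}
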