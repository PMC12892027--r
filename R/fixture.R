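## Deterministic reference fixture: an attempt roster, coupon ledger and
## recruitment forest whose cleaning funnel (508 attempts -> 330 valid ->
## 324 analyzed), recruiter productivity (75/60/39 over 174), seed
## composition, degree summary (47.5% <= 5, 25.6% > 10, max 99), wave depth
## (21) and coupon exhaustion (113/218) reproduce the published study
## exactly. The construction is pure arithmetic — no randomness — so
## rebuilding it always gives byte-identical tables.

fixture_q2_values <- function() {
  # 154 values <= 5 (mode at 5), 87 in 6..10, 83 above 10 with max 99
  low <- rep(c(1L, 2L, 3L, 4L, 5L), c(10L, 15L, 25L, 30L, 74L))
  mid <- rep(c(6L, 7L, 8L, 9L, 10L), c(20L, 15L, 20L, 12L, 20L))
  high <- rep(c(12L, 15L, 20L, 25L, 30L, 40L, 50L, 70L, 99L),
              c(8L, 20L, 18L, 12L, 10L, 6L, 5L, 3L, 1L))
  list(low = low, mid = mid, high = high)
}

#' Build the packaged reference study fixture
#'
#' Deterministically constructs the raw attempt roster, coupon ledger,
#' recruitment forest and ground-truth labels of a complete web-RDS data
#' collection: 12 seeds (6 south / 4 north / 1 west / 1 center; 9 men /
#' 3 women), 508 access attempts of which 156 are removed as duplicate or
#' ineligible (12 automatic blocks, 24 manual patterns, 120 failed
#' screens), 22 incomplete, 330 valid enrollments with chains 21 waves
#' deep, 6 device-consistency exclusions, recruiter productivity
#' 75/60/39 over 174, and 113 of 218 coupon-using participants exhausting
#' all 3 invitations. Running the intake pipeline and the diagnostics on
#' this bundle reproduces the published counts and percentages.
#'
#' @return A `webrds_fixture` list: `roster`, `ledger`, `forest`, `truth`.
#' @export
make_paper_fixture <- function() {
  ## --- participants and forest --------------------------------------------
  seed_ids <- sprintf("S%02d", 1:12)
  pid <- seed_ids
  recruiter <- rep(NA_character_, 12)
  wave <- rep(0L, 12)
  role <- c(rep(3L, 7), rep(0L, 5)) # S01..S07 productive, S08..S12 not
  analysis <- rep(TRUE, 12)

  add_node <- function(id, parent, rl, an) {
    pid <<- c(pid, id)
    recruiter <<- c(recruiter, parent)
    wave <<- c(wave, wave[match(parent, pid)] + 1L)
    role <<- c(role, rl)
    analysis <<- c(analysis, an)
  }

  # one 21-wave chain under S01; its first 20 links are 1-recruit recruiters
  chain_ids <- sprintf("R%03d", 1:21)
  add_node(chain_ids[1], "S01", 1L, TRUE)
  for (k in 2:21) add_node(chain_ids[k], chain_ids[k - 1],
                           if (k <= 20) 1L else 0L, TRUE)

  # breadth-first bushy remainder: 32 more 3-recruit, 60 2-recruit,
  # 55 1-recruit recruiters, then leaves; 291 counted recruits in all
  slots <- c(rep("S01", 2), rep(sprintf("S%02d", 2:7), each = 3))
  roles_queue <- rep(c(3L, 2L, 1L), c(32L, 60L, 55L))
  for (i in seq_len(291)) {
    parent <- slots[1]
    slots <- slots[-1]
    id <- sprintf("R%03d", 21L + i)
    rl <- if (i <= length(roles_queue)) roles_queue[i] else 0L
    add_node(id, parent, rl, TRUE)
    if (rl > 0) slots <- c(slots, rep(id, rl))
  }
  stopifnot(length(slots) == 0)

  # six consistency-excluded recruits, attached to the first six 2-recruit
  # recruiters (each has a spare invitation)
  class2_ids <- pid[role == 2L]
  for (k in 1:6) add_node(sprintf("R%03d", 312L + k), class2_ids[k], 0L, FALSE)

  n_part <- length(pid) # 330
  stopifnot(n_part == 330L)
  idx <- seq_len(n_part)
  day <- 3L * wave + (idx %% 3L)
  seed_of <- pid
  for (i in idx) {
    if (!is.na(recruiter[i])) seed_of[i] <- seed_of[match(recruiter[i], pid)]
  }

  ## --- coupons -------------------------------------------------------------
  codes <- outer(idx, 1:3, function(i, j) sprintf("K%05d%02d", i, j))
  next_code <- rep(1L, n_part)
  take_code <- function(issuer_id) {
    i <- match(issuer_id, pid)
    stopifnot(next_code[i] <= 3L)
    cd <- codes[i, next_code[i]]
    next_code[i] <<- next_code[i] + 1L
    cd
  }
  enroll_code <- character(n_part)
  enroll_code[1:12] <- sprintf("SEED%02d", 1:12)
  for (i in 13:n_part) enroll_code[i] <- take_code(recruiter[i])

  forest <- tibble(
    person_id = pid, recruiter_id = recruiter, coupon_code = enroll_code,
    day = day, wave = wave, seed_id = seed_of, analysis = analysis
  )

  ## --- identities ----------------------------------------------------------
  emails <- synth_emails(508)
  base_dob <- as.Date("1980-01-04") + 7L * (0:519)
  part_email <- emails[idx]
  part_dob <- base_dob[idx]

  ## --- traits --------------------------------------------------------------
  age_group <- rep(c("15-24", "25-34", "35+"),
                   length.out = n_part + 20)[21:(n_part + 20)]
  sex <- rep(c("male", "female", "male", "male", "female"),
             length.out = n_part)
  zone <- rep(c("south", "north", "west", "south", "north", "center"),
              length.out = n_part)
  # seeds match the published composition exactly
  age_group[1:12] <- c(rep("15-24", 3), rep("25-34", 4), rep("35+", 5))
  sex[1:12] <- c("male", "male", "male", "female", "male", "male", "male",
                 "female", "male", "male", "male", "female")
  zone[1:12] <- c(rep("south", 6), rep("north", 4), "west", "center")
  ever_cig <- rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), length.out = n_part)

  ## --- network-size answers ------------------------------------------------
  qv <- fixture_q2_values()
  is_recruiter <- role > 0
  nonrec_analysis <- which(!is_recruiter & analysis) # 150 of them
  class1 <- which(role == 1L)
  q2 <- integer(n_part)
  low_holders <- c(nonrec_analysis, class1[seq_len(4)])
  q2[low_holders] <- qv$low
  rest <- setdiff(which(is_recruiter & analysis), class1[seq_len(4)])
  q2[rest] <- c(qv$mid, qv$high)[seq_along(rest)]
  q2[!analysis] <- 6L
  q1 <- pmin(q2 + rep(c(0L, 1L, 2L), length.out = n_part), 99L)

  ## --- valid attempt rows --------------------------------------------------
  dev_ecig <- rep(TRUE, n_part)
  dev_htp <- idx %% 3L == 0L
  dev_vape <- idx %% 3L == 1L
  dev_ecig[!analysis] <- FALSE
  dev_htp[!analysis] <- FALSE
  dev_vape[!analysis] <- FALSE

  rows <- tibble(
    coupon_code = enroll_code, email = part_email, dob = part_dob, day = day,
    used_ends_12mo = TRUE, age_ok = TRUE, resident = TRUE, completed = TRUE,
    device_ecig = dev_ecig, device_htp = dev_htp, device_vape = dev_vape,
    q1_network = q1, q2_network = q2,
    age_group = age_group, sex = sex, zone = zone, ever_cigarette = ever_cig,
    .priority = 0L,
    .kind = ifelse(is.na(recruiter), "seed",
                   ifelse(analysis, "valid", "inconsistent")),
    .person = pid
  )

  ## --- extra (removed) attempt rows ---------------------------------------
  # issuers of the 166 fraudulent/ineligible/incomplete coupon spends:
  # 54 two-recruit recruiters (beyond the 6 holding an excluded recruit) x1,
  # 14 one-recruit recruiters x2, 40 leaves x2 and 4 leaves x1
  class1_bushy <- setdiff(pid[role == 1L], chain_ids)
  leaves <- setdiff(pid[role == 0L & analysis],
                    c(seed_ids, chain_ids[21]))
  extra_issuers <- c(
    class2_ids[7:60],
    rep(class1_bushy[seq_len(14)], each = 2L),
    rep(leaves[seq_len(40)], each = 2L),
    leaves[41:44]
  )
  stopifnot(length(extra_issuers) == 166L)
  extra_codes <- vapply(extra_issuers, take_code, "")
  extra_day <- day[match(extra_issuers, pid)] + 1L

  blank_row <- function(code, email, dob, dy, kind, priority,
                        screen = c(TRUE, TRUE, TRUE), completed = TRUE,
                        devices = c(TRUE, FALSE, FALSE),
                        q1 = 5L, q2 = 5L) {
    tibble(coupon_code = code, email = email, dob = dob, day = dy,
           used_ends_12mo = screen[1], age_ok = screen[2],
           resident = screen[3], completed = completed,
           device_ecig = devices[1], device_htp = devices[2],
           device_vape = devices[3], q1_network = q1, q2_network = q2,
           age_group = NA_character_, sex = NA_character_,
           zone = NA_character_, ever_cigarette = NA,
           .priority = priority, .kind = kind, .person = NA_character_)
  }

  # 12 automatic blocks: reuse the enrolling codes of 12 wave-1 recruits
  blocked_victims <- match(sprintf("R%03d", 22:33), pid)
  blocked <- purrr::map_dfr(seq_len(12), function(k) {
    v <- blocked_victims[k]
    blank_row(enroll_code[v], emails[330 + k], base_dob[330 + k],
              day[v] + 1L, "blocked_auto", 1L)
  })

  # 24 manual patterns against distinct kept victims
  victims <- match(sprintf("R%03d", 40:63), pid)
  invert_email <- function(e) {
    local <- sub("@.*$", "", e)
    toks <- strsplit(local, "\\.")[[1]]
    paste0(paste(rev(toks), collapse = "."), "@", sub("^[^@]*@", "", e))
  }
  manual <- purrr::map_dfr(seq_len(24), function(k) {
    v <- victims[k]
    if (k <= 12) {
      em <- invert_email(part_email[v]) # token inversion
      db <- base_dob[342 + k]
    } else if (k <= 20) {
      em <- sub("@", paste0(k, "@"), part_email[v]) # numeric variant
      db <- base_dob[342 + k]
    } else {
      em <- sub("a", "e", part_email[v]) # near-miss email, adjacent DOB
      db <- part_dob[v] + 1L
    }
    dy <- max(day[v], extra_day[k]) + 1L
    blank_row(extra_codes[k], em, db, dy, "manual_pattern", 2L)
  })

  # 120 eligibility failures (code invalidated)
  fail_pattern <- rep(1:3, length.out = 120)
  inelig <- purrr::map_dfr(seq_len(120), function(k) {
    screen <- c(fail_pattern[k] != 1, fail_pattern[k] != 2,
                fail_pattern[k] != 3)
    blank_row(extra_codes[24 + k], emails[366 + k], base_dob[366 + k],
              extra_day[24 + k], "ineligible", 1L,
              screen = screen, completed = FALSE, devices = c(NA, NA, NA),
              q1 = NA_integer_, q2 = NA_integer_)
  })

  # 22 incomplete questionnaires
  incomplete <- purrr::map_dfr(seq_len(22), function(k) {
    blank_row(extra_codes[144 + k], emails[486 + k], base_dob[490 + k],
              extra_day[144 + k], "incomplete", 1L,
              completed = FALSE, devices = c(NA, NA, NA),
              q1 = NA_integer_, q2 = NA_integer_)
  })

  roster <- bind_rows(rows, blocked, manual, inelig, incomplete) %>%
    arrange(.data$day, .data$.priority, dplyr::desc(.data$.kind == "seed")) %>%
    mutate(attempt_id = row_number())
  truth <- select(roster, "attempt_id", truth_kind = ".kind",
                  truth_person_id = ".person")
  roster <- roster %>%
    select("attempt_id", "coupon_code", "email", "dob", "day",
           "used_ends_12mo", "age_ok", "resident", "completed",
           "device_ecig", "device_htp", "device_vape",
           "q1_network", "q2_network", "age_group", "sex", "zone",
           "ever_cigarette")

  ## --- ledger --------------------------------------------------------------
  code_to_attempt <- setNames(roster$attempt_id, roster$coupon_code)
  all_codes <- as.vector(t(codes)) # participant order, 3 codes each
  issuer_of <- rep(pid, each = 3L)
  status <- rep("unused", length(all_codes))
  used_codes <- c(enroll_code[13:n_part], extra_codes)
  status[all_codes %in% used_codes] <- "used"
  status[all_codes %in% extra_codes[25:144]] <- "invalidated" # ineligible
  first_use <- code_to_attempt[all_codes]
  ledger <- bind_rows(
    tibble(code = sprintf("SEED%02d", 1:12), issuer_id = "STUDY",
           issuer_dob = as.Date(NA), status = "used", issued_day = 0L,
           used_day = 0L,
           used_by = as.integer(code_to_attempt[sprintf("SEED%02d", 1:12)])),
    tibble(code = all_codes, issuer_id = issuer_of,
           issuer_dob = part_dob[match(issuer_of, pid)],
           status = status,
           issued_day = day[match(issuer_of, pid)],
           used_day = ifelse(status == "unused", NA_integer_,
                             roster$day[first_use]),
           used_by = ifelse(status == "unused", NA_integer_,
                            as.integer(first_use)))
  )

  structure(list(roster = roster, ledger = ledger, forest = forest,
                 truth = truth),
            class = "webrds_fixture")
}

#' @export
print.webrds_fixture <- function(x, ...) {
  cat("<webrds_fixture>  attempts:", nrow(x$roster),
      " participants:", nrow(x$forest),
      " coupons:", nrow(x$ledger), "\n")
  invisible(x)
}
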