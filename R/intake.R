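## Intake cleaning: the multistep verification funnel that turns a raw
## attempt roster into an analysis-ready participant roster, with an audit
## trail of every removal.

# --- email normalization ----------------------------------------------------
# Manual-stage normalization, fixed order: lowercase -> strip "+tag" ->
# tokenize local part on "." / "_" -> strip trailing digits per token ->
# drop empty tokens. Two comparison keys are derived: tokens in original
# order (catches separator toggles and numeric variants) and tokens sorted
# (additionally catches first/last-name inversions).

email_parts <- function(x) {
  x <- tolower(trimws(x))
  list(local = sub("@.*$", "", x), domain = sub("^[^@]*@", "", x))
}

email_tokens <- function(x) {
  p <- email_parts(x)
  local <- sub("\\+.*$", "", p$local)
  toks <- strsplit(local, "[._]")
  toks <- lapply(toks, function(t) {
    t <- sub("[0-9]+$", "", t)
    t[nzchar(t)]
  })
  list(tokens = toks, domain = p$domain)
}

email_key_ordered <- function(x) {
  et <- email_tokens(x)
  paste0(vapply(et$tokens, paste, "", collapse = ""), "@", et$domain)
}

email_key_sorted <- function(x) {
  et <- email_tokens(x)
  paste0(vapply(et$tokens, function(t) paste(sort(t), collapse = ""), ""),
         "@", et$domain)
}

norm_email_exact <- function(x) tolower(trimws(x))

valid_email <- function(x) {
  !is.na(x) & grepl("^[^@[:space:]]+@[^@[:space:]]+$", x)
}

#' Automatic blocking of repeated access attempts
#'
#' Reproduces the data-collection system's first filter: an attempt is
#' blocked if its invitation code was already used by any earlier attempt,
#' or if its (lowercased) email address or date of birth exactly matches an
#' earlier *kept* attempt. First arrival wins. Rows with a malformed email
#' or missing date of birth are routed to a quarantine list rather than
#' silently dropped.
#'
#' @param roster Attempt roster tibble ordered by `attempt_id` (arrival
#'   order); needs `attempt_id`, `coupon_code`, `email`, `dob`.
#' @param keys Which identifiers trigger the block: any subset of
#'   `c("coupon", "email", "dob")`.
#' @return List with `kept`, `removed` (plus `reason`), and `quarantined`
#'   tibbles.
#' @export
block_automatic <- function(roster, keys = c("coupon", "email", "dob")) {
  keys <- match.arg(keys, c("coupon", "email", "dob"), several.ok = TRUE)
  n <- nrow(roster)
  reason <- rep(NA_character_, n)
  quarantined <- !valid_email(roster$email) | is.na(roster$dob)
  emails <- norm_email_exact(roster$email)
  dobs <- as.character(roster$dob)
  codes <- as.character(roster$coupon_code)
  seen_codes <- new.env(hash = TRUE)
  kept_emails <- new.env(hash = TRUE)
  kept_dobs <- new.env(hash = TRUE)
  for (i in seq_len(n)) {
    if (quarantined[i]) next
    if ("coupon" %in% keys && !is.null(seen_codes[[codes[i]]])) {
      reason[i] <- "repeated_coupon"
    } else if ("email" %in% keys && !is.null(kept_emails[[emails[i]]])) {
      reason[i] <- "repeated_email"
    } else if ("dob" %in% keys && !is.null(kept_dobs[[dobs[i]]])) {
      reason[i] <- "repeated_dob"
    }
    if ("coupon" %in% keys) assign(codes[i], TRUE, envir = seen_codes)
    if (is.na(reason[i])) {
      assign(emails[i], TRUE, envir = kept_emails)
      assign(dobs[i], TRUE, envir = kept_dobs)
    }
  }
  removed <- !is.na(reason)
  list(
    kept = roster[!removed & !quarantined, , drop = FALSE],
    removed = mutate(roster[removed, , drop = FALSE],
                     reason = reason[removed]),
    quarantined = roster[quarantined, , drop = FALSE]
  )
}

#' Manual-pattern duplicate and self-recruitment detection
#'
#' Implements the manual review stage as three deterministic rules applied
#' in arrival order against already-kept attempts:
#' \describe{
#'   \item{token match}{after normalization, the sorted local-part tokens
#'     equal a kept attempt's — reason `token_inversion` when the token
#'     order differs, `numeric_variant` when only digits/separators differ;}
#'   \item{similar email + close DOB}{normalized edit distance at most
#'     `similarity_threshold` *and* date of birth within `dob_window` days
#'     of the kept attempt — reason `similar_email_dob`;}
#'   \item{self-recruitment}{the attempt's date of birth equals the
#'     recruiting participant's own (looked up through the coupon ledger)
#'     under a different email — reason `self_recruit`.}
#' }
#' Ties between kept attempts resolve to the earliest.
#'
#' @param roster Attempt roster (after automatic blocking).
#' @param ledger Optional coupon ledger with `code` and `issuer_dob`,
#'   enabling the self-recruitment rule.
#' @param similarity_threshold Normalized edit-distance threshold
#'   (default 0.2).
#' @param dob_window Days of date-of-birth proximity treated as
#'   "implausibly similar" (default 1).
#' @return List with `kept` and `removed` (with `reason`, `matched_attempt`).
#' @export
flag_manual_patterns <- function(roster, ledger = NULL,
                                 similarity_threshold = 0.2,
                                 dob_window = 1) {
  n <- nrow(roster)
  reason <- rep(NA_character_, n)
  matched <- rep(NA_integer_, n)
  key_sorted <- email_key_sorted(roster$email)
  key_ordered <- email_key_ordered(roster$email)
  local_key <- sub("@.*$", "", key_ordered)
  domain <- sub("^[^@]*@", "", key_ordered)
  dob_num <- as.numeric(roster$dob)
  issuer_dob <- rep(NA_real_, n)
  if (!is.null(ledger)) {
    idx <- match(roster$coupon_code, ledger$code)
    issuer_dob <- as.numeric(ledger$issuer_dob[idx])
  }
  kept <- integer(0)
  for (i in seq_len(n)) {
    hit <- match(key_sorted[i], key_sorted[kept])
    if (!is.na(hit)) {
      j <- kept[hit]
      reason[i] <- if (identical(key_ordered[i], key_ordered[j])) {
        "numeric_variant"
      } else {
        "token_inversion"
      }
      matched[i] <- roster$attempt_id[j]
      next
    }
    if (!is.na(issuer_dob[i]) && !is.na(dob_num[i]) &&
        dob_num[i] == issuer_dob[i]) {
      reason[i] <- "self_recruit"
      next
    }
    if (length(kept)) {
      # distance on the normalized local part (a mismatch in domain counts
      # one edit), scaled by the longer local part
      d <- as.vector(adist(local_key[i], local_key[kept])) +
        (domain[i] != domain[kept])
      nd <- d / pmax(nchar(local_key[i]), nchar(local_key[kept]))
      close <- which(nd <= similarity_threshold &
                       abs(dob_num[i] - dob_num[kept]) <= dob_window)
      if (length(close)) {
        j <- kept[close[1]] # earliest kept wins ties
        reason[i] <- "similar_email_dob"
        matched[i] <- roster$attempt_id[j]
        next
      }
    }
    kept <- c(kept, i)
  }
  removed <- !is.na(reason)
  list(
    kept = roster[!removed, , drop = FALSE],
    removed = mutate(roster[removed, , drop = FALSE],
                     reason = reason[removed],
                     matched_attempt = matched[removed])
  )
}

#' Eligibility screen
#'
#' An attempt is eligible only if all three screening answers (ENDS use in
#' the past 12 months, age at least 15, residence) are affirmative; missing
#' answers are treated conservatively as ineligible. The invitation code of
#' an ineligible attempt is invalidated in the ledger and cannot be reused.
#'
#' @param roster Attempt roster.
#' @param ledger Optional coupon ledger; returned with ineligible attempts'
#'   codes marked `invalidated`.
#' @return List with `eligible`, `ineligible` (with `reason`), and `ledger`.
#' @export
screen_eligibility <- function(roster, ledger = NULL) {
  a1 <- roster$used_ends_12mo %in% TRUE
  a2 <- roster$age_ok %in% TRUE
  a3 <- roster$resident %in% TRUE
  miss <- is.na(roster$used_ends_12mo) | is.na(roster$age_ok) |
    is.na(roster$resident)
  ok <- a1 & a2 & a3
  reason <- ifelse(miss, "missing_screen", "failed_screen")
  if (!is.null(ledger)) {
    bad_codes <- roster$coupon_code[!ok]
    ledger$status[ledger$code %in% bad_codes] <- "invalidated"
  }
  list(
    eligible = roster[ok, , drop = FALSE],
    ineligible = mutate(roster[!ok, , drop = FALSE], reason = reason[!ok]),
    ledger = ledger
  )
}

#' Device-use consistency check
#'
#' Completed, eligible records that nevertheless carry no affirmative
#' device-use field (electronic cigarette, heated tobacco, vaporizer) are
#' excluded from analysis. Excluded participants remain in the recruitment
#' forest: their ties are real and are retained for generating the
#' recruitment network.
#'
#' @param roster Valid (deduplicated, eligible, completed) roster.
#' @return List with `analysis` and `excluded` tibbles.
#' @export
check_consistency <- function(roster) {
  any_device <- (roster$device_ecig %in% TRUE) |
    (roster$device_htp %in% TRUE) | (roster$device_vape %in% TRUE)
  list(
    analysis = roster[any_device, , drop = FALSE],
    excluded = mutate(roster[!any_device, , drop = FALSE],
                      reason = "inconsistent_device_fields")
  )
}

#' Run the full intake-cleaning funnel
#'
#' Applies, in order: automatic blocking (repeated code/email/DOB), manual
#' pattern review (email similarity, self-recruitment), the eligibility
#' screen, the completeness filter, and the device-consistency check —
#' mirroring the narrative order of the verification process. Returns the
#' analysis roster, a removal audit trail, and a funnel report whose
#' percentages recompute exactly from the counts.
#'
#' @param roster Raw attempt roster in arrival order.
#' @param ledger Optional coupon ledger (enables self-recruitment lookup and
#'   code invalidation).
#' @param similarity_threshold,dob_window Passed to
#'   [flag_manual_patterns()].
#' @param keys Passed to [block_automatic()].
#' @return A `webrds_funnel` list: `analysis`, `valid`, `removals`
#'   (attempt_id, stage, reason), `quarantined`, `report`
#'   (a `webrds_funnel_report`), and the updated `ledger`.
#' @export
intake_funnel <- function(roster, ledger = NULL,
                          similarity_threshold = 0.2, dob_window = 1,
                          keys = c("coupon", "email", "dob")) {
  stopifnot(nrow(roster) == 0 || !is.unsorted(roster$attempt_id))
  auto <- block_automatic(roster, keys = keys)
  man <- flag_manual_patterns(auto$kept, ledger = ledger,
                              similarity_threshold = similarity_threshold,
                              dob_window = dob_window)
  scr <- screen_eligibility(man$kept, ledger = ledger)
  complete <- scr$eligible[scr$eligible$completed %in% TRUE, , drop = FALSE]
  incomplete <- scr$eligible[!(scr$eligible$completed %in% TRUE), , drop = FALSE]
  cons <- check_consistency(complete)
  removals <- bind_rows(
    tibble(attempt_id = auto$removed$attempt_id, stage = "automatic",
           reason = auto$removed$reason),
    tibble(attempt_id = auto$quarantined$attempt_id, stage = "quarantine",
           reason = "malformed_identity"),
    tibble(attempt_id = man$removed$attempt_id, stage = "manual",
           reason = man$removed$reason),
    tibble(attempt_id = scr$ineligible$attempt_id, stage = "eligibility",
           reason = scr$ineligible$reason),
    tibble(attempt_id = incomplete$attempt_id, stage = "completeness",
           reason = "incomplete"),
    tibble(attempt_id = cons$excluded$attempt_id, stage = "consistency",
           reason = "inconsistent_device_fields")
  )
  report <- build_funnel_report(
    n_attempts = nrow(roster),
    n_quarantined = nrow(auto$quarantined),
    n_blocked_auto = nrow(auto$removed),
    n_invalid_manual = nrow(man$removed),
    n_ineligible = nrow(scr$ineligible),
    n_incomplete = nrow(incomplete),
    n_valid = nrow(complete),
    n_inconsistent = nrow(cons$excluded)
  )
  structure(
    list(analysis = cons$analysis, valid = complete, removals = removals,
         quarantined = auto$quarantined, report = report,
         ledger = scr$ledger),
    class = "webrds_funnel"
  )
}

#' Build a funnel report from stage counts
#'
#' @param n_attempts,n_quarantined,n_blocked_auto,n_invalid_manual,n_ineligible,n_incomplete,n_valid,n_inconsistent
#'   Stage counts.
#' @return A `webrds_funnel_report` list of counts plus half-up one-decimal
#'   percentages (`pct_invalid_total` and `pct_incomplete` are over attempts,
#'   `pct_inconsistent` over valid records).
#' @export
build_funnel_report <- function(n_attempts, n_quarantined = 0,
                                n_blocked_auto = 0, n_invalid_manual = 0,
                                n_ineligible = 0, n_incomplete = 0,
                                n_valid = 0, n_inconsistent = 0) {
  accounted <- n_quarantined + n_blocked_auto + n_invalid_manual +
    n_ineligible + n_incomplete + n_valid
  if (accounted != n_attempts) {
    abort(paste0("funnel stages do not account for every attempt (",
                 accounted, " vs ", n_attempts, "): pipeline bug."))
  }
  n_invalid_total <- n_blocked_auto + n_invalid_manual + n_ineligible
  rep <- list(
    n_attempts = n_attempts,
    n_quarantined = n_quarantined,
    n_blocked_auto = n_blocked_auto,
    n_invalid_manual = n_invalid_manual,
    n_ineligible = n_ineligible,
    n_invalid_total = n_invalid_total,
    n_incomplete = n_incomplete,
    n_valid = n_valid,
    n_inconsistent = n_inconsistent,
    n_analysis = n_valid - n_inconsistent,
    pct_invalid_total = pct1(n_invalid_total, n_attempts),
    pct_incomplete = pct1(n_incomplete, n_attempts),
    pct_valid = pct1(n_valid, n_attempts),
    pct_inconsistent = pct1(n_inconsistent, n_valid),
    pct_analysis = pct1(n_valid - n_inconsistent, n_attempts)
  )
  structure(rep, class = "webrds_funnel_report")
}

#' @export
print.webrds_funnel_report <- function(x, ...) {
  cat("<funnel report>\n")
  cat(sprintf("  attempts                 %5d\n", x$n_attempts))
  if (x$n_quarantined)
    cat(sprintf("  quarantined (malformed)  %5d\n", x$n_quarantined))
  cat(sprintf("  invalid / ineligible     %5d  (%.1f%%)\n",
              x$n_invalid_total, x$pct_invalid_total))
  cat(sprintf("    automatic blocks       %5d\n", x$n_blocked_auto))
  cat(sprintf("    manual patterns        %5d\n", x$n_invalid_manual))
  cat(sprintf("    failed screen          %5d\n", x$n_ineligible))
  cat(sprintf("  incomplete               %5d  (%.1f%%)\n",
              x$n_incomplete, x$pct_incomplete))
  cat(sprintf("  valid participants       %5d\n", x$n_valid))
  cat(sprintf("  consistency exclusions   %5d  (%.1f%%)\n",
              x$n_inconsistent, x$pct_inconsistent))
  cat(sprintf("  analyzed                 %5d\n", x$n_analysis))
  invisible(x)
}

#' @export
tidy.webrds_funnel_report <- function(x, ...) {
  tibble(
    stage = c("attempts", "quarantined", "blocked_automatic",
              "invalid_manual", "ineligible", "incomplete", "valid",
              "inconsistent", "analysis"),
    n = c(x$n_attempts, x$n_quarantined, x$n_blocked_auto,
          x$n_invalid_manual, x$n_ineligible, x$n_incomplete, x$n_valid,
          x$n_inconsistent, x$n_analysis)
  )
}
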