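# Screening strategies and the overlay of screening on simulated histories:
# invitations, attendance, test positivity, biopsy, screen detection, lead
# time, overdiagnosis.

#' Enumerate the PSA screening strategy grid
#'
#' The full deduplicated grid: interval strategies start at 50-55, use
#' intervals of 1, 2, 3, 4 or 8 years, stop by age 69 and have at least two
#' tests; once-in-a-lifetime tests are offered at each age 50-69. With the
#' default bounds this yields 230 strategies. Strategy ids read
#' `"{start}-{last}@{interval}"`, singles `"{age}@once"`.
#'
#' @param start_range integer range of start ages for interval strategies.
#' @param stop_cap latest allowed test age.
#' @param intervals integer screening intervals (years).
#' @param single_ages ages at which a single lifetime test is offered.
#' @return tibble with `strategy_id`, `start_age`, `interval` (NA for
#'   singles), `last_test_age`, `n_tests` and a `test_ages` list-column.
#' @examples
#' nrow(enumerate_strategies())  # 230
#' @export
enumerate_strategies <- function(start_range = 50:55, stop_cap = 69,
                                 intervals = c(1, 2, 3, 4, 8),
                                 single_ages = 50:69) {
  rows <- list()
  for (s in start_range) {
    for (d in intervals) {
      lasts <- seq(s + d, stop_cap, by = d)
      lasts <- lasts[lasts <= stop_cap]
      for (l in lasts) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          strategy_id = sprintf("%d-%d@%d", s, l, d),
          start_age = s, interval = d, last_test_age = l,
          test_ages = list(as.numeric(seq(s, l, by = d)))
        )
      }
    }
  }
  for (a in single_ages) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      strategy_id = sprintf("%d@once", a),
      start_age = a, interval = NA_real_, last_test_age = a,
      test_ages = list(as.numeric(a))
    )
  }
  out <- dplyr::distinct(dplyr::bind_rows(rows), strategy_id, .keep_all = TRUE)
  out$n_tests <- lengths(out$test_ages)
  out[c("strategy_id", "start_age", "interval", "last_test_age", "n_tests",
        "test_ages")]
}

#' Screening process parameters
#'
#' @param attendance probability of attending each invitation (default 0.80).
#' @param biopsy_compliance probability of biopsy after a positive test
#'   (default 0.90).
#' @param biopsy_sensitivity probability a biopsy finds the cancer
#'   (default 0.90).
#' @param test_positivity probability of PSA at or above the cutoff given
#'   each of the 18 preclinical states; the default rises with tumour stage
#'   and extent (episode-sensitivity representation of a 3 ng/mL cutoff).
#' @param psa_cutoff_ng_ml documentation field (default 3).
#' @param attendance_mode `"per_invitation"` (independent draw each
#'   invitation, the default) or `"never_attender"` (a fixed fraction of men
#'   attends every invitation, the rest none).
#' @return list of class `screening_params`.
#' @export
screening_params <- function(attendance = 0.80, biopsy_compliance = 0.90,
                             biopsy_sensitivity = 0.90,
                             test_positivity = default_test_positivity(),
                             psa_cutoff_ng_ml = 3,
                             attendance_mode = c("per_invitation", "never_attender")) {
  probs <- c(attendance, biopsy_compliance, biopsy_sensitivity, test_positivity)
  if (any(probs < 0 | probs > 1)) {
    stop("screening probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(test_positivity) != 18L) {
    stop("test_positivity must have one entry per preclinical state", call. = FALSE)
  }
  structure(
    list(attendance = attendance, biopsy_compliance = biopsy_compliance,
         biopsy_sensitivity = biopsy_sensitivity,
         test_positivity = test_positivity,
         psa_cutoff_ng_ml = psa_cutoff_ng_ml,
         attendance_mode = match.arg(attendance_mode)),
    class = "screening_params"
  )
}

#' @rdname screening_params
#' @export
default_test_positivity <- function() {
  st <- disease_stages()
  p <- c(0.55, 0.75, 0.90)[st$t_i] * c(1, 1.05, 1.1)[st$g_i]
  p[st$e_i == 2] <- pmin(1, p[st$e_i == 2] * 1.1)
  pmin(p, 0.99)
}

# Vectorised overlay of one strategy on a cohort: walks test ages in order,
# drawing attendance / positivity / compliance / sensitivity from
# age-slotted counter streams so a larger test-age set can only detect more.
#' @keywords internal
screen_overlay <- function(cohort, test_ages, sparams) {
  p <- cohort$persons
  seed <- cohort$master_seed
  n <- nrow(p)
  ids <- p$person_id
  det_age <- rep(NA_real_, n)
  det_state <- rep(NA_integer_, n)
  n_inv <- numeric(length(test_ages))
  n_att <- numeric(length(test_ages))
  never <- if (sparams$attendance_mode == "never_attender") {
    runif_ctr(seed, ids, .SLOT$never_att) >= sparams$attendance
  } else rep(FALSE, n)

  for (ti in seq_along(test_ages)) {
    a <- test_ages[ti]
    j <- a - 50L
    col <- match(a, cohort$screen_ages)
    if (is.na(col)) stop("test age outside cohort screen_ages", call. = FALSE)
    elig <- p$ocd_age > a & (is.na(p$cdx_age) | p$cdx_age > a) & is.na(det_age)
    n_inv[ti] <- sum(elig)
    att <- if (sparams$attendance_mode == "never_attender") {
      elig & !never
    } else {
      elig & runif_ctr(seed, ids, .SLOT$att + j) < sparams$attendance
    }
    n_att[ti] <- sum(att)
    cand <- which(att & cohort$state_mat[, col] > 0L)
    if (length(cand)) {
      s <- cohort$state_mat[cand, col]
      keep <- runif_ctr(seed, ids[cand], .SLOT$pos + j) < sparams$test_positivity[s]
      cand <- cand[keep]; s <- s[keep]
      keep <- runif_ctr(seed, ids[cand], .SLOT$cmp + j) < sparams$biopsy_compliance
      cand <- cand[keep]; s <- s[keep]
      keep <- runif_ctr(seed, ids[cand], .SLOT$sens + j) < sparams$biopsy_sensitivity
      cand <- cand[keep]; s <- s[keep]
      det_age[cand] <- a
      det_state[cand] <- s
    }
  }
  list(det_age = det_age, det_state = det_state,
       test_ages = test_ages, n_invitations = n_inv, n_tests = n_att)
}

#' Overlay a screening strategy on one man's history
#'
#' Walks the strategy's test ages in order. At each age before the man's
#' clinical diagnosis or death he is invited; attendance, test positivity
#' given his preclinical state, biopsy compliance and biopsy sensitivity are
#' Bernoulli draws from dedicated screening substreams, so the underlying
#' history is unchanged. Screening stops at the first screen detection. A
#' test scheduled exactly at the clinical-diagnosis or death age does not
#' take place.
#'
#' @param history a [generate_history()] result (same `master_seed` lineage).
#' @param strategy one row of [enumerate_strategies()] (or a list with
#'   `test_ages`).
#' @param params [screening_params()].
#' @param master_seed the run's master seed.
#' @return object of class `screened_history`: list with `base`,
#'   `invitations`, `tests_attended`, `screen_dx_age`, `screen_dx_state`,
#'   `stage_at_screen_dx`, `lead_time`, `overdiagnosed`.
#' @export
apply_screening <- function(history, strategy, params, master_seed) {
  test_ages <- if (is.list(strategy$test_ages)) strategy$test_ages[[1]] else strategy$test_ages
  if (!length(test_ages)) stop("strategy has no test ages", call. = FALSE)
  id <- history$person_id
  e <- history$state_entries
  invitations <- 0L; attended <- 0L
  det_age <- NA_real_; det_state <- NA_integer_
  never <- if (params$attendance_mode == "never_attender") {
    runif_ctr(master_seed, id, .SLOT$never_att) >= params$attendance
  } else FALSE

  for (a in test_ages) {
    j <- a - 50L
    if (a >= history$other_cause_death_age) break
    if (!is.na(history$clinical_dx_age) && a >= history$clinical_dx_age) break
    invitations <- invitations + 1L
    attends <- if (params$attendance_mode == "never_attender") !never
               else runif_ctr(master_seed, id, .SLOT$att + j) < params$attendance
    if (!attends) next
    attended <- attended + 1L
    hit <- which(e$age <= a & a < e$exit)
    if (!length(hit)) next
    s <- e$state[hit[1]]
    if (runif_ctr(master_seed, id, .SLOT$pos + j) >= params$test_positivity[s]) next
    if (runif_ctr(master_seed, id, .SLOT$cmp + j) >= params$biopsy_compliance) next
    if (runif_ctr(master_seed, id, .SLOT$sens + j) >= params$biopsy_sensitivity) next
    det_age <- as.numeric(a); det_state <- s
    break
  }

  sh <- structure(
    list(base = history, invitations = invitations, tests_attended = attended,
         screen_dx_age = det_age, screen_dx_state = det_state,
         stage_at_screen_dx = if (!is.na(det_state)) disease_stages()[det_state, 1:4] else NULL,
         lead_time = if (!is.na(det_age) && !is.na(history$clinical_dx_age))
           history$clinical_dx_age - det_age else NA_real_,
         overdiagnosed = NA),
    class = "screened_history"
  )
  if (!is.na(det_age)) sh$overdiagnosed <- classify_overdiagnosis(sh)
  sh
}

#' Classify a screen detection as overdiagnosis
#'
#' `TRUE` iff the cancer would not have been clinically diagnosed during the
#' man's lifetime in the absence of screening: the counterfactual clinical
#' diagnosis is absent or falls at or after his other-cause death age.
#'
#' @param sh a `screened_history` with a screen detection.
#' @return logical.
#' @export
classify_overdiagnosis <- function(sh) {
  if (is.na(sh$screen_dx_age)) {
    stop("classify_overdiagnosis() requires a screen detection", call. = FALSE)
  }
  base <- sh$base
  is.infinite(base$cdx_latent) || base$cdx_latent >= base$other_cause_death_age
}
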