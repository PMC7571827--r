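# Per-strategy aggregation of paired person-level results into per-1000-men
# harms, benefits and discounted economics.

#' Back-calculate biopsy counts from detections
#'
#' Total biopsies implied by the numbers of screen-detected and clinically
#' detected cancers and the mean positive predictive values of a biopsy in
#' the screened and clinical settings:
#' `screen_detected / ppv_screen + clinically_detected / ppv_clinical`.
#'
#' @param screen_detected,clinically_detected detection counts.
#' @param ppv_screen PPV of a biopsy after a positive screen (default 0.227).
#' @param ppv_clinical PPV of a diagnostic biopsy at clinical presentation
#'   (default 0.358).
#' @return number of biopsies.
#' @examples
#' count_biopsies(227, 0)  # 1000
#' @export
count_biopsies <- function(screen_detected, clinically_detected,
                           ppv_screen = 0.227, ppv_clinical = 0.358) {
  if (ppv_screen <= 0 || ppv_screen > 1 || ppv_clinical <= 0 || ppv_clinical > 1) {
    stop("PPVs must lie in (0, 1]", call. = FALSE)
  }
  screen_detected / ppv_screen + clinically_detected / ppv_clinical
}

# Event stream for a set of diagnoses (either arm). Each row: person, the
# utility state entered (qstate) and/or cost item incurred (citem), entry
# age, multiplicity w, and the person's death age in that arm (for duration
# truncation and for dropping costs after death).
#' @keywords internal
dx_event_stream <- function(person, dx_age, state, treatment, death_age,
                            pc_death_age, as_switch, ppv, utility_table) {
  d_pall <- utility_table$duration_years[utility_table$state == "palliative"]
  d_term <- utility_table$duration_years[utility_table$state == "terminal"]
  rows <- list()
  add <- function(sel, qstate, citem, age, w = 1) {
    if (!any(sel)) return(invisible())
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      person = person[sel], qstate = qstate, citem = citem,
      age = age[sel], w = if (length(w) == 1) w else w[sel],
      death = death_age[sel]
    )
  }
  all <- rep(TRUE, length(person))
  add(all, "biopsy", "biopsy", dx_age, 1 / ppv)
  add(all, "cancer_diagnosis", "staging", dx_age)
  add(all, NA_character_, "follow_up", dx_age)

  # curative-intent blocks start at diagnosis (RP/RT) or at the active-
  # surveillance switch time (switchers are modelled as receiving RP)
  t_rp <- ifelse(treatment == "RP", dx_age,
                 ifelse(treatment == "AS" & as_switch <= 7, dx_age + as_switch, NA))
  is_rp <- !is.na(t_rp)
  add(is_rp, "prostatectomy", "rp", t_rp)
  add(is_rp, "post_rp", NA_character_, t_rp + 1 / 6)
  add(is_rp, "postrecovery", NA_character_, t_rp + 1)
  is_rt <- treatment == "RT"
  add(is_rt, "radiation", "rt", dx_age)
  add(is_rt, "post_rt", NA_character_, dx_age + 1 / 6)
  add(is_rt, "postrecovery", NA_character_, dx_age + 1)
  is_as <- treatment == "AS"
  add(is_as, "active_surveillance", "as", dx_age)

  died_pc <- !is.na(pc_death_age)
  if (any(died_pc)) {
    t_term <- pmax(dx_age, pc_death_age - d_term)
    t_pall <- pmax(dx_age, pc_death_age - d_term - d_pall)
    add(died_pc, "palliative", NA_character_, t_pall)
    add(died_pc, "terminal", "advanced", t_term)
  }
  if (!length(rows)) return(empty_event_stream())
  dplyr::bind_rows(rows)
}

#' @keywords internal
empty_event_stream <- function() {
  tibble::tibble(person = integer(0), qstate = character(0),
                 citem = character(0), age = numeric(0), w = numeric(0),
                 death = numeric(0))
}

# Discounted components of an event stream:
#   D[state] = sum w * disc(entry age) * truncated duration
#   C[item]  = sum w * disc(entry age), for events incurred before death
#' @keywords internal
econ_components <- function(events, utility_table, cost_table, dspec) {
  D <- stats::setNames(numeric(nrow(utility_table)), utility_table$state)
  C <- stats::setNames(numeric(nrow(cost_table)), cost_table$item)
  if (!nrow(events)) return(list(D = D, C = C))
  disc <- (1 + dspec$annual_rate)^(-(pmax(events$age, dspec$reference_age) -
                                       dspec$reference_age))
  qi <- match(events$qstate, utility_table$state)
  has_q <- !is.na(qi)
  if (any(has_q)) {
    d_full <- utility_table$duration_years[qi[has_q]]
    d_eff <- pmax(0, pmin(d_full, events$death[has_q] - events$age[has_q]))
    D_add <- rowsum(events$w[has_q] * disc[has_q] * d_eff, qi[has_q])
    D[as.integer(rownames(D_add))] <- D[as.integer(rownames(D_add))] + D_add[, 1]
  }
  ci <- match(events$citem, cost_table$item)
  has_c <- !is.na(ci) & events$age < events$death
  if (any(has_c)) {
    C_add <- rowsum(events$w[has_c] * disc[has_c], ci[has_c])
    C[as.integer(rownames(C_add))] <- C[as.integer(rownames(C_add))] + C_add[, 1]
  }
  list(D = D, C = C)
}

# QALY loss and total cost implied by stored components and the (possibly
# perturbed) utility / cost tables.
#' @keywords internal
loss_from_components <- function(D, utility_table,
                                 u_col = "utility") {
  u <- stats::setNames(utility_table[[u_col]], utility_table$state)
  sum((1 - u[names(D)]) * D)
}

#' @keywords internal
cost_from_components <- function(C, cost_table, cost_col = "unit_cost_eur") {
  cc <- stats::setNames(cost_table[[cost_col]], cost_table$item)
  sum(cc[names(C)] * C)
}

# Base (no-screen) arm event stream for a cohort.
#' @keywords internal
base_event_stream <- function(cohort, ppv_clinical, utility_table) {
  p <- cohort$persons
  dx <- which(!is.na(p$cdx_age))
  if (!length(dx)) return(empty_event_stream())
  dx_event_stream(
    person = p$person_id[dx], dx_age = p$cdx_age[dx], state = p$dx_state[dx],
    treatment = p$treatment[dx], death_age = p$death_age[dx],
    pc_death_age = ifelse(p$death_cause[dx] == "pc", p$pc_death_latent[dx], NA_real_),
    as_switch = p$as_switch[dx], ppv = ppv_clinical,
    utility_table = utility_table
  )
}

# Full per-strategy accounting against a cohort: detections, cure, deaths,
# life-years, discounted components. Returns the outcome row plus the
# screen-arm component vectors.
#' @keywords internal
aggregate_strategy <- function(cohort, overlay, strategy_id, sparams, econ,
                               base) {
  p <- cohort$persons
  seed <- cohort$master_seed
  n <- cohort$n
  per1000 <- 1000 / n

  det <- which(!is.na(overlay$det_age))
  det_age <- overlay$det_age[det]
  det_state <- overlay$det_state[det]
  ids <- p$person_id[det]

  over <- is.infinite(p$cdx_latent[det]) | p$cdx_latent[det] >= p$ocd_age[det]
  relevant <- !over
  lead <- p$cdx_latent[det] - det_age
  cured <- rep(FALSE, length(det))
  if (any(relevant)) {
    u <- runif_ctr(seed, ids[relevant], .SLOT$cure)
    cured[relevant] <- u < cure_probability(lead[relevant], cohort$survival$cure)
  }

  # death ages in the screened arm (only cured men change)
  death_screen <- p$death_age
  death_screen[det[cured]] <- p$ocd_age[det[cured]]
  pc_death_screen_flag <- p$death_cause == "pc"
  pc_death_screen_flag[det[cured]] <- FALSE

  # life-years gained (cured men live from their counterfactual pc death to
  # their other-cause death)
  gain_lo <- p$death_age[det[cured]]
  gain_hi <- p$ocd_age[det[cured]]
  lyg_undisc <- sum(gain_hi - gain_lo)
  lyg_disc <- sum(discounted_years(gain_lo, gain_hi, econ$dspec))

  # screened-arm events: base events minus detected men's base rows, plus
  # detected men's screen-pathway rows, plus the screening process itself
  treatment_screen <- if (length(det)) {
    allocate_treatment(det_age, det_state, cohort$policy, seed, ids = ids)
  } else character(0)
  as_switch <- -log(runif_ctr(seed, ids, .SLOT$as_switch)) /
    cohort$survival$as_switch_rate
  pc_death_det <- ifelse(relevant & !cured & p$pc_death_latent[det] < p$ocd_age[det],
                         p$pc_death_latent[det], NA_real_)
  det_events <- dx_event_stream(
    person = ids, dx_age = det_age, state = det_state,
    treatment = treatment_screen, death_age = death_screen[det],
    pc_death_age = pc_death_det, as_switch = as_switch,
    ppv = econ$ppv_screen, utility_table = econ$utility_table
  )
  removed <- base$events[base$events$person %in% ids, , drop = FALSE]

  # attended tests carry the attendance state and the PSA test cost;
  # every invitation carries the invitation cost
  screen_proc <- tibble::tibble(
    person = NA_integer_,
    qstate = c(rep("screening_attendance", length(overlay$test_ages)),
               rep(NA_character_, length(overlay$test_ages))),
    citem = c(rep("psa_test", length(overlay$test_ages)),
              rep("invitation", length(overlay$test_ages))),
    age = rep(overlay$test_ages, 2),
    w = c(overlay$n_tests, overlay$n_invitations),
    death = Inf
  )

  comp_removed <- econ_components(removed, econ$utility_table, econ$cost_table, econ$dspec)
  comp_det <- econ_components(det_events, econ$utility_table, econ$cost_table, econ$dspec)
  comp_proc <- econ_components(screen_proc, econ$utility_table, econ$cost_table, econ$dspec)
  D_screen <- base$comp$D - comp_removed$D + comp_det$D + comp_proc$D
  C_screen <- base$comp$C - comp_removed$C + comp_det$C + comp_proc$C

  loss_screen <- loss_from_components(D_screen, econ$utility_table)
  cost_screen <- cost_from_components(C_screen, econ$cost_table)

  n_cdx_base <- sum(!is.na(p$cdx_age))
  clin_det_screen <- n_cdx_base - sum(relevant)
  deaths_base <- sum(p$death_cause == "pc")
  deaths_screen <- sum(pc_death_screen_flag)

  row <- tibble::tibble(
    strategy_id = strategy_id,
    invitations = sum(overlay$n_invitations) * per1000,
    tests = sum(overlay$n_tests) * per1000,
    screen_detected = length(det) * per1000,
    clinically_detected = clin_det_screen * per1000,
    biopsies = count_biopsies(length(det), clin_det_screen,
                              econ$ppv_screen, econ$ppv_clinical) * per1000,
    overdiagnosed = sum(over) * per1000,
    overdiagnosis_pct = if (length(det)) 100 * sum(over) / length(det) else NA_real_,
    pc_deaths_screen_arm = deaths_screen * per1000,
    pc_deaths_noscreen_arm = deaths_base * per1000,
    pcm_reduction_pct = if (deaths_base > 0)
      100 * (1 - deaths_screen / deaths_base) else NA_real_,
    life_years_gained = lyg_undisc * per1000,
    life_years_gained_disc = lyg_disc * per1000,
    qaly_loss_screen = loss_screen * per1000,
    qaly_loss_noscreen = base$loss * per1000,
    qalys_gained = qalys_gained(lyg_disc * per1000,
                                loss_screen * per1000, base$loss * per1000),
    total_cost = cost_screen * per1000,
    net_cost = (cost_screen - base$cost) * per1000
  )
  list(row = row, D_screen = D_screen, C_screen = C_screen,
       lyg_disc = lyg_disc * per1000, lyg_undisc = lyg_undisc * per1000)
}
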