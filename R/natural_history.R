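# No-screening disease trajectories: onset, progression through the 18-state
# graph, clinical detection, competing other-cause death. The cohort kernel
# is fully vectorised; the per-person API (generate_history, stage_at) runs
# the same kernel for a single id, so a person is bit-identical whichever
# route produced them.

# Core vectorised history generator. Progression is simulated latently
# (beyond other-cause death) because overdiagnosis classification needs the
# counterfactual clinical-diagnosis age; observed fields are censored views.
#' @keywords internal
sim_histories <- function(params, life_table, ids, seed, screen_ages = 50:69) {
  k <- nh_kernel(params)
  n <- length(ids)
  nb <- length(k$onset_rates)

  ocd <- sample_other_cause_death(life_table, ids, seed, min_age = 50)

  # onset age by inversion of the piecewise-constant cumulative hazard
  E <- -log(runif_ctr(seed, ids, .SLOT$onset))
  band <- findInterval(E, k$onset_cumhaz)
  has_onset <- band <= nb
  onset_latent <- rep(Inf, n)
  bi <- band[has_onset]
  onset_latent[has_onset] <- k$onset_breaks[bi] +
    (E[has_onset] - k$onset_cumhaz[bi]) / k$onset_rates[bi]

  u_s <- runif_ctr(seed, ids, .SLOT$onset_state)
  onset_state <- ifelse(has_onset, findInterval(u_s, k$onset_state_cum) + 1L, NA_integer_)

  # progression / clinical detection: only people whose onset precedes death
  # can ever be screen-detected or clinically diagnosed
  active <- which(onset_latent < ocd)
  cur_state <- onset_state[active]
  cur_age <- onset_latent[active]
  cdx_latent <- rep(Inf, n)
  dx_state <- rep(NA_integer_, n)
  iv_person <- list(); iv_state <- list(); iv_entry <- list(); iv_exit <- list()
  max_deg <- ncol(k$dest)

  for (step in 0:6) {
    if (!length(active)) break
    s <- cur_state
    tot <- k$prog_total[s] + k$clin[s]
    u_h <- runif_ctr(seed, ids[active], .SLOT$prog_hold + 2 * step)
    hold <- ifelse(tot > 0, -log(u_h) / tot, Inf)
    new_age <- cur_age + hold

    iv_person[[step + 1L]] <- ids[active]
    iv_state[[step + 1L]] <- s
    iv_entry[[step + 1L]] <- cur_age
    iv_exit[[step + 1L]] <- new_age

    u_d <- runif_ctr(seed, ids[active], .SLOT$prog_dest + 2 * step)
    p_clin <- ifelse(tot > 0, k$clin[s] / tot, 0)
    absorbed <- tot == 0
    detect <- !absorbed & u_d < p_clin
    move <- !absorbed & !detect

    det_idx <- active[detect]
    cdx_latent[det_idx] <- new_age[detect]
    dx_state[det_idx] <- s[detect]

    if (any(move)) {
      v <- (u_d[move] - p_clin[move]) / (1 - p_clin[move])
      sm <- s[move]
      j <- rep(1L, sum(move))
      if (max_deg > 1) {
        for (cix in 1:(max_deg - 1)) j <- j + (v > k$cumw[cbind(sm, cix)])
      }
      cur_state <- k$dest[cbind(sm, j)]
      cur_age <- new_age[move]
      active <- active[move]
    } else {
      active <- integer(0)
    }
  }

  intervals <- tibble::tibble(
    person_id = unlist(iv_person, use.names = FALSE) %||% integer(0),
    state = as.integer(unlist(iv_state, use.names = FALSE) %||% integer(0)),
    entry = unlist(iv_entry, use.names = FALSE) %||% numeric(0),
    exit = unlist(iv_exit, use.names = FALSE) %||% numeric(0)
  )

  # latent preclinical occupancy at each integer screening age
  state_mat <- matrix(0L, n, length(screen_ages),
                      dimnames = list(NULL, screen_ages))
  if (nrow(intervals)) {
    row_of <- match(intervals$person_id, ids)
    for (jj in seq_along(screen_ages)) {
      a <- screen_ages[jj]
      hit <- intervals$entry <= a & a < intervals$exit
      state_mat[row_of[hit], jj] <- intervals$state[hit]
    }
  }

  persons <- tibble::tibble(
    person_id = ids,
    ocd_age = ocd,
    onset_latent = onset_latent,
    onset_state = onset_state,
    onset_age = ifelse(onset_latent < ocd, onset_latent, NA_real_),
    cdx_latent = cdx_latent,
    cdx_age = ifelse(cdx_latent < ocd, cdx_latent, NA_real_),
    dx_state = ifelse(cdx_latent < ocd, dx_state, NA_integer_)
  )
  list(persons = persons, intervals = intervals, state_mat = state_mat)
}

#' Simulate a no-screening cohort
#'
#' Generates `n` men entering alive and cancer-free at exact age 50, each with
#' an other-cause death age, a latent disease trajectory through the 18
#' preclinical states, a clinical diagnosis (if detection precedes death) and
#' a clinical-pathway prostate-cancer death age after treatment allocation.
#' Every draw is a pure function of `(master_seed, person_id)`, so the same
#' man is reproducible independently of cohort size, and screening overlays
#' share these histories unchanged (common random numbers).
#'
#' @param params natural-history parameters ([make_nh_fixture()]).
#' @param life_table life table ([make_life_table()]).
#' @param n cohort size.
#' @param master_seed integer master seed for the whole run.
#' @param policy treatment policy ([default_treatment_policy()]).
#' @param survival survival model ([default_survival_model()]).
#' @param screen_ages integer ages at which preclinical state is tabulated
#'   for later screening overlays.
#' @return an object of class `pc_cohort`: list with `persons` (one row per
#'   man), `intervals` (preclinical state spells), `state_mat`, and the
#'   inputs.
#' @examples
#' coh <- simulate_cohort(make_nh_fixture(), make_life_table(), 500, 1)
#' dplyr::count(coh$persons, diagnosed = !is.na(cdx_age))
#' @export
simulate_cohort <- function(params, life_table, n, master_seed,
                            policy = default_treatment_policy(),
                            survival = default_survival_model(),
                            screen_ages = 50:69) {
  stopifnot(n >= 1)
  sim <- sim_histories(params, life_table, seq_len(n), master_seed, screen_ages)
  sim$persons <- assign_clinical_outcomes(sim$persons, policy, survival, master_seed)
  structure(
    list(persons = sim$persons, intervals = sim$intervals,
         state_mat = sim$state_mat, params = params, life_table = life_table,
         policy = policy, survival = survival, master_seed = master_seed,
         n = n, screen_ages = screen_ages),
    class = "pc_cohort"
  )
}

#' @export
print.pc_cohort <- function(x, ...) {
  p <- x$persons
  cat("<pc_cohort> ", x$n, " men, master_seed ", x$master_seed, "\n", sep = "")
  cat("  onset before death: ", sum(!is.na(p$onset_age)),
      "; clinically diagnosed: ", sum(!is.na(p$cdx_age)),
      "; prostate-cancer deaths: ", sum(p$death_cause == "pc"), "\n", sep = "")
  invisible(x)
}

#' Generate one man's no-screening history
#'
#' Runs the cohort kernel for a single person id; the result is bit-identical
#' to the corresponding row of [simulate_cohort()] at the same master seed.
#'
#' @inheritParams simulate_cohort
#' @param person_id integer id.
#' @return object of class `person_history`: a list with
#'   `other_cause_death_age`, `onset_age` (NA if none before death),
#'   `state_entries` (tibble of `age`, `t_stage`, `gleason`, `extent`),
#'   `clinical_dx_age`, `stage_at_clinical_dx`, and latent counterfactual
#'   fields used by the screening overlay.
#' @export
generate_history <- function(params, life_table, person_id, master_seed) {
  sim <- sim_histories(params, life_table, as.integer(person_id), master_seed)
  p <- sim$persons[1, ]
  st <- disease_stages()
  iv <- sim$intervals
  entries <- tibble::tibble(
    age = iv$entry, state = iv$state,
    t_stage = st$t_stage[iv$state], gleason = st$gleason[iv$state],
    extent = st$extent[iv$state], exit = iv$exit
  )
  structure(
    list(
      person_id = as.integer(person_id),
      other_cause_death_age = p$ocd_age,
      onset_age = p$onset_age,
      state_entries = entries,
      clinical_dx_age = p$cdx_age,
      stage_at_clinical_dx = if (!is.na(p$dx_state)) st[p$dx_state, 1:4] else NULL,
      onset_latent = p$onset_latent,
      cdx_latent = p$cdx_latent,
      dx_state_latent = p$dx_state,
      master_seed = master_seed
    ),
    class = "person_history"
  )
}

#' @export
print.person_history <- function(x, ...) {
  cat("<person_history> id ", x$person_id,
      ", other-cause death at ", round(x$other_cause_death_age, 1), "\n", sep = "")
  if (is.na(x$onset_age)) {
    cat("  no preclinical onset before death\n")
  } else {
    cat("  onset at ", round(x$onset_age, 1), "; clinical dx ",
        if (is.na(x$clinical_dx_age)) "never (censored by death)"
        else paste0("at ", round(x$clinical_dx_age, 1)), "\n", sep = "")
  }
  invisible(x)
}

#' Preclinical stage occupied at an age
#'
#' Returns the disease stage a man occupies at `age`, or `NULL` if he has not
#' yet had onset, has already been clinically diagnosed, or has died of other
#' causes. State spells are half-open `[entry, exit)`: a query at exactly the
#' entry age returns that state.
#'
#' @param history a `person_history`.
#' @param age query age (years, >= 0).
#' @return one row of [disease_stages()] or `NULL`.
#' @export
stage_at <- function(history, age) {
  stopifnot(inherits(history, "person_history"), age >= 0)
  if (age >= history$other_cause_death_age) return(NULL)
  if (!is.na(history$clinical_dx_age) && age >= history$clinical_dx_age) return(NULL)
  e <- history$state_entries
  hit <- which(e$age <= age & age < e$exit)
  if (!length(hit)) return(NULL)
  disease_stages()[e$state[hit[1]], 1:4]
}
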