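# Treatment allocation at diagnosis, prostate-cancer survival with treatment
# effects, and the lead-time-dependent cure applied to screen-detected
# cancers.

#' Default treatment allocation policy
#'
#' Probability of each primary treatment (radical prostatectomy `RP`,
#' radiation therapy `RT`, active surveillance `AS`, or `none`) by age band at
#' diagnosis, tumour stage, Gleason category and extent. Distant cases may be
#' treated but treatment never improves their survival. Values are synthetic
#' placeholders with the qualitative pattern of clinical practice (younger
#' and higher-grade men treated radically more often, older men managed
#' conservatively).
#'
#' @return tibble with columns `age_lo`, `age_hi`, `t_stage`, `gleason`,
#'   `extent`, `RP`, `RT`, `AS`, `none` (rows sum to 1).
#' @export
default_treatment_policy <- function() {
  st <- disease_stages()
  bands <- tibble::tibble(age_lo = c(0, 65, 75), age_hi = c(65, 75, Inf))
  pol <- tidyr::crossing(bands, st[c("t_stage", "gleason", "extent", "g_i", "e_i")])
  base <- matrix(0, nrow(pol), 4, dimnames = list(NULL, c("RP", "RT", "AS", "none")))
  for (i in seq_len(nrow(pol))) {
    r <- pol[i, ]
    if (r$extent == "distant") {
      base[i, ] <- c(0, 0.30, 0, 0.70)
    } else if (r$gleason == "<7") {
      base[i, ] <- c(0.25, 0.15, 0.55, 0.05)
    } else if (r$gleason == "7") {
      base[i, ] <- c(0.45, 0.35, 0.15, 0.05)
    } else {
      base[i, ] <- c(0.40, 0.45, 0.05, 0.10)
    }
    if (r$age_lo >= 75 && r$extent != "distant") {
      base[i, ] <- c(0.05, 0.35, 0.30, 0.30)        # conservative at high age
    } else if (r$age_lo >= 65 && r$extent != "distant") {
      base[i, ] <- base[i, c(2, 1, 3, 4)] * c(1, 1, 1, 1)
      base[i, ] <- base[i, ] / sum(base[i, ])
    }
  }
  out <- dplyr::bind_cols(pol[c("age_lo", "age_hi", "t_stage", "gleason", "extent")],
                          tibble::as_tibble(base))
  attr(out, "synthetic") <- TRUE
  out
}

#' Default prostate-cancer survival model
#'
#' Baseline (untreated) survival from clinical diagnosis is exponential with
#' a rate depending on Gleason category and extent; curative treatment of
#' local-regional disease scales the hazard by `hr` (default 0.56). Active
#' surveillance applies the curative hazard ratio only from the switch time
#' of the 30%-by-7-years switchers. `cure` holds the parameters of the
#' lead-time-dependent cure probability
#' \eqn{c(L) = c_{max} (1 - e^{-\beta L})} for screen-detected relevant
#' cancers. Baseline rates are synthetic placeholders.
#'
#' @param hr curative hazard ratio in (0, 1] (default 0.56).
#' @param as_switch_prob_7y probability of switching from active surveillance
#'   to curative treatment within 7 years (default 0.30).
#' @param cure list with `c_max` in `[0, 1]` and `beta >= 0`.
#' @return list of class `survival_model`.
#' @export
default_survival_model <- function(hr = 0.56, as_switch_prob_7y = 0.30,
                                   cure = list(c_max = 0.8, beta = 0.2)) {
  stopifnot(hr > 0, hr <= 1, as_switch_prob_7y >= 0, as_switch_prob_7y < 1)
  rates <- rbind(
    "local-regional" = c("<7" = 0.015, "7" = 0.045, ">7" = 0.10),
    "distant"        = c("<7" = 0.20,  "7" = 0.28,  ">7" = 0.38)
  )
  structure(
    list(rates = rates, hr = hr,
         as_switch_rate = -log(1 - as_switch_prob_7y) / 7,
         cure = cure,
         meta = list(synthetic = TRUE)),
    class = "survival_model"
  )
}

#' Lead-time-dependent cure probability
#'
#' \eqn{c(L) = c_{max}(1 - e^{-\beta L})}: no benefit at zero lead time,
#' nondecreasing, asymptote `c_max <= 1`. Screen-detected non-overdiagnosed
#' cancers are cured with this probability; cured men die of other causes.
#'
#' @param lead_time nonnegative lead time(s) in years.
#' @param cure_params list with `c_max` and `beta`.
#' @return probability vector.
#' @examples
#' cure_probability(5, list(c_max = 0.6, beta = 0.2))
#' @export
cure_probability <- function(lead_time, cure_params) {
  if (any(lead_time < 0)) stop("lead_time must be >= 0", call. = FALSE)
  stopifnot(cure_params$c_max >= 0, cure_params$c_max <= 1, cure_params$beta >= 0)
  cure_params$c_max * (1 - exp(-cure_params$beta * lead_time))
}

# policy row lookup index for vectors of (age, state id)
.policy_lookup <- function(policy, age, state) {
  st <- disease_stages()
  key_pol <- paste(policy$age_lo, policy$t_stage, policy$gleason, policy$extent)
  floors <- sort(unique(policy$age_lo))
  age_lo <- floors[findInterval(age, floors)]
  key <- paste(age_lo, st$t_stage[state], st$gleason[state], st$extent[state])
  idx <- match(key, key_pol)
  if (anyNA(idx)) {
    stop("treatment policy has no row for: ", key[which(is.na(idx))[1]],
         call. = FALSE)
  }
  idx
}

#' Allocate treatment at diagnosis
#'
#' Categorical draw from the policy row matching the man's age band and
#' disease stage at diagnosis. Deterministic given `(seed, id)`: the same
#' draw is reused when the same man is diagnosed at a different age or stage
#' in a paired arm (common random numbers).
#'
#' @param age age(s) at diagnosis.
#' @param state integer state id(s) (see [disease_stages()]).
#' @param policy treatment policy table.
#' @param seed master seed.
#' @param ids person id(s).
#' @return character vector in `c("RP", "RT", "AS", "none")`.
#' @export
allocate_treatment <- function(age, state, policy, seed, ids = seq_along(age)) {
  idx <- .policy_lookup(policy, age, state)
  probs <- as.matrix(policy[idx, c("RP", "RT", "AS", "none"), drop = FALSE])
  bad <- abs(rowSums(probs) - 1) > 1e-8
  if (any(bad)) stop("treatment policy rows must sum to 1", call. = FALSE)
  cum <- t(apply(probs, 1, cumsum))
  u <- runif_ctr(seed, ids, .SLOT$treat)
  j <- 1L + (u > cum[, 1]) + (u > cum[, 2]) + (u > cum[, 3])
  c("RP", "RT", "AS", "none")[j]
}

# survival time from diagnosis given treatment; E is an Exp(1) deviate and
# tau_as the latent active-surveillance switch time
.pc_survival_time <- function(E, lambda, treatment, extent_i, hr, tau_as) {
  t_base <- E / lambda
  out <- t_base
  curative <- extent_i == 1L & treatment %in% c("RP", "RT")
  out[curative] <- (E / (hr * lambda))[curative]
  as_cur <- extent_i == 1L & treatment == "AS"
  if (any(as_cur)) {
    tau <- tau_as[as_cur]
    Ei <- E[as_cur]; li <- lambda[as_cur]
    switched <- tau <= 7
    t_as <- Ei / li
    late <- switched & Ei > li * tau
    t_as[late] <- (tau + (Ei - li * tau) / (hr * li))[late]
    out[as_cur] <- t_as
  }
  out
}

#' Sample a prostate-cancer death age
#'
#' Draws a time from clinical diagnosis to prostate-cancer death from the
#' exponential baseline for the man's Gleason/extent class, applying the
#' curative hazard ratio for treated local-regional disease, and the
#' from-switch-time hazard ratio for active-surveillance switchers. Distant
#' disease never benefits from treatment.
#'
#' @inheritParams allocate_treatment
#' @param dx_age age(s) at diagnosis.
#' @param treatment character vector of treatments.
#' @param model a [default_survival_model()].
#' @return prostate-cancer death age(s), `dx_age` + survival time.
#' @export
sample_pc_death_age <- function(dx_age, state, treatment, model, seed,
                                ids = seq_along(dx_age)) {
  st <- disease_stages()
  lambda <- model$rates[cbind(st$e_i[state], st$g_i[state])]
  E <- -log(runif_ctr(seed, ids, .SLOT$surv))
  tau <- -log(runif_ctr(seed, ids, .SLOT$as_switch)) / model$as_switch_rate
  dx_age + .pc_survival_time(E, lambda, treatment, st$e_i[state], model$hr, tau)
}

# Vectorised clinical pathway for a persons table: treatment, latent
# prostate-cancer death, realised death age and cause in the no-screen arm.
#' @keywords internal
assign_clinical_outcomes <- function(persons, policy, survival, seed) {
  n <- nrow(persons)
  persons$treatment <- NA_character_
  persons$as_switch <- NA_real_
  persons$pc_death_latent <- Inf
  dx <- which(!is.na(persons$cdx_age))
  if (length(dx)) {
    ids <- persons$person_id[dx]
    state <- persons$dx_state[dx]
    age <- persons$cdx_age[dx]
    tr <- allocate_treatment(age, state, policy, seed, ids = ids)
    persons$treatment[dx] <- tr
    persons$as_switch[dx] <- -log(runif_ctr(seed, ids, .SLOT$as_switch)) /
      survival$as_switch_rate
    persons$pc_death_latent[dx] <-
      sample_pc_death_age(age, state, tr, survival, seed, ids = ids)
  }
  persons$death_age <- pmin(persons$ocd_age, persons$pc_death_latent)
  persons$death_cause <- ifelse(persons$pc_death_latent < persons$ocd_age, "pc", "other")
  persons
}

#' Resolve a screen-detected cancer
#'
#' Applies the cure model to one screen-detected man: overdiagnosed men never
#' die of prostate cancer; relevant (non-overdiagnosed) men are cured with
#' probability `cure_probability(lead_time)` and otherwise die of prostate
#' cancer at the same age as on their counterfactual clinical pathway
#' (common-random-numbers pairing).
#'
#' @param sh a `screened_history` with a screen detection
#'   (see [apply_screening()]).
#' @param policy treatment policy (allocation at the screen-detection stage).
#' @param model survival model (cure parameters).
#' @param master_seed master seed of the run.
#' @return list with `treatment`, `overdiagnosed`, `cured`,
#'   `pc_death_age` (NA if none) and `death_age` in the screened arm.
#' @export
resolve_screen_detected <- function(sh, policy, model, master_seed) {
  if (is.na(sh$screen_dx_age)) {
    stop("resolve_screen_detected() requires a screen detection", call. = FALSE)
  }
  base <- sh$base
  id <- base$person_id
  tr <- allocate_treatment(sh$screen_dx_age, sh$screen_dx_state, policy,
                           master_seed, ids = id)
  over <- classify_overdiagnosis(sh)
  cured <- FALSE
  pc_death <- NA_real_
  if (!over) {
    lead <- base$cdx_latent - sh$screen_dx_age
    u <- runif_ctr(master_seed, id, .SLOT$cure)
    cured <- u < cure_probability(lead, model$cure)
    if (!cured) {
      # counterfactual clinical-pathway death age
      tr_base <- allocate_treatment(base$cdx_latent, base$dx_state_latent,
                                    policy, master_seed, ids = id)
      pc_death <- sample_pc_death_age(base$cdx_latent, base$dx_state_latent,
                                      tr_base, model, master_seed, ids = id)
    }
  }
  death <- if (!is.na(pc_death)) min(base$other_cause_death_age, pc_death)
           else base$other_cause_death_age
  list(treatment = tr, overdiagnosed = over, cured = cured,
       pc_death_age = if (!is.na(pc_death) && pc_death < base$other_cause_death_age)
         pc_death else NA_real_,
       death_age = death)
}
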