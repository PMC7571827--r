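# Natural-history parameter sets: structure, validation, synthetic fixture.
#
# A parameter set holds (i) a piecewise-constant onset hazard on 5-year age
# bands from cohort entry at 50, written as
#   rate(band k) = onset_scale * base_rate_k * exp(onset_shape * (mid_k - 60)),
# (ii) a categorical distribution of the state at onset, (iii) exponential
# progression rates along the severity-increasing edge graph, and (iv) a
# per-state clinical-detection hazard times a global clin_scale. The scale
# and shape fields are the natural free parameters for calibration.

#' Construct / validate a natural-history parameter set
#'
#' @param onset list with `breaks` (band edges, years), `base_rates`
#'   (per-year hazard at the shape reference age 60, one per band), `scale`
#'   and `shape`.
#' @param onset_state_probs length-18 probability vector over the states at
#'   onset (see [disease_stages()]).
#' @param progression tibble `from, to, rate` on severity-increasing edges.
#' @param clin_rates length-18 per-year clinical-detection hazard.
#' @param clin_scale global multiplier on `clin_rates`.
#' @param meta free-form metadata list (`synthetic`, seed, ...).
#' @return object of class `nh_params`.
#' @export
nh_params <- function(onset, onset_state_probs, progression, clin_rates,
                      clin_scale = 1, meta = list()) {
  p <- structure(
    list(onset = onset, onset_state_probs = onset_state_probs,
         progression = progression, clin_rates = clin_rates,
         clin_scale = clin_scale, meta = meta),
    class = "nh_params"
  )
  validate_nh_params(p)
}

#' @keywords internal
validate_nh_params <- function(p) {
  o <- p$onset
  if (length(o$base_rates) != length(o$breaks) - 1L) {
    stop("onset: need one base rate per band", call. = FALSE)
  }
  if (any(o$base_rates < 0) || o$scale < 0) stop("onset rates must be >= 0", call. = FALSE)
  sp <- p$onset_state_probs
  if (length(sp) != 18L || any(sp < 0) || abs(sum(sp) - 1) > 1e-8) {
    stop("onset_state_probs must be 18 nonnegative values summing to 1", call. = FALSE)
  }
  if (any(p$progression$rate < 0)) stop("progression rates must be >= 0", call. = FALSE)
  st <- disease_stages()
  sev <- function(i) st$t_i[i] + st$g_i[i] + st$e_i[i]
  ok_dir <- with(p$progression,
                 st$t_i[to] >= st$t_i[from] & st$g_i[to] >= st$g_i[from] &
                 st$e_i[to] >= st$e_i[from] & sev(to) > sev(from))
  if (!all(ok_dir)) stop("progression edges must increase severity", call. = FALSE)
  if (length(p$clin_rates) != 18L || any(p$clin_rates < 0) || p$clin_scale < 0) {
    stop("clinical detection rates must be 18 nonnegative values", call. = FALSE)
  }
  p
}

#' Synthetic natural-history parameter fixture
#'
#' A complete, internally consistent parameter set with onset hazard
#' increasing in age, severity-ordered progression and clinical-detection
#' rates for all 18 preclinical states. All values are synthetic (labelled in
#' `meta`): they are plausible for prostate cancer but are not the calibrated
#' values of any published model. `scale` multiplies the onset hazard, so
#' overall lifetime clinical incidence is tunable; the default gives a
#' lifetime risk of clinical diagnosis near 10%.
#'
#' @param scale positive multiplier on the onset hazard (default 1).
#' @param seed integer; jitters rates reproducibly (same seed, same fixture).
#' @return an [nh_params()] object.
#' @examples
#' p <- make_nh_fixture()
#' p$onset$scale
#' @export
make_nh_fixture <- function(scale = 1, seed = 1) {
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) || scale <= 0) {
    stop("`scale` must be a positive real", call. = FALSE)
  }
  jitter <- function(ids, slot) exp(0.1 * stats::qnorm(runif_ctr(seed, ids, slot)))

  breaks <- seq(50, 90, by = 5)
  nb <- length(breaks) - 1L
  onset <- list(
    breaks = breaks,
    base_rates = 0.0023 * jitter(seq_len(nb), 901),
    scale = scale,
    shape = 0.08
  )

  sp <- numeric(18)
  sp[state_id("T1", "<7", "local-regional")] <- 0.80
  sp[state_id("T1", "7", "local-regional")]  <- 0.10
  sp[state_id("T2", "<7", "local-regional")] <- 0.10

  st <- disease_stages()
  ed <- progression_edges()
  # per-edge base intensity by which component increases
  kind <- ifelse(st$t_i[ed$to] > st$t_i[ed$from], "t",
                 ifelse(st$g_i[ed$to] > st$g_i[ed$from], "g", "e"))
  base <- c(t = 0.09, g = 0.06, e = 0.03)[kind]
  # distant spread accelerates with local stage
  base[kind == "e"] <- base[kind == "e"] * c(1, 2, 4)[st$t_i[ed$from[kind == "e"]]]
  ed$rate <- base * jitter(seq_len(nrow(ed)), 902)

  clin_t <- c(0.035, 0.10, 0.25)[st$t_i]
  clin_g <- c(1, 1.3, 1.6)[st$g_i]
  clin_e <- c(1, 3)[st$e_i]
  clin <- clin_t * clin_g * clin_e * jitter(st$state, 903)

  nh_params(
    onset = onset, onset_state_probs = sp, progression = ed, clin_rates = clin,
    meta = list(synthetic = TRUE, seed = seed, scale = scale,
                label = "synthetic fixture, not calibrated registry values")
  )
}

# Effective (post-scale) quantities and lookup tables used by the simulation
# kernel.
#' @keywords internal
nh_kernel <- function(params) {
  o <- params$onset
  mids <- (utils::head(o$breaks, -1) + utils::tail(o$breaks, -1)) / 2
  onset_rates <- o$scale * o$base_rates * exp(o$shape * (mids - 60))
  widths <- diff(o$breaks)
  cumhaz <- c(0, cumsum(onset_rates * widths))

  clin <- params$clin_scale * params$clin_rates

  ed <- params$progression
  prog_total <- vapply(1:18, function(s) sum(ed$rate[ed$from == s]), numeric(1))
  max_deg <- max(table(factor(ed$from, levels = 1:18)))
  dest <- matrix(NA_integer_, 18, max_deg)
  cumw <- matrix(1, 18, max_deg)  # normalised cumulative destination weights
  for (s in 1:18) {
    rows <- which(ed$from == s)
    if (length(rows) && prog_total[s] > 0) {
      w <- ed$rate[rows] / prog_total[s]
      dest[s, seq_along(rows)] <- ed$to[rows]
      cumw[s, seq_along(rows)] <- cumsum(w)
      if (length(rows) < max_deg) {
        dest[s, (length(rows) + 1):max_deg] <- ed$to[rows[length(rows)]]
      }
    }
  }
  list(
    onset_breaks = o$breaks, onset_rates = onset_rates, onset_cumhaz = cumhaz,
    onset_state_cum = cumsum(params$onset_state_probs),
    clin = clin, prog_total = prog_total, dest = dest, cumw = cumw
  )
}

#' Override calibration-facing natural-history parameters
#'
#' Applies named values among `onset_scale`, `onset_shape`, `clin_scale` to a
#' parameter set; the free-parameter surface used by [calibrate_incidence()].
#'
#' @param params an `nh_params` object.
#' @param values named numeric vector.
#' @return modified `nh_params`.
#' @export
set_free_params <- function(params, values) {
  for (nm in names(values)) {
    switch(nm,
      onset_scale = { params$onset$scale <- values[[nm]] },
      onset_shape = { params$onset$shape <- values[[nm]] },
      clin_scale  = { params$clin_scale <- values[[nm]] },
      stop("unknown free parameter: ", nm, call. = FALSE)
    )
  }
  validate_nh_params(params)
}
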