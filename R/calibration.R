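# Calibration of natural-history parameters to age-group clinical incidence,
# and mortality validation. The objective simulates a cohort with a fixed
# seed per evaluation (common random numbers), making it a deterministic
# function of the parameters, and is minimised derivative-free.

.AGE_BREAKS <- seq(50, 75, by = 5)

#' Predict clinical incidence by 5-year age group
#'
#' Simulates an unscreened cohort and tabulates clinical prostate-cancer
#' incidence per 100,000 person-years in 5-year age bands 50-75. Person-years
#' are years lived (to death from any cause) within each band.
#'
#' @param params natural-history parameters.
#' @param life_table life table.
#' @param n cohort size (>= 1e4 for stable bands; smaller n is allowed and
#'   flagged).
#' @param seed simulation seed.
#' @param age_breaks band edges (default 50, 55, ..., 75).
#' @return tibble `age_group, cases, person_years, incidence_per_100k`.
#' @export
predict_incidence <- function(params, life_table, n, seed,
                              age_breaks = .AGE_BREAKS) {
  coh <- simulate_cohort(params, life_table, n, seed)
  p <- coh$persons
  nb <- length(age_breaks) - 1
  lab <- paste(utils::head(age_breaks, -1), age_breaks[-1] - 1, sep = "-")
  cases <- py <- numeric(nb)
  for (k in seq_len(nb)) {
    lo <- age_breaks[k]; hi <- age_breaks[k + 1]
    cases[k] <- sum(!is.na(p$cdx_age) & p$cdx_age >= lo & p$cdx_age < hi)
    py[k] <- sum(pmax(0, pmin(p$death_age, hi) - lo))
  }
  tibble::tibble(
    age_group = lab, cases = cases, person_years = py,
    incidence_per_100k = ifelse(py > 0, 1e5 * cases / py, 0)
  )
}

#' Generate synthetic calibration targets
#'
#' Simulates `n` unscreened histories under a known parameter set and
#' tabulates clinical incidence per 100,000 person-years by 5-year age group
#' 50-75 — the ground truth for parameter-recovery experiments. Deterministic
#' in `(params, life_table, n, seed)`. The period column is collapsed to a
#' single synthetic period.
#'
#' @inheritParams predict_incidence
#' @return tibble `age_group, period, incidence_per_100k` with attributes
#'   `synthetic = TRUE` and `warning` if any band had too few person-years.
#' @export
make_calibration_targets <- function(params, life_table, n, seed) {
  if (n < 1e4) warning("n < 1e4: incidence bands will be noisy", call. = FALSE)
  inc <- predict_incidence(params, life_table, n, seed)
  out <- tibble::tibble(
    age_group = inc$age_group, period = "synthetic",
    incidence_per_100k = inc$incidence_per_100k
  )
  attr(out, "synthetic") <- TRUE
  if (any(inc$person_years < 100)) {
    attr(out, "warning") <- "some age bands have under 100 person-years"
  }
  out
}

#' Read or write calibration targets as delimited text
#' @param path file path.
#' @param x targets tibble.
#' @export
read_calibration_targets <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  tibble::as_tibble(df[c("age_group", "period", "incidence_per_100k")])
}

#' @rdname read_calibration_targets
#' @export
write_calibration_targets <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Specify a calibration
#'
#' @param free named numeric vector of starting values for the free
#'   parameters (any of `onset_scale`, `onset_shape`, `clin_scale`).
#' @param lower,upper named bounds (finite), same names as `free`.
#' @param n cohort size per objective evaluation.
#' @param seed simulation seed reused at every evaluation (common random
#'   numbers across evaluations).
#' @param weights per-band loss weights (recycled).
#' @param max_eval Nelder-Mead evaluation budget.
#' @param restarts number of optimiser starts (the first from `free`, others
#'   jittered).
#' @return list of class `calibration_spec`.
#' @export
calibration_spec <- function(free, lower, upper, n = 5e4, seed = 1,
                             weights = 1, max_eval = 200, restarts = 1) {
  stopifnot(length(free) >= 1, all(names(free) %in% names(lower)),
            all(names(free) %in% names(upper)))
  if (any(!is.finite(unlist(lower))) || any(!is.finite(unlist(upper)))) {
    stop("bounds must be finite", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  structure(
    list(free = free, lower = lower[names(free)], upper = upper[names(free)],
         n = n, seed = seed, weights = weights, max_eval = max_eval,
         restarts = restarts),
    class = "calibration_spec"
  )
}

# box transform: unconstrained x <-> bounded theta
.to_bounded <- function(x, lo, hi) lo + (hi - lo) * stats::plogis(x)
.to_unbounded <- function(theta, lo, hi) stats::qlogis((theta - lo) / (hi - lo))

#' Weighted relative-error calibration loss
#'
#' `sum_k w_k (pred_k / target_k - 1)^2` over target cells with positive
#' target (scale-free across bands).
#'
#' @param pred,target incidence vectors.
#' @param weights weights (recycled).
#' @return loss value.
#' @export
calibration_loss <- function(pred, target, weights = 1) {
  w <- rep_len(weights, length(target))
  keep <- target > 0 & w > 0
  sum(w[keep] * (pred[keep] / target[keep] - 1)^2)
}

#' Calibrate natural-history parameters to incidence targets
#'
#' Derivative-free (Nelder-Mead) minimisation of the weighted squared
#' relative error between predicted and target age-group incidence. Each
#' objective evaluation simulates a fresh cohort with the same seed, so the
#' objective is deterministic in the parameters and the whole fit is
#' reproducible from the spec.
#'
#' @param spec a [calibration_spec()].
#' @param targets calibration targets ([make_calibration_targets()] format).
#' @param params baseline parameter set to perturb.
#' @param life_table life table.
#' @return object of class `nh_calibration`: list with `params` (fitted),
#'   `estimate` (named vector), `loss`, `trace` (tibble of evaluations),
#'   `converged`, `budget_exhausted`.
#' @export
calibrate_incidence <- function(spec, targets, params, life_table) {
  stopifnot(inherits(spec, "calibration_spec"), nrow(targets) >= 1)
  lo <- unlist(spec$lower); hi <- unlist(spec$upper)
  tgt <- targets$incidence_per_100k
  trace <- new.env(parent = emptyenv())
  trace$rows <- list()

  objective <- function(x) {
    theta <- stats::setNames(.to_bounded(x, lo, hi), names(spec$free))
    p <- set_free_params(params, theta)
    pred <- predict_incidence(p, life_table, spec$n, spec$seed)$incidence_per_100k
    loss <- calibration_loss(pred, tgt, spec$weights)
    trace$rows[[length(trace$rows) + 1L]] <- c(theta, loss = loss)
    loss
  }

  starts <- list(.to_unbounded(unlist(spec$free), lo, hi))
  if (spec$restarts > 1) {
    for (r in 2:spec$restarts) {
      jit <- stats::qnorm(runif_ctr(spec$seed, r, 950 + seq_along(lo)))
      starts[[r]] <- starts[[1]] + 0.5 * jit
    }
  }
  best <- NULL
  if (length(lo) == 1L) {
    # one free parameter: golden-section search on the bounded interval
    opt <- stats::optimize(function(th) objective(.to_unbounded(th, lo, hi)),
                           interval = c(lo, hi), tol = (hi - lo) * 1e-4)
    # optimize() evaluates at interior points only; keep the start if better
    v0 <- objective(starts[[1]])
    best <- if (v0 <= opt$objective) {
      list(par = starts[[1]], value = v0, convergence = 0L)
    } else {
      list(par = .to_unbounded(opt$minimum, lo, hi), value = opt$objective,
           convergence = 0L)
    }
  } else {
    for (x0 in starts) {
      fit <- stats::optim(x0, objective, method = "Nelder-Mead",
                          control = list(maxit = spec$max_eval))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }

  theta <- stats::setNames(.to_bounded(best$par, lo, hi), names(spec$free))
  tr <- tibble::as_tibble(do.call(rbind, trace$rows))
  budget <- best$convergence == 1L
  if (budget) warning("evaluation budget exhausted; returning best-so-far",
                      call. = FALSE)
  structure(
    list(params = set_free_params(params, theta), estimate = theta,
         loss = best$value, trace = tr, converged = best$convergence == 0L,
         budget_exhausted = budget, spec = spec),
    class = "nh_calibration"
  )
}

#' @export
print.nh_calibration <- function(x, ...) {
  cat("<nh_calibration> loss ", signif(x$loss, 4),
      if (x$budget_exhausted) " (budget exhausted)", "\n", sep = "")
  print(round(x$estimate, 4))
  invisible(x)
}

#' @rdname tidy.ce_result
#' @method tidy nh_calibration
#' @export
tidy.nh_calibration <- function(x, ...) {
  tibble::tibble(term = names(x$estimate), estimate = unname(x$estimate),
                 lower = unlist(x$spec$lower), upper = unlist(x$spec$upper))
}

#' @rdname tidy.ce_result
#' @method glance nh_calibration
#' @export
glance.nh_calibration <- function(x, ...) {
  tibble::tibble(loss = x$loss, n_eval = nrow(x$trace),
                 converged = x$converged,
                 budget_exhausted = x$budget_exhausted)
}

#' Validate predicted prostate-cancer mortality against targets
#'
#' Tabulates predicted prostate-cancer mortality per 100,000 person-years by
#' age band from an unscreened cohort and lays it alongside target values;
#' no fitting is performed.
#'
#' @inheritParams predict_incidence
#' @param mortality_targets tibble `age_group, mortality_per_100k`.
#' @return tibble with predicted and target mortality and relative errors.
#' @export
validate_mortality <- function(params, life_table, n, seed, mortality_targets,
                               age_breaks = .AGE_BREAKS) {
  coh <- simulate_cohort(params, life_table, n, seed)
  p <- coh$persons
  nb <- length(age_breaks) - 1
  lab <- paste(utils::head(age_breaks, -1), age_breaks[-1] - 1, sep = "-")
  deaths <- py <- numeric(nb)
  for (k in seq_len(nb)) {
    lo <- age_breaks[k]; hi <- age_breaks[k + 1]
    deaths[k] <- sum(p$death_cause == "pc" & p$death_age >= lo & p$death_age < hi)
    py[k] <- sum(pmax(0, pmin(p$death_age, hi) - lo))
  }
  pred <- ifelse(py > 0, 1e5 * deaths / py, 0)
  tgt <- mortality_targets$mortality_per_100k[
    match(lab, mortality_targets$age_group)]
  tibble::tibble(
    age_group = lab, predicted_per_100k = pred, target_per_100k = tgt,
    rel_error = ifelse(!is.na(tgt) & tgt > 0, pred / tgt - 1, NA_real_)
  )
}
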