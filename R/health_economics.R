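# Quality-of-life losses, discounting and costs.
#
# The QALY loss of an arm is sum_i (1 - u_i) * d_i * n_i over health states
# i, with each man's duration truncated at his death and each state entry
# discounted (lump sum at entry age) to the cohort entry age 50. Costs are
# unit costs attached to events and discounted the same way. The engine
# stores, per strategy and arm, the discounted truncated duration sum per
# utility state and the discounted event count per cost item, so sensitivity
# analyses on utilities and unit costs never re-simulate.

#' Default utility table (synthetic)
#'
#' One row per health state: utility `u` in `[0, 1]`, duration `d` in years,
#' and the low/high variants used by the univariate sensitivity analysis.
#' The postrecovery row (utility 0.95 for 9 years after radical
#' prostatectomy or radiation therapy) reflects the convention of combining
#' treatment side-effect frequencies with side-effect utilities; the
#' remaining values are synthetic placeholders on realistic scales.
#'
#' @return tibble `state, utility, duration_years, u_low, u_high`.
#' @export
default_utility_table <- function() {
  out <- tibble::tribble(
    ~state,                 ~utility, ~duration_years, ~u_low, ~u_high,
    "screening_attendance",     0.99,           1 / 52,   0.97,    1.00,
    "biopsy",                   0.90,           3 / 52,   0.87,    0.94,
    "cancer_diagnosis",         0.80,           1 / 12,   0.75,    0.85,
    "prostatectomy",            0.67,            1 / 6,   0.56,    0.80,
    "post_rp",                  0.77,           10 / 12,  0.70,    0.85,
    "radiation",                0.73,            1 / 6,   0.60,    0.85,
    "post_rt",                  0.78,           10 / 12,  0.71,    0.86,
    "active_surveillance",      0.97,               7,    0.85,    1.00,
    "postrecovery",             0.95,               9,    0.87,    1.00,
    "palliative",               0.60,             0.5,    0.24,    0.86,
    "terminal",                 0.40,             0.5,    0.24,    0.56
  )
  attr(out, "synthetic") <- TRUE
  out
}

#' Default unit-cost table (synthetic), EUR
#'
#' @return tibble `item, unit_cost_eur`.
#' @export
default_cost_table <- function() {
  out <- tibble::tribble(
    ~item,        ~unit_cost_eur,
    "invitation",              5,
    "psa_test",               30,
    "biopsy",                350,
    "rp",                   9000,
    "rt",                   8000,
    "as",                   4500,
    "staging",               600,
    "follow_up",            1500,
    "advanced",            25000
  )
  attr(out, "synthetic") <- TRUE
  out
}

#' Read or write utility / cost tables as delimited text
#' @param path file path.
#' @param x the table.
#' @return the tibble (readers) or `path` invisibly (writers).
#' @export
read_utility_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' @rdname read_utility_table
#' @export
write_utility_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_utility_table
#' @export
read_cost_table <- read_utility_table

#' @rdname read_utility_table
#' @export
write_cost_table <- write_utility_table

#' Discounting
#'
#' Present value at the reference age (cohort entry, default 50) of an
#' amount incurred at `at_age`, with annual compounding and a continuous
#' exponent: `amount / (1 + rate)^(at_age - reference_age)`.
#'
#' @param amount amount(s) in EUR or QALYs.
#' @param at_age age(s) at which the amount is incurred (>= reference age).
#' @param spec list with `annual_rate` (default 0.035) and `reference_age`
#'   (default 50).
#' @return discounted amount(s).
#' @export
discount <- function(amount, at_age, spec = discount_spec()) {
  if (any(at_age < spec$reference_age)) {
    stop("at_age must be >= the discounting reference age", call. = FALSE)
  }
  amount / (1 + spec$annual_rate)^(at_age - spec$reference_age)
}

#' @rdname discount
#' @param annual_rate annual discount rate (>= 0).
#' @param reference_age cohort entry age.
#' @export
discount_spec <- function(annual_rate = 0.035, reference_age = 50) {
  stopifnot(annual_rate >= 0)
  list(annual_rate = annual_rate, reference_age = reference_age)
}

# discounted value of one undiscounted year-flow between ages a and b:
# integral_a^b (1+r)^-(t - ref) dt
#' @keywords internal
discounted_years <- function(from, to, spec = discount_spec()) {
  if (spec$annual_rate == 0) return(to - from)
  lr <- log(1 + spec$annual_rate)
  v <- function(t) (1 + spec$annual_rate)^(-(t - spec$reference_age))
  (v(from) - v(to)) / lr
}

#' Total quality-of-life loss
#'
#' Direct evaluation of sum_i (1 - u_i) * d_i * n_i over health states. The
#' counts `n_i` are the (possibly fractional) numbers of men entering each
#' state; duration truncation at death and discounting, when wanted, must
#' already be folded into the counts (the pipeline does this per person).
#'
#' @param state_counts named numeric vector, or tibble with `state` and `n`.
#' @param table utility table ([default_utility_table()]).
#' @return QALY loss (scalar).
#' @examples
#' qaly_loss(c(postrecovery = 1), default_utility_table())  # 0.45
#' @export
qaly_loss <- function(state_counts, table = default_utility_table()) {
  if (is.data.frame(state_counts)) {
    counts <- stats::setNames(state_counts$n, state_counts$state)
  } else {
    counts <- state_counts
  }
  idx <- match(names(counts), table$state)
  if (anyNA(idx)) {
    stop("unknown health state: ", names(counts)[which(is.na(idx))[1]],
         call. = FALSE)
  }
  sum((1 - table$utility[idx]) * table$duration_years[idx] * counts)
}

#' QALYs gained by a strategy
#'
#' Net life-years gained minus the excess quality-of-life loss of the
#' screened arm over the unscreened arm.
#'
#' @param lyg (discounted) life-years gained.
#' @param loss_screen,loss_noscreen QALY losses of the two paired arms.
#' @return QALYs gained.
#' @export
qalys_gained <- function(lyg, loss_screen, loss_noscreen) {
  lyg - (loss_screen - loss_noscreen)
}

#' Total discounted cost of an event stream
#'
#' Each event carries a cost item, an age and a multiplicity; the total is
#' the discounted sum of unit costs.
#'
#' @param events tibble with `item`, `age`, `n`.
#' @param costs cost table ([default_cost_table()]).
#' @param spec discounting spec.
#' @return total discounted cost.
#' @export
total_cost <- function(events, costs = default_cost_table(),
                       spec = discount_spec()) {
  idx <- match(events$item, costs$item)
  if (anyNA(idx)) {
    stop("missing unit cost for item: ", events$item[which(is.na(idx))[1]],
         call. = FALSE)
  }
  sum(costs$unit_cost_eur[idx] * discount(events$n, events$age, spec))
}
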