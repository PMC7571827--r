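# Shared fixtures. Everything is generated in code; moderately sized cohorts
# are cached per session so several tests can reuse them.

fx <- new.env(parent = emptyenv())

fx_life_table <- function() {
  if (is.null(fx$lt)) fx$lt <- make_life_table()
  fx$lt
}

fx_params <- function() {
  if (is.null(fx$p)) fx$p <- make_nh_fixture()
  fx$p
}

# near-immortal life table: all deaths in [150, 151); lets sojourn tests run
# without death truncation
fx_immortal_lt <- function() make_life_table(c(0, 0, 0), max_age = 150)

fx_cohort <- function(n = 2e4, seed = 11) {
  key <- paste0("coh_", n, "_", seed)
  if (is.null(fx[[key]])) {
    fx[[key]] <- simulate_cohort(fx_params(), fx_life_table(), n, seed)
  }
  fx[[key]]
}

# chi-square test of observed year-of-death counts against life-table
# probabilities, merging cells with small expectation into the tail
chisq_death_p <- function(death_ages, lt, min_age = 0, n_min = 5) {
  p <- prostasim:::.death_year_probs(lt, min_age)
  ages <- lt$age[lt$age >= min_age]
  obs <- tabulate(match(floor(death_ages), ages), nbins = length(ages))
  exp_n <- p * length(death_ages)
  keep <- exp_n >= n_min
  if (sum(!keep)) {
    obs_k <- c(obs[keep], sum(obs[!keep]))
    p_k <- c(p[keep], sum(p[!keep]))
  } else {
    obs_k <- obs; p_k <- p
  }
  pos <- p_k > 0
  stats::chisq.test(obs_k[pos], p = p_k[pos] / sum(p_k[pos]))$p.value
}
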