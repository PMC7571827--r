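test_that("the state space and progression graph have the documented shape", {
  st <- disease_stages()
  expect_equal(nrow(st), 18)
  expect_equal(nrow(dplyr::distinct(st, t_stage, gleason, extent)), 18)
  ed <- prostasim:::progression_edges()
  # every edge raises exactly one severity component by one level
  d_t <- st$t_i[ed$to] - st$t_i[ed$from]
  d_g <- st$g_i[ed$to] - st$g_i[ed$from]
  d_e <- st$e_i[ed$to] - st$e_i[ed$from]
  expect_true(all(d_t >= 0 & d_g >= 0 & d_e >= 0))
  expect_true(all(d_t + d_g + d_e == 1))
})

test_that("fixture construction validates its inputs and is reproducible", {
  expect_error(make_nh_fixture(scale = 0), "positive")
  expect_error(make_nh_fixture(scale = -1), "positive")
  expect_identical(make_nh_fixture(seed = 5), make_nh_fixture(seed = 5))
  expect_false(identical(make_nh_fixture(seed = 5), make_nh_fixture(seed = 6)))
  expect_true(make_nh_fixture()$meta$synthetic)
})

test_that("zero onset hazard means no onset and no diagnosis ever", {
  p <- set_free_params(fx_params(), c(onset_scale = 0))
  coh <- simulate_cohort(p, fx_life_table(), 2000, master_seed = 3)
  expect_true(all(is.na(coh$persons$onset_age)))
  expect_true(all(is.na(coh$persons$cdx_age)))
  expect_true(all(coh$persons$death_cause == "other"))
})

test_that("near-instant clinical detection collapses diagnosis onto onset", {
  p <- fx_params()
  p$clin_scale <- 1e6
  coh <- simulate_cohort(p, fx_life_table(), 5000, master_seed = 3)
  pp <- coh$persons
  got <- !is.na(pp$onset_age)
  expect_true(all(abs(pp$cdx_latent[got] - pp$onset_latent[got]) < 1e-3))
})

test_that("with zero progression every case is diagnosed in its onset state", {
  p <- fx_params()
  p$progression$rate[] <- 0
  coh <- simulate_cohort(p, fx_life_table(), 5000, master_seed = 3)
  pp <- coh$persons
  dx <- !is.na(pp$cdx_age)
  expect_true(any(dx))
  expect_equal(pp$dx_state[dx], pp$onset_state[dx])
})

test_that("a person regenerated alone is bit-identical to his cohort row", {
  coh <- fx_cohort(2000, seed = 21)
  for (id in c(1L, 57L, 1999L)) {
    h <- generate_history(fx_params(), fx_life_table(), id, master_seed = 21)
    row <- coh$persons[id, ]
    expect_identical(h$other_cause_death_age, row$ocd_age)
    expect_identical(h$onset_latent, row$onset_latent)
    expect_identical(h$cdx_latent, row$cdx_latent)
    expect_identical(h$clinical_dx_age, row$cdx_age)
  }
  # and independent of cohort size
  coh_small <- simulate_cohort(fx_params(), fx_life_table(), 60, master_seed = 21)
  expect_identical(coh_small$persons$ocd_age, coh$persons$ocd_age[1:60])
  expect_identical(coh_small$persons$cdx_latent, coh$persons$cdx_latent[1:60])
})

test_that("visited stages never decrease in any severity component", {
  coh <- fx_cohort(2e4, seed = 11)
  st <- disease_stages()
  iv <- dplyr::arrange(coh$intervals, person_id, entry)
  by_p <- split(iv$state, iv$person_id)
  multi <- by_p[lengths(by_p) > 1]
  for (states in multi[seq_len(min(500, length(multi)))]) {
    expect_true(all(diff(st$t_i[states]) >= 0))
    expect_true(all(diff(st$g_i[states]) >= 0))
    expect_true(all(diff(st$e_i[states]) >= 0))
  }
  # event ages strictly increasing
  expect_true(all(iv$exit > iv$entry))
})

test_that("stage_at replays the state spells with inclusive entry", {
  h <- NULL
  for (id in 1:400) {
    cand <- generate_history(fx_params(), fx_life_table(), id, master_seed = 5)
    if (!is.na(cand$onset_age) && nrow(cand$state_entries) > 1) { h <- cand; break }
  }
  expect_false(is.null(h))
  expect_null(stage_at(h, h$onset_age - 0.5))
  e <- h$state_entries
  first <- stage_at(h, e$age[1])
  expect_equal(prostasim:::state_id(first$t_stage, first$gleason, first$extent),
               e$state[1])
  # piecewise-constant and consistent with the spell table at random ages
  set.seed(1)
  for (a in stats::runif(200, 45, h$other_cause_death_age + 5)) {
    s <- stage_at(h, a)
    dead <- a >= h$other_cause_death_age
    dxed <- !is.na(h$clinical_dx_age) && a >= h$clinical_dx_age
    hit <- which(e$age <= a & a < e$exit)
    if (dead || dxed || !length(hit)) {
      expect_null(s)
    } else {
      expect_equal(prostasim:::state_id(s$t_stage, s$gleason, s$extent),
                   e$state[hit[1]])
    }
  }
})

test_that("mean preclinical sojourn matches the phase-type oracle", {
  p <- fx_params()
  lt <- fx_immortal_lt()  # deaths only at 150: no truncation of the sojourn
  coh <- simulate_cohort(p, lt, 4e4, master_seed = 13)
  pp <- coh$persons
  soj <- pp$cdx_latent[is.finite(pp$cdx_latent)] -
    pp$onset_latent[is.finite(pp$cdx_latent)]
  or <- phase_type_oracle(p)
  se <- or$sd / sqrt(length(soj))
  expect_lt(abs(mean(soj) - or$mean), 3 * se)
})

test_that("simulated lifetime clinical risk matches the integral oracle", {
  p <- fx_params()
  lt <- fx_life_table()
  target <- lifetime_clinical_risk_oracle(p, lt)
  coh <- simulate_cohort(p, lt, 1e5, master_seed = 29)
  risk <- mean(!is.na(coh$persons$cdx_age))
  se <- sqrt(target * (1 - target) / 1e5)
  expect_lt(abs(risk - target), 3 * se + 0.002)  # + integration-grid slack
  # the default fixture is tuned to roughly 10% lifetime clinical risk
  expect_gt(risk, 0.07)
  expect_lt(risk, 0.14)
})
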