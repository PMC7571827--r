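test_that("treatment allocation honours degenerate and missing policy rows", {
  pol <- default_treatment_policy()
  pol$RP <- 1; pol$RT <- 0; pol$AS <- 0; pol$none <- 0
  tr <- allocate_treatment(rep(60, 50), rep(1L, 50), pol, seed = 1, ids = 1:50)
  expect_true(all(tr == "RP"))

  pol2 <- default_treatment_policy()
  pol2 <- pol2[!(pol2$age_lo == 0 & pol2$t_stage == "T1" & pol2$gleason == "<7" &
                   pol2$extent == "local-regional"), ]
  missing_state <- prostasim:::state_id("T1", "<7", "local-regional")
  expect_error(allocate_treatment(50, missing_state, pol2, seed = 1),
               "no row for")
})

test_that("allocation frequencies match the policy row (multinomial oracle)", {
  pol <- default_treatment_policy()
  pol$RP <- 0.5; pol$RT <- 0.3; pol$AS <- 0.2; pol$none <- 0
  n <- 1e5
  tr <- allocate_treatment(rep(60, n), rep(5L, n), pol, seed = 3, ids = 1:n)
  probs <- c(RP = 0.5, RT = 0.3, AS = 0.2, none = 0)
  for (nm in names(probs)) {
    p_hat <- mean(tr == nm)
    se <- sqrt(probs[[nm]] * (1 - probs[[nm]]) / n)
    expect_lt(abs(p_hat - probs[[nm]]), 3 * se + 1e-12)
  }
})

test_that("the curative hazard ratio scales exponential survival as 1/hr", {
  model <- default_survival_model()
  st <- prostasim:::state_id("T2", "7", "local-regional")
  n <- 1e5
  lam <- model$rates["local-regional", "7"]
  t_rp <- sample_pc_death_age(rep(0, n), rep(st, n), rep("RP", n), model,
                              seed = 5, ids = 1:n)
  t_none <- sample_pc_death_age(rep(0, n), rep(st, n), rep("none", n), model,
                                seed = 5, ids = 1:n)
  med_th <- log(2) / (0.56 * lam)
  se_med <- 1 / (0.56 * lam * sqrt(n))
  expect_lt(abs(stats::median(t_rp) - med_th), 3 * se_med)
  # identical Exp(1) deviates, so the ratio is exact
  expect_equal(t_none * (1 / 0.56), t_rp, tolerance = 1e-12)

  # hr = 1 reproduces the baseline distribution exactly
  model1 <- default_survival_model(hr = 1)
  t_hr1 <- sample_pc_death_age(rep(0, n), rep(st, n), rep("RP", n), model1,
                               seed = 5, ids = 1:n)
  expect_equal(t_hr1, t_none, tolerance = 1e-12)
})

test_that("active surveillance without switching is exactly baseline", {
  model <- default_survival_model(as_switch_prob_7y = 1e-12)
  st <- prostasim:::state_id("T1", "<7", "local-regional")
  n <- 2e4
  t_as <- sample_pc_death_age(rep(0, n), rep(st, n), rep("AS", n), model,
                              seed = 7, ids = 1:n)
  t_none <- sample_pc_death_age(rep(0, n), rep(st, n), rep("none", n), model,
                                seed = 7, ids = 1:n)
  expect_equal(t_as, t_none, tolerance = 1e-9)
  # and the default model switches about 30% within 7 years
  m <- default_survival_model()
  tau <- -log(prostasim:::runif_ctr(7, 1:n, prostasim:::.SLOT$as_switch)) /
    m$as_switch_rate
  expect_lt(abs(mean(tau <= 7) - 0.30), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("treatment never improves survival for distant disease", {
  model <- default_survival_model()
  st <- prostasim:::state_id("T2", "7", "distant")
  n <- 1e4
  t_rp <- sample_pc_death_age(rep(0, n), rep(st, n), rep("RP", n), model,
                              seed = 9, ids = 1:n)
  t_none <- sample_pc_death_age(rep(0, n), rep(st, n), rep("none", n), model,
                                seed = 9, ids = 1:n)
  expect_equal(t_rp, t_none, tolerance = 1e-12)
})

test_that("cure probability has the stated form and limits", {
  expect_equal(cure_probability(0, list(c_max = 0.6, beta = 0.2)), 0)
  expect_equal(cure_probability(5, list(c_max = 0.6, beta = 0.2)),
               0.6 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(cure_probability(1e6, list(c_max = 0.6, beta = 50)), 0.6,
               tolerance = 1e-9)
  L <- seq(0, 40, by = 0.5)
  expect_true(all(diff(cure_probability(L, list(c_max = 0.9, beta = 0.1))) >= 0))
  expect_error(cure_probability(-1, list(c_max = 0.5, beta = 1)), ">= 0")
})

test_that("resolve_screen_detected applies the cure model per its contract", {
  coh <- fx_cohort(2e4, seed = 11)
  g <- enumerate_strategies()
  s <- g[g$strategy_id == "55-64@3", ]
  sp <- screening_params()
  ov <- prostasim:::screen_overlay(coh, s$test_ages[[1]], sp)
  det <- which(!is.na(ov$det_age))
  expect_gt(length(det), 20)
  n_over <- 0; n_cured <- 0; probs <- c()
  for (id in det) {
    h <- generate_history(fx_params(), fx_life_table(), id, master_seed = 11)
    sh <- apply_screening(h, s, sp, master_seed = 11)
    res <- resolve_screen_detected(sh, coh$policy, coh$survival, master_seed = 11)
    if (res$overdiagnosed) {
      n_over <- n_over + 1
      expect_true(is.na(res$pc_death_age))    # overdiagnosed never die of PC
    } else {
      probs <- c(probs, cure_probability(h$cdx_latent - sh$screen_dx_age,
                                         coh$survival$cure))
      if (res$cured) {
        n_cured <- n_cured + 1
        expect_equal(res$death_age, h$other_cause_death_age)
      } else {
        # dies on the counterfactual clinical pathway
        expect_identical(res$pc_death_age,
                         if (coh$persons$death_cause[id] == "pc")
                           coh$persons$pc_death_latent[id] else NA_real_)
      }
    }
  }
  # realised cure fraction within 3 SE of the mean cure probability
  # (binomial mixture oracle)
  mu <- mean(probs)
  se <- sqrt(sum(probs * (1 - probs))) / length(probs)
  expect_lt(abs(n_cured / length(probs) - mu), 3 * se)
})
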