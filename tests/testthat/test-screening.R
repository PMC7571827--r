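test_that("the strategy grid has the published combinatorics", {
  g <- enumerate_strategies()
  expect_equal(nrow(g), 230)
  expect_equal(nrow(dplyr::distinct(g, strategy_id)), 230)
  # interval strategies: bounds and alignment
  iv <- g[!is.na(g$interval), ]
  expect_true(all(iv$start_age >= 50 & iv$start_age <= 55))
  expect_true(all(iv$last_test_age <= 69))
  expect_true(all((iv$last_test_age - iv$start_age) %% iv$interval == 0))
  expect_true(all(iv$n_tests >= 2))
  expect_equal(sum(is.na(g$interval)), 20)

  s <- g[g$strategy_id == "55-64@3", ]
  expect_equal(s$test_ages[[1]], c(55, 58, 61, 64))
  expect_equal(s$n_tests, 4)
  expect_equal(g$n_tests[g$strategy_id == "50-69@1"], 20)
  expect_equal(g$n_tests[g$strategy_id == "51-69@2"], 10)
})

test_that("screening parameter probabilities are validated", {
  expect_error(screening_params(attendance = 1.2), "\\[0, 1\\]")
  expect_error(screening_params(test_positivity = rep(0.5, 5)), "per preclinical state")
})

test_that("zero attendance reduces a screened history to its base", {
  sp <- screening_params(attendance = 0)
  g <- enumerate_strategies()
  s <- g[g$strategy_id == "50-69@1", ]
  for (id in 1:30) {
    h <- generate_history(fx_params(), fx_life_table(), id, master_seed = 2)
    sh <- apply_screening(h, s, sp, master_seed = 2)
    expect_equal(sh$tests_attended, 0)
    expect_true(is.na(sh$screen_dx_age))
  }
})

test_that("certain screening detects a prevalent case at the first test", {
  sp <- screening_params(attendance = 1, biopsy_compliance = 1,
                         biopsy_sensitivity = 1,
                         test_positivity = rep(1, 18))
  strat <- list(test_ages = 60)
  coh <- fx_cohort(2e4, seed = 11)
  p <- coh$persons
  col <- match(60, coh$screen_ages)
  prevalent <- which(coh$state_mat[, col] > 0 & p$ocd_age > 60 &
                       (is.na(p$cdx_age) | p$cdx_age > 60))
  ov <- prostasim:::screen_overlay(coh, 60, sp)
  expect_equal(sort(which(!is.na(ov$det_age))), sort(prevalent))

  # with compliance and sensitivity at 0.9 each, detection of a prevalent
  # case is Bernoulli(0.81)
  sp2 <- screening_params(attendance = 1, biopsy_compliance = 0.9,
                          biopsy_sensitivity = 0.9,
                          test_positivity = rep(1, 18))
  ov2 <- prostasim:::screen_overlay(coh, 60, sp2)
  frac <- sum(!is.na(ov2$det_age)) / length(prevalent)
  se <- sqrt(0.81 * 0.19 / length(prevalent))
  expect_lt(abs(frac - 0.81), 3 * se)
})

test_that("per-person screening replays the cohort overlay exactly", {
  coh <- fx_cohort(2000, seed = 21)
  g <- enumerate_strategies()
  sp <- screening_params()
  for (sid in c("55-64@3", "50-69@1", "57@once")) {
    s <- g[g$strategy_id == sid, ]
    ov <- prostasim:::screen_overlay(coh, s$test_ages[[1]], sp)
    for (id in c(1:40, which(!is.na(ov$det_age))[1:5])) {
      if (is.na(id)) next
      h <- generate_history(fx_params(), fx_life_table(), id, master_seed = 21)
      sh <- apply_screening(h, s, sp, master_seed = 21)
      expect_identical(sh$screen_dx_age,
                       if (is.na(ov$det_age[id])) NA_real_ else ov$det_age[id])
    }
  }
})

test_that("the base arm is invariant under any screening overlay", {
  coh <- fx_cohort(2000, seed = 21)
  before <- coh$persons
  g <- enumerate_strategies()
  for (sid in c("55-64@3", "50-69@1")) {
    invisible(prostasim:::screen_overlay(coh, g$test_ages[[which(g$strategy_id == sid)]],
                                         screening_params()))
  }
  expect_identical(coh$persons, before)
})

test_that("detections are monotone when one test-age set nests another", {
  coh <- fx_cohort(2e4, seed = 11)
  sp <- screening_params()
  nested <- list(list(a = c(55, 59), b = c(55, 57, 59, 61)),
                 list(a = 60, b = c(56, 58, 60, 62, 64)),
                 list(a = c(52, 56, 60), b = seq(50, 68, 2)))
  for (ns in nested) {
    stopifnot(all(ns$a %in% ns$b))
    ov_a <- prostasim:::screen_overlay(coh, ns$a, sp)
    ov_b <- prostasim:::screen_overlay(coh, ns$b, sp)
    det_a <- !is.na(ov_a$det_age)
    det_b <- !is.na(ov_b$det_age)
    expect_true(all(det_b[det_a]))          # person-level monotonicity
    expect_true(all(ov_b$det_age[det_a] <= ov_a$det_age[det_a]))
  }
})

test_that("invitation accounting matches its definition", {
  coh <- fx_cohort(2000, seed = 21)
  sp <- screening_params()
  ages <- c(55, 58, 61, 64)
  ov <- prostasim:::screen_overlay(coh, ages, sp)
  p <- coh$persons
  # recount invitations: each test age before death, clinical dx and screen dx
  expected <- 0
  for (ti in seq_along(ages)) {
    a <- ages[ti]
    elig <- p$ocd_age > a & (is.na(p$cdx_age) | p$cdx_age > a) &
      (is.na(ov$det_age) | ov$det_age >= a)
    expected <- expected + sum(elig)
  }
  expect_equal(sum(ov$n_invitations), expected)
  expect_true(all(ov$n_tests <= ov$n_invitations))
})

test_that("overdiagnosis follows its counterfactual definition", {
  h <- generate_history(fx_params(), fx_life_table(), 1, master_seed = 1)
  h$other_cause_death_age <- 80
  h$cdx_latent <- 70
  h$clinical_dx_age <- 70
  sh <- structure(list(base = h, screen_dx_age = 60), class = "screened_history")
  expect_false(classify_overdiagnosis(sh))
  expect_equal(h$clinical_dx_age - sh$screen_dx_age, 10)

  h$cdx_latent <- Inf
  sh$base <- h
  expect_true(classify_overdiagnosis(sh))

  h$cdx_latent <- 85   # diagnosis would fall after death
  sh$base <- h
  expect_true(classify_overdiagnosis(sh))

  sh$screen_dx_age <- NA_real_
  expect_error(classify_overdiagnosis(sh), "screen detection")
})

test_that("switching off clinical detection makes every detection an overdiagnosis", {
  p <- fx_params()
  p$clin_scale <- 0
  coh <- simulate_cohort(p, fx_life_table(), 2e4, master_seed = 17)
  ov <- prostasim:::screen_overlay(coh, seq(50, 68, 2), screening_params())
  det <- which(!is.na(ov$det_age))
  expect_gt(length(det), 0)
  pp <- coh$persons
  over <- is.infinite(pp$cdx_latent[det]) | pp$cdx_latent[det] >= pp$ocd_age[det]
  expect_true(all(over))
})

test_that("never-attender mode fixes each man's attendance for life", {
  sp <- screening_params(attendance = 0.5, attendance_mode = "never_attender")
  coh <- fx_cohort(2000, seed = 21)
  ov <- prostasim:::screen_overlay(coh, c(55, 56, 57), sp)
  # attended counts per age should track the same attender subset: a man
  # invited at all three ages attends either all or none
  h <- generate_history(fx_params(), fx_life_table(), 7, master_seed = 21)
  sh <- apply_screening(h, list(test_ages = c(55, 56, 57)), sp, master_seed = 21)
  expect_true(sh$tests_attended %in% c(0L, sh$invitations))
})
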