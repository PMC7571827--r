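test_that("pairwise ICERs follow their definition", {
  a <- list(net_cost = 0, qalys_gained = 0)
  b <- list(net_cost = 1e5, qalys_gained = 5)
  expect_equal(icer(a, b), 20000)
  expect_equal(icer(list(net_cost = 3, qalys_gained = 1),
                    list(net_cost = 3, qalys_gained = 2)), 0)
  expect_error(icer(a, list(net_cost = 1, qalys_gained = 0)), "equal QALYs")
})

test_that("strong and weak dominance behave on textbook cases", {
  pts <- tibble::tibble(strategy_id = c("cheap_good", "dear_bad"),
                        net_cost = c(10, 20), qalys_gained = c(2, 1))
  fr <- build_frontier(pts)
  expect_equal(fr$dominated$strategy_id, "dear_bad")
  expect_equal(fr$dominated$reason, "strong")

  # middle point with ICER above the next segment's is weakly dominated
  pts2 <- tibble::tibble(strategy_id = c("lo", "mid", "hi"),
                         net_cost = c(10, 60, 70),
                         qalys_gained = c(1, 2, 4))
  fr2 <- build_frontier(pts2)
  expect_equal(fr2$dominated$strategy_id, "mid")
  expect_equal(fr2$dominated$reason, "weak")
  eff <- fr2$efficient$strategy_id
  expect_equal(setdiff(eff, ".no_screening"), c("lo", "hi"))

  # ties on identical points keep the lexicographically smallest id
  pts3 <- tibble::tibble(strategy_id = c("b_dup", "a_dup"),
                         net_cost = c(10, 10), qalys_gained = c(1, 1))
  fr3 <- build_frontier(pts3)
  expect_true("a_dup" %in% fr3$efficient$strategy_id)
  expect_equal(fr3$dominated$strategy_id, "b_dup")
})

test_that("frontier equals the support-function oracle on random clouds", {
  for (trial in 1:150) {
    pts <- random_ce_points(n = sample(2:12, 1), seed = trial)
    fr <- build_frontier(pts)
    eff <- sort(setdiff(fr$efficient$strategy_id, ".no_screening"))
    expect_equal(eff, frontier_oracle(pts), info = paste("trial", trial))
    ic <- fr$efficient$icer[-1]
    if (length(ic) > 1) expect_true(all(diff(ic) > 0))
  }
})

test_that("the frontier is invariant to ordering and dominated duplication", {
  pts <- random_ce_points(12, seed = 999)
  fr <- build_frontier(pts)
  shuffled <- pts[sample(nrow(pts)), ]
  expect_equal(build_frontier(shuffled)$efficient$strategy_id,
               fr$efficient$strategy_id)
  # duplicating a dominated point changes nothing on the frontier
  dom <- fr$dominated$strategy_id[1]
  dup <- pts[pts$strategy_id == dom, ]
  dup$strategy_id <- "zzz_copy"
  expect_equal(build_frontier(dplyr::bind_rows(pts, dup))$efficient$strategy_id,
               fr$efficient$strategy_id)
})

test_that("every excluded point is certified dominated or ICER-breaking", {
  for (trial in 201:230) {
    pts <- random_ce_points(10, seed = trial)
    fr <- build_frontier(pts)
    eff <- fr$efficient
    for (k in seq_len(nrow(fr$dominated))) {
      sid <- fr$dominated$strategy_id[k]
      p <- pts[pts$strategy_id == sid, ]
      if (fr$dominated$reason[k] == "strong") {
        anchor <- tibble::tibble(net_cost = 0, qalys_gained = 0)
        others <- dplyr::bind_rows(pts[pts$strategy_id != sid,
                                       c("net_cost", "qalys_gained")], anchor)
        expect_true(any(others$net_cost <= p$net_cost &
                          others$qalys_gained >= p$qalys_gained &
                          (others$net_cost < p$net_cost |
                             others$qalys_gained > p$qalys_gained)))
      } else {
        # inserting it into the efficient list breaks ICER monotonicity
        aug <- dplyr::bind_rows(eff[c("strategy_id", "net_cost", "qalys_gained")],
                                p[c("strategy_id", "net_cost", "qalys_gained")])
        aug <- dplyr::arrange(aug, net_cost)
        ics <- diff(aug$net_cost) / diff(aug$qalys_gained)
        expect_false(all(is.finite(ics)) && all(diff(ics) > 0) && all(ics > 0))
      }
    }
  }
})

test_that("optimum selection takes the largest ICER at or below the threshold", {
  # published efficient list: strategy labels with their ICERs; the optimum
  # at 20000 EUR/QALY must be the 55-64@3 row at 19733
  tbl1 <- tibble::tibble(
    strategy_id = c("56@once", "57@once", "55-58@3", "55-59@4", "55-61@3",
                    "54-63@3", "55-64@3", "54-64@2", "55-65@2", "53-65@2",
                    "54-66@2", "53-67@2", "52-68@2", "50-68@2", "51-69@2",
                    "53-69@1", "52-69@1", "50-69@1"),
    icer = c(10211, 10946, 12814, 13129, 14738, 18417, 19733, 22395, 24589,
             24819, 28053, 29565, 36805, 43831, 50572, 55083, 57448, 97784)
  )
  # rebuild the implied (qaly, cost) points: unit QALY steps, costs from the
  # running ICER sums, then push through the full frontier machinery
  qal <- seq_len(nrow(tbl1))
  cost <- cumsum(tbl1$icer)
  pts <- tibble::tibble(strategy_id = tbl1$strategy_id, net_cost = cost,
                        qalys_gained = qal)
  fr <- build_frontier(pts, wtp = 20000)
  expect_equal(setdiff(fr$efficient$strategy_id, ".no_screening"),
               tbl1$strategy_id)
  expect_equal(fr$efficient$icer[-1], tbl1$icer)
  expect_equal(fr$optimum, "55-64@3")
  expect_equal(fr$efficient$icer[fr$efficient$strategy_id == "55-64@3"], 19733)

  expect_true(is.na(select_optimum(fr, wtp = 5000)))     # below the smallest
  expect_equal(select_optimum(fr, wtp = Inf), "50-69@1") # most effective
})

test_that("tidy, glance and autoplot expose the frontier", {
  pts <- random_ce_points(10, seed = 77)
  fr <- build_frontier(pts)
  td <- tidy(fr)
  expect_true(all(c("strategy_id", "status", "icer") %in% names(td)))
  expect_equal(nrow(td), 10)
  gl <- glance(fr)
  expect_equal(gl$n_efficient + gl$n_dominated, 10)
  expect_s3_class(autoplot(fr), "ggplot")
})
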