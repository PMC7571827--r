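# Independent oracles used to check the simulation and the frontier.

# ---- phase-type oracle for the preclinical sojourn ------------------------
# Transient generator over the 18 preclinical states with absorption into
# clinical detection; expected absorption time from the onset distribution,
# by direct linear algebra (independent of the simulation kernel).
phase_type_oracle <- function(params) {
  k <- prostasim:::nh_kernel(params)
  ed <- params$progression
  Q <- matrix(0, 18, 18)
  for (r in seq_len(nrow(ed))) Q[ed$from[r], ed$to[r]] <- Q[ed$from[r], ed$to[r]] + ed$rate[r]
  diag(Q) <- -(k$prog_total + k$clin)
  alpha <- params$onset_state_probs
  m1 <- solve(-Q, rep(1, 18))          # E[T | start s]
  m2 <- solve(-Q, m1)                  # used for E[T^2]/2
  mean_t <- sum(alpha * m1)
  var_t <- 2 * sum(alpha * m2) - mean_t^2
  list(Q = Q, mean = mean_t, sd = sqrt(var_t))
}

# density grid of the time from onset to clinical detection (phase-type),
# by explicit uniformised stepping of the Kolmogorov equations
phase_type_cdf_grid <- function(params, dt = 0.05, t_max = 80) {
  or <- phase_type_oracle(params)
  M <- diag(18) + or$Q * dt            # one-step transition (dt small)
  M[M < 0] <- 0
  p <- params$onset_state_probs
  steps <- ceiling(t_max / dt)
  surv <- numeric(steps + 1)           # P(not yet detected) at t = i*dt
  surv[1] <- sum(p)
  for (i in seq_len(steps)) {
    p <- as.numeric(p %*% M)
    surv[i + 1] <- sum(p)
  }
  list(t = (0:steps) * dt, surv = surv)
}

# continuous all-cause survival from a life table (uniform deaths in-year)
lt_survival_fun <- function(lt, min_age = 50) {
  ages <- lt$age[lt$age >= min_age]
  q <- lt$qx[lt$age >= min_age]
  S <- cumprod(c(1, 1 - q))
  function(a) {
    k <- findInterval(a, ages)
    k[k < 1] <- 1
    k[k > length(ages)] <- length(ages)
    frac <- a - ages[k]
    out <- S[k] * (1 - pmin(pmax(frac, 0), 1) * q[k])
    out[a >= max(ages) + 1] <- 0
    out
  }
}

# closed-form (numerical-integration) lifetime probability of clinical
# diagnosis before other-cause death, for a cohort entering alive and
# cancer-free at 50
lifetime_clinical_risk_oracle <- function(params, lt, da = 0.1, dt = 0.1) {
  k <- prostasim:::nh_kernel(params)
  Sd <- lt_survival_fun(lt, 50)
  pt <- phase_type_cdf_grid(params, dt = dt, t_max = 80)
  # detection-delay probability mass in [t, t+dt)
  det_mass <- -diff(pt$surv)
  t_mid <- pt$t[-1] - dt / 2
  # onset density on a fine age grid
  a_grid <- seq(50 + da / 2, 90 - da / 2, by = da)
  band <- findInterval(a_grid, k$onset_breaks)
  H <- k$onset_cumhaz[band] + (a_grid - k$onset_breaks[band]) * k$onset_rates[band]
  f_onset <- k$onset_rates[band] * exp(-H) * da
  total <- 0
  for (i in seq_along(a_grid)) {
    total <- total + f_onset[i] * sum(det_mass * Sd(a_grid[i] + t_mid))
  }
  total
}

# ---- frontier oracle -------------------------------------------------------
# Support-function characterisation: a point is efficient iff it is the
# unique maximiser of net monetary benefit lambda * qaly - cost for some
# lambda > 0 (the no-screening anchor is the maximiser for small lambda).
# Candidate lambdas are midpoints between consecutive distinct pairwise
# slopes, plus one beyond the largest.
frontier_oracle <- function(points) {
  pts <- rbind(data.frame(strategy_id = ".no_screening", net_cost = 0,
                          qalys_gained = 0),
               as.data.frame(points[c("strategy_id", "net_cost", "qalys_gained")]))
  # identical coordinates: keep lexicographically smallest id
  pts <- pts[order(pts$net_cost, -pts$qalys_gained, pts$strategy_id), ]
  pts <- pts[!duplicated(pts[c("net_cost", "qalys_gained")]), ]
  q <- pts$qalys_gained; cc <- pts$net_cost
  n <- length(q)
  slopes <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (q[i] != q[j]) slopes <- c(slopes, (cc[i] - cc[j]) / (q[i] - q[j]))
  }
  slopes <- sort(unique(slopes[slopes > 0]))
  lambdas <- c(slopes[1] / 2,
               if (length(slopes) > 1) (slopes[-1] + slopes[-length(slopes)]) / 2,
               slopes[length(slopes)] * 2 + 1)
  eff <- character(0)
  for (l in lambdas) {
    nmb <- l * q - cc
    top <- which(nmb == max(nmb))
    if (length(top) == 1) eff <- union(eff, pts$strategy_id[top])
  }
  sort(setdiff(eff, ".no_screening"))
}

random_ce_points <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    strategy_id = sprintf("s%02d", seq_len(n)),
    net_cost = round(stats::runif(n, 0.5, 100), 1),
    qalys_gained = round(stats::runif(n, -2, 10), 2)
  )
}
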