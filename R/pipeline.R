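# Orchestration: run configuration, the full strategy grid on shared
# histories, economics recomputation, univariate sensitivity analysis,
# summaries and delimited outputs.

#' Default run configuration
#'
#' Assembles every input of a full analysis with package defaults: the
#' synthetic life table and natural-history fixture, the 230-strategy grid,
#' screening parameters (attendance 0.80, biopsy compliance 0.90, biopsy
#' sensitivity 0.90, PSA cutoff 3 ng/mL), biopsy PPVs 0.227 (screen) and
#' 0.358 (clinical), 3.5% discounting from cohort entry at 50, and a WTP
#' threshold of 20000 EUR/QALY. The default desk cohort is 200,000 men.
#'
#' @param cohort_size number of simulated men.
#' @param master_seed single master seed governing every draw of the run.
#' @param ... overrides for any config element (`life_table`, `nh`, `grid`,
#'   `screening`, `policy`, `survival`, `utility_table`, `cost_table`,
#'   `discount`, `wtp`, `ppv_screen`, `ppv_clinical`, `cost_sens_pct`).
#' @return list of class `run_config`.
#' @export
default_run_config <- function(cohort_size = 2e5, master_seed = 1, ...) {
  cfg <- list(
    cohort_size = cohort_size,
    master_seed = master_seed,
    life_table = make_life_table(),
    nh = make_nh_fixture(),
    grid = enumerate_strategies(),
    screening = screening_params(),
    policy = default_treatment_policy(),
    survival = default_survival_model(),
    utility_table = default_utility_table(),
    cost_table = default_cost_table(),
    discount = discount_spec(),
    wtp = 20000,
    ppv_screen = 0.227,
    ppv_clinical = 0.358,
    cost_sens_pct = 0.20
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(dots)] <- dots
  validate_run_config(structure(cfg, class = "run_config"))
}

#' @keywords internal
validate_run_config <- function(cfg) {
  if (cfg$cohort_size < 1e3) {
    stop("config field `cohort_size`: must be >= 1000", call. = FALSE)
  }
  if (length(cfg$master_seed) != 1 || !is.finite(cfg$master_seed)) {
    stop("config field `master_seed`: one finite integer required", call. = FALSE)
  }
  validate_life_table(cfg$life_table)
  validate_nh_params(cfg$nh)
  if (!nrow(cfg$grid)) stop("config field `grid`: no strategies", call. = FALSE)
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys (all optional, defaults fill the rest):
#' `cohort_size`, `master_seed`, `wtp`, `discount_rate`,
#' `life_table: {makeham: [a, b, c], max_age}` or `{path}`,
#' `natural_history: {scale, seed, onset_scale, onset_shape, clin_scale}`,
#' `screening: {attendance, biopsy_compliance, biopsy_sensitivity,
#' attendance_mode}`, `survival: {hr, as_switch_prob_7y, cure: {c_max, beta}}`,
#' `ppv: {screen, clinical}`, `grid: {start_range, stop_cap, intervals,
#' single_ages}`, `utility_table: {path}`, `cost_table: {path}`.
#' Violations are reported with their field path.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  num <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1) {
      stop("config field `", field, "`: expected a single number", call. = FALSE)
    }
    x
  }
  if (!is.null(y$cohort_size)) args$cohort_size <- num(y$cohort_size, "cohort_size")
  if (!is.null(y$master_seed)) args$master_seed <- num(y$master_seed, "master_seed")
  if (!is.null(y$wtp)) args$wtp <- num(y$wtp, "wtp")
  if (!is.null(y$discount_rate)) {
    args$discount <- discount_spec(num(y$discount_rate, "discount_rate"))
  }
  if (!is.null(y$life_table)) {
    lt <- y$life_table
    args$life_table <- if (!is.null(lt$path)) read_life_table(lt$path)
      else make_life_table(unlist(lt$makeham %||% c(5e-4, 3e-5, 0.09)),
                           lt$max_age %||% 100)
  }
  if (!is.null(y$natural_history)) {
    nh <- y$natural_history
    p <- make_nh_fixture(scale = nh$scale %||% 1, seed = nh$seed %||% 1)
    free <- nh[intersect(names(nh), c("onset_scale", "onset_shape", "clin_scale"))]
    if (length(free)) p <- set_free_params(p, unlist(free))
    args$nh <- p
  }
  if (!is.null(y$screening)) {
    s <- y$screening
    args$screening <- screening_params(
      attendance = s$attendance %||% 0.80,
      biopsy_compliance = s$biopsy_compliance %||% 0.90,
      biopsy_sensitivity = s$biopsy_sensitivity %||% 0.90,
      attendance_mode = s$attendance_mode %||% "per_invitation"
    )
  }
  if (!is.null(y$survival)) {
    sv <- y$survival
    args$survival <- default_survival_model(
      hr = sv$hr %||% 0.56,
      as_switch_prob_7y = sv$as_switch_prob_7y %||% 0.30,
      cure = list(c_max = sv$cure$c_max %||% 0.8, beta = sv$cure$beta %||% 0.2)
    )
  }
  if (!is.null(y$ppv)) {
    if (!is.null(y$ppv$screen)) args$ppv_screen <- num(y$ppv$screen, "ppv.screen")
    if (!is.null(y$ppv$clinical)) args$ppv_clinical <- num(y$ppv$clinical, "ppv.clinical")
  }
  if (!is.null(y$grid)) {
    g <- y$grid
    args$grid <- enumerate_strategies(
      start_range = if (!is.null(g$start_range)) g$start_range[1]:g$start_range[2] else 50:55,
      stop_cap = g$stop_cap %||% 69,
      intervals = unlist(g$intervals %||% c(1, 2, 3, 4, 8)),
      single_ages = if (!is.null(g$single_ages)) g$single_ages[1]:g$single_ages[2] else 50:69
    )
  }
  if (!is.null(y$utility_table$path)) args$utility_table <- read_utility_table(y$utility_table$path)
  if (!is.null(y$cost_table$path)) args$cost_table <- read_cost_table(y$cost_table$path)
  do.call(default_run_config, args)
}

#' Run the full strategy grid on shared histories
#'
#' Simulates the no-screening cohort once, overlays every strategy on the
#' same histories (paired design, common random numbers), computes
#' per-strategy harms, benefits and discounted economics, and returns the
#' results table plus the stored economic components that let
#' [run_sensitivity()] re-price utilities and costs without re-simulating.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param keep_cohort keep the simulated cohort in the result (memory-heavy).
#' @param progress print per-stage progress.
#' @return object of class `psa_grid`: list with `results` (one row per
#'   strategy plus the `no_screening` row), `components`, `config`.
#' @export
run_grid <- function(config = default_run_config(), keep_cohort = FALSE,
                     progress = FALSE) {
  cfg <- validate_run_config(config)
  t0 <- Sys.time()
  say <- function(...) if (progress) message(sprintf("[%5.1fs] ", as.numeric(Sys.time() - t0, units = "secs")), ...)

  say("simulating ", cfg$cohort_size, " histories")
  cohort <- simulate_cohort(cfg$nh, cfg$life_table, cfg$cohort_size,
                            cfg$master_seed, policy = cfg$policy,
                            survival = cfg$survival)

  econ <- list(utility_table = cfg$utility_table, cost_table = cfg$cost_table,
               dspec = cfg$discount, ppv_screen = cfg$ppv_screen,
               ppv_clinical = cfg$ppv_clinical)
  base_events <- base_event_stream(cohort, cfg$ppv_clinical, cfg$utility_table)
  base_comp <- econ_components(base_events, cfg$utility_table, cfg$cost_table,
                               cfg$discount)
  base <- list(events = base_events, comp = base_comp,
               loss = loss_from_components(base_comp$D, cfg$utility_table),
               cost = cost_from_components(base_comp$C, cfg$cost_table))

  say("overlaying ", nrow(cfg$grid), " strategies")
  nS <- nrow(cfg$grid)
  rows <- vector("list", nS)
  Dm <- matrix(0, nS, nrow(cfg$utility_table),
               dimnames = list(cfg$grid$strategy_id, cfg$utility_table$state))
  Cm <- matrix(0, nS, nrow(cfg$cost_table),
               dimnames = list(cfg$grid$strategy_id, cfg$cost_table$item))
  lyg_disc <- lyg_undisc <- numeric(nS)
  for (i in seq_len(nS)) {
    ov <- screen_overlay(cohort, cfg$grid$test_ages[[i]], cfg$screening)
    agg <- aggregate_strategy(cohort, ov, cfg$grid$strategy_id[i],
                              cfg$screening, econ, base)
    rows[[i]] <- agg$row
    Dm[i, ] <- agg$D_screen
    Cm[i, ] <- agg$C_screen
    lyg_disc[i] <- agg$lyg_disc
    lyg_undisc[i] <- agg$lyg_undisc
    if (i %% 50 == 0) say(i, " strategies done")
  }

  per1000 <- 1000 / cfg$cohort_size
  p <- cohort$persons
  noscreen_row <- tibble::tibble(
    strategy_id = "no_screening",
    invitations = 0, tests = 0, screen_detected = 0,
    clinically_detected = sum(!is.na(p$cdx_age)) * per1000,
    biopsies = count_biopsies(0, sum(!is.na(p$cdx_age)),
                              cfg$ppv_screen, cfg$ppv_clinical) * per1000,
    overdiagnosed = 0, overdiagnosis_pct = NA_real_,
    pc_deaths_screen_arm = sum(p$death_cause == "pc") * per1000,
    pc_deaths_noscreen_arm = sum(p$death_cause == "pc") * per1000,
    pcm_reduction_pct = 0, life_years_gained = 0, life_years_gained_disc = 0,
    qaly_loss_screen = base$loss * per1000,
    qaly_loss_noscreen = base$loss * per1000,
    qalys_gained = 0, total_cost = base$cost * per1000, net_cost = 0
  )
  results <- dplyr::bind_rows(c(list(noscreen_row), rows))
  results <- dplyr::left_join(
    results,
    cfg$grid[c("strategy_id", "start_age", "interval", "last_test_age", "n_tests")],
    by = "strategy_id"
  )
  say("done")

  structure(
    list(results = results,
         components = list(D_screen = Dm, C_screen = Cm,
                           D_base = base_comp$D, C_base = base_comp$C,
                           lyg_disc = lyg_disc, lyg_undisc = lyg_undisc),
         config = cfg,
         cohort = if (keep_cohort) cohort else NULL),
    class = "psa_grid"
  )
}

# Re-price stored components under (possibly perturbed) utility/cost tables.
#' @keywords internal
recompute_economics <- function(grid, utility_table = grid$config$utility_table,
                                cost_table = grid$config$cost_table) {
  cmp <- grid$components
  cfg <- grid$config
  per1000 <- 1000 / cfg$cohort_size
  u <- stats::setNames(utility_table$utility, utility_table$state)
  cc <- stats::setNames(cost_table$unit_cost_eur, cost_table$item)
  one_minus_u <- 1 - u[colnames(cmp$D_screen)]
  loss_screen <- as.numeric(cmp$D_screen %*% one_minus_u)
  loss_base <- sum((1 - u[names(cmp$D_base)]) * cmp$D_base)
  cost_screen <- as.numeric(cmp$C_screen %*% cc[colnames(cmp$C_screen)])
  cost_base <- sum(cc[names(cmp$C_base)] * cmp$C_base)
  tibble::tibble(
    strategy_id = rownames(cmp$D_screen),
    qalys_gained = cmp$lyg_disc - (loss_screen - loss_base) * per1000,
    net_cost = (cost_screen - cost_base) * per1000
  )
}

#' Univariate sensitivity analysis
#'
#' For each health-state utility (replaced by its high and low variant) and
#' each unit cost (+/- `cost_sens_pct`), re-prices the stored components of
#' the SAME simulated histories, rebuilds the frontier and reselects the
#' optimum. Counts, detections and deaths never change across scenarios.
#'
#' @param grid a [run_grid()] result.
#' @return tibble `scenario, parameter, direction, optimum, start_age,
#'   last_test_age, interval, icer`.
#' @export
run_sensitivity <- function(grid) {
  cfg <- grid$config
  ut0 <- cfg$utility_table
  ct0 <- cfg$cost_table
  pct <- cfg$cost_sens_pct

  scenarios <- list(list(label = "Base case", parameter = "none",
                         direction = "base", ut = ut0, ct = ct0))
  for (i in seq_len(nrow(ut0))) {
    for (dir in c("high", "low")) {
      ut <- ut0
      ut$utility[i] <- if (dir == "high") ut0$u_high[i] else ut0$u_low[i]
      scenarios[[length(scenarios) + 1L]] <- list(
        label = sprintf("%s utility for %s",
                        if (dir == "high") "Highest" else "Lowest", ut0$state[i]),
        parameter = ut0$state[i], direction = dir, ut = ut, ct = ct0)
    }
  }
  for (j in seq_len(nrow(ct0))) {
    for (sgn in c(1, -1)) {
      ct <- ct0
      ct$unit_cost_eur[j] <- ct0$unit_cost_eur[j] * (1 + sgn * pct)
      scenarios[[length(scenarios) + 1L]] <- list(
        label = sprintf("Costs of %s %+d%%", ct0$item[j], as.integer(sgn * 100 * pct)),
        parameter = ct0$item[j],
        direction = if (sgn > 0) "up" else "down", ut = ut0, ct = ct)
    }
  }

  strat <- cfg$grid
  purrr::map_dfr(scenarios, function(sc) {
    pts <- recompute_economics(grid, sc$ut, sc$ct)
    fr <- build_frontier(pts, wtp = cfg$wtp)
    opt <- fr$optimum
    k <- match(opt, strat$strategy_id)
    tibble::tibble(
      scenario = sc$label, parameter = sc$parameter, direction = sc$direction,
      optimum = opt %||% NA_character_,
      start_age = if (!is.na(opt)) strat$start_age[k] else NA_real_,
      last_test_age = if (!is.na(opt)) strat$last_test_age[k] else NA_real_,
      interval = if (!is.na(opt)) strat$interval[k] else NA_real_,
      icer = if (!is.na(opt))
        fr$efficient$icer[match(opt, fr$efficient$strategy_id)] else NA_real_
    )
  })
}

#' Summarise a grid run
#'
#' Builds the cost-effectiveness frontier from the results table, selects
#' the optimum at the configured willingness-to-pay, and reports the
#' harms/benefits row of the optimum.
#'
#' @param grid a [run_grid()] result.
#' @param wtp threshold (default from the config).
#' @return object of class `psa_summary`: list with `frontier` (a
#'   `ce_result`), `optimum_row`, `results`.
#' @export
summarize_grid <- function(grid, wtp = grid$config$wtp) {
  res <- grid$results[grid$results$strategy_id != "no_screening", ]
  fr <- build_frontier(res[c("strategy_id", "net_cost", "qalys_gained")], wtp)
  opt_row <- if (!is.na(fr$optimum)) res[res$strategy_id == fr$optimum, ] else NULL
  structure(list(frontier = fr, optimum_row = opt_row, results = grid$results,
                 wtp = wtp),
            class = "psa_summary")
}

#' @export
print.psa_summary <- function(x, ...) {
  print(x$frontier)
  if (!is.null(x$optimum_row)) {
    r <- x$optimum_row
    cat(sprintf(paste0("optimum %s: PCM reduction %.1f%%, %.1f LYG/1000,\n",
                       "  %.1f%% of screen-detected overdiagnosed, net cost %.0f EUR/1000\n"),
                r$strategy_id, r$pcm_reduction_pct, r$life_years_gained,
                r$overdiagnosis_pct, r$net_cost))
  }
  invisible(x)
}

#' @rdname tidy.ce_result
#' @method tidy psa_grid
#' @export
tidy.psa_grid <- function(x, ...) x$results

#' @rdname tidy.ce_result
#' @method glance psa_grid
#' @export
glance.psa_grid <- function(x, ...) {
  s <- summarize_grid(x)
  g <- glance(s$frontier)
  g$cohort_size <- x$config$cohort_size
  g$master_seed <- x$config$master_seed
  g
}

#' Plot a grid run on the cost-effectiveness plane
#'
#' Net cost against QALYs gained per 1000 men for every strategy, coloured
#' by screening interval, with the efficient frontier drawn through.
#'
#' @param object a `psa_grid`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot psa_grid
#' @export
autoplot.psa_grid <- function(object, ...) {
  res <- object$results[object$results$strategy_id != "no_screening", ]
  res$interval_lab <- ifelse(is.na(res$interval), "once", as.character(res$interval))
  fr <- summarize_grid(object)$frontier
  ggplot2::ggplot(res, ggplot2::aes(x = .data$qalys_gained, y = .data$net_cost)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$interval_lab), alpha = 0.8) +
    ggplot2::geom_line(data = fr$efficient, colour = "grey30") +
    ggplot2::labs(x = "QALYs gained per 1000 men",
                  y = "Net cost per 1000 men (EUR, discounted)",
                  colour = "interval (y)") +
    ggplot2::theme_minimal()
}

#' Write run outputs as delimited tables plus a manifest
#'
#' Writes `results.csv`, `frontier.csv` (strategy, cost, QALY, ICER, status)
#' and, when supplied, `sensitivity.csv`, together with `manifest.json`
#' recording the seed, package version and a parameter hash.
#'
#' @param grid a [run_grid()] result.
#' @param dir output directory (created if needed).
#' @param sensitivity optional [run_sensitivity()] table.
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(grid, dir, sensitivity = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- grid$results
  res$test_ages <- NULL
  utils::write.csv(as.data.frame(res), file.path(dir, "results.csv"),
                   row.names = FALSE)
  fr <- tidy(summarize_grid(grid)$frontier)
  utils::write.csv(as.data.frame(fr), file.path(dir, "frontier.csv"),
                   row.names = FALSE)
  if (!is.null(sensitivity)) {
    utils::write.csv(as.data.frame(sensitivity),
                     file.path(dir, "sensitivity.csv"), row.names = FALSE)
  }
  manifest <- list(
    master_seed = grid$config$master_seed,
    cohort_size = grid$config$cohort_size,
    package_version = as.character(utils::packageVersion("prostasim")),
    r_version = R.version.string,
    parameter_hash = rlang::hash(grid$config[
      c("nh", "screening", "survival", "utility_table", "cost_table",
        "discount", "wtp", "ppv_screen", "ppv_clinical")])
  )
  writeLines(.to_json(manifest), file.path(dir, "manifest.json"))
  invisible(dir)
}

# minimal JSON writer for the flat manifest (values are scalars)
#' @keywords internal
.to_json <- function(x) {
  esc <- function(s) gsub('"', '\\\\"', s)
  kv <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    val <- if (is.numeric(v)) format(v, digits = 15) else paste0('"', esc(as.character(v)), '"')
    paste0('"', esc(nm), '": ', val)
  }, character(1))
  paste0("{\n  ", paste(kv, collapse = ",\n  "), "\n}")
}
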