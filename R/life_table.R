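# Life tables: synthetic Gompertz-Makeham fixture, IO, and sampling of
# other-cause death ages.

#' Build a synthetic Gompertz-Makeham life table
#'
#' Produces a single-year life table whose conditional death probabilities
#' follow a Gompertz-Makeham hazard \eqn{h(t) = a + b e^{c t}}. The table is
#' a stand-in for a national all-cause life table: smooth, three parameters,
#' realistic adult mortality. The final row closes the table out with
#' `qx = 1`.
#'
#' @param makeham numeric vector `c(a, b, c)` of nonnegative hazard
#'   parameters: constant background rate `a`, senescent level `b` and slope
#'   `c` (per year of age).
#' @param max_age integer last age in the table (>= 70); `qx` is forced to 1
#'   there.
#' @return A tibble with columns `age` (0..`max_age`) and `qx`, the
#'   conditional probability of death within one year. Carries attribute
#'   `synthetic = TRUE`.
#' @examples
#' lt <- make_life_table()
#' life_expectancy(lt, at_age = 50)
#' @export
make_life_table <- function(makeham = c(5e-4, 3e-5, 0.09), max_age = 100) {
  if (length(makeham) != 3 || any(!is.finite(makeham)) || any(makeham < 0)) {
    stop("`makeham` must be three finite nonnegative reals c(a, b, c)",
         call. = FALSE)
  }
  if (max_age < 70) stop("`max_age` must be at least 70", call. = FALSE)
  a <- makeham[1]; b <- makeham[2]; cc <- makeham[3]
  age <- 0:max_age
  # integrated hazard over [age, age + 1)
  H <- if (cc > 0) {
    a + b / cc * (exp(cc * (age + 1)) - exp(cc * age))
  } else {
    a + b
  }
  qx <- pmin(1, 1 - exp(-H))
  qx[length(qx)] <- 1
  lt <- tibble::tibble(age = age, qx = qx)
  attr(lt, "synthetic") <- TRUE
  validate_life_table(lt)
}

#' @keywords internal
validate_life_table <- function(lt) {
  stopifnot(all(c("age", "qx") %in% names(lt)))
  if (any(lt$qx < 0 | lt$qx > 1)) stop("life table qx outside [0, 1]", call. = FALSE)
  if (lt$qx[nrow(lt)] != 1) stop("life table must close out with qx = 1", call. = FALSE)
  if (any(diff(lt$age) != 1)) stop("life table ages must increase by 1", call. = FALSE)
  lt
}

#' Read or write a life table as delimited text
#'
#' Plain CSV with header `age,qx`; comment lines starting `#` are ignored on
#' read and a `# synthetic` marker is written for generated tables.
#'
#' @param path file path.
#' @param lt a life table tibble as from [make_life_table()].
#' @return `read_life_table()` returns the life-table tibble.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  validate_life_table(tibble::as_tibble(df[c("age", "qx")]))
}

#' @rdname read_life_table
#' @export
write_life_table <- function(lt, path) {
  validate_life_table(lt)
  con <- file(path, "w")
  on.exit(close(con))
  if (isTRUE(attr(lt, "synthetic"))) {
    writeLines("# synthetic Gompertz-Makeham life table (generated, not observed data)", con)
  }
  utils::write.csv(as.data.frame(lt), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# P(death in year k | alive at min_age), k = min_age..max_age
.death_year_probs <- function(lt, min_age = 0) {
  keep <- lt$age >= min_age
  q <- lt$qx[keep]
  S <- cumprod(c(1, 1 - q))[seq_along(q)]  # survival to start of each year
  p <- S * q
  p / sum(p)                                # sums to 1 because final qx = 1
}

#' Remaining life expectancy from a life table
#'
#' Expected death age for a person alive at `at_age`, with deaths placed
#' uniformly within their year (so each year of death contributes its
#' midpoint).
#'
#' @param lt life table.
#' @param at_age conditioning age (a table age).
#' @return expected age at death (years).
#' @export
life_expectancy <- function(lt, at_age = 0) {
  validate_life_table(lt)
  p <- .death_year_probs(lt, min_age = at_age)
  ages <- lt$age[lt$age >= at_age]
  sum(p * (ages + 0.5))
}

#' Sample other-cause death ages from a life table
#'
#' Draws `length(ids)` death ages, each from the discrete year-of-death
#' distribution implied by the table, with uniform placement within the year
#' of death. Optionally conditions on survival to `min_age` (used for cohort
#' entry at age 50). Draws come from the counter-based stream, so the age for
#' a given `(seed, id)` never depends on how many other people are sampled.
#'
#' @param lt life table.
#' @param ids integer person ids (one draw each).
#' @param seed master seed.
#' @param min_age condition on being alive at this age (default 0).
#' @return numeric vector of death ages.
#' @export
sample_other_cause_death <- function(lt, ids, seed, min_age = 0) {
  validate_life_table(lt)
  p <- .death_year_probs(lt, min_age = min_age)
  cp <- cumsum(p)
  cp[length(cp)] <- 1
  u_year <- runif_ctr(seed, ids, .SLOT$ocd_year)
  u_frac <- runif_ctr(seed, ids, .SLOT$ocd_frac)
  year <- findInterval(u_year, cp, left.open = TRUE) + 1L
  ages <- lt$age[lt$age >= min_age]
  ages[year] + u_frac
}
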