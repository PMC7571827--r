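# Cost-effectiveness analysis: dominance elimination, efficient frontier,
# ICERs, willingness-to-pay optimum.

#' Incremental cost-effectiveness ratio between two points
#'
#' `(cost_b - cost_a) / (qaly_b - qaly_a)`; `b` must be strictly more
#' effective than `a`.
#'
#' @param a,b lists or one-row data frames with `net_cost` and
#'   `qalys_gained`.
#' @return EUR per QALY.
#' @export
icer <- function(a, b) {
  dq <- b$qalys_gained - a$qalys_gained
  if (dq == 0) stop("ICER undefined: equal QALYs", call. = FALSE)
  (b$net_cost - a$net_cost) / dq
}

#' Build the cost-effectiveness frontier
#'
#' Takes one `(net_cost, qalys_gained)` point per strategy (both incremental
#' to no screening), anchors the analysis at the no-screening point (0, 0),
#' removes strongly dominated strategies (at least as expensive as and less
#' effective than an alternative), then iteratively removes weakly
#' (extended-) dominated strategies until ICERs are strictly increasing along
#' the cost-ordered efficient list. Equivalent to the upper-left convex hull
#' of the point cloud.
#'
#' @param points data frame with `strategy_id`, `net_cost`, `qalys_gained`
#'   (per 1000 men).
#' @param wtp willingness-to-pay threshold in EUR per QALY (default 20000).
#' @return object of class `ce_result`: list with `efficient` (cost-ordered
#'   tibble with `icer`), `dominated` (with `reason` in strong/weak),
#'   `optimum` (strategy id or `NA`), `wtp`, `points`.
#' @examples
#' pts <- tibble::tibble(strategy_id = c("a", "b"),
#'                       net_cost = c(1e5, 2e5), qalys_gained = c(5, 6))
#' build_frontier(pts)$efficient
#' @export
build_frontier <- function(points, wtp = 20000) {
  stopifnot(nrow(points) >= 1)
  pts <- tibble::as_tibble(points[c("strategy_id", "net_cost", "qalys_gained")])
  if (!all(is.finite(pts$net_cost)) || !all(is.finite(pts$qalys_gained))) {
    stop("frontier points must be finite", call. = FALSE)
  }
  anchor <- tibble::tibble(strategy_id = ".no_screening",
                           net_cost = 0, qalys_gained = 0)
  all_pts <- dplyr::bind_rows(anchor, pts)

  # identical (cost, qaly) duplicates: keep the lexicographically smallest id
  all_pts <- dplyr::arrange(all_pts, net_cost, dplyr::desc(qalys_gained),
                            strategy_id)
  dup <- duplicated(all_pts[c("net_cost", "qalys_gained")])

  reason <- rep(NA_character_, nrow(all_pts))
  reason[dup] <- "strong"
  for (i in seq_len(nrow(all_pts))) {
    if (!is.na(reason[i])) next
    dom <- all_pts$net_cost <= all_pts$net_cost[i] &
      all_pts$qalys_gained >= all_pts$qalys_gained[i] &
      (all_pts$net_cost < all_pts$net_cost[i] |
         all_pts$qalys_gained > all_pts$qalys_gained[i]) &
      is.na(reason)
    dom[i] <- FALSE
    if (any(dom)) reason[i] <- "strong"
  }

  cand <- all_pts[is.na(reason), ]
  # cand is cost-ordered with strictly increasing cost and qalys; scan a
  # stack, popping points whose incremental ICER is not strictly below the
  # next segment's (weak / extended dominance)
  stack <- 1L
  if (nrow(cand) > 1) {
    for (i in 2:nrow(cand)) {
      while (length(stack) >= 2) {
        top <- stack[length(stack)]
        below <- stack[length(stack) - 1]
        ic_in <- icer(cand[below, ], cand[top, ])
        ic_out <- icer(cand[top, ], cand[i, ])
        if (ic_out <= ic_in) stack <- stack[-length(stack)] else break
      }
      stack <- c(stack, i)
    }
  }
  weak_ids <- cand$strategy_id[-stack]
  reason[match(weak_ids, all_pts$strategy_id)] <- "weak"

  eff <- cand[stack, ]
  eff$icer <- c(NA_real_,
                if (nrow(eff) > 1)
                  diff(eff$net_cost) / diff(eff$qalys_gained) else numeric(0))
  dominated <- tibble::tibble(strategy_id = all_pts$strategy_id[!is.na(reason)],
                              reason = reason[!is.na(reason)])
  dominated <- dominated[dominated$strategy_id != ".no_screening", ]

  res <- structure(
    list(efficient = eff, dominated = dominated, optimum = NA_character_,
         wtp = wtp, points = pts),
    class = "ce_result"
  )
  res$optimum <- select_optimum(res, wtp)
  res
}

#' Select the optimum strategy at a willingness-to-pay threshold
#'
#' Among efficient strategies, the one with the largest ICER at or below
#' `wtp`; `NA` if every efficient ICER exceeds it.
#'
#' @param result a `ce_result` from [build_frontier()].
#' @param wtp threshold in EUR per QALY.
#' @return strategy id or `NA_character_`.
#' @export
select_optimum <- function(result, wtp = result$wtp) {
  eff <- result$efficient
  eff <- eff[!is.na(eff$icer) & eff$strategy_id != ".no_screening", ]
  ok <- eff$icer <= wtp
  if (!any(ok)) return(NA_character_)
  eff$strategy_id[which.max(ifelse(ok, eff$icer, -Inf))]
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result> ", nrow(x$points), " strategies; ",
      sum(x$efficient$strategy_id != ".no_screening"), " efficient, ",
      nrow(x$dominated), " dominated\n", sep = "")
  cat("  optimum at WTP ", format(x$wtp, big.mark = " "), " EUR/QALY: ",
      if (is.na(x$optimum)) "none (no screening)" else x$optimum, "\n", sep = "")
  print(x$efficient)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cost-effectiveness result
#'
#' One row per strategy with its frontier status (`efficient`, `strong`,
#' `weak`) and the ICER for efficient strategies.
#'
#' @param x a `ce_result`.
#' @param ... unused.
#' @return tibble.
#' @method tidy ce_result
#' @export
tidy.ce_result <- function(x, ...) {
  eff <- x$efficient
  out <- x$points
  out$status <- "efficient"
  out$status[match(x$dominated$strategy_id, out$strategy_id)] <- x$dominated$reason
  out$icer <- eff$icer[match(out$strategy_id, eff$strategy_id)]
  dplyr::arrange(out, .data$net_cost)
}

#' @rdname tidy.ce_result
#' @method glance ce_result
#' @export
glance.ce_result <- function(x, ...) {
  tibble::tibble(
    n_strategies = nrow(x$points),
    n_efficient = sum(x$efficient$strategy_id != ".no_screening"),
    n_dominated = nrow(x$dominated),
    optimum = x$optimum,
    optimum_icer = if (!is.na(x$optimum))
      x$efficient$icer[match(x$optimum, x$efficient$strategy_id)] else NA_real_,
    wtp = x$wtp
  )
}

#' Plot the cost-effectiveness plane with the efficient frontier
#'
#' @param object a `ce_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ce_result
#' @export
autoplot.ce_result <- function(object, ...) {
  pts <- tidy(object)
  eff <- object$efficient
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$qalys_gained, y = .data$net_cost)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), alpha = 0.7) +
    ggplot2::geom_line(data = eff, colour = "black") +
    ggplot2::geom_point(
      data = eff[which(eff$strategy_id == object$optimum), ],
      shape = 21, size = 3, stroke = 1.2, colour = "black"
    ) +
    ggplot2::labs(x = "QALYs gained per 1000 men",
                  y = "Net cost per 1000 men (EUR, discounted)",
                  colour = NULL,
                  title = "Cost-effectiveness plane and efficient frontier") +
    ggplot2::theme_minimal()
}
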