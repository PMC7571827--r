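# The 18 preclinical detectable states: 3 T stages x 3 Gleason categories
# x 2 extents, with a severity-ordered acyclic progression graph.

.T_STAGES <- c("T1", "T2", "T3")
.GLEASONS <- c("<7", "7", ">7")
.EXTENTS  <- c("local-regional", "distant")

#' The 18 preclinical disease states
#'
#' Enumerates every combination of tumour stage (T1 < T2 < T3), Gleason
#' category (<7 < 7 < >7) and extent (local-regional < distant). The integer
#' `state` id indexes all per-state parameter vectors in the package.
#'
#' @return tibble with columns `state`, `t_stage`, `gleason`, `extent` and the
#'   integer severity ranks `t_i`, `g_i`, `e_i`.
#' @examples
#' disease_stages()
#' @export
disease_stages <- function() {
  grid <- tidyr::expand_grid(e_i = 1:2, t_i = 1:3, g_i = 1:3)
  tibble::tibble(
    state   = seq_len(nrow(grid)),
    t_stage = .T_STAGES[grid$t_i],
    gleason = .GLEASONS[grid$g_i],
    extent  = .EXTENTS[grid$e_i],
    t_i     = grid$t_i,
    g_i     = grid$g_i,
    e_i     = grid$e_i
  )
}

#' @keywords internal
state_id <- function(t_stage, gleason, extent) {
  t_i <- match(t_stage, .T_STAGES)
  g_i <- match(gleason, .GLEASONS)
  e_i <- match(extent, .EXTENTS)
  if (anyNA(t_i) || anyNA(g_i) || anyNA(e_i)) {
    stop("unknown disease stage label", call. = FALSE)
  }
  as.integer((e_i - 1L) * 9L + (t_i - 1L) * 3L + g_i)
}

# Severity-increasing single-step edges: raise exactly one of the three
# ordered components. The graph is acyclic by construction.
#' @keywords internal
progression_edges <- function() {
  st <- disease_stages()
  edges <- list()
  for (i in seq_len(nrow(st))) {
    r <- st[i, ]
    if (r$t_i < 3) {
      edges[[length(edges) + 1L]] <- c(i, state_id(.T_STAGES[r$t_i + 1], r$gleason, r$extent))
    }
    if (r$g_i < 3) {
      edges[[length(edges) + 1L]] <- c(i, state_id(r$t_stage, .GLEASONS[r$g_i + 1], r$extent))
    }
    if (r$e_i < 2) {
      edges[[length(edges) + 1L]] <- c(i, state_id(r$t_stage, r$gleason, .EXTENTS[2]))
    }
  }
  m <- do.call(rbind, edges)
  tibble::tibble(from = as.integer(m[, 1]), to = as.integer(m[, 2]))
}
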