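#' Hexagonal neighborhood index table
#'
#' Linear indices of all cells within hex distance `radius` of each cell
#' (inclusive of the cell itself), as an `n x K` matrix. Used by the
#' reference cellular automaton to accumulate neighborhood sums.
#'
#' @param config a [lattice_config()].
#' @param radius neighborhood radius (hex rings).
#' @return integer matrix, one row per cell.
#' @export
hex_neighborhoods <- function(config, radius) {
  tpl <- hex_ball(config, 1L, radius)
  K <- length(tpl)
  out <- matrix(0L, config$n, K)
  out[1L, ] <- tpl
  # neighborhoods are not pure translations in offset coordinates (row
  # parity), so BFS per cell; grids are small enough for this precomputation.
  for (i in seq_len(config$n)[-1L]) out[i, ] <- hex_ball(config, i, radius)
  out
}

#' Reference cellular-automaton parameters
#'
#' The discretized Turing rule used as a cross-validation oracle for the
#' chemical model. `N1` is the number of active cells within radius `s` of a
#' focal cell, `N2` the number within radius `t_range` (default `2 * s`).
#' The basic rule activates a cell when `N1 > N2 * w`; the banded variant
#' activates only in `N2 * w1 < N1 <= N2 * w2`, which yields self-dividing
#' (replicating) domains.
#'
#' @param w activation threshold ratio (basic rule).
#' @param w1,w2 band edges for the banded rule, `0 < w1 < w2 < 1`.
#' @param s inner neighborhood radius.
#' @param t_range outer neighborhood radius (`> s`).
#' @return An object of class `ca_params`.
#' @export
ca_params <- function(w = 0.650, w1 = w, w2 = NA_real_, s = 2L,
                      t_range = 2L * s) {
  if (t_range <= s) stop("t_range must exceed s")
  stopifnot_prob(w, "w")
  if (!is.na(w2) && !(w2 > w1 && w1 > 0 && w2 < 1)) {
    stop("need 1 > w2 > w1 > 0")
  }
  structure(list(w = w, w1 = w1, w2 = w2, s = as.integer(s),
                 t_range = as.integer(t_range)),
            class = "ca_params")
}

#' Neighborhood activation sums
#'
#' @param state binary vector over cells.
#' @param nb_s,nb_t index matrices from [hex_neighborhoods()] for the inner
#'   and outer radii.
#' @return list with `N1`, `N2` per cell.
#' @export
neighborhood_sums <- function(state, nb_s, nb_t) {
  n <- length(state)
  list(N1 = rowSums(matrix(state[nb_s], n)),
       N2 = rowSums(matrix(state[nb_t], n)))
}

#' One step of the basic threshold rule
#'
#' `1` if `N1 > N2 * w`, `0` if `N1 < N2 * w`, unchanged on exact equality
#' (tested exactly on the rational product; the equality branch keeps an
#' all-zero grid quiescent). Synchronous update.
#'
#' @param state binary vector over cells.
#' @param params a [ca_params()].
#' @param nb_s,nb_t neighborhood index matrices (precompute once per grid).
#' @return the next binary state vector.
#' @export
step_expression1 <- function(state, params, nb_s, nb_t) {
  ns <- neighborhood_sums(state, nb_s, nb_t)
  thr <- ns$N2 * params$w
  ifelse(ns$N1 > thr, 1, ifelse(ns$N1 < thr, 0, state))
}

#' One step of the banded (self-replication) rule
#'
#' Applies, in order: `0` if `N1 > N2 * w2`; else `1` if `N1 > N2 * w1`;
#' unchanged if `N1 = N2 * w1`; else `0`. The upper cutoff kills domain
#' cores, which splits growing domains and produces replication.
#'
#' @inheritParams step_expression1
#' @return the next binary state vector.
#' @export
step_expression2 <- function(state, params, nb_s, nb_t) {
  if (is.na(params$w2)) stop("params$w2 must be set for the banded rule")
  ns <- neighborhood_sums(state, nb_s, nb_t)
  lo <- ns$N2 * params$w1
  hi <- ns$N2 * params$w2
  out <- ifelse(ns$N1 > hi, 0,
                ifelse(ns$N1 > lo, 1,
                       ifelse(ns$N1 == lo, state, 0)))
  out
}

#' Run the reference cellular automaton
#'
#' @param config a [lattice_config()].
#' @param params a [ca_params()]; the banded rule is used when `w2` is set.
#' @param steps number of synchronous updates.
#' @param init initial binary state; default random with activation
#'   probability `fill`.
#' @param fill initial activation probability when `init` is NULL.
#' @return list with `state` (final binary vector), `active` (per-step count
#'   of active cells) and the inputs.
#' @export
run_ca <- function(config, params = ca_params(), steps = 200L,
                   init = NULL, fill = 0.3) {
  if (is.null(init)) init <- as.numeric(stats::runif(config$n) < fill)
  nb_s <- hex_neighborhoods(config, params$s)
  nb_t <- hex_neighborhoods(config, params$t_range)
  stepper <- if (is.na(params$w2)) step_expression1 else step_expression2
  state <- init
  active <- numeric(steps)
  for (k in seq_len(steps)) {
    state <- stepper(state, params, nb_s, nb_t)
    active[k] <- sum(state)
  }
  list(state = state, active = active, params = params, config = config)
}
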