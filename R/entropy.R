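#' Maximum configuration entropy
#'
#' Stirling-approximated log of the number of ways to distribute `m`
#' indistinguishable molecules equally over `X` cells:
#' `(m log m - m) - X * ((m/X) log(m/X) - m/X)` in natural-log units
#' (Boltzmann constant 1). This is the entropy of the perfectly uniform
#' arrangement and the reference point for morphological entropy.
#'
#' @param m total molecule count (>= 0).
#' @param X number of cells (>= 1).
#' @return entropy value (0 when `m = 0` or `X = 1`).
#' @export
max_config_entropy <- function(m, X) {
  if (X < 1) stop("X must be >= 1")
  if (m == 0) return(0)
  u <- m / X
  (m * log(m) - m) - (u * log(u) - u) * X
}

#' Configuration entropy of an occupancy vector
#'
#' `(m log m - m) - sum(U log U - U)` over per-cell occupancies `U`
#' (with `0 log 0 := 0`), natural-log units. Equals [max_config_entropy()]
#' when the occupancy is exactly uniform, and 0 when all molecules sit in a
#' single cell.
#'
#' @param occupancies non-negative per-cell counts.
#' @return entropy value.
#' @export
config_entropy <- function(occupancies) {
  if (any(occupancies < 0)) stop("occupancies must be >= 0")
  m <- sum(occupancies)
  if (m == 0) return(0)
  u <- occupancies[occupancies > 0]
  (m * log(m) - m) - sum(u * log(u) - u)
}

#' Morphological entropy
#'
#' Maximum configuration entropy minus actual configuration entropy of an
#' occupancy vector: 0 for a uniform spatial arrangement, maximal when all
#' molecules are clustered in one cell. Larger values mean more spatial
#' order (lower placement entropy).
#'
#' @param occupancies non-negative per-cell counts.
#' @return value in `[0, max_config_entropy(sum(occupancies),
#'   length(occupancies))]`.
#' @examples
#' morphological_entropy(rep(1, 6))        # uniform -> 0
#' morphological_entropy(c(6, 0, 0, 0, 0, 0))  # clustered -> 6 log 6
#' @export
morphological_entropy <- function(occupancies) {
  max_config_entropy(sum(occupancies), length(occupancies)) -
    config_entropy(occupancies)
}

#' Diffusion entropy production of the current state
#'
#' Discrete analogue of the integral of `(grad C)^2 / C` (diffusion
#' coefficient and Boltzmann constant both 1): for every unordered pair of
#' adjacent cells and every selected species, the squared count difference
#' divided by the mean of the two counts, summed. Pairs with both counts zero
#' contribute nothing. Uniform occupancy gives 0.
#'
#' @param grid a `grid_state`.
#' @param species species ids to include (default all 15 free species).
#' @return entropy production value for this state.
#' @export
diffusion_entropy_production <- function(grid, species = 1:15) {
  nbr <- grid$config$nbr
  total <- 0
  for (s in species) {
    a <- grid$species[, s]
    for (d in c(1L, 5L, 6L)) {  # E, SE, SW: each adjacency counted once
      b <- a[nbr[, d]]
      den <- (a + b) / 2
      ok <- den > 0
      if (any(ok)) total <- total + sum((a[ok] - b[ok])^2 / den[ok])
    }
  }
  total
}

#' Cumulative reaction entropy production
#'
#' One unit of entropy is produced per molecule converted by any reaction
#' whose products do not include molecule 1, and one unit is consumed per
#' molecule returned to molecule 1. Given per-step tallies of the two, the
#' cumulative sum is the reaction entropy production trajectory.
#'
#' @param plus per-step counts of molecules converted away from molecule 1.
#' @param minus per-step counts of molecules returned to molecule 1.
#' @return numeric vector of the cumulative entropy production.
#' @examples
#' reaction_entropy_production(c(100, 50), c(30, 20))  # 70, 100
#' @export
reaction_entropy_production <- function(plus, minus) {
  if (length(plus) != length(minus)) stop("tallies must have equal length")
  cumsum(plus - minus)
}
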