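#' Local information-polymer ratio
#'
#' The molecule-6 fraction carried by the polymer-1 boxes of each cell:
#' `sum(n6) / sum(n6 + n7)` over all boxes present. This is the morphology
#' parameter `w` that the ratio-conversion reaction reads. Cells with no
#' polymer-1 box return `NA` (no informant, no conversion).
#'
#' @param grid a `grid_state`.
#' @return numeric(n) of per-cell ratios, `NA` where no box is present.
#' @export
read_local_w <- function(grid) {
  tot6 <- as.vector(grid$p1_counts %*% grid$p1_comps[, 1])
  tot <- as.vector(grid$p1_counts %*%
                     (grid$p1_comps[, 1] + grid$p1_comps[, 2]))
  w <- tot6 / tot
  w[tot == 0] <- NA_real_
  w
}

#' Synthesize information polymers (polymer 1)
#'
#' In every cell that holds at least one unit of molecule 11 and at least one
#' polymer-1 box (the template), one new box is assembled with the same
#' molecule-6/7 composition as the cell's existing boxes, debiting
#' `round(w * p1_size)` free molecule-6 and the complement of molecule-7
#' monomers. At most one synthesis per cell per step; skipped when the free
#' monomer pools are insufficient. Polymer 1 never decomposes, so the founder
#' ratio is inherited indefinitely.
#'
#' @param grid a `grid_state`.
#' @return the updated `grid_state`.
#' @export
synthesize_polymer1 <- function(grid) {
  w <- read_local_w(grid)
  p1 <- grid$p1_size
  n6_new <- round_half_up(w * p1)
  elig <- !is.na(w) & grid$species[, 11] >= 1 &
    grid$species[, 6] >= n6_new & grid$species[, 7] >= (p1 - n6_new)
  elig[is.na(elig)] <- FALSE
  if (!any(elig)) return(grid)
  idx <- which(elig)
  comp6 <- n6_new[idx]
  for (u in unique(comp6)) {
    k <- match(u, grid$p1_comps[, 1])
    if (is.na(k)) {
      grid$p1_comps <- rbind(grid$p1_comps, c(u, p1 - u))
      grid$p1_counts <- cbind(grid$p1_counts, 0)
      k <- nrow(grid$p1_comps)
    }
    at <- idx[comp6 == u]
    grid$p1_counts[at, k] <- grid$p1_counts[at, k] + 1
  }
  grid$species[idx, 6] <- grid$species[idx, 6] - comp6
  grid$species[idx, 7] <- grid$species[idx, 7] - (p1 - comp6)
  grid
}

#' Synthesize membrane polymers (polymer 2)
#'
#' In every cell that holds at least one unit of molecule 13 and at least 100
#' free molecule-12 monomers, 100 monomers are linked into one new polymer-2
#' box. At most one synthesis per cell per step. The spatial accumulation of
#' these boxes is what renders the cell-like region.
#'
#' @param grid a `grid_state`.
#' @return the updated `grid_state`.
#' @export
synthesize_polymer2 <- function(grid) {
  elig <- grid$species[, 13] >= 1 & grid$species[, 12] >= 100
  if (any(elig)) {
    grid$poly2[elig] <- grid$poly2[elig] + 1
    grid$species[elig, 12] <- grid$species[elig, 12] - 100
  }
  grid
}

#' Degrade membrane polymers
#'
#' In cells with no molecule 13, each polymer-2 box independently degrades
#' with probability `p` (default 5%), returning its 100 molecule-12 monomers
#' to the free pool. Cells holding molecule 13 are protected.
#'
#' @param grid a `grid_state`.
#' @param p per-box degradation probability.
#' @return the updated `grid_state`.
#' @export
degrade_polymer2 <- function(grid, p = 0.05) {
  stopifnot_prob(p, "p")
  at <- which(grid$species[, 13] == 0 & grid$poly2 > 0)
  if (length(at)) {
    deg <- stats::rbinom(length(at), grid$poly2[at], p)
    grid$poly2[at] <- grid$poly2[at] - deg
    grid$species[at, 12] <- grid$species[at, 12] + 100 * deg
  }
  grid
}
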