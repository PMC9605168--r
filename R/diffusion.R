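#' Residual-rate table
#'
#' The residual rate `r` of a species is the fraction of its molecules that
#' stay in their cell each time step; `1 - r` diffuses evenly toward the six
#' neighbors. It plays the role of an inverse diffusion coefficient: `r=0`
#' is the fastest diffusion, `r=1` immobilizes the species. Defaults are the
#' standard parameter set: molecule 2 diffuses slowly (r = 0.75) and molecule
#' 3 quickly (r = 0.05), which creates the short-range/long-range morphogen
#' pair driving the Turing mechanism; molecules 4 and 5 inherit the rates of
#' 2 and 3; the bookkeeping species 8-11 and 13-15 do not diffuse at all.
#'
#' @param species numeric(15) of per-species residual rates.
#' @param poly1 residual rate of polymer-1 boxes.
#' @param poly2 residual rate of polymer-2 boxes.
#' @return An object of class `residual_rate_table`.
#' @export
residual_rate_table <- function(species = c(0, 0.75, 0.05, 0.75, 0.05,
                                            0, 0, 1, 1, 1, 1, 0, 1, 1, 1),
                                poly1 = 0.1, poly2 = 0.75) {
  if (length(species) != 15) stop("species must have length 15")
  stopifnot_prob(species, "residual rates")
  stopifnot_prob(poly1, "poly1 residual rate")
  stopifnot_prob(poly2, "poly2 residual rate")
  structure(list(species = species, poly1 = poly1, poly2 = poly2),
            class = "residual_rate_table")
}

# Choose, for each row, a uniformly random subset of `k[i]` of the 6 neighbor
# slots (0 <= k <= 6). Returns an m x 6 0/1 matrix. Ranks 6 uniform keys per
# row; slot is selected iff its rank <= k.
sample_direction_subsets <- function(k) {
  m <- length(k)
  keys <- matrix(stats::runif(6L * m), m, 6L)
  rank <- matrix(1L, m, 6L)
  for (j in 1:6) {
    for (l in 1:6) {
      if (l != j) rank[, j] <- rank[, j] + (keys[, l] < keys[, j])
    }
  }
  (rank <= k) * 1
}

#' Diffuse one free species across the lattice
#'
#' Synchronous residual-rate diffusion: each cell with `b` molecules keeps
#' `round(b * r)` and sends the rest evenly to its six neighbors
#' (`floor(moved / 6)` each); the indivisible remainder (`moved mod 6`
#' molecules) is handed one-by-one to distinct neighbors chosen uniformly at
#' random. All sends are computed from the pre-step state. Species totals are
#' conserved exactly.
#'
#' @param grid a `grid_state`.
#' @param species species id in 1..15.
#' @param r residual rate in \[0, 1\].
#' @return the updated `grid_state`.
#' @export
diffuse_species <- function(grid, species, r) {
  stopifnot_prob(r, "r")
  grid$species[, species] <- diffuse_counts(grid$species[, species],
                                            grid$config$nbr, r)
  grid
}

# Core of the species diffusion rule on a raw count vector.
diffuse_counts <- function(b, nbr, r) {
  if (r >= 1 || all(b == 0)) return(b)
  stay <- round_half_up(b * r)
  moved <- b - stay
  q <- moved %/% 6
  rem <- moved %% 6
  recv <- numeric(length(b))
  for (d in 1:6) recv[nbr[, d]] <- recv[nbr[, d]] + q
  has_rem <- which(rem > 0)
  if (length(has_rem)) {
    pick <- sample_direction_subsets(rem[has_rem])
    for (d in 1:6) {
      tgt <- nbr[has_rem, d]
      recv[tgt] <- recv[tgt] + pick[, d]
    }
  }
  stay + recv
}

# Split per-cell mover counts into 6 neighbor directions uniformly
# (multinomial with equal probabilities, realized by sequential binomials).
split_to_directions <- function(mov) {
  n <- length(mov)
  send <- matrix(0, n, 6L)
  rem <- mov
  for (d in 1:5) {
    x <- stats::rbinom(n, rem, 1 / (7 - d))
    send[, d] <- x
    rem <- rem - x
  }
  send[, 6] <- rem
  send
}

#' Diffuse polymer boxes
#'
#' Each polymer box independently stays in its cell with probability `r` and
#' otherwise hops to one uniformly chosen neighbor. Polymer-1 boxes keep their
#' monomer composition when moving. Box totals are conserved exactly; in
#' expectation the rule matches the fractional species rule.
#'
#' @param grid a `grid_state`.
#' @param box_kind `"poly1"` or `"poly2"`.
#' @param r residual (stay) probability in \[0, 1\].
#' @return the updated `grid_state`.
#' @export
diffuse_boxes <- function(grid, box_kind = c("poly1", "poly2"), r) {
  box_kind <- match.arg(box_kind)
  stopifnot_prob(r, "r")
  if (r >= 1) return(grid)
  nbr <- grid$config$nbr
  if (box_kind == "poly2") {
    grid$poly2 <- diffuse_box_counts(grid$poly2, nbr, r)
  } else {
    for (k in seq_len(ncol(grid$p1_counts))) {
      grid$p1_counts[, k] <- diffuse_box_counts(grid$p1_counts[, k], nbr, r)
    }
  }
  grid
}

diffuse_box_counts <- function(cnt, nbr, r) {
  if (all(cnt == 0)) return(cnt)
  stay <- stats::rbinom(length(cnt), cnt, r)
  send <- split_to_directions(cnt - stay)
  recv <- numeric(length(cnt))
  for (d in 1:6) recv[nbr[, d]] <- recv[nbr[, d]] + send[, d]
  stay + recv
}

# Apply one full diffusion sweep: all 15 species then both polymer kinds.
diffuse_all <- function(grid, rates) {
  for (s in 1:15) {
    if (rates$species[s] < 1) {
      grid$species[, s] <- diffuse_counts(grid$species[, s],
                                          grid$config$nbr, rates$species[s])
    }
  }
  grid <- diffuse_boxes(grid, "poly1", rates$poly1)
  diffuse_boxes(grid, "poly2", rates$poly2)
}
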