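#' Periodic hexagonal lattice configuration
#'
#' Defines the simulation arena: a 2D hexagonal grid with periodic (toroidal)
#' boundaries, stored in odd-row-offset coordinates. Every cell has exactly six
#' distinct neighbors and the neighbor relation is symmetric.
#'
#' Rows are indexed 1..height, columns 1..width, and a cell `(row, col)` maps
#' to linear index `(row - 1) * width + col` (row-major). Neighbor offsets
#' follow the odd-row-offset convention: rows of even parity are shifted half
#' a cell relative to rows of odd parity. Because the row parity pattern must
#' itself be periodic, the number of rows must be even; an odd row count would
#' break neighbor symmetry across the vertical wrap.
#'
#' @param width number of columns (>= 3).
#' @param height number of rows (even, >= 4).
#' @return An object of class `lattice_config`: a list with `width`, `height`,
#'   `n` (cell count) and `nbr`, an `n x 6` integer matrix whose row `i` holds
#'   the linear indices of cell `i`'s neighbors in the fixed direction order
#'   E, W, NE, NW, SE, SW.
#' @examples
#' cfg <- lattice_config(6, 6)
#' cfg$nbr[1, ]  # the six neighbors of cell (1, 1), wrapped periodically
#' @export
lattice_config <- function(width = 100L, height = 100L) {
  width <- as.integer(width)
  height <- as.integer(height)
  if (is.na(width) || width < 3L) stop("width must be >= 3")
  if (is.na(height) || height < 4L || height %% 2L != 0L) {
    stop("height must be an even integer >= 4 (periodic hexagonal rows)")
  }
  n <- width * height
  row <- rep(seq_len(height), each = width)
  col <- rep(seq_len(width), times = height)
  wrap_r <- function(r) ((r - 1L) %% height) + 1L
  wrap_c <- function(c) ((c - 1L) %% width) + 1L
  lin <- function(r, c) (wrap_r(r) - 1L) * width + wrap_c(c)

  # odd-row-offset: rows with (row - 1) odd are shifted right half a cell
  odd <- (row - 1L) %% 2L == 1L
  dc_up <- ifelse(odd, 1L, 0L)    # column shift of NE/SE for shifted rows
  nbr <- cbind(
    E  = lin(row,      col + 1L),
    W  = lin(row,      col - 1L),
    NE = lin(row - 1L, col + dc_up),
    NW = lin(row - 1L, col + dc_up - 1L),
    SE = lin(row + 1L, col + dc_up),
    SW = lin(row + 1L, col + dc_up - 1L)
  )
  structure(list(width = width, height = height, n = n, nbr = nbr),
            class = "lattice_config")
}

#' @export
print.lattice_config <- function(x, ...) {
  cat(sprintf("Periodic hexagonal lattice: %d x %d (%d cells)\n",
              x$height, x$width, x$n))
  invisible(x)
}

#' Linear index of a (row, col) cell
#' @param config a [lattice_config()].
#' @param row,col 1-based cell coordinates.
#' @return integer linear index.
#' @export
cell_index <- function(config, row, col) {
  if (any(row < 1L | row > config$height | col < 1L | col > config$width)) {
    stop("coordinate out of range")
  }
  (row - 1L) * config$width + col
}

#' The six neighbors of a cell
#'
#' @param config a [lattice_config()].
#' @param row,col 1-based cell coordinates.
#' @return a 6 x 2 integer matrix of (row, col) neighbor coordinates in
#'   direction order E, W, NE, NW, SE, SW, wrapped periodically.
#' @examples
#' cfg <- lattice_config(6, 6)
#' neighbors(cfg, 1, 1)
#' @export
neighbors <- function(config, row, col) {
  i <- cell_index(config, row, col)
  idx <- config$nbr[i, ]
  cbind(row = ((idx - 1L) %/% config$width) + 1L,
        col = ((idx - 1L) %% config$width) + 1L)
}

# All cells within hex (graph) distance `radius` of cell `center` (linear
# index), inclusive. BFS on the neighbor graph; on a hexagonal lattice graph
# distance equals hex distance.
hex_ball <- function(config, center, radius) {
  seen <- logical(config$n)
  seen[center] <- TRUE
  frontier <- center
  if (radius > 0) {
    for (k in seq_len(radius)) {
      nxt <- unique(as.vector(config$nbr[frontier, , drop = FALSE]))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
  }
  which(seen)
}

#' Initial condition specification
#'
#' Background molecule counts placed uniformly in every cell, a central seed
#' of the two morphogen precursors (molecules 2 and 3), and a founding
#' population of information polymers (polymer 1) whose monomer ratio encodes
#' the morphology parameter `w`.
#'
#' @param mol1_per_cell raw-material molecules per cell.
#' @param mol6_per_cell,mol7_per_cell free monomers of the information polymer.
#' @param mol12_per_cell free monomers of the membrane polymer.
#' @param mol14_per_cell,mol15_per_cell counts of the two window-control
#'   molecules, placed uniformly.
#' @param seed_amount_mol2,seed_amount_mol3 molecules 2 and 3 added to each
#'   seed-region cell.
#' @param seed_radius hex radius of the central seed disk (radius 2 covers
#'   19 cells).
#' @param polymer1_initial_count number of founding polymer-1 boxes.
#' @param polymer1_initial_w molecule-6 fraction encoded by the founders.
#' @param polymer1_radius hex radius of the central disk over which founders
#'   are scattered uniformly at random.
#' @return An object of class `initial_condition_spec`.
#' @export
initial_condition_spec <- function(mol1_per_cell = 1e6,
                                   mol6_per_cell = 5e4,
                                   mol7_per_cell = 5e4,
                                   mol12_per_cell = 1e5,
                                   mol14_per_cell = 3,
                                   mol15_per_cell = 9,
                                   seed_amount_mol2 = 100,
                                   seed_amount_mol3 = 100,
                                   seed_radius = 2L,
                                   polymer1_initial_count = 10L,
                                   polymer1_initial_w = 0.650,
                                   polymer1_radius = 3L) {
  amounts <- c(mol1_per_cell, mol6_per_cell, mol7_per_cell, mol12_per_cell,
               mol14_per_cell, mol15_per_cell, seed_amount_mol2,
               seed_amount_mol3, polymer1_initial_count)
  if (any(amounts < 0)) stop("all amounts must be >= 0")
  stopifnot_prob(polymer1_initial_w, "polymer1_initial_w")
  structure(list(mol1_per_cell = mol1_per_cell,
                 mol6_per_cell = mol6_per_cell,
                 mol7_per_cell = mol7_per_cell,
                 mol12_per_cell = mol12_per_cell,
                 mol14_per_cell = mol14_per_cell,
                 mol15_per_cell = mol15_per_cell,
                 seed_amount_mol2 = seed_amount_mol2,
                 seed_amount_mol3 = seed_amount_mol3,
                 seed_radius = as.integer(seed_radius),
                 polymer1_initial_count = as.integer(polymer1_initial_count),
                 polymer1_initial_w = polymer1_initial_w,
                 polymer1_radius = as.integer(polymer1_radius)),
            class = "initial_condition_spec")
}

#' Initialize the lattice state
#'
#' Builds a `grid_state`: per-cell integer counts of the 15 molecular species,
#' polymer-1 boxes (grouped by monomer composition) and polymer-2 box counts.
#' Counts are stored as doubles but are integer-valued at all times.
#'
#' @param config a [lattice_config()].
#' @param init an [initial_condition_spec()].
#' @param p1_size polymer-1 box capacity in monomers (molecule 6 + molecule 7).
#' @return An object of class `grid_state`: list with `config`, `species`
#'   (`n x 15` count matrix), `p1_comps` (compositions, columns `n6`, `n7`),
#'   `p1_counts` (`n x ncomp` box counts), `poly2` (length-`n` box counts),
#'   `p1_size` and `time_step`.
#' @examples
#' g <- initialize_grid(lattice_config(10, 10), initial_condition_spec())
#' g$species[1, 1]   # 1e6 molecules of species 1 in every cell
#' @export
initialize_grid <- function(config, init = initial_condition_spec(),
                            p1_size = 100L) {
  n <- config$n
  species <- matrix(0, n, 15)
  species[, 1]  <- init$mol1_per_cell
  species[, 6]  <- init$mol6_per_cell
  species[, 7]  <- init$mol7_per_cell
  species[, 12] <- init$mol12_per_cell
  species[, 14] <- init$mol14_per_cell
  species[, 15] <- init$mol15_per_cell

  center <- cell_index(config, config$height %/% 2L, config$width %/% 2L)
  seed_cells <- hex_ball(config, center, init$seed_radius)
  species[seed_cells, 2] <- species[seed_cells, 2] + init$seed_amount_mol2
  species[seed_cells, 3] <- species[seed_cells, 3] + init$seed_amount_mol3

  n6 <- round_half_up(init$polymer1_initial_w * p1_size)
  p1_comps <- cbind(n6 = n6, n7 = p1_size - n6)
  p1_counts <- matrix(0, n, 1)
  if (init$polymer1_initial_count > 0) {
    region <- hex_ball(config, center, init$polymer1_radius)
    at <- sample(region, init$polymer1_initial_count, replace = TRUE)
    tab <- tabulate(at, nbins = n)
    p1_counts[, 1] <- tab
  }

  structure(list(config = config,
                 species = species,
                 p1_comps = p1_comps,
                 p1_counts = p1_counts,
                 poly2 = numeric(n),
                 p1_size = as.integer(p1_size),
                 time_step = 0L),
            class = "grid_state")
}

#' Grand total monomer count of a grid
#'
#' Free molecules of all 15 species, plus the monomer content of every
#' polymer-1 box (its full capacity) and 100 molecule-12 units per polymer-2
#' box. This quantity is exactly conserved by every simulation step: the
#' reaction network only converts molecules, never creates or destroys them.
#'
#' @param grid a `grid_state`.
#' @return a single number (exact integer value).
#' @export
grand_total <- function(grid) {
  sum(grid$species) +
    sum(grid$p1_counts %*% (grid$p1_comps[, 1] + grid$p1_comps[, 2])) +
    100 * sum(grid$poly2)
}

#' @export
print.grid_state <- function(x, ...) {
  cat(sprintf("grid_state: %d x %d hexagonal lattice, t = %d\n",
              x$config$height, x$config$width, x$time_step))
  cat(sprintf("  grand total monomers: %.0f\n", grand_total(x)))
  cat(sprintf("  polymer-1 boxes: %.0f, polymer-2 boxes: %.0f\n",
              sum(x$p1_counts), sum(x$poly2)))
  invisible(x)
}
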