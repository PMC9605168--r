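#' Membrane-polymer mask
#'
#' Binary indicator of the "cellular region": a lattice cell is in the mask
#' iff it holds at least `threshold` polymer-2 boxes.
#'
#' @param grid a `grid_state`.
#' @param threshold minimum box count (>= 1).
#' @return logical vector over cells.
#' @export
polymer2_mask <- function(grid, threshold = 1) {
  if (threshold < 1) stop("threshold must be >= 1")
  grid$poly2 >= threshold
}

#' Connected domains of a mask
#'
#' Connected components of the masked cells under hexagonal 6-adjacency with
#' periodic wrap.
#'
#' @param mask logical vector over cells.
#' @param config the [lattice_config()] the mask lives on.
#' @return list with `n_domains`, `sizes` (descending) and `labels`
#'   (component id per cell, 0 outside the mask).
#' @export
count_domains <- function(mask, config) {
  labels <- integer(config$n)
  idx <- which(mask)
  if (!length(idx)) {
    return(list(n_domains = 0L, sizes = integer(0), labels = labels))
  }
  sub <- match(seq_len(config$n), idx)        # cell -> vertex id or NA
  from <- rep(seq_along(idx), 3L)
  to_cells <- as.vector(config$nbr[idx, c(1L, 5L, 6L)])  # each edge once
  to <- sub[to_cells]
  keep <- !is.na(to)
  g <- igraph::graph_from_edgelist(cbind(from[keep], to[keep]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  labels[idx] <- comp$membership
  list(n_domains = as.integer(comp$no),
       sizes = sort(as.integer(comp$csize), decreasing = TRUE),
       labels = labels)
}

#' Domain report for one state
#'
#' @param grid a `grid_state`.
#' @param threshold mask threshold (boxes per cell).
#' @return one-row data.frame: `step`, `coverage` (mask fraction),
#'   `n_domains`, `largest` (largest domain size).
#' @export
domain_report <- function(grid, threshold = 1) {
  mask <- polymer2_mask(grid, threshold)
  cd <- count_domains(mask, grid$config)
  data.frame(step = grid$time_step,
             coverage = mean(mask),
             n_domains = cd$n_domains,
             largest = if (cd$n_domains) cd$sizes[1] else 0L)
}

#' Classify a domain time series into a qualitative pattern class
#'
#' Operationalization of the visual pattern categories: `mesh` when the
#' membrane region ends up covering a large fraction of the lattice,
#' `extinct` when it disappears after having existed, `replicating` when the
#' domain count rose above 1 while coverage stayed moderate, `stationary`
#' otherwise.
#'
#' @param reports data.frame with columns `step`, `coverage`, `n_domains`
#'   (as produced during a run), covering at least 500 steps.
#' @param coverage_mesh coverage fraction above which the pattern is `mesh`.
#' @return one of `"mesh"`, `"replicating"`, `"stationary"`, `"extinct"`.
#' @export
classify_pattern <- function(reports, coverage_mesh = 0.25) {
  if (nrow(reports) < 2 || max(reports$step) < 500) {
    stop("need reports spanning at least 500 steps")
  }
  final <- reports[nrow(reports), ]
  if (final$coverage > coverage_mesh) return("mesh")
  if (final$coverage == 0 && any(reports$coverage > 0)) return("extinct")
  if (max(reports$n_domains) > 1 && final$coverage > 0) return("replicating")
  "stationary"
}
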