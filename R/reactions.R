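#' Reaction network definition
#'
#' The fixed cyclic reaction network among the 15 species. Rates are
#' per-step reaction probabilities. The per-step schedule applies stages in a
#' fixed order inside every cell:
#'
#' * **A** morphogen maturation: 2 -> 4 (5%), 3 -> 5 (2%).
#' * **B** amplification: 4 + 1 -> 4 + 8, 4 + 1 -> 4 + 11, 5 + 1 -> 5 + 9
#'   (each 100%; each catalyst unit converts one unit of the molecule-1 pool,
#'   drawn down in listed order).
#' * **C** threshold comparison: the pooled 8 + 9 count converts to 10 at the
#'   local information-polymer ratio `w` (rounded half up), then the
#'   remainder resets 8 -> 1, 9 -> 1 (100%).
#' * **D** pair annihilation: 10 + 11 -> 1 + 1 (100%); the more abundant of
#'   the two survives.
#' * **E** window subsystem: 14 + 11 -> 14 + 1, 15 + 11 -> 15 + 13,
#'   13 + 11 -> 11 + 11 (each 100%, single pass in listed order); molecule 13
#'   persists only when the surviving molecule-11 count falls in a finite
#'   window set by the counts of molecules 14 and 15.
#' * **F** morphogen regeneration: 11 + 1 -> 11 + 2, 11 + 1 -> 11 + 3,
#'   13 + 1 -> 13 + 2, 13 + 1 -> 13 + 3, 14 + 1 -> 14 + 2, 14 + 1 -> 14 + 3
#'   (100%). By default this stage runs only in cells where molecule 13 is
#'   present (`regen_gate = "mol13"`): membrane-active cells are the
#'   morphogen sources, which ties the source strength to the persistence
#'   window and keeps the pattern amplitude self-limited. With
#'   `regen_gate = "none"` the stage runs unconditionally in every cell
#'   (molecule 14 then acts as a ubiquitous weak source).
#' * **G** removals back to the raw material: 4 -> 1 (5%), 5 -> 1 (5%),
#'   8 -> 1 (100%), 9 -> 1 (100%), 10 -> 1 (5%), 11 -> 1 (5%), 13 -> 1 (75%).
#'
#' Every rule conserves the total molecule count exactly.
#'
#' @param rate_2_4,rate_3_5 stage-A probabilities.
#' @param removal named numeric of stage-G removal probabilities with names
#'   `m4, m5, m8, m9, m10, m11, m13`.
#' @param regen_gate `"mol13"` (default) or `"none"`, see stage F above.
#' @return An object of class `network_definition`.
#' @export
network_definition <- function(rate_2_4 = 0.05, rate_3_5 = 0.02,
                               removal = c(m4 = 0.05, m5 = 0.05, m8 = 1,
                                           m9 = 1, m10 = 0.05, m11 = 0.05,
                                           m13 = 0.75),
                               regen_gate = c("mol13", "none")) {
  stopifnot_prob(rate_2_4, "rate_2_4")
  stopifnot_prob(rate_3_5, "rate_3_5")
  need <- c("m4", "m5", "m8", "m9", "m10", "m11", "m13")
  if (!all(need %in% names(removal))) {
    stop("removal must name ", paste(need, collapse = ", "))
  }
  stopifnot_prob(removal, "removal rates")
  structure(list(rate_2_4 = rate_2_4, rate_3_5 = rate_3_5,
                 removal = removal[need],
                 regen_gate = match.arg(regen_gate)),
            class = "network_definition")
}

#' First-order stochastic conversion
#'
#' Converts each of `count` molecules with probability `p` per step, realized
#' as `floor(count * p)` plus one additional unit with probability equal to
#' the fractional part, so the expectation is exactly `count * p`.
#' Vectorized over `count`.
#'
#' @param count non-negative counts.
#' @param p reaction probability in \[0, 1\].
#' @return list with `remaining` and `converted` (both integer-valued).
#' @examples
#' set.seed(1)
#' apply_first_order(100, 0.05)$converted  # exactly 5
#' @export
apply_first_order <- function(count, p) {
  stopifnot_prob(p, "p")
  if (any(count < 0)) stop("count must be >= 0")
  converted <- floor_bernoulli(count * p)
  list(remaining = count - converted, converted = converted)
}

#' Catalytic conversion
#'
#' A catalyst converts substrate one-for-one: at `p = 1` exactly
#' `min(substrate, catalyst)` units convert ("as many as the number of
#' catalyst molecules"); at `p < 1` that cap is converted first-order at `p`.
#' The catalyst is unchanged. Vectorized.
#'
#' @param substrate,catalyst non-negative counts.
#' @param p reaction probability.
#' @return converted counts.
#' @export
apply_catalytic <- function(substrate, catalyst, p = 1) {
  stopifnot_prob(p, "p")
  cap <- pmin(substrate, catalyst)
  if (p == 1) cap else apply_first_order(cap, p)$converted
}

#' Pair annihilation
#'
#' `min(a, b)` pairs react, each releasing two units of molecule 1; the more
#' abundant partner survives. Vectorized.
#'
#' @param count_a,count_b non-negative counts.
#' @return list with `a_left`, `b_left`, `released` (molecule-1 units).
#' @export
apply_pair_annihilation <- function(count_a, count_b) {
  k <- pmin(count_a, count_b)
  list(a_left = count_a - k, b_left = count_b - k, released = 2 * k)
}

#' Ratio-controlled conversion
#'
#' Converts `round(count * w)` units, where `w` is the molecule-6 fraction
#' read from the cell's information polymers. This realizes the `N2 * w`
#' term of the Turing threshold rule. `w = NA` (no informant present) gives 0.
#' Vectorized over both arguments.
#'
#' @param count non-negative counts.
#' @param w fraction in \[0, 1\], or NA.
#' @return converted counts.
#' @export
apply_ratio_conversion <- function(count, w) {
  if (any(!is.na(w) & (w < 0 | w > 1))) stop("w must be in [0, 1]")
  conv <- round_half_up(count * w)
  conv[is.na(conv)] <- 0
  pmin(conv, count)
}

#' Window subsystem
#'
#' Single pass, in listed order, of the three control reactions
#' 14 + 11 -> 14 + 1, 15 + 11 -> 15 + 13, 13 + 11 -> 11 + 11 (all at 100%).
#' Molecules 14 and 15 act purely catalytically. The net effect is that
#' molecule 13 survives only when the incoming molecule-11 count lies in a
#' finite contiguous window whose lower edge tracks the molecule-14 count and
#' whose upper edge tracks roughly twice the molecule-15 count. Vectorized.
#'
#' @param n11 incoming molecule-11 count.
#' @param n13 incoming molecule-13 count.
#' @param c14,c15 molecule-14 and -15 counts (unchanged by the pass).
#' @return list with `n11`, `n13` (outgoing counts) and `released_mol1`.
#' @examples
#' # with 3 of molecule 14 and 9 of molecule 15, molecule 13 persists only
#' # for molecule-11 inputs between 4 and 20:
#' out <- apply_window_subsystem(0:30, 0, 3, 9)
#' range(which(out$n13 > 0) - 1)
#' @export
apply_window_subsystem <- function(n11, n13, c14, c15) {
  d <- pmin(c14, n11)            # 11 destroyed to molecule 1
  n11 <- n11 - d
  m <- pmin(c15, n11)            # 11 converted to 13
  n11 <- n11 - m
  n13 <- n13 + m
  k <- pmin(n13, n11)            # 13 + 11 -> 11 + 11
  n13 <- n13 - k
  n11 <- n11 + k
  list(n11 = n11, n13 = n13, released_mol1 = d,
       to13 = m, from13 = k)
}

# Vectorized reaction engine over all cells. `S` is the n x 15 count matrix,
# `w_local` a length-n vector (NA where no informant). Applies stages A-F
# and optionally G. Returns list(S, plus, minus): entropy-production tallies
# counting molecules converted away from (plus) / back to (minus) molecule 1
# -- conversions whose product is neither source nor molecule 1 count as plus.
react_cells <- function(S, w_local, network, stages = c("AF", "G", "AG")) {
  stages <- match.arg(stages)
  plus <- 0
  minus <- 0
  if (stages != "G") {
    # A: morphogen maturation
    fo <- apply_first_order(S[, 2], network$rate_2_4)
    S[, 2] <- fo$remaining; S[, 4] <- S[, 4] + fo$converted
    plus <- plus + sum(fo$converted)
    fo <- apply_first_order(S[, 3], network$rate_3_5)
    S[, 3] <- fo$remaining; S[, 5] <- S[, 5] + fo$converted
    plus <- plus + sum(fo$converted)

    # B: catalytic amplification from the molecule-1 pool, listed order
    pool <- S[, 1]
    for (tgt in list(c(4L, 8L), c(4L, 11L), c(5L, 9L))) {
      conv <- pmin(pool, S[, tgt[1]])
      pool <- pool - conv
      S[, tgt[2]] <- S[, tgt[2]] + conv
      plus <- plus + sum(conv)
    }
    S[, 1] <- pool

    # C: ratio conversion 8,9 -> 10, then reset 8,9 -> 1. The two signal
    # carriers are pooled before rounding so the surviving molecule-11
    # condition is exactly n11 > round((n8 + n9) * w), the threshold
    # comparison of the reference automaton.
    sig <- S[, 8] + S[, 9]
    conv <- apply_ratio_conversion(sig, w_local)
    S[, 10] <- S[, 10] + conv
    plus <- plus + sum(conv)
    minus <- minus + sum(sig - conv)
    S[, 1] <- S[, 1] + (sig - conv)
    S[, 8] <- 0
    S[, 9] <- 0

    # D: pair annihilation 10 + 11 -> 1 + 1
    pa <- apply_pair_annihilation(S[, 10], S[, 11])
    S[, 10] <- pa$a_left; S[, 11] <- pa$b_left
    S[, 1] <- S[, 1] + pa$released
    minus <- minus + sum(pa$released)

    # E: window subsystem
    ws <- apply_window_subsystem(S[, 11], S[, 13], S[, 14], S[, 15])
    S[, 11] <- ws$n11; S[, 13] <- ws$n13
    S[, 1] <- S[, 1] + ws$released_mol1
    minus <- minus + sum(ws$released_mol1)
    plus <- plus + sum(ws$to13) + sum(ws$from13)

    # F: morphogen regeneration, listed order; by default only
    # membrane-active cells (molecule 13 present) act as sources
    gate <- if ((network$regen_gate %||% "mol13") == "mol13") {
      as.numeric(S[, 13] >= 1)
    } else 1
    pool <- S[, 1]
    for (tgt in list(c(11L, 2L), c(11L, 3L), c(13L, 2L), c(13L, 3L),
                     c(14L, 2L), c(14L, 3L))) {
      conv <- pmin(pool, S[, tgt[1]]) * gate
      pool <- pool - conv
      S[, tgt[2]] <- S[, tgt[2]] + conv
      plus <- plus + sum(conv)
    }
    S[, 1] <- pool
  }
  if (stages != "AF") {
    # G: removals back to molecule 1
    rem <- network$removal
    sp <- c(4L, 5L, 8L, 9L, 10L, 11L, 13L)
    for (i in seq_along(sp)) {
      fo <- apply_first_order(S[, sp[i]], rem[[i]])
      S[, sp[i]] <- fo$remaining
      S[, 1] <- S[, 1] + fo$converted
      minus <- minus + sum(fo$converted)
    }
  }
  list(S = S, plus = plus, minus = minus)
}

#' Run the full reaction schedule inside one cell
#'
#' Applies stages A-G of the reaction network to a single cell's species
#' counts. Diffusion and polymer synthesis are separate operations; this is
#' purely the multiset rewriting step.
#'
#' @param counts numeric(15) of species counts.
#' @param network a [network_definition()].
#' @param w_local the cell's information-polymer ratio (NA if no informant;
#'   ratio conversion is then skipped).
#' @return numeric(15) of updated counts (same total).
#' @export
step_cell_reactions <- function(counts, network = network_definition(),
                                w_local = NA_real_) {
  if (length(counts) != 15 || any(counts < 0)) {
    stop("counts must be 15 non-negative values")
  }
  out <- react_cells(matrix(counts, 1, 15), w_local, network, stages = "AG")
  drop(out$S)
}
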