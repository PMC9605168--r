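test_that("first-order conversion is exact on integer expectations", {
  set.seed(1)
  expect_equal(apply_first_order(100, 0.05)$converted, 5)
  expect_equal(apply_first_order(0, 0.5)$converted, 0)
  fo <- apply_first_order(7, 1)
  expect_equal(fo$converted, 7)
  expect_equal(fo$remaining, 0)
  expect_error(apply_first_order(10, 1.5), "\\[0, 1\\]")
  expect_error(apply_first_order(-1, 0.5), ">= 0")
})

test_that("fractional first-order conversion is Bernoulli on the fraction", {
  # count 10, p 0.05: expected 0.5, so converted is 0 or 1 with prob 1/2 each
  set.seed(2)
  draws <- replicate(4000, apply_first_order(10, 0.05)$converted)
  expect_true(all(draws %in% 0:1))
  expect_lt(abs(mean(draws) - 0.5), 3 * 0.5 / sqrt(4000))
})

test_that("catalytic conversion is capped by both substrate and catalyst", {
  expect_equal(apply_catalytic(1e6, 50, 1), 50)
  expect_equal(apply_catalytic(10, 50, 1), 10)
  expect_equal(apply_catalytic(100, 0, 1), 0)
  set.seed(3)
  expect_equal(apply_catalytic(1000, 100, 0.5), 50)
})

test_that("pair annihilation retains the more abundant partner", {
  expect_equal(apply_pair_annihilation(30, 20),
               list(a_left = 10, b_left = 0, released = 40))
  expect_equal(apply_pair_annihilation(0, 7),
               list(a_left = 0, b_left = 7, released = 0))
  expect_equal(apply_pair_annihilation(5, 5),
               list(a_left = 0, b_left = 0, released = 10))
})

test_that("ratio conversion rounds count * w and skips undefined w", {
  expect_equal(apply_ratio_conversion(200, 0.65), 130)
  expect_equal(apply_ratio_conversion(200, 0), 0)
  expect_equal(apply_ratio_conversion(200, 1), 200)
  expect_equal(apply_ratio_conversion(200, NA_real_), 0)
  expect_error(apply_ratio_conversion(10, 1.5), "\\[0, 1\\]")
})

test_that("window subsystem matches a scalar sequential oracle", {
  for (n11 in 0:60) {
    for (cfg in list(c(3, 9), c(0, 0), c(5, 2))) {
      got <- apply_window_subsystem(n11, 0, cfg[1], cfg[2])
      want <- window_oracle(n11, 0, cfg[1], cfg[2])
      expect_equal(got$n11, unname(want["n11"]))
      expect_equal(got$n13, unname(want["n13"]))
      expect_equal(got$released_mol1, unname(want["released"]))
    }
  }
})

test_that("molecule 13 persists on a single contiguous window of molecule 11", {
  # standard counts: 3 of molecule 14, 9 of molecule 15
  out <- apply_window_subsystem(0:200, 0, 3, 9)
  persist <- which(out$n13 > 0) - 1L
  expect_equal(persist, 4:20)
  # contiguity and monotone boundaries across control counts
  for (c14 in 0:5) {
    for (c15 in c(2, 5, 9, 12)) {
      p <- which(apply_window_subsystem(0:200, 0, c14, c15)$n13 > 0) - 1L
      if (length(p)) {
        expect_equal(p, seq(min(p), max(p)))  # one contiguous interval
        expect_equal(min(p), c14 + 1)         # lower edge tracks mol 14
        expect_equal(max(p), c14 + 2 * c15 - 1)  # upper edge tracks mol 15
      } else {
        expect_true(c15 == 0)
      }
    }
  }
  # degenerate cases
  z <- apply_window_subsystem(0, 5, 3, 9)
  expect_equal(z$n13, 5)
  expect_equal(apply_window_subsystem(50, 0, 0, 0)$n13, 0)
})

test_that("surviving molecule 11 reproduces the CA threshold comparison", {
  # after stages C-D, 11 survives iff n11 > round((n8 + n9) * w)
  set.seed(7)
  net <- network_definition()
  for (i in 1:1000) {
    n8 <- sample(0:200, 1); n9 <- sample(0:200, 1)
    n11 <- sample(0:300, 1); w <- stats::runif(1)
    counts <- numeric(15)
    counts[8] <- n8; counts[9] <- n9; counts[11] <- n11
    S <- matrix(counts, 1, 15)
    out <- protocellsim:::react_cells(S, w, net, stages = "AF")$S
    survived <- out[1, 11] > 0
    expect_identical(survived, n11 > protocellsim:::round_half_up((n8 + n9) * w))
  }
})

test_that("the full per-cell schedule conserves the molecule total exactly", {
  set.seed(11)
  for (gate in c("mol13", "none")) {
    net <- network_definition(regen_gate = gate)
    for (i in 1:50) {
      counts <- rpois(15, lambda = sample(c(2, 40, 1e4), 15, replace = TRUE))
      w <- if (i %% 3 == 0) NA_real_ else stats::runif(1)
      out <- step_cell_reactions(counts, net, w)
      expect_identical(sum(out), as.numeric(sum(counts)))
      expect_true(all(out >= 0))
    }
  }
})

test_that("empty cells are fixed points and the source gate works", {
  net <- network_definition()
  expect_equal(step_cell_reactions(numeric(15), net, 0.65), numeric(15))
  # molecule 14 alone: gated schedule produces no morphogens...
  counts <- numeric(15); counts[1] <- 1e6; counts[14] <- 3; counts[15] <- 9
  set.seed(1)
  out <- step_cell_reactions(counts, net, NA_real_)
  expect_equal(out[2], 0)
  expect_equal(out[3], 0)
  # ...while the ungated schedule yields 3 units each of molecules 2 and 3
  set.seed(1)
  out2 <- step_cell_reactions(counts, network_definition(regen_gate = "none"),
                              NA_real_)
  expect_equal(out2[2], 3)
  expect_equal(out2[3], 3)
})
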