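test_that("an all-empty grid is a fixed point of the full step", {
  cfg <- run_config(width = 6, height = 6, steps = 1, seed = 1,
                    init = initial_condition_spec(
                      mol1_per_cell = 0, mol6_per_cell = 0, mol7_per_cell = 0,
                      mol12_per_cell = 0, mol14_per_cell = 0,
                      mol15_per_cell = 0, seed_amount_mol2 = 0,
                      seed_amount_mol3 = 0, polymer1_initial_count = 0))
  g <- initialize_grid(lattice_config(6, 6), cfg$init)
  out <- step_grid(g, cfg)
  expect_equal(out$grid$species, g$species)
  expect_equal(out$grid$poly2, g$poly2)
  expect_equal(out$plus, 0)
  expect_equal(out$minus, 0)
})

test_that("the grand total is conserved exactly along a standard run", {
  cfg <- run_config(width = 20, height = 20, steps = 100, seed = 7,
                    record_every = 5)
  run <- run_protocell(cfg)
  expect_length(unique(run$ledger$total), 1L)
  expect_identical(run$ledger$total[1], grand_total(run$grid))
})

test_that("identical configuration and seed reproduce the trajectory", {
  cfg <- run_config(width = 12, height = 12, steps = 60, seed = 99,
                    record_every = 10)
  a <- run_protocell(cfg)
  b <- run_protocell(cfg)
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$grid$species, b$grid$species)
  expect_identical(a$grid$poly2, b$grid$poly2)
  c <- run_protocell(run_config(width = 12, height = 12, steps = 60,
                                seed = 100, record_every = 10))
  expect_false(identical(a$grid$species, c$grid$species))
})

test_that("invalid configurations are rejected", {
  expect_error(run_config(steps = 0), "steps")
  expect_error(sweep_protocell(run_config(), "unknown_axis", 1), "unknown")
  expect_error(seed_geometry(lattice_config(10, 10), 4), "case")
})

test_that("sweeps apply the requested axis and normalize percent inputs", {
  base <- run_config(width = 8, height = 8, steps = 2, seed = 1,
                     record_every = 1)
  sw <- sweep_protocell(base, "mol14", c(1, 5))
  expect_length(sw, 2L)
  expect_equal(sw[["1"]]$config$init$mol14_per_cell, 1)
  expect_equal(sw[["5"]]$config$init$mol14_per_cell, 5)
  sw2 <- sweep_protocell(base, "removal_13", 75)
  expect_equal(sw2[["75"]]$config$network$removal[["m13"]], 0.75)
  sw3 <- sweep_protocell(base, "w", 0.6)
  expect_equal(sw3[["0.6"]]$config$init$polymer1_initial_w, 0.6)
  # a single-value w sweep reproduces a direct run exactly
  direct <- run_protocell(sw3[["0.6"]]$config)
  expect_identical(sw3[["0.6"]]$ledger, direct$ledger)
})

test_that("early pattern formation is insensitive to the seed geometry", {
  # the three central seed arrangements all ignite a membrane domain in the
  # first 200 steps
  for (case in 1:3) {
    run <- run_protocell(run_config(width = 16, height = 16, steps = 200,
                                    seed = 3, seed_case = case,
                                    record_every = 25))
    led <- run$ledger
    expect_true(any(led$coverage[led$step >= 50 & led$step <= 200] > 0),
                label = sprintf("seed case %d ignites", case))
  }
})

test_that("snapshots and exports round-trip through delimited text", {
  run <- run_protocell(run_config(width = 8, height = 8, steps = 10, seed = 2,
                                  record_every = 5, snapshot_every = 5))
  expect_length(run$snapshots, 2L)
  snap <- run$snapshots[[1]]
  expect_named(snap, c("step", "row", "col", "kind", "count"))
  expect_equal(unique(snap$step), 5L)
  # the long form carries the full conserved inventory
  is_box <- snap$kind %in% c("poly1", "poly2")
  expect_equal(sum(snap$count[!is_box]) + 100 * sum(snap$count[is_box]),
               run$ledger$total[1])
  dir <- file.path(tempdir(), "protocell-run-test")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  paths <- write_run(run, dir)
  expect_true(file.exists(paths[1]))
  led <- utils::read.delim(paths[1])
  expect_equal(nrow(led), nrow(run$ledger))
  expect_equal(led$total, run$ledger$total)
})

test_that("print, summary and plot methods run cleanly", {
  run <- tiny_run(steps = 40, seed = 1, width = 12, height = 12)
  expect_output(print(run), "protocell_run")
  s <- summary(run)
  expect_output(print(s), "pattern class")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(run))
})
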