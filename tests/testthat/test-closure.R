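test_that("polydisperse initialization draws the prescribed distribution", {
  st <- build_voronoi_tissue(400, tissue_box(sqrt(800), sqrt(200)), seed = 2)
  # assignment only (no relax): check the draw statistics at N = 400
  s1 <- initialize_polydisperse(st, shape_distribution(4.2, 0.45), seed = 9,
                                relax = FALSE)
  expect_equal(sd(s1$p0), 0.45, tolerance = 0.05)
  expect_equal(mean(s1$p0), 4.2, tolerance = 0.07)
  expect_true(all(s1$p0 > 0))
  # determinism
  s2 <- initialize_polydisperse(st, shape_distribution(4.2, 0.45), seed = 9,
                                relax = FALSE)
  expect_identical(s1$p0, s2$p0)
  # degenerate distribution: zero width
  s3 <- initialize_polydisperse(st, shape_distribution(4.0, 0), seed = 1,
                                relax = FALSE)
  expect_true(all(s3$p0 == 4.0))
  # misconfigured distribution: too many non-positive draws
  expect_error(initialize_polydisperse(st, shape_distribution(0.5, 1),
                                       seed = 1, relax = FALSE),
               "misconfigured")
})

test_that("deformation steps follow the schedule algebra exactly", {
  st <- build_hex_tissue(4, 4)
  st$box0 <- st$box
  A0 <- st$box$Lx * st$box$Ly
  sch <- closure_schedule(delta = 0.00125)
  # uniaxial: dA after k steps is exactly k * delta (width fixed)
  s <- st
  for (k in 1:8) s <- apply_deformation_step(s, sch)
  expect_equal(s$box$Lx, st$box$Lx)
  expect_equal(1 - s$box$Lx * s$box$Ly / A0, 8 * 0.00125, tolerance = 1e-12)
  # 360 steps of 0.125% reach 45% closure
  expect_equal(360 * 0.00125, 0.45)
  # isotropic: identical area decrement per step, aspect preserved
  si <- st
  schi <- closure_schedule(delta = 0.00125, mode = "isotropic")
  for (k in 1:8) si <- apply_deformation_step(si, schi)
  expect_equal(1 - si$box$Lx * si$box$Ly / A0, 8 * 0.00125, tolerance = 1e-12)
  expect_equal(si$box$Lx / si$box$Ly, st$box$Lx / st$box$Ly, tolerance = 1e-12)
  # geometry error: stepping past zero height
  sch_big <- closure_schedule(delta = 0.4)
  s2 <- apply_deformation_step(st, sch_big)
  s2 <- apply_deformation_step(s2, sch_big)
  expect_error(apply_deformation_step(s2, sch_big), "non-positive")
})

test_that("preferred-perimeter shrinkage is linear with the stated slope", {
  st <- build_hex_tissue(4, 4)
  p0_init <- st$p0
  sch <- closure_schedule(shrink_slope = 0.5)
  s <- update_preferred_perimeters(st, 0.4, sch)
  expect_equal(s$p0, 0.8 * p0_init, tolerance = 1e-14)
  # c = 0: no shrinkage at any stage
  s0 <- update_preferred_perimeters(st, 0.7, closure_schedule(shrink_slope = 0))
  expect_equal(s0$p0, p0_init)
  # mean ratio is linear in dA with slope -c by construction
  ratios <- vapply(c(0.1, 0.3, 0.6), function(d)
    mean(update_preferred_perimeters(st, d, sch)$p0 / p0_init), numeric(1))
  expect_equal(ratios, 1 - 0.5 * c(0.1, 0.3, 0.6), tolerance = 1e-12)
  expect_error(closure_schedule(shrink_slope = -1), "non-negative")
})

test_that("ingression removes cells at the configured rate", {
  sch <- closure_schedule(ingression_fraction = 0.1)
  # fI = 0: no removals ever
  st <- vor36()
  set.seed(1)
  expect_identical(length(ingress_cells(st, sch, 0)$cells), 36L)
  # binomial count over a simulated run: 240 steps at p = fI N0 / n_steps
  set.seed(7)
  n_steps <- 240
  p_step <- 0.1 * 36 / n_steps
  removed <- 0L
  s <- st
  for (k in seq_len(n_steps)) {
    s2 <- ingress_cells(s, sch, p_step)
    if (!is.null(attr(s2, "ingressed"))) removed <- removed + 1L
    s <- s2
  }
  # 3.6 expected; allow a generous binomial spread
  expect_gte(removed, 1L)
  expect_lte(removed, 9L)
  expect_equal(length(s$cells), 36L - removed)
})

test_that("a short closure run satisfies the trajectory invariants", {
  traj <- fixture("traj32", function()
    run_closure(n_cells = 32, schedule = closure_schedule(dA_max = 0.1),
                seed = 4, keep_snapshots = TRUE, snapshot_dA = 0.1))
  expect_true(traj$valid)
  r <- traj$records
  # records every 0.01 in dA, plus the initial state
  expect_equal(nrow(r), 11L)
  expect_true(all(diff(r$dA) > 0))
  # box bookkeeping: dA from the box equals dA from summed cell areas
  snap <- traj$snapshots[[1]]
  g <- cell_geometry(snap$state)
  A0 <- snap$state$box0$Lx * snap$state$box0$Ly
  expect_equal(1 - sum(g$area) / A0, snap$dA, tolerance = 1e-9)
  # cell count bookkeeping matches the event log
  expect_equal(r$n_cells[nrow(r)],
               32L - sum(traj$events$type == "ingression"))
  # reproducibility: identical seed, identical trajectory
  traj2 <- run_closure(n_cells = 32,
                       schedule = closure_schedule(dA_max = 0.1), seed = 4)
  expect_equal(traj2$records, r[, names(traj2$records)])
})
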