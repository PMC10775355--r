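test_that("closure staging follows its definition", {
  fr <- data.frame(frame_time = c(0, 60, 120, 180),
                   as_area = c(12000, 11000, 8000, 4950))
  st <- closure_stage(fr, A0 = 11000)
  # frames before the A0 crossing are dropped
  expect_equal(nrow(st), 3L)
  expect_equal(st$dA, c(0, 3000, 6050) / 11000)
  expect_equal(st$dA[3], 0.55)
  # linear area decrease gives dA linear in time
  lin <- data.frame(frame_time = 0:10 * 60, as_area = 11000 - 0:10 * 500)
  stl <- closure_stage(lin, 11000)
  expect_equal(diff(stl$dA), rep(500 / 11000, 10), tolerance = 1e-12)
  # series that never reaches A0
  expect_error(closure_stage(data.frame(frame_time = 0:2,
                                        as_area = c(15000, 14000, 13000))),
               "never reaches")
})

test_that("central-region filter applies the 75%/90% ellipse rule", {
  ell <- list(cx = 0, cy = 0, a = 100, b = 50, phi = 0)
  cells <- data.frame(x = c(0, 80, 70, 0, 0), y = c(0, 0, 0, 42.5, 46))
  keep <- central_region_filter(cells, ell)
  expect_identical(keep, c(TRUE,   # center
                           FALSE,  # 0.80 a on the major axis: excluded
                           TRUE,   # 0.70 a: inside
                           TRUE,   # 0.85 b on the minor axis: kept
                           FALSE)) # 0.92 b: excluded
  # rotation of the ellipse rotates the region with it
  ell2 <- list(cx = 0, cy = 0, a = 100, b = 50, phi = pi / 2)
  expect_true(central_region_filter(data.frame(x = 0, y = 70), ell2))
  expect_false(central_region_filter(data.frame(x = 70, y = 0), ell2))
  expect_error(central_region_filter(cells, list(a = NA, b = 1)), "ellipse")
})

test_that("junction straightness matches closed forms and guards", {
  expect_equal(junction_straightness(5, 5), 1)
  expect_equal(junction_straightness(4.65, 5), 0.93)
  # semicircular arc: dv = 2r, L = pi r
  expect_equal(junction_straightness(2, pi), 2 / pi)
  expect_error(junction_straightness(5.1, 5), "artifact")
  expect_error(junction_straightness(1, 0), "positive")
})

test_that("recoil fitting recovers planted double-exponential parameters", {
  # noiseless: near-exact recovery
  tr0 <- generate_ablation_traces(1, noise = 0, seed = 2)[[1]]
  f0 <- fit_recoil(tr0)
  expect_equal(f0$vr, attr(tr0, "truth")$vr, tolerance = 1e-3)
  # 2% noise: vr within 5%
  tr <- generate_ablation_traces(1, noise = 0.02, seed = 3)[[1]]
  f <- fit_recoil(tr)
  expect_equal(f$vr, attr(tr, "truth")$vr, tolerance = 0.05)
  # nested single-exponential limit: vr = A1 b0
  tt <- seq(0, 20, by = 0.2)
  d1 <- 2 - 1.5 * exp(-0.8 * tt)
  fs <- fit_recoil(data.frame(t = tt, d = d1))
  expect_equal(fs$vr, 1.5 * 0.8, tolerance = 1e-3)
  # constant trace: zero recoil
  fc <- fit_recoil(data.frame(t = tt, d = rep(2, length(tt))))
  expect_equal(fc$vr, 0, tolerance = 1e-8)
  # guards
  expect_error(fit_recoil(data.frame(t = 1:5, d = 1:5)), "10")
})

test_that("crossover fit recovers a planted breakpoint and flags degeneracy", {
  sr <- generate_straightness_recoil(n = 97, s_star = 0.93, seed = 5)
  cf <- crossover_fit(sr$S, sr$vr, n_boot = 50)
  expect_equal(cf$s_star, 0.93, tolerance = 0.02)
  expect_false(cf$degenerate)
  expect_gt(cf$slope, 0)
  # pure flat data: breakpoint unidentifiable
  set.seed(6)
  S <- runif(60, 0.75, 1)
  flat <- crossover_fit(S, rnorm(60, 0.3, 0.05), n_boot = 20)
  expect_true(flat$degenerate)
  # all S outside the candidate grid
  expect_error(crossover_fit(rep(0.5, 20), rnorm(20),
                             breaks = seq(0.8, 0.95, 0.01)),
               "one side")
})

test_that("stage-binned summaries use the quoted bin edges", {
  set.seed(8)
  dA <- runif(300, 0, 0.9)
  # hump peaking in the middle interval
  v <- 0.3 + 0.5 * exp(-((dA - 0.55) / 0.15)^2) + rnorm(300, 0, 0.02)
  b <- stage_binned_stats(v, dA)
  expect_equal(b$bin, c("dA<0.4", "0.4<=dA<0.7", "dA>=0.7"))
  expect_equal(sum(b$n), 300L)
  expect_true(b$median[2] > b$median[1] && b$median[2] > b$median[3])
  # permutation invariance
  p <- sample(300)
  expect_equal(stage_binned_stats(v[p], dA[p]), b)
  # empty bins are reported, not dropped
  b2 <- stage_binned_stats(v[dA < 0.4], dA[dA < 0.4])
  expect_equal(b2$n[2:3], c(0L, 0L))
  expect_true(all(is.na(b2$median[2:3])))
})

test_that("recoil recovery is unbiased and tightly distributed at 2% noise", {
  # intrinsic estimator spread for the double-exponential initial slope at
  # this noise level: typical error ~3%; the distribution's tail is bounded
  traces <- generate_ablation_traces(40, noise = 0.02, seed = 11)
  err <- vapply(traces, function(tr) {
    f <- fit_recoil(tr, n_starts = 6)
    (f$vr - attr(tr, "truth")$vr) / attr(tr, "truth")$vr
  }, numeric(1))
  expect_lt(median(abs(err)), 0.05)
  expect_gte(mean(abs(err) < 0.1), 0.95)
  expect_lt(abs(mean(err)), 0.03)  # no systematic bias
})
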