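test_that("tracked cohorts are deterministic and satisfy table invariants", {
  spec <- cohort_spec(n_embryos = 3, cells_per_embryo = 60, seed = 12)
  co <- generate_tracked_cohort(spec)
  co2 <- generate_tracked_cohort(spec)
  expect_identical(co$cells, co2$cells)
  expect_identical(co$junctions, co2$junctions)
  # invariants: positive geometry, straightness bounded by 1
  expect_true(all(co$cells$area > 0))
  expect_true(all(co$cells$perimeter > 0))
  expect_true(all(co$junctions$dv <= co$junctions$L))
  expect_true(all(co$cells$aspect >= 1))
  # ingression: about 10% of cells disappear over the series
  first <- co$cells[co$cells$frame == 1 & co$cells$embryo == 1, ]
  last_fr <- max(co$cells$frame[co$cells$embryo == 1])
  last <- co$cells[co$cells$frame == last_fr & co$cells$embryo == 1, ]
  expect_equal(nrow(first) - nrow(last), round(0.1 * 60))
})

test_that("pooled onset shape-index dispersion matches the target", {
  co <- generate_tracked_cohort(cohort_spec(n_embryos = 12,
                                            cells_per_embryo = 200,
                                            seed = 3))
  first <- co$cells[co$cells$frame == 1, ]
  q <- shape_index(first$area, first$perimeter)
  expect_lt(abs(sd(q) - 0.45), 0.03)
})

test_that("staging the generated series recovers the planted area rate", {
  spec <- cohort_spec(n_embryos = 1, cells_per_embryo = 40,
                      embryo_rate_sd = 0, seed = 5)
  co <- generate_tracked_cohort(spec)
  st <- closure_stage(co$frames[co$frames$embryo == 1, ], A0 = spec$A0)
  fit <- lm(dA ~ frame_time, data = st)
  expect_equal(unname(coef(fit)[2]), spec$area_rate / spec$A0,
               tolerance = 0.01)
})

test_that("embryo variability scales of zero give identical embryos", {
  spec <- cohort_spec(n_embryos = 3, cells_per_embryo = 30,
                      embryo_q_sd = 0, embryo_rate_sd = 0, seed = 6)
  co <- generate_tracked_cohort(spec)
  e1 <- co$cells[co$cells$embryo == 1, !(names(co$cells) == "embryo")]
  e2 <- co$cells[co$cells$embryo == 2, !(names(co$cells) == "embryo")]
  expect_equal(unname(as.matrix(e1[, -1])), unname(as.matrix(e2[, -1])),
               tolerance = 1e-12)
})

test_that("cohort CSV round-trips through the documented schema", {
  co <- generate_tracked_cohort(cohort_spec(n_embryos = 2,
                                            cells_per_embryo = 20, seed = 7))
  d <- withr::local_tempdir()
  write_cohort_csv(co, d)
  expect_true(all(file.exists(file.path(d, c("frames.csv", "cells.csv",
                                             "junctions.csv", "truth.json")))))
  back <- read_cohort_csv(d)
  expect_equal(back$cells$area, co$cells$area, tolerance = 1e-12)
  expect_equal(nrow(back$junctions), nrow(co$junctions))
  expect_error(read_cohort_csv(withr::local_tempdir()), "missing")
})

test_that("ablation traces carry exact ground truth and mirror the hump", {
  traces <- generate_ablation_traces(50, noise = 0, seed = 9)
  tr <- traces[[1]]
  tru <- attr(tr, "truth")
  # the sampled curve is exactly the double exponential
  expect_equal(tr$d,
               tru$A1 * exp(tru$b0 * tr$t) + tru$A2 * exp(tru$d0 * tr$t) +
                 tru$C, tolerance = 1e-12)
  expect_equal(tru$vr, tru$A1 * tru$b0 + tru$A2 * tru$d0, tolerance = 1e-12)
  # binned true vr peaks in the middle closure interval by construction
  vr <- vapply(traces, function(t) attr(t, "truth")$vr, numeric(1))
  dA <- vapply(traces, function(t) attr(t, "truth")$dA, numeric(1))
  b <- stage_binned_stats(vr, dA)
  expect_true(b$median[2] > b$median[1] && b$median[2] > b$median[3])
  # bit-identical regeneration
  traces2 <- generate_ablation_traces(50, noise = 0, seed = 9)
  expect_identical(traces[[5]]$d, traces2[[5]]$d)
})

test_that("straightness tracks a supplied tension curve monotonically", {
  # noiseless generator: per-frame mean straightness is an increasing
  # function of the tension proxy, so their ranks agree exactly
  proxy <- function(dA) 0.02 + 0.1 * exp(-((dA - 0.55) / 0.2)^2)
  spec <- cohort_spec(n_embryos = 1, cells_per_embryo = 30, noise_sd = 0,
                      embryo_q_sd = 0, embryo_rate_sd = 0,
                      tension_proxy = proxy, seed = 10)
  co <- generate_tracked_cohort(spec)
  st <- closure_stage(co$frames, A0 = spec$A0)
  sbar <- vapply(st$frame, function(f) {
    j <- co$junctions[co$junctions$frame == f, ]
    mean(junction_straightness(j$dv, j$L))
  }, numeric(1))
  expect_equal(cor(sbar, proxy(st$dA), method = "spearman"), 1,
               tolerance = 1e-9)
})
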