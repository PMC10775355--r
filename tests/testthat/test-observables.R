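test_that("shape tensor matches rectangle and hexagon closed forms", {
  # 2x1 axis-aligned rectangle: aspect 2, orientation 0
  rs <- rect_state(2, 1)
  shp <- cell_shape_tensor(rs)
  expect_equal(shp$aspect, 2, tolerance = 1e-12)
  expect_equal(shp$angle, 0, tolerance = 1e-12)
  # rotated 90 degrees: same aspect, orientation folded to +-pi/2
  rs2 <- rect_state(1, 2)
  shp2 <- cell_shape_tensor(rs2)
  expect_equal(shp2$aspect, 2, tolerance = 1e-12)
  expect_equal(abs(shp2$angle), pi / 2, tolerance = 1e-12)
  # regular hexagon: isotropic, orientation flagged undefined
  hx <- hex44()
  shph <- cell_shape_tensor(hx, cells = 1L)
  expect_true(shph$isotropic)
  expect_true(is.na(shph$angle))
})

test_that("orientational order parameter follows its definition", {
  mk <- function(angles) data.frame(cell = seq_along(angles), aspect = 2,
                                    angle = angles, isotropic = FALSE)
  expect_equal(order_parameter(mk(rep(0, 50))), 1)
  expect_equal(order_parameter(mk(rep(pi / 2, 50))), -1)
  # uniform angles: |Q| < 3/sqrt(N) (circular-statistics bound)
  set.seed(11)
  N <- 4000
  expect_lt(abs(order_parameter(mk(runif(N, -pi / 2, pi / 2)))), 3 / sqrt(N))
  # all-isotropic state: defined as 0 with a warning
  iso <- data.frame(cell = 1, aspect = 1, angle = NA_real_, isotropic = TRUE)
  expect_warning(q0 <- order_parameter(iso), "isotropic")
  expect_equal(q0, 0)
})

test_that("junction tension matches the hexagon closed form and the energy derivative", {
  # uniform p0 = 3.5 on the unit-area honeycomb: every junction carries
  # tau = 2 (p_hex - 3.5) ~= 0.4448
  hx <- build_hex_tissue(4, 4, p0 = 3.5)
  tau <- junction_tension(hx)
  expect_equal(tau, rep(2 * (q_hex - 3.5), length(tau)), tolerance = 1e-9)
  expect_equal(2 * (q_hex - 3.5), 0.4448, tolerance = 1e-4)

  # finite-difference oracle: tau equals the derivative of the energy with
  # respect to elongating that junction at fixed other junction lengths
  st <- vor36()
  set.seed(13)
  st$p0 <- runif(36, 3.4, 4.0)
  jn <- tissue_junctions(st)
  tau <- junction_tension(st, junctions = jn)
  g <- cell_geometry(st)
  edge_energy <- function(len_vec) {
    per <- vapply(seq_along(st$cells), function(ci)
      sum(len_vec[jn$cell_i == ci | jn$cell_j == ci]), numeric(1))
    sum(0.5 * (g$area - 1)^2 + 0.5 * (per - st$p0)^2)
  }
  h <- 1e-6
  for (e in c(1, 17, 50)) {
    lp <- jn$length; lp[e] <- lp[e] + h
    lm <- jn$length; lm[e] <- lm[e] - h
    fd <- (edge_energy(lp) - edge_energy(lm)) / (2 * h)
    expect_equal(tau[e], fd, tolerance = 1e-4)
  }
})

test_that("observable records are exact on ground states and label-invariant", {
  hx <- build_hex_tissue(4, 4, p0 = 3.6)
  rec <- observable_record(hx, dA = 0.1)
  expect_equal(rec$q_mean, q_hex, tolerance = 1e-12)
  expect_equal(rec$q_sd, 0)
  expect_equal(rec$tension_mean, 2 * (q_hex - 3.6), tolerance = 1e-9)
  expect_equal(rec$fr, 1)
  expect_equal(rec$n_cells, 16L)

  # permutation invariance under cell relabeling
  st <- vor36()
  set.seed(14)
  st$p0 <- runif(36, 3.5, 4.1)
  perm <- sample(36)
  st2 <- st
  st2$cells <- st$cells[perm]
  st2$p0 <- st$p0[perm]
  st2$cell_ids <- st$cell_ids[perm]
  r1 <- observable_record(st, dA = 0)
  r2 <- observable_record(st2, dA = 0)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("monodisperse relaxed state reports q_mean = p0 at zero tension", {
  # floppy uniform lattice relaxes so that every cell reaches p0 exactly
  hx <- build_hex_tissue(4, 4, p0 = 3.95)
  set.seed(6)
  hx$vertices <- hx$vertices + matrix(rnorm(64, 0, 0.04), ncol = 2)
  out <- minimize_tissue(hx, settings = minimizer_settings(tol = 1e-8))
  rec <- observable_record(out$state)
  expect_equal(rec$q_mean, 3.95, tolerance = 1e-3)
  expect_equal(rec$tension_mean, 0, tolerance = 1e-4)
})
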