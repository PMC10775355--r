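# Shared fixtures, built lazily and cached for the session.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

hex44 <- function() fixture("hex44", function() build_hex_tissue(4, 4))

vor36 <- function() fixture("vor36", function()
  build_voronoi_tissue(36, tissue_box(6, 6), seed = 3))

# perimeter of a regular hexagon of unit area (shape index of a hexagon)
q_hex <- 2 * sqrt(6) * 3^(-0.25)

# one free-standing w x h rectangular cell inside a 2w x 2h periodic box;
# bypasses the trivalence validator (geometry kernels do not need it)
rect_state <- function(w, h) {
  tissue_state(rbind(c(0, 0), c(w, 0), c(w, h), c(0, h)),
               list(1:4), p0 = 2 * (w + h), a0 = w * h,
               box = tissue_box(2 * w, 2 * h), validate = FALSE)
}

# independent R-side energy (shoelace + edge sums), used as oracle
r_energy <- function(state, params = energy_params()) {
  tot <- 0
  for (i in seq_along(state$cells)) {
    cy <- state$cells[[i]]
    v <- state$vertices[cy, , drop = FALSE]
    # unwrap via cumulative minimum image
    for (k in seq_len(nrow(v))[-1]) {
      d <- v[k, ] - v[k - 1, ]
      d <- d - c(state$box$Lx, state$box$Ly) * round(d / c(state$box$Lx, state$box$Ly))
      v[k, ] <- v[k - 1, ] + d
    }
    x <- v[, 1]; y <- v[, 2]
    x1 <- c(x[-1], x[1]); y1 <- c(y[-1], y[1])
    a <- sum(x * y1 - x1 * y) / 2
    p <- sum(sqrt((x1 - x)^2 + (y1 - y)^2))
    tot <- tot + 0.5 * params$ka * (a - params$a0)^2 +
      0.5 * params$kp * (p - state$p0[i])^2
  }
  tot
}
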