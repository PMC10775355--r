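# unwrap one cell cycle to contiguous coordinates (minimum image chain)
.unwrap_cycle <- function(state, cy) {
  v <- state$vertices[cy, , drop = FALSE]
  d <- rbind(c(0, 0), .min_image(v[-1L, , drop = FALSE] -
                                 v[-nrow(v), , drop = FALSE], state$box))
  sweep(apply(d, 2L, cumsum), 2L, v[1L, ], "+")
}

#' Cell shape tensor: aspect ratio and orientation
#'
#' Builds the area-weighted second-moment tensor of each cell polygon about
#' its centroid (minimum-image unwrapped) and returns the aspect ratio
#' `alpha = sqrt(lambda_max / lambda_min)` and the orientation `theta` of the
#' major axis relative to the x (anterior--posterior) axis, folded to
#' `[-pi/2, pi/2]`. Cells with `alpha < 1 + 1e-9` are flagged isotropic
#' (orientation ill-defined) and are excluded from the order parameter.
#'
#' @param state a [tissue_state()].
#' @param cells integer indices of cells to measure (default all).
#' @return data frame with columns `cell`, `aspect`, `angle`, `isotropic`.
#' @export
cell_shape_tensor <- function(state, cells = seq_along(state$cells)) {
  out <- data.frame(cell = cells, aspect = NA_real_, angle = NA_real_,
                    isotropic = FALSE)
  for (r in seq_along(cells)) {
    P <- .unwrap_cycle(state, state$cells[[cells[r]]])
    # local origin at the first vertex: avoids catastrophic cancellation in
    # the second moments when the cell sits far from the box origin
    x <- P[, 1] - P[1, 1]; y <- P[, 2] - P[1, 2]
    x1 <- c(x[-1], x[1]); y1 <- c(y[-1], y[1])
    cr <- x * y1 - x1 * y
    A <- sum(cr) / 2
    if (abs(A) < .Machine$double.eps * 100)
      stop("zero-area cell ", state$cell_ids[cells[r]])
    cx <- sum((x + x1) * cr) / (6 * A)
    cy_ <- sum((y + y1) * cr) / (6 * A)
    # raw second moments of the polygon area about the origin
    ixx <- sum((x^2 + x * x1 + x1^2) * cr) / 12
    iyy <- sum((y^2 + y * y1 + y1^2) * cr) / 12
    ixy <- sum((x * y1 + 2 * x * y + 2 * x1 * y1 + x1 * y) * cr) / 24
    mxx <- ixx / A - cx^2
    myy <- iyy / A - cy_^2
    mxy <- ixy / A - cx * cy_
    tr <- mxx + myy
    dd <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
    lmax <- tr / 2 + dd
    lmin <- tr / 2 - dd
    alpha <- sqrt(lmax / max(lmin, .Machine$double.xmin))
    theta <- 0.5 * atan2(2 * mxy, mxx - myy)
    if (theta > pi / 2) theta <- theta - pi
    if (theta < -pi / 2) theta <- theta + pi
    out$aspect[r] <- alpha
    out$angle[r] <- theta
    out$isotropic[r] <- alpha < 1 + 1e-9
  }
  out$angle[out$isotropic] <- NA_real_
  out
}

#' Orientational order parameter
#'
#' `Q = <cos(2 theta)>` over anisotropic cells, with `theta` the angle of
#' each cell's major axis to the anterior--posterior (x) axis: 0 for randomly
#' aligned cells, 1 for perfect alignment with the AP axis, -1 for alignment
#' with the perpendicular axis.
#'
#' @param state a [tissue_state()], or a data frame from
#'   [cell_shape_tensor()].
#' @return Scalar in `[-1, 1]`; an all-isotropic tissue returns 0 with a
#'   warning.
#' @export
order_parameter <- function(state) {
  shp <- if (inherits(state, "tissue_state")) cell_shape_tensor(state) else state
  ang <- shp$angle[!shp$isotropic]
  if (!length(ang)) {
    warning("all cells isotropic: order parameter undefined, returning 0")
    return(0)
  }
  mean(cos(2 * ang))
}

#' Junction tension
#'
#' The tension carried by a junction shared by cells i and j is the sum of
#' the two perimeter-spring tensions,
#' `tau_J = kp (p_i - p0_i) + kp (p_j - p0_j)`,
#' evaluated at the current perimeters and current (actively shrunken)
#' preferred perimeters. Equals the derivative of the tissue energy with
#' respect to an elongation of that junction at fixed other junction
#' lengths.
#'
#' @param state a [tissue_state()].
#' @param params an [energy_params()].
#' @param junctions optional junction table from [tissue_junctions()]
#'   (recomputed if omitted).
#' @return Numeric vector of tensions aligned with the junction table rows.
#' @export
junction_tension <- function(state, params = energy_params(),
                             junctions = NULL) {
  if (is.null(junctions)) junctions <- tissue_junctions(state)
  if (any(junctions$cell_i == junctions$cell_j))
    stop("junction with identical cells on both sides")
  g <- cell_geometry(state)
  ten <- params$kp * (g$perimeter - state$p0)
  ten[junctions$cell_i] + ten[junctions$cell_j]
}

#' Assemble an observable record
#'
#' Tissue-level summary at one closure stage: mean and SD of the cell shape
#' index, mean and SD of the aspect ratio, orientational order, mean
#' junction tension, rigid-junction fraction, cell count and energy. Means
#' are unweighted over cells.
#'
#' @param state a minimized [tissue_state()].
#' @param params an [energy_params()].
#' @param dA fractional area change stamp.
#' @param eps_tension tension floor defining a rigid junction.
#' @return One-row data frame with columns `dA`, `q_mean`, `q_sd`,
#'   `ar_mean`, `ar_sd`, `Q_order`, `tension_mean`, `fr`, `n_cells`,
#'   `energy`.
#' @export
observable_record <- function(state, params = energy_params(), dA = 0,
                              eps_tension = 1e-4) {
  g <- cell_geometry(state)
  q <- shape_index(g$area, g$perimeter)
  shp <- cell_shape_tensor(state)
  jn <- tissue_junctions(state)
  tau <- junction_tension(state, params, jn)
  data.frame(
    dA = dA,
    q_mean = mean(q),
    q_sd = stats::sd(q),
    ar_mean = mean(shp$aspect),
    ar_sd = stats::sd(shp$aspect),
    Q_order = suppressWarnings(order_parameter(shp)),
    tension_mean = mean(tau),
    fr = mean(tau > eps_tension),
    n_cells = length(state$cells),
    energy = tissue_energy(state, params)
  )
}
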