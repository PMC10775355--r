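#' Rigid-junction fraction
#'
#' Fraction of junctions whose tension exceeds the numerical floor
#' `eps_tension`. "Non-zero tension" requires a floor in floating point; the
#' default `1e-4` (units `kp * sqrt(a0)`) sits well above the minimizer's
#' force residual, and results should be insensitive to its choice over
#' `[1e-5, 1e-3]`.
#'
#' @param state a minimized [tissue_state()].
#' @param params an [energy_params()].
#' @param eps_tension tension floor.
#' @return Scalar in `[0, 1]`.
#' @export
rigid_fraction <- function(state, params = energy_params(),
                           eps_tension = 1e-4) {
  mean(junction_tension(state, params) > eps_tension)
}

#' Wrapping percolation of a junction subset
#'
#' Does the given subset of junctions form a connected path that wraps the
#' periodic box in x and/or y? Detected by a union-find over vertices that
#' tracks each node's displacement to its component root; an edge closing a
#' loop with non-zero winding in a direction wraps in that direction.
#'
#' @param state a [tissue_state()].
#' @param junction_idx integer rows of [tissue_junctions()] in the subset,
#'   or a logical vector over junctions.
#' @param junctions optional precomputed junction table.
#' @return List with logical `wraps_x`, `wraps_y`.
#' @export
wrapping_percolation <- function(state, junction_idx, junctions = NULL) {
  if (is.null(junctions)) junctions <- tissue_junctions(state)
  if (is.logical(junction_idx)) junction_idx <- which(junction_idx)
  if (!length(junction_idx)) return(list(wraps_x = FALSE, wraps_y = FALSE))
  sub <- junctions[junction_idx, , drop = FALSE]
  d <- .min_image(state$vertices[sub$v2, , drop = FALSE] -
                  state$vertices[sub$v1, , drop = FALSE], state$box)
  res <- vm_percolate(nrow(state$vertices), cbind(sub$v1, sub$v2), d,
                      state$box$Lx, state$box$Ly)
  list(wraps_x = res$wraps_x, wraps_y = res$wraps_y)
}

#' Tension-percolation classification of a tissue
#'
#' A tissue is solid when its tension-bearing junctions percolate: the rigid
#' subnetwork must wrap the periodic box in both directions. The
#' rigid-junction fraction `fr` is also reported against the calibrated
#' threshold `fc` (about 0.66 for Voronoi-like networks).
#'
#' @inheritParams rigid_fraction
#' @param fc percolation threshold used for the summary comparison.
#' @return Object of class `"percolation_result"`: list with `fr`,
#'   `wraps_x`, `wraps_y`, `classification` ("solid" iff the rigid network
#'   wraps in both directions), `eps_tension`, `fc`.
#' @export
percolation_result <- function(state, params = energy_params(),
                               eps_tension = 1e-4, fc = 0.66) {
  jn <- tissue_junctions(state)
  tau <- junction_tension(state, params, jn)
  rigid <- tau > eps_tension
  w <- wrapping_percolation(state, rigid, jn)
  structure(list(fr = mean(rigid), wraps_x = w$wraps_x, wraps_y = w$wraps_y,
                 classification = if (w$wraps_x && w$wraps_y) "solid" else "fluid",
                 eps_tension = eps_tension, fc = fc),
            class = "percolation_result")
}

#' @export
print.percolation_result <- function(x, ...) {
  cat(sprintf("percolation_result: fr = %.3f (fc = %.2f), wraps x:%s y:%s -> %s\n",
              x$fr, x$fc, x$wraps_x, x$wraps_y, x$classification))
  invisible(x)
}

#' Calibrate the bond-percolation threshold on random Voronoi networks
#'
#' For each trial, builds a random periodic Voronoi tiling, assigns every
#' junction an independent uniform score, and finds the exact occupation
#' fraction at which the occupied subnetwork first wraps in both periodic
#' directions (edges added in increasing score order with an incremental
#' winding union-find; this is the limit of bisecting on the marking
#' probability with a common random-number coupling). Returns the mean and
#' standard error of the per-trial thresholds.
#'
#' @param n_cells cells per tiling (>= 64 recommended).
#' @param n_trials independent tilings.
#' @param seed RNG seed.
#' @param box periodic box (default square with unit mean cell area).
#' @return List with `fc`, `se`, and the per-trial `thresholds`.
#' @export
calibrate_fc_voronoi <- function(n_cells = 256, n_trials = 50, seed = 1,
                                 box = NULL) {
  if (n_cells < 4) stop("n_cells too small for a percolation estimate")
  if (is.null(box)) {
    L <- sqrt(n_cells)
    box <- tissue_box(L, L)
  }
  set.seed(seed)
  trial_seeds <- sample.int(2^31 - 2, n_trials)
  thr <- vapply(seq_len(n_trials), function(t) {
    st <- build_voronoi_tissue(n_cells, box, seed = trial_seeds[t])
    jn <- tissue_junctions(st)
    ne <- nrow(jn)
    set.seed(trial_seeds[t] + 1L)
    ord <- sample.int(ne)  # uniform scores == random addition order
    sub <- jn[ord, ]
    d <- .min_image(st$vertices[sub$v2, , drop = FALSE] -
                    st$vertices[sub$v1, , drop = FALSE], st$box)
    k <- vm_percolation_onset(nrow(st$vertices), cbind(sub$v1, sub$v2), d,
                              st$box$Lx, st$box$Ly)
    if (k == 0L) NA_real_ else k / ne
  }, numeric(1))
  thr <- thr[!is.na(thr)]
  list(fc = mean(thr), se = stats::sd(thr) / sqrt(length(thr)),
       thresholds = thr)
}

#' Rigidity phase diagram over (mean shape index, closure stage)
#'
#' For each initial mean preferred shape index on the grid, runs the uniaxial
#' closure protocol and evaluates the rigid-junction fraction at each
#' requested stage, classifying each grid point as solid or fluid by
#' two-direction wrapping of the tension network (with `fr` vs `fc` reported
#' as the summary statistic). States are prepared by the deformation
#' protocol itself, not as independent fresh tilings, matching how a closure
#' trajectory traverses the diagram; an overlay trajectory path can be
#' attached for plotting.
#'
#' @param q0_grid initial mean preferred shape indices.
#' @param dA_grid closure stages at which to evaluate.
#' @param n_cells,box_aspect tiling size and box aspect ratio.
#' @param schedule a [closure_schedule()]; its `dA_max` is raised to cover
#'   `dA_grid`.
#' @param dist an [shape_distribution()] supplying the polydispersity.
#' @param params,settings energy and minimizer controls.
#' @param seed RNG seed.
#' @param fc percolation threshold for classification summary.
#' @param eps_tension rigid-tension floor.
#' @param overlay optional `closure_trajectory` whose (q_mean, dA) path is
#'   stored alongside the grid.
#' @return Object of class `"phase_diagram"`: list with `grid` (data frame
#'   `q0_mean, q_mean, dA, fr, wraps_x, wraps_y, classification`) and
#'   `overlay` (data frame or NULL). Minimization failures mark grid points
#'   `classification = "invalid"` rather than being dropped.
#' @export
build_phase_diagram <- function(q0_grid, dA_grid, n_cells = 64,
                                box_aspect = 2, schedule = closure_schedule(),
                                dist = shape_distribution(),
                                params = energy_params(),
                                settings = minimizer_settings(), seed = 1,
                                fc = 0.66, eps_tension = 1e-4,
                                overlay = NULL) {
  if (!length(q0_grid) || !length(dA_grid)) stop("empty grid")
  dA_grid <- sort(dA_grid)
  schedule$dA_max <- max(max(dA_grid), schedule$dA_max)
  rows <- list()
  for (q0 in q0_grid) {
    d <- dist
    d$q_mean <- q0
    traj <- run_closure(n_cells = n_cells, box_aspect = box_aspect,
                        schedule = schedule, dist = d, params = params,
                        settings = settings, seed = seed,
                        keep_snapshots = TRUE, snapshot_dA = dA_grid,
                        eps_tension = eps_tension)
    for (dA in dA_grid) {
      snap_i <- which.min(abs(vapply(traj$snapshots, function(s) s$dA,
                                     numeric(1)) - dA))
      snap <- traj$snapshots[[snap_i]]
      ok <- traj$valid || snap$dA <= max(traj$records$dA)
      if (!ok || abs(snap$dA - dA) > schedule$delta) {
        rows[[length(rows) + 1L]] <- data.frame(
          q0_mean = q0, q_mean = NA_real_, dA = dA, fr = NA_real_,
          wraps_x = NA, wraps_y = NA, classification = "invalid")
        next
      }
      pr <- percolation_result(snap$state, params, eps_tension, fc)
      g <- cell_geometry(snap$state)
      rows[[length(rows) + 1L]] <- data.frame(
        q0_mean = q0, q_mean = mean(shape_index(g$area, g$perimeter)),
        dA = dA, fr = pr$fr, wraps_x = pr$wraps_x, wraps_y = pr$wraps_y,
        classification = pr$classification)
    }
  }
  ov <- if (!is.null(overlay))
    overlay$records[, c("dA", "q_mean")] else NULL
  structure(list(grid = do.call(rbind, rows), fc = fc, overlay = ov),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("phase_diagram:", nrow(x$grid), "grid points, fc =", x$fc, "\n")
  print(utils::head(x$grid, 10))
  invisible(x)
}
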