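#' Energy parameters
#'
#' Moduli and preferred area of the vertex-model energy
#' `E = sum_i 1/2 ka (a_i - a0)^2 + 1/2 kp (p_i - p0_i)^2`.
#' All quantities are nondimensionalized by `a0 = 1` and `kp = 1`, which set
#' the model units; `ka = kp = 1` for all cells by default.
#'
#' @param ka area modulus (energy / area^2).
#' @param kp perimeter modulus (energy / length^2).
#' @param a0 preferred cell area (shared scalar).
#' @return An object of class `"energy_params"`.
#' @export
energy_params <- function(ka = 1, kp = 1, a0 = 1) {
  if (ka <= 0 || kp <= 0 || a0 <= 0) stop("ka, kp and a0 must be positive")
  structure(list(ka = ka, kp = kp, a0 = a0), class = "energy_params")
}

#' Minimizer settings
#'
#' Controls for the FIRE quasistatic minimizer. The force tolerance is in
#' units of `kp * sqrt(a0)`; minimization stops when the largest per-vertex
#' force magnitude drops below it. The default tolerance sits two decades
#' below the rigid-tension floor (1e-4), so junction tensions and the
#' rigid-junction fraction are insensitive to the residual.
#'
#' @param tol force tolerance.
#' @param max_iter iteration budget across all FIRE restarts.
#' @param dt0,dt_max initial and maximal FIRE timestep.
#' @param alpha0 initial velocity-mixing coefficient.
#' @param f_inc,f_dec,f_alpha timestep growth/shrink and mixing decay factors.
#' @param n_min downhill steps before acceleration starts.
#' @param t1_check_every iterations between short-edge (T1) scans during
#'   descent when T1 moves are enabled.
#' @param t1_res_gate scan for collapsing junctions only once the force
#'   residual is below this value (so transient dips during descent do not
#'   trigger reconnections; units `kp * sqrt(a0)`).
#' @return An object of class `"minimizer_settings"`.
#' @export
minimizer_settings <- function(tol = 1e-5, max_iter = 4e5, dt0 = 0.05,
                               dt_max = 0.5, alpha0 = 0.1, f_inc = 1.1,
                               f_dec = 0.5, f_alpha = 0.99, n_min = 5,
                               t1_check_every = 10, t1_res_gate = 1e-3) {
  if (tol <= 0) stop("force tolerance must be positive")
  structure(list(tol = tol, max_iter = as.integer(max_iter), dt0 = dt0,
                 dt_max = dt_max, alpha0 = alpha0, f_inc = f_inc,
                 f_dec = f_dec, f_alpha = f_alpha, n_min = as.integer(n_min),
                 t1_check_every = as.integer(t1_check_every),
                 t1_res_gate = t1_res_gate),
            class = "minimizer_settings")
}

#' Tissue energy
#'
#' Sum over cells of `1/2 ka (a_i - a0)^2 + 1/2 kp (p_i - p0_i)^2` with
#' areas and perimeters measured under the minimum-image convention.
#'
#' @param state a [tissue_state()].
#' @param params an [energy_params()].
#' @return Scalar energy.
#' @export
tissue_energy <- function(state, params = energy_params()) {
  fc <- .flat_cells(state)
  vm_energy(state$vertices, fc$starts, fc$verts, state$p0, params$a0,
            params$ka, params$kp, state$box$Lx, state$box$Ly)
}

#' Analytic vertex forces
#'
#' Minus the gradient of [tissue_energy()] with respect to the vertex
#' positions, assembled analytically from each adjacent cell's area and
#' perimeter gradients. Under periodic boundaries the forces sum to zero
#' (translation invariance).
#'
#' @inheritParams tissue_energy
#' @return Numeric matrix (V x 2) of forces.
#' @export
vertex_forces <- function(state, params = energy_params()) {
  fc <- .flat_cells(state)
  vm_forces(state$vertices, fc$starts, fc$verts, state$p0, params$a0,
            params$ka, params$kp, state$box$Lx, state$box$Ly)
}

#' Quasistatic energy minimization
#'
#' Relaxes the vertex positions with FIRE until force balance: the largest
#' per-vertex force drops below `settings$tol`, where vertices joined by
#' near-zero tension-pinned edges (rosette-like higher-order vertices) are
#' treated as single units. With `allow_t1 = TRUE`, edges shorter than the
#' T1 threshold `t1_length` trigger a trial [t1_flip()] during descent
#' (scanned every `settings$t1_check_every` iterations). A flip is accepted
#' only when its rotated edge opens up under a brief relaxation; a flip
#' whose new edge immediately re-contracts marks a mechanically stable
#' short edge, which is kept (pinned) rather than fuelling an unphysical
#' flip-flop sequence. Accepted flips are logged in the report.
#'
#' @param state a [tissue_state()].
#' @param params an [energy_params()].
#' @param settings a [minimizer_settings()].
#' @param allow_t1 enable neighbor exchanges during descent.
#' @param t1_length T1 threshold length (default `0.02 * sqrt(a0)`).
#' @param post_length edge length after a flip (default `1.5 * t1_length`).
#' @param blocked character keys ("v1 v2") of junctions whose flip was
#'   already rejected (pinned short edges); they are not re-probed. The
#'   final set is returned in the report so a quasistatic driver can carry
#'   it between deformation steps and re-examine pinned edges at its own
#'   cadence.
#' @param accept_neutral also accept reconnections that leave the energy
#'   unchanged (zero-cost moves). Off for quasistatic trajectories (the
#'   athermal limit has no noise to realize degenerate flips); on when
#'   annealing a state to locate the floppy/compatible phase, where
#'   zero-cost rearrangements are the equilibration moves.
#' @return A list with `state` (relaxed) and `report`: final `energy`,
#'   `residual`, `iterations`, `converged` flag and a data frame
#'   `t1_events`. Non-convergence within the iteration budget is reported
#'   explicitly (`converged = FALSE`), never silently.
#' @export
minimize_tissue <- function(state, params = energy_params(),
                            settings = minimizer_settings(),
                            allow_t1 = FALSE, t1_length = NULL,
                            post_length = NULL, blocked = character(0),
                            accept_neutral = FALSE) {
  if (is.null(t1_length)) t1_length <- 0.02 * sqrt(params$a0)
  if (is.null(post_length)) post_length <- 1.5 * t1_length
  iter_left <- settings$max_iter
  total_iter <- 0L
  t1_log <- list()
  repeat {
    fc <- .flat_cells(state)
    jn <- tissue_junctions(state)
    edges <- cbind(jn$v1 - 1L, jn$v2 - 1L)
    flippable <- if (allow_t1)
      !(paste(pmin(jn$v1, jn$v2), pmax(jn$v1, jn$v2)) %in% blocked)
    else rep(FALSE, nrow(jn))
    t1l <- if (allow_t1) t1_length else -1
    res <- vm_fire(state$vertices, fc$starts, fc$verts, state$p0, params$a0,
                   params$ka, params$kp, state$box$Lx, state$box$Ly,
                   settings$tol, iter_left, settings$dt0, settings$dt_max,
                   settings$alpha0, settings$f_inc, settings$f_dec,
                   settings$f_alpha, settings$n_min,
                   edges, flippable, t1l, settings$t1_check_every,
                   0.01 * t1_length, settings$t1_res_gate)
    state$vertices <- res$vertices
    total_iter <- total_iter + res$iterations
    iter_left <- iter_left - res$iterations
    if (res$status == 2L) {
      # Candidate short edges, shortest first. Quasistatic bifurcation test:
      # relax a no-flip branch (short edge pinned) and a flipped branch for
      # a few hundred steps each; the reconnection is kept only if it
      # releases elastic energy beyond tolerance AND its rotated edge opens.
      # Degenerate zero-tension wanders in floppy pockets fail the energy
      # test (both branches are equivalent minima) and the edge is pinned,
      # which also prevents flip-flop wars at stable higher-order vertices.
      probe_relax <- function(s) {
        fcp <- .flat_cells(s)
        jp <- tissue_junctions(s)
        vm_fire(s$vertices, fcp$starts, fcp$verts, s$p0,
                params$a0, params$ka, params$kp, s$box$Lx, s$box$Ly,
                settings$tol, 500L, settings$dt0, settings$dt_max,
                settings$alpha0, settings$f_inc, settings$f_dec,
                settings$f_alpha, settings$n_min,
                cbind(jp$v1 - 1L, jp$v2 - 1L), rep(FALSE, nrow(jp)), -1,
                settings$t1_check_every, 0.01 * t1_length,
                settings$t1_res_gate)
      }
      cand <- res$short_edges
      flipped <- FALSE
      for (e in cand[order(jn$length[cand])]) {
        vpair <- c(jn$v1[e], jn$v2[e])
        base <- probe_relax(state)
        trial <- tryCatch(
          t1_flip(state, vpair, post_length = post_length),
          error = function(err) err)
        if (!inherits(trial, "error")) {
          probe <- probe_relax(trial)
          d <- .min_image(probe$vertices[vpair[2], , drop = FALSE] -
                          probe$vertices[vpair[1], , drop = FALSE],
                          trial$box)
          opened <- sqrt(sum(d^2)) > post_length
          dE <- base$energy - probe$energy
          # neutral mode drops the opening requirement: zero-cost flips in
          # a floppy network open only lazily, yet their existence is the
          # point being probed
          keep_flip <- if (accept_neutral) dE > -1e-9 else
            (opened && dE > 1e-9)
          total_iter <- total_iter + base$iterations + probe$iterations
          iter_left <- iter_left - base$iterations - probe$iterations
          if (keep_flip) {
            trial$vertices <- probe$vertices
            info <- attr(trial, "t1_info")
            t1_log[[length(t1_log) + 1L]] <- data.frame(
              iteration = total_iter, v1 = vpair[1], v2 = vpair[2],
              lost_i = info$lost[1], lost_j = info$lost[2],
              gained_i = info$gained[1], gained_j = info$gained[2],
              released = dE)
            state <- trial
            flipped <- TRUE
            break
          }
        } else {
          total_iter <- total_iter + base$iterations
          iter_left <- iter_left - base$iterations
        }
        # keep the relaxed no-flip branch; pin the edge for this relaxation
        state$vertices <- base$vertices
        blocked <- c(blocked, paste(min(vpair), max(vpair)))
      }
      if (iter_left > 0L) next
    }
    converged <- res$status == 0L
    t1_events <- if (length(t1_log)) do.call(rbind, t1_log) else
      data.frame(iteration = integer(0), v1 = integer(0), v2 = integer(0),
                 lost_i = integer(0), lost_j = integer(0),
                 gained_i = integer(0), gained_j = integer(0),
                 released = numeric(0))
    return(list(state = state,
                report = list(energy = res$energy, residual = res$residual,
                              iterations = total_iter, converged = converged,
                              t1_events = t1_events, blocked = blocked)))
  }
}
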