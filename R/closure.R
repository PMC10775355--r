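#' Closure deformation schedule
#'
#' Parameters of the quasistatic dorsal-closure protocol: at every step the
#' box height is reduced by a fixed fraction `delta` of its *initial* height
#' (width fixed, uniaxial mode), preferred perimeters shrink linearly with
#' the fractional area change, and cells ingress at a constant rate. The
#' isotropic mode rescales both box lengths to produce the identical
#' per-step area decrement and serves as a control: it produces the same
#' `dA` trajectory but no orientational order.
#'
#' @param delta per-step height decrement as a fraction of the initial
#'   height (default 0.00125, i.e. 0.125%).
#' @param dA_max target maximal fractional area change (in `(0, 1)`).
#' @param shrink_slope linear shrink rate `c` of the preferred perimeters:
#'   `p0_i(dA) = p0_i(0) (1 - c dA)`.
#' @param ingression_fraction fraction of the initial cells removed over the
#'   full run (about 0.1 experimentally).
#' @param mode `"uniaxial"` or `"isotropic"`.
#' @param record_stride record observables every this much `dA`.
#' @return An object of class `"closure_schedule"`.
#' @export
closure_schedule <- function(delta = 0.00125, dA_max = 0.8,
                             shrink_slope = 0.65, ingression_fraction = 0.1,
                             mode = c("uniaxial", "isotropic"),
                             record_stride = 0.01) {
  mode <- match.arg(mode)
  if (delta <= 0 || delta >= 1) stop("delta must be in (0, 1)")
  if (dA_max <= 0 || dA_max >= 1) stop("dA_max must be in (0, 1)")
  if (shrink_slope < 0) stop("shrink_slope must be non-negative")
  if (ingression_fraction < 0 || ingression_fraction >= 1)
    stop("ingression_fraction must be in [0, 1)")
  structure(list(delta = delta, dA_max = dA_max, shrink_slope = shrink_slope,
                 ingression_fraction = ingression_fraction, mode = mode,
                 record_stride = record_stride),
            class = "closure_schedule")
}

#' Initial preferred-shape-index distribution
#'
#' The polydisperse initial condition: preferred shape indices
#' `q0_i = p0_i / sqrt(a0)` are drawn from a normal distribution whose
#' standard deviation (0.45) is matched to the measured cell-to-cell
#' variability at the onset of closure.
#'
#' @param q_mean mean initial preferred shape index.
#' @param q_sd standard deviation of the initial preferred shape index.
#' @return An object of class `"shape_distribution"`.
#' @export
shape_distribution <- function(q_mean = 4.2, q_sd = 0.45) {
  if (q_sd < 0) stop("q_sd must be non-negative")
  structure(list(q_mean = q_mean, q_sd = q_sd, family = "normal"),
            class = "shape_distribution")
}

#' Assign polydisperse preferred perimeters and relax
#'
#' Draws `q0_i` from the normal distribution (resampling any non-positive
#' draw; it is an error if more than 1% of draws are expected non-positive),
#' sets `p0_i = q0_i sqrt(a0)`, and minimizes the energy. The resulting
#' *actual* shape-index distribution is recorded in the attribute
#' `"q_actual"` for comparison against the measured onset distribution.
#'
#' @param state a [tissue_state()].
#' @param dist a [shape_distribution()].
#' @param seed integer seed (same seed, same assignment).
#' @param params,settings energy and minimizer controls.
#' @param relax minimize after assignment (default TRUE).
#' @param t1_length,post_length T1 threshold and post-flip edge length
#'   passed to [minimize_tissue()].
#' @return The relaxed [tissue_state()] with attributes `"q_actual"` and
#'   `"init_report"`.
#' @export
initialize_polydisperse <- function(state, dist, seed = 1,
                                    params = energy_params(),
                                    settings = minimizer_settings(),
                                    relax = TRUE, t1_length = NULL,
                                    post_length = NULL) {
  n <- length(state$cells)
  if (dist$q_sd > 0 &&
      stats::pnorm(0, dist$q_mean, dist$q_sd) > 0.01)
    stop("distribution misconfigured: >1% of preferred-perimeter draws would be non-positive")
  set.seed(seed)
  q0 <- stats::rnorm(n, dist$q_mean, dist$q_sd)
  for (guard in 1:100) {
    bad <- q0 <= 0
    if (!any(bad)) break
    q0[bad] <- stats::rnorm(sum(bad), dist$q_mean, dist$q_sd)
  }
  state$p0 <- q0 * sqrt(state$a0)
  rep <- NULL
  if (relax) {
    out <- minimize_tissue(state, params, settings, allow_t1 = TRUE,
                           t1_length = t1_length, post_length = post_length)
    state <- out$state
    rep <- out$report
  }
  g <- cell_geometry(state)
  attr(state, "q_actual") <- shape_index(g$area, g$perimeter)
  attr(state, "init_report") <- rep
  state
}

#' One quasistatic deformation step
#'
#' Uniaxial mode: the box height is reduced by `delta` times the *initial*
#' height (width fixed) and all vertex y coordinates are rescaled affinely.
#' Isotropic mode: both box lengths are rescaled by a common factor chosen
#' to produce the identical per-step area decrement. The state is not
#' re-minimized here; the protocol does that after every step.
#'
#' @param state a [tissue_state()] carrying a `box0` element (the initial
#'   box, attached by [run_closure()]; defaults to the current box).
#' @param schedule a [closure_schedule()].
#' @return The deformed [tissue_state()].
#' @export
apply_deformation_step <- function(state, schedule) {
  box0 <- if (!is.null(state$box0)) state$box0 else state$box
  A0 <- box0$Lx * box0$Ly
  dec <- schedule$delta * A0  # per-step area decrement (width-fixed algebra)
  if (schedule$mode == "uniaxial") {
    new_Ly <- state$box$Ly - schedule$delta * box0$Ly
    if (new_Ly <= 0) stop("deformation step would make the box height non-positive")
    ratio <- new_Ly / state$box$Ly
    state$vertices[, 2] <- state$vertices[, 2] * ratio
    state$box <- tissue_box(state$box$Lx, new_Ly)
  } else {
    A <- state$box$Lx * state$box$Ly
    if (A - dec <= 0) stop("deformation step would make the box area non-positive")
    s <- sqrt((A - dec) / A)
    state$vertices <- state$vertices * s
    state$box <- tissue_box(state$box$Lx * s, state$box$Ly * s)
  }
  state$box0 <- box0
  state
}

#' Linear active shrinkage of preferred perimeters
#'
#' `p0_i(dA) = p0_i(0) (1 - c dA)`, floored at zero; the preferred area is
#' left unchanged. The initial `p0` vector is taken from `state$p0_init`
#' (attached by [run_closure()]; defaults to the current `p0`).
#'
#' @param state a [tissue_state()].
#' @param dA current fractional area change.
#' @param schedule a [closure_schedule()].
#' @return The updated [tissue_state()].
#' @export
update_preferred_perimeters <- function(state, dA, schedule) {
  p0_init <- if (!is.null(state$p0_init)) state$p0_init else state$p0
  state$p0_init <- p0_init
  state$p0 <- pmax(p0_init * (1 - schedule$shrink_slope * dA), 0)
  state
}

#' Random cell ingression
#'
#' With probability `p_step` (the per-step rate that spreads
#' `ingression_fraction` of the initial cells uniformly over the run), one
#' uniformly chosen cell is removed by a T2 collapse. Uses the current RNG
#' stream. Skips silently when no cell can be removed.
#'
#' @param state a [tissue_state()].
#' @param schedule a [closure_schedule()].
#' @param p_step per-step removal probability.
#' @return The (possibly reduced) [tissue_state()]; attribute `"ingressed"`
#'   carries the removed cell id if an ingression happened.
#' @export
ingress_cells <- function(state, schedule, p_step) {
  attr(state, "ingressed") <- NULL
  if (p_step <= 0 || stats::runif(1) > p_step) return(state)
  if (length(state$cells) <= 3L) return(state)
  victim <- state$cell_ids[sample.int(length(state$cells), 1L)]
  out <- tryCatch(t2_remove_cell(state, victim), error = function(e) NULL)
  if (is.null(out)) return(state)
  attr(out, "ingressed") <- victim
  out
}

#' Run the dorsal-closure protocol
#'
#' The full simulation: a random periodic Voronoi tiling (box area
#' `n_cells * a0`, aspect `box_aspect`), polydisperse preferred perimeters,
#' then a loop of deformation step, preferred-perimeter update, optional
#' ingression and T1-enabled energy minimization until `dA_max`.
#' Observables are recorded every `record_stride` in `dA`; every recorded
#' state satisfies the force tolerance. A minimization failure aborts with
#' the partial trajectory flagged invalid.
#'
#' @param n_cells initial cell count.
#' @param box_aspect initial box aspect ratio `Lx / Ly`.
#' @param schedule a [closure_schedule()].
#' @param dist a [shape_distribution()].
#' @param params,settings energy and minimizer controls.
#' @param seed integer seed; the trajectory is a pure function of the
#'   configuration and this seed.
#' @param allow_t1 enable neighbor exchanges during the run (on for headline
#'   runs, so that their absence is an observation, not an assumption).
#' @param keep_snapshots store tissue states at `snapshot_dA`.
#' @param snapshot_dA stages at which to keep snapshots.
#' @param eps_tension rigid-tension floor for the recorded `fr`.
#' @param stop_after_t1 stop the run right after the first neighbor
#'   exchange (used by fluidization controls, where one event settles the
#'   question).
#' @param t1_length,post_length T1 threshold and post-flip edge length
#'   passed to [minimize_tissue()] (defaults `0.02 sqrt(a0)` and 1.5 times
#'   that).
#' @param accept_neutral also accept energy-neutral reconnections (see
#'   [minimize_tissue()]); off for the athermal headline protocol, useful
#'   for controls that probe whether zero-cost rearrangements exist.
#' @return Object of class `"closure_trajectory"`: list with `records` (one
#'   row per recorded stage: `dA, q_mean, q_sd, ar_mean, ar_sd, Q_order,
#'   tension_mean, fr, n_cells, n_t1, energy`), `events` (T1 and ingression
#'   log), `snapshots`, `init` (initial actual shape indices), `config`,
#'   and `valid`.
#' @export
run_closure <- function(n_cells = 256, box_aspect = 2,
                        schedule = closure_schedule(),
                        dist = shape_distribution(),
                        params = energy_params(),
                        settings = minimizer_settings(), seed = 1,
                        allow_t1 = TRUE, keep_snapshots = FALSE,
                        snapshot_dA = NULL, eps_tension = 1e-4,
                        stop_after_t1 = FALSE, t1_length = NULL,
                        post_length = NULL, accept_neutral = FALSE) {
  set.seed(seed)
  sub_seeds <- sample.int(2^31 - 2, 2)
  A0 <- n_cells * params$a0
  box <- tissue_box(sqrt(A0 * box_aspect), sqrt(A0 / box_aspect))
  state <- build_voronoi_tissue(n_cells, box, seed = sub_seeds[1],
                                a0 = params$a0)
  state <- initialize_polydisperse(state, dist, seed = sub_seeds[2],
                                   params = params, settings = settings,
                                   t1_length = t1_length,
                                   post_length = post_length)
  q_actual0 <- attr(state, "q_actual")
  state$box0 <- state$box
  state$p0_init <- state$p0
  set.seed(seed + 1709L)  # stream for ingression draws

  n_steps <- round(schedule$dA_max / schedule$delta)
  p_step <- schedule$ingression_fraction * n_cells / n_steps
  records <- list()
  events <- list()
  snapshots <- list()
  n_t1 <- 0L        # spontaneous neighbor exchanges
  n_t1_assoc <- 0L  # exchanges in the relaxation right after an ingression
  valid <- TRUE
  next_record <- 0
  next_snap <- if (keep_snapshots && length(snapshot_dA)) sort(snapshot_dA) else numeric(0)

  note_state <- function(dA) {
    rec <- observable_record(state, params, dA, eps_tension)
    rec$n_t1 <- n_t1
    rec$n_t1_ingression <- n_t1_assoc
    records[[length(records) + 1L]] <<- rec
    if (length(next_snap) && dA + 1e-9 >= next_snap[1]) {
      snapshots[[length(snapshots) + 1L]] <<- list(dA = dA, state = state)
      next_snap <<- next_snap[-1L]
    }
  }
  note_state(0)
  next_record <- schedule$record_stride
  # pinned (rejected-flip) junctions carry over from the initial relaxation
  init_rep <- attr(state, "init_report")
  pinned <- if (!is.null(init_rep)) init_rep$blocked else character(0)

  for (k in seq_len(n_steps)) {
    dA <- k * schedule$delta
    state <- apply_deformation_step(state, schedule)
    state <- update_preferred_perimeters(state, dA, schedule)
    state <- ingress_cells(state, schedule, p_step)
    ing <- attr(state, "ingressed")
    if (!is.null(ing))
      events[[length(events) + 1L]] <- data.frame(
        type = "ingression", step = k, dA = dA, cell = ing,
        v1 = NA_integer_, v2 = NA_integer_, assoc_ingression = NA,
        released = NA_real_)
    # re-examine pinned junctions periodically (every 0.02 in dA): the
    # loading changes slowly, so earlier flip rejections rarely reverse
    if (k %% 16L == 0L) pinned <- character(0)
    out <- minimize_tissue(state, params, settings, allow_t1 = allow_t1,
                           t1_length = t1_length, post_length = post_length,
                           blocked = pinned, accept_neutral = accept_neutral)
    pinned <- out$report$blocked
    state <- out$state
    if (nrow(out$report$t1_events)) {
      # exchanges in the relaxation that follows a cell ingression are
      # remodelling around the ingressing cell, reported separately from
      # spontaneous exchanges (the fluidization signature)
      assoc <- !is.null(ing)
      if (assoc) n_t1_assoc <- n_t1_assoc + nrow(out$report$t1_events)
      else n_t1 <- n_t1 + nrow(out$report$t1_events)
      for (r in seq_len(nrow(out$report$t1_events)))
        events[[length(events) + 1L]] <- data.frame(
          type = "t1", step = k, dA = dA, cell = NA_integer_,
          v1 = out$report$t1_events$v1[r], v2 = out$report$t1_events$v2[r],
          assoc_ingression = assoc,
          released = out$report$t1_events$released[r])
    }
    if (!out$report$converged) {
      warning("minimization failed at dA = ", signif(dA, 4),
              "; trajectory flagged invalid")
      valid <- FALSE
      note_state(dA)
      break
    }
    if (dA + 1e-9 >= next_record || k == n_steps) {
      note_state(dA)
      next_record <- next_record + schedule$record_stride
    }
    if (stop_after_t1 && n_t1 > 0L) break
  }

  structure(list(
    records = do.call(rbind, records),
    events = if (length(events)) do.call(rbind, events) else
      data.frame(type = character(0), step = integer(0), dA = numeric(0),
                 cell = integer(0), v1 = integer(0), v2 = integer(0),
                 assoc_ingression = logical(0), released = numeric(0)),
    snapshots = snapshots,
    init = list(q_actual = q_actual0),
    config = list(n_cells = n_cells, box_aspect = box_aspect,
                  schedule = schedule, dist = dist, params = params,
                  settings = settings, seed = seed, allow_t1 = allow_t1,
                  eps_tension = eps_tension),
    valid = valid
  ), class = "closure_trajectory")
}

#' @export
print.closure_trajectory <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf(
    "closure_trajectory: %d records to dA = %.3f, %d spontaneous T1 (+%d at ingressions), %d ingressions, %s\n",
    n, x$records$dA[n],
    sum(x$events$type == "t1" & !x$events$assoc_ingression),
    sum(x$events$type == "t1" & x$events$assoc_ingression),
    sum(x$events$type == "ingression"),
    if (x$valid) "valid" else "INVALID (minimization failure)"))
  invisible(x)
}

#' @export
plot.closure_trajectory <- function(x, which = c("q_mean", "tension_mean", "Q_order", "fr"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  for (w in which)
    graphics::plot(x$records$dA, x$records[[w]], type = "l",
                   xlab = expression(Delta * A), ylab = w, ...)
  invisible(x)
}
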