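#' Synthetic tracked-cohort specification
#'
#' Parameters of the generator that emulates segmented-and-tracked
#' amnioserosa imaging data: per-embryo frame series with a linearly
#' decreasing AS area, per-cell areas and perimeters consistent with a
#' normal shape-index distribution whose mean follows a prescribed drift
#' curve (piecewise linear with a minimum at `dA_min`, mirroring the
#' measured non-monotonic trajectory), about 10% cell ingression, junction
#' (contour, end-to-end) pairs with straightness tied to a tension proxy
#' curve, and embryo-to-embryo variability.
#'
#' @param n_embryos number of embryos.
#' @param cells_per_embryo cells tracked per embryo at onset.
#' @param A0 reference staging area (um^2).
#' @param area_rate AS-area decrease (um^2/s), linear in time.
#' @param frame_dt frame interval (s).
#' @param dA_max closure depth reached by the series.
#' @param q_start,q_min,dA_min,q_end the shape-index drift curve: linear
#'   from `q_start` at `dA = 0` to `q_min` at `dA_min`, then linear to
#'   `q_end` at `dA_max`.
#' @param q_sd target pooled cell-to-cell shape-index SD (0.45 at onset).
#' @param perimeter_slope linear decrease rate of the mean perimeter per
#'   unit `dA` (fraction of the onset value).
#' @param ingression_fraction fraction of cells removed over the series.
#' @param embryo_q_sd between-embryo SD of the shape-index offset (part of
#'   `q_sd`); `0` with `embryo_rate_sd = 0` makes all embryos identical.
#' @param embryo_rate_sd between-embryo lognormal SD of the area rate.
#' @param s_base,s_gain junction straightness model: mean
#'   `S = s_base + s_gain * tension_proxy(dA)`, clipped to `(0, 1]`.
#' @param tension_proxy function of `dA` giving the tension proxy used for
#'   straightness (default a smooth hump peaking at `dA = 0.55`).
#' @param noise_sd measurement noise scale (relative) on areas, perimeters
#'   and straightness.
#' @param seed RNG seed.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_embryos = 12, cells_per_embryo = 200, A0 = 11000,
                        area_rate = 0.82, frame_dt = 60, dA_max = 0.8,
                        q_start = 4.05, q_min = 3.9, dA_min = 0.55,
                        q_end = 4.0, q_sd = 0.45, perimeter_slope = 0.5,
                        ingression_fraction = 0.1, embryo_q_sd = 0.1,
                        embryo_rate_sd = 0.1, s_base = 0.90,
                        s_gain = 0.5, tension_proxy = NULL,
                        noise_sd = 0.02, seed = 1) {
  if (area_rate <= 0 || frame_dt <= 0) stop("rates must be positive")
  if (dA_max <= 0 || dA_max >= 1) stop("dA_max must be in (0, 1)")
  if (q_sd < embryo_q_sd) stop("embryo_q_sd cannot exceed the pooled q_sd")
  if (is.null(tension_proxy))
    tension_proxy <- function(dA) 0.02 + 0.1 * exp(-((dA - 0.55) / 0.2)^2)
  structure(as.list(environment()), class = "cohort_spec")
}

# sample a left-truncated normal whose TRUNCATED mean and SD match the
# targets (moment-matched underlying parameters, memoized per target pair);
# keeps the pooled shape-index SD on target despite the geometric lower
# bound of the shape index
.trunc_cache <- new.env(parent = emptyenv())
.rtrunc_norm <- function(n, m, s, lo) {
  key <- paste(round(m, 3), round(s, 3), lo)
  par <- .trunc_cache[[key]]
  if (is.null(par)) {
    if (lo < m - 6 * s) {
      par <- c(m, s)
    } else {
      # 1-d solve in the standardized truncation point a = (lo - mu)/sigma:
      # (mean_t - lo)/sd_t depends on a alone and decreases monotonically
      lam_f <- function(a) stats::dnorm(a) /
        stats::pnorm(a, lower.tail = FALSE)
      ratio <- function(a) {
        lam <- lam_f(a)
        (lam - a) / sqrt(max(1 + a * lam - lam^2, 1e-12))
      }
      target <- (m - lo) / s
      # for a left-truncated normal (mean - lo)/sd > 1 always (exponential
      # tail limit); targets at or below that bound take the limiting shape
      a <- if (target <= ratio(5)) 5 else
        stats::uniroot(function(a) ratio(a) - target, c(-12, 5),
                       tol = 1e-10)$root
      lam <- lam_f(a)
      sig <- s / sqrt(max(1 + a * lam - lam^2, 1e-12))
      par <- c(lo - a * sig, sig)
    }
    .trunc_cache[[key]] <- par
  }
  a <- (lo - par[1]) / par[2]
  u <- stats::runif(n, stats::pnorm(a), 1)
  par[1] + par[2] * stats::qnorm(u)
}

.q_drift <- function(spec, dA) {
  ifelse(dA <= spec$dA_min,
         spec$q_start + (spec$q_min - spec$q_start) * dA / spec$dA_min,
         spec$q_min + (spec$q_end - spec$q_min) *
           (dA - spec$dA_min) / (spec$dA_max - spec$dA_min))
}

#' Generate a synthetic tracked-cell cohort
#'
#' Emulates the tables produced by segmentation and tracking of live
#' dorsal-closure recordings. A pure function of `(spec, seed)`.
#'
#' @param spec a [cohort_spec()].
#' @return Object of class `"tracked_cohort"`: list of data frames
#'   `frames` (embryo, frame, frame_time, as_area, ellipse fit), `cells`
#'   (embryo, frame, cell id, centroid, area, perimeter, aspect, angle)
#'   and `junctions` (embryo, frame, contour length `L`, end-to-end `dv`),
#'   plus `truth` (every ground-truth parameter and curve used).
#' @export
generate_tracked_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  A_start <- 1.02 * spec$A0  # series begins just above the staging area
  A_end <- (1 - spec$dA_max) * spec$A0
  frames_l <- list()
  cells_l <- list()
  junc_l <- list()
  identical_embryos <- spec$embryo_q_sd == 0 && spec$embryo_rate_sd == 0
  for (e in seq_len(spec$n_embryos)) {
    # with all variability scales at zero, every embryo replays the same
    # stream and the cohort collapses to identical replicates
    set.seed(spec$seed + if (identical_embryos) 1L else 1000L * e)
    rate <- spec$area_rate *
      exp(stats::rnorm(1, 0, spec$embryo_rate_sd) - spec$embryo_rate_sd^2 / 2)
    q_off <- stats::rnorm(1, 0, spec$embryo_q_sd)
    duration <- (A_start - A_end) / rate
    tt <- seq(0, duration, by = spec$frame_dt)
    as_area <- A_start - rate * tt
    dA <- pmax(0, (spec$A0 - as_area) / spec$A0)
    nfr <- length(tt)
    n0 <- spec$cells_per_embryo
    # ingression schedule: each removed cell disappears at a random frame
    n_ing <- round(spec$ingression_fraction * n0)
    ing_cell <- sample.int(n0, n_ing)
    ing_frame <- sample.int(nfr, n_ing, replace = TRUE)
    gone_at <- rep(Inf, n0)
    gone_at[ing_cell] <- ing_frame
    # fixed relative size weights per cell
    w <- stats::rlnorm(n0, 0, 0.25)
    # ellipse: semi-major fixed (width of the opening is held), minor shrinks
    b0_ell <- sqrt(A_start / (2 * pi))
    a_ell <- 2 * b0_ell
    sd_within <- sqrt(spec$q_sd^2 - spec$embryo_q_sd^2)
    for (fr in seq_len(nfr)) {
      alive <- which(gone_at > fr)
      na <- length(alive)
      b_ell <- as_area[fr] / (pi * a_ell)
      frames_l[[length(frames_l) + 1L]] <- data.frame(
        embryo = e, frame = fr, frame_time = tt[fr], as_area = as_area[fr],
        ell_cx = 0, ell_cy = 0, ell_a = a_ell, ell_b = b_ell, ell_phi = 0)
      area <- as_area[fr] * w[alive] / sum(w[alive])
      area <- area * exp(stats::rnorm(na, 0, spec$noise_sd))
      # shape indices: truncated at the disk bound (no closed curve has
      # q < 2 sqrt(pi)), moment-matched so mean and SD stay on target
      q <- .rtrunc_norm(na, .q_drift(spec, dA[fr]) + q_off, sd_within, 3.55)
      # centroids uniform in the central ellipse
      rad <- sqrt(stats::runif(na))
      ang <- stats::runif(na, 0, 2 * pi)
      align <- min(1, 0.75 * dA[fr])  # alignment grows as the box flattens
      theta <- ifelse(stats::runif(na) < align,
                      stats::rnorm(na, 0, 0.35),
                      stats::runif(na, -pi / 2, pi / 2))
      theta <- pmin(pmax(theta, -pi / 2), pi / 2)
      cells_l[[length(cells_l) + 1L]] <- data.frame(
        embryo = e, frame = fr, frame_time = tt[fr], cell = alive,
        x = 0.95 * a_ell * rad * cos(ang), y = 0.95 * b_ell * rad * sin(ang),
        area = area, perimeter = q * sqrt(area),
        aspect = 1 + abs(stats::rnorm(na, 0.4 * (1 + dA[fr]), 0.25)),
        angle = theta)
      # junctions: straightness tracks the tension proxy
      nj <- 3L * na
      L <- stats::rlnorm(nj, log(mean(q * sqrt(area)) / 6), 0.2)
      s_mean <- min(1, spec$s_base + spec$s_gain * spec$tension_proxy(dA[fr]))
      S <- pmin(1, pmax(0.5, s_mean - abs(stats::rnorm(nj, 0, spec$noise_sd))))
      junc_l[[length(junc_l) + 1L]] <- data.frame(
        embryo = e, frame = fr, frame_time = tt[fr], L = L, dv = S * L)
    }
  }
  structure(list(
    frames = do.call(rbind, frames_l),
    cells = do.call(rbind, cells_l),
    junctions = do.call(rbind, junc_l),
    truth = list(spec = spec, A_start = A_start,
                 q_drift = .q_drift(spec, seq(0, spec$dA_max, 0.01)))
  ), class = "tracked_cohort")
}

#' @export
print.tracked_cohort <- function(x, ...) {
  cat(sprintf(
    "tracked_cohort: %d embryos, %d frames, %d cell rows, %d junction rows\n",
    length(unique(x$frames$embryo)), nrow(x$frames), nrow(x$cells),
    nrow(x$junctions)))
  invisible(x)
}

#' Write / read a tracked cohort as CSV files
#'
#' Three CSVs (`frames.csv`, `cells.csv`, `junctions.csv`) with the
#' documented headers, plus a `truth.json` sidecar when ground truth is
#' present.
#'
#' @param cohort a [generate_tracked_cohort()] result (or a compatible
#'   list of data frames).
#' @param dir output directory (created if missing).
#' @return `write_cohort_csv` returns `dir` invisibly; `read_cohort_csv`
#'   returns a `"tracked_cohort"` (without ground truth unless the sidecar
#'   is present).
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$frames, file.path(dir, "frames.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$junctions, file.path(dir, "junctions.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    tr$spec$tension_proxy <- NULL  # functions are not serialized
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  need <- file.path(dir, c("frames.csv", "cells.csv", "junctions.csv"))
  if (!all(file.exists(need)))
    stop("missing cohort files in ", dir)
  out <- list(frames = utils::read.csv(need[1]),
              cells = utils::read.csv(need[2]),
              junctions = utils::read.csv(need[3]), truth = NULL)
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) out$truth <- jsonlite::read_json(tj,
                                                        simplifyVector = TRUE)
  structure(out, class = "tracked_cohort")
}

#' Generate synthetic laser-ablation recoil traces
#'
#' Double-exponential vertex-separation traces sampled at the imaging rate
#' (5 Hz), with the true recoil velocity drawn from a hump-shaped function
#' of the closure stage peaking at `dA_peak` (the non-monotonic tension
#' prediction). All ground-truth parameters are attached per trace for
#' recovery tests.
#'
#' @param n number of cuts.
#' @param v_base,v_peak,dA_peak,width recoil-velocity hump (um/s):
#'   `vr(dA) = v_base + (v_peak - v_base) exp(-((dA - dA_peak)/width)^2)`.
#' @param noise relative measurement noise (fraction of the recoil
#'   amplitude).
#' @param fps frame rate (Hz).
#' @param n_frames post-cut frames per trace.
#' @param b0,d0 fast and slow rates (1/s, negative).
#' @param fast_frac fraction of the recoil amplitude in the fast mode.
#' @param d_pre pre-cut vertex separation (um).
#' @param seed RNG seed.
#' @return List of data frames (`t`, `d`), each with attribute `"truth"`
#'   (list: `A1, b0, A2, d0, C, vr, dA`).
#' @export
generate_ablation_traces <- function(n = 97, v_base = 0.25, v_peak = 0.75,
                                     dA_peak = 0.55, width = 0.2,
                                     noise = 0.02, fps = 5, n_frames = 576,
                                     b0 = -0.6, d0 = -0.05,
                                     fast_frac = 0.8, d_pre = 0.5,
                                     seed = 1) {
  if (n < 1) stop("need at least one trace")
  if (b0 >= 0 || d0 >= 0) stop("recoil rates must be negative")
  set.seed(seed)
  dA <- stats::runif(n, 0, 0.8)
  vr <- v_base + (v_peak - v_base) * exp(-((dA - dA_peak) / width)^2)
  tt <- seq(0, (n_frames - 1) / fps, by = 1 / fps)
  lapply(seq_len(n), function(i) {
    M <- vr[i] / (-fast_frac * b0 - (1 - fast_frac) * d0)
    A1 <- -fast_frac * M
    A2 <- -(1 - fast_frac) * M
    C <- d_pre + M
    d <- A1 * exp(b0 * tt) + A2 * exp(d0 * tt) + C +
      stats::rnorm(length(tt), 0, noise * M)
    tr <- data.frame(t = tt, d = d)
    attr(tr, "truth") <- list(A1 = A1, b0 = b0, A2 = A2, d0 = d0, C = C,
                              vr = vr[i], dA = dA[i])
    tr
  })
}

#' Generate synthetic (straightness, recoil) pairs from a hinge
#'
#' Pairs drawn from the flat-then-linear crossover model with Gaussian
#' noise, for breakpoint-recovery tests: recoil is independent of
#' straightness below `s_star` and rises linearly above it.
#'
#' @param n number of pairs.
#' @param s_star planted breakpoint.
#' @param v_flat flat recoil level (um/s).
#' @param slope rise above the breakpoint (um/s per unit straightness).
#' @param noise recoil noise SD (um/s).
#' @param s_range straightness range sampled uniformly.
#' @param seed RNG seed.
#' @return data frame with columns `S`, `vr`, and attribute `"truth"`.
#' @export
generate_straightness_recoil <- function(n = 97, s_star = 0.93,
                                         v_flat = 0.3, slope = 5,
                                         noise = 0.05,
                                         s_range = c(0.75, 1), seed = 1) {
  set.seed(seed)
  S <- stats::runif(n, s_range[1], s_range[2])
  vr <- v_flat + slope * pmax(S - s_star, 0) + stats::rnorm(n, 0, noise)
  out <- data.frame(S = S, vr = vr)
  attr(out, "truth") <- list(s_star = s_star, v_flat = v_flat, slope = slope)
  out
}

#' Deterministic percolation test fixtures
#'
#' Tissue states with a designated "rigid" junction subset whose wrapping
#' verdict is known: a single chain crossing the box in x only, the full
#' junction set (wraps both ways), the empty set, or a random Voronoi
#' tiling with junctions marked independently at probability `f`.
#'
#' @param kind `"chain"`, `"full"`, `"empty"` or `"voronoi"`.
#' @param size cells (Voronoi) or hexagon columns (lattice kinds).
#' @param f marking probability for `kind = "voronoi"`.
#' @param seed RNG seed.
#' @return List with `state`, `rigid` (junction row indices into
#'   [tissue_junctions()]), `expect` (named logical wraps).
#' @export
generate_percolation_fixture <- function(kind = c("chain", "full", "empty",
                                                  "voronoi"),
                                         size = 6, f = 0.9, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "voronoi") {
    L <- sqrt(size)
    state <- build_voronoi_tissue(size, tissue_box(L, L), seed = seed)
    jn <- tissue_junctions(state)
    set.seed(seed + 1L)
    rigid <- which(stats::runif(nrow(jn)) < f)
    return(list(state = state, rigid = rigid,
                expect = c(wraps_x = NA, wraps_y = NA)))
  }
  k <- size + size %% 2L  # even rows for periodicity
  state <- build_hex_tissue(size, k)
  jn <- tissue_junctions(state)
  if (kind == "full")
    return(list(state = state, rigid = seq_len(nrow(jn)),
                expect = c(wraps_x = TRUE, wraps_y = TRUE)))
  if (kind == "empty")
    return(list(state = state, rigid = integer(0),
                expect = c(wraps_x = FALSE, wraps_y = FALSE)))
  # chain: greedy walk in +x until the path closes through the periodic
  # boundary; wraps in x only
  d <- .min_image(state$vertices[jn$v2, , drop = FALSE] -
                  state$vertices[jn$v1, , drop = FALSE], state$box)
  start <- 1L
  v <- start
  used <- integer(0)
  xtot <- 0
  repeat {
    inc <- which(jn$v1 == v | jn$v2 == v)
    inc <- setdiff(inc, used[length(used)])
    dx <- ifelse(jn$v1[inc] == v, d[inc, 1], -d[inc, 1])
    e <- inc[which.max(dx)]
    used <- c(used, e)
    xtot <- xtot + max(dx)
    v <- if (jn$v1[e] == v) jn$v2[e] else jn$v1[e]
    if (v == start) break
    if (length(used) > nrow(jn)) stop("chain walk failed to close")
  }
  if (abs(xtot) < state$box$Lx / 2) stop("chain closed without winding in x")
  list(state = state, rigid = used,
       expect = c(wraps_x = TRUE, wraps_y = FALSE))
}
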