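#' Closure staging from the amnioserosa area
#'
#' Converts an AS-area time series into the fractional area change
#' `dA(t) = (A0 - A(t)) / A0`. Analysis starts at the first frame whose
#' area has dropped to the reference `A0` (11,000 um^2 in the experiments,
#' chosen so that embryos can be averaged on a common clock); earlier
#' frames are dropped.
#'
#' @param frames data frame with columns `frame_time` (s) and `as_area`
#'   (um^2), one row per frame (per embryo).
#' @param A0 reference area (um^2).
#' @return The input frames at and after the `A0` crossing, with a new
#'   column `dA`.
#' @export
closure_stage <- function(frames, A0 = 11000) {
  stopifnot(all(c("frame_time", "as_area") %in% names(frames)))
  if (all(frames$as_area > A0))
    stop("area series never reaches the reference area A0 = ", A0)
  frames <- frames[order(frames$frame_time), , drop = FALSE]
  start <- which(frames$as_area <= A0)[1L]
  out <- frames[seq(start, nrow(frames)), , drop = FALSE]
  out$dA <- (A0 - out$as_area) / A0
  out
}

#' Central-region cell filter
#'
#' Keeps cells whose centroid lies within the central region of the fitted
#' AS ellipse: inside the ellipse scaled to 75% of the semi-major and 90%
#' of the semi-minor axis. Peripheral cells and cells near the canthi are
#' excluded from model--experiment comparisons.
#'
#' @param cells data frame with centroid columns `x`, `y` (um).
#' @param ellipse list or one-row data frame with `cx`, `cy` (center),
#'   `a` (semi-major), `b` (semi-minor), `phi` (orientation, rad).
#' @param major_frac,minor_frac the axis fractions defining the region.
#' @return Logical vector: `TRUE` for cells inside the central region.
#' @export
central_region_filter <- function(cells, ellipse, major_frac = 0.75,
                                  minor_frac = 0.90) {
  if (is.null(ellipse) || any(!is.finite(c(ellipse$a, ellipse$b))))
    stop("missing ellipse fit for the frame")
  dx <- cells$x - ellipse$cx
  dy <- cells$y - ellipse$cy
  xr <- cos(ellipse$phi) * dx + sin(ellipse$phi) * dy
  yr <- -sin(ellipse$phi) * dx + cos(ellipse$phi) * dy
  (xr / (major_frac * ellipse$a))^2 + (yr / (minor_frac * ellipse$b))^2 <= 1
}

#' Junction straightness
#'
#' `S = dv / L`: end-to-end vertex distance over contour length. A taut
#' (tension-bearing) junction is straight (`S` near 1); a wiggly junction
#' is presumed tension-free. `S` is the imaging-side proxy for junction
#' tension.
#'
#' @param dv end-to-end distance (um).
#' @param L contour length (um), `> 0`.
#' @return `S` in `(0, 1]`.
#' @export
junction_straightness <- function(dv, L) {
  if (any(L <= 0)) stop("contour length must be positive")
  if (any(dv > L * (1 + 1e-12)))
    stop("dv > L: segmentation artifact (straightness would exceed 1)")
  dv / L
}

#' Fit a laser-ablation recoil trace
#'
#' Nonlinear least squares of the double-exponential recoil model
#' `d(t) = A1 exp(b0 t) + A2 exp(d0 t) + C`
#' to the post-cut vertex separation, with multi-start initialization.
#' The initial recoil velocity is the slope at the cut,
#' `vr = A1 b0 + A2 d0`, the quantity proportional to the pre-cut junction
#' tension.
#'
#' @param trace data frame with columns `t` (s, `>= 0`, strictly
#'   increasing) and `d` (um); at least 10 samples.
#' @param n_starts number of random multi-start initializations.
#' @param seed RNG seed for the starts.
#' @return Object of class `"recoil_fit"`: list with `A1`, `b0`, `A2`,
#'   `d0`, `C`, `vr`, `sigma` (residual SD), `converged`, `n_obs`.
#'   Non-convergence from every start is an error, never a silent
#'   best-effort value.
#' @export
fit_recoil <- function(trace, n_starts = 8, seed = 1) {
  stopifnot(all(c("t", "d") %in% names(trace)))
  if (nrow(trace) < 10) stop("need at least 10 post-cut samples")
  if (any(diff(trace$t) <= 0)) stop("times must be strictly increasing")
  t <- trace$t
  d <- trace$d
  span <- max(t) - min(t)
  amp <- max(d) - min(d)
  if (stats::sd(d) < 1e-12 * max(1, mean(abs(d)))) {
    # perfectly flat trace: zero recoil, no exponential structure to fit
    return(structure(list(A1 = 0, b0 = -1, A2 = 0, d0 = -0.1, C = mean(d),
                          vr = 0, sigma = 0, converged = TRUE,
                          n_obs = nrow(trace)), class = "recoil_fit"))
  }
  set.seed(seed)
  dt <- stats::median(diff(t))
  best <- NULL
  for (s in seq_len(n_starts)) {
    # rates log-spread from the slowest resolvable (1/span) up to the
    # sampling rate; amplitudes split the observed rise
    r1 <- -10^stats::runif(1, log10(2 / span), log10(0.5 / dt))
    r2 <- -10^stats::runif(1, log10(0.5 / span), log10(0.05 / dt))
    f <- stats::runif(1, 0.2, 0.8)
    st <- list(A1 = -f * amp, b0 = r1, A2 = -(1 - f) * amp, d0 = r2,
               C = max(d))
    fit <- tryCatch(
      minpack.lm::nlsLM(d ~ A1 * exp(b0 * t) + A2 * exp(d0 * t) + C,
                        start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("recoil fit did not converge from any of ", n_starts,
         " starts (n = ", nrow(trace), " samples)")
  cf <- as.list(stats::coef(best$fit))
  structure(list(A1 = cf$A1, b0 = cf$b0, A2 = cf$A2, d0 = cf$d0, C = cf$C,
                 vr = cf$A1 * cf$b0 + cf$A2 * cf$d0,
                 sigma = sqrt(best$rss / (nrow(trace) - 5)),
                 converged = TRUE, n_obs = nrow(trace)),
            class = "recoil_fit")
}

#' @export
print.recoil_fit <- function(x, ...) {
  cat(sprintf(
    "recoil_fit: vr = %.4g um/s (A1=%.3g b0=%.3g, A2=%.3g d0=%.3g, C=%.3g; sigma=%.3g)\n",
    x$vr, x$A1, x$b0, x$A2, x$d0, x$C, x$sigma))
  invisible(x)
}

#' Straightness--recoil crossover (hinge) fit
#'
#' Fits a continuous flat-then-linear function of junction straightness to
#' recoil velocities: `vr = v0` for `S <= S*` and
#' `vr = v0 + m (S - S*)` above. The breakpoint grid search minimizes the
#' residual sum of squares; a bootstrap gives an interval for `S*`. In the
#' experiments the crossover sits near `S* ~ 0.93`: below it recoil is
#' independent of straightness, above it recoil rises approximately
#' linearly.
#'
#' @param S,vr paired junction straightness and initial recoil velocity
#'   (at least 10 pairs spanning the candidate breakpoints).
#' @param breaks candidate breakpoints (default an interior grid over the
#'   observed `S` range).
#' @param n_boot bootstrap replicates for the breakpoint interval.
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `"crossover_fit"`: list with `s_star`, `flat`
#'   (level below), `slope` (above), `rss`, `boot_ci` (2.5/97.5
#'   percentiles), `degenerate` flag (slope indistinguishable from 0 or
#'   breakpoint at the grid edge).
#' @export
crossover_fit <- function(S, vr, breaks = NULL, n_boot = 200, seed = 1) {
  if (length(S) != length(vr)) stop("S and vr must be paired")
  if (length(S) < 10) stop("need at least 10 (S, vr) pairs")
  if (is.null(breaks)) {
    qs <- stats::quantile(S, c(0.05, 0.95))
    breaks <- seq(qs[1], qs[2], length.out = 101)
  }
  fit_one <- function(S, vr) {
    rss <- vapply(breaks, function(b) {
      x <- pmax(S - b, 0)
      sum(stats::resid(stats::lm(vr ~ x))^2)
    }, numeric(1))
    b <- breaks[which.min(rss)]
    m <- stats::lm(vr ~ pmax(S - b, 0))
    list(s_star = b, flat = unname(stats::coef(m)[1]),
         slope = unname(stats::coef(m)[2]), rss = min(rss))
  }
  if (all(S <= min(breaks)) || all(S >= max(breaks)))
    stop("all straightness values on one side of every candidate breakpoint")
  main <- fit_one(S, vr)
  set.seed(seed)
  boot <- replicate(n_boot, {
    i <- sample.int(length(S), replace = TRUE)
    fit_one(S[i], vr[i])$s_star
  })
  se_slope <- tryCatch(
    summary(stats::lm(vr ~ pmax(S - main$s_star, 0)))$coefficients[2, 2],
    error = function(e) Inf)
  degenerate <- !is.finite(se_slope) || abs(main$slope) < 2 * se_slope ||
    main$s_star %in% range(breaks)
  structure(c(main, list(boot_ci = stats::quantile(boot, c(0.025, 0.975)),
                         degenerate = degenerate)),
            class = "crossover_fit")
}

#' @export
print.crossover_fit <- function(x, ...) {
  cat(sprintf(
    "crossover_fit: S* = %.3f [%.3f, %.3f], flat = %.3g, slope = %.3g%s\n",
    x$s_star, x$boot_ci[1], x$boot_ci[2], x$flat, x$slope,
    if (x$degenerate) " (DEGENERATE: breakpoint unidentifiable)" else ""))
  invisible(x)
}

#' Stage-binned summaries
#'
#' Summarizes values (e.g. recoil velocities) across closure-stage bins.
#' The default bin edges are the three intervals used for the recoil
#' boxplots: `dA < 0.4`, `0.4 <= dA < 0.7`, `dA >= 0.7`.
#'
#' @param values numeric vector.
#' @param dA closure stages, same length.
#' @param breaks interior bin edges.
#' @return data frame with one row per bin: `bin`, `n`, `median`, `q25`,
#'   `q75`, `p05`, `p95`. Empty bins are reported with `n = 0`, not
#'   dropped.
#' @export
stage_binned_stats <- function(values, dA, breaks = c(0.4, 0.7)) {
  stopifnot(length(values) == length(dA))
  edges <- c(-Inf, sort(breaks), Inf)
  labs <- character(length(edges) - 1L)
  for (i in seq_along(labs)) {
    labs[i] <- if (i == 1L) sprintf("dA<%g", edges[2])
    else if (i == length(labs)) sprintf("dA>=%g", edges[i])
    else sprintf("%g<=dA<%g", edges[i], edges[i + 1])
  }
  bin <- cut(dA, edges, right = FALSE, labels = labs)
  out <- do.call(rbind, lapply(seq_along(labs), function(i) {
    v <- values[as.integer(bin) == i]
    if (!length(v))
      return(data.frame(bin = labs[i], n = 0L, median = NA_real_,
                        q25 = NA_real_, q75 = NA_real_, p05 = NA_real_,
                        p95 = NA_real_))
    q <- stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    data.frame(bin = labs[i], n = length(v), median = q[3], q25 = q[2],
               q75 = q[4], p05 = q[1], p95 = q[5])
  }))
  out
}
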