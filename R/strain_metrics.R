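#' @title Strain morphology indices and area-based fit error
#' @name strain_metrics
#' @description
#' Seven indices summarize the morphology of one segmental strain curve:
#' times to 10/50/90% of total shortening, pre-stretch, systolic strain
#' (at pulmonary valve closure), post-systolic strain and peak strain.
#' These are the screening outputs. The fit error between modelled and
#' measured traces is the time-integrated squared strain difference per
#' segment over a window from QRS onset to 50% relaxation of the global
#' RV strain, summed over segments and weighted together with a
#' cycle-time mismatch penalty.
NULL

#' Objective weights for the total fit error
#'
#' @param alpha weight of the segment area errors (1/s); default 1.
#' @param beta weight of the squared cycle-time mismatch (1/s^2);
#'   default 0.1.
#' @return list of class `objective_weights`.
#' @export
objectiveWeights <- function(alpha = 1, beta = 0.1) {
  stopifnot(alpha > 0, beta >= 0)
  structure(list(alpha = alpha, beta = beta), class = "objective_weights")
}

# first time y crosses below `level`, linearly interpolated; NA if never
firstCrossingBelow <- function(t, y, level) {
  below <- which(y <= level)
  if (length(below) == 0L) return(NA_real_)
  i <- below[1L]
  if (i == 1L) return(t[1L])
  # interpolate between i-1 and i
  t[i - 1L] + (level - y[i - 1L]) / (y[i] - y[i - 1L]) * (t[i] - t[i - 1L])
}

#' Extract the seven strain-morphology indices of one segment
#'
#' Peak strain is the cycle minimum; pre-stretch is the (non-negative)
#' maximum strain between QRS onset and the time of peak; the total
#' shortening span is pre-stretch minus peak. Times to X% shortening are
#' the first (interpolated) crossings of `prestretch - X/100 * span`
#' after QRS onset, reported relative to QRS onset. Systolic strain is
#' the strain at pulmonary valve closure; post-systolic strain is
#' systolic minus peak strain. A flat curve (zero span) is flagged
#' degenerate with all crossing times zero.
#'
#' @param trace a [strainTrace()].
#' @param segment one of `wallSegments()`.
#' @param t_pvc pulmonary valve closure time; defaults to the trace's.
#' @return list of class `strain_indices`: `t10`, `t50`, `t90` (s),
#'   `prestretch`, `systolic_strain`, `post_systolic_strain`,
#'   `peak_strain` (percent), and `degenerate` flag.
#' @export
extractIndices <- function(trace, segment, t_pvc = trace$t_pvc) {
  y <- segmentStrain(trace, segment)
  t <- trace$t
  keep <- t >= trace$t_qrs
  t <- t[keep]; y <- y[keep]
  ipk <- which.min(y)
  peak <- y[ipk]
  prestretch <- max(0, max(y[seq_len(ipk)]))
  span <- prestretch - peak
  systolic <- stats::approx(t, y, t_pvc, rule = 2)$y
  if (span <= .Machine$double.eps^0.5) {
    out <- list(t10 = 0, t50 = 0, t90 = 0, prestretch = prestretch,
                systolic_strain = systolic,
                post_systolic_strain = systolic - peak,
                peak_strain = peak, degenerate = TRUE)
    return(structure(out, class = "strain_indices"))
  }
  tx <- vapply(c(0.10, 0.50, 0.90), function(f)
    firstCrossingBelow(t, y, prestretch - f * span), numeric(1L))
  out <- list(t10 = tx[1L] - trace$t_qrs, t50 = tx[2L] - trace$t_qrs,
              t90 = tx[3L] - trace$t_qrs, prestretch = prestretch,
              systolic_strain = systolic,
              post_systolic_strain = systolic - peak,
              peak_strain = peak, degenerate = FALSE)
  structure(out, class = "strain_indices")
}

#' @export
print.strain_indices <- function(x, ...) {
  cat(sprintf(
    "<strain_indices> t10/50/90 = %.3f/%.3f/%.3f s, peak = %.1f%%, pre-stretch = %.1f%%, systolic = %.1f%%, post-systolic = %.1f%%%s\n",
    x$t10, x$t50, x$t90, x$peak_strain, x$prestretch, x$systolic_strain,
    x$post_systolic_strain, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# flatten indices of all five segments into one named output vector
# (the screening output map: 7 indices x 5 segments = 35 outputs)
indexVector <- function(trace) {
  fields <- c("t10", "t50", "t90", "prestretch", "systolic_strain",
              "post_systolic_strain", "peak_strain")
  out <- numeric(0)
  for (seg in wallSegments()) {
    ix <- extractIndices(trace, seg)
    v <- unlist(ix[fields])
    names(v) <- paste(fields, seg, sep = ".")
    out <- c(out, v)
  }
  out
}

#' Fit window from measured RV traces
#'
#' The global RV strain is the unweighted mean of the three RV free-wall
#' segments. The window runs from QRS onset to 50% relaxation of the
#' global RV strain: the first time after the global minimum at which the
#' global strain has recovered half-way from the minimum toward its
#' end-of-cycle value (measuring toward the end value keeps the rule
#' robust to measurement drift). A curve that never recovers that far
#' yields `t_end = T` with a warning.
#'
#' @param trace a [strainTrace()] with the three RV segments.
#' @return list of class `fit_window` with `t_start`, `t_end`.
#' @export
fitWindow <- function(trace) {
  g <- rowMeans(trace$strain[, c("RV_apex", "RV_mid", "RV_base"), drop = FALSE])
  t <- trace$t
  ipk <- which.min(g)
  peak <- g[ipk]
  endv <- g[length(g)]
  target <- peak + 0.5 * (endv - peak)
  tEnd <- NA_real_
  if (ipk < length(g)) {
    after <- ipk:length(g)
    hit <- which(g[after] >= target)
    if (length(hit) > 0L) {
      i <- after[hit[1L]]
      if (i == ipk || g[i] == g[i - 1L]) tEnd <- t[i]
      else tEnd <- t[i - 1L] + (target - g[i - 1L]) / (g[i] - g[i - 1L]) *
          (t[i] - t[i - 1L])
    }
  }
  if (is.na(tEnd)) {
    warning("global RV strain never reaches 50% relaxation; using t_end = T")
    tEnd <- trace$T
  }
  structure(list(t_start = trace$t_qrs, t_end = tEnd), class = "fit_window")
}

#' Area-based squared error of one segment over a window
#'
#' `A^2 = integral over the window of (model - measured)^2 dt`, by the
#' trapezoid rule on a common uniform resampling (default 2 ms). Both
#' series are linearly interpolated; beyond their support they are
#' extended with their boundary value, so a modelled cycle shorter than
#' the measured window is held at its final strain (the cycle-time
#' mismatch itself is penalized separately in [totalError()]).
#'
#' @param tModel,yModel model time base and strain series.
#' @param tMeas,yMeas measured time base and strain series.
#' @param window a [fitWindow()] (or list with `t_start`, `t_end`).
#' @param dt resampling step (s).
#' @return the squared error in percent^2 * s.
#' @export
segmentAreaError <- function(tModel, yModel, tMeas, yMeas, window,
                             dt = 0.002) {
  if (window$t_start >= window$t_end)
    stop("fit window is empty (t_start >= t_end)")
  if (window$t_start > max(tModel) || window$t_start > max(tMeas))
    stop("fit window lies outside the support of the series")
  grid <- seq(window$t_start, window$t_end, by = dt)
  if (grid[length(grid)] < window$t_end) grid <- c(grid, window$t_end)
  m <- stats::approx(tModel, yModel, grid, rule = 2)$y
  q <- stats::approx(tMeas, yMeas, grid, rule = 2)$y
  trapz(grid, (m - q)^2)
}

#' Total fit error between a modelled and a measured trace
#'
#' `E_SS = alpha * (A^2_RVapex + A^2_RVmid + A^2_RVbase + A^2_IVS +
#' A^2_LVfw) + beta * (T_model - T_meas)^2`, with the window computed
#' from the measured trace. A crashed model result has infinite error.
#'
#' @param model a `model_result` or a [strainTrace()].
#' @param measured a [strainTrace()].
#' @param weights an [objectiveWeights()].
#' @param window optionally a precomputed [fitWindow()] of the measured
#'   trace (saves recomputation in tight loops).
#' @param dt resampling step (s).
#' @return the dimensionless summed squared error.
#' @export
totalError <- function(model, measured, weights = objectiveWeights(),
                       window = NULL, dt = 0.002) {
  if (inherits(model, "model_result")) {
    if (model$status != "ok") return(Inf)
    model <- model$trace
  }
  if (is.null(window)) window <- fitWindow(measured)
  a2 <- 0
  for (seg in wallSegments()) {
    a2 <- a2 + segmentAreaError(model$t, segmentStrain(model, seg),
                                measured$t, segmentStrain(measured, seg),
                                window, dt = dt)
  }
  weights$alpha * a2 + weights$beta * (model$T - measured$T)^2
}

# precompiled per-subject objective context: the measured trace resampled
# on its own fit window (uniform grid from QRS onset), so repeated error
# evaluations only resample the model side
subjectContext <- function(measured, weights = objectiveWeights(),
                           dt = 0.002) {
  window <- fitWindow(measured)
  grid <- seq(window$t_start, window$t_end, by = dt)
  meas <- vapply(wallSegments(), function(seg)
    stats::approx(measured$t, segmentStrain(measured, seg), grid,
                  rule = 2)$y, numeric(length(grid)))
  list(window = window, grid = grid, dt = dt, meas = meas, T = measured$T,
       weights = weights)
}

# fast path used by the qMC and PSO drivers; when the model trace shares
# the context's uniform grid (same dt, starting at 0) the resampling is a
# row-subset, else it falls back to linear interpolation
contextError <- function(result, ctx) {
  if (inherits(result, "model_result")) {
    if (result$status != "ok") return(Inf)
    result <- result$trace
  }
  ng <- length(ctx$grid)
  nr <- length(result$t)
  aligned <- ctx$grid[1L] == 0 && result$t[1L] == 0 && nr >= 2L &&
    abs((result$t[2L] - result$t[1L]) - ctx$dt) < 1e-12
  if (aligned) {
    M <- result$strain[pmin(seq_len(ng), nr), , drop = FALSE]
  } else {
    M <- vapply(seq_len(5L), function(i)
      stats::approx(result$t, result$strain[, i], ctx$grid, rule = 2)$y,
      numeric(ng))
  }
  Dsq <- (M - ctx$meas)^2
  a2 <- sum(ctx$dt * (colSums(Dsq) - (Dsq[1L, ] + Dsq[ng, ]) / 2))
  ctx$weights$alpha * a2 + ctx$weights$beta * (result$T - ctx$T)^2
}
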