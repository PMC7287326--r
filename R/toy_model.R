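#' @title Bundled forward model: equal-tension multi-segment strain simulator
#' @name toy_model
#' @description
#' A deterministic, phenomenological stand-in for a full cardiovascular
#' mechanics model. It reproduces the regional strain phenomenology that
#' matters for testing the reduction pipeline -- pre-stretch of weak or
#' late-activated segments, reduced peak strain, post-systolic shortening
#' -- via an equal-tension force balance across the three RV free-wall
#' segments, and exposes a configurable "crash" region that emulates
#' numerically unstable simulations for non-physiological parameter
#' combinations. It makes no claim to haemodynamic realism.
NULL

#' Forward-model settings
#'
#' @param dt sampling step (s); default 2 ms.
#' @param baseAmplitude amplitude of the global RV shortening waveform
#'   (percent strain) at reference cardiac output.
#' @param crashStiffMax,crashContrMin crash predicate thresholds on the
#'   *normalized* linear-stiffness and contractility coordinates: a point
#'   is crashed when any wall segment has stiffness coordinate below
#'   `crashStiffMax` and contractility coordinate above `crashContrMin`
#'   simultaneously (a weak-wall/over-driven corner of the hypercube,
#'   calibrated to roughly 3% of its volume).
#' @param crashEnabled set `FALSE` to disable the crash region.
#' @return a list of class `toy_model_config`.
#' @export
toyModelConfig <- function(dt = 0.002, baseAmplitude = 20,
                           crashStiffMax = 0.06, crashContrMin = 0.90,
                           crashEnabled = TRUE) {
  structure(list(dt = dt, baseAmplitude = baseAmplitude,
                 crashStiffMax = crashStiffMax, crashContrMin = crashContrMin,
                 crashEnabled = crashEnabled),
            class = "toy_model_config")
}

# reference physical values used when a registry does not carry a
# parameter (reduced/demo registries): the full-registry references.
modelDefaults <- function() {
  tt <- tissueTemplate()
  seg <- stats::setNames(tt$ref, tt$short)
  g <- globalTemplate()
  glob <- stats::setNames(g$reference, g$name)
  list(seg = seg, glob = glob)
}

# precompiled registry lookup (indices of every parameter the model
# reads, or NA when the registry does not carry it); cached per registry
.modelCache <- new.env(parent = emptyenv())

segShorts <- function() c("SfAct", "kLin", "dT", "AmRef", "VWall", "Ls0",
                          "k1", "TauC", "TauR", "VMax")

modelContext <- function(space) {
  key <- paste(space$D, paste(space$params$name, collapse = "|"), sep = ":")
  ctx <- .modelCache[[key]]
  if (!is.null(ctx)) return(ctx)
  nm <- space$params$name
  defaults <- modelDefaults()
  shorts <- segShorts()
  segIdx <- sapply(wallSegments(), function(seg)
    match(paste(shorts, seg, sep = "_"), nm))
  rownames(segIdx) <- shorts
  globNames <- c("AVdelay", "CO", "HR", "MAP", "cycleTime", "relSysDur")
  globIdx <- stats::setNames(match(globNames, nm), globNames)
  ctx <- list(lower = space$params$lower, upper = space$params$upper,
              segIdx = segIdx, globIdx = globIdx,
              segDefaults = defaults$seg[shorts],
              globDefaults = defaults$glob[globNames])
  .modelCache[[key]] <- ctx
  ctx
}

# physical values for a set of (possibly absent) registry indices
physAt <- function(x, idx, defaults, ctx) {
  out <- defaults
  ok <- !is.na(idx)
  i <- idx[ok]
  out[ok] <- ctx$lower[i] + x[i] * (ctx$upper[i] - ctx$lower[i])
  out
}

crashPredicate <- function(x, config, ctx = NULL) {
  if (!config$crashEnabled) return(FALSE)
  if (is.null(ctx)) {
    kn <- x[paste("kLin", wallSegments(), sep = "_")]
    cn <- x[paste("SfAct", wallSegments(), sep = "_")]
  } else {
    ki <- ctx$segIdx["kLin", ]; ci <- ctx$segIdx["SfAct", ]
    kn <- ifelse(is.na(ki), NA_real_, x[ifelse(is.na(ki), 1L, ki)])
    cn <- ifelse(is.na(ci), NA_real_, x[ifelse(is.na(ci), 1L, ci)])
  }
  any(!is.na(kn) & !is.na(cn) &
        kn < config$crashStiffMax & cn > config$crashContrMin)
}

#' Cardiac event times implied by a parameter point
#'
#' QRS onset is time zero by convention; pulmonary valve closure is
#' AV-delay plus the systolic duration (relative systole duration times
#' cycle time); the cycle time is the sampled `cycleTime` parameter.
#'
#' @param point full-dimensional normalized point.
#' @param space the `parameter_space` the point lives in.
#' @param config a [toyModelConfig()].
#' @return list with `t_qrs`, `t_pvc`, `T`.
#' @export
eventTimes <- function(point, space, config = toyModelConfig()) {
  ctx <- modelContext(space)
  if (!is.null(names(point))) point <- point[paramNames(space)]
  g <- physAt(point, ctx$globIdx, ctx$globDefaults, ctx)
  list(t_qrs = 0, t_pvc = g[["AVdelay"]] + g[["relSysDur"]] * g[["cycleTime"]],
       T = g[["cycleTime"]])
}

# activation waveform: a twitch -- active tension rises quickly over the
# first 60% of the segment's systole (with a mild time-warp controlled
# by the shortening velocity), plateaus until end-systole, then decays
# smoothly over half the remaining cycle. The early rise + plateau is
# deliberately a different temporal shape from the slow global
# shortening drive, so a segment's passive (tension-to-strain) and
# active (tension-generating) parameters imprint distinguishable
# signatures on its strain.
activation <- function(t, tact, dur, q, T) {
  a <- numeric(length(t))
  tau <- (t - tact) / dur
  rise <- tau > 0 & tau <= 1
  a[rise] <- sin(0.5 * pi * pmin(tau[rise] / 0.6, 1)^q)^2
  tend <- tact + dur
  relax <- 0.5 * (T - tend)
  if (relax > 0) {
    tau2 <- (t - tend) / relax
    fall <- tau2 > 0 & tau2 < 1
    a[fall] <- cos(0.5 * pi * tau2[fall])^2
  }
  a
}

#' Evaluate the forward model at a normalized point
#'
#' For the RV free wall the three segments share a common tension
#' `F(t)`: each segment obeys `F = k_s * u_s + c_s * a_s(t)` with `u_s`
#' the segment strain, `k_s` an effective linear stiffness, `c_s` an
#' effective contractility and `a_s(t)` the activation waveform. `F(t)`
#' is the unique tension making the mean RV segment strain equal a
#' prescribed global shortening waveform `G(t)` (a raised-cosine-squared
#' pulse supported on `[AV-delay, t_pvc]`, amplitude scaled by cardiac
#' output and heart rate), after which each `u_s` follows in closed form.
#' IVS and LVfw are single segments loaded by the same tension with their
#' own parameters. Strain is returned in percent, re-referenced to zero
#' at QRS onset.
#'
#' Effective parameters: `c_s` scales with contractility `SfAct`, wall
#' reference area and (length-dependent activation) zero-stress sarcomere
#' length; `k_s` scales with the linear stiffness component, the
#' passive-stiffness exponent `k1`, wall volume and mean arterial
#' pressure; the activation delay `dT_s` shifts `a_s`, and the
#' contraction/relaxation time constants stretch its duration. The
#' placeholder parameters (`res1`, `res2`, `glob*`) are never read.
#'
#' @param point full-dimensional normalized point in `[0,1]^D` (named or
#'   in registry order).
#' @param space the `parameter_space`.
#' @param config a [toyModelConfig()].
#' @return a list of class `model_result`: `status` (`"ok"` or
#'   `"crashed"`), and `trace` (a [strainTrace()]) when ok.
#' @export
evaluateModel <- function(point, space, config = toyModelConfig()) {
  if (length(point) != space$D)
    stop("point has length ", length(point), ", expected D = ", space$D)
  if (!is.null(names(point))) point <- point[paramNames(space)]
  if (anyNA(point))
    stop("point names do not match the registry")
  if (any(point < 0 | point > 1))
    stop("point outside [0,1]^D for parameter(s): ",
         paste(paramNames(space)[point < 0 | point > 1], collapse = ", "))
  ctx <- modelContext(space)
  if (crashPredicate(point, config, ctx))
    return(structure(list(status = "crashed", trace = NULL),
                     class = "model_result"))

  g <- physAt(point, ctx$globIdx, ctx$globDefaults, ctx)
  T <- g[["cycleTime"]]; avd <- g[["AVdelay"]]
  tsys <- g[["relSysDur"]] * T
  tpvc <- avd + tsys
  t <- seq(0, T, by = config$dt)

  # global RV shortening waveform: slow (quartic) rise from AV-delay to
  # peak shortening at pulmonary valve closure, then a relaxation tail
  # over half the remaining diastole back to baseline (C1-smooth at
  # t_pvc). The rise is deliberately flatter than the activation
  # waveform's, so early active-tension imbalances between segments
  # surface as pre-stretch before global shortening takes hold.
  amp <- config$baseAmplitude * (g[["CO"]] / 5) * sqrt(70 / g[["HR"]])
  trelax <- 0.5 * (T - tpvc)
  G <- numeric(length(t))
  rise <- t > avd & t <= tpvc
  G[rise] <- -amp * sin(0.5 * pi * (t[rise] - avd) / tsys)^4
  fall <- t > tpvc & t < tpvc + trelax
  G[fall] <- -amp * cos(0.5 * pi * (t[fall] - tpvc) / trelax)^2

  segs <- wallSegments()
  cs <- ks <- numeric(5L)
  act <- matrix(0, length(t), 5L, dimnames = list(NULL, segs))
  for (i in seq_along(segs)) {
    p <- physAt(point, ctx$segIdx[, i], ctx$segDefaults, ctx)
    cs[i] <- p[["SfAct"]] * (p[["AmRef"]] / 100) *
      (1 + 0.5 * (p[["Ls0"]] / 1.8 - 1))
    ks[i] <- p[["kLin"]] * (1 + 0.3 * (p[["k1"]] / 10 - 1)) *
      (p[["VWall"]] / 80)^0.25 * (1 + 0.2 * (g[["MAP"]] / 92 - 1))
    dur <- tsys * clamp((p[["TauC"]] + p[["TauR"]]) / 0.25, 0.5, 1.5)
    q <- sqrt(p[["VMax"]] / 7)
    act[, i] <- activation(t, avd + p[["dT"]], dur, q, T)
  }

  rv <- 1:3  # RV_apex, RV_mid, RV_base
  H <- 3 / sum(1 / ks[rv])
  drive <- (act[, rv, drop = FALSE] %*% (cs[rv] / ks[rv])) / 3
  Ft <- (G + drive[, 1L]) * H

  strain <- matrix(0, length(t), 5L, dimnames = list(NULL, segs))
  for (i in seq_len(5L))
    strain[, i] <- (Ft - cs[i] * act[, i]) / ks[i]

  # strain is exactly zero at t = 0 (= QRS onset) by construction
  trace <- strainTrace(t, strain, t_qrs = 0, t_pvc = tpvc, T = T,
                       rezero = FALSE)
  structure(list(status = "ok", trace = trace), class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat("<model_result> status:", x$status, "\n")
  if (x$status == "ok") print(x$trace)
  invisible(x)
}

#' Bind a forward model to a space and configuration
#'
#' Returns the single-argument evaluator `function(point) -> model_result`
#' expected by the screening, qMC and reduction drivers.
#'
#' @param space a `parameter_space`.
#' @param config a [toyModelConfig()].
#' @return a function of one normalized full-dimensional point.
#' @export
makeToyModel <- function(space, config = toyModelConfig()) {
  force(space); force(config)
  function(point) evaluateModel(point, space, config)
}
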