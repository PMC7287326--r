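# shared fixtures: small registries and piecewise-linear traces, all
# built in code

# minimal registry for normalization arithmetic
tinySpace <- function() {
  parameterSpace(data.frame(
    name = c("a", "b", "c"),
    group = "global",
    lower = c(0, -10, 2),
    upper = c(1, 10, 6),
    reference = c(0.5, 0, 4),
    units = "-",
    stringsAsFactors = FALSE
  ))
}

# a strain trace where every segment follows the same piecewise-linear
# curve defined by breakpoints (tb, yb); dense uniform sampling
pwTrace <- function(tb, yb, t_pvc, T, dt = 0.001, segments = NULL) {
  t <- seq(0, T, by = dt)
  y <- stats::approx(tb, yb, t, rule = 2)$y
  strain <- matrix(y, length(t), 5L,
                   dimnames = list(NULL, wallSegments()))
  if (!is.null(segments)) {
    for (seg in names(segments)) {
      ys <- stats::approx(segments[[seg]]$tb, segments[[seg]]$yb, t,
                          rule = 2)$y
      strain[, seg] <- ys
    }
  }
  strainTrace(t, strain, t_qrs = 0, t_pvc = t_pvc, T = T, rezero = FALSE)
}

# normalized coordinate helpers for the compact registry
compactPoint <- function(space, ...) {
  x <- referencePoint(space)
  mods <- list(...)
  for (nm in names(mods)) x[nm] <- mods[[nm]]
  x
}

# vectorized validity check of one Morris trajectory
checkTrajectory <- function(traj, z) {
  pts <- traj$points
  D <- ncol(pts)
  lv <- pts * (z - 1)
  onGrid <- max(abs(lv - round(lv))) < 1e-9 && all(pts >= 0) && all(pts <= 1)
  steps <- diff(pts)                      # D x D
  nChanged <- rowSums(abs(steps) > 1e-12)
  oneAtATime <- all(nChanged == 1L)
  mags <- apply(abs(steps), 1L, max)
  delta <- morrisDelta(z)
  stepOk <- max(abs(mags - delta)) < 1e-9
  changedCols <- apply(abs(steps) > 1e-12, 1L, which)
  eachOnce <- length(changedCols) == D && setequal(changedCols, seq_len(D))
  onGrid && oneAtATime && stepOk && eachOnce
}
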