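#' @title Constriction particle swarm optimization
#' @name pso
#' @description
#' Particle swarm optimization on the unit hypercube with Clerc's
#' constriction settings (inertia `w = 0.729`, acceleration
#' `c1 = c2 = 1.49445`), seeded from the best quasi-Monte Carlo samples
#' with zero initial velocity. Positions outside `[0,1]^D` receive
#' infinite error (so bound violations can never become personal or
#' global bests), and the run stops when every particle's dimensionless
#' energy -- squared velocity norm plus squared distances to its
#' personal and the global best -- falls below a threshold, or at the
#' iteration cap.
NULL

#' Swarm settings
#'
#' @param pop population size (default 30).
#' @param w inertia weight.
#' @param c1,c2 cognitive and social acceleration constants.
#' @param energyTol per-particle convergence threshold on the energy.
#' @param maxIter iteration cap.
#' @return list of class `pso_config`.
#' @export
psoConfig <- function(pop = 30, w = 0.729, c1 = 1.49445, c2 = 1.49445,
                      energyTol = 0.1, maxIter = 1000) {
  structure(list(pop = pop, w = w, c1 = c1, c2 = c2,
                 energyTol = energyTol, maxIter = maxIter),
            class = "pso_config")
}

#' Initialize a swarm from the best qMC samples
#'
#' Particles start at the `pop` lowest-error finite points with zero
#' velocity and personal best equal to their position. Near-duplicate
#' candidates (coinciding to ~1e-6 in every coordinate, as happens when
#' best points of a larger subset are projected onto a smaller one) are
#' collapsed first: a swarm of identical zero-velocity particles has no
#' dynamics left. If fewer distinct finite points than `pop` remain the
#' population is padded with fresh Sobol points; with none at all this
#' is an error.
#'
#' @param points `n x d` matrix of candidate starting points.
#' @param errors length-`n` vector of their objective values (may
#'   contain `Inf`).
#' @param objective `function(x) -> scalar` (used to evaluate pad
#'   points).
#' @param config a [psoConfig()].
#' @return object of class `swarm_state`.
#' @export
initSwarm <- function(points, errors, objective, config = psoConfig()) {
  finite <- which(is.finite(errors))
  if (length(finite) == 0L)
    stop("no finite-error starting points for the swarm")
  d <- ncol(points)
  finite <- finite[order(errors[finite])]
  dup <- duplicated(round(points[finite, , drop = FALSE], 6L))
  finite <- finite[!dup]
  take <- finite[seq_len(min(config$pop, length(finite)))]
  X <- points[take, , drop = FALSE]
  f <- errors[take]
  if (nrow(X) < config$pop) {
    pad <- sobolPoints(config$pop - nrow(X), d)
    fpad <- apply(pad, 1L, objective)
    X <- rbind(X, pad)
    f <- c(f, fpad)
  }
  # if every seed already sits inside the energy-convergence ball the
  # swarm would halt before refining anything; re-seed the worst half
  # with Sobol points so the energy criterion measures actual
  # contraction of the search
  en <- rowSums(sweep(X, 2L, X[which.min(f), ])^2)
  if (max(en) < config$energyTol && nrow(X) > 1L) {
    nRep <- nrow(X) %/% 2L
    idx <- order(f, decreasing = TRUE)[seq_len(nRep)]
    pad <- sobolPoints(nRep, d)
    X[idx, ] <- pad
    f[idx] <- apply(pad, 1L, objective)
  }
  g <- which.min(f)
  structure(list(X = X, V = matrix(0, config$pop, d),
                 XP = X, fp = f, xg = X[g, ], fg = f[g],
                 iteration = 0L, config = config),
            class = "swarm_state")
}

#' @export
print.swarm_state <- function(x, ...) {
  cat(sprintf(
    "<swarm_state> %d particles in %d-D; iteration %d, best error %.4g, max energy %.3g\n",
    nrow(x$X), ncol(x$X), x$iteration, x$fg, max(particleEnergy(x))))
  invisible(x)
}

#' Dimensionless particle energy
#'
#' `E_k = |v_k|^2 + |x_k - xp_k|^2 + |x_k - xg|^2`.
#'
#' @param state a `swarm_state`.
#' @return numeric vector of per-particle energies.
#' @export
particleEnergy <- function(state) {
  rowSums(state$V^2) + rowSums((state$X - state$XP)^2) +
    rowSums(sweep(state$X, 2L, state$xg)^2)
}

#' One swarm iteration
#'
#' Per particle: draw `Z1, Z2` elementwise standard uniform, update
#' `v <- w v + c1 Z1 (xp - x) + c2 Z2 (xg - x)`, move `x <- x + v`,
#' evaluate (infinite error outside `[0,1]^d`), and update personal and
#' global bests on improvement.
#'
#' @param state a `swarm_state`.
#' @param objective `function(x) -> scalar`.
#' @return the updated `swarm_state`.
#' @export
psoStep <- function(state, objective) {
  cfg <- state$config
  pop <- nrow(state$X)
  d <- ncol(state$X)
  Z1 <- matrix(stats::runif(pop * d), pop, d)
  Z2 <- matrix(stats::runif(pop * d), pop, d)
  G <- matrix(state$xg, pop, d, byrow = TRUE)
  state$V <- cfg$w * state$V + cfg$c1 * Z1 * (state$XP - state$X) +
    cfg$c2 * Z2 * (G - state$X)
  state$X <- state$X + state$V
  inb <- rowSums(state$X < 0 | state$X > 1) == 0L
  f <- rep(Inf, pop)
  for (k in which(inb)) f[k] <- objective(state$X[k, ])
  # ties update the personal best to the latest position (so plateaus,
  # e.g. a locally flat objective, still let the swarm contract)
  improve <- is.finite(f) & f <= state$fp
  state$XP[improve, ] <- state$X[improve, , drop = FALSE]
  state$fp[improve] <- f[improve]
  g <- which.min(state$fp)
  if (state$fp[g] < state$fg) {
    state$fg <- state$fp[g]
    state$xg <- state$XP[g, ]
  }
  state$iteration <- state$iteration + 1L
  state
}

#' Run the swarm to convergence
#'
#' Iterates [psoStep()] until all particle energies fall below
#' `energyTol` or `maxIter` is reached.
#'
#' @param state a `swarm_state` (see [initSwarm()]).
#' @param objective `function(x) -> scalar`.
#' @param maxIter,energyTol override the state's configuration.
#' @return list of class `pso_result`: `par` (best point), `value`
#'   (best error), `iterations`, `converged`, and `trace`
#'   (data.frame: iteration, best_error, max_energy; best error is
#'   non-increasing by construction).
#' @export
runPso <- function(state, objective, maxIter = state$config$maxIter,
                   energyTol = state$config$energyTol) {
  stopifnot(maxIter >= 1)
  bestTrace <- numeric(0)
  energyTrace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    state <- psoStep(state, objective)
    it <- it + 1L
    e <- particleEnergy(state)
    bestTrace[it] <- state$fg
    energyTrace[it] <- max(e)
    if (all(e < energyTol)) { converged <- TRUE; break }
  }
  structure(list(par = state$xg, value = state$fg, iterations = it,
                 converged = converged, state = state,
                 trace = data.frame(iteration = seq_len(it),
                                    best_error = bestTrace,
                                    max_energy = energyTrace)),
            class = "pso_result")
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf(
    "<pso_result> best error %.6g after %d iterations (%s)\n",
    x$value, x$iterations,
    if (x$converged) "energy-converged" else "iteration cap"))
  invisible(x)
}

#' Convenience wrapper: qMC-seeded PSO on an objective
#'
#' Seeds the swarm from `nSeed` Sobol points (or supplied candidates)
#' and runs to convergence.
#'
#' @param objective `function(x) -> scalar` on `[0,1]^d`.
#' @param d dimension.
#' @param config a [psoConfig()].
#' @param seed optional RNG seed.
#' @param candidates,candidateErrors optional starting points and their
#'   errors (e.g. from a `qmc_result`); defaults to `4 * pop` Sobol
#'   points evaluated with `objective`.
#' @return a `pso_result`.
#' @export
psoFit <- function(objective, d, config = psoConfig(), seed = NULL,
                   candidates = NULL, candidateErrors = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(candidates)) {
    candidates <- sobolPoints(4 * config$pop, d)
    candidateErrors <- apply(candidates, 1L, objective)
  }
  state <- initSwarm(candidates, candidateErrors, objective, config)
  runPso(state, objective)
}
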