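#' @title Morris elementary-effect screening
#' @name morris
#' @description
#' One-at-a-time screening on a z-level grid. Each trajectory visits
#' `D + 1` grid points, changing every parameter exactly once by a step
#' of magnitude `Delta = z / (2 (z - 1))`. Elementary effects are signed
#' difference quotients; `mu*` is the mean absolute elementary effect
#' over trajectories, a proxy for the total sensitivity index. A
#' parameter is unimportant when its `mu*` falls below the column mean
#' for every output; screening repeats on the retained subset until no
#' parameter can be omitted.
NULL

#' Morris step size on a z-level grid
#' @param z number of grid levels (even, >= 2).
#' @return `z / (2 * (z - 1))`; 4/7 for the default `z = 8`.
#' @export
morrisDelta <- function(z) {
  stopifnot(z >= 2, z %% 2 == 0)
  z / (2 * (z - 1))
}

#' Generate one Morris trajectory
#'
#' The base point is drawn uniformly from the grid levels
#' `{0, 1/(z-1), ..., 1}` per coordinate; parameters are then changed
#' one at a time in random order by `+Delta` where feasible within
#' `[0, 1]`, else `-Delta` (for even `z` exactly one direction is always
#' feasible, so every grid point is equally likely to be visited).
#'
#' @param D dimension.
#' @param z number of grid levels (even); default 8.
#' @return list of class `morris_trajectory`: `points` (a
#'   `(D+1) x D` matrix of grid points), `order` (the permutation of
#'   parameter indices), `deltas` (signed step per parameter), `z`.
#' @export
generateTrajectory <- function(D, z = 8) {
  delta <- morrisDelta(z)
  stepLv <- z %/% 2L
  baseLv <- sample.int(z, D, replace = TRUE) - 1L
  up <- baseLv + stepLv <= z - 1L
  down <- baseLv - stepLv >= 0L
  dir <- integer(D)
  both <- up & down
  dir[up & !down] <- 1L
  dir[down & !up] <- -1L
  if (any(both))
    dir[both] <- ifelse(stats::runif(sum(both)) < 0.5, 1L, -1L)
  ord <- sample.int(D)
  lv <- matrix(baseLv, nrow = D + 1L, ncol = D, byrow = TRUE)
  for (j in seq_len(D)) {
    i <- ord[j]
    lv[(j + 1L):(D + 1L), i] <- baseLv[i] + dir[i] * stepLv
  }
  structure(list(points = lv / (z - 1), order = ord,
                 deltas = dir * delta, z = z),
            class = "morris_trajectory")
}

#' Elementary effects of one trajectory
#'
#' `E_ij = (Y_j(x + e_i Delta) - Y_j(x)) / Delta` using the signed step
#' actually taken for parameter `i`.
#'
#' @param traj a [generateTrajectory()] result.
#' @param outputs numeric matrix `(D+1) x J`: model outputs at each
#'   trajectory point, in trajectory order.
#' @return numeric matrix `D x J` of signed elementary effects.
#' @export
elementaryEffects <- function(traj, outputs) {
  outputs <- as.matrix(outputs)
  D <- ncol(traj$points)
  if (nrow(outputs) != D + 1L)
    stop("outputs must have D + 1 = ", D + 1L, " rows")
  E <- matrix(NA_real_, D, ncol(outputs))
  colnames(E) <- colnames(outputs)
  for (j in seq_len(D)) {
    i <- traj$order[j]
    E[i, ] <- (outputs[j + 1L, ] - outputs[j, ]) / traj$deltas[i]
  }
  E
}

#' Mean absolute elementary effect over trajectories
#'
#' @param effects list of `D x J` elementary-effect matrices (one per
#'   successful trajectory).
#' @return `D x J` matrix of `mu*` values.
#' @export
muStar <- function(effects) {
  if (length(effects) == 0L) stop("no successful trajectories")
  acc <- abs(effects[[1L]])
  for (r in seq_along(effects)[-1L]) acc <- acc + abs(effects[[r]])
  acc / length(effects)
}

#' Split parameters into important and unimportant
#'
#' Parameter `i` is unimportant (excluded) iff for *every* output `j`
#' its `mu*_ij` lies strictly below the column mean
#' `(1/D) sum_k mu*_kj`; ties retain the parameter.
#'
#' @param mu `D x J` matrix of `mu*` values, rownames = parameter names.
#' @return list with character vectors `important` and `excluded`.
#' @export
selectImportant <- function(mu) {
  mu <- as.matrix(mu)
  if (is.null(rownames(mu))) rownames(mu) <- paste0("p", seq_len(nrow(mu)))
  colMu <- colMeans(mu)
  below <- sweep(mu, 2L, colMu, `<`)
  excl <- rowSums(below) == ncol(mu)
  list(important = rownames(mu)[!excl], excluded = rownames(mu)[excl])
}

#' Leave-one-out convergence of the important set
#'
#' Converged when recomputing `mu*` with any single trajectory omitted
#' leaves the important-parameter set unchanged.
#'
#' @param effects list of per-trajectory elementary-effect matrices
#'   (length >= 2).
#' @return logical.
#' @export
looConvergence <- function(effects) {
  stopifnot(length(effects) >= 2L)
  full <- selectImportant(muStar(effects))$important
  for (r in seq_along(effects)) {
    loo <- selectImportant(muStar(effects[-r]))$important
    if (!setequal(loo, full)) return(FALSE)
  }
  TRUE
}

#' Iterative Morris screening of a forward model
#'
#' Each round generates trajectories on the current active subset
#' (excluded parameters fixed at their normalized reference), evaluates
#' the model at every trajectory point, computes the 35 screening
#' outputs (7 strain indices x 5 segments), and discards any trajectory
#' containing a crashed evaluation. Sampling continues until the budget
#' of successful trajectories is met or a hard attempt cap
#' (`capFactor * budget`) is reached. Parameters unimportant for all
#' outputs are excluded; screening repeats on the reduced subset until a
#' round excludes nothing or `maxRounds` is reached. Excluded parameters
#' never re-enter.
#'
#' @param space a `parameter_space`.
#' @param model evaluator `function(point) -> model_result` (see
#'   [makeToyModel()]).
#' @param budget successful trajectories per round.
#' @param z grid levels.
#' @param maxRounds round cap.
#' @param capFactor hard cap on attempts per round, as multiple of
#'   `budget`.
#' @param seed optional integer seed.
#' @param mask optional starting `subset_mask` (default: all active).
#' @return list of per-round records (class `morris_result`): `round`,
#'   `n_attempted`, `n_successful`, `mu_star`, `effects`, `important`,
#'   `excluded`, `loo_converged`.
#' @export
runScreening <- function(space, model, budget = 50, z = 8, maxRounds = 10,
                         capFactor = 5, seed = NULL, mask = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mask)) mask <- subsetMask(space, paramNames(space))
  rounds <- list()
  for (round in seq_len(maxRounds)) {
    active <- mask$active
    d <- length(active)
    if (d == 0L) break
    effects <- list()
    attempted <- 0L
    while (length(effects) < budget && attempted < capFactor * budget) {
      attempted <- attempted + 1L
      traj <- generateTrajectory(d, z)
      Y <- matrix(NA_real_, d + 1L, 35L)
      okAll <- TRUE
      for (k in seq_len(d + 1L)) {
        res <- model(restrictPoint(space, mask, traj$points[k, ]))
        if (res$status != "ok") { okAll <- FALSE; break }
        v <- indexVector(res$trace)
        Y[k, ] <- v
        if (k == 1L) colnames(Y) <- names(v)
      }
      if (!okAll) next
      E <- elementaryEffects(traj, Y)
      rownames(E) <- active
      effects[[length(effects) + 1L]] <- E
    }
    if (length(effects) == 0L)
      stop("all Morris trajectories crashed in round ", round)
    mu <- muStar(effects)
    sel <- selectImportant(mu)
    rounds[[round]] <- structure(
      list(round = round, n_attempted = attempted,
           n_successful = length(effects), mu_star = mu,
           effects = effects, important = sel$important,
           excluded = sel$excluded,
           loo_converged = if (length(effects) >= 2L)
             looConvergence(effects) else NA),
      class = "morris_result")
    if (length(sel$excluded) == 0L) break
    mask <- subsetMask(space, sel$important)
  }
  rounds
}

#' @export
print.morris_result <- function(x, ...) {
  cat(sprintf(
    "<morris_result> round %d: %d/%d trajectories successful; %d important, %d excluded%s\n",
    x$round, x$n_successful, x$n_attempted, length(x$important),
    length(x$excluded),
    if (isTRUE(x$loo_converged)) " (LOO-converged)" else ""))
  invisible(x)
}

#' Serialize screening rounds to JSON-ready records
#'
#' @param rounds result of [runScreening()].
#' @return list of plain lists (round, n_attempted, n_successful,
#'   excluded, retained) suitable for JSON serialization; the `mu_star`
#'   matrices are kept as attributes for CSV export.
#' @export
screeningSummary <- function(rounds) {
  lapply(rounds, function(r)
    list(round = r$round, n_attempted = r$n_attempted,
         n_successful = r$n_successful,
         excluded = r$excluded, retained = r$important))
}
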