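#' @title Identifiability-driven subset reduction loop
#' @name reduction
#' @description
#' Orchestrates the second stage of the pipeline: Sobol qMC sweep of the
#' current subset, per-parameter diaphony over the best fits of every
#' subject, omission of the least-identifiable parameters, and
#' validation of each omission by comparing swarm-optimized cohort fit
#' errors before and after. Accepted rounds shrink the subset
#' monotonically; a rejected proposal is retried with half as many
#' omissions before the loop stops. The full audit trail is returned.
NULL

#' Rank active parameters by worst-case identifiability
#'
#' For each parameter the maximum diaphony over subjects is taken; the
#' ranking is ascending (least identifiable first), ties broken by
#' registry order.
#'
#' @param diaphonyTable `d_active x n_subjects` matrix with parameter
#'   rownames (see `qmc_result$diaphony`).
#' @return data.frame with columns `name`, `max_diaphony`, ordered
#'   ascending.
#' @export
rankParameters <- function(diaphonyTable) {
  if (any(is.na(diaphonyTable)))
    stop("diaphony table has missing entries")
  maxd <- apply(diaphonyTable, 1L, max)
  ord <- order(maxd)   # stable: ties keep registry (row) order
  data.frame(name = rownames(diaphonyTable)[ord], max_diaphony = maxd[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Propose a reduced subset
#'
#' Omits the `kOmit` lowest-ranked (least identifiable) parameters,
#' fixing them at their normalized reference values.
#'
#' @param space a `parameter_space`.
#' @param mask the current `subset_mask`.
#' @param ranked result of [rankParameters()].
#' @param kOmit number of parameters to omit (`1 <= kOmit < n_active`).
#' @return the reduced `subset_mask`.
#' @export
proposeReduction <- function(space, mask, ranked, kOmit) {
  nAct <- length(mask$active)
  if (kOmit < 1 || kOmit >= nAct)
    stop("kOmit must satisfy 1 <= kOmit < ", nAct)
  drop <- ranked$name[seq_len(kOmit)]
  subsetMask(space, setdiff(mask$active, drop))
}

# run PSO against every subject on a given mask; seeds from the qMC
# best points of that subject projected to the mask's active coordinates
cohortPso <- function(space, mask, subjects, model, qmcResult, psoCfg,
                      weights, seedRoot) {
  traces <- lapply(subjects, function(s)
    if (inherits(s, "virtual_subject")) s$trace else s)
  ctxs <- lapply(traces, subjectContext, weights = weights)
  nS <- length(subjects)
  errors <- numeric(nS)
  positions <- matrix(NA_real_, nS, length(mask$active),
                      dimnames = list(NULL, mask$active))
  for (s in seq_len(nS)) {
    ctx <- ctxs[[s]]
    objective <- function(x) {
      res <- model(restrictPoint(space, mask, x))
      contextError(res, ctx)
    }
    idx <- qmcResult$best_idx[[s]]
    if (length(idx) == 0L) stop("no finite qMC errors for subject ", s)
    cand <- qmcResult$points[idx, , drop = FALSE]
    if (is.null(colnames(cand)))
      colnames(cand) <- rownames(qmcResult$diaphony)
    # project candidate points onto this mask's active coordinates and
    # re-evaluate them there: the cached qMC errors belong to the full
    # subset and are invalid once a coordinate has been fixed
    cand <- cand[, mask$active, drop = FALSE]
    candErr <- apply(cand, 1L, objective)
    set.seed(stageSeed(seedRoot, paste0("pso-subject-", s)))
    state <- initSwarm(cand, candErr, objective, psoCfg)
    fit <- runPso(state, objective)
    errors[s] <- fit$value
    positions[s, ] <- fit$par
  }
  list(errors = errors, positions = positions)
}

#' Validate a proposed reduction by swarm re-fit
#'
#' Runs PSO per subject on both subsets (inactive parameters fixed at
#' reference) and accepts the reduction iff the mean cohort error after
#' is within `(1 + tol)` times the mean error before.
#'
#' @param space a `parameter_space`.
#' @param maskBefore,maskAfter the two `subset_mask`s.
#' @param subjects list of measured traces or `virtual_subject`s.
#' @param model evaluator `function(point) -> model_result`.
#' @param qmcResult the `qmc_result` of the *before* subset (PSO seeds).
#' @param psoCfg a [psoConfig()].
#' @param tol acceptance tolerance on the mean-error ratio; default 0.5.
#' @param absTol absolute slack on the mean-error comparison (default
#'   0.01, i.e. an RMS strain deviation of ~0.15% over a half-second
#'   window, far below echo noise): when both fits are essentially
#'   perfect the ratio is pure numerical noise and must not drive the
#'   decision.
#' @param weights an [objectiveWeights()].
#' @param seedRoot integer seed root. The per-subset swarm seed is
#'   derived from the subset content, so validating a subset against
#'   itself reproduces the identical fit (ratio exactly 1).
#' @param beforeFit optional cached `list(errors, positions)` for the
#'   before subset (e.g. the previous accepted round's after-fit).
#' @return list: `accepted`, `before`, `after` (each
#'   `list(errors, positions)`), `ratio`.
#' @export
validateReduction <- function(space, maskBefore, maskAfter, subjects,
                              model, qmcResult, psoCfg = psoConfig(),
                              tol = 0.5, absTol = 0.01,
                              weights = objectiveWeights(),
                              seedRoot = 1L, beforeFit = NULL) {
  maskSeed <- function(mask)
    stageSeed(seedRoot, paste(mask$active, collapse = ","))
  if (is.null(beforeFit))
    beforeFit <- cohortPso(space, maskBefore, subjects, model, qmcResult,
                           psoCfg, weights, maskSeed(maskBefore))
  afterFit <- cohortPso(space, maskAfter, subjects, model, qmcResult,
                        psoCfg, weights, maskSeed(maskAfter))
  mb <- mean(beforeFit$errors)
  ma <- mean(afterFit$errors)
  ratio <- ma / mb
  list(accepted = is.finite(ma) && ma <= (1 + tol) * mb + absTol,
       before = beforeFit, after = afterFit, ratio = ratio)
}

#' Reduction-loop settings
#'
#' @param nQmc Sobol samples per round.
#' @param Nb best-set size for the diaphony.
#' @param omitQuantile per round, all parameters whose max-over-subjects
#'   diaphony falls below this quantile of the active set are proposed
#'   for omission (at least one).
#' @param tol acceptance tolerance on the mean-error ratio.
#' @param floor minimum subset size; the loop never proposes below it.
#' @param maxRounds round cap.
#' @param pso a [psoConfig()] used for validation fits.
#' @param finalPso a [psoConfig()] for the final estimation stage: after
#'   the loop stops, a fresh Sobol sweep of the final subset seeds one
#'   full swarm fit per subject. Defaults to the validation settings
#'   with a tighter energy tolerance (0.01): validation only compares
#'   two fits obtained under the same rule, but the reported estimates
#'   should be limited by identifiability, not by the stopping rule.
#' @param weights an [objectiveWeights()].
#' @return list of class `reduction_config`.
#' @export
reductionConfig <- function(nQmc = 2^14, Nb = 100, omitQuantile = 0.25,
                            tol = 0.5, floor = 5, maxRounds = 10,
                            pso = psoConfig(),
                            finalPso = psoConfig(pop = pso$pop, w = pso$w,
                                                 c1 = pso$c1, c2 = pso$c2,
                                                 energyTol = 0.01,
                                                 maxIter = pso$maxIter),
                            weights = objectiveWeights()) {
  structure(list(nQmc = nQmc, Nb = Nb, omitQuantile = omitQuantile,
                 tol = tol, floor = floor, maxRounds = maxRounds,
                 pso = pso, finalPso = finalPso, weights = weights),
            class = "reduction_config")
}

#' Run the full qMC / diaphony / PSO reduction loop
#'
#' Per round: Sobol sweep of the active subset, diaphony ranking,
#' proposal of the least-identifiable parameters for omission (quantile
#' policy), PSO validation. On rejection the proposal is retried with
#' half as many omissions; the loop stops when no reduction is accepted,
#' the subset reaches the floor, or `maxRounds` is hit. The *before*
#' errors of round `r > 1` reuse the accepted after-fit of round
#' `r - 1`.
#'
#' @param space a `parameter_space`.
#' @param mask0 the starting `subset_mask`.
#' @param subjects list of measured traces or `virtual_subject`s.
#' @param model evaluator `function(point) -> model_result`.
#' @param config a [reductionConfig()].
#' @param seed integer seed root.
#' @return object of class `reduction_record`: `rounds` (audit trail),
#'   `final_mask`, and `final_fit` (`list(errors, positions)`): the
#'   final estimation on the accepted subset, seeded from a fresh Sobol
#'   sweep of that subset rather than from projected points of a larger
#'   one, so the estimates are free of inherited compensation.
#' @export
runReduction <- function(space, mask0, subjects, model,
                         config = reductionConfig(), seed = 1L) {
  stopifnot(length(mask0$active) >= 1L)
  mask <- mask0
  rounds <- list()
  lastFit <- NULL
  for (round in seq_len(config$maxRounds)) {
    nAct <- length(mask$active)
    if (nAct <= config$floor) break
    pts <- sobolPoints(config$nQmc, nAct)
    colnames(pts) <- mask$active
    qres <- evaluateCohort(pts, model, subjects, space, mask,
                           Nb = config$Nb, weights = config$weights)
    ranked <- rankParameters(qres$diaphony)
    thr <- stats::quantile(ranked$max_diaphony, config$omitQuantile)
    kOmit <- max(1L, sum(ranked$max_diaphony <= thr))
    kOmit <- min(kOmit, nAct - config$floor)
    accepted <- FALSE
    rec <- NULL
    while (kOmit >= 1L) {
      maskAfter <- proposeReduction(space, mask, ranked, kOmit)
      val <- validateReduction(space, mask, maskAfter, subjects, model,
                               qres, psoCfg = config$pso,
                               tol = config$tol,
                               weights = config$weights,
                               seedRoot = stageSeed(seed, paste0("round-", round)),
                               beforeFit = lastFit)
      rec <- list(round = round, subset_before = mask$active,
                  subset_after = maskAfter$active,
                  omitted = setdiff(mask$active, maskAfter$active),
                  diaphony_table = qres$diaphony,
                  max_diaphony = stats::setNames(ranked$max_diaphony,
                                                 ranked$name),
                  qmc_success_rate = qres$success_rate,
                  pso_before = val$before$errors,
                  pso_after = val$after$errors,
                  ratio = val$ratio, accepted = val$accepted)
      rounds[[length(rounds) + 1L]] <- rec
      lastFit <- val$before   # cache stays valid for the current mask
      if (val$accepted) {
        mask <- maskAfter
        lastFit <- val$after
        accepted <- TRUE
        break
      }
      kOmit <- kOmit %/% 2L
    }
    if (!accepted) break
  }
  # final estimation on the accepted subset: fresh sweep, full swarm fit
  finalFit <- lastFit
  if (length(mask$active) >= 1L) {
    pts <- sobolPoints(config$nQmc, length(mask$active))
    colnames(pts) <- mask$active
    qFinal <- evaluateCohort(pts, model, subjects, space, mask,
                             Nb = config$Nb, weights = config$weights)
    finalFit <- cohortPso(space, mask, subjects, model, qFinal,
                          config$finalPso, config$weights,
                          stageSeed(seed, "final-estimate"))
  }
  structure(list(rounds = rounds, final_mask = mask, final_fit = finalFit),
            class = "reduction_record")
}

#' @export
print.reduction_record <- function(x, ...) {
  cat("<reduction_record>", length(x$rounds), "round(s); final subset:",
      length(x$final_mask$active), "parameters\n")
  for (r in x$rounds) {
    cat(sprintf(
      "  round %d: %d -> %d (%s), mean E_SS %.3g -> %.3g, %s\n",
      r$round, length(r$subset_before), length(r$subset_after),
      paste(r$omitted, collapse = ","),
      mean(r$pso_before), mean(r$pso_after),
      if (r$accepted) "accepted" else "rejected"))
  }
  invisible(x)
}

#' Serialize a reduction record to JSON-ready form
#' @param record a `reduction_record`.
#' @return plain nested list.
#' @export
reductionSummary <- function(record) {
  list(
    final_subset = record$final_mask$active,
    rounds = lapply(record$rounds, function(r)
      list(round = r$round, subset_before = r$subset_before,
           subset_after = r$subset_after, omitted = r$omitted,
           qmc_success_rate = r$qmc_success_rate,
           mean_error_before = mean(r$pso_before),
           mean_error_after = mean(r$pso_after),
           ratio = r$ratio, accepted = r$accepted))
  )
}
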