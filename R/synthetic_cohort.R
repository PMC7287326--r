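#' @title Synthetic echo-like cohort generator
#' @name synthetic_cohort
#' @description
#' Virtual subjects with known ground-truth parameters and
#' echocardiography-like strain measurements, so every pipeline stage is
#' testable without clinical data. Three disease-stage archetypes mirror
#' the clinical taxonomy of arrhythmogenic cardiomyopathy screening:
#' `concealed` (near-reference tissue with mild basal heterogeneity),
#' `electrical` (increased RV basal activation delay) and `structural`
#' (reduced RV basal/mid contractility with increased stiffness). The
#' measurement model resamples the simulated strain to the echo frame
#' rate, adds white noise and a linear baseline drift, and re-zeroes at
#' QRS onset.
NULL

#' Cohort noise settings
#'
#' @param frameRate echo sampling rate (Hz); default 60.
#' @param noiseSd strain noise standard deviation (percent); default 0.5.
#' @param driftMax linear drift magnitude (percent per cycle), drawn
#'   uniformly in `[-driftMax, driftMax]`; default 1. Drift is on by
#'   default so the 50%-relaxation fit-window logic is exercised.
#' @return list of class `cohort_noise_config`.
#' @export
cohortNoiseConfig <- function(frameRate = 60, noiseSd = 0.5, driftMax = 1) {
  structure(list(frameRate = frameRate, noiseSd = noiseSd,
                 driftMax = driftMax),
            class = "cohort_noise_config")
}

# stage archetypes on the normalized scale; values only applied to
# parameters actually present in the registry
stageArchetype <- function(stage, names) {
  x <- list()
  jitter <- function(mu, sd) function() clamp(stats::rnorm(1L, mu, sd), 0.02, 0.98)
  unif <- function(a, b) function() stats::runif(1L, a, b)
  # every subject carries genuine regional heterogeneity in the
  # disease-prone mid/basal RV segments (contractility, stiffness,
  # activation delay), clearly above the measurement noise floor, so
  # recovery of these parameters is a meaningful target
  for (p in c("SfAct_RV_mid", "SfAct_RV_base", "kLin_RV_mid",
              "kLin_RV_base", "dT_RV_mid", "dT_RV_base"))
    x[[p]] <- jitter(0.5, 0.12)
  if (stage == "electrical") {
    x[["dT_RV_base"]] <- unif(0.75, 0.95)
    x[["dT_RV_mid"]] <- unif(0.55, 0.75)
  } else if (stage == "structural") {
    x[["SfAct_RV_base"]] <- unif(0.10, 0.30)
    x[["SfAct_RV_mid"]] <- unif(0.20, 0.40)
    x[["kLin_RV_base"]] <- unif(0.65, 0.85)
    x[["kLin_RV_mid"]] <- unif(0.60, 0.80)
    x[["dT_RV_base"]] <- unif(0.55, 0.75)
  }
  x[names(x) %in% names]
}

# global physiology varying between subjects: cycle time (heart rate)
# and AV delay. Cardiac output and relative systole duration stay at
# reference: in this phenomenological model they are fully compensable
# by tissue-parameter rescaling (amplitude) and cycle-time/delay shifts
# (timing), so subject-level variation in them would make the remaining
# estimates only identifiable up to that equivalence class.
globalJitterNames <- function() c("cycleTime", "AVdelay")

#' Generate a cohort of virtual subjects
#'
#' Ground-truth points are drawn per stage archetype around the
#' normalized reference; truths falling in the forward model's crash
#' region are rejected and redrawn. Measurements derive from the model
#' evaluated at the truth, resampled to the frame interval, with
#' additive Gaussian noise and a linear drift, re-zeroed at QRS onset.
#'
#' @param space a `parameter_space`.
#' @param n number of subjects; default 15.
#' @param stageMix named integer vector summing to `n`; by default the
#'   6/4/5 concealed/electrical/structural composition, rescaled to `n`
#'   by largest remainder when `n` differs from 15.
#' @param noise a [cohortNoiseConfig()].
#' @param modelConfig a [toyModelConfig()].
#' @param seed optional integer seed.
#' @return list of `virtual_subject` objects: `subject_id`, `stage`,
#'   `truth` (named normalized point), `trace` (measured
#'   [strainTrace()]).
#' @export
makeCohort <- function(space, n = 15, stageMix = NULL,
                       noise = cohortNoiseConfig(),
                       modelConfig = toyModelConfig(), seed = NULL) {
  stopifnot(n >= 1)
  if (is.null(stageMix)) {
    frac <- c(concealed = 6, electrical = 4, structural = 5) / 15
    stageMix <- floor(frac * n)
    rem <- n - sum(stageMix)
    if (rem > 0) {
      extra <- order(frac * n - floor(frac * n), decreasing = TRUE)[seq_len(rem)]
      stageMix[extra] <- stageMix[extra] + 1L
    }
  }
  if (sum(stageMix) != n)
    stop("stageMix must sum to n")
  if (!is.null(seed)) set.seed(seed)
  stages <- rep(names(stageMix), times = stageMix)
  nm <- paramNames(space)
  ref <- referencePoint(space)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      truth <- clamp(ref + stats::rnorm(space$D, 0, 0.03), 0.02, 0.98)
      names(truth) <- nm
      for (g in intersect(globalJitterNames(), nm))
        truth[g] <- clamp(ref[g] + stats::rnorm(1L, 0, 0.08), 0.05, 0.95)
      arch <- stageArchetype(stages[i], nm)
      for (p in names(arch)) truth[p] <- arch[[p]]()
      if (!crashPredicate(truth, modelConfig)) break
    }
    res <- evaluateModel(truth, space, modelConfig)
    stopifnot(res$status == "ok")
    tr <- res$trace
    tGrid <- seq(0, tr$T, by = 1 / noise$frameRate)
    drift <- stats::runif(1L, -noise$driftMax, noise$driftMax)
    meas <- vapply(wallSegments(), function(seg) {
      y <- stats::approx(tr$t, segmentStrain(tr, seg), tGrid, rule = 2)$y
      y + stats::rnorm(length(tGrid), 0, noise$noiseSd) +
        drift * tGrid / tr$T
    }, numeric(length(tGrid)))
    measured <- strainTrace(tGrid, meas, t_qrs = 0, t_pvc = tr$t_pvc,
                            T = tr$T, rezero = TRUE)
    subjects[[i]] <- structure(
      list(subject_id = sprintf("S%02d", i), stage = stages[i],
           truth = truth, trace = measured),
      class = "virtual_subject")
  }
  subjects
}

#' @export
print.virtual_subject <- function(x, ...) {
  cat(sprintf("<virtual_subject> %s (%s stage), T = %.3f s\n",
              x$subject_id, x$stage, x$trace$T))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One strain CSV per subject (see [writeStrainCsv()]) plus a
#' ground-truth JSON with stages and normalized truth vectors.
#'
#' @param cohort list of `virtual_subject`s.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth <- list()
  for (s in cohort) {
    writeStrainCsv(s$trace, file.path(dir, paste0(s$subject_id, ".csv")))
    truth[[s$subject_id]] <- list(stage = s$stage,
                                  truth = as.list(s$truth))
  }
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing the ground-truth JSON requires the jsonlite package")
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
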