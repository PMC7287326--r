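#' @title Sobol quasi-Monte Carlo exploration and diaphony
#' @name qmc
#' @description
#' Unscrambled Sobol sampling of the active subset, one forward-model
#' evaluation per sample reused across all subjects, per-subject fit
#' errors, best-N selection and the per-parameter diaphony: the modulus
#' of the mean unit phasor `|mean(exp(2 pi i x))|` of the best-set
#' coordinates. Diaphony 0 means the best fits are spread homogeneously
#' over the parameter's range (unidentifiable); 1 means they coincide
#' (sharply identified).
NULL

.sobolCache <- new.env(parent = emptyenv())

sobolBits <- 30L

# direction integers V (bits x dims) from the bundled Joe-Kuo constants
sobolDirections <- function(d) {
  if (!is.null(.sobolCache$V) && ncol(.sobolCache$V) >= d)
    return(.sobolCache$V[, seq_len(d), drop = FALSE])
  path <- system.file("extdata", "sobol_directions.csv",
                      package = "strainreduce", mustWork = TRUE)
  tab <- utils::read.csv(path)
  maxd <- max(tab$dim)
  if (d > maxd)
    stop("Sobol direction-number table covers ", maxd,
         " dimensions; requested ", d)
  L <- sobolBits
  V <- matrix(0, L, maxd)
  V[, 1L] <- 2^(L - seq_len(L))          # first dimension: m_k = 1
  for (r in seq_len(nrow(tab))) {
    dim <- tab$dim[r]
    poly <- tab$poly[r]
    s <- floor(log2(poly))
    a <- as.integer(intToBits(poly))[seq_len(s + 1L)]  # bit 1 = x^0
    m <- as.numeric(tab[r, paste0("m", seq_len(s))])
    v <- numeric(L)
    v[seq_len(s)] <- m * 2^(L - seq_len(s))
    for (k in (s + 1L):L) {
      val <- bitwXor(v[k - s], v[k - s] %/% 2^s)
      for (i in seq_len(s - 1L)) {
        if (s > 1L && a[s + 1L - i] == 1L)
          val <- bitwXor(val, v[k - i])
      }
      v[k] <- val
    }
    V[, dim] <- v
  }
  .sobolCache$V <- V
  V[, seq_len(d), drop = FALSE]
}

#' Generate Sobol low-discrepancy points
#'
#' First `n` points of the unscrambled Sobol sequence (Joe-Kuo direction
#' numbers, Gray-code order) with the all-zeros initial point skipped.
#' Deterministic: no seed is consumed.
#'
#' @param n number of points.
#' @param d dimension (up to 128).
#' @return `n x d` matrix with entries in `[0, 1)`.
#' @export
sobolPoints <- function(n, d) {
  stopifnot(n >= 1, d >= 1)
  if (n >= 2^sobolBits) stop("n too large for the 30-bit generator")
  V <- sobolDirections(d)
  X <- matrix(0, n, d)
  state <- numeric(d)
  for (i in seq_len(n)) {
    # Gray-code index: rightmost zero bit of (i - 1)
    c <- 1L
    m <- i - 1L
    while (m %% 2L == 1L) { m <- m %/% 2L; c <- c + 1L }
    state <- bitwXor(state, V[c, ])
    X[i, ] <- state
  }
  X / 2^sobolBits
}

#' First-harmonic diaphony of a coordinate sample
#'
#' `d = |(1/N) sum_j exp(2 pi i x_j)|`: 1 when all values coincide, 0
#' for a perfectly homogeneous (e.g. equispaced) set. Invariant under a
#' common shift modulo 1.
#'
#' @param x numeric vector of coordinates in `[0, 1]`.
#' @return the diaphony in `[0, 1]`.
#' @export
diaphony <- function(x) {
  if (length(x) == 0L) stop("diaphony of an empty set is undefined")
  Mod(mean(exp(2i * pi * x)))
}

#' Evaluate a point set against a cohort of measured traces
#'
#' One forward-model evaluation per point, reused across subjects (the
#' cycle time is part of the sampled input space, so a single sweep
#' serves every subject). Crashed evaluations receive infinite error for
#' all subjects.
#'
#' @param points `n x d_active` matrix of normalized samples over the
#'   active subset.
#' @param model evaluator `function(point) -> model_result`.
#' @param subjects list of measured [strainTrace()]s (or
#'   `virtual_subject`s, whose `$trace` is used).
#' @param space a `parameter_space`.
#' @param mask the `subset_mask` the points live in.
#' @param Nb best-set size per subject (default 100).
#' @param weights an [objectiveWeights()].
#' @return object of class `qmc_result`: `points`, `errors`
#'   (`n x n_subjects`), `best_idx` (list of ascending-error indices),
#'   `diaphony` (`d_active x n_subjects`, rownames = parameter names),
#'   `success_rate`.
#' @export
evaluateCohort <- function(points, model, subjects, space, mask,
                           Nb = 100, weights = objectiveWeights()) {
  stopifnot(length(subjects) >= 1L)
  traces <- lapply(subjects, function(s)
    if (inherits(s, "virtual_subject")) s$trace else s)
  ctxs <- lapply(traces, subjectContext, weights = weights)
  n <- nrow(points)
  nS <- length(subjects)
  errors <- matrix(Inf, n, nS)
  ok <- logical(n)
  for (i in seq_len(n)) {
    res <- model(restrictPoint(space, mask, points[i, ]))
    if (res$status == "ok") {
      ok[i] <- TRUE
      for (s in seq_len(nS)) errors[i, s] <- contextError(res$trace, ctxs[[s]])
    }
  }
  if (!any(ok))
    warning("all qMC evaluations crashed; errors are all infinite")
  bestIdx <- lapply(seq_len(nS), function(s) {
    finite <- which(is.finite(errors[, s]))
    finite[order(errors[finite, s])][seq_len(min(Nb, length(finite)))]
  })
  dia <- matrix(NA_real_, ncol(points), nS,
                dimnames = list(mask$active, NULL))
  for (s in seq_len(nS)) {
    if (length(bestIdx[[s]]) > 0L)
      dia[, s] <- apply(points[bestIdx[[s]], , drop = FALSE], 2L, diaphony)
  }
  structure(list(points = points, errors = errors, best_idx = bestIdx,
                 diaphony = dia, success_rate = mean(ok)),
            class = "qmc_result")
}

#' @export
print.qmc_result <- function(x, ...) {
  cat(sprintf(
    "<qmc_result> %d points x %d parameters, %d subject(s); success rate %.3f\n",
    nrow(x$points), ncol(x$points), ncol(x$errors), x$success_rate))
  best <- vapply(seq_len(ncol(x$errors)), function(s)
    if (length(x$best_idx[[s]]) > 0L)
      x$errors[x$best_idx[[s]][1L], s] else Inf, numeric(1L))
  cat("  best error per subject:",
      paste(sprintf("%.3g", best), collapse = ", "), "\n")
  invisible(x)
}
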