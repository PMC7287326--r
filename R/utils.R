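# internal helpers shared across modules

#' Derive a stage-specific seed from a root seed
#'
#' Every stochastic stage (trajectory generation, swarm updates, cohort
#' noise) consumes its own named seed derived from a single root, so stages
#' are independently reproducible and no stage relies on hidden global RNG
#' state left behind by another.
#'
#' @param root integer root seed.
#' @param label character stage name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stageSeed <- function(root, label) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(root) + h) %% 2147483647)
}

# trapezoid rule on an arbitrary (sorted) grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# deep-merge override list into defaults (used by config readers)
mergeList <- function(defaults, override) {
  if (is.null(override)) return(defaults)
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && is.list(override[[nm]])) {
      defaults[[nm]] <- mergeList(defaults[[nm]], override[[nm]])
    } else {
      defaults[[nm]] <- override[[nm]]
    }
  }
  defaults
}
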