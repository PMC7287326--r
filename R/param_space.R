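#' @title Parameter registry and dimensionless normalization
#' @name param_space
#' @description
#' The registry is an ordered list of parameter definitions (name, wall
#' group, physical bounds, reference value, units). All downstream machinery
#' (screening, quasi-Monte Carlo sampling, swarm optimization) works on the
#' dimensionless unit hypercube: each physical domain is linearly mapped to
#' `[0, 1]`. Subsets are expressed as masks that fix excluded parameters at
#' their (normalized) reference values.
NULL

#' Wall-segment group labels
#'
#' The five modelled wall segments (right-ventricular free wall split into
#' apex/mid/base, inter-ventricular septum, left-ventricular free wall),
#' plus `"global"` for non-ventricular parameters.
#' @export
wallSegments <- function() c("RV_apex", "RV_mid", "RV_base", "IVS", "LVfw")

parameterGroups <- function() c(wallSegments(), "global")

#' Construct a parameter space from a definition table
#'
#' @param defs data.frame with columns `name`, `group`, `lower`, `upper`,
#'   `reference`, `units`. Row order is the (stable) iteration order.
#' @return an object of class `parameter_space` with elements `params`
#'   (the definition table) and `D` (dimension).
#' @export
parameterSpace <- function(defs) {
  defs <- as.data.frame(defs, stringsAsFactors = FALSE)
  needed <- c("name", "group", "lower", "upper", "reference", "units")
  missing <- setdiff(needed, names(defs))
  if (length(missing) > 0L)
    stop("registry is missing column(s): ", paste(missing, collapse = ", "))
  defs <- defs[, needed]
  if (anyDuplicated(defs$name))
    stop("duplicate parameter name(s): ",
         paste(unique(defs$name[duplicated(defs$name)]), collapse = ", "))
  bad <- !defs$group %in% parameterGroups()
  if (any(bad))
    stop("unknown group(s): ", paste(unique(defs$group[bad]), collapse = ", "))
  if (any(defs$lower >= defs$upper))
    stop("lower >= upper for: ",
         paste(defs$name[defs$lower >= defs$upper], collapse = ", "))
  off <- defs$reference < defs$lower | defs$reference > defs$upper
  if (any(off))
    stop("reference outside bounds for: ", paste(defs$name[off], collapse = ", "))
  rownames(defs) <- NULL
  structure(list(params = defs, D = nrow(defs)), class = "parameter_space")
}

#' @export
print.parameter_space <- function(x, ...) {
  cat("<parameter_space> D =", x$D, "parameters\n")
  tab <- table(factor(x$params$group, levels = parameterGroups()))
  cat("  per group:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Parameter names of a space (in registry order)
#' @param space a `parameter_space`.
#' @return character vector of length `D`.
#' @export
paramNames <- function(space) space$params$name

# --- tissue parameter template -------------------------------------------
# Twelve tissue parameters per wall segment. The bounds are package
# defaults, deliberately wide for the RV mid and basal segments (the
# disease-affected regions in arrhythmogenic cardiomyopathy) and narrow
# elsewhere to cover inter-subject variability only.
tissueTemplate <- function() {
  data.frame(
    short = c("AmRef", "Ls0", "SfAct", "TauC", "TauR", "VMax",
              "VWall", "dT", "k1", "kLin", "res1", "res2"),
    ref        = c(100, 1.8, 120, 0.15, 0.10, 7, 80, 0.00, 10, 3.0, 0.5, 0.5),
    lowNarrow  = c(80, 1.70, 84, 0.12, 0.08, 5, 60, -0.02, 7, 2.4, 0, 0),
    highNarrow = c(120, 1.90, 156, 0.18, 0.12, 9, 100, 0.02, 13, 3.6, 1, 1),
    lowWide    = c(50, 1.50, 12, 0.05, 0.04, 2, 40, -0.05, 1, 0.8, 0, 0),
    highWide   = c(150, 2.10, 240, 0.30, 0.20, 14, 160, 0.12, 30, 9.0, 1, 1),
    units = c("cm2", "um", "kPa", "s", "s", "um/s", "mL", "s", "-", "kPa/%",
              "-", "-"),
    stringsAsFactors = FALSE
  )
}

globalTemplate <- function() {
  real <- data.frame(
    name = c("AVdelay", "CO", "HR", "MAP", "cycleTime", "relSysDur"),
    lower = c(0.00, 4.0, 60, 70, 0.60, 0.30),
    upper = c(0.08, 6.0, 80, 110, 1.20, 0.50),
    reference = c(0.02, 5.0, 70, 92, 0.85, 0.40),
    units = c("s", "L/min", "bpm", "mmHg", "s", "-"),
    stringsAsFactors = FALSE
  )
  pad <- data.frame(
    name = sprintf("glob%02d", seq_len(44)),
    lower = 0, upper = 1, reference = 0.5, units = "-",
    stringsAsFactors = FALSE
  )
  out <- rbind(real, pad)
  out[order(out$name), , drop = FALSE]
}

#' Build the default 110-parameter registry
#'
#' Twelve tissue parameters for each of the five wall segments (60
#' ventricular parameters) plus 50 global, non-ventricular parameters.
#' Tissue parameters: wall reference area `AmRef`, zero-stress sarcomere
#' length `Ls0`, contractility `SfAct`, contraction and relaxation time
#' constants `TauC`/`TauR`, shortening velocity `VMax`, wall volume
#' `VWall`, activation delay `dT`, passive-stiffness exponent `k1`, linear
#' stiffness component `kLin`, and two reserved placeholders `res1`/`res2`
#' that no forward model reads (they exist so screening has genuinely
#' unimportant inputs to find). Bound widths follow the disease prior: wide
#' for RV mid/basal tissue, narrow elsewhere. The numeric defaults are a
#' package fixture, not measured values.
#'
#' Ordering is group-major (RV_apex, RV_mid, RV_base, IVS, LVfw, global)
#' and alphabetical within group, so two calls always agree.
#'
#' @return a `parameter_space` with `D = 110`.
#' @export
defaultRegistry <- function() {
  tt <- tissueTemplate()
  tt <- tt[order(tt$short), , drop = FALSE]
  rows <- list()
  for (seg in wallSegments()) {
    wide <- seg %in% c("RV_mid", "RV_base")
    rows[[seg]] <- data.frame(
      name = paste(tt$short, seg, sep = "_"),
      group = seg,
      lower = if (wide) tt$lowWide else tt$lowNarrow,
      upper = if (wide) tt$highWide else tt$highNarrow,
      reference = tt$ref,
      units = tt$units,
      stringsAsFactors = FALSE
    )
  }
  g <- globalTemplate()
  rows$global <- data.frame(
    name = g$name, group = "global", lower = g$lower, upper = g$upper,
    reference = g$reference, units = g$units, stringsAsFactors = FALSE
  )
  parameterSpace(do.call(rbind, rows))
}

#' Build a compact 20-parameter demonstration registry
#'
#' A small space for desk-scale end-to-end runs: contractility, linear
#' stiffness and activation delay for the three RV free-wall segments,
#' contractility for IVS and LVfw, five real global parameters (AV delay,
#' cardiac output, mean arterial pressure, cycle time, relative systole
#' duration) and four placeholder parameters (`glob01`..`glob04`) that the
#' forward model never reads.
#'
#' @return a `parameter_space` with `D = 20`.
#' @export
compactRegistry <- function() {
  full <- defaultRegistry()$params
  keep <- c(
    paste(rep(c("SfAct", "kLin", "dT"), each = 3),
          rep(c("RV_apex", "RV_mid", "RV_base"), times = 3), sep = "_"),
    "SfAct_IVS", "SfAct_LVfw",
    "AVdelay", "CO", "MAP", "cycleTime", "relSysDur",
    sprintf("glob%02d", 1:4)
  )
  defs <- full[match(keep, full$name), , drop = FALSE]
  # keep group-major, alphabetical-within-group ordering
  defs <- defs[order(factor(defs$group, levels = parameterGroups()), defs$name), ]
  parameterSpace(defs)
}

# --- normalization --------------------------------------------------------

#' Normalize physical parameter values to the unit hypercube
#'
#' `x_i = (physical_i - lower_i) / (upper_i - lower_i)`.
#'
#' @param space a `parameter_space`.
#' @param physical numeric vector of length `D` in registry order.
#' @return named numeric vector in `[0, 1]^D`.
#' @export
normalizeParams <- function(space, physical) {
  p <- space$params
  if (length(physical) != space$D)
    stop("expected ", space$D, " values, got ", length(physical))
  out <- (physical - p$lower) / (p$upper - p$lower)
  bad <- which(physical < p$lower | physical > p$upper)
  if (length(bad) > 0L)
    stop("physical value out of bounds for parameter(s): ",
         paste(p$name[bad], collapse = ", "))
  stats::setNames(out, p$name)
}

#' Map normalized coordinates back to physical values
#'
#' Inverse of [normalizeParams()].
#'
#' @param space a `parameter_space`.
#' @param x numeric vector of length `D` in `[0, 1]`.
#' @return named numeric vector of physical values.
#' @export
denormalizeParams <- function(space, x) {
  p <- space$params
  if (length(x) != space$D)
    stop("expected ", space$D, " values, got ", length(x))
  stats::setNames(p$lower + x * (p$upper - p$lower), p$name)
}

#' Normalized reference point of a registry
#' @param space a `parameter_space`.
#' @return named vector: each parameter's reference value on the unit scale.
#' @export
referencePoint <- function(space) {
  p <- space$params
  stats::setNames((p$reference - p$lower) / (p$upper - p$lower), p$name)
}

# --- subset masks ---------------------------------------------------------

#' Define an active-parameter subset
#'
#' Inactive parameters are fixed at given normalized values (default:
#' their normalized reference), mirroring the convention that omitted
#' parameters stay at the reference configuration.
#'
#' @param space a `parameter_space`.
#' @param active character vector of active parameter names.
#' @param fixedValues optional named numeric vector of normalized values
#'   for inactive parameters; missing entries default to the reference.
#' @return an object of class `subset_mask` with elements `active` and
#'   `fixed` (named vector over all inactive parameters).
#' @export
subsetMask <- function(space, active, fixedValues = NULL) {
  all <- paramNames(space)
  unknown <- setdiff(active, all)
  if (length(unknown) > 0L)
    stop("unknown parameter name(s) in mask: ", paste(unknown, collapse = ", "))
  active <- all[all %in% active]   # registry order
  inactive <- setdiff(all, active)
  fixed <- referencePoint(space)[inactive]
  if (!is.null(fixedValues)) {
    unknown <- setdiff(names(fixedValues), inactive)
    if (length(unknown) > 0L)
      stop("fixed value given for non-inactive parameter(s): ",
           paste(unknown, collapse = ", "))
    fixed[names(fixedValues)] <- fixedValues
  }
  if (any(fixed < 0 | fixed > 1))
    stop("fixed normalized values must lie in [0, 1]")
  structure(list(active = active, fixed = fixed), class = "subset_mask")
}

#' @export
print.subset_mask <- function(x, ...) {
  cat("<subset_mask>", length(x$active), "active /", length(x$fixed),
      "fixed\n")
  invisible(x)
}

#' Embed a subset point into the full-dimensional space
#'
#' @param space a `parameter_space`.
#' @param mask a `subset_mask`.
#' @param subPoint numeric vector over the active parameters (mask order).
#' @return named full-dimensional normalized point.
#' @export
restrictPoint <- function(space, mask, subPoint) {
  if (length(subPoint) != length(mask$active))
    stop("subPoint has length ", length(subPoint), ", expected ",
         length(mask$active))
  x <- stats::setNames(numeric(space$D), paramNames(space))
  x[mask$active] <- subPoint
  x[names(mask$fixed)] <- mask$fixed
  x
}

#' Project a full-dimensional point onto the active coordinates
#' @param space a `parameter_space`.
#' @param mask a `subset_mask`.
#' @param x full-dimensional normalized point (named or registry order).
#' @return numeric vector over the active parameters.
#' @export
projectPoint <- function(space, mask, x) {
  if (is.null(names(x))) names(x) <- paramNames(space)
  x[mask$active]
}

# --- YAML registry IO -----------------------------------------------------

#' Read a parameter registry from YAML
#'
#' The file is a YAML list of records with fields `name`, `group`,
#' `lower`, `upper`, `reference`, `units`.
#'
#' @param path file path.
#' @return a `parameter_space`.
#' @export
readRegistryYaml <- function(path) {
  raw <- readYamlSafe(path)
  defs <- do.call(rbind, lapply(raw, function(r)
    data.frame(name = r$name, group = r$group, lower = as.numeric(r$lower),
               upper = as.numeric(r$upper), reference = as.numeric(r$reference),
               units = r$units %||% "-", stringsAsFactors = FALSE)))
  parameterSpace(defs)
}

#' Write a parameter registry to YAML
#' @param space a `parameter_space`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeRegistryYaml <- function(space, path) {
  recs <- lapply(seq_len(space$D), function(i) as.list(space$params[i, ]))
  yaml::write_yaml(recs, path)
  invisible(path)
}
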