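#' @title Strain CSV dialect, run configuration and persistence
#' @name cli_io
#' @description
#' The on-disk strain dialect is a plain CSV with columns `time_s`,
#' `rv_apex`, `rv_mid`, `rv_base`, `ivs`, `lvfw` (percent strain) and
#' three metadata header lines `# t_qrs=`, `# t_pvc=`, `# T=` (seconds).
#' Run configuration is YAML with defaults matching the package's
#' standard settings; every run record embeds the resolved
#' configuration. All times are seconds, all strains percent.
NULL

# yaml's 1.1 scalar rules turn bare `n`/`y`/`yes`/`no` into logicals,
# which mangles short keys like `n`; only canonical true/false survive
# as booleans here
readYamlSafe <- function(path) {
  keepToken <- function(x)
    if (tolower(x) %in% c("true", "false")) as.logical(x) else x
  yaml::read_yaml(path, handlers = list("bool#yes" = keepToken,
                                        "bool#no" = keepToken))
}

csvColumns <- function() {
  stats::setNames(c("rv_apex", "rv_mid", "rv_base", "ivs", "lvfw"),
                  wallSegments())
}

#' Write a strain trace to CSV
#'
#' @param trace a [strainTrace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStrainCsv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# t_qrs=%.15g", trace$t_qrs),
               sprintf("# t_pvc=%.15g", trace$t_pvc),
               sprintf("# T=%.15g", trace$T)), con)
  df <- data.frame(time_s = trace$t)
  cols <- csvColumns()
  for (seg in names(cols)) df[[cols[[seg]]]] <- trace$strain[, seg]
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a strain trace from CSV
#'
#' Validates the dialect: all five segment columns, monotone time, and
#' the three metadata lines must be present. Strain that is nonzero at
#' QRS onset beyond 1e-6 is re-referenced with a warning.
#'
#' @param path file path.
#' @return a [strainTrace()].
#' @export
readStrainCsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  isMeta <- grepl("^#", lines)
  meta <- lines[isMeta]
  getMeta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (length(hit) == 0L)
      stop("missing metadata line '# ", key, "=' in ", path)
    as.numeric(sub(".*=", "", hit[1L]))
  }
  t_qrs <- getMeta("t_qrs"); t_pvc <- getMeta("t_pvc"); T <- getMeta("T")
  df <- utils::read.csv(text = paste(lines[!isMeta], collapse = "\n"))
  cols <- csvColumns()
  missing <- setdiff(c("time_s", unname(cols)), names(df))
  if (length(missing) > 0L)
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  if (is.unsorted(df$time_s, strictly = TRUE))
    stop("non-monotone time column in ", path)
  strain <- as.matrix(df[, unname(cols)])
  colnames(strain) <- names(cols)
  atQrs <- apply(strain, 2L, function(y)
    stats::approx(df$time_s, y, t_qrs, rule = 2)$y)
  if (any(abs(atQrs) > 1e-6))
    warning("strain nonzero at QRS onset; re-referencing ", basename(path))
  strainTrace(df$time_s, strain, t_qrs = t_qrs, t_pvc = t_pvc, T = T,
              rezero = TRUE)
}

#' Default run configuration
#'
#' Nested defaults for every pipeline stage: Morris screening
#' (`z = 8`, trajectory budget, round cap), qMC (`n`, best-set size),
#' PSO (population 30, `w = 0.729`, `c1 = c2 = 1.49445`, energy
#' tolerance 0.1, 1000-iteration cap), the reduction loop, objective
#' weights (`alpha = 1`, `beta = 0.1`) and the root seed.
#'
#' @param overrides optional nested list of overrides (deep-merged).
#' @return list of class `run_config`.
#' @export
runConfig <- function(overrides = NULL) {
  defaults <- list(
    registry = "default",
    model = list(dt = 0.002, baseAmplitude = 20, crashStiffMax = 0.06,
                 crashContrMin = 0.90, crashEnabled = TRUE),
    morris = list(z = 8, trajectory_budget = 50, max_rounds = 10),
    qmc = list(n = 2^14, Nb = 100),
    pso = list(pop = 30, w = 0.729, c1 = 1.49445, c2 = 1.49445,
               energy_tol = 0.1, max_iter = 1000),
    reduction = list(tol = 0.5, omit_quantile = 0.25, floor = 5,
                     max_rounds = 10),
    weights = list(alpha = 1, beta = 0.1),
    cohort = list(n = 15, frame_rate = 60, noise_sd = 0.5, drift_max = 1),
    seed = 1L
  )
  structure(mergeList(defaults, overrides), class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file path; values deep-merge over [runConfig()]
#'   defaults.
#' @return a `run_config`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  runConfig(readYamlSafe(path))
}

# resolve config sub-blocks into the typed configuration objects
configModel <- function(cfg)
  toyModelConfig(dt = cfg$model$dt, baseAmplitude = cfg$model$baseAmplitude,
                 crashStiffMax = cfg$model$crashStiffMax,
                 crashContrMin = cfg$model$crashContrMin,
                 crashEnabled = cfg$model$crashEnabled)

configPso <- function(cfg)
  psoConfig(pop = cfg$pso$pop, w = cfg$pso$w, c1 = cfg$pso$c1,
            c2 = cfg$pso$c2, energyTol = cfg$pso$energy_tol,
            maxIter = cfg$pso$max_iter)

configWeights <- function(cfg)
  objectiveWeights(alpha = cfg$weights$alpha, beta = cfg$weights$beta)

configRegistry <- function(cfg) {
  if (identical(cfg$registry, "default")) defaultRegistry()
  else if (identical(cfg$registry, "compact")) compactRegistry()
  else readRegistryYaml(cfg$registry)
}

configReduction <- function(cfg)
  reductionConfig(nQmc = cfg$qmc$n, Nb = cfg$qmc$Nb,
                  omitQuantile = cfg$reduction$omit_quantile,
                  tol = cfg$reduction$tol, floor = cfg$reduction$floor,
                  maxRounds = cfg$reduction$max_rounds,
                  pso = configPso(cfg), weights = configWeights(cfg))
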