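#' Construct a strain trace
#'
#' A strain trace holds time-sampled percent engineering strain for the
#' five wall segments plus the cardiac event times used downstream: QRS
#' onset (the strain reference instant), pulmonary valve closure, and the
#' cycle time. Strain is referenced so that every segment is zero at QRS
#' onset; negative strain means shortening.
#'
#' @param t numeric time samples (s), strictly increasing, spanning
#'   `[0, T]`.
#' @param strain numeric matrix `length(t) x 5` with column names
#'   `wallSegments()`; percent strain.
#' @param t_qrs QRS-onset time (s).
#' @param t_pvc pulmonary valve closure time (s).
#' @param T cycle time (s).
#' @param rezero if `TRUE` (default) subtract each segment's value at
#'   `t_qrs` so the reference invariant holds exactly.
#' @return an object of class `strain_trace`.
#' @export
strainTrace <- function(t, strain, t_qrs, t_pvc, T, rezero = TRUE) {
  strain <- as.matrix(strain)
  if (is.null(colnames(strain)) && ncol(strain) == 5L)
    colnames(strain) <- wallSegments()
  missing <- setdiff(wallSegments(), colnames(strain))
  if (length(missing) > 0L)
    stop("strain matrix missing segment column(s): ",
         paste(missing, collapse = ", "))
  strain <- strain[, wallSegments(), drop = FALSE]
  if (nrow(strain) != length(t)) stop("strain rows must match length(t)")
  if (is.unsorted(t, strictly = TRUE)) stop("time samples must be strictly increasing")
  if (!(t_qrs >= 0 && t_qrs < t_pvc && t_pvc < T))
    stop("event times must satisfy 0 <= t_qrs < t_pvc < T")
  if (rezero) {
    ref <- apply(strain, 2L, function(y) stats::approx(t, y, t_qrs, rule = 2)$y)
    strain <- sweep(strain, 2L, ref)
  }
  structure(list(t = as.numeric(t), strain = strain,
                 t_qrs = t_qrs, t_pvc = t_pvc, T = T),
            class = "strain_trace")
}

#' @export
print.strain_trace <- function(x, ...) {
  cat(sprintf(
    "<strain_trace> %d samples over [0, %.3f] s; t_qrs = %.3f s, t_pvc = %.3f s\n",
    length(x$t), x$T, x$t_qrs, x$t_pvc))
  pk <- apply(x$strain, 2L, min)
  cat("  peak strain (%):",
      paste(sprintf("%s %.1f", names(pk), pk), collapse = ", "), "\n")
  invisible(x)
}

# strain of one segment, with basic checking
segmentStrain <- function(trace, segment) {
  if (!segment %in% colnames(trace$strain))
    stop("segment not present in trace: ", segment)
  trace$strain[, segment]
}
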