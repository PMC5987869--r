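#' Simulate a realignment-parameter trace for one run
#'
#' Head position over scans is modelled as a six-parameter random walk
#' (3 translations in mm, 3 rotations in radians). Each scan-to-scan step is
#' Gaussian with standard deviation `severity` (mm); rotation steps are
#' scaled so their arc length on a sphere of radius `rotation_radius_mm` has
#' the same standard deviation. An optional spike injects abrupt
#' displacements of a stated magnitude on a stated number of consecutive
#' transitions, emulating the sudden movements that motion QC must catch.
#'
#' @param n_scans Number of scan volumes (>= 2).
#' @param severity Per-step standard deviation in mm; 0 gives a still head.
#' @param spike_spec Optional list with `transition_index` (1-based index of
#'   the first affected transition), `axis` (1..6 or a column name),
#'   `magnitude_mm` and `n_consecutive` (default 1).
#' @param seed Integer seed or `NULL`.
#' @param rotation_radius_mm Radius used to put rotations on the mm scale.
#' @return A `motion_trace`: an `n_scans` x 6 numeric matrix with columns
#'   `x_mm`, `y_mm`, `z_mm`, `pitch_rad`, `roll_rad`, `yaw_rad`.
#' @examples
#' tr <- generate_motion_trace(20, severity = 0.05, seed = 1)
#' @export
generate_motion_trace <- function(n_scans, severity = 0.05,
                                  spike_spec = NULL, seed = NULL,
                                  rotation_radius_mm = 50) {
  n_scans <- check_count(n_scans, "n_scans", min = 2L)
  if (!is.numeric(severity) || severity < 0)
    stop("'severity' must be non-negative")
  cols <- c("x_mm", "y_mm", "z_mm", "pitch_rad", "roll_rad", "yaw_rad")
  steps <- with_seed(seed, {
    s <- matrix(rnorm((n_scans - 1L) * 6L, sd = severity),
                n_scans - 1L, 6L)
    s[, 4:6] <- s[, 4:6] / rotation_radius_mm
    s
  })
  if (severity == 0) steps[] <- 0
  if (!is.null(spike_spec)) {
    idx <- check_count(spike_spec$transition_index, "transition_index")
    nc <- check_count(spike_spec$n_consecutive %||% 1L, "n_consecutive")
    axis <- spike_spec$axis %||% 1L
    if (is.character(axis)) axis <- match(axis, cols)
    if (is.na(axis) || axis < 1 || axis > 6) stop("unknown spike axis")
    if (idx < 1 || idx + nc - 1L > n_scans - 1L)
      stop("spike transition index out of range for this run length")
    mag <- spike_spec$magnitude_mm
    if (axis > 3) mag <- mag / rotation_radius_mm
    steps[idx:(idx + nc - 1L), axis] <-
      steps[idx:(idx + nc - 1L), axis] + mag
  }
  trace <- rbind(0, apply(steps, 2, cumsum))
  dimnames(trace) <- list(NULL, cols)
  structure(trace, class = c("motion_trace", "matrix", "array"))
}

#' Write a motion trace as a 6-column TSV
#' @param trace A `motion_trace` (or n x 6 matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motion_tsv <- function(trace, path) {
  write.table(as.data.frame(unclass(trace)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 6-column realignment-parameter TSV
#' @param path File with columns x_mm, y_mm, z_mm, pitch_rad, roll_rad,
#'   yaw_rad (header optional; six numeric columns required).
#' @return A `motion_trace` matrix.
#' @export
read_motion_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  m <- as.matrix(read.table(path, sep = "\t", header = has_header))
  if (ncol(m) != 6) stop("motion table must have exactly 6 columns")
  dimnames(m) <- list(NULL, c("x_mm", "y_mm", "z_mm",
                              "pitch_rad", "roll_rad", "yaw_rad"))
  structure(m, class = c("motion_trace", "matrix", "array"))
}
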