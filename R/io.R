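#' Read and write trajectory CSV files
#'
#' Trajectories are exchanged as plain CSV with columns `t`, `x`, `y`
#' (seconds / cm); metadata travels in the trial table, keyed by
#' participant, day, phase and trial number.
#'
#' @param trajectory A `trajectory` (or data.frame with `t`, `x`, `y`).
#' @param path File path.
#' @return `read_trajectory_csv()` returns a `trajectory` data.frame;
#'   `write_trajectory_csv()` returns `path` invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(trajectory[, c("t", "x", "y")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("t", "x", "y") %in% names(d)))
    stop("trajectory CSV needs columns t, x, y")
  class(d) <- c("trajectory", "data.frame")
  d
}
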