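#' Target layout for the sequential reaching task
#'
#' Builds the workspace geometry: a central via target at the origin with
#' four outer targets. Targets 1 and 4 lie on the y-axis at +/- 10 cm; targets
#' 2 and 3 lie at 5 cm from the via target with 126 degrees between them,
#' symmetric about the y-axis. All targets are 1 cm diameter discs; the start
#' box is a 2 x 2 cm square centred on the via target and the preparation box
#' sits to the left of the workspace.
#'
#' @param target_diameter Target disc diameter in cm.
#' @param start_box_side Side of the square start box in cm.
#' @param prep_box_side Side of the square preparation box in cm.
#' @return An object of class `target_layout`: a list with `via` (2-vector),
#'   `targets` (4 x 2 matrix, cm), `target_diameter`, `start_box_side`,
#'   `prep_box_side`.
#' @examples
#' lay <- make_target_layout()
#' sqrt(sum(lay$targets[1, ]^2)) # 10 cm
#' @export
make_target_layout <- function(target_diameter = 1, start_box_side = 2,
                               prep_box_side = 2) {
  ang <- 126 / 2 * pi / 180 # half-angle from y-axis for targets 2 and 3
  targets <- rbind(
    t1 = c(0, 10),
    t2 = 5 * c(-sin(ang), cos(ang)),
    t3 = 5 * c(sin(ang), cos(ang)),
    t4 = c(0, -10)
  )
  colnames(targets) <- c("x", "y")
  structure(
    list(
      via = c(x = 0, y = 0),
      targets = targets,
      target_diameter = target_diameter,
      start_box_side = start_box_side,
      prep_box_side = prep_box_side
    ),
    class = "target_layout"
  )
}

#' @export
print.target_layout <- function(x, ...) {
  cat("Sequential reaching target layout\n")
  cat(sprintf("  via target at (%.1f, %.1f) cm, target diameter %.1f cm\n",
              x$via[1], x$via[2], x$target_diameter))
  for (i in seq_len(nrow(x$targets))) {
    cat(sprintf("  T%d at (%6.2f, %6.2f) cm, |T%d - via| = %.2f cm\n",
                i, x$targets[i, 1], x$targets[i, 2], i,
                sqrt(sum((x$targets[i, ] - x$via)^2))))
  }
  invisible(x)
}

# Visit order of target centres for one trial: out-and-back to each outer
# target through the via point, eight movements ending on the via target.
#' Ordered target centres visited in one trial
#'
#' Returns the 8 target centres crossed during the 8 reaching movements of a
#' trial, in order: T1, via, T2, via, T3, via, T4, via (the start position,
#' the via target, precedes the first).
#'
#' @param layout A `target_layout`.
#' @param outer_order Permutation of 1:4 giving the order in which the outer
#'   targets are visited.
#' @return 8 x 2 matrix of target centres (cm), rownames identify targets.
#' @export
trial_sequence <- function(layout = make_target_layout(), outer_order = 1:4) {
  stopifnot(length(outer_order) == 4, setequal(outer_order, 1:4))
  seq_pts <- matrix(NA_real_, 8, 2, dimnames = list(NULL, c("x", "y")))
  nm <- character(8)
  for (i in 1:4) {
    seq_pts[2 * i - 1, ] <- layout$targets[outer_order[i], ]
    seq_pts[2 * i, ] <- layout$via
    nm[2 * i - 1] <- rownames(layout$targets)[outer_order[i]]
    nm[2 * i] <- "via"
  }
  rownames(seq_pts) <- nm
  seq_pts
}
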