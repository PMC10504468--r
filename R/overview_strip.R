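# Overview strip: per (nucleotide position x time point) color grid of the
# most occupied structure, laid out on the composite time axis.

#' Build the overview color matrix
#'
#' For every time point of the trajectory, takes the most occupied structure
#' (ties broken by ascending id), computes its per-nucleotide colors and pads
#' positions beyond the current transcript length with the background color.
#' Each column occupies the half-open x interval from its own time point to
#' the next (step-function convention; the last column extends to x = 1), so
#' the columns tile `[x(t_first), 1]` without gaps or overlaps. Reading the
#' strip left to right shows where the dominant structure changes.
#'
#' @param traj A non-empty (typically occupancy-filtered) `fold_trajectory`.
#' @param axis A `time_axis` for the same trajectory.
#' @param unpaired Color of unpaired nucleotides.
#' @param background Color of not-yet-transcribed positions.
#' @return An `overview_matrix`: list with `colors` (`max_length` x n_times
#'   character matrix of hex colors; row 1 is the 5' end), `times`,
#'   `dominant_id`, `x_left`, `x_right`, `max_length` and `background`.
#' @export
build_overview <- function(traj, axis, unpaired = unpaired_color(),
                           background = "#FFFFFF") {
  stopifnot(inherits(traj, "fold_trajectory"), inherits(axis, "time_axis"))
  if (!length(traj$times))
    stop("trajectory has no time points", call. = FALSE)
  nt <- length(traj$times)
  cols <- matrix(background, nrow = traj$max_length, ncol = nt)
  dom <- integer(nt)
  for (k in seq_len(nt)) {
    recs <- traj$records[traj$records$time == traj$times[k], , drop = FALSE]
    recs <- recs[order(-recs$occupancy, recs$id), , drop = FALSE]
    dom[k] <- recs$id[1L]
    nuc <- nucleotide_colors(parse_dotbracket(recs$structure[1L]),
                             unpaired = unpaired)
    cols[seq_along(nuc), k] <- nuc
  }
  x <- time_to_x(axis, traj$times)
  structure(list(colors = cols, times = traj$times, dominant_id = dom,
                 x_left = x, x_right = c(x[-1L], 1),
                 max_length = traj$max_length, background = background),
            class = "overview_matrix")
}

#' @export
print.overview_matrix <- function(x, ...) {
  cat(sprintf("<overview_matrix> %d positions x %d time points\n",
              x$max_length, length(x$times)))
  invisible(x)
}
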