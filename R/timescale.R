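# Composite linear/logarithmic time axis.
#
# The horizontal axis devotes a fixed 75% of its width to the (often
# comparatively short) cotranscriptional phase on a linear scale, and the
# remaining 25% to the post-transcriptional phase on a logarithmic scale,
# with the end of transcription pinned at x = 0.75.

.axis_split <- 0.75

#' Build the composite time axis
#'
#' Maps simulation time to a horizontal fraction in `[0, 1]`: 0 at the first
#' displayed time point, 0.75 at the end of transcription (linear in
#' between), 1 at the last time point (logarithmic after the end of
#' transcription). Degenerate trajectories fall back gracefully: if the
#' simulation stops when transcription ends the axis is fully linear; if no
#' transcript growth is observed the axis is fully logarithmic starting at
#' the first positive time point; a single time point maps everything to 1.
#'
#' @param traj Either a `fold_trajectory` (the axis is derived from its time
#'   points and [transcription_end_time()]), or the numeric start time `t0`.
#' @param t_end,t_max End-of-transcription and final simulation times, only
#'   when `traj` is numeric.
#' @return A `time_axis`: list with `t0`, `t_end`, `t_max`, `split` (0.75)
#'   and `mode` (`"composite"`, `"linear"`, `"log"` or `"point"`).
#' @examples
#' ax <- time_axis(0, 1, 100)
#' time_to_x(ax, 1) # 0.75
#' @export
time_axis <- function(traj, t_end = NULL, t_max = NULL) {
  if (inherits(traj, "fold_trajectory")) {
    if (!length(traj$times))
      stop("trajectory has no time points", call. = FALSE)
    t0 <- traj$times[1L]
    te <- transcription_end_time(traj)
    tm <- traj$times[length(traj$times)]
    if (te == t0 && tm > te && t0 <= 0) {
      # no observed growth and the file starts at t = 0: log scale needs a
      # positive anchor, so start at the first positive time point
      pos <- traj$times[traj$times > 0]
      if (!length(pos))
        stop("cannot build a log axis: no positive time points", call. = FALSE)
      t0 <- te <- pos[1L]
    }
    return(time_axis(t0, te, tm))
  }
  t0 <- traj
  if (!is.numeric(t0) || !is.numeric(t_end) || !is.numeric(t_max) ||
      any(!is.finite(c(t0, t_end, t_max))))
    stop("axis times must be finite numbers", call. = FALSE)
  if (!(t0 <= t_end && t_end <= t_max))
    stop("axis times must satisfy t0 <= t_end <= t_max", call. = FALSE)
  mode <- if (t0 < t_end && t_end < t_max) "composite"
  else if (t_end == t_max && t0 < t_max) "linear"
  else if (t0 == t_end && t_end < t_max) "log"
  else "point"
  if (mode == "log" && t0 <= 0)
    stop("a fully logarithmic axis requires t0 > 0", call. = FALSE)
  if (mode == "composite" && t_end <= 0)
    stop("the logarithmic segment requires t_end > 0", call. = FALSE)
  structure(list(t0 = t0, t_end = t_end, t_max = t_max,
                 split = .axis_split, mode = mode),
            class = "time_axis")
}

#' Map simulation time to axis fraction
#'
#' Linear from `t0` to `t_end` over `[0, 0.75]`, then logarithmic from
#' `t_end` to `t_max` over `[0.75, 1]`:
#' `x = 0.75 (t - t0) / (t_end - t0)` for `t <= t_end`, and
#' `x = 0.75 + 0.25 log(t / t_end) / log(t_max / t_end)` beyond. Strictly
#' increasing on `[t0, t_max]`. Times outside the range are clamped with a
#' warning.
#'
#' @param axis A `time_axis`.
#' @param t Time(s) in seconds.
#' @return Fraction(s) in `[0, 1]`.
#' @export
time_to_x <- function(axis, t) {
  stopifnot(inherits(axis, "time_axis"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("`t` must be finite", call. = FALSE)
  if (any(t < axis$t0 | t > axis$t_max)) {
    warning("time(s) outside [t0, t_max] clamped to the axis range",
            call. = FALSE)
    t <- pmin(pmax(t, axis$t0), axis$t_max)
  }
  switch(axis$mode,
    composite = {
      x <- ifelse(t <= axis$t_end,
                  axis$split * (t - axis$t0) / (axis$t_end - axis$t0),
                  axis$split + (1 - axis$split) *
                    log(t / axis$t_end) / log(axis$t_max / axis$t_end))
      as.numeric(x)
    },
    linear = (t - axis$t0) / (axis$t_max - axis$t0),
    log = log(t / axis$t0) / log(axis$t_max / axis$t0),
    point = rep(1, length(t))
  )
}

#' Map axis fraction back to simulation time
#'
#' Exact inverse of [time_to_x()] on `[0, 1]`; round-trips within 1e-9
#' relative error. Supports cursor semantics: an x position under the mouse
#' corresponds to a unique simulation time.
#'
#' @param axis A `time_axis`.
#' @param x Fraction(s) in `[0, 1]`.
#' @return Time(s) in seconds.
#' @export
x_to_time <- function(axis, x) {
  stopifnot(inherits(axis, "time_axis"))
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1))
    stop("`x` must lie in [0, 1]", call. = FALSE)
  switch(axis$mode,
    composite = {
      t <- ifelse(x <= axis$split,
                  axis$t0 + (x / axis$split) * (axis$t_end - axis$t0),
                  axis$t_end *
                    (axis$t_max / axis$t_end)^((x - axis$split) / (1 - axis$split)))
      as.numeric(t)
    },
    linear = axis$t0 + x * (axis$t_max - axis$t0),
    log = axis$t0 * (axis$t_max / axis$t0)^x,
    point = rep(axis$t_max, length(x))
  )
}

#' Tick positions for a composite time axis
#'
#' Cosmetic helper for the renderer: evenly spaced ticks on the linear
#' segment, decade ticks on the logarithmic segment.
#'
#' @param axis A `time_axis`.
#' @param n_linear Target number of linear-segment ticks.
#' @return A data frame with columns `time`, `x` and `label`.
#' @export
axis_ticks <- function(axis, n_linear = 5) {
  stopifnot(inherits(axis, "time_axis"))
  if (axis$mode == "point")
    return(data.frame(time = axis$t_max, x = 1,
                      label = format(axis$t_max, digits = 3)))
  lin_hi <- if (axis$mode == "log") axis$t0 else axis$t_end
  tt <- if (axis$mode == "log") numeric(0) else {
    p <- pretty(c(axis$t0, lin_hi), n = n_linear)
    p[p >= axis$t0 & p <= lin_hi]
  }
  if (axis$mode != "linear") {
    lo <- if (axis$mode == "log") axis$t0 else axis$t_end
    dec <- 10^seq(ceiling(log10(lo)), floor(log10(axis$t_max)))
    tt <- c(tt, dec[dec > lo & dec <= axis$t_max], axis$t_max)
  }
  tt <- sort(unique(tt))
  data.frame(time = tt, x = time_to_x(axis, tt),
             label = format(tt, digits = 3, trim = TRUE))
}

#' @export
print.time_axis <- function(x, ...) {
  cat(sprintf("<time_axis> mode %s: t0 = %s, t_end = %s (x = %.2f), t_max = %s\n",
              x$mode, format(x$t0, digits = 6), format(x$t_end, digits = 6),
              if (x$mode == "point") 1 else time_to_x(x, x$t_end),
              format(x$t_max, digits = 6)))
  invisible(x)
}
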