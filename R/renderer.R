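# SVG composition: treemap of structure drawings + overview strip on the
# composite time axis, single frames and frame series.

.svg_ns <- "http://www.w3.org/2000/svg"
.num <- function(x) sprintf("%.3f", x)

#' Rendering configuration
#'
#' @param min_occupancy Occupancy threshold applied before rendering
#'   (default 0.01: with per-time-point sums of at most 1, at most 100
#'   structures can pass at any time point).
#' @param speed Animation frame rate in frames per second.
#' @param width,height Canvas size in pixels.
#' @param seed Seed forwarded to [layout_structure()] so repeated renders
#'   are byte-identical.
#' @param unpaired Color of unpaired nucleotides.
#' @param background Canvas and not-yet-transcribed color.
#' @return A `render_config` list.
#' @export
render_config <- function(min_occupancy = 0.01, speed = 2, width = 800,
                          height = 600, seed = 1L,
                          unpaired = unpaired_color(),
                          background = "#FFFFFF") {
  if (!is.numeric(min_occupancy) || min_occupancy < 0 || min_occupancy > 1)
    stop("`min_occupancy` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(speed) || speed <= 0)
    stop("`speed` must be > 0 frames per second", call. = FALSE)
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0)
    stop("canvas dimensions must be positive", call. = FALSE)
  structure(list(min_occupancy = min_occupancy, speed = speed,
                 width = width, height = height, seed = as.integer(seed),
                 unpaired = unpaired, background = background),
            class = "render_config")
}

.add <- function(parent, name, ..., text = NULL) {
  node <- xml2::xml_add_child(parent, name)
  attrs <- list(...)
  if (length(attrs)) {
    for (nm in names(attrs)) xml2::xml_set_attr(node, nm, as.character(attrs[[nm]]))
  }
  if (!is.null(text)) xml2::xml_set_text(node, text)
  node
}

# One structure drawing inside a treemap tile.
.draw_structure <- function(g, struct, tile, seed, sequence, unpaired) {
  pt <- parse_dotbracket(struct)
  lay <- layout_structure(pt, seed = seed)
  sc <- scale_layout(lay, tile$x, tile$y, tile$w, tile$h)
  xy <- sc$coords
  r <- min(max(0.35 * sc$scale, 0.6), 9)
  if (pt$n > 1L) {
    pts <- paste(sprintf("%.3f,%.3f", xy[, 1L], xy[, 2L]), collapse = " ")
    .add(g, "polyline", points = pts, fill = "none", stroke = "#999999",
         "stroke-width" = .num(max(0.12 * sc$scale, 0.3)), class = "backbone")
  }
  pr <- base_pairs(pt)
  if (nrow(pr)) {
    hex <- .hue_to_hex(hue_for_center(pr$center))
    for (q in seq_len(nrow(pr))) {
      .add(g, "line", x1 = .num(xy[pr$i[q], 1L]), y1 = .num(xy[pr$i[q], 2L]),
           x2 = .num(xy[pr$j[q], 1L]), y2 = .num(xy[pr$j[q], 2L]),
           stroke = hex[q], "stroke-width" = .num(max(0.5 * r, 0.4)),
           class = "basepair")
    }
  }
  nuc <- nucleotide_colors(pt, unpaired = unpaired)
  for (p in seq_len(pt$n)) {
    .add(g, "circle", cx = .num(xy[p, 1L]), cy = .num(xy[p, 2L]),
         r = .num(r), fill = nuc[p], class = "nucleotide")
  }
  if (!is.null(sequence) && r >= 4) {
    letters <- strsplit(substr(sequence, 1L, pt$n), "", fixed = TRUE)[[1L]]
    for (p in seq_len(pt$n)) {
      .add(g, "text", x = .num(xy[p, 1L]), y = .num(xy[p, 2L] + 0.35 * r),
           "text-anchor" = "middle", "font-size" = .num(1.1 * r),
           "font-family" = "monospace", fill = "#000000",
           class = "nucleotide-letter", text = letters[p])
    }
  }
}

#' Render one composite frame as SVG
#'
#' Produces a standalone SVG: the top panel holds the occupancy treemap of
#' the displayed structures at the selected time point, each tile containing
#' one colored structure drawing; the bottom panel shows the overview strip
#' of dominant-structure nucleotide colors on the composite time axis, with
#' a black vertical line at 75% of the axis width marking the end of
#' transcription and a red cursor at the selected time point. The current
#' time and the sum of displayed occupancies (four decimals) are annotated.
#'
#' The occupancy filter is applied internally, so rendering a pre-filtered
#' trajectory and filtering on the fly give identical output. Rendering is
#' fully deterministic: equal inputs, time and seed yield byte-identical
#' documents.
#'
#' @param traj A `fold_trajectory`.
#' @param t Time point to display (seconds); snapped to the nearest previous
#'   simulation time point, clamped to the time range with a warning.
#' @param cfg A [render_config()].
#' @return An `xml_document` (SVG 1.1); write it with [write_svg()].
#' @export
render_frame <- function(traj, t, cfg = render_config()) {
  stopifnot(inherits(traj, "fold_trajectory"))
  if (!inherits(cfg, "render_config"))
    stop("`cfg` must be a render_config", call. = FALSE)
  ftraj <- filter_by_occupancy(traj, cfg$min_occupancy)
  if (!length(ftraj$times))
    stop("no time points remain after occupancy filtering", call. = FALSE)
  if (t < min(ftraj$times) || t > max(ftraj$times)) {
    warning("requested time is outside the displayed range; clamped",
            call. = FALSE)
    t <- min(max(t, min(ftraj$times)), max(ftraj$times))
  }
  slice <- slice_at_time(ftraj, t)
  axis <- time_axis(ftraj)
  ov <- build_overview(ftraj, axis, unpaired = cfg$unpaired,
                       background = cfg$background)

  W <- cfg$width
  H <- cfg$height
  tm <- list(x = 10, y = 10, w = W - 20, h = 0.60 * H - 20)
  st <- list(x = 45, y = 0.66 * H, w = W - 90, h = 0.22 * H)

  doc <- xml2::xml_new_root("svg", xmlns = .svg_ns, version = "1.1",
                            width = .num(W), height = .num(H),
                            viewBox = paste("0 0", .num(W), .num(H)))
  .add(doc, "rect", x = "0", y = "0", width = .num(W), height = .num(H),
       fill = cfg$background, class = "canvas")

  # top panel: occupancy treemap of structure drawings
  tiles <- layout_treemap(slice, tm$w, tm$h)
  disp <- slice$records[slice$records$occupancy > 0, , drop = FALSE]
  gmap <- .add(doc, "g", class = "treemap")
  for (k in seq_len(nrow(tiles))) {
    tile <- list(x = tm$x + tiles$x[k], y = tm$y + tiles$y[k],
                 w = tiles$w[k], h = tiles$h[k])
    g <- .add(gmap, "g", class = "treemap-tile",
              "data-id" = tiles$id[k],
              "data-occupancy" = sprintf("%.6f", tiles$value[k]))
    .add(g, "rect", x = .num(tile$x), y = .num(tile$y),
         width = .num(tile$w), height = .num(tile$h),
         fill = "none", stroke = "#444444", "stroke-width" = "1",
         class = "tile-border")
    rec <- disp[k, ]
    .draw_structure(g, rec$structure, tile, cfg$seed, traj$sequence,
                    cfg$unpaired)
    .add(g, "text", x = .num(tile$x + 3), y = .num(tile$y + 11),
         "font-size" = "10", "font-family" = "sans-serif", fill = "#333333",
         class = "tile-label",
         text = sprintf("id %d (%.4f)", rec$id, rec$occupancy))
  }

  # bottom panel: overview strip on the composite time axis
  gov <- .add(doc, "g", class = "overview")
  .add(gov, "rect", x = .num(st$x), y = .num(st$y), width = .num(st$w),
       height = .num(st$h), fill = cfg$background, stroke = "#444444",
       "stroke-width" = "0.5", class = "strip-border")
  cell_h <- st$h / ov$max_length
  for (k in seq_along(ov$times)) {
    cx <- st$x + ov$x_left[k] * st$w
    cw <- (ov$x_right[k] - ov$x_left[k]) * st$w
    if (cw <= 0) next
    for (p in seq_len(ov$max_length)) {
      col <- ov$colors[p, k]
      if (col == ov$background) next
      # 5' end (position 1) at the bottom of the strip
      .add(gov, "rect", x = .num(cx), y = .num(st$y + st$h - p * cell_h),
           width = .num(cw), height = .num(cell_h), fill = col,
           class = "overview-cell")
    }
  }

  # axis ticks
  gax <- .add(doc, "g", class = "axis")
  ticks <- axis_ticks(axis)
  for (k in seq_len(nrow(ticks))) {
    txx <- st$x + ticks$x[k] * st$w
    .add(gax, "line", x1 = .num(txx), y1 = .num(st$y + st$h),
         x2 = .num(txx), y2 = .num(st$y + st$h + 5), stroke = "#000000",
         "stroke-width" = "1", class = "tick")
    .add(gax, "text", x = .num(txx), y = .num(st$y + st$h + 17),
         "text-anchor" = "middle", "font-size" = "10",
         "font-family" = "sans-serif", class = "tick-label",
         text = ticks$label[k])
  }

  # end-of-transcription marker (75% of the axis width on composite axes)
  x_end <- st$x + time_to_x(axis, axis$t_end) * st$w
  .add(doc, "line", id = "transcription-end-marker",
       x1 = .num(x_end), y1 = .num(st$y - 8),
       x2 = .num(x_end), y2 = .num(st$y + st$h + 8),
       stroke = "#000000", "stroke-width" = "1.5")

  # red cursor at the displayed time point
  x_cur <- st$x + time_to_x(axis, slice$time) * st$w
  .add(doc, "line", id = "time-cursor",
       x1 = .num(x_cur), y1 = .num(st$y - 8),
       x2 = .num(x_cur), y2 = .num(st$y + st$h + 8),
       stroke = "#CC0000", "stroke-width" = "1.5")

  # annotations
  .add(doc, "text", x = .num(st$x), y = .num(H - 18), "font-size" = "13",
       "font-family" = "sans-serif", class = "time-label",
       text = sprintf("t = %s s", .fmt_num(slice$time)))
  .add(doc, "text", x = .num(st$x + st$w), y = .num(H - 18),
       "text-anchor" = "end", "font-size" = "13",
       "font-family" = "sans-serif", class = "sum-occupancy",
       text = sprintf("sum of occupancies: %.4f", slice$sum_occupancy))
  doc
}

#' Write an SVG document to a file
#'
#' @param doc An `xml_document` from [render_frame()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_svg <- function(doc, path) {
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Render the whole trajectory as an SVG frame series
#'
#' One frame per displayed (post-filtering) time point, in time order. The
#' frame duration implied by `cfg$speed` is reported in the returned
#' metadata so external tools can assemble the series into an animation.
#'
#' @param traj A `fold_trajectory`.
#' @param cfg A [render_config()].
#' @param outdir Directory for the frame files (created if needed).
#' @param prefix Frame file name prefix.
#' @return A `fold_animation`: list with `files`, `times`, `fps` and
#'   `frame_duration_ms` (`1000 / fps`).
#' @export
render_animation <- function(traj, cfg = render_config(), outdir,
                             prefix = "frame") {
  stopifnot(inherits(traj, "fold_trajectory"))
  ftraj <- filter_by_occupancy(traj, cfg$min_occupancy)
  if (!length(ftraj$times))
    stop("no time points remain after occupancy filtering", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(outdir, sprintf("%s_%04d.svg", prefix,
                                     seq_along(ftraj$times)))
  for (k in seq_along(ftraj$times))
    write_svg(render_frame(ftraj, ftraj$times[k], cfg), files[k])
  structure(list(files = files, times = ftraj$times, fps = cfg$speed,
                 frame_duration_ms = 1000 / cfg$speed),
            class = "fold_animation")
}

#' @export
print.fold_animation <- function(x, ...) {
  cat(sprintf("<fold_animation> %d frames at %g fps (%g ms/frame)\n",
              length(x$files), x$fps, x$frame_duration_ms))
  invisible(x)
}

#' Minimum dwell time of the scrubbing skip rule
#'
#' When scrubbing over the time axis, drawing a frame only pays off if the
#' cursor rests long enough; the threshold grows with the number of
#' structures that would have to be drawn. A time point selected for less
#' than `5 * m` milliseconds is skipped (no frame emitted), where `m` is the
#' maximal number of structures per time point in the file (see
#' [max_structures()]). `m = 0` yields 0 ms: empty time points are never
#' skipped.
#'
#' @param m Non-negative integer count(s) of structures.
#' @return Threshold(s) in milliseconds: `5 * m`.
#' @examples
#' min_dwell_time(20) # 100 ms
#' @export
min_dwell_time <- function(m) {
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0) ||
      any(m != trunc(m)))
    stop("`m` must be non-negative integer(s)", call. = FALSE)
  5 * m
}

#' Maximal number of structures per time point
#'
#' The constant `m` of the skip rule ([min_dwell_time()]), taken over the
#' whole file.
#'
#' @param traj A `fold_trajectory`.
#' @return An integer (0 for an empty trajectory).
#' @export
max_structures <- function(traj) {
  stopifnot(inherits(traj, "fold_trajectory"))
  if (!length(traj$times)) return(0L)
  max(vapply(traj$times,
             function(t) sum(traj$records$time == t), 0L))
}
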