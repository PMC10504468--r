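# Occupancy treemap: tile the structure panel into rectangles with areas
# proportional to occupancy.

# Worst aspect ratio over a strip of areas laid as one vertical column of
# height H (strip width = sum(areas) / H).
.worst_aspect <- function(areas, H) {
  w <- sum(areas) / H
  h <- areas / w
  max(pmax(w / h, h / w))
}

#' Treemap layout of a time slice
#'
#' Tiles the full panel into one rectangle per displayed structure, area
#' proportional to occupancy. Tiles are grouped into vertical strips laid
#' left to right in descending occupancy order; within a strip, tiles stack
#' top to bottom. Strip breaks are chosen greedily to minimize the worst
#' tile aspect ratio (squarified-strip treemap), while the left-to-right
#' strip order guarantees that tile left edges never decrease as occupancy
#' decreases -- the most occupied structure is always leftmost.
#'
#' The tiling is relative: tiles always fill the whole panel regardless of
#' how much of the ensemble is displayed; the displayed fraction is reported
#' separately as the sum of occupancies.
#'
#' @param slice A `time_slice` (records sorted by descending occupancy), or
#'   a numeric vector of occupancies (sorted internally).
#' @param panel_w,panel_h Panel dimensions in drawing units (> 0); origin is
#'   the top-left corner, y grows downward.
#' @return A data frame with one row per tile: `id`, `value` (occupancy),
#'   `x`, `y`, `w`, `h`. Zero rows for an empty slice.
#' @export
layout_treemap <- function(slice, panel_w, panel_h) {
  if (!is.numeric(panel_w) || !is.numeric(panel_h) ||
      panel_w <= 0 || panel_h <= 0)
    stop("panel dimensions must be positive", call. = FALSE)
  if (inherits(slice, "time_slice")) {
    vals <- slice$records$occupancy
    ids <- slice$records$id
  } else if (is.numeric(slice)) {
    ord <- order(-slice, seq_along(slice))
    vals <- slice[ord]
    ids <- ord
  } else {
    stop("`slice` must be a time_slice or a numeric vector", call. = FALSE)
  }
  keep <- vals > 0
  vals <- vals[keep]
  ids <- ids[keep]
  empty <- data.frame(id = integer(), value = numeric(), x = numeric(),
                      y = numeric(), w = numeric(), h = numeric())
  if (!length(vals)) {
    if (length(keep)) stop("total occupancy is zero", call. = FALSE)
    return(empty)
  }
  areas <- vals / sum(vals) * panel_w * panel_h
  n <- length(areas)
  out <- vector("list", n)
  x <- 0
  i <- 1L
  while (i <= n) {
    k <- 1L
    worst <- .worst_aspect(areas[i], panel_h)
    while (i + k <= n) {
      cand <- .worst_aspect(areas[i:(i + k)], panel_h)
      if (cand <= worst) {
        worst <- cand
        k <- k + 1L
      } else break
    }
    strip <- areas[i:(i + k - 1L)]
    sw <- sum(strip) / panel_h
    y <- 0
    for (s in seq_along(strip)) {
      h <- strip[s] / sw
      out[[i + s - 1L]] <- data.frame(id = ids[i + s - 1L],
                                      value = vals[i + s - 1L],
                                      x = x, y = y, w = sw, h = h)
      y <- y + h
    }
    x <- x + sw
    i <- i + k
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
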