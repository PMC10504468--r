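# Deterministic 2D layout of a secondary-structure graph: radial nested-loop
# initialization followed by a fixed number of seeded spring-relaxation
# iterations. Legibility and bitwise reproducibility are the goals here, not
# replication of any particular drawing engine's coordinates.

# Run code with a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  force(code)
}

# Items (unpaired bases / helices) along the region [lo, hi], using only the
# nesting layer pairs in `partner0`.
.scan_items <- function(partner0, lo, hi) {
  items <- list()
  k <- lo
  while (k <= hi) {
    p <- partner0[k]
    if (!is.na(p) && p > k && p <= hi) {
      h <- 1L
      while (!is.na(partner0[k + h]) && partner0[k + h] == p - h &&
             p - h > k + h) h <- h + 1L
      items[[length(items) + 1L]] <- list(type = "helix", i = k, j = p, len = h)
      k <- p + 1L
    } else {
      items[[length(items) + 1L]] <- list(type = "base", pos = k)
      k <- k + 1L
    }
  }
  items
}

.n_slots <- function(items) {
  if (!length(items)) return(0L)
  sum(vapply(items, function(it) if (it$type == "helix") 2L else 1L, 1L))
}

.loop_radius <- function(nslots, bb) {
  m <- max(nslots, 2L)
  max(m * bb / (2 * pi), bb / (2 * sin(pi / m)))
}

# Radial construction: every loop is a circle whose circumference allots one
# slot per unpaired base and two per emerging helix; helices leave their loop
# as parallel rails of stacked pairs. Pseudoknot layers are ignored here.
.radial_init <- function(partner0, n, bb = 1) {
  coords <- matrix(0, n, 2)
  place_loop <- function(i, j, center, theta_in, closed) {
    lo <- if (closed) i + 1L else i
    hi <- if (closed) j - 1L else j
    items <- if (lo <= hi) .scan_items(partner0, lo, hi) else list()
    nslots <- .n_slots(items) + if (closed) 2L else 0L
    if (nslots == 0L) return(invisible())
    r <- .loop_radius(nslots, bb)
    # closed loops reserve slots 0 and nslots-1, straddling theta_in, for
    # the (already placed) closing pair
    slot_angle <- function(t) theta_in + 2 * pi * (t + 0.5) / nslots
    t <- if (closed) 1L else 0L
    for (it in items) {
      if (it$type == "base") {
        a <- slot_angle(t)
        coords[it$pos, ] <<- center + r * c(cos(a), sin(a))
        t <- t + 1L
      } else {
        a1 <- slot_angle(t)
        a2 <- slot_angle(t + 1L)
        A <- center + r * c(cos(a1), sin(a1))
        B <- center + r * c(cos(a2), sin(a2))
        amid <- (a1 + a2) / 2
        u <- c(cos(amid), sin(amid))
        for (p in seq_len(it$len) - 1L) {
          coords[it$i + p, ] <<- A + p * bb * u
          coords[it$j - p, ] <<- B + p * bb * u
        }
        ii <- it$i + it$len - 1L
        jj <- it$j - it$len + 1L
        if (jj - ii > 1L) {
          child_items <- .scan_items(partner0, ii + 1L, jj - 1L)
          cr <- .loop_radius(.n_slots(child_items) + 2L, bb)
          M <- (coords[ii, ] + coords[jj, ]) / 2
          w <- sqrt(sum((coords[ii, ] - coords[jj, ])^2))
          dd <- sqrt(max(cr^2 - (w / 2)^2, 0))
          place_loop(ii, jj, M + dd * u, atan2(-u[2], -u[1]), closed = TRUE)
        }
        t <- t + 2L
      }
    }
    invisible()
  }
  place_loop(1L, n, c(0, 0), pi / 2, closed = FALSE)
  coords
}

# Fixed-iteration spring relaxation: backbone and pair edges are springs at
# rest length bb; all node pairs repel with an inverse-square force. The step
# size cools linearly, so the result is a pure deterministic function of the
# starting coordinates.
.relax_layout <- function(coords, edges, bb, n_iter) {
  n <- nrow(coords)
  if (n < 2L || n_iter < 1L) return(coords)
  kspr <- 0.5
  krep <- 0.05 * bb^2
  temps <- seq(0.15 * bb, 0.01 * bb, length.out = n_iter)
  a <- edges[, 1L]
  b <- edges[, 2L]
  for (it in seq_len(n_iter)) {
    dx <- outer(coords[, 1L], coords[, 1L], "-")
    dy <- outer(coords[, 2L], coords[, 2L], "-")
    d2 <- dx * dx + dy * dy
    d2[d2 < 1e-8] <- 1e-8
    d3 <- d2 * sqrt(d2)
    fx <- rowSums(krep * dx / d3)
    fy <- rowSums(krep * dy / d3)
    ex <- coords[a, 1L] - coords[b, 1L]
    ey <- coords[a, 2L] - coords[b, 2L]
    ed <- sqrt(ex^2 + ey^2)
    ed[ed < 1e-8] <- 1e-8
    f <- kspr * (ed - bb)
    sx <- f * ex / ed
    sy <- f * ey / ed
    agx <- rowsum(c(-sx, sx), c(a, b))
    agy <- rowsum(c(-sy, sy), c(a, b))
    nodes <- as.integer(rownames(agx))
    fx[nodes] <- fx[nodes] + agx[, 1L]
    fy[nodes] <- fy[nodes] + agy[, 1L]
    fm <- sqrt(fx^2 + fy^2)
    fm[fm < 1e-12] <- 1e-12
    step <- pmin(fm, temps[it])
    coords[, 1L] <- coords[, 1L] + fx / fm * step
    coords[, 2L] <- coords[, 2L] + fy / fm * step
  }
  coords
}

#' Deterministic 2D layout of a secondary structure
#'
#' Produces one coordinate per nucleotide from a nested-loop radial
#' construction (loops drawn as circles, helices as parallel rails), refined
#' by a fixed number of spring-relaxation iterations: backbone and base-pair
#' edges act as unit-length springs, all nodes repel. A small seeded jitter
#' breaks symmetric degeneracies; the same pair table and seed always yield
#' bitwise-identical coordinates. Pseudoknotted pairs (bracket layers beyond
#' the first) contribute springs during relaxation but do not take part in
#' the radial nesting, so knotted structures stay drawable.
#'
#' @param pt A `pair_table`.
#' @param seed Integer seed for the jitter (the caller's RNG state is
#'   preserved).
#' @param iterations Number of relaxation iterations.
#' @return A `structure_layout`: list with `coords` (n x 2 matrix) and
#'   `bbox` (`xmin`, `ymin`, `xmax`, `ymax`).
#' @export
layout_structure <- function(pt, seed = 1L, iterations = 200L) {
  stopifnot(inherits(pt, "pair_table"))
  n <- pt$n
  bb <- 1
  partner0 <- ifelse(!is.na(pt$layer) & pt$layer == 0L, pt$partner,
                     NA_integer_)
  coords <- if (n == 1L) matrix(0, 1L, 2L) else .radial_init(partner0, n, bb)
  if (n > 1L) {
    coords <- coords + .with_seed(seed,
      matrix(stats::runif(2L * n, -0.01, 0.01) * bb, n, 2L))
    pr <- base_pairs(pt)
    edges <- rbind(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L),
                   if (nrow(pr)) cbind(pr$i, pr$j))
    coords <- .relax_layout(coords, edges, bb, as.integer(iterations))
  }
  structure(list(coords = coords,
                 bbox = c(xmin = min(coords[, 1L]), ymin = min(coords[, 2L]),
                          xmax = max(coords[, 1L]), ymax = max(coords[, 2L]))),
            class = "structure_layout")
}

#' Fit a structure layout into a rectangle
#'
#' Uniformly scales and centers the coordinates into the target rectangle,
#' preserving the aspect ratio (no distortion), with a fractional padding
#' margin on every side.
#'
#' @param layout A `structure_layout`.
#' @param x,y,w,h Target rectangle (origin top-left, y down).
#' @param pad Fraction of the rectangle kept as margin on each side.
#' @return A list with `coords` (scaled n x 2 matrix) and `scale` (units per
#'   layout unit; use it to size markers consistently).
#' @export
scale_layout <- function(layout, x, y, w, h, pad = 0.08) {
  stopifnot(inherits(layout, "structure_layout"), w > 0, h > 0,
            pad >= 0, pad < 0.5)
  bw <- layout$bbox["xmax"] - layout$bbox["xmin"]
  bh <- layout$bbox["ymax"] - layout$bbox["ymin"]
  avail_w <- w * (1 - 2 * pad)
  avail_h <- h * (1 - 2 * pad)
  s <- if (bw <= 0 && bh <= 0) 1
  else min(if (bw > 0) avail_w / bw else Inf,
           if (bh > 0) avail_h / bh else Inf)
  cx <- (layout$bbox["xmin"] + layout$bbox["xmax"]) / 2
  cy <- (layout$bbox["ymin"] + layout$bbox["ymax"]) / 2
  out <- layout$coords
  out[, 1L] <- x + w / 2 + (out[, 1L] - cx) * s
  out[, 2L] <- y + h / 2 + (out[, 2L] - cy) * s
  list(coords = unname(out), scale = unname(s))
}
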