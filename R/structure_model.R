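# Dot-bracket parsing, helices and imaginary centers.

# Bracket layers: 0 = "()", 1 = "[]", 2 = "{}", 3 = "<>".
.db_open  <- c("(" = 0L, "[" = 1L, "{" = 2L, "<" = 3L)
.db_close <- c(")" = 0L, "]" = 1L, "}" = 2L, ">" = 3L)

#' Parse a dot-bracket string into a pair table
#'
#' Matches brackets with an independent stack per bracket layer, so crossing
#' (pseudoknotted) pairs are representable as long as each layer is balanced
#' on its own. Recognized characters are `.` for unpaired positions and the
#' bracket alphabets `()`, `[]`, `{}` and `<>` (layers 0 to 3). Positions are
#' 1-based.
#'
#' @param s A single non-empty dot-bracket string.
#' @return An object of class `pair_table`: a list with elements
#'   `n` (structure length), `partner` (integer vector; `partner[i]` is the
#'   pairing partner of position `i`, or `NA` if unpaired) and `layer`
#'   (integer vector; bracket layer of the pair at position `i`, or `NA`).
#' @examples
#' pt <- parse_dotbracket("((..[[..))..]]")
#' pt$partner
#' @seealso [helices()], [serialize_dotbracket()]
#' @export
parse_dotbracket <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s))
    stop("`s` must be a single dot-bracket string", call. = FALSE)
  if (!nzchar(s))
    stop("dot-bracket string is empty", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  partner <- rep(NA_integer_, n)
  layer <- rep(NA_integer_, n)
  stacks <- rep(list(integer()), 4L)
  for (k in seq_len(n)) {
    ch <- chars[k]
    if (ch == ".") next
    if (ch %in% names(.db_open)) {
      l <- .db_open[[ch]]
      stacks[[l + 1L]] <- c(stacks[[l + 1L]], k)
    } else if (ch %in% names(.db_close)) {
      l <- .db_close[[ch]]
      st <- stacks[[l + 1L]]
      if (!length(st))
        stop(sprintf("unmatched '%s' at position %d", ch, k), call. = FALSE)
      i <- st[length(st)]
      stacks[[l + 1L]] <- st[-length(st)]
      partner[i] <- k
      partner[k] <- i
      layer[i] <- l
      layer[k] <- l
    } else {
      stop(sprintf("unknown character '%s' at position %d", ch, k),
           call. = FALSE)
    }
  }
  for (l in 0:3) {
    st <- stacks[[l + 1L]]
    if (length(st))
      stop(sprintf("unmatched '%s' at position %d",
                   names(.db_open)[match(l, .db_open)], st[1L]),
           call. = FALSE)
  }
  structure(list(n = n, partner = partner, layer = layer),
            class = "pair_table")
}

#' Re-emit the dot-bracket string of a pair table
#'
#' Inverse of [parse_dotbracket()]: each pair is written with the bracket
#' alphabet of its layer, unpaired positions as dots.
#'
#' @param pt A `pair_table`.
#' @return A dot-bracket string.
#' @export
serialize_dotbracket <- function(pt) {
  stopifnot(inherits(pt, "pair_table"))
  out <- rep(".", pt$n)
  for (i in seq_len(pt$n)) {
    j <- pt$partner[i]
    if (!is.na(j) && j > i) {
      l <- pt$layer[i]
      out[i] <- names(.db_open)[match(l, .db_open)]
      out[j] <- names(.db_close)[match(l, .db_close)]
    }
  }
  paste(out, collapse = "")
}

#' Base pairs of a pair table
#'
#' @param pt A `pair_table`.
#' @return A data frame with columns `i`, `j` (`i < j`), `layer` and `center`
#'   (the imaginary center `(i + j) / 2`), ordered by `i`.
#' @export
base_pairs <- function(pt) {
  stopifnot(inherits(pt, "pair_table"))
  i <- which(!is.na(pt$partner) & pt$partner > seq_len(pt$n))
  data.frame(i = i, j = pt$partner[i], layer = pt$layer[i],
             center = (i + pt$partner[i]) / 2)
}

#' Imaginary center of a base pair
#'
#' The imaginary center of a pair (i, j) is the sequence-coordinate midpoint
#' `(i + j) / 2`, a half-integer. All pairs of a perfect (unbulged) helix
#' share one center; the smallest possible shift between helices, e.g. across
#' a 1-nt bulge, is 0.5.
#'
#' @param i,j 1-based paired positions with `i < j`.
#' @return `(i + j) / 2`, exact half-integer arithmetic.
#' @examples
#' imaginary_center(25, 38) # 31.5
#' @export
imaginary_center <- function(i, j) {
  if (!all(is.finite(i)) || !all(is.finite(j)) || any(i < 1) || any(i >= j))
    stop("positions must satisfy 1 <= i < j", call. = FALSE)
  (i + j) / 2
}

#' Decompose a structure into helices
#'
#' A helix is a maximal run of directly stacked pairs (i, j), (i+1, j-1), ...
#' within one bracket layer; any interruption (bulge, internal loop, layer
#' change) starts a new helix. Every pair belongs to exactly one helix.
#'
#' @param pt A `pair_table`.
#' @return A list of objects of class `rna_helix`, each a list with a data
#'   frame `pairs` (columns `i`, `j`, `layer`) and the numeric vector
#'   `centers` of per-pair imaginary centers.
#' @export
helices <- function(pt) {
  pr <- base_pairs(pt)
  if (!nrow(pr)) return(list())
  runs <- list()
  start <- 1L
  for (r in seq_len(nrow(pr))[-1L]) {
    prev <- pr[r - 1L, ]
    cur <- pr[r, ]
    stacked <- cur$i == prev$i + 1L && cur$j == prev$j - 1L &&
      cur$layer == prev$layer
    if (!stacked) {
      runs[[length(runs) + 1L]] <- pr[start:(r - 1L), ]
      start <- r
    }
  }
  runs[[length(runs) + 1L]] <- pr[start:nrow(pr), ]
  lapply(runs, function(d) {
    rownames(d) <- NULL
    structure(list(pairs = d[, c("i", "j", "layer")], centers = d$center),
              class = "rna_helix")
  })
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("<pair_table> %d nt, %d pairs, %d helices\n",
              x$n, nrow(base_pairs(x)), length(helices(x))))
  cat(" ", serialize_dotbracket(x), "\n")
  invisible(x)
}
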