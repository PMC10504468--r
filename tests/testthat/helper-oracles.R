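# Independent oracles and fixture builders used across the test files.

# Recursive-descent matcher for single-layer dot-bracket strings; independent
# of the package's stack-based parser. Returns a 2-column matrix of pairs
# (i, j) or NULL.
rd_pairs <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  pairs <- list()
  pos <- 1L
  parse_seq <- function() {
    while (pos <= length(chars)) {
      ch <- chars[pos]
      if (ch == ".") {
        pos <<- pos + 1L
      } else if (ch == "(") {
        open <- pos
        pos <<- pos + 1L
        parse_seq()
        stopifnot(pos <= length(chars), chars[pos] == ")")
        pairs[[length(pairs) + 1L]] <<- c(open, pos)
        pos <<- pos + 1L
      } else {
        return(invisible())
      }
    }
  }
  parse_seq()
  if (length(pairs)) do.call(rbind, pairs) else NULL
}

# Random balanced single-layer dot-bracket string of length n.
gen_balanced <- function(n) {
  out <- character(n)
  open <- 0L
  for (k in seq_len(n)) {
    left <- n - k
    if (open > left) {
      out[k] <- ")"
      open <- open - 1L
      next
    }
    r <- runif(1)
    if (open > 0L && r < 0.3) {
      out[k] <- ")"
      open <- open - 1L
    } else if (r < 0.65 && open < left) {
      out[k] <- "("
      open <- open + 1L
    } else {
      out[k] <- "."
    }
  }
  paste(out, collapse = "")
}

# Canonical sorted "i-j" pair strings for comparing pair sets.
pair_keys <- function(pt) {
  pr <- base_pairs(pt)
  sort(sprintf("%d-%d", pr$i, pr$j))
}

# Quick in-code trajectory: one row per element of the arguments.
make_traj <- function(id, time, occupancy, structure, energy = NULL,
                      sequence = NULL) {
  if (is.null(energy)) energy <- rep(-1, length(id))
  trajectory(data.frame(id = id, time = time, occupancy = occupancy,
                        structure = structure, energy = energy,
                        stringsAsFactors = FALSE), sequence = sequence)
}
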