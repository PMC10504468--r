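# Synthetic trajectory generator: growing transcripts with competing
# helices, for tests, demonstrations and benchmarking.

.dots <- function(n) strrep(".", n)

# Hairpin of k stacked pairs starting at `start` (1-based), padded with dots
# to total length L.
.hairpin <- function(L, start, k, loop) {
  stopifnot(start - 1 + 2 * k + loop <= L, loop >= 3, k >= 1)
  paste0(.dots(start - 1), strrep("(", k), .dots(loop), strrep(")", k),
         .dots(L - (start - 1) - 2 * k - loop))
}

# 5'-proximal hairpin: forms as soon as the chain is long enough.
.struct_a <- function(L) {
  span <- min(L, 12L)
  k <- min(4L, (span - 3L) %/% 2L)
  if (k < 1L) return(.dots(L))
  .hairpin(L, 1L, k, span - 2L * k)
}

# Competing hairpin reaching to the 3' end; needs L >= 12.
.struct_b <- function(L) {
  avail <- L - 2L
  k <- min(6L, (avail - 3L) %/% 2L)
  .hairpin(L, 3L, k, avail - 2L * k)
}

.n_pairs <- function(s) nrow(base_pairs(parse_dotbracket(s)))

.energy_of <- function(s) -1.5 * .n_pairs(s)

#' Generate a synthetic folding trajectory
#'
#' Emulates the output of a cotranscriptional folding simulation: the
#' transcript grows from 8 nt to `final_length` at 50 nt/s over the first
#' 75% of the time points (linearly spaced), then folds on for a further
#' 1000-fold time span covered by the remaining 25% of time points
#' (log-spaced). Occupancies at every time point sum to 1 across 1-3
#' structures, with a small seeded perturbation; the same preset and seed
#' always produce an identical trajectory, and the caller's RNG state is
#' untouched.
#'
#' Presets:
#' \describe{
#'   \item{`"single-hairpin"`}{one lineage (id 0), a 5'-proximal hairpin
#'     carrying the full ensemble at every time point.}
#'   \item{`"helix-competition"`}{a 5' hairpin (id 0) loses the ensemble to
#'     a competing 3'-reaching hairpin (id 1) while transcription is still
#'     running, so the dominant id switches during transcription; a residual
#'     unfolded lineage (id 2) stays minor.}
#'   \item{`"late-refold"`}{id 0 dominates the whole cotranscriptional
#'     phase; only after transcription ends does its occupancy decay in
#'     favor of the refolded id 1, so the dominant id switches in the
#'     logarithmic part of the time course.}
#' }
#'
#' @param preset One of `"single-hairpin"`, `"helix-competition"`,
#'   `"late-refold"`.
#' @param seed Integer seed for the occupancy perturbation and the sequence.
#' @param n_timepoints Total number of time points (>= 2).
#' @param final_length Final transcript length in nt (>= 8; the competition
#'   presets need >= 12 so that the second helix fits).
#' @return A `fold_trajectory` with an attached random sequence.
#' @examples
#' traj <- generate_fixture("helix-competition", seed = 1,
#'                          n_timepoints = 12, final_length = 30)
#' traj
#' @export
generate_fixture <- function(preset = c("single-hairpin", "helix-competition",
                                        "late-refold"),
                             seed = 1L, n_timepoints = 12L,
                             final_length = 30L) {
  preset <- match.arg(preset)
  if (!is.numeric(n_timepoints) || n_timepoints < 2L)
    stop("`n_timepoints` must be >= 2", call. = FALSE)
  if (!is.numeric(final_length) || final_length < 8L)
    stop("`final_length` must be >= 8", call. = FALSE)
  n_timepoints <- as.integer(n_timepoints)
  final_length <- as.integer(final_length)
  if (preset != "single-hairpin" && final_length < 12L)
    stop(sprintf("preset '%s' needs final_length >= 12 to fit a competing helix",
                 preset), call. = FALSE)

  n_tr <- as.integer(ceiling(0.75 * n_timepoints))
  n_post <- n_timepoints - n_tr
  t_end <- final_length / 50            # 50 nt/s transcription rate
  times_tr <- seq(t_end / n_tr, t_end, length.out = n_tr)
  lengths <- as.integer(round(seq(8L, final_length, length.out = n_tr)))
  if (final_length > 8L)
    lengths[-n_tr] <- pmin(lengths[-n_tr], final_length - 1L)
  lengths <- as.integer(cummax(pmax(lengths, 8L)))
  times_post <- if (n_post > 0L)
    t_end * 1000^(seq_len(n_post) / n_post) else numeric(0)

  .with_seed(seed, {
    sequence <- paste(sample(c("A", "C", "G", "U"), final_length,
                             replace = TRUE), collapse = "")
    rows <- list()
    emit <- function(t, id, occ, struct) {
      rows[[length(rows) + 1L]] <<- data.frame(
        id = id, time = t, occupancy = occ, structure = struct,
        energy = .energy_of(struct), stringsAsFactors = FALSE)
    }
    add_timepoint <- function(t, L, p0, competing) {
      if (!competing) {
        emit(t, 0L, 1, .struct_a(L))
        return(invisible())
      }
      p0 <- min(max(p0 + stats::runif(1, -0.02, 0.02), 0.03), 0.97)
      w <- c(p0 * 0.96, (1 - p0) * 0.96, 0.04)
      w <- w / sum(w)
      emit(t, 0L, w[1L], .struct_a(L))
      emit(t, 1L, w[2L], .struct_b(L))
      emit(t, 2L, w[3L], .dots(L))
    }
    if (preset == "single-hairpin") {
      for (k in seq_len(n_tr)) emit(times_tr[k], 0L, 1, .struct_a(lengths[k]))
      for (t in times_post) emit(t, 0L, 1, .struct_a(final_length))
    } else if (preset == "helix-competition") {
      comp <- lengths >= 12L
      nc <- sum(comp)
      s <- if (nc > 1L) seq(0, 1, length.out = nc) else 1
      ci <- 0L
      for (k in seq_len(n_tr)) {
        if (comp[k]) {
          ci <- ci + 1L
          add_timepoint(times_tr[k], lengths[k], 0.88 - 0.76 * s[ci],
                        competing = TRUE)
        } else {
          add_timepoint(times_tr[k], lengths[k], 1, competing = FALSE)
        }
      }
      for (t in times_post)
        add_timepoint(t, final_length, 0.12, competing = TRUE)
    } else { # late-refold
      for (k in seq_len(n_tr))
        add_timepoint(times_tr[k], lengths[k], 0.92, competing = lengths[k] >= 12L)
      for (t in times_post) {
        p0 <- 0.92 * (t / t_end)^(-0.7)   # slow post-transcriptional decay
        add_timepoint(t, final_length, p0, competing = TRUE)
      }
    }
    trajectory(do.call(rbind, rows), sequence = sequence)
  })
}
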