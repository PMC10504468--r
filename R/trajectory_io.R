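# Trajectory file I/O, validation, filtering and per-time-point queries.

.required_cols <- c("id", "time", "occupancy", "structure", "energy")

# Accept a file path, a single string with embedded newlines, or a character
# vector of lines.
.read_input_lines <- function(input) {
  if (is.character(input) && length(input) != 1L) return(input)
  if (!is.character(input) || length(input) != 1L || is.na(input))
    stop("input must be a file path or character text", call. = FALSE)
  if (grepl("\n", input, fixed = TRUE))
    return(strsplit(input, "\n", fixed = TRUE)[[1L]])
  if (file.exists(input)) return(readLines(input, warn = FALSE))
  input
}

# Shortest decimal rendering that round-trips the double exactly.
.fmt_num <- function(x) {
  s <- sprintf("%.15g", x)
  exact <- as.numeric(s) == x
  s[!exact] <- sprintf("%.17g", x[!exact])
  s
}

#' Construct a folding trajectory from a record table
#'
#' Validates and wraps simulation records into a `fold_trajectory`. Checks
#' that occupancies lie in `[0, 1]`, times are finite and non-negative,
#' structures are balanced dot-bracket strings, and that the maximum
#' structure length per time point never decreases (transcription only grows
#' the chain). Per-time-point occupancy sums above `1 + 1e-6` and duplicated
#' ids within a time point are tolerated with a warning, since aggregated
#' stochastic simulations can produce slightly inconsistent tables.
#'
#' @param records A data frame with columns `id` (integer lineage label
#'   grouping a structure across transcript lengths), `time` (seconds),
#'   `occupancy` (fraction of the ensemble), `structure` (dot-bracket) and
#'   `energy` (kcal/mol).
#' @param sequence Optional nucleotide string, at least as long as the
#'   longest structure; annotation characters are permitted.
#' @return A `fold_trajectory`: list with `records` (in input order),
#'   `times` (sorted unique time points), `max_length` and `sequence`.
#' @seealso [parse_trajectory()] to read the file format directly.
#' @export
trajectory <- function(records, sequence = NULL) {
  if (!is.data.frame(records))
    stop("`records` must be a data frame", call. = FALSE)
  missing <- setdiff(.required_cols, names(records))
  if (length(missing))
    stop(sprintf("records are missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  records <- as.data.frame(records)[, .required_cols]
  rownames(records) <- NULL
  n <- nrow(records)
  if (n) {
    if (any(records$id != trunc(records$id)))
      stop("`id` must be integer-valued", call. = FALSE)
    records$id <- as.integer(records$id)
    if (any(!is.finite(records$time)) || any(records$time < 0))
      stop("`time` must be finite and >= 0", call. = FALSE)
    if (any(!is.finite(records$occupancy)) ||
        any(records$occupancy < 0 | records$occupancy > 1))
      stop("`occupancy` must lie in [0, 1]", call. = FALSE)
    if (any(!is.finite(records$energy)))
      stop("`energy` must be finite", call. = FALSE)
    records$structure <- as.character(records$structure)
    for (k in seq_len(n)) parse_dotbracket(records$structure[k])
  }
  times <- sort(unique(records$time))
  len <- nchar(records$structure)
  max_length <- if (n) max(len) else 0L
  if (length(times) > 1L) {
    maxlen_by_t <- vapply(times, function(t) max(len[records$time == t]), 0)
    if (any(diff(maxlen_by_t) < 0))
      stop(sprintf(
        "maximum structure length decreases at time %s; transcripts cannot shrink",
        .fmt_num(times[which(diff(maxlen_by_t) < 0)[1L] + 1L])), call. = FALSE)
  }
  if (n) {
    sums <- vapply(times, function(t) sum(records$occupancy[records$time == t]), 0)
    if (any(sums > 1 + 1e-6))
      warning(sprintf("occupancies at time %s sum to %.6g (> 1)",
                      .fmt_num(times[which.max(sums)]), max(sums)),
              call. = FALSE)
    dup <- vapply(times, function(t) anyDuplicated(records$id[records$time == t]) > 0L,
                  FALSE)
    if (any(dup))
      warning(sprintf("duplicated structure ids at time %s",
                      .fmt_num(times[which(dup)[1L]])), call. = FALSE)
  }
  if (!is.null(sequence)) {
    sequence <- toupper(trimws(sequence))
    if (!nzchar(sequence)) stop("`sequence` is empty", call. = FALSE)
    if (nchar(sequence) < max_length)
      stop(sprintf("sequence length %d is shorter than the longest structure (%d nt)",
                   nchar(sequence), max_length), call. = FALSE)
  }
  structure(list(records = records, times = times,
                 max_length = as.integer(max_length), sequence = sequence),
            class = "fold_trajectory")
}

#' Parse a folding-trajectory file
#'
#' Reads the whitespace-separated trajectory format: the first non-comment
#' line is a header that must contain the column names
#' `id time occupancy structure energy` (any order; extra columns are
#' ignored; columns are matched by name, never by position). Lines starting
#' with `#` and blank lines are skipped. Scientific notation is accepted for
#' all numeric fields. Row-level problems (non-integer id, non-numeric
#' values, occupancy outside `[0, 1]`, unbalanced structure) are reported
#' with the offending line number.
#'
#' @param input File path, single string, or character vector of lines.
#' @return A validated [trajectory()] object (`fold_trajectory`).
#' @examples
#' parse_trajectory(c("id time occupancy structure energy",
#'                    "0 0.1 1.0 .... -0.0"))
#' @export
parse_trajectory <- function(input) {
  lines <- .read_input_lines(input)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    stop("empty trajectory file: no header line found", call. = FALSE)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  missing <- setdiff(.required_cols, header)
  if (length(missing))
    stop(sprintf("trajectory header is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  idx <- match(.required_cols, header)
  rows <- lines[-1L]
  rownum <- lineno[-1L]
  if (!length(rows))
    stop("trajectory file has a header but no data rows", call. = FALSE)
  fields <- strsplit(trimws(rows), "\\s+")
  short <- lengths(fields) < length(header)
  if (any(short)) {
    k <- which(short)[1L]
    stop(sprintf("line %d: expected %d fields, found %d",
                 rownum[k], length(header), lengths(fields)[k]), call. = FALSE)
  }
  col <- function(j) vapply(fields, `[[`, "", j)
  as_num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- is.na(v)
    if (any(bad)) {
      k <- which(bad)[1L]
      stop(sprintf("line %d: %s '%s' is not a number", rownum[k], what, s[k]),
           call. = FALSE)
    }
    v
  }
  id <- as_num(col(idx[1L]), "id")
  bad <- id != trunc(id)
  if (any(bad))
    stop(sprintf("line %d: id '%s' is not an integer",
                 rownum[which(bad)[1L]], col(idx[1L])[which(bad)[1L]]),
         call. = FALSE)
  time <- as_num(col(idx[2L]), "time")
  bad <- !is.finite(time) | time < 0
  if (any(bad))
    stop(sprintf("line %d: time must be finite and >= 0, got '%s'",
                 rownum[which(bad)[1L]], col(idx[2L])[which(bad)[1L]]),
         call. = FALSE)
  occ <- as_num(col(idx[3L]), "occupancy")
  bad <- !is.finite(occ) | occ < 0 | occ > 1
  if (any(bad))
    stop(sprintf("line %d: occupancy %s is outside [0, 1]",
                 rownum[which(bad)[1L]], col(idx[3L])[which(bad)[1L]]),
         call. = FALSE)
  struct <- col(idx[4L])
  for (k in seq_along(struct)) {
    res <- tryCatch({ parse_dotbracket(struct[k]); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(res))
      stop(sprintf("line %d: invalid structure: %s", rownum[k], res),
           call. = FALSE)
  }
  energy <- as_num(col(idx[5L]), "energy")
  bad <- !is.finite(energy)
  if (any(bad))
    stop(sprintf("line %d: energy must be finite", rownum[which(bad)[1L]]),
         call. = FALSE)
  trajectory(data.frame(id = as.integer(id), time = time, occupancy = occ,
                        structure = struct, energy = energy,
                        stringsAsFactors = FALSE))
}

#' Write a trajectory file
#'
#' Emits the whitespace-separated format read by [parse_trajectory()].
#' Times and occupancies are printed with enough digits to round-trip
#' exactly; energies with two decimals (kcal/mol convention).
#'
#' @param traj A `fold_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "fold_trajectory"))
  r <- traj$records
  lines <- c(paste(.required_cols, collapse = " "),
             sprintf("%d %s %s %s %.2f", r$id, .fmt_num(r$time),
                     .fmt_num(r$occupancy), r$structure, r$energy))
  writeLines(lines, path)
  invisible(path)
}

#' Load the nucleotide sequence for a simulation
#'
#' The sequence is uploaded separately from the trajectory: either a raw
#' (non-FASTA) string, or FASTA, of which the first record is used. The
#' result is uppercased with surrounding whitespace stripped. Arbitrary
#' annotation characters (e.g. `&`, `N`, design-constraint symbols) are kept
#' as-is, so specific positions can be marked up in the drawings.
#'
#' @param input File path, single string, or character vector of lines.
#' @return A single uppercase sequence string.
#' @examples
#' load_sequence(">x\nacgu")  # "ACGU"
#' load_sequence("NNNAA&GG")
#' @export
load_sequence <- function(input) {
  lines <- .read_input_lines(input)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty sequence input", call. = FALSE)
  if (startsWith(trimws(lines[1L]), ">")) {
    tmp <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp))
    writeLines(lines, tmp)
    set <- Biostrings::readBStringSet(tmp)
    if (!length(set)) stop("FASTA input contains no sequence", call. = FALSE)
    if (length(set) > 1L)
      warning(sprintf("FASTA input has %d records; using the first ('%s')",
                      length(set), names(set)[1L]), call. = FALSE)
    seq <- as.character(set[[1L]])
  } else {
    seq <- paste(trimws(lines), collapse = "")
  }
  seq <- toupper(trimws(seq))
  if (!nzchar(seq)) stop("empty sequence input", call. = FALSE)
  seq
}

#' Drop low-occupancy structures
#'
#' Removes records whose occupancy is below `min_occupancy`; time points left
#' without any record disappear from the trajectory entirely, so filtering
#' may shorten the displayed time course. With per-time-point occupancy sums
#' of at most 1, a threshold of 0.01 bounds the number of displayed
#' structures per time point at 100.
#'
#' @param traj A `fold_trajectory`.
#' @param min_occupancy Threshold in `[0, 1]`; records with
#'   `occupancy < min_occupancy` are removed.
#' @return A new `fold_trajectory` (possibly with no records).
#' @export
filter_by_occupancy <- function(traj, min_occupancy) {
  stopifnot(inherits(traj, "fold_trajectory"))
  if (!is.numeric(min_occupancy) || length(min_occupancy) != 1L ||
      !is.finite(min_occupancy) || min_occupancy < 0 || min_occupancy > 1)
    stop("`min_occupancy` must be a single number in [0, 1]", call. = FALSE)
  keep <- traj$records$occupancy >= min_occupancy
  suppressWarnings(trajectory(traj$records[keep, , drop = FALSE],
                              sequence = traj$sequence))
}

#' Extract the displayed ensemble at a time point
#'
#' Uses the nearest-previous convention: the slice is taken at the largest
#' simulation time point `<= t` (or the first time point if `t` precedes
#' it), matching a cursor scrubbing over discrete simulation outputs.
#' Records are sorted by descending occupancy, ties broken by ascending id.
#'
#' @param traj A non-empty `fold_trajectory`.
#' @param t Query time in seconds.
#' @return A `time_slice`: list with `time`, `records` (sorted) and
#'   `sum_occupancy`.
#' @export
slice_at_time <- function(traj, t) {
  stopifnot(inherits(traj, "fold_trajectory"))
  if (!length(traj$times))
    stop("trajectory has no time points", call. = FALSE)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t))
    stop("`t` must be a single finite number", call. = FALSE)
  k <- findInterval(t, traj$times)
  if (k < 1L) k <- 1L
  tp <- traj$times[k]
  recs <- traj$records[traj$records$time == tp, , drop = FALSE]
  recs <- recs[order(-recs$occupancy, recs$id), , drop = FALSE]
  rownames(recs) <- NULL
  structure(list(time = tp, records = recs,
                 sum_occupancy = sum(recs$occupancy)),
            class = "time_slice")
}

#' Time at which transcription ends
#'
#' The trajectory format carries no explicit transcript-length column, so the
#' end of transcription is detected as the earliest time point at which the
#' maximum structure length reaches its overall maximum.
#'
#' @param traj A non-empty `fold_trajectory`.
#' @return A time in seconds (one of `traj$times`).
#' @export
transcription_end_time <- function(traj) {
  stopifnot(inherits(traj, "fold_trajectory"))
  if (!length(traj$times))
    stop("trajectory has no time points", call. = FALSE)
  len <- nchar(traj$records$structure)
  for (tp in traj$times) {
    if (max(len[traj$records$time == tp]) == traj$max_length) return(tp)
  }
  traj$times[length(traj$times)]
}

#' Summary table of a time slice
#'
#' The tabular companion of a rendered frame: one row per displayed
#' structure, in display order (descending occupancy), with the sum of
#' displayed occupancies attached -- the fraction of the ensemble actually
#' shown.
#'
#' @param slice A `time_slice`.
#' @return A data frame with columns `id`, `time`, `occupancy`, `structure`,
#'   `energy` and attribute `"sum_occupancy"`.
#' @export
summary_table <- function(slice) {
  stopifnot(inherits(slice, "time_slice"))
  df <- slice$records[, .required_cols, drop = FALSE]
  rownames(df) <- NULL
  attr(df, "sum_occupancy") <- slice$sum_occupancy
  df
}

#' @export
print.fold_trajectory <- function(x, ...) {
  cat(sprintf("<fold_trajectory> %d records, %d time points, max length %d nt%s\n",
              nrow(x$records), length(x$times), x$max_length,
              if (is.null(x$sequence)) "" else ", with sequence"))
  if (length(x$times))
    cat(sprintf("  time range: %s .. %s s\n",
                format(min(x$times), digits = 6),
                format(max(x$times), digits = 6)))
  invisible(x)
}

#' @export
print.time_slice <- function(x, ...) {
  cat(sprintf("<time_slice> t = %s s, %d structures, sum of occupancies %.4f\n",
              format(x$time, digits = 6), nrow(x$records), x$sum_occupancy))
  invisible(x)
}
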