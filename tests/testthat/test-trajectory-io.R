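test_that("a minimal valid file parses into a one-record trajectory", {
  traj <- parse_trajectory(c("id time occupancy structure energy",
                             "0 0.1 1.0 .... -0.0"))
  expect_s3_class(traj, "fold_trajectory")
  expect_equal(nrow(traj$records), 1L)
  expect_equal(traj$max_length, 4L)
  expect_equal(traj$times, 0.1)
  expect_identical(traj$records$id, 0L)
})

test_that("columns are matched by header name, not position", {
  a <- parse_trajectory(c("id time occupancy structure energy",
                          "3 0.5 0.6 ((..)) -1.2",
                          "4 0.5 0.4 ...... 0.0"))
  b <- parse_trajectory(c("time id structure occupancy energy",
                          "0.5 3 ((..)) 0.6 -1.2",
                          "0.5 4 ...... 0.4 0.0"))
  expect_equal(a$records, b$records)
  expect_equal(a$times, b$times)
})

test_that("extra columns and comment lines are ignored", {
  traj <- parse_trajectory(c("# a comment",
                            "id foo time occupancy structure energy",
                            "",
                            "1 x 2e-1 0.5 (...) -3.1",
                            "# more commentary",
                            "2 y 2e-1 0.5 ..... 0.0"))
  expect_equal(nrow(traj$records), 2L)
  expect_equal(traj$records$time, c(0.2, 0.2))
})

test_that("format errors name the missing column or the offending line", {
  expect_error(parse_trajectory(c("id time structure energy", "0 1 . 0")),
               "occupancy")
  expect_error(parse_trajectory(character(0)), "empty")
  expect_error(parse_trajectory("id time occupancy structure energy"),
               "no data rows")
  hdr <- "id time occupancy structure energy"
  expect_error(parse_trajectory(c(hdr, "0 1 1.5 .... 0")), "line 2.*1\\.5")
  expect_error(parse_trajectory(c(hdr, "0 1 1 .... 0", "1.5 1 1 .... 0")),
               "line 3.*integer")
  expect_error(parse_trajectory(c(hdr, "0 abc 1 .... 0")), "line 2")
  expect_error(parse_trajectory(c(hdr, "0 1 1 ((.) 0")), "line 2.*structure")
  expect_error(parse_trajectory(c(hdr, "0 1 1 .... nan")), "line 2")
})

test_that("inconsistent trajectories warn but still load", {
  hdr <- "id time occupancy structure energy"
  expect_warning(parse_trajectory(c(hdr, "0 1 0.9 .... 0", "1 1 0.9 .... 0")),
                 "sum")
  expect_warning(parse_trajectory(c(hdr, "0 1 0.4 .... 0", "0 1 0.3 .... 0")),
                 "duplicated")
})

test_that("shrinking transcripts are rejected", {
  expect_error(make_traj(c(0L, 0L), c(1, 2), c(1, 1), c(".....", "...")),
               "length decreases")
})

test_that("load_sequence handles FASTA, raw strings and annotations", {
  expect_equal(load_sequence(">x\nacgu\n"), "ACGU")
  expect_equal(load_sequence("ACGUACGU"), "ACGUACGU")
  expect_equal(load_sequence("NNNAA&GG"), "NNNAA&GG")
  expect_warning(out <- load_sequence(">a\nacg\n>b\nuuu\n"), "first")
  expect_equal(out, "ACG")
  expect_error(load_sequence("  \n "), "empty")
})

test_that("occupancy filtering drops records and empty time points", {
  traj <- make_traj(c(1L, 2L, 3L), c(1, 1, 1), c(0.5, 0.3, 0.005),
                    rep("....", 3))
  f <- filter_by_occupancy(traj, 0.01)
  expect_equal(nrow(f$records), 2L)
  expect_equal(slice_at_time(f, 1)$sum_occupancy, 0.8)
  # a time point where everything is below threshold disappears entirely
  traj2 <- make_traj(c(1L, 1L, 1L), c(1, 2, 3), c(0.5, 0.004, 0.5),
                     rep("....", 3))
  f2 <- filter_by_occupancy(traj2, 0.01)
  expect_equal(f2$times, c(1, 3))
  # threshold 0 is the identity
  expect_equal(filter_by_occupancy(traj, 0)$records, traj$records)
  expect_error(filter_by_occupancy(traj, 1.2), "min_occupancy")
})

test_that("filtering is idempotent and monotone in the threshold", {
  set.seed(42)
  traj <- make_traj(1:20, rep(c(1, 2), each = 10), rep(0.1, 20),
                    rep("....", 20))
  traj$records$occupancy <- runif(20, 0, 0.1)
  traj <- trajectory(traj$records)
  prev_n <- Inf
  for (th in c(0, 0.01, 0.03, 0.08, 0.2)) {
    f <- filter_by_occupancy(traj, th)
    expect_equal(filter_by_occupancy(f, th)$records, f$records)
    expect_lte(nrow(f$records), prev_n)
    prev_n <- nrow(f$records)
    for (tp in f$times)
      expect_gte(sum(f$records$occupancy[f$records$time == tp]), th)
  }
})

test_that("slice_at_time uses nearest-previous time and a stable tie-break", {
  traj <- make_traj(c(1L, 1L, 1L), c(1, 2, 3), c(1, 1, 1),
                    c("....", ".....", "......"))
  expect_equal(slice_at_time(traj, 2.5)$time, 2)
  expect_equal(slice_at_time(traj, 2)$time, 2)
  expect_equal(slice_at_time(traj, 0.1)$time, 1)  # before the first point
  # tied occupancies: ascending id, as the independent sort on (-occ, id)
  tie <- make_traj(c(7L, 3L), c(1, 1), c(0.4, 0.4), c("....", "...."))
  sl <- slice_at_time(tie, 1)
  ord <- order(-c(0.4, 0.4), c(7L, 3L))
  expect_equal(sl$records$id, c(7L, 3L)[ord])
  expect_equal(sl$records$id, c(3L, 7L))
  expect_error(slice_at_time(filter_by_occupancy(tie, 1), 1), "no time points")
})

test_that("transcription end is the first attainment of the maximum length", {
  traj <- make_traj(rep(1L, 5), 1:5, rep(1, 5),
                    strrep(".", c(10, 20, 30, 30, 30)))
  expect_equal(transcription_end_time(traj), 3)
  expect_equal(transcription_end_time(make_traj(1L, 7, 1, "....")), 7)
  flat <- make_traj(rep(1L, 3), 1:3, rep(1, 3), rep("....", 3))
  expect_equal(transcription_end_time(flat), 1)
})

test_that("summary tables report the displayed rows plus their sum", {
  traj <- make_traj(c(1L, 2L), c(1, 1), c(0.6, 0.3), c("....", "(..)"),
                    energy = c(-1, -2.5))
  sl <- slice_at_time(traj, 1)
  tab <- summary_table(sl)
  expect_equal(nrow(tab), 2L)
  expect_equal(names(tab), c("id", "time", "occupancy", "structure", "energy"))
  expect_equal(attr(tab, "sum_occupancy"), sum(tab$occupancy))
  one <- filter_by_occupancy(traj, 0.5)
  tab1 <- summary_table(slice_at_time(one, 1))
  expect_equal(nrow(tab1), 1L)
  expect_equal(attr(tab1, "sum_occupancy"), 0.6)
})

test_that("write then parse round-trips the trajectory", {
  for (preset in c("single-hairpin", "helix-competition", "late-refold")) {
    traj <- generate_fixture(preset, seed = 7, n_timepoints = 8,
                             final_length = 24)
    path <- withr::local_tempfile(fileext = ".drf")
    write_trajectory(traj, path)
    back <- parse_trajectory(path)
    expect_identical(back$records$id, traj$records$id)
    expect_identical(back$records$time, traj$records$time)
    expect_identical(back$records$occupancy, traj$records$occupancy)
    expect_identical(back$records$structure, traj$records$structure)
    expect_equal(back$records$energy, round(traj$records$energy, 2))
  }
})
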