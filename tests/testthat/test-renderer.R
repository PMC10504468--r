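strip_geometry <- function(doc) {
  border <- xml2::xml_find_first(doc, "//*[local-name()='rect' and @class='strip-border']")
  list(x = as.numeric(xml2::xml_attr(border, "x")),
       w = as.numeric(xml2::xml_attr(border, "width")))
}

marker_x <- function(doc, id) {
  node <- xml2::xml_find_first(doc, sprintf("//*[local-name()='line' and @id='%s']", id))
  as.numeric(xml2::xml_attr(node, "x1"))
}

test_that("a single-structure frame has one tile and the 75% marker", {
  traj <- generate_fixture("single-hairpin", seed = 1, n_timepoints = 8,
                           final_length = 20)
  doc <- render_frame(traj, transcription_end_time(traj))
  tiles <- xml2::xml_find_all(doc, "//*[local-name()='g' and @class='treemap-tile']")
  expect_length(tiles, 1L)
  st <- strip_geometry(doc)
  expect_equal((marker_x(doc, "transcription-end-marker") - st$x) / st$w,
               0.75, tolerance = 1e-3)
})

test_that("frames are well-formed, self-contained SVG with annotations", {
  traj <- generate_fixture("helix-competition", seed = 2, n_timepoints = 10,
                           final_length = 24)
  t <- traj$times[6]
  doc <- render_frame(traj, t)
  path <- withr::local_tempfile(fileext = ".svg")
  write_svg(doc, path)
  reread <- xml2::read_xml(path)  # parses => well-formed
  expect_equal(xml2::xml_name(reread), "svg")
  txt <- paste(readLines(path), collapse = "\n")
  expect_false(grepl("href", txt))  # no external references
  sl <- slice_at_time(filter_by_occupancy(traj, 0.01), t)
  lab <- xml2::xml_text(xml2::xml_find_first(
    reread, "//*[local-name()='text' and @class='sum-occupancy']"))
  expect_match(lab, sprintf("%.4f", sl$sum_occupancy), fixed = TRUE)
  cur <- marker_x(reread, "time-cursor")
  st <- strip_geometry(reread)
  ax <- time_axis(filter_by_occupancy(traj, 0.01))
  expect_equal((cur - st$x) / st$w, time_to_x(ax, sl$time), tolerance = 1e-3)
})

test_that("rendering is deterministic and commutes with filtering", {
  traj <- generate_fixture("late-refold", seed = 3, n_timepoints = 8,
                           final_length = 20)
  t <- traj$times[4]
  a <- as.character(render_frame(traj, t))
  b <- as.character(render_frame(traj, t))
  expect_identical(a, b)
  pre <- filter_by_occupancy(traj, 0.01)
  expect_identical(as.character(render_frame(pre, t)), a)
})

test_that("out-of-range frame times are clamped with a warning", {
  traj <- generate_fixture("single-hairpin", seed = 1, n_timepoints = 6,
                           final_length = 16)
  expect_warning(doc <- render_frame(traj, max(traj$times) * 10), "clamped")
  lab <- xml2::xml_text(xml2::xml_find_first(
    doc, "//*[local-name()='text' and @class='time-label']"))
  expect_match(lab, paste0(format(max(traj$times)), " s"), fixed = TRUE)
})

test_that("animations emit one frame per displayed time point", {
  traj <- generate_fixture("helix-competition", seed = 5, n_timepoints = 12,
                           final_length = 24)
  outdir <- withr::local_tempdir()
  anim <- render_animation(traj, render_config(speed = 4), outdir)
  expect_length(anim$files, 12L)
  expect_true(all(file.exists(anim$files)))
  expect_equal(anim$frame_duration_ms, 250)
  # a harsher filter that removes time points shrinks the frame series
  cfg <- render_config(min_occupancy = 0.2)
  kept <- filter_by_occupancy(traj, 0.2)
  anim2 <- render_animation(traj, cfg, withr::local_tempdir())
  expect_length(anim2$files, length(kept$times))
  halfhalf <- make_traj(c(0L, 1L), c(1, 1), c(0.5, 0.5), c("....", "(..)"))
  expect_error(render_animation(halfhalf, render_config(min_occupancy = 0.9),
                                withr::local_tempdir()),
               "no time points")
})

test_that("the dwell threshold is 5 ms per structure", {
  expect_equal(min_dwell_time(1), 5)
  expect_equal(min_dwell_time(20), 100)
  expect_equal(min_dwell_time(0), 0)
  expect_error(min_dwell_time(-1), "non-negative")
  expect_error(min_dwell_time(2.5), "integer")
  traj <- generate_fixture("helix-competition", seed = 1)
  m <- max_structures(traj)
  expect_equal(min_dwell_time(m), 5 * m)
})

test_that("render configuration is validated", {
  expect_error(render_config(min_occupancy = 2), "\\[0, 1\\]")
  expect_error(render_config(speed = 0), "speed")
  expect_error(render_config(width = -5), "positive")
})
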