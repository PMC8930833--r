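# Video standardization, vessel segmentation, scan lines, kymographs,
# artifact flagging and ejection verification.

test_that("standardization resamples to the target geometry", {
  set.seed(1)
  raw <- video_stack(array(runif(64 * 96 * 40, 0, 255), c(64, 96, 40)),
                     frame_rate = 10, pulse_frame = 20)
  std <- standardize_video(raw, width = 48, height = 32, depth = 20)
  expect_equal(dim(std$frames), c(32, 48, 20))
  expect_equal(length(std$timestamps), 20)
  # pulse lands at the frame nearest the original pulse time
  expect_equal(std$timestamps[std$pulse_frame],
               raw$timestamps[raw$pulse_frame], tolerance = 0.1)
})

test_that("standardization is value-identical on already-standard input", {
  set.seed(2)
  raw <- video_stack(array(sample(0:255, 32 * 48 * 10, TRUE), c(32, 48, 10)),
                     frame_rate = 10, pulse_frame = 5)
  std <- standardize_video(raw, width = 48, height = 32, depth = 10)
  expect_identical(std$frames, raw$frames * 1)
  expect_equal(std$timestamps, raw$timestamps)
})

test_that("temporal downsampling block-averages frame pairs exactly", {
  # frames come in identical pairs; each output frame equals its pair value
  set.seed(3)
  vals <- sample(0:255, 12)
  frames <- array(0, c(8, 8, 24))
  for (i in 1:12) {
    frames[, , 2 * i - 1] <- vals[i]
    frames[, , 2 * i] <- vals[i]
  }
  raw <- video_stack(frames, frame_rate = 20, pulse_frame = 2)
  std <- standardize_video(raw, width = 8, height = 8, depth = 12)
  for (i in 1:12) expect_true(all(std$frames[, , i] == vals[i]))

  # and against a direct block-mean oracle for non-paired data
  set.seed(4)
  frames <- array(sample(0:255, 8 * 8 * 24, TRUE), c(8, 8, 24))
  raw <- video_stack(frames, frame_rate = 20, pulse_frame = 2)
  std <- standardize_video(raw, width = 8, height = 8, depth = 12)
  oracle <- round((frames[, , seq(1, 23, 2)] + frames[, , seq(2, 24, 2)]) / 2)
  expect_equal(std$frames, oracle)
})

test_that("empty or single-frame stacks are rejected", {
  raw <- video_stack(array(0, c(8, 8, 1)), frame_rate = 10)
  expect_error(standardize_video(raw), "single-frame")
})

test_that("segmentation finds the tube with a centerline close to truth", {
  fx <- fixture("tube20", function() rendered_tube(duration = 20, noise_sd = 4))
  cands <- segment_vessels(fx$green)
  expect_length(cands, 1)
  pts <- cands[[1]]$centerline$points
  # truth centerline is horizontal at y = 48
  expect_lt(mean(abs(pts[, "y"] - 48)), 1)
  expect_equal(rowSums(cands[[1]]$centerline$tangents^2),
               rep(1, nrow(pts)), tolerance = 1e-8)
})

test_that("a blank video yields the no-usable-arteriole error", {
  blank <- video_stack(array(30, c(48, 64, 12)), frame_rate = 10,
                       pulse_frame = 5)
  expect_error(segment_vessels(blank), "no usable arteriole")
})

test_that("two disjoint tubes give two candidates", {
  fx <- fixture("two_tubes", function() {
    sc1 <- quiet_scene(duration = 8, diameter = 14,
                       centerline = cbind(x = c(1, 128), y = c(24, 24)))
    sc2 <- quiet_scene(duration = 8, diameter = 14,
                       centerline = cbind(x = c(1, 128), y = c(72, 72)))
    t1 <- simulate_diameter_trace(sc1)
    t2 <- simulate_diameter_trace(sc2)
    v1 <- render_vessel_video(t1, sc1)$green
    v2 <- render_vessel_video(t2, sc2)$green
    video_stack(pmax(v1$frames, v2$frames), timestamps = v1$timestamps,
                pulse_frame = v1$pulse_frame)
  })
  cands <- segment_vessels(fx)
  expect_length(cands, 2)
})

test_that("arteriole selection is uniform, seeded, and the identity for one", {
  one <- list(list(mask = 1))
  expect_identical(select_arteriole(one, 5), one[[1]])
  two <- list("A", "B")
  expect_identical(select_arteriole(two, 7), select_arteriole(two, 7))
  picks <- vapply(1:10000, function(i)
    select_arteriole(two, seed = i) == "A", logical(1))
  expect_lt(abs(mean(picks) - 0.5), 0.02)
  expect_error(select_arteriole(list()), "no candidates")
})

test_that("scan lines are perpendicular, capped at 8, and cross the vessel", {
  fx <- fixture("tube20", function() rendered_tube(duration = 20, noise_sd = 4))
  cands <- segment_vessels(fx$green)
  lines <- suppressWarnings(
    place_scan_lines(cands[[1]]$centerline, cands[[1]]$mask))
  expect_lte(length(lines), 8)
  expect_gte(length(lines), 5)
  for (ln in lines) {
    d <- ln$p2 - ln$p1
    d <- d / sqrt(sum(d^2))
    # vessel is horizontal: lines must be vertical
    expect_lt(abs(d[1]), 0.05)
    # line crosses the mask
    u <- seq(0, 1, length.out = 50)
    hits <- cands[[1]]$mask[cbind(
      pmin(pmax(round(ln$p1[2] + u * (ln$p2[2] - ln$p1[2])), 1), 96),
      pmin(pmax(round(ln$p1[1] + u * (ln$p2[1] - ln$p1[1])), 1), 128))]
    expect_gte(sum(hits), 3)
  }
})

test_that("short centerlines yield fewer than 8 stations", {
  ctr <- list(points = cbind(x = seq(40, 56), y = rep(24, 17)),
              tangents = cbind(rep(1, 17), rep(0, 17)))
  mask <- matrix(FALSE, 48, 96)
  mask[14:34, 30:66] <- TRUE
  lines <- place_scan_lines(ctr, mask)
  expect_lt(length(lines), 8)
  expect_gte(length(lines), 1)
})

test_that("lines that do not cross the vessel are eliminated", {
  # centerline extends far beyond the masked vessel: stations off the mask
  # produce no foreground run and are dropped
  mask <- matrix(FALSE, 48, 128)
  mask[19:29, 1:50] <- TRUE
  ctr <- list(points = cbind(x = seq(5, 124), y = rep(24, 120)),
              tangents = cbind(rep(1, 120), rep(0, 120)))
  lines <- place_scan_lines(ctr, mask)
  expect_lt(length(lines), 8)
  for (ln in lines) expect_lt((ln$p1[1] + ln$p2[1]) / 2, 55)
  # fully off the vessel: nothing to draw
  empty <- matrix(FALSE, 48, 128)
  empty[40:44, 100:120] <- TRUE
  expect_error(place_scan_lines(ctr, empty), "unable to draw lines")
})

test_that("kymographs reproduce constant fields and flip with the line", {
  vid <- video_stack(array(77, c(48, 64, 6)), frame_rate = 10, pulse_frame = 3)
  line <- structure(list(index = 1L, p1 = c(32, 4), p2 = c(32, 44),
                         spacing = 1), class = "ScanLine")
  ky <- build_kymograph(vid, line)
  expect_true(all(ky$grid == 77))
  expect_equal(ncol(ky$grid), 6)

  fx <- fixture("tube20", function() rendered_tube(duration = 20, noise_sd = 4))
  fwd <- structure(list(index = 1L, p1 = c(60, 18), p2 = c(60, 78),
                        spacing = 1), class = "ScanLine")
  rev <- structure(list(index = 1L, p1 = c(60, 78), p2 = c(60, 18),
                        spacing = 1), class = "ScanLine")
  k1 <- build_kymograph(fx$green, fwd)
  k2 <- build_kymograph(fx$green, rev)
  expect_equal(k1$grid, k2$grid[nrow(k2$grid):1, ], tolerance = 1e-10)
  # widths downstream are identical
  f1 <- fit_intensity_mixture(k1)
  expect_equal(width_per_frame(k1, f1), width_per_frame(k2, f1),
               tolerance = 1e-10)
})

test_that("artifact flagging spares clean recordings and catches blur", {
  set.seed(11)
  frames <- array(rnorm(48 * 64 * 120, 100, 8), c(48, 64, 120))
  frames[frames < 0] <- 0; frames[frames > 255] <- 255
  vid <- video_stack(frames, frame_rate = 10, pulse_frame = 50)
  flags <- flag_artifact_frames(vid)
  # false-positive rate on artifact-free noise stays at the nominal level
  expect_lte(mean(flags), 0.01)

  # strongly blurred frame: focus feature collapses, |z| > 3
  blurred <- frames
  blurred[, , 80] <- EBImage::gblur(frames[, , 80], sigma = 4)
  vid2 <- video_stack(blurred, frame_rate = 10, pulse_frame = 50)
  flags2 <- flag_artifact_frames(vid2)
  expect_true(flags2[80])
  expect_lt(attr(flags2, "z")[80], -3)

  # constant stack: degenerate baseline
  flat <- video_stack(array(100, c(16, 16, 20)), frame_rate = 10,
                      pulse_frame = 10)
  expect_error(flag_artifact_frames(flat), "degenerate baseline")
})

test_that("frames within three baseline SDs are retained", {
  set.seed(12)
  frames <- array(rnorm(32 * 32 * 80, 100, 8), c(32, 32, 80))
  frames[frames < 0] <- 0; frames[frames > 255] <- 255
  vid <- video_stack(frames, frame_rate = 10, pulse_frame = 40)
  flags <- flag_artifact_frames(vid)
  z <- attr(flags, "z")
  expect_true(all(!flags[abs(z) <= 3]))
  expect_true(all(flags[abs(z) > 3]))
})

test_that("ejection is verified from the red channel and leaks are caught", {
  # long pre-pulse window so a leak 10 s before the pulse is observable
  sc <- scene_config(duration = 60, baseline_s = 25, pulse_time = 25,
                     noise_sd = 3, dilation_peaks = list())
  truth <- simulate_diameter_trace(sc)
  tip <- pipette_tip_region(sc)

  puffed <- render_vessel_video(truth, sc)
  res <- verify_ejection(puffed$red, tip)
  expect_true(res$ejected)
  expect_false(res$leak_before_pulse)

  no_puff <- render_vessel_video(truth, sc, puff_frame = NA)
  res2 <- verify_ejection(no_puff$red, tip)
  expect_false(res2$ejected)

  early <- render_vessel_video(truth, sc,
                               puff_frame = truth$pulse_frame - 100)
  res3 <- verify_ejection(early$red, tip)
  expect_true(res3$leak_before_pulse)

  expect_error(verify_ejection(puffed$red, list(x = -50, y = -50, radius = 1)),
               "empty")
})
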