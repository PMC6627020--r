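# deterministic speed/NII series with programmed recoil peaks
make_series <- function(n = 120, peaks = c(30, 60, 90), amp = 5,
                        base = 0.3, nii0 = 3.0, drop = 0.8, jitter = 0,
                        seed = 1) {
  set.seed(seed)
  sp <- rep(base, n - 1)
  nii <- rep(nii0, n)
  for (p in peaks) {
    sp[p + c(-1, 0, 1)] <- base * c((amp + 1) / 2, amp, (amp + 1) / 2)
    nii[p + (0:3)] <- nii0 - drop
  }
  if (jitter > 0) {
    sp <- sp + abs(rnorm(n - 1, 0, jitter))
    nii <- nii + rnorm(n, 0, jitter)
  }
  list(speeds = sp, nii = nii)
}

test_that("programmed recoil peaks are detected exactly", {
  s <- make_series()
  ev <- detect_phase4(s$speeds, s$nii)
  expect_equal(ev$peak_frame, c(30, 60, 90))
  expect_equal(ev$peak_speed, rep(1.5, 3))
  expect_true(all(ev$nii_drop < 0))
  # onset = base frame of the monotone speed rise
  expect_equal(ev$onset_frame, c(28, 58, 88))
})

test_that("constant tracks and non-rounding peaks yield no events", {
  flat <- make_series(peaks = integer(0))
  expect_equal(nrow(detect_phase4(flat$speeds, flat$nii)), 0L)
  # speed peak with NII *increasing*: deformation, not recoil
  s <- make_series(peaks = 50, drop = -0.8)
  expect_equal(nrow(detect_phase4(s$speeds, s$nii)), 0L)
  expect_error(detect_phase4(rep(1, 10), rep(2, 10)), "length mismatch")
})

test_that("event count is monotone in the detection thresholds", {
  s <- make_series(peaks = c(20, 50, 80, 110), amp = 4, jitter = 0.05,
                   seed = 4)
  n_by_bf <- vapply(c(1.2, 2, 3, 4.5),
                    function(bf) nrow(detect_phase4(s$speeds, s$nii,
                                                    baseline_factor = bf)),
                    integer(1))
  expect_true(all(diff(n_by_bf) <= 0))
  n_by_prom <- vapply(c(0.05, 0.3, 0.8, 1.5),
                      function(pr) nrow(detect_phase4(s$speeds, s$nii,
                                                      min_prominence = pr)),
                      integer(1))
  expect_true(all(diff(n_by_prom) <= 0))
})

test_that("aligned ensemble reproduces identical programmed peaks", {
  s <- make_series(n = 400, peaks = seq(30, 390, 40))
  ev <- detect_phase4(s$speeds, s$nii)
  expect_equal(nrow(ev), 10L)
  traces <- data.frame(time_min = (seq_len(400) - 1) * 5,
                       speed = c(s$speeds, NA), nii = s$nii)
  ens <- align_events(ev, traces, mode = "peak", window = 15,
                      frame_interval_min = 5)
  mid <- which(ens$table$rel_time_min == 0)
  expect_equal(ens$table$mean_speed[mid], 1.5)
  expect_equal(max(ens$table$sem_speed, na.rm = TRUE), 0)
  expect_true(all(ens$table$n[ens$table$n > 0] == 10))
})

test_that("ensemble mean equals a brute-force average of the traces", {
  s <- make_series(n = 200, peaks = c(40, 90, 140), jitter = 0.02, seed = 9)
  ev <- detect_phase4(s$speeds, s$nii)
  traces <- data.frame(time_min = (seq_len(200) - 1) * 5,
                       speed = c(s$speeds, NA), nii = s$nii)
  ens <- align_events(ev, traces, mode = "onset", window = 20,
                      frame_interval_min = 5)
  brute <- colMeans(ens$traces$speed, na.rm = TRUE)
  expect_equal(unname(ens$table$mean_speed), unname(brute), tolerance = 1e-12)
})

test_that("a single event has a mean but no s.e.m.", {
  s <- make_series(peaks = 60)
  ev <- detect_phase4(s$speeds, s$nii)
  traces <- data.frame(time_min = (seq_len(120) - 1) * 5,
                       speed = c(s$speeds, NA))
  ens <- align_events(ev, traces, mode = "peak", window = 10,
                      frame_interval_min = 5)
  expect_true(all(is.na(ens$table$sem_speed)))
  expect_equal(ens$table$mean_speed[ens$table$rel_time_min == 0], 1.5)
})

test_that("pore-centre alignment puts time zero at the crossing", {
  tr <- trajectory(seq(0, 40, 2), rep(0, 21), seq(0, 100, 5))
  traces <- data.frame(time_min = tr$time_min, speed = c(rep(0.4, 20), NA))
  ens <- align_events(NULL, traces, mode = "pore_center",
                      trajectory = tr, pore = 21, window = 20,
                      frame_interval_min = 5)
  # x = 21 um is crossed at t = 52.5, snapped to the nearest sampled frame
  expect_true(ens$t0 %in% c(50, 55))
  pore_line <- list(p1 = c(21, -5), p2 = c(21, 5))
  ens2 <- align_events(NULL, traces, mode = "pore_center", trajectory = tr,
                       pore = pore_line, window = 20, frame_interval_min = 5)
  expect_equal(ens2$t0, ens$t0)
})

test_that("step partition is exhaustive, disjoint and correctly sized", {
  steps <- data.frame(cell_id = "c1", frame = 1:20,
                      speed = rep(0.3, 20), delta_nii = rep(0.05, 20))
  ev <- data.frame(cell_id = "c1", onset_frame = 5L, peak_frame = 6L,
                   end_frame = 7L, peak_speed = 1.5, nii_drop = -0.8)
  part <- partition_steps(steps, ev)
  expect_equal(nrow(part$phase4_steps), 3L)
  expect_equal(nrow(part$remaining_steps), 17L)
  expect_setequal(c(part$phase4_steps$frame, part$remaining_steps$frame), 1:20)
  # no events: everything is remaining
  none <- partition_steps(steps, ev[0, ])
  expect_equal(nrow(none$remaining_steps), 20L)
})

test_that("partition recovers a programmed speed contrast", {
  set.seed(17)
  n_events <- 50
  steps <- NULL; evs <- NULL
  for (k in seq_len(n_events)) {
    cid <- paste0("c", k)
    sp <- abs(rnorm(30, 0.3, 0.03))
    sp[14:16] <- abs(rnorm(3, 0.6, 0.03))  # phase-IV steps at 2x speed
    steps <- rbind(steps, data.frame(cell_id = cid, frame = 1:30, speed = sp))
    evs <- rbind(evs, data.frame(cell_id = cid, onset_frame = 14L,
                                 peak_frame = 15L, end_frame = 16L,
                                 peak_speed = max(sp), nii_drop = -0.5))
  }
  part <- partition_steps(steps, evs)
  med <- part$summary[part$summary$metric == "speed", ]
  ratio <- med$median[med$group == "phase4"] /
           med$median[med$group == "remaining"]
  expect_lt(abs(ratio / 2 - 1), 0.15)
})

test_that("group comparison behaves on identical and shifted samples", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 2.9)
  res <- compare_groups(x, x)
  expect_gte(res$mw_p, 0.99)
  expect_gte(res$ks_p, 0.99)
  expect_error(compare_groups(1:2, 1:10), "at least 3")
  set.seed(31)
  hits <- 0
  for (r in 1:50) {
    a <- rnorm(50); b <- rnorm(50, 2)  # 2 s.d. shift
    res <- compare_groups(a, b)
    if (res$mw_p < 0.001 && res$ks_p < 0.001) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.95)
})

test_that("events survive the movie pipeline with noise", {
  sim <- simulate_migration_movie(small_scenario(noise_sd = 19, seed = 5))
  seq_ <- segment_stack(sim$stack, smooth_sigma = 2)
  met <- shape_metrics_track(seq_)
  tr <- trajectory(seq_$centroids_um[, 1], seq_$centroids_um[, 2],
                   seq_$times_min)
  ev <- detect_phase4(step_speeds(tr), met$table$nii)
  expect_equal(nrow(ev), 1L)
  expect_lte(abs(ev$peak_frame - sim$event_frames), 1)
})
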