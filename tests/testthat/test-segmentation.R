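test_that("Otsu segmentation recovers a disc area to 1%", {
  img <- disc_image(50)
  mf <- segment_frame(img, "otsu")
  expect_equal(mf$n_objects, 1L)
  expect_lt(abs(sum(mf$mask) / (pi * 50^2) - 1), 0.01)
})

test_that("uniform frames give an empty mask, flagged not an error", {
  mf <- segment_frame(matrix(7, 64, 64))
  expect_true(mf$empty)
  expect_equal(sum(mf$mask), 0)
})

test_that("objects below min_area are removed", {
  img <- disc_image(20, center = c(40, 40), size = c(120, 120)) +
    disc_image(7, center = c(90, 90), size = c(120, 120)) - 10
  mf <- segment_frame(img, "otsu", min_area = 200)
  expect_equal(mf$n_objects, 1L)
  mf2 <- segment_frame(img, "otsu", min_area = 50)
  expect_equal(mf2$n_objects, 2L)
})

test_that("labelling is 8-connected", {
  m <- matrix(0, 20, 20)
  m[5:8, 5:8] <- 1
  m[9:12, 9:12] <- 1  # touches only diagonally
  mf <- segment_frame(m, method = 0.5, min_area = 0)
  expect_equal(mf$n_objects, 1L)
})

test_that("segmentation is idempotent on binary input", {
  m1 <- segment_frame(disc_image(30), "otsu")$mask
  m2 <- segment_frame(matrix(as.numeric(m1), nrow(m1)), "otsu")$mask
  expect_identical(m1, m2)
})

test_that("mask area is non-increasing in a fixed threshold", {
  set.seed(42)
  img <- disc_image(30, size = c(101, 101)) + matrix(rnorm(101^2, 0, 15), 101)
  areas <- vapply(c(50, 80, 110, 140, 170),
                  function(th) sum(segment_frame(img, th, min_area = 0)$mask),
                  numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("outline of a rasterized disc matches the analytic circle", {
  ol <- extract_outline(disc_mask(100))
  expect_lt(abs(poly_area(ol) / (pi * 100^2) - 1), 0.01)
  expect_lt(abs(poly_perimeter(ol) / (2 * pi * 100) - 1), 0.02)
})

test_that("outline of a square has near-analytic perimeter and area", {
  m <- matrix(0L, 100, 100)
  m[26:75, 26:75] <- 1L
  ol <- extract_outline(m)
  expect_lt(abs(poly_perimeter(ol) / 200 - 1), 0.02)
  expect_lt(abs(poly_area(ol) / 2500 - 1), 0.01)
})

test_that("degenerate and multi-component outlines are rejected", {
  one_px <- matrix(0L, 9, 9); one_px[5, 5] <- 1L
  expect_error(extract_outline(one_px), "degenerate|too small")
  two <- matrix(0L, 40, 40); two[5:15, 5:15] <- 1L; two[25:35, 25:35] <- 1L
  expect_error(extract_outline(two), "multi-component")
})

test_that("polygon centroid agrees with mask centroid within rasterization", {
  m <- disc_mask(40)
  ol <- extract_outline(m)
  pc <- poly_centroid(ol)
  idx <- which(m == 1L, arr.ind = TRUE)
  expect_lt(abs(pc[1] - mean(idx[, 2])), 0.1)
  expect_lt(abs(pc[2] - mean(idx[, 1])), 0.1)
})

test_that("stack round-trips through TIFF and rejects bad input", {
  sim <- simulate_migration_movie(small_scenario(n_frames = 10L))
  path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(sim$stack$frames, function(f) f / 255), path)
  st <- load_stack(path, pixel_size_um = 0.5, frame_interval_min = 5)
  expect_length(st$frames, 10L)
  expect_equal(dim(st$frames[[1]]), c(256L, 256L))
  expect_error(load_stack(tempfile()), "cannot read")
  expect_error(load_stack(path, channel = 3L), "channel")
  # single-frame stack is accepted
  tiff::writeTIFF(sim$stack$frames[[1]] / 255, path)
  expect_length(load_stack(path)$frames, 1L)
  # mismatched frame sizes violate the stack invariant
  expect_error(frame_stack(list(matrix(0, 4, 4), matrix(0, 5, 5))),
               "non-uniform")
})

test_that("tracking recovers the programmed centroid path", {
  sim <- simulate_migration_movie(small_scenario())
  seq_ <- segment_stack(sim$stack)
  err <- sqrt((seq_$centroids_px[, 1] - sim$truth$cx_px)^2 +
              (seq_$centroids_px[, 2] - sim$truth$cy_px)^2)
  expect_lt(sqrt(mean(err^2)), 1)           # RMS within 1 px
  expect_gte(mean(err <= 2), 0.99)          # >= 99% within 2 px
})

test_that("largest policy ignores a transient second object", {
  main <- lapply(1:4, function(i) disc_mask(20, center = c(40, 30 + 5 * i),
                                            size = c(100, 100)))
  main[[3]] <- main[[3]] + disc_mask(9, center = c(80, 80), size = c(100, 100))
  masks <- lapply(seq_along(main), function(i) as_mask_frame(main[[i]], i))
  seq_ <- track_single_nucleus(masks, policy = "largest")
  expect_equal(nrow(seq_$centroids_px), 4L)
  # y stays on the main object's track (x-coordinate column is centroid x)
  expect_true(all(abs(seq_$centroids_px[, 2] - 40) < 1))
})

test_that("short gaps are interpolated and flagged, long gaps split", {
  mk <- function(y) as_mask_frame(disc_mask(15, center = c(40, y),
                                            size = c(100, 100)))
  empty <- as_mask_frame(matrix(0L, 100, 100))
  masks <- list(mk(20), mk(30), empty, mk(50), mk(60))
  seq_ <- track_single_nucleus(masks, max_gap = 2L)
  expect_equal(seq_$gap_interpolated, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(seq_$centroids_px[3, 1], 40, tolerance = 0.05)
  # a 3-frame gap with max_gap = 2 splits; the longest segment is kept
  masks2 <- list(mk(20), empty, empty, empty, mk(50), mk(60))
  seq2 <- track_single_nucleus(masks2, max_gap = 2L)
  expect_equal(seq2$frames, c(5L, 6L))
})

test_that("nearest-centroid policy without a seed needs a unique start", {
  two <- disc_mask(15, center = c(30, 30), size = c(100, 100)) +
         disc_mask(15, center = c(70, 70), size = c(100, 100))
  masks <- list(as_mask_frame(two, 1L), as_mask_frame(two, 2L))
  expect_error(track_single_nucleus(masks, policy = "nearest_centroid"),
               "seed_centroid")
  seq_ <- track_single_nucleus(masks, policy = "nearest_centroid",
                               seed_centroid = c(70, 70))
  expect_lt(abs(seq_$centroids_px[1, 1] - 70), 1)
})
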