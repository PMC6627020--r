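# shared fixtures: analytic shapes, rasterized discs, small movies, oracles

# star-shaped random polygon: simple by construction (radii vs sorted angles)
random_star_polygon <- function(n = 12, r_range = c(0.5, 1.5), seed = 1) {
  set.seed(seed)
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, r_range[1], r_range[2])
  list(x = r * cos(th), y = r * sin(th))
}

# binary disc image (rows = y, cols = x), pixel centres at integers
disc_image <- function(radius, center = NULL, size = NULL, fg = 200, bg = 10) {
  if (is.null(size)) size <- rep(ceiling(2 * radius) + 21, 2)
  if (is.null(center)) center <- (size + 1) / 2
  xs <- matrix(rep(seq_len(size[2]), each = size[1]), size[1])
  ys <- matrix(rep(seq_len(size[1]), size[2]), size[1])
  m <- (xs - center[2])^2 + (ys - center[1])^2 <= radius^2
  bg + (fg - bg) * m
}

disc_mask <- function(radius, center = NULL, size = NULL) {
  m <- disc_image(radius, center, size, fg = 1, bg = 0)
  storage.mode(m) <- "integer"
  m
}

# Ramanujan approximation of the ellipse perimeter (independent oracle)
ramanujan_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# small fast movie used across unit tests (one programmed recoil peak)
small_scenario <- function(seed = 1, noise_sd = 0, n_frames = 24L,
                           onset = max(2L, min(11L, n_frames - 4L))) {
  migration_scenario(
    n_frames = n_frames,
    image_size = c(256L, 256L),
    peak_schedule = data.frame(onset_frame = onset, duration = 3L,
                               amplitude_factor = 5),
    noise_sd = noise_sd,
    seed = seed
  )
}

# mask_frame wrapper for hand-built binary images
as_mask_frame <- function(m, frame_index = 1L) {
  segment_frame(m, method = 0.5, min_area = 0, fill_holes = FALSE,
                frame_index = frame_index)
}
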