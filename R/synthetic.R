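#' Migration-movie scenario
#'
#' Parameters of a synthetic time-lapse of a single labelled nucleus that
#' translates with a programmed speed profile and deforms through an
#' elongated / pinched ("hourglass") shape, recoiling to a circular disc
#' during each programmed speed peak. The defaults emulate confined
#' interstitial migration: 0.3 um/min baseline speed (reported interstitial
#' speeds are 0.2-0.4 um/min), 5-min frame interval, 0.5 um pixels,
#' 7 um nucleus radius, 512 x 512 px field. The default deformation
#' (elongation 1.2, pinch 0.15) sets the programmed NII drop of a recoil
#' to about 0.8.
#'
#' @param n_frames number of frames.
#' @param frame_interval_min minutes per frame.
#' @param pixel_size_um microns per pixel.
#' @param image_size `c(rows, cols)` in px.
#' @param nucleus_radius_um undeformed nucleus radius.
#' @param baseline_speed baseline centroid speed, um/min.
#' @param peak_schedule data.frame with `onset_frame`, `duration` (frames),
#'   `amplitude_factor` (peak speed as a multiple of baseline); peaks must
#'   be disjoint.
#' @param elongation_base axis-stretch factor of the deformed shape (>= 1).
#' @param pinch_base hourglass pinch of the deformed shape, in \[0, 1).
#' @param recovery_frames frames over which the nucleus re-deforms after a
#'   recoil.
#' @param heading_deg direction of motion, degrees.
#' @param heading_jitter_deg s.d. of per-step Gaussian heading jitter.
#' @param fg_intensity,bg_intensity nuclear and background intensities.
#' @param noise_sd additive Gaussian intensity noise s.d. (0 = noise-free).
#' @param seed integer seed; seeded runs are bit-reproducible.
#' @return A `migration_scenario` list.
#' @export
migration_scenario <- function(n_frames = 60L,
                               frame_interval_min = 5,
                               pixel_size_um = 0.5,
                               image_size = c(512L, 512L),
                               nucleus_radius_um = 7,
                               baseline_speed = 0.3,
                               peak_schedule = data.frame(
                                 onset_frame = c(15L, 30L, 45L),
                                 duration = 3L,
                                 amplitude_factor = 5),
                               elongation_base = 1.2,
                               pinch_base = 0.15,
                               recovery_frames = 4L,
                               heading_deg = 30,
                               heading_jitter_deg = 0,
                               fg_intensity = 200,
                               bg_intensity = 10,
                               noise_sd = 0,
                               seed = 1L) {
  stopifnot(n_frames >= 2L, frame_interval_min > 0, pixel_size_um > 0,
            nucleus_radius_um > 0, baseline_speed >= 0,
            elongation_base >= 1, pinch_base >= 0, pinch_base < 1)
  sc <- structure(mget(names(formals())), class = "migration_scenario")
  if (nrow(peak_schedule) > 1L) {
    ps <- peak_schedule[order(peak_schedule$onset_frame), ]
    if (any(ps$onset_frame[-1] <= ps$onset_frame[-nrow(ps)] +
            ps$duration[-nrow(ps)])) {
      stop("peak_schedule windows must be disjoint")
    }
  }
  sc
}

# per-frame speed multiplier (triangular bump within each peak window) and
# shape relaxation (1 = round disc) with a post-peak recovery ramp
scenario_profiles <- function(sc) {
  n <- sc$n_frames
  mult <- rep(1, n)
  relax <- rep(0, n)
  peak_frames <- integer(0)
  for (k in seq_len(nrow(sc$peak_schedule))) {
    on <- sc$peak_schedule$onset_frame[k]
    dur <- sc$peak_schedule$duration[k]
    amp <- sc$peak_schedule$amplitude_factor[k]
    pk <- on + (dur - 1L) %/% 2L
    if (pk >= n || on < 2L) {
      stop("peak at frame ", pk, " falls outside the movie (frames 2..",
           n - 1L, ")")
    }
    f <- on:min(on + dur - 1L, n)
    tri <- 1 - abs(f - pk) / ((dur + 1) / 2)
    mult[f] <- 1 + (amp - 1) * tri
    # rounding: ramps up to full relaxation at the peak frame, holds over
    # the window, then re-deforms over recovery_frames
    up <- on:pk
    relax[up] <- pmax(relax[up], (up - on + 1) / (pk - on + 1))
    hold <- pk:min(on + dur - 1L, n)
    relax[hold] <- 1
    rec <- seq_len(sc$recovery_frames)
    down <- pk + dur - 1L + rec - 1L
    ok <- down <= n
    relax[down[ok]] <- pmax(relax[down[ok]], rev(rec / (sc$recovery_frames + 1))[ok])
    peak_frames <- c(peak_frames, pk)
  }
  list(mult = mult, relax = relax, peak_frames = peak_frames)
}

# rasterize the nucleus: union of two discs (pinch p) stretched by factor
# `ea` along the heading axis; p = 0, ea = 1 gives a plain disc
rasterize_nucleus <- function(nr, nc, cx, cy, r_px, ea, p, theta) {
  xs <- matrix(rep(seq_len(nc), each = nr), nr) - cx
  ys <- matrix(rep(seq_len(nr), nc), nr) - cy
  s <- (xs * cos(theta) + ys * sin(theta)) / ea
  tq <- -xs * sin(theta) + ys * cos(theta)
  s0 <- 1.2 * r_px * p
  rs <- r_px * (1 - 0.3 * p)
  ((s - s0)^2 + tq^2 <= rs^2) | ((s + s0)^2 + tq^2 <= rs^2)
}

#' Simulate a migration movie with ground truth
#'
#' Renders the scenario into a `frame_stack` and returns the exact
#' programmed ground truth alongside: centroid path, per-step speeds,
#' per-frame shape parameters, and the programmed recoil-peak frames.
#'
#' @param scenario a [migration_scenario()].
#' @return List with `stack` (a `frame_stack`), `truth` (data.frame:
#'   frame, time_min, cx_px, cy_px, cx_um, cy_um, elongation, pinch,
#'   relax, step_speed_um_min — the speed of the step leaving each frame,
#'   NA for the last), `event_frames` (programmed peak frames), and
#'   `scenario`.
#' @export
simulate_migration_movie <- function(scenario) {
  sc <- scenario
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(sc$seed)
  n <- sc$n_frames
  nr <- sc$image_size[1]; nc <- sc$image_size[2]
  dt <- sc$frame_interval_min
  r_px <- sc$nucleus_radius_um / sc$pixel_size_um
  pr <- scenario_profiles(sc)
  speeds <- sc$baseline_speed * pr$mult[seq_len(n - 1L)]      # um/min, step t
  headings <- (sc$heading_deg +
    if (sc$heading_jitter_deg > 0) stats::rnorm(n - 1L, 0, sc$heading_jitter_deg)
    else rep(0, n - 1L)) * pi / 180
  steps_px <- speeds * dt / sc$pixel_size_um
  dx <- c(0, cumsum(steps_px * cos(headings)))
  dy <- c(0, cumsum(steps_px * sin(headings)))
  margin <- r_px * sc$elongation_base * (1 + 1.2 * sc$pinch_base) + 3
  cx <- (nc - (max(dx) - min(dx))) / 2 - min(dx) + dx
  cy <- (nr - (max(dy) - min(dy))) / 2 - min(dy) + dy
  if (min(cx) < margin || max(cx) > nc - margin ||
      min(cy) < margin || max(cy) > nr - margin) {
    stop("programmed path does not fit: nucleus would leave the image frame")
  }
  ea <- sc$elongation_base + (1 - sc$elongation_base) * pr$relax
  pinch <- sc$pinch_base * (1 - pr$relax)
  frames <- vector("list", n)
  frame_theta <- c(headings[1], headings)  # shape axis follows motion
  for (f in seq_len(n)) {
    m <- rasterize_nucleus(nr, nc, cx[f], cy[f], r_px, ea[f], pinch[f],
                           frame_theta[f])
    img <- sc$bg_intensity + (sc$fg_intensity - sc$bg_intensity) * m
    if (sc$noise_sd > 0) img <- img + stats::rnorm(nr * nc, 0, sc$noise_sd)
    frames[[f]] <- matrix(img, nr, nc)
  }
  truth <- data.frame(
    frame = seq_len(n),
    time_min = (seq_len(n) - 1L) * dt,
    cx_px = cx, cy_px = cy,
    cx_um = cx * sc$pixel_size_um, cy_um = cy * sc$pixel_size_um,
    elongation = ea, pinch = pinch, relax = pr$relax,
    step_speed_um_min = c(speeds, NA)
  )
  list(stack = frame_stack(frames, sc$pixel_size_um, sc$frame_interval_min),
       truth = truth,
       event_frames = pr$peak_frames,
       scenario = sc)
}

#' Force-curve scenario
#'
#' Parameters of a synthetic AFM force-distance cycle on a soft sample:
#' Hertzian sphere-on-flat approach up to `max_force`, a retraction scaled
#' so that the enclosed hysteresis area is a set fraction of the approach
#' work, an optional adhesion dip, and additive Gaussian force noise.
#' Defaults follow a typical nuclear-indentation setup: 10-um-diameter
#' bead (radius 5 um), 15 nN force setpoint, incompressible sample
#' (nu = 0.5), E = 1 kPa.
#'
#' @param youngs_modulus sample elastic modulus, Pa.
#' @param bead_radius probe sphere radius, um.
#' @param poisson_ratio sample Poisson ratio.
#' @param max_force force setpoint terminating the approach, nN.
#' @param hysteresis_fraction dissipated fraction of the approach work,
#'   in \[0, 1).
#' @param adhesion_depth depth of the retraction adhesion dip, nN (0 =
#'   none).
#' @param spring_constant cantilever spring constant, N/m.
#' @param noise_sd force noise s.d.: nN when `noise_type = "additive"`, a
#'   relative fraction when `"multiplicative"`.
#' @param noise_type `"additive"` Gaussian noise on the force, or
#'   `"multiplicative"` (force scaled by `1 + N(0, noise_sd)`).
#' @param n_contact,n_baseline samples in the contact and baseline parts.
#' @param z_contact piezo position of first contact, um.
#' @param seed integer seed.
#' @return A `curve_scenario` list.
#' @export
curve_scenario <- function(youngs_modulus = 1000,
                           bead_radius = 5,
                           poisson_ratio = 0.5,
                           max_force = 15,
                           hysteresis_fraction = 0.3,
                           adhesion_depth = 0,
                           spring_constant = 0.1,
                           noise_sd = 0,
                           noise_type = c("additive", "multiplicative"),
                           n_contact = 400L,
                           n_baseline = 200L,
                           z_contact = 1,
                           seed = 1L) {
  noise_type <- match.arg(noise_type)
  stopifnot(youngs_modulus > 0, bead_radius > 0,
            poisson_ratio >= 0, poisson_ratio < 0.5 + 1e-9,
            max_force > 0, hysteresis_fraction >= 0, hysteresis_fraction < 1,
            spring_constant > 0, n_contact >= 50L, n_baseline >= 50L)
  structure(mget(names(formals())), class = "curve_scenario")
}

# Hertz prefactor in nN / um^(3/2): F = C * delta^(3/2)
hertz_prefactor <- function(E_pa, bead_radius_um, poisson_ratio) {
  (4 / 3) * (E_pa * 1e-3 / (1 - poisson_ratio^2)) * sqrt(bead_radius_um)
}

#' Simulate an AFM force-distance cycle with ground truth
#'
#' @param scenario a [curve_scenario()].
#' @return List with `curve` (a `force_curve`, see [force_curve()]) and
#'   `truth` (scenario parameters plus the programmed maximal indentation
#'   `delta_max_um`, approach work `e_approach_J`, and contact position).
#' @export
simulate_force_curve <- function(scenario) {
  sc <- scenario
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(sc$seed)
  C <- hertz_prefactor(sc$youngs_modulus, sc$bead_radius, sc$poisson_ratio)
  delta_max <- (sc$max_force / C)^(2 / 3)
  k_nn_um <- sc$spring_constant * 1000  # N/m -> nN/um
  delta <- seq(0, delta_max, length.out = sc$n_contact)
  f_app <- C * delta^1.5
  z_base <- seq(0, sc$z_contact, length.out = sc$n_baseline + 1L)[-(sc$n_baseline + 1L)]
  z_app <- c(z_base, sc$z_contact + delta + f_app / k_nn_um)
  force_app <- c(rep(0, sc$n_baseline), f_app)
  f_ret <- (1 - sc$hysteresis_fraction) * f_app
  z_ret <- sc$z_contact + delta + f_ret / k_nn_um
  z_ret <- rev(z_ret); f_ret <- rev(f_ret)
  if (sc$adhesion_depth > 0) {
    # adhesion dip just past pull-off, then release back to baseline
    n_ad <- 60L
    frac <- seq_len(n_ad) / (n_ad + 1L)
    z_ad <- sc$z_contact - frac * 0.4
    f_ad <- -sc$adhesion_depth * sin(pi * frac)^2 /
      max(sin(pi * frac)^2)
    z_ret <- c(z_ret, z_ad)
    f_ret <- c(f_ret, f_ad)
  }
  n_tail <- 40L
  z_tail <- seq(min(z_ret) - 0.01, min(z_ret) - 0.3, length.out = n_tail)
  z_ret <- c(z_ret, z_tail); f_ret <- c(f_ret, rep(0, n_tail))
  if (sc$noise_sd > 0) {
    if (sc$noise_type == "additive") {
      force_app <- force_app + stats::rnorm(length(force_app), 0, sc$noise_sd)
      f_ret <- f_ret + stats::rnorm(length(f_ret), 0, sc$noise_sd)
    } else {
      force_app <- force_app * (1 + stats::rnorm(length(force_app), 0, sc$noise_sd))
      f_ret <- f_ret * (1 + stats::rnorm(length(f_ret), 0, sc$noise_sd))
    }
  }
  curve <- force_curve(approach = data.frame(z_um = z_app, force_nN = force_app),
                       retraction = data.frame(z_um = z_ret, force_nN = f_ret),
                       bead_radius_um = sc$bead_radius,
                       spring_constant_N_m = sc$spring_constant)
  e_app <- C * 2 / 5 * delta_max^2.5 * 1e-15  # nN um -> J
  list(curve = curve,
       truth = c(unclass(sc),
                 list(delta_max_um = delta_max, e_approach_J = e_app)))
}
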