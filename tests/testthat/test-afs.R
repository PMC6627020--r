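test_that("contact point is exact on a noise-free Hertz curve", {
  sim <- simulate_force_curve(curve_scenario())
  ct <- find_contact_point(sim$curve)
  expect_lt(abs(ct$z_contact - sim$truth$z_contact), 1e-4)
  expect_lte(abs(ct$contact_index - (sim$truth$n_baseline + 1L)), 2L)
})

test_that("a pure-baseline curve raises a no-contact error", {
  set.seed(2)
  flat <- force_curve(
    approach = data.frame(z_um = seq(0, 2, length.out = 300),
                          force_nN = rnorm(300, 0, 0.01)),
    retraction = data.frame(z_um = seq(2, 0, length.out = 300),
                            force_nN = rnorm(300, 0, 0.01)),
    bead_radius_um = 5)
  expect_error(find_contact_point(flat), "no contact")
})

test_that("contact detection stays within 5 samples at SNR 20", {
  errs <- vapply(1:100, function(s) {
    sim <- simulate_force_curve(curve_scenario(noise_sd = 15 / 20,
                                               n_contact = 150L,
                                               n_baseline = 60L, seed = s))
    abs(find_contact_point(sim$curve)$contact_index - 61L)
  }, numeric(1))
  expect_lte(max(errs), 5)
})

test_that("indentation conversion handles limit cases", {
  # rigid surface: force rises with no sample deformation
  z <- seq(0, 2, length.out = 300)
  k <- 0.1
  f <- pmax(z - 1, 0) * k * 1000  # all piezo travel becomes bending
  rigid <- force_curve(data.frame(z_um = z, force_nN = f),
                       data.frame(z_um = rev(z), force_nN = rev(f)),
                       bead_radius_um = 5, spring_constant_N_m = k)
  ind <- to_indentation(rigid, list(contact_index = 151L, z_contact = 1,
                                    baseline = 0, mad = 0))
  expect_lt(max(ind$delta_um), 1e-9)
  # zero force throughout: indentation equals piezo travel past contact
  free <- force_curve(data.frame(z_um = z, force_nN = rep(0, 300)),
                      data.frame(z_um = rev(z), force_nN = rep(0, 300)),
                      bead_radius_um = 5, spring_constant_N_m = k)
  ind2 <- to_indentation(free, list(contact_index = 151L, z_contact = 1,
                                    baseline = 0, mad = 0))
  expect_equal(ind2$delta_um, pmax(z - 1, 0), tolerance = 1e-12)
  # generator indentation round-trips exactly
  sim <- simulate_force_curve(curve_scenario())
  ind3 <- to_indentation(sim$curve, find_contact_point(sim$curve))
  expect_equal(max(ind3$delta_um), sim$truth$delta_max_um, tolerance = 1e-4)
})

test_that("penetration at a setpoint matches the Hertz closed form", {
  sim <- simulate_force_curve(curve_scenario(youngs_modulus = 1000,
                                             bead_radius = 5))
  ind <- to_indentation(sim$curve, find_contact_point(sim$curve))
  pen <- penetration_at(2, ind)
  C <- (4 / 3) * (1000 * 1e-3 / (1 - 0.5^2)) * sqrt(5)
  expect_equal(pen, (2 / C)^(2 / 3), tolerance = 1e-3)
  # stiffer sample penetrates less at the same force
  sim2 <- simulate_force_curve(curve_scenario(youngs_modulus = 2000))
  pen2 <- penetration_at(2, to_indentation(sim2$curve,
                                           find_contact_point(sim2$curve)))
  expect_lt(pen2, pen)
  expect_error(penetration_at(99, ind), "never reached")
})

test_that("Hertz fit round-trips the generator modulus", {
  sim <- simulate_force_curve(curve_scenario(youngs_modulus = 1000))
  fit <- fit_hertz_sphere(to_indentation(sim$curve,
                                         find_contact_point(sim$curve)), 5)
  expect_lt(abs(fit$youngs_modulus_Pa - 1000), 1)
  expect_lt(fit$residual_rms_rel, 1e-6)
})

test_that("a linear force curve is flagged by a large Hertz residual", {
  z <- seq(0, 3, length.out = 400)
  lin <- structure(data.frame(delta_um = pmax(z - 1, 0),
                              force_nN = pmax(z - 1, 0) * 7),
                   class = c("indentation_curve", "data.frame"))
  fit <- fit_hertz_sphere(lin, 5)
  expect_gt(fit$residual_rms_rel, 0.05)
})

test_that("dissipation energies recover the programmed hysteresis", {
  sim <- simulate_force_curve(curve_scenario(hysteresis_fraction = 0.3))
  en <- dissipation_energies(sim$curve)
  expect_equal(en$relative_dissipation, 0.30, tolerance = 0.01)
  expect_equal(en$e_approach_J, sim$truth$e_approach_J, tolerance = 1e-3)
  expect_equal(en$e_dissipation_J, en$e_approach_J - en$e_retraction_J)
  # elastic limit: identical approach and retraction dissipate nothing
  el <- simulate_force_curve(curve_scenario(hysteresis_fraction = 0))
  expect_equal(dissipation_energies(el$curve)$relative_dissipation, 0,
               tolerance = 1e-6)
})

test_that("adhesion is measured but excluded from retraction work", {
  base <- simulate_force_curve(curve_scenario(hysteresis_fraction = 0.3))
  shallow <- simulate_force_curve(curve_scenario(hysteresis_fraction = 0.3,
                                                 adhesion_depth = 0.3))
  deep <- simulate_force_curve(curve_scenario(hysteresis_fraction = 0.3,
                                              adhesion_depth = 0.6))
  expect_equal(min(deep$curve$retraction$force_nN), -0.6, tolerance = 1e-9)
  e0 <- dissipation_energies(base$curve)
  e1 <- dissipation_energies(shallow$curve)
  e2 <- dissipation_energies(deep$curve)
  expect_equal(e0$e_adhesion_J, 0, tolerance = 1e-18)
  expect_gt(e2$e_adhesion_J, e1$e_adhesion_J)
  expect_equal(e1$e_retraction_J, e2$e_retraction_J, tolerance = 1e-3)
})

test_that("energy bookkeeping invariants hold across generator settings", {
  for (h in c(0, 0.15, 0.45)) {
    en <- dissipation_energies(
      simulate_force_curve(curve_scenario(hysteresis_fraction = h))$curve)
    expect_gte(en$e_approach_J, en$e_retraction_J - 1e-18)
    expect_gte(en$e_retraction_J, 0)
    expect_gte(en$relative_dissipation, -1e-9)
    expect_lte(en$relative_dissipation, 1)
  }
})

test_that("the modulus is unit-homogeneous (um/nN vs nm/pN inputs)", {
  sim <- simulate_force_curve(curve_scenario())
  ind <- to_indentation(sim$curve, find_contact_point(sim$curve))
  E1 <- fit_hertz_sphere(ind, 5)$youngs_modulus_Pa
  scaled <- structure(data.frame(delta_um = ind$delta_um * 1000,
                                 force_nN = ind$force_nN * 1000),
                      class = c("indentation_curve", "data.frame"))
  # lengths x1000 and forces x1000 scale the fitted prefactor by
  # 1000^(-1/2) and sqrt(R) by 1000^(1/2): E comes back scaled by 1/1000
  E2 <- fit_hertz_sphere(scaled, 5 * 1000)$youngs_modulus_Pa
  expect_equal(E2 * 1000, E1, tolerance = 1e-9)
})

test_that("force curves round-trip through text files", {
  sim <- simulate_force_curve(curve_scenario(adhesion_depth = 0.4))
  path <- tempfile(fileext = ".txt")
  n <- max(nrow(sim$curve$approach), nrow(sim$curve$retraction))
  pad <- function(v) c(v, rep(NA, n - length(v)))
  utils::write.table(
    data.frame(z_app = pad(sim$curve$approach$z_um),
               f_app = pad(sim$curve$approach$force_nN),
               z_ret = pad(sim$curve$retraction$z_um),
               f_ret = pad(sim$curve$retraction$force_nN)),
    path, row.names = FALSE)
  rt <- read_force_curve(path, bead_radius_um = 5, spring_constant_N_m = 0.1)
  expect_equal(rt$approach$force_nN, sim$curve$approach$force_nN)
  res <- analyze_force_curve(rt)
  expect_equal(res$youngs_modulus_Pa, 1000, tolerance = 1e-3)
  expect_equal(res$relative_dissipation, 0.3, tolerance = 0.01)
})

test_that("repeated probings are summarised per cell by the median", {
  rows <- do.call(rbind, lapply(1:6, function(s) {
    sim <- simulate_force_curve(curve_scenario(
      youngs_modulus = 1000, noise_sd = 0.02, noise_type = "multiplicative",
      seed = s))
    cbind(cell_id = if (s <= 3) "a" else "b", analyze_force_curve(sim$curve))
  }))
  summ <- summarize_cell_mechanics(rows)
  expect_equal(nrow(summ), 2L)
  expect_equal(summ$n_curves, c(3L, 3L))
  expect_equal(summ$youngs_modulus_Pa[1],
               median(rows$youngs_modulus_Pa[1:3]))
})
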