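#' AFM force-distance curve
#'
#' Container for one probing cycle. The approach segment must be ordered
#' toward the sample (piezo position increasing); force is in nN, piezo
#' position in um.
#'
#' @param approach,retraction data.frames with columns `z_um`, `force_nN`.
#' @param bead_radius_um probe sphere radius, um.
#' @param spring_constant_N_m cantilever spring constant, N/m; optional
#'   when forces are already expressed against tip-sample distance.
#' @return A `force_curve` object.
#' @export
force_curve <- function(approach, retraction, bead_radius_um,
                        spring_constant_N_m = NULL) {
  stopifnot(all(c("z_um", "force_nN") %in% names(approach)),
            all(c("z_um", "force_nN") %in% names(retraction)),
            bead_radius_um > 0)
  structure(list(approach = approach, retraction = retraction,
                 bead_radius_um = bead_radius_um,
                 spring_constant_N_m = spring_constant_N_m),
            class = "force_curve")
}

#' Read a force curve from delimited text
#'
#' Accepts two layouts: four numeric columns (approach z, approach force,
#' retraction z, retraction force; rows may be padded with NA) or three
#' columns (`segment` = "approach"/"retraction", z, force). A `#`-comment
#' header is ignored.
#'
#' @param path input text file.
#' @param bead_radius_um,spring_constant_N_m probe calibration (see
#'   [force_curve()]).
#' @param sep field separator (default: any whitespace).
#' @return A `force_curve`.
#' @export
read_force_curve <- function(path, bead_radius_um, spring_constant_N_m = NULL,
                             sep = "") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) == 4L && all(vapply(tab, is.numeric, logical(1)))) {
    app <- stats::na.omit(data.frame(z_um = tab[[1]], force_nN = tab[[2]]))
    ret <- stats::na.omit(data.frame(z_um = tab[[3]], force_nN = tab[[4]]))
  } else if (ncol(tab) == 3L) {
    seg <- tolower(tab[[1]])
    app <- data.frame(z_um = tab[[2]][seg == "approach"],
                      force_nN = tab[[3]][seg == "approach"])
    ret <- data.frame(z_um = tab[[2]][seg == "retraction"],
                      force_nN = tab[[3]][seg == "retraction"])
  } else {
    stop("unrecognised force-curve layout: need 4 numeric or 3 labelled columns")
  }
  force_curve(app, ret, bead_radius_um, spring_constant_N_m)
}

#' Locate the contact point on the approach curve
#'
#' The force baseline is the median of the first 30% of approach samples;
#' contact is the first sample whose force exceeds
#' `baseline + noise_k * MAD` and stays above for at least 5 consecutive
#' samples. The piezo position of contact is then refined to sub-sample
#' precision by a whole-curve fit of the Hertzian contact profile
#' `F = C max(z' - z0, 0)^(3/2)` (with `z'` the bending-corrected piezo
#' position), profiling out `C` and optimizing `z0` — this uses the
#' high-signal deep-contact part of the curve, where the threshold
#' crossing alone is systematically late under noise.
#'
#' @param curve a `force_curve` (>= 100 approach samples).
#' @param noise_k threshold multiplier on the baseline MAD (default 5).
#' @return List with `contact_index` (approach sample nearest the refined
#'   contact), `crossing_index` (first above-threshold sample),
#'   `z_contact` (refined piezo position of zero indentation), `baseline`,
#'   `mad`.
#' @export
find_contact_point <- function(curve, noise_k = 5) {
  z <- curve$approach$z_um
  f <- curve$approach$force_nN
  n <- length(f)
  if (n < 100L) stop("need at least 100 approach samples")
  base_idx <- seq_len(max(10L, floor(0.3 * n)))
  baseline <- stats::median(f[base_idx])
  noise <- stats::mad(f[base_idx])
  if (noise == 0) noise <- max(1e-6, 1e-6 * max(abs(f)))
  above <- f > baseline + noise_k * noise
  cand <- which(above)
  cand <- cand[cand <= n - 4L]
  ok <- cand[vapply(cand, function(i) all(above[i:(i + 4L)]), logical(1))]
  if (length(ok) == 0L) stop("no contact found: force never leaves baseline")
  i0 <- ok[1]
  k <- curve$spring_constant_N_m
  fr <- f - baseline
  zc <- z - if (is.null(k)) 0 else fr / (k * 1000)
  rss <- function(z0) {
    g <- pmax(zc - z0, 0)^1.5
    s2 <- sum(g * g)
    if (s2 == 0) return(sum(fr^2))
    sum((fr - sum(fr * g) / s2 * g)^2)
  }
  # coarse scan over every sample position up to the crossing, then local
  # refinement of the bracket (rss can be flat-ish far from the optimum)
  grid <- seq_len(i0)
  rss_g <- vapply(zc[grid], rss, numeric(1))
  jbest <- grid[which.min(rss_g)]
  lo <- zc[max(1L, jbest - 2L)]
  hi <- zc[min(i0, jbest + 2L)]
  z0 <- if (hi > lo) stats::optimize(rss, c(lo, hi), tol = 1e-8)$minimum
        else zc[jbest]
  list(contact_index = which.min(abs(zc - z0)), crossing_index = i0,
       z_contact = unname(z0), baseline = baseline, mad = noise)
}

#' Convert a force-distance segment to force-indentation
#'
#' Indentation is piezo travel past contact minus cantilever bending:
#' `delta = (z - z_contact) - force / k`; negative values before contact
#' are clipped to 0. Without a spring constant the curve is assumed to be
#' already expressed against tip-sample distance (no bending term).
#'
#' @param curve a `force_curve`.
#' @param contact optional result of [find_contact_point()]; computed when
#'   missing.
#' @param segment `"approach"` or `"retraction"`.
#' @return An `indentation_curve`: data.frame `delta_um`, `force_nN` with
#'   attributes `contact_index`, `z_contact`.
#' @export
to_indentation <- function(curve, contact = NULL,
                           segment = c("approach", "retraction")) {
  segment <- match.arg(segment)
  if (is.null(contact)) contact <- find_contact_point(curve)
  seg <- curve[[segment]]
  k <- curve$spring_constant_N_m
  bend <- if (is.null(k)) 0 else (seg$force_nN - contact$baseline) / (k * 1000)
  delta <- (seg$z_um - contact$z_contact) - bend
  delta <- pmax(delta, 0)
  structure(data.frame(delta_um = delta,
                       force_nN = seg$force_nN - contact$baseline),
            contact_index = contact$contact_index,
            z_contact = contact$z_contact,
            class = c("indentation_curve", "data.frame"))
}

#' Penetration depth at a force setpoint
#'
#' Indentation at the first point of the approach curve where the force
#' reaches the setpoint, with linear interpolation between samples.
#'
#' @param force_setpoint target force, nN.
#' @param ind an `indentation_curve` (approach segment).
#' @return Penetration in um.
#' @export
penetration_at <- function(force_setpoint, ind) {
  f <- ind$force_nN; d <- ind$delta_um
  if (max(f) < force_setpoint) {
    stop("setpoint ", force_setpoint, " nN never reached (max ",
         signif(max(f), 4), " nN)")
  }
  i <- which(f >= force_setpoint)[1]
  if (i == 1L || f[i] == force_setpoint) return(d[i])
  w <- (force_setpoint - f[i - 1L]) / (f[i] - f[i - 1L])
  d[i - 1L] + w * (d[i] - d[i - 1L])
}

#' Hertz sphere fit of a force-indentation curve
#'
#' Least-squares fit of `F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2)`
#' over a stated fraction of the indentation range (default 10-90% of the
#' maximal indentation, excluding contact-point uncertainty near delta = 0
#' and deep-indentation substrate effects). The model is linear in
#' `delta^(3/2)`, so the fit is a through-origin linear regression.
#'
#' @param ind an `indentation_curve` (approach segment).
#' @param bead_radius_um probe sphere radius, um.
#' @param poisson_ratio sample Poisson ratio (default 0.5, incompressible).
#' @param fit_fraction length-2 fraction of the maximal indentation to fit
#'   over.
#' @return List with `youngs_modulus_Pa`, `prefactor_nN_um32`,
#'   `residual_rms_rel` (RMS residual relative to the maximal fitted
#'   force), and `n_fit`.
#' @export
fit_hertz_sphere <- function(ind, bead_radius_um, poisson_ratio = 0.5,
                             fit_fraction = c(0.1, 0.9)) {
  sel <- ind$delta_um > 0 & is.finite(ind$force_nN)
  dmax <- max(ind$delta_um)
  sel <- sel & ind$delta_um >= fit_fraction[1] * dmax &
               ind$delta_um <= fit_fraction[2] * dmax
  if (sum(sel) < 20L) stop("fewer than 20 post-contact samples in fit range")
  x <- ind$delta_um[sel]^1.5
  y <- ind$force_nN[sel]
  C <- sum(x * y) / sum(x * x)
  if (!is.finite(C) || C <= 0) stop("Hertz fit did not converge")
  E <- C * 0.75 * (1 - poisson_ratio^2) / sqrt(bead_radius_um) * 1e3  # Pa
  resid <- y - C * x
  list(youngs_modulus_Pa = E,
       prefactor_nN_um32 = C,
       residual_rms_rel = sqrt(mean(resid^2)) / max(abs(C * x)),
       n_fit = sum(sel))
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Approach/retraction energies and dissipation
#'
#' Integrates force over indentation for the approach and retraction
#' segments (trapezoidal rule, positive-force part only). The adhesion
#' energy — the area of the negative-force part of the retraction — is
#' reported separately and excluded from the retraction work, because it
#' measures bead-sample stickiness rather than deformation.
#' `E_dissipation = E_approach - E_retraction`; the relative dissipation is
#' `E_dissipation / E_approach`.
#'
#' @param curve a `force_curve`.
#' @param contact optional [find_contact_point()] result.
#' @return List of class `mechanics_energies` with `e_approach_J`,
#'   `e_retraction_J`, `e_adhesion_J`, `e_dissipation_J`,
#'   `relative_dissipation` (all energies in joules; 1 nN um = 1e-15 J).
#' @export
dissipation_energies <- function(curve, contact = NULL) {
  if (is.null(contact)) contact <- find_contact_point(curve)
  app <- to_indentation(curve, contact, "approach")
  ret <- to_indentation(curve, contact, "retraction")
  seg_work <- function(ic) {
    keep <- ic$force_nN > 0 & ic$delta_um > 0
    if (sum(keep) < 2L) return(0)
    o <- order(ic$delta_um[keep])
    abs(trapz(ic$delta_um[keep][o], ic$force_nN[keep][o]))
  }
  e_app <- seg_work(app) * 1e-15
  e_ret <- seg_work(ret) * 1e-15
  # adhesion: negative-force part of the retraction, integrated over piezo
  # travel (the tip is off the surface, indentation is not defined there)
  radh <- curve$retraction
  fneg <- pmin(radh$force_nN - contact$baseline, 0)
  o <- order(radh$z_um)
  e_adh <- abs(trapz(radh$z_um[o], fneg[o])) * 1e-15
  if (e_app <= 0) stop("approach curve carries no positive-force work")
  structure(list(
    e_approach_J = e_app,
    e_retraction_J = e_ret,
    e_adhesion_J = e_adh,
    e_dissipation_J = e_app - e_ret,
    relative_dissipation = (e_app - e_ret) / e_app
  ), class = "mechanics_energies")
}

#' Full mechanics analysis of one force curve
#'
#' Contact point, penetration at a setpoint, Hertz modulus, and energies.
#'
#' @param curve a `force_curve`.
#' @param setpoint_nN force setpoint for the penetration readout
#'   (default 2 nN).
#' @param poisson_ratio,fit_fraction passed to [fit_hertz_sphere()].
#' @param noise_k passed to [find_contact_point()].
#' @return A one-row data.frame with contact, penetration, modulus, energy
#'   and dissipation columns.
#' @export
analyze_force_curve <- function(curve, setpoint_nN = 2, poisson_ratio = 0.5,
                                fit_fraction = c(0.1, 0.9), noise_k = 5) {
  ct <- find_contact_point(curve, noise_k)
  app <- to_indentation(curve, ct, "approach")
  fit <- fit_hertz_sphere(app, curve$bead_radius_um, poisson_ratio,
                          fit_fraction)
  en <- dissipation_energies(curve, ct)
  data.frame(
    z_contact_um = ct$z_contact,
    penetration_um = penetration_at(setpoint_nN, app),
    setpoint_nN = setpoint_nN,
    youngs_modulus_Pa = fit$youngs_modulus_Pa,
    fit_residual_rel = fit$residual_rms_rel,
    e_approach_J = en$e_approach_J,
    e_retraction_J = en$e_retraction_J,
    e_adhesion_J = en$e_adhesion_J,
    e_dissipation_J = en$e_dissipation_J,
    relative_dissipation = en$relative_dissipation
  )
}

#' Summarise repeated probings per cell
#'
#' Repeated force curves on the same cell (typically 3-5) are summarised
#' by the median of each mechanical readout.
#'
#' @param results data.frame of per-curve rows from [analyze_force_curve()]
#'   with an added `cell_id` column.
#' @return One row per cell with median readouts and `n_curves`.
#' @export
summarize_cell_mechanics <- function(results) {
  stopifnot("cell_id" %in% names(results))
  num <- names(results)[vapply(results, is.numeric, logical(1))]
  out <- do.call(rbind, lapply(split(results, results$cell_id), function(d) {
    row <- as.data.frame(lapply(d[num], stats::median))
    cbind(data.frame(cell_id = d$cell_id[1], n_curves = nrow(d)), row)
  }))
  rownames(out) <- NULL
  out
}
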