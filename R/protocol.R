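# End-to-end geometric-route protocol on a toy host-guest complex:
# bound-state conformational PMF, five sequential angular PMFs (restraints
# applied cumulatively), separation PMF with all restraints on, bulk
# conformational PMF, analytic bulk reorientation, and composition.

#' Reference three-bead toy host-guest complex
#'
#' A stiff bead-and-spring triangle (three 12-amu beads, harmonic bonds)
#' bound in a Gaussian well displaced from the host-frame origin, so that the
#' bound guest sits at separation ~4 A in the direction theta = 90, phi = 0
#' and all angular coordinates are well away from their poles.  The Euler
#' reference structure is pre-rotated so the bound orientation reads
#' (Theta, Phi, Psi) ~ (90, 0, 0).
#'
#' @param well_depth well depth per bead, kcal/mol
#' @param well_sigma well width, A
#' @param well_center well centre, A
#' @param k_bond bond stiffness, kcal/(mol A^2)
#' @return list with the [toy_system()] (`system`), centred conformational
#'   reference (`ref_conf`), Euler reference (`ref_euler`), and the bound
#'   coordinates (`x_bound`)
#' @export
toy_complex <- function(well_depth = 6, well_sigma = 1.2,
                        well_center = c(4, 0, 0), k_bond = 300) {
  tri <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.92, 1.44, 0))
  rel <- sweep(tri, 2, colMeans(tri))
  ref_euler <- rel %*% rotation_from_euler(90, 0, 0)
  x_bound <- sweep(rel, 2, well_center, `+`)
  sys <- toy_system(
    masses = c(12, 12, 12), positions = x_bound,
    bonds = rbind(c(1, 2, k_bond, 1.5), c(2, 3, k_bond, 1.5),
                  c(1, 3, k_bond, 2.4)),
    host = host_gaussian_wells(centers = rbind(well_center),
                               depths = well_depth, sigmas = well_sigma))
  list(system = sys, ref_conf = rel, ref_euler = ref_euler,
       x_bound = x_bound, well_center = well_center)
}

#' Configuration for the toy binding protocol
#'
#' Collects every tunable of [end_to_end_toy_binding()] with the package's
#' study-condition defaults: restraint force constants 0.1 kcal/(mol deg^2)
#' (angular) and 100 kcal/(mol A^2) (conformational RMSD), bin widths of
#' 1 deg / 0.05 A / 0.1 A for angular, RMSD and separation profiles, a
#' reference separation of 14 A where the toy host field is negligible, and
#' a site boundary at 7 A.
#'
#' @param k_rmsd,k_ang restraint force constants
#' @param r_star reference (non-interacting) separation, A
#' @param site_radius site boundary for the bound basin / site wall, A
#' @param v0 standard-state volume, A^3
#' @param temperature kelvin
#' @param steps_scale multiplies every per-stage step budget
#' @param seed integer seed for the whole protocol
#' @param dt,friction integrator parameters
#' @return a configuration list
#' @export
toy_binding_config <- function(k_rmsd = 100, k_ang = 0.1, r_star = 14,
                               site_radius = 7, v0 = 1661, temperature = 300,
                               steps_scale = 1, seed = 1, dt = 0.002,
                               friction = 5, estimator = "naive") {
  list(k_rmsd = k_rmsd, k_ang = k_ang, r_star = r_star,
       site_radius = site_radius, v0 = v0, temperature = temperature,
       steps_scale = steps_scale, seed = seed, dt = dt, friction = friction,
       estimator = estimator,
       centers = list(rmsd = 0, Theta = 90, Phi = 0, Psi = 0,
                      theta = 90, phi = 0))
}

#' Full geometric-route binding free energy of the toy complex
#'
#' Orchestrates the stepwise protocol: (1) bound-state conformational PMF
#' along the fitted guest RMSD; (2-6) PMFs along Theta, Phi, Psi, theta, phi
#' with the restraints of the previous stages applied cumulatively; (7) the
#' separation PMF with all restraints active, stratified into consecutive
#' windows; (8) the bulk conformational PMF; plus the analytic bulk
#' reorientation term.  The nine terms compose into the standard binding
#' free energy; every sampled term carries a two-block error.
#'
#' A flat-bottom radial wall at `site_radius` bounds the site region during
#' the bound-state stages; its placement is in the far tail of the bound
#' distribution, so the composed result is insensitive to its exact form.
#'
#' @param complex a [toy_complex()]
#' @param config a [toy_binding_config()]
#' @return a `cycle_result` with the per-stage PMFs attached as
#'   `attr(, "pmfs")` and the stage table as `attr(, "stages")`
#' @export
end_to_end_toy_binding <- function(complex = toy_complex(),
                                   config = toy_binding_config()) {
  cfg <- config
  sys <- complex$system
  th <- thermo_state(cfg$temperature)
  sc <- cfg$steps_scale
  seed <- as.integer(cfg$seed)

  cv_rmsd <- colvar("rmsd", ref = complex$ref_conf, mode = "fitted")
  cv_Theta <- colvar("Theta", ref = complex$ref_euler)
  cv_Phi <- colvar("Phi", ref = complex$ref_euler)
  cv_Psi <- colvar("Psi", ref = complex$ref_euler)
  cv_theta <- colvar("theta")
  cv_phi <- colvar("phi")
  cv_sep <- colvar("separation")

  r_rmsd <- restraint(cv_rmsd, cfg$centers$rmsd, cfg$k_rmsd)
  r_Theta <- restraint(cv_Theta, cfg$centers$Theta, cfg$k_ang)
  r_Phi <- restraint(cv_Phi, cfg$centers$Phi, cfg$k_ang)
  r_Psi <- restraint(cv_Psi, cfg$centers$Psi, cfg$k_ang)
  r_theta <- restraint(cv_theta, cfg$centers$theta, cfg$k_ang)
  r_phi <- restraint(cv_phi, cfg$centers$phi, cfg$k_ang)
  wall <- restraint(cv_sep, cfg$site_radius, 20, type = "upper_wall")

  run_stage <- function(cv, lo, hi, bw, n_windows, steps, restr, x0,
                        stage_seed, host_on = TRUE) {
    s <- sys
    if (!host_on) s$host <- host_none()
    compute_pmf(s, cv, lo = lo, hi = hi, bin_width = bw,
                n_windows = n_windows, steps_per_window = round(steps * sc),
                dt = cfg$dt, friction = cfg$friction,
                temperature = th, seed = stage_seed, restraints = restr,
                x0 = x0, estimator = cfg$estimator)
  }
  time_ns <- function(pm) {
    sum(vapply(pm$runs, function(r) r$n_steps, numeric(1))) * cfg$dt / 1000
  }
  rel_dg <- function(pm, restr, closed = c(FALSE, FALSE)) {
    restraint_dg_from_pmf(pm$profile, restr, th, direction = "release",
                          blocks = pm$blocks, closed = closed)
  }

  x0 <- complex$x_bound
  stages <- list()

  # 1. bound-state conformational PMF (site wall only)
  stages$c_site <- run_stage(cv_rmsd, 0, 0.45, 0.05, 1, 4e5,
                             list(wall), x0, seed + 11L)
  # 2-4. Euler angles, restraints imposed cumulatively
  stages$Theta_site <- run_stage(cv_Theta, 10, 170, 1, 2, 5e5,
                                 list(wall, r_rmsd), x0, seed + 12L)
  stages$Phi_site <- run_stage(cv_Phi, -180, 180, 1, 1, 5e5,
                               list(wall, r_rmsd, r_Theta), x0, seed + 13L)
  stages$Psi_site <- run_stage(cv_Psi, -180, 180, 1, 1, 5e5,
                               list(wall, r_rmsd, r_Theta, r_Phi), x0,
                               seed + 14L)
  # 5-6. polar angles of the guest COM
  stages$theta_site <- run_stage(cv_theta, 10, 170, 1, 2, 5e5,
                                 list(wall, r_rmsd, r_Theta, r_Phi, r_Psi),
                                 x0, seed + 15L)
  stages$phi_site <- run_stage(cv_phi, -180, 180, 1, 1, 5e5,
                               list(wall, r_rmsd, r_Theta, r_Phi, r_Psi,
                                    r_theta), x0, seed + 16L)
  # 7. separation PMF, all restraints on, no wall
  stages$separation <- run_stage(cv_sep, 2.6, cfg$r_star, 0.1, 3, 1.2e6,
                                 list(r_rmsd, r_Theta, r_Phi, r_Psi,
                                      r_theta, r_phi), x0, seed + 17L)
  # 8. bulk conformational PMF (guest alone)
  stages$c_bulk <- run_stage(cv_rmsd, 0, 0.45, 0.05, 1, 4e5,
                             list(), complex$ref_conf, seed + 18L,
                             host_on = FALSE)

  d_c_site <- rel_dg(stages$c_site, r_rmsd, closed = c(TRUE, FALSE))
  d_Theta <- rel_dg(stages$Theta_site, r_Theta)
  d_Phi <- rel_dg(stages$Phi_site, r_Phi, closed = c(TRUE, TRUE))
  d_Psi <- rel_dg(stages$Psi_site, r_Psi, closed = c(TRUE, TRUE))
  d_theta <- rel_dg(stages$theta_site, r_theta)
  d_phi <- rel_dg(stages$phi_site, r_phi, closed = c(TRUE, TRUE))
  sep <- separation_standard_term(stages$separation$profile, r_theta, r_phi,
                                  r_star = cfg$r_star, thermo = th,
                                  v0 = cfg$v0,
                                  basin = c(2.6, cfg$site_radius),
                                  blocks = stages$separation$blocks)
  d_c_bulk <- restraint_dg_from_pmf(stages$c_bulk$profile, r_rmsd, th,
                                    direction = "impose",
                                    blocks = stages$c_bulk$blocks,
                                    closed = c(TRUE, FALSE))
  d_o_bulk <- analytic_bulk_orientation(cfg$k_ang, cfg$k_ang, cfg$k_ang,
                                        centers = c(cfg$centers$Theta,
                                                    cfg$centers$Phi,
                                                    cfg$centers$Psi), th)

  contribs <- list(
    cycle_contribution("c_site", d_c_site$dg, d_c_site$error,
                       time_ns(stages$c_site)),
    cycle_contribution("Theta_site", d_Theta$dg, d_Theta$error,
                       time_ns(stages$Theta_site)),
    cycle_contribution("Phi_site", d_Phi$dg, d_Phi$error,
                       time_ns(stages$Phi_site)),
    cycle_contribution("Psi_site", d_Psi$dg, d_Psi$error,
                       time_ns(stages$Psi_site)),
    cycle_contribution("theta_site", d_theta$dg, d_theta$error,
                       time_ns(stages$theta_site)),
    cycle_contribution("phi_site", d_phi$dg, d_phi$error,
                       time_ns(stages$phi_site)),
    cycle_contribution("separation_term", sep$dg, sep$error,
                       time_ns(stages$separation)),
    cycle_contribution("c_bulk", d_c_bulk$dg, d_c_bulk$error,
                       time_ns(stages$c_bulk)),
    cycle_contribution("o_bulk", d_o_bulk))
  res <- compose_cycle(contribs, th, cfg$v0)
  attr(res, "pmfs") <- lapply(stages, function(s) s$profile)
  attr(res, "stages") <- stages
  attr(res, "config") <- cfg
  res
}

#' Brute-force reference for the toy binding free energy
#'
#' Convenience wrapper running [brute_force_keq()] with the site definition
#' matching [end_to_end_toy_binding()] (guest COM inside `site_radius`).
#'
#' @inheritParams end_to_end_toy_binding
#' @param n_samples Monte-Carlo samples
#' @param seed integer seed
#' @return list from [brute_force_keq()] (includes `dg_bind` and `dg_se`)
#' @export
toy_binding_oracle <- function(complex = toy_complex(),
                               config = toy_binding_config(),
                               n_samples = 6e5, seed = 1234) {
  brute_force_keq(complex$system, site_center = c(0, 0, 0),
                  site_radius = config$site_radius,
                  thermo = thermo_state(config$temperature),
                  n_samples = n_samples, seed = seed,
                  proposal_center = complex$well_center,
                  v0 = config$v0)
}
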