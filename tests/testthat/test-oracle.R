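# Brute-force configurational-integral oracle.

test_that("analytic harmonic restraint free energy matches closed forms", {
  th <- thermo_state(300)
  kT <- 1 / th$beta
  # azimuthal 360-degree domain, k = 0.1 kcal/(mol deg^2)
  ell <- sqrt(2 * pi * kT / 0.1)
  expect_equal(analytic_harmonic_dg(0.1, 0, c(-180, 180), thermo = th),
               -kT * log(ell / 360), tolerance = 1e-6)
  expect_equal(analytic_harmonic_dg(0, 0, c(-180, 180), thermo = th), 0)
  expect_lt(analytic_harmonic_dg(1e-9, 0, c(-180, 180), thermo = th), 1e-5)
  # polar angle with sin Jacobian at 90 degrees: stiff-limit formula
  d2r <- pi / 180
  stiff <- -kT * log(ell * d2r * sin(90 * d2r) / 2)  # /int_0^pi sin = 2
  expect_equal(analytic_harmonic_dg(0.1, 90, c(0, 180), jacobian = TRUE,
                                    thermo = th), stiff, tolerance = 0.01)
  expect_error(analytic_harmonic_dg(0.1, 200, c(-180, 180)), "outside")
})

# bin-averaged closed-form profile: the oracle reports the Boltzmann mass
# of each bin, so the exact reference is the bin average of exp(-beta w)
bin_avg_ref <- function(wfun, centers, bw, kT = kT300) {
  v <- vapply(centers, function(c0)
    -kT * log(integrate(function(z) exp(-wfun(z) / kT),
                        c0 - bw / 2, c0 + bw / 2)$value / bw), numeric(1))
  v - min(v)
}

test_that("brute-force PMF reproduces closed-form marginals", {
  # harmonic trap: w(x) = k/2 x^2
  sys <- harmonic_bead(k = 3)
  cv <- colvar("axis_projection", axis = c(1, 0, 0))
  p <- brute_force_pmf(sys, cv, lo = -1.5, hi = 1.5, bin_width = 0.1,
                       range = 5, n_grid = c(200, 150, 150))
  ref <- bin_avg_ref(function(z) 1.5 * z^2, p$centers, 0.1)
  expect_lt(max(abs(p$value - ref)), 0.01)
  # separable quartic + transverse harmonic: marginal is the quartic
  dw <- double_well_bead(height = 2.5)
  p2 <- brute_force_pmf(dw, cv, lo = -1.6, hi = 1.6, bin_width = 0.05,
                        range = 5, n_grid = c(800, 80, 80))
  ref2 <- bin_avg_ref(function(z) 2.5 * (z^2 - 1)^2, p2$centers, 0.05)
  expect_lt(max(abs(p2$value - ref2)[ref2 < 6]), 0.01)
  expect_error(brute_force_pmf(toy_complex()$system, cv, 0, 1, 0.1),
               "single-bead")
})

test_that("oracle results are grid-convergent", {
  sys <- double_well_bead(height = 2.5)
  cv <- colvar("axis_projection", axis = c(1, 0, 0))
  coarse <- brute_force_pmf(sys, cv, -1.6, 1.6, 0.1, range = 5,
                            n_grid = c(400, 60, 60))
  fine <- brute_force_pmf(sys, cv, -1.6, 1.6, 0.1, range = 5,
                          n_grid = c(800, 120, 120))
  sel <- fine$value <= 4   # thermally relevant region
  expect_lt(max(abs(coarse$value - fine$value)[sel]), 0.02)
})

test_that("square-well K_eq matches the hand formula", {
  th <- thermo_state(300)
  eps <- 3; a <- 1
  sys <- toy_system(masses = 12, positions = rbind(c(0, 0, 0)),
                    host = host_square_well(radius = a, depth = eps))
  o <- brute_force_keq(sys, site_center = c(0, 0, 0), site_radius = a,
                       thermo = th, n_grid = 161)
  v <- 4 / 3 * pi * a^3
  expect_equal(o$keq, v * exp(th$beta * eps), tolerance = 0.02)
  # no well: the binding free energy is purely entropic, -kT ln(v/V0)
  sys0 <- toy_system(masses = 12, positions = rbind(c(0, 0, 0)),
                     host = host_square_well(radius = a, depth = 0))
  o0 <- brute_force_keq(sys0, site_center = c(0, 0, 0), site_radius = a,
                        thermo = th, n_grid = 161)
  expect_equal(o0$dg_bind, -log(v / 1661) / th$beta, tolerance = 0.02)
})

test_that("Monte-Carlo K_eq is deterministic by seed and self-consistent", {
  tc <- toy_complex()
  a <- brute_force_keq(tc$system, site_radius = 7, n_samples = 5e4, seed = 91)
  b <- brute_force_keq(tc$system, site_radius = 7, n_samples = 5e4, seed = 91)
  expect_identical(a$keq, b$keq)
  c <- brute_force_keq(tc$system, site_radius = 7, n_samples = 2e5, seed = 92)
  # independent runs agree within combined standard errors
  expect_lt(abs(a$dg_bind - c$dg_bind),
            4 * sqrt(a$dg_se^2 + c$dg_se^2))
})

test_that("the product of stepwise ratios telescopes to the direct K_eq", {
  tc <- toy_complex()
  rc <- list(restraint(colvar("rmsd", ref = tc$ref_conf), 0, 100))
  ro <- list(restraint(colvar("Theta", ref = tc$ref_euler), 90, 0.1),
             restraint(colvar("Phi", ref = tc$ref_euler), 0, 0.1),
             restraint(colvar("Psi", ref = tc$ref_euler), 0, 0.1))
  ra <- list(restraint(colvar("theta"), 90, 0.1),
             restraint(colvar("phi"), 0, 0.1))
  id <- keq_cycle_identity(tc$system, site_radius = 7, restraints_c = rc,
                           restraints_o = ro, restraints_a = ra,
                           n_samples = 1e5, seed = 93)
  expect_lt(id$relative_gap, 1e-6)
  # and the direct ratio agrees with the independent K_eq integrator
  o <- brute_force_keq(tc$system, site_radius = 7, n_samples = 4e5, seed = 94)
  expect_lt(abs(log(id$keq / o$keq)), 5 * (o$dg_se * thermo_state(300)$beta +
                                           0.05))
})
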