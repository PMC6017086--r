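# Toy systems: potentials, forces, Langevin sampler, fixture generators.

test_that("potential energy matches construction and rejects bad input", {
  well <- toy_system(masses = 12, positions = rbind(c(0, 0, 0)),
                     host = host_gaussian_wells(rbind(c(0, 0, 0)), 5, 1.2))
  expect_equal(potential_energy(well, rbind(c(0, 0, 0))), -5)
  bonded <- toy_system(masses = c(12, 12),
                       positions = rbind(c(0, 0, 0), c(1.5, 0, 0)),
                       bonds = cbind(1, 2, 300, 1.5))
  expect_equal(potential_energy(bonded, bonded$positions), 0)
  expect_error(potential_energy(bonded, rbind(c(0, 0, 0))), "rows")
  expect_error(potential_energy(bonded, rbind(c(0, 0, NaN), c(0, 0, 0))))
})

test_that("analytic forces match central finite differences on every host", {
  set.seed(23)
  systems <- list(
    toy_system(masses = c(12, 12, 12),
               positions = matrix(rnorm(9), 3, 3),
               bonds = rbind(c(1, 2, 300, 1.5), c(2, 3, 300, 1.5),
                             c(1, 3, 300, 2.4)),
               host = host_gaussian_wells(rbind(c(1, 0, 0), c(-1, 0, 2)),
                                          c(6, 3), c(1.2, 0.8))),
    toy_system(masses = 12, positions = rbind(c(0.4, 0.2, -0.3)),
               host = host_double_well()),
    toy_system(masses = 12, positions = rbind(c(0.3, -0.5, 0.2)),
               host = host_harmonic(k = 2)),
    toy_system(masses = rep(12, 4), positions = matrix(rnorm(12, sd = 2), 4, 3),
               bonds = rbind(c(1, 2, 200, 1.5), c(2, 3, 200, 1.5),
                             c(3, 4, 200, 1.5)),
               dihedrals = rbind(c(1, 2, 3, 4, 2, 1, 0))))
  for (sys in systems) {
    X <- sys$positions + matrix(rnorm(length(sys$positions), sd = 0.3),
                                nrow(sys$positions), 3)
    ff <- guest_forces(sys, X)
    g <- fd_gradient(function(Z) potential_energy(sys, Z), X)
    expect_lt(max(abs(ff$forces + g)), 1e-6)
  }
})

test_that("zero-friction limit conserves energy (no systematic drift)", {
  sys <- toy_system(masses = c(12, 12), positions = rbind(c(0,0,0), c(1.6,0,0)),
                    bonds = cbind(1, 2, 300, 1.5))
  tr <- run_trajectory(sys, n_steps = 10000, dt = 0.001, friction = 0,
                       seed = 1, stride = 10)
  etot <- tr$potential + tr$kinetic
  drift <- abs(coef(lm(etot ~ tr$step))[2]) * 10000
  expect_lt(drift, 1e-4)
})

test_that("Langevin sampling reproduces equipartition and trap statistics", {
  sys <- harmonic_bead(k = 3)
  tr <- run_trajectory(sys, n_steps = 4e5, dt = 0.002, friction = 2, seed = 2,
                       stride = 20,
                       cvs = list(colvar("axis_projection", axis = c(1, 0, 0))))
  x <- tr$cv[-(1:500), 1]
  # effective sample size with an AR(1) correction for autocorrelation
  rho <- cor(x[-1], x[-length(x)])
  neff <- length(x) * (1 - rho) / (1 + rho)
  se_var <- var(x) * sqrt(2 / neff)
  expect_lt(abs(var(x) - kT300 / 3), 3 * se_var)
  ke <- tr$kinetic[-(1:500)]
  rho_k <- cor(ke[-1], ke[-length(ke)])
  neff_k <- length(ke) * (1 - rho_k) / (1 + rho_k)
  expect_lt(abs(mean(ke) - 1.5 * kT300), 3 * sd(ke) / sqrt(neff_k))
})

test_that("trajectories are bit-identical for identical seeds", {
  sys <- harmonic_bead()
  a <- run_trajectory(sys, 2000, seed = 9, stride = 10,
                      cvs = list(colvar("separation")))
  b <- run_trajectory(sys, 2000, seed = 9, stride = 10,
                      cvs = list(colvar("separation")))
  expect_identical(a$cv, b$cv)
  expect_identical(a$x_final, b$x_final)
  c <- run_trajectory(sys, 2000, seed = 10, stride = 10,
                      cvs = list(colvar("separation")))
  expect_false(identical(a$cv, c$cv))
})

test_that("a zero-step protocol records only the initial frame", {
  sys <- harmonic_bead()
  tr <- run_trajectory(sys, 0, seed = 4, cvs = list(colvar("separation")))
  expect_equal(length(tr$step), 1)
  expect_equal(tr$step[1], 0)
})

test_that("an unobservable CV is rejected before any dynamics", {
  sys <- harmonic_bead()  # single bead: no orientation
  expect_error(run_trajectory(sys, 100, seed = 1,
                              cvs = list(colvar("Theta", ref = diag(3)))),
               "at least 3")
})

test_that("a stiff dihedral restraint pins the sampled circular mean", {
  # 1-3 / 2-4 bonds keep the chain bent so the torsion stays well defined
  d13 <- sqrt(5)
  sys <- toy_system(masses = rep(12, 4),
                    positions = rbind(c(-1, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                      c(2, -1, 0)),
                    bonds = rbind(c(1, 2, 300, sqrt(2)), c(2, 3, 300, 1),
                                  c(3, 4, 300, sqrt(2)),
                                  c(1, 3, 100, d13), c(2, 4, 100, d13)))
  cvd <- colvar("dihedral", atoms = 1:4)
  # 0.02 kcal/(mol deg^2) confines the torsion to sigma ~ 5.5 degrees while
  # keeping the restrained oscillation slow against the time step
  tr <- run_trajectory(sys, n_steps = 1e5, dt = 0.001, friction = 5, seed = 31,
                       cvs = list(cvd), stride = 10,
                       restraints = list(restraint(cvd, 180, 0.02)))
  ang <- tr$cv[-(1:500), 1] * pi / 180
  cmean <- atan2(mean(sin(ang)), mean(cos(ang))) * 180 / pi
  cmean <- (cmean + 360) %% 360   # near 180 either side
  expect_lt(abs(cmean - 180), 1)
})

test_that("configurational sampling matches the Boltzmann distribution", {
  # double well along x: analytic marginal known up to normalization
  sys <- double_well_bead(height = 2, halfwidth = 1)
  tr <- run_trajectory(sys, n_steps = 1e6, dt = 0.002, friction = 20, seed = 41,
                       stride = 1000,   # 2 ps between samples: ~independent
                       cvs = list(colvar("axis_projection", axis = c(1, 0, 0))))
  x <- tr$cv[-1, 1]
  edges <- seq(-1.6, 1.6, by = 0.4)
  obs <- table(cut(x[x >= -1.6 & x <= 1.6], edges))
  u <- function(z) 2 * (z^2 - 1)^2
  pbin <- vapply(seq_len(length(edges) - 1), function(i)
    integrate(function(z) exp(-u(z) / kT300), edges[i], edges[i + 1])$value,
    numeric(1))
  pbin <- pbin / sum(pbin)
  ntot <- sum(obs)
  chi2 <- sum((as.numeric(obs) - ntot * pbin)^2 / (ntot * pbin))
  expect_lt(chi2, qchisq(0.99, df = length(pbin) - 1))
})

test_that("dihedral-series generator hits its modes and weights", {
  one <- generate_dihedral_series(list(list(phi1 = 180, phi2 = 180,
                                            weight = 1, spread = 5)),
                                  n_frames = 2000, seed = 51)
  lab <- classify_frames(one, netropsin_conformer_model())
  expect_gte(mean(lab == "1"), 0.99)
  two <- generate_dihedral_series(list(
    list(phi1 = 90, phi2 = 90, weight = 0.5, spread = 8),
    list(phi1 = 180, phi2 = 180, weight = 0.5, spread = 8)),
    n_frames = 6000, seed = 52)
  w <- mean(attr(two, "labels") == 1)
  expect_lt(abs(w - 0.5), 3 * sqrt(0.25 / 6000))
  expect_error(generate_dihedral_series(list(), 100, seed = 1))
  # reproducible by seed
  again <- generate_dihedral_series(list(
    list(phi1 = 90, phi2 = 90, weight = 0.5, spread = 8),
    list(phi1 = 180, phi2 = 180, weight = 0.5, spread = 8)),
    n_frames = 6000, seed = 52)
  expect_identical(two$phi1, again$phi1)
})
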