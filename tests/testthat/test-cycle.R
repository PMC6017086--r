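# Cycle composition: restraint free energies from PMFs, bulk terms, the
# standard-state separation term, and the composed result.

flat_profile <- function(kind = "Phi", lo = -180, hi = 180, bw = 1) {
  centers <- seq(lo + bw / 2, hi - bw / 2, by = bw)
  pmf_profile(centers, rep(0, length(centers)), cv_kind = kind,
              temperature = 300)
}

test_that("restraint free energy from a flat PMF matches the closed form", {
  th <- thermo_state(300)
  p <- flat_profile("Phi")
  r <- restraint(colvar("Phi", ref = diag(3)), 0, 0.1)
  got <- restraint_dg_from_pmf(p, r, th, "impose", closed = c(TRUE, TRUE))
  expect_equal(got$dg, analytic_harmonic_dg(0.1, 0, c(-180, 180), thermo = th),
               tolerance = 1e-3)
  # polar kind with the sin Jacobian
  pth <- flat_profile("theta", 0.5, 179.5)   # open poles, 179 bins
  rth <- restraint(colvar("theta"), 90, 0.1)
  got2 <- restraint_dg_from_pmf(pth, rth, th, "impose", closed = c(TRUE, TRUE))
  expect_equal(got2$dg,
               analytic_harmonic_dg(0.1, 90, c(0.5, 179.5), jacobian = TRUE,
                                    thermo = th), tolerance = 1e-3)
})

test_that("a vanishing restraint costs nothing; release negates impose", {
  th <- thermo_state(300)
  p <- flat_profile("Phi")
  r0 <- restraint(colvar("Phi", ref = diag(3)), 0, 1e-12)
  expect_lt(abs(restraint_dg_from_pmf(p, r0, th, "impose",
                                      closed = c(TRUE, TRUE))$dg), 1e-6)
  set.seed(3)
  centers <- seq(-4.95, 4.95, 0.1)
  wobble <- pmf_profile(centers, 0.3 * (centers - 1)^2 + 0.2 * sin(centers),
                        cv_kind = "separation", temperature = 300)
  r <- restraint(colvar("separation"), 1, 2)
  a <- restraint_dg_from_pmf(wobble, r, th, "impose", closed = c(TRUE, TRUE))
  b <- restraint_dg_from_pmf(wobble, r, th, "release", closed = c(TRUE, TRUE))
  expect_identical(a$dg, -b$dg)
})

test_that("quadratic PMF plus harmonic restraint follows Gaussian algebra", {
  th <- thermo_state(300)
  kT <- 1 / th$beta
  K <- 1.2; k <- 0.8; x0 <- 0.5; c0 <- -0.3
  centers <- seq(-5.975, 5.975, 0.05)
  p <- pmf_profile(centers, 0.5 * K * (centers - x0)^2,
                   cv_kind = "separation", temperature = 300)
  r <- restraint(colvar("separation"), c0, k)
  got <- restraint_dg_from_pmf(p, r, th, "impose", closed = c(TRUE, TRUE))$dg
  closed_form <- -kT * (0.5 * log(K / (K + k))) +
    0.5 * (K * k / (K + k)) * (x0 - c0)^2
  expect_equal(got, closed_form, tolerance = 1e-3)
})

test_that("tail coverage and domain violations are reported", {
  th <- thermo_state(300)
  p <- flat_profile("separation", 0, 3, 0.1)
  r_out <- restraint(colvar("separation"), 5, 1)
  expect_error(restraint_dg_from_pmf(p, r_out, th), "outside")
  r_weak <- restraint(colvar("separation"), 1.5, 1e-4)
  expect_error(restraint_dg_from_pmf(p, r_weak, th), "edge mass")
})

test_that("analytic bulk reorientation obeys limits and the stiff formula", {
  th <- thermo_state(300)
  kT <- 1 / th$beta
  expect_lt(analytic_bulk_orientation(1e-9, 1e-9, 1e-9, thermo = th), 1e-4)
  ks <- c(0.02, 0.05, 0.1, 0.5, 2)
  vals <- vapply(ks, function(k)
    analytic_bulk_orientation(k, 0.1, 0.1, thermo = th), numeric(1))
  expect_true(all(diff(vals) > 0))   # strictly increasing in k_Theta
  ell <- sqrt(2 * pi * kT / 0.1) * pi / 180   # radians
  stiff <- -kT * log(ell^3 * sin(pi / 2) / (8 * pi^2))
  expect_equal(analytic_bulk_orientation(0.1, 0.1, 0.1, c(90, 0, 0), th),
               stiff, tolerance = 0.01)
  expect_error(analytic_bulk_orientation(-1, 1, 1), "force constants")
})

test_that("square-well separation term reduces to the hand formula", {
  th <- thermo_state(300)
  kT <- 1 / th$beta
  bw <- 0.05
  centers <- seq(bw / 2, 10 - bw / 2, bw)
  w <- rep(0, length(centers))          # flat: basin given explicitly
  p <- pmf_profile(centers, w, cv_kind = "separation", temperature = 300,
                   anchor = "none")
  kpin <- 50                             # stiff positional pinning
  rth <- restraint(colvar("theta"), 90, kpin)
  rph <- restraint(colvar("phi"), 0, kpin)
  got <- separation_standard_term(p, rth, rph, r_star = 10, thermo = th,
                                  v0 = 1661, basin = c(0, 1))
  d2r <- pi / 180
  ell <- sqrt(2 * pi * kT / kpin) * d2r
  omega <- ell^2 * sin(pi / 2)          # pinned solid angle
  r_eff <- got$r_star_eff
  expect_equal(got$dg, -kT * log(r_eff^2 * omega * got$I_star / 1661),
               tolerance = 1e-6)
  expect_equal(got$I_star, sum(centers <= 1) * bw, tolerance = 1e-12)
  expect_equal(got$S_star / r_eff^2, omega, tolerance = 1e-4)
})

test_that("doubling the standard volume shifts the term by kT ln 2 exactly", {
  th <- thermo_state(300)
  centers <- seq(0.025, 9.975, 0.05)
  w <- -2 / th$beta * log(centers / 10) - 8 * (centers < 1)
  p <- pmf_profile(centers, w, cv_kind = "separation", temperature = 300,
                   anchor = "none")
  rth <- restraint(colvar("theta"), 90, 0.1)
  rph <- restraint(colvar("phi"), 0, 0.1)
  a <- separation_standard_term(p, rth, rph, 10, th, v0 = 1661,
                                basin = c(0, 2))
  b <- separation_standard_term(p, rth, rph, 10, th, v0 = 3322,
                                basin = c(0, 2))
  expect_equal(b$dg - a$dg, log(2) / th$beta, tolerance = 1e-12)
})

test_that("the term is robust to extending the reference separation", {
  # physical plateau carries the r^2 geometric tail: w = -2kT ln r + well
  th <- thermo_state(300)
  centers <- seq(0.025, 11.975, 0.05)
  w <- -2 / th$beta * log(centers) - 8 * exp(-(centers - 1)^2 / 0.08)
  p <- pmf_profile(centers, w, cv_kind = "separation", temperature = 300,
                   anchor = "none")
  rth <- restraint(colvar("theta"), 90, 0.1)
  rph <- restraint(colvar("phi"), 0, 0.1)
  near <- separation_standard_term(p, rth, rph, 8, th, basin = c(0, 3))
  far <- separation_standard_term(p, rth, rph, 11.9, th, basin = c(0, 3))
  expect_lt(abs(near$dg - far$dg), 0.2)
  expect_error(separation_standard_term(p, rth, rph, r_star = 15, thermo = th),
               "does not reach")
})

table1_contributions <- function() {
  read_contributions(system.file("extdata", "dna_ligand_contributions.csv",
                                 package = "geomroute"))
}

test_that("composing the DNA-ligand table reproduces its printed total", {
  res <- compose_cycle(table1_contributions())
  expect_equal(res$dg_bind, -13.2, tolerance = 1e-12)
  expect_equal(res$error, sqrt(1.6^2 + 1.2^2 + 0.6^2), tolerance = 1e-12)
  expect_equal(res$time_ns, 971)
})

test_that("composition is order-invariant, additive and Eq-consistent", {
  contribs <- table1_contributions()
  th <- thermo_state(300)
  res <- compose_cycle(contribs, th)
  set.seed(5)
  perm <- compose_cycle(sample(contribs), th)
  expect_identical(perm$dg_bind, res$dg_bind)
  # bookkeeping can never drift from the stored components
  expect_equal(res$dg_bind,
               sum(vapply(res$contributions, function(ct) ct$dg, numeric(1))),
               tolerance = 1e-12)
  # K_eq consistency: -(1/beta) ln(K_eq C0) == dG_bind
  expect_equal(-log(res$keq / res$v0) / th$beta, res$dg_bind,
               tolerance = 1e-10)
  # all-zero contributions: dG = 0 and K_eq = V0
  term_names <- c("c_site", "Theta_site", "Phi_site", "Psi_site",
                  "theta_site", "phi_site", "separation_term", "c_bulk",
                  "o_bulk")
  zeros <- lapply(term_names, cycle_contribution, dg = 0)
  z <- compose_cycle(zeros, th)
  expect_equal(z$dg_bind, 0)
  expect_equal(z$keq, z$v0)
})

test_that("missing or duplicated contributions are named in the error", {
  contribs <- table1_contributions()
  expect_error(compose_cycle(contribs[-3]), "Phi_site")
  expect_error(compose_cycle(c(contribs, contribs[3])), "duplicate")
})
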