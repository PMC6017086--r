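# Brute-force ground truth: direct numerical integration of configurational
# integrals on toy systems, independent of any sampling machinery.
#
# Low-dimensional systems (a single free bead) are handled by deterministic
# tensor-grid quadrature.  The full 3-bead host-guest integral (9 degrees of
# freedom) uses seeded importance-sampling Monte Carlo with closed-form
# proposal densities (uniform orientations via smeared bond shells), which is
# deterministic given the seed and reports its standard error.

#' Closed-form / quadrature free energy of one harmonic restraint on a flat
#' landscape
#'
#' \eqn{\Delta G = -kT \ln[\int_D e^{-\beta u(\xi)} J(\xi) d\xi /
#' \int_D J(\xi) d\xi]} with \eqn{u = k/2 (\xi - c)^2} and \eqn{J = \sin\xi}
#' for polar-type angles (else 1).  Used to validate the cycle composer.
#'
#' @param k force constant (kcal/(mol deg^2) for angular domains); `k = 0`
#'   returns 0 exactly
#' @param center restraint centre (must lie inside `domain`)
#' @param domain `c(lo, hi)` in degrees (or CV units)
#' @param jacobian apply the `sin(xi)` polar Jacobian (domain in degrees)
#' @param thermo a [thermo_state()]
#' @return free energy of imposing the restraint, kcal/mol (>= 0)
#' @export
analytic_harmonic_dg <- function(k, center, domain, jacobian = FALSE,
                                 thermo = thermo_state()) {
  th <- as_thermo(thermo)
  stopifnot(k >= 0, length(domain) == 2, domain[2] > domain[1])
  if (center < domain[1] || center > domain[2])
    stop("restraint centre lies outside the domain")
  if (k == 0) return(0)
  beta <- th$beta
  J <- if (jacobian) function(x) sin(x * pi / 180) else function(x) rep(1, length(x))
  num <- integrate(function(x) exp(-beta * 0.5 * k * (x - center)^2) * J(x),
                   domain[1], domain[2], rel.tol = 1e-10)$value
  den <- integrate(J, domain[1], domain[2], rel.tol = 1e-10)$value
  -log(num / den) / beta
}

#' Brute-force PMF by configurational quadrature
#'
#' Integrates \eqn{e^{-\beta U}} over a tensor grid of all bead coordinates,
#' bins the collective variable, and returns
#' \eqn{w(\xi) = -kT \ln \int \delta(\xi(x)-\xi) e^{-\beta U} dx} anchored to
#' min = 0.  Polar-type angles (`theta`, `Theta`) are reported without the
#' geometric \eqn{\sin\xi} factor, matching [estimate_pmf()].
#'
#' Exhaustive quadrature is limited to systems whose coordinate space is low
#' dimensional (a single free bead, 3 dims); larger systems must use the
#' Monte-Carlo integrator underlying [brute_force_keq()].
#'
#' @param system a [toy_system()] with one bead
#' @param cv the [colvar()] to bin
#' @param lo,hi,bin_width CV grid
#' @param thermo a [thermo_state()]
#' @param range half-width of the coordinate box around the system reference
#'   positions, A
#' @param n_grid quadrature points per dimension (scalar or length-3; the
#'   spacing along the binned direction should be finer than `bin_width`)
#' @return a [pmf_profile()] with estimator `"oracle"`
#' @export
brute_force_pmf <- function(system, cv, lo, hi, bin_width,
                            thermo = thermo_state(), range = 6, n_grid = 121) {
  th <- as_thermo(thermo)
  n <- length(system$masses)
  if (n != 1)
    stop("exhaustive quadrature supports single-bead systems (3 dims); ",
         "use the Monte-Carlo K_eq integrator for larger guests")
  n_grid <- rep_len(n_grid, 3)
  # cell-centred (midpoint) grids: no point ever sits on a CV bin edge when
  # the spacing is commensurate with the bin width
  step <- 2 * range / n_grid
  g <- lapply(1:3, function(d)
    system$positions[1, d] - range + step[d] * (seq_len(n_grid[d]) - 0.5))
  grid <- as.matrix(expand.grid(g[[1]], g[[2]], g[[3]]))
  cube <- aperm(array(grid, dim = c(nrow(grid), 3, 1)), c(3, 2, 1))
  u <- as.numeric(.cpp_energy_batch(sys_to_cpp(system), cube))
  xi <- .cpp_cv_batch(list(unclass(cv)), cube, system$masses)[, 1]
  wgt <- exp(-th$beta * (u - min(u))) * prod(step)
  nb <- as.integer(round((hi - lo) / bin_width))
  if (abs(nb - (hi - lo) / bin_width) > 1e-9) stop("non-integral bin count")
  # the profile is the bin-averaged Boltzmann mass; the coordinate grid
  # must be fine against (ideally commensurate with) the bin width, or the
  # binning aliases
  j <- floor((xi - lo) / bin_width) + 1L
  okj <- j >= 1 & j <= nb
  mass <- numeric(nb)
  tab <- rowsum(wgt[okj], j[okj])
  mass[as.integer(rownames(tab))] <- tab[, 1]
  centers <- lo + bin_width * (seq_len(nb) - 0.5)
  if (any(mass <= 0)) mass[mass <= 0] <- NA
  w <- -log(mass) / th$beta
  if (cv$kind %in% jacobian_kinds)
    w <- w + log(sin(centers * pi / 180)) / th$beta
  pmf_profile(centers, w, count = mass, cv_kind = cv$kind,
              temperature = th$temperature, estimator = "oracle")
}

# ---------------------------------------------------------------------------
# Importance-sampling machinery for multi-bead configurational integrals
# ---------------------------------------------------------------------------

# density of v = r0*u + sigma*eta with u uniform on the sphere, eta ~ N(0, I):
# a "smeared shell" covering all orientations with closed-form density
shell_density <- function(v_norm, r0, sigma) {
  s2 <- sigma^2
  pref <- (2 * pi * s2)^(-1.5) * exp(-(v_norm^2 + r0^2) / (2 * s2))
  x <- r0 * v_norm / s2
  # sinh(x)/x, stable for small x
  shx <- ifelse(x < 1e-6, 1 + x^2 / 6, sinh(x) / x)
  pref * shx
}

sample_shell <- function(m, r0, sigma) {
  u <- matrix(rnorm(3 * m), m, 3)
  u <- u / sqrt(rowSums(u^2))
  r0 * u + sigma * matrix(rnorm(3 * m), m, 3)
}

# internal-coordinate proposal for a <=3 bead guest: bead 1 at origin, the
# others on smeared shells at their bond rest lengths.  Returns coordinates
# relative to bead 1 and the log proposal density.
propose_internal <- function(system, m, sigma) {
  n <- length(system$masses)
  rel <- array(0, dim = c(n, 3, m))
  logq <- numeric(m)
  if (n >= 2) {
    r12 <- bond_r0(system, 1, 2)
    b <- sample_shell(m, r12, sigma)
    rel[2, , ] <- t(b)
    logq <- logq + log(shell_density(sqrt(rowSums(b^2)), r12, sigma))
  }
  if (n >= 3) {
    r13 <- bond_r0(system, 1, 3)
    b <- sample_shell(m, r13, sigma)
    rel[3, , ] <- t(b)
    logq <- logq + log(shell_density(sqrt(rowSums(b^2)), r13, sigma))
  }
  list(rel = rel, logq = logq)
}

bond_r0 <- function(system, i, j) {
  b <- system$bonds
  hit <- which((b[, 1] == i & b[, 2] == j) | (b[, 1] == j & b[, 2] == i))
  if (length(hit)) b[hit[1], 4]
  else sqrt(sum((system$positions[i, ] - system$positions[j, ])^2))
}

# centre-of-mass proposal: Gaussian around the binding well mixed with a
# uniform draw over the site ball; returns positions and densities
propose_com <- function(m, site_center, site_radius, proposal_center,
                        proposal_sigma, p_mix = 0.75) {
  ball <- matrix(rnorm(3 * m), m, 3)
  ball <- ball / sqrt(rowSums(ball^2)) * site_radius * runif(m)^(1 / 3)
  ball <- sweep(ball, 2, site_center, `+`)
  gaus <- sweep(matrix(rnorm(3 * m, sd = proposal_sigma), m, 3), 2,
                proposal_center, `+`)
  pick <- matrix(runif(m) < p_mix, m, 3)
  R <- ifelse(pick, gaus, ball)
  d2g <- rowSums(sweep(R, 2, proposal_center)^2)
  d2s <- rowSums(sweep(R, 2, site_center)^2)
  q <- p_mix * (2 * pi * proposal_sigma^2)^(-1.5) * exp(-d2g / (2 * proposal_sigma^2)) +
    (1 - p_mix) * (d2s <= site_radius^2) / (4 / 3 * pi * site_radius^3)
  list(R = R, q = q, inside = d2s <= site_radius^2)
}

# assemble site configurations: internal coordinates re-centred on COM = R
place_at_com <- function(rel, masses, Rcom) {
  n <- dim(rel)[1]
  com_rel <- apply(rel, c(2, 3), function(z) sum(masses * z)) / sum(masses)
  cube <- rel
  for (i in seq_len(n)) for (b in 1:3)
    cube[i, b, ] <- rel[i, b, ] - com_rel[b, ] + Rcom[, b]
  cube
}

# restraint energy for a batch of configurations (cube: n x 3 x m)
restraint_energy_batch <- function(restraints, cube, masses) {
  if (!length(restraints)) return(numeric(dim(cube)[3]))
  vals <- .cpp_cv_batch(lapply(restraints, function(r) r$cv), cube, masses)
  u <- numeric(dim(cube)[3])
  for (j in seq_along(restraints)) {
    r <- restraints[[j]]
    d <- vals[, j] - r$center
    if (r$cv$kind %in% c("phi", "Phi", "Psi", "dihedral"))
      d <- d - 360 * round(d / 360)
    if (r$type == "upper_wall") d <- pmax(d, 0)
    if (r$type == "lower_wall") d <- pmin(d, 0)
    u <- u + 0.5 * r$k * d^2
  }
  u
}

#' Brute-force equilibrium constant of a toy host-guest system
#'
#' Computes \eqn{K_{eq} = \int_{site} d1 \int dx\, e^{-\beta U} /
#' \int_{bulk} d1\, \delta(x_1 - x_1^*) \int dx\, e^{-\beta U}} directly,
#' with the guest centre of mass integrated over a spherical site region.
#' Single-bead guests use deterministic 3D quadrature; two- and three-bead
#' guests use seeded importance sampling over centre-of-mass position,
#' orientation and internal coordinates, with the same internal samples in
#' the site and bulk integrals.  The bulk reference pins the centre of mass
#' where the host field is negligible.
#'
#' @param system a [toy_system()] with 1..3 beads
#' @param site_center,site_radius spherical site region for the guest COM, A
#' @param thermo a [thermo_state()]
#' @param n_samples Monte-Carlo sample count (multi-bead guests)
#' @param seed integer seed (required for multi-bead guests)
#' @param proposal_center centre of the positional proposal (default: site
#'   centre of mass of the host wells, else site centre)
#' @param proposal_sigma positional proposal width, A
#' @param bond_sigma internal-coordinate proposal width, A
#' @param n_grid grid points per dimension (single-bead quadrature)
#' @return list with `keq` (A^3), `se` (standard error, A^3; 0 for
#'   quadrature), `dg_bind` given `v0`, and diagnostics
#' @param v0 standard-state volume, A^3
#' @export
brute_force_keq <- function(system, site_center = c(0, 0, 0), site_radius,
                            thermo = thermo_state(), n_samples = 4e5,
                            seed = NULL, proposal_center = NULL,
                            proposal_sigma = 1.5, bond_sigma = NULL,
                            n_grid = 101, v0 = 1661) {
  th <- as_thermo(thermo)
  n <- length(system$masses)
  if (n > 3) stop("brute-force K_eq supports guests of at most 3 beads")
  if (is.null(proposal_center)) {
    proposal_center <- if (system$host$type == "wells")
      colMeans(system$host$centers) else site_center
  }
  if (sqrt(sum((proposal_center - site_center)^2)) > site_radius)
    stop("site region must contain the binding well; check site_center/radius")

  if (n == 1) {
    g <- lapply(1:3, function(d)
      seq(site_center[d] - site_radius, site_center[d] + site_radius,
          length.out = n_grid))
    step <- vapply(g, function(x) x[2] - x[1], numeric(1))
    grid <- as.matrix(expand.grid(g[[1]], g[[2]], g[[3]]))
    inside <- sqrt(rowSums(sweep(grid, 2, site_center)^2)) <= site_radius
    grid <- grid[inside, , drop = FALSE]
    cube <- aperm(array(grid, dim = c(nrow(grid), 3, 1)), c(3, 2, 1))
    u <- as.numeric(.cpp_energy_batch(sys_to_cpp(system), cube))
    keq <- sum(exp(-th$beta * u)) * prod(step)
    return(list(keq = keq, se = 0, method = "quadrature",
                dg_bind = -log(keq / v0) / th$beta, n = nrow(grid)))
  }

  if (is.null(seed)) stop("Monte-Carlo K_eq needs an explicit seed")
  if (is.null(bond_sigma)) bond_sigma <- 3 * sqrt(1 / (th$beta * max(system$bonds[, 3])))
  set.seed(as.integer(seed))
  m <- as.integer(n_samples)
  prop <- propose_internal(system, m, bond_sigma)
  com <- propose_com(m, site_center, site_radius, proposal_center,
                     proposal_sigma)

  # internal (bulk) energies: beads at rel coordinates, no host
  bulk_sys <- system
  bulk_sys$host <- host_none()
  u_int <- as.numeric(.cpp_energy_batch(sys_to_cpp(bulk_sys), prop$rel))
  lw_int <- -th$beta * u_int - prop$logq
  sc <- max(lw_int)
  w_int <- exp(lw_int - sc)
  denom <- mean(w_int)

  # site configurations: same internal samples, COM placed in the site
  cube <- place_at_com(prop$rel, system$masses, com$R)
  u_tot <- as.numeric(.cpp_energy_batch(sys_to_cpp(system), cube))
  w_site <- exp(-th$beta * u_tot - prop$logq - sc) / com$q * com$inside
  numer <- mean(w_site)

  keq <- numer / denom
  # delta-method standard error of the ratio with correlated numerator/denom
  vn <- var(w_site) / m; vd <- var(w_int) / m
  cv_nd <- cov(w_site, w_int) / m
  se <- keq * sqrt(vn / numer^2 + vd / denom^2 - 2 * cv_nd / (numer * denom))
  list(keq = keq, se = se, method = "importance_mc",
       dg_bind = -log(keq / v0) / th$beta,
       dg_se = se / keq / th$beta, n = m)
}

#' Term-by-term reconstruction of the thermodynamic-cycle identity
#'
#' Evaluates the product of configurational-integral ratios of the stepwise
#' cycle (conformational, orientational and positional restraints imposed in
#' sequence) with the same Monte-Carlo sample set, and checks that the
#' product telescopes to the direct site/bulk ratio.  This is an internal
#' identity of the thermodynamic cycle itself, valid for any restraint
#' strengths.
#'
#' @inheritParams brute_force_keq
#' @param restraints_c,restraints_o,restraints_a lists of [restraint()]s for
#'   the conformational, orientational (Euler) and positional (polar) groups
#' @return list with per-stage ratios, their product, and the direct ratio
#' @export
keq_cycle_identity <- function(system, site_center = c(0, 0, 0), site_radius,
                               restraints_c = list(), restraints_o = list(),
                               restraints_a = list(),
                               thermo = thermo_state(), n_samples = 2e5,
                               seed, proposal_center = NULL,
                               proposal_sigma = 1.5, bond_sigma = NULL) {
  th <- as_thermo(thermo)
  n <- length(system$masses)
  if (n < 2) stop("cycle identity needs a multi-bead guest")
  if (missing(seed)) stop("an explicit seed is required")
  if (is.null(proposal_center)) {
    proposal_center <- if (system$host$type == "wells")
      colMeans(system$host$centers) else site_center
  }
  if (is.null(bond_sigma)) bond_sigma <- 3 * sqrt(1 / (th$beta * max(system$bonds[, 3])))
  set.seed(as.integer(seed))
  m <- as.integer(n_samples)
  prop <- propose_internal(system, m, bond_sigma)
  com <- propose_com(m, site_center, site_radius, proposal_center,
                     proposal_sigma)
  masses <- system$masses
  cube <- place_at_com(prop$rel, masses, com$R)
  u_tot <- as.numeric(.cpp_energy_batch(sys_to_cpp(system), cube))
  inside <- com$inside
  qR <- com$q

  uc <- restraint_energy_batch(restraints_c, cube, masses)
  uo <- restraint_energy_batch(restraints_o, cube, masses)
  ua <- restraint_energy_batch(restraints_a, cube, masses)

  base <- -th$beta * u_tot - prop$logq
  sc <- max(base[inside])
  Zs <- function(extra) mean(exp(base - sc - th$beta * extra) / qR * inside)
  z0 <- Zs(0); z1 <- Zs(uc); z2 <- Zs(uc + uo); z3 <- Zs(uc + uo + ua)

  bulk_sys <- system
  bulk_sys$host <- host_none()
  u_int <- as.numeric(.cpp_energy_batch(sys_to_cpp(bulk_sys), prop$rel))
  # bulk restraint energies at the pinned reference: conformational and
  # orientational terms are COM-independent, so evaluate on rel coordinates
  ucb <- restraint_energy_batch(restraints_c, prop$rel, masses)
  uob <- restraint_energy_batch(restraints_o, prop$rel, masses)
  baseb <- -th$beta * u_int - prop$logq
  scb <- max(baseb)
  Zb <- function(extra) mean(exp(baseb - scb - th$beta * extra))
  b0 <- Zb(0); b1 <- Zb(ucb); b2 <- Zb(ucb + uob)

  ratios <- c(site_c = z0 / z1, site_o = z1 / z2, site_a = z2 / z3,
              cross = z3 / b2 * exp(sc - scb),
              bulk_o = b2 / b1, bulk_c = b1 / b0)
  direct <- z0 / b0 * exp(sc - scb)
  list(ratios = ratios, product = prod(ratios), direct = direct,
       keq = direct, relative_gap = abs(prod(ratios) / direct - 1))
}
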