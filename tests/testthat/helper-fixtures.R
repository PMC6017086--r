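# Shared fixtures and numeric helpers (all inputs generated in code).

kT300 <- 1 / thermo_state(300)$beta

# central finite-difference gradient of a scalar function of an (n x 3) matrix
fd_gradient <- function(f, X, h = 1e-5) {
  g <- X * 0
  for (i in seq_len(nrow(X))) for (b in 1:3) {
    Xp <- X; Xp[i, b] <- Xp[i, b] + h
    Xm <- X; Xm[i, b] <- Xm[i, b] - h
    g[i, b] <- (f(Xp) - f(Xm)) / (2 * h)
  }
  g
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  matrix(c(q0^2+q1^2-q2^2-q3^2, 2*(q1*q2-q0*q3), 2*(q1*q3+q0*q2),
           2*(q1*q2+q0*q3), q0^2-q1^2+q2^2-q3^2, 2*(q2*q3-q0*q1),
           2*(q1*q3-q0*q2), 2*(q2*q3+q0*q1), q0^2-q1^2-q2^2+q3^2),
         3, 3, byrow = TRUE)
}

# one bead in an isotropic harmonic trap
harmonic_bead <- function(k = 3, mass = 12) {
  toy_system(masses = mass, positions = rbind(c(0, 0, 0)),
             host = host_harmonic(k = k))
}

# one bead in a quartic double well along x with transverse confinement
double_well_bead <- function(height = 2.5, halfwidth = 1, k_perp = 5) {
  toy_system(masses = 12, positions = rbind(c(halfwidth, 0, 0)),
             host = host_double_well(axis = c(1, 0, 0), height = height,
                                     halfwidth = halfwidth, k_perp = k_perp))
}

# stiff triangle guest pinned by three wells at its reference bead positions:
# every orientational PMF is sharply quadratic around (90, 0, 0)
pinned_triangle <- function(depth = 8, sigma = 0.8, k_bond = 300) {
  tri <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.92, 1.44, 0))
  rel <- sweep(tri, 2, colMeans(tri))
  sys <- toy_system(
    masses = c(12, 12, 12), positions = rel,
    bonds = rbind(c(1, 2, k_bond, 1.5), c(2, 3, k_bond, 1.5),
                  c(1, 3, k_bond, 2.4)),
    host = host_gaussian_wells(centers = rel, depths = depth, sigmas = sigma))
  list(system = sys, ref_conf = rel,
       ref_euler = rel %*% rotation_from_euler(90, 0, 0))
}

# quadratic fit R^2 of a profile
quadratic_r2 <- function(x, y) {
  fit <- lm(y ~ x + I(x^2))
  summary(fit)$r.squared
}
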