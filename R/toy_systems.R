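# Toy host-guest model systems and the Langevin sampler.
#
# The host is an analytic external field (infinitely heavy), so the guest's
# bonded terms plus the field define the full potential.  Host conformational
# restraints of the cycle are exercised on guest internal coordinates.

#' Analytic host potentials
#'
#' Constructors for the external fields acting on each guest bead:
#' * `host_gaussian_wells()`: a sum of 3D Gaussian wells,
#'   \eqn{U(x) = -\sum_w \epsilon_w e^{-|x-c_w|^2/2\sigma_w^2}}; one well is a
#'   simple binding pocket, several wells make an angularly modulated pocket
#'   that pins the guest orientation.
#' * `host_double_well()`: a quartic double well along one axis,
#'   \eqn{U = h\,(s^2-w^2)^2/w^4 + \tfrac12 k_\perp |x_\perp|^2} with
#'   \eqn{s} the coordinate along `axis`.
#' * `host_harmonic()`: an isotropic harmonic trap.
#' * `host_square_well()`: a spherical square well (depth `depth` inside
#'   `radius`); discontinuous, intended for quadrature oracles, not dynamics.
#' * `host_none()`: no field (bulk).
#'
#' @param centers numeric matrix (wells x 3) of well centers, A
#' @param depths,sigmas well depths (kcal/mol, > 0 means attractive) and
#'   widths (A)
#' @param axis,center,height,halfwidth,k_perp double-well geometry
#' @param k harmonic trap stiffness, kcal/(mol A^2)
#' @param radius,depth square-well geometry
#' @return a `host_potential` list understood by [toy_system()]
#' @export
host_gaussian_wells <- function(centers, depths, sigmas) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  depths <- rep_len(as.numeric(depths), nrow(centers))
  sigmas <- rep_len(as.numeric(sigmas), nrow(centers))
  stopifnot(all(is.finite(centers)), all(sigmas > 0))
  structure(list(type = "wells", centers = centers, depths = depths,
                 sigmas = sigmas), class = "host_potential")
}

#' @rdname host_gaussian_wells
#' @export
host_double_well <- function(axis = c(1, 0, 0), center = c(0, 0, 0),
                             height = 2, halfwidth = 1, k_perp = 5) {
  stopifnot(height > 0, halfwidth > 0, k_perp >= 0)
  structure(list(type = "axis_double_well", axis = as.numeric(axis),
                 center = as.numeric(center), height = height,
                 halfwidth = halfwidth, k_perp = k_perp),
            class = "host_potential")
}

#' @rdname host_gaussian_wells
#' @export
host_harmonic <- function(center = c(0, 0, 0), k = 1) {
  stopifnot(k > 0)
  structure(list(type = "harmonic", center = as.numeric(center), k = k),
            class = "host_potential")
}

#' @rdname host_gaussian_wells
#' @export
host_square_well <- function(center = c(0, 0, 0), radius = 1, depth = 5) {
  stopifnot(radius > 0)
  structure(list(type = "square_well", center = as.numeric(center),
                 radius = radius, depth = depth), class = "host_potential")
}

#' @rdname host_gaussian_wells
#' @export
host_none <- function() structure(list(type = "none"), class = "host_potential")

#' Host reference frame
#'
#' An orthonormal triad plus origin defining the (fixed) host frame in which
#' polar and Euler angles are measured.
#'
#' @param origin frame origin, A
#' @param rotation 3x3 matrix whose rows are the host axes expressed in world
#'   coordinates (a host-frame vector is `rotation %*% (x - origin)`)
#' @export
host_frame <- function(origin = c(0, 0, 0), rotation = diag(3)) {
  rotation <- as.matrix(rotation)
  stopifnot(length(origin) == 3, all(dim(rotation) == c(3, 3)))
  if (max(abs(rotation %*% t(rotation) - diag(3))) > 1e-8)
    stop("host frame rotation must be orthonormal")
  list(origin = as.numeric(origin), rotation = rotation)
}

#' Toy host-guest system
#'
#' A bead-and-spring guest in an analytic host field.  Harmonic bonds are
#' given as `cbind(i, j, k, r0)` (1-based bead indices, k in kcal/(mol A^2),
#' r0 in A); cosine dihedrals as `cbind(i, j, k, l, kd, mult, phi0_deg)` with
#' \eqn{U = k_d (1 + \cos(n\phi - \phi_0))}.
#'
#' @param masses bead masses, amu (all > 0)
#' @param positions reference bead positions, (n x 3) matrix, A
#' @param bonds,dihedrals bonded terms (see Details), or `NULL`
#' @param host a [host_gaussian_wells()]-family potential
#' @param frame a [host_frame()]
#' @return object of class `toy_system`
#' @export
toy_system <- function(masses, positions, bonds = NULL, dihedrals = NULL,
                       host = host_none(), frame = host_frame()) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  masses <- as.numeric(masses)
  if (length(masses) != nrow(positions))
    stop("masses and positions disagree on the number of beads")
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("all bead masses must be finite and > 0")
  if (length(masses) < 1) stop("guest needs at least one bead")
  if (!is.null(bonds)) {
    bonds <- matrix(as.numeric(bonds), ncol = 4)
    if (any(bonds[, 1:2] < 1 | bonds[, 1:2] > length(masses)))
      stop("bond indices out of range")
  }
  if (!is.null(dihedrals)) dihedrals <- matrix(as.numeric(dihedrals), ncol = 7)
  stopifnot(inherits(host, "host_potential"))
  structure(list(masses = masses, positions = positions, bonds = bonds,
                 dihedrals = dihedrals, host = host, frame = frame),
            class = "toy_system")
}

# 0-based bond/dihedral tables for the compiled core
sys_to_cpp <- function(system) {
  b <- system$bonds
  if (!is.null(b)) b[, 1:2] <- b[, 1:2] - 1
  d <- system$dihedrals
  if (!is.null(d)) d[, 1:4] <- d[, 1:4] - 1
  list(masses = system$masses, bonds = b, dihedrals = d,
       host = unclass(system$host))
}

#' Potential energy and forces of a toy system
#'
#' Host field plus bonded guest terms.  `guest_forces()` returns the analytic
#' gradient (as forces, `-dU/dx`), which matches central finite differences.
#'
#' @param system a [toy_system()]
#' @param positions (n x 3) bead positions, A
#' @return `potential_energy()`: energy in kcal/mol; `guest_forces()`: a list
#'   with `energy` and the (n x 3) `forces` matrix in kcal/(mol A)
#' @export
potential_energy <- function(system, positions) {
  positions <- as.matrix(positions)
  if (any(!is.finite(positions))) stop("non-finite positions")
  .cpp_potential_energy(sys_to_cpp(system), positions)
}

#' @rdname potential_energy
#' @export
guest_forces <- function(system, positions) {
  positions <- as.matrix(positions)
  if (any(!is.finite(positions))) stop("non-finite positions")
  .cpp_forces(sys_to_cpp(system), positions)
}

#' One Langevin (BAOAB) integration step
#'
#' Mostly a building block for tests; production sampling goes through
#' [run_trajectory()].  With `friction = 0` the scheme reduces to velocity
#' Verlet (no noise).  No step-size sanity check is attempted: too-large `dt`
#' shows up as energy drift or a NaN error, not a warning.
#'
#' @param system a [toy_system()]
#' @param state list with `positions` and `velocities` (n x 3 each)
#' @param thermo a [thermo_state()] (or temperature in K)
#' @param dt time step, ps
#' @param friction Langevin friction, 1/ps (>= 0)
#' @param restraints list of [restraint()] specifications
#' @return updated state list
#' @export
langevin_step <- function(system, state, thermo = thermo_state(), dt = 0.002,
                          friction = 5, restraints = list()) {
  th <- as_thermo(thermo)
  rec <- .cpp_run_md(sys_to_cpp(system), as.matrix(state$positions),
                     as.matrix(state$velocities),
                     lapply(restraints, unclass), list(),
                     1L, dt, friction, th$temperature, 0L)
  list(positions = rec$x_final, velocities = rec$v_final)
}

#' Sample a toy system with Langevin dynamics
#'
#' Runs `n_steps` of BAOAB Langevin dynamics, streaming collective-variable
#' values and energies every `stride` steps.  Fully deterministic for a given
#' `seed`: identical seeds give bit-identical records.
#'
#' @param system a [toy_system()]
#' @param n_steps number of steps (>= 0); `0` records only the initial frame
#' @param dt time step, ps
#' @param friction Langevin friction, 1/ps
#' @param seed integer seed (required; there is no implicit global RNG use)
#' @param temperature kelvin, or a [thermo_state()]
#' @param cvs list of [colvar()] observers evaluated at every record
#' @param restraints list of [restraint()] specifications
#' @param stride record every `stride` steps
#' @param x0,v0 optional initial positions/velocities; defaults are the
#'   system's reference positions and a Maxwell-Boltzmann draw
#' @return list of class `trajectory_record` with `step`, `time_ps`, `cv`
#'   (matrix, one column per observer), `potential`, `kinetic`, and the final
#'   phase-space point
#' @export
run_trajectory <- function(system, n_steps, dt = 0.002, friction = 5,
                           seed, temperature = 300, cvs = list(),
                           restraints = list(), stride = 10L,
                           x0 = NULL, v0 = NULL) {
  if (missing(seed)) stop("an explicit integer seed is required")
  th <- as_thermo(temperature)
  for (cv in cvs) check_cv_observable(cv, system)
  for (r in restraints) check_cv_observable(r$cv, system)
  if (is.null(x0)) x0 <- system$positions
  set.seed(as.integer(seed))
  rec <- .cpp_run_md(sys_to_cpp(system), as.matrix(x0),
                     if (is.null(v0)) NULL else as.matrix(v0),
                     lapply(restraints, unclass), lapply(cvs, unclass),
                     as.integer(n_steps), dt, friction, th$temperature,
                     as.integer(max(stride, 1)))
  structure(list(step = rec$step, time_ps = rec$step * dt, cv = rec$cv,
                 potential = rec$potential, kinetic = rec$kinetic,
                 x_final = rec$x_final, v_final = rec$v_final,
                 dt = dt, seed = seed,
                 cv_names = vapply(cvs, function(z) z$kind, character(1))),
            class = "trajectory_record")
}

# a CV must be evaluable on the system before any dynamics starts
check_cv_observable <- function(cv, system) {
  n <- length(system$masses)
  atoms <- if (is.null(cv$atoms)) seq_len(n) else cv$atoms
  if (any(atoms < 1 | atoms > n))
    stop("collective variable '", cv$kind, "' refers to beads outside the system")
  need <- switch(cv$kind, Theta = , Phi = , Psi = , rmsd = 3L,
                 dihedral = 4L, bond = 2L, 1L)
  if (cv$kind %in% c("Theta", "Phi", "Psi", "rmsd") && length(atoms) < need)
    stop("collective variable '", cv$kind, "' needs at least ", need,
         " beads; got ", length(atoms))
  if (cv$kind %in% c("dihedral", "bond") && length(atoms) != need)
    stop("collective variable '", cv$kind, "' needs exactly ", need, " beads")
  if (cv$kind %in% c("Theta", "Phi", "Psi")) {
    ref <- cv$ref
    if (is.null(ref)) stop("orientation CV needs a reference structure")
    rc <- sweep(ref, 2, colMeans(ref))
    if (min(svd(rc)$d[1:2]) < 1e-8)
      stop("orientation CV reference is collinear/degenerate")
  }
  invisible(TRUE)
}

#' Synthetic dihedral-angle time series
#'
#' Draws `(phi1, phi2)` frames from a wrapped-Gaussian mixture on the torus
#' `(-180, 180]^2` plus a stated fraction of "transition" frames drawn
#' uniformly outside every mode's classification box (so that a threshold
#' classifier can recover the generating fractions).
#'
#' @param modes data.frame or list of lists with `phi1`, `phi2` (centers,
#'   degrees), `weight`, `spread` (wrapped-normal SD, degrees)
#' @param n_frames number of frames
#' @param transition_fraction fraction of frames drawn as transitions
#' @param seed integer seed
#' @param exclusion_threshold half-width (degrees) of the per-coordinate box
#'   around each mode center (and its sign images) excluded when drawing
#'   transition frames; match the classifier threshold
#' @return a [dihedral_series()] with attribute `labels` giving the generating
#'   component of each frame (mode index or 0 for transition)
#' @export
generate_dihedral_series <- function(modes, n_frames, transition_fraction = 0,
                                     seed, exclusion_threshold = 45) {
  if (missing(seed)) stop("an explicit integer seed is required")
  modes <- as.data.frame(do.call(rbind, lapply(modes, function(m)
    data.frame(phi1 = m$phi1, phi2 = m$phi2, weight = m$weight,
               spread = m$spread))))
  if (nrow(modes) == 0) stop("empty mode list")
  stopifnot(all(modes$spread > 0), all(modes$weight >= 0),
            transition_fraction >= 0, transition_fraction < 1)
  modes$weight <- modes$weight / sum(modes$weight)
  set.seed(as.integer(seed))
  n_trans <- rbinom(1, n_frames, transition_fraction)
  comp <- integer(n_frames)
  idx_trans <- if (n_trans > 0) sample.int(n_frames, n_trans) else integer(0)
  comp[idx_trans] <- 0L
  rest <- setdiff(seq_len(n_frames), idx_trans)
  comp[rest] <- sample.int(nrow(modes), length(rest), replace = TRUE,
                           prob = modes$weight)
  phi <- matrix(NA_real_, n_frames, 2)
  for (m in seq_len(nrow(modes))) {
    sel <- which(comp == m)
    if (!length(sel)) next
    phi[sel, 1] <- wrap_deg(modes$phi1[m] + rnorm(length(sel), 0, modes$spread[m]))
    phi[sel, 2] <- wrap_deg(modes$phi2[m] + rnorm(length(sel), 0, modes$spread[m]))
  }
  if (length(idx_trans)) {
    centers <- cbind(modes$phi1, modes$phi2)
    draw <- function(k) matrix(runif(2 * k, -180, 180), ncol = 2)
    need <- idx_trans
    while (length(need)) {
      cand <- draw(length(need))
      bad <- apply(cand, 1, function(p) in_any_mode_box(p, centers,
                                                        exclusion_threshold))
      phi[need[!bad], ] <- cand[!bad, , drop = FALSE]
      need <- need[bad]
    }
  }
  phi[phi <= -180] <- phi[phi <= -180] + 360
  out <- dihedral_series(phi[, 1], phi[, 2])
  attr(out, "labels") <- comp
  out
}

wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y <= -180] <- 180
  y
}

in_any_mode_box <- function(p, centers, threshold) {
  for (i in seq_len(nrow(centers))) {
    c1 <- abs(centers[i, 1]); c2 <- abs(centers[i, 2])
    d1 <- min(ang_dist_deg(p[1], c1), ang_dist_deg(p[1], -c1))
    d2 <- min(ang_dist_deg(p[2], c2), ang_dist_deg(p[2], -c2))
    if (d1 <= threshold && d2 <= threshold) return(TRUE)
  }
  FALSE
}
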