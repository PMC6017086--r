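# Collective variables of the geometric route, with analytic gradients.
#
# All angles are reported in degrees (gradients in degrees/A), matching the
# angular force-constant convention kcal/(mol deg^2); internals are radians.
# Degenerate geometries (on-axis azimuth, gimbal lock, zero distance) return
# deterministic conventional values with a `degenerate` flag rather than
# failing mid-trajectory.

#' Collective-variable specification
#'
#' Builds the description of one coarse variable for use as an observer,
#' biased coordinate or restraint target.  Kinds:
#' `"separation"` (guest COM to host origin distance, A),
#' `"axis_projection"` (guest COM projected on a host-frame axis, A),
#' `"theta"`/`"phi"` (polar/azimuthal angle of the guest COM in the host
#' frame, degrees), `"Theta"`/`"Phi"`/`"Psi"` (ZYZ Euler angles of the
#' best-fit rotation from a reference structure, degrees), `"rmsd"`
#' (conformational RMSD to a reference, fitted or distance-matrix mode, A),
#' `"dihedral"` (signed torsion of four beads, degrees), and `"bond"`
#' (distance between two beads, A).
#'
#' @param kind one of the kinds above
#' @param atoms 1-based bead indices the CV acts on (default: all)
#' @param frame a [host_frame()] (origin + axes)
#' @param ref reference coordinates (n x 3) for `rmsd`/Euler kinds
#' @param axis host-frame direction for `axis_projection`
#' @param mode `"fitted"` or `"dmatrix"` for `rmsd`
#' @return a `colvar` specification list
#' @export
colvar <- function(kind, atoms = NULL, frame = host_frame(), ref = NULL,
                   axis = c(1, 0, 0), mode = c("fitted", "dmatrix")) {
  kind <- match.arg(kind, c("separation", "axis_projection", "theta", "phi",
                            "Theta", "Phi", "Psi", "rmsd", "dihedral", "bond"))
  mode <- match.arg(mode)
  structure(list(kind = kind, atoms = atoms, origin = frame$origin,
                 frame = frame$rotation,
                 ref = if (!is.null(ref)) matrix(as.numeric(ref), ncol = 3),
                 axis = as.numeric(axis), mode = mode),
            class = "colvar")
}

#' Evaluate a collective variable
#'
#' @param cv a [colvar()]
#' @param positions (n x 3) coordinates, A
#' @param masses bead masses (used for centre-of-mass weighting); default 1
#' @return list with `value`, per-atom `grad` (n x 3; degrees/A for angular
#'   kinds) and a `degenerate` flag
#' @export
cv_value <- function(cv, positions, masses = NULL) {
  positions <- as.matrix(positions)
  if (is.null(masses)) masses <- rep(1, nrow(positions))
  .cpp_cv_eval(unclass(cv), positions, as.numeric(masses))
}

#' Separation distance between guest COM and host origin
#'
#' @param guest_coords (n x 3) guest coordinates, A
#' @param frame a [host_frame()]
#' @param masses guest masses (COM weights)
#' @return list with `value` (A), `grad`, `degenerate`
#' @export
separation_distance <- function(guest_coords, frame = host_frame(),
                                masses = NULL) {
  cv_value(colvar("separation", frame = frame), guest_coords, masses)
}

#' Polar angles of the guest COM in the host frame
#'
#' `theta` is measured from the host z axis (0..180 deg), `phi` is the
#' azimuth in the host x-y plane (-180..180 deg).  On-axis configurations
#' (sin theta = 0) leave `phi` undefined: it is returned as 0 with
#' `degenerate = TRUE`.
#'
#' @inheritParams separation_distance
#' @return list with `theta`, `phi` (degrees), their gradients, and flags
#' @export
polar_angles <- function(guest_coords, frame = host_frame(), masses = NULL) {
  th <- cv_value(colvar("theta", frame = frame), guest_coords, masses)
  ph <- cv_value(colvar("phi", frame = frame), guest_coords, masses)
  list(theta = th$value, phi = ph$value, grad_theta = th$grad,
       grad_phi = ph$grad, degenerate = th$degenerate || ph$degenerate)
}

#' Least-squares best-fit rotation
#'
#' Optimal proper rotation (quaternion construction, det = +1 always)
#' mapping the centred reference onto the centred moving coordinates.
#'
#' @param moving,reference (n x 3) coordinate matrices, n >= 3 non-collinear
#' @return 3x3 rotation matrix `R` with `moving - centroid ~ (reference -
#'   centroid) %*% t(R)`
#' @export
best_fit_rotation <- function(moving, reference) {
  moving <- as.matrix(moving); reference <- as.matrix(reference)
  if (nrow(moving) != nrow(reference))
    stop("moving and reference atom counts differ")
  if (nrow(moving) < 3) stop("best-fit rotation needs >= 3 atoms")
  rc <- sweep(reference, 2, colMeans(reference))
  if (min(svd(rc)$d[1:2]) < 1e-10)
    stop("reference selection is collinear; orientation is undefined")
  fit <- .cpp_best_fit_rotation(moving, reference)
  fit$R
}

#' ZYZ Euler angles of a rotation matrix
#'
#' Decomposes a proper rotation as `R = Rz(Phi) %*% Ry(Theta) %*% Rz(Psi)`
#' with `Theta` in `[0, 180]` and `Phi`, `Psi` in `(-180, 180]` degrees.  At
#' gimbal lock (`Theta` = 0 or 180) only `Phi + Psi` (resp. `Phi - Psi`) is
#' defined; the convention `Phi = 0` is returned with `degenerate = TRUE`.
#'
#' @param R 3x3 proper rotation matrix (orthonormal within 1e-8)
#' @return list with `Theta`, `Phi`, `Psi` (degrees) and `degenerate`
#' @export
euler_angles <- function(R) {
  R <- as.matrix(R)
  if (max(abs(R %*% t(R) - diag(3))) > 1e-8 || det(R) < 0)
    stop("not a proper rotation matrix")
  st <- sqrt(R[1, 3]^2 + R[2, 3]^2)
  Theta <- atan2(st, R[3, 3]) * 180 / pi
  if (st < 1e-7) {
    Phi <- 0
    Psi <- if (R[3, 3] > 0) atan2(-R[1, 2], R[1, 1]) * 180 / pi
           else             atan2(R[1, 2], -R[1, 1]) * 180 / pi
    return(list(Theta = Theta, Phi = Phi, Psi = wrap180(Psi),
                degenerate = TRUE))
  }
  Phi <- atan2(R[2, 3], R[1, 3]) * 180 / pi
  Psi <- atan2(R[3, 2], -R[3, 1]) * 180 / pi
  list(Theta = Theta, Phi = wrap180(Phi), Psi = wrap180(Psi),
       degenerate = FALSE)
}

wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y <= -180 + 1e-12] <- 180 * sign(180)
  ifelse(y <= -180, 180, y)
}

#' Rotation matrix from ZYZ Euler angles
#'
#' Inverse of [euler_angles()]: `rotation_from_euler(euler_angles(R))`
#' reproduces `R` away from gimbal lock.
#'
#' @param Theta,Phi,Psi angles in degrees
#' @return 3x3 rotation matrix
#' @export
rotation_from_euler <- function(Theta, Phi, Psi) {
  if (is.list(Theta)) { Phi <- Theta$Phi; Psi <- Theta$Psi; Theta <- Theta$Theta }
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
  }
  ry <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, byrow = TRUE)
  }
  rz(Phi) %*% ry(Theta) %*% rz(Psi)
}

#' Conformational RMSD collective variable
#'
#' `mode = "fitted"`: RMSD after optimal superposition (invariant under any
#' rigid-body motion of the moving set) -- the default restraint coordinate,
#' since rigid-body motion is handled by the angular coarse variables.
#' `mode = "dmatrix"`: root-mean-square difference of all intramolecular pair
#' distances (distance RMSD).
#'
#' @param moving,reference (n x 3) coordinate matrices with equal n
#' @param mode `"fitted"` or `"dmatrix"`
#' @return list with `value` (A), `grad`, `degenerate`
#' @export
rmsd_cv <- function(moving, reference, mode = c("fitted", "dmatrix")) {
  mode <- match.arg(mode)
  moving <- as.matrix(moving); reference <- as.matrix(reference)
  if (nrow(moving) != nrow(reference))
    stop("moving and reference atom counts differ")
  if (mode == "dmatrix" && nrow(moving) < 2)
    stop("distance-matrix RMSD needs >= 2 atoms")
  cv_value(colvar("rmsd", ref = reference, mode = mode), moving)
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention, value in `(-180, 180]` degrees; cis = 0,
#' trans = 180.  A collinear central bond leaves the torsion undefined
#' (`degenerate = TRUE`).
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors, A
#' @return list with `value` (degrees), `grad` (4 x 3), `degenerate`
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  X <- rbind(p1, p2, p3, p4)
  cv_value(colvar("dihedral", atoms = 1:4), X)
}
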