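# Thermodynamic-cycle composition: restraint free energies from PMFs, the
# analytic bulk reorientation term, the standard-state separation term, and
# the sum into K_eq and the standard binding free energy.
#
# Sign convention (fixed package-wide): every contribution is emitted on the
# scale on which the nine terms ADD to the standard binding free energy --
# site terms are restraint releases (negative of imposition), bulk terms are
# impositions (positive), and the separation term is -kT ln(S* I* C°).

#' Named contribution to the binding cycle
#'
#' @param name one of `c_site`, `Theta_site`, `Phi_site`, `Psi_site`,
#'   `theta_site`, `phi_site`, `separation_term`, `c_bulk`, `o_bulk`
#' @param dg free energy, kcal/mol
#' @param error statistical error, kcal/mol (`NA` for analytic terms)
#' @param time_ns sampling-time bookkeeping, ns (optional)
#' @return a `cycle_contribution`
#' @export
cycle_contribution <- function(name, dg, error = NA_real_, time_ns = NA_real_) {
  name <- match.arg(name, cycle_term_names)
  stopifnot(is.finite(dg))
  structure(list(name = name, dg = dg, error = error, time_ns = time_ns),
            class = "cycle_contribution")
}

cycle_term_names <- c("c_site", "Theta_site", "Phi_site", "Psi_site",
                      "theta_site", "phi_site", "separation_term",
                      "c_bulk", "o_bulk")

#' Free energy of imposing (or releasing) a harmonic restraint, from a PMF
#'
#' \deqn{\Delta G_{impose} = -\frac{1}{\beta}\ln
#'   \frac{\int e^{-\beta(w(\xi)+u(\xi))} J(\xi)\,d\xi}
#'        {\int e^{-\beta w(\xi)} J(\xi)\,d\xi}}
#' with \eqn{J = \sin\xi} for polar-type angles (`theta`, `Theta`; profiles
#' from [estimate_pmf()] and [brute_force_pmf()] exclude this geometric
#' factor) and \eqn{J = 1} otherwise.  `direction = "release"` returns the
#' exact negative.  Quadrature is trapezoidal on the bin centres; the PMF
#' domain defines the accessible range of the coordinate, and the integrand
#' must be negligible at the domain edges (tail mass below `tail_tol` of the
#' whole), otherwise an error reports the mass deficit.
#'
#' @param pmf a [pmf_profile()]
#' @param restraint a [restraint()] on the same CV kind
#' @param thermo a [thermo_state()]
#' @param direction `"impose"` or `"release"`
#' @param blocks optional list of per-block profiles for the error estimate
#' @param tail_tol edge-mass tolerance (fraction of the integral)
#' @param closed logical `c(lower, upper)`: an edge marked closed is a
#'   natural boundary of the coordinate (RMSD = 0, a periodic wrap) and is
#'   exempt from the tail-coverage check
#' @return list with `dg` (kcal/mol) and `error` (NA without blocks)
#' @export
restraint_dg_from_pmf <- function(pmf, restraint, thermo = thermo_state(),
                                  direction = c("impose", "release"),
                                  blocks = NULL, tail_tol = 1e-6,
                                  closed = c(FALSE, FALSE)) {
  direction <- match.arg(direction)
  th <- as_thermo(thermo)
  one <- function(p) {
    stopifnot(inherits(p, "pmf_profile"))
    x <- p$centers
    w <- p$value
    if (restraint$center < x[1] - p$bin_width / 2 ||
        restraint$center > x[length(x)] + p$bin_width / 2)
      stop("restraint centre lies outside the PMF domain")
    ok <- is.finite(w)
    if (!all(ok)) {
      # unsampled bins carry no weight only if the neighbourhood is high
      w[!ok] <- max(w[ok]) + 20 / th$beta
    }
    dxc <- x - restraint$center
    if (p$cv_kind %in% c("phi", "Phi", "Psi", "dihedral"))
      dxc <- dxc - 360 * round(dxc / 360)
    u <- 0.5 * restraint$k * dxc^2
    J <- if (p$cv_kind %in% jacobian_kinds) sin(x * pi / 180) else rep(1, length(x))
    fnum <- exp(-th$beta * (w - min(w) + u - min(u))) * J
    fden <- exp(-th$beta * (w - min(w))) * J
    # midpoint rule on bin centres: every bin carries its full width
    num <- sum(fnum) * p$bin_width
    den <- sum(fden) * p$bin_width
    edge <- c(1, length(x))[!closed]
    tail_mass <- if (length(edge)) sum(fnum[edge]) * p$bin_width / num else 0
    if (tail_mass > tail_tol)
      stop(sprintf(paste0("PMF domain does not cover the restrained region: ",
                          "edge mass %.2e of the integral (tolerance %.0e)"),
                   tail_mass, tail_tol))
    # undo the underflow-protection shift of u
    -log(num / den) / th$beta + min(u)
  }
  dg <- one(pmf)
  err <- if (!is.null(blocks)) block_error(vapply(blocks, one, numeric(1)))
         else NA_real_
  if (direction == "release") dg <- -dg
  list(dg = dg, error = err)
}

#' Analytic bulk reorientation free energy
#'
#' Free-energy cost of imposing the three Euler-angle restraints on a freely
#' tumbling quasi-rigid guest in the bulk:
#' \deqn{\Delta G_o^{bulk} = -\frac{1}{\beta}\ln\frac{
#'   \int e^{-\beta u_\Theta}\sin\Theta\,d\Theta\,
#'   \int e^{-\beta u_\Phi}d\Phi\, \int e^{-\beta u_\Psi}d\Psi}{8\pi^2}}
#' (radian measure internally; inputs in degrees).
#'
#' @param k_Theta,k_Phi,k_Psi force constants, kcal/(mol deg^2) (> 0)
#' @param centers restraint centres `c(Theta0, Phi0, Psi0)`, degrees
#' @param thermo a [thermo_state()]
#' @return free energy, kcal/mol (positive; grows without bound as k grows)
#' @export
analytic_bulk_orientation <- function(k_Theta, k_Phi, k_Psi,
                                      centers = c(90, 0, 0),
                                      thermo = thermo_state()) {
  th <- as_thermo(thermo)
  if (any(c(k_Theta, k_Phi, k_Psi) <= 0))
    stop("orientational force constants must be > 0")
  beta <- th$beta
  d2r <- pi / 180
  iTheta <- integrate(function(x)
    exp(-beta * 0.5 * k_Theta * (x - centers[1])^2) * sin(x * d2r),
    0, 180, rel.tol = 1e-10)$value * d2r
  iPhi <- integrate(function(x)
    exp(-beta * 0.5 * k_Phi * angdiff(x, centers[2])^2),
    -180, 180, rel.tol = 1e-10)$value * d2r
  iPsi <- integrate(function(x)
    exp(-beta * 0.5 * k_Psi * angdiff(x, centers[3])^2),
    -180, 180, rel.tol = 1e-10)$value * d2r
  -log(iTheta * iPhi * iPsi / (8 * pi^2)) / beta
}

# signed periodic angular difference in degrees, result in (-180, 180]
angdiff <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  ifelse(d <= -180, d + 360, d)
}

#' Standard-state separation term
#'
#' Computes \eqn{-\frac{1}{\beta}\ln(S^* I^* C^\circ)} from a separation PMF
#' obtained with the conformational, orientational and positional restraints
#' active:
#' \eqn{I^* = \int_{site} e^{-\beta w(r)} dr} over the bound basin with the
#' PMF re-anchored to \eqn{w(r^*) = 0}, and
#' \eqn{S^* = r^{*2} \int\int e^{-\beta u_a(\theta,\varphi)}
#' \sin\theta\,d\theta\,d\varphi} evaluated at the reference separation;
#' \eqn{C^\circ = 1/V^\circ}.
#'
#' The basin defaults to the contiguous region around the global minimum up
#' to the highest intervening point toward `r_star`; profiles with more than
#' one pronounced minimum (for example a non-native electrostatic minimum
#' along the separation path) require an explicit `basin` interval.
#'
#' @param separation_pmf a [pmf_profile()] along the separation distance,
#'   reaching `r_star`
#' @param theta_restraint,phi_restraint the positional [restraint()]s
#'   (kcal/(mol deg^2), centres in degrees)
#' @param r_star reference separation, A (anchoring point; the nearest bin
#'   centre is used)
#' @param thermo a [thermo_state()]
#' @param v0 standard-state volume, A^3 (1 M corresponds to 1661 A^3)
#' @param basin optional `c(lo, hi)` interval for the bound basin, A
#' @param blocks optional per-block separation profiles for the error
#' @return list with `dg`, `error`, `S_star` (A^2), `I_star` (A),
#'   `r_star_eff`, `basin`
#' @export
separation_standard_term <- function(separation_pmf, theta_restraint,
                                     phi_restraint, r_star,
                                     thermo = thermo_state(), v0 = 1661,
                                     basin = NULL, blocks = NULL) {
  th <- as_thermo(thermo)
  stopifnot(inherits(separation_pmf, "pmf_profile"))
  x <- separation_pmf$centers
  bw <- separation_pmf$bin_width
  if (r_star > x[length(x)] + bw / 2 + 1e-9)
    stop("separation PMF does not reach r_star")
  ist <- which.min(abs(x - r_star))
  r_eff <- x[ist]

  pick_basin <- function(w) {
    imin <- which.min(w[1:ist])
    if (!is.null(basin)) {
      sel <- which(x >= basin[1] - 1e-9 & x <= basin[2] + 1e-9)
      if (!length(sel)) stop("empty basin interval")
      return(sel)
    }
    # default: global minimum up to the highest barrier toward r_star
    path <- w[imin:ist]
    ibar <- imin - 1 + which.max(path)
    # ambiguity check: another pronounced minimum between barrier and r_star
    if (ibar < ist) {
      beyond <- w[ibar:ist]
      if (min(beyond) < w[ibar] - 2 / th$beta && which.min(beyond) > 1 &&
          (ibar - imin) > 1)
        stop(paste("separation profile has multiple pronounced minima;",
                   "supply the bound-basin interval explicitly"))
    }
    seq_len(max(ibar - 1, imin))
  }

  one <- function(p) {
    w <- p$value
    if (any(!is.finite(w)))
      stop("separation PMF has unsampled bins; cannot integrate the basin")
    w <- w - w[ist]                       # anchor w(r*) = 0
    sel <- pick_basin(w)
    I_star <- sum(exp(-th$beta * w[sel])) * bw
    list(I_star = I_star, sel = sel)
  }

  beta <- th$beta
  d2r <- pi / 180
  itheta <- integrate(function(a)
    exp(-beta * 0.5 * theta_restraint$k * (a - theta_restraint$center)^2) *
      sin(a * d2r), 0, 180, rel.tol = 1e-10)$value * d2r
  iphi <- integrate(function(a)
    exp(-beta * 0.5 * phi_restraint$k * angdiff(a, phi_restraint$center)^2),
    -180, 180, rel.tol = 1e-10)$value * d2r
  S_star <- r_eff^2 * itheta * iphi

  main <- one(separation_pmf)
  dg <- -log(S_star * main$I_star / v0) / beta
  err <- if (!is.null(blocks)) {
    vals <- vapply(blocks, function(p)
      -log(S_star * one(p)$I_star / v0) / beta, numeric(1))
    block_error(vals)
  } else NA_real_
  list(dg = dg, error = err, S_star = S_star, I_star = main$I_star,
       r_star_eff = r_eff, basin = range(x[main$sel]))
}

#' Compose the binding cycle
#'
#' Sums the nine named contributions into the standard binding free energy,
#' propagates their errors in quadrature, and reports the equilibrium
#' constant \eqn{K_{eq} = e^{-\beta \Delta G^\circ_{bind}} V^\circ} so that
#' \eqn{\Delta G^\circ_{bind} = -(1/\beta)\ln(K_{eq} C^\circ)} holds exactly.
#'
#' @param contributions list of nine [cycle_contribution()]s (each name
#'   exactly once, any order)
#' @param thermo a [thermo_state()]
#' @param v0 standard-state volume, A^3
#' @return object of class `cycle_result`
#' @export
compose_cycle <- function(contributions, thermo = thermo_state(), v0 = 1661) {
  th <- as_thermo(thermo)
  nm <- vapply(contributions, function(ct) ct$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate contribution(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  miss <- setdiff(cycle_term_names, nm)
  if (length(miss))
    stop("missing contribution(s): ", paste(miss, collapse = ", "))
  ord <- match(cycle_term_names, nm)
  contributions <- contributions[ord]
  dgs <- vapply(contributions, function(ct) ct$dg, numeric(1))
  errs <- vapply(contributions, function(ct) ct$error, numeric(1))
  times <- vapply(contributions, function(ct) ct$time_ns, numeric(1))
  dg <- sum(dgs)
  err <- if (all(is.na(errs))) NA_real_ else sqrt(sum(errs^2, na.rm = TRUE))
  keq <- exp(-th$beta * dg) * v0
  structure(list(contributions = contributions, dg_bind = dg, error = err,
                 keq = keq, v0 = v0, temperature = th$temperature,
                 time_ns = if (all(is.na(times))) NA_real_
                           else sum(times, na.rm = TRUE)),
            class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  cat("Contributions to the standard binding free energy\n")
  cat(sprintf("  %-18s %14s %18s\n", "contribution", "PMF (kcal/mol)",
              "sampling time (ns)"))
  for (ct in x$contributions) {
    e <- if (is.na(ct$error)) "" else sprintf(" +/- %.1f", ct$error)
    t <- if (is.na(ct$time_ns)) "-" else sprintf("%g", ct$time_ns)
    cat(sprintf("  %-18s %9.1f%-9s %12s\n", ct$name, ct$dg, e, t))
  }
  e <- if (is.na(x$error)) "" else sprintf(" +/- %.1f", x$error)
  t <- if (is.na(x$time_ns)) "-" else sprintf("%g", x$time_ns)
  cat(sprintf("  %-18s %9.1f%-9s %12s\n", "dG_bind", x$dg_bind, e, t))
  cat(sprintf("  K_eq = %.4g A^3 (K_eq C0 = %.4g) at T = %g K, V0 = %g A^3\n",
              x$keq, x$keq / x$v0, x$temperature, x$v0))
  invisible(x)
}
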