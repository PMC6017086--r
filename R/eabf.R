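# Extended adaptive biasing force sampling and PMF estimation.
#
# A fictitious particle lambda is coupled harmonically to the collective
# variable; lambda carries the adaptive bias (running mean coupling force per
# bin, ramped linearly until a bin holds n_full samples) and is reflected at
# the window boundaries.  Accumulators are plain per-bin sums, so estimates
# are invariant to the time ordering of the samples.

#' Harmonic restraint specification
#'
#' `u(xi) = k/2 (xi - center)^2` on a collective variable; `type` selects a
#' full harmonic or a half-harmonic wall (`"upper_wall"` acts only beyond
#' `center`, `"lower_wall"` only below).  Units: `k` in kcal/(mol A^2) for
#' distance-like CVs and kcal/(mol deg^2) for angular CVs.
#'
#' @param cv a [colvar()]
#' @param center restraint centre, CV units
#' @param k force constant (> 0)
#' @param type `"harmonic"`, `"upper_wall"` or `"lower_wall"`
#' @param center_to optional target for a moving (steering) restraint
#' @return a `restraint` specification
#' @export
restraint <- function(cv, center, k,
                      type = c("harmonic", "upper_wall", "lower_wall"),
                      center_to = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(cv, "colvar"), is.finite(center), k > 0)
  structure(list(cv = unclass(cv), center = center, k = k, type = type,
                 center_to = center_to), class = "restraint")
}

default_bin_width <- function(kind) {
  switch(kind,
         theta = , phi = , Theta = , Phi = , Psi = , dihedral = 1,
         rmsd = 0.05,
         0.1)
}

#' ABF grid for one sampling window
#'
#' @param lo,hi window bounds, CV units; `(hi - lo)/bin_width` must be an
#'   integer within 1e-9
#' @param bin_width bin width (defaults: 1 deg angular, 0.05 A RMSD,
#'   0.1 A separation)
#' @param n_full bin count at which the adaptive bias is applied at full
#'   strength (linear ramp below)
#' @return an `abf_grid` list
#' @export
abf_grid <- function(lo, hi, bin_width, n_full = 200) {
  stopifnot(hi > lo, bin_width > 0, n_full > 0)
  nb <- (hi - lo) / bin_width
  if (abs(nb - round(nb)) > 1e-9 * max(1, nb))
    stop("(hi - lo) is not an integral number of bins")
  nb <- as.integer(round(nb))
  if (nb < 2) stop("grid needs at least 2 bins")
  structure(list(lo = lo, hi = hi, bin_width = bin_width, n_bins = nb,
                 n_full = n_full), class = "abf_grid")
}

# coupling constant / fictitious mass defaults: lambda-xi RMS mismatch
# sqrt(kT/kc) = bin_width/2, lambda oscillation period ~ 50 dt
eabf_defaults <- function(grid, thermo, dt) {
  kT <- 1 / thermo$beta
  kc <- 4 * kT / grid$bin_width^2
  tau <- 50 * dt
  mlam <- kc * (tau / (2 * pi))^2 * 418.4
  list(coupling_k = kc, lambda_mass = mlam)
}

#' Run one eABF sampling window
#'
#' Propagates the system plus the extended degree of freedom and returns the
#' raw accumulators (per-bin counts and coupling-force sums, plus the
#' conditional lambda averages per physical-CV bin needed by the CZAR
#' estimator), split into `n_blocks` equal time blocks for error estimation.
#'
#' @param system a [toy_system()]
#' @param cv the biased [colvar()] (must be observable on the system)
#' @param grid an [abf_grid()]
#' @param n_steps,dt,friction,temperature Langevin parameters
#' @param seed integer seed (required)
#' @param restraints additional static [restraint()]s (the geometric
#'   restraints of the cycle)
#' @param coupling_k,lambda_mass,ext_friction extended-particle parameters;
#'   defaults keep the lambda-xi RMS mismatch at half a bin width
#' @param x0 initial positions (default: system reference)
#' @param stride record the (xi, lambda) series every `stride` steps
#'   (0 = none)
#' @param n_blocks number of equal time blocks kept separately
#' @return an `eabf_run` object
#' @export
run_eabf <- function(system, cv, grid, n_steps, dt = 0.002, friction = 5,
                     temperature = 300, seed, restraints = list(),
                     coupling_k = NULL, lambda_mass = NULL,
                     ext_friction = NULL, x0 = NULL, stride = 0L,
                     n_blocks = 2L) {
  if (missing(seed)) stop("an explicit integer seed is required")
  th <- as_thermo(temperature)
  check_cv_observable(cv, system)
  for (r in restraints) check_cv_observable(r$cv, system)
  defs <- eabf_defaults(grid, th, dt)
  if (is.null(coupling_k)) coupling_k <- defs$coupling_k
  if (is.null(lambda_mass)) lambda_mass <- defs$lambda_mass
  if (is.null(ext_friction)) ext_friction <- friction
  if (is.null(x0)) x0 <- system$positions
  if (n_steps < 1) stop("zero-length trajectory: nothing to estimate")
  periodic <- cv_is_periodic(cv$kind) && abs((grid$hi - grid$lo) - 360) < 1e-9
  set.seed(as.integer(seed))
  raw <- .cpp_run_eabf(sys_to_cpp(system), as.matrix(x0), unclass(cv),
                       lapply(restraints, unclass),
                       grid$lo, grid$hi, grid$n_bins, grid$n_full,
                       coupling_k, lambda_mass, ext_friction,
                       as.integer(n_steps), dt, friction, th$temperature,
                       as.integer(stride), as.integer(n_blocks), periodic)
  structure(c(raw, list(cv_kind = cv$kind, temperature = th$temperature,
                        coupling_k = coupling_k, n_steps = n_steps,
                        dt = dt, seed = seed, n_blocks = n_blocks,
                        periodic = periodic)),
            class = "eabf_run")
}

#' PMF profile container
#'
#' A binned free-energy profile along one collective variable, anchored so
#' that the minimum over sampled bins is zero.
#'
#' @param centers bin centres, CV units (strictly increasing, uniform)
#' @param value free energy per bin, kcal/mol
#' @param count per-bin sample counts (optional)
#' @param gradient per-bin mean-force estimate dA/dxi (optional; used for
#'   seam-matching when merging windows)
#' @param cv_kind,temperature,estimator,window metadata
#' @param metadata further key=value metadata carried through file IO
#' @param anchor `"min"` (default) anchors min(value) = 0; `"none"` keeps
#'   values as given
#' @return object of class `pmf_profile`
#' @export
pmf_profile <- function(centers, value, count = NULL, gradient = NULL,
                        cv_kind = "unknown", temperature = NA_real_,
                        estimator = "external", window = 1L,
                        metadata = list(), anchor = c("min", "none")) {
  anchor <- match.arg(anchor)
  stopifnot(length(centers) == length(value))
  if (length(centers) > 1) {
    d <- diff(centers)
    if (any(d <= 0)) stop("bin centres must be strictly increasing")
    if (max(abs(d - d[1])) > 1e-6 * d[1]) stop("bin centres must be uniform")
  }
  ok <- is.finite(value)
  if (!any(ok)) stop("profile has no finite values")
  if (anchor == "min") value <- value - min(value[ok])
  structure(list(centers = as.numeric(centers), value = as.numeric(value),
                 count = count, gradient = gradient, cv_kind = cv_kind,
                 temperature = temperature, estimator = estimator,
                 window = window, metadata = metadata,
                 bin_width = if (length(centers) > 1) diff(centers)[1] else NA_real_),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("pmf_profile: %s, %d bins of %.4g on [%.4g, %.4g], T = %g K, %s\n",
              x$cv_kind, length(x$centers), x$bin_width,
              x$centers[1] - x$bin_width / 2,
              x$centers[length(x$centers)] + x$bin_width / 2,
              x$temperature, x$estimator))
  cat(sprintf("  range %.4g kcal/mol, min at %.4g\n", max(x$value) - min(x$value),
              x$centers[which.min(x$value)]))
  invisible(x)
}

# geometric (Jacobian) entropy -kT ln sin(xi) is removed from polar-type
# angle profiles so that restraint quadrature can apply sin(xi) explicitly
jacobian_kinds <- c("theta", "Theta")

# integrate a per-bin gradient to a profile value (midpoint rule on bins)
integrate_gradient <- function(centers, grad) {
  bw <- diff(centers)[1]
  v <- c(0, cumsum((grad[-length(grad)] + grad[-1]) / 2 * bw))
  v
}

cv_is_periodic <- function(kind) kind %in% c("phi", "Phi", "Psi", "dihedral")

estimate_from_sums <- function(cnt, fsum, zcnt, zsum, centers, kind,
                               beta, kc, estimator, periodic = FALSE) {
  kT <- 1 / beta
  bw <- diff(centers)[1]
  nb <- length(centers)
  if (estimator == "naive") {
    ok <- cnt > 0
    if (!any(ok)) stop("no samples in any bin")
    grad <- rep(NA_real_, length(cnt))
    grad[ok] <- -fsum[ok] / cnt[ok]      # dA/dlambda = -<F_lambda>
  } else {
    # CZAR: dA/dz = -kT dln rho(z)/dz + kc <lambda - z>_z
    ok <- zcnt > 0
    if (sum(ok) < 3) stop("too few sampled bins for the CZAR estimator")
    lr <- rep(NA_real_, nb)
    lr[ok] <- log(zcnt[ok])
    dlr <- rep(NA_real_, nb)
    nbr <- function(j, d) {
      if (periodic) (j - 1 + d) %% nb + 1
      else if (j + d >= 1 && j + d <= nb) j + d else NA_integer_
    }
    for (j in which(ok)) {
      jm <- nbr(j, -1L); jp <- nbr(j, 1L)
      okm <- !is.na(jm) && ok[jm]; okp <- !is.na(jp) && ok[jp]
      if (okm && okp) dlr[j] <- (lr[jp] - lr[jm]) / (2 * bw)
      else if (okp) dlr[j] <- (lr[jp] - lr[j]) / bw
      else if (okm) dlr[j] <- (lr[j] - lr[jm]) / bw
    }
    grad <- -kT * dlr + kc * zsum / pmax(zcnt, 1)
    grad[!ok] <- NA_real_
  }
  if (kind %in% jacobian_kinds) {
    # remove the -kT ln sin(xi) geometric term (xi in degrees):
    # w_free = w_raw + kT ln sin(xi)
    grad <- grad + kT * (pi / 180) / tan(centers * pi / 180)
  }
  grad
}

#' Estimate a PMF from an eABF run
#'
#' `estimator = "czar"` (default) removes the harmonic-coupling convolution
#' using the sampled distribution of the physical CV; `"naive"` integrates
#' the binned mean force felt by the extended particle (adequate only in the
#' stiff-coupling regime).  For polar-type angles (`theta`, `Theta`) the
#' geometric `-kT ln sin(xi)` term is removed, so downstream restraint
#' quadrature applies the `sin` Jacobian explicitly.
#'
#' Interior bins without samples are flagged as gaps; integration proceeds
#' per contiguous segment (values in later segments are offset by simple
#' continuation and marked in `metadata$gaps`).
#'
#' @param run an `eabf_run` from [run_eabf()]
#' @param estimator `"czar"` or `"naive"`
#' @param block `NULL` for the full run, or a block index (1..n_blocks)
#' @return a [pmf_profile()]
#' @export
estimate_pmf <- function(run, estimator = c("czar", "naive"), block = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(run, "eabf_run"))
  beta <- 1 / (KB_KCAL * run$temperature)
  if (is.null(block)) {
    cnt <- run$count; fsum <- run$force_sum
    zcnt <- run$z_count; zsum <- run$z_lambda_sum
  } else {
    cnt <- run$block_count[block, ]; fsum <- run$block_force_sum[block, ]
    zcnt <- run$block_z_count[block, ]; zsum <- run$block_z_lambda_sum[block, ]
  }
  centers <- run$centers
  grad <- estimate_from_sums(cnt, fsum, zcnt, zsum, centers, run$cv_kind,
                             beta, run$coupling_k, estimator,
                             periodic = isTRUE(run$periodic))
  ok <- is.finite(grad)
  gaps <- which(!ok & seq_along(ok) > min(which(ok)) &
                  seq_along(ok) < max(which(ok)))
  g0 <- grad
  g0[!ok] <- 0   # continuation across gaps
  value <- integrate_gradient(centers, g0)
  value[!ok] <- NA_real_
  # counts reported on the sampling histogram actually used
  counts <- if (estimator == "naive") cnt else zcnt
  pmf_profile(centers, value, count = counts, gradient = grad,
              cv_kind = run$cv_kind, temperature = run$temperature,
              estimator = estimator,
              metadata = list(gaps = gaps, n_steps = run$n_steps))
}

#' Split a sampling range into consecutive windows
#'
#' Equal-width (to the nearest bin), non-overlapping windows exactly covering
#' `[lo, hi]`, with boundaries snapped to bin edges.
#'
#' @param lo,hi full range, CV units
#' @param n_windows number of windows (1..5 in routine use)
#' @param bin_width bin width the boundaries must snap to
#' @return list of `c(lo, hi)` pairs
#' @export
stratify_windows <- function(lo, hi, n_windows, bin_width) {
  stopifnot(n_windows >= 1, hi > lo, bin_width > 0)
  nb <- (hi - lo) / bin_width
  if (abs(nb - round(nb)) > 1e-9 * max(1, nb))
    stop("(hi - lo) is not an integral number of bins")
  nb <- as.integer(round(nb))
  per <- diff(round(seq(0, nb, length.out = n_windows + 1)))
  if (any(per < 2)) stop("windows narrower than 2 bins; reduce n_windows")
  edges <- lo + cumsum(c(0, per)) * bin_width
  edges[length(edges)] <- hi
  lapply(seq_len(n_windows), function(i) c(edges[i], edges[i + 1]))
}

#' Merge PMF profiles from consecutive windows
#'
#' Windows must abut exactly and share one bin width.  When every profile
#' carries a per-bin mean-force `gradient`, the merged profile is obtained by
#' integrating the concatenated gradient (mean-force continuity at the
#' seams); otherwise successive profiles are offset so values match across
#' each seam.  The merged profile is re-anchored to min = 0.
#'
#' @param profiles list of [pmf_profile()]s, in increasing order
#' @return a single [pmf_profile()]
#' @export
merge_windows <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  if (length(profiles) == 1)
    return(pmf_profile(profiles[[1]]$centers, profiles[[1]]$value,
                       count = profiles[[1]]$count,
                       gradient = profiles[[1]]$gradient,
                       cv_kind = profiles[[1]]$cv_kind,
                       temperature = profiles[[1]]$temperature,
                       estimator = profiles[[1]]$estimator))
  bw <- vapply(profiles, function(p) p$bin_width, numeric(1))
  if (max(abs(bw - bw[1])) > 1e-9 * bw[1])
    stop("window bin widths differ; cannot merge")
  bw <- bw[1]
  for (i in seq_len(length(profiles) - 1)) {
    hi_i <- profiles[[i]]$centers[length(profiles[[i]]$centers)] + bw / 2
    lo_n <- profiles[[i + 1]]$centers[1] - bw / 2
    if (abs(hi_i - lo_n) > 1e-6 * bw)
      stop(sprintf("windows %d and %d are not contiguous: gap [%g, %g]",
                   i, i + 1, hi_i, lo_n))
  }
  centers <- unlist(lapply(profiles, function(p) p$centers))
  counts <- unlist(lapply(profiles, function(p)
    if (is.null(p$count)) rep(NA_real_, length(p$centers)) else p$count))
  grads <- lapply(profiles, function(p) p$gradient)
  if (!any(vapply(grads, is.null, logical(1)))) {
    grad <- unlist(grads)
    g0 <- grad; g0[!is.finite(g0)] <- 0
    value <- integrate_gradient(centers, g0)
    value[!is.finite(grad)] <- NA_real_
  } else {
    value <- profiles[[1]]$value
    grad <- NULL
    for (i in seq_len(length(profiles) - 1)) {
      nxt <- profiles[[i + 1]]$value
      off <- value[length(value)] - nxt[1] +
        (profiles[[i + 1]]$centers[1] -
           profiles[[i]]$centers[length(profiles[[i]]$centers)]) *
        0  # plain value continuity across the one-bin seam
      value <- c(value, nxt + off)
    }
  }
  pmf_profile(centers, value, count = counts, gradient = grad,
              cv_kind = profiles[[1]]$cv_kind,
              temperature = profiles[[1]]$temperature,
              estimator = profiles[[1]]$estimator)
}

#' Compute a PMF over a stratified range
#'
#' Convenience driver: stratifies `[lo, hi]` into windows, steers the system
#' into each window, runs eABF per window, and merges.  Also returns
#' per-block merged profiles for [block_error()] analysis.
#'
#' @inheritParams run_eabf
#' @param lo,hi full CV range
#' @param bin_width bin width (default by CV kind)
#' @param n_windows number of consecutive windows (<= 5 in routine use)
#' @param steps_per_window sampling steps per window
#' @param equil_steps unbiased/steered equilibration steps before each window
#' @param n_full ABF ramp threshold, samples per bin
#' @param estimator passed to [estimate_pmf()]
#' @return list with `profile`, `blocks` (list of per-block profiles),
#'   `windows`, and the per-window `runs`
#' @export
compute_pmf <- function(system, cv, lo, hi, bin_width = NULL,
                        n_windows = 1, steps_per_window, dt = 0.002,
                        friction = 5, temperature = 300, seed,
                        restraints = list(), n_full = 200,
                        equil_steps = 2000, estimator = "czar",
                        x0 = NULL, n_blocks = 2L) {
  if (missing(seed)) stop("an explicit integer seed is required")
  if (is.null(bin_width)) bin_width <- default_bin_width(cv$kind)
  wins <- stratify_windows(lo, hi, n_windows, bin_width)
  if (is.null(x0)) x0 <- system$positions
  th <- as_thermo(temperature)
  runs <- vector("list", length(wins))
  profs <- vector("list", length(wins))
  blockp <- vector("list", length(wins))
  x <- as.matrix(x0)
  for (i in seq_along(wins)) {
    w <- wins[[i]]
    target <- mean(w)
    cur <- cv_value(cv, x, system$masses)$value
    if (equil_steps > 0) {
      steer_k <- if (cv$kind %in% c("theta", "phi", "Theta", "Phi", "Psi",
                                    "dihedral")) 0.5 else 50
      st <- run_trajectory(system, n_steps = equil_steps, dt = dt,
                           friction = friction, seed = seed + 7919L * i,
                           temperature = th,
                           restraints = c(restraints, list(
                             restraint(cv, center = cur, k = steer_k,
                                       center_to = target))),
                           stride = 0, x0 = x)
      x <- st$x_final
    }
    runs[[i]] <- run_eabf(system, cv, abf_grid(w[1], w[2], bin_width, n_full),
                          n_steps = steps_per_window, dt = dt,
                          friction = friction, temperature = th,
                          seed = seed + 104729L * i, restraints = restraints,
                          x0 = x, n_blocks = n_blocks)
    x <- runs[[i]]$x_final
    profs[[i]] <- estimate_pmf(runs[[i]], estimator)
  }
  blocks <- lapply(seq_len(n_blocks), function(b)
    merge_windows(lapply(runs, function(r) estimate_pmf(r, estimator, block = b))))
  list(profile = merge_windows(profs), blocks = blocks, windows = wins,
       runs = runs)
}

#' Block error of a derived free-energy quantity
#'
#' The statistical data are divided into blocks of equal size and the target
#' quantity recomputed on each block.  For two blocks the error is half the
#' absolute difference; for more, the standard error over blocks.
#'
#' @param block_values numeric vector of per-block estimates (length >= 2),
#'   or a list whose elements are per-block inputs to `fun`
#' @param fun optional function applied to each element of `block_values`
#' @return the error estimate (kcal/mol for free energies)
#' @examples
#' block_error(c(-34.0, -36.4))  # 1.2
#' @export
block_error <- function(block_values, fun = NULL) {
  if (!is.null(fun)) block_values <- vapply(block_values, fun, numeric(1))
  block_values <- as.numeric(block_values)
  n <- length(block_values)
  if (n < 2) stop("need at least two blocks")
  if (n == 2) return(abs(diff(block_values)) / 2)
  sd(block_values) / sqrt(n)
}
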