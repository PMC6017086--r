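# eABF sampler, PMF estimators, window stratification, merging, block error.

test_that("a flat landscape yields zero mean force and a flat PMF", {
  sys <- toy_system(masses = 12, positions = rbind(c(0, 0, 0)))
  run <- run_eabf(sys, colvar("axis_projection", axis = c(1, 0, 0)),
                  abf_grid(-1, 1, 0.1), n_steps = 3e5, seed = 61)
  p <- estimate_pmf(run, "naive")
  expect_lt(max(abs(p$value)), 0.1)
  # per-bin mean force has nothing to estimate: small against the scale of
  # the instantaneous coupling-force fluctuations sqrt(kc kT) ~ 12
  mf <- run$force_sum / pmax(run$count, 1)
  expect_lt(max(abs(mf)), 1.0)
})

test_that("eABF recovers a harmonic PMF with both estimators", {
  sys <- harmonic_bead(k = 3)
  pm <- compute_pmf(sys, colvar("axis_projection", axis = c(1, 0, 0)),
                    lo = -1.5, hi = 1.5, bin_width = 0.05,
                    steps_per_window = 6e5, seed = 62, estimator = "czar")
  ref <- 0.5 * 3 * pm$profile$centers^2
  sel <- ref - min(ref) <= 2
  aligned <- function(p) p$value[sel] - min(p$value[sel])
  refa <- ref[sel] - min(ref[sel])
  expect_lt(max(abs(aligned(pm$profile) - refa)), 0.1)
  naive <- merge_windows(lapply(pm$runs, estimate_pmf, estimator = "naive"))
  expect_lt(max(abs(aligned(naive) - refa)), 0.1)
})

test_that("eABF matches brute-force quadrature on the quartic double well", {
  sys <- double_well_bead(height = 2.5)
  cv <- colvar("axis_projection", axis = c(1, 0, 0))
  pm <- compute_pmf(sys, cv, lo = -1.6, hi = 1.6, bin_width = 0.05,
                    steps_per_window = 8e5, seed = 63, estimator = "czar")
  oracle <- brute_force_pmf(sys, cv, lo = -1.6, hi = 1.6, bin_width = 0.05,
                            range = 5, n_grid = c(400, 80, 80))
  sel <- oracle$value <= 3   # compare over the thermally relevant range
  dev <- pm$profile$value[sel] - oracle$value[sel]
  dev <- dev - mean(dev)
  expect_lt(max(abs(dev)), 0.15)
})

test_that("CZAR removes the coupling convolution that broadens naive PMFs", {
  sys <- harmonic_bead(k = 2)
  cv <- colvar("axis_projection", axis = c(1, 0, 0))
  kT <- kT300
  # moderate coupling: naive curvature is the harmonic-convolution value
  kc <- 8
  run <- run_eabf(sys, cv, abf_grid(-1.8, 1.8, 0.05), n_steps = 1.2e6,
                  seed = 64, coupling_k = kc)
  fit_k <- function(p, lim = 1) {
    sel <- abs(p$centers) <= lim
    2 * coef(lm(p$value[sel] ~ p$centers[sel] + I(p$centers[sel]^2)))[3]
  }
  k_naive <- fit_k(estimate_pmf(run, "naive"))
  k_czar <- fit_k(estimate_pmf(run, "czar"))
  k_conv <- 1 / (1 / 2 + 1 / kc)   # Gaussian convolution algebra
  expect_lt(abs(k_naive - k_conv), 0.12)
  expect_lt(abs(k_czar - 2), 0.12)
  # stiff coupling: the two estimators coincide
  run2 <- run_eabf(sys, cv, abf_grid(-1.8, 1.8, 0.05), n_steps = 2e6,
                   seed = 65, coupling_k = 400)
  pn <- estimate_pmf(run2, "naive"); pc <- estimate_pmf(run2, "czar")
  sel <- 0.5 * 2 * pn$centers^2 <= 2
  expect_lt(max(abs((pn$value - pc$value)[sel] -
                    mean((pn$value - pc$value)[sel]))), 0.05)
})

test_that("zero-length runs are rejected, not silently empty", {
  sys <- harmonic_bead()
  expect_error(run_eabf(sys, colvar("separation"), abf_grid(0, 1, 0.1),
                        n_steps = 0, seed = 1), "zero-length")
})

test_that("window stratification snaps equal windows to bin edges", {
  w <- stratify_windows(0, 30, 5, 0.1)
  expect_equal(vapply(w, `[`, numeric(1), 2)[1:4], c(6, 12, 18, 24))
  expect_equal(stratify_windows(2, 8, 1, 0.1), list(c(2, 8)))
  w3 <- stratify_windows(0, 10, 3, 0.1)
  b <- unlist(w3)
  expect_true(all(abs(b / 0.1 - round(b / 0.1)) < 1e-9))
  expect_equal(w3[[1]][2], 3.3)  # 100 bins -> 33/34/33
  expect_error(stratify_windows(0, 1, 4, 0.2), "narrower")
})

test_that("merging windows reproduces the unsplit profile", {
  # synthetic exact check: split a known gradient into three windows
  centers <- seq(0.05, 3.95, by = 0.1)
  grad <- 2 * (centers - 2)
  full <- pmf_profile(centers, cumsum(grad) * 0, gradient = grad,
                      cv_kind = "separation", temperature = 300)
  parts <- list(1:13, 14:26, 27:40)
  profs <- lapply(parts, function(ix)
    pmf_profile(centers[ix], rep(0, length(ix)), gradient = grad[ix],
                cv_kind = "separation", temperature = 300))
  merged <- merge_windows(profs)
  truth <- (centers - 2)^2; truth <- truth - min(truth)
  expect_equal(merged$value, truth, tolerance = 1e-10)
  # single profile passes through (re-anchored)
  one <- merge_windows(profs[1])
  expect_equal(min(one$value), 0)
  # contract violations
  expect_error(merge_windows(list(profs[[1]], profs[[3]])), "contiguous")
  bad <- pmf_profile(seq(1.325, 2.575, by = 0.05), rep(0, 26),
                     cv_kind = "separation", temperature = 300)
  expect_error(merge_windows(list(profs[[1]], bad)), "bin width")
  # sampled split-then-merge reproduces the closed-form profile
  sys <- harmonic_bead(k = 3)
  cv <- colvar("axis_projection", axis = c(1, 0, 0))
  pm3 <- compute_pmf(sys, cv, lo = -1.5, hi = 1.5, bin_width = 0.05,
                     n_windows = 3, steps_per_window = 4e5, seed = 66,
                     estimator = "naive")
  ref <- 1.5 * pm3$profile$centers^2
  sel <- ref - min(ref) <= 2
  d <- pm3$profile$value[sel] - ref[sel]
  expect_lt(max(abs(d - mean(d))), 0.1)
})

test_that("block error follows its definition and tracks the true scatter", {
  expect_equal(block_error(c(-35, -35)), 0)
  expect_equal(block_error(c(-34.0, -36.4)), 1.2)
  expect_equal(block_error(c(1, 2, 3, 4)), sd(1:4) / 2)
  expect_error(block_error(3.14), "two blocks")
  # two-block error on a harmonic restraint free energy is consistent with
  # the scatter of independent repeats (within a factor of 3)
  sys <- harmonic_bead(k = 3)
  cv <- colvar("axis_projection", axis = c(1, 0, 0))
  r <- restraint(cv, 0, 5)
  dgs <- numeric(4); errs <- numeric(4)
  for (i in 1:4) {
    pm <- compute_pmf(sys, cv, lo = -1.5, hi = 1.5, bin_width = 0.05,
                      steps_per_window = 1.5e5, seed = 70 + i)
    est <- restraint_dg_from_pmf(pm$profile, r, blocks = pm$blocks)
    dgs[i] <- est$dg; errs[i] <- est$error
  }
  scatter <- sd(dgs)
  expect_gt(mean(errs), scatter / 3)
  expect_lt(mean(errs), scatter * 3)
})

test_that("accumulators are order-independent sums over blocks", {
  sys <- harmonic_bead(k = 3)
  run <- run_eabf(sys, colvar("axis_projection", axis = c(1, 0, 0)),
                  abf_grid(-1.5, 1.5, 0.1), n_steps = 1e5, seed = 81,
                  n_blocks = 2)
  expect_equal(colSums(run$block_count), as.numeric(run$count))
  expect_equal(colSums(run$block_force_sum), as.numeric(run$force_sum))
  expect_equal(colSums(run$block_z_count), as.numeric(run$z_count))
})
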