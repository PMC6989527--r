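test_that("canonical sampling satisfies equipartition on the harmonic reference", {
  for (dims in c(1, 3)) {
    h <- make_harmonic_reference(1, dims)
    tr <- run_canonical(h, 300, 2e5, seed = 21 + dims, thin = 5,
                        moves = list(bead_step = 1.2))
    se <- block_se(tr$energy)
    expect_lt(abs(mean(tr$energy) - harmonic_mean_energy(h, 300)), 3 * se)
  }
})

test_that("the two-body benchmark collapses to the contact distance at low T", {
  sys <- two_body_system(eps = 4, sigma = 3.5)
  tr <- run_canonical(sys, 5, 20000, seed = 4, thin = 100,
                      start = rbind(c(0, 0, 0), c(5.5, 0, 0)))
  d_final <- sqrt(sum((tr$final_coords[2, ] - tr$final_coords[1, ])^2))
  expect_equal(d_final, 3.5, tolerance = 0.05)
})

test_that("identical seeds give bit-identical trajectories", {
  sys <- small_system()
  a <- run_canonical(sys, 400, 5000, seed = 33, thin = 10)
  b <- run_canonical(sys, 400, 5000, seed = 33, thin = 10)
  expect_identical(a$energy, b$energy)
  expect_identical(a$coords, b$coords)
  w <- mc_weight(c(-10, 0, 10), c(-10, 0, 5) / 1, 300, 700)
  ma <- run_multicanonical(sys, w, n_steps = 5000, seed = 9, thin = 10)
  mb <- run_multicanonical(sys, w, n_steps = 5000, seed = 9, thin = 10)
  expect_identical(ma$energy, mb$energy)
})

test_that("a non-finite starting energy is rejected", {
  sys <- two_body_system()
  bad <- rbind(c(0, 0, 0), c(0, 0, 0))   # coincident beads: infinite core
  expect_error(run_canonical(sys, 300, 100, start = bad), "non-finite")
})

test_that("occupancy ratios obey detailed balance against the Boltzmann law", {
  h <- make_harmonic_reference(1, 1)
  tr <- run_canonical(h, 300, 4e5, seed = 17, thin = 2,
                      moves = list(bead_step = 1.0))
  x <- tr$lam
  kT <- 0.0019872 * 300
  p_hat <- c(mean(x >= 0 & x < 0.4), mean(x >= 0.8 & x < 1.2))
  z <- stats::pnorm(c(0.4, 1.2), sd = sqrt(kT)) -
    stats::pnorm(c(0, 0.8), sd = sqrt(kT))
  expect_equal(p_hat[1] / p_hat[2], z[1] / z[2], tolerance = 0.1)
})

test_that("the flat-histogram estimate recovers the analytic density of states", {
  for (dims in 1:2) {
    h <- make_harmonic_reference(1, dims)
    w <- suppressWarnings(
      estimate_mc_weight(h, NULL, seed = 5, n_bins = 100,
                         steps_per_iteration = 5e4, pilot_steps = 2e4,
                         moves = list(bead_step = 1.2)))
    g <- w$energy_grid
    sel <- g > 0.2 & g < stats::quantile(g, 0.9)
    dev <- w$ln_dos[sel] - harmonic_ln_dos(h, g[sel])
    dev <- dev - mean(dev)
    expect_lt(sqrt(mean(dev^2)), 0.25)
  }
})

test_that("the algebraically canonical weight reproduces canonical sampling exactly", {
  sys <- small_system()
  kT <- 0.0019872 * 500
  grid <- seq(-30, 30, length.out = 50)
  w <- mc_weight(grid, grid / kT, T_low = 500, T_high = 500)
  ca <- run_canonical(sys, 500, 20000, seed = 12, thin = 10)
  mu <- run_multicanonical(sys, w, n_steps = 20000, seed = 12, thin = 10)
  expect_identical(ca$energy, mu$energy)
  uw <- reweight(mu, 500, w)
  expect_equal(as.numeric(uw), rep(1 / length(mu$energy), length(mu$energy)),
               tolerance = 1e-9)
})

test_that("flatness follows the min/max definition and hand-binned counts", {
  expect_equal(flatness(rep(seq(0.5, 9.5, 1), 7), c(0, 10), n_bins = 10), 1.0)
  expect_equal(flatness(c(0.1, 0.2, 5), c(0, 10), n_bins = 10), 0.0)
  set.seed(2)
  e <- runif(500, -3, 7)
  h <- table(cut(e, seq(-5, 10, length.out = 16)))
  expect_equal(flatness(e, c(-5, 10), n_bins = 15),
               min(h) / max(h))
  expect_error(flatness(c(1, 2), c(5, 6)), "inside")
})

test_that("multicanonical production random-walks across the energy band with round trips", {
  sys <- build_system()
  cyl <- default_restraint(sys)
  w <- suppressWarnings(estimate_mc_weight(sys, cyl, seed = 2))
  expect_true(w$diagnostics$converged)
  it <- w$diagnostics$iterations
  expect_gte(it$flatness[nrow(it)], 0.5)   # the stopping criterion
  tr <- run_multicanonical(sys, w, cyl, n_steps = 3e5, seed = 102, thin = 50,
                           save_coords = FALSE)
  band <- w$diagnostics$target_E_range
  expect_gte(round_trips(tr, band) / 3, 1)       # >= 1 per 1e5 steps
  expect_gt(flatness(tr, band), 0)
  # reweighted <lambda> agrees with a direct canonical average at 300 K
  w300 <- reweight(tr, 300)
  can <- run_canonical(sys, 300, 1e5, cyl, seed = 103, thin = 20,
                       save_coords = FALSE)
  se <- sqrt(block_se(tr$lam, as.numeric(w300))^2 + block_se(can$lam)^2)
  expect_lt(abs(sum(tr$lam * w300) - mean(can$lam)), 3 * se)
})
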