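kT300 <- 0.0019872 * 300

# wrap a canonical run of the 1D harmonic reference as an umbrella run
harmonic_run <- function(k_bias, center, seed, n_steps = 2e5, k_sys = 1) {
  h <- make_harmonic_reference(k_sys, 1)
  bias <- if (k_bias > 0) list(k = k_bias, center = center) else NULL
  tr <- run_canonical(h, 300, n_steps, seed = seed, thin = 4, bias = bias,
                      moves = list(bead_step = 1.0), save_coords = FALSE)
  tr$bias <- list(k = k_bias, center = center)
  tr$lam_ref <- 0
  tr
}

test_that("WHAM recovers the analytic harmonic PMF from a single window", {
  runs <- structure(list(harmonic_run(0, 0, 3, 4e5)), class = "umbrella_set")
  pmf <- wham(runs, bin_width = 0.1, T = 300, reference = "min")
  sel <- which(abs(pmf$lamp) <= 1 & !is.na(pmf$G))
  dev <- pmf$G[sel] - 0.5 * pmf$lamp[sel]^2
  dev <- dev - dev[which.min(abs(pmf$lamp[sel]))]
  expect_lt(max(abs(dev)), 0.05)
})

test_that("overlapping windows reproduce the single-window PMF", {
  one <- structure(list(harmonic_run(0, 0, 3, 4e5)), class = "umbrella_set")
  two <- structure(list(harmonic_run(1, -0.8, 31), harmonic_run(1, 0.8, 32)),
                   class = "umbrella_set")
  p1 <- wham(one, bin_width = 0.1, T = 300, reference = "min")
  p2 <- wham(two, bin_width = 0.1, T = 300, reference = "min")
  m <- merge(data.frame(lamp = round(p1$lamp, 6), G1 = p1$G),
             data.frame(lamp = round(p2$lamp, 6), G2 = p2$G))
  m <- m[!is.na(m$G1) & !is.na(m$G2) & abs(m$lamp) < 1, ]
  d <- m$G1 - m$G2
  expect_lt(max(abs(d - mean(d))), 0.08)
})

test_that("uniform unbiased histograms give a flat PMF", {
  fake <- structure(list(list(lam = rep(seq(0.05, 4.95, 0.1), 20),
                              bias = list(k = 0, center = 0), lam_ref = 0)),
                    class = "umbrella_set")
  pmf <- wham(fake, bin_width = 0.5, T = 300)
  expect_equal(max(abs(pmf$G[!is.na(pmf$G)])), 0, tolerance = 1e-9)
})

test_that("umbrella lambda fluctuations match the closed-form variance", {
  # system k/2 x^2 plus bias k_w x^2: total (k/2 + k_w) x^2
  tr <- harmonic_run(0.5, 0, 13, 2e5)
  expect_equal(stats::var(tr$lam), kT300 / (2 * (0.5 + 0.5)), tolerance = 0.03)
})

test_that("a zero-force-constant bias reduces to plain canonical sampling", {
  h <- make_harmonic_reference(1, 1)
  a <- run_canonical(h, 300, 5000, seed = 40, thin = 5,
                     bias = list(k = 0, center = 2))
  b <- run_canonical(h, 300, 5000, seed = 40, thin = 5)
  expect_identical(a$energy, b$energy)
})

test_that("umbrella runs are reproducible and report window overlap", {
  sys <- two_body_system()
  cyl <- default_restraint(sys)
  ws <- window_spec(4, 0, 6, 0.3, n_seeds = 1)
  seeds <- list(native_pose(sys))
  r1 <- run_umbrella(sys, ws, seeds, 4000, restraints = cyl, rng_seed = 5,
                     lam_ref = 3.5)
  r2 <- run_umbrella(sys, ws, seeds, 4000, restraints = cyl, rng_seed = 5,
                     lam_ref = 3.5)
  expect_identical(r1[[2]]$lam, r2[[2]]$lam)
  expect_true(all(attr(r1, "overlaps") > 0))
})

test_that("binding depth reads the bound-window average off the PMF", {
  flat <- structure(list(lamp = seq(0.125, 10, 0.25),
                         G = rep(0, 40), bin_width = 0.25,
                         counts = rep(10, 40), temperature = 300),
                    class = "pmf_profile")
  expect_equal(binding_dG(flat), 0)
  well <- flat
  well$G <- ifelse(well$lamp <= 2.5, -3, 0)
  expect_equal(binding_dG(well), -3)
  far <- flat
  far$lamp <- far$lamp + 5
  expect_error(binding_dG(far), "lambda")
})

test_that("binned PMF depth of the two-body system matches the grid oracle", {
  sys <- two_body_system()
  cyl <- default_restraint(sys)
  ws <- window_spec(16, 0, 24.5, 0.3, n_seeds = 2)
  # each window starts from the on-axis pose at its own center
  seeds <- lapply(ws$center, function(ctr)
    rbind(c(0, 0, 0), c(3.5 + ctr, 0, 0)))
  runs <- run_umbrella(sys, ws, seeds, n_steps = 30000,
                       restraints = cyl, lam_ref = 3.5, rng_seed = 77,
                       thin = 5, save_coords = FALSE)
  pmf <- wham(trailing_runs(runs, 0.8), bin_width = 0.25, T = 300)
  dG <- binding_dG(pmf)
  dG_oracle <- two_body_grid_dG()
  expect_lt(abs(dG - dG_oracle), 0.3)
})

test_that("effective volume obeys its closed forms", {
  # constant G over a known site volume returns that volume
  bin <- 0.25
  cells <- expand.grid(lamp = seq(bin / 2, 2.5 - bin / 2, bin),
                       v = seq(-3.875, 3.875, bin),
                       zeta = seq(-3.875, 3.875, bin))
  cells <- cells[sqrt(cells$v^2 + cells$zeta^2) <= 3, ]
  g3d <- list(cells = cbind(cells, G = -5), bin = bin, radius = 3,
              temperature = 300)
  expect_equal(effective_volume(g3d, dG = -5, T = 300, radius = 3),
               nrow(cells) * bin^3, tolerance = 1e-9)
  # 3D harmonic well G = k d^2 (depth 0): Gaussian integral (pi kT / k)^(3/2)
  k <- 0.5
  fine <- 0.1
  cg <- expand.grid(lamp = seq(fine / 2, 2.5, fine),
                    v = seq(-3.95, 3.95, fine), zeta = seq(-3.95, 3.95, fine))
  r2 <- (cg$lamp - 1.25)^2 + cg$v^2 + cg$zeta^2
  g3h <- list(cells = cbind(cg, G = k * r2), bin = fine, radius = 4,
              temperature = 300)
  expect_equal(effective_volume(g3h, dG = 0, T = 300),
               (pi * kT300 / k)^1.5, tolerance = 0.05 * (pi * kT300 / k)^1.5)
  # deepening the well shrinks the volume relative to its depth
  g_deep <- g3h
  g_deep$cells$G <- 4 * k * r2
  expect_lt(effective_volume(g_deep, 0, 300),
            effective_volume(g3h, 0, 300))
  expect_error(effective_volume(g3h, 0, 300, bound_width = -1), "site")
})

test_that("the standard-state identity holds exactly for binding results", {
  br <- binding_result(-10, 5, T = 300)
  expect_equal(br$dG0 - br$dG, kT300 * log(1661 / 5), tolerance = 1e-12)
  expect_equal(standard_dG(-7.3, 1661), -7.3, tolerance = 1e-12)
  expect_error(standard_dG(-7.3, 0), "positive")
})

test_that("range errors follow the block formula and identical blocks give zero", {
  sys <- two_body_system()
  cyl <- default_restraint(sys)
  ws <- window_spec(8, 0, 21, 0.3, n_seeds = 1)
  runs <- run_umbrella(sys, ws, rep(list(native_pose(sys)), 8),
                       n_steps = 12000, restraints = cyl, lam_ref = 3.5,
                       rng_seed = 15, thin = 5, save_coords = FALSE)
  re <- range_error(runs, fractions = c(0.5, 1.0), n_blocks = 2)
  expect_equal(nrow(re), 2)
  # hand computation of the 2-block estimate for the full range
  blocks <- vapply(1:2, function(b) {
    blk <- trailing_runs(runs, 1.0)
    blk <- mcdock:::.subset_runs(blk, function(n)
      seq.int(floor((b - 1) * n / 2) + 1L, floor(b * n / 2)))
    binding_dG(wham(blk))
  }, numeric(1))
  expect_equal(re$eps[2], stats::sd(blocks) / sqrt(2), tolerance = 1e-9)
  # duplicated data: identical blocks, zero error
  dup <- runs
  for (i in seq_along(dup)) {
    dup[[i]]$lam <- rep(runs[[i]]$lam, 2)
    dup[[i]]$v <- rep(runs[[i]]$v, 2)
    dup[[i]]$zeta <- rep(runs[[i]]$zeta, 2)
    dup[[i]]$energy <- rep(runs[[i]]$energy, 2)
  }
  re0 <- range_error(dup, fractions = c(0.5, 1.0), n_blocks = 2)
  expect_equal(re0$eps[2], 0, tolerance = 1e-9)
  expect_error(range_error(runs, fractions = 1.5), "fractions")
})

test_that("WHAM is invariant under window refinement on the analytic well", {
  coarse <- structure(list(harmonic_run(0.6, -1, 61, 1e5),
                           harmonic_run(0.6, 1, 62, 1e5)),
                      class = "umbrella_set")
  fine <- structure(list(harmonic_run(0.6, -1.2, 63, 1e5),
                         harmonic_run(0.6, -0.4, 64, 1e5),
                         harmonic_run(0.6, 0.4, 65, 1e5),
                         harmonic_run(0.6, 1.2, 66, 1e5)),
                    class = "umbrella_set")
  pc <- wham(coarse, bin_width = 0.15, T = 300, reference = "min")
  pf <- wham(fine, bin_width = 0.15, T = 300, reference = "min")
  m <- merge(data.frame(lamp = round(pc$lamp, 6), Gc = pc$G),
             data.frame(lamp = round(pf$lamp, 6), Gf = pf$G))
  m <- m[!is.na(m$Gc) & !is.na(m$Gf) & abs(m$lamp) < 1.2, ]
  d <- m$Gc - m$Gf
  expect_lt(max(abs(d - mean(d))), 0.1)
})
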