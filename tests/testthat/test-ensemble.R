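test_that("reweighting restores exact two-level populations", {
  # enumerable two-level toy: energies 0 and dE sampled flat (ln n = 0)
  dE <- 1.2
  kT <- 0.0019872 * 300
  fake <- structure(list(energy = rep(c(0, dE), each = 500),
                         ensemble = "multicanonical",
                         weight = mc_weight(c(-1, 0, dE, 2),
                                            rep(0, 4), 300, 700)),
                    class = "trajectory")
  w <- reweight(fake, 300)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  ratio <- sum(w[fake$energy > 0]) / sum(w[fake$energy == 0])
  expect_equal(ratio, exp(-dE / kT), tolerance = 1e-9)
  expect_error(reweight(structure(list(ensemble = "canonical"),
                                  class = "trajectory"), 300),
               "canonical")
})

test_that("reweighted mean energy satisfies equipartition", {
  h <- make_harmonic_reference(1, 3)
  w <- suppressWarnings(
    estimate_mc_weight(h, NULL, seed = 6, n_bins = 100,
                       steps_per_iteration = 5e4, pilot_steps = 2e4,
                       moves = list(bead_step = 1.0)))
  tr <- run_multicanonical(h, w, n_steps = 2e5, seed = 7, thin = 5,
                           moves = list(bead_step = 1.0))
  w300 <- reweight(tr, 300)
  se <- block_se(tr$energy, as.numeric(w300))
  expect_lt(abs(sum(tr$energy * w300) - harmonic_mean_energy(h, 300)),
            3 * se + 0.01)
})

test_that("distance features follow the chain-separation exclusion rule", {
  x <- cbind(1:5 * 3.8, 0, 0)
  f3 <- distance_features(x, exclude_within = 3)
  expect_equal(names(f3), "d1_5")            # only |i-j| > 3 retained
  expect_equal(unname(f3), 4 * 3.8)
  expect_length(distance_features(x[1:4, ], exclude_within = 3), 0)
  f0 <- distance_features(x, exclude_within = 0)
  expect_length(f0, choose(5, 2))
  # stable ordering across frames
  expect_identical(names(distance_features(x + 1, exclude_within = 1)),
                   names(distance_features(x, exclude_within = 1)))
  expect_error(distance_features(x, selection = c(1, 9)), "topology")
})

test_that("weighted PCA reduces to standard PCA under equal weights", {
  set.seed(8)
  X <- matrix(rnorm(300), 100, 3) %*% matrix(c(3, 1, 0, 1, 2, 0, 0, 0, 0.5), 3, 3)
  p <- weighted_pca(X)
  ref <- eigen(stats::cov(X) * (nrow(X) - 1) / nrow(X), symmetric = TRUE)
  expect_equal(p$values, ref$values, tolerance = 1e-8)
  expect_equal(abs(p$rotation), abs(ref$vectors), tolerance = 1e-6)
})

test_that("weighted PCA captures collinear variance on PC1 and fixes signs", {
  t <- seq(-2, 2, length.out = 50)
  X <- cbind(t, 2 * t, -t)
  p <- weighted_pca(X)
  expect_equal(p$values[1], sum(p$values), tolerance = 1e-10)
  m <- which.max(abs(p$rotation[, 1]))
  expect_gt(p$rotation[m, 1], 0)
})

test_that("doubling a frame's weight equals duplicating the frame", {
  set.seed(10)
  X <- matrix(rnorm(60), 20, 3)
  w <- rep(1, 20); w[7] <- 2
  p1 <- weighted_pca(X, structure(w / sum(w), class = "frame_weights"))
  p2 <- weighted_pca(rbind(X, X[7, , drop = FALSE]))
  expect_equal(p1$values, p2$values, tolerance = 1e-9)
  expect_equal(p1$center, p2$center, tolerance = 1e-9)
})

test_that("free-energy landscapes encode population ratios exactly", {
  kT <- 0.0019872 * 300
  pr <- rbind(cbind(rnorm(200, -3, 0.2), rnorm(200, 0, 0.2)),
              cbind(rnorm(100, 3, 0.2), rnorm(100, 0, 0.2)))
  w <- uniform_weights(300)
  fel <- build_fel(pr, w, T = 300, nx = 30, ny = 10)
  expect_equal(min(fel$F, na.rm = TRUE), 0)
  expect_true(anyNA(fel$F))                  # empty cells carry no value
  cl <- cluster_representatives(fel, pr, w)
  expect_gte(nrow(cl), 2)
  expect_equal(cl$delta_F[1], 0)
  # the two clouds dominate; stray single-frame basins may trail far behind
  expect_equal(cl$weight[1:2], c(2 / 3, 1 / 3), tolerance = 0.05)
  expect_equal(cl$delta_F[2], kT * log(2), tolerance = 0.25)
  # representative frames sit inside their cloud
  expect_lt(abs(pr[cl$representative[1], 1] + 3), 1)
  expect_lt(abs(pr[cl$representative[2], 1] - 3), 1)
})

test_that("uniform weight over cells gives a flat landscape", {
  g <- expand.grid(seq(0.5, 4.5), seq(0.5, 4.5))
  fel <- build_fel(as.matrix(g), uniform_weights(nrow(g)), T = 300,
                   nx = 5, ny = 5)
  expect_equal(max(fel$F, na.rm = TRUE), 0, tolerance = 1e-12)
})

test_that("cluster ranking matches brute-force weight sums", {
  set.seed(12)
  centers <- rbind(c(-4, 0), c(0, 4), c(4, -2))
  n <- c(150, 90, 60)
  pr <- do.call(rbind, lapply(1:3, function(i)
    cbind(rnorm(n[i], centers[i, 1], 0.3), rnorm(n[i], centers[i, 2], 0.3))))
  w <- structure(rep(c(1, 2, 4), n) / sum(rep(c(1, 2, 4), n)),
                 class = "frame_weights")
  fel <- build_fel(pr, w, nx = 40, ny = 40)
  cl <- cluster_representatives(fel, pr, w)
  brute <- sort(tapply(as.numeric(w), rep(1:3, n), sum), decreasing = TRUE)
  expect_equal(cl$weight[1:3], as.numeric(brute), tolerance = 0.03)
})

test_that("single compact cloud yields one cluster at delta F zero", {
  set.seed(13)
  pr <- cbind(rnorm(200), rnorm(200))
  fel <- build_fel(pr, uniform_weights(200), nx = 8, ny = 8)
  cl <- cluster_representatives(fel, pr, uniform_weights(200))
  expect_equal(cl$delta_F[1], 0)
  expect_gt(cl$weight[1], 0.9)
})

test_that("R-value axioms hold and it decays monotonically with contact loss", {
  ref <- matrix(FALSE, 5, 4); ref[cbind(1:4, 1:4)] <- TRUE
  expect_equal(rvalue(ref, ref), 1.0)
  expect_equal(rvalue(!ref, ref), 0.0)
  frame <- ref; frame[4, 4] <- FALSE
  expect_equal(rvalue(frame, ref), 0.75)
  r_prev <- 1
  for (k in 1:4) {
    frame <- ref; frame[cbind(seq_len(k), seq_len(k))] <- FALSE
    r <- rvalue(frame, ref)
    expect_lte(r, r_prev)
    r_prev <- r
  }
  expect_error(rvalue(ref, matrix(FALSE, 5, 4)), "no contacts")
  expect_error(rvalue(ref, ref[1:4, ]), "shape")
})

test_that("stability assay keeps native contacts at 300 K and loses them when overheated", {
  sys <- build_system()
  st0 <- stability_assay(sys, native_pose(sys), T_list = 300, n_steps = 0,
                         n_repeats = 1)
  expect_true(all(st0$series$R == 1.0))
  st <- stability_assay(sys, native_pose(sys), T_list = c(300, 900),
                        n_steps = 15000, n_repeats = 2, seed = 14)
  agg <- tapply(st$summary$R_mean, st$summary$T, mean)
  expect_gte(agg[["300"]], 0.8)
  expect_lt(agg[["900"]], agg[["300"]])
})

test_that("Kabsch superposition matches a brute-force rotational search", {
  set.seed(15)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose(A, A)$rmsd, 0, tolerance = 1e-10)
  ax <- c(1, 2, 3) / sqrt(14); th <- 1.1
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  expect_equal(superpose(A %*% R, A)$rmsd, 0, tolerance = 1e-10)
  # noisy pair: compare with axis-angle grid search + local refinement
  B <- A %*% R + matrix(rnorm(30, 0, 0.3), 10, 3)
  fit <- superpose(B, A)
  obj <- function(p) {
    th <- sqrt(sum(p^2))
    Rr <- if (th < 1e-12) diag(3) else {
      u <- p / th
      Ku <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3)
      diag(3) + sin(th) * Ku + (1 - cos(th)) * Ku %*% Ku
    }
    Bc <- sweep(B, 2, colMeans(B)); Ac <- sweep(A, 2, colMeans(A))
    sqrt(mean(rowSums((Bc %*% Rr - Ac)^2)))
  }
  grid <- as.matrix(expand.grid(seq(-pi, pi, 0.8), seq(-pi, pi, 0.8),
                                seq(-pi, pi, 0.8)))
  vals <- apply(grid, 1, obj)
  best <- optim(grid[which.min(vals), ], obj,
                control = list(reltol = 1e-14))$value
  expect_equal(fit$rmsd, best, tolerance = 1e-3)
  expect_error(superpose(A, A, mask = 1:2), "at least 3")
  C <- cbind(1:5, 1:5, 1:5)  # collinear
  expect_error(superpose(C, C), "collinear")
})

test_that("RMSF is zero for rigid frames and sqrt(3) sigma under isotropic jitter", {
  set.seed(16)
  nb <- 60   # many beads, so the rigid-body fit absorbs little of the jitter
  base <- matrix(rnorm(3 * nb, sd = 4), nb, 3)
  rigid <- array(rep(base, 10), c(nb, 3, 10))
  expect_equal(max(rmsf(rigid)), 0, tolerance = 1e-10)
  sig <- 0.3
  jit <- array(rep(base, 300), c(nb, 3, 300)) + rnorm(nb * 3 * 300, 0, sig)
  r <- rmsf(jit)
  expect_equal(mean(r), sig * sqrt(3), tolerance = 0.05)
  expect_warning(rmsf_by_window(jit, rep(c("a", "b"), c(299, 1))), "skipped")
})
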