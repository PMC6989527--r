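test_that("system construction is deterministic and satisfies the bound-pose contract", {
  s1 <- build_system()
  s2 <- build_system()
  expect_identical(s1, s2)
  expect_gte(nrow(s1$native_contacts), 8)
  lam <- lambda_coords(ligand_com(s1, native_pose(s1)), default_restraint(s1))["lam"]
  expect_gte(lam, 2.5)
  expect_lte(lam, 4.5)
  expect_true(all(native_contacts_formed(s1, native_pose(s1))))
})

test_that("overlapping receptor beads are rejected with a message", {
  expect_error(build_system(r_excluded = 2.5), "excluded-volume")
})

test_that("native pose beats 100 locally-minimized random unbound poses", {
  sys <- build_system()
  cyl <- default_restraint(sys)
  np <- native_pose(sys)
  e_native <- total_energy(sys, np)
  expect_equal(e_native, -sum(sys$native_contacts$eps), tolerance = 1e-10)
  nrec <- nrow(sys$receptor_beads)
  nlig <- sys$ligand_topology$n
  set.seed(101)
  worst <- Inf
  for (i in 1:100) {
    # random rigid placement of the straight chain in the unbound region
    lamv <- runif(1, 8, 28); vv <- runif(2, -3, 3)
    com <- lambda_to_com(c(lamv, vv), cyl)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    lig <- outer((seq_len(nlig) - (nlig + 1) / 2) * sys$ligand_topology$bond_length, ax)
    lig <- sweep(lig, 2, com, `+`)
    x <- np
    x[nrec + seq_len(nlig), ] <- lig
    obj <- function(p) {
      x[nrec + seq_len(nlig), ] <- matrix(p, nlig, 3)
      total_energy(sys, x)
    }
    fit <- optim(as.numeric(lig), obj, method = "BFGS",
                 control = list(maxit = 40))
    worst <- min(worst, fit$value)
  }
  expect_lt(e_native, worst)
})

test_that("total energy equals an independent term-by-term re-summation", {
  sys <- small_system()
  set.seed(7)
  x <- native_pose(sys) + matrix(rnorm(length(native_pose(sys)), 0, 0.8),
                                 ncol = 3)
  nrec <- nrow(sys$receptor_beads)
  n <- sys$ligand_topology$n
  lig <- x[nrec + seq_len(n), ]
  tp <- sys$ligand_topology
  e_bond <- sum(tp$k_bond * (sqrt(rowSums(diff(lig)^2)) - tp$bond_length)^2)
  e_ang <- 0
  for (i in 2:(n - 1)) {
    a <- lig[i - 1, ] - lig[i, ]; b <- lig[i + 1, ] - lig[i, ]
    th <- acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
    e_ang <- e_ang + tp$k_angle * (th - tp$theta0)^2
  }
  con <- sys$native_contacts
  d <- sqrt(rowSums((x[con$rec, ] - x[nrec + con$lig, ])^2))
  e_go <- sum(con$eps * (5 * (con$sigma / d)^12 - 6 * (con$sigma / d)^10))
  rp <- sys$rep_pairs + 1
  dr <- sqrt(rowSums((x[rp[, 1], ] - x[rp[, 2], ])^2))
  dex <- 2 * sys$nonnative_repulsion$radius
  e_rep <- sum(ifelse(dr < dex,
                      sys$nonnative_repulsion$eps_rep * ((dex / dr)^12 - 1), 0))
  expect_equal(total_energy(sys, x), e_bond + e_ang + e_go + e_rep,
               tolerance = 1e-10)
})

test_that("contacts vanish at large separation, leaving bonded terms only", {
  sys <- small_system()
  x <- native_pose(sys)
  nrec <- nrow(sys$receptor_beads)
  lig <- seq_len(sys$ligand_topology$n) + nrec
  x[lig, 1] <- x[lig, 1] + 1e5
  expect_equal(total_energy(sys, x), 0, tolerance = 1e-8)  # straight chain: no bonded strain
  expect_error(total_energy(sys, x[-1, ]), "coordinates")
})

test_that("two-body benchmark gives -eps at the contact minimum", {
  sys <- two_body_system(eps = 4, sigma = 3.5)
  expect_equal(total_energy(sys, native_pose(sys)), -4, tolerance = 1e-12)
})

test_that("energy is invariant under joint rigid motions", {
  sys <- small_system()
  set.seed(11)
  x <- native_pose(sys) + matrix(rnorm(3 * (nrow(native_pose(sys))), 0, 0.3),
                                 ncol = 3)
  e0 <- total_energy(sys, x)
  for (i in 1:5) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, 2 * pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    xr <- sweep(x %*% R, 2, rnorm(3, 0, 5), `+`)
    expect_equal(total_energy(sys, xr), e0, tolerance = 1e-8)
  }
})

test_that("the attractive well rises monotonically beyond sigma", {
  sys <- two_body_system(eps = 4, sigma = 3.5)
  d <- seq(3.5, 12, 0.05)
  e <- vapply(d, function(r)
    total_energy(sys, rbind(c(0, 0, 0), c(r, 0, 0))), numeric(1))
  expect_true(all(diff(e) > 0))
  expect_equal(min(e), -4, tolerance = 1e-12)
})

test_that("harmonic reference exposes the advertised closed forms", {
  h <- make_harmonic_reference(1, 1)
  expect_equal(harmonic_mean_energy(h, 300), 0.29808, tolerance = 1e-6)
  expect_equal(harmonic_pmf(h, 0), 0)
  expect_equal(harmonic_pmf(h, 2), 2)
  h2 <- make_harmonic_reference(1, 2)
  expect_equal(diff(harmonic_ln_dos(h2, c(1, 5))), 0)  # flat in E for 2D
  expect_error(make_harmonic_reference(-1, 1))
})
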