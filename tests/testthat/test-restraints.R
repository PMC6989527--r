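test_that("cylinder coordinates project and invert exactly", {
  cyl <- cylinder_restraint(origin = c(1, 2, 3), axis = c(1, 1, 0))
  expect_equal(unname(lambda_coords(c(1, 2, 3), cyl)), c(0, 0, 0))
  com <- c(1, 2, 3) + 6.64 * cyl$axis
  expect_equal(unname(lambda_coords(com, cyl)["lam"]), 6.64, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:10) {
    p <- rnorm(3, sd = 10)
    expect_equal(lambda_to_com(lambda_coords(p, cyl), cyl), p,
                 tolerance = 1e-10)
  }
})

test_that("flat-bottom cylinder energy matches the k*d^2 convention", {
  cyl <- cylinder_restraint()
  expect_equal(cylinder_energy(c(10, 0, 0), cyl), 0)
  expect_equal(cylinder_energy(c(10, 5, 0), cyl), 1.0)   # 1.0 * 1^2
  expect_equal(cylinder_energy(c(30.5, 0, 0), cyl), 5.0) # 20.0 * 0.25
  half <- cylinder_restraint(half_k = TRUE)
  expect_equal(cylinder_energy(c(10, 5, 0), half), 0.5)
})

test_that("cylinder energy is continuous with continuous first differences", {
  cyl <- cylinder_restraint()
  r <- seq(3.5, 4.5, 1e-4)
  e <- cylinder_energy(cbind(10, r, 0), cyl)
  d1 <- diff(e) / 1e-4
  expect_lt(max(abs(diff(e))), 1e-3)          # continuity
  expect_lt(max(abs(diff(d1))), 1e-2)         # no slope jump at the wall
  lam <- seq(29.5, 30.5, 1e-4)
  e2 <- cylinder_energy(cbind(lam, 0, 0), cyl)
  expect_lt(max(abs(diff(diff(e2) / 1e-4))), 0.2)
})

test_that("restraint energy is invariant under rotations about the axis", {
  cyl <- cylinder_restraint()
  set.seed(5)
  for (i in 1:10) {
    lam <- runif(1, 0, 32); r <- runif(1, 0, 7); phi <- runif(2, 0, 2 * pi)
    p1 <- lambda_to_com(c(lam, r * cos(phi[1]), r * sin(phi[1])), cyl)
    p2 <- lambda_to_com(c(lam, r * cos(phi[2]), r * sin(phi[2])), cyl)
    expect_equal(cylinder_energy(p1, cyl), cylinder_energy(p2, cyl),
                 tolerance = 1e-10)
  }
})

test_that("position restraints follow sum k|x - x_ref|^2 over the mask", {
  ref <- matrix(rnorm(30), 10, 3)
  expect_equal(position_restraint_energy(ref, ref, 1), 0)
  x <- ref; x[4, ] <- x[4, ] + c(2, 0, 0)
  expect_equal(position_restraint_energy(x, ref, 1.0), 4.0)
  expect_equal(position_restraint_energy(x, ref, 1.0, mask = integer(0)), 0)
  expect_equal(position_restraint_energy(x, ref, 1.0, mask = c(1, 2)), 0)
  expect_error(position_restraint_energy(x[-1, ], ref, 1), "dimensions")
})

test_that("pocket origin matches a brute-force distance filter", {
  set.seed(9)
  rec <- matrix(rnorm(300, sd = 12), ncol = 3)
  lig <- matrix(rnorm(15, sd = 2), ncol = 3)
  near <- vapply(seq_len(nrow(rec)), function(i)
    min(sqrt(colSums((t(lig) - rec[i, ])^2))) <= 10, logical(1))
  expect_equal(pocket_axis_from_complex(rec, lig),
               colMeans(rec[near, , drop = FALSE]), tolerance = 1e-12)
  one <- matrix(c(0, 0, 5), 1, 3)
  expect_equal(unname(pocket_axis_from_complex(one, lig)), c(0, 0, 5))
  far <- matrix(c(100, 100, 100), 1, 3)
  expect_error(pocket_axis_from_complex(far, lig), "within")
})

test_that("symmetric pockets give an origin on the symmetry axis", {
  rec <- rbind(c(0, 1, 1), c(0, -1, 1), c(0, 1, -1), c(0, -1, -1))
  lig <- matrix(c(2, 0, 0), 1, 3)
  expect_equal(unname(pocket_axis_from_complex(rec, lig)), c(0, 0, 0))
})
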