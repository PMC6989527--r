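# shared fixtures and independent oracles used across the suite

kB <- 0.0019872

# weighted one-sample Kolmogorov-Smirnov distance between a weighted sample
# and an unweighted reference sample
ks_weighted <- function(x, w, y) {
  o <- order(x)
  Fy <- stats::ecdf(y)
  max(abs(cumsum(w[o] / sum(w)) - Fy(x[o])))
}

# block standard error of a (weighted) mean over a correlated series
block_se <- function(x, w = NULL, n_blocks = 5) {
  n <- length(x)
  if (is.null(w)) w <- rep(1, n)
  idx <- split(seq_len(n), cut(seq_len(n), n_blocks, labels = FALSE))
  m <- vapply(idx, function(i) sum(x[i] * w[i]) / sum(w[i]), numeric(1))
  stats::sd(m) / sqrt(n_blocks)
}

# potential of the two-body benchmark (Go 12-10 + cylinder restraint),
# written independently of the package energy path
two_body_potential <- function(X, eps, sigma, cyl) {
  r <- sqrt(rowSums(X^2))
  q <- sigma / r
  eps * (5 * q^12 - 6 * q^10) + cylinder_energy(X, cyl)
}

# exhaustive 3D-grid partition-sum oracle for the two-body benchmark:
# standard-state binding free energy with the same site definition the
# pipeline uses (lambda' in [0, bound_width], transverse within radius)
two_body_grid_dG0 <- function(eps = 4, sigma = 3.5, T = 300,
                              bound_width = 2.5, h = 0.05, V0 = 1661) {
  cyl <- default_restraint(two_body_system(eps, sigma))
  kT <- kB * T
  gx <- seq(sigma - 0.75, sigma + bound_width + 0.25, h)
  gy <- seq(-4.8, 4.8, h)
  X <- as.matrix(expand.grid(gx, gy, gy))
  U <- two_body_potential(X, eps, sigma, cyl)
  lamp <- X[, 1] - sigma
  site <- lamp >= 0 & lamp <= bound_width & sqrt(X[, 2]^2 + X[, 3]^2) <= 4
  Z <- sum(exp(-U[site] / kT)) * h^3
  -kT * log(Z / V0)
}

# grid oracle for the PMF depth with the pipeline's binned definition:
# G per lambda'-bin from the transverse integral, referenced to the
# analytic unbound plateau, averaged over the bound window
two_body_grid_dG <- function(eps = 4, sigma = 3.5, T = 300,
                             bound_width = 2.5, bin_width = 0.25, h = 0.05) {
  sys <- two_body_system(eps, sigma)
  cyl <- default_restraint(sys)
  kT <- kB * T
  gy <- seq(-4.8, 4.8, h)
  tr <- as.matrix(expand.grid(gy, gy))
  edges <- seq(0, bound_width, bin_width)
  Gbin <- vapply(seq_len(length(edges) - 1), function(b) {
    xs <- seq(sigma + edges[b] + h / 2, sigma + edges[b + 1] - h / 2, h)
    z <- 0
    for (x in xs) {
      X <- cbind(x, tr)
      z <- z + sum(exp(-two_body_potential(X, eps, sigma, cyl) / kT)) * h^3
    }
    -kT * log(z / (bin_width))
  }, numeric(1))
  # analytic plateau: per unit lambda, transverse integral of the bare
  # cylinder wall (no interaction far from the receptor)
  rr <- seq(h / 2, 12, h)
  A <- sum(exp(-cyl$k_perp * pmax(rr - cyl$radius, 0)^2 / kT) * 2 * pi * rr * h)
  G_plat <- -kT * log(A)
  mean(Gbin - G_plat)
}

# tiny deterministic toy system shared by several tests
small_system <- function() build_system(ligand_length = 4, n_loops = 2)
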