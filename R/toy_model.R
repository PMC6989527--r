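#' Build the coarse-grained receptor-ligand toy system
#'
#' Constructs a bead-level Go-model stand-in for an antibody-peptide
#' complex: a rigid receptor groove (back wall, floor and two side rows)
#' holding a short ligand chain in a natively bound pose, plus a few
#' harmonically tethered "loop" beads at the pocket mouth that mimic
#' flexible binding-site loops. Native contacts are defined from the bound
#' pose (every receptor bead of the floor/side rows paired with its facing
#' ligand bead, and each loop bead with its nearest ligand bead), with the
#' 12-10 well minimum `sigma_ij` set to the bound-pose pair distance, so the
#' bound pose is the exact minimum of every contact term and the native
#' energy equals `-sum(eps_ij)`.
#'
#' The pocket axis points out of the groove (+x); its origin is the COM of
#' the receptor beads within 10 Angstrom of the bound ligand (see
#' [pocket_axis_from_complex()]), placing the bound-pose ligand COM at
#' lambda of about 3, just outside the lower edge of the default restraint
#' cylinder's flat region.
#'
#' @param ligand_length number of ligand beads (default 6).
#' @param bond_length ligand bond length, Angstrom.
#' @param k_bond,k_angle bonded force constants (kcal/mol/A^2,
#'   kcal/mol/rad^2); the equilibrium angle is straight (pi).
#' @param eps native-contact well depth, kcal/mol per contact. The default
#'   is calibrated so the native basin is occupied at 300 K while bound and
#'   unbound states exchange around 700 K.
#' @param loop_eps well depth of loop-ligand contacts (default `eps`).
#' @param r_excluded excluded-volume radius per bead, Angstrom; nonnative
#'   pairs repel below `2 * r_excluded`.
#' @param eps_rep excluded-volume energy scale, kcal/mol.
#' @param tether_k harmonic tether force constant on loop beads,
#'   kcal/mol/A^2 (`k * d^2` convention, like MD-engine position
#'   restraints).
#' @param n_loops number of mouth loop beads (0, 2 or 4).
#' @return An object of class `toy_system`.
#' @export
build_system <- function(ligand_length = 6, bond_length = 3.8,
                         k_bond = 10, k_angle = 2, eps = 2.0,
                         loop_eps = eps, r_excluded = 1.5, eps_rep = 1.0,
                         tether_k = 1.0, n_loops = 4) {
  n <- as.integer(ligand_length)
  stopifnot(n >= 1, bond_length > 0, eps >= 0, r_excluded > 0)
  if (!n_loops %in% c(0L, 2L, 4L)) stop("n_loops must be 0, 2 or 4")
  x_bind <- 3.5
  yy <- (seq_len(n) - (n + 1) / 2) * bond_length
  lig0 <- cbind(x = rep(x_bind, n), y = yy, z = rep(0, n))

  back <- cbind(-5.0, yy, 0)
  floor_row <- cbind(0.0, yy, 0)
  side_up <- cbind(2.5, yy, 3.5)
  side_dn <- cbind(2.5, yy, -3.5)
  rec <- rbind(back, floor_row, side_up, side_dn)
  loop_idx <- integer(0)
  if (n_loops > 0) {
    ly <- min(2.0, max(abs(yy)))
    loops <- rbind(c(5.5, ly, 3.2), c(5.5, -ly, -3.2))
    if (n_loops == 4) loops <- rbind(loops, c(5.5, -ly, 3.2), c(5.5, ly, -3.2))
    loop_idx <- nrow(rec) + seq_len(nrow(loops))
    rec <- rbind(rec, loops)
  }
  rownames(rec) <- NULL; colnames(rec) <- c("x", "y", "z")

  # native contacts: floor + sides pair with the facing ligand bead,
  # loops with their nearest bound-pose ligand bead
  con <- data.frame(rec = integer(0), lig = integer(0), eps = numeric(0),
                    sigma = numeric(0))
  for (i in seq_len(n)) {
    for (ridx in c(n + i, 2 * n + i, 3 * n + i)) {  # floor, side up, side down
      s <- sqrt(sum((rec[ridx, ] - lig0[i, ])^2))
      con <- rbind(con, data.frame(rec = ridx, lig = i, eps = eps, sigma = s))
    }
  }
  for (ridx in loop_idx) {
    d <- sqrt(rowSums(sweep(lig0, 2, rec[ridx, ])^2))
    i <- which.min(d)
    con <- rbind(con, data.frame(rec = ridx, lig = i, eps = loop_eps,
                                 sigma = d[i]))
  }

  d_ex <- 2 * r_excluded
  # geometry validation: receptor beads must not overlap
  dd <- as.matrix(stats::dist(rec))
  diag(dd) <- Inf
  if (any(dd < d_ex - 1e-9)) {
    w <- which(dd < d_ex - 1e-9, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid geometry: receptor beads %d and %d are %.2f A apart, closer than the excluded-volume diameter %.2f A",
                 w[1], w[2], dd[w[1], w[2]], d_ex))
  }

  origin <- pocket_axis_from_complex(rec, lig0, cutoff = 10)
  axis <- c(1, 0, 0)
  sys <- structure(list(
    receptor_beads = rec,
    loop_idx = loop_idx,
    tether_k = tether_k,
    ligand_topology = list(n = n, bond_length = bond_length,
                           k_bond = k_bond, k_angle = k_angle,
                           theta0 = pi),
    native_contacts = con,
    nonnative_repulsion = list(radius = r_excluded, eps_rep = eps_rep),
    pocket_axis = list(origin = origin, axis = axis),
    native_ligand = lig0,
    config = list(ligand_length = n, bond_length = bond_length,
                  k_bond = k_bond, k_angle = k_angle, eps = eps,
                  loop_eps = loop_eps, r_excluded = r_excluded,
                  eps_rep = eps_rep, tether_k = tether_k, n_loops = n_loops)
  ), class = "toy_system")
  sys$rep_pairs <- .repulsion_pairs(sys)
  sys
}

#' Two-body analytic benchmark system
#'
#' Degenerate toy system -- one receptor bead at the origin, one ligand
#' bead, a single native contact -- whose partition function is computable
#' by direct 3D grid summation, used as the exact oracle for the
#' umbrella/WHAM/standard-state pipeline.
#'
#' @param eps well depth, kcal/mol.
#' @param sigma contact distance, Angstrom.
#' @param r_excluded,eps_rep excluded-volume parameters (unused between the
#'   single native pair, kept for a consistent topology).
#' @return A `toy_system` with one bead per molecule. Its `native_ligand`
#'   pose sits on the pocket axis at `lambda = sigma`.
#' @export
two_body_system <- function(eps = 4, sigma = 3.5, r_excluded = 1.5,
                            eps_rep = 1.0) {
  rec <- matrix(c(0, 0, 0), 1, 3, dimnames = list(NULL, c("x", "y", "z")))
  lig0 <- matrix(c(sigma, 0, 0), 1, 3, dimnames = list(NULL, c("x", "y", "z")))
  con <- data.frame(rec = 1L, lig = 1L, eps = eps, sigma = sigma)
  sys <- structure(list(
    receptor_beads = rec, loop_idx = integer(0), tether_k = 0,
    ligand_topology = list(n = 1L, bond_length = 0, k_bond = 0,
                           k_angle = 0, theta0 = pi),
    native_contacts = con,
    nonnative_repulsion = list(radius = r_excluded, eps_rep = eps_rep),
    pocket_axis = list(origin = c(0, 0, 0), axis = c(1, 0, 0)),
    native_ligand = lig0,
    config = list(ligand_length = 1L, eps = eps, sigma = sigma)
  ), class = "toy_system")
  sys$rep_pairs <- .repulsion_pairs(sys)
  sys
}

# nonbonded repulsion pair list (0-based global indices for the engine):
# nonnative receptor-ligand pairs, ligand-ligand pairs >= 2 bonds apart,
# and mobile-loop vs other-receptor pairs. Fixed-fixed pairs are constant
# and skipped.
.repulsion_pairs <- function(sys) {
  nrec <- nrow(sys$receptor_beads)
  n <- sys$ligand_topology$n
  native <- paste(sys$native_contacts$rec, sys$native_contacts$lig)
  pairs <- NULL
  rl <- expand.grid(rec = seq_len(nrec), lig = seq_len(n))
  rl <- rl[!paste(rl$rec, rl$lig) %in% native, , drop = FALSE]
  if (nrow(rl)) pairs <- cbind(rl$rec - 1L, nrec + rl$lig - 1L)
  if (n > 2) {
    ll <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    ll <- ll[ll[, 2] - ll[, 1] >= 2, , drop = FALSE]
    if (nrow(ll)) pairs <- rbind(pairs, cbind(nrec + ll[, 1] - 1L,
                                              nrec + ll[, 2] - 1L))
  }
  for (l in sys$loop_idx) {
    other <- setdiff(seq_len(nrec), l)
    other <- other[other > l | !(other %in% sys$loop_idx)]  # avoid loop-loop dups
    if (length(other))
      pairs <- rbind(pairs, cbind(pmin(l, other) - 1L, pmax(l, other) - 1L))
  }
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2)
  storage.mode(pairs) <- "integer"
  unique(pairs)
}

#' Native (bound) pose coordinates of a toy system
#'
#' Full coordinate matrix (receptor beads first, then ligand beads) with
#' the ligand in its natively bound pose and all loop beads at their
#' reference positions.
#'
#' @param system a `toy_system`.
#' @return (n_receptor + n_ligand) x 3 matrix.
#' @export
native_pose <- function(system) {
  stopifnot(inherits(system, "toy_system"))
  unname(rbind(system$receptor_beads, system$native_ligand))
}

#' Default cylinder restraint of a toy system
#'
#' The restraint used during dynamic docking: origin and axis from the
#' system's pocket, lambda range 2.5-30 Angstrom, radius 4 Angstrom, force
#' constants 1.0 (perpendicular) and 20.0 (parallel) kcal/mol/A^2.
#'
#' @param system a `toy_system`.
#' @param ... overrides passed to [cylinder_restraint()].
#' @export
default_restraint <- function(system, ...) {
  cylinder_restraint(origin = system$pocket_axis$origin,
                     axis = system$pocket_axis$axis, ...)
}

# engine-facing packed representation
.pack_system <- function(system, restraints = NULL, bias = NULL) {
  pk <- if (inherits(system, "harmonic_reference")) {
    list(harmonic = TRUE, hk = system$k, hdims = as.integer(system$dims))
  } else {
    stopifnot(inherits(system, "toy_system"))
    list(harmonic = FALSE,
         rec_ref = unname(as.matrix(system$receptor_beads)),
         nlig = as.integer(system$ligand_topology$n),
         loops = as.integer(system$loop_idx - 1L),
         tether_k = system$tether_k,
         bond_r0 = system$ligand_topology$bond_length,
         k_bond = system$ligand_topology$k_bond,
         theta0 = system$ligand_topology$theta0,
         k_angle = system$ligand_topology$k_angle,
         con = cbind(as.integer(system$native_contacts$rec - 1L),
                     as.integer(nrow(system$receptor_beads) +
                                  system$native_contacts$lig - 1L)),
         con_eps = as.numeric(system$native_contacts$eps),
         con_sigma = as.numeric(system$native_contacts$sigma),
         rep_pairs = system$rep_pairs,
         d_ex = 2 * system$nonnative_repulsion$radius,
         eps_rep = system$nonnative_repulsion$eps_rep)
  }
  if (is.null(restraints)) {
    # the pocket frame is still used to report (lam, v, zeta); energy off
    ax <- if (inherits(system, "toy_system")) system$pocket_axis else
      list(origin = c(0, 0, 0), axis = c(1, 0, 0))
    axis <- ax$axis / sqrt(sum(ax$axis^2))
    b <- transverse_basis(axis)
    pk$cyl_on <- FALSE
    pk$cyl_origin <- as.numeric(ax$origin)
    pk$cyl_axis <- axis
    pk$cyl_v <- b$v
    pk$cyl_z <- b$zeta
    pk$lam_min <- 0; pk$lam_max <- 0; pk$radius <- 1
    pk$k_perp <- 0; pk$k_par <- 0; pk$half <- 1
  } else {
    stopifnot(inherits(restraints, "cylinder_restraint"))
    pk$cyl_on <- TRUE
    pk$cyl_origin <- restraints$origin
    pk$cyl_axis <- restraints$axis
    pk$cyl_v <- restraints$v
    pk$cyl_z <- restraints$zeta
    pk$lam_min <- restraints$lam_min
    pk$lam_max <- restraints$lam_max
    pk$radius <- restraints$radius
    pk$k_perp <- restraints$k_perp
    pk$k_par <- restraints$k_par
    pk$half <- restraints$half
  }
  if (is.null(bias)) {
    pk$bias_on <- FALSE
  } else {
    pk$bias_on <- TRUE
    pk$bias_k <- bias$k
    pk$bias_c <- bias$center
  }
  pk
}

#' Total potential energy of a toy system
#'
#' Sum of bonded (bond stretch + angle bending), attractive Go 12-10
#' native-contact and excluded-volume terms:
#' `E = sum k_b (d - d0)^2 + sum k_a (theta - pi)^2 +
#'  sum eps_ij (5 (s/r)^12 - 6 (s/r)^10) + sum_rep eps_rep ((d_ex/r)^12 - 1)
#'  [r < d_ex]`.
#' Restraint terms (tethers, cylinder) are separate; see
#' [position_restraint_energy()] and [cylinder_energy()].
#'
#' @param system a `toy_system`.
#' @param coordinates full coordinate matrix as from [native_pose()].
#' @return energy in kcal/mol.
#' @export
total_energy <- function(system, coordinates) {
  coordinates <- unname(as.matrix(coordinates))
  n_expected <- nrow(system$receptor_beads) + system$ligand_topology$n
  if (nrow(coordinates) != n_expected || ncol(coordinates) != 3)
    stop("expected ", n_expected, " x 3 coordinates, got ",
         nrow(coordinates), " x ", ncol(coordinates))
  cpp_system_energy(.pack_system(system), coordinates)
}

#' Ligand center of mass of a full coordinate matrix
#' @param system a `toy_system`.
#' @param coordinates full coordinate matrix.
#' @return 3-vector.
#' @export
ligand_com <- function(system, coordinates) {
  nrec <- nrow(system$receptor_beads)
  colMeans(coordinates[nrec + seq_len(system$ligand_topology$n), , drop = FALSE])
}

#' @export
print.toy_system <- function(x, ...) {
  cat("Coarse-grained Go-model receptor-ligand system\n")
  cat(sprintf("  receptor beads: %d (%d flexible loop beads)\n",
              nrow(x$receptor_beads), length(x$loop_idx)))
  cat(sprintf("  ligand beads:   %d (bond %.2f A)\n",
              x$ligand_topology$n, x$ligand_topology$bond_length))
  cat(sprintf("  native contacts: %d, total well depth %.2f kcal/mol\n",
              nrow(x$native_contacts), sum(x$native_contacts$eps)))
  lvz <- lambda_coords(ligand_com(x, native_pose(x)), default_restraint(x))
  cat(sprintf("  bound-pose ligand COM at lambda = %.2f A\n", lvz["lam"]))
  invisible(x)
}

#' Simulate canonical dynamics of a toy system
#'
#' Convenience `simulate` method: a canonical Metropolis Monte-Carlo run of
#' `nsim` steps at temperature `T` (see [run_canonical()]).
#'
#' @param object a `toy_system`.
#' @param nsim number of Monte-Carlo steps.
#' @param seed RNG seed.
#' @param T temperature, K.
#' @param ... passed on to [run_canonical()].
#' @return a `trajectory`.
#' @export
simulate.toy_system <- function(object, nsim = 10000, seed = NULL, T = 300, ...) {
  run_canonical(object, T = T, n_steps = nsim, seed = seed, ...)
}
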