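#' Cylindrical center-of-mass restraint
#'
#' Defines the flat-bottom cylindrical restraint that confines the ligand
#' center of mass (COM) to the binding-pocket search volume during dynamic
#' docking: free inside a cylinder of given `radius` spanning
#' `[lam_min, lam_max]` along `axis`, harmonically penalized outside.
#' Force constants follow the AMBER-style convention `k * d^2` (no factor
#' 1/2); set `half_k = TRUE` for the `k/2 * d^2` convention.
#'
#' The default geometry is a cylinder from 2.5 to 30 Angstrom along the axis
#' with a 4 Angstrom radius, a perpendicular force constant of 1.0 and a
#' parallel force constant of 20.0 kcal/mol/A^2.
#'
#' @param origin 3-vector, pocket center (lambda = 0), Angstrom.
#' @param axis 3-vector giving the cylinder axis direction (normalized
#'   internally).
#' @param lam_min,lam_max axial range of the flat-bottom region, Angstrom.
#' @param radius cylinder radius, Angstrom.
#' @param k_perp,k_par force constants perpendicular/parallel to the axis,
#'   kcal/mol/A^2.
#' @param half_k logical; use the `k/2 * d^2` convention instead of `k * d^2`.
#' @return An object of class `cylinder_restraint`.
#' @export
cylinder_restraint <- function(origin = c(0, 0, 0), axis = c(1, 0, 0),
                               lam_min = 2.5, lam_max = 30.0, radius = 4.0,
                               k_perp = 1.0, k_par = 20.0, half_k = FALSE) {
  stopifnot(length(origin) == 3, length(axis) == 3)
  if (!(lam_min < lam_max)) stop("lam_min must be < lam_max")
  if (!(radius > 0)) stop("radius must be positive")
  if (k_perp < 0 || k_par < 0) stop("force constants must be >= 0")
  nax <- sqrt(sum(axis^2))
  if (nax < 1e-12) stop("axis must be non-zero")
  axis <- axis / nax
  basis <- transverse_basis(axis)
  structure(list(origin = as.numeric(origin), axis = axis,
                 v = basis$v, zeta = basis$zeta,
                 lam_min = lam_min, lam_max = lam_max, radius = radius,
                 k_perp = k_perp, k_par = k_par,
                 half = if (half_k) 0.5 else 1.0),
            class = "cylinder_restraint")
}

#' Deterministic transverse basis of a cylinder axis
#'
#' Completes the (unit) axis to a fixed right-handed orthonormal frame
#' `(axis, v, zeta)`; `v` and `zeta` span the plane in which the transverse
#' COM coordinates are measured. The frame depends only on the axis vector,
#' so transverse coordinates are reproducible across runs.
#'
#' @param axis unit 3-vector.
#' @return list with unit vectors `v` and `zeta` (`v x zeta = axis`).
#' @export
transverse_basis <- function(axis) {
  ref <- if (abs(axis[3]) > 0.9) c(0, 1, 0) else c(0, 0, 1)
  v <- c(ref[2] * axis[3] - ref[3] * axis[2],
         ref[3] * axis[1] - ref[1] * axis[3],
         ref[1] * axis[2] - ref[2] * axis[1])
  v <- v / sqrt(sum(v^2))
  zeta <- c(axis[2] * v[3] - axis[3] * v[2],
            axis[3] * v[1] - axis[1] * v[3],
            axis[1] * v[2] - axis[2] * v[1])
  list(v = v, zeta = zeta)
}

#' Cylinder coordinates of a point
#'
#' Projects a COM position onto the cylinder frame: `lam` is the axial
#' component of `com - origin`, `(v, zeta)` the transverse components. The
#' transform is an orthonormal change of basis, so
#' `origin + lam*axis + v*v_hat + zeta*zeta_hat` recovers `com` exactly.
#'
#' @param com 3-vector (or n x 3 matrix of positions).
#' @param cyl a [cylinder_restraint()].
#' @return named vector `(lam, v, zeta)`, or an n x 3 matrix.
#' @export
lambda_coords <- function(com, cyl) {
  stopifnot(inherits(cyl, "cylinder_restraint"))
  if (is.matrix(com)) {
    d <- sweep(com, 2, cyl$origin)
    out <- cbind(lam = as.numeric(d %*% cyl$axis),
                 v = as.numeric(d %*% cyl$v),
                 zeta = as.numeric(d %*% cyl$zeta))
    return(out)
  }
  d <- as.numeric(com) - cyl$origin
  c(lam = sum(d * cyl$axis), v = sum(d * cyl$v), zeta = sum(d * cyl$zeta))
}

#' Inverse of [lambda_coords()]
#' @param lvz vector `(lam, v, zeta)`.
#' @param cyl a [cylinder_restraint()].
#' @return 3-vector COM position.
#' @export
lambda_to_com <- function(lvz, cyl) {
  cyl$origin + lvz[1] * cyl$axis + lvz[2] * cyl$v + lvz[3] * cyl$zeta
}

#' Flat-bottom cylinder restraint energy
#'
#' Zero inside the cylinder; outside, additive harmonic terms
#' `k_perp*(r - radius)^2` for radial excess and `k_par*(lam - lam_max)^2`
#' (resp. `k_par*(lam_min - lam)^2`) beyond the axial range (times 1/2 under
#' the `half_k` convention).
#'
#' @inheritParams lambda_coords
#' @return energy in kcal/mol.
#' @export
cylinder_energy <- function(com, cyl) {
  lvz <- lambda_coords(com, cyl)
  if (is.matrix(lvz)) {
    r <- sqrt(lvz[, "v"]^2 + lvz[, "zeta"]^2)
    lam <- lvz[, "lam"]
  } else {
    r <- sqrt(lvz["v"]^2 + lvz["zeta"]^2)
    lam <- lvz["lam"]
  }
  e <- cyl$k_perp * pmax(r - cyl$radius, 0)^2 +
    cyl$k_par * pmax(lam - cyl$lam_max, 0)^2 +
    cyl$k_par * pmax(cyl$lam_min - lam, 0)^2
  unname(cyl$half * e)
}

#' Harmonic position-restraint energy
#'
#' `sum_masked k * |x - x_ref|^2` over the selected beads (`k/2` if
#' `half_k`), mirroring weak position restraints that keep non-pocket parts
#' of the receptor near their reference structure.
#'
#' @param coordinates,reference n x 3 matrices.
#' @param k force constant, kcal/mol/A^2.
#' @param mask integer or logical selection of restrained rows; `NULL`
#'   restrains all.
#' @param half_k logical, see [cylinder_restraint()].
#' @return energy in kcal/mol.
#' @export
position_restraint_energy <- function(coordinates, reference, k, mask = NULL,
                                      half_k = FALSE) {
  coordinates <- as.matrix(coordinates)
  reference <- as.matrix(reference)
  if (!all(dim(coordinates) == dim(reference)))
    stop("coordinates and reference must have identical dimensions")
  if (is.null(mask)) mask <- seq_len(nrow(coordinates))
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) == 0) return(0)
  d2 <- rowSums((coordinates[mask, , drop = FALSE] -
                   reference[mask, , drop = FALSE])^2)
  (if (half_k) 0.5 else 1.0) * k * sum(d2)
}

#' Pocket center from a bound complex
#'
#' The cylinder origin (lambda = 0) is the COM of the receptor beads lying
#' within `cutoff` of any ligand bead in the bound complex, a point deep
#' inside the receptor.
#'
#' @param receptor,ligand coordinate matrices (n x 3).
#' @param cutoff neighborhood distance, Angstrom (default 10).
#' @return 3-vector pocket origin.
#' @export
pocket_axis_from_complex <- function(receptor, ligand, cutoff = 10) {
  receptor <- as.matrix(receptor); ligand <- as.matrix(ligand)
  if (nrow(receptor) == 0 || nrow(ligand) == 0)
    stop("receptor and ligand selections must be non-empty")
  d2 <- outer(rowSums(receptor^2), rep(1, nrow(ligand))) +
    outer(rep(1, nrow(receptor)), rowSums(ligand^2)) -
    2 * receptor %*% t(ligand)
  near <- apply(d2, 1, min) <= cutoff^2 + 1e-12
  if (!any(near)) stop("no receptor bead within ", cutoff, " A of the ligand")
  colMeans(receptor[near, , drop = FALSE])
}

#' @export
print.cylinder_restraint <- function(x, ...) {
  cat("Cylindrical COM restraint\n")
  cat(sprintf("  origin: (%.2f, %.2f, %.2f) A\n", x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  axis:   (%.3f, %.3f, %.3f)\n", x$axis[1], x$axis[2], x$axis[3]))
  cat(sprintf("  lambda: [%.1f, %.1f] A, radius %.1f A\n", x$lam_min, x$lam_max, x$radius))
  cat(sprintf("  k_perp %.2f, k_par %.2f kcal/mol/A^2 (%s convention)\n",
              x$k_perp, x$k_par, if (x$half == 1) "k*d^2" else "k/2*d^2"))
  invisible(x)
}
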