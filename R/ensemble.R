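#' Canonical reweighting of a multicanonical trajectory
#'
#' Restores the canonical ensemble at temperature `T` from a flat-histogram
#' production run: frame `i` receives weight
#' `w_i` proportional to `exp(ln n(E_i) - E_i/kT)`, normalized to sum 1.
#' With the algebraically canonical weight (`ln n(E) = E/kT + c`) all
#' frames get equal weight.
#'
#' @param trajectory a multicanonical `trajectory`.
#' @param T target temperature, K.
#' @param weight the [mc_weight()] used to generate the trajectory
#'   (defaults to the one stored in it).
#' @return numeric vector of class `frame_weights` summing to 1, with
#'   attribute `target_T`.
#' @export
reweight <- function(trajectory, T, weight = NULL) {
  stopifnot(inherits(trajectory, "trajectory"))
  if (trajectory$ensemble != "multicanonical")
    stop("trajectory is already canonical; reweighting applies to multicanonical runs")
  weight <- weight %||% trajectory$weight
  stopifnot(inherits(weight, "mc_weight"))
  lnw <- ln_dos_at(weight, trajectory$energy) - trajectory$energy / .kT(T)
  w <- exp(lnw - max(lnw))
  w <- w / sum(w)
  structure(w, class = "frame_weights", target_T = T)
}

#' Uniform frame weights
#' @param n number of frames.
#' @param T nominal temperature attribute, K.
#' @export
uniform_weights <- function(n, T = 300) {
  structure(rep(1 / n, n), class = "frame_weights", target_T = T)
}

#' Effective sample size of frame weights
#' @param w `frame_weights`.
#' @export
effective_samples <- function(w) 1 / sum(w^2)

#' Intramolecular distance features
#'
#' Upper-triangle pairwise distances between selected beads, omitting pairs
#' closer than or equal to `exclude_within` positions along the chain (the
#' convention used for disordered-peptide PCA: with the default 3, pairs of
#' +/-3 neighbors and closer are excluded). Feature order is fixed
#' (row-major over the retained upper triangle) and stable across frames.
#'
#' @param x an n x 3 coordinate matrix (one frame) or a `trajectory`
#'   (features computed per frame into a matrix).
#' @param selection indices of the beads, in chain order. For a
#'   `trajectory`, defaults to the ligand beads.
#' @param exclude_within exclude pairs with `|i - j| <= exclude_within`
#'   (sequence separation along `selection`); 0 keeps all pairs.
#' @return numeric feature vector, or frames x features matrix.
#' @export
distance_features <- function(x, selection = NULL, exclude_within = 3) {
  UseMethod("distance_features")
}

.feature_pairs <- function(m, exclude_within) {
  if (m < 2) return(matrix(integer(0), 0, 2))
  p <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  p <- p[p[, 2] - p[, 1] > exclude_within, , drop = FALSE]
  p[order(p[, 1], p[, 2]), , drop = FALSE]
}

#' @export
distance_features.matrix <- function(x, selection = NULL, exclude_within = 3) {
  if (is.null(selection)) selection <- seq_len(nrow(x))
  if (length(selection) == 0) stop("empty selection")
  if (any(selection < 1 | selection > nrow(x)))
    stop("selection outside topology")
  xs <- x[selection, , drop = FALSE]
  p <- .feature_pairs(length(selection), exclude_within)
  if (nrow(p) == 0) return(numeric(0))
  d <- sqrt(rowSums((xs[p[, 1], , drop = FALSE] - xs[p[, 2], , drop = FALSE])^2))
  names(d) <- paste0("d", p[, 1], "_", p[, 2])
  d
}

#' @export
distance_features.trajectory <- function(x, selection = NULL,
                                         exclude_within = 3) {
  n <- dim(x$coords)[1]
  if (is.null(selection)) {
    nlig <- x$system_config$ligand_length %||% n
    selection <- (n - nlig + 1):n
  }
  nf <- dim(x$coords)[3]
  out <- t(vapply(seq_len(nf), function(i)
    distance_features.matrix(x$coords[, , i], selection, exclude_within),
    numeric(nrow(.feature_pairs(length(selection), exclude_within)))))
  out
}

#' Intermolecular distance features for docking landscapes
#'
#' All receptor-bead x ligand-bead distances (optionally restricted to a
#' receptor selection, e.g. the pocket beads); these distinguish binding
#' poses and are the default feature set for the docking free-energy
#' landscape.
#'
#' @param trajectory a `trajectory` of a `toy_system`.
#' @param system the `toy_system` sampled.
#' @param receptor_sel receptor bead indices (default: all beads carrying
#'   native contacts).
#' @return frames x features matrix.
#' @export
intermolecular_features <- function(trajectory, system, receptor_sel = NULL) {
  nrec <- nrow(system$receptor_beads)
  nlig <- system$ligand_topology$n
  if (is.null(receptor_sel)) receptor_sel <- sort(unique(system$native_contacts$rec))
  nf <- dim(trajectory$coords)[3]
  out <- matrix(0, nf, length(receptor_sel) * nlig)
  for (i in seq_len(nf)) {
    x <- trajectory$coords[, , i]
    r <- x[receptor_sel, , drop = FALSE]
    l <- x[nrec + seq_len(nlig), , drop = FALSE]
    d <- sqrt(outer(rowSums(r^2), rep(1, nlig)) +
                outer(rep(1, length(receptor_sel)), rowSums(l^2)) -
                2 * r %*% t(l))
    out[i, ] <- as.numeric(d)
  }
  out
}

#' Weighted principal component analysis
#'
#' Eigen-decomposition of the weighted covariance about the weighted mean.
#' Axes are ordered by decreasing eigenvalue and their sign is fixed by
#' making the largest-magnitude loading positive, so projections are
#' reproducible.
#'
#' @param features frames x d feature matrix.
#' @param weights `frame_weights` (default uniform: standard PCA).
#' @return list of class `weighted_pca` with `rotation` (d x d), `values`
#'   (eigenvalues), `center`, and `projections` (frames x d).
#' @export
weighted_pca <- function(features, weights = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (is.null(weights)) weights <- uniform_weights(n)
  w <- as.numeric(weights)
  if (length(w) != n) stop("one weight per frame required")
  if (any(w < 0) || sum(w) <= 0) stop("weights must be non-negative with positive total")
  if (sum(w > 0) < 2) stop("need at least 2 frames with positive weight")
  w <- w / sum(w)
  ctr <- colSums(features * w)
  xc <- sweep(features, 2, ctr)
  cv <- crossprod(xc, xc * w)
  eg <- eigen(cv, symmetric = TRUE)
  rot <- eg$vectors
  for (j in seq_len(ncol(rot))) {
    m <- which.max(abs(rot[, j]))
    if (rot[m, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(rotation = rot, values = pmax(eg$values, 0), center = ctr,
                 projections = xc %*% rot),
            class = "weighted_pca")
}

#' @export
print.weighted_pca <- function(x, ...) {
  tv <- sum(x$values)
  cat("Weighted PCA:", length(x$values), "components\n")
  cat("  variance explained:",
      paste0(sprintf("%.1f%%", 100 * head(x$values, 3) / tv), collapse = ", "),
      "(PC1-3)\n")
  invisible(x)
}

#' Free-energy landscape on a 2D projection grid
#'
#' `F(cell) = -kT ln(sum of frame weights in cell)`, shifted so the global
#' minimum is 0. Empty cells are `NA` (no finite free energy), not zero.
#'
#' @param projections frames x >=2 matrix (first two columns used) or a
#'   `weighted_pca`.
#' @param weights `frame_weights`.
#' @param T temperature, K.
#' @param nx,ny grid size.
#' @param xlim,ylim optional grid limits (default: data range, padded).
#' @return object of class `fel`: `x`, `y` (cell centers), `F` (nx x ny,
#'   NA where empty), `W` (cell weights), `cell` (per-frame cell index),
#'   `temperature`.
#' @export
build_fel <- function(projections, weights = NULL, T = 300, nx = 40, ny = 40,
                      xlim = NULL, ylim = NULL) {
  if (inherits(projections, "weighted_pca")) projections <- projections$projections
  pr <- as.matrix(projections)[, 1:2, drop = FALSE]
  n <- nrow(pr)
  if (is.null(weights)) weights <- uniform_weights(n)
  w <- as.numeric(weights)
  pad <- 1e-8
  if (is.null(xlim)) xlim <- range(pr[, 1]) + c(-pad, pad)
  if (is.null(ylim)) ylim <- range(pr[, 2]) + c(-pad, pad)
  ix <- pmin(pmax(1L, findInterval(pr[, 1], seq(xlim[1], xlim[2], length.out = nx + 1),
                                   rightmost.closed = TRUE)), nx)
  iy <- pmin(pmax(1L, findInterval(pr[, 2], seq(ylim[1], ylim[2], length.out = ny + 1),
                                   rightmost.closed = TRUE)), ny)
  W <- matrix(0, nx, ny)
  for (i in seq_len(n)) W[ix[i], iy[i]] <- W[ix[i], iy[i]] + w[i]
  FF <- matrix(NA_real_, nx, ny)
  occ <- W > 0
  FF[occ] <- -.kT(T) * log(W[occ])
  FF <- FF - min(FF, na.rm = TRUE)
  structure(list(x = (head(seq(xlim[1], xlim[2], length.out = nx + 1), -1) +
                        diff(xlim) / nx / 2),
                 y = (head(seq(ylim[1], ylim[2], length.out = ny + 1), -1) +
                        diff(ylim) / ny / 2),
                 F = FF, W = W, cell = cbind(ix, iy), temperature = T),
            class = "fel")
}

#' @export
print.fel <- function(x, ...) {
  cat(sprintf("Free-energy landscape: %d x %d grid at %g K, %d occupied cells\n",
              length(x$x), length(x$y), x$temperature, sum(x$W > 0)))
  cat(sprintf("  max finite F = %.2f kcal/mol\n", max(x$F, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.fel <- function(x, ...) {
  image(x$x, x$y, x$F, col = hcl.colors(64, "viridis", rev = TRUE),
        xlab = "PC1", ylab = "PC2", main = "Free-energy landscape (kcal/mol)",
        ...)
  invisible(x)
}

#' Basin clustering of a free-energy landscape with representatives
#'
#' Finds basins by steepest descent on the FEL grid: every occupied cell
#' joins its lowest-free-energy neighbor (8-neighborhood) until a local
#' minimum is reached; local minima seed the clusters. Cluster free
#' energies are `-kT ln(cluster weight)` relative to the most populated
#' cluster (0 for the top-ranked one), and each cluster's representative
#' frame is the one nearest (in the projection plane) to the cluster's
#' weighted mean.
#'
#' Basin detection runs on a lightly smoothed copy of the landscape (3 x 3
#' binomial kernel, two passes): raw sparse histograms fragment a single
#' basin into spurious sub-minima wherever a cell happens to be empty,
#' while the smoothed surface restores the connectivity; cluster weights
#' are still summed from the raw, unsmoothed cell weights.
#'
#' @param fel an [build_fel()] landscape.
#' @param projections frames x >=2 projection matrix (same frames as the
#'   FEL).
#' @param weights `frame_weights` used for the FEL.
#' @param k_max maximum number of clusters returned.
#' @param smooth number of smoothing passes (0 disables).
#' @return data.frame of class `fel_clusters`: `cluster`, `delta_F`
#'   (kcal/mol), `weight`, `n_frames`, `representative` (frame index),
#'   `pc1`, `pc2`; with attribute `assignment` (per-frame cluster id,
#'   NA for frames in no ranked cluster).
#' @export
cluster_representatives <- function(fel, projections, weights = NULL,
                                    k_max = 10, smooth = 2) {
  if (inherits(projections, "weighted_pca")) projections <- projections$projections
  pr <- as.matrix(projections)[, 1:2, drop = FALSE]
  n <- nrow(pr)
  if (is.null(weights)) weights <- uniform_weights(n)
  w <- as.numeric(weights)
  nx <- length(fel$x); ny <- length(fel$y)
  occ <- which(fel$W > 0, arr.ind = TRUE)
  if (nrow(occ) == 0) stop("no occupied cells in the landscape")
  Ws <- fel$W
  if (smooth > 0) for (pass in seq_len(smooth)) Ws <- .blur3(Ws)
  Fv <- matrix(NA_real_, nx, ny)
  Fv[Ws > 0] <- -.kT(fel$temperature) * log(Ws[Ws > 0])
  # steepest-descent target of every cell of the (smoothed) landscape
  occ_s <- which(Ws > 0, arr.ind = TRUE)
  idx <- function(i, j) (j - 1L) * nx + i
  target <- rep(NA_integer_, nx * ny)
  for (r in seq_len(nrow(occ_s))) {
    i <- occ_s[r, 1]; j <- occ_s[r, 2]
    best_i <- i; best_j <- j; best_F <- Fv[i, j]
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny && !is.na(Fv[ii, jj]) &&
          Fv[ii, jj] < best_F) {
        best_F <- Fv[ii, jj]; best_i <- ii; best_j <- jj
      }
    }
    target[idx(i, j)] <- idx(best_i, best_j)
  }
  # follow descent paths to basins
  basin <- rep(NA_integer_, nx * ny)
  for (r in seq_len(nrow(occ))) {
    path <- idx(occ[r, 1], occ[r, 2])
    cur <- path
    repeat {
      nxt <- target[cur]
      if (is.na(nxt) || nxt == cur) break
      cur <- nxt
      path <- c(path, cur)
      if (length(path) > nx * ny) stop("descent cycle; malformed landscape")
    }
    basin[path] <- cur
  }
  cells <- idx(fel$cell[, 1], fel$cell[, 2])
  frame_basin <- basin[cells]
  bw <- tapply(w, frame_basin, sum)
  ord <- order(bw, decreasing = TRUE)
  keep <- head(ord, k_max)
  out <- data.frame(cluster = seq_along(keep),
                    delta_F = -.kT(fel$temperature) *
                      log(as.numeric(bw[keep]) / as.numeric(bw[keep[1]])),
                    weight = as.numeric(bw[keep]),
                    n_frames = NA_integer_, representative = NA_integer_,
                    pc1 = NA_real_, pc2 = NA_real_)
  assignment <- rep(NA_integer_, n)
  for (k in seq_along(keep)) {
    b <- as.integer(names(bw)[keep[k]])
    members <- which(frame_basin == b)
    assignment[members] <- k
    out$n_frames[k] <- length(members)
    wm <- w[members] / sum(w[members])
    ctr <- c(sum(pr[members, 1] * wm), sum(pr[members, 2] * wm))
    d2 <- (pr[members, 1] - ctr[1])^2 + (pr[members, 2] - ctr[2])^2
    rep_f <- members[which.min(d2)]
    out$representative[k] <- rep_f
    out$pc1[k] <- pr[rep_f, 1]; out$pc2[k] <- pr[rep_f, 2]
  }
  structure(out, assignment = assignment, class = c("fel_clusters", "data.frame"))
}

# 3x3 binomial blur with zero padding
.blur3 <- function(W) {
  nx <- nrow(W); ny <- ncol(W)
  P <- matrix(0, nx + 2, ny + 2)
  P[2:(nx + 1), 2:(ny + 1)] <- W
  k <- c(1, 2, 1)
  out <- matrix(0, nx, ny)
  for (di in 0:2) for (dj in 0:2)
    out <- out + k[di + 1] * k[dj + 1] *
      P[(1:nx) + di, (1:ny) + dj, drop = FALSE]
  out / 16
}

#' Intermolecular contact matrix of a frame
#'
#' Boolean receptor-bead x ligand-bead contact indicator: a pair is in
#' contact when its distance is below `cutoff`.
#'
#' @param system a `toy_system`.
#' @param coordinates full coordinate matrix.
#' @param cutoff contact distance, Angstrom (default 4.5).
#' @return logical n_receptor x n_ligand matrix.
#' @export
contact_map <- function(system, coordinates, cutoff = 4.5) {
  nrec <- nrow(system$receptor_beads)
  nlig <- system$ligand_topology$n
  r <- coordinates[seq_len(nrec), , drop = FALSE]
  l <- coordinates[nrec + seq_len(nlig), , drop = FALSE]
  d2 <- outer(rowSums(r^2), rep(1, nlig)) +
    outer(rep(1, nrec), rowSums(l^2)) - 2 * r %*% t(l)
  d2 < cutoff^2
}

#' Formed native contacts of a frame
#'
#' A native contact is "formed" when its pair distance is below
#' `factor * sigma_ij` (default 1.2, the usual Go-model convention, which
#' makes all native contacts formed at the native pose by construction).
#'
#' @param system a `toy_system`.
#' @param coordinates full coordinate matrix.
#' @param factor multiple of the contact distance.
#' @return logical vector over the native contact list.
#' @export
native_contacts_formed <- function(system, coordinates, factor = 1.2) {
  nrec <- nrow(system$receptor_beads)
  con <- system$native_contacts
  d <- sqrt(rowSums((coordinates[con$rec, , drop = FALSE] -
                       coordinates[nrec + con$lig, , drop = FALSE])^2))
  d < factor * con$sigma
}

#' R-value: fraction of reference contacts retained
#'
#' `R = |contacts(frame) intersect contacts(reference)| /
#' |contacts(reference)|`. With the natively bound pose as reference this
#' is R(native), 1 at the native pose and decaying as contacts are lost.
#'
#' @param frame_contacts,reference_contacts logical contact matrices of the
#'   same shape (see [contact_map()]), or logical vectors.
#' @return value in \[0, 1\].
#' @export
rvalue <- function(frame_contacts, reference_contacts) {
  if (!all(dim(frame_contacts) %||% length(frame_contacts) ==
             dim(reference_contacts) %||% length(reference_contacts)))
    stop("contact matrices must have the same shape")
  nref <- sum(reference_contacts)
  if (nref == 0) stop("reference has no contacts")
  sum(frame_contacts & reference_contacts) / nref
}

#' R(native) of a frame
#' @param system a `toy_system`.
#' @param coordinates full coordinate matrix.
#' @param factor contact criterion, see [native_contacts_formed()].
#' @export
rvalue_native <- function(system, coordinates, factor = 1.2) {
  mean(native_contacts_formed(system, coordinates, factor))
}

#' Canonical stability assay
#'
#' Unrestrained canonical runs started from a given structure at each
#' temperature in `T_list`, tracking the R-value of the interface with
#' respect to the starting structure; summarized by the mean and standard
#' deviation over the final 40% of each run. Stable binding configurations
#' keep R near 1 at low temperature; far above the binding temperature the
#' contacts decay.
#'
#' @param system a `toy_system`.
#' @param start_frame starting full coordinate matrix (e.g. a bound pose).
#' @param T_list temperatures, K (default `c(300, 400)`).
#' @param n_steps steps per run.
#' @param n_repeats independent repeats per temperature.
#' @param seed base RNG seed (repeat r at temperature t uses distinct
#'   derived seeds).
#' @param thin frame recording interval.
#' @param cutoff contact cutoff for the reference contact map, Angstrom.
#' @param moves move-set overrides.
#' @return list of class `stability_assay`: `series` (data.frame T,
#'   repeat, step, R) and `summary` (per-T, per-repeat mean/SD over the
#'   final 40%).
#' @export
stability_assay <- function(system, start_frame, T_list = c(300, 400),
                            n_steps = 20000, n_repeats = 3, seed = 1,
                            thin = 20L, cutoff = 4.5, moves = NULL) {
  ref_cm <- contact_map(system, start_frame, cutoff)
  if (sum(ref_cm) == 0) stop("starting frame has no intermolecular contacts")
  series <- NULL
  summ <- NULL
  for (ti in seq_along(T_list)) {
    for (r in seq_len(n_repeats)) {
      if (n_steps == 0) {
        df <- data.frame(T = T_list[ti], rep = r, step = 0L, R = 1.0)
      } else {
        tr <- run_canonical(system, T_list[ti], n_steps, restraints = NULL,
                            seed = seed + 1000L * ti + r, thin = thin,
                            start = start_frame, moves = moves)
        R <- vapply(seq_along(tr$energy), function(i)
          rvalue(contact_map(system, tr$coords[, , i], cutoff), ref_cm),
          numeric(1))
        df <- data.frame(T = T_list[ti], rep = r, step = tr$step, R = R)
      }
      series <- rbind(series, df)
      fin <- df[df$step >= max(df$step) * 0.6, , drop = FALSE]
      summ <- rbind(summ, data.frame(T = T_list[ti], rep = r,
                                     R_mean = mean(fin$R), R_sd = sd(fin$R)))
    }
  }
  structure(list(series = series, summary = summ, cutoff = cutoff,
                 n_steps = n_steps), class = "stability_assay")
}

#' @export
print.stability_assay <- function(x, ...) {
  cat("Canonical stability assay (R-value vs start over final 40%):\n")
  agg <- aggregate(cbind(R_mean, R_sd) ~ T, data = x$summary, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal rotation and translation of `mobile` onto `reference` over the
#' masked beads, via SVD of the cross-covariance with a proper-rotation
#' (determinant) correction; returns the post-fit RMSD.
#'
#' @param mobile,reference n x 3 coordinate matrices.
#' @param mask indices (or logical) of beads used for the fit; default all.
#' @return list: rotation `R` (3 x 3), translation `t`, `rmsd` (Angstrom,
#'   over the mask), `coords` (all of `mobile` transformed).
#' @export
superpose <- function(mobile, reference, mask = NULL) {
  mobile <- unname(as.matrix(mobile)); reference <- unname(as.matrix(reference))
  if (!all(dim(mobile) == dim(reference))) stop("dimension mismatch")
  if (is.null(mask)) mask <- seq_len(nrow(mobile))
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) < 3) stop("need at least 3 beads in the mask")
  A <- mobile[mask, , drop = FALSE]; B <- reference[mask, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  s <- svd(crossprod(Ac, Bc))
  if (min(s$d) < 1e-10 && sum(s$d > 1e-10) < 2)
    stop("degenerate (collinear) mask")
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  tv <- cb - as.numeric(ca %*% R)
  fitted <- sweep(mobile %*% R, 2, tv, `+`)
  rmsd <- sqrt(mean(rowSums((fitted[mask, , drop = FALSE] - B)^2)))
  list(R = R, t = tv, rmsd = rmsd, coords = fitted)
}

#' RMSD after optimal superposition
#' @inheritParams superpose
#' @export
rmsd <- function(mobile, reference, mask = NULL) {
  superpose(mobile, reference, mask)$rmsd
}

#' Per-bead RMSF of a group of frames
#'
#' Frames are iteratively superposed (over `mask`) onto their running mean
#' structure until the mean converges, then
#' `RMSF_b = sqrt(mean |x_b - <x_b>|^2)`.
#'
#' @param frames 3D array (beads x 3 x frames) or list of coordinate
#'   matrices.
#' @param mask beads used for the superposition fit (default all).
#' @param max_iter,tol iteration controls for the mean-structure fit.
#' @return numeric vector of per-bead RMSF, Angstrom.
#' @export
rmsf <- function(frames, mask = NULL, max_iter = 10, tol = 1e-5) {
  if (is.list(frames)) frames <- simplify2array(frames)
  nf <- dim(frames)[3]
  if (nf < 2) stop("need at least 2 frames")
  fitted <- lapply(seq_len(nf), function(i) frames[, , i])
  mean_s <- fitted[[1]]
  for (it in seq_len(max_iter)) {
    fitted <- lapply(fitted, function(x) superpose(x, mean_s, mask)$coords)
    new_mean <- Reduce(`+`, fitted) / nf
    if (max(abs(new_mean - mean_s)) < tol) { mean_s <- new_mean; break }
    mean_s <- new_mean
  }
  arr <- simplify2array(fitted)
  sqrt(rowMeans(apply(arr, 3, function(x) rowSums((x - mean_s)^2))))
}

#' RMSF per pathway window
#'
#' Groups frames by a factor (e.g. the umbrella window / lambda' bin they
#' came from) and computes the per-bead RMSF within each group after
#' iterative superposition on the group mean. Groups with fewer than 2
#' frames are skipped with a warning.
#'
#' @param frames 3D array (beads x 3 x frames) or list of matrices.
#' @param groups factor/vector of length n_frames.
#' @param mask superposition mask (e.g. the rigid receptor core).
#' @return beads x groups matrix of RMSF values (Angstrom); skipped groups
#'   are columns of NA.
#' @export
rmsf_by_window <- function(frames, groups, mask = NULL) {
  if (is.list(frames)) frames <- simplify2array(frames)
  groups <- as.factor(groups)
  out <- matrix(NA_real_, dim(frames)[1], nlevels(groups),
                dimnames = list(NULL, levels(groups)))
  for (g in levels(groups)) {
    sel <- which(groups == g)
    if (length(sel) < 2) {
      warning("group ", g, " has fewer than 2 frames; skipped")
      next
    }
    out[, g] <- rmsf(frames[, , sel, drop = FALSE], mask)
  }
  out
}
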