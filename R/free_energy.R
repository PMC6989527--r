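#' Umbrella-sampling runs along the pathway coordinate
#'
#' One canonical run per (window, seed structure) with a harmonic bias
#' `k_w * (lambda - lam_ref - center)^2` on the ligand COM's axial
#' coordinate. The recorded frame energies exclude the bias (WHAM supplies
#' it analytically). Loop tethers and the transverse part of the cylinder
#' restraint stay active; lambda' is lambda relative to the bound reference
#' structure (`lam_ref`).
#'
#' @param system a `toy_system` (or `harmonic_reference` for oracle runs).
#' @param windows a [window_spec()].
#' @param seed_frames list (one element per window) of starting coordinate
#'   matrices, e.g. from [pick_path()]; recycled over seeds per window.
#' @param n_steps Monte-Carlo steps per run.
#' @param T temperature, K (default 300).
#' @param restraints optional [cylinder_restraint()]; during umbrella
#'   sampling its parallel restraint is redundant with the bias but
#'   harmless since windows sit inside the flat region.
#' @param lam_ref lambda of the bound reference structure, Angstrom
#'   (lambda' = lambda - lam_ref).
#' @param rng_seed base seed; run (window i, seed s) uses
#'   `rng_seed + 97*i + s`.
#' @param thin frame recording interval.
#' @param moves move-set overrides.
#' @param save_coords keep frame coordinates (needed for RMSF analysis).
#' @return list of class `umbrella_set`; each element is an `umbrella_run`:
#'   a `trajectory` with `bias` (k, center in lambda'), `window`, `seed_id`
#'   and `lam_ref` fields.
#' @export
run_umbrella <- function(system, windows, seed_frames, n_steps, T = 300,
                         restraints = NULL, lam_ref = NULL, rng_seed = 1,
                         thin = 10L, moves = NULL, save_coords = TRUE) {
  stopifnot(inherits(windows, "window_spec"))
  n_seeds <- attr(windows, "n_seeds")
  if (is.null(lam_ref)) {
    lam_ref <- if (inherits(system, "toy_system"))
      unname(lambda_coords(ligand_com(system, native_pose(system)),
                           default_restraint(system))["lam"])
    else 0
  }
  runs <- list()
  for (i in seq_len(nrow(windows))) {
    sf <- seed_frames[[min(i, length(seed_frames))]]
    if (is.matrix(sf)) sf <- list(sf)
    for (s in seq_len(n_seeds)) {
      start <- sf[[min(s, length(sf))]]
      bias <- list(k = windows$k[i], center = lam_ref + windows$center[i])
      tr <- run_canonical(system, T, n_steps, restraints = restraints,
                          seed = rng_seed + 97L * i + s, thin = thin,
                          start = start, bias = bias, moves = moves)
      tr$bias <- list(k = windows$k[i], center = windows$center[i])
      tr$window <- i
      tr$seed_id <- s
      tr$lam_ref <- lam_ref
      if (!save_coords) tr$coords <- NULL
      class(tr) <- c("umbrella_run", "trajectory")
      runs[[length(runs) + 1]] <- tr
    }
  }
  ov <- .window_overlaps(runs, windows, lam_ref)
  if (any(ov == 0))
    stop("zero lambda-histogram overlap between adjacent windows ",
         paste(which(ov == 0), collapse = ", "),
         "; increase the bias force constant or the number of windows")
  structure(runs, overlaps = ov, lam_ref = lam_ref, temperature = T,
            class = "umbrella_set")
}

# fraction of shared lambda' support between adjacent windows (0.25 A bins)
.window_overlaps <- function(runs, windows, lam_ref) {
  k <- nrow(windows)
  lamp_by_w <- lapply(seq_len(k), function(i) {
    unlist(lapply(runs[vapply(runs, function(r) r$window, 1) == i],
                  function(r) r$lam - r$lam_ref))
  })
  vapply(seq_len(k - 1), function(i) {
    a <- lamp_by_w[[i]]; b <- lamp_by_w[[i + 1]]
    br <- seq(floor(min(a, b) / 0.25) * 0.25, ceiling(max(a, b) / 0.25) * 0.25, 0.25)
    ha <- tabulate(findInterval(a, br), nbins = length(br))
    hb <- tabulate(findInterval(b, br), nbins = length(br))
    sum(ha > 0 & hb > 0) / max(1, sum(hb > 0))
  }, numeric(1))
}

#' @export
print.umbrella_set <- function(x, ...) {
  cat(sprintf("Umbrella sampling: %d runs at %g K (lambda_ref = %.2f A)\n",
              length(x), attr(x, "temperature"), attr(x, "lam_ref")))
  cat(sprintf("  adjacent-window overlap: min %.2f, median %.2f\n",
              min(attr(x, "overlaps")), stats::median(attr(x, "overlaps"))))
  invisible(x)
}

#' Weighted histogram analysis method (WHAM)
#'
#' Combines the biased window histograms along lambda' into the unbiased
#' potential of mean force by self-consistent iteration of the window free
#' energies `f_i`:
#' `p_b = sum_i n_ib / sum_i N_i exp((f_i - U_i(lambda_b))/kT)`,
#' `f_i = -kT ln sum_b p_b exp(-U_i(lambda_b)/kT)`,
#' until `max |delta f_i| < tolerance`. The PMF `G = -kT ln p` is
#' re-referenced so that the mean over the unbound plateau (the outermost
#' `plateau_width` of the sampled lambda' range) is zero, making the bound
#' well depth directly readable.
#'
#' @param runs an `umbrella_set` (or list of runs with `lam`, `lam_ref` and
#'   `bias`).
#' @param bin_width lambda' bin width, Angstrom (default 0.25).
#' @param T temperature, K.
#' @param tolerance convergence threshold on the window shifts, kcal/mol.
#' @param max_iter maximum self-consistency iterations.
#' @param reference `"plateau"` (default) or `"min"` (zero at the minimum).
#' @param plateau_width width of the unbound reference region, Angstrom.
#' @return object of class `pmf_profile`: `lamp` (bin centers), `G`
#'   (kcal/mol), `error` (per-bin Poisson estimate), `counts`, `f`
#'   (window shifts), `bin_width`, `temperature`, `reference`, `lam_ref`.
#' @export
wham <- function(runs, bin_width = 0.25, T = 300, tolerance = 1e-8,
                 max_iter = 50000, reference = c("plateau", "min"),
                 plateau_width = 2.5) {
  reference <- match.arg(reference)
  stopifnot(length(runs) >= 1)
  kT <- .kT(T)
  lam_ref <- runs[[1]]$lam_ref %||% 0
  lamp <- lapply(runs, function(r) r$lam - (r$lam_ref %||% 0))
  all_l <- unlist(lamp)
  lo <- floor(min(all_l) / bin_width) * bin_width
  hi <- ceiling(max(all_l) / bin_width) * bin_width
  nb <- round((hi - lo) / bin_width)
  centers <- lo + (seq_len(nb) - 0.5) * bin_width
  nr <- length(runs)
  counts <- matrix(0, nr, nb)
  for (i in seq_len(nr)) {
    b <- pmin(pmax(floor((lamp[[i]] - lo) / bin_width) + 1, 1), nb)
    counts[i, ] <- tabulate(b, nbins = nb)
  }
  N <- rowSums(counts)
  ntot <- colSums(counts)
  # bias energy of window i at bin b (k*d^2 convention on lambda')
  U <- matrix(0, nr, nb)
  for (i in seq_len(nr)) {
    bs <- runs[[i]]$bias
    if (!is.null(bs) && bs$k > 0) U[i, ] <- bs$k * (centers - bs$center)^2
  }
  expU <- exp(-U / kT)
  f <- rep(0, nr)
  for (it in seq_len(max_iter)) {
    denom <- colSums(N * exp(f / kT) * expU)      # length nb
    p <- ifelse(ntot > 0, ntot / denom, 0)
    p <- p / sum(p)
    fnew <- as.numeric(-kT * log(expU %*% p))
    fnew <- fnew - fnew[1]
    resid <- max(abs(fnew - f))
    f <- fnew
    if (resid < tolerance) break
    if (it == max_iter)
      stop(sprintf("WHAM did not converge in %d iterations (residual %.2g kcal/mol)",
                   max_iter, resid))
  }
  G <- rep(NA_real_, nb)
  occ <- ntot > 0
  G[occ] <- -kT * log(p[occ])
  err <- rep(NA_real_, nb)
  err[occ] <- kT / sqrt(ntot[occ])
  if (reference == "plateau") {
    # the plateau ends at the outermost window center: bins beyond it are
    # sampled only by the last window's tail and carry biased-high G
    cmax <- suppressWarnings(max(vapply(runs, function(r) {
      bs <- r$bias
      if (!is.null(bs) && bs$k > 0) bs$center else -Inf
    }, numeric(1))))
    if (!is.finite(cmax)) cmax <- max(all_l)
    plat <- occ & centers <= cmax & centers > cmax - plateau_width
    if (!any(plat)) plat <- occ & centers >= max(centers[occ]) - plateau_width
    G <- G - weighted.mean(G[plat], ntot[plat])
  } else {
    G <- G - min(G, na.rm = TRUE)
  }
  structure(list(lamp = centers, G = G, error = err, counts = ntot,
                 f = as.numeric(f), bin_width = bin_width, temperature = T,
                 reference = reference, plateau_width = plateau_width,
                 lam_ref = lam_ref, iterations = it),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  occ <- !is.na(x$G)
  cat(sprintf("PMF along lambda': %d bins of %.2f A over [%.2f, %.2f] A at %g K\n",
              sum(occ), x$bin_width, min(x$lamp[occ]), max(x$lamp[occ]),
              x$temperature))
  cat(sprintf("  reference: %s; depth at minimum %.2f kcal/mol (WHAM converged in %d iterations)\n",
              x$reference, min(x$G, na.rm = TRUE), x$iterations))
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, ...) {
  plot(x$lamp, x$G, type = "l", xlab = "lambda' (A)", ylab = "G (kcal/mol)",
       main = "Potential of mean force", ...)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Binding free energy from the PMF depth
#'
#' The PMF value averaged over the bound-end window
#' `lambda' in [0, bound_width]` (default 2.5 Angstrom), with the PMF
#' referenced to the unbound plateau -- the depth of the bound basin.
#'
#' @param pmf a [wham()] profile referenced to the plateau.
#' @param bound_width width of the bound averaging window, Angstrom.
#' @return Delta G in kcal/mol (negative for binding).
#' @export
binding_dG <- function(pmf, bound_width = 2.5) {
  stopifnot(inherits(pmf, "pmf_profile"))
  occ <- !is.na(pmf$G)
  if (min(pmf$lamp[occ]) > 0 + pmf$bin_width)
    stop("PMF does not reach lambda' = 0; cannot take the bound-window average")
  sel <- occ & pmf$lamp >= 0 & pmf$lamp <= bound_width
  if (!any(sel)) stop("no occupied PMF bins in the bound window")
  mean(pmf$G[sel])
}

#' Unbiased 3D free-energy grid over the binding site
#'
#' Histograms the WHAM-unbiased frame weights over (lambda', v, zeta) and
#' converts cell densities to free energies relative to the bulk density
#' (the mean density over the unbound-plateau cells inside the restraint
#' radius), so that `G(lambda,v,zeta) -> 0` in the unbound region per unit
#' volume. Empty cells have infinite free energy and simply do not
#' contribute Boltzmann weight.
#'
#' @param runs an `umbrella_set`.
#' @param pmf the [wham()] fit of the same runs (for the window shifts).
#' @param bin cell edge length, Angstrom (default 0.25).
#' @param radius transverse extent of the site region, Angstrom (the
#'   restraint cylinder radius).
#' @return object of class `g3d_grid`: data.frame of occupied cells
#'   (`lamp`, `v`, `zeta`, `G`), `bin`, `radius`, `temperature`.
#' @export
g3d_from_runs <- function(runs, pmf, bin = 0.25, radius = 4) {
  kT <- .kT(pmf$temperature)
  lamp <- unlist(lapply(runs, function(r) r$lam - (r$lam_ref %||% 0)))
  v <- unlist(lapply(runs, function(r) r$v))
  z <- unlist(lapply(runs, function(r) r$zeta))
  N <- vapply(runs, function(r) length(r$lam), numeric(1))
  f <- pmf$f
  # WHAM frame weights: w_i = 1 / sum_r N_r exp((f_r - U_r(lambda_i)) / kT)
  denom <- rep(0, length(lamp))
  for (i in seq_along(runs)) {
    bs <- runs[[i]]$bias
    Ui <- if (!is.null(bs) && bs$k > 0) bs$k * (lamp - bs$center)^2 else 0
    denom <- denom + N[i] * exp((f[i] - Ui) / kT)
  }
  w <- 1 / denom
  w <- w / sum(w)
  cl <- floor(lamp / bin); cv <- floor(v / bin); cz <- floor(z / bin)
  key <- paste(cl, cv, cz)
  ws <- tapply(w, key, sum)
  parts <- do.call(rbind, strsplit(names(ws), " "))
  cells <- data.frame(lamp = (as.numeric(parts[, 1]) + 0.5) * bin,
                      v = (as.numeric(parts[, 2]) + 0.5) * bin,
                      zeta = (as.numeric(parts[, 3]) + 0.5) * bin,
                      w = as.numeric(ws))
  # bulk reference: mean density over plateau cells inside the radius,
  # counting the empty in-radius cells as zero density
  plat_lo <- max(lamp) - pmf$plateau_width
  r_in <- sqrt(cells$v^2 + cells$zeta^2) <= radius
  plat <- cells$lamp >= plat_lo & r_in
  n_plat_cells <- length(seq(floor(plat_lo / bin), floor(max(lamp) / bin))) *
    sum(.disc_cells(radius, bin))
  if (!any(plat)) stop("no occupied cells in the plateau region")
  rho_bulk <- sum(cells$w[plat]) / (n_plat_cells * bin^3)
  rho <- cells$w / bin^3
  cells$G <- -kT * log(rho / rho_bulk)
  structure(list(cells = cells, bin = bin, radius = radius,
                 temperature = pmf$temperature, rho_bulk = rho_bulk),
            class = "g3d_grid")
}

# logical grid of transverse cells with center inside the radius
.disc_cells <- function(radius, bin) {
  g <- seq(-ceiling(radius / bin) * bin + bin / 2,
           ceiling(radius / bin) * bin - bin / 2, by = bin)
  outer(g, g, function(a, b) sqrt(a^2 + b^2) <= radius)
}

#' Effective (Boltzmann-weighted) binding-site volume
#'
#' `V_eff = sum_site exp(-(G(lambda,v,zeta) - dG)/kT) * dlambda dv dzeta`
#' over the site region (lambda' within the bound window, transverse
#' position within the restraint radius) -- the volume term of the
#' standard-state correction, measured relative to the site depth `dG`.
#' A site of constant `G = dG` over volume V gives exactly V.
#'
#' @param g3d a [g3d_from_runs()] grid (or any object with `cells`
#'   data.frame carrying `lamp`, `v`, `zeta`, `G`, plus `bin` and
#'   `temperature`).
#' @param dG the PMF depth [binding_dG()], kcal/mol.
#' @param T temperature, K (default: the grid's).
#' @param bound_width site extent along lambda', Angstrom.
#' @param radius transverse site radius, Angstrom (default: the grid's).
#' @return V_eff in Angstrom^3.
#' @export
effective_volume <- function(g3d, dG, T = NULL, bound_width = 2.5,
                             radius = NULL) {
  T <- T %||% g3d$temperature
  radius <- radius %||% g3d$radius
  cells <- g3d$cells
  site <- cells$lamp >= 0 & cells$lamp <= bound_width &
    sqrt(cells$v^2 + cells$zeta^2) <= radius
  if (!any(site)) stop("empty site region")
  sum(exp(-(cells$G[site] - dG) / .kT(T))) * g3d$bin^3
}

#' Standard-state binding free energy
#'
#' Converts the restraint-defined site affinity into the 1 M standard
#' state: `dG0 = dG + kT ln(V0 / V_eff)`, with `V0 = 1661` Angstrom^3 the
#' volume per molecule at 1 M and `V_eff` the Boltzmann-weighted site
#' volume. With the printed worked-example inputs (-19.92 kcal/mol,
#' 0.735 A^3) this gives -15.31 kcal/mol at 300 K.
#'
#' @param dG PMF depth, kcal/mol.
#' @param V_eff effective site volume, Angstrom^3.
#' @param T temperature, K.
#' @param V0 standard-state volume per molecule, Angstrom^3 (1661 at 1 M).
#' @return Delta G0_b in kcal/mol.
#' @export
standard_dG <- function(dG, V_eff, T = 300, V0 = 1661) {
  if (!is.finite(V_eff) || V_eff <= 0) stop("V_eff must be positive")
  dG + .kT(T) * log(V0 / V_eff)
}

#' Binding result container
#'
#' Bundles the PMF depth, effective site volume, the standard-state
#' correction and the range-based error; the identity
#' `dG0 = dG + kT ln(V0/V_eff)` holds exactly for the stored fields.
#'
#' @param dG PMF depth, kcal/mol.
#' @param V_eff effective site volume, Angstrom^3.
#' @param T temperature, K.
#' @param error range-based error estimate on dG, kcal/mol (optional).
#' @param V0 standard-state volume, Angstrom^3.
#' @return object of class `binding_result`.
#' @export
binding_result <- function(dG, V_eff, T = 300, error = NA_real_, V0 = 1661) {
  structure(list(dG = dG, error = error, V_eff = V_eff, T = T, V0 = V0,
                 dG0 = standard_dG(dG, V_eff, T, V0)),
            class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  cat("Binding free energy\n")
  cat(sprintf("  PMF depth       dG    = %.2f kcal/mol%s\n", x$dG,
              if (is.finite(x$error)) sprintf(" (+/- %.2f)", x$error) else ""))
  cat(sprintf("  site volume     V_eff = %.3g A^3 (V0 = %g A^3)\n", x$V_eff, x$V0))
  cat(sprintf("  standard state  dG0_b = %.2f kcal/mol at %g K\n", x$dG0, x$T))
  invisible(x)
}

#' Free energies over trailing trajectory ranges with block errors
#'
#' Recomputes WHAM and the bound-window depth on trailing fractions of
#' every umbrella run, estimating the statistical error of each range as
#' the standard deviation of the depth across `n_blocks` non-overlapping
#' consecutive blocks divided by `sqrt(n_blocks)`. The error-minimizing
#' range is the recommended production range.
#'
#' @param runs an `umbrella_set`.
#' @param fractions trailing fractions of each run to analyze.
#' @param n_blocks blocks per range for the error estimate (default 2).
#' @param bound_width bound-window width, Angstrom.
#' @param ... passed to [wham()].
#' @return data.frame (`fraction`, `n_frames`, `dG`, `eps`) with attribute
#'   `best` (row index of the smallest error).
#' @export
range_error <- function(runs, fractions = c(0.25, 0.5, 0.75, 1.0),
                        n_blocks = 2, bound_width = 2.5, ...) {
  stopifnot(length(fractions) >= 2)
  nf <- vapply(runs, function(r) length(r$lam), numeric(1))
  if (any(fractions > 1 | fractions <= 0)) stop("fractions must be in (0, 1]")
  subset_runs <- function(idx_fun) .subset_runs(runs, idx_fun)
  res <- lapply(fractions, function(fr) {
    keep <- trailing_runs(runs, fr)
    dG <- binding_dG(wham(keep, ...), bound_width)
    m <- floor(fr * min(nf))
    bs <- vapply(seq_len(n_blocks), function(b) {
      blk <- subset_runs(function(n) {
        start <- n - floor(fr * n) + 1L
        len <- floor(fr * n)
        i0 <- start + floor((b - 1) * len / n_blocks)
        i1 <- start + floor(b * len / n_blocks) - 1L
        seq.int(i0, max(i0, i1))
      })
      binding_dG(wham(blk, ...), bound_width)
    }, numeric(1))
    c(dG = dG, eps = sd(bs) / sqrt(n_blocks), n = sum(floor(fr * nf)))
  })
  out <- data.frame(fraction = fractions,
                    n_frames = vapply(res, `[[`, numeric(1), "n"),
                    dG = vapply(res, `[[`, numeric(1), "dG"),
                    eps = vapply(res, `[[`, numeric(1), "eps"))
  attr(out, "best") <- which.min(out$eps)
  out
}

.subset_runs <- function(runs, idx_fun) {
  out <- lapply(runs, function(r) {
    n <- length(r$lam)
    sel <- idx_fun(n)
    r$lam <- r$lam[sel]; r$v <- r$v[sel]; r$zeta <- r$zeta[sel]
    r$energy <- r$energy[sel]
    if (!is.null(r$coords)) r$coords <- r$coords[, , sel, drop = FALSE]
    if (!is.null(r$step)) r$step <- r$step[sel]
    r
  })
  attributes(out) <- attributes(runs)
  out
}

#' Trailing fraction of every umbrella run
#'
#' Keeps the final `fraction` of each run's frames -- the equilibrated
#' production range used for the reported free energy.
#'
#' @param runs an `umbrella_set`.
#' @param fraction trailing fraction in (0, 1].
#' @export
trailing_runs <- function(runs, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  .subset_runs(runs, function(n) seq.int(n - floor(fraction * n) + 1L, n))
}
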