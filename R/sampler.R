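#' @title Canonical and multicanonical Monte-Carlo sampling
#' @name sampler
#' @description
#' The sampling engine is Metropolis Monte Carlo with a mixed move set:
#' single-bead displacements (ligand and flexible loop beads), rigid-body
#' translations of the ligand, and rigid rotations about the ligand COM.
#' Monte-Carlo step counts play the role nanoseconds play in MD protocols.
NULL

.default_moves <- list(bead_step = 0.35, trans_step = 0.8, rot_step = 0.5,
                       p_trans = 0.15, p_rot = 0.15)

.moves <- function(moves) modifyList(.default_moves, moves %||% list())

.start_coords <- function(system, start) {
  if (!is.null(start)) return(unname(as.matrix(start)))
  if (inherits(system, "harmonic_reference")) return(matrix(0, 1, 3))
  native_pose(system)
}

.new_trajectory <- function(res, system, ensemble, T, restraints, seed, thin,
                            n_steps, weight = NULL) {
  structure(list(coords = res$coords, energy = res$energy,
                 lam = res$lam, v = res$v, zeta = res$zeta,
                 step = res$step, acceptance = res$acceptance,
                 final_coords = res$final_coords,
                 ensemble = ensemble, temperature = T,
                 restraints = restraints, seed = seed, thin = thin,
                 n_steps = n_steps, weight = weight,
                 system_config = system$config %||% system),
            class = "trajectory")
}

#' Canonical Metropolis Monte-Carlo run
#'
#' Samples the Boltzmann ensemble at temperature `T` with acceptance
#' `min(1, exp(-dE/kT))`. The recorded per-frame energy is the system
#' potential plus tether and cylinder-restraint terms (umbrella bias, when
#' present, enters the acceptance but not the recorded energy, as WHAM
#' expects).
#'
#' @param system a `toy_system` or `harmonic_reference`.
#' @param T temperature, K.
#' @param n_steps Monte-Carlo steps.
#' @param restraints optional [cylinder_restraint()].
#' @param seed RNG seed; identical seeds give bit-identical trajectories.
#' @param thin record every `thin`-th step.
#' @param start starting coordinates (default: native pose / origin).
#' @param bias optional `list(k, center)` harmonic umbrella bias
#'   `k*(lambda-center)^2` on the ligand COM lambda.
#' @param moves list overriding move-set parameters (`bead_step`,
#'   `trans_step`, `rot_step`, `p_trans`, `p_rot`).
#' @param save_coords store frame coordinates (disable to save memory when
#'   only energies and cylinder coordinates are needed).
#' @return object of class `trajectory`.
#' @export
run_canonical <- function(system, T, n_steps, restraints = NULL, seed = NULL,
                          thin = 10L, start = NULL, bias = NULL, moves = NULL,
                          save_coords = TRUE) {
  stopifnot(T > 0, n_steps >= 0)
  mv <- .moves(moves)
  pk <- .pack_system(system, restraints, bias)
  x0 <- .start_coords(system, start)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run_mc(pk, x0, T, FALSE, c(0, 1), c(0, 0), 1, 1,
                    as.integer(n_steps), as.integer(thin),
                    mv$bead_step, mv$trans_step, mv$rot_step,
                    mv$p_trans, mv$p_rot, save_coords)
  .new_trajectory(res, system, "canonical", T, restraints, seed, thin, n_steps)
}

#' Multicanonical weight (tabulated log density of states)
#'
#' Container for the estimated `ln n(E)` on an energy grid. Between grid
#' points it is interpolated piecewise-linearly; outside the grid it is
#' extrapolated linearly with the canonical slopes `1/kT_low` (below) and
#' `1/kT_high` (above), so that sampling stays well-behaved at the energy
#' range edges.
#'
#' @param energy_grid strictly increasing bin centers, kcal/mol.
#' @param ln_dos estimated log density of states per bin (up to an additive
#'   constant).
#' @param T_low,T_high temperature range the flat ensemble is meant to
#'   cover, K.
#' @param diagnostics optional estimation diagnostics.
#' @param slope_lo,slope_hi optional extrapolation slopes overriding the
#'   canonical defaults; the estimator supplies a measured low-energy
#'   slope, which grows steeply near the ground state where the density of
#'   states collapses.
#' @return object of class `mc_weight`.
#' @export
mc_weight <- function(energy_grid, ln_dos, T_low = 300, T_high = 700,
                      diagnostics = NULL, slope_lo = NULL, slope_hi = NULL) {
  stopifnot(length(energy_grid) == length(ln_dos), length(energy_grid) >= 2,
            all(diff(energy_grid) > 0), all(is.finite(ln_dos)),
            T_low > 0, T_high >= T_low)
  structure(list(energy_grid = as.numeric(energy_grid),
                 ln_dos = as.numeric(ln_dos),
                 T_low = T_low, T_high = T_high,
                 slope_lo = slope_lo %||% (1 / .kT(T_low)),
                 slope_hi = slope_hi %||% (1 / .kT(T_high)),
                 diagnostics = diagnostics),
            class = "mc_weight")
}

#' Evaluate ln n(E) of a multicanonical weight
#' @param weight an `mc_weight`.
#' @param E energies, kcal/mol.
#' @return interpolated/extrapolated `ln n(E)`.
#' @export
ln_dos_at <- function(weight, E) {
  cpp_lndos_interp(weight$energy_grid, weight$ln_dos,
                   weight$slope_lo, weight$slope_hi, as.numeric(E))
}

#' Estimate the multicanonical weight by iterative pre-runs
#'
#' Iterative estimation of the log density of states `ln n(E)` over the
#' energy range bracketed by canonical pilot runs at `T_low` and `T_high`.
#' The first pre-run samples with the canonical weight at `T_high`; each
#' subsequent pre-run samples with the current flat-histogram weight, and
#' after every pre-run `ln n(E)` is re-estimated from *all* pre-run
#' histograms combined by multiple-histogram (WHAM-type) reweighting --
#' every pre-run's sampling weight is known exactly, so the combined
#' estimator uses all data and can correct earlier over- or
#' under-estimates. Bins beyond the explored range are extrapolated with
#' the local statistical-temperature slope (clipped between the canonical
#' slopes at `T_high` and `T_low`), which lets the explored range grow
#' steadily toward the low-energy (bound) end. Iterations stop when the
#' latest pre-run's energy histogram over the explored range is flat
#' (min/max ratio at least `flatness_target`).
#'
#' @param system a `toy_system` or `harmonic_reference`.
#' @param restraints optional [cylinder_restraint()] active during
#'   estimation (and in later production runs with this weight).
#' @param T_low,T_high target temperature range, K (defaults 300, 700).
#' @param max_iterations maximum number of pre-runs.
#' @param steps_per_iteration Monte-Carlo steps per pre-run.
#' @param flatness_target histogram min/max ratio that stops the
#'   iteration (default 0.5).
#' @param n_bins number of energy bins (default 200).
#' @param pilot_steps steps of each canonical pilot run used to bracket the
#'   energy range.
#' @param seed RNG seed.
#' @param start starting coordinates (default native pose).
#' @param moves move-set overrides, see [run_canonical()].
#' @param E_range optional explicit `c(E_lo, E_hi)` overriding the pilots.
#' @return an `mc_weight` with per-iteration diagnostics
#'   (`iteration`, `flatness`, `visited`) and the last histogram.
#' @export
estimate_mc_weight <- function(system, restraints = NULL, T_low = 300,
                               T_high = 700, max_iterations = 60,
                               steps_per_iteration = 100000,
                               flatness_target = 0.5, n_bins = 200,
                               pilot_steps = 30000, seed = NULL, start = NULL,
                               moves = NULL, E_range = NULL) {
  stopifnot(max_iterations >= 1, T_high > T_low)
  if (!is.null(seed)) set.seed(seed)
  x0 <- .start_coords(system, start)
  pk <- .pack_system(system, restraints)
  E_start <- cpp_full_energy(pk, x0)
  if (is.null(E_range)) {
    pilot_lo <- run_canonical(system, T_low, pilot_steps, restraints,
                              thin = 5L, start = x0, moves = moves,
                              save_coords = FALSE)
    burn_hi <- run_canonical(system, T_high, pilot_steps, restraints,
                             thin = pilot_steps, start = x0, moves = moves,
                             save_coords = FALSE)
    pilot_hi <- run_canonical(system, T_high, pilot_steps, restraints,
                              thin = 5L, start = burn_hi$final_coords,
                              moves = moves, save_coords = FALSE)
    E_lo <- min(pilot_lo$energy, pilot_hi$energy, E_start) - 0.5
    E_hi <- as.numeric(quantile(pilot_hi$energy, 0.99)) + 1
    if (E_hi <= E_lo + 1) E_hi <- E_lo + 2
    # the band over which the production histogram must come out flat:
    # typical energies between the low- and high-temperature ensembles
    target_E <- c(stats::median(pilot_lo$energy),
                  as.numeric(quantile(pilot_hi$energy, 0.95)))
  } else {
    E_lo <- E_range[1]; E_hi <- E_range[2]
    target_E <- E_range
  }
  width <- (E_hi - E_lo) / n_bins
  grid <- E_lo + (seq_len(n_bins) - 0.5) * width
  beta_lo <- 1 / .kT(T_low); beta_hi <- 1 / .kT(T_high)
  S_cur <- grid * beta_hi                  # canonical weight at T_high
  S_runs <- NULL                           # n_runs x n_bins sampling weights
  H_runs <- NULL                           # n_runs x n_bins histograms
  cur <- x0
  diag_rows <- NULL
  H <- NULL
  for (it in seq_len(max_iterations)) {
    wobj <- mc_weight(grid, S_cur, T_low, T_high)
    tr <- run_multicanonical(system, wobj, restraints,
                             n_steps = steps_per_iteration, thin = 1L,
                             start = cur, moves = moves, save_coords = FALSE)
    cur <- tr$final_coords
    inr <- tr$energy >= E_lo & tr$energy <= E_hi
    b <- floor((tr$energy[inr] - E_lo) / width) + 1
    H <- tabulate(pmin(b, n_bins), nbins = n_bins)
    S_runs <- rbind(S_runs, S_cur)
    H_runs <- rbind(H_runs, H)
    ever <- colSums(H_runs) > 0
    span <- which(ever)[1]:max(which(ever))
    tgt <- which(grid >= target_E[1] & grid <= target_E[2])
    # flatness over the recent pre-runs combined (the weight changes
    # little between late iterations, so they sample near-identically)
    Hrec <- colSums(H_runs[max(1, it - 2):it, , drop = FALSE])
    flat <- if (all(Hrec[tgt] > 0)) min(Hrec[tgt]) / max(Hrec[tgt]) else 0
    diag_rows <- rbind(diag_rows,
                       data.frame(iteration = it, flatness = flat,
                                  visited = sum(H > 0),
                                  E_min_seen = grid[span[1]]))
    if (flat >= flatness_target) break
    ln_n <- .multi_hist_lnn(H_runs, S_runs)
    S_cur <- .canonical_floor(grid, .extend_lnn(grid, ln_n, beta_lo, beta_hi),
                              beta_lo)
  }
  ln_n <- .multi_hist_lnn(H_runs, S_runs)
  ln_n <- .canonical_floor(grid, .extend_lnn(grid, ln_n, beta_lo, beta_hi),
                           beta_lo)
  ever <- colSums(H_runs) > 0
  span <- which(ever)[1]:max(which(ever))
  if (length(span) < 2)
    stop("energy range never explored; check the starting structure and range")
  if (any(!is.finite(ln_n[span]))) {
    holes <- grid[span][!is.finite(ln_n[span])]
    warning(sprintf("energy range not bridged: %d interior bins unvisited (around E = %.2f); last histogram attached to diagnostics",
                    length(holes), holes[1]))
    ln_n[span] <- .fill_gaps(grid[span], ln_n[span])
  }
  converged <- diag_rows$flatness[nrow(diag_rows)] >= flatness_target
  if (!converged)
    warning("flatness target not reached within max_iterations; weight may be rough")
  diag <- list(iterations = diag_rows,
               final_hist = data.frame(E = grid, count = H, visited = ever),
               E_range = c(E_lo, E_hi), target_E_range = target_E,
               bin_width = width, converged = converged)
  mc_weight(grid[span], ln_n[span], T_low, T_high, diagnostics = diag)
}

# multiple-histogram estimator of ln n(E) from pre-runs with known
# sampling weights S_runs (n_runs x n_bins); self-consistent in the run
# normalizers f_k, all in log space
.multi_hist_lnn <- function(H_runs, S_runs, max_iter = 500, tol = 1e-8) {
  nk <- nrow(H_runs)
  Ht <- colSums(H_runs)
  N <- rowSums(H_runs)
  lnN <- log(pmax(N, 1))
  f <- rep(0, nk)
  lse <- function(x) { m <- max(x); if (!is.finite(m)) return(-Inf); m + log(sum(exp(x - m))) }
  occ <- Ht > 0
  ln_n <- rep(NA_real_, ncol(H_runs))
  for (i in seq_len(max_iter)) {
    # ln denom_b = logsumexp_k ( ln N_k + f_k - S_k(b) )
    A <- sweep(-S_runs, 1, lnN + f, `+`)        # nk x nb
    ln_den <- apply(A, 2, lse)
    ln_n[occ] <- log(Ht[occ]) - ln_den[occ]
    fnew <- vapply(seq_len(nk), function(k)
      -lse(ln_n[occ] - S_runs[k, occ]), numeric(1))
    fnew <- fnew - fnew[1]
    resid <- max(abs(fnew - f))
    f <- fnew
    if (resid < tol) break
  }
  ln_n - max(ln_n, na.rm = TRUE)
}

# extend ln n(E) beyond the explored bins with the local
# statistical-temperature slope, clipped to the canonical slopes
.extend_lnn <- function(grid, ln_n, beta_lo, beta_hi, fit_bins = 6) {
  ok <- which(is.finite(ln_n))
  lo <- ok[1]; hi <- ok[length(ok)]
  out <- ln_n
  out[lo:hi] <- .fill_gaps(grid[lo:hi], ln_n[lo:hi])
  ln_n <- out
  slope_at <- function(idx) {
    sel <- idx
    if (length(sel) < 2) return(NA_real_)
    stats::coef(stats::lm(ln_n[sel] ~ grid[sel]))[2]
  }
  if (lo > 1) {
    # clip at the T_low canonical slope: below the explored frontier the
    # walk then behaves like a canonical T_low tail -- it advances into
    # lower energies without ever creating a deep artificial trap
    s <- min(max(slope_at(lo:min(lo + fit_bins - 1, hi)), beta_hi,
                 na.rm = TRUE), beta_lo)
    out[1:(lo - 1)] <- ln_n[lo] + s * (grid[1:(lo - 1)] - grid[lo])
  }
  if (hi < length(grid)) {
    s <- min(max(slope_at(max(hi - fit_bins + 1, lo):hi), beta_hi,
                 na.rm = TRUE), beta_lo)
    out[(hi + 1):length(grid)] <- ln_n[hi] + s * (grid[(hi + 1):length(grid)] - grid[hi])
  }
  out
}

# below the energy where the statistical temperature reaches T_low, the
# weight goes over to the canonical T_low form (tangent construction):
# flat-histogram sampling of bins whose density of states is vanishingly
# small would require astronomically long sojourns, so the low-energy tail
# is sampled canonically at T_low instead
.canonical_floor <- function(grid, ln_n, beta_lo) {
  # top-down sweep capping dS/dE at beta_lo (statistical temperature never
  # below T_low); removes estimator noise dips at rarely-visited bins too
  for (i in (length(ln_n) - 1):1)
    ln_n[i] <- max(ln_n[i], ln_n[i + 1] - beta_lo * (grid[i + 1] - grid[i]))
  ln_n
}

# linear interpolation across interior unvisited bins
.fill_gaps <- function(x, y) {
  bad <- !is.finite(y)
  if (!any(bad)) return(y)
  y[bad] <- approx(x[!bad], y[!bad], xout = x[bad], rule = 2)$y
  y
}

#' Multicanonical production run
#'
#' Metropolis sampling on the multicanonical effective potential: moves are
#' accepted with probability `min(1, n(E_old)/n(E_new))`, which makes the
#' energy histogram flat over the covered range and the dynamics a random
#' walk in energy between the low-`T_low` and high-`T_high` regions.
#'
#' @inheritParams run_canonical
#' @param weight an [mc_weight()] covering the reachable energy range (via
#'   its extrapolation rule).
#' @return a `trajectory` with `ensemble = "multicanonical"`; the weight is
#'   stored for later reweighting.
#' @export
run_multicanonical <- function(system, weight, restraints = NULL,
                               n_steps = 1e5, seed = NULL, thin = 10L,
                               start = NULL, moves = NULL, save_coords = TRUE) {
  stopifnot(inherits(weight, "mc_weight"))
  mv <- .moves(moves)
  pk <- .pack_system(system, restraints)
  x0 <- .start_coords(system, start)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run_mc(pk, x0, weight$T_low, TRUE,
                    weight$energy_grid, weight$ln_dos,
                    weight$slope_lo, weight$slope_hi,
                    as.integer(n_steps), as.integer(thin),
                    mv$bead_step, mv$trans_step, mv$rot_step,
                    mv$p_trans, mv$p_rot, save_coords)
  .new_trajectory(res, system, "multicanonical", NA_real_, restraints, seed,
                  thin, n_steps, weight = weight)
}

#' Energy-histogram flatness
#'
#' Ratio min/max of the binned energy histogram over `E_range`; 1 for a
#' perfectly flat histogram, 0 if any bin in range is empty.
#'
#' @param x a `trajectory` or numeric energy vector.
#' @param E_range `c(lo, hi)` energy range, kcal/mol.
#' @param n_bins number of bins (default 20).
#' @return ratio in \[0, 1\].
#' @export
flatness <- function(x, E_range, n_bins = 20) {
  E <- if (inherits(x, "trajectory")) x$energy else as.numeric(x)
  stopifnot(length(E_range) == 2, E_range[1] < E_range[2])
  inr <- E >= E_range[1] & E <= E_range[2]
  if (!any(inr)) stop("no frames with energy inside E_range")
  h <- tabulate(pmin(pmax(floor((E[inr] - E_range[1]) /
                                  diff(E_range) * n_bins) + 1, 1), n_bins),
                nbins = n_bins)
  min(h) / max(h)
}

#' Number of energy round trips of a trajectory
#'
#' Counts complete excursions between the lowest and highest thirds of the
#' given energy range, a standard diagnostic of multicanonical mixing.
#'
#' @param trajectory a `trajectory`.
#' @param E_range energy range `c(lo, hi)`; defaults to the range of the
#'   trajectory energies.
#' @return integer count of low-to-high-to-low (or inverse) round trips,
#'   i.e. boundary-to-boundary crossings minus one, halved.
#' @export
round_trips <- function(trajectory, E_range = NULL) {
  E <- trajectory$energy
  if (is.null(E_range)) E_range <- range(E)
  lo <- E_range[1] + diff(E_range) / 3
  hi <- E_range[2] - diff(E_range) / 3
  state <- 0L; crossings <- 0L
  for (e in E) {
    if (e <= lo) {
      if (state == 1L) crossings <- crossings + 1L
      state <- -1L
    } else if (e >= hi) {
      if (state == -1L) crossings <- crossings + 1L
      state <- 1L
    }
  }
  crossings %/% 2L
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("%s Monte-Carlo trajectory: %d frames (every %d of %g steps)\n",
              x$ensemble, length(x$energy), x$thin, x$n_steps))
  if (x$ensemble == "canonical")
    cat(sprintf("  T = %g K\n", x$temperature))
  cat(sprintf("  energy range [%.2f, %.2f] kcal/mol, acceptance %.2f\n",
              min(x$energy), max(x$energy), x$acceptance))
  cat(sprintf("  lambda range [%.2f, %.2f] A\n", min(x$lam), max(x$lam)))
  invisible(x)
}

#' @export
summary.trajectory <- function(object, ...) {
  out <- data.frame(frames = length(object$energy),
                    mean_E = mean(object$energy), sd_E = sd(object$energy),
                    mean_lam = mean(object$lam), acceptance = object$acceptance)
  out
}

#' @export
print.mc_weight <- function(x, ...) {
  cat(sprintf("Multicanonical weight: ln n(E) on %d bins over [%.2f, %.2f] kcal/mol\n",
              length(x$energy_grid), min(x$energy_grid), max(x$energy_grid)))
  cat(sprintf("  flat ensemble target %g-%g K\n", x$T_low, x$T_high))
  if (!is.null(x$diagnostics))
    cat(sprintf("  estimation: %d iterations, final ln f = %.2g, converged: %s\n",
                nrow(x$diagnostics$iterations), x$diagnostics$final_lnf,
                x$diagnostics$converged))
  invisible(x)
}

#' @export
plot.mc_weight <- function(x, ...) {
  plot(x$energy_grid, x$ln_dos, type = "l", xlab = "E (kcal/mol)",
       ylab = "ln n(E) + const", main = "Multicanonical weight", ...)
  invisible(x)
}

#' Extract frame coordinates from a trajectory
#' @param trajectory a `trajectory`.
#' @param i frame index.
#' @return n x 3 coordinate matrix.
#' @export
frame_coords <- function(trajectory, i) {
  trajectory$coords[, , i]
}
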