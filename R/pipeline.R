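#' Full two-stage binding pipeline, in memory
#'
#' Runs the complete methodology on a toy system: multicanonical weight
#' estimation, flat-histogram docking production, canonical reweighting to
#' the target temperature, free-energy-landscape clustering of binding
#' poses, pathway seed selection, umbrella sampling along lambda', WHAM,
#' and the standard-state binding free energy.
#'
#' @param config a [default_config()] list; `config$seed` drives every
#'   stage's RNG deterministically.
#' @param system optional pre-built `toy_system` (default: built from
#'   `config$system`).
#' @param verbose print stage progress.
#' @return list of class `binding_pipeline`: `system`, `restraint`,
#'   `weight`, `dock` (trajectory), `weights300`, `pca`, `fel`, `clusters`
#'   (NULL when the feature space is one-dimensional), `path`, `runs`
#'   (umbrella set), `pmf`, `ranges`, `result` (a [binding_result()]).
#' @export
binding_pipeline <- function(config = default_config(), system = NULL,
                             verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed
  if (is.null(system)) system <- do.call(build_system, config$system)
  cyl <- do.call(default_restraint, c(list(system), config$restraint))
  sc <- config$sampler

  say("stage weight: flat-histogram estimation (%d bins, target %g-%g K)",
      sc$n_bins, sc$T_low, sc$T_high)
  weight <- estimate_mc_weight(system, cyl, T_low = sc$T_low,
                               T_high = sc$T_high,
                               max_iterations = sc$max_iterations,
                               steps_per_iteration = sc$steps_per_iteration,
                               flatness_target = sc$flatness_target,
                               n_bins = sc$n_bins, pilot_steps = sc$pilot_steps,
                               seed = seed)

  say("stage dock: multicanonical production (%d replicas x %g steps)",
      sc$n_replicas, sc$production_steps)
  docks <- lapply(seq_len(sc$n_replicas), function(r)
    run_multicanonical(system, weight, cyl, n_steps = sc$production_steps,
                       seed = seed + 1000L * r, thin = sc$thin))
  dock <- if (sc$n_replicas == 1) docks[[1]] else .pool_trajectories(docks)

  Tt <- config$analysis$T_target
  w300 <- reweight(dock, Tt)

  feats <- intermolecular_features(dock, system)
  pca <- weighted_pca(feats, w300)
  fel <- NULL; clusters <- NULL
  if (ncol(pca$projections) >= 2) {
    fel <- build_fel(pca, w300, T = Tt, nx = config$analysis$fel_bins,
                     ny = config$analysis$fel_bins)
    clusters <- cluster_representatives(fel, pca, w300,
                                        k_max = config$analysis$k_max)
    say("stage fel/cluster: %d basins, top cluster holds %.0f%% of the weight",
        nrow(clusters), 100 * clusters$weight[1])
  }

  # bound reference structure: representative of the top basin when
  # available, otherwise the native pose
  if (!is.null(clusters)) {
    ref_frame <- clusters$representative[1]
    ref_coords <- frame_coords(dock, ref_frame)
  } else {
    ref_coords <- native_pose(system)
  }
  lam_ref <- unname(lambda_coords(ligand_com(system, ref_coords), cyl)["lam"])

  pc <- config$path
  lam_hi <- cyl$lam_max - lam_ref - 2.0
  windows <- window_spec(pc$n_windows, 0, lam_hi, pc$k_bias, pc$n_seeds)
  lamp <- dock$lam - lam_ref
  pools <- assign_windows(lamp, windows)
  pool_frames <- sort(unique(unlist(pools)))
  contacts <- vector("list", length(dock$lam))
  for (i in pool_frames)
    contacts[[i]] <- contact_map(system, frame_coords(dock, i),
                                 config$analysis$contact_cutoff)
  path <- pick_path(pools, contacts, n_seeds = pc$n_seeds, weights = w300,
                    pool_cap = pc$pool_cap)
  say("stage path: chain score %.2f over %d windows", path$score,
      pc$n_windows)

  uc <- config$umbrella
  seed_frames <- lapply(path$seeds, function(ids)
    lapply(ids, function(i) frame_coords(dock, i)))
  runs <- run_umbrella(system, windows, seed_frames, n_steps = uc$n_steps,
                       T = Tt, restraints = cyl, lam_ref = lam_ref,
                       rng_seed = seed + 500000L, thin = uc$thin)
  say("stage umbrella: %d runs, min adjacent overlap %.2f", length(runs),
      min(attr(runs, "overlaps")))

  ranges <- range_error(runs, bound_width = uc$bound_width,
                        bin_width = uc$bin_width, T = Tt,
                        plateau_width = uc$plateau_width)
  best <- attr(ranges, "best")
  prod_runs <- trailing_runs(runs, ranges$fraction[best])
  pmf <- wham(prod_runs, bin_width = uc$bin_width, T = Tt,
              plateau_width = uc$plateau_width)
  dG <- binding_dG(pmf, uc$bound_width)
  g3d <- g3d_from_runs(prod_runs, pmf, bin = uc$g3d_bin, radius = cyl$radius)
  V_eff <- effective_volume(g3d, dG, bound_width = uc$bound_width)
  result <- binding_result(dG, V_eff, T = Tt, error = ranges$eps[best])
  say("result (trailing %.0f%% of each run): dG = %.2f, V_eff = %.3g A^3, dG0 = %.2f kcal/mol",
      100 * ranges$fraction[best], result$dG, result$V_eff, result$dG0)

  structure(list(system = system, restraint = cyl, weight = weight,
                 dock = dock, weights300 = w300, pca = pca, fel = fel,
                 clusters = clusters, lam_ref = lam_ref, windows = windows,
                 path = path, runs = runs, pmf = pmf, ranges = ranges,
                 g3d = g3d, result = result, config = config),
            class = "binding_pipeline")
}

#' @export
print.binding_pipeline <- function(x, ...) {
  cat("Two-stage binding pipeline\n")
  print(x$system)
  if (!is.null(x$clusters)) {
    cat("Top binding-pose clusters (delta F, kcal/mol):\n")
    print(head(as.data.frame(x$clusters)[, c("cluster", "delta_F", "n_frames")], 5),
          row.names = FALSE)
  }
  print(x$result)
  invisible(x)
}

.pool_trajectories <- function(trajs) {
  out <- trajs[[1]]
  out$coords <- do.call(function(...) {
    arrs <- list(...)
    array(unlist(arrs), dim = c(dim(arrs[[1]])[1:2],
                                sum(vapply(arrs, function(a) dim(a)[3], 1))))
  }, lapply(trajs, `[[`, "coords"))
  for (f in c("energy", "lam", "v", "zeta", "step"))
    out[[f]] <- unlist(lapply(trajs, `[[`, f))
  out$n_steps <- sum(vapply(trajs, `[[`, numeric(1), "n_steps"))
  out
}

.stages <- c("weight", "dock", "fel", "cluster", "stability", "path",
             "umbrella", "wham", "dg", "report")

.artifact <- function(run_dir, name) file.path(run_dir, name)

.require_artifact <- function(run_dir, name, stage, prior) {
  p <- .artifact(run_dir, name)
  if (!file.exists(p))
    stop(sprintf("stage '%s' requires '%s'; run stage '%s' first",
                 stage, name, prior))
  p
}

.stamp_csv <- function(df, path, config, extra = NULL) {
  con <- file(path, "w")
  writeLines(c(sprintf("# config_hash: %s", config_hash(config)),
               sprintf("# seed: %s", config$seed), extra), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

.read_stamped_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  read.csv(text = paste(lines[!hdr], collapse = "\n"))
}

#' Run one pipeline stage against a run directory
#'
#' File-based staged execution with resumability: each stage reads the
#' artifacts of its prerequisites from `run_dir`, writes its own artifacts
#' (CSV/JSON/plain text, each stamped with the configuration hash and
#' seed), and errors naming the missing prior stage when invoked out of
#' order. Stages: `weight`, `dock`, `fel`, `cluster`, `stability`, `path`,
#' `umbrella`, `wham`, `dg`, `report`.
#'
#' @param stage stage name.
#' @param config a [default_config()].
#' @param run_dir artifact directory (created if missing).
#' @return invisibly, the paths of the artifacts written.
#' @export
run_stage <- function(stage, config = default_config(), run_dir = "run") {
  stage <- match.arg(stage, .stages)
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  system <- do.call(build_system, config$system)
  cyl <- do.call(default_restraint, c(list(system), config$restraint))
  seed <- config$seed
  Tt <- config$analysis$T_target
  out <- switch(stage,
    weight = {
      sc <- config$sampler
      w <- estimate_mc_weight(system, cyl, T_low = sc$T_low, T_high = sc$T_high,
                              max_iterations = sc$max_iterations,
                              steps_per_iteration = sc$steps_per_iteration,
                              flatness_target = sc$flatness_target,
                              n_bins = sc$n_bins, pilot_steps = sc$pilot_steps,
                              seed = seed)
      write_weight(w, .artifact(run_dir, "weight.txt"))
    },
    dock = {
      w <- read_weight(.require_artifact(run_dir, "weight.txt", stage, "weight"))
      sc <- config$sampler
      tr <- run_multicanonical(system, w, cyl, n_steps = sc$production_steps,
                               seed = seed + 1000L, thin = sc$thin)
      write_trajectory(tr, .artifact(run_dir, "dock.csv"))
    },
    fel = {
      d <- .load_dock(run_dir, system, stage)
      w300 <- .dock_weights(d, run_dir, config, system, stage)
      pca <- weighted_pca(intermolecular_features(d, system), w300)
      proj <- data.frame(frame = seq_len(nrow(pca$projections)),
                         pc1 = pca$projections[, 1],
                         pc2 = pca$projections[, 2], weight = as.numeric(w300))
      .stamp_csv(proj, .artifact(run_dir, "projections.csv"), config)
      fel <- build_fel(pca, w300, T = Tt, nx = config$analysis$fel_bins,
                       ny = config$analysis$fel_bins)
      cells <- which(fel$W > 0, arr.ind = TRUE)
      .stamp_csv(data.frame(pc1 = fel$x[cells[, 1]], pc2 = fel$y[cells[, 2]],
                            F = fel$F[cells], weight = fel$W[cells]),
                 .artifact(run_dir, "fel.csv"), config)
    },
    cluster = {
      d <- .load_dock(run_dir, system, stage)
      pr <- .read_stamped_csv(.require_artifact(run_dir, "projections.csv",
                                                stage, "fel"))
      w300 <- structure(pr$weight, class = "frame_weights", target_T = Tt)
      fel <- build_fel(cbind(pr$pc1, pr$pc2), w300, T = Tt,
                       nx = config$analysis$fel_bins,
                       ny = config$analysis$fel_bins)
      cl <- cluster_representatives(fel, cbind(pr$pc1, pr$pc2), w300,
                                    k_max = config$analysis$k_max)
      ref <- native_pose(system)
      cl$rvalue_native <- vapply(cl$representative, function(i)
        rvalue_native(system, frame_coords(d, i)), numeric(1))
      cl$rmsd <- vapply(cl$representative, function(i)
        rmsd(frame_coords(d, i), ref), numeric(1))
      cl$lam <- d$lam[cl$representative]
      .stamp_csv(as.data.frame(cl), .artifact(run_dir, "clusters.csv"), config)
    },
    stability = {
      d <- .load_dock(run_dir, system, stage)
      cl <- .read_stamped_csv(.require_artifact(run_dir, "clusters.csv",
                                                stage, "cluster"))
      st <- stability_assay(system, frame_coords(d, cl$representative[1]),
                            n_steps = config$analysis$stability_steps,
                            n_repeats = config$analysis$stability_repeats,
                            seed = seed + 2000L,
                            cutoff = config$analysis$contact_cutoff)
      .stamp_csv(st$summary, .artifact(run_dir, "stability.csv"), config)
    },
    path = {
      d <- .load_dock(run_dir, system, stage)
      cl <- .read_stamped_csv(.require_artifact(run_dir, "clusters.csv",
                                                stage, "cluster"))
      w300 <- .dock_weights(d, run_dir, config, system, stage)
      lam_ref <- d$lam[cl$representative[1]]
      pcfg <- config$path
      windows <- window_spec(pcfg$n_windows, 0, cyl$lam_max - lam_ref - 2.0,
                             pcfg$k_bias, pcfg$n_seeds)
      pools <- assign_windows(d$lam - lam_ref, windows)
      contacts <- vector("list", length(d$lam))
      for (i in sort(unique(unlist(pools))))
        contacts[[i]] <- contact_map(system, frame_coords(d, i),
                                     config$analysis$contact_cutoff)
      sel <- pick_path(pools, contacts, n_seeds = pcfg$n_seeds,
                       weights = w300, pool_cap = pcfg$pool_cap)
      rows <- do.call(rbind, lapply(seq_len(nrow(windows)), function(wd)
        data.frame(window = wd, center = windows$center[wd],
                   k = windows$k[wd], lam_ref = lam_ref,
                   seed_rank = seq_along(sel$seeds[[wd]]),
                   frame = sel$seeds[[wd]],
                   score = sel$score)))
      .stamp_csv(rows, .artifact(run_dir, "path.csv"), config)
    },
    umbrella = {
      d <- .load_dock(run_dir, system, stage)
      pth <- .read_stamped_csv(.require_artifact(run_dir, "path.csv",
                                                 stage, "path"))
      pcfg <- config$path
      windows <- window_spec(pcfg$n_windows, min(pth$center), max(pth$center),
                             pth$k[1], pcfg$n_seeds)
      seed_frames <- lapply(split(pth, pth$window), function(g)
        lapply(g$frame, function(i) frame_coords(d, i)))
      runs <- run_umbrella(system, windows, seed_frames,
                           n_steps = config$umbrella$n_steps, T = Tt,
                           restraints = cyl, lam_ref = pth$lam_ref[1],
                           rng_seed = seed + 500000L,
                           thin = config$umbrella$thin, save_coords = FALSE)
      rows <- do.call(rbind, lapply(runs, function(r)
        data.frame(window = r$window, seed_id = r$seed_id, k = r$bias$k,
                   center = r$bias$center, lam_ref = r$lam_ref,
                   step = r$step, energy = r$energy, lam = r$lam,
                   v = r$v, zeta = r$zeta)))
      .stamp_csv(rows, .artifact(run_dir, "umbrella.csv"), config)
    },
    wham = {
      runs <- .load_umbrella(run_dir, stage)
      pmf <- wham(runs, bin_width = config$umbrella$bin_width, T = Tt,
                  plateau_width = config$umbrella$plateau_width)
      .stamp_csv(data.frame(lamp = pmf$lamp, G = pmf$G, error = pmf$error,
                            counts = pmf$counts),
                 .artifact(run_dir, "pmf.csv"), config,
                 extra = sprintf("# lam_ref: %g", pmf$lam_ref))
    },
    dg = {
      runs <- .load_umbrella(run_dir, stage)
      .require_artifact(run_dir, "pmf.csv", stage, "wham")
      uc <- config$umbrella
      pmf <- wham(runs, bin_width = uc$bin_width, T = Tt,
                  plateau_width = uc$plateau_width)
      dG <- binding_dG(pmf, uc$bound_width)
      ranges <- range_error(runs, bound_width = uc$bound_width,
                            bin_width = uc$bin_width, T = Tt,
                            plateau_width = uc$plateau_width)
      g3d <- g3d_from_runs(runs, pmf, bin = uc$g3d_bin, radius = cyl$radius)
      V_eff <- effective_volume(g3d, dG, bound_width = uc$bound_width)
      res <- binding_result(dG, V_eff, T = Tt,
                            error = ranges$eps[attr(ranges, "best")])
      jsonlite::write_json(list(config_hash = config_hash(config),
                                seed = config$seed, dG = res$dG,
                                error = res$error, V_eff = res$V_eff,
                                dG0 = res$dG0, T = res$T, V0 = res$V0),
                           .artifact(run_dir, "binding.json"),
                           auto_unbox = TRUE, digits = NA)
      .artifact(run_dir, "binding.json")
    },
    report = {
      cl <- .read_stamped_csv(.require_artifact(run_dir, "clusters.csv",
                                                stage, "cluster"))
      pmf <- .read_stamped_csv(.require_artifact(run_dir, "pmf.csv",
                                                 stage, "wham"))
      bind <- jsonlite::read_json(.require_artifact(run_dir, "binding.json",
                                                    stage, "dg"))
      rep <- list(config_hash = config_hash(config), seed = config$seed,
                  clusters = cl, pmf_depth = min(pmf$G, na.rm = TRUE),
                  binding = bind)
      jsonlite::write_json(rep, .artifact(run_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      .artifact(run_dir, "report.json")
    })
  invisible(out)
}

.load_dock <- function(run_dir, system, stage) {
  p <- .require_artifact(run_dir, "dock.csv", stage, "dock")
  tr <- read_trajectory(p)
  fr <- tr$frames
  nb <- nrow(system$receptor_beads) + system$ligand_topology$n
  cc <- as.matrix(fr[, grepl("^[xyz][0-9]+$", names(fr)), drop = FALSE])
  coords <- array(0, c(nb, 3, nrow(fr)))
  for (i in seq_len(nrow(fr)))
    coords[, , i] <- matrix(cc[i, ], nb, 3, byrow = TRUE)
  structure(list(coords = coords, energy = fr$energy, lam = fr$lam,
                 v = fr$v, zeta = fr$zeta, step = fr$step,
                 ensemble = tr$meta[["ensemble"]], thin = as.integer(tr$meta[["thin"]]),
                 n_steps = as.numeric(tr$meta[["n_steps"]]),
                 system_config = system$config),
            class = "trajectory")
}

.dock_weights <- function(dock, run_dir, config, system, stage) {
  w <- read_weight(.require_artifact(run_dir, "weight.txt", stage, "weight"))
  dock$weight <- w
  reweight(dock, config$analysis$T_target)
}

.load_umbrella <- function(run_dir, stage) {
  p <- .require_artifact(run_dir, "umbrella.csv", stage, "umbrella")
  df <- .read_stamped_csv(p)
  runs <- lapply(split(df, list(df$window, df$seed_id), drop = TRUE), function(g) {
    structure(list(lam = g$lam, v = g$v, zeta = g$zeta, energy = g$energy,
                   step = g$step, window = g$window[1], seed_id = g$seed_id[1],
                   bias = list(k = g$k[1], center = g$center[1]),
                   lam_ref = g$lam_ref[1]),
              class = c("umbrella_run", "trajectory"))
  })
  class(runs) <- "umbrella_set"
  runs
}

#' Run the full staged pipeline into a run directory
#' @param config a [default_config()].
#' @param run_dir artifact directory.
#' @param stages stages to execute, in order (default all).
#' @export
run_pipeline <- function(config = default_config(), run_dir = "run",
                         stages = .stages) {
  for (s in stages) {
    message("running stage: ", s)
    run_stage(s, config, run_dir)
  }
  invisible(run_dir)
}
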