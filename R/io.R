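#' Read a PDB-format structure
#'
#' Thin wrapper over `bio3d::read.pdb` returning coordinates plus
#' chain/residue labels -- enough to compute contacts, cylinder coordinates
#' and RMSD on real complexes. ATOM/HETATM records are pre-validated so a
#' malformed line is reported with its line number.
#'
#' @param path PDB file.
#' @return list of class `structure_model`: `coords` (n x 3), `atoms`
#'   (data.frame with `chain`, `resno`, `resid`, `elety`), `chains`.
#' @export
read_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))))
      stop(sprintf("malformed PDB record at line %d: %s", i,
                   substr(ln, 1, 40)))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom
  structure(list(coords = cbind(x = atoms$x, y = atoms$y, z = atoms$z),
                 atoms = atoms[, c("chain", "resno", "resid", "elety", "type")],
                 chains = unique(atoms$chain)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("PDB structure: %d atoms, chains %s\n", nrow(x$coords),
              paste(x$chains, collapse = ", ")))
  invisible(x)
}

#' Coordinates of one chain of a structure
#' @param model a `structure_model`.
#' @param chain chain identifier.
#' @param calpha keep only CA pseudo-atoms/atoms.
#' @export
chain_coords <- function(model, chain, calpha = FALSE) {
  sel <- model$atoms$chain == chain
  if (calpha) sel <- sel & model$atoms$elety == "CA"
  if (!any(sel)) stop("no atoms in chain ", chain)
  model$coords[sel, , drop = FALSE]
}

#' Write bead coordinates as PDB-format pseudo-atom records
#'
#' One CA pseudo-atom per bead; receptor beads on chain R, ligand beads on
#' chain L. Files written this way round-trip through [read_structure()].
#'
#' @param system a `toy_system`.
#' @param coordinates full coordinate matrix (default: native pose).
#' @param path output file.
#' @export
write_structure <- function(system, coordinates = NULL, path) {
  if (is.null(coordinates)) coordinates <- native_pose(system)
  nrec <- nrow(system$receptor_beads)
  n <- nrow(coordinates)
  chain <- c(rep("R", nrec), rep("L", n - nrec))
  bio3d::write.pdb(file = path, xyz = as.numeric(t(coordinates)),
                   type = rep("ATOM", n), resno = seq_len(n),
                   resid = rep("GLY", n), elety = rep("CA", n),
                   chain = chain)
  invisible(path)
}

#' Export a trajectory as columnar CSV
#'
#' Documented plain-text layout: '#'-prefixed header metadata (ensemble,
#' temperature, seed, thinning, config hash) followed by one row per frame
#' with `step`, `energy`, `lam`, `v`, `zeta` and the flattened coordinates
#' (`x1, y1, z1, x2, ...`).
#'
#' @param trajectory a `trajectory`.
#' @param path output file.
#' @param coords include coordinate columns (default TRUE).
#' @export
write_trajectory <- function(trajectory, path, coords = TRUE) {
  meta <- c(sprintf("# ensemble: %s", trajectory$ensemble),
            sprintf("# temperature: %s", trajectory$temperature),
            sprintf("# seed: %s", trajectory$seed %||% NA),
            sprintf("# thin: %d", trajectory$thin),
            sprintf("# n_steps: %g", trajectory$n_steps))
  df <- data.frame(step = trajectory$step, energy = trajectory$energy,
                   lam = trajectory$lam, v = trajectory$v,
                   zeta = trajectory$zeta)
  if (coords && !is.null(trajectory$coords)) {
    nb <- dim(trajectory$coords)[1]
    flat <- t(apply(trajectory$coords, 3, function(x) as.numeric(t(x))))
    colnames(flat) <- paste0(rep(c("x", "y", "z"), nb),
                             rep(seq_len(nb), each = 3))
    df <- cbind(df, flat)
  }
  con <- file(path, "w")
  writeLines(meta, con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#' @param path file path.
#' @return list with `meta` (named character) and `frames` (data.frame).
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- sub("^# ", "", lines[hdr])
  kv <- strsplit(meta, ": ")
  meta <- setNames(vapply(kv, function(x) paste(x[-1], collapse = ": "),
                          character(1)),
                   vapply(kv, `[[`, character(1), 1))
  frames <- read.csv(text = paste(lines[!hdr], collapse = "\n"))
  list(meta = meta, frames = frames)
}

#' Persist a multicanonical weight as two-column text
#'
#' '#'-prefixed metadata (temperature range, bin width) followed by
#' `E ln_dos` pairs, the interchange format for the estimated density of
#' states.
#'
#' @param weight an [mc_weight()].
#' @param path output file.
#' @export
write_weight <- function(weight, path) {
  con <- file(path, "w")
  writeLines(c(sprintf("# T_low: %g", weight$T_low),
               sprintf("# T_high: %g", weight$T_high),
               "# columns: E ln_dos"), con)
  utils::write.table(data.frame(E = weight$energy_grid,
                                ln_dos = weight$ln_dos),
                     con, row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a weight file written by [write_weight()]
#' @param path file path.
#' @return an [mc_weight()].
#' @export
read_weight <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), lines, value = TRUE)
    as.numeric(sub(".*: ", "", ln[1]))
  }
  tab <- read.table(text = paste(lines[!hdr], collapse = "\n"))
  mc_weight(tab[[1]], tab[[2]], T_low = get("T_low"), T_high = get("T_high"))
}

#' Default pipeline configuration
#'
#' All parameters of the staged pipeline in one serializable list: system
#' construction, restraint geometry, sampler budgets, analysis settings and
#' the global RNG seed. Step budgets are sized so the full pipeline runs on
#' one CPU in minutes.
#'
#' @param seed global RNG seed.
#' @return named list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    system = list(ligand_length = 6, bond_length = 3.8, k_bond = 10,
                  k_angle = 2, eps = 2.0, r_excluded = 1.5, eps_rep = 1.0,
                  tether_k = 1.0, n_loops = 4),
    restraint = list(lam_min = 2.5, lam_max = 30.0, radius = 4.0,
                     k_perp = 1.0, k_par = 20.0),
    sampler = list(T_low = 300, T_high = 700, max_iterations = 60,
                   steps_per_iteration = 100000, flatness_target = 0.5,
                   n_bins = 200, pilot_steps = 30000,
                   production_steps = 1000000, thin = 100, n_replicas = 1),
    analysis = list(T_target = 300, fel_bins = 40, k_max = 10,
                    contact_cutoff = 4.5,
                    stability_steps = 20000, stability_repeats = 3),
    path = list(n_windows = 16, n_seeds = 3, k_bias = 0.3, pool_cap = 50),
    umbrella = list(n_steps = 30000, thin = 10, bin_width = 0.25,
                    bound_width = 2.5, plateau_width = 2.5, g3d_bin = 0.25),
    seed = seed
  ), class = "run_config")
}

#' Read / write a pipeline configuration (YAML)
#' @param path YAML file.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(modifyList(unclass(default_config()), cfg), class = "run_config")
}

#' @rdname read_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' FNV-1a hash of a configuration (provenance stamp)
#'
#' Short stable hex digest embedded in every pipeline artifact so outputs
#' can be traced to the exact configuration + seed that produced them.
#'
#' @param config any serializable object.
#' @return 8-hex-digit character scalar.
#' @export
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply in two 16-bit halves (doubles stay exact)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * m + ((h1 * m) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
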