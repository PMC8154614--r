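# R-side interface to the compiled DPD engine.

hydrophobic_beads <- c("C2", "C2p", "T1", "T2")

#' DPD simulation configuration
#'
#' Reduced DPD units throughout: lengths in r_c, energies in k_BT = 1, bead
#' mass 1.  The drag and random-force amplitudes are tied by the
#' fluctuation-dissipation relation `sigma^2 = 2 * gamma * k_BT`.
#'
#' @param L cubic box edge (r_c).
#' @param steps number of integration steps.
#' @param seed integer seed controlling initial placement, velocities and
#'   the thermostat noise stream.
#' @param density reduced bead density (r_c^-3).
#' @param dt integration timestep (DPD units).
#' @param stride steps between stored trajectory frames.
#' @param gamma pairwise drag coefficient.
#' @param sigma random-force amplitude; defaults to `sqrt(2 * gamma)`.
#' @param wt_pct optional surfactant weight percent (with `molecule`).
#' @param molecule optional molecule (topology) name for the composition.
#' @param counts optional named vector of explicit molecule counts,
#'   overriding `wt_pct`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(L, steps, seed, density = 3, dt = 0.01, stride = 1000,
                       gamma = 4.5, sigma = sqrt(2 * gamma), wt_pct = NULL,
                       molecule = NULL, counts = NULL) {
  stopifnot(L > 0, steps >= 0, density > 0, dt > 0, stride >= 1, gamma >= 0)
  if (abs(sigma^2 - 2 * gamma) > 1e-9)
    stop("fluctuation-dissipation violated: need sigma^2 = 2 * gamma")
  structure(list(L = L, steps = as.integer(steps), seed = as.integer(seed),
                 density = density, dt = dt, stride = as.integer(stride),
                 gamma = gamma, sigma = sigma, wt_pct = wt_pct,
                 molecule = molecule, counts = counts),
            class = "sim_config")
}

topology_bond_params <- function(tp, paramset) {
  k <- match(tp$beads, paramset$beads)
  if (anyNA(k)) stop("topology '", tp$name, "' uses beads missing from the ",
                     "parameter set")
  bi <- k[tp$bonds$i]; bj <- k[tp$bonds$j]
  idx <- cbind(bi, bj)
  r0 <- bond_r0(tp$bonds$r_target, paramset$a[idx], paramset$R[idx],
                paramset$k_b)
  list(type_index = k, r0 = r0)
}

#' Assemble an initial simulation state
#'
#' Places `counts[m]` copies of each molecule as random walks with bond-length
#' steps, fills the remainder of the `round(density * L^3)` beads with water,
#' and draws Maxwell velocities with the center-of-mass drift removed.  Bond
#' rest lengths are calibrated per bond from the parameter set via
#' [bond_r0()].
#'
#' @param topologies list of [dpd_topology()] objects (may be empty for a
#'   pure water box).
#' @param counts named integer vector of molecule counts (names matching the
#'   topologies), or `NULL` for pure water.
#' @param paramset a `dpd_paramset` object (see [build_paramset()]) covering all used beads plus `W`.
#' @param cfg a [sim_config()].
#' @return an object of class `dpd_system`.
#' @export
build_system <- function(topologies, counts, paramset, cfg) {
  stopifnot(inherits(paramset, "dpd_paramset"), inherits(cfg, "sim_config"))
  if (inherits(topologies, "dpd_topology")) topologies <- list(topologies)
  if (length(topologies))
    names(topologies) <- vapply(topologies, `[[`, character(1), "name")
  if (is.null(counts)) counts <- integer(0)
  if (length(counts) && is.null(names(counts)))
    stop("counts must be named by topology")
  n_total <- round(cfg$density * cfg$L^3)
  n_surf_beads <- sum(vapply(names(counts), function(m)
    counts[[m]] * length(topologies[[m]]$beads), numeric(1)))
  n_water <- n_total - n_surf_beads
  if (n_water < 0)
    stop("composition needs ", n_surf_beads, " beads but the box holds only ",
         n_total, " at density ", cfg$density)
  w_idx <- match("W", paramset$beads)
  if (is.na(w_idx)) stop("parameter set lacks the water bead W")

  set.seed(cfg$seed)
  pos <- matrix(0, n_total, 3)
  type <- integer(n_total)
  mol_id <- integer(n_total)      # 0 = water
  mol_of <- character(0)
  bonds <- list(); angles <- list()
  at <- 0L; mol <- 0L
  for (m in names(counts)) {
    tp <- topologies[[m]]
    bp <- topology_bond_params(tp, paramset)
    nb <- length(tp$beads)
    # bead placement order following the bond list keeps steps bonded
    for (cpy in seq_len(counts[[m]])) {
      mol <- mol + 1L
      mol_of[mol] <- m
      base <- at
      placed <- rep(FALSE, nb)
      pos[base + 1L, ] <- runif(3, 0, cfg$L)
      placed[1L] <- TRUE
      repeat {
        todo <- FALSE
        for (b in seq_len(nrow(tp$bonds))) {
          i <- tp$bonds$i[b]; j <- tp$bonds$j[b]
          if (placed[i] == placed[j]) next
          todo <- TRUE
          from <- if (placed[i]) i else j
          to <- if (placed[i]) j else i
          dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
          p <- pos[base + from, ] + tp$bonds$r_target[b] * dir
          pos[base + to, ] <- p %% cfg$L
          placed[to] <- TRUE
        }
        if (!todo) break
      }
      type[base + seq_len(nb)] <- bp$type_index
      mol_id[base + seq_len(nb)] <- mol
      bonds[[length(bonds) + 1L]] <- data.frame(
        i = base + tp$bonds$i, j = base + tp$bonds$j, r0 = bp$r0,
        k_b = paramset$k_b)
      if (nrow(tp$angles))
        angles[[length(angles) + 1L]] <- data.frame(
          i = base + tp$angles$i, j = base + tp$angles$j,
          k = base + tp$angles$k, theta0 = tp$angles$theta0 * pi / 180,
          k_a = paramset$k_a)
      at <- at + nb
    }
  }
  if (n_water > 0) {
    pos[at + seq_len(n_water), ] <- matrix(runif(3 * n_water, 0, cfg$L),
                                           ncol = 3)
    type[at + seq_len(n_water)] <- w_idx
  }
  vel <- matrix(rnorm(3 * n_total), n_total, 3)
  vel <- sweep(vel, 2, colMeans(vel))   # remove momentum drift
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(i = integer(), j = integer(), r0 = numeric(), k_b = numeric())
  angles <- if (length(angles)) do.call(rbind, angles) else
    data.frame(i = integer(), j = integer(), k = integer(),
               theta0 = numeric(), k_a = numeric())
  structure(list(positions = pos, velocities = vel, type_index = type,
                 mol_id = mol_id, mol_name = mol_of, bonds = bonds,
                 angles = angles, L = cfg$L, paramset = paramset,
                 step = 0), class = "dpd_system")
}

#' Run a DPD simulation
#'
#' Integrates the system with velocity Verlet and the pairwise DPD
#' thermostat, storing a frame every `cfg$stride` steps.  Trajectories are
#' bitwise reproducible for a given `cfg$seed`.
#'
#' @param system a `dpd_system` from [build_system()].
#' @param cfg a [sim_config()].
#' @param units a [unit_map()] recorded with the trajectory.
#' @return an object of class `dpd_trajectory`: `frames` (list of wrapped
#'   position matrices), `frame_steps`, `temperatures` (kinetic temperature
#'   at each frame), bead/molecule annotations, box and unit metadata, and
#'   `final` (the advanced system state for continuation).
#' @export
run_simulation <- function(system, cfg, units = unit_map()) {
  stopifnot(inherits(system, "dpd_system"), inherits(cfg, "sim_config"))
  ps <- system$paramset
  res <- cpp_run(system$positions, system$velocities,
                 system$type_index - 1L, ps$a, ps$R,
                 system$bonds$i - 1L, system$bonds$j - 1L,
                 system$bonds$r0, system$bonds$k_b,
                 system$angles$i - 1L, system$angles$j - 1L,
                 system$angles$k - 1L, system$angles$theta0,
                 system$angles$k_a, system$L, cfg$dt, cfg$steps, cfg$stride,
                 cfg$gamma, cfg$sigma, cfg$seed, system$step)
  final <- system
  final$positions <- res$positions
  final$velocities <- res$velocities
  final$step <- res$final_step
  structure(list(frames = res$frames, frame_steps = res$frame_steps,
                 temperatures = res$temperatures,
                 type_index = system$type_index,
                 bead_names = ps$beads[system$type_index],
                 mol_id = system$mol_id, mol_name = system$mol_name,
                 hydrophobic = ps$beads[system$type_index] %in%
                   hydrophobic_beads,
                 L = system$L, dt = cfg$dt, stride = cfg$stride,
                 seed = cfg$seed, units = units, final = final),
            class = "dpd_trajectory")
}

#' @export
print.dpd_trajectory <- function(x, ...) {
  cat(sprintf(
    "<dpd_trajectory> %d frames, %d beads, %d molecules, box %.1f rc\n",
    length(x$frames), length(x$type_index), max(0, x$mol_id), x$L))
  invisible(x)
}

#' Evaluate forces on a configuration
#'
#' One full force evaluation (conservative + bonded, plus the thermostat pair
#' forces when `gamma`/`sigma` are nonzero), exposed for testing and
#' diagnostics.  Pair contributions are accumulated in sorted pair order so
#' cell-list and all-pairs traversal agree bitwise.
#'
#' @param system a `dpd_system` (see [build_system()]).
#' @param gamma,sigma thermostat amplitudes (0 for conservative forces only).
#' @param dt timestep (enters the random-force scaling).
#' @param seed,step noise-stream counters.
#' @param use_cells logical; use the cell-list neighbor search or the
#'   all-pairs loop.
#' @return an `n x 3` force matrix.
#' @export
compute_forces <- function(system, gamma = 0, sigma = 0, dt = 0.01,
                           seed = 0, step = 0, use_cells = TRUE) {
  ps <- system$paramset
  cpp_forces(system$positions, system$velocities, system$type_index - 1L,
             ps$a, ps$R, system$bonds$i - 1L, system$bonds$j - 1L,
             system$bonds$r0, system$bonds$k_b, system$angles$i - 1L,
             system$angles$j - 1L, system$angles$k - 1L,
             system$angles$theta0, system$angles$k_a, system$L, dt, gamma,
             sigma, seed, step, use_cells)
}

#' Kinetic temperature of a velocity set
#'
#' @param vel an `n x 3` velocity matrix (unit bead mass).
#' @return `sum(v^2) / (3 n)` in k_BT.
#' @export
kinetic_temperature <- function(vel) sum(vel^2) / (3 * nrow(vel))

#' Export a trajectory to XYZ text
#'
#' @param traj a `dpd_trajectory`.
#' @param path output file.
#' @param scale length multiplier applied to coordinates (e.g.
#'   `traj$units$rc_A` for Angstrom output).
#' @return `path`, invisibly.
#' @export
export_xyz <- function(traj, path, scale = 1) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(traj$type_index)
  for (fi in seq_along(traj$frames)) {
    writeLines(c(as.character(n),
                 sprintf("frame %d step %d", fi, traj$frame_steps[fi])), con)
    fr <- traj$frames[[fi]] * scale
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$bead_names, fr[, 1],
                       fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' @rdname read_trajectory
#' @param traj a `dpd_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "dpd_trajectory"))
  saveRDS(traj, path)
  invisible(path)
}

#' Read or write a trajectory archive
#'
#' Trajectories are stored as self-describing serialized R archives.
#'
#' @param path archive path.
#' @return a `dpd_trajectory`.
#' @export
read_trajectory <- function(path) {
  traj <- readRDS(path)
  stopifnot(inherits(traj, "dpd_trajectory"))
  traj
}
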