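# Deterministic test-input generators: planted-micelle trajectories whose
# CMC, aggregation number and shape classes are known by construction, and
# scaled-down simulation configurations.

# quasi-uniform packing of n points inside an ellipsoid: grid points sorted
# by ellipsoidal norm, so the planted gyration ratios track the semi-axis
# ratios deterministically (no sampling noise in the planted shape)
pack_in_ellipsoid <- function(n, semi) {
  h <- (4 / 3 * pi * prod(semi) / n)^(1 / 3) * 0.9
  repeat {
    gr <- lapply(semi, function(s) seq(-s, s, by = h))
    pts <- as.matrix(expand.grid(gr[[1]], gr[[2]], gr[[3]]))
    nrm <- sqrt((pts[, 1] / semi[1])^2 + (pts[, 2] / semi[2])^2 +
                  (pts[, 3] / semi[3])^2)
    if (sum(nrm <= 1) >= n) break
    h <- h * 0.85
  }
  keep <- order(nrm, pts[, 1], pts[, 2], pts[, 3])[seq_len(n)]
  pts[keep, , drop = FALSE]
}

#' Generate a planted-micelle trajectory
#'
#' Builds a synthetic surfactant trajectory whose ground truth is known by
#' construction: `sizes[k]` molecules are packed into aggregate `k` (an
#' ellipsoidal blob with the requested semi-axis ratios), `n_monomers`
#' molecules float free, and every frame reproduces the same partition (each
#' aggregate and monomer is rigidly translated by a small per-frame jitter).
#' Each molecule is a hydrophobic tail bead plus a head bead.  The generator
#' verifies that every planted aggregate is connected at the clustering
#' cutoff and that distinct aggregates/monomers stay separated, so the
#' analysis pipeline must recover the planted truth exactly.
#'
#' @param sizes integer vector of planted aggregate sizes (each > 1).
#' @param n_monomers number of free monomers.
#' @param L box edge (r_c).
#' @param n_frames number of frames.
#' @param seed RNG seed; the archive is bitwise reproducible from it.
#' @param ratios length-2 vector `c(A/B, B/C)` of planted semi-axis ratios,
#'   or a list with one entry per aggregate.
#' @param cutoff clustering cutoff the plant must respect (r_c).
#' @param jitter standard deviation of the rigid per-frame translations.
#' @param units a [unit_map()].
#' @return a `dpd_trajectory` with an extra `planted` element: `sizes`,
#'   `n_monomers`, `n_agg` (the exact weight average), `cmc_mM` (the exact
#'   free-monomer concentration), and the per-aggregate `ratios`.
#' @export
make_planted_trajectory <- function(sizes, n_monomers, L = 20, n_frames = 5,
                                    seed = 1, ratios = c(1, 1),
                                    cutoff = 1.0, jitter = 0.05,
                                    units = unit_map()) {
  stopifnot(all(sizes > 1), n_monomers >= 0, L > 0, n_frames >= 1)
  if (!is.list(ratios)) ratios <- rep(list(ratios), length(sizes))
  stopifnot(length(ratios) == length(sizes))
  set.seed(seed)
  head_offset <- 0.4
  n_agg <- length(sizes)

  # per-aggregate point clouds (tail beads), packed at reduced density ~3
  clouds <- vector("list", n_agg)
  extents <- numeric(n_agg)
  for (k in seq_len(n_agg)) {
    rr <- ratios[[k]]
    shape <- c(rr[1] * rr[2], rr[2], 1)
    scale <- (3 * sizes[k] / (4 * pi * 3 * prod(shape)))^(1 / 3)
    semi <- pmax(shape * scale, 0.35)
    pts <- pack_in_ellipsoid(sizes[k], semi)
    adj <- as.matrix(dist(pts)) < cutoff     # no wrapping within a blob
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    if (igraph::count_components(g) != 1L)
      stop("could not build a connected aggregate of size ", sizes[k],
           " at the requested shape")
    clouds[[k]] <- pts
    extents[k] <- max(sqrt(rowSums(pts^2))) + head_offset
  }

  # place aggregate centers and monomers with guaranteed separation
  margin <- cutoff + 0.5
  centers <- matrix(NA_real_, n_agg + n_monomers, 3)
  radius <- c(extents, rep(head_offset, n_monomers))
  for (k in seq_len(nrow(centers))) {
    ok <- FALSE
    for (try in 1:2000) {
      cand <- runif(3, 0, L)
      ok <- TRUE
      if (k > 1L) for (m in seq_len(k - 1L)) {
        d <- cand - centers[m, ]
        d <- d - L * round(d / L)
        if (sqrt(sum(d^2)) < radius[k] + radius[m] + margin) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) stop("planted specification does not fit in a box of edge ", L,
                  " (overcrowded)")
    centers[k, ] <- cand
  }

  # base coordinates: per molecule a tail bead and a head bead
  n_mol <- sum(sizes) + n_monomers
  n_beads <- 2L * n_mol
  base <- matrix(NA_real_, n_beads, 3)
  mol_id <- integer(n_beads); hyd <- logical(n_beads)
  bead_names <- character(n_beads)
  group_of_mol <- integer(n_mol)   # which aggregate/monomer group
  at <- 0L; mol <- 0L
  add_mol <- function(tail_xyz, dirh = NULL) {
    mol <<- mol + 1L
    if (is.null(dirh)) dirh <- rnorm(3)
    nrm <- sqrt(sum(dirh^2))
    dirh <- if (nrm > 1e-9) dirh / nrm else c(0, 0, 1)
    base[at + 1L, ] <<- tail_xyz
    base[at + 2L, ] <<- tail_xyz + head_offset * dirh
    mol_id[at + 1:2] <<- mol
    hyd[at + 1:2] <<- c(TRUE, FALSE)
    bead_names[at + 1:2] <<- c("C2", "OHp")
    at <<- at + 2L
  }
  for (k in seq_len(n_agg)) {
    # heads point radially outward, preserving the planted shape ratios
    for (p in seq_len(sizes[k]))
      add_mol(centers[k, ] + clouds[[k]][p, ], dirh = clouds[[k]][p, ])
    group_of_mol[(mol - sizes[k] + 1L):mol] <- k
  }
  for (m in seq_len(n_monomers)) {
    add_mol(centers[n_agg + m, ])
    group_of_mol[mol] <- n_agg + m
  }

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    shift <- matrix(rnorm(3 * (n_agg + n_monomers), sd = jitter),
                    n_agg + n_monomers, 3)
    if (f == 1L) shift[] <- 0
    fr <- base + shift[group_of_mol[mol_id], ]
    frames[[f]] <- fr %% L
  }

  truth <- list(sizes = as.integer(sizes), n_monomers = as.integer(n_monomers),
                n_agg = sum(sizes^2) / sum(sizes),
                cmc_mM = counts_to_mM(n_monomers, L, units),
                ratios = ratios)
  structure(list(frames = frames, frame_steps = seq_len(n_frames),
                 temperatures = rep(NA_real_, n_frames),
                 type_index = match(bead_names, c("C2", "OHp")),
                 bead_names = bead_names, mol_id = mol_id,
                 mol_name = rep("planted", n_mol), hydrophobic = hyd,
                 L = L, dt = NA_real_, stride = 1L, seed = seed,
                 units = units, planted = truth),
            class = "dpd_trajectory")
}

#' Scaled-down self-assembly simulation configuration
#'
#' A reduced-box variant of the standard self-assembly protocol (density 3,
#' dt 0.01, 5 wt %): suitable for desk-scale runs rather than the full
#' 40 r_c production boxes.
#'
#' @param family surfactant family token (see [build_surfactant()]).
#' @param tail tail carbon count.
#' @param box box edge (r_c).
#' @param steps integration steps.
#' @param seed RNG seed.
#' @param wt_pct surfactant weight percent.
#' @param stride frame stride.
#' @return a [sim_config()] with the `molecule` field set to the topology
#'   name.
#' @export
make_small_sim_config <- function(family, tail, box = 12, steps = 2e5,
                                  seed = 1234, wt_pct = 5, stride = 1000) {
  tp <- build_surfactant(family, tail)   # validates family/tail
  sim_config(L = box, steps = steps, seed = seed, stride = stride,
             wt_pct = wt_pct, molecule = tp$name)
}

#' Serialize or parse a simulation configuration
#'
#' @param cfg a [sim_config()].
#' @param path file path (YAML).
#' @return `write_sim_config`: `path` invisibly; `read_sim_config`: the
#'   parsed [sim_config()].
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 12L)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  doc <- yaml::read_yaml(path)
  do.call(sim_config, doc)
}
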