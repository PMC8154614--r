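# Shared fixtures built in code.

the_library <- default_bead_library()
the_tables <- dpd_tables()

# a minimal hand-built trajectory: `mols` is a list of per-molecule tail-bead
# coordinate matrices (one hydrophobic bead per row); a head bead is not
# needed for clustering-only tests
toy_trajectory <- function(mols, L) {
  pos <- do.call(rbind, mols)
  mol_id <- rep(seq_along(mols), vapply(mols, nrow, integer(1)))
  structure(list(frames = list(pos), frame_steps = 1,
                 temperatures = NA_real_,
                 type_index = rep(1L, nrow(pos)),
                 bead_names = rep("C2", nrow(pos)),
                 mol_id = mol_id, mol_name = rep("toy", length(mols)),
                 hydrophobic = rep(TRUE, nrow(pos)), L = L, dt = NA_real_,
                 stride = 1L, seed = 0L, units = unit_map()),
            class = "dpd_trajectory")
}

# independent union-find over an explicit pair list (oracle for clustering)
oracle_partition <- function(n, pairs) {
  parent <- seq_len(n)
  root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    a <- root(pairs[k, 1]); b <- root(pairs[k, 2])
    if (a != b) parent[b] <- a
  }
  vapply(seq_len(n), root, integer(1))
}

# canonical form of a partition: sorted list of sorted member vectors
canon_partition <- function(membership) {
  unname(lapply(split(seq_along(membership), membership), sort))[
    order(vapply(split(seq_along(membership), membership),
                 function(g) min(g), numeric(1)))]
}

# minimum-image distance matrix (R-side oracle)
oracle_dists <- function(pos, L) {
  n <- nrow(pos)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- pos[i, ] - pos[j, ]
    d <- d - L * round(d / L)
    D[i, j] <- sqrt(sum(d^2))
  }
  D
}

# small all-water system
water_system <- function(L, seed, steps = 0) {
  ps <- build_paramset(the_library, list(), mode = "table")
  cfg <- sim_config(L = L, steps = steps, seed = seed, stride = 100)
  list(sys = build_system(list(), NULL, ps, cfg), cfg = cfg, ps = ps)
}

min_image_r <- function(p1, p2, L) {
  d <- p1 - p2
  d <- d - L * round(d / L)
  sqrt(sum(d^2))
}
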