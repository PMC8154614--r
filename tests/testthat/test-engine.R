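# Hand-built two- and three-bead systems for force checks.
micro_system <- function(pos, beads, L = 10, bonds = NULL, angles = NULL,
                         vel = NULL) {
  ps <- build_paramset(the_library, list(), mode = "table",
                       beads = names(the_library$beads))
  if (is.null(bonds))
    bonds <- data.frame(i = integer(), j = integer(), r0 = numeric(),
                        k_b = numeric())
  if (is.null(angles))
    angles <- data.frame(i = integer(), j = integer(), k = integer(),
                         theta0 = numeric(), k_a = numeric())
  if (is.null(vel)) vel <- matrix(0, nrow(pos), 3)
  structure(list(positions = pos, velocities = vel,
                 type_index = match(beads, ps$beads),
                 mol_id = rep(0L, nrow(pos)), mol_name = character(),
                 bonds = bonds, angles = angles, L = L, paramset = ps,
                 step = 0), class = "dpd_system")
}

# total potential energy evaluated in R (finite-difference oracle)
toy_energy <- function(sys) {
  ps <- sys$paramset; L <- sys$L
  U <- 0
  n <- nrow(sys$positions)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sys$positions[i, ] - sys$positions[j, ]
    d <- d - L * round(d / L); r <- sqrt(sum(d^2))
    R <- ps$R[sys$type_index[i], sys$type_index[j]]
    a <- ps$a[sys$type_index[i], sys$type_index[j]]
    if (r < R) U <- U + 0.5 * a * R * (1 - r / R)^2
  }
  if (nrow(sys$bonds)) for (b in seq_len(nrow(sys$bonds))) {
    d <- sys$positions[sys$bonds$i[b], ] - sys$positions[sys$bonds$j[b], ]
    d <- d - L * round(d / L)
    U <- U + 0.5 * sys$bonds$k_b[b] * (sqrt(sum(d^2)) - sys$bonds$r0[b])^2
  }
  if (nrow(sys$angles)) for (t in seq_len(nrow(sys$angles))) {
    an <- sys$angles[t, ]
    rij <- sys$positions[an$i, ] - sys$positions[an$j, ]
    rkj <- sys$positions[an$k, ] - sys$positions[an$j, ]
    rij <- rij - L * round(rij / L); rkj <- rkj - L * round(rkj / L)
    ct <- sum(rij * rkj) / sqrt(sum(rij^2) * sum(rkj^2))
    U <- U + 0.5 * an$k_a * (acos(max(-1, min(1, ct))) - an$theta0)^2
  }
  U
}

vec_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

num_grad <- function(sys, h = 1e-6) {
  g <- matrix(0, nrow(sys$positions), 3)
  for (i in seq_len(nrow(sys$positions))) for (d in 1:3) {
    sp <- sys; sp$positions[i, d] <- sp$positions[i, d] + h
    sm <- sys; sm$positions[i, d] <- sm$positions[i, d] - h
    g[i, d] <- (toy_energy(sp) - toy_energy(sm)) / (2 * h)
  }
  g
}

test_that("conservative force is soft, truncated, antisymmetric and matches
           the potential gradient", {
  R_ww <- 1.0; a_ww <- 25
  at_r <- function(r) {
    sys <- micro_system(rbind(c(1, 1, 1), c(1 + r, 1, 1)), c("W", "W"))
    compute_forces(sys)
  }
  expect_equal(at_r(R_ww), matrix(0, 2, 3))        # null at the cutoff
  expect_equal(at_r(1.2), matrix(0, 2, 3))         # null beyond
  f <- at_r(1e-9)                                  # soft core: -> a_ij
  expect_equal(abs(f[1, 1]), a_ww, tolerance = 1e-6)
  for (r in seq(0.1, 0.9, by = 0.2)) {
    f <- at_r(r)
    expect_equal(f[1, ], -f[2, ])                  # pairwise antisymmetry
    expect_equal(f[2, 1], a_ww * (1 - r / R_ww), tolerance = 1e-10)
    sys <- micro_system(rbind(c(1, 1, 1), c(1 + r, 1, 1)), c("W", "W"))
    expect_equal(compute_forces(sys), -num_grad(sys), tolerance = 1e-5)
  }
})

test_that("bonded forces vanish at equilibrium and match finite differences", {
  bonds <- data.frame(i = 1, j = 2, r0 = 0.5, k_b = 150)
  sys <- micro_system(rbind(c(4, 4, 4), c(4.5, 4, 4)), c("OHp", "OHp"),
                      bonds = bonds)
  f <- compute_forces(sys)
  # at r = r0 only the nonbonded soft force remains
  nb <- sys; nb$bonds <- nb$bonds[0, ]
  expect_equal(f, compute_forces(nb), tolerance = 1e-12)

  # three-bead bent molecule: forces equal the numerical gradient
  angles <- data.frame(i = 1, j = 2, k = 3, theta0 = pi * 2 / 3, k_a = 5)
  bonds3 <- data.frame(i = c(1, 2), j = c(2, 3), r0 = 0.45, k_b = 150)
  pos <- rbind(c(4, 4, 4), c(4.6, 4, 4), c(5.0, 4.5, 4.1))
  sys3 <- micro_system(pos, c("C2", "C2", "C2"), bonds = bonds3,
                       angles = angles)
  f3 <- compute_forces(sys3)
  expect_equal(f3, -num_grad(sys3), tolerance = 1e-5)
  # net force and torque vanish for the isolated bonded cluster
  expect_equal(colSums(f3), c(0, 0, 0), tolerance = 1e-10)
  tq <- colSums(do.call(rbind, lapply(1:3, function(i)
    vec_cross(pos[i, ], f3[i, ]))))
  expect_equal(tq, c(0, 0, 0), tolerance = 1e-10)

  # angle at theta0 exerts no angular force
  p0 <- rbind(c(4, 4, 4), c(4.45, 4, 4),
              c(4.45 + 0.45 * cos(pi / 3), 4 + 0.45 * sin(pi / 3), 4))
  se <- micro_system(p0, c("C2", "C2", "C2"),
                     angles = data.frame(i = 1, j = 2, k = 3,
                                         theta0 = pi * 2 / 3, k_a = 5))
  no_ang <- se; no_ang$angles <- no_ang$angles[0, ]
  expect_equal(compute_forces(se), compute_forces(no_ang), tolerance = 1e-9)
})

test_that("cell-list and all-pairs force evaluation agree exactly", {
  for (n in c(40, 200)) {
    ws <- water_system(L = 6, seed = n)
    sys <- ws$sys
    sys$positions <- sys$positions[seq_len(n), , drop = FALSE]
    sys$velocities <- matrix(rnorm(3 * n), n, 3)
    sys$type_index <- sys$type_index[seq_len(n)]
    f_cell <- compute_forces(sys, gamma = 4.5, sigma = 3, seed = 9, step = 4,
                             use_cells = TRUE)
    f_all <- compute_forces(sys, gamma = 4.5, sigma = 3, seed = 9, step = 4,
                            use_cells = FALSE)
    expect_identical(f_cell, f_all)
  }
})

test_that("integration is deterministic, momentum conserving, and inert for
           an empty force field", {
  # single stationary bead: nothing moves
  ps <- build_paramset(the_library, list(), mode = "table")
  cfg <- sim_config(L = 4, steps = 50, seed = 1, stride = 10, gamma = 0,
                    sigma = 0)
  sys <- micro_system(rbind(c(2, 2, 2)), "W", L = 4)
  tr <- run_simulation(sys, cfg)
  expect_equal(tr$final$positions, sys$positions)
  expect_equal(tr$final$velocities, sys$velocities)

  ws <- water_system(L = 5, seed = 33, steps = 300)
  tr1 <- run_simulation(ws$sys, ws$cfg)
  tr2 <- run_simulation(ws$sys, ws$cfg)
  expect_identical(tr1$frames, tr2$frames)      # bitwise reproducible
  expect_identical(tr1$final$velocities, tr2$final$velocities)
  # total momentum conserved to accumulation accuracy
  p <- colSums(tr1$final$velocities)
  expect_lt(max(abs(p)), 1e-8 * nrow(ws$sys$positions))
})

test_that("box filling honors the bead density", {
  ws <- water_system(L = 10, seed = 2)
  expect_equal(nrow(ws$sys$positions), 3000)   # rho L^3 at rho = 3
  tp <- build_surfactant("XYL", 8)
  cfg <- sim_config(L = 6, steps = 0, seed = 2)
  ps <- build_paramset(the_library, list(tp), mode = "table")
  sys <- build_system(list(tp), c(XYL8 = 10L), ps, cfg)
  expect_equal(nrow(sys$positions), round(3 * 6^3))
  expect_equal(sum(sys$mol_id > 0), 10L * length(tp$beads))
  # over-filled composition is rejected before integration
  expect_error(build_system(list(tp), c(XYL8 = 200L), ps, cfg),
               "composition")
})

test_that("weight-percent composition round-trips within one molecule", {
  tp <- build_surfactant("MEA", 8)
  for (w in c(4, 5, 6)) {
    cc <- wtpct_to_counts(w, tp, L = 10)
    expect_lt(abs(cc$wt_pct_actual - w),
              100 * tp$molar_mass / (cc$n_beads_total * 12))  # ~1 molecule
    # an exhaustive scan of nearby counts finds no closer composition
    realized <- function(n) {
      nw <- cc$n_beads_total - n * length(tp$beads)
      100 * n * tp$molar_mass / (n * tp$molar_mass + nw * 36.03)
    }
    cand <- pmax(0, cc$n_molecules + (-2:2))
    expect_equal(cc$n_molecules,
                 cand[which.min(abs(realized(cand) - w))])
  }
})

test_that("short thermostatted runs hold the set-point temperature", {
  ws <- water_system(L = 5, seed = 12, steps = 3000)
  tr <- run_simulation(ws$sys, ws$cfg)
  expect_equal(mean(tail(tr$temperatures, 20)), 1.0, tolerance = 0.05)
})
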