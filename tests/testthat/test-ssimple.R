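cfgS <- ssimple_config()

# nested-bisection oracle for a two-species speciation problem: solves the
# simultaneous mass balance x_f = 1/(1 + sum_y K_xy y_f c_y) independently of
# the package's fixed-point solver
bisect <- function(f, lo, hi, tol = 1e-13) {
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}
oracle_two_species <- function(K, c1, c2) {
  x2_given <- function(x1)
    bisect(function(x2) x2 * (1 + K[2, 1] * x1 * c1 + K[2, 2] * x2 * c2) - 1,
           0, 1)
  x1 <- bisect(function(x1) {
    x2 <- x2_given(x1)
    x1 * (1 + K[1, 1] * x1 * c1 + K[1, 2] * x2 * c2) - 1
  }, 0, 1)
  c(x1, x2_given(x1))
}

test_that("association constant is symmetric, positive and anchored at the
           dispersion-only value", {
  # eps = 0 pair: pure van der Waals association, exp(5.6 / RT) at 298 K
  expect_equal(association_constant(0, 0, cfgS),
               exp(5.6 / (8.31446e-3 * 298)))
  expect_equal(association_constant(0, 0, cfgS), 9.5845, tolerance = 1e-4)
  set.seed(1)
  for (k in 1:20) {
    ex <- runif(1, -8, 3); ey <- runif(1, -8, 3)
    expect_identical(association_constant(ex, ey, cfgS),
                     association_constant(ey, ex, cfgS))
    expect_gt(association_constant(ex, ey, cfgS), 0)
  }
  # stronger donor/acceptor complementarity binds tighter
  expect_gt(association_constant(-4.5, 2.8, cfgS),
            association_constant(-0.3, 0.4, cfgS))
  # monotone in the polarity product
  prods <- seq(-20, 5, by = 1)
  K <- vapply(prods, function(p) association_constant(p, 1, cfgS), numeric(1))
  expect_true(all(diff(K) < 0))
})

test_that("speciation satisfies the mass balance and its limits", {
  # dilute limit: a single vanishing species stays free
  ph <- solve_speciation(ssip_phase(2.0, 1e-10, cfgS), cfgS)
  expect_equal(ph$free_fractions, 1, tolerance = 1e-8)

  # two species with a hand-set K matrix against the bisection oracle
  K <- matrix(c(4, 120, 120, 0.5), 2, 2)
  ph <- solve_speciation(ssip_phase(c(1, -1), c(8, 21), cfgS), cfgS, K = K)
  expect_equal(ph$free_fractions, oracle_two_species(K, 8, 21),
               tolerance = 1e-9)

  # mass conservation: free + 1:1-bound recovers every total concentration
  for (bead in c("W", "ES", "AM3")) {
    ph <- solve_speciation(bead_phase(the_library$beads[[bead]], cfgS), cfgS)
    free <- ph$free_fractions * ph$conc
    bound <- as.numeric(ph$K %*% free) * free
    expect_equal(free + bound, ph$conc, tolerance = 1e-8, label = bead)
  }
})

test_that("speciation residual is tiny for every packaged bead liquid", {
  for (bead in names(the_library$beads)) {
    ph <- solve_speciation(bead_phase(the_library$beads[[bead]], cfgS), cfgS)
    res <- max(abs(ph$free_fractions -
                     1 / (1 + as.numeric(ph$K %*%
                                           (ph$free_fractions * ph$conc)))))
    expect_lt(res, 1e-8)
    expect_true(all(ph$free_fractions > 0 & ph$free_fractions <= 1))
  }
})

test_that("free fractions respond monotonically to concentration and K", {
  base <- solve_speciation(ssip_phase(c(2, -2), c(10, 10), cfgS), cfgS)
  denser <- solve_speciation(ssip_phase(c(2, -2), c(10, 30), cfgS), cfgS)
  expect_lt(denser$free_fractions[1], base$free_fractions[1])
  K <- base$K; K[1, 2] <- K[2, 1] <- K[1, 2] * 10
  tighter <- solve_speciation(ssip_phase(c(2, -2), c(10, 10), cfgS), cfgS,
                              K = K)
  expect_lt(tighter$free_fractions[1], base$free_fractions[1])
})

test_that("solvation free energy has the reference-state and monotonicity
           properties", {
  # all-K-unity phase solvates any probe with exactly zero free energy
  ph <- ssip_phase(c(1.5, -0.7), c(40, 60), cfgS)
  ph <- solve_speciation(ph, cfgS, K = matrix(1, 2, 2))
  expect_equal(solvation_free_energy(0.3, ph, cfgS, K_probe = c(1, 1)), 0,
               tolerance = 1e-10)

  # closed-form confinement term equals an explicit K = 1 speciation solve
  f_closed <- dpdchem:::confinement_free_fraction(ph$theta, cfgS)
  expect_equal(ph$free_fractions, rep(f_closed, 2), tolerance = 1e-10)

  # stronger donors are solvated more favorably by an acceptor phase
  acc <- solve_speciation(ssip_phase(-3, 25, cfgS), cfgS)
  g <- solvation_free_energy(seq(0.5, 4, by = 0.5), acc, cfgS)
  expect_true(all(diff(g) < 0))
  expect_error(solvation_free_energy(1, ssip_phase(1, 1, cfgS), cfgS),
               "not solved")
})

test_that("transfer free energies vanish on the diagonal and respect SSIP
           permutation", {
  expect_equal(transfer_free_energy("W", "W", the_library, cfgS)$dG, 0,
               tolerance = 1e-8)
  for (bead in names(the_library$beads))
    expect_equal(transfer_free_energy(bead, bead, the_library, cfgS)$dG, 0,
                 tolerance = 1e-8, label = bead)
  # permuting a bead's SSIP list does not change transfer energies
  b <- the_library$beads$ES
  set.seed(7)
  bp <- dpd_bead("ESperm", sample(b$ssips), b$volume, b$liquid_conc,
                 b$a_self, b$R_self)
  expect_equal(transfer_free_energy(bp, "W", the_library, cfgS)$dG,
               transfer_free_energy("ES", "W", the_library, cfgS)$dG)
})

test_that("the tertiary amide transfers into water more favorably than the
           secondary amide", {
  g <- vapply(c(AM2 = "AM2", AM3p = "AM3p"), function(b)
    transfer_free_energy(b, "W", the_library, cfgS)$dG, numeric(1))
  expect_lt(g[["AM3p"]], g[["AM2"]])
})

test_that("a two-SSIP toy bead matches an exhaustive oracle computation", {
  cfg <- cfgS
  solv <- dpd_bead("S", c(1.0, -1.0), 40, 20, 20, 1)   # solvent bead
  solu <- dpd_bead("U", c(2.0, -3.0), 40, 10, 20, 1)   # solute bead
  lib <- dpd_library(list(solv, solu))
  got <- transfer_free_energy("U", "S", lib, cfg)

  # oracle: solvent speciation by nested bisection, then the dilute-probe
  # free fractions and the closed-form confinement reference
  K <- outer(c(1, -1), c(1, -1),
             function(x, y) exp(-(x * y + cfg$E_vdW) / cfg$RT))
  xf_solv <- oracle_two_species(K, 20, 20)
  free_conc <- xf_solv * c(20, 20)
  conf <- function(ctot) (-1 + sqrt(1 + 4 * ctot)) / (2 * ctot)
  gs_in_S <- vapply(c(2, -3), function(e) {
    Kp <- exp(-(e * c(1, -1) + cfg$E_vdW) / cfg$RT)
    xf <- 1 / (1 + sum(Kp * free_conc))
    cfg$RT * (log(xf) - log(conf(40)))
  }, numeric(1))
  # pure solute liquid: symmetric two-species problem
  Ku <- outer(c(2, -3), c(2, -3),
              function(x, y) exp(-(x * y + cfg$E_vdW) / cfg$RT))
  xf_solu <- oracle_two_species(Ku, 10, 10)
  gs_in_U <- cfg$RT * (log(xf_solu) - log(conf(20)))
  expect_equal(got$dG, sum(gs_in_S - gs_in_U), tolerance = 1e-8)
})
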