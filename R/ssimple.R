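# SSIP-level liquid speciation and solvation.
#
# A liquid is modelled as a mixture of surface site interaction points
# (SSIPs).  Pairs of SSIPs associate 1:1 with an equilibrium constant set by
# their polarity parameters; solving the pairing equilibria gives the free
# fraction of every SSIP species, from which solvation and bead transfer free
# energies follow.

#' SSIMPLE model configuration
#'
#' @param E_vdW van der Waals SSIP-SSIP interaction energy (kJ/mol; negative).
#' @param c_max maximum possible SSIP concentration (mol/L).
#' @param temperature temperature in K (only through RT; the SSIP polarities
#'   themselves are room-temperature values).
#' @param tol convergence tolerance on the speciation mass-balance residual.
#' @param max_iter maximum fixed-point iterations.
#' @param relax damping factor of the fixed-point update (0 < relax <= 1).
#' @return an object of class `ssimple_config`.
#' @export
ssimple_config <- function(E_vdW = -5.6, c_max = 300, temperature = 298,
                           tol = 1e-12, max_iter = 10000L, relax = 0.5) {
  stopifnot(E_vdW < 0, c_max > 0, temperature > 0, tol > 0, max_iter >= 1,
            relax > 0, relax <= 1)
  structure(list(E_vdW = E_vdW, c_max = c_max, temperature = temperature,
                 RT = 8.31446e-3 * temperature, tol = tol,
                 max_iter = as.integer(max_iter), relax = relax),
            class = "ssimple_config")
}

#' SSIP-SSIP association constant
#'
#' Equilibrium constant (1 M reference state) for the 1:1 contact between two
#' SSIPs of polarity `eps_x` and `eps_y`:
#' `K = exp(-(eps_x * eps_y + E_vdW) / RT)`.
#' The electrostatic term `eps_x * eps_y` is negative (favorable) for
#' complementary donor/acceptor pairs; `E_vdW` is the polarity-independent
#' dispersion contribution common to every contact.
#'
#' @param eps_x,eps_y SSIP polarity parameters.
#' @param cfg an [ssimple_config()].
#' @return the association constant (dimensionless with the 1 M reference;
#'   used as M^-1 in the mass balance).  Vectorized over `eps_x`/`eps_y`.
#' @export
association_constant <- function(eps_x, eps_y, cfg = ssimple_config()) {
  exp(-(eps_x * eps_y + cfg$E_vdW) / cfg$RT)
}

#' Construct an SSIP phase
#'
#' A phase is a multiset of SSIP species, each with a polarity `eps` and a
#' total concentration.  Species with equal polarity may be merged; the
#' speciation is invariant under such merging.
#'
#' @param eps numeric vector of SSIP polarities.
#' @param conc matching vector of total concentrations (mol/L, >= 0).
#' @param cfg an [ssimple_config()] (used for the occupancy bound).
#' @return an object of class `ssip_phase` with fields `eps`, `conc`,
#'   `theta` (fractional occupancy) and, after [solve_speciation()],
#'   `free_fractions`.
#' @export
ssip_phase <- function(eps, conc, cfg = ssimple_config()) {
  stopifnot(length(eps) == length(conc), length(eps) >= 1L,
            all(is.finite(eps)), all(is.finite(conc)), all(conc >= 0))
  theta <- sum(conc) / cfg$c_max
  if (theta > 1)
    stop("total SSIP concentration ", sum(conc), " M exceeds c_max = ",
         cfg$c_max, " M")
  structure(list(eps = as.numeric(eps), conc = as.numeric(conc),
                 theta = theta, free_fractions = NULL),
            class = "ssip_phase")
}

#' The SSIP phase of a pure bead liquid
#'
#' Each SSIP of the bead appears at the bead-liquid concentration; SSIPs of
#' equal polarity are merged into one species.
#'
#' @param bead a [dpd_bead()].
#' @param cfg an [ssimple_config()].
#' @return an [ssip_phase()].
#' @export
bead_phase <- function(bead, cfg = ssimple_config()) {
  stopifnot(inherits(bead, "dpd_bead"))
  tab <- table(bead$ssips)
  eps <- as.numeric(names(tab))
  ssip_phase(eps, as.numeric(tab) * bead$liquid_conc, cfg)
}

#' Solve the SSIP pairing equilibria of a phase
#'
#' Finds the free fraction `x_f` of every species satisfying the simultaneous
#' 1:1 mass balance `x_f = 1 / (1 + sum_y K_xy * y_f * c_y)` by damped
#' fixed-point iteration, falling back on a bisection of the equivalent
#' scalar problem when only one species is present.
#'
#' @param phase an [ssip_phase()].
#' @param cfg an [ssimple_config()].
#' @param K optional association-constant matrix overriding
#'   [association_constant()] (test hook; must be symmetric, length(eps)^2).
#' @return the phase with `free_fractions` filled in and attribute-free
#'   residual below `cfg$tol`.
#' @export
solve_speciation <- function(phase, cfg = ssimple_config(), K = NULL) {
  stopifnot(inherits(phase, "ssip_phase"))
  n <- length(phase$eps)
  if (is.null(K)) K <- outer(phase$eps, phase$eps, association_constant, cfg)
  stopifnot(is.matrix(K), all(dim(K) == n), all(K > 0))
  cc <- phase$conc
  relax <- cfg$relax
  res <- Inf
  # damped fixed point; on stagnation retry with stronger damping (the map
  # is a contraction for physical K but can oscillate at high occupancy)
  for (attempt in 1:4) {
    xf <- rep(1, n)
    for (it in seq_len(cfg$max_iter)) {
      xf_new <- 1 / (1 + as.numeric(K %*% (xf * cc)))
      xf <- (1 - relax) * xf + relax * xf_new
      res <- max(abs(xf - 1 / (1 + as.numeric(K %*% (xf * cc)))))
      if (res < cfg$tol) {
        phase$free_fractions <- xf
        phase$K <- K
        return(phase)
      }
    }
    relax <- relax / 4
  }
  stop("speciation did not converge after ", cfg$max_iter,
       " iterations (residual ", signif(res, 3), ")")
}

# Free fraction in the interaction-free reference phase: all association
# constants unity at total SSIP concentration c_tot.  Every species is then
# equivalent and the mass balance reduces to c_tot*f^2 + f - 1 = 0.
confinement_free_fraction <- function(theta, cfg = ssimple_config()) {
  c_tot <- theta * cfg$c_max
  if (c_tot <= 0) return(1)
  (-1 + sqrt(1 + 4 * c_tot)) / (2 * c_tot)
}

#' Solvation free energy of one SSIP in a solved phase
#'
#' `dG_x = RT * (ln x_f - ln x_f_conf)`: the first term is the chemical
#' potential lowering from pairing with the phase's SSIPs (through the solved
#' free fraction of a dilute probe SSIP `x`), the second the confinement
#' reference obtained with every association constant set to one at the same
#' fractional occupancy theta, so that a phase with only dispersion-free
#' unit-constant contacts solvates every SSIP with zero free energy.
#'
#' @param eps_x polarity of the probe SSIP (vectorized).
#' @param phase a solved [ssip_phase()] (see [solve_speciation()]).
#' @param cfg an [ssimple_config()].
#' @param K_probe optional vector/matrix of probe-phase association constants
#'   overriding [association_constant()] (rows = probes, cols = species).
#' @return solvation free energy in kJ/mol (vector over `eps_x`).
#' @export
solvation_free_energy <- function(eps_x, phase, cfg = ssimple_config(),
                                  K_probe = NULL) {
  stopifnot(inherits(phase, "ssip_phase"))
  if (is.null(phase$free_fractions))
    stop("phase is not solved; call solve_speciation() first")
  if (is.null(K_probe))
    K_probe <- outer(eps_x, phase$eps, association_constant, cfg)
  K_probe <- matrix(K_probe, nrow = length(eps_x))
  free_conc <- phase$free_fractions * phase$conc
  xf <- 1 / (1 + as.numeric(K_probe %*% free_conc))
  f_conf <- confinement_free_fraction(phase$theta, cfg)
  cfg$RT * (log(xf) - log(f_conf))
}

#' Bead transfer free energy between pure bead liquids
#'
#' Free-energy change for moving bead `i` from its own pure liquid to a
#' dilute solution in the pure liquid of bead `j`, obtained by summing the
#' per-SSIP solvation free-energy differences over bead `i`'s SSIPs.  The
#' solvent phase is solved alone; the dilute solute probes the solvent's
#' free SSIP concentrations and confinement occupancy.
#'
#' @param bead_i,bead_j bead names or [dpd_bead()] objects.
#' @param library a [dpd_library()] (used when beads are given by name).
#' @param cfg an [ssimple_config()].
#' @return a list of class `dpd_transfer` with elements `dG` (kJ/mol),
#'   `per_ssip` (data frame with the solute SSIPs and their solvation free
#'   energies in both liquids), and the bead names.
#' @export
transfer_free_energy <- function(bead_i, bead_j,
                                 library = default_bead_library(),
                                 cfg = ssimple_config()) {
  resolve <- function(b) {
    if (inherits(b, "dpd_bead")) return(b)
    if (!b %in% names(library$beads)) stop("unknown bead: ", b)
    library$beads[[b]]
  }
  bi <- resolve(bead_i); bj <- resolve(bead_j)
  if (is.null(bi$liquid_conc) || is.null(bj$liquid_conc))
    stop("both beads need a reference-liquid concentration")
  phase_i <- solve_speciation(bead_phase(bi, cfg), cfg)
  phase_j <- solve_speciation(bead_phase(bj, cfg), cfg)
  g_in_i <- solvation_free_energy(bi$ssips, phase_i, cfg)
  g_in_j <- solvation_free_energy(bi$ssips, phase_j, cfg)
  structure(list(bead_i = bi$name, bead_j = bj$name,
                 dG = sum(g_in_j - g_in_i),
                 per_ssip = data.frame(eps = bi$ssips, dG_pure_i = g_in_i,
                                       dG_dilute_j = g_in_j)),
            class = "dpd_transfer")
}

#' @export
print.dpd_transfer <- function(x, ...) {
  cat(sprintf("<dpd_transfer> dG(%s -> dilute in %s) = %.3f kJ/mol\n",
              x$bead_i, x$bead_j, x$dG))
  print(x$per_ssip, row.names = FALSE)
  invisible(x)
}
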