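# Reduced-unit to laboratory-unit conversions.

AVOGADRO <- 6.02214076e23

#' Reduced-unit conversion map
#'
#' @param rc_A physical length of the DPD unit r_c in Angstrom.
#' @param waters_per_W number of water molecules represented by one W bead.
#' @param water_molar_mass molar mass of water (g/mol).
#' @return an object of class `unit_map`.
#' @export
unit_map <- function(rc_A = 5.64, waters_per_W = 2,
                     water_molar_mass = 18.015) {
  stopifnot(rc_A > 0, waters_per_W > 0)
  structure(list(rc_A = rc_A, waters_per_W = waters_per_W,
                 water_molar_mass = water_molar_mass,
                 w_bead_mass = waters_per_W * water_molar_mass),
            class = "unit_map")
}

#' Box volume in litres
#'
#' @param L box edge in r_c.
#' @param units a [unit_map()].
#' @return volume in litres (1 A^3 = 1e-27 L).
#' @export
box_volume_litres <- function(L, units = unit_map()) {
  (L * units$rc_A)^3 * 1e-27
}

#' Convert a molecule count in a periodic box to millimolar
#'
#' @param n number of molecules.
#' @param L box edge in r_c.
#' @param units a [unit_map()].
#' @return concentration in mM.
#' @export
counts_to_mM <- function(n, L, units = unit_map()) {
  1000 * n / (AVOGADRO * box_volume_litres(L, units))
}

#' Convert a weight-percent composition to a molecule count
#'
#' For a box of `round(rho * L^3)` beads filled with one surfactant species
#' plus water, returns the number of surfactant molecules whose mass
#' fraction is closest to `wt_pct` percent (remaining beads are W).
#'
#' @param wt_pct surfactant weight percent (0-100).
#' @param topology a [dpd_topology()] (its `molar_mass` and bead count are
#'   used).
#' @param L box edge in r_c.
#' @param rho reduced bead density.
#' @param units a [unit_map()].
#' @return a list with `n_molecules`, `n_water_beads`, `n_beads_total`, and
#'   the realized weight percent `wt_pct_actual`.
#' @export
wtpct_to_counts <- function(wt_pct, topology, L, rho = 3,
                            units = unit_map()) {
  stopifnot(wt_pct >= 0, wt_pct < 100, inherits(topology, "dpd_topology"))
  w <- wt_pct / 100
  n_total <- round(rho * L^3)
  n_per_mol <- length(topology$beads)
  m_s <- topology$molar_mass; m_w <- units$w_bead_mass
  n_s <- round(w * n_total * m_w / (m_s * (1 - w) + w * n_per_mol * m_w))
  n_w <- n_total - n_s * n_per_mol
  if (n_w < 0) stop("composition does not fit: ", n_s, " molecules of ",
                    topology$name, " need more than ", n_total, " beads")
  realized <- 100 * n_s * m_s / (n_s * m_s + n_w * m_w)
  list(n_molecules = n_s, n_water_beads = n_w, n_beads_total = n_total,
       wt_pct_actual = realized)
}
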