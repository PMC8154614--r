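# Conversion of transfer free energies and bead geometry into the full DPD
# parameter set: mismatch terms Delta-a, repulsions a_ij, contact radii R_ij,
# and calibrated bond rest lengths r0.

#' DPD parameterization configuration
#'
#' @param c_P matching constant converting thermal transfer free energies
#'   into repulsion-parameter mismatch (appropriate for bead density 3).
#' @param v_r reference (water bead) volume in cubic Angstrom.
#' @param k_b harmonic bond spring constant (k_BT).
#' @param k_a harmonic 1-3 angle spring constant (k_BT).
#' @param rho reduced bead density (r_c^-3).
#' @param RT thermal energy in kJ/mol at the working temperature.
#' @return an object of class `param_config`.
#' @export
param_config <- function(c_P = 0.291, v_r = 42.0, k_b = 150, k_a = 5,
                         rho = 3, RT = 8.31446e-3 * 298) {
  stopifnot(c_P > 0, v_r > 0, k_b > 0, k_a > 0, rho > 0, RT > 0)
  structure(list(c_P = c_P, v_r = v_r, k_b = k_b, k_a = k_a, rho = rho,
                 RT = RT), class = "param_config")
}

#' Repulsion mismatch from transfer free energies
#'
#' Converts the pair of bead transfer free energies into the mismatch term of
#' the repulsion combination rule:
#' `Delta_a = ((v_r/v_i) dG_ij + (v_r/v_j) dG_ji) / (2 c_P RT)`.
#' Each transfer free energy is normalized by the bead's volume relative to
#' the water reference volume, averaged over the two transfer directions,
#' expressed in thermal units, and scaled by the matching constant into DPD
#' repulsion units.
#'
#' @param bead_i,bead_j [dpd_bead()] objects (volumes are taken from them).
#' @param dG_ij transfer free energy of bead i from its pure liquid into
#'   dilute solution in liquid j (kJ/mol); `dG_ji` vice versa.
#' @param dG_ji see `dG_ij`.
#' @param cfg a [param_config()].
#' @return the mismatch Delta-a in k_BT.
#' @export
delta_a <- function(bead_i, bead_j, dG_ij, dG_ji, cfg = param_config()) {
  stopifnot(inherits(bead_i, "dpd_bead"), inherits(bead_j, "dpd_bead"))
  ((cfg$v_r / bead_i$volume) * dG_ij + (cfg$v_r / bead_j$volume) * dG_ji) /
    (2 * cfg$c_P * cfg$RT)
}

#' Pairwise repulsion from self terms and mismatch
#'
#' Combination rule `a_ij = (a_ii + a_jj)/2 + Delta_a_ij`.
#'
#' @param a_ii,a_jj self-repulsion parameters (k_BT).
#' @param delta mismatch term (k_BT).
#' @return `a_ij` in k_BT.  Warns (but still returns) if the result is
#'   non-positive, since the soft conservative force then vanishes.
#' @export
repulsion <- function(a_ii, a_jj, delta) {
  stopifnot(all(a_ii > 0), all(a_jj > 0))
  a <- (a_ii + a_jj) / 2 + delta
  if (any(a <= 0)) warning("non-positive repulsion parameter a_ij = ",
                           paste(signif(a[a <= 0], 4), collapse = ", "))
  a
}

#' Pairwise contact radius
#'
#' Arithmetic mixing `R_ij = (R_ii + R_jj)/2`, the rule reproduced by the
#' full packaged contact-radius table.
#'
#' @param R_ii,R_jj self contact radii (r_c).
#' @return `R_ij` in r_c.
#' @export
contact_radius <- function(R_ii, R_jj) (R_ii + R_jj) / 2

#' Calibrated harmonic bond rest length
#'
#' Between bonded beads the soft nonbonded repulsion adds to the harmonic
#' spring, so the energy minimum sits beyond the spring rest length.  Setting
#' the derivative of the combined potential to zero at the desired bond
#' length gives
#' `r0 = r_target - (a_ij / k_b) * (1 - r_target / R_ij)`
#' for `r_target < R_ij`; beyond the repulsion range the nonbonded force is
#' null and `r0 = r_target`.
#'
#' @param r_target desired equilibrium bond length (r_c).
#' @param a_ij repulsion parameter of the bonded pair (k_BT).
#' @param R_ij contact radius of the bonded pair (r_c).
#' @param k_b bond spring constant (k_BT).
#' @return the rest length `r0` (r_c).  Errors if the calibration would be
#'   unphysical (`r0 <= 0`).
#' @export
bond_r0 <- function(r_target, a_ij, R_ij, k_b = 150) {
  stopifnot(all(r_target > 0), all(k_b > 0), all(R_ij > 0))
  r0 <- ifelse(r_target < R_ij,
               r_target - (a_ij / k_b) * (1 - r_target / R_ij),
               r_target)
  if (any(r0 <= 0))
    stop("bond calibration gives non-positive r0 (r_target = ",
         paste(r_target[r0 <= 0], collapse = ", "), ")")
  r0
}

#' Packaged pairwise parameter tables
#'
#' Returns the packaged 14-bead matrices: contact radii `R` (r_c), repulsion
#' parameters `a` (k_BT) and mismatch terms `delta_a` (k_BT), all symmetric
#' with rows/columns in the canonical bead order.
#'
#' @return a list with matrices `R`, `a`, `delta_a`.
#' @export
dpd_tables <- function() {
  rd <- function(f) as.matrix(read.delim(
    system.file("extdata", f, package = "dpdchem", mustWork = TRUE),
    row.names = 1, check.names = FALSE))
  list(R = rd("contact_radii.tsv"), a = rd("repulsion.tsv"),
       delta_a = rd("delta_a.tsv"))
}

#' Build the complete DPD parameter set for a molecule set
#'
#' Assembles symmetric `a`, `delta_a` and `R` matrices over every bead used
#' by the given molecules (plus water), and calibrates every bond's rest
#' length `r0` from its pair's `a_ij`/`R_ij` via [bond_r0()].
#'
#' @param library a [dpd_library()].
#' @param molecules list of [dpd_topology()] objects.
#' @param cfg a [param_config()].
#' @param mode `"table"` uses the packaged pairwise tables (the published
#'   values for the 14 packaged beads); `"computed"` derives `delta_a` from
#'   the SSIP pipeline ([transfer_free_energy()] then [delta_a()]) and
#'   combines with the library's self terms.
#' @param ssimple_cfg an [ssimple_config()] (computed mode only).
#' @param beads optional character vector of bead names to parameterize;
#'   defaults to the beads used by `molecules` plus water.
#' @return an object of class `dpd_paramset`: bead names, matrices `a`,
#'   `delta_a`, `R`, data frame `bonds` (columns `bead_i`, `bead_j`,
#'   `r_target`, `r0`) pooled over molecules, spring constants, and `mode`.
#' @export
build_paramset <- function(library, molecules, cfg = param_config(),
                           mode = c("table", "computed"),
                           ssimple_cfg = ssimple_config(), beads = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(library, "dpd_library"))
  if (inherits(molecules, "dpd_topology")) molecules <- list(molecules)
  used <- if (is.null(beads))
    unique(c("W", unlist(lapply(molecules, `[[`, "beads"))))
  else unique(c("W", beads))
  missing <- setdiff(used, names(library$beads))
  if (length(missing)) stop("beads not in library: ",
                            paste(missing, collapse = ", "))
  n <- length(used)
  if (mode == "table") {
    tabs <- dpd_tables()
    absent <- setdiff(used, rownames(tabs$a))
    if (length(absent))
      stop("no packaged table entries for bead(s): ",
           paste(absent, collapse = ", "), "; use mode = \"computed\"")
    a  <- tabs$a[used, used, drop = FALSE]
    da <- tabs$delta_a[used, used, drop = FALSE]
    R  <- tabs$R[used, used, drop = FALSE]
  } else {
    beads <- library$beads[used]
    a_self <- vapply(beads, `[[`, numeric(1), "a_self")
    R_self <- vapply(beads, `[[`, numeric(1), "R_self")
    da <- matrix(0, n, n, dimnames = list(used, used))
    for (p in seq_len(n)) for (q in seq_len(n)) {
      if (q <= p) next
      g_pq <- transfer_free_energy(beads[[p]], beads[[q]], library,
                                   ssimple_cfg)$dG
      g_qp <- transfer_free_energy(beads[[q]], beads[[p]], library,
                                   ssimple_cfg)$dG
      da[p, q] <- da[q, p] <- delta_a(beads[[p]], beads[[q]], g_pq, g_qp, cfg)
    }
    a <- outer(a_self, a_self, function(x, y) (x + y) / 2) + da
    R <- outer(R_self, R_self, contact_radius)
    dimnames(a) <- dimnames(R) <- list(used, used)
  }
  bonds <- NULL
  for (tp in molecules) {
    if (nrow(tp$bonds) == 0L) next
    bi <- tp$beads[tp$bonds$i]; bj <- tp$beads[tp$bonds$j]
    bonds <- rbind(bonds, data.frame(bead_i = bi, bead_j = bj,
                                     r_target = tp$bonds$r_target))
  }
  if (!is.null(bonds)) {
    bonds <- unique(bonds)
    idx <- cbind(match(bonds$bead_i, used), match(bonds$bead_j, used))
    bonds$r0 <- bond_r0(bonds$r_target, a[idx], R[idx], cfg$k_b)
    rownames(bonds) <- NULL
  } else {
    bonds <- data.frame(bead_i = character(), bead_j = character(),
                        r_target = numeric(), r0 = numeric())
  }
  structure(list(beads = used, a = a, delta_a = da, R = R, bonds = bonds,
                 k_b = cfg$k_b, k_a = cfg$k_a, mode = mode),
            class = "dpd_paramset")
}

#' @export
print.dpd_paramset <- function(x, ...) {
  cat(sprintf("<dpd_paramset> %d beads (%s), mode = %s, %d distinct bonds\n",
              length(x$beads), paste(x$beads, collapse = ", "), x$mode,
              nrow(x$bonds)))
  invisible(x)
}
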