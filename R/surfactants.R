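# Coarse-grained surfactant topologies.
#
# Head-group bead assignments follow the package's coarse-graining of each
# family (ester heads built on ES, amide heads on AM2/AM3p/AM3, sugar heads
# on ACp + OHp rings).  Linker-bond target lengths come from the packaged
# atomistically derived bond table where a family-specific value exists;
# remaining bonds fall back on documented defaults (alkyl C2-C2 bonds use the
# ethylene-ethylene equilibrium distance 0.445 r_c).

# Approximate fragment molar masses (g/mol) used to convert weight-percent
# compositions into molecule counts.  W counts two waters.
bead_masses <- c(W = 36.03, T1 = 15.03, T2 = 29.06, C2 = 28.05, C2p = 28.05,
                 OH1 = 31.03, OHp = 30.03, OH2 = 45.06, EO = 44.05,
                 ACp = 46.03, ES = 72.06, AM2 = 71.08, AM3p = 84.10,
                 AM3 = 85.11)

# Default bond target lengths (r_c) for bonds without a packaged value.
default_rtarget <- function(bi, bj) {
  key <- paste(sort(c(bi, bj)), collapse = "-")
  alkyl <- c("C2-C2" = 0.445, "C2-T2" = 0.445, "C2-C2p" = 0.445,
             "C2p-C2p" = 0.445, "C2p-T2" = 0.445, "C2-T1" = 0.395,
             "C2p-T1" = 0.395)
  other <- c("EO-EO" = 0.55, "EO-OH2" = 0.55, "ACp-OHp" = 0.50,
             "ACp-C2" = 0.55, "OHp-OHp" = 0.45, "AM3p-OHp" = 0.68)
  if (key %in% names(alkyl)) return(unname(alkyl[key]))
  if (key %in% names(other)) return(unname(other[key]))
  stop("no packaged or default bond length for pair ", key)
}

#' Packaged atomistic bond-length targets
#'
#' Returns the packaged table of per-family bond parameters: the target bond
#' length `r_target` obtained from molecular-mechanics structures and the
#' published calibrated rest length `r0` (both in r_c).
#'
#' @return a data frame with columns `family`, `bead_i`, `bead_j`,
#'   `r_target`, `r0`.
#' @export
bond_table <- function() {
  read.delim(system.file("extdata", "bond_table.tsv", package = "dpdchem",
                         mustWork = TRUE), stringsAsFactors = FALSE)
}

lookup_rtarget <- function(family, bi, bj, tab = bond_table()) {
  pair <- (tab$bead_i == bi & tab$bead_j == bj) |
          (tab$bead_i == bj & tab$bead_j == bi)
  hit <- tab[pair & tab$family == family, , drop = FALSE]
  if (nrow(hit)) return(hit$r_target[1L])
  # fall back on the same bead pair parameterized in a sibling family
  hit <- tab[pair, , drop = FALSE]
  if (nrow(hit)) return(hit$r_target[1L])
  default_rtarget(bi, bj)
}

surfactant_families <- c("GLY", "XYL", "MEA", "DEA", "TEDA", "MEGA", "HEGA",
                         "GLUCO", "MALTO", "CYGLU", "CYMAL")

# Head definitions: anchor bead plus a linear chain of head beads hanging off
# the anchor (sugar heads are assembled separately as rings).
head_chains <- list(
  GLY  = list(anchor = "ES",   chain = c("OHp", "OHp")),
  XYL  = list(anchor = "ES",   chain = c("OHp", "OHp", "OHp", "OHp")),
  MEA  = list(anchor = "AM2",  chain = "OH1"),
  DEA  = list(anchor = "AM3p", chain = "OH1", extra = "OH1"),
  TEDA = list(anchor = "AM2",  chain = c("EO", "EO", "OH2")),
  MEGA = list(anchor = "AM3",  chain = c("OHp", "OHp", "OHp", "OHp", "OHp")),
  HEGA = list(anchor = "AM3p", chain = c("OHp", "OHp", "OHp", "OHp", "OHp"),
              extra = "OH1"))

# Alkyl carbons absorbed into the head anchor bead (the carbonyl carbon plus
# the alpha carbon for ester/amide heads; none for glycosidic sugar heads).
absorbed_carbons <- c(GLY = 2, XYL = 2, MEA = 2, DEA = 2, TEDA = 2, MEGA = 2,
                      HEGA = 2, GLUCO = 0, MALTO = 0, CYGLU = 0, CYMAL = 0)

tail_beads <- function(n_carbons, absorbed) {
  rem <- n_carbons - absorbed
  if (rem < 2 || rem %% 2 != 0)
    stop("unsupported tail length: ", n_carbons, " carbons (",
         rem, " after the head bead; need an even count >= 2)")
  c(rep("C2", (rem - 2) / 2), "T2")
}

#' Build a coarse-grained surfactant topology
#'
#' Assembles the bead sequence, bonds and 1-3 angles for one of the packaged
#' surfactant families at a given hydrophobic tail length.  Bond targets are
#' taken from the packaged atomistic bond table where available and from
#' documented defaults otherwise; angles along linear chains default to the
#' extended trans geometry (theta0 = 180 degrees).
#'
#' @param family one of `r paste0('\x60', surfactant_families, '\x60', collapse = ", ")`.
#' @param tail_carbons number of carbons in the hydrophobic tail (8, 10 or 12
#'   for the linear families; 4 for the cyclohexyl-tailed CYGLU/CYMAL, whose
#'   tail ends in a cyclohexyl group).
#' @return a [dpd_topology()] named `<family><tail_carbons>`.
#' @examples
#' build_surfactant("MEGA", 8)
#' @export
build_surfactant <- function(family, tail_carbons) {
  family <- match.arg(family, surfactant_families)
  cyclo <- family %in% c("CYGLU", "CYMAL")
  if (cyclo) {
    if (tail_carbons != 4)
      stop("family ", family, " is packaged with a 4-carbon linker tail")
  } else if (!tail_carbons %in% c(8L, 10L, 12L)) {
    stop("unsupported tail length for ", family,
         ": choose 8, 10 or 12 carbons")
  }
  tab <- bond_table()
  beads <- character(); bonds <- NULL; angles <- NULL
  add_bead <- function(b) { beads[[length(beads) + 1L]] <<- b; length(beads) }
  add_bond <- function(i, j, rt = NULL) {
    if (is.null(rt)) rt <- lookup_rtarget(family, beads[i], beads[j], tab)
    bonds <<- rbind(bonds, data.frame(i = i, j = j, r_target = rt))
  }
  add_angles_along <- function(path) {
    if (length(path) < 3L) return(invisible())
    for (t in seq_len(length(path) - 2L))
      angles <<- rbind(angles, data.frame(i = path[t], j = path[t + 1L],
                                          k = path[t + 2L], theta0 = 180))
  }

  # hydrophobic tail, terminal bead first
  tail <- if (cyclo) c(rep("C2p", 3L), rep("C2", tail_carbons / 2L))
          else rev(tail_beads(tail_carbons, absorbed_carbons[[family]]))
  idx_tail <- vapply(tail, add_bead, integer(1))
  for (t in seq_len(length(idx_tail) - 1L))
    add_bond(idx_tail[t], idx_tail[t + 1L])
  if (cyclo)  # close the cyclohexyl ring (three C2p beads)
    add_bond(idx_tail[1L], idx_tail[3L])
  tail_end <- idx_tail[length(idx_tail)]

  if (family %in% names(head_chains)) {
    hd <- head_chains[[family]]
    anchor <- add_bead(hd$anchor)
    add_bond(tail_end, anchor)
    prev <- anchor
    for (b in hd$chain) { cur <- add_bead(b); add_bond(prev, cur); prev <- cur }
    if (!is.null(hd$extra)) {   # second substituent on the anchor
      cur <- add_bead(hd$extra); add_bond(anchor, cur)
    }
    main <- c(if (cyclo) integer() else idx_tail, anchor,
              seq(anchor + 1L, length.out = length(hd$chain)))
    add_angles_along(main)
  } else {
    # sugar heads: pyranose ring as ACp + 3 OHp with a pendant OHp (CH2OH)
    add_ring <- function(attach_to, rt_link = NULL) {
      acp <- add_bead("ACp")
      if (!is.null(attach_to)) add_bond(attach_to, acp, rt_link)
      o1 <- add_bead("OHp"); add_bond(acp, o1)
      o2 <- add_bead("OHp"); add_bond(o1, o2)
      o3 <- add_bead("OHp"); add_bond(o2, o3)
      add_bond(o3, acp)                      # ring closure
      pend <- add_bead("OHp"); add_bond(o3, pend)
      list(acp = acp, link_out = o2)
    }
    r1 <- add_ring(tail_end, lookup_rtarget(family, beads[tail_end], "ACp", tab))
    if (family %in% c("MALTO", "CYMAL"))
      add_ring(r1$link_out, default_rtarget("ACp", "OHp"))
    add_angles_along(c(idx_tail[!cyclo | seq_along(idx_tail) > 3L], r1$acp))
  }

  dpd_topology(name = paste0(family, tail_carbons), beads = beads,
               bonds = bonds, angles = angles,
               molar_mass = sum(bead_masses[beads]))
}
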