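#' @useDynLib dpdchem, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd setNames rnorm runif dist
#' @importFrom utils read.delim head tail
NULL

# Bead tokens use a trailing "p" in place of a prime: OHp = OH', AM3p = AM3',
# C2p = C2', ACp = AC'.

#' Construct a DPD bead type
#'
#' A bead is a coarse-grained molecular fragment characterized by its surface
#' site interaction points (SSIPs), van der Waals volume, reference-liquid
#' concentration, and self-interaction parameters.
#'
#' @param name bead token (e.g. `"W"`, `"ES"`, `"AM3p"`).
#' @param ssips numeric vector of SSIP polarity parameters; positive values
#'   are H-bond-donor-like sites, negative values acceptor-like sites.
#' @param volume van der Waals volume in cubic Angstrom.
#' @param liquid_conc molar concentration (mol/L) of the pure reference bead
#'   liquid used for speciation.
#' @param a_self self-repulsion parameter (k_BT).
#' @param R_self self contact radius (r_c).
#' @param liquid optional list with provenance of `liquid_conc`
#'   (`molecule`, `density`, `molar_mass`, `divisor`).
#' @return an object of class `dpd_bead`.
#' @export
dpd_bead <- function(name, ssips, volume, liquid_conc, a_self, R_self,
                     liquid = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  ssips <- as.numeric(ssips)
  if (length(ssips) == 0L || any(!is.finite(ssips)))
    stop("bead '", name, "': SSIP list must be non-empty and finite")
  if (!is.finite(volume) || volume <= 0)
    stop("bead '", name, "': volume must be positive")
  if (!is.finite(liquid_conc) || liquid_conc <= 0)
    stop("bead '", name, "': liquid_conc must be positive")
  if (!is.finite(a_self) || a_self <= 0)
    stop("bead '", name, "': a_self must be positive")
  if (!is.finite(R_self) || R_self <= 0)
    stop("bead '", name, "': R_self must be positive")
  structure(
    list(name = name,
         # canonical order: descending |epsilon|, ties broken by value
         ssips = ssips[order(-abs(ssips), ssips)],
         volume = volume, liquid_conc = liquid_conc,
         a_self = a_self, R_self = R_self, liquid = liquid),
    class = "dpd_bead")
}

#' @export
print.dpd_bead <- function(x, ...) {
  cat(sprintf("<dpd_bead %s> v = %.1f A^3, c(liquid) = %.2f M, a_ii = %.2f kBT, R_ii = %.3f rc\n",
              x$name, x$volume, x$liquid_conc, x$a_self, x$R_self))
  cat("  SSIPs:", paste(format(x$ssips), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a molecule topology
#'
#' @param name molecule token, e.g. `"MEGA8"`.
#' @param beads character vector of bead names in chain order.
#' @param bonds data frame with columns `i`, `j` (1-based bead indices) and
#'   `r_target` (desired equilibrium bond length, r_c).
#' @param angles data frame with columns `i`, `j`, `k` and `theta0` (degrees),
#'   or `NULL` for none.
#' @param molar_mass molar mass in g/mol, used for weight-percent compositions.
#' @return an object of class `dpd_topology`.
#' @export
dpd_topology <- function(name, beads, bonds, angles = NULL, molar_mass) {
  stopifnot(is.character(name), length(name) == 1L)
  beads <- as.character(beads)
  n <- length(beads)
  if (n == 0L) stop("topology '", name, "': no beads")
  bonds <- as.data.frame(bonds)
  if (!all(c("i", "j", "r_target") %in% names(bonds)))
    stop("topology '", name, "': bonds need columns i, j, r_target")
  bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
  if (nrow(bonds) > 0L) {
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("topology '", name, "': bond index out of range")
    if (any(bonds$i == bonds$j))
      stop("topology '", name, "': self bond")
    if (any(!is.finite(bonds$r_target) | bonds$r_target <= 0))
      stop("topology '", name, "': r_target must be positive")
  }
  if (is.null(angles)) {
    angles <- data.frame(i = integer(), j = integer(), k = integer(),
                         theta0 = numeric())
  } else {
    angles <- as.data.frame(angles)
    if (!all(c("i", "j", "k", "theta0") %in% names(angles)))
      stop("topology '", name, "': angles need columns i, j, k, theta0")
    angles$i <- as.integer(angles$i); angles$j <- as.integer(angles$j)
    angles$k <- as.integer(angles$k)
    if (nrow(angles) > 0L) {
      if (any(angles$i < 1L | angles$i > n | angles$j < 1L | angles$j > n |
              angles$k < 1L | angles$k > n))
        stop("topology '", name, "': angle index out of range")
      if (any(angles$theta0 <= 0 | angles$theta0 > 180))
        stop("topology '", name, "': theta0 must lie in (0, 180]")
    }
  }
  if (!is.finite(molar_mass) || molar_mass <= 0)
    stop("topology '", name, "': molar_mass must be positive")
  # connectivity of the bond graph
  if (n > 1L) {
    g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    if (igraph::count_components(g) != 1L)
      stop("topology '", name, "': bond graph is not connected")
  }
  bonds <- bonds[, c("i", "j", "r_target")]
  angles <- angles[, c("i", "j", "k", "theta0")]
  rownames(bonds) <- NULL
  rownames(angles) <- NULL
  structure(list(name = name, beads = beads, bonds = bonds, angles = angles,
                 molar_mass = molar_mass),
            class = "dpd_topology")
}

#' @export
print.dpd_topology <- function(x, ...) {
  cat(sprintf("<dpd_topology %s> %d beads, %d bonds, %d angles, M = %.1f g/mol\n",
              x$name, length(x$beads), nrow(x$bonds), nrow(x$angles),
              x$molar_mass))
  cat("  chain:", paste(x$beads, collapse = "-"), "\n")
  invisible(x)
}

LIBRARY_SCHEMA <- "dpdchem-bead-library-1"

bead_fields <- c("name", "ssips", "volume", "a_self", "R_self", "liquid",
                 "liquid_conc")
topology_fields <- c("name", "beads", "bonds", "angles", "molar_mass")

#' Assemble a bead library
#'
#' @param beads list of [dpd_bead()] objects.
#' @param topologies list of [dpd_topology()] objects (may be empty).
#' @return an object of class `dpd_library`.
#' @export
dpd_library <- function(beads, topologies = list()) {
  if (length(beads) == 0L) stop("bead library must contain at least one bead")
  stopifnot(all(vapply(beads, inherits, logical(1), "dpd_bead")))
  nm <- vapply(beads, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate bead name: ",
                              nm[duplicated(nm)][1L])
  names(beads) <- nm
  stopifnot(all(vapply(topologies, inherits, logical(1), "dpd_topology")))
  for (tp in topologies) {
    unknown <- setdiff(tp$beads, nm)
    if (length(unknown))
      stop("topology '", tp$name, "' references unknown bead(s): ",
           paste(unknown, collapse = ", "))
  }
  if (length(topologies))
    names(topologies) <- vapply(topologies, `[[`, character(1), "name")
  structure(list(schema = LIBRARY_SCHEMA, beads = beads,
                 topologies = topologies),
            class = "dpd_library")
}

#' @export
print.dpd_library <- function(x, ...) {
  cat(sprintf("<dpd_library> %d beads (%s), %d topologies\n",
              length(x$beads), paste(names(x$beads), collapse = ", "),
              length(x$topologies)))
  invisible(x)
}

liquid_conc_from_provenance <- function(liquid) {
  1000 * liquid$density / liquid$molar_mass / liquid$divisor
}

#' Load a bead library file
#'
#' Reads and validates the package's YAML bead-library format.  When a bead
#' entry carries reference-liquid provenance (`liquid: {molecule, density,
#' molar_mass, divisor}`), the liquid concentration is computed from it as
#' `1000 * density / molar_mass / divisor`; otherwise an explicit
#' `liquid_conc` field is required.
#'
#' @param path path to a library file.
#' @param w_per_bead number of water molecules represented by one W bead
#'   (the divisor applied to the water-molecule concentration when deriving
#'   the W bead-liquid concentration).  Default 2, matching the simulation
#'   convention of one solvent bead per two waters.
#' @return a validated [dpd_library()].
#' @export
load_bead_library <- function(path, w_per_bead = 2) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("malformed bead library file '", path, "': ", conditionMessage(e)))
  if (!identical(doc$schema, LIBRARY_SCHEMA))
    stop("unsupported schema: ", deparse(doc$schema),
         " (expected ", LIBRARY_SCHEMA, ")")
  if (length(doc$beads) == 0L) stop("bead library file has an empty bead list")
  beads <- lapply(doc$beads, function(b) {
    unknown <- setdiff(names(b), bead_fields)
    if (length(unknown))
      stop("bead entry '", b$name %||% "?", "': unknown field(s): ",
           paste(unknown, collapse = ", "))
    conc <- if (!is.null(b$liquid)) {
      lq <- b$liquid
      if (identical(b$name, "W")) lq$divisor <- w_per_bead
      liquid_conc_from_provenance(lq)
    } else b$liquid_conc
    if (is.null(conc)) stop("bead entry '", b$name %||% "?",
                            "': needs liquid provenance or liquid_conc")
    dpd_bead(b$name, b$ssips, b$volume, conc, b$a_self, b$R_self,
             liquid = b$liquid)
  })
  topologies <- lapply(doc$topologies %||% list(), function(tp) {
    unknown <- setdiff(names(tp), topology_fields)
    if (length(unknown))
      stop("topology entry '", tp$name %||% "?", "': unknown field(s): ",
           paste(unknown, collapse = ", "))
    dpd_topology(tp$name, unlist(tp$beads),
                 bonds = do.call(rbind, lapply(tp$bonds, as.data.frame)),
                 angles = if (length(tp$angles))
                   do.call(rbind, lapply(tp$angles, as.data.frame)),
                 molar_mass = tp$molar_mass)
  })
  dpd_library(beads, topologies)
}

#' Write a bead library file
#'
#' Serializes a library to the package's YAML format with canonical key
#' order, so that `write_bead_library()` followed by [load_bead_library()]
#' round-trips to a structurally identical object.
#'
#' @param library a [dpd_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bead_library <- function(library, path) {
  stopifnot(inherits(library, "dpd_library"))
  doc <- list(
    schema = library$schema,
    beads = lapply(unname(library$beads), function(b) {
      out <- list(name = b$name, ssips = as.numeric(b$ssips),
                  volume = b$volume, a_self = b$a_self, R_self = b$R_self)
      if (!is.null(b$liquid)) out$liquid <- b$liquid
      else out$liquid_conc <- b$liquid_conc
      out
    }),
    topologies = lapply(unname(library$topologies), function(tp) {
      list(name = tp$name, beads = as.list(tp$beads),
           bonds = lapply(seq_len(nrow(tp$bonds)), function(r)
             as.list(tp$bonds[r, ])),
           angles = lapply(seq_len(nrow(tp$angles)), function(r)
             as.list(tp$angles[r, ])),
           molar_mass = tp$molar_mass)
    }))
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}

#' The packaged 14-bead library
#'
#' Loads the library shipped with the package: the water bead W, ester ES,
#' ether EO, acetal ACp, the three amides AM2/AM3p/AM3, alkyl beads
#' C2/C2p/T1/T2 and the hydroxyl beads OH1/OHp/OH2, with their SSIP sets,
#' van der Waals volumes, self repulsions, self radii, and reference-liquid
#' concentrations.
#'
#' @inheritParams load_bead_library
#' @return a [dpd_library()].
#' @export
default_bead_library <- function(w_per_bead = 2) {
  load_bead_library(system.file("extdata", "bead_library.yaml",
                                package = "dpdchem", mustWork = TRUE),
                    w_per_bead = w_per_bead)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
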