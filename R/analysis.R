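# Trajectory post-processing: aggregate detection, size distributions,
# critical micelle concentration, aggregation number, and gyration-tensor
# shape classification.

unwrap_about_first <- function(pos, L) {
  ref <- pos[1L, ]
  d <- sweep(pos, 2, ref)
  d <- d - L * round(d / L)
  sweep(d, 2, ref, `+`)
}

#' Cluster one frame into aggregates
#'
#' Two surfactant molecules belong to the same aggregate iff they are
#' connected through pairs of hydrophobic-tail beads closer than `cutoff`
#' under minimum-image distances.  Water beads and molecules are ignored;
#' every surfactant molecule (including free monomers) lands in exactly one
#' aggregate.
#'
#' @param traj a `dpd_trajectory`.
#' @param frame frame index.
#' @param cutoff tail-bead contact distance (r_c).
#' @return an object of class `aggregate_frame`: `sizes` (one per
#'   aggregate), `members` (list of molecule ids), `com` and `semi_axes`
#'   (rows matching aggregates; semi-axes NA for single-bead aggregates).
#' @export
cluster_frame <- function(traj, frame, cutoff = 1.0) {
  stopifnot(inherits(traj, "dpd_trajectory"))
  if (is.null(traj$hydrophobic) || !any(traj$hydrophobic & traj$mol_id > 0))
    stop("trajectory has no hydrophobic-bead annotation for its molecules")
  pos <- traj$frames[[frame]]
  n_mol <- max(traj$mol_id)
  tail_sel <- which(traj$hydrophobic & traj$mol_id > 0)
  tp <- pos[tail_sel, , drop = FALSE]
  pr <- cpp_pairs_within(tp, traj$L, cutoff)
  mol_a <- traj$mol_id[tail_sel[pr[, 1]]]
  mol_b <- traj$mol_id[tail_sel[pr[, 2]]]
  keep <- mol_a != mol_b
  g <- igraph::graph_from_edgelist(cbind(mol_a[keep], mol_b[keep]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_mol - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(n_mol)]
  comp <- match(comp, unique(comp))
  members <- split(seq_len(n_mol), comp)
  sizes <- lengths(members)
  com <- matrix(NA_real_, length(members), 3)
  axes <- matrix(NA_real_, length(members), 3,
                 dimnames = list(NULL, c("A", "B", "C")))
  for (aidx in seq_along(members)) {
    sel <- which(traj$mol_id %in% members[[aidx]])
    up <- unwrap_about_first(pos[sel, , drop = FALSE], traj$L)
    com[aidx, ] <- colMeans(up) %% traj$L
    if (length(sel) >= 2L)
      axes[aidx, ] <- shape_descriptor(pos[sel, , drop = FALSE], traj$L)
  }
  structure(list(frame = frame, sizes = as.integer(sizes), members = members,
                 com = com, semi_axes = axes, n_molecules = n_mol,
                 L = traj$L),
            class = "aggregate_frame")
}

#' Premicelle/micelle size threshold from an aggregation-number histogram
#'
#' Locates the boundary between the monomer/premicelle population and the
#' micelle population of `P(N)`.  If the histogram support has a gap (a run
#' of unpopulated sizes between two populated ones), the midpoint of the
#' first gap is returned; otherwise the smallest size at the deepest local
#' minimum between the low-N mode and the high-N mode.  A histogram with no
#' separate micelle population yields `NA` with attribute
#' `reason = "no micelle population"`.
#'
#' @param P either a named vector/table of counts by aggregate size, or an
#'   integer vector of observed sizes.
#' @return the size threshold `N_cut`, or flagged `NA`.
#' @export
find_ncut <- function(P) {
  if (is.null(names(P)) && !inherits(P, "table")) P <- table(P)
  N <- as.integer(names(P)); cnt <- as.numeric(P)
  if (length(N) == 0L) stop("empty histogram")
  o <- order(N); N <- N[o]; cnt <- cnt[o]
  full <- numeric(max(N)); full[N] <- cnt
  support <- which(full > 0)
  no_micelle <- structure(NA_integer_, reason = "no micelle population")
  if (length(support) < 2L) return(no_micelle)
  # gap rule: first run of empty sizes strictly between populated sizes
  gaps <- which(diff(support) > 1L)
  if (length(gaps)) {
    lo <- support[gaps[1L]]; hi <- support[gaps[1L] + 1L]
    return(as.integer(floor((lo + hi) / 2)))
  }
  # contiguous support: the deepest valley between the low-N and high-N
  # modes.  A size k is a valley candidate iff some smaller size and some
  # larger size both carry more weight; the deepest candidate wins, ties
  # going to the smallest N.  No candidate (monotone or unimodal histogram)
  # means no separate micelle population.
  lo <- support[1L]; hi <- support[length(support)]
  cand <- integer(0)
  for (k in support) {
    if (k == lo || k == hi) next
    left <- max(full[lo:(k - 1L)]); right <- max(full[(k + 1L):hi])
    if (left > full[k] && right > full[k]) cand <- c(cand, k)
  }
  if (!length(cand)) return(no_micelle)
  as.integer(cand[which.min(full[cand])])
}

#' Critical micelle concentration from clustered frames
#'
#' Averages, over post-equilibration frames, the number of surfactant
#' molecules that are free or in submicellar aggregates (size `< N_cut`,
#' monomers included) and converts it to mM through the box volume and the
#' r_c length scale.
#'
#' @param frames list of [cluster_frame()] results.
#' @param N_cut micelle size threshold.
#' @param units a [unit_map()].
#' @param equilibration index of the first frame to include.
#' @return a list with `cmc_mM`, `sd_mM`, and the per-frame series
#'   `free_molecules` / `series_mM`.
#' @export
cmc <- function(frames, N_cut, units = unit_map(), equilibration = 1L) {
  stopifnot(length(frames) >= 1L, is.finite(N_cut))
  if (equilibration > length(frames))
    stop("no frames after the equilibration cutoff")
  use <- frames[seq(equilibration, length(frames))]
  L <- use[[1L]]$L
  free <- vapply(use, function(fr) sum(fr$sizes[fr$sizes < N_cut]),
                 numeric(1))
  series <- counts_to_mM(free, L, units)
  list(cmc_mM = mean(series), sd_mM = if (length(series) > 1L) sd(series)
       else 0, free_molecules = free, series_mM = series)
}

#' Weight-average aggregation number
#'
#' Per frame, the weighted average micelle size `sum(N_i^2) / sum(N_i)` over
#' aggregates larger than `N_cut`; reported as the time average together
#' with the observed range.
#'
#' @param frames list of [cluster_frame()] results.
#' @param N_cut micelle size threshold.
#' @param equilibration index of the first frame to include.
#' @return list with `n_agg` (time mean), `range` (min/max of the per-frame
#'   values), and the per-frame `series` (NA for frames without micelles).
#'   If no frame contains a micelle, `n_agg` is `NA` with attribute
#'   `reason = "no micelles"`.
#' @export
n_agg <- function(frames, N_cut, equilibration = 1L) {
  use <- frames[seq(equilibration, length(frames))]
  series <- vapply(use, function(fr) {
    s <- fr$sizes[fr$sizes > N_cut]
    if (!length(s)) NA_real_ else sum(s^2) / sum(s)
  }, numeric(1))
  if (all(is.na(series)))
    return(list(n_agg = structure(NA_real_, reason = "no micelles"),
                range = c(NA_real_, NA_real_), series = series))
  list(n_agg = mean(series, na.rm = TRUE),
       range = range(series, na.rm = TRUE), series = series)
}

#' Spheroid semi-axes of an aggregate
#'
#' Eigenvalues `lambda1 >= lambda2 >= lambda3` of the gyration tensor of the
#' member positions (unwrapped about the aggregate, equal bead masses) give
#' the semi-axes `(A, B, C) = sqrt(5 * lambda)` under the uniform-ellipsoid
#' convention; the ratios `A/B` and `B/C` are convention independent.
#'
#' @param pos member bead positions (n x 3, wrapped coordinates).
#' @param L periodic box edge; `Inf` for already-unwrapped coordinates.
#' @return named vector `c(A, B, C)` with `A >= B >= C`.  A degenerate
#'   (collinear or coincident) aggregate has `C` floored at a small epsilon
#'   and carries attribute `degenerate = TRUE`.
#' @export
shape_descriptor <- function(pos, L = Inf) {
  stopifnot(is.matrix(pos), nrow(pos) >= 2L)
  if (is.finite(L)) pos <- unwrap_about_first(pos, L)
  d <- sweep(pos, 2, colMeans(pos))
  S <- crossprod(d) / nrow(d)
  lam <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  lam <- pmax(lam, 0)
  ax <- sqrt(5 * lam)
  eps <- 1e-8
  degenerate <- ax[3L] < eps
  ax <- pmax(ax, eps)
  out <- c(A = ax[1L], B = ax[2L], C = ax[3L])
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

#' Classify aggregate shapes from semi-axis ratios
#'
#' Bins the per-aggregate ratios `A/B` and `B/C` into a 2D histogram and
#' assigns each micelle to a shape class: sphere (both ratios below the
#' threshold), prolate/rod (`A/B` above, `B/C` below), oblate/disc (`A/B`
#' below, `B/C` above), irregular (both above).
#'
#' @param frames list of [cluster_frame()] results.
#' @param N_cut micelle size threshold (only aggregates with `N > N_cut`
#'   are classified); use 0 to classify everything with computed axes.
#' @param threshold ratio separating "equal" from "elongated" axes.
#' @param breaks bin edges for both ratio axes of the histogram.
#' @param equilibration index of the first frame to include.
#' @return list with `fractions` (named, sums to 1), `counts`, `ratios`
#'   (data frame `AB`, `BC`), and `histogram` (matrix of bin counts).
#' @export
classify_shapes <- function(frames, N_cut = 0, threshold = 1.5,
                            breaks = seq(1, 4, by = 0.1),
                            equilibration = 1L) {
  use <- frames[seq(equilibration, length(frames))]
  ab <- numeric(); bc <- numeric()
  for (fr in use) {
    sel <- which(fr$sizes > N_cut & !is.na(fr$semi_axes[, 1L]))
    if (!length(sel)) next
    ab <- c(ab, fr$semi_axes[sel, "A"] / fr$semi_axes[sel, "B"])
    bc <- c(bc, fr$semi_axes[sel, "B"] / fr$semi_axes[sel, "C"])
  }
  classes <- c("sphere", "prolate", "oblate", "irregular")
  if (!length(ab))
    return(list(fractions = setNames(rep(NA_real_, 4), classes),
                counts = setNames(integer(4), classes),
                ratios = data.frame(AB = ab, BC = bc), histogram = NULL))
  cls <- ifelse(ab <= threshold,
                ifelse(bc <= threshold, "sphere", "oblate"),
                ifelse(bc <= threshold, "prolate", "irregular"))
  counts <- table(factor(cls, levels = classes))
  br <- unique(c(breaks, Inf))
  h <- table(cut(ab, br, include.lowest = TRUE),
             cut(bc, br, include.lowest = TRUE))
  list(fractions = setNames(as.numeric(counts) / sum(counts), classes),
       counts = setNames(as.integer(counts), classes),
       ratios = data.frame(AB = ab, BC = bc),
       histogram = unclass(h))
}

# First frame at which the rolling mean of the free-monomer count stays
# within two late-run standard deviations of the late-run mean.
detect_equilibration <- function(monomers, window = 5L) {
  nf <- length(monomers)
  if (nf < 2L * window) return(1L)
  late <- monomers[seq(floor(nf / 2) + 1L, nf)]
  mu <- mean(late); s <- max(sd(late), 0.5)
  roll <- vapply(seq_len(nf - window + 1L), function(i)
    mean(monomers[i:(i + window - 1L)]), numeric(1))
  ok <- which(abs(roll - mu) <= 2 * s)
  if (!length(ok)) return(floor(nf / 2) + 1L)
  ok[1L]
}

#' Analyze a surfactant trajectory
#'
#' Full micelle-analysis pipeline: clusters every frame, pools the
#' post-equilibration aggregate-size histogram `P(N)`, locates the
#' premicelle/micelle threshold `N_cut`, and reports the critical micelle
#' concentration, the weight-average aggregation number, and the shape-class
#' fractions.
#'
#' @param traj a `dpd_trajectory`.
#' @param cutoff tail-bead clustering distance (r_c).
#' @param equilibration first frame to include in the pooled statistics;
#'   `NULL` detects it from the stabilization of the free-monomer count.
#' @param units a [unit_map()].
#' @param shape_threshold ratio threshold for [classify_shapes()].
#' @return an object of class `aggregate_report`.
#' @export
analyze_trajectory <- function(traj, cutoff = 1.0, equilibration = NULL,
                               units = unit_map(), shape_threshold = 1.5) {
  frames <- lapply(seq_along(traj$frames), function(fi)
    cluster_frame(traj, fi, cutoff))
  monomers <- vapply(frames, function(fr) sum(fr$sizes == 1L), numeric(1))
  if (is.null(equilibration)) equilibration <- detect_equilibration(monomers)
  pooled <- unlist(lapply(frames[seq(equilibration, length(frames))],
                          `[[`, "sizes"))
  P <- table(pooled)
  ncut <- find_ncut(P)
  if (is.na(ncut)) {
    cmc_res <- list(cmc_mM = NA_real_, sd_mM = NA_real_,
                    free_molecules = NULL, series_mM = NULL)
    nagg_res <- list(n_agg = structure(NA_real_, reason = "no micelles"),
                     range = c(NA_real_, NA_real_), series = NULL)
    shp <- NULL
  } else {
    cmc_res <- cmc(frames, ncut, units, equilibration)
    nagg_res <- n_agg(frames, ncut, equilibration)
    shp <- classify_shapes(frames, ncut, shape_threshold,
                           equilibration = equilibration)
  }
  structure(list(P = data.frame(N = as.integer(names(P)),
                                count = as.integer(P)),
                 N_cut = ncut, cmc = cmc_res, n_agg = nagg_res,
                 shapes = shp, equilibration = equilibration,
                 cutoff = cutoff, frames = frames),
            class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat("<aggregate_report>\n")
  cat("  N_cut:", x$N_cut, "\n")
  if (!is.na(x$N_cut)) {
    cat(sprintf("  CMC: %.3f mM (sd %.3f)\n", x$cmc$cmc_mM, x$cmc$sd_mM))
    cat(sprintf("  N_agg: %.1f (range %.1f-%.1f)\n", x$n_agg$n_agg,
                x$n_agg$range[1L], x$n_agg$range[2L]))
    if (!is.null(x$shapes))
      cat("  shapes:", paste(names(x$shapes$fractions),
                             sprintf("%.2f", x$shapes$fractions),
                             collapse = ", "), "\n")
  } else cat("  no micelle population\n")
  invisible(x)
}
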