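test_that("clustering groups molecules through tail-bead contacts", {
  # two far-apart molecules form two aggregates
  tr <- toy_trajectory(list(rbind(c(1, 1, 1)), rbind(c(5, 5, 5))), L = 12)
  fr <- cluster_frame(tr, 1, cutoff = 1.0)
  expect_equal(sort(fr$sizes), c(1L, 1L))

  # a chain of five molecules, each within the cutoff of the next, is one
  # aggregate (transitivity)
  chain <- lapply(0:4, function(k) rbind(c(1 + 0.9 * k, 1, 1)))
  fr <- cluster_frame(toy_trajectory(chain, L = 12), 1, cutoff = 1.0)
  expect_equal(fr$sizes, 5L)

  # contacts across the periodic boundary are honored
  wrap <- toy_trajectory(list(rbind(c(0.2, 1, 1)), rbind(c(11.8, 1, 1))),
                         L = 12)
  fr <- cluster_frame(wrap, 1, cutoff = 1.0)
  expect_equal(fr$sizes, 2L)

  expect_error(cluster_frame(
    structure(list(frames = list(matrix(1, 1, 3)), mol_id = 1L,
                   hydrophobic = FALSE, L = 5),
              class = "dpd_trajectory"), 1), "hydrophobic")
})

test_that("clustering equals a brute-force union-find oracle on random
           placements", {
  set.seed(42)
  for (rep in 1:5) {
    L <- 8
    mols <- lapply(seq_len(40), function(k) rbind(runif(3, 0, L)))
    tr <- toy_trajectory(mols, L)
    fr <- cluster_frame(tr, 1, cutoff = 1.0)
    got <- integer(40)
    for (ai in seq_along(fr$members)) got[fr$members[[ai]]] <- ai
    pos <- do.call(rbind, mols)
    D <- oracle_dists(pos, L)
    pairs <- which(D < 1.0 & upper.tri(D), arr.ind = TRUE)
    want <- oracle_partition(40, pairs)
    expect_identical(canon_partition(got), canon_partition(want))
  }
})

test_that("clustering is invariant under periodic translation", {
  set.seed(9)
  mols <- lapply(seq_len(30), function(k) rbind(runif(3, 0, 10)))
  tr <- toy_trajectory(mols, 10)
  base <- sort(cluster_frame(tr, 1)$sizes)
  for (shift in list(c(3.3, 0, 0), c(-2, 5.1, 9.9))) {
    tr2 <- tr
    tr2$frames[[1]] <- sweep(tr$frames[[1]], 2, shift, `+`) %% 10
    expect_equal(sort(cluster_frame(tr2, 1)$sizes), base)
  }
})

test_that("N_cut detection handles gaps, interior minima and degenerate
           histograms", {
  # clear gap between premicelles and micelles: midpoint of the gap
  P <- setNames(c(100, 20, 5, 40), c(1, 2, 3, 30))
  expect_equal(find_ncut(P), 16L)
  # contiguous bimodal histogram: deepest interior minimum (exhaustive scan)
  cnt <- c(50, 30, 18, 10, 7, 5, 3, 6, 11, 16, 12, 6)
  P2 <- setNames(cnt, 1:12)
  expect_equal(find_ncut(P2), which.min(cnt[2:9]) + 1L)  # oracle: scan
  expect_equal(find_ncut(P2), 7L)
  # monotone decreasing: no micelle population
  P3 <- setNames(c(90, 40, 12, 3, 1), 1:5)
  expect_true(is.na(find_ncut(P3)))
  expect_equal(attr(find_ncut(P3), "reason"), "no micelle population")
  # raw size observations are accepted too
  expect_equal(find_ncut(c(rep(1, 50), rep(2, 7), rep(25, 20))), 13L)
})

test_that("CMC counting and unit conversion match hand calculations", {
  mk_frame <- function(sizes, L) {
    structure(list(frame = 1, sizes = as.integer(sizes),
                   members = split(seq_len(sum(sizes)),
                                   rep(seq_along(sizes), sizes)),
                   com = NULL, semi_axes = NULL,
                   n_molecules = sum(sizes), L = L),
              class = "aggregate_frame")
  }
  # 12 free molecules in a (40 rc)^3 box at rc = 5.64 A: hand conversion
  # 12 / (N_A * (40 * 5.64 A)^3) = 1.7354 mM
  fr <- mk_frame(rep(1, 12), 40)
  res <- cmc(list(fr), N_cut = 10)
  expect_equal(res$cmc_mM, 1.7354, tolerance = 1e-4)
  expect_equal(res$sd_mM, 0)

  # everything in one large micelle: CMC = 0
  res0 <- cmc(list(mk_frame(30, 20)), N_cut = 10)
  expect_equal(res0$cmc_mM, 0)

  # identical frames have zero spread; conservation holds per frame
  frames <- list(mk_frame(c(1, 1, 4, 25), 20), mk_frame(c(1, 1, 4, 25), 20))
  res2 <- cmc(frames, N_cut = 10)
  expect_equal(res2$sd_mM, 0)
  expect_equal(res2$free_molecules, c(6, 6))
  total <- counts_to_mM(31, 20)
  expect_equal(res2$cmc_mM + counts_to_mM(25, 20), total)
  expect_error(cmc(frames, 10, equilibration = 5), "equilibration")
})

test_that("aggregation number is the weight average with its observed range", {
  mk <- function(sizes) structure(
    list(frame = 1, sizes = as.integer(sizes), members = NULL, com = NULL,
         semi_axes = NULL, n_molecules = sum(sizes), L = 10),
    class = "aggregate_frame")
  expect_equal(n_agg(list(mk(c(30, 30, 30))), N_cut = 5)$n_agg, 30)
  # {10, 10, 40}: (100 + 100 + 1600) / 60 = 30
  r <- n_agg(list(mk(c(10, 10, 40))), N_cut = 5)
  expect_equal(r$n_agg, 30)
  expect_equal(r$range, c(30, 30))   # single frame: point range
  # weight average dominates the number average (Cauchy-Schwarz)
  set.seed(5)
  for (k in 1:10) {
    sizes <- sample(6:80, sample(2:6, 1))
    expect_gte(n_agg(list(mk(sizes)), N_cut = 5)$n_agg, mean(sizes))
  }
  r2 <- n_agg(list(mk(c(2, 3))), N_cut = 5)
  expect_true(is.na(r2$n_agg))
  expect_equal(attr(r2$n_agg, "reason"), "no micelles")
})

test_that("gyration semi-axes match analytic and hand-computed oracles", {
  set.seed(11)
  # isotropic cloud: near-unit ratios
  sph <- matrix(rnorm(3 * 4000), ncol = 3)
  sph <- sph / sqrt(rowSums(sph^2)) * runif(4000)^(1 / 3)
  ax <- shape_descriptor(sph, L = Inf)
  expect_lt(ax["A"] / ax["B"], 1.1)
  expect_lt(ax["B"] / ax["C"], 1.1)

  # points on a 4:1:1 ellipsoid surface: A/B near 4, B/C near 1
  u <- matrix(rnorm(3 * 4000), ncol = 3); u <- u / sqrt(rowSums(u^2))
  ell <- sweep(u, 2, c(4, 1, 1), `*`)
  ax <- shape_descriptor(ell, L = Inf)
  expect_equal(unname(ax["A"] / ax["B"]), 4, tolerance = 0.1)
  expect_equal(unname(ax["B"] / ax["C"]), 1, tolerance = 0.1)

  # four fixed points: tensor diag(1/2, 2, 0) by hand
  pts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 2, 0), c(0, -2, 0))
  ax <- shape_descriptor(pts, L = Inf)
  expect_equal(unname(ax["A"]), sqrt(5 * 2))
  expect_equal(unname(ax["B"]), sqrt(5 * 0.5))
  expect_true(isTRUE(attr(ax, "degenerate")))   # planar: C floored

  # unwrapping: a compact blob straddling the boundary is handled
  blob <- sweep(sph[1:100, ] * 0.5, 2, c(0.1, 5, 5), `+`) %% 10
  ax_wrap <- shape_descriptor(blob, L = 10)
  ax_flat <- shape_descriptor(sweep(sph[1:100, ] * 0.5, 2, c(5, 5, 5), `+`),
                              L = 10)
  expect_equal(unname(ax_wrap), unname(ax_flat), tolerance = 1e-10)
})

test_that("shape classification separates planted populations", {
  tr_sph <- make_planted_trajectory(sizes = rep(40, 3), n_monomers = 0,
                                    L = 24, n_frames = 3, seed = 21,
                                    ratios = c(1, 1))
  frames <- lapply(seq_along(tr_sph$frames), function(i)
    cluster_frame(tr_sph, i))
  cls <- classify_shapes(frames, N_cut = 5)
  expect_equal(sum(cls$fractions), 1)
  expect_equal(unname(cls$fractions["sphere"]), 1)

  tr_pro <- make_planted_trajectory(sizes = rep(40, 3), n_monomers = 0,
                                    L = 30, n_frames = 3, seed = 22,
                                    ratios = c(3, 1))
  frames <- lapply(seq_along(tr_pro$frames), function(i)
    cluster_frame(tr_pro, i))
  cls <- classify_shapes(frames, N_cut = 5)
  expect_gte(unname(cls$fractions["prolate"]), 0.95)
})

test_that("the full pipeline recovers planted truth exactly", {
  tr <- make_planted_trajectory(sizes = c(30, 30, 30), n_monomers = 12,
                                L = 24, n_frames = 4, seed = 3)
  rep <- analyze_trajectory(tr, equilibration = 1)
  truth <- tr$planted
  expect_equal(rep$n_agg$n_agg, truth$n_agg)       # 30, exactly
  expect_equal(rep$cmc$cmc_mM, truth$cmc_mM)       # exact free count
  expect_equal(unname(rep$shapes$fractions["sphere"]), 1)
  # conservation: free + micellized = total per frame
  for (fr in rep$frames)
    expect_equal(sum(fr$sizes), truth$n_monomers + sum(truth$sizes))
  # histogram support is exactly the planted one
  expect_setequal(rep$P$N, c(1L, 30L))
})
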