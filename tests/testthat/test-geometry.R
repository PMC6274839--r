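test_that("weighted centroid matches direct arithmetic", {
  pts <- cbind(0:10, 0, 0)
  w <- c(0.5, rep(1, 9), 0.5)
  expect_equal(weighted_centroid(pts, w), c(5, 0, 0))
  expect_equal(weighted_centroid(matrix(c(1, 2, 3), 1, 3), 1), c(1, 2, 3))

  set.seed(11)
  for (rep in 1:5) {
    pts <- matrix(rnorm(33), 11, 3)
    w <- runif(11)
    direct <- colSums(pts * w) / sum(w)
    expect_equal(weighted_centroid(pts, w), direct, tolerance = 1e-12)
  }
  expect_error(weighted_centroid(pts, rep(0, 11)), "positive sum")
  expect_error(weighted_centroid(pts, c(1, 2)), "lengths differ")
})

test_that("default scheme reproduces the shared-endpoint segment ranges", {
  sch <- segment_scheme()
  expect_equal(sch$segments$res_first[1], 106)
  expect_equal(sch$segments$res_last[1], 116)
  expect_equal(sch$segments$res_first[2], 116)
  expect_equal(sch$segments$res_last[11], 216)
  expect_equal(nrow(sch$segments), 11)
})

test_that("axis of two symmetric straight chains lies on their midline", {
  ens <- straight_two_chain(n_frames = 3, residues = 1:25,
                            spacing = 0.15, gap = 1)
  sch <- segment_scheme(first_residue = 1, segment_length = 11,
                        n_segments = 2)
  ax <- build_axis(ens, sch)
  expect_equal(dim(ax$vertices)[1], 2)
  expect_equal(dim(ax$tangents)[1], 1)
  expect_lt(max(abs(ax$vertices[, 2, ])), 1e-12)  # y = 0 midline
  expect_lt(max(abs(ax$vertices[, 3, ])), 1e-12)
  expect_equal(as.vector(ax$tangents[1, , 1]), c(1, 0, 0), tolerance = 1e-12)
})

test_that("default scheme yields 11 vertices and 10 tangents per frame", {
  w <- sample_wlc_ensemble(n_vertices = 11, b_nm = 1.485, lp_nm = 200,
                           n_frames = 3, seed = 12)
  ens <- build_coiled_coil_ensemble(w)
  ax <- build_axis(ens)
  expect_equal(dim(ax$vertices)[1], 11)
  expect_equal(dim(ax$tangents)[1], 10)
  norms <- sqrt(apply(ax$tangents^2, c(1, 3), sum))
  expect_lt(max(abs(norms - 1)), 1e-9)
})

test_that("vertices equal the independent centroid-then-midpoint oracle", {
  set.seed(13)
  ens <- straight_two_chain(n_frames = 3, residues = 1:25,
                            perturb = function(d, f) {
    d$x_nm <- d$x_nm + rnorm(nrow(d), sd = 0.02)
    d$y_nm <- d$y_nm + rnorm(nrow(d), sd = 0.02)
    d$z_nm <- d$z_nm + rnorm(nrow(d), sd = 0.02)
    d
  })
  sch <- segment_scheme(first_residue = 1, segment_length = 11,
                        n_segments = 2)
  ax <- build_axis(ens, sch)
  w <- c(0.5, rep(1, 9), 0.5)
  for (f in 1:3) {
    fr <- ens[ens$frame == f, ]
    for (i in 1:2) {
      res <- seq(sch$segments$res_first[i], sch$segments$res_last[i])
      cent <- function(ch) {
        sub <- fr[fr$chain_id == ch & fr$residue_index %in% res, ]
        sub <- sub[order(sub$residue_index), ]
        colSums(as.matrix(sub[, c("x_nm", "y_nm", "z_nm")]) * w) / sum(w)
      }
      oracle <- (cent("A") + cent("B")) / 2
      expect_equal(as.vector(ax$vertices[i, , f]), unname(oracle),
                   tolerance = 1e-12)
    }
  }
})

test_that("axis is equivariant under rigid motion; arc lengths invariant", {
  set.seed(14)
  w <- sample_wlc_ensemble(n_vertices = 11, b_nm = 1.485, lp_nm = 80,
                           n_frames = 4, seed = 14)
  ens <- build_coiled_coil_ensemble(w)
  rot <- random_rot_oracle(); shift <- c(0.3, -1, 2)
  moved_tbl <- apply_rigid(as.data.frame(ens), rot, shift)
  moved <- conformation_ensemble(moved_tbl, temperature_K = 300)
  ax0 <- build_axis(ens)
  ax1 <- build_axis(moved)
  for (f in 1:4) {
    expect_equal(ax1$vertices[, , f],
                 sweep(ax0$vertices[, , f] %*% t(rot), 2, shift, "+"),
                 tolerance = 1e-9)
    expect_equal(ax1$tangents[, , f], ax0$tangents[, , f] %*% t(rot),
                 tolerance = 1e-9)
  }
  expect_equal(ax1$s_nm, ax0$s_nm, tolerance = 1e-9)
  expect_true(all(diff(ax0$s_nm) > 0))
})

test_that("missing C-alpha atoms are reported with chain and residue", {
  ens <- straight_two_chain(n_frames = 3, residues = 1:20)
  sch <- segment_scheme(first_residue = 1, segment_length = 11,
                        n_segments = 2)  # needs residues up to 21
  expect_error(build_axis(ens, sch), "chain A, residue 21")
})

test_that("distance profile: parallel rigid chains give d = gap, sd = 0", {
  ens <- straight_two_chain(n_frames = 3, residues = 1:25, gap = 1)
  sch <- segment_scheme(first_residue = 1, segment_length = 11,
                        n_segments = 2)
  d <- helix_distance_profile(ens, sch)
  expect_equal(d$d_mean_nm, c(1, 1), tolerance = 1e-12)
  expect_equal(d$d_sd_nm, c(0, 0), tolerance = 1e-12)
})

test_that("distance profile is invariant under chain-label exchange", {
  set.seed(15)
  ens <- straight_two_chain(n_frames = 3, residues = 1:25,
                            perturb = function(d, f) {
    d$y_nm <- d$y_nm + rnorm(nrow(d), sd = 0.03); d
  })
  sch <- segment_scheme(first_residue = 1, segment_length = 11,
                        n_segments = 2)
  swapped_tbl <- as.data.frame(ens)
  swapped_tbl$chain_id <- ifelse(swapped_tbl$chain_id == "A", "B", "A")
  swapped <- conformation_ensemble(swapped_tbl, temperature_K = 300)
  expect_equal(helix_distance_profile(ens, sch)$d_mean_nm,
               helix_distance_profile(swapped, sch)$d_mean_nm,
               tolerance = 1e-12)
})

test_that("built coiled-coil reproduces twice the inter-axis radius", {
  w <- sample_wlc_ensemble(n_vertices = 11, b_nm = 1.485, lp_nm = 150,
                           n_frames = 5, seed = 16)
  ens <- build_coiled_coil_ensemble(w, inter_axis_radius_nm = 0.49)
  d <- helix_distance_profile(ens)
  expect_true(all(abs(d$d_mean_nm - 0.98) < 0.01))
})
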