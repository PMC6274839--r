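make_axis <- function(tangents, s = NULL) {
  # minimal axis_polyline around a tangent array [n_t, 3, nf]
  n_t <- dim(tangents)[1]; nf <- dim(tangents)[3]
  vertices <- array(0, dim = c(n_t + 1, 3, nf))
  for (i in seq_len(n_t)) {
    vertices[i + 1, , ] <- vertices[i, , ] + tangents[i, , ]
  }
  ax <- coilflex:::axis_from_vertices(vertices, (seq_len(nf) - 1) * 10)
  if (!is.null(s)) ax$s_nm <- s
  ax
}

test_that("rigid ensembles give unit correlation with zero sem", {
  t1 <- matrix(rnorm(15), 5, 3)
  t1 <- t1 / sqrt(rowSums(t1^2))
  tangents <- aperm(array(rep(t(t1), 8), dim = c(3, 5, 8)), c(2, 1, 3))
  prof <- correlation_profile(make_axis(tangents))
  expect_equal(prof$c, rep(1, 5), tolerance = 1e-12)
  expect_equal(prof$sem, rep(0, 5), tolerance = 1e-12)
})

test_that("two symmetric tilted frames give c = cos(theta)", {
  theta <- 0.3
  tangents <- array(0, dim = c(2, 3, 2))
  tangents[1, , ] <- c(0, 0, 1)  # clamped first position
  tangents[2, , 1] <- c(sin(theta), 0, cos(theta))
  tangents[2, , 2] <- c(-sin(theta), 0, cos(theta))
  prof <- correlation_profile(make_axis(tangents), n_blocks = 2)
  expect_equal(prof$c[2], cos(theta), tolerance = 1e-12)
})

test_that("correlation equals the double-loop oracle on random tangents", {
  set.seed(17)
  tangents <- array(rnorm(6 * 3 * 40), dim = c(6, 3, 40))
  for (f in 1:40) {
    tangents[, , f] <- tangents[, , f] /
      sqrt(rowSums(tangents[, , f]^2))
  }
  prof <- correlation_profile(make_axis(tangents))
  expect_equal(prof$c, correlation_oracle(tangents), tolerance = 1e-12)
})

test_that("correlation profile is invariant under a global rotation", {
  w <- sample_wlc_ensemble(n_vertices = 8, lp_nm = 50, n_frames = 100,
                           seed = 18)
  ax <- as_axis_polyline(w)
  rot <- random_rot_oracle()
  ax_rot <- ax
  for (f in seq_len(dim(ax$tangents)[3])) {
    ax_rot$tangents[, , f] <- ax$tangents[, , f] %*% t(rot)
  }
  expect_equal(correlation_profile(ax_rot)$c, correlation_profile(ax)$c,
               tolerance = 1e-12)
})

test_that("fully disordered positions are refused", {
  tangents <- array(0, dim = c(2, 3, 2))
  tangents[1, , ] <- c(0, 0, 1)
  tangents[2, , 1] <- c(1, 0, 0)
  tangents[2, , 2] <- c(-1, 0, 0)  # mean tangent vanishes
  expect_error(correlation_profile(make_axis(tangents), n_blocks = 2),
               "disordered")
})

test_that("exact exponential profiles are fit exactly by both estimators", {
  s <- seq(0, 13.5, by = 1.5)
  prof <- tibble::tibble(position = seq_along(s), s_nm = s,
                         c = exp(-s / 100), sem = 0)
  ls <- fit_lp(prof, 300, "least_squares")
  sec <- fit_lp(prof, 300, "secant")
  expect_equal(ls$lp_nm, 100, tolerance = 1e-9)
  expect_equal(ls$lp_se_nm, 0, tolerance = 1e-6)
  expect_equal(sec$lp_nm, 100, tolerance = 1e-9)
  # forced zero intercept agrees on an exact line through the origin
  ls0 <- fit_lp(prof, 300, "least_squares", intercept = FALSE)
  expect_equal(ls0$lp_nm, 100, tolerance = 1e-9)
})

test_that("flat profiles are flagged rigid (infinite Lp)", {
  prof <- tibble::tibble(position = 1:5, s_nm = (0:4) * 1.5,
                         c = rep(1, 5), sem = 0)
  expect_equal(fit_lp(prof, 300)$lp_nm, Inf)
  expect_equal(fit_lp(prof, 300, "secant")$lp_nm, Inf)
  expect_error(fit_lp(tibble::tibble(position = 1:3, s_nm = 0:2,
                                     c = c(1, 0.5, -0.1), sem = 0), 300),
               "<= 0")
})

test_that("mid-chain sag separates the secant from the least-squares fit", {
  # three points: ends on the exp(-s/100) line, middle sagging below it
  s <- c(0, 5, 10)
  cvals <- c(1, exp(-5 / 100) * 0.97, exp(-10 / 100))
  prof <- tibble::tibble(position = 1:3, s_nm = s, c = cvals, sem = 0)
  sec <- fit_lp(prof, 300, "secant")
  ls <- fit_lp(prof, 300, "least_squares")
  expect_equal(sec$lp_nm, 100, tolerance = 1e-9)  # secant ignores interior
  # direct arithmetic: LS slope on the 3 points
  y <- log(cvals)
  slope <- sum((s - mean(s)) * (y - mean(y))) / sum((s - mean(s))^2)
  expect_equal(ls$lp_nm, -1 / slope, tolerance = 1e-12)
  expect_gt(sec$lp_nm, ls$lp_nm)
})

test_that("stiffness conversion follows Lp = k/(kB T)", {
  expect_equal(stiffness_from_lp(100, 300), 100 * 1.380649e-23 * 300,
               tolerance = 1e-15)
  expect_equal(stiffness_from_lp(100, 600), 2 * stiffness_from_lp(100, 300))
  expect_equal(lp_from_stiffness(stiffness_from_lp(123.4, 310), 310),
               123.4, tolerance = 1e-12)
  expect_error(stiffness_from_lp(-1, 300), "positive")
  expect_error(lp_from_stiffness(1e-19, -300), "positive")
})

test_that("tidy and glance expose the fit in broom style", {
  s <- seq(0, 13.5, by = 1.5)
  prof <- tibble::tibble(position = seq_along(s), s_nm = s,
                         c = exp(-s / 100), sem = 0)
  fit <- fit_lp(prof, 300)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$lp_nm, 100, tolerance = 1e-9)
  gl <- glance(fit)
  expect_true(all(c("slope_per_nm", "r_squared", "n_positions")
                  %in% names(gl)))
})

test_that("uniform chains have uniform local slopes", {
  s <- seq(0, 13.5, by = 1.5)
  prof <- tibble::tibble(position = seq_along(s), s_nm = s,
                         c = exp(-s / 80), sem = 0)
  flex <- flexibility_profile(prof)
  expect_equal(flex$local_slope_per_nm, rep(-1 / 80, nrow(flex)),
               tolerance = 1e-9)
  expect_equal(flex$local_lp_nm, rep(80, nrow(flex)), tolerance = 1e-6)
})

test_that("flexible regions are reported as residue intervals", {
  sch <- segment_scheme()
  s <- (0:9) * 1.485
  cvals <- exp(-s / 100)
  cvals[5:10] <- cvals[5:10] * exp(-(s[5:10] - s[4]) / 30)  # soften middle
  prof <- tibble::tibble(position = 1:10, s_nm = s, c = cvals, sem = 0)
  flex <- flexibility_profile(prof, sch)
  expect_true(all(grepl("^residues \\d+-\\d+$", flex$label)))
  top <- most_flexible_region(flex)
  expect_equal(nrow(top), 1)
  expect_match(top$label, "residues")
})

test_that("blockwise estimates feed a correct Student t comparison", {
  a <- c(100, 101, 99, 100)
  b <- c(150, 151, 149, 150)
  est_a <- list(lp_nm = mean(a)); est_b <- list(lp_nm = mean(b))
  cmp <- compare_lp(est_a, est_b, a, b)
  # hand-computed pooled t statistic
  sp2 <- (var(a) * 3 + var(b) * 3) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(cmp$t_statistic, t_hand, tolerance = 1e-12)
  expect_lt(cmp$p_value, 0.01)
  expect_equal(cmp$ratio, mean(a) / mean(b), tolerance = 1e-12)

  same <- compare_lp(est_a, est_a, a, a)
  expect_equal(same$ratio, 1)
  expect_equal(same$p_value, 1)
  expect_error(compare_lp(est_a, est_b, a, 150), "at least 2 block")
})

test_that("Lp estimation ignores time rescaling (frame order only)", {
  w <- sample_wlc_ensemble(n_vertices = 11, lp_nm = 100, n_frames = 400,
                           seed = 19)
  ax1 <- as_axis_polyline(w, time_ps = (seq_len(400) - 1) * 10)
  ax2 <- as_axis_polyline(w, time_ps = (seq_len(400) - 1) * 1000)
  expect_equal(fit_lp(correlation_profile(ax1), 300)$lp_nm,
               fit_lp(correlation_profile(ax2), 300)$lp_nm,
               tolerance = 1e-12)
})
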