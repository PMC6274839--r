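#' Tangent-correlation profile of an axis polyline
#'
#' For each tangent position *i* the time-averaged unit tangent
#' \eqn{\langle t_i\rangle = \sum_j t_{ij} / |\sum_j t_{ij}|} is formed and
#' the profile value is the time average of the scalar product
#' \eqn{c_i = \langle (t_{ij}, \langle t_i\rangle) \rangle_j}.  For a
#' worm-like chain this decays as \eqn{\exp(-s/L_p)} with contour distance
#' *s*, and unlike the classic correlation with the first tangent
#' (`reference = "first"`, \eqn{c_i = \langle (t_{ij}, t_{1j})\rangle_j}) it
#' remains unbiased for intrinsically curved filaments, because the
#' deterministic curvature is absorbed into the position-wise mean tangent.
#'
#' Uncertainties come from block averaging: frames are split into
#' `n_blocks` contiguous blocks and the SEM is the standard deviation of
#' block means divided by `sqrt(n_blocks)`, which is robust to the strong
#' autocorrelation of consecutive snapshots.
#'
#' @param axis An `axis_polyline` from [build_axis()] or
#'   [as_axis_polyline()].
#' @param n_blocks Number of contiguous blocks for the SEM (default 8).
#' @param reference `"mean"` for the mean-tangent estimator (default) or
#'   `"first"` for the classic same-frame first-tangent correlation.
#' @return A `correlation_profile` tibble: `position`, `s_nm`, `c`, `sem`,
#'   with attributes `n_frames`, `n_blocks`, `reference`.
#' @export
correlation_profile <- function(axis, n_blocks = 8,
                                reference = c("mean", "first")) {
  reference <- match.arg(reference)
  tg <- axis$tangents
  n_t <- dim(tg)[1]; nf <- dim(tg)[3]
  if (nf < 2) abort("correlation profile needs at least two frames")
  n_blocks <- max(2L, min(as.integer(n_blocks), nf))

  if (reference == "mean") {
    msum <- apply(tg, c(1, 2), sum)            # [n_t, 3]
    norm <- sqrt(rowSums(msum^2))
    bad <- which(norm < 1e-9 * nf)
    if (length(bad) > 0) {
      abort(paste0("position ", paste(bad, collapse = ", "),
                   " fully disordered: vanishing mean tangent"))
    }
    u <- msum / norm
    # scalar products t_ij . <t_i> per frame: [n_t, nf]
    cij <- matrix(0, n_t, nf)
    for (k in 1:3) cij <- cij + matrix(tg[, k, ], n_t, nf) * u[, k]
  } else {
    cij <- matrix(0, n_t, nf)
    for (k in 1:3) {
      tk <- matrix(tg[, k, ], n_t, nf)
      cij <- cij + tk * rep(tk[1, ], each = n_t)
    }
  }

  ci <- rowMeans(cij)
  blk <- cut(seq_len(nf), breaks = n_blocks, labels = FALSE)
  bm <- vapply(seq_len(n_blocks),
               function(b) rowMeans(cij[, blk == b, drop = FALSE]),
               numeric(n_t))
  sem <- apply(matrix(bm, n_t, n_blocks), 1, sd) / sqrt(n_blocks)

  new_tibble(
    tibble(position = seq_len(n_t), s_nm = axis$s_nm, c = ci, sem = sem),
    class = "correlation_profile",
    n_frames = nf, n_blocks = n_blocks, reference = reference,
    scheme = axis$scheme
  )
}

#' Persistence length from a correlation profile
#'
#' Fits the exponential decay \eqn{c(s) = \exp(-s/L_p)} on the log scale.
#' Two slope estimators are offered, matching common practice for
#' flexibility plots: ordinary least squares of `ln c` on `s` over all
#' positions (default with a free intercept; set `intercept = FALSE` to
#' force the theoretical zero intercept), or the secant through the first
#' and last points only.  `Lp = -1/slope`; a slope above `-1e-12` per nm is
#' reported as an infinite persistence length (rigid rod).  The standard
#' error is propagated from the slope standard error as
#' `|slope_se / slope^2|` (least squares only).  Bending stiffness
#' `k = Lp * kB * T` (J nm) is attached.
#'
#' @param profile A [correlation_profile()] with all `c > 0`.
#' @param temperature_K Absolute temperature, kelvin.
#' @param method `"least_squares"` or `"secant"`.
#' @param intercept Least squares only: free intercept (default `TRUE`).
#' @return An `lp_fit` object; see [tidy()] and [glance()] methods.
#' @export
fit_lp <- function(profile, temperature_K = 300,
                   method = c("least_squares", "secant"), intercept = TRUE) {
  method <- match.arg(method)
  if (any(profile$c <= 0)) {
    abort("correlation values <= 0: log-linear fit undefined (disorder beyond the worm-like-chain model)")
  }
  s <- profile$s_nm
  y <- log(profile$c)
  if (method == "least_squares") {
    if (length(s) < 3) abort("least-squares fit needs at least 3 positions")
    fit <- if (intercept) lm(y ~ s) else lm(y ~ s - 1)
    # exact exponential profiles are legitimate (rigid fixtures); silence
    # lm's perfect-fit warning rather than propagating it per call
    sm <- suppressWarnings(summary(fit))$coefficients
    slope <- sm["s", "Estimate"]
    slope_se <- sm["s", "Std. Error"]
    if (!is.finite(slope_se)) slope_se <- 0  # exact line: zero residuals
    intercept_val <- if (intercept) coef(fit)[["(Intercept)"]] else 0
    r2 <- suppressWarnings(summary(fit))$r.squared
  } else {
    i1 <- 1L; i2 <- length(s)
    if (s[i2] <= s[i1]) abort("secant needs s_last > s_first")
    slope <- (y[i2] - y[i1]) / (s[i2] - s[i1])
    slope_se <- NA_real_
    intercept_val <- y[i1] - slope * s[i1]
    r2 <- NA_real_
  }
  if (slope >= -1e-12) {
    lp <- Inf
    lp_se <- NA_real_
  } else {
    lp <- -1 / slope
    lp_se <- if (is.na(slope_se)) NA_real_ else abs(slope_se / slope^2)
  }
  structure(list(
    lp_nm = lp, lp_se_nm = lp_se, method = method,
    slope_per_nm = slope, slope_se_per_nm = slope_se,
    intercept = intercept_val, r_squared = r2,
    temperature_K = temperature_K,
    stiffness_J_nm = stiffness_from_lp(lp, temperature_K),
    n_positions = length(s),
    n_frames = attr(profile, "n_frames") %||% NA_integer_
  ), class = "lp_fit")
}

#' @rdname fit_lp
#' @export
fit_lp_least_squares <- function(profile, temperature_K = 300,
                                 intercept = TRUE) {
  fit_lp(profile, temperature_K, method = "least_squares",
         intercept = intercept)
}

#' @rdname fit_lp
#' @export
fit_lp_secant <- function(profile, temperature_K = 300) {
  fit_lp(profile, temperature_K, method = "secant")
}

#' @export
print.lp_fit <- function(x, ...) {
  cat(sprintf("<lp_fit:%s> Lp = %s nm%s  (T = %g K, k = %g J nm)\n",
              x$method,
              if (is.finite(x$lp_nm)) sprintf("%.1f", x$lp_nm) else "Inf",
              if (is.finite(x$lp_se_nm %||% NA_real_) && !is.na(x$lp_se_nm))
                sprintf(" +/- %.1f", x$lp_se_nm) else "",
              x$temperature_K, x$stiffness_J_nm))
  invisible(x)
}

#' Tidy a persistence-length fit
#'
#' @param x An `lp_fit`.
#' @param ... Unused.
#' @return One-row tibble (`tidy`: method, Lp and its SE; `glance`: full fit
#'   diagnostics).
#' @method tidy lp_fit
#' @export
tidy.lp_fit <- function(x, ...) {
  tibble(method = x$method, lp_nm = x$lp_nm, lp_se_nm = x$lp_se_nm,
         temperature_K = x$temperature_K, stiffness_J_nm = x$stiffness_J_nm)
}

#' @rdname tidy.lp_fit
#' @method glance lp_fit
#' @export
glance.lp_fit <- function(x, ...) {
  tibble(method = x$method, lp_nm = x$lp_nm, lp_se_nm = x$lp_se_nm,
         slope_per_nm = x$slope_per_nm, slope_se_per_nm = x$slope_se_per_nm,
         intercept = x$intercept, r_squared = x$r_squared,
         n_positions = x$n_positions, n_frames = x$n_frames,
         temperature_K = x$temperature_K, stiffness_J_nm = x$stiffness_J_nm)
}

#' Convert between persistence length and bending stiffness
#'
#' For a thermally fluctuating elastic rod, `Lp = k / (kB * T)`, so
#' `k = Lp * kB * T` with `kB = 1.380649e-23` J/K.  `Lp` in nm gives `k` in
#' joule-nanometres.
#'
#' @param lp_nm Persistence length, nm (> 0; may be `Inf`).
#' @param stiffness_J_nm Bending stiffness, J nm.
#' @param temperature_K Absolute temperature, kelvin (> 0).
#' @return Stiffness in J nm, or persistence length in nm.
#' @export
stiffness_from_lp <- function(lp_nm, temperature_K) {
  if (any(temperature_K <= 0)) abort("temperature must be positive")
  if (any(lp_nm <= 0)) abort("persistence length must be positive")
  lp_nm * .kB * temperature_K
}

#' @rdname stiffness_from_lp
#' @export
lp_from_stiffness <- function(stiffness_J_nm, temperature_K) {
  if (any(temperature_K <= 0)) abort("temperature must be positive")
  if (any(stiffness_J_nm <= 0)) abort("stiffness must be positive")
  stiffness_J_nm / (.kB * temperature_K)
}

#' Local flexibility along the chain
#'
#' Local slope of `ln c` versus `s` at each interior position, by central
#' differences: `slope_i = (ln c_{i+1} - ln c_{i-1}) / (s_{i+1} -
#' s_{i-1})`.  For a uniform worm-like chain all local slopes equal
#' `-1/Lp`; a locally soft region shows up as a dip (steepest negative
#' slope).  When the profile carries a [segment_scheme()], each slope is
#' mapped to the author-numbered residue interval its tangent pair spans.
#'
#' @param profile A [correlation_profile()] with all `c > 0`.
#' @param scheme Optional [segment_scheme()]; defaults to the scheme stored
#'   in the profile, if any.
#' @return A `flexibility_profile` tibble: `position`, `s_nm`,
#'   `local_slope_per_nm`, `local_lp_nm`, and (with a scheme) `res_first`,
#'   `res_last`, `label`; the steepest position is flagged in
#'   `most_flexible`.
#' @export
flexibility_profile <- function(profile, scheme = NULL) {
  if (nrow(profile) < 3) abort("need at least 3 positions")
  if (any(profile$c <= 0)) abort("correlation values <= 0: log undefined")
  scheme <- scheme %||% attr(profile, "scheme")
  s <- profile$s_nm
  y <- log(profile$c)
  n <- length(s)
  ii <- 2:(n - 1)
  slope <- (y[ii + 1] - y[ii - 1]) / (s[ii + 1] - s[ii - 1])
  out <- tibble(position = ii, s_nm = s[ii], local_slope_per_nm = slope,
                local_lp_nm = ifelse(slope >= -1e-12, Inf, -1 / slope))
  if (!is.null(scheme)) {
    # tangent i spans segments i and i+1 (vertices i, i+1)
    out$res_first <- scheme$segments$res_first[out$position]
    out$res_last <- scheme$segments$res_last[pmin(out$position + 1,
                                                  scheme$n_segments)]
    out$label <- sprintf("residues %d-%d", out$res_first, out$res_last)
  }
  out$most_flexible <- seq_len(nrow(out)) == which.min(out$local_slope_per_nm)
  new_tibble(out, class = "flexibility_profile")
}

#' Most flexible region of a flexibility profile
#'
#' @param flex A [flexibility_profile()].
#' @return One-row tibble for the steepest (most negative) local slope.
#' @export
most_flexible_region <- function(flex) {
  flex[flex$most_flexible, , drop = FALSE]
}

#' Block-wise persistence length estimates
#'
#' Splits the frames into contiguous blocks, estimates Lp independently in
#' each block, and returns the vector of block estimates — the replicate
#' unit used for condition comparisons.
#'
#' @param axis An `axis_polyline`.
#' @param n_blocks Number of contiguous frame blocks (default 8).
#' @param temperature_K Kelvin.
#' @inheritParams fit_lp
#' @return Numeric vector of length `n_blocks` (nm; may contain `Inf`).
#' @export
blockwise_lp <- function(axis, n_blocks = 8, temperature_K = 300,
                         method = c("least_squares", "secant"),
                         intercept = TRUE) {
  method <- match.arg(method)
  nf <- dim(axis$tangents)[3]
  blk <- cut(seq_len(nf), breaks = n_blocks, labels = FALSE)
  vapply(seq_len(n_blocks), function(b) {
    sub <- axis
    sub$tangents <- axis$tangents[, , blk == b, drop = FALSE]
    sub$vertices <- axis$vertices[, , blk == b, drop = FALSE]
    sub$time_ps <- axis$time_ps[blk == b]
    prof <- correlation_profile(sub, n_blocks = 2)
    fit_lp(prof, temperature_K, method = method, intercept = intercept)$lp_nm
  }, numeric(1))
}

#' Compare persistence lengths of two conditions
#'
#' Ratio of full-trajectory estimates plus a two-sample, two-tailed,
#' equal-variance Student's t-test on block-wise Lp estimates.
#'
#' @param est_a,est_b `lp_fit` objects (numerator and denominator).
#' @param blocks_a,blocks_b Numeric vectors of block-wise Lp estimates
#'   (at least 2 each), e.g. from [blockwise_lp()].
#' @return One-row tibble: `ratio`, `t_statistic`, `df`, `p_value`,
#'   `lp_a_nm`, `lp_b_nm`.
#' @export
compare_lp <- function(est_a, est_b, blocks_a, blocks_b) {
  if (length(blocks_a) < 2 || length(blocks_b) < 2) {
    abort("need at least 2 block estimates per condition")
  }
  # blocks fitted as rigid (infinite Lp) carry no usable scatter
  blocks_a <- blocks_a[is.finite(blocks_a)]
  blocks_b <- blocks_b[is.finite(blocks_b)]
  if (length(blocks_a) < 2 || length(blocks_b) < 2) {
    abort("fewer than 2 finite block estimates per condition")
  }
  ratio <- est_a$lp_nm / est_b$lp_nm
  if (var(blocks_a) == 0 && var(blocks_b) == 0) {
    # both constant: t-test degenerates; equal means carry no evidence
    df <- length(blocks_a) + length(blocks_b) - 2
    same <- isTRUE(all.equal(mean(blocks_a), mean(blocks_b)))
    tt <- list(statistic = c(t = if (same) 0 else Inf),
               parameter = c(df = df),
               p.value = if (same) 1 else 0)
  } else {
    tt <- t.test(blocks_a, blocks_b, var.equal = TRUE,
                 alternative = "two.sided")
  }
  tibble(ratio = ratio,
         t_statistic = unname(tt$statistic),
         df = unname(tt$parameter),
         p_value = tt$p.value,
         lp_a_nm = est_a$lp_nm, lp_b_nm = est_b$lp_nm)
}
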