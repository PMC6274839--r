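#' Discrete Kratky-Porod (worm-like chain) ensemble sampler
#'
#' Draws independent equilibrium conformations of a discrete worm-like
#' chain: the first tangent is clamped to +z (defining the body frame),
#' and each subsequent joint bends by a polar angle drawn from the
#' Kratky-Porod equilibrium density
#' \eqn{p(\theta) \propto \exp(-(L_p/b)(1-\cos\theta))\sin\theta}
#' with uniform azimuth.  Sampling is by exact inverse-CDF in
#' \eqn{\cos\theta} (no small-angle approximation), so soft joints with
#' large bending angles are handled correctly.  A deterministic intrinsic
#' bend can be added at every joint (rotation about `bend_axis`), producing
#' an intrinsically curved filament whose thermal persistence length is
#' still `lp_nm`; a single joint can be softened by a given factor.
#'
#' @param n_vertices Number of polygon vertices (default 11, i.e. 10
#'   tangents).
#' @param b_nm Segment length, nm (default 1.5).
#' @param lp_nm True persistence length, nm (> 0).
#' @param n_frames Number of independent conformations (default 8000).
#' @param intrinsic_bend_deg Deterministic bend per joint, degrees
#'   (0 = intrinsically straight).
#' @param bend_axis Unit 3-vector; the intrinsic bend rotates the
#'   propagation direction about this axis (default x, bending in the
#'   y-z plane).
#' @param soft_joint Optional `list(index =, factor =)`: joint `index`
#'   (between tangents `index - 1` and `index`, so 2..n_tangents) has its
#'   stiffness divided by `factor` (>= 1).
#' @param rigid_motion If `TRUE`, a random rigid rotation + translation is
#'   applied to every frame (exercises the superposition path; the default
#'   clamped output needs no alignment).
#' @param seed Optional integer seed; same seed, same ensemble.
#' @return A `wlc_ensemble`: list with `vertices` (`[n_vertices, 3,
#'   n_frames]`, nm), `tangents`, `s_nm`, and the generating parameters.
#'   Convert with [as_axis_polyline()] to feed the estimators, or with
#'   [build_coiled_coil_ensemble()] to obtain a pseudo-atomic ensemble.
#' @export
sample_wlc_ensemble <- function(n_vertices = 11, b_nm = 1.5, lp_nm = 100,
                                n_frames = 8000, intrinsic_bend_deg = 0,
                                bend_axis = c(1, 0, 0), soft_joint = NULL,
                                rigid_motion = FALSE, seed = NULL) {
  if (b_nm <= 0 || lp_nm <= 0 || n_frames < 1 || n_vertices < 2) {
    abort("invalid worm-like-chain parameters")
  }
  if (!is.null(soft_joint)) {
    if (is.null(soft_joint$index) || is.null(soft_joint$factor) ||
        soft_joint$factor < 1) {
      abort("soft_joint must be list(index =, factor >= 1)")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  kappa <- lp_nm / b_nm
  n_t <- n_vertices - 1L
  bend_axis <- bend_axis / sqrt(sum(bend_axis^2))
  rot_bend <- if (intrinsic_bend_deg != 0) {
    rotation_about_axis(bend_axis, intrinsic_bend_deg * pi / 180)
  } else NULL

  tangents <- array(0, dim = c(n_t, 3L, n_frames))
  cur <- matrix(rep(c(0, 0, 1), each = n_frames), n_frames, 3)
  tangents[1, , ] <- t(cur)
  for (i in seq_len(n_t)[-1]) {
    if (!is.null(rot_bend)) cur <- cur %*% t(rot_bend)
    k_i <- kappa
    if (!is.null(soft_joint) && soft_joint$index == i) {
      k_i <- kappa / soft_joint$factor
    }
    cth <- kp_sample_cos(runif(n_frames), k_i)
    sth <- sqrt(pmax(0, 1 - cth^2))
    phi <- runif(n_frames, 0, 2 * pi)
    # orthonormal basis perpendicular to the current tangent, per frame
    use_x <- abs(cur[, 1]) < 0.9
    h <- cbind(ifelse(use_x, 1, 0), ifelse(use_x, 0, 1), 0)
    e1 <- row_cross(h, cur)
    e1 <- e1 / sqrt(rowSums(e1^2))
    e2 <- row_cross(cur, e1)
    cur <- cth * cur + sth * (cos(phi) * e1 + sin(phi) * e2)
    cur <- cur / sqrt(rowSums(cur^2))
    tangents[i, , ] <- t(cur)
  }

  vertices <- array(0, dim = c(n_vertices, 3L, n_frames))
  for (i in seq_len(n_t)) {
    vertices[i + 1, , ] <- vertices[i, , ] + b_nm * tangents[i, , ]
  }

  if (rigid_motion) {
    for (f in seq_len(n_frames)) {
      rot <- random_rotation()
      shift <- rnorm(3, sd = 5)
      vertices[, , f] <- vertices[, , f] %*% t(rot) +
        matrix(shift, n_vertices, 3, byrow = TRUE)
      tangents[, , f] <- tangents[, , f] %*% t(rot)
    }
  }

  structure(list(
    vertices = vertices, tangents = tangents,
    s_nm = (seq_len(n_t) - 1) * b_nm, b_nm = b_nm, lp_true_nm = lp_nm,
    intrinsic_bend_deg = intrinsic_bend_deg, bend_axis = bend_axis,
    soft_joint = soft_joint, n_frames = n_frames, seed = seed
  ), class = "wlc_ensemble")
}

#' @export
print.wlc_ensemble <- function(x, ...) {
  cat(sprintf(
    "<wlc_ensemble> %d frames, %d vertices, b = %g nm, Lp = %g nm%s\n",
    x$n_frames, dim(x$vertices)[1], x$b_nm, x$lp_true_nm,
    if (x$intrinsic_bend_deg != 0)
      sprintf(", intrinsic bend %g deg/joint", x$intrinsic_bend_deg) else ""))
  invisible(x)
}

# inverse CDF of cos(theta) for p(cos) ~ exp(kappa * cos), stable at large kappa
kp_sample_cos <- function(u, kappa) {
  pmin(1, pmax(-1, 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa))
}

#' Mean joint-angle cosine of the discrete Kratky-Porod density
#'
#' Closed form \eqn{\langle\cos\theta\rangle = \coth\kappa - 1/\kappa}
#' with \eqn{\kappa = L_p / b}; the Monte-Carlo sampler must reproduce it.
#'
#' @param kappa Dimensionless stiffness `lp_nm / b_nm`.
#' @return Mean cosine.
#' @export
kp_mean_cos <- function(kappa) 1 / tanh(kappa) - 1 / kappa

rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c1 <- cos(angle); s1 <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * c1 + s1 * K + (1 - c1) * (a %o% a)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Coerce an object to an axis polyline
#'
#' @param x Object to coerce (e.g. a `wlc_ensemble`).
#' @param ... Passed to methods.
#' @return An `axis_polyline`.
#' @export
as_axis_polyline <- function(x, ...) UseMethod("as_axis_polyline")

#' @export
as_axis_polyline.axis_polyline <- function(x, ...) x

#' @export
as_axis_polyline.wlc_ensemble <- function(x, time_ps = NULL, ...) {
  axis_from_vertices(x$vertices,
                     time_ps %||% (seq_len(x$n_frames) - 1) * 10,
                     scheme = NULL)
}

# ---- ideal alpha-helix backbone (NeRF internal-to-Cartesian) ---------------

# standard backbone geometry (nm, degrees); phi/psi of the ideal alpha-helix
.helix_geom <- list(
  b_n_ca = 0.1458, b_ca_c = 0.1525, b_c_n = 0.1329, b_c_o = 0.1231,
  b_n_h = 0.101,
  ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
  ang_ca_c_o = 120.8,
  phi = -57, psi = -47, omega = 180
)

# place atom D given A-B-C, bond length r (C-D), angle theta (B-C-D, deg),
# dihedral phi (A-B-C-D, deg)
nerf_place <- function(a, b, c_, r, theta_deg, phi_deg) {
  theta <- theta_deg * pi / 180; phi <- phi_deg * pi / 180
  bc <- c_ - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  c_ + (-r * cos(theta)) * bc +
    (r * sin(theta) * cos(phi)) * m + (r * sin(theta) * sin(phi)) * n
}

# backbone coordinates of an ideal straight-axis alpha-helix.
# returns list of [n,3] matrices: N, CA, C, O, H (H row 1 is NA)
ideal_helix_backbone <- function(n_residues) {
  g <- .helix_geom
  N <- CA <- C <- O <- H <- matrix(NA_real_, n_residues, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  # seed C of residue 1 via a virtual previous atom to fix the plane
  C[1, ] <- nerf_place(c(-1, 1, 0), N[1, ], CA[1, ], g$b_ca_c,
                       g$ang_n_ca_c, g$phi + 180)
  for (i in 2:n_residues) {
    N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ], g$b_c_n,
                         g$ang_ca_c_n, g$psi)
    CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ], g$b_n_ca,
                          g$ang_c_n_ca, g$omega)
    C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ], g$b_ca_c,
                         g$ang_n_ca_c, g$phi)
    # carbonyl O of residue i-1: dihedral N(i)-CA(i-1)-C(i-1)-O = psi + 180
    O[i - 1, ] <- nerf_place(N[i, ], CA[i - 1, ], C[i - 1, ], g$b_c_o,
                             g$ang_ca_c_o, 180)
    # amide H of residue i: in-plane, opposite the C(i-1)/CA(i) bisector
    u1 <- C[i - 1, ] - N[i, ]; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- CA[i, ] - N[i, ]; u2 <- u2 / sqrt(sum(u2^2))
    hd <- -(u1 + u2); hd <- hd / sqrt(sum(hd^2))
    H[i, ] <- N[i, ] + g$b_n_h * hd
  }
  # last O: reuse the helical psi
  O[n_residues, ] <- nerf_place(N[n_residues, ], CA[n_residues, ],
                                C[n_residues, ], g$b_c_o, g$ang_ca_c_o,
                                g$psi + 180)
  list(N = N, CA = CA, C = C, O = O, H = H)
}

#' Single-frame ideal alpha-helix fixture
#'
#' Backbone (N, H, CA, C, O) of an ideal straight alpha-helix
#' (phi = -57, psi = -47, standard bond geometry).  Such a helix of *n*
#' residues has exactly *n* - 4 backbone i+4 -> i hydrogen bonds, which
#' makes it the canonical fixture for the H-bond detector.
#'
#' @param n_residues Number of residues (>= 5 for any H-bond to exist).
#' @param chain_id Chain label.
#' @param first_residue Author number of the first residue.
#' @param with_hydrogens Include amide hydrogens (residue 1 has none).
#' @return Atom tibble (one frame) as in a [conformation_ensemble].
#' @export
ideal_helix_frame <- function(n_residues = 20, chain_id = "A",
                              first_residue = 1, with_hydrogens = TRUE) {
  bb <- ideal_helix_backbone(n_residues)
  res <- seq(first_residue, length.out = n_residues)
  rows <- purrr::map_dfr(seq_len(n_residues), function(i) {
    nm <- c("N", if (with_hydrogens && !any(is.na(bb$H[i, ]))) "H",
            "CA", "C", "O")
    pos <- rbind(bb$N[i, ],
                 if (with_hydrogens && !any(is.na(bb$H[i, ]))) bb$H[i, ],
                 bb$CA[i, ], bb$C[i, ], bb$O[i, ])
    tibble(frame = 1L, time_ps = 0, chain_id = chain_id,
           residue_index = res[i], residue_name = "ALA", atom_name = nm,
           x_nm = pos[, 1], y_nm = pos[, 2], z_nm = pos[, 3])
  })
  rows
}

# cylindrical parameters of backbone atoms around the ideal helix axis,
# measured once from a long internally built helix; cached per session
.helix_cyl_cache <- new.env(parent = emptyenv())
helix_cyl_params <- function() {
  if (!is.null(.helix_cyl_cache$params)) return(.helix_cyl_cache$params)
  n <- 41
  bb <- ideal_helix_backbone(n)
  mid <- 11:30
  ca <- bb$CA
  ctr <- colMeans(ca)
  pc <- prcomp(ca, center = TRUE)
  e3 <- pc$rotation[, 1]
  if (sum((ca[n, ] - ca[1, ]) * e3) < 0) e3 <- -e3
  e1 <- pc$rotation[, 2]; e1 <- e1 - sum(e1 * e3) * e3
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  cyl <- function(p) {
    rel <- sweep(p, 2, ctr)
    z <- rel %*% e3
    x <- rel %*% e1; y <- rel %*% e2
    list(z = as.vector(z), r = sqrt(x^2 + y^2)[, 1],
         ph = atan2(y, x)[, 1])
  }
  cca <- cyl(ca)
  # unwrap CA phases and fit twist/rise per residue over the middle stretch
  ph <- cca$ph
  for (i in 2:n) {
    while (ph[i] - ph[i - 1] > pi) ph[i] <- ph[i] - 2 * pi
    while (ph[i] - ph[i - 1] < -pi) ph[i] <- ph[i] + 2 * pi
  }
  idx <- mid
  twist <- coef(lm(ph[idx] ~ idx))[["idx"]]
  rise <- coef(lm(cca$z[idx] ~ idx))[["idx"]]
  per_type <- function(p) {
    cc <- cyl(p)
    dph <- (cc$ph - ph + pi) %% (2 * pi) - pi
    dz <- cc$z - cca$z
    list(r = mean(cc$r[idx]), dph = mean(dph[idx]), dz = mean(dz[idx]))
  }
  params <- list(
    twist_rad = twist, rise_nm = rise, r_ca = mean(cca$r[idx]),
    types = list(CA = list(r = mean(cca$r[idx]), dph = 0, dz = 0),
                 N = per_type(bb$N), C = per_type(bb$C),
                 O = per_type(bb$O), H = per_type(bb$H))
  )
  .helix_cyl_cache$params <- params
  params
}

#' Build a pseudo-atomic coiled-coil ensemble around a worm-like chain
#'
#' Interpolates a smooth centerline through each frame's chain vertices,
#' transports a reference frame along it, and places two parallel chains of
#' backbone atoms helically around axes offset by `inter_axis_radius_nm` on
#' opposite sides of the centerline.  Atom positions use cylindrical
#' (radius, phase, rise) offsets measured from an internally built ideal
#' straight alpha-helix, so local backbone geometry — including the i+4 -> i
#' hydrogen-bonding pattern — stays essentially ideal for gentle bends.
#' Feeding the result to [build_axis()] with the matching segment scheme
#' recovers the worm-like-chain centerline.
#'
#' @param wlc A `wlc_ensemble` from [sample_wlc_ensemble()]; its contour
#'   length must match `(n_residues - 1) * rise_per_residue_nm` within 5%.
#' @param chain_ids Two chain labels.
#' @param first_residue,last_residue Author numbering of the modelled
#'   segment (defaults 106-216).
#' @param inter_axis_radius_nm Distance of each chain's helical axis from
#'   the centerline (default 0.49 nm, i.e. helices ~0.98 nm apart).
#' @param rise_per_residue_nm Axial rise per residue (default 0.1485 nm).
#' @param backbone `"CA-only"` (default) or `"N-CA-C-O"` for the full
#'   main chain (enables the H-bond stage).
#' @param with_hydrogens Add amide hydrogens (only with `"N-CA-C-O"`).
#'   On by default because at standard alpha-helix geometry the i+2 and
#'   i+3 carbonyls also sit within the 0.35 nm donor-acceptor cutoff, so
#'   distance-only counting triple-counts the helical bond pattern; the
#'   H-N-O angle criterion isolates the true i+4 -> i bonds.
#' @param frame_spacing_ps Snapshot spacing for the timestamps.
#' @param temperature_K Bath temperature attached to the ensemble.
#' @return A [conformation_ensemble].
#' @export
build_coiled_coil_ensemble <- function(wlc, chain_ids = c("A", "B"),
                                       first_residue = 106,
                                       last_residue = 216,
                                       inter_axis_radius_nm = 0.49,
                                       rise_per_residue_nm = 0.1485,
                                       backbone = c("CA-only", "N-CA-C-O"),
                                       with_hydrogens = TRUE,
                                       frame_spacing_ps = 10,
                                       temperature_K = 300) {
  backbone <- match.arg(backbone)
  if (inter_axis_radius_nm <= 0) abort("inter-axis radius must be positive")
  n_res <- last_residue - first_residue + 1L
  if (n_res < 11) abort("residue span too short for a segment scheme")
  n_v <- dim(wlc$vertices)[1]
  wlc_len <- (n_v - 1) * wlc$b_nm
  target_len <- (n_res - 1) * rise_per_residue_nm
  # the polygon vertices are segment centroids, so the chain overhangs the
  # vertex span by up to half a segment at each end
  extra <- (target_len - wlc_len) / 2
  if (extra < -1e-9 || extra > wlc$b_nm + 1e-9) {
    abort(sprintf(
      "span/rise inconsistency: chain contour %.3f nm vs vertex span %.3f nm",
      target_len, wlc_len))
  }
  hp <- helix_cyl_params()
  atom_types <- if (backbone == "CA-only") "CA" else {
    c("N", if (with_hydrogens) "H", "CA", "C", "O")
  }
  nf <- wlc$n_frames
  u <- (seq_len(n_v) - 1) * wlc$b_nm
  s_res <- (seq_len(n_res) - 1) * rise_per_residue_nm - extra
  res_ids <- seq(first_residue, last_residue)

  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    V <- wlc$vertices[, , f]
    sx <- splinefun(u, V[, 1], method = "natural")
    sy <- splinefun(u, V[, 2], method = "natural")
    sz <- splinefun(u, V[, 3], method = "natural")
    C <- cbind(sx(s_res), sy(s_res), sz(s_res))
    Tg <- cbind(sx(s_res, deriv = 1), sy(s_res, deriv = 1),
                sz(s_res, deriv = 1))
    Tg <- Tg / sqrt(rowSums(Tg^2))
    # parallel-transported (rotation-minimizing) frame
    Nrm <- matrix(0, n_res, 3)
    h <- if (abs(Tg[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n0 <- h - sum(h * Tg[1, ]) * Tg[1, ]
    Nrm[1, ] <- n0 / sqrt(sum(n0^2))
    for (r in 2:n_res) {
      v <- Nrm[r - 1, ] - sum(Nrm[r - 1, ] * Tg[r, ]) * Tg[r, ]
      Nrm[r, ] <- v / sqrt(sum(v^2))
    }
    Bn <- row_cross(Tg, Nrm)

    per_chain <- lapply(seq_along(chain_ids), function(ci) {
      sgn <- if (ci == 1) 1 else -1
      axis_pts <- C + sgn * inter_axis_radius_nm * Nrm
      purrr::map_dfr(atom_types, function(at) {
        tp <- hp$types[[at]]
        ph <- hp$twist_rad * (seq_len(n_res) - 1) + tp$dph
        pos <- axis_pts + tp$r * (cos(ph) * Nrm + sin(ph) * Bn) + tp$dz * Tg
        tibble(chain_id = chain_ids[ci], residue_index = res_ids,
               atom_name = at, x_nm = pos[, 1], y_nm = pos[, 2],
               z_nm = pos[, 3])
      })
    })
    fr <- bind_rows(per_chain)
    # fixed atom order: chain, residue, backbone order
    fr <- fr[order(match(fr$chain_id, chain_ids), fr$residue_index,
                   match(fr$atom_name, c("N", "H", "CA", "C", "O"))), ]
    fr$frame <- f
    fr$time_ps <- (f - 1) * frame_spacing_ps
    fr$residue_name <- "ALA"
    frames[[f]] <- fr
  }
  conformation_ensemble(bind_rows(frames), chain_ids, temperature_K)
}

#' Rigid-rod coiled-coil ensemble (degenerate fixture)
#'
#' Identical straight coiled-coil frames, optionally with independent
#' Gaussian coordinate jitter.  With zero jitter the persistence pipeline
#' must report an infinite persistence length and all region H-bond
#' standard deviations must vanish.
#'
#' @param n_frames Number of (identical) frames.
#' @param jitter_nm Standard deviation of per-coordinate Gaussian noise
#'   (0 = exactly rigid).
#' @param seed Optional seed for the jitter.
#' @inheritParams build_coiled_coil_ensemble
#' @return A [conformation_ensemble].
#' @export
rigid_rod_ensemble <- function(n_frames = 50, jitter_nm = 0, seed = NULL,
                               chain_ids = c("A", "B"), first_residue = 106,
                               last_residue = 216,
                               inter_axis_radius_nm = 0.49,
                               rise_per_residue_nm = 0.1485,
                               backbone = "N-CA-C-O",
                               with_hydrogens = TRUE,
                               frame_spacing_ps = 10, temperature_K = 300) {
  if (jitter_nm < 0) abort("jitter must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n_res <- last_residue - first_residue + 1L
  b <- (n_res - 1) * rise_per_residue_nm / 10
  n_v <- 11L
  vertices <- array(0, dim = c(n_v, 3L, n_frames))
  vertices[, 3, ] <- (seq_len(n_v) - 1) * b
  tangents <- array(0, dim = c(n_v - 1L, 3L, n_frames))
  tangents[, 3, ] <- 1
  wlc <- structure(list(vertices = vertices, tangents = tangents,
                        s_nm = (seq_len(n_v - 1L) - 1) * b, b_nm = b,
                        lp_true_nm = Inf, intrinsic_bend_deg = 0,
                        bend_axis = c(1, 0, 0), soft_joint = NULL,
                        n_frames = n_frames, seed = seed),
                   class = "wlc_ensemble")
  ens <- build_coiled_coil_ensemble(
    wlc, chain_ids = chain_ids, first_residue = first_residue,
    last_residue = last_residue,
    inter_axis_radius_nm = inter_axis_radius_nm,
    rise_per_residue_nm = rise_per_residue_nm, backbone = backbone,
    with_hydrogens = with_hydrogens, frame_spacing_ps = frame_spacing_ps,
    temperature_K = temperature_K)
  if (jitter_nm > 0) {
    ens$x_nm <- ens$x_nm + rnorm(nrow(ens), sd = jitter_nm)
    ens$y_nm <- ens$y_nm + rnorm(nrow(ens), sd = jitter_nm)
    ens$z_nm <- ens$z_nm + rnorm(nrow(ens), sd = jitter_nm)
  }
  ens
}
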