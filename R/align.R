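#' Discard the equilibration portion of an ensemble
#'
#' Removes all frames earlier than `t_start_ps`, the standard trick for
#' dropping the relaxation transient before computing ensemble averages
#' (e.g. keeping 20-100 ns of a 100 ns trajectory saved every 10 ps leaves
#' 8000 frames).
#'
#' @param ens A [conformation_ensemble].
#' @param t_start_ps Keep frames with `time_ps >= t_start_ps`; must lie
#'   before the last frame time.
#' @return The trimmed [conformation_ensemble]; frames are renumbered from 1.
#' @export
trim_equilibration <- function(ens, t_start_ps) {
  times <- ens_times(ens)
  if (t_start_ps >= max(times)) {
    abort(paste0("t_start_ps (", t_start_ps,
                 ") is at or beyond the last frame time (", max(times), ")"))
  }
  keep_frames <- unique(ens$frame)[times >= t_start_ps]
  out <- ens[ens$frame %in% keep_frames, , drop = FALSE]
  if (nrow(out) == 0) abort("trimming removed every frame")
  out$frame <- match(out$frame, keep_frames)
  conformation_ensemble(out, attr(ens, "chain_ids"),
                        attr(ens, "temperature_K"), validate = FALSE)
}

#' Remove rigid-body motion by iterative superposition
#'
#' Least-squares (Kabsch) superposition of every frame onto an iteratively
#' refined mean structure of the selected atoms: frames are first fitted to
#' frame 1, then twice re-fitted to the running mean.  Each frame undergoes a
#' proper rotation plus translation only, so all intra-frame distances are
#' preserved exactly.  Superposing fixes the body frame in which the
#' time-averaged tangent of the correlation analysis is meaningful.
#'
#' @param ens A [conformation_ensemble].
#' @param selection A [selection_spec]; defaults to all C-alpha atoms of both
#'   chains. At least 3 non-collinear atoms are required.
#' @param max_passes Upper bound on mean-structure refinement passes; the
#'   iteration stops early once coordinates change by less than 1e-12 nm
#'   (2-3 passes suffice in practice).
#' @return The superposed [conformation_ensemble].
#' @export
superpose <- function(ens, selection = selection_spec(), max_passes = 50) {
  idx <- selection_indices(ens, selection)
  if (length(idx) < 3) abort("superposition needs at least 3 selected atoms")
  xyz <- ens_xyz_matrix(ens)
  xi <- bio3d::atom2xyz(idx)

  ref_coords <- matrix(xyz[1, xi], ncol = 3, byrow = TRUE)
  sv <- svd(scale(ref_coords, scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-12)) {
    abort("selected atoms are collinear or degenerate; cannot superpose")
  }

  fitted <- bio3d::fit.xyz(fixed = xyz[1, ], mobile = xyz,
                           fixed.inds = xi, mobile.inds = xi)
  for (pass in seq_len(max_passes)) {
    mean_ref <- colMeans(fitted)
    new_fit <- bio3d::fit.xyz(fixed = mean_ref, mobile = fitted,
                              fixed.inds = xi, mobile.inds = xi)
    delta <- max(abs(new_fit - fitted))
    fitted <- new_fit
    if (delta < 1e-12) break
  }
  # anchor the converged configuration by rigidly mapping its mean onto the
  # input's first frame; for an already-superposed ensemble this map is the
  # identity, which makes the operation idempotent
  mean_sel <- matrix(colMeans(fitted)[xi], ncol = 3, byrow = TRUE)
  tr <- kabsch_transform(mean_sel, ref_coords)
  for (f in seq_len(nrow(fitted))) {
    m <- matrix(fitted[f, ], ncol = 3, byrow = TRUE)
    m <- sweep(m %*% t(tr$rotation), 2, tr$translation, "+")
    fitted[f, ] <- as.vector(t(m))
  }
  ens_set_xyz(ens, fitted)
}

# rigid transform (rotation, translation) carrying `from` onto `to` in the
# least-squares sense; both are n x 3 matrices
kabsch_transform <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  H <- crossprod(sweep(from, 2, cf), sweep(to, 2, ct))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = rot, translation = as.vector(ct - rot %*% cf))
}

#' Per-frame best-fit RMSD from a reference structure
#'
#' The classic equilibration diagnostic: each frame is rigidly superposed
#' onto the reference over the selected atoms and the root-mean-square
#' deviation of those atoms is reported against time.
#'
#' @param ens A [conformation_ensemble].
#' @param selection A [selection_spec]; default all C-alpha atoms.
#' @param reference Reference coordinates: a single-frame tibble with the
#'   same atom layout as `ens` (e.g. `dplyr::filter(ens, frame == 1)`), or
#'   `NULL` to use the first frame.
#' @return Tibble with columns `frame`, `time_ps`, `rmsd_nm`.
#' @export
rmsd_timecourse <- function(ens, selection = selection_spec(),
                            reference = NULL) {
  idx <- selection_indices(ens, selection)
  xi <- bio3d::atom2xyz(idx)
  xyz <- ens_xyz_matrix(ens)
  if (is.null(reference)) {
    ref <- xyz[1, ]
  } else {
    reference <- as_tibble(reference)
    nf <- length(unique(reference$frame %||% 1))
    if (nf != 1) abort("reference must be a single frame")
    if (nrow(reference) * 3 != ncol(xyz)) {
      abort("reference atom layout does not match the ensemble")
    }
    ref <- as.vector(rbind(reference$x_nm, reference$y_nm, reference$z_nm))
  }
  fitted <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                           fixed.inds = xi, mobile.inds = xi)
  dev <- fitted[, xi, drop = FALSE] -
    matrix(ref[xi], nrow(fitted), length(xi), byrow = TRUE)
  r <- sqrt(rowMeans(dev^2) * 3)  # mean over atoms, not coordinates
  tibble(frame = unique(ens$frame), time_ps = ens_times(ens), rmsd_nm = r)
}
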