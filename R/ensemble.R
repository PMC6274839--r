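#' Conformational ensemble of a two-chain coiled-coil
#'
#' A `conformation_ensemble` is a tibble with one row per atom per frame and
#' columns `frame` (1-based frame index), `time_ps`, `chain_id`,
#' `residue_index` (author numbering, inclusive), `residue_name`, `atom_name`,
#' and coordinates `x_nm`, `y_nm`, `z_nm` in nanometres.  Two attributes carry
#' ensemble-level metadata: `chain_ids` (exactly two labels) and
#' `temperature_K` (absolute temperature of the simulated or sampled bath).
#'
#' Atom ordering must be identical in every frame; this invariant is checked
#' at construction and is what allows the analysis stages to treat the table
#' as a dense `atoms x 3 x frames` array internally.
#'
#' @param atoms Data frame with the columns listed above (`residue_name` is
#'   optional and defaults to `"UNK"`; `time_ps` defaults to
#'   `(frame - 1) * 10`).
#' @param chain_ids Character vector of exactly two chain labels. Defaults to
#'   the chains present in `atoms`.
#' @param temperature_K Absolute temperature in kelvin (> 0).
#' @param validate Set `FALSE` to skip invariant checks (internal fast path).
#'
#' @return A `conformation_ensemble` tibble.
#' @examples
#' atoms <- tidyr::expand_grid(frame = 1:3, chain_id = c("A", "B"),
#'                             residue_index = 1:5)
#' atoms <- dplyr::mutate(atoms, atom_name = "CA", residue_name = "ALA",
#'                        x_nm = residue_index * 0.15,
#'                        y_nm = ifelse(chain_id == "A", 0.5, -0.5), z_nm = 0,
#'                        time_ps = (frame - 1) * 10)
#' ens <- conformation_ensemble(atoms, temperature_K = 300)
#' n_frames(ens)
#' @export
conformation_ensemble <- function(atoms, chain_ids = NULL, temperature_K = 300,
                                  validate = TRUE) {
  atoms <- as_tibble(atoms)
  req <- c("frame", "chain_id", "residue_index", "atom_name",
           "x_nm", "y_nm", "z_nm")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("ensemble table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"residue_name" %in% names(atoms)) atoms$residue_name <- "UNK"
  if (!"time_ps" %in% names(atoms)) atoms$time_ps <- (atoms$frame - 1) * 10
  atoms$frame <- as.integer(atoms$frame)
  atoms$residue_index <- as.integer(atoms$residue_index)
  atoms <- atoms[order(atoms$frame), , drop = FALSE]
  chain_ids <- chain_ids %||% sort(unique(atoms$chain_id))

  if (validate) {
    if (length(chain_ids) != 2) {
      abort("a conformation ensemble has exactly two chains")
    }
    if (!is.numeric(temperature_K) || length(temperature_K) != 1 ||
        !is.finite(temperature_K) || temperature_K <= 0) {
      abort("temperature_K must be a single positive number")
    }
    for (ch in chain_ids) {
      if (!any(atoms$chain_id == ch)) {
        abort(paste0("chain ", ch, " not found"))
      }
    }
    if (!all(is.finite(atoms$x_nm)) || !all(is.finite(atoms$y_nm)) ||
        !all(is.finite(atoms$z_nm))) {
      abort("non-finite coordinates in ensemble")
    }
    frames <- unique(atoms$frame)
    if (length(frames) < 2) {
      abort("an ensemble needs at least two frames")
    }
    counts <- tabulate(match(atoms$frame, frames))
    if (length(unique(counts)) != 1) {
      bad <- frames[counts != counts[1]]
      abort(paste0("frames with differing atom counts: ",
                   paste(head(bad, 10), collapse = ", ")))
    }
    n_at <- counts[1]
    key <- paste(atoms$chain_id, atoms$residue_index, atoms$atom_name)
    key1 <- key[seq_len(n_at)]
    if (!all(key == rep(key1, times = length(frames)))) {
      abort("atom ordering differs between frames")
    }
    for (ch in chain_ids) {
      in_f1 <- atoms$chain_id[seq_len(n_at)] == ch
      if (!any(in_f1)) abort(paste0("chain ", ch, " not found in frame 1"))
    }
  }

  new_tibble(atoms, class = "conformation_ensemble",
             chain_ids = chain_ids, temperature_K = temperature_K)
}

#' @rdname conformation_ensemble
#' @param x,ens A `conformation_ensemble`.
#' @export
n_frames <- function(ens) length(unique(ens$frame))

#' @rdname conformation_ensemble
#' @export
ensemble_temperature <- function(ens) attr(ens, "temperature_K")

#' @rdname conformation_ensemble
#' @export
ensemble_chains <- function(ens) attr(ens, "chain_ids")

#' @export
print.conformation_ensemble <- function(x, ...) {
  nf <- n_frames(x)
  cat(sprintf(
    "<conformation_ensemble> %d frames x %d atoms; chains %s; T = %g K\n",
    nf, nrow(x) / nf, paste(attr(x, "chain_ids"), collapse = ","),
    attr(x, "temperature_K")))
  NextMethod()
}

# ---- internal dense-array view ---------------------------------------------

# per-frame atom metadata (frame 1 rows, coordinates dropped)
ens_atom_meta <- function(ens) {
  nf <- n_frames(ens)
  n_at <- nrow(ens) / nf
  meta <- ens[seq_len(n_at),
              c("chain_id", "residue_index", "residue_name", "atom_name")]
  as_tibble(meta)
}

# coordinates as an [atoms, 3, frames] array (nm)
ens_coords_array <- function(ens) {
  nf <- n_frames(ens)
  n_at <- nrow(ens) / nf
  arr <- array(0, dim = c(n_at, 3L, nf))
  arr[, 1L, ] <- matrix(ens$x_nm, n_at, nf)
  arr[, 2L, ] <- matrix(ens$y_nm, n_at, nf)
  arr[, 3L, ] <- matrix(ens$z_nm, n_at, nf)
  arr
}

# coordinates as a bio3d-style [frames, 3*atoms] xyz matrix (nm)
ens_xyz_matrix <- function(ens) {
  arr <- ens_coords_array(ens)
  n_at <- dim(arr)[1]; nf <- dim(arr)[3]
  m <- matrix(0, nf, 3L * n_at)
  for (k in 1:3) m[, seq(k, 3L * n_at, by = 3L)] <- t(arr[, k, ])
  m
}

# write a [frames, 3*atoms] xyz matrix back into the ensemble tibble
ens_set_xyz <- function(ens, xyz) {
  nf <- n_frames(ens)
  n_at <- nrow(ens) / nf
  out <- ens
  out$x_nm <- as.vector(t(xyz[, seq(1, 3 * n_at, by = 3), drop = FALSE]))
  out$y_nm <- as.vector(t(xyz[, seq(2, 3 * n_at, by = 3), drop = FALSE]))
  out$z_nm <- as.vector(t(xyz[, seq(3, 3 * n_at, by = 3), drop = FALSE]))
  out
}

# per-frame times (one per frame, in frame order)
ens_times <- function(ens) {
  nf <- n_frames(ens)
  n_at <- nrow(ens) / nf
  ens$time_ps[seq(1, nrow(ens), by = n_at)]
}

#' Atom selection specification
#'
#' Describes which atoms participate in a superposition or RMSD computation:
#' both chains, an inclusive author-numbered residue interval, and a set of
#' atom names (default the C-alpha trace).
#'
#' @param chain_ids Two chain labels, or `NULL` for the ensemble's chains.
#' @param residue_range Inclusive integer interval `c(first, last)`.
#' @param atom_names Character vector of atom names.
#' @return A `selection_spec` list.
#' @export
selection_spec <- function(chain_ids = NULL, residue_range = NULL,
                           atom_names = "CA") {
  if (!is.null(residue_range)) {
    if (length(residue_range) != 2 || residue_range[2] < residue_range[1]) {
      abort("residue_range must be an inclusive interval c(first, last)")
    }
  }
  structure(list(chain_ids = chain_ids, residue_range = residue_range,
                 atom_names = atom_names),
            class = "selection_spec")
}

# resolve a selection to atom row indices within one frame
selection_indices <- function(ens, selection) {
  meta <- ens_atom_meta(ens)
  chains <- selection$chain_ids %||% attr(ens, "chain_ids")
  keep <- meta$chain_id %in% chains & meta$atom_name %in% selection$atom_names
  if (!is.null(selection$residue_range)) {
    keep <- keep & meta$residue_index >= selection$residue_range[1] &
      meta$residue_index <= selection$residue_range[2]
    for (ch in chains) {
      want <- seq(selection$residue_range[1], selection$residue_range[2])
      have <- unique(meta$residue_index[meta$chain_id == ch & keep])
      miss <- setdiff(want, have)
      if (length(miss) > 0) {
        abort(paste0("chain ", ch, " lacks selected residue(s) ",
                     paste(head(miss, 5), collapse = ", ")))
      }
    }
  }
  idx <- which(keep)
  if (length(idx) == 0) abort("selection matches no atoms")
  idx
}
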