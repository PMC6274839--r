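#' Geometric criterion for main-chain hydrogen bonds
#'
#' A backbone amide N-H donating to a backbone carbonyl O is counted when
#' the donor-acceptor N...O distance is at most `max_da_nm` and, whenever an
#' amide hydrogen is present, the H-N...O angle at the donor nitrogen is at
#' most `max_angle_deg` (the common MD-analysis convention of 0.35 nm /
#' 30 degrees).  With `require_hydrogen = FALSE` the angle condition is
#' simply skipped for donors without a hydrogen, which is the distance-only
#' fallback used for hydrogen-free pseudo-atomic backbones.
#'
#' @param max_da_nm Donor-acceptor N...O cutoff, nm (> 0; default 0.35).
#' @param max_angle_deg H-N...O angle cutoff, degrees in (0, 90];
#'   default 30.
#' @param require_hydrogen If `TRUE`, detection on a frame without amide
#'   hydrogens is an error rather than silently falling back to
#'   distance-only counting.
#' @return An `hbond_criterion` list.
#' @export
hbond_criterion <- function(max_da_nm = 0.35, max_angle_deg = 30,
                            require_hydrogen = FALSE) {
  if (max_da_nm <= 0) abort("distance cutoff must be positive")
  if (max_angle_deg <= 0 || max_angle_deg > 90) {
    abort("angle cutoff must lie in (0, 90] degrees")
  }
  structure(list(max_da_nm = max_da_nm, max_angle_deg = max_angle_deg,
                 require_hydrogen = require_hydrogen),
            class = "hbond_criterion")
}

# index map of backbone donors/acceptors in one frame layout
hbond_index_map <- function(meta) {
  ni <- which(meta$atom_name == "N")
  oi <- which(meta$atom_name == "O")
  hi <- which(meta$atom_name %in% c("H", "HN"))
  if (length(ni) == 0 || length(oi) == 0) {
    abort("backbone N and O atoms are required for H-bond detection")
  }
  hmatch <- match(paste(meta$chain_id[ni], meta$residue_index[ni]),
                  paste(meta$chain_id[hi], meta$residue_index[hi]))
  list(
    n_idx = ni, o_idx = oi, h_idx = hi[hmatch],  # h_idx NA where no H
    don_chain = meta$chain_id[ni], don_res = meta$residue_index[ni],
    acc_chain = meta$chain_id[oi], acc_res = meta$residue_index[oi]
  )
}

# core detection on a coordinate matrix [atoms, 3] given an index map
detect_hbonds_coords <- function(xyz, map, criterion) {
  if (criterion$require_hydrogen && all(is.na(map$h_idx))) {
    abort(paste0("no amide hydrogens present; rerun with a criterion where ",
                 "require_hydrogen = FALSE for distance-only counting"))
  }
  nd <- length(map$n_idx); na_ <- length(map$o_idx)
  npos <- xyz[map$n_idx, , drop = FALSE]
  opos <- xyz[map$o_idx, , drop = FALSE]
  d2 <- outer(rowSums(npos^2), rep(1, na_)) +
    outer(rep(1, nd), rowSums(opos^2)) - 2 * npos %*% t(opos)
  d2[d2 < 0] <- 0
  within <- d2 <= criterion$max_da_nm^2
  # exclude self and sequence-adjacent pairs within the same chain
  same_chain <- outer(map$don_chain, map$acc_chain, "==")
  near_seq <- abs(outer(map$don_res, map$acc_res, "-")) < 2
  within[same_chain & near_seq] <- FALSE
  hits <- which(within, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(tibble(donor_chain = character(), donor_res = integer(),
                  acceptor_chain = character(), acceptor_res = integer(),
                  distance_nm = numeric(), angle_deg = numeric()))
  }
  di <- hits[, 1]; ai <- hits[, 2]
  dist_nm <- sqrt(d2[hits])
  ang <- rep(NA_real_, length(di))
  hh <- map$h_idx[di]
  has_h <- !is.na(hh)
  if (any(has_h)) {
    nh <- xyz[hh[has_h], , drop = FALSE] - npos[di[has_h], , drop = FALSE]
    no <- opos[ai[has_h], , drop = FALSE] - npos[di[has_h], , drop = FALSE]
    cosang <- rowSums(nh * no) /
      (sqrt(rowSums(nh^2)) * sqrt(rowSums(no^2)))
    cosang <- pmin(1, pmax(-1, cosang))
    ang[has_h] <- acos(cosang) * 180 / pi
  }
  keep <- is.na(ang) | ang <= criterion$max_angle_deg
  tibble(donor_chain = map$don_chain[di], donor_res = map$don_res[di],
         acceptor_chain = map$acc_chain[ai], acceptor_res = map$acc_res[ai],
         distance_nm = dist_nm, angle_deg = ang)[keep, , drop = FALSE]
}

#' Detect main-chain hydrogen bonds in one frame
#'
#' Considers every backbone N-H...O=C pair (intra- and inter-chain) whose
#' donor and acceptor are at least two residues apart in sequence when on
#' the same chain, and applies the geometric criterion.
#'
#' @param frame_atoms A single frame: an atom tibble (as in a
#'   [conformation_ensemble]) containing backbone `N` and `O` atoms and
#'   optionally amide `H`.
#' @param criterion An [hbond_criterion()].
#' @return Tibble of bonds: `donor_chain`, `donor_res`, `acceptor_chain`,
#'   `acceptor_res`, `distance_nm`, `angle_deg` (`NA` when no hydrogen).
#' @examples
#' helix <- ideal_helix_frame(20)
#' nrow(detect_mainchain_hbonds(helix))  # 16 = 20 - 4
#' @export
detect_mainchain_hbonds <- function(frame_atoms,
                                    criterion = hbond_criterion()) {
  frame_atoms <- as_tibble(frame_atoms)
  if ("frame" %in% names(frame_atoms) &&
      length(unique(frame_atoms$frame)) > 1) {
    abort("frame_atoms spans several frames; filter to one frame first")
  }
  map <- hbond_index_map(frame_atoms)
  xyz <- as.matrix(frame_atoms[, c("x_nm", "y_nm", "z_nm")])
  detect_hbonds_coords(xyz, map, criterion)
}

#' Residue regions for hydrogen-bond bookkeeping
#'
#' A region is a named set of inclusive, non-overlapping author-numbered
#' residue intervals (possibly disjoint), counted over both chains.
#' `hbond_regions()` builds the region table from a named list of interval
#' matrices/vectors; `tpm_middle_regions()` returns the three regions
#' conventionally used for the tropomyosin middle fragment: the flanks of
#' the trypsin-cleavage neighbourhood (106-129 plus 138-160), the
#' cleavage-site neighbourhood itself (129-138), and the C-terminal half
#' (161-215).
#'
#' @param ... Named intervals: each argument is `c(first, last)` or a
#'   two-column matrix of intervals.
#' @return Tibble with columns `region`, `res_first`, `res_last`.
#' @export
hbond_regions <- function(...) {
  args <- list(...)
  if (length(args) == 0 || is.null(names(args)) || any(names(args) == "")) {
    abort("every region must be named")
  }
  out <- purrr::imap_dfr(args, function(iv, nm) {
    m <- if (is.matrix(iv)) iv else matrix(iv, ncol = 2, byrow = TRUE)
    tibble(region = nm, res_first = as.integer(m[, 1]),
           res_last = as.integer(m[, 2]))
  })
  if (any(out$res_last < out$res_first)) {
    abort("interval end before start")
  }
  for (nm in unique(out$region)) {
    iv <- out[out$region == nm, , drop = FALSE]
    iv <- iv[order(iv$res_first), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv$res_first[-1] <= iv$res_last[-nrow(iv)])) {
      abort(paste0("overlapping intervals within region ", nm))
    }
  }
  out
}

#' @rdname hbond_regions
#' @export
tpm_middle_regions <- function() {
  hbond_regions(
    "106-129,138-160" = rbind(c(106, 129), c(138, 160)),
    "129-138" = c(129, 138),
    "161-215" = c(161, 215)
  )
}

#' Region-wise hydrogen-bond statistics over an ensemble
#'
#' Detects main-chain hydrogen bonds in every frame and assigns each bond
#' to a region if its donor residue lies in one of the region's intervals
#' (either chain; counts are summed over both chains).  Reports the mean
#' and standard deviation of the per-frame counts per region.
#'
#' @param ens A [conformation_ensemble] with backbone N and O atoms.
#' @param regions Region table from [hbond_regions()] /
#'   [tpm_middle_regions()].
#' @param criterion An [hbond_criterion()].
#' @param per_frame If `TRUE`, return the long per-frame count table
#'   instead of the summary.
#' @return Summary tibble `region`, `mean`, `sd`, `n_frames`, or (with
#'   `per_frame = TRUE`) a tibble `frame`, `time_ps`, `region`, `count`.
#' @export
region_hbond_stats <- function(ens, regions = tpm_middle_regions(),
                               criterion = hbond_criterion(),
                               per_frame = FALSE) {
  regions <- as_tibble(regions)
  if (nrow(regions) == 0) abort("empty region table")
  meta <- ens_atom_meta(ens)
  covered <- range(meta$residue_index)
  if (any(regions$res_first < covered[1] | regions$res_last > covered[2])) {
    abort("region outside the ensemble residue coverage")
  }
  map <- hbond_index_map(meta)
  coords <- ens_coords_array(ens)
  nf <- dim(coords)[3]
  region_names <- unique(regions$region)
  counts <- matrix(0L, nf, length(region_names),
                   dimnames = list(NULL, region_names))
  for (f in seq_len(nf)) {
    bonds <- detect_hbonds_coords(coords[, , f], map, criterion)
    for (r in region_names) {
      iv <- regions[regions$region == r, , drop = FALSE]
      inr <- rep(FALSE, nrow(bonds))
      for (j in seq_len(nrow(iv))) {
        inr <- inr | (bonds$donor_res >= iv$res_first[j] &
                        bonds$donor_res <= iv$res_last[j])
      }
      counts[f, r] <- sum(inr)
    }
  }
  times <- ens_times(ens)
  if (per_frame) {
    return(tibble(
      frame = rep(seq_len(nf), times = length(region_names)),
      time_ps = rep(times, times = length(region_names)),
      region = rep(region_names, each = nf),
      count = as.integer(counts)
    ))
  }
  tibble(region = region_names,
         mean = unname(colMeans(counts)),
         sd = unname(apply(counts, 2, sd)),
         n_frames = nf)
}
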