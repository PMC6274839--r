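#' Segment scheme for the polygonal coiled-coil axis
#'
#' The coiled-coil axis is approximated by a polygon whose vertices are
#' midpoints between per-chain weighted centroids of short residue segments.
#' Consecutive segments share exactly one residue: segment *i* spans residues
#' `first + (i-1)*(L-1)` to `first + i*(L-1)` where `L` is the segment
#' length.  With the defaults (first residue 106, 11-residue segments,
#' 11 segments) the segments are 106-116, 116-126, ..., 206-216 — about
#' three helical turns each — and the shared endpoint residues carry weight
#' 1/2 so every residue contributes a total weight of one.
#'
#' @param first_residue First residue (author numbering) of segment 1.
#' @param segment_length Residues per segment (default 11).
#' @param n_segments Number of segments (>= 2).
#' @param endpoint_weight Weight of the first and last residue of each
#'   segment (default 0.5).
#' @return A `segment_scheme` list with a `segments` tibble
#'   (`segment`, `res_first`, `res_last`).
#' @export
segment_scheme <- function(first_residue = 106, segment_length = 11,
                           n_segments = 11, endpoint_weight = 0.5) {
  if (n_segments < 2) abort("need at least two segments")
  if (segment_length < 2) abort("segments need at least two residues")
  stride <- segment_length - 1
  segs <- tibble(
    segment = seq_len(n_segments),
    res_first = first_residue + (seq_len(n_segments) - 1) * stride,
    res_last = first_residue + seq_len(n_segments) * stride
  )
  structure(list(first_residue = first_residue,
                 segment_length = segment_length,
                 n_segments = n_segments,
                 endpoint_weight = endpoint_weight,
                 segments = segs),
            class = "segment_scheme")
}

#' @export
print.segment_scheme <- function(x, ...) {
  cat(sprintf("<segment_scheme> %d segments of %d residues, residues %d-%d\n",
              x$n_segments, x$segment_length, x$first_residue,
              max(x$segments$res_last)))
  invisible(x)
}

segment_weights <- function(scheme) {
  c(scheme$endpoint_weight,
    rep(1, scheme$segment_length - 2),
    scheme$endpoint_weight)
}

#' Weighted centroid of a point set
#'
#' @param positions Numeric matrix with one row per point and 3 columns, or a
#'   data frame with columns `x_nm`, `y_nm`, `z_nm`.
#' @param weights Non-negative weights, one per point, with positive sum.
#' @return Length-3 numeric vector, `sum(w * p) / sum(w)`.
#' @export
weighted_centroid <- function(positions, weights) {
  if (is.data.frame(positions)) {
    positions <- as.matrix(positions[, c("x_nm", "y_nm", "z_nm")])
  }
  positions <- as.matrix(positions)
  if (nrow(positions) != length(weights)) {
    abort("positions and weights lengths differ")
  }
  ws <- sum(weights)
  if (!is.finite(ws) || ws <= 0) abort("weights must have a positive sum")
  as.vector(crossprod(positions, weights)) / ws
}

# Weighted segment centroids of the C-alpha trace of one chain, all frames.
# Returns array [n_segments, 3, n_frames].
chain_segment_centroids <- function(coords, meta, chain, scheme) {
  w <- segment_weights(scheme)
  nf <- dim(coords)[3]
  out <- array(0, dim = c(scheme$n_segments, 3L, nf))
  for (i in seq_len(scheme$n_segments)) {
    resids <- seq(scheme$segments$res_first[i], scheme$segments$res_last[i])
    rows <- vapply(resids, function(r) {
      hit <- which(meta$chain_id == chain & meta$residue_index == r &
                     meta$atom_name == "CA")
      if (length(hit) == 0) {
        abort(paste0("missing CA atom: chain ", chain, ", residue ", r))
      }
      hit[1]
    }, integer(1))
    seg <- coords[rows, , , drop = FALSE]  # [L, 3, nf]
    for (k in 1:3) out[i, k, ] <- colSums(seg[, k, ] * w) / sum(w)
  }
  out
}

#' Build the polygonal molecular axis of a coiled-coil ensemble
#'
#' For every frame, weighted centroids of the C-alpha atoms of each residue
#' segment are computed per chain; the midpoint between the two chain
#' centroids is a polygon vertex, and unit vectors between consecutive
#' vertices are the axis tangents.  The arc-length coordinate of tangent *i*
#' is the cumulative time-mean vertex-to-vertex distance up to vertex *i*
#' (`s = 0` at the first tangent), giving the whole trajectory one fixed
#' abscissa.
#'
#' @param ens A [conformation_ensemble] with C-alpha atoms covering every
#'   scheme residue in both chains.
#' @param scheme A [segment_scheme].
#' @return An `axis_polyline`: list with `vertices` (`[n_vertices, 3,
#'   n_frames]` array, nm), `tangents` (`[n_tangents, 3, n_frames]` unit
#'   vectors), `s_nm` (arc-length of each tangent), `time_ps`, and the
#'   `scheme`.  Use [as_tibble()] for a long tangent table.
#' @export
build_axis <- function(ens, scheme = segment_scheme()) {
  coords <- ens_coords_array(ens)
  meta <- ens_atom_meta(ens)
  chains <- attr(ens, "chain_ids")
  ca <- chain_segment_centroids(coords, meta, chains[1], scheme)
  cb <- chain_segment_centroids(coords, meta, chains[2], scheme)
  vertices <- (ca + cb) / 2
  axis_from_vertices(vertices, ens_times(ens), scheme)
}

# shared constructor: vertices [n_v, 3, nf] -> axis_polyline
axis_from_vertices <- function(vertices, time_ps, scheme = NULL) {
  n_v <- dim(vertices)[1]; nf <- dim(vertices)[3]
  d <- vertices[-1, , , drop = FALSE] - vertices[-n_v, , , drop = FALSE]
  len <- sqrt(d[, 1, , drop = FALSE]^2 + d[, 2, , drop = FALSE]^2 +
                d[, 3, , drop = FALSE]^2)  # [n_t, 1, nf]
  if (any(len < 1e-12)) abort("coincident consecutive vertices")
  tangents <- array(0, dim = dim(d))
  for (k in 1:3) tangents[, k, ] <- d[, k, ] / len[, 1, ]
  seg_mean <- rowMeans(matrix(len, n_v - 1, nf))
  s <- cumsum(c(0, seg_mean[-(n_v - 1)]))
  structure(list(vertices = vertices, tangents = tangents, s_nm = s,
                 segment_mean_nm = seg_mean, time_ps = time_ps,
                 scheme = scheme),
            class = "axis_polyline")
}

#' @export
print.axis_polyline <- function(x, ...) {
  cat(sprintf(
    "<axis_polyline> %d vertices, %d tangents, %d frames; contour %.3f nm\n",
    dim(x$vertices)[1], dim(x$tangents)[1], dim(x$vertices)[3],
    sum(x$segment_mean_nm)))
  invisible(x)
}

#' @method as_tibble axis_polyline
#' @export
as_tibble.axis_polyline <- function(x, ...) {
  n_t <- dim(x$tangents)[1]; nf <- dim(x$tangents)[3]
  tibble(
    frame = rep(seq_len(nf), each = n_t),
    time_ps = rep(x$time_ps, each = n_t),
    position = rep(seq_len(n_t), nf),
    s_nm = rep(x$s_nm, nf),
    tx = as.vector(x$tangents[, 1, ]),
    ty = as.vector(x$tangents[, 2, ]),
    tz = as.vector(x$tangents[, 3, ])
  )
}

#' Inter-helix distance profile
#'
#' Distances between the two chains' segment centroids, frame by frame,
#' summarised as mean and standard deviation per segment — the local
#' separation of the two alpha-helices along the coiled-coil.
#'
#' @inheritParams build_axis
#' @return Tibble with columns `segment`, `res_first`, `res_last`,
#'   `d_mean_nm`, `d_sd_nm`, `n_frames`.
#' @export
helix_distance_profile <- function(ens, scheme = segment_scheme()) {
  coords <- ens_coords_array(ens)
  meta <- ens_atom_meta(ens)
  chains <- attr(ens, "chain_ids")
  ca <- chain_segment_centroids(coords, meta, chains[1], scheme)
  cb <- chain_segment_centroids(coords, meta, chains[2], scheme)
  nf <- dim(ca)[3]
  dd <- sqrt((ca[, 1, ] - cb[, 1, ])^2 + (ca[, 2, ] - cb[, 2, ])^2 +
               (ca[, 3, ] - cb[, 3, ])^2)
  dd <- matrix(dd, scheme$n_segments, nf)
  tibble(
    segment = scheme$segments$segment,
    res_first = scheme$segments$res_first,
    res_last = scheme$segments$res_last,
    d_mean_nm = rowMeans(dd),
    d_sd_nm = apply(dd, 1, sd),
    n_frames = nf
  )
}
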