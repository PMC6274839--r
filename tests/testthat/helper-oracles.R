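# Independent brute-force oracles and tiny fixture builders.
# Everything here is deliberately naive (double loops, closed forms) so it
# shares no code path with the package implementation it checks.

# Kabsch superposition of mobile onto fixed (n x 3 matrices); returns the
# transformed mobile coordinates. Classic SVD construction.
kabsch_oracle <- function(mobile, fixed) {
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  A <- sweep(mobile, 2, cm)
  B <- sweep(fixed, 2, cf)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(A %*% t(R), 2, cf, "+")
}

rmsd_oracle <- function(mobile, fixed) {
  moved <- kabsch_oracle(mobile, fixed)
  sqrt(mean(rowSums((moved - fixed)^2)))
}

# all-pairs H-bond search over one frame tibble, nested loops
hbond_oracle <- function(atoms, max_d = 0.35, max_ang = 30) {
  ns <- atoms[atoms$atom_name == "N", ]
  os <- atoms[atoms$atom_name == "O", ]
  hs <- atoms[atoms$atom_name %in% c("H", "HN"), ]
  out <- list()
  for (i in seq_len(nrow(ns))) {
    for (j in seq_len(nrow(os))) {
      if (ns$chain_id[i] == os$chain_id[j] &&
          abs(ns$residue_index[i] - os$residue_index[j]) < 2) next
      d <- sqrt((ns$x_nm[i] - os$x_nm[j])^2 + (ns$y_nm[i] - os$y_nm[j])^2 +
                  (ns$z_nm[i] - os$z_nm[j])^2)
      if (d > max_d) next
      h <- hs[hs$chain_id == ns$chain_id[i] &
                hs$residue_index == ns$residue_index[i], ]
      if (nrow(h) == 1) {
        u <- c(h$x_nm - ns$x_nm[i], h$y_nm - ns$y_nm[i], h$z_nm - ns$z_nm[i])
        v <- c(os$x_nm[j] - ns$x_nm[i], os$y_nm[j] - ns$y_nm[i],
               os$z_nm[j] - ns$z_nm[i])
        ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
        if (ang > max_ang) next
      }
      out[[length(out) + 1]] <- data.frame(
        donor_chain = ns$chain_id[i], donor_res = ns$residue_index[i],
        acceptor_chain = os$chain_id[j], acceptor_res = os$residue_index[j])
    }
  }
  if (length(out) == 0) {
    return(data.frame(donor_chain = character(), donor_res = integer(),
                      acceptor_chain = character(), acceptor_res = integer()))
  }
  do.call(rbind, out)
}

# double-loop mean-tangent correlation: tangents is [n_t, 3, n_frames]
correlation_oracle <- function(tangents) {
  n_t <- dim(tangents)[1]; nf <- dim(tangents)[3]
  sapply(seq_len(n_t), function(i) {
    m <- c(0, 0, 0)
    for (j in seq_len(nf)) m <- m + tangents[i, , j]
    u <- m / sqrt(sum(m^2))
    tot <- 0
    for (j in seq_len(nf)) tot <- tot + sum(tangents[i, , j] * u)
    tot / nf
  })
}

# small two-chain CA ensemble laid on straight parallel lines, with an
# optional per-frame coordinate perturbation function
straight_two_chain <- function(n_frames = 3, residues = 1:12,
                               spacing = 0.15, gap = 1,
                               perturb = NULL, temperature = 300) {
  base <- expand.grid(chain_id = c("A", "B"), residue_index = residues,
                      stringsAsFactors = FALSE)
  base <- base[order(base$chain_id, base$residue_index), ]
  rows <- lapply(seq_len(n_frames), function(f) {
    d <- base
    d$frame <- f
    d$time_ps <- (f - 1) * 10
    d$atom_name <- "CA"
    d$residue_name <- "ALA"
    d$x_nm <- d$residue_index * spacing
    d$y_nm <- ifelse(d$chain_id == "A", gap / 2, -gap / 2)
    d$z_nm <- 0
    if (!is.null(perturb)) d <- perturb(d, f)
    d
  })
  conformation_ensemble(do.call(rbind, rows), temperature_K = temperature)
}

# apply a random rigid motion to the coordinate columns of a frame table
apply_rigid <- function(d, rot, shift) {
  m <- as.matrix(d[, c("x_nm", "y_nm", "z_nm")]) %*% t(rot)
  d$x_nm <- m[, 1] + shift[1]
  d$y_nm <- m[, 2] + shift[2]
  d$z_nm <- m[, 3] + shift[3]
  d
}

random_rot_oracle <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
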