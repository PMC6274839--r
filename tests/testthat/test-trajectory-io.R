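test_that("multi-model PDB round trip preserves counts and coordinates", {
  ens <- straight_two_chain(n_frames = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, path)
  back <- read_ensemble(path, chain_ids = c("A", "B"))
  expect_equal(n_frames(back), 3)
  expect_setequal(unique(back$chain_id), c("A", "B"))
  expect_equal(nrow(back), nrow(ens))
  # PDB stores angstroms to 3 decimals: 1e-4 nm grid, so 1e-3 nm is safe
  expect_lt(max(abs(back$x_nm - ens$x_nm)), 1e-3)
  expect_lt(max(abs(back$y_nm - ens$y_nm)), 1e-3)
  expect_lt(max(abs(back$z_nm - ens$z_nm)), 1e-3)
  expect_equal(back$residue_index, ens$residue_index)
})

test_that("xyz-table round trip is exact and PDB-precision-free", {
  set.seed(41)
  ens <- straight_two_chain(n_frames = 4, perturb = function(d, f) {
    d$x_nm <- d$x_nm + rnorm(nrow(d), sd = 0.05); d
  })
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ensemble(ens, path, format = "xyz")
  back <- read_ensemble(path, format = "xyz")
  expect_equal(back$x_nm, ens$x_nm, tolerance = 1e-12)
  expect_equal(back$time_ps, ens$time_ps)
  expect_equal(back$atom_name, ens$atom_name)
})

test_that("a declared chain missing from the file is a hard error", {
  ens <- straight_two_chain(n_frames = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, path)
  expect_error(read_ensemble(path, chain_ids = c("A", "C")),
               "chain C not found")
})

test_that("models with differing atom counts are rejected with frame ids", {
  ens <- straight_two_chain(n_frames = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, path)
  lines <- readLines(path)
  atom_rows <- which(startsWith(lines, "ATOM"))
  writeLines(lines[-atom_rows[length(atom_rows)]], path)  # drop one atom
  expect_error(read_ensemble(path), "differing atom counts")
})

test_that("ensemble invariants are enforced at construction", {
  ens <- straight_two_chain(n_frames = 3)
  one_chain <- ens[ens$chain_id == "A", ]
  expect_error(conformation_ensemble(one_chain, chain_ids = c("A", "B")),
               "chain B not found")
  expect_error(conformation_ensemble(ens, chain_ids = c("A", "B"),
                                     temperature_K = -5),
               "positive")
  scrambled <- ens
  scrambled$atom_name[1] <- "CB"
  expect_error(conformation_ensemble(scrambled), "ordering differs")
})

test_that("trimming drops pre-equilibration frames and keeps spacing", {
  # 10 ps spacing over 0 ... 99990 ps; trimming at 20 ns leaves 8000 frames
  n <- 10000
  atoms <- data.frame(
    frame = rep(seq_len(n), each = 2),
    time_ps = rep((seq_len(n) - 1) * 10, each = 2),
    chain_id = c("A", "B"), residue_index = 1L, residue_name = "ALA",
    atom_name = "CA", x_nm = 0, y_nm = c(0.5, -0.5), z_nm = 0)
  ens <- conformation_ensemble(atoms)
  trimmed <- trim_equilibration(ens, 20000)
  expect_equal(n_frames(trimmed), 8000)
  expect_gte(min(trimmed$time_ps), 20000)

  small <- straight_two_chain(n_frames = 5)
  expect_identical(trim_equilibration(small, 0)$x_nm, small$x_nm)
  expect_error(trim_equilibration(small, 1e6), "beyond the last frame")
})

test_that("superposition removes rigid motions exactly", {
  set.seed(7)
  base <- straight_two_chain(n_frames = 6, perturb = function(d, f) {
    # bend the template (so it is not collinear), then place it rigidly
    d$z_nm <- d$z_nm + 0.02 * d$x_nm^2
    apply_rigid(d, random_rot_oracle(), rnorm(3, sd = 2))
  })
  sup <- superpose(base)
  arr <- coilflex:::ens_coords_array(sup)
  mean_str <- apply(arr, c(1, 2), mean)
  per_frame_rmsd <- apply(arr, 3, function(m) sqrt(mean(rowSums((m - mean_str)^2))))
  expect_lt(max(per_frame_rmsd), 1e-6)
})

test_that("superposition is an isometry and is idempotent", {
  set.seed(8)
  ens <- straight_two_chain(n_frames = 4, perturb = function(d, f) {
    d$x_nm <- d$x_nm + rnorm(nrow(d), sd = 0.03)
    d$y_nm <- d$y_nm + rnorm(nrow(d), sd = 0.03)
    d$z_nm <- d$z_nm + rnorm(nrow(d), sd = 0.03)
    d
  })
  sup <- superpose(ens)
  d0 <- dist(as.matrix(ens[ens$frame == 2, c("x_nm", "y_nm", "z_nm")]))
  d1 <- dist(as.matrix(sup[sup$frame == 2, c("x_nm", "y_nm", "z_nm")]))
  expect_lt(max(abs(d0 - d1)), 1e-9)
  sup2 <- superpose(sup)
  expect_lt(max(abs(sup2$x_nm - sup$x_nm)), 1e-9)
  expect_lt(max(abs(sup2$y_nm - sup$y_nm)), 1e-9)
  expect_lt(max(abs(sup2$z_nm - sup$z_nm)), 1e-9)
})

test_that("collinear selections cannot be superposed", {
  ens <- straight_two_chain(n_frames = 3)
  sel <- selection_spec(chain_ids = c("A", "A"))  # one straight line
  expect_error(superpose(ens, sel), "collinear")
})

test_that("rmsd timecourse matches an independent Kabsch oracle", {
  set.seed(9)
  ens <- straight_two_chain(n_frames = 5, perturb = function(d, f) {
    if (f >= 3) d$x_nm <- d$x_nm + rnorm(nrow(d), sd = 0.1)
    d
  })
  rt <- rmsd_timecourse(ens)
  expect_equal(nrow(rt), 5)
  expect_equal(rt$rmsd_nm[1], 0, tolerance = 1e-9)
  ref <- as.matrix(ens[ens$frame == 1, c("x_nm", "y_nm", "z_nm")])
  f4 <- as.matrix(ens[ens$frame == 4, c("x_nm", "y_nm", "z_nm")])
  expect_equal(rt$rmsd_nm[4], rmsd_oracle(f4, ref), tolerance = 1e-9)
})

test_that("rmsd ignores whole-body translation and rigid pre-motion", {
  ens <- straight_two_chain(n_frames = 3, perturb = function(d, f) {
    d$x_nm <- d$x_nm + (f - 1) * 1.0  # pure translation per frame
    d
  })
  rt <- rmsd_timecourse(ens)
  expect_lt(max(rt$rmsd_nm), 1e-9)

  set.seed(10)
  base <- straight_two_chain(n_frames = 4, perturb = function(d, f) {
    d$z_nm <- d$z_nm + rnorm(nrow(d), sd = 0.05); d
  })
  rot <- random_rot_oracle(); shift <- c(1, -2, 0.5)
  moved_tbl <- apply_rigid(as.data.frame(base), rot, shift)
  moved <- conformation_ensemble(moved_tbl, temperature_K = 300)
  expect_equal(rmsd_timecourse(base)$rmsd_nm,
               rmsd_timecourse(moved)$rmsd_nm, tolerance = 1e-9)
})
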