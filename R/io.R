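#' Read a conformational ensemble from disk
#'
#' Two on-disk dialects are supported: multi-model PDB (`MODEL`/`ENDMDL`
#' records, coordinates in angstroms, converted to nm on read) and a plain
#' TSV "xyz table" with one row per atom per frame and columns
#' `frame_index`, `time_ps`, `chain_id`, `residue_index`, `atom_name`,
#' `x_nm`, `y_nm`, `z_nm` (optionally `residue_name`).  The TSV dialect
#' stores full double precision and is the preferred round-trip format for
#' synthetic ensembles; PDB is limited to 0.1 pm printed precision
#' (1e-4 nm).
#'
#' @param path File to read.
#' @param format `"pdb"`, `"xyz"`, or `"auto"` (by file extension:
#'   `.pdb` vs anything else).
#' @param chain_ids Two chain labels expected in the file; defaults to the
#'   chains found. A declared chain absent from the first model is an error.
#' @param temperature_K Bath temperature to attach, kelvin.
#' @param frame_spacing_ps Time between PDB models (PDB stores no times);
#'   ignored for the xyz table, which carries `time_ps`.
#' @return A [conformation_ensemble].
#' @export
read_ensemble <- function(path, format = c("auto", "pdb", "xyz"),
                          chain_ids = NULL, temperature_K = 300,
                          frame_spacing_ps = 10) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  if (format == "pdb") {
    read_ensemble_pdb(path, chain_ids, temperature_K, frame_spacing_ps)
  } else {
    read_ensemble_xyz(path, chain_ids, temperature_K)
  }
}

read_ensemble_pdb <- function(path, chain_ids, temperature_K,
                              frame_spacing_ps) {
  # pre-scan for per-model atom counts so a ragged file fails loudly
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_id <- cumsum(startsWith(lines, "MODEL"))
  if (max(model_id) >= 2) {
    counts <- tabulate(model_id[is_atom], nbins = max(model_id[is_atom]))
    if (length(unique(counts)) != 1) {
      bad <- which(counts != counts[1])
      abort(paste0("frames with differing atom counts: ",
                   paste(head(bad, 10), collapse = ", ")))
    }
  }

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nf <- nrow(pdb$xyz)
  chain_ids <- chain_ids %||% sort(unique(at$chain))
  for (ch in chain_ids) {
    if (!any(at$chain == ch)) abort(paste0("chain ", ch, " not found"))
  }
  n_at <- nrow(at)
  xyz <- pdb$xyz * 0.1  # angstrom -> nm
  atoms <- tibble(
    frame = rep(seq_len(nf), each = n_at),
    time_ps = rep((seq_len(nf) - 1) * frame_spacing_ps, each = n_at),
    chain_id = rep(at$chain, nf),
    residue_index = rep(as.integer(at$resno), nf),
    residue_name = rep(at$resid, nf),
    atom_name = rep(at$elety, nf),
    x_nm = as.vector(t(xyz[, seq(1, 3 * n_at, by = 3), drop = FALSE])),
    y_nm = as.vector(t(xyz[, seq(2, 3 * n_at, by = 3), drop = FALSE])),
    z_nm = as.vector(t(xyz[, seq(3, 3 * n_at, by = 3), drop = FALSE]))
  )
  conformation_ensemble(atoms, chain_ids, temperature_K)
}

read_ensemble_xyz <- function(path, chain_ids, temperature_K) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("frame_index", "time_ps", "chain_id", "residue_index",
           "atom_name", "x_nm", "y_nm", "z_nm")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("xyz table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  chain_ids <- chain_ids %||% sort(unique(tab$chain_id))
  for (ch in chain_ids) {
    if (!any(tab$chain_id == ch)) abort(paste0("chain ", ch, " not found"))
  }
  atoms <- tibble(
    frame = as.integer(tab$frame_index),
    time_ps = tab$time_ps,
    chain_id = as.character(tab$chain_id),
    residue_index = as.integer(tab$residue_index),
    residue_name = if ("residue_name" %in% names(tab))
      as.character(tab$residue_name) else "UNK",
    atom_name = as.character(tab$atom_name),
    x_nm = tab$x_nm, y_nm = tab$y_nm, z_nm = tab$z_nm
  )
  conformation_ensemble(atoms, chain_ids, temperature_K)
}

#' Write a conformational ensemble to disk
#'
#' @inheritParams read_ensemble
#' @param ens A [conformation_ensemble].
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  if (format == "pdb") {
    meta <- ens_atom_meta(ens)
    xyz <- ens_xyz_matrix(ens) * 10  # nm -> angstrom
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = meta$residue_index,
                     resid = meta$residue_name,
                     chain = meta$chain_id,
                     elety = meta$atom_name)
  } else {
    tab <- tibble(
      frame_index = ens$frame, time_ps = ens$time_ps,
      chain_id = ens$chain_id, residue_index = ens$residue_index,
      residue_name = ens$residue_name, atom_name = ens$atom_name,
      x_nm = ens$x_nm, y_nm = ens$y_nm, z_nm = ens$z_nm
    )
    readr::write_tsv(tab, path, progress = FALSE)
  }
  invisible(path)
}
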