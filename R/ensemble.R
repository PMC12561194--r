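#' Build a topology table
#'
#' A topology is a plain tibble describing the atoms shared by every frame
#' of a conformational ensemble: one row per atom, in fixed atom order.
#' Residue identity is keyed by `(chain_id, residue_number)`; the residue
#' name is carried for display and selection only.
#'
#' @param atom_name Character vector of atom names (e.g. `"CA"`, `"NE2"`).
#' @param element Character vector of element symbols (`"C"`, `"N"`, ...).
#' @param residue_number Integer vector of residue numbers.
#' @param residue_name Character vector of three-letter residue names.
#' @param chain_id Character vector of chain identifiers.
#' @return A tibble with one row per atom and the five columns above.
#' @examples
#' topology(c("CA", "CB"), c("C", "C"), c(1, 1), c("ALA", "ALA"), c("A", "A"))
#' @export
topology <- function(atom_name, element, residue_number, residue_name,
                     chain_id) {
  n <- length(atom_name)
  if (n < 1) abort("A topology needs at least one atom.")
  out <- tibble(
    atom_name = as.character(atom_name),
    element = as.character(element),
    residue_number = as.integer(residue_number),
    residue_name = as.character(residue_name),
    chain_id = as.character(chain_id)
  )
  if (anyNA(out)) abort("Topology fields must not contain NA.")
  out
}

#' Construct a conformational ensemble
#'
#' Bundles a topology with an ordered list of coordinate frames (N x 3
#' matrices in Angstrom). All frames must match the topology's atom count,
#' and the object is treated as immutable after construction: derived
#' series reference frames by index.
#'
#' @param topology A topology tibble, see [topology()].
#' @param coords A list of N x 3 numeric matrices, one per frame.
#' @param time_ps Optional numeric vector of frame times in picoseconds.
#' @return An object of class `ps_ensemble`.
#' @export
ensemble <- function(topology, coords, time_ps = NULL) {
  if (!is.data.frame(topology)) abort("`topology` must be a data frame.")
  if (!is.list(coords) || length(coords) < 1) {
    abort("`coords` must be a non-empty list of N x 3 matrices.")
  }
  n_atoms <- nrow(topology)
  for (i in seq_along(coords)) {
    m <- coords[[i]]
    if (!is.matrix(m) || ncol(m) != 3 || nrow(m) != n_atoms) {
      abort(paste0("Frame ", i, " is not an ", n_atoms, " x 3 matrix."))
    }
    if (!all(is.finite(m))) {
      abort(paste0("Frame ", i, " contains non-finite coordinates."))
    }
  }
  if (!is.null(time_ps) && length(time_ps) != length(coords)) {
    abort("`time_ps` must have one entry per frame.")
  }
  structure(
    list(topology = topology, coords = coords, time_ps = time_ps),
    class = "ps_ensemble"
  )
}

#' @export
print.ps_ensemble <- function(x, ...) {
  cat(
    "<ps_ensemble> ", n_frames(x), " frames x ", n_atoms(x), " atoms (",
    dplyr::n_distinct(x$topology$chain_id, x$topology$residue_number),
    " residues)\n",
    sep = ""
  )
  invisible(x)
}

#' Ensemble dimensions
#'
#' @param x A `ps_ensemble`.
#' @return Number of frames / atoms.
#' @export
n_frames <- function(x) length(x$coords)

#' @rdname n_frames
#' @export
n_atoms <- function(x) nrow(x$topology)

#' Extract one frame's coordinates
#'
#' @param x A `ps_ensemble`.
#' @param i Frame index (1-based).
#' @return An N x 3 coordinate matrix in Angstrom.
#' @export
frame_coords <- function(x, i) {
  if (i < 1 || i > n_frames(x)) abort("Frame index out of range.")
  x$coords[[i]]
}

# ---------------------------------------------------------------------------
# Multi-model PDB I/O (bio3d-backed, with validation producing the error
# contracts this package documents).

#' Read a conformational ensemble from a multi-model PDB file
#'
#' One frame per `MODEL` record (a file without `MODEL` records yields a
#' single frame). `ATOM` and `HETATM` records are both retained; topology
#' is taken from the first model. Models with inconsistent atom counts and
#' unparsable coordinate fields are rejected with informative errors.
#'
#' @param path Path to a PDB file.
#' @return A [ensemble()] object.
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) abort("No ATOM/HETATM records found.")

  # Validate coordinate fields line by line (PDB 3.3 columns 31-54).
  atom_lines <- which(is_atom)
  for (ln in atom_lines) {
    fields <- c(
      substr(lines[ln], 31, 38), substr(lines[ln], 39, 46),
      substr(lines[ln], 47, 54)
    )
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      abort(paste0("Unparsable coordinate field at line ", ln, "."))
    }
  }

  # Validate per-model atom counts before handing over to bio3d.
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1) {
    model_ends <- which(startsWith(lines, "ENDMDL"))
    if (length(model_ends) != length(model_starts)) {
      abort("Unbalanced MODEL/ENDMDL records.")
    }
    counts <- mapply(
      function(s, e) sum(is_atom[s:e]),
      model_starts, model_ends
    )
    if (length(unique(counts)) != 1) {
      bad <- which(counts != counts[1])[1]
      abort(paste0(
        "Inconsistent atom count in model ", bad, ": ", counts[bad],
        " atoms versus ", counts[1], " in model 1."
      ))
    }
  }

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  elem <- trimws(atoms$elesy)
  guess <- toupper(substr(trimws(atoms$elety), 1, 1))
  elem <- ifelse(is.na(elem) | elem == "", guess, elem)
  topo <- topology(
    atom_name = trimws(atoms$elety),
    element = elem,
    residue_number = atoms$resno,
    residue_name = trimws(atoms$resid),
    chain_id = ifelse(is.na(atoms$chain) | atoms$chain == "", "A",
      atoms$chain
    )
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  coords <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  ensemble(topo, coords)
}

#' Write a conformational ensemble as a multi-model PDB file
#'
#' Writes standard `MODEL`/`ENDMDL` blocks with fixed-width 8.3
#' coordinates, the PDB interchange convention this package round-trips at
#' 1e-3 Angstrom precision.
#'
#' @param x A [ensemble()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(x, path) {
  if (!inherits(x, "ps_ensemble")) abort("`x` must be a ps_ensemble.")
  if (n_frames(x) < 1) abort("Ensemble has no frames to write.")
  allc <- unlist(x$coords)
  if (any(abs(allc) > 9999.999)) {
    abort("Coordinate magnitude exceeds 9999.999 A; PDB fixed width overflow.")
  }
  xyz <- do.call(rbind, lapply(x$coords, function(m) as.vector(t(m))))
  topo <- x$topology
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    resno = topo$residue_number,
    resid = topo$residue_name,
    chain = topo$chain_id,
    elety = topo$atom_name,
    elesy = topo$element
  )
  invisible(path)
}
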