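# Geometric protein-ligand interaction detection and per-residue
# interaction fingerprints.

#' Geometric contact criteria
#'
#' All cutoffs follow common interaction-fingerprint practice and are
#' serialised into every fingerprint output for provenance.
#'
#' @param shell_radius Residue-shell radius around the ligand (Angstrom).
#' @param hbond_dist Donor-acceptor heavy-atom distance cutoff.
#' @param hbond_angle Minimum D-H...A angle in degrees (used only when an
#'   explicit hydrogen is available; otherwise the distance-only
#'   heavy-atom fallback applies and events carry `heavy_only = TRUE`).
#' @param hydrophobic_dist Apolar-carbon pair distance cutoff.
#' @param pi_centroid_dist Ring-centroid distance cutoff for pi-stacking.
#' @param pi_plane_angle Maximum interplanar angle (degrees) for parallel
#'   pi-stacking.
#' @param pi_ion_dist Ring-centroid to charged-group distance cutoff.
#' @param pi_ion_axis_angle Maximum angle between the ring normal and the
#'   centroid-to-ion vector (degrees).
#' @param apolar_bond_dist Distance heuristic (Angstrom) below which a
#'   carbon counts as bonded to N/O/S and is therefore polar.
#' @return A list of class `ps_contact_config`.
#' @export
contact_config <- function(shell_radius = 5.0,
                           hbond_dist = 3.5, hbond_angle = 120,
                           hydrophobic_dist = 4.0,
                           pi_centroid_dist = 5.5, pi_plane_angle = 30,
                           pi_ion_dist = 5.0, pi_ion_axis_angle = 30,
                           apolar_bond_dist = 1.8) {
  vals <- list(
    shell_radius = shell_radius, hbond_dist = hbond_dist,
    hbond_angle = hbond_angle, hydrophobic_dist = hydrophobic_dist,
    pi_centroid_dist = pi_centroid_dist, pi_plane_angle = pi_plane_angle,
    pi_ion_dist = pi_ion_dist, pi_ion_axis_angle = pi_ion_axis_angle,
    apolar_bond_dist = apolar_bond_dist
  )
  for (nm in names(vals)) stopifnot_scalar_number(vals[[nm]], nm, TRUE)
  if (hbond_angle > 180 || pi_plane_angle > 180 || pi_ion_axis_angle > 180) {
    abort("Angles must lie in (0, 180].")
  }
  structure(vals, class = "ps_contact_config")
}

empty_events <- function() {
  tibble(
    frame = integer(), chain_id = character(), residue_number = integer(),
    residue_name = character(), interaction_type = character(),
    atom_i = integer(), atom_j = integer(),
    distance = numeric(), angle = numeric(), heavy_only = logical()
  )
}

#' Residues within a shell of the ligand
#'
#' Minimum-distance criterion over heavy atoms with a closed boundary: a
#' residue is in the shell if any of its non-ligand heavy atoms lies
#' within `radius` of any ligand heavy atom.
#'
#' @param ens A [ensemble()].
#' @param ligand Ligand selection (expression, `ps_selection`, indices).
#' @param frame Frame index (default 1).
#' @param radius Shell radius in Angstrom (default 5).
#' @return Tibble: `chain_id`, `residue_number`, `residue_name`,
#'   `min_dist`, sorted by residue.
#' @export
shell_residues <- function(ens, ligand, frame = 1, radius = 5.0) {
  lig <- as_selection(ligand, ens)
  if (lig$empty) abort("Ligand selection is empty.")
  topo <- ens$topology
  co <- frame_coords(ens, frame)
  heavy <- topo$element != "H"
  lig_idx <- intersect(lig$indices, which(heavy))
  prot_idx <- setdiff(which(heavy), lig$indices)
  if (length(prot_idx) == 0) {
    return(tibble(
      chain_id = character(), residue_number = integer(),
      residue_name = character(), min_dist = numeric()
    ))
  }
  dmat <- cross_dist(co[prot_idx, , drop = FALSE], co[lig_idx, , drop = FALSE])
  mind <- apply(dmat, 1, min)
  res <- tibble(
    chain_id = topo$chain_id[prot_idx],
    residue_number = topo$residue_number[prot_idx],
    residue_name = topo$residue_name[prot_idx],
    d = mind
  )
  res <- dplyr::summarise(
    dplyr::group_by(res, .data$chain_id, .data$residue_number,
      .data$residue_name
    ),
    min_dist = min(.data$d), .groups = "drop"
  )
  out <- dplyr::filter(res, .data$min_dist <= radius)
  dplyr::arrange(out, .data$chain_id, .data$residue_number)
}

# All pairwise distances between rows of a (n x 3) and b (m x 3).
cross_dist <- function(a, b) {
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Carbons counted as apolar: element C with no N/O/S atom within the
# bonding-distance heuristic (no bond topology is perceived).
apolar_carbons <- function(topo, co, config) {
  is_c <- which(topo$element == "C")
  polar <- which(topo$element %in% c("N", "O", "S"))
  if (length(polar) == 0) {
    return(is_c)
  }
  d <- cross_dist(co[is_c, , drop = FALSE], co[polar, , drop = FALSE])
  is_c[apply(d, 1, min) > config$apolar_bond_dist]
}

#' Detect hydrogen bonds in one frame
#'
#' With explicit hydrogens on the donor (an `H` atom within 1.2 Angstrom
#' of the donor heavy atom), an event requires donor-acceptor heavy
#' distance <= `hbond_dist` and D-H...A angle >= `hbond_angle`. Without
#' hydrogens the documented heavy-atom-only fallback applies (distance
#' criterion alone) and the event is flagged `heavy_only`.
#'
#' @param ens A [ensemble()].
#' @param donors,acceptors Selections of donor heavy atoms and acceptor
#'   atoms.
#' @param frame Frame index.
#' @param config A [contact_config()].
#' @return Event tibble (one row per donor-acceptor pair satisfying the
#'   criteria), with geometry columns so events can be re-checked.
#' @export
detect_hbonds <- function(ens, donors, acceptors, frame = 1,
                          config = contact_config()) {
  don <- as_selection(donors, ens)
  acc <- as_selection(acceptors, ens)
  if (don$empty || acc$empty) {
    return(empty_events())
  }
  topo <- ens$topology
  co <- frame_coords(ens, frame)
  h_idx <- which(topo$element == "H")
  dmat <- cross_dist(
    co[don$indices, , drop = FALSE],
    co[acc$indices, , drop = FALSE]
  )
  hits <- which(dmat <= config$hbond_dist, arr.ind = TRUE)
  if (nrow(hits) > 0) {
    same <- don$indices[hits[, 1]] == acc$indices[hits[, 2]]
    hits <- hits[!same, , drop = FALSE]
  }
  if (nrow(hits) == 0) {
    return(empty_events())
  }
  rows <- lapply(seq_len(nrow(hits)), function(r) {
    di <- don$indices[hits[r, 1]]
    ai <- acc$indices[hits[r, 2]]
    d <- dmat[hits[r, 1], hits[r, 2]]
    hs <- integer(0)
    if (length(h_idx) > 0) {
      dh <- row_norms(sweep(co[h_idx, , drop = FALSE], 2, co[di, ]))
      hs <- h_idx[dh <= 1.2]
    }
    if (length(hs) > 0) {
      angs <- vapply(hs, function(hi) {
        vec_angle(co[di, ] - co[hi, ], co[ai, ] - co[hi, ])
      }, numeric(1))
      ang <- max(angs)
      if (ang < config$hbond_angle) {
        return(NULL)
      }
      heavy_only <- FALSE
    } else {
      ang <- NA_real_
      heavy_only <- TRUE
    }
    tibble(
      frame = as.integer(frame),
      chain_id = topo$chain_id[di],
      residue_number = topo$residue_number[di],
      residue_name = topo$residue_name[di],
      interaction_type = "hbond",
      atom_i = as.integer(di), atom_j = as.integer(ai),
      distance = d, angle = ang, heavy_only = heavy_only
    )
  })
  dplyr::bind_rows(c(list(empty_events()), rows))
}

vec_angle <- function(v1, v2) {
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

#' Detect hydrophobic contacts in one frame
#'
#' An event pairs an apolar protein carbon with an apolar ligand carbon
#' within `hydrophobic_dist`. Apolarity uses the documented distance
#' heuristic (carbon with no N/O/S within `apolar_bond_dist`).
#'
#' @inheritParams detect_hbonds
#' @param ligand Ligand selection.
#' @return Event tibble keyed by the protein residue.
#' @export
detect_hydrophobic <- function(ens, ligand, frame = 1,
                               config = contact_config()) {
  lig <- as_selection(ligand, ens)
  if (lig$empty) abort("Ligand selection is empty.")
  topo <- ens$topology
  co <- frame_coords(ens, frame)
  apc <- apolar_carbons(topo, co, config)
  lig_c <- intersect(apc, lig$indices)
  prot_c <- setdiff(apc, lig$indices)
  if (length(lig_c) == 0 || length(prot_c) == 0) {
    return(empty_events())
  }
  d <- cross_dist(co[prot_c, , drop = FALSE], co[lig_c, , drop = FALSE])
  hits <- which(d <= config$hydrophobic_dist, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(empty_events())
  }
  pi_ <- prot_c[hits[, 1]]
  li_ <- lig_c[hits[, 2]]
  tibble(
    frame = as.integer(frame),
    chain_id = topo$chain_id[pi_],
    residue_number = topo$residue_number[pi_],
    residue_name = topo$residue_name[pi_],
    interaction_type = "hydrophobic",
    atom_i = as.integer(pi_), atom_j = as.integer(li_),
    distance = d[hits], angle = NA_real_, heavy_only = NA
  )
}

ring_geometry <- function(co, idx) {
  pts <- co[idx, , drop = FALSE]
  centroid <- colMeans(pts)
  centred <- sweep(pts, 2, centroid)
  sv <- svd(centred)
  normal <- sv$v[, 3]
  list(centroid = centroid, normal = normal / sqrt(sum(normal^2)))
}

#' Detect parallel pi-stacking between two rings in one frame
#'
#' Ring planes are fit by least squares; an event requires centroid
#' distance <= `pi_centroid_dist` and interplanar angle <=
#' `pi_plane_angle` (parallel-only rule; T-shaped geometries are not
#' counted).
#'
#' @inheritParams detect_hbonds
#' @param ring_a,ring_b Selections of the two rings' atoms (>= 3 each).
#' @return Event tibble (zero or one row), keyed by `ring_a`'s residue.
#' @export
detect_pi_stack <- function(ens, ring_a, ring_b, frame = 1,
                            config = contact_config()) {
  ra <- as_selection(ring_a, ens)
  rb <- as_selection(ring_b, ens)
  if (length(ra$indices) < 3 || length(rb$indices) < 3) {
    abort("Ring selections need at least 3 atoms each.")
  }
  topo <- ens$topology
  co <- frame_coords(ens, frame)
  ga <- ring_geometry(co, ra$indices)
  gb <- ring_geometry(co, rb$indices)
  d <- sqrt(sum((ga$centroid - gb$centroid)^2))
  ang <- vec_angle(ga$normal, gb$normal)
  ang <- min(ang, 180 - ang)  # plane angle, orientation-free
  if (d <= config$pi_centroid_dist && ang <= config$pi_plane_angle) {
    i1 <- ra$indices[1]
    return(tibble(
      frame = as.integer(frame),
      chain_id = topo$chain_id[i1],
      residue_number = topo$residue_number[i1],
      residue_name = topo$residue_name[i1],
      interaction_type = "pi_stack",
      atom_i = as.integer(i1), atom_j = as.integer(rb$indices[1]),
      distance = d, angle = ang, heavy_only = NA
    ))
  }
  empty_events()
}

#' Detect a pi-ion (e.g. pi-anion) interaction in one frame
#'
#' An event requires the ring-centroid to ion-group-centroid distance <=
#' `pi_ion_dist` and the angle between the ring normal and the
#' centroid-to-ion vector <= `pi_ion_axis_angle` (the ion must sit above
#' or below the ring face, not in its plane).
#'
#' @inheritParams detect_hbonds
#' @param ring Ring selection (>= 3 atoms).
#' @param ion_group Selection of the charged group's atoms.
#' @return Event tibble (zero or one row), keyed by the ion group's
#'   residue.
#' @export
detect_pi_ion <- function(ens, ring, ion_group, frame = 1,
                          config = contact_config()) {
  rg <- as_selection(ring, ens)
  ig <- as_selection(ion_group, ens)
  if (length(rg$indices) < 3) abort("Ring selection needs >= 3 atoms.")
  if (ig$empty) abort("Ion group selection is empty.")
  topo <- ens$topology
  co <- frame_coords(ens, frame)
  g <- ring_geometry(co, rg$indices)
  ion <- colMeans(co[ig$indices, , drop = FALSE])
  v <- ion - g$centroid
  d <- sqrt(sum(v^2))
  ang <- vec_angle(g$normal, v)
  ang <- min(ang, 180 - ang)
  if (d <= config$pi_ion_dist && ang <= config$pi_ion_axis_angle) {
    i1 <- ig$indices[1]
    return(tibble(
      frame = as.integer(frame),
      chain_id = topo$chain_id[i1],
      residue_number = topo$residue_number[i1],
      residue_name = topo$residue_name[i1],
      interaction_type = "pi_ion",
      atom_i = as.integer(rg$indices[1]), atom_j = as.integer(i1),
      distance = d, angle = ang, heavy_only = NA
    ))
  }
  empty_events()
}

#' Interaction fingerprint over an ensemble or basin
#'
#' Per-residue, per-type contact frequencies over a set of frames. A
#' residue-type pair counts at most once per frame (presence/absence),
#' so frequencies are fractions in `[0, 1]`. Hydrogen bonds (protein
#' N/O donors against ligand O/N acceptors and vice versa, heavy-atom
#' fallback when no hydrogens are present) and hydrophobic contacts are
#' always computed; pi-stacking and pi-ion terms are added when the ring
#' and ion-group selections are supplied.
#'
#' @param ens A [ensemble()].
#' @param ligand Ligand selection.
#' @param frames Integer frame indices (default: all frames).
#' @param config A [contact_config()].
#' @param ligand_ring Optional selection of the ligand's aromatic ring.
#' @param protein_rings Optional named list of ring selections (names
#'   ignored; residue identity is taken from the atoms).
#' @param protein_ion_groups Optional list of charged-group selections
#'   paired against `ligand_ring`.
#' @param scope Label stored on the result (e.g. `"ensemble"` or a basin
#'   id).
#' @return A `ps_ifp` tibble: `chain_id`, `residue_number`,
#'   `residue_name`, `interaction_type`, `frequency`, `n_frames`, with
#'   the serialised config in attributes.
#' @export
fingerprint <- function(ens, ligand, frames = NULL,
                        config = contact_config(),
                        ligand_ring = NULL, protein_rings = NULL,
                        protein_ion_groups = NULL,
                        scope = "ensemble") {
  lig <- as_selection(ligand, ens)
  if (lig$empty) abort("Ligand selection is empty.")
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  topo <- ens$topology
  # Default hbond partners: protein N/O heavy atoms vs ligand N/O.
  prot_no <- setdiff(which(topo$element %in% c("N", "O")), lig$indices)
  lig_no <- intersect(which(topo$element %in% c("N", "O")), lig$indices)
  events <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    t <- frames[k]
    ev <- dplyr::bind_rows(
      detect_hbonds(ens, prot_no, lig_no, frame = t, config = config),
      detect_hydrophobic(ens, lig, frame = t, config = config)
    )
    if (!is.null(ligand_ring) && !is.null(protein_rings)) {
      for (pr in protein_rings) {
        ev <- dplyr::bind_rows(
          ev,
          detect_pi_stack(ens, pr, ligand_ring, frame = t, config = config)
        )
      }
    }
    if (!is.null(ligand_ring) && !is.null(protein_ion_groups)) {
      for (ion in protein_ion_groups) {
        ev <- dplyr::bind_rows(
          ev,
          detect_pi_ion(ens, ligand_ring, ion, frame = t, config = config)
        )
      }
    }
    events[[k]] <- ev
  }
  all_ev <- dplyr::bind_rows(events)
  if (nrow(all_ev) == 0) {
    out <- tibble(
      chain_id = character(), residue_number = integer(),
      residue_name = character(), interaction_type = character(),
      frequency = numeric(), n_frames = integer()
    )
  } else {
    per_frame <- dplyr::distinct(
      all_ev,
      .data$frame, .data$chain_id, .data$residue_number,
      .data$residue_name, .data$interaction_type
    )
    out <- dplyr::summarise(
      dplyr::group_by(per_frame, .data$chain_id, .data$residue_number,
        .data$residue_name, .data$interaction_type
      ),
      frequency = dplyr::n() / length(frames), .groups = "drop"
    )
    out <- dplyr::mutate(out, n_frames = length(frames))
    out <- dplyr::arrange(out, .data$chain_id, .data$residue_number,
      .data$interaction_type
    )
  }
  attr(out, "scope") <- scope
  attr(out, "config") <- unclass(config)
  class(out) <- c("ps_ifp", class(out))
  out
}

#' Select dual-basin hotspot residues
#'
#' A residue qualifies when its maximum per-type contact frequency
#' reaches `min_frequency` in every required basin (all basins when
#' `require_all_basins`, any one otherwise) -- the "conserved in both
#' energy wells" rule used to nominate mutagenesis hotspots. Qualifying
#' residues are ranked by mean (over basins) of the max-type frequency,
#' descending; ties break by residue number ascending.
#'
#' @param fingerprints Named list of `ps_ifp` tibbles, one per basin, or
#'   a single long tibble with a `basin` column.
#' @param min_frequency Persistence threshold in `[0, 1]` (default 0.5).
#' @param require_all_basins Require persistence in every basin
#'   (default `TRUE`).
#' @return Tibble: `chain_id`, `residue_number`, `residue_name`,
#'   `supporting_types`, `mean_frequency`, plus one `freq_<basin>`
#'   column per basin.
#' @export
select_hotspots <- function(fingerprints, min_frequency = 0.5,
                            require_all_basins = TRUE) {
  if (is.data.frame(fingerprints)) {
    if (!"basin" %in% names(fingerprints)) {
      abort("A single fingerprint table needs a `basin` column.")
    }
    long <- as_tibble(fingerprints)
  } else {
    if (is.null(names(fingerprints)) || any(names(fingerprints) == "")) {
      names(fingerprints) <- paste0("basin", seq_along(fingerprints))
    }
    long <- dplyr::bind_rows(
      lapply(names(fingerprints), function(nm) {
        dplyr::mutate(as_tibble(fingerprints[[nm]]), basin = nm)
      })
    )
  }
  basins <- unique(long$basin)
  per_res <- dplyr::summarise(
    dplyr::group_by(long, .data$chain_id, .data$residue_number,
      .data$residue_name, .data$basin
    ),
    max_freq = max(.data$frequency),
    types = list(unique(
      .data$interaction_type[.data$frequency >= min_frequency]
    )),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(
    dplyr::select(per_res, -"types"),
    names_from = "basin", values_from = "max_freq",
    names_prefix = "freq_", values_fill = 0
  )
  freq_cols <- paste0("freq_", basins)
  qual <- if (require_all_basins) {
    Reduce(`&`, lapply(freq_cols, function(cn) {
      wide[[cn]] >= min_frequency
    }))
  } else {
    Reduce(`|`, lapply(freq_cols, function(cn) {
      wide[[cn]] >= min_frequency
    }))
  }
  out <- wide[qual, , drop = FALSE]
  if (nrow(out) == 0) {
    return(dplyr::mutate(out,
      supporting_types = list(), mean_frequency = numeric(0)
    ))
  }
  out$mean_frequency <- rowMeans(as.matrix(out[, freq_cols, drop = FALSE]))
  types_by_res <- dplyr::summarise(
    dplyr::group_by(per_res, .data$chain_id, .data$residue_number),
    supporting_types = list(sort(unique(unlist(.data$types)))),
    .groups = "drop"
  )
  out <- dplyr::left_join(
    out, types_by_res,
    by = c("chain_id", "residue_number")
  )
  dplyr::arrange(out, dplyr::desc(.data$mean_frequency),
    .data$residue_number
  )
}

#' Write a fingerprint as long-format TSV
#'
#' Columns: residue, interaction type, scope and frequency -- the
#' radar-plot-ready layout.
#'
#' @param ifp A `ps_ifp`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ifp_tsv <- function(ifp, path) {
  df <- as.data.frame(ifp)
  df$scope <- attr(ifp, "scope") %||% "ensemble"
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
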