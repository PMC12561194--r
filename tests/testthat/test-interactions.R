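# Interaction detectors, fingerprints and hotspot selection.

# Tiny two-molecule frame builder: ligand atoms in residue 101 chain L,
# protein atoms in numbered residues chain A.
two_part_ensemble <- function(prot, lig, prot_elem = NULL,
                              lig_elem = NULL, prot_res = NULL) {
  np <- nrow(prot)
  nl <- nrow(lig)
  prot_elem <- prot_elem %||% rep("C", np)
  lig_elem <- lig_elem %||% rep("C", nl)
  prot_res <- prot_res %||% seq_len(np)
  topo <- topology(
    atom_name = c(paste0("P", seq_len(np)), paste0("L", seq_len(nl))),
    element = c(prot_elem, lig_elem),
    residue_number = c(prot_res, rep(101L, nl)),
    residue_name = c(rep("ALA", np), rep("TYL", nl)),
    chain_id = c(rep("A", np), rep("L", nl))
  )
  ensemble(topo, list(rbind(prot, lig)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("shell_residues applies the closed 5 A minimum-distance rule", {
  prot <- rbind(c(4.9, 0, 0), c(0, 5.1, 0), c(0, 0, 4.0))
  ens <- two_part_ensemble(prot, matrix(c(0, 0, 0), ncol = 3))
  sh <- shell_residues(ens, "resname TYL", radius = 5)
  expect_true(1 %in% sh$residue_number) # 4.9 in
  expect_false(2 %in% sh$residue_number) # 5.1 out
  expect_true(3 %in% sh$residue_number)
})

test_that("shell identification matches brute-force all-pairs distances", {
  gen <- generate_two_basin_ensemble(ensemble_spec(n_frames = 3, seed = 2))
  ens <- gen$ensemble
  topo <- ens$topology
  co <- frame_coords(ens, 2)
  lig <- resolve_selection(topo, "resname TYL")$indices
  sh <- shell_residues(ens, "resname TYL", frame = 2, radius = 5)
  # brute force over every residue and atom pair
  oracle <- c()
  for (rn in unique(topo$residue_number[topo$chain_id == "A"])) {
    idx <- which(topo$residue_number == rn & topo$chain_id == "A")
    dmin <- min(vapply(idx, function(i) {
      min(sqrt(colSums((t(co[lig, , drop = FALSE]) - co[i, ])^2)))
    }, numeric(1)))
    if (dmin <= 5) oracle <- c(oracle, rn)
  }
  expect_equal(sort(sh$residue_number[sh$chain_id == "A"]), sort(oracle))
})

test_that("hydrogen-bond detector honours distance and angle criteria", {
  # donor N with explicit H pointing at the acceptor: D-A 2.9, angle 165
  d <- 2.9
  lig_o <- c(0, 0, 0)
  don_n <- c(0, 0, d)
  h <- c(0.07, 0, d - 1.0) # slightly off-axis: D-H...A approx 176 deg
  build <- function(don, h) {
    two_part_ensemble(
      prot = rbind(don, h), lig = matrix(lig_o, ncol = 3),
      prot_elem = c("N", "H"), lig_elem = "O", prot_res = c(1L, 1L)
    )
  }
  ev <- detect_hbonds(build(don_n, h), donors = "name P1",
    acceptors = "name L1"
  )
  expect_equal(nrow(ev), 1)
  expect_false(ev$heavy_only)
  expect_gte(ev$angle, 120)

  # too far: 3.6 A
  ev2 <- detect_hbonds(build(c(0, 0, 3.6), c(0, 0, 2.6)),
    donors = "name P1", acceptors = "name L1"
  )
  expect_equal(nrow(ev2), 0)

  # bad angle: H points away (D-H...A approx 100 deg or less)
  h_bad <- don_n + c(0.98, 0, 0.17)
  ev3 <- detect_hbonds(build(don_n, h_bad),
    donors = "name P1", acceptors = "name L1"
  )
  expect_equal(nrow(ev3), 0)

  # heavy-only fallback is flagged
  ens4 <- two_part_ensemble(
    prot = matrix(don_n, ncol = 3), lig = matrix(lig_o, ncol = 3),
    prot_elem = "N", lig_elem = "O"
  )
  ev4 <- detect_hbonds(ens4, donors = "name P1", acceptors = "name L1")
  expect_equal(nrow(ev4), 1)
  expect_true(ev4$heavy_only)
})

test_that("hydrophobic detector pairs apolar carbons only", {
  mk <- function(dist, prot_elem = "C") {
    two_part_ensemble(
      prot = matrix(c(dist, 0, 0), ncol = 3),
      lig = matrix(c(0, 0, 0), ncol = 3),
      prot_elem = prot_elem, lig_elem = "C"
    )
  }
  expect_equal(nrow(detect_hydrophobic(mk(3.8), "resname TYL")), 1)
  expect_equal(nrow(detect_hydrophobic(mk(4.5), "resname TYL")), 0)
  expect_equal(nrow(detect_hydrophobic(mk(3.0, "O"), "resname TYL")), 0)
  # carbon bonded to oxygen (within 1.8 A) is polar -> excluded
  ens <- two_part_ensemble(
    prot = rbind(c(3.0, 0, 0), c(3.0, 1.4, 0)),
    lig = matrix(c(0, 0, 0), ncol = 3),
    prot_elem = c("C", "O"), lig_elem = "C", prot_res = c(1L, 1L)
  )
  expect_equal(nrow(detect_hydrophobic(ens, "resname TYL")), 0)
})

hexagon <- function(centre = c(0, 0, 0), radius = 1.4, normal_z = TRUE) {
  th <- pi / 3 * (0:5)
  ring <- cbind(radius * cos(th), radius * sin(th), 0)
  sweep(ring, 2, centre, "+")
}

test_that("pi-stacking requires parallel rings within range", {
  ringb <- hexagon(c(0, 0, 3.8))
  mk <- function(ringb) {
    two_part_ensemble(
      prot = ringb, lig = hexagon(),
      prot_res = rep(1L, 6)
    )
  }
  ev <- detect_pi_stack(mk(ringb), "chain A", "resname TYL")
  expect_equal(nrow(ev), 1)
  expect_lt(ev$angle, 1)

  far <- hexagon(c(0, 0, 6.0))
  expect_equal(nrow(detect_pi_stack(mk(far), "chain A", "resname TYL")), 0)

  perp <- hexagon()[, c(1, 3, 2)] # rotate into the xz plane
  perp <- sweep(perp, 2, c(0, 0, 3.8), "+")
  expect_equal(nrow(detect_pi_stack(mk(perp), "chain A", "resname TYL")), 0)
})

test_that("pi-ion detector enforces the axial geometry", {
  mk <- function(ion) {
    two_part_ensemble(
      prot = matrix(ion, ncol = 3), lig = hexagon(),
      prot_elem = "O"
    )
  }
  on_axis <- detect_pi_ion(mk(c(0, 0, 3.5)), "resname TYL", "chain A")
  expect_equal(nrow(on_axis), 1)
  in_plane <- detect_pi_ion(mk(c(3.5, 0, 0)), "resname TYL", "chain A")
  expect_equal(nrow(in_plane), 0)
  too_far <- detect_pi_ion(mk(c(0, 0, 5.5)), "resname TYL", "chain A")
  expect_equal(nrow(too_far), 0)
})

test_that("every emitted event re-satisfies its criteria when rechecked", {
  gen <- generate_two_basin_ensemble(ensemble_spec(
    n_frames = 30, basin_occupancies = c(0.5, 0.5),
    planted_contacts = tibble::tibble(
      resnum = c(2, 9), type = c("hbond", "hydrophobic"),
      basin = c(1, 2), frequency = c(0.9, 0.9)
    ),
    seed = 77
  ))
  ens <- gen$ensemble
  cfg <- contact_config()
  for (t in seq_len(n_frames(ens))) {
    co <- frame_coords(ens, t)
    hyd <- detect_hydrophobic(ens, "resname TYL", frame = t, config = cfg)
    if (nrow(hyd) > 0) {
      d <- sqrt(rowSums((co[hyd$atom_i, , drop = FALSE] -
        co[hyd$atom_j, , drop = FALSE])^2))
      expect_true(all(abs(d - hyd$distance) < 1e-9))
      expect_true(all(d <= cfg$hydrophobic_dist))
    }
  }
})

test_that("fingerprint frequencies are planted fractions and bounded", {
  gen <- generate_two_basin_ensemble(ensemble_spec(
    n_frames = 200, basin_occupancies = c(0.5, 0.5),
    planted_contacts = tibble::tibble(
      resnum = c(3, 7, 11), type = c("hydrophobic", "hbond", "hydrophobic"),
      basin = c(1, 1, 1), frequency = c(0.70, 1.0, 0)
    ),
    seed = 13
  ))
  f1 <- gen$truth$frames$frame[gen$truth$frames$basin == 1]
  ifp <- fingerprint(gen$ensemble, "resname TYL", frames = f1)
  get_freq <- function(rn, ty) {
    row <- ifp[ifp$residue_number == rn & ifp$interaction_type == ty, ]
    if (nrow(row) == 0) 0 else row$frequency
  }
  expect_equal(get_freq(3, "hydrophobic"), 0.70)
  expect_equal(get_freq(7, "hbond"), 1.0)
  expect_equal(get_freq(11, "hydrophobic"), 0.0)
  expect_true(all(ifp$frequency >= 0 & ifp$frequency <= 1))

  # permutation invariance over frames
  ifp_rev <- fingerprint(gen$ensemble, "resname TYL", frames = rev(f1))
  expect_equal(
    dplyr::arrange(tibble::as_tibble(ifp), residue_number, interaction_type),
    dplyr::arrange(
      tibble::as_tibble(ifp_rev), residue_number, interaction_type
    )
  )
})

test_that("hotspot selection applies the dual-basin persistence rule", {
  fp <- function(rows) {
    out <- tibble::tibble(
      chain_id = "A",
      residue_number = vapply(rows, `[[`, integer(1), 1),
      residue_name = "ALA",
      interaction_type = vapply(rows, `[[`, character(1), 2),
      frequency = vapply(rows, `[[`, numeric(1), 3),
      n_frames = 100L
    )
    class(out) <- c("ps_ifp", class(out))
    out
  }
  b1 <- fp(list(
    list(5L, "hbond", 0.8), list(9L, "hydrophobic", 0.9),
    list(12L, "hbond", 0.4)
  ))
  b2 <- fp(list(
    list(5L, "hbond", 0.7), list(9L, "hydrophobic", 0.1),
    list(12L, "hbond", 0.45)
  ))
  hs <- select_hotspots(list(a = b1, b = b2), min_frequency = 0.5)
  expect_equal(hs$residue_number, 5L) # persistent in both
  # 0.9/0.1 residue excluded with require_all_basins
  expect_false(9L %in% hs$residue_number)
  # but included when any basin suffices
  hs_any <- select_hotspots(list(a = b1, b = b2),
    min_frequency = 0.5, require_all_basins = FALSE
  )
  expect_setequal(hs_any$residue_number, c(5L, 9L))
})

test_that("planted dual-basin motif is recovered exactly against decoys", {
  motif <- c(3L, 5L, 8L, 11L, 14L, 20L)
  decoys <- c(2L, 9L, 22L)
  plant <- dplyr::bind_rows(
    tidyr::expand_grid(resnum = motif, basin = c(1L, 2L)) |>
      dplyr::mutate(type = "hydrophobic", frequency = 0.75),
    tidyr::expand_grid(resnum = decoys, basin = c(1L, 2L)) |>
      dplyr::mutate(type = "hydrophobic", frequency = 0.30)
  )
  gen <- generate_two_basin_ensemble(ensemble_spec(
    n_frames = 240, basin_occupancies = c(0.5, 0.5),
    planted_contacts = plant, seed = 23
  ))
  frames_of <- split(gen$truth$frames$frame, gen$truth$frames$basin)
  fps <- lapply(frames_of, function(fr) {
    fingerprint(gen$ensemble, "resname TYL", frames = fr)
  })
  hs <- select_hotspots(fps, min_frequency = 0.5)
  hits <- hs$residue_number[hs$residue_number != 16L]
  precision <- mean(hits %in% motif)
  recall <- mean(motif %in% hits)
  expect_equal(precision, 1)
  expect_equal(recall, 1)
})
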