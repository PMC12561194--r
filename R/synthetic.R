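# Synthetic toy systems with planted statistical structure.
#
# The generators emulate the statistical features of a solvated
# glycosyltransferase-ligand MD trajectory that the analysis stages
# consume -- two-basin conformational exchange, persistent per-residue
# contacts, pre-reaction-state geometry, tunnel centerlines and noisy
# initial-rate data -- without any physical realism. Planting is by exact
# counts (largest-remainder allocation plus a seeded shuffle), so
# downstream recovery tests have zero sampling slack.

#' Toy protein/ligand/donor topology and reference geometry
#'
#' Builds the documented toy system: 24 pseudo-residues of 4 atoms each
#' (`CA`, `C`, `O`, `CB`) arranged on a ring of the given radius forming a
#' pocket, a central 8-atom ligand (`TYL`: planar 6-carbon ring plus the
#' two hydroxyl oxygens `O4` and `O8`, the C4-OH / C8-OH acceptor roles),
#' and a 3-atom sugar-donor fragment (`UPG`) whose `C1` is the anomeric
#' carbon. Residue 16 is a histidine whose fourth atom is the catalytic
#' side-chain nitrogen `NE2`.
#'
#' @param ring_radius Protein ring radius in Angstrom.
#' @param n_residues Number of pseudo-residues on the ring.
#' @return List with `topology` and the reference `coords` matrix.
#' @export
build_toy_system <- function(ring_radius = 8, n_residues = 24) {
  if (n_residues < 17) abort("Need at least 17 residues (16 is catalytic).")
  ang <- 2 * pi * (seq_len(n_residues) - 1) / n_residues
  atom_name <- character(0)
  element <- character(0)
  resnum <- integer(0)
  resname <- character(0)
  chain <- character(0)
  coords <- NULL
  for (i in seq_len(n_residues)) {
    his <- i == 16L
    nm <- c("CA", "C", "O", if (his) "NE2" else "CB")
    el <- c("C", "C", "O", if (his) "N" else "C")
    r <- ring_radius
    u <- c(cos(ang[i]), sin(ang[i]), 0)
    pos <- rbind(
      r * u,
      (r + 0.8) * u + c(0, 0, 0.5),
      (r + 1.2) * u + c(0, 0, 1.5),
      (r - 1.5) * u
    )
    atom_name <- c(atom_name, nm)
    element <- c(element, el)
    resnum <- c(resnum, rep(i, 4))
    resname <- c(resname, rep(if (his) "HIS" else "ALA", 4))
    chain <- c(chain, rep("A", 4))
    coords <- rbind(coords, pos)
  }
  # Ligand: planar hexagon, radius 1.4 A, with para hydroxyl oxygens.
  ring_ang <- pi / 3 * (0:5)
  lig <- rbind(
    cbind(1.4 * cos(ring_ang), 1.4 * sin(ring_ang), 0),
    c(2.75, 0, 0),   # O8 (C8-OH oxygen role), bonded to C1 at angle 0
    c(-2.75, 0, 0)   # O4 (C4-OH oxygen role), bonded to C4 at angle 180
  )
  atom_name <- c(atom_name, paste0("C", 1:6), "O8", "O4")
  element <- c(element, rep("C", 6), "O", "O")
  resnum <- c(resnum, rep(101L, 8))
  resname <- c(resname, rep("TYL", 8))
  chain <- c(chain, rep("L", 8))
  coords <- rbind(coords, lig)
  # Donor fragment: anomeric carbon C1 plus ring oxygen and C2,
  # parked above the acceptor oxygen (non-reactive pose).
  don <- rbind(
    c(2.75, 0, 5.5),
    c(2.75, 0, 6.9),
    c(4.25, 0, 5.5)
  )
  atom_name <- c(atom_name, "C1", "O5", "C2")
  element <- c(element, "C", "O", "C")
  resnum <- c(resnum, rep(102L, 3))
  resname <- c(resname, rep("UPG", 3))
  chain <- c(chain, rep("L", 3))
  coords <- rbind(coords, don)
  topo <- topology(atom_name, element, resnum, resname, chain)
  list(topology = topo, coords = unname(coords))
}

#' Specification for a planted two-basin ensemble
#'
#' Collects everything [generate_two_basin_ensemble()] needs. Basin
#' occupancies and planted frequencies are realised by exact counts, not
#' Bernoulli draws. Planted contacts are given as a tibble with columns
#' `resnum`, `type` (`"hbond"` or `"hydrophobic"`), `basin` and
#' `frequency`; the generator places the residue's side-chain atom at a
#' geometry that satisfies (or violates) the corresponding detector
#' criterion with margin in exactly the requested fraction of that
#' basin's frames.
#'
#' @param n_frames Number of frames.
#' @param basin_occupancies Probabilities summing to 1, one per basin.
#' @param ring_radii Protein ring radius per basin (Angstrom); the radius
#'   difference separates the basins in both RMSD and Rg.
#' @param jitter_sigma Isotropic Gaussian jitter per coordinate
#'   (Angstrom). Must stay small against the planting margins (<= 0.3).
#' @param planted_contacts Tibble as described above (may be `NULL`).
#' @param planted_prs `list(basin =, rate =)` or `NULL`: fraction of that
#'   basin's frames given compliant pre-reaction-state geometry (both key
#'   distances at 3.0 A; non-compliant frames sit at 5.5 A).
#' @param basin_references Optional list of coordinate matrices overriding
#'   the ring-built references (one per basin, toy topology order).
#' @param seed Master seed; sub-streams are derived per purpose.
#' @return A list of class `ps_ensemble_spec`.
#' @export
ensemble_spec <- function(n_frames = 2000,
                          basin_occupancies = c(0.9, 0.1),
                          ring_radii = c(8, 9.2),
                          jitter_sigma = 0.1,
                          planted_contacts = NULL,
                          planted_prs = NULL,
                          basin_references = NULL,
                          seed = 1) {
  if (n_frames < 1) abort("`n_frames` must be at least 1.")
  occ <- as.numeric(basin_occupancies)
  if (abs(sum(occ) - 1) > 1e-9 || any(occ < 0)) {
    abort("`basin_occupancies` must be non-negative and sum to 1.")
  }
  if (is.null(basin_references) && length(ring_radii) != length(occ)) {
    abort("One ring radius per basin is required.")
  }
  if (jitter_sigma < 0) abort("`jitter_sigma` must be non-negative.")
  if (jitter_sigma > 0.3) {
    warn("jitter_sigma > 0.3 A can erode exact-count planting margins.")
  }
  if (!is.null(planted_contacts)) {
    pc <- as_tibble(planted_contacts)
    need <- c("resnum", "type", "basin", "frequency")
    if (!all(need %in% names(pc))) {
      abort("`planted_contacts` needs columns resnum, type, basin, frequency.")
    }
    if (!all(pc$type %in% c("hbond", "hydrophobic"))) {
      abort("Plantable contact types are 'hbond' and 'hydrophobic'.")
    }
    if (any(pc$frequency < 0 | pc$frequency > 1)) {
      abort("Planted frequencies must lie in [0, 1].")
    }
    if (any(pc$type == "hydrophobic" & pc$resnum == 16)) {
      abort("Residue 16 is catalytic (no CB atom); cannot plant hydrophobic.")
    }
    planted_contacts <- pc
  }
  if (!is.null(planted_prs)) {
    if (!is.list(planted_prs) ||
      !all(c("basin", "rate") %in% names(planted_prs))) {
      abort("`planted_prs` must be list(basin =, rate =).")
    }
    if (planted_prs$rate < 0 || planted_prs$rate > 1) {
      abort("Planted PRS rate must lie in [0, 1].")
    }
  }
  structure(
    list(
      n_frames = as.integer(n_frames), basin_occupancies = occ,
      ring_radii = ring_radii, jitter_sigma = jitter_sigma,
      planted_contacts = planted_contacts, planted_prs = planted_prs,
      basin_references = basin_references, seed = seed
    ),
    class = "ps_ensemble_spec"
  )
}

#' Generate a planted multi-basin toy ensemble
#'
#' Each frame is drawn by (i) assigning a basin by exact-count occupancy
#' (largest-remainder allocation, seeded shuffle), (ii) taking that
#' basin's reference geometry, (iii) adding isotropic Gaussian jitter,
#' then (iv) overwriting the planted contact and pre-reaction-state atoms
#' so the planted labels hold exactly. The returned ground truth is
#' sufficient to score every downstream stage without re-deriving labels.
#'
#' @param spec An [ensemble_spec()].
#' @return List with `ensemble` (a [ensemble()]), `truth` (list of
#'   tibbles: `frames`, `contacts`, `prs`) and `selections` (named list
#'   of selection expressions for the special atoms).
#' @export
generate_two_basin_ensemble <- function(spec) {
  if (!inherits(spec, "ps_ensemble_spec")) {
    abort("`spec` must come from ensemble_spec().")
  }
  k <- length(spec$basin_occupancies)
  sys <- build_toy_system(ring_radius = spec$ring_radii[1] %||% 8)
  topo <- sys$topology
  refs <- spec$basin_references
  if (is.null(refs)) {
    refs <- lapply(spec$ring_radii, function(r) {
      build_toy_system(ring_radius = r)$coords
    })
  } else {
    for (r in refs) {
      if (!is.matrix(r) || nrow(r) != nrow(topo) || ncol(r) != 3) {
        abort("Basin reference frames must match the toy topology.")
      }
    }
  }
  n <- spec$n_frames
  counts <- largest_remainder(spec$basin_occupancies, n)
  labels <- rep(seq_len(k), counts)
  labels <- with_seed(sub_seed(spec$seed, 1), sample(labels))

  coords <- with_seed(sub_seed(spec$seed, 2), {
    lapply(seq_len(n), function(t) {
      refs[[labels[t]]] +
        matrix(rnorm(3 * nrow(topo), sd = spec$jitter_sigma), ncol = 3)
    })
  })

  idx_of <- function(expr) resolve_selection(topo, expr)$indices
  i_o8 <- idx_of("resname TYL and name O8")
  i_o4 <- idx_of("resname TYL and name O4")
  i_ring <- idx_of(paste("resname TYL and name", "C2 C3 C5 C6"))
  i_don <- idx_of("resname UPG")
  i_c1 <- idx_of("resname UPG and name C1")
  i_ne2 <- idx_of("resnum 16 and name NE2")

  truth_contacts <- NULL
  pc <- spec$planted_contacts
  if (!is.null(pc)) {
    for (r in seq_len(nrow(pc))) {
      bframes <- which(labels == pc$basin[r])
      m <- as.integer(round_half_up(pc$frequency[r] * length(bframes)))
      chosen <- with_seed(
        sub_seed(spec$seed, 10 + r),
        bframes[sample.int(length(bframes))][seq_len(m)]
      )
      resn <- pc$resnum[r]
      atomnm <- if (pc$type[r] == "hbond") "O" else "CB"
      i_atom <- idx_of(paste("chain A and resnum", resn, "and name", atomnm))
      i_ca <- idx_of(paste("chain A and resnum", resn, "and name CA"))
      for (t in chosen) {
        fr <- coords[[t]]
        if (pc$type[r] == "hbond") {
          # Anchor on the ligand hydroxyl oxygen facing the residue.
          anchor <- if (sum(fr[i_ca, 1:2] * fr[i_o8, 1:2]) >= 0) {
            i_o8
          } else {
            i_o4
          }
          d <- 2.9
          ai <- anchor
        } else {
          # Nearest apolar ring carbon to the residue.
          dd <- row_norms(sweep(
            fr[i_ring, , drop = FALSE], 2, fr[i_ca, ]
          ))
          ai <- i_ring[which.min(dd)]
          d <- 3.4
        }
        # Outward direction lifted out of plane so the placed atom keeps
        # clear of the ligand oxygens (apolarity heuristic margin);
        # hbond oxygens go above the ligand plane, hydrophobic carbons
        # below, so planted atoms of different types never crowd each
        # other into the polar-bond heuristic radius.
        zlift <- if (pc$type[r] == "hbond") 1 else -1
        u <- fr[i_ca, ] - fr[ai, ]
        u <- u / sqrt(sum(u^2))
        u <- u + c(0, 0, zlift)
        u <- u / sqrt(sum(u^2))
        fr[i_atom, ] <- fr[ai, ] + d * u
        coords[[t]] <- fr
      }
      sat <- logical(n)
      sat[chosen] <- TRUE
      truth_contacts <- dplyr::bind_rows(
        truth_contacts,
        tibble(
          frame = bframes, resnum = resn, type = pc$type[r],
          basin = pc$basin[r], satisfied = sat[bframes]
        )
      )
    }
  }

  prs_truth <- NULL
  if (!is.null(spec$planted_prs)) {
    bframes <- which(labels == spec$planted_prs$basin)
    m <- as.integer(round_half_up(spec$planted_prs$rate * length(bframes)))
    chosen <- with_seed(
      sub_seed(spec$seed, 4),
      bframes[sample.int(length(bframes))][seq_len(m)]
    )
    compliant <- logical(n)
    compliant[chosen] <- TRUE
    don_off <- sweep(sys$coords[i_don, , drop = FALSE], 2,
      sys$coords[i_c1, ]
    )
    for (t in seq_len(n)) {
      fr <- coords[[t]]
      d <- if (compliant[t]) 3.0 else 5.5
      o8 <- fr[i_o8, ]
      fr[i_don, ] <- sweep(don_off, 2, o8 + c(0, 0, d), "+")
      # Catalytic nitrogen approaches from below and outward, keeping it
      # clear of any planted hydrophobic carbons under the ligand.
      fr[i_ne2, ] <- o8 + d * c(1, 0, -1) / sqrt(2)
      coords[[t]] <- fr
    }
    prs_truth <- tibble(frame = seq_len(n), compliant = compliant)
  }

  list(
    ensemble = ensemble(topo, coords),
    truth = list(
      frames = tibble(frame = seq_len(n), basin = labels),
      contacts = truth_contacts,
      prs = prs_truth
    ),
    selections = list(
      protein_ca = "chain A and name CA",
      protein = "chain A",
      ligand = "resname TYL",
      acceptor_c8 = "resname TYL and name O8",
      acceptor_c4 = "resname TYL and name O4",
      anomeric_c = "resname UPG and name C1",
      catalytic_n = "resnum 16 and name NE2"
    )
  )
}

#' Specification for a toy tunnel
#'
#' @param centerline `list(type = "straight", length =)`,
#'   `list(type = "arc", radius =, angle =)` (angle in radians), or
#'   `list(type = "polyline", points = <n x 3 matrix>)`.
#' @param radius_profile Sphere radii (Angstrom), linearly interpolated
#'   along normalised arc length.
#' @param sphere_spacing Arc-length spacing between sphere centres.
#' @param seed Seed (kept for interface uniformity; the toy tunnel is
#'   deterministic).
#' @return A list of class `ps_tunnel_spec`.
#' @export
toy_tunnel_spec <- function(centerline = list(type = "straight", length = 20),
                            radius_profile = 2,
                            sphere_spacing = 1,
                            seed = 1) {
  if (any(radius_profile <= 0)) abort("Radii must be positive.")
  stopifnot_scalar_number(sphere_spacing, "sphere_spacing", positive = TRUE)
  structure(
    list(
      centerline = centerline, radius_profile = as.numeric(radius_profile),
      sphere_spacing = sphere_spacing, seed = seed
    ),
    class = "ps_tunnel_spec"
  )
}

#' Generate a toy tunnel profile
#'
#' Samples the centerline at the requested arc-length spacing (both ends
#' included) and attaches interpolated radii.
#'
#' @param spec A [toy_tunnel_spec()].
#' @return A [tunnel_profile()] tibble.
#' @export
generate_toy_tunnel <- function(spec) {
  if (!inherits(spec, "ps_tunnel_spec")) {
    abort("`spec` must come from toy_tunnel_spec().")
  }
  cl <- spec$centerline
  pts <- switch(cl$type,
    straight = {
      L <- cl$length
      s <- seq(0, L, by = spec$sphere_spacing)
      if (tail(s, 1) < L - 1e-9) s <- c(s, L)
      cbind(0, 0, s)
    },
    arc = {
      R <- cl$radius
      L <- R * cl$angle
      s <- seq(0, L, by = spec$sphere_spacing)
      if (tail(s, 1) < L - 1e-9) s <- c(s, L)
      th <- s / R
      cbind(R * cos(th), R * sin(th), 0)
    },
    polyline = {
      p <- cl$points
      if (!is.matrix(p) || ncol(p) != 3 || nrow(p) < 2) {
        abort("Polyline needs an n x 3 matrix with n >= 2.")
      }
      seg <- sqrt(rowSums(diff(p)^2))
      cum <- c(0, cumsum(seg))
      L <- tail(cum, 1)
      s <- seq(0, L, by = spec$sphere_spacing)
      if (tail(s, 1) < L - 1e-9) s <- c(s, L)
      t(vapply(s, function(si) {
        j <- max(which(cum <= si + 1e-12))
        if (j >= nrow(p)) return(p[nrow(p), ])
        f <- (si - cum[j]) / seg[j]
        p[j, ] + f * (p[j + 1, ] - p[j, ])
      }, numeric(3)))
    },
    abort("Unknown centerline type.")
  )
  nsph <- nrow(pts)
  rp <- spec$radius_profile
  radii <- if (length(rp) == 1) {
    rep(rp, nsph)
  } else {
    stats::approx(
      seq(0, 1, length.out = length(rp)), rp,
      xout = seq(0, 1, length.out = nsph)
    )$y
  }
  tunnel_profile(pts[, 1], pts[, 2], pts[, 3], radii, label = "toy")
}

#' Specification for noisy Michaelis-Menten rate data
#'
#' @param km_mM Michaelis constant (mM).
#' @param kcat_per_s Turnover number (per second).
#' @param enzyme_conc Enzyme concentration (same unit family as rates;
#'   rate = kcat * E * S / (Km + S)).
#' @param substrate_grid_mM Substrate concentrations (>= 4 points), the
#'   0-7 mM range typical of initial-rate assays on tyrosol.
#' @param noise_cv Multiplicative noise coefficient of variation (>= 0).
#' @param seed Seed.
#' @return A list of class `ps_rate_spec`.
#' @export
rate_data_spec <- function(km_mM = 4.32, kcat_per_s = 0.22,
                           enzyme_conc = 1,
                           substrate_grid_mM = c(0.25, 0.5, 1, 2, 3, 4, 5, 7),
                           noise_cv = 0, seed = 1) {
  stopifnot_scalar_number(km_mM, "km_mM", positive = TRUE)
  stopifnot_scalar_number(kcat_per_s, "kcat_per_s", positive = TRUE)
  stopifnot_scalar_number(enzyme_conc, "enzyme_conc", positive = TRUE)
  if (length(substrate_grid_mM) < 4 || any(substrate_grid_mM < 0)) {
    abort("`substrate_grid_mM` needs >= 4 non-negative points.")
  }
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  structure(
    list(
      km_mM = km_mM, kcat_per_s = kcat_per_s, enzyme_conc = enzyme_conc,
      substrate_grid_mM = as.numeric(substrate_grid_mM),
      noise_cv = noise_cv, seed = seed
    ),
    class = "ps_rate_spec"
  )
}

#' Generate noisy initial-rate data
#'
#' `rate = kcat * E * S / (Km + S) * (1 + eps)` with
#' `eps ~ Normal(0, noise_cv)`, seeded.
#'
#' @param spec A [rate_data_spec()].
#' @return Tibble with columns `S_mM` and `rate`.
#' @export
generate_rate_data <- function(spec) {
  if (!inherits(spec, "ps_rate_spec")) {
    abort("`spec` must come from rate_data_spec().")
  }
  s <- spec$substrate_grid_mM
  v <- spec$kcat_per_s * spec$enzyme_conc * s / (spec$km_mM + s)
  eps <- with_seed(
    spec$seed,
    rnorm(length(s), mean = 0, sd = spec$noise_cv)
  )
  tibble(S_mM = s, rate = v * (1 + eps))
}
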