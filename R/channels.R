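# Tunnel centerline metrics, a simplified grid tunnel search, and
# grid-based pocket volume / surface area.

# Fixed per-element van der Waals radii (Angstrom); unknown elements get
# the carbon radius.
ATOM_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2)

atom_radius <- function(element) {
  r <- ATOM_RADII[element]
  r[is.na(r)] <- ATOM_RADII[["C"]]
  unname(r)
}

#' Construct a tunnel profile
#'
#' A tunnel profile is the CAVER-style sequence of centerline spheres:
#' centres along the tunnel axis plus the local free radius.
#'
#' @param x,y,z Sphere centre coordinates (Angstrom).
#' @param radius Sphere radii (positive, Angstrom).
#' @param label Optional label.
#' @return A `ps_tunnel` tibble with columns `x`, `y`, `z`, `radius`.
#' @export
tunnel_profile <- function(x, y, z, radius, label = "tunnel") {
  if (length(x) < 2) abort("A tunnel profile needs >= 2 spheres.")
  if (any(radius <= 0)) abort("Sphere radii must be positive.")
  out <- tibble(
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    radius = as.numeric(radius)
  )
  if (anyNA(out)) abort("Tunnel profile values must be finite.")
  attr(out, "label") <- label
  class(out) <- c("ps_tunnel", class(out))
  out
}

#' Tunnel geometry metrics
#'
#' From a centerline profile computes:
#' * `length` — sum of segment lengths (Angstrom);
#' * `curvature` — length divided by the straight-line distance between
#'   the endpoints (dimensionless, >= 1; 1 for a straight tunnel);
#' * `bottleneck_radius` — the minimum sphere radius;
#' * `cost` — `cost_scale * sum(l_i / r_i^2)` with `l_i` the segment
#'   length and `r_i` the mean of the segment's endpoint radii (the
#'   narrow-segment-penalising cost integral);
#' * `throughput` — `exp(-cost)`, in `(0, 1]`; higher for shorter,
#'   wider, straighter tunnels.
#'
#' The absolute scale of `cost` depends on `cost_scale` (default 1),
#' which is an explicit parameter: throughput values are comparable only
#' at a fixed `cost_scale`.
#'
#' @param profile A `ps_tunnel` (or data frame with `x`, `y`, `z`,
#'   `radius`).
#' @param cost_scale Multiplier on the cost integral (default 1).
#' @return One-row tibble: `length`, `curvature`, `bottleneck_radius`,
#'   `cost`, `throughput`, `n_spheres`.
#' @export
tunnel_metrics <- function(profile, cost_scale = 1) {
  p <- as.data.frame(profile)
  if (!all(c("x", "y", "z", "radius") %in% names(p))) {
    abort("`profile` needs columns x, y, z, radius.")
  }
  if (nrow(p) < 2) abort("A tunnel profile needs >= 2 spheres.")
  centres <- as.matrix(p[, c("x", "y", "z")])
  seg <- sqrt(rowSums(diff(centres)^2))
  len <- sum(seg)
  chord <- sqrt(sum((centres[nrow(centres), ] - centres[1, ])^2))
  if (chord < 1e-9) {
    abort("Tunnel endpoints coincide; curvature is undefined.")
  }
  rmean <- (head(p$radius, -1) + tail(p$radius, -1)) / 2
  cost <- cost_scale * sum(seg / rmean^2)
  tibble(
    length = len,
    curvature = len / chord,
    bottleneck_radius = min(p$radius),
    cost = cost,
    throughput = exp(-cost),
    n_spheres = nrow(p)
  )
}

#' Read / write a tunnel profile CSV
#'
#' Interchange format: CSV with columns `x`, `y`, `z`, `radius`
#' (Angstrom), one row per centerline sphere.
#'
#' @param path File path.
#' @return A `ps_tunnel` tibble.
#' @export
read_tunnel_profile_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y", "z", "radius") %in% names(df))) {
    abort("Tunnel CSV needs columns x, y, z, radius.")
  }
  if (nrow(df) == 0) abort("Empty profile: the CSV has a header only.")
  for (cn in c("x", "y", "z", "radius")) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      abort(paste0(
        "Malformed value in column '", cn, "' at data row ", bad,
        " (line ", bad + 1, ")."
      ))
    }
    df[[cn]] <- v
  }
  tunnel_profile(df$x, df$y, df$z, df$radius,
    label = sub("\\.csv$", "", basename(path))
  )
}

#' @rdname read_tunnel_profile_csv
#' @param profile A `ps_tunnel`.
#' @export
write_tunnel_profile_csv <- function(profile, path) {
  p <- as.data.frame(profile)[, c("x", "y", "z", "radius")]
  utils::write.csv(p, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Build the free-space grid around a frame: voxel centres on a regular
# lattice over the atom bounding box padded by `pad`; a voxel is free iff
# its clearance (distance to the nearest atom surface) exceeds the probe
# radius.
free_space_grid <- function(coords, elements, grid_spacing, probe_radius,
                            pad = 2) {
  radii <- atom_radius(elements)
  lo <- apply(coords, 2, min) - pad
  hi <- apply(coords, 2, max) + pad
  ax <- lapply(1:3, function(k) seq(lo[k], hi[k], by = grid_spacing))
  dims <- vapply(ax, length, integer(1))
  centres <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  # Clearance = min over atoms of (distance to centre - atom radius),
  # computed in chunks to bound memory.
  n <- nrow(centres)
  clearance <- rep(Inf, n)
  chunk <- max(1L, floor(2e6 / nrow(coords)))
  s <- 1L
  while (s <= n) {
    e <- min(n, s + chunk - 1L)
    d <- cross_dist(centres[s:e, , drop = FALSE], coords)
    d <- sweep(d, 2, radii)
    clearance[s:e] <- apply(d, 1, min)
    s <- e + 1L
  }
  list(
    axes = ax, dims = dims, centres = centres,
    clearance = clearance, free = clearance > probe_radius,
    spacing = grid_spacing
  )
}

grid_index <- function(grid, point) {
  ii <- vapply(1:3, function(k) {
    which.min(abs(grid$axes[[k]] - point[k]))
  }, integer(1))
  # expand.grid varies the first factor fastest
  ii[1] + (ii[2] - 1) * grid$dims[1] +
    (ii[3] - 1) * grid$dims[1] * grid$dims[2]
}

grid_neighbours <- function(grid, idx) {
  d1 <- grid$dims[1]
  d2 <- grid$dims[2]
  d3 <- grid$dims[3]
  i3 <- (idx - 1) %/% (d1 * d2) + 1
  rem <- (idx - 1) %% (d1 * d2)
  i2 <- rem %/% d1 + 1
  i1 <- rem %% d1 + 1
  out <- integer(0)
  if (i1 > 1) out <- c(out, idx - 1)
  if (i1 < d1) out <- c(out, idx + 1)
  if (i2 > 1) out <- c(out, idx - d1)
  if (i2 < d2) out <- c(out, idx + d1)
  if (i3 > 1) out <- c(out, idx - d1 * d2)
  if (i3 < d3) out <- c(out, idx + d1 * d2)
  out
}

on_boundary <- function(grid, idx) {
  d1 <- grid$dims[1]
  d2 <- grid$dims[2]
  d3 <- grid$dims[3]
  i3 <- (idx - 1) %/% (d1 * d2) + 1
  rem <- (idx - 1) %% (d1 * d2)
  i2 <- rem %/% d1 + 1
  i1 <- rem %% d1 + 1
  i1 == 1 | i1 == d1 | i2 == 1 | i2 == d2 | i3 == 1 | i3 == d3
}

# Vectorised 6-neighbourhood of a set of voxel indices.
neighbours_of_set <- function(grid, idxs) {
  d1 <- grid$dims[1]
  d2 <- grid$dims[2]
  d3 <- grid$dims[3]
  i3 <- (idxs - 1) %/% (d1 * d2) + 1
  rem <- (idxs - 1) %% (d1 * d2)
  i2 <- rem %/% d1 + 1
  i1 <- rem %% d1 + 1
  unique(c(
    idxs[i1 > 1] - 1, idxs[i1 < d1] + 1,
    idxs[i2 > 1] - d1, idxs[i2 < d2] + d1,
    idxs[i3 > 1] - d1 * d2, idxs[i3 < d3] + d1 * d2
  ))
}

# Connected free voxels reachable from `start` using only voxels with
# clearance >= thr (6-neighbourhood). Returns logical vector.
reachable_at <- function(grid, start, thr) {
  ok <- grid$free & grid$clearance >= thr
  if (!ok[start]) {
    return(rep(FALSE, length(ok)))
  }
  seen <- logical(length(ok))
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier) > 0) {
    nb <- neighbours_of_set(grid, frontier)
    nb <- nb[ok[nb] & !seen[nb]]
    seen[nb] <- TRUE
    frontier <- nb
  }
  seen
}

#' Widest-path tunnel search on a free-space grid
#'
#' Discretises space around the structure, marks voxels free when no
#' atom surface comes within `probe_radius`, and finds the
#' bottleneck-optimal escape path: among all paths from the start voxel
#' to the grid boundary it maximises the minimum clearance along the
#' path (computed by a binary search over the sorted clearance values,
#' each step a 6-neighbour flood fill, followed by a breadth-first
#' shortest path on the admissible subgraph with deterministic ascending
#' voxel-index tie-breaks). The returned centerline carries the local
#' clearance as the sphere radius.
#'
#' @param ens A [ensemble()] (or an N x 3 coordinate matrix plus
#'   `elements`).
#' @param start Length-3 start point inside the cavity.
#' @param frame Frame index when `ens` is an ensemble.
#' @param probe_radius Probe radius in Angstrom (default 1.4, a water
#'   molecule).
#' @param grid_spacing Voxel edge length in Angstrom (default 0.5).
#' @param elements Element vector when `ens` is a bare matrix.
#' @return A list: `found` (logical), `profile` (`ps_tunnel` or `NULL`),
#'   `bottleneck_radius`, `grid_spacing`.
#' @export
grid_tunnel_search <- function(ens, start, frame = 1, probe_radius = 1.4,
                               grid_spacing = 0.5, elements = NULL) {
  if (inherits(ens, "ps_ensemble")) {
    coords <- frame_coords(ens, frame)
    elements <- ens$topology$element
  } else {
    coords <- ens
    if (is.null(elements)) elements <- rep("C", nrow(coords))
  }
  grid <- free_space_grid(coords, elements, grid_spacing, probe_radius)
  sidx <- grid_index(grid, start)
  if (!grid$free[sidx]) {
    abort("Start point is not in free space (clearance <= probe radius).")
  }
  # Binary search over candidate bottleneck clearances.
  cand <- sort(unique(grid$clearance[grid$free]))
  lo <- 1L
  hi <- length(cand)
  best <- NA_real_
  # reachable() must hit the boundary for a tunnel to exist.
  esc <- function(thr) {
    seen <- reachable_at(grid, sidx, thr)
    any(seen & on_boundary(grid, seq_along(seen)))
  }
  if (!esc(cand[1])) {
    return(list(
      found = FALSE, profile = NULL, bottleneck_radius = NA_real_,
      grid_spacing = grid_spacing
    ))
  }
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (esc(cand[mid])) lo <- mid else hi <- mid - 1L
  }
  thr <- cand[lo]
  # Shortest path (BFS) on the admissible subgraph; ties resolved by
  # ascending voxel index through the ordered frontier expansion.
  ok <- grid$free & grid$clearance >= thr
  pred <- integer(length(ok))
  seen <- logical(length(ok))
  seen[sidx] <- TRUE
  frontier <- sidx
  target <- NA_integer_
  bnd <- on_boundary(grid, seq_along(ok))
  while (length(frontier) > 0 && is.na(target)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- grid_neighbours(grid, v)
      nb <- nb[ok[nb] & !seen[nb]]
      nb <- sort(nb)
      seen[nb] <- TRUE
      pred[nb] <- v
      nxt <- c(nxt, nb)
    }
    hitb <- nxt[bnd[nxt]]
    if (length(hitb) > 0) target <- min(hitb)
    frontier <- sort(unique(nxt))
  }
  if (is.na(target)) {
    # start itself on boundary with a degenerate grid
    return(list(
      found = FALSE, profile = NULL, bottleneck_radius = NA_real_,
      grid_spacing = grid_spacing
    ))
  }
  path <- target
  while (path[1] != sidx) path <- c(pred[path[1]], path)
  centres <- grid$centres[path, , drop = FALSE]
  radii <- grid$clearance[path]
  list(
    found = TRUE,
    profile = tunnel_profile(
      centres[, 1], centres[, 2], centres[, 3], radii,
      label = "grid_search"
    ),
    bottleneck_radius = min(radii),
    grid_spacing = grid_spacing
  )
}

#' Grid-based pocket volume and surface area
#'
#' Flood-fills connected free voxels (6-neighbourhood) from a seed point,
#' bounded by the protein occupancy and the padded atom bounding box.
#' `volume = voxel count * spacing^3`; the surface area estimator counts
#' exposed voxel faces and applies the documented 2/3 correction for the
#' staircase bias of face counting on smooth surfaces. If the filled
#' region touches the bounding box the pocket is not enclosed and the
#' result is flagged `unbounded`.
#'
#' @param ens A [ensemble()] or an N x 3 coordinate matrix.
#' @param seed_point Length-3 point inside the pocket.
#' @param frame Frame index when `ens` is an ensemble.
#' @param grid_spacing Voxel edge length (default 0.5 Angstrom).
#' @param probe_radius Probe radius (default 1.4 Angstrom).
#' @param elements Element vector when `ens` is a bare matrix.
#' @return One-row tibble: `volume`, `surface_area`, `n_voxels`,
#'   `grid_spacing`, `probe_radius`, `unbounded`.
#' @export
pocket_metrics <- function(ens, seed_point, frame = 1, grid_spacing = 0.5,
                           probe_radius = 1.4, elements = NULL) {
  if (inherits(ens, "ps_ensemble")) {
    coords <- frame_coords(ens, frame)
    elements <- ens$topology$element
  } else {
    coords <- ens
    if (is.null(elements)) elements <- rep("C", nrow(coords))
  }
  grid <- free_space_grid(coords, elements, grid_spacing, probe_radius)
  sidx <- grid_index(grid, seed_point)
  if (grid$clearance[sidx] <= 0) {
    abort("Seed point lies inside an atom.")
  }
  if (!grid$free[sidx]) {
    abort("Seed point is not in free space (clearance <= probe radius).")
  }
  seen <- reachable_at(grid, sidx, -Inf)
  members <- which(seen)
  unbounded <- any(on_boundary(grid, members))
  # Exposed faces: neighbour not in the pocket (or face on the grid box).
  faces <- 0L
  memb_set <- logical(length(seen))
  memb_set[members] <- TRUE
  for (v in members) {
    nb <- grid_neighbours(grid, v)
    faces <- faces + (6L - length(nb)) + sum(!memb_set[nb])
  }
  tibble(
    volume = length(members) * grid_spacing^3,
    surface_area = faces * grid_spacing^2 * 2 / 3,
    n_voxels = length(members),
    grid_spacing = grid_spacing,
    probe_radius = probe_radius,
    unbounded = unbounded
  )
}
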