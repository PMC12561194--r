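# Shared fixture builders. Everything is generated in code; no data
# files.

rotation_z <- function(theta) {
  rbind(
    c(cos(theta), -sin(theta), 0),
    c(sin(theta), cos(theta), 0),
    c(0, 0, 1)
  )
}

# Uniform-ish random rotation from three seeded angles.
random_rotation <- function() {
  th <- stats::runif(3, 0, 2 * pi)
  rx <- rbind(
    c(1, 0, 0),
    c(0, cos(th[1]), -sin(th[1])),
    c(0, sin(th[1]), cos(th[1]))
  )
  ry <- rbind(
    c(cos(th[2]), 0, sin(th[2])),
    c(0, 1, 0),
    c(-sin(th[2]), 0, cos(th[2]))
  )
  rx %*% ry %*% rotation_z(th[3])
}

# Minimal topology of n generic carbon atoms in one residue.
carbon_topology <- function(n, resname = "LIG", chain = "X",
                            elements = rep("C", n)) {
  topology(
    atom_name = paste0("C", seq_len(n)),
    element = elements,
    residue_number = rep(1L, n),
    residue_name = rep(resname, n),
    chain_id = rep(chain, n)
  )
}

# Quasi-uniform points on a sphere (Fibonacci lattice), used to build
# enclosing atom shells for pocket/tunnel fixtures.
fib_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

# Spherical shell of "atoms" enclosing a free cavity of radius
# `cavity_r` for carbon atoms (1.7 A) and the given probe.
cavity_shell <- function(cavity_r, probe = 1.4, n = 1200) {
  fib_sphere(n, cavity_r + 1.7 + probe)
}

# Shell with a cylindrical exit channel along +z whose free radius (to
# the atom surface) is `channel_r`. Returns the atom coordinates.
cavity_with_channel <- function(cavity_r = 5, channel_r = 2, probe = 1.4,
                                n_shell = 1200, ring_atoms = 14) {
  shell_r <- cavity_r + 1.7 + probe
  shell <- fib_sphere(n_shell, shell_r)
  tube_r <- channel_r + 1.7
  # remove shell atoms blocking the channel mouth
  open_ang <- atan2(tube_r, shell_r)
  ang <- atan2(sqrt(shell[, 1]^2 + shell[, 2]^2), shell[, 3])
  shell <- shell[ang > open_ang, , drop = FALSE]
  ta <- 2 * pi * (seq_len(ring_atoms) - 1) / ring_atoms
  zline <- seq(shell_r * 0.5, shell_r + 4, by = 0.8)
  tube <- do.call(rbind, lapply(zline, function(z) {
    cbind(tube_r * cos(ta), tube_r * sin(ta), z)
  }))
  rbind(shell, tube)
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")

# Independent widest-path oracle on a coarse grid using igraph: maximum
# over boundary voxels of the maximin clearance, via thresholded
# connectivity.
igraph_bottleneck <- function(coords, start, probe, spacing) {
  grid <- pocketshaper:::free_space_grid(coords, rep("C", nrow(coords)),
    spacing, probe
  )
  sidx <- pocketshaper:::grid_index(grid, start)
  free <- which(grid$free)
  if (!(sidx %in% free)) return(NA_real_)
  thr_values <- sort(unique(grid$clearance[free]), decreasing = TRUE)
  bnd <- pocketshaper:::on_boundary(grid, seq_along(grid$free))
  for (thr in thr_values) {
    keep <- which(grid$free & grid$clearance >= thr)
    id <- match(seq_along(grid$free), keep)
    edges <- c()
    for (v in keep) {
      for (nb in pocketshaper:::grid_neighbours(grid, v)) {
        if (nb > v && !is.na(id[nb])) edges <- c(edges, id[v], id[nb])
      }
    }
    g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
    if (length(edges) > 0) g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)$membership
    s_comp <- comp[id[sidx]]
    if (is.na(s_comp)) next
    targets <- id[bnd & !is.na(id)]
    targets <- targets[!is.na(targets)]
    if (any(comp[targets] == s_comp)) return(thr)
  }
  NA_real_
}

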