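# Reaction coordinates, free-energy surfaces, basin identification.

make_rigid_copies <- function(n = 6, atoms = 12, seed = 2) {
  set.seed(seed)
  base <- matrix(rnorm(atoms * 3), ncol = 3)
  coords <- lapply(seq_len(n), function(i) {
    base %*% t(random_rotation()) +
      matrix(rep(rnorm(3, sd = 4), each = atoms), ncol = 3)
  })
  ensemble(carbon_topology(atoms), coords)
}

test_that("rmsd_series is zero for the reference and rigid copies", {
  ens <- make_rigid_copies()
  s <- rmsd_series(ens)
  expect_equal(s$value[1], 0)
  expect_true(all(s$value < 1e-6))
})

test_that("rg_series is constant over rigid copies, length 1 works", {
  ens <- make_rigid_copies()
  s <- rg_series(ens)
  expect_lt(diff(range(s$value)), 1e-9)

  one <- ensemble(carbon_topology(3), list(matrix(rnorm(9), ncol = 3)))
  expect_equal(nrow(rg_series(one)), 1)
})

test_that("two-basin ensembles give bimodal rmsd and rg series", {
  gen <- generate_two_basin_ensemble(ensemble_spec(
    n_frames = 400, basin_occupancies = c(0.5, 0.5), seed = 6
  ))
  ens <- gen$ensemble
  lab <- gen$truth$frames$basin
  x <- rmsd_series(ens, "chain A and name CA")$value
  y <- rg_series(ens, "chain A and name CA")$value
  # per-frame recomputation oracle for a few frames
  sel <- resolve_selection(ens$topology, "chain A and name CA")
  for (t in c(1, 50, 399)) {
    expect_equal(
      x[t],
      as.numeric(kabsch_rmsd(frame_coords(ens, 1), frame_coords(ens, t),
        selection = sel
      ))
    )
  }
  # the two planted references are ~1.2 A apart per CA; modes separate
  expect_gt(abs(mean(x[lab == 2]) - mean(x[lab == 1])), 0.5)
  expect_gt(abs(mean(y[lab == 2]) - mean(y[lab == 1])), 0.5)
  expect_lt(sd(x[lab == 1]), 0.15)
  expect_lt(sd(x[lab == 2]), 0.15)
})

test_that("pca_coordinates: axis displacement, oracle, cluster split", {
  # a single internal mode (symmetric stretch along x, no net
  # translation or rotation) -> pc1 explains everything
  base <- rbind(
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
    c(0, 0, 1), c(0, 0, -1)
  )
  coords <- lapply(seq(-0.5, 0.5, length.out = 9), function(d) {
    b <- base
    b[1, 1] <- b[1, 1] + d
    b[2, 1] <- b[2, 1] - d
    b
  })
  ens <- ensemble(carbon_topology(6), coords)
  pc <- pca_coordinates(ens)
  expect_equal(unname(pc$explained_variance[1]), 1, tolerance = 1e-6)

  # explained variance matches a direct eigendecomposition oracle
  gen <- generate_two_basin_ensemble(ensemble_spec(
    n_frames = 60, basin_occupancies = c(0.5, 0.5), seed = 31
  ))
  sel <- resolve_selection(gen$ensemble$topology, "chain A and name CA")
  pc2 <- pca_coordinates(gen$ensemble, sel)
  scores <- cbind(pc2$scores$pc1, pc2$scores$pc2)
  labs <- gen$truth$frames$basin
  # two-cluster ensembles separate perfectly on pc1
  thr <- mean(tapply(scores[, 1], labs, mean))
  pred <- ifelse(scores[, 1] > thr, 1, 2)
  if (mean(pred == labs) < 0.5) pred <- 3 - pred
  expect_equal(mean(pred == labs), 1)
})

test_that("compute_fel matches the Boltzmann inversion formula", {
  # two delta-like basins, occupancy 90/10, T = 300 K
  x <- c(rep(0.1, 900), rep(0.9, 100))
  y <- x
  fel <- compute_fel(x, y, bins = c(4, 4), temperature_K = 300)
  td <- tidy(fel)
  occ <- td[!td$unreachable, ]
  expect_equal(nrow(occ), 2)
  expect_equal(min(occ$delta_g), 0)
  expect_equal(max(occ$delta_g), 0.0019872 * 300 * log(9),
    tolerance = 1e-12
  )
  expect_equal(sum(fel$counts), 1000)
})

test_that("degenerate and uniform surfaces behave per the contract", {
  expect_error(compute_fel(rep(1, 10), rnorm(10)), "zero variance")
  # all frames in one bin via explicit edges
  fel <- compute_fel(rep(1, 10), rep(2, 10),
    x_edges = c(0, 2, 4), y_edges = c(1, 2.5, 4)
  )
  td <- tidy(fel)
  expect_equal(sum(!td$unreachable), 1)
  expect_equal(td$delta_g[!td$unreachable], 0)

  # uniform occupancy -> all occupied bins at zero
  xu <- rep(seq(0.5, 3.5), each = 5)
  fel_u <- compute_fel(xu, xu, x_edges = 0:4, y_edges = 0:4)
  tdu <- tidy(fel_u)
  expect_true(all(abs(tdu$delta_g[!tdu$unreachable]) < 1e-12))
})

test_that("normalization identity holds over occupied bins", {
  gen <- generate_two_basin_ensemble(ensemble_spec(
    n_frames = 500, basin_occupancies = c(0.7, 0.3), seed = 8
  ))
  x <- rmsd_series(gen$ensemble, "chain A and name CA")
  y <- rg_series(gen$ensemble, "chain A and name CA")
  fel <- compute_fel(x, y, bins = c(15, 15))
  kbt <- fel$kB * fel$temperature_K
  p_max <- max(fel$counts) / sum(fel$counts)
  s <- sum(exp(-fel$delta_g[!is.na(fel$delta_g)] / kbt)) * p_max
  expect_equal(s, 1, tolerance = 1e-9)
})

test_that("the surface is invariant to frame order", {
  set.seed(44)
  x <- rnorm(300)
  y <- rnorm(300)
  perm <- sample(300)
  f1 <- compute_fel(x, y, bins = c(10, 10))
  f2 <- compute_fel(x[perm], y[perm],
    x_edges = f1$x_edges, y_edges = f1$y_edges
  )
  expect_equal(f1$counts, f2$counts)
  expect_equal(f1$delta_g, f2$delta_g)
})

# Independent exhaustive scan used as the minima oracle: candidate bins
# strictly below all occupied 8-neighbours.
exhaustive_minima <- function(dg) {
  out <- NULL
  for (i in seq_len(nrow(dg))) {
    for (j in seq_len(ncol(dg))) {
      if (is.na(dg[i, j])) next
      nb <- c()
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          ni <- i + di
          nj <- j + dj
          if (ni >= 1 && ni <= nrow(dg) && nj >= 1 && nj <= ncol(dg)) {
            nb <- c(nb, dg[ni, nj])
          }
        }
      }
      nb <- nb[!is.na(nb)]
      if (length(nb) == 0 || all(dg[i, j] < nb)) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  out
}

test_that("find_minima equals the exhaustive scan on random surfaces", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- c(rnorm(150, 0), rnorm(100, 3), rnorm(50, -2.5))
    y <- c(rnorm(150, 0), rnorm(100, -3), rnorm(50, 2.5))
    fel <- compute_fel(x, y, bins = c(9, 9))
    got <- find_minima(fel, min_separation_bins = 1)
    oracle <- exhaustive_minima(fel$delta_g)
    expect_equal(
      sort(paste(got$i, got$j)),
      sort(paste(oracle[, 1], oracle[, 2]))
    )
    # the global basin is the overall minimum
    expect_equal(got$delta_g[1], min(fel$delta_g, na.rm = TRUE))
    expect_equal(got$kind[1], "global")
  }
})

test_that("single-bin and convex surfaces give exactly one basin", {
  fel1 <- compute_fel(rep(1, 20), rep(1, 20),
    x_edges = c(0, 2), y_edges = c(0, 2)
  )
  b1 <- find_minima(fel1)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$kind, "global")

  # convex bowl: radially symmetric unimodal counts
  set.seed(10)
  x <- rnorm(4000)
  y <- rnorm(4000)
  fel2 <- compute_fel(x, y, bins = c(7, 7))
  b2 <- find_minima(fel2, min_separation_bins = 3)
  expect_equal(b2$kind[1], "global")
  expect_equal(b2$i[1], 4)
  expect_equal(b2$j[1], 4)
})

test_that("representative frames match brute force and tie rules", {
  gen <- generate_two_basin_ensemble(ensemble_spec(
    n_frames = 300, basin_occupancies = c(0.7, 0.3), seed = 12
  ))
  x <- rmsd_series(gen$ensemble, "chain A and name CA")
  y <- rg_series(gen$ensemble, "chain A and name CA")
  fel <- compute_fel(x, y, bins = c(12, 12))
  basins <- representative_frames(find_minima(fel, 3), fel)
  sx <- sd(fel$x_values)
  sy <- sd(fel$y_values)
  for (r in seq_len(min(2, nrow(basins)))) {
    mem <- basins$members[[r]]
    d2 <- ((fel$x_values[mem] - basins$x[r]) / sx)^2 +
      ((fel$y_values[mem] - basins$y[r]) / sy)^2
    expect_equal(basins$representative[r], mem[which.min(d2)])
    expect_true(basins$representative[r] %in% mem)
  }
  # one member -> that frame; equidistant ties -> lowest frame index
  fel_t <- compute_fel(c(1, 1, 1), c(1, 1, 3.5),
    x_edges = c(0, 2), y_edges = c(0, 2, 3, 4)
  )
  bt <- representative_frames(find_minima(fel_t, 1), fel_t)
  expect_equal(bt$representative, c(1L, 3L))
})

test_that("basin free-energy gaps recover planted occupancy ratios", {
  for (occ1 in c(0.6, 0.75, 0.9)) {
    gen <- generate_two_basin_ensemble(ensemble_spec(
      n_frames = 800, basin_occupancies = c(occ1, 1 - occ1), seed = 19
    ))
    x <- rmsd_series(gen$ensemble, "chain A and name CA")
    y <- rg_series(gen$ensemble, "chain A and name CA")
    fel <- compute_fel(x, y, bins = c(12, 12))
    basins <- find_minima(fel, 3)
    expected <- 0.0019872 * 300 * log(occ1 / (1 - occ1))
    # peak-bin estimate within a one-bin discretisation allowance
    expect_equal(basin_ddg(basins), expected, tolerance = 0.25)
    # occupancy-integrated estimate is exact up to stray frames
    expect_equal(basin_population_ddg(fel, basins), expected,
      tolerance = 0.02
    )
  }
})
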