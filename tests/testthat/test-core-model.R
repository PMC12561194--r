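# Ensemble model, PDB round trip, selections, geometric primitives.

test_that("multi-model PDB writing and reading round-trips coordinates", {
  set.seed(41)
  topo <- carbon_topology(10)
  coords <- lapply(1:3, function(i) matrix(round(rnorm(30), 3), ncol = 3))
  ens <- ensemble(topo, coords)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(ens, path)

  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "MODEL")), 3)

  back <- read_multimodel_pdb(path)
  expect_equal(n_frames(back), 3)
  expect_equal(n_atoms(back), 10)
  for (i in 1:3) {
    expect_equal(frame_coords(back, i), frame_coords(ens, i),
      tolerance = 1e-3
    )
  }
  # topology carried through
  expect_equal(back$topology$residue_name, topo$residue_name)
  expect_equal(back$topology$residue_number, topo$residue_number)
})

test_that("single coordinate set yields one frame; fixed-width format", {
  topo <- carbon_topology(1)
  ens <- ensemble(topo, list(matrix(c(1, 2, 3), ncol = 3)))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(ens, path)
  line <- grep("^ATOM", readLines(path), value = TRUE)[1]
  expect_equal(substr(line, 31, 54), "   1.000   2.000   3.000")
  back <- read_multimodel_pdb(path)
  expect_equal(n_frames(back), 1)
})

test_that("PDB I/O error contracts: range, model mismatch, bad fields", {
  topo <- carbon_topology(1)
  big <- ensemble(topo, list(matrix(c(10000.5, 0, 0), ncol = 3)))
  expect_error(
    write_multimodel_pdb(big, withr::local_tempfile(fileext = ".pdb")),
    "9999.999"
  )
  expect_error(ensemble(topo, list()), "non-empty")

  # hand-built file with inconsistent atom counts across models
  atom <- function(i, x) {
    sprintf(
      "ATOM  %5d  C%-2d LIG X   1    %8.3f%8.3f%8.3f  1.00  0.00",
      i, i, x, 0, 0
    )
  }
  bad <- c(
    "MODEL        1", atom(1, 1), atom(2, 2), "ENDMDL",
    "MODEL        2", atom(1, 1), "ENDMDL", "END"
  )
  p1 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, p1)
  expect_error(read_multimodel_pdb(p1), "model 2")

  garbled <- c("MODEL        1", atom(1, 1), "ENDMDL")
  substr(garbled[2], 33, 38) <- "x.oops"
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(garbled, p2)
  expect_error(read_multimodel_pdb(p2), "line 2")
})

test_that("selection mini-language resolves, unions and flags misses", {
  topo <- build_toy_system()$topology
  ne2 <- resolve_selection(topo, "resnum 16 and name NE2")
  expect_length(ne2$indices, 1)
  expect_equal(topo$atom_name[ne2$indices], "NE2")

  miss <- resolve_selection(topo, "resname XXX")
  expect_true(miss$empty)
  expect_length(miss$indices, 0)

  # union matches a brute-force filter, in ascending order
  un <- resolve_selection(topo, "resnum 61 or resnum 62")
  expect_equal(un$indices, which(topo$residue_number %in% c(61, 62)))
  un2 <- resolve_selection(topo, "resnum 3 or resnum 5")
  oracle <- sort(which(topo$residue_number %in% c(3, 5)))
  expect_equal(un2$indices, oracle)
  expect_false(is.unsorted(un2$indices, strictly = TRUE))

  # and binds tighter than or
  mix <- resolve_selection(topo, "resname TYL and name O8 or resnum 16")
  expect_equal(
    mix$indices,
    sort(union(
      which(topo$residue_name == "TYL" & topo$atom_name == "O8"),
      which(topo$residue_number == 16)
    ))
  )
  # multiple values after a key
  multi <- resolve_selection(topo, "name C2 C3")
  expect_equal(multi$indices, which(topo$atom_name %in% c("C2", "C3")))
})

test_that("selection parse errors report the offending position", {
  topo <- carbon_topology(3)
  expect_error(resolve_selection(topo, "bogus 5"), "position 1")
  expect_error(resolve_selection(topo, "resnum"), "at least one value")
  expect_error(resolve_selection(topo, "(resnum 1"), "parenthesis")
  expect_error(resolve_selection(topo, ""), "non-empty")
})

test_that("kabsch_rmsd: identity, rigid-motion invariance, symmetry", {
  set.seed(7)
  a <- matrix(rnorm(30), ncol = 3)
  expect_equal(as.numeric(kabsch_rmsd(a, a)), 0)

  # 37 degrees about z plus translation (5, -2, 1)
  b <- a %*% t(rotation_z(37 * pi / 180)) +
    matrix(rep(c(5, -2, 1), each = 10), ncol = 3)
  expect_lt(as.numeric(kabsch_rmsd(a, b)), 1e-6)

  # invariance under random proper rotations of either frame
  for (k in 1:5) {
    set.seed(100 + k)
    m <- matrix(rnorm(24), ncol = 3)
    r0 <- as.numeric(kabsch_rmsd(a[1:8, ], m))
    rot <- random_rotation()
    m2 <- m %*% t(rot) + matrix(rep(rnorm(3), each = 8), ncol = 3)
    expect_equal(as.numeric(kabsch_rmsd(a[1:8, ], m2)), r0,
      tolerance = 1e-6
    )
  }

  # symmetry
  set.seed(8)
  c2 <- matrix(rnorm(30), ncol = 3)
  expect_equal(
    as.numeric(kabsch_rmsd(a, c2)), as.numeric(kabsch_rmsd(c2, a)),
    tolerance = 1e-9
  )
})

test_that("kabsch_rmsd two-atom case matches a brute-force search", {
  ref <- rbind(c(0.5, 0, 0), c(-0.5, 0, 0))
  mob <- rbind(c(0, 1, 0), c(0, -1, 0))
  val <- kabsch_rmsd(ref, mob)
  expect_true(attr(val, "degenerate"))
  # brute force over in-plane rotation angles (the optimum is planar)
  grid <- seq(0, 2 * pi, length.out = 100000)
  best <- min(vapply(grid, function(th) {
    m <- mob %*% t(rotation_z(th))
    sqrt(mean(rowSums((m - ref)^2)))
  }, numeric(1)))
  expect_equal(as.numeric(val), best, tolerance = 1e-6)
  expect_equal(as.numeric(val), 0.5, tolerance = 1e-6)
})

test_that("kabsch_rmsd agrees with the bio3d fitted-RMSD oracle", {
  set.seed(99)
  for (k in 1:3) {
    a <- matrix(rnorm(45), ncol = 3)
    b <- a + matrix(rnorm(45, sd = 0.3), ncol = 3)
    mine <- as.numeric(kabsch_rmsd(a, b))
    oracle <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
    expect_lt(abs(mine - oracle), 5.1e-4) # bio3d rounds to 3 decimals
  }
})

test_that("radius_of_gyration analytic cases and invariances", {
  expect_equal(radius_of_gyration(matrix(c(3, 4, 5), ncol = 3)), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1)
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  expect_equal(radius_of_gyration(sq), sqrt(2))

  set.seed(12)
  m <- matrix(rnorm(30), ncol = 3)
  rg0 <- radius_of_gyration(m)
  moved <- m %*% t(random_rotation()) +
    matrix(rep(c(3, -1, 2), each = 10), ncol = 3)
  expect_equal(radius_of_gyration(moved), rg0, tolerance = 1e-9)

  # mass weighting shifts the centre of mass
  expect_error(radius_of_gyration(two, masses = c(1, -1)), "positive")
  expect_equal(radius_of_gyration(two, masses = c(3, 1)), sqrt(0.75))
})

test_that("equilibration_window finds plateaus and flags drift", {
  const <- equilibration_window(rep(2, 50), window = 5, tolerance = 1e-9)
  expect_equal(const$start, 1L)
  expect_true(const$equilibrated)

  step <- c(rep(10, 10), rep(1, 90))
  res <- equilibration_window(step, window = 10, tolerance = 0.01)
  expect_lte(res$start, 21L)
  expect_gte(res$start, 10L)
  expect_true(res$equilibrated)
  # direct evaluation of the rule at the returned index
  n <- length(step)
  means <- vapply(seq_len(n - 9), function(s) mean(step[s:(s + 9)]),
    numeric(1)
  )
  expect_true(all(abs(means[res$start:length(means)] -
    means[length(means)]) <= 0.01))
  if (res$start > 1) {
    expect_gt(abs(means[res$start - 1] - means[length(means)]), 0.01)
  }

  drift <- equilibration_window(seq(0, 1, length.out = 100),
    window = 10, tolerance = 1e-4
  )
  expect_false(drift$equilibrated)
  expect_true(is.na(drift$start))

  expect_error(equilibration_window(1:10, window = 1, tolerance = 1), "window")
  expect_error(equilibration_window(1:10, window = 8, tolerance = 1), "twice")
})
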