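# Reaction coordinates and two-dimensional free-energy landscapes.

#' Per-frame RMSD reaction coordinate
#'
#' Kabsch RMSD of every frame against a fixed reference frame, computed on
#' a selection (conventionally the C-alpha backbone).
#'
#' @param ens A [ensemble()].
#' @param selection Selection expression, `ps_selection` or indices.
#' @param reference Reference frame index (default 1) or an N x 3 matrix.
#' @return Tibble with columns `frame`, `value` (Angstrom); attribute
#'   `rc_name = "rmsd"`.
#' @export
rmsd_series <- function(ens, selection = NULL, reference = 1) {
  sel <- if (is.null(selection)) NULL else as_selection(selection, ens)
  if (!is.null(sel) && sel$empty) abort("Selection is empty.")
  ref <- if (is.matrix(reference)) reference else frame_coords(ens, reference)
  vals <- vapply(
    ens$coords,
    function(m) as.numeric(kabsch_rmsd(ref, m, selection = sel)),
    numeric(1)
  )
  out <- tibble(frame = seq_len(n_frames(ens)), value = vals)
  attr(out, "rc_name") <- "rmsd"
  out
}

#' Per-frame radius-of-gyration reaction coordinate
#'
#' @inheritParams rmsd_series
#' @param masses Optional per-atom masses over the selection.
#' @return Tibble with columns `frame`, `value` (Angstrom); attribute
#'   `rc_name = "rg"`.
#' @export
rg_series <- function(ens, selection = NULL, masses = NULL) {
  sel <- if (is.null(selection)) NULL else as_selection(selection, ens)
  if (!is.null(sel) && sel$empty) abort("Selection is empty.")
  vals <- vapply(
    ens$coords,
    function(m) radius_of_gyration(m, selection = sel, masses = masses),
    numeric(1)
  )
  out <- tibble(frame = seq_len(n_frames(ens)), value = vals)
  attr(out, "rc_name") <- "rg"
  out
}

#' Principal-component reaction coordinates
#'
#' Frames are superposed onto the ensemble-mean structure of the
#' selection before the coordinate covariance is diagonalised; the
#' series are the projections onto the top two eigenvectors. Sign
#' convention: the largest-magnitude loading of each component is made
#' positive, so projections are deterministic.
#'
#' @inheritParams rmsd_series
#' @return List with `scores` (tibble `frame`, `pc1`, `pc2`) and
#'   `explained_variance` (length-2 numeric, fractions of total).
#' @export
pca_coordinates <- function(ens, selection = NULL) {
  if (n_frames(ens) < 3) abort("PCA needs at least 3 frames.")
  sel <- if (is.null(selection)) NULL else as_selection(selection, ens)
  idx <- if (is.null(sel)) seq_len(n_atoms(ens)) else sel$indices
  if (length(idx) == 0) abort("Selection is empty.")
  # Superpose onto the mean structure (two rounds: mean of frames fitted
  # to frame 1, then refit to that mean).
  fitted <- lapply(ens$coords, function(m) {
    superpose_onto(m[idx, , drop = FALSE], ens$coords[[1]][idx, , drop = FALSE])
  })
  mean1 <- Reduce(`+`, fitted) / length(fitted)
  fitted <- lapply(fitted, function(m) superpose_onto(m, mean1))
  mat <- do.call(rbind, lapply(fitted, function(m) as.vector(t(m))))
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  expl <- if (sum(ev) > 0) ev[1:2] / sum(ev) else c(NA_real_, NA_real_)
  scores <- pc$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  list(
    scores = tibble(
      frame = seq_len(n_frames(ens)),
      pc1 = scores[, 1], pc2 = scores[, 2]
    ),
    explained_variance = setNames(expl, c("pc1", "pc2"))
  )
}

# Optimal superposition of `mobile` onto `ref` (both already subset);
# returns the transformed mobile coordinates.
superpose_onto <- function(mobile, ref) {
  ca <- colMeans(ref)
  cb <- colMeans(mobile)
  a <- sweep(ref, 2, ca)
  b <- sweep(mobile, 2, cb)
  h <- t(b) %*% a
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(b %*% t(rot), 2, ca, "+")
}

#' Build a two-dimensional free-energy surface
#'
#' Bins two reaction-coordinate series on a `Bx` x `By` histogram over
#' their observed ranges (last bin right-closed) and converts occupancy
#' to relative free energy, `dG_ij = -kB * T * ln(P_ij / P_max)`, zeroed
#' at the most populated bin. Empty bins are unreachable (`NA`), never
#' assigned a finite free energy.
#'
#' @param x,y Reaction-coordinate series: numeric vectors or the tibbles
#'   returned by [rmsd_series()] / [rg_series()].
#' @param bins Length-2 integer vector `(Bx, By)`, each >= 2.
#' @param temperature_K Temperature in Kelvin (default 300).
#' @param x_edges,y_edges Optional explicit bin edges overriding `bins`.
#' @return A `ps_fel` object: bin edges, `counts` and `delta_g` matrices
#'   (kcal/mol), per-frame bin assignment, `temperature_K`, `kB`.
#' @export
compute_fel <- function(x, y, bins = c(40, 40), temperature_K = 300,
                        x_edges = NULL, y_edges = NULL) {
  xv <- if (is.data.frame(x)) x$value else as.numeric(x)
  yv <- if (is.data.frame(y)) y$value else as.numeric(y)
  if (length(xv) != length(yv)) abort("`x` and `y` must have equal length.")
  if (!all(is.finite(xv)) || !all(is.finite(yv))) {
    abort("Reaction coordinates must be finite.")
  }
  if (is.null(x_edges)) {
    if (bins[1] < 2) abort("Need at least 2 bins per axis.")
    if (diff(range(xv)) == 0) {
      abort(paste0(
        "x axis has zero variance; supply explicit `x_edges` to bin a ",
        "degenerate coordinate."
      ))
    }
    x_edges <- seq(min(xv), max(xv), length.out = bins[1] + 1)
  }
  if (is.null(y_edges)) {
    if (bins[2] < 2) abort("Need at least 2 bins per axis.")
    if (diff(range(yv)) == 0) {
      abort(paste0(
        "y axis has zero variance; supply explicit `y_edges` to bin a ",
        "degenerate coordinate."
      ))
    }
    y_edges <- seq(min(yv), max(yv), length.out = bins[2] + 1)
  }
  bx <- length(x_edges) - 1
  by <- length(y_edges) - 1
  ix <- findInterval(xv, x_edges, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(yv, y_edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, nrow = bx, ncol = by)
  for (t in seq_along(ix)) {
    counts[ix[t], iy[t]] <- counts[ix[t], iy[t]] + 1L
  }
  p <- counts / sum(counts)
  pmax <- max(p)
  dg <- matrix(NA_real_, nrow = bx, ncol = by)
  occ <- counts > 0
  dg[occ] <- -KB_KCAL * temperature_K * log(p[occ] / pmax)
  structure(
    list(
      x_edges = x_edges, y_edges = y_edges, counts = counts, delta_g = dg,
      temperature_K = temperature_K, kB = KB_KCAL,
      frame_bin = tibble(frame = seq_along(ix), i = ix, j = iy),
      x_name = attr(x, "rc_name") %||% "x",
      y_name = attr(y, "rc_name") %||% "y",
      x_values = xv, y_values = yv
    ),
    class = "ps_fel"
  )
}

#' @export
print.ps_fel <- function(x, ...) {
  cat(
    "<ps_fel> ", nrow(x$counts), " x ", ncol(x$counts), " bins over (",
    x$x_name, ", ", x$y_name, "), ", sum(x$counts), " frames, T = ",
    x$temperature_K, " K\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a free-energy surface
#'
#' Long-format tibble of the surface: one row per bin with midpoints,
#' `count`, `delta_g` and an `unreachable` flag.
#'
#' @param x A `ps_fel` object.
#' @param ... Unused.
#' @method tidy ps_fel
#' @export
tidy.ps_fel <- function(x, ...) {
  xm <- (head(x$x_edges, -1) + tail(x$x_edges, -1)) / 2
  ym <- (head(x$y_edges, -1) + tail(x$y_edges, -1)) / 2
  counts <- x$counts
  dg <- x$delta_g
  grid <- tidyr::expand_grid(
    i = seq_along(xm), j = seq_along(ym)
  )
  dplyr::mutate(grid,
    x = xm[.data$i], y = ym[.data$j],
    count = counts[cbind(.data$i, .data$j)],
    delta_g = dg[cbind(.data$i, .data$j)],
    unreachable = .data$count == 0
  )
}

#' @rdname tidy.ps_fel
#' @method glance ps_fel
#' @export
glance.ps_fel <- function(x, ...) {
  tibble(
    n_frames = sum(x$counts),
    n_bins_x = nrow(x$counts), n_bins_y = ncol(x$counts),
    n_occupied = sum(x$counts > 0),
    max_delta_g = max(x$delta_g, na.rm = TRUE),
    temperature_K = x$temperature_K
  )
}

#' Locate free-energy basins
#'
#' An occupied bin is a candidate minimum if its free energy is strictly
#' below every occupied 8-neighbour (unreachable neighbours are ignored).
#' Candidates closer than `min_separation_bins` in Chebyshev distance are
#' merged keeping the lower free energy; ties break lexicographically by
#' bin index. The lowest basin is `"global"`, the rest `"local"`.
#'
#' @param fel A `ps_fel` from [compute_fel()].
#' @param min_separation_bins Minimum Chebyshev separation between
#'   reported basins (default 2).
#' @return Tibble of basins sorted by `delta_g`: `kind`, `i`, `j`,
#'   `delta_g`, `x`, `y`, `n_frames`, `members` (list column of frame
#'   indices falling in the basin bin).
#' @export
find_minima <- function(fel, min_separation_bins = 2) {
  if (!inherits(fel, "ps_fel")) abort("`fel` must be a ps_fel.")
  dg <- fel$delta_g
  bx <- nrow(dg)
  by <- ncol(dg)
  cand <- NULL
  for (i in seq_len(bx)) {
    for (j in seq_len(by)) {
      if (is.na(dg[i, j])) next
      is_min <- TRUE
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          ni <- i + di
          nj <- j + dj
          if (ni < 1 || ni > bx || nj < 1 || nj > by) next
          if (!is.na(dg[ni, nj]) && dg[ni, nj] <= dg[i, j]) is_min <- FALSE
        }
      }
      if (is_min) cand <- rbind(cand, c(i, j, dg[i, j]))
    }
  }
  if (is.null(cand)) {
    return(tibble(
      kind = character(), i = integer(), j = integer(),
      delta_g = numeric(), x = numeric(), y = numeric(),
      n_frames = integer(), members = list()
    ))
  }
  cand <- as.data.frame(cand)
  names(cand) <- c("i", "j", "delta_g")
  cand <- cand[order(cand$delta_g, cand$i, cand$j), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    ok <- TRUE
    for (s in which(keep)) {
      cheb <- max(
        abs(cand$i[r] - cand$i[s]),
        abs(cand$j[r] - cand$j[s])
      )
      if (cheb < min_separation_bins) ok <- FALSE
    }
    keep[r] <- ok
  }
  cand <- cand[keep, , drop = FALSE]
  xm <- (head(fel$x_edges, -1) + tail(fel$x_edges, -1)) / 2
  ym <- (head(fel$y_edges, -1) + tail(fel$y_edges, -1)) / 2
  members <- lapply(seq_len(nrow(cand)), function(r) {
    fb <- fel$frame_bin
    fb$frame[fb$i == cand$i[r] & fb$j == cand$j[r]]
  })
  tibble(
    kind = c("global", rep("local", nrow(cand) - 1)),
    i = as.integer(cand$i), j = as.integer(cand$j),
    delta_g = cand$delta_g,
    x = xm[cand$i], y = ym[cand$j],
    n_frames = vapply(members, length, integer(1)),
    members = members
  )
}

#' Representative frame of each basin
#'
#' Among a basin's member frames, picks the one closest (Euclidean, in
#' per-axis z-scored coordinates so Angstrom-scale RMSD and Rg weigh
#' equally) to the basin bin centre; ties go to the lowest frame index.
#'
#' @param basins Tibble from [find_minima()].
#' @param fel The `ps_fel` the basins came from.
#' @return `basins` with an added integer column `representative`.
#' @export
representative_frames <- function(basins, fel) {
  if (nrow(basins) == 0) {
    return(dplyr::mutate(basins, representative = integer(0)))
  }
  mx <- mean(fel$x_values)
  sx <- sd(fel$x_values)
  my <- mean(fel$y_values)
  sy <- sd(fel$y_values)
  if (sx == 0) sx <- 1
  if (sy == 0) sy <- 1
  rep_idx <- vapply(seq_len(nrow(basins)), function(r) {
    mem <- basins$members[[r]]
    if (length(mem) == 0) abort("Basin has no member frames.")
    dx <- (fel$x_values[mem] - basins$x[r]) / sx
    dy <- (fel$y_values[mem] - basins$y[r]) / sy
    d2 <- dx^2 + dy^2
    mem[which.min(d2)]  # which.min takes the first = lowest frame index
  }, numeric(1))
  dplyr::mutate(basins, representative = as.integer(rep_idx))
}

#' Free-energy difference between two basins
#'
#' Convenience wrapper returning `delta_g(b) - delta_g(a)` for two rows
#' of a [find_minima()] table, the quantity compared against
#' `kB * T * ln(p_a / p_b)` in occupancy-recovery checks.
#'
#' @param basins Tibble from [find_minima()].
#' @param a,b Row indices (default global vs first local).
#' @return Numeric, kcal/mol.
#' @export
basin_ddg <- function(basins, a = 1, b = 2) {
  if (nrow(basins) < max(a, b)) abort("Not enough basins.")
  basins$delta_g[b] - basins$delta_g[a]
}

#' Population-based free-energy difference between two basins
#'
#' Estimates the basin free-energy gap from integrated occupancies
#' rather than peak bin heights: counts are summed over the
#' `(2r+1) x (2r+1)` bin neighbourhood of each basin minimum and the gap
#' is `kB * T * ln(N_a / N_b)`. For well-separated basins whose spread
#' fits inside the neighbourhood this recovers the planted occupancy
#' ratio without single-bin discretisation noise.
#'
#' @param fel The `ps_fel` the basins came from.
#' @param basins Tibble from [find_minima()].
#' @param a,b Row indices (default global vs first local).
#' @param radius Neighbourhood radius in bins (default 1).
#' @return Numeric, kcal/mol: `G(b) - G(a)`.
#' @export
basin_population_ddg <- function(fel, basins, a = 1, b = 2, radius = 1) {
  if (nrow(basins) < max(a, b)) abort("Not enough basins.")
  pop <- function(r) {
    ii <- max(1, basins$i[r] - radius):min(nrow(fel$counts),
      basins$i[r] + radius
    )
    jj <- max(1, basins$j[r] - radius):min(ncol(fel$counts),
      basins$j[r] + radius
    )
    sum(fel$counts[ii, jj])
  }
  na <- pop(a)
  nb <- pop(b)
  if (na == 0 || nb == 0) abort("Empty basin neighbourhood.")
  fel$kB * fel$temperature_K * log(na / nb)
}

#' Export a free-energy surface as a TSV matrix
#'
#' Writes the `delta_g` matrix (rows = x bins) with `NA` for unreachable
#' bins.
#'
#' @param fel A `ps_fel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fel_tsv <- function(fel, path) {
  m <- fel$delta_g
  utils::write.table(
    m,
    file = path, sep = "\t", row.names = FALSE, col.names = FALSE,
    na = "NA"
  )
  invisible(path)
}
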