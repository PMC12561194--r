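#' Minimal RMSD after optimal rigid superposition (Kabsch)
#'
#' Computes the root-mean-square deviation between two frames after the
#' optimal proper rotation and translation of `mobile` onto `ref`,
#' restricted to `selection`. The rotation is obtained from the singular
#' value decomposition of the cross-covariance matrix with the usual
#' determinant-sign (reflection) correction, so only proper rotations are
#' used.
#'
#' @param ref,mobile N x 3 coordinate matrices sharing one topology, or
#'   frame indices are not accepted here — extract with [frame_coords()].
#' @param selection Optional `ps_selection` or integer atom indices; by
#'   default all atoms.
#' @param weights Optional per-atom weights (e.g. masses) over the
#'   selection; uniform by default.
#' @return The minimal RMSD in Angstrom (non-negative). If the selection
#'   has fewer than 3 atoms or degenerate (collinear) geometry the value
#'   is still defined; attribute `degenerate` is set to `TRUE`.
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' kabsch_rmsd(a, a)  # 0
#' @export
kabsch_rmsd <- function(ref, mobile, selection = NULL, weights = NULL) {
  if (!is.matrix(ref) || !is.matrix(mobile) ||
    ncol(ref) != 3 || ncol(mobile) != 3) {
    abort("`ref` and `mobile` must be N x 3 coordinate matrices.")
  }
  if (nrow(ref) != nrow(mobile)) {
    abort("`ref` and `mobile` must have the same number of atoms.")
  }
  idx <- if (is.null(selection)) {
    seq_len(nrow(ref))
  } else if (inherits(selection, "ps_selection")) {
    selection$indices
  } else {
    as.integer(selection)
  }
  if (length(idx) == 0) abort("Selection is empty.")
  a <- ref[idx, , drop = FALSE]
  b <- mobile[idx, , drop = FALSE]
  w <- if (is.null(weights)) rep(1, length(idx)) else as.numeric(weights)
  if (length(w) != length(idx) || any(w <= 0)) {
    abort("`weights` must be positive, one per selected atom.")
  }
  w <- w / sum(w)
  ca <- colSums(a * w)
  cb <- colSums(b * w)
  a <- sweep(a, 2, ca)
  b <- sweep(b, 2, cb)
  # Cross-covariance and SVD-based optimal proper rotation.
  h <- t(b * w) %*% a
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  s <- c(1, 1, d)
  rot <- sv$v %*% diag(s) %*% t(sv$u)
  br <- b %*% t(rot)
  val <- sqrt(sum(w * rowSums((br - a)^2)))
  degenerate <- length(idx) < 3 || sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)
  attr(val, "degenerate") <- degenerate
  val
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the selected atoms from
#' their centre of mass: `sqrt(sum(m_i * |r_i - r_com|^2) / sum(m_i))`.
#'
#' @param coords N x 3 coordinate matrix in Angstrom.
#' @param selection Optional selection (default: all atoms).
#' @param masses Optional per-atom masses over the selection; uniform by
#'   default. Must be positive.
#' @return Radius of gyration in Angstrom.
#' @examples
#' sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
#' radius_of_gyration(sq)  # sqrt(2)
#' @export
radius_of_gyration <- function(coords, selection = NULL, masses = NULL) {
  if (!is.matrix(coords) || ncol(coords) != 3) {
    abort("`coords` must be an N x 3 matrix.")
  }
  idx <- if (is.null(selection)) {
    seq_len(nrow(coords))
  } else if (inherits(selection, "ps_selection")) {
    selection$indices
  } else {
    as.integer(selection)
  }
  if (length(idx) == 0) abort("Selection is empty.")
  x <- coords[idx, , drop = FALSE]
  m <- if (is.null(masses)) rep(1, length(idx)) else as.numeric(masses)
  if (length(m) != length(idx)) abort("One mass per selected atom required.")
  if (any(m <= 0)) abort("Masses must be positive.")
  m <- m / sum(m)
  com <- colSums(x * m)
  sqrt(sum(m * rowSums(sweep(x, 2, com)^2)))
}

#' Detect the equilibrated portion of a scalar time series
#'
#' Finds the earliest window start such that every subsequent
#' sliding-window mean stays within `tolerance` of the final window's
#' mean. This is a plateau rule for deciding how much of a trajectory to
#' discard before analysis (e.g. an RMSD series that stabilises late in
#' the run).
#'
#' @param series Numeric vector (e.g. per-frame RMSD in Angstrom).
#' @param window Window width in frames (>= 2).
#' @param tolerance Allowed deviation of any window mean from the final
#'   window mean, same units as `series`.
#' @return One-row tibble: `start` (1-based index of the first
#'   equilibrated frame; `NA` if never equilibrated) and `equilibrated`.
#' @export
equilibration_window <- function(series, window, tolerance) {
  series <- as.numeric(series)
  if (window < 2) abort("`window` must be at least 2.")
  if (length(series) < 2 * window) {
    abort("`series` must be at least twice the window length.")
  }
  n <- length(series)
  k <- n - window + 1
  csum <- c(0, cumsum(series))
  means <- (csum[(window + 1):(n + 1)] - csum[1:k]) / window
  final <- means[k]
  ok <- abs(means - final) <= tolerance
  # smallest s such that ok[s:k] are all TRUE; the final window satisfies
  # the rule trivially, so a plateau must start at least one window
  # before it to count as equilibrated (otherwise a drifting series
  # would always "equilibrate" at its very end).
  bad <- which(!ok)
  if (length(bad) == 0) {
    return(tibble(start = 1L, equilibrated = TRUE))
  }
  s <- max(bad) + 1L
  if (s > k - 1L) {
    return(tibble(start = NA_integer_, equilibrated = FALSE))
  }
  tibble(start = as.integer(s), equilibrated = TRUE)
}

# Pairwise distance between two single atoms of a frame.
atom_distance <- function(coords, i, j) {
  sqrt(sum((coords[i, ] - coords[j, ])^2))
}

# Per-frame distances between two single-atom selections.
pair_distance_series <- function(ens, sel_a, sel_b) {
  sa <- as_selection(sel_a, ens)
  sb <- as_selection(sel_b, ens)
  if (length(sa$indices) != 1 || length(sb$indices) != 1) {
    abort("Distance series requires single-atom selections on both sides.")
  }
  vapply(
    ens$coords,
    function(m) atom_distance(m, sa$indices, sb$indices),
    numeric(1)
  )
}
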