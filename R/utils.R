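# Internal helpers shared across modules.

# Half-up decimal rounding. base::round() rounds half to even, which does
# not reproduce conventional table rounding (e.g. 0.735 -> 0.74).
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-12) / scale
}

# Euclidean norms of the rows of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m^2))

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards. Makes every generator a pure
# function of its spec.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a purpose-specific sub-seed from a master seed so independent
# random streams (basin labels, jitter, contact placement, ...) do not
# interact. Kept below 2^31 - 1.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647)
}

# Deterministic largest-remainder allocation of `n` items to probabilities
# `p` (sums to n exactly).
largest_remainder <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number."))
  }
  if (positive && x <= 0) {
    abort(paste0("`", name, "` must be positive."))
  }
  invisible(x)
}
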