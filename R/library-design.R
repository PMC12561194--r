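# Saturation-mutagenesis screening arithmetic and NNK coverage
# statistics.

# NNK degenerate codon: N = A/C/G/T, K = G/T -> 32 equiprobable codons.
# Amino-acid codon multiplicities under NNK: Leu/Arg/Ser have 3 codons
# each, Ala/Gly/Pro/Thr/Val have 2, the remaining twelve amino acids
# have 1, and 1 codon (TAG) is a stop.
NNK_CLASSES <- list(
  list(count = 3L, mult = 3L),   # L, R, S
  list(count = 5L, mult = 2L),   # A, G, P, T, V
  list(count = 12L, mult = 1L)   # the remaining twelve
)
NNK_CODONS <- 32L

#' Saturation-mutagenesis library totals
#'
#' Total clones for screening `n_sites` single-site libraries at
#' `clones_per_site` transformants each (e.g. 8 sites x 94 clones = 752
#' versus 23 x 94 = 2162 for a whole-pocket campaign).
#'
#' @param n_sites Number of mutagenised sites.
#' @param clones_per_site Transformants screened per site.
#' @param coverage_target Coverage probability the per-site count was
#'   designed for (stored for provenance; default 0.95).
#' @param codon_scheme Degenerate codon scheme label (default "NNK").
#' @return One-row tibble: `n_sites`, `clones_per_site`, `total_clones`,
#'   `coverage_target`, `codon_scheme`.
#' @examples
#' library_total(8, 94)   # 752
#' library_total(23, 94)  # 2162
#' @export
library_total <- function(n_sites, clones_per_site, coverage_target = 0.95,
                          codon_scheme = "NNK") {
  if (n_sites < 1 || clones_per_site < 1) {
    abort("`n_sites` and `clones_per_site` must be positive integers.")
  }
  tibble(
    n_sites = as.integer(n_sites),
    clones_per_site = as.integer(clones_per_site),
    total_clones = as.integer(n_sites) * as.integer(clones_per_site),
    coverage_target = coverage_target,
    codon_scheme = codon_scheme
  )
}

#' Probability that n clones cover all 20 amino acids
#'
#' Exact inclusion-exclusion over amino-acid subsets, grouped by NNK
#' multiplicity class for tractability: the probability that a missed
#' set with total codon weight `w` explains all draws is
#' `(1 - w/32)^n`, summed with alternating signs over the class-grouped
#' subsets. The `"equal20"` scheme replaces the NNK weights with 20
#' equiprobable outcomes (the idealised coupon-collector).
#'
#' @param n Number of clones drawn.
#' @param scheme `"NNK"` (default) or `"equal20"`.
#' @return Probability in `[0, 1]` that all 20 amino acids appear.
#' @export
coverage_probability <- function(n, scheme = c("NNK", "equal20")) {
  scheme <- match.arg(scheme)
  if (n < 20) {
    return(0)
  }
  if (scheme == "equal20") {
    k <- 0:20
    return(max(0, min(1, sum((-1)^k * choose(20, k) * (1 - k / 20)^n))))
  }
  total <- 0
  for (a in 0:NNK_CLASSES[[1]]$count) {
    for (b in 0:NNK_CLASSES[[2]]$count) {
      for (cc in 0:NNK_CLASSES[[3]]$count) {
        w <- 3 * a + 2 * b + cc
        term <- choose(NNK_CLASSES[[1]]$count, a) *
          choose(NNK_CLASSES[[2]]$count, b) *
          choose(NNK_CLASSES[[3]]$count, cc) *
          (-1)^(a + b + cc) * (1 - w / NNK_CODONS)^n
        total <- total + term
      }
    }
  }
  max(0, min(1, total))
}

#' Clones needed to cover all 20 amino acids at a site
#'
#' Smallest `n` such that the probability of observing every amino acid
#' among `n` NNK clones reaches `confidence` (exact unequal-probability
#' coupon-collector via [coverage_probability()]). Note this
#' all-amino-acid criterion demands substantially more clones than the
#' common `3 * V` oversampling rule for degenerate-codon coverage; see
#' [oversampling_clones()] for that convention.
#'
#' @param confidence Target coverage probability in (0, 1).
#' @param scheme `"NNK"` (default) or `"equal20"`.
#' @return Smallest integer `n` with coverage probability >= confidence.
#' @export
nnk_coverage_clones <- function(confidence = 0.95,
                                scheme = c("NNK", "equal20")) {
  scheme <- match.arg(scheme)
  if (confidence <= 0 || confidence >= 1) {
    abort("`confidence` must lie strictly between 0 and 1.")
  }
  lo <- 20L
  if (coverage_probability(lo, scheme) >= confidence) {
    return(lo)
  }
  hi <- 40L
  while (coverage_probability(hi, scheme) < confidence) {
    lo <- hi
    hi <- hi * 2L
    if (hi > 1e7) abort("Coverage search did not terminate.")
  }
  while (lo < hi - 1L) {
    mid <- (lo + hi) %/% 2L
    if (coverage_probability(mid, scheme) >= confidence) hi <- mid else lo <- mid
  }
  hi
}

#' Transformants per site by the codon-oversampling rule
#'
#' The widely used screening-effort convention for degenerate codon
#' libraries: `n = -V * ln(1 - F)` transformants give probability `F`
#' that any particular codon variant among `V` equiprobable codons has
#' been sampled (equivalently, expected coverage F of the codon space).
#' For NNK (`V = 32`) at `F = 0.95` this gives 95.9, conventionally
#' quoted as approximately 94-96 transformants per site.
#'
#' @param confidence Target coverage fraction F in (0, 1).
#' @param n_codons Number of equiprobable codon variants (default 32).
#' @return One-row tibble: `raw` (`-V ln(1-F)`) and `clones` (rounded
#'   up).
#' @export
oversampling_clones <- function(confidence = 0.95, n_codons = 32) {
  if (confidence <= 0 || confidence >= 1) {
    abort("`confidence` must lie strictly between 0 and 1.")
  }
  raw <- -n_codons * log(1 - confidence)
  tibble(raw = raw, clones = ceiling(raw))
}

#' Monte-Carlo estimate of NNK amino-acid coverage
#'
#' Seeded simulation oracle for [coverage_probability()]: draws `n`
#' codons per trial from the NNK weights and reports the fraction of
#' trials in which all 20 amino acids appeared.
#'
#' @param n Clones per trial.
#' @param trials Number of trials.
#' @param seed Seed.
#' @param scheme `"NNK"` or `"equal20"`.
#' @return Estimated coverage probability.
#' @export
coverage_probability_mc <- function(n, trials = 1e5, seed = 1,
                                    scheme = c("NNK", "equal20")) {
  scheme <- match.arg(scheme)
  probs <- if (scheme == "NNK") {
    c(rep(3, 3), rep(2, 5), rep(1, 12), 1) / 32  # 20 aa + stop
  } else {
    rep(1 / 20, 20)
  }
  n_aa <- 20L
  with_seed(seed, {
    hits <- 0L
    chunk <- max(1L, min(trials, floor(2e6 / n)))
    left <- trials
    while (left > 0) {
      m <- min(chunk, left)
      draws <- sample.int(length(probs), m * n, replace = TRUE, prob = probs)
      trial_id <- rep(seq_len(m), times = n)
      is_aa <- draws <= n_aa
      key <- (trial_id[is_aa] - 1) * n_aa + draws[is_aa]
      first <- !duplicated(key)
      n_distinct_aa <- tabulate(trial_id[is_aa][first], nbins = m)
      hits <- hits + sum(n_distinct_aa == n_aa)
      left <- left - m
    }
    hits / trials
  })
}
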