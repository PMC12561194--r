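# Michaelis-Menten fitting and catalytic-efficiency reporting.

#' Fit Michaelis-Menten kinetics
#'
#' Nonlinear least squares on `v = Vmax * S / (Km + S)` (Levenberg-
#' Marquardt via minpack.lm), initialised from the Hanes-Woolf direct
#' linear estimate (`S/v` regressed on `S`). `kcat = Vmax / [E]`;
#' standard errors come from the local curvature of the fit. Unweighted
#' least squares by default; `relative_weights = TRUE` weights residuals
#' by `1/v`.
#'
#' @param data Data frame with columns `S_mM` (substrate, mM) and `rate`
#'   (same units as `Vmax`), >= 4 distinct substrate levels.
#' @param enzyme_conc Enzyme concentration; sets the `kcat` scale
#'   (`kcat` comes out in `rate`-units per enzyme-unit; with rates in
#'   per-second-equivalents and `enzyme_conc = 1` it is per second).
#' @param relative_weights Weight residuals by `1/rate` (default FALSE).
#' @return A `ps_mm_fit`: list with `km_mM`, `vmax`, `kcat_per_s`,
#'   `efficiency` (kcat/Km), standard errors, `n_points`, the data and
#'   the underlying `nls` object. A warning is attached when
#'   `max(S) < 2 * Km` (poorly constrained Vmax).
#' @examples
#' d <- generate_rate_data(rate_data_spec(km_mM = 2, kcat_per_s = 1))
#' fit_michaelis_menten(d, enzyme_conc = 1)
#' @export
fit_michaelis_menten <- function(data, enzyme_conc = 1,
                                 relative_weights = FALSE) {
  df <- as.data.frame(data)
  if (!all(c("S_mM", "rate") %in% names(df))) {
    abort("`data` needs columns S_mM and rate.")
  }
  df <- df[is.finite(df$S_mM) & is.finite(df$rate), , drop = FALSE]
  if (length(unique(df$S_mM)) < 4) {
    abort("Need at least 4 distinct substrate concentrations.")
  }
  if (any(df$rate < 0)) abort("Rates must be non-negative.")
  stopifnot_scalar_number(enzyme_conc, "enzyme_conc", positive = TRUE)
  # Hanes-Woolf: S/v = S/Vmax + Km/Vmax.
  pos <- df$S_mM > 0 & df$rate > 0
  init <- if (sum(pos) >= 2) {
    hw <- stats::lm(I(S_mM / rate) ~ S_mM, data = df[pos, ])
    vmax0 <- 1 / coef(hw)[2]
    km0 <- coef(hw)[1] * vmax0
    if (!is.finite(vmax0) || vmax0 <= 0 || !is.finite(km0) || km0 <= 0) {
      c(vmax = max(df$rate) * 1.2, km = median(df$S_mM))
    } else {
      c(vmax = unname(vmax0), km = unname(km0))
    }
  } else {
    c(vmax = max(df$rate) * 1.2, km = median(df$S_mM))
  }
  w <- if (relative_weights) 1 / pmax(df$rate, 1e-12)^2 else rep(1, nrow(df))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rate ~ vmax * S_mM / (km + S_mM),
      data = df,
      start = list(vmax = init[["vmax"]], km = init[["km"]]),
      weights = w,
      lower = c(1e-12, 1e-12),
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-15, ptol = 1e-15
      )
    ),
    error = function(e) {
      abort(paste0(
        "Michaelis-Menten fit did not converge: ", conditionMessage(e),
        " (last initialisation: Vmax = ", signif(init[["vmax"]], 6),
        ", Km = ", signif(init[["km"]], 6), ")."
      ))
    }
  )
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) {
    c(vmax = NA_real_, km = NA_real_)
  })
  km <- unname(est[["km"]])
  vmax <- unname(est[["vmax"]])
  kcat <- vmax / enzyme_conc
  out <- structure(
    list(
      km_mM = km, vmax = vmax, kcat_per_s = kcat,
      efficiency = kcat / km,
      se_km = unname(se[["km"]]),
      se_vmax = unname(se[["vmax"]]),
      se_kcat = unname(se[["vmax"]]) / enzyme_conc,
      n_points = nrow(df), enzyme_conc = enzyme_conc,
      data = as_tibble(df), fit = fit,
      s_max_warning = max(df$S_mM) < 2 * km
    ),
    class = "ps_mm_fit"
  )
  if (out$s_max_warning) {
    warn(paste0(
      "max(S) = ", max(df$S_mM), " mM is below 2 * Km = ",
      signif(2 * km, 4), " mM; Vmax is poorly constrained."
    ))
  }
  out
}

#' @export
print.ps_mm_fit <- function(x, ...) {
  cat(
    "<ps_mm_fit> n = ", x$n_points,
    "\n  Km   = ", signif(x$km_mM, 6), " mM (se ", signif(x$se_km, 3), ")",
    "\n  kcat = ", signif(x$kcat_per_s, 6), " s^-1 (se ",
    signif(x$se_kcat, 3), ")",
    "\n  kcat/Km = ", signif(x$efficiency, 6), " s^-1 mM^-1\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy / glance methods for Michaelis-Menten fits
#'
#' `tidy()` returns one row per parameter with estimate and standard
#' error; `glance()` returns the one-row fit summary including the
#' derived catalytic efficiency.
#'
#' @param x A `ps_mm_fit`.
#' @param ... Unused.
#' @method tidy ps_mm_fit
#' @export
tidy.ps_mm_fit <- function(x, ...) {
  tibble(
    term = c("km_mM", "vmax", "kcat_per_s"),
    estimate = c(x$km_mM, x$vmax, x$kcat_per_s),
    std.error = c(x$se_km, x$se_vmax, x$se_kcat)
  )
}

#' @rdname tidy.ps_mm_fit
#' @method glance ps_mm_fit
#' @export
glance.ps_mm_fit <- function(x, ...) {
  tibble(
    km_mM = x$km_mM, kcat_per_s = x$kcat_per_s,
    efficiency = x$efficiency,
    efficiency_rounded = round_half_up(x$efficiency, 2),
    n_points = x$n_points,
    s_max_warning = x$s_max_warning
  )
}

#' Catalytic efficiency with reporting convention
#'
#' `kcat / Km`, reported both raw and rounded half-up to two decimals --
#' the convention used in kinetics tables (efficiencies like 0.05 or
#' 0.74 in s^-1 mM^-1).
#'
#' @param kcat Turnover number (s^-1).
#' @param km Michaelis constant (mM).
#' @return One-row tibble: `raw`, `rounded_2dp`.
#' @examples
#' catalytic_efficiency(1.45, 1.96)  # raw 0.7398, rounded 0.74
#' @export
catalytic_efficiency <- function(kcat, km) {
  stopifnot_scalar_number(kcat, "kcat", positive = TRUE)
  stopifnot_scalar_number(km, "km", positive = TRUE)
  raw <- kcat / km
  tibble(raw = raw, rounded_2dp = round_half_up(raw, 2))
}

#' Fold change with half-up rounding
#'
#' `numerator / denominator`, rounded half-up to the requested decimals
#' (default 1, the convention for quoting improvement factors such as
#' "14.8-fold"). The unrounded ratio is returned alongside.
#'
#' @param numerator,denominator Positive numbers.
#' @param decimals Decimals for the rounded value (default 1).
#' @return One-row tibble: `raw`, `rounded`.
#' @examples
#' fold_change(0.74, 0.05)  # 14.8
#' @export
fold_change <- function(numerator, denominator, decimals = 1) {
  stopifnot_scalar_number(numerator, "numerator")
  if (!is.numeric(denominator) || denominator <= 0) {
    abort("`denominator` must be positive.")
  }
  raw <- numerator / denominator
  tibble(raw = raw, rounded = round_half_up(raw, decimals))
}

#' Total turnover number
#'
#' `TTN = [product formed] / [enzyme]`, both in the same molar unit
#' family. If unit tags are supplied they must match.
#'
#' @param product Product concentration formed over the full reaction
#'   course.
#' @param enzyme Enzyme concentration (> 0).
#' @param product_unit,enzyme_unit Optional unit tags; a mismatch is an
#'   error (convert before calling).
#' @return One-row tibble: `product`, `enzyme`, `ttn`.
#' @examples
#' total_turnover(2000, 10)  # e.g. 2 mM product over 10 uM enzyme = 200
#' @export
total_turnover <- function(product, enzyme, product_unit = NULL,
                           enzyme_unit = NULL) {
  stopifnot_scalar_number(product, "product")
  stopifnot_scalar_number(enzyme, "enzyme", positive = TRUE)
  if (product < 0) abort("`product` must be non-negative.")
  if (!is.null(product_unit) || !is.null(enzyme_unit)) {
    if (is.null(product_unit) || is.null(enzyme_unit) ||
      product_unit != enzyme_unit) {
      abort(paste0(
        "Unit mismatch: product in '", product_unit %||% "?",
        "', enzyme in '", enzyme_unit %||% "?",
        "'; convert to a common molar unit first."
      ))
    }
  }
  tibble(product = product, enzyme = enzyme, ttn = product / enzyme)
}
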