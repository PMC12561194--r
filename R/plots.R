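# ggplot2 visualisations for the main result types.

#' Plot a free-energy landscape
#'
#' Heatmap of the relative free energy over the two reaction
#' coordinates; unreachable bins are left blank.
#'
#' @param object A `ps_fel`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ps_fel <- function(object, ...) {
  df <- tidy(object)
  df <- df[!df$unreachable, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$delta_g)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(
      name = expression(Delta * G ~ "(kcal/mol)"),
      direction = -1
    ) +
    ggplot2::labs(
      x = object$x_name, y = object$y_name,
      title = "Free-energy landscape"
    ) +
    ggplot2::theme_minimal()
}

#' Radar-style plot of an interaction fingerprint
#'
#' Residue-by-residue contact frequencies on a polar axis, one line per
#' interaction type -- the layout used to compare wild-type and mutant
#' binding-pocket engagement.
#'
#' @param object A `ps_ifp` from [fingerprint()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ps_ifp <- function(object, ...) {
  df <- as_tibble(object)
  df$residue <- paste0(df$residue_name, df$residue_number)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$residue, y = .data$frequency,
    group = .data$interaction_type, colour = .data$interaction_type
  )) +
    ggplot2::geom_polygon(fill = NA) +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      y = "contact frequency", x = NULL,
      colour = "interaction",
      title = paste0(
        "Interaction fingerprint (",
        attr(object, "scope") %||% "ensemble", ")"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a tunnel radius profile
#'
#' Local free radius against distance along the centerline, with the
#' bottleneck marked.
#'
#' @param object A `ps_tunnel`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ps_tunnel <- function(object, ...) {
  p <- as.data.frame(object)
  centres <- as.matrix(p[, c("x", "y", "z")])
  s <- c(0, cumsum(sqrt(rowSums(diff(centres)^2))))
  df <- tibble(arc_length = s, radius = p$radius)
  ggplot2::ggplot(df, ggplot2::aes(.data$arc_length, .data$radius)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(
      yintercept = min(p$radius), linetype = "dashed", colour = "red"
    ) +
    ggplot2::labs(
      x = "distance along tunnel (Å)", y = "radius (Å)",
      title = paste0("Tunnel profile (", attr(object, "label") %||%
        "tunnel", ")")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Michaelis-Menten fit
#'
#' Observed initial rates with the fitted saturation curve.
#'
#' @param object A `ps_mm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ps_mm_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(S_mM = seq(0, max(d$S_mM), length.out = 200))
  grid$rate <- object$vmax * grid$S_mM / (object$km_mM + grid$S_mM)
  ggplot2::ggplot(d, ggplot2::aes(.data$S_mM, .data$rate)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "[S] (mM)", y = "initial rate",
      title = sprintf(
        "Michaelis-Menten fit: Km = %.3g mM, kcat = %.3g s^-1",
        object$km_mM, object$kcat_per_s
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot an atom-pair distance histogram
#'
#' @param hist Tibble from [distance_histogram()].
#' @return A ggplot.
#' @export
plot_distance_histogram <- function(hist) {
  df <- as_tibble(hist)
  df$mid <- (df$bin_lo + df$bin_hi) / 2
  ggplot2::ggplot(df, ggplot2::aes(.data$mid, .data$count)) +
    ggplot2::geom_col(
      width = df$bin_hi - df$bin_lo, fill = "grey60", colour = "grey30"
    ) +
    ggplot2::labs(
      x = "distance (Å)", y = "frames",
      title = attr(hist, "pair_label") %||% "distance distribution"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
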