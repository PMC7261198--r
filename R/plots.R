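#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a helical-wheel projection
#'
#' Residues on the unit circle at their wheel angles, coloured by charge
#' class, with the detected basic face shaded.
#'
#' @param object A `wheel_projection` from [helical_wheel()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wheel_projection <- function(object, ...) {
  fs <- attr(object, "face_start_deg")
  fw <- attr(object, "face_width_deg")
  df <- dplyr::mutate(tibble::as_tibble(object),
    x = cos(.data$angle_deg * pi / 180),
    y = sin(.data$angle_deg * pi / 180),
    label = paste0(.data$aa, .data$residue)
  )
  arc <- tibble::tibble(
    a = seq(fs, fs + fw, length.out = 100) * pi / 180
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(
      data = dplyr::mutate(arc, x = 1.25 * cos(.data$a), y = 1.25 * sin(.data$a)),
      colour = "darkgreen", linewidth = 1.5
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$charge_class), size = 4) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
      nudge_y = 0.12, size = 3
    ) +
    ggplot2::scale_colour_manual(
      values = c(basic = "darkgreen", acidic = "red3", neutral = "grey40")
    ) +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void() +
    ggplot2::labs(
      colour = NULL,
      title = paste0("Helical wheel: ", attr(object, "label"))
    )
}

#' Plot a free-energy surface
#'
#' One-dimensional surfaces are drawn as a line with minima marked;
#' two-dimensional surfaces as a filled raster (masked bins blank).
#'
#' @param object An `fes` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fes <- function(object, ...) {
  cvs <- attr(object, "cvs")
  if (length(cvs) == 1) {
    ggplot2::ggplot(object, ggplot2::aes(.data[[cvs]], .data$f)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(
        data = attr(object, "minima"), colour = "red3", size = 2
      ) +
      ggplot2::labs(y = "free energy (kJ/mol)") +
      ggplot2::theme_classic()
  } else {
    ggplot2::ggplot(
      object,
      ggplot2::aes(.data[[cvs[1]]], .data[[cvs[2]]], fill = .data$f)
    ) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(na.value = "white") +
      ggplot2::labs(fill = "F (kJ/mol)") +
      ggplot2::theme_classic()
  }
}

#' Plot a PMF profile with bootstrap uncertainty
#'
#' @param object A `pmf_profile` (optionally with an `sd` column).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmf_profile <- function(object, ...) {
  g <- ggplot2::ggplot(object, ggplot2::aes(.data$center, .data$f))
  if ("sd" %in% names(object)) {
    g <- g + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$f - .data$sd, ymax = .data$f + .data$sd),
      fill = "grey80"
    )
  }
  g + ggplot2::geom_line() +
    ggplot2::labs(
      x = "radial distance (nm)", y = "PMF (kJ/mol)"
    ) +
    ggplot2::theme_classic()
}

#' Plot trajectory collective-variable traces
#'
#' @param object A `cg_trajectory`.
#' @param cvs Which columns to draw (default helicity, compaction, energy).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cg_trajectory <- function(object,
                                   cvs = c("s_alpha", "s_rg", "e_total"),
                                   ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "sweep", dplyr::all_of(cvs)),
    -"sweep",
    names_to = "cv", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$sweep, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~cv, scales = "free_y", ncol = 1) +
    ggplot2::theme_classic()
}

#' Plot a radius-of-gyration distribution with baselines
#'
#' @param object An `rg_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rg_distribution <- function(object, ...) {
  bl <- attr(object, "baselines")
  ggplot2::ggplot(object, ggplot2::aes(.data$rg, .data$density)) +
    ggplot2::geom_col(width = diff(object$rg[1:2]), fill = "grey70") +
    ggplot2::geom_vline(
      xintercept = bl$rg_glob[1], colour = "red3", linetype = 2
    ) +
    ggplot2::geom_vline(
      xintercept = bl$rg_coil[1], colour = "blue3", linetype = 2
    ) +
    ggplot2::labs(x = "Rg (Angstrom)", y = "density") +
    ggplot2::theme_classic()
}

#' Plot reweighted per-residue helicity
#'
#' @param helicity Tibble from [reweighted_per_residue_helicity()], or a
#'   named list of such tibbles (one per condition).
#' @return A ggplot object.
#' @export
plot_helicity_profile <- function(helicity) {
  if (is.data.frame(helicity)) helicity <- list(profile = helicity)
  df <- dplyr::bind_rows(helicity, .id = "condition")
  ggplot2::ggplot(
    df, ggplot2::aes(.data$residue, .data$helicity, colour = .data$condition)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(y = "helical fraction") +
    ggplot2::theme_classic()
}
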