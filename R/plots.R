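#' @method autoplot dimer_fit
#' @export
autoplot.dimer_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    total_density = exp(seq(log(min(d$total_density)),
                            log(max(d$total_density)), length.out = 200))
  )
  grid$fitted <- dimeric_fraction(grid$total_density, object$k_diss) *
    object$e_tilde
  ggplot2::ggplot(d, ggplot2::aes(x = .data$total_density,
                                  y = .data$fret / .data$acceptor_fraction)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$fitted), colour = "firebrick",
                       linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "total surface density [T]",
                  y = "FRET / acceptor fraction",
                  title = sprintf("k_diss = %.3g, intrinsic FRET = %.3g",
                                  object$k_diss, object$e_tilde)) +
    ggplot2::theme_minimal()
}

#' @method autoplot brightness_distribution
#' @export
autoplot.brightness_distribution <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$mid,
                                                  y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$se, 0),
                                      ymax = .data$mean + .data$se),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "molecular brightness (photons/molecule/exposure)",
                  y = "normalized counts",
                  title = sprintf("%d cells", object$n_cells)) +
    ggplot2::theme_minimal()
  if (object$scale == "log") p <- p + ggplot2::scale_x_log10()
  p
}

#' @method autoplot pair_distribution
#' @export
autoplot.pair_distribution <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(r = object$r, p = object$p),
                  ggplot2::aes(x = .data$r, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (Å)", y = "P(r)",
                  title = sprintf("D_max = %.1f Å, Rg = %.2f Å",
                                  object$d_max, object$rg)) +
    ggplot2::theme_minimal()
}

#' @method autoplot guinier_fit
#' @export
autoplot.guinier_fit <- function(object, ...) {
  ggplot2::ggplot(object$window, ggplot2::aes(x = .data$q^2,
                                              y = log(.data$intensity))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = log(.data$fitted)),
                       colour = "firebrick") +
    ggplot2::labs(x = expression(q^2), y = "ln I(q)",
                  title = sprintf("Guinier: Rg = %.2f Å, qmax*Rg = %.2f",
                                  object$rg, object$qmax_rg)) +
    ggplot2::theme_minimal()
}

#' Butterfly-style plot of uptake differences along the sequence
#'
#' @param diffs Output of [uptake_difference()].
#' @return A ggplot object: per-peptide RFU difference against peptide
#'   midpoint, one panel per time point, significant peptides highlighted.
#' @export
plot_uptake_difference <- function(diffs) {
  check_columns(diffs, c("start", "end", "time", "delta_rfu", "significant"),
                "diffs")
  diffs$mid <- (diffs$start + diffs$end) / 2
  ggplot2::ggplot(diffs, ggplot2::aes(x = .data$mid, y = .data$delta_rfu,
                                      colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       yend = .data$delta_rfu)) +
    ggplot2::facet_wrap(~time, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "residue", y = expression(Delta * "RFU")) +
    ggplot2::theme_minimal()
}

#' Ranked kinase-signal curve with cumulative share
#'
#' @param ranked Output of [rank_kinases()].
#' @param cutoff Optional signal cutoff drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_kinase_ranking <- function(ranked, cutoff = NULL) {
  check_columns(ranked, c("rank", "signal", "cumulative_fraction"), "ranked")
  p <- ggplot2::ggplot(ranked, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$signal), width = 1,
                      fill = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_fraction *
                                      max(.data$signal)),
                       colour = "firebrick") +
    ggplot2::labs(x = "kinase rank", y = "signal",
                  title = "ranked kinase signals (red: cumulative share)") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = 2)
  }
  p
}
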