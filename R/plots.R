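#' Plot a reactor trajectory
#'
#' Time-series panels of a simulated run: `"concentrations"` shows biomasses
#' and the metabolite pool (g/L), `"fractions"` the per-species biomass
#' fractions, `"enzymes"` the relative key-enzyme levels per pathway and
#' `"growth"` the realised specific growth rates with the dilution rate
#' overlaid (the washout line: a species declines whenever its curve is
#' below `D`).
#'
#' @param object A `reactor_trajectory`.
#' @param what Panel to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reactor_trajectory <- function(object,
                                        what = c("concentrations",
                                                 "fractions", "enzymes",
                                                 "growth"), ...) {
  what <- match.arg(what)
  sp <- traj_attr(object, "species")
  met <- traj_attr(object, "metabolites")
  if (what == "concentrations") {
    cols <- c(paste0("X_", sp), met)
    long <- tidyr::pivot_longer(object[c("t", cols)], cols = -"t",
                                names_to = "series", values_to = "value")
    long$series <- factor(long$series, levels = cols)
    ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value,
                                       colour = .data$series)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (h)", y = "concentration (g/L)",
                    colour = NULL) +
      ggplot2::theme_minimal()
  } else if (what == "fractions") {
    fr <- biomass_fractions(object)
    ggplot2::ggplot(fr, ggplot2::aes(.data$t, .data$fraction,
                                     colour = .data$species)) +
      ggplot2::geom_line() +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(x = "time (h)", y = "biomass fraction", colour = NULL) +
      ggplot2::theme_minimal()
  } else if (what == "enzymes") {
    cols <- grep("^psi_rel_", names(object), value = TRUE)
    long <- tidyr::pivot_longer(object[c("t", cols)], cols = -"t",
                                names_to = "series", values_to = "value")
    long$species <- sub("^psi_rel_([^_]+)_.*$", "\\1", long$series)
    long$pathway <- sub("^psi_rel_[^_]+_", "", long$series)
    ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value,
                                       colour = .data$pathway)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~species) +
      ggplot2::labs(x = "time (h)", y = expression(Psi["rel"]),
                    colour = "pathway") +
      ggplot2::theme_minimal()
  } else {
    cols <- paste0("mu_", sp)
    long <- tidyr::pivot_longer(object[c("t", "D", cols)],
                                cols = dplyr::all_of(cols),
                                names_to = "species", values_to = "mu")
    long$species <- sub("^mu_", "", long$species)
    ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$mu,
                                       colour = .data$species)) +
      ggplot2::geom_line() +
      ggplot2::geom_step(ggplot2::aes(y = .data$D), colour = "grey40",
                         linetype = "dashed") +
      ggplot2::labs(x = "time (h)", y = "specific growth rate (1/h)",
                    colour = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Plot a coexistence scan
#'
#' Heat map of a species' averaged final biomass fraction over the pulse
#' frequency / duty-cycle plane, one facet per dilution rate. Points where
#' both species persist are outlined.
#'
#' @param object A `coexistence_scan`.
#' @param species Which species' fraction to fill by (default the last one,
#'   conventionally the slow grower of interest).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coexistence_scan <- function(object, species = NULL, ...) {
  all_sp <- attr(object, "comonod_species")
  species <- species %||% all_sp[length(all_sp)]
  fill_col <- paste0("frac_", species)
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$w), factor(.data$s))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data[[fill_col]])) +
    ggplot2::geom_point(data = df[df$coexistence %in% TRUE, ],
                        shape = 1, size = 2) +
    ggplot2::facet_wrap(~D, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(x = "pulse frequency w (1/h)", y = "duty cycle s",
                  fill = paste0(species, "\nfraction")) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic batch dataset
#'
#' Observed channels against time, one facet per initial-glucose condition.
#'
#' @param object A `batch_dataset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.batch_dataset <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value,
                                   colour = .data$channel)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~condition, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (h)", y = "concentration (g/L)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a kinetics fit
#'
#' Observations overlaid with the fitted model's trajectories, per condition
#' and channel.
#'
#' @param object A `kinetics_fit`.
#' @param data The `batch_dataset` that was fitted (defaults to refitting
#'   conditions from the stored design is not possible, so pass the data).
#' @param ... Passed to [run_batch()].
#' @return A ggplot object.
#' @export
autoplot.kinetics_fit <- function(object, data, ...) {
  stopifnot(inherits(data, "batch_dataset"))
  times <- attr(data, "comonod_times")
  X0 <- attr(data, "comonod_X0") %||% 0.05
  sp <- object$species
  pred <- purrr::map_dfr(sort(unique(data$condition)), function(S0) {
    traj <- run_batch(sp, S0 = S0, X0 = X0, t_end = max(times), ...)
    tibble::tibble(condition = S0, t = traj$t,
                   X = traj[[paste0("X_", sp$name)]],
                   GLU = traj$GLU, ACE = traj$ACE, ETH = traj$ETH) |>
      tidyr::pivot_longer(cols = c("X", "GLU", "ACE", "ETH"),
                          names_to = "channel", values_to = "value")
  })
  ggplot2::ggplot(tibble::as_tibble(data),
                  ggplot2::aes(.data$t, .data$value,
                               colour = .data$channel)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = pred) +
    ggplot2::facet_wrap(~condition, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (h)", y = "concentration (g/L)", colour = NULL) +
    ggplot2::theme_minimal()
}
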