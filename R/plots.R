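#' Plot a fitted dark-adaptation curve
#'
#' Fitted biphasic curve (with the cone--rod break marked) over the cyan
#' threshold points used for fitting, optionally with red points overlaid.
#'
#' @param object A `da_fit` object.
#' @param points Optional tibble of threshold points (`t_min`,
#'   `threshold_log`, optionally `color`).
#' @param t_max Right edge of the time axis, minutes.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot da_fit
#' @export
autoplot.da_fit <- function(object, points = NULL, t_max = 60, ...) {
  tt <- seq(0, t_max, by = 0.1)
  curve_df <- tibble::tibble(t_min = tt,
                             threshold_log = da_threshold(object$params, tt))
  p <- ggplot2::ggplot(curve_df,
                       ggplot2::aes(x = .data$t_min,
                                    y = .data$threshold_log)) +
    ggplot2::geom_line(color = "skyblue3", linewidth = 0.9) +
    ggplot2::geom_vline(xintercept = object$params$CRB, linetype = "dashed",
                        color = "grey40") +
    ggplot2::labs(x = "Time after bleach offset (min)",
                  y = "Threshold (logUnits)")
  if (!is.null(points)) {
    pts <- tibble::as_tibble(points)
    if ("color" %in% names(pts)) {
      p <- p + ggplot2::geom_point(
        data = pts,
        ggplot2::aes(color = .data$color), size = 1.4) +
        ggplot2::scale_color_manual(
          values = c(cyan505 = "dodgerblue3", red627 = "firebrick"),
          name = "stimulus")
    } else {
      p <- p + ggplot2::geom_point(data = pts, color = "dodgerblue3",
                                   size = 1.4)
    }
  }
  p
}

#' Plot an outcome against age with normative prediction bands
#'
#' Scatter of an outcome versus age by group, faceted by eccentricity, with
#' the normative fixed-effect line and 95% prediction band overlaid.
#'
#' @param outcomes Locus-outcome tibble (needs `age`, `group`,
#'   `eccentricity_deg` and the outcome column).
#' @param model The matching `da_normative` model.
#' @param outcome Outcome column name (default: the model's).
#' @param level Band coverage.
#' @return A ggplot object.
#' @export
plot_outcome_age <- function(outcomes, model, outcome = model$outcome_name,
                             level = 0.95) {
  d <- tibble::as_tibble(outcomes)
  ages <- seq(min(d$age), max(d$age), length.out = 50)
  band <- tidyr::expand_grid(age = ages,
                             eccentricity_deg = model$ecc_levels) |>
    (\(g) dplyr::bind_cols(
      g["eccentricity_deg"],
      predict_interval(model, g$age, g$eccentricity_deg,
                       level = level)[c("age", "pi_low", "predicted_median",
                                        "pi_high")]))()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data[[outcome]])) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$age, ymin = .data$pi_low,
                                      ymax = .data$pi_high),
                         inherit.aes = FALSE, alpha = 0.15) +
    ggplot2::geom_line(data = band,
                       ggplot2::aes(x = .data$age,
                                    y = .data$predicted_median),
                       inherit.aes = FALSE, color = "grey30") +
    ggplot2::geom_point(ggplot2::aes(color = .data$group,
                                     shape = .data$group), size = 1.6) +
    ggplot2::scale_color_manual(values = c(healthy = "grey55",
                                           AMD = "darkorange2")) +
    ggplot2::scale_shape_manual(values = c(healthy = 16, AMD = 17)) +
    ggplot2::facet_wrap(~eccentricity_deg,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Age (years)", y = outcome)
}

#' Plot a covariate-adjusted ROC curve
#'
#' @param object A `da_aroc` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot da_aroc
#' @export
autoplot.da_aroc <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$fpf, y = .data$tpf)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         color = "grey60") +
    ggplot2::geom_step(color = "steelblue4", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive fraction",
                  y = "True positive fraction",
                  title = paste0(object$marker_name, ", AAUC = ",
                                 signif(object$aauc, 3)))
}

#' Pairwise deviation scatter
#'
#' Scatter of one outcome's deviation against another's (e.g. RIT delay vs
#' FT deviation), by group, with the healthy upper quantile marked.
#'
#' @param deviations Long deviation tibble from [compute_deviations()].
#' @param x,y Outcome names for the axes.
#' @param quantile_line Healthy-cohort quantile to mark (default 0.975).
#' @return A ggplot object.
#' @export
plot_deviation_pair <- function(deviations, x = "RIT", y = "FT",
                                quantile_line = 0.975) {
  d <- deviations |>
    dplyr::filter(.data$outcome_name %in% c(x, y)) |>
    dplyr::select(dplyr::any_of(c("subject_id", "group",
                                  "eccentricity_deg")),
                  "outcome_name", "deviation") |>
    tidyr::pivot_wider(names_from = "outcome_name",
                       values_from = "deviation")
  qx <- if ("group" %in% names(d)) {
    quantile(d[[x]][d$group == "healthy"], quantile_line, na.rm = TRUE)
  } else NA_real_
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[x]], y = .data[[y]]))
  if ("group" %in% names(d)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$group,
                                              shape = .data$group),
                                 size = 1.6) +
      ggplot2::scale_color_manual(values = c(healthy = "grey55",
                                             AMD = "darkorange2")) +
      ggplot2::scale_shape_manual(values = c(healthy = 16, AMD = 17))
  } else {
    p <- p + ggplot2::geom_point(size = 1.6)
  }
  if (is.finite(qx)) {
    p <- p + ggplot2::geom_vline(xintercept = qx, linetype = "dashed",
                                 color = "grey40")
  }
  p + ggplot2::labs(x = paste(x, "deviation"), y = paste(y, "deviation"))
}
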