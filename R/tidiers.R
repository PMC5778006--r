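#' Tidy a flow state
#'
#' @param x A `flow_state`.
#' @param net Optional `vasc_network` whose class/subtype columns are joined
#'   in.
#' @param ... Unused.
#' @return A tibble, one row per segment.
#' @method tidy flow_state
#' @export
tidy.flow_state <- function(x, net = NULL, ...) {
  out <- x$segments
  if (!is.null(net)) {
    keep <- intersect(c("segment_id", "diameter_um", "length_um", "class",
                        "subtype", "cap_order"), names(net$segments))
    out <- dplyr::left_join(net$segments[, keep], out, by = "segment_id")
  }
  out
}

#' One-row summary of a flow state
#'
#' @param x A `flow_state`.
#' @param ... Unused.
#' @return A tibble with mean absolute flow and velocity, pressure range,
#'   total boundary inflow, and the iteration count when available.
#' @method glance flow_state
#' @export
glance.flow_state <- function(x, ...) {
  q0 <- x$nodes$boundary_inflow_nlmin
  tibble::tibble(
    n_segments = nrow(x$segments),
    mean_abs_flow_nlmin = mean(abs(x$segments$flow_nlmin)),
    mean_abs_velocity_mm_s = mean(abs(x$segments$velocity_mm_s)),
    pressure_min_mmHg = min(x$nodes$pressure_mmHg),
    pressure_max_mmHg = max(x$nodes$pressure_mmHg),
    total_inflow_nlmin = sum(q0[q0 > 0]),
    mean_hd = mean(x$segments$hd),
    iterations = if (!is.null(attr(x, "iterations")))
      nrow(attr(x, "iterations")) else NA_integer_
  )
}

#' Tidy an oxygen solution
#'
#' @param x An `oxygen_solution`.
#' @param what `"segments"` (per-segment blood PO2/SO2), `"tissue"` (grid
#'   PO2) or `"sources"` (per-element strengths).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy oxygen_solution
#' @export
tidy.oxygen_solution <- function(x, what = c("segments", "tissue", "sources"),
                                 ...) {
  what <- match.arg(what)
  x[[what]]
}

#' One-row summary of an oxygen solution
#'
#' @param x An `oxygen_solution`.
#' @param ... Unused.
#' @return A tibble: mean/min tissue PO2, mean SO2, extraction fraction,
#'   O2 balance and iteration count.
#' @method glance oxygen_solution
#' @export
glance.oxygen_solution <- function(x, ...) {
  tibble::tibble(
    mean_tissue_po2_mmHg = mean(x$tissue$po2_mmHg),
    min_tissue_po2_mmHg = min(x$tissue$po2_mmHg),
    mean_so2 = mean(x$segments$so2),
    extraction_fraction = x$extraction_fraction,
    o2_influx_umol_min = x$balance$o2_influx_umol_min,
    consumption_umol_min = x$balance$consumption_umol_min,
    iterations = x$iterations
  )
}

#' Tidy a perturbation result
#'
#' @param x A `perturbation_result`.
#' @param ... Unused.
#' @return The per-segment percentage-change tibble.
#' @method tidy perturbation_result
#' @export
tidy.perturbation_result <- function(x, ...) x$segments

#' One-row summary of a perturbation result
#'
#' @param x A `perturbation_result`.
#' @param ... Unused.
#' @return A tibble with the spec fields and mean changes in the constricted
#'   set.
#' @method glance perturbation_result
#' @export
glance.perturbation_result <- function(x, ...) {
  thr <- x$throat
  tibble::tibble(
    kind = x$spec$kind,
    extent = x$spec$extent,
    diameter_change = x$spec$diameter_change,
    n_modified = length(x$constricted),
    throat_velocity_pct = if (!is.null(thr) && nrow(thr))
      mean(thr$velocity_pct, na.rm = TRUE) else NA_real_,
    throat_flow_pct = if (!is.null(thr) && nrow(thr))
      mean(thr$flow_pct, na.rm = TRUE) else NA_real_,
    excluded_zero_flow = x$excluded_zero_flow
  )
}

#' Plot a flow state
#'
#' Scatter of |flow| (log scale) against vessel diameter, coloured by vessel
#' class when a network is supplied.
#'
#' @param object A `flow_state`.
#' @param net Optional `vasc_network` providing diameters and classes.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flow_state
#' @export
autoplot.flow_state <- function(object, net = NULL, ...) {
  if (is.null(net)) stop("autoplot.flow_state needs the network (net =)")
  df <- tidy(object, net = net)
  df$abs_flow <- pmax(abs(df$flow_nlmin), 1e-6)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diameter_um, y = .data$abs_flow,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "diameter (µm)", y = "|flow| (nl/min)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an oxygen solution
#'
#' Mid-depth slice of the tissue PO2 field.
#'
#' @param object An `oxygen_solution`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot oxygen_solution
#' @export
autoplot.oxygen_solution <- function(object, ...) {
  tz <- object$tissue
  mid <- tz$z_um[which.min(abs(tz$z_um - stats::median(tz$z_um)))]
  sl <- tz[tz$z_um == mid, ]
  ggplot2::ggplot(sl, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                   fill = .data$po2_mmHg)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "PO2 (mmHg)") +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("tissue PO2, z = %.0f µm", mid)) +
    ggplot2::theme_minimal()
}

#' Plot a perturbation result
#'
#' Box plots of the chosen percentage change by vessel class, with the
#' extreme-outlier rule of [box_stats()] marked as points.
#'
#' @param object A `perturbation_result`.
#' @param metric Column of the per-segment table to plot
#'   (default `"velocity_pct"`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot perturbation_result
#' @export
autoplot.perturbation_result <- function(object, metric = "velocity_pct", ...) {
  df <- object$segments[!is.na(object$segments[[metric]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data[[metric]])) +
    ggplot2::geom_boxplot(coef = 3, outlier.colour = "red",
                          outlier.shape = 4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = NULL, y = paste(metric, "(%)")) +
    ggplot2::theme_minimal()
}
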