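# ggplot2 displays for the main result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col labs
#'   facet_wrap theme_minimal scale_color_viridis_c coord_equal
NULL

#' Plot a flow waveform
#'
#' @param object A [flow_waveform()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flow_waveform
#' @export
autoplot.flow_waveform <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$t_s, y = .data$q_mL_s)) +
    geom_line(color = "#b2182b") +
    labs(x = "time (s)", y = "flow (mL/s)", title = "Inlet flow waveform") +
    theme_minimal()
}

#' Plot a pressure trace
#'
#' @param object A `pressure_trace` from [solve_rcr()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pressure_trace
#' @export
autoplot.pressure_trace <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$t_s, y = Pa_to_mmHg(.data$p_Pa))) +
    geom_line(color = "#2166ac") +
    labs(x = "time (s)", y = "pressure (mmHg)",
         title = "Windkessel outlet pressure (last cycle)") +
    theme_minimal()
}

#' Plot cross-section profiles along a branch
#'
#' Area and maximum diameter versus station, the per-branch analogue of a
#' lumen profile plot.
#'
#' @param object A `cross_sections` tibble from [extract_sections()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cross_sections
#' @export
autoplot.cross_sections <- function(object, ...) {
  d <- tibble(station_mm = rep(object$station_mm, 2),
              value = c(object$area_cm2, object$dmax_cm),
              measure = rep(c("area (cm²)", "Dmax (cm)"),
                            each = nrow(object)))
  ggplot(d, aes(x = .data$station_mm, y = .data$value)) +
    geom_line() + geom_point(size = 0.8) +
    facet_wrap(~measure, scales = "free_y") +
    labs(x = "station along branch (mm)", y = NULL,
         title = "Branch cross-section profile") +
    theme_minimal()
}

#' Plot outlet flow waveforms of a network solution
#'
#' @param object A `network_solution`.
#' @param outlets Outlet labels to show (default all terminals).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot network_solution
#' @export
autoplot.network_solution <- function(object, outlets = NULL, ...) {
  d <- object$flows |>
    filter(grepl("^t_", .data$to)) |>
    mutate(outlet = sub("^t_", "", .data$to))
  if (!is.null(outlets)) d <- filter(d, .data$outlet %in% outlets)
  ggplot(d, aes(x = .data$t_s, y = m3_s_to_mL_s(.data$q_m3_s),
                color = .data$outlet)) +
    geom_line() +
    labs(x = "time (s)", y = "flow (mL/s)", color = "outlet",
         title = "Outlet flow (last cycle)") +
    theme_minimal()
}

#' Plot an indicator map as a projected point cloud
#'
#' Surface vertices projected on the x-z plane, coloured by the chosen
#' indicator.
#'
#' @param object An [indicator_maps()] tibble.
#' @param indicator One of `"tawss"`, `"osi"`, `"ecap"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot indicator_maps
#' @export
autoplot.indicator_maps <- function(object, indicator = c("tawss", "osi", "ecap"), ...) {
  indicator <- match.arg(indicator)
  surface <- attr(object, "surface")
  d <- tidy(surface) |> left_join(as_tibble(object), by = "vertex")
  ggplot(d, aes(x = .data$x, y = .data$z, color = .data[[indicator]])) +
    geom_point(size = 0.3) +
    scale_color_viridis_c() +
    coord_equal() +
    labs(x = "x (mm)", y = "z (mm)", color = toupper(indicator),
         title = sprintf("%s map (x-z projection)", toupper(indicator))) +
    theme_minimal()
}

#' Plot a configuration comparison
#'
#' LSA flow share and arch-to-LSA systolic pressure drop per configuration.
#'
#' @param object A `config_comparison` from [compare_configurations()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot config_comparison
#' @export
autoplot.config_comparison <- function(object, ...) {
  d <- tibble(configuration = rep(object$configuration, 2),
              value = c(object$lsa_share_pct, object$dp_arch_lsa_mmHg),
              measure = rep(c("LSA share (%)", "ΔP arch→LSA (mmHg)"),
                            each = nrow(object)))
  d$configuration <- factor(d$configuration, levels = c("PRE", "SBSG", "HYBRID"))
  ggplot(d, aes(x = .data$configuration, y = .data$value)) +
    geom_col(fill = "#4393c3") +
    facet_wrap(~measure, scales = "free_y") +
    labs(x = NULL, y = NULL, title = "Treatment-configuration comparison") +
    theme_minimal()
}
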