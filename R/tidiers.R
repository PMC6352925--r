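#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a suspension simulation into long format
#'
#' @param x a `suspension_sim`.
#' @param variables columns to keep (default: all state and flux
#'   columns).
#' @param ... unused.
#' @return Tibble with `time`, `variable`, `value`.
#' @export
tidy.suspension_sim <- function(x, variables = NULL, ...) {
  keep <- variables %||% setdiff(names(x), "time")
  tidyr::pivot_longer(x[, c("time", keep)], -"time",
                      names_to = "variable", values_to = "value")
}

#' One-row summary of a suspension simulation
#'
#' @param x a `suspension_sim`.
#' @param ... unused.
#' @return One-row tibble: scenario name, duration, peak FBP (µM), ATP
#'   change at the end relative to t = 0, cumulative glucose uptake and
#'   lactate production (µmol/l cell water), time-averaged lactate
#'   production and O2 consumption rates (µM/s).
#' @export
glance.suspension_sim <- function(x, ...) {
  scn <- attr(x, "scenario")
  dur <- max(x$time)
  tibble::tibble(
    scenario = scn$name,
    duration = dur,
    peak_fbp = max(x$fbp),
    atp_change = x$atp[nrow(x)] / x$atp[1] - 1,
    cum_glc = max(x$cum_glc),
    cum_lac = max(x$cum_lac),
    mean_lac_rate = max(x$cum_lac) / dur,
    mean_o2_rate = max(x$cum_o2) / dur,
    f_active_end = x$f_active[nrow(x)])
}

#' Tidy a fitted parameter set
#'
#' @param x a `glycodyn_fit`.
#' @param ... unused.
#' @return Tibble with `term`, `estimate` (one row per free parameter)
#'   and `identifiable` (FALSE for flat directions).
#' @export
tidy.glycodyn_fit <- function(x, ...) {
  if (!length(x$free)) return(tibble::tibble(term = character(0),
                                             estimate = numeric(0),
                                             identifiable = logical(0)))
  tibble::tibble(term = x$free,
                 estimate = unlist(x$params[x$free]),
                 identifiable = !(x$free %in% x$flat))
}

#' One-row summary of a fit
#'
#' @param x a `glycodyn_fit`.
#' @param ... unused.
#' @export
glance.glycodyn_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective,
                 n_obs = nrow(x$data),
                 n_free = length(x$free),
                 n_flat = length(x$flat),
                 n_starts = nrow(x$starts))
}

default_panel_vars <- c("glc", "fbp", "atp", "nadh", "lac", "f_active",
                        "j_head", "j_tail", "j_o2")

#' Plot a suspension simulation
#'
#' Faceted time courses of the main state variables and fluxes.
#'
#' @param object a `suspension_sim`.
#' @param variables columns to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.suspension_sim <- function(object,
                                    variables = default_panel_vars,
                                    ...) {
  long <- tidy.suspension_sim(object, variables = variables)
  long$variable <- factor(long$variable, levels = variables)
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = attr(object, "scenario")$name) +
    ggplot2::theme_minimal()
}

#' Plot the ATP-synthesis channels of a tissue simulation
#'
#' Oxidative, throughput-glycolytic and store-derived glycolytic ATP
#' synthesis over time for one layer and cell type, the classic view of
#' FBP-store buffering during cycling blood flow.
#'
#' @param object a `tissue_sim`.
#' @param layer,cell_type selection (defaults: config `report_layer`,
#'   type 1).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tissue_sim <- function(object, layer = NULL, cell_type = 1,
                                ...) {
  cfg <- attr(object, "config")
  layer <- layer %||% cfg$report_layer
  d <- dplyr::filter(object, .data$layer == !!layer,
                     .data$cell_type == !!cell_type)
  long <- tidyr::pivot_longer(
    d[, c("time", "atp_syn_ox", "atp_syn_glyc_throughput",
          "atp_syn_glyc_store")],
    -"time", names_to = "channel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     color = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(
      values = c(atp_syn_ox = "#2166ac",
                 atp_syn_glyc_throughput = "grey30",
                 atp_syn_glyc_store = "#b2182b")) +
    ggplot2::labs(x = "time (s)", y = "ATP synthesis (uM/s)",
                  title = sprintf("layer %d, cell type %d", layer,
                                  cell_type)) +
    ggplot2::theme_minimal()
}

#' Plot concentration profiles of an ascites simulation
#'
#' Solute concentration versus distance from the boundary at selected
#' times.
#'
#' @param object an `ascites_sim`.
#' @param solute column to plot (default glucose).
#' @param times time points (default: 4 evenly spread samples).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ascites_sim <- function(object, solute = "glc", times = NULL,
                                 ...) {
  tt <- unique(object$time)
  times <- times %||% tt[unique(pmax(1, round(seq(1, length(tt),
                                                  length.out = 4))))]
  d <- dplyr::filter(object, .data$time %in% times)
  ggplot2::ggplot(d, ggplot2::aes(.data$distance, .data[[solute]],
                                  color = factor(.data$time))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (um)", y = paste0(solute, " (uM)"),
                  color = "time (s)") +
    ggplot2::theme_minimal()
}
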