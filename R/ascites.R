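#' Ascites-fluid diffusion configuration
#'
#' Describes glucose/O2 diffusion from the peritoneal boundary into
#' ascites fluid, optionally containing suspended tumor cells: a stack
#' of fluid layers (planar geometry) or concentric shells around a
#' vessel (radial geometry).
#'
#' @param n_layers number of fluid layers (63 in the packaged
#'   scenarios).
#' @param layer_width layer width, µm (10 µm packaged; maximal diffusion
#'   distance = `n_layers * layer_width`).
#' @param geometry `"planar"` (stacked layers) or `"radial"`.
#' @param vessel_radius inner radius for radial geometry, µm.
#' @param boundary_glc,boundary_o2,boundary_lac,boundary_pyr fixed
#'   concentrations at the peritoneal/vessel boundary, µM.
#' @param init_glc,init_o2,init_lac,init_pyr initial fluid
#'   concentrations, µM (e.g. 167 µM glucose in the cell-free transient
#'   scenario).
#' @param cell_volume_fraction tumor cell volume fraction in the fluid
#'   (0 = cell-free, 0.25 in the packaged steady-state scenario).
#' @param d_glc,d_o2,d_lac,d_pyr diffusion coefficients in ascites
#'   fluid, µm^2/s.
#' @param duration simulated time, s (transient mode).
#' @param steady_state iterate to the steady state instead of a fixed
#'   duration.
#' @param dt_out output interval, s.
#' @return An `ascites_config` object.
#' @export
ascites_config <- function(n_layers = 63, layer_width = 10,
                           geometry = c("planar", "radial"),
                           vessel_radius = 10,
                           boundary_glc = 5500, boundary_o2 = 60,
                           boundary_lac = 2000, boundary_pyr = 60,
                           init_glc = 167, init_o2 = 60,
                           init_lac = 2000, init_pyr = 60,
                           cell_volume_fraction = 0,
                           d_glc = 600, d_o2 = 2500, d_lac = 650,
                           d_pyr = 650,
                           duration = 180, steady_state = FALSE,
                           dt_out = 5) {
  geometry <- match.arg(geometry)
  stopifnot(n_layers >= 1, layer_width > 0, duration > 0,
            cell_volume_fraction >= 0, cell_volume_fraction < 1)
  structure(list(n_layers = n_layers, layer_width = layer_width,
                 geometry = geometry, vessel_radius = vessel_radius,
                 boundary_glc = boundary_glc, boundary_o2 = boundary_o2,
                 boundary_lac = boundary_lac,
                 boundary_pyr = boundary_pyr,
                 init_glc = init_glc, init_o2 = init_o2,
                 init_lac = init_lac, init_pyr = init_pyr,
                 cell_volume_fraction = cell_volume_fraction,
                 d_glc = d_glc, d_o2 = d_o2, d_lac = d_lac,
                 d_pyr = d_pyr, duration = duration,
                 steady_state = steady_state, dt_out = dt_out),
            class = "ascites_config")
}

ascites_context <- function(cfg, p) {
  n <- cfg$n_layers
  w <- cfg$layer_width
  if (cfg$geometry == "radial") {
    r <- cfg$vessel_radius + w * (0:n)
    vol <- pi * diff(r^2)
    area <- 2 * pi * r
  } else {
    vol <- rep(w, n)
    area <- rep(1, n + 1)
  }
  has_cells <- cfg$cell_volume_fraction > 0
  icw <- cfg$cell_volume_fraction * p$water_frac
  fluid <- 1 - cfg$cell_volume_fraction
  theta <- c(glc = fluid, o2 = fluid + icw, lac = fluid + icw,
             pyr = fluid + icw)
  # layer-major ordering (species within layer, layers consecutive)
  # keeps the Jacobian banded: only same-species diffusion couples
  # adjacent layers, at a fixed index offset of nspec
  nspec <- if (has_cells) 12L else 4L
  i_sol <- function(s) seq.int(s, by = nspec, length.out = n)
  i_cell <- function(block) seq.int(4L + block, by = nspec,
                                    length.out = n)
  ds <- c(glc = cfg$d_glc, o2 = cfg$d_o2, lac = cfg$d_lac,
          pyr = cfg$d_pyr)
  list(n = n, w = w, vol = vol, area = area, icw = icw, theta = theta,
       has_cells = has_cells, nspec = nspec, i_sol = i_sol,
       i_cell = i_cell, ds = ds, nstate = nspec * n)
}

ascites_deriv <- function(t, y, ctx, cfg, p) {
  n <- ctx$n
  dy <- numeric(length(y))
  sol <- list(glc = y[ctx$i_sol(1)], o2 = y[ctx$i_sol(2)],
              lac = y[ctx$i_sol(3)], pyr = y[ctx$i_sol(4)])
  src <- list(glc = 0, o2 = 0, lac = 0, pyr = 0)
  if (ctx$has_cells) {
    fbp <- y[ctx$i_cell(1)]; atp <- y[ctx$i_cell(2)]
    apool <- y[ctx$i_cell(3)]; pi_ <- y[ctx$i_cell(4)]
    nadh <- y[ctx$i_cell(5)]; f_act <- y[ctx$i_cell(6)]
    fl <- cell_fluxes_raw(sol$glc, sol$o2, fbp, atp, apool - atp, pi_,
                          nadh, sol$pyr, sol$lac, f_act, apool, p)
    dy[ctx$i_cell(1)] <- (fl$j_head - fl$j_tail / 2 - fl$j_sink) /
      p$r_pgi
    dy[ctx$i_cell(2)] <- -2 * fl$j_head + 2 * fl$j_tail +
      fl$j_oxphos_atp - fl$j_hyd
    dy[ctx$i_cell(3)] <- -fl$j_pool_loss + fl$j_pool_resyn
    dy[ctx$i_cell(4)] <- fl$j_hyd + 2 * fl$j_head - 2 * fl$j_tail -
      fl$j_oxphos_atp + fl$j_pool_loss - fl$j_pool_resyn
    dy[ctx$i_cell(5)] <- fl$j_tail - fl$j_ldh - fl$j_mito
    f_c <- pmin(pmax(f_act, 0), 1)
    dy[ctx$i_cell(6)] <- -p$k_inact * p$r_pgi * pmax(fbp, 0) * f_c +
      p$k_react * (1 - f_c)
    dy[ctx$i_cell(7)] <- fl$j_head
    dy[ctx$i_cell(8)] <- fl$j_ldh
    src$glc <- -fl$j_head * ctx$icw
    src$o2 <- -fl$j_o2 * ctx$icw
    src$lac <- fl$j_ldh * ctx$icw
    src$pyr <- (fl$j_tail - fl$j_ldh - fl$j_mito) * ctx$icw
  }
  bnd <- c(cfg$boundary_glc, cfg$boundary_o2, cfg$boundary_lac,
           cfg$boundary_pyr)
  snames <- c("glc", "o2", "lac", "pyr")
  for (s in 1:4) {
    nm <- snames[s]
    dy[ctx$i_sol(s)] <- diffuse_layers(sol[[nm]], bnd[s],
                                       ctx$ds[[nm]], ctx,
                                       ctx$theta[[nm]]) +
      src[[nm]] / ctx$theta[[nm]]
  }
  list(dy)
}

#' Run an ascites-fluid diffusion scenario
#'
#' Integrates diffusion from a fixed-concentration boundary into layered
#' ascites fluid, with the full dynamic cell model running in every
#' layer when cells are present. In steady-state mode the integration
#' continues until the maximum relative rate of change of the solute
#' profiles falls below `ss_tol` (non-convergence is reported with the
#' residual).
#'
#' @param cfg an [ascites_config()].
#' @param p a [cell_parameters()] set.
#' @param ss_tol steady-state criterion, 1/s.
#' @param max_time cap on integration time in steady-state mode, s.
#' @param rtol,atol solver tolerances.
#' @return Tibble of class `ascites_sim`: per (time, layer) the solute
#'   concentrations (+ cell states when present), layer mid-point
#'   `distance` (µm) and the volume weight of each layer. Attribute
#'   `volume_weighted_mean`: tibble of the volume-weighted mean solute
#'   concentrations per time (what a sampled-fluid measurement would
#'   see).
#' @export
run_ascites <- function(cfg, p = cell_parameters(), ss_tol = 1e-6,
                        max_time = 20000, rtol = 1e-6, atol = 1e-6) {
  stopifnot(inherits(cfg, "ascites_config"))
  ctx <- ascites_context(cfg, p)
  n <- ctx$n
  y <- numeric(ctx$nstate)
  y[ctx$i_sol(1)] <- cfg$init_glc
  y[ctx$i_sol(2)] <- cfg$init_o2
  y[ctx$i_sol(3)] <- cfg$init_lac
  y[ctx$i_sol(4)] <- cfg$init_pyr
  if (ctx$has_cells) {
    y[ctx$i_cell(1)] <- 100
    y[ctx$i_cell(2)] <- p$atp_init
    y[ctx$i_cell(3)] <- p$a_pool_init
    y[ctx$i_cell(4)] <- p$pi_init
    y[ctx$i_cell(5)] <- 30
    y[ctx$i_cell(6)] <- 1
  }
  func <- function(t, y, parms) ascites_deriv(t, y, ctx, cfg, p)
  if (cfg$steady_state) {
    t_now <- 0
    chunk <- 500
    res <- NULL
    repeat {
      out <- deSolve::lsoda(y, c(t_now, t_now + chunk), func,
                            parms = NULL, rtol = rtol, atol = atol,
                            jactype = "bandint", bandup = ctx$nspec,
                            banddown = ctx$nspec, maxsteps = 100000)
      y <- out[nrow(out), -1]
      t_now <- t_now + chunk
      d <- unlist(func(t_now, y, NULL))
      isol <- c(ctx$i_sol(1), ctx$i_sol(2), ctx$i_sol(3), ctx$i_sol(4))
      resid <- max(abs(d[isol]) / pmax(abs(y[isol]), 1))
      if (resid < ss_tol) break
      if (t_now >= max_time) {
        stop("ascites steady state did not converge: residual ",
             format(resid), " 1/s after ", t_now, " s", call. = FALSE)
      }
    }
    out <- matrix(c(t_now, y), nrow = 1)
  } else {
    times <- unique(c(seq(0, cfg$duration, by = cfg$dt_out),
                      cfg$duration))
    out <- deSolve::lsoda(y, times, func, parms = NULL, rtol = rtol,
                          atol = atol, jactype = "bandint",
                          bandup = ctx$nspec, banddown = ctx$nspec,
                          maxsteps = 100000)
    if (attr(out, "istate")[1] < 0) {
      stop("ascites integration failed", call. = FALSE)
    }
  }
  ascites_result(out, ctx, cfg, p)
}

ascites_result <- function(out, ctx, cfg, p) {
  times <- out[, 1]
  n <- ctx$n
  dist <- cfg$layer_width * (seq_len(n) - 0.5) +
    if (cfg$geometry == "radial") cfg$vessel_radius else 0
  wgt <- ctx$vol / sum(ctx$vol)
  grab <- function(idx) as.vector(out[, 1 + idx, drop = FALSE])
  res <- tibble::tibble(
    time = rep(times, n),
    layer = rep(seq_len(n), each = length(times)),
    distance = rep(dist, each = length(times)),
    weight = rep(wgt, each = length(times)),
    glc = grab(ctx$i_sol(1)), o2 = grab(ctx$i_sol(2)),
    lac = grab(ctx$i_sol(3)), pyr = grab(ctx$i_sol(4)))
  if (ctx$has_cells) {
    res$fbp <- grab(ctx$i_cell(1))
    res$atp <- grab(ctx$i_cell(2))
    res$a_pool <- grab(ctx$i_cell(3))
    res$pi_ <- grab(ctx$i_cell(4))
    res$nadh <- grab(ctx$i_cell(5))
    res$f_active <- grab(ctx$i_cell(6))
    res$cum_glc <- grab(ctx$i_cell(7))
    res$cum_lac_net <- grab(ctx$i_cell(8))
    pp <- cell_fluxes_raw(res$glc, res$o2, res$fbp, res$atp,
                          res$a_pool - res$atp, res$pi_, res$nadh,
                          res$pyr, res$lac, res$f_active, res$a_pool, p)
    res$j_head <- pp$j_head
    res$j_o2 <- pp$j_o2
    res$j_ldh <- pp$j_ldh
  }
  vwm <- dplyr::group_by(res, .data$time)
  vwm <- dplyr::summarise(
    vwm,
    glc = sum(.data$glc * .data$weight),
    o2 = sum(.data$o2 * .data$weight),
    lac = sum(.data$lac * .data$weight),
    .groups = "drop")
  attr(res, "volume_weighted_mean") <- vwm
  attr(res, "config") <- cfg
  attr(res, "params") <- p
  class(res) <- c("ascites_sim", class(res))
  res
}

#' Packaged ascites configurations
#'
#' `dataset6_cellfree`: cell-free fluid initially at 167 µM glucose,
#' glucose diffusing in from the peritoneal boundary for 3 minutes
#' (planar stack of 63 x 10 µm layers).
#' `dataset7_25pct`: steady-state gradients in a 25 vol% tumor-cell
#' suspension over 630 µm from the vessel (radial).
#'
#' @param name configuration name.
#' @return An [ascites_config()].
#' @export
packaged_ascites_config <- function(name = c("dataset6_cellfree",
                                             "dataset7_25pct")) {
  name <- match.arg(name)
  path <- system.file("extdata", "configs", paste0(name, ".yml"),
                      package = "glycodyn", mustWork = TRUE)
  load_config(path)
}
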