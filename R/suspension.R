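#' Describe an in-vitro suspension experiment
#'
#' A suspension scenario mirrors the classical Ehrlich ascites tumor cell
#' (EATC) experiments: an aerated (or anoxic) stirred suspension of
#' glucose-depleted cells respiring on abundant lactate, to which glucose
#' (and optionally pyruvate) is added at t = 0.
#'
#' @param cell_volume_fraction cell volume per suspension volume
#'   (e.g. 0.022 or 0.029).
#' @param glc_added glucose added to the medium at t = 0, µM.
#' @param pyr_added pyruvate added at t = 0, µM (default 0).
#' @param o2_mode `"aerated"` (dissolved O2 held constant) or `"anoxic"`.
#' @param o2_fixed dissolved O2 during aerated incubation, µM.
#' @param duration simulated time after addition, s.
#' @param pre_depletion start from glucose-depleted cells spun up to their
#'   aerobic steady state on lactate (default `TRUE`).
#' @param initial_lac lactate in the shared medium/cell pool at t = 0, µM.
#' @param initial_pyr pyruvate at the start of the spin-up, µM.
#' @param spinup length of the constant-environment spin-up used to
#'   generate the depleted initial state, s.
#' @param sampling output time grid, s; default 0.1 s steps for the first
#'   minute and 1 s steps afterwards so the 5 s/10 s observables are
#'   on-grid.
#' @param name optional scenario label.
#' @return A `suspension_scenario` object (list).
#' @export
suspension_scenario <- function(cell_volume_fraction, glc_added,
                                pyr_added = 0,
                                o2_mode = c("aerated", "anoxic"),
                                o2_fixed = 200, duration = 300,
                                pre_depletion = TRUE, initial_lac = 5000,
                                initial_pyr = 25, spinup = 3000,
                                sampling = NULL, name = NULL) {
  o2_mode <- match.arg(o2_mode)
  stopifnot(cell_volume_fraction > 0, cell_volume_fraction < 1,
            duration > 0, glc_added >= 0, pyr_added >= 0,
            initial_lac >= 0, spinup >= 0)
  if (is.null(sampling)) {
    sampling <- c(seq(0, min(60, duration), by = 0.1),
                  if (duration > 60) seq(61, duration, by = 1))
  }
  sampling <- sort(unique(c(0, sampling[sampling <= duration])))
  structure(
    list(name = name %||% "suspension",
         cell_volume_fraction = cell_volume_fraction,
         glc_added = glc_added, pyr_added = pyr_added,
         o2_mode = o2_mode, o2_fixed = o2_fixed, duration = duration,
         pre_depletion = pre_depletion, initial_lac = initial_lac,
         initial_pyr = initial_pyr, spinup = spinup, sampling = sampling),
    class = "suspension_scenario")
}

#' @export
print.suspension_scenario <- function(x, ...) {
  cat("<suspension_scenario> ", x$name, "\n",
      "  cells ", 100 * x$cell_volume_fraction, " vol%, +",
      x$glc_added, " uM glucose",
      if (x$pyr_added > 0) paste0(" +", x$pyr_added, " uM pyruvate"),
      ", ", x$o2_mode, ", ", x$duration, " s\n", sep = "")
  invisible(x)
}

# medium/cell coupling factors for a suspension
suspension_factors <- function(scn, p) {
  vfw <- scn$cell_volume_fraction * p$water_frac
  med <- 1 - scn$cell_volume_fraction
  list(
    # glucose lives in the medium only (free intracellular glucose is not
    # tracked; the head section includes transport)
    f_glc = vfw / med,
    # lactate/pyruvate equilibrate quickly over medium + cell water
    f_exch = vfw / (vfw + med)
  )
}

# steady depleted state by spin-up at zero glucose (aerated)
depleted_state <- function(scn, p) {
  y0 <- c(glc = 0, o2 = scn$o2_fixed, fbp = 20, atp = p$atp_init,
          a_pool = p$a_pool_init, pi_ = p$pi_init, nadh = 30,
          pyr = scn$initial_pyr, lac = scn$initial_lac, f_active = 1,
          cum_glc = 0, cum_lac = 0, cum_o2 = 0, cum_sink = 0,
          cum_mito = 0)
  if (scn$spinup <= 0) return(y0)
  fac <- suspension_factors(scn, p)
  # hold the lactate pool (replenished in vivo / experimentally abundant)
  # and the adenine pool (intact before the experiment); holding the
  # pool also suppresses its phosphate release/consumption terms so the
  # Pi balance stays consistent
  func <- function(t, y, parms) {
    core <- deriv_core(y, "fixed", scn$o2_fixed, fac$f_glc, fac$f_exch, p)
    d <- core$deriv
    d[9L] <- 0   # lactate held during depletion
    d[5L] <- 0   # adenine pool intact before the experiment
    d[6L] <- d[6L] - core$fluxes$j_pool_loss + core$fluxes$j_pool_resyn
    list(d)
  }
  out <- deSolve::lsoda(unname(y0), c(0, scn$spinup), func, parms = NULL,
                        rtol = 1e-8, atol = 1e-8, maxsteps = 50000)
  y <- out[nrow(out), -1]
  names(y) <- state_names()
  y[c("cum_glc", "cum_lac", "cum_o2", "cum_sink", "cum_mito")] <- 0
  y
}

#' Run a suspension experiment
#'
#' Integrates the cell model coupled to the two-compartment suspension
#' balance: the medium change of glucose equals
#' `-j_head * cell_volume_fraction * water_frac / (1 - cell_volume_fraction)`
#' and lactate/pyruvate are treated as one fast-equilibrating pool over
#' medium plus cell water. Under `o2_mode = "aerated"` dissolved O2 is
#' held constant; under `"anoxic"` it is zero.
#'
#' @param scn a [suspension_scenario()].
#' @param p a [cell_parameters()] set.
#' @param rtol,atol solver tolerances (stiff BDF-capable `lsoda`).
#' @return A tibble of class `suspension_sim`: one row per sample time
#'   with all state variables (µM), derived `adp`/`nad`, all fluxes
#'   (µM/s) and the content observables in µmol/ml cell volume
#'   (`fbp_content`, `atp_content`, `cum_glc_content`,
#'   `cum_lac_content`). Attributes `scenario` and `params` carry the
#'   inputs.
#' @examples
#' \donttest{
#' scn <- suspension_scenario(0.029, glc_added = 776, duration = 120)
#' sim <- run_suspension(scn, cell_parameters())
#' sim[sim$time == 5, c("time", "j_head", "j_ldh")]
#' }
#' @export
run_suspension <- function(scn, p = cell_parameters(), rtol = 1e-8,
                           atol = 1e-8) {
  stopifnot(inherits(scn, "suspension_scenario"))
  p <- validate_cell_parameters(p)
  fac <- suspension_factors(scn, p)
  y0 <- if (scn$pre_depletion) depleted_state(scn, p) else
    c(glc = 0, o2 = scn$o2_fixed, fbp = 20, atp = p$atp_init,
      a_pool = p$a_pool_init, pi_ = p$pi_init, nadh = 30,
      pyr = scn$initial_pyr, lac = scn$initial_lac, f_active = 1,
      cum_glc = 0, cum_lac = 0, cum_o2 = 0, cum_sink = 0, cum_mito = 0)
  y0[["glc"]] <- y0[["glc"]] + scn$glc_added
  y0[["pyr"]] <- y0[["pyr"]] + scn$pyr_added
  o2_mode <- if (scn$o2_mode == "anoxic") "anoxic" else "fixed"
  y0[["o2"]] <- if (o2_mode == "anoxic") 0 else scn$o2_fixed
  func <- function(t, y, parms) {
    list(deriv_core(y, o2_mode, scn$o2_fixed, fac$f_glc, fac$f_exch,
                    p)$deriv)
  }
  out <- deSolve::lsoda(unname(y0), scn$sampling, func, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0) {
    stop("integration failure in suspension scenario '", scn$name,
         "' near t = ", format(out[nrow(out), 1]), " s", call. = FALSE)
  }
  colnames(out) <- c("time", state_names())
  assert_trajectory(out, what = paste0("scenario '", scn$name, "'"))
  res <- trajectory_tibble(out, p, o2_mode = o2_mode,
                           o2_fixed = scn$o2_fixed)
  attr(res, "scenario") <- scn
  attr(res, "params") <- p
  class(res) <- c("suspension_sim", class(res))
  res
}

# assemble the result tibble: states + derived + fluxes + contents
trajectory_tibble <- function(out, p, o2_mode = "state", o2_fixed = 200) {
  df <- tibble::as_tibble(as.data.frame(out))
  if (o2_mode == "fixed") df$o2 <- o2_fixed
  if (o2_mode == "anoxic") df$o2 <- 0
  df$adp <- df$a_pool - df$atp
  df$nad <- p$nad_total - df$nadh
  fl <- purrr::pmap(
    list(df$glc, df$o2, df$fbp, df$atp, df$adp, df$pi_, df$nadh, df$pyr,
         df$lac, df$f_active, df$a_pool),
    function(glc, o2, fbp, atp, adp, pi_, nadh, pyr, lac, f_active,
             a_pool) {
      unlist(cell_fluxes_raw(glc, o2, fbp, atp, adp, pi_, nadh, pyr, lac,
                             f_active, a_pool, p))
    })
  fl <- tibble::as_tibble(do.call(rbind, fl))
  df <- dplyr::bind_cols(df, fl)
  # contents per ml cell volume = µM (per L cell water) * water_frac / 1000
  cf <- p$water_frac / 1000
  df$fbp_content <- df$fbp * cf
  df$atp_content <- df$atp * cf
  df$cum_glc_content <- df$cum_glc * cf
  df$cum_lac_content <- df$cum_lac * cf
  df
}

#' Packaged suspension scenarios
#'
#' Returns one of the packaged scenario descriptions of the classical
#' EATC suspension experiments:
#' `exp1_92uM` (92 µM glucose to 2.2 vol% cells, 300 s),
#' `exp2_776uM` (776 µM glucose to 2.9 vol% cells, 300 s),
#' `exp3_11mM_1h` (11.1 mM glucose, aerobic, 1 h),
#' `exp4_dose_response` (dose list, see [peak_fbp_dose_response()]),
#' `exp5_fast_accumulation` (77 µM glucose, first 10 s observables),
#' `exp6_anoxia` (11.1 mM glucose, anoxic, 1 h),
#' `exp7_pyruvate` (10 mM glucose + 5 mM pyruvate).
#'
#' @param name scenario name as above.
#' @return A [suspension_scenario()] (for `exp4_dose_response`, a scenario
#'   with attribute `doses`).
#' @export
packaged_scenario <- function(name = c("exp1_92uM", "exp2_776uM",
                                       "exp3_11mM_1h",
                                       "exp4_dose_response",
                                       "exp5_fast_accumulation",
                                       "exp6_anoxia", "exp7_pyruvate")) {
  name <- match.arg(name)
  path <- system.file("extdata", "scenarios", paste0(name, ".yml"),
                      package = "glycodyn", mustWork = TRUE)
  load_config(path)
}
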