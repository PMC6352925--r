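#' Cell state vector
#'
#' Constructs the dynamic state of one cell type at one time point. All
#' concentrations in µM (µmol per litre intracellular water); cumulative
#' counters in µmol per litre intracellular water. `adp` and `nad` are
#' derived quantities (`a_pool - atp` and `nad_total - nadh`), never
#' stored.
#'
#' @param glc extracellular glucose, µM.
#' @param o2 dissolved O2, µM.
#' @param fbp fructose 1,6-bisphosphate, µM.
#' @param atp ATP, µM.
#' @param a_pool adenine nucleotide pool ATP + ADP, µM.
#' @param pi_ inorganic phosphate, µM.
#' @param nadh NADH, µM.
#' @param pyr pyruvate, µM.
#' @param lac lactate, µM.
#' @param f_active active fraction of the glycolytic head section.
#' @param cum_glc,cum_lac,cum_o2,cum_sink,cum_mito cumulative glucose
#'   uptake (6C), lactate production, O2 consumption, biomass-sink carbon
#'   (6C) and mitochondrial pyruvate oxidation (3C).
#' @param p a [cell_parameters()] set (used for invariant checks).
#' @return Named numeric vector of class `glycodyn_state`.
#' @export
cell_state <- function(glc = 0, o2 = 200, fbp = 0, atp = NULL,
                       a_pool = NULL, pi_ = NULL, nadh = 50, pyr = 25,
                       lac = 5000, f_active = 1,
                       cum_glc = 0, cum_lac = 0, cum_o2 = 0,
                       cum_sink = 0, cum_mito = 0, p = cell_parameters()) {
  if (is.null(atp)) atp <- p$atp_init
  if (is.null(a_pool)) a_pool <- p$a_pool_init
  if (is.null(pi_)) pi_ <- p$pi_init
  s <- c(glc = glc, o2 = o2, fbp = fbp, atp = atp, a_pool = a_pool,
         pi_ = pi_, nadh = nadh, pyr = pyr, lac = lac,
         f_active = f_active, cum_glc = cum_glc, cum_lac = cum_lac,
         cum_o2 = cum_o2, cum_sink = cum_sink, cum_mito = cum_mito)
  check_cell_state(s, p)
  structure(s, class = c("glycodyn_state", "numeric"))
}

check_cell_state <- function(s, p, tol = 1e-6) {
  conc <- c("glc", "o2", "fbp", "atp", "a_pool", "pi_", "nadh", "pyr", "lac")
  neg <- conc[s[conc] < -tol]
  if (length(neg)) {
    stop("invariant violation: negative state variable(s): ",
         paste(neg, collapse = ", "), call. = FALSE)
  }
  if (s[["f_active"]] < -tol || s[["f_active"]] > 1 + tol) {
    stop("invariant violation: f_active outside [0, 1]", call. = FALSE)
  }
  if (s[["atp"]] > s[["a_pool"]] + tol) {
    stop("invariant violation: atp exceeds a_pool", call. = FALSE)
  }
  if (s[["nadh"]] > p$nad_total + tol) {
    stop("invariant violation: nadh exceeds nad_total", call. = FALSE)
  }
  invisible(TRUE)
}

state_names <- function() {
  c("glc", "o2", "fbp", "atp", "a_pool", "pi_", "nadh", "pyr", "lac",
    "f_active", "cum_glc", "cum_lac", "cum_o2", "cum_sink", "cum_mito")
}

flux_names <- function() {
  c("j_head", "j_tail", "j_oxphos_atp", "j_o2", "j_ldh", "j_hyd",
    "j_pool_loss", "j_sink", "j_mito", "j_pool_resyn")
}

# All fluxes at one (unchecked) state; internal hot path shared by every
# integrator. Substrate concentrations are floored at 0 so that tiny
# solver undershoots produce zero (not complex/negative-denominator)
# rates; this is a smooth continuation, not state clamping.
cell_fluxes_raw <- function(glc, o2, fbp, atp, adp, pi_, nadh, pyr, lac,
                            f_active, a_pool, p) {
  glc <- pmax(glc, 0); o2 <- pmax(o2, 0); fbp <- pmax(fbp, 0)
  atp <- pmax(atp, 0); adp <- pmax(adp, 0); pi_ <- pmax(pi_, 0)
  nadh <- pmin(pmax(nadh, 0), p$nad_total); pyr <- pmax(pyr, 0)
  lac <- pmax(lac, 0); f_active <- pmin(pmax(f_active, 0), 1)
  nad <- p$nad_total - nadh
  cap <- p$glycolytic_capacity_scale

  j_head <- if (p$head_form == 1) {
    p$vmax_head * cap * f_active * (glc / (p$km_glc_head + glc)) *
      (atp / (p$km_atp_head + atp))
  } else {
    p$vmax_head * cap * f_active * glc * atp /
      (p$km_glc_head * p$km_atp_head + p$km_atp_head * glc +
         p$km_glc_head * atp + glc * atp)
  }

  j_tail <- p$vmax_tail * cap *
    (fbp / (p$km_fbp_tail + fbp)) * (nad / (p$km_nad_tail + nad)) *
    (adp / (p$km_adp_tail + adp)) * (pi_ / (p$km_pi_tail + pi_)) /
    (1 + nadh / p$ki_nadh_tail)

  j_oxphos_atp <- p$vmax_oxphos *
    (adp / (p$km_adp_ox + adp)) * (pi_ / (p$km_pi_ox + pi_)) *
    (o2 / (p$km_o2_ox + o2)) * (nadh / (p$km_nadh_ox + nadh)) *
    (pyr / (p$km_pyr_ox + pyr))
  j_o2 <- j_oxphos_atp / (2 * p$p_over_o)
  j_mito <- j_o2 / 3  # pyruvate + NADH pairs (lactate equivalents)

  vr <- p$vf_ldh * p$km_lac_ldh * p$km_nad_ldh /
    (p$km_pyr_ldh * p$km_nadh_ldh * p$keq_ldh)
  j_ldh <- (p$vf_ldh * (pyr / p$km_pyr_ldh) * (nadh / p$km_nadh_ldh) -
              vr * (lac / p$km_lac_ldh) * (nad / p$km_nad_ldh)) /
    ((1 + pyr / p$km_pyr_ldh) * (1 + nadh / p$km_nadh_ldh) +
       (1 + lac / p$km_lac_ldh) * (1 + nad / p$km_nad_ldh) - 1)

  # pool-linear demand, gated by ATP availability so the rate vanishes
  # smoothly when ATP is exhausted (no state clamping needed)
  j_hyd <- pmax(0, p$hyd_max - p$hyd_pool_slope *
                  (p$a_pool_init - a_pool)) *
    atp / (p$km_atp_hyd + atp)
  j_pool_loss <- p$k_pool_loss * pmax(0, adp - p$adp_threshold)
  j_pool_resyn <- p$k_resyn * pmax(0, p$a_pool_init - a_pool)
  j_sink <- p$k_sink * p$r_pgi * fbp

  list(j_head = j_head, j_tail = j_tail, j_oxphos_atp = j_oxphos_atp,
       j_o2 = j_o2, j_ldh = j_ldh, j_hyd = j_hyd,
       j_pool_loss = j_pool_loss, j_sink = j_sink, j_mito = j_mito,
       j_pool_resyn = j_pool_resyn)
}

#' Mass-balance right-hand side of the cell model
#'
#' Computes the time derivative of every state variable together with the
#' flux vector, for one cell in a prescribed environment. The
#' stoichiometry is: the head section consumes 1 glucose + 2 ATP per
#' 6-carbon unit and feeds the PGI pool; the tail section per 3-carbon
#' unit consumes 1/2 FBP-equivalent, 1 NAD, 2 ADP, 1 Pi and yields
#' 1 pyruvate, 1 NADH, 2 ATP; mitochondria oxidize pyruvate and NADH in
#' 1:1 pairs at 3 O2 per pair with `2 * p_over_o` ATP per O2; LDH
#' interconverts pyruvate + NADH and lactate + NAD; ATP hydrolysis scales
#' with the adenine pool; the pool degrades first-order in ADP above a
#' threshold and resynthesizes slowly.
#'
#' @param state named numeric vector with the elements of [cell_state()].
#' @param env list with `o2_mode` (`"state"`, `"fixed"`, `"anoxic"`) and,
#'   for `"fixed"`, `o2_fixed` (µM); plus optional dilution factors
#'   `f_glc`, `f_exch` converting intracellular fluxes to shared-pool
#'   concentration changes (both default 1 = closed single compartment).
#' @param p a [cell_parameters()] set.
#' @return list with `deriv` (named derivatives) and `fluxes` (named flux
#'   vector: `j_head`, `j_tail`, `j_oxphos_atp`, `j_o2`, `j_ldh`,
#'   `j_hyd`, `j_pool_loss`, `j_sink`, `j_mito`, `j_pool_resyn`).
#' @export
cell_rhs <- function(state, env = list(), p = cell_parameters()) {
  s <- state
  if (is.null(names(s)) || !all(state_names() %in% names(s))) {
    stop("state must be a named vector with elements ",
         paste(state_names(), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(s))) {
    stop("non-finite state variable(s): ",
         paste(names(s)[!is.finite(s)], collapse = ", "), call. = FALSE)
  }
  o2_mode <- env$o2_mode %||% "state"
  y <- unname(s[state_names()])
  core <- deriv_core(y, o2_mode = o2_mode,
                     o2_fixed = env$o2_fixed %||% 200,
                     f_glc = env$f_glc %||% 1,
                     f_exch = env$f_exch %||% 1, p = p)
  d <- core$deriv
  names(d) <- state_names()
  list(deriv = d, fluxes = core$fluxes)
}

# Shared derivative core on the fixed state ordering of state_names():
#  1 glc, 2 o2, 3 fbp, 4 atp, 5 a_pool, 6 pi_, 7 nadh, 8 pyr, 9 lac,
# 10 f_active, 11 cum_glc, 12 cum_lac, 13 cum_o2, 14 cum_sink, 15 cum_mito
deriv_core <- function(y, o2_mode, o2_fixed, f_glc, f_exch, p) {
  o2 <- switch(o2_mode,
               state = y[2L],
               fixed = o2_fixed,
               anoxic = 0,
               stop("unknown o2_mode: ", o2_mode, call. = FALSE))
  adp <- y[5L] - y[4L]
  fl <- cell_fluxes_raw(y[1L], o2, y[3L], y[4L], adp, y[6L], y[7L],
                        y[8L], y[9L], y[10L], y[5L], p)
  f_act <- min(max(y[10L], 0), 1)
  net_red <- fl$j_tail - fl$j_ldh - fl$j_mito
  d <- c(
    -fl$j_head * f_glc,
    if (o2_mode == "state") -fl$j_o2 else 0,
    (fl$j_head - fl$j_tail / 2 - fl$j_sink) / p$r_pgi,
    -2 * fl$j_head + 2 * fl$j_tail + fl$j_oxphos_atp - fl$j_hyd,
    -fl$j_pool_loss + fl$j_pool_resyn,
    fl$j_hyd + 2 * fl$j_head - 2 * fl$j_tail - fl$j_oxphos_atp +
      fl$j_pool_loss - fl$j_pool_resyn,
    net_red,
    net_red * f_exch,
    fl$j_ldh * f_exch,
    -p$k_inact * p$r_pgi * max(y[3L], 0) * f_act +
      p$k_react * (1 - f_act),
    fl$j_head,
    max(fl$j_ldh, 0),
    fl$j_o2,
    fl$j_sink,
    fl$j_mito
  )
  list(deriv = d, fluxes = fl)
}

# Post-integration assertion layer: no state may undershoot zero by more
# than the solver's absolute tolerance allows.
assert_trajectory <- function(out, tol = 1e-5, what = "simulation") {
  conc <- c("glc", "o2", "fbp", "atp", "a_pool", "pi_", "nadh", "pyr", "lac")
  cols <- intersect(colnames(out), conc)
  for (cn in cols) {
    if (any(out[, cn] < -tol)) {
      stop(what, ": state '", cn, "' became negative (min ",
           format(min(out[, cn])), ")", call. = FALSE)
    }
  }
  if ("f_active" %in% colnames(out) &&
      (any(out[, "f_active"] < -tol) || any(out[, "f_active"] > 1 + tol))) {
    stop(what, ": f_active left [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
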