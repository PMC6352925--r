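#' Flux laws of the cell model
#'
#' The five rate laws plus the head-section feedback kinetics. All fluxes
#' are in µmol per litre intracellular water per second (µM/s);
#' head-section flux is in 6-carbon units, tail-section and LDH fluxes in
#' 3-carbon units.
#'
#' @name fluxes
#' @param p a [cell_parameters()] set.
NULL

chk_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (any(!is.finite(x)) || any(x < 0)) {
      stop("domain error: argument '", nm, "' must be non-negative and finite",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

mm <- function(s, km) s / (km + s)

#' @describeIn fluxes Glycolytic head section (glucose transport +
#'   hexokinase + phosphofructokinase): consumes 1 glucose and 2 ATP per
#'   6-carbon unit, produces FBP. Saturable in glucose and ATP, scaled by
#'   the active fraction `f_active` of the delayed-feedback target.
#'   Monotone non-decreasing in each argument and bounded by
#'   `f_active * vmax_head * glycolytic_capacity_scale`.
#' @param glc extracellular glucose, µM.
#' @param atp ATP, µM.
#' @param f_active active fraction of the head section, in \[0, 1\].
#' @export
head_flux <- function(glc, atp, f_active, p) {
  chk_nonneg(glc = glc, atp = atp, f_active = f_active)
  if (any(f_active > 1)) {
    stop("domain error: argument 'f_active' must be <= 1", call. = FALSE)
  }
  vmax <- p$vmax_head * p$glycolytic_capacity_scale
  if (p$head_form == 1) {
    vmax * f_active * mm(glc, p$km_glc_head) * mm(atp, p$km_atp_head)
  } else {
    # ternary-complex denominator: shared binding interaction
    vmax * f_active * glc * atp /
      (p$km_glc_head * p$km_atp_head + p$km_atp_head * glc +
         p$km_glc_head * atp + glc * atp)
  }
}

#' @describeIn fluxes Lumped glycolytic tail section (aldolase through
#'   pyruvate kinase). Per 3-carbon unit: consumes 1/2 FBP, 1 NAD, 2 ADP
#'   and 1 Pi; produces 1 pyruvate, 1 NADH and 2 ATP. Saturable in FBP,
#'   NAD (= `nad_total - nadh`), ADP and Pi; inhibited by NADH with
#'   constant `ki_nadh_tail`. Bounded by
#'   `vmax_tail * glycolytic_capacity_scale`.
#' @param fbp fructose 1,6-bisphosphate, µM.
#' @param nadh NADH, µM (must not exceed `nad_total`).
#' @param adp ADP, µM.
#' @param pi_ inorganic phosphate, µM.
#' @export
tail_flux <- function(fbp, nadh, adp, pi_, p) {
  chk_nonneg(fbp = fbp, nadh = nadh, adp = adp, pi_ = pi_)
  if (any(nadh > p$nad_total + 1e-9)) {
    stop("invariant violation: nadh exceeds nad_total", call. = FALSE)
  }
  nad <- pmax(p$nad_total - nadh, 0)
  p$vmax_tail * p$glycolytic_capacity_scale *
    mm(fbp, p$km_fbp_tail) * mm(nad, p$km_nad_tail) *
    mm(adp, p$km_adp_tail) * mm(pi_, p$km_pi_tail) /
    (1 + nadh / p$ki_nadh_tail)
}

#' @describeIn fluxes Oxidative phosphorylation. ATP synthesis saturable
#'   in ADP, Pi and O2 (and gated by saturable NADH and pyruvate
#'   availability, the mitochondrial substrates); O2 consumption is
#'   stoichiometrically coupled as `j_o2 = j_atp / (2 * p_over_o)`.
#'   Returns a list with `j_atp` and `j_o2` (µM/s).
#' @param o2 dissolved O2, µM.
#' @param pyr pyruvate, µM.
#' @export
oxphos_flux <- function(adp, pi_, o2, p, nadh = NULL, pyr = NULL) {
  chk_nonneg(adp = adp, pi_ = pi_, o2 = o2)
  gate <- 1
  if (!is.null(nadh)) {
    chk_nonneg(nadh = nadh)
    gate <- gate * mm(nadh, p$km_nadh_ox)
  }
  if (!is.null(pyr)) {
    chk_nonneg(pyr = pyr)
    gate <- gate * mm(pyr, p$km_pyr_ox)
  }
  j_atp <- p$vmax_oxphos * mm(adp, p$km_adp_ox) * mm(pi_, p$km_pi_ox) *
    mm(o2, p$km_o2_ox) * gate
  list(j_atp = j_atp, j_o2 = j_atp / (2 * p$p_over_o))
}

#' @describeIn fluxes Reversible lactate dehydrogenase,
#'   pyruvate + NADH = lactate + NAD. Two-substrate reversible
#'   Michaelis–Menten law; the reverse maximal rate follows from the
#'   Haldane relationship so the net flux vanishes exactly at
#'   thermodynamic equilibrium `lac * nad / (pyr * nadh) = keq_ldh`.
#'   Positive flux = net lactate production; negative = lactate
#'   consumption (respiration on lactate when glucose is absent).
#' @param lac lactate, µM.
#' @export
ldh_flux <- function(pyr, nadh, lac, p, nad = NULL) {
  chk_nonneg(pyr = pyr, nadh = nadh, lac = lac)
  if (is.null(nad)) nad <- pmax(p$nad_total - nadh, 0)
  if (any(nadh > p$nad_total + 1e-9)) {
    stop("invariant violation: nadh exceeds nad_total", call. = FALSE)
  }
  # Haldane: keq = (vf * km_lac * km_nad) / (vr * km_pyr * km_nadh)
  vr <- p$vf_ldh * p$km_lac_ldh * p$km_nad_ldh /
    (p$km_pyr_ldh * p$km_nadh_ldh * p$keq_ldh)
  num <- p$vf_ldh * (pyr / p$km_pyr_ldh) * (nadh / p$km_nadh_ldh) -
    vr * (lac / p$km_lac_ldh) * (nad / p$km_nad_ldh)
  den <- (1 + pyr / p$km_pyr_ldh) * (1 + nadh / p$km_nadh_ldh) +
    (1 + lac / p$km_lac_ldh) * (1 + nad / p$km_nad_ldh) - 1
  num / den
}

#' @describeIn fluxes ATP hydrolysis for maintenance, growth and cell
#'   function. Linear in the fall of the adenine nucleotide pool
#'   (ATP + ADP): `max(0, hyd_max - hyd_pool_slope * (a_pool_init -
#'   a_pool))`; equals `hyd_max` with an intact pool, clamped at zero.
#'   (Inside [cell_rhs()] this demand is additionally multiplied by the
#'   ATP-availability factor `atp / (km_atp_hyd + atp)` so that ATP
#'   consumption vanishes smoothly if ATP runs out.)
#' @param a_pool adenine nucleotide pool ATP + ADP, µM.
#' @export
atp_hydrolysis_flux <- function(a_pool, p) {
  chk_nonneg(a_pool = a_pool)
  if (any(a_pool > p$a_pool_init + 1e-6)) {
    stop("invariant violation: a_pool exceeds a_pool_init", call. = FALSE)
  }
  pmax(0, p$hyd_max - p$hyd_pool_slope * (p$a_pool_init - a_pool))
}

#' @describeIn fluxes Delayed feedback of the PGI pool on the head
#'   section: second-order inactivation by PGI, first-order reactivation.
#'   Returns dF/dt (1/s); the fixed point is
#'   `k_react / (k_react + k_inact * pgi)` and trajectories remain in
#'   \[0, 1\] because both boundary derivatives point inward.
#' @param pgi total phosphorylated glycolytic intermediates, µM
#'   6-carbon equivalents.
#' @export
feedback_rate <- function(f_active, pgi, p) {
  chk_nonneg(f_active = f_active, pgi = pgi)
  if (any(f_active > 1)) {
    stop("domain error: argument 'f_active' must be <= 1", call. = FALSE)
  }
  -p$k_inact * pgi * f_active + p$k_react * (1 - f_active)
}

#' @describeIn fluxes Total PGI pool (6-carbon equivalents) implied by
#'   the FBP concentration: `r_pgi * fbp`.
#' @export
pgi_total <- function(fbp, p) {
  chk_nonneg(fbp = fbp)
  p$r_pgi * fbp
}
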