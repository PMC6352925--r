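#' Kinetic parameter set for the cell model
#'
#' Builds and validates the full set of kinetic constants of the
#' coarse-grained cell model: maximal rates and Michaelis/inhibition
#' constants of the glycolytic head and tail sections, oxidative
#' phosphorylation, the reversible lactate dehydrogenase (LDH) law, the
#' ATP-hydrolysis/adenine-pool coupling, the delayed feedback on the head
#' section, and bookkeeping constants (PGI:FBP ratio, conserved pools,
#' intracellular water fraction).
#'
#' All intracellular concentrations are in µmol per litre intracellular
#' water ("µM") and all fluxes in µM/s. Head-section fluxes are in
#' 6-carbon units, tail-section fluxes in 3-carbon units.
#'
#' @param ... named parameter overrides applied on top of the default
#'   EATC (Ehrlich ascites tumor cell) set, e.g. `vmax_head = 100`.
#' @param base optional named list/`glycodyn_params` to start from instead
#'   of the packaged EATC defaults.
#'
#' @return A `glycodyn_params` object (named list of numeric scalars).
#'
#' @details Parameter groups:
#' \describe{
#'   \item{head section}{`vmax_head` (µM/s, 6C), `km_glc_head` (µM),
#'     `km_atp_head` (µM), `head_form` (1 = multiplicative Michaelis
#'     product, 2 = ternary-complex denominator).}
#'   \item{tail section}{`vmax_tail` (µM/s, 3C), `km_fbp_tail`,
#'     `km_nad_tail`, `km_adp_tail`, `km_pi_tail`, `ki_nadh_tail` (all µM).}
#'   \item{oxidative phosphorylation}{`vmax_oxphos` (µM ATP/s),
#'     `km_adp_ox`, `km_pi_ox`, `km_o2_ox`, `km_nadh_ox`, `km_pyr_ox` (µM),
#'     `p_over_o` (mol ATP per mol O atom).}
#'   \item{lactate dehydrogenase}{`vf_ldh` (µM/s), `km_pyr_ldh`,
#'     `km_nadh_ldh`, `km_lac_ldh`, `km_nad_ldh` (µM), `keq_ldh`
#'     (dimensionless; the reverse Vmax follows from the Haldane
#'     relationship).}
#'   \item{ATP demand and adenine pool}{`hyd_max` (µM/s),
#'     `hyd_pool_slope` (1/s), `km_atp_hyd` (µM, ATP availability
#'     gate of the hydrolysis law), `k_pool_loss` (1/s),
#'     `adp_threshold` (µM), `k_resyn` (1/s).}
#'   \item{head-section feedback}{`k_inact` (µM^-1 s^-1), `k_react`
#'     (s^-1).}
#'   \item{bookkeeping}{`r_pgi` (total PGI : FBP, 6C equivalents, >= 1),
#'     `k_sink` (1/s, first-order PGI biomass sink), `nad_total`,
#'     `a_pool_init`, `atp_init`, `pi_init` (µM), `water_frac`
#'     (intracellular water fraction of cell volume),
#'     `glycolytic_capacity_scale` (joint multiplier on `vmax_head` and
#'     `vmax_tail`; 1 = full tumor capacity).}
#' }
#'
#' @examples
#' p <- cell_parameters()
#' p$km_glc_head
#' low <- cell_parameters(glycolytic_capacity_scale = 0.1)
#' @export
cell_parameters <- function(..., base = NULL) {
  p <- if (is.null(base)) eatc_default_parameters() else as.list(base)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  validate_cell_parameters(p)
}

#' Default EATC parameter set
#'
#' The calibrated parameter set for Ehrlich ascites tumor cells used by
#' every packaged scenario. Read from the packaged parameter file
#' `extdata/params/eatc_default.yml`.
#'
#' @return Named list of parameter values (not yet classed; see
#'   [cell_parameters()]).
#' @keywords internal
eatc_default_parameters <- function() {
  path <- system.file("extdata", "params", "eatc_default.yml",
                      package = "glycodyn", mustWork = TRUE)
  read_parameter_file(path, validate = FALSE)
}

param_names <- function() {
  c("vmax_head", "km_glc_head", "km_atp_head", "head_form",
    "vmax_tail", "km_fbp_tail", "km_nad_tail", "km_adp_tail",
    "km_pi_tail", "ki_nadh_tail",
    "vmax_oxphos", "km_adp_ox", "km_pi_ox", "km_o2_ox",
    "km_nadh_ox", "km_pyr_ox", "p_over_o",
    "vf_ldh", "km_pyr_ldh", "km_nadh_ldh", "km_lac_ldh", "km_nad_ldh",
    "keq_ldh",
    "hyd_max", "hyd_pool_slope", "km_atp_hyd", "k_pool_loss",
    "adp_threshold", "k_resyn",
    "k_inact", "k_react",
    "r_pgi", "k_sink",
    "nad_total", "a_pool_init", "atp_init", "pi_init",
    "water_frac", "glycolytic_capacity_scale")
}

validate_cell_parameters <- function(p) {
  p <- as.list(p)
  missing <- setdiff(param_names(), names(p))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(p), param_names())
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- p[param_names()]
  bad <- names(p)[!vapply(p, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad)) {
    stop("parameter(s) not finite numeric scalars: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  strictly_pos <- setdiff(param_names(),
                          c("k_sink", "k_resyn", "k_pool_loss",
                            "adp_threshold", "hyd_pool_slope", "head_form"))
  for (nm in strictly_pos) {
    if (p[[nm]] <= 0) stop("parameter ", nm, " must be > 0", call. = FALSE)
  }
  for (nm in c("k_sink", "k_resyn", "k_pool_loss", "adp_threshold",
               "hyd_pool_slope")) {
    if (p[[nm]] < 0) stop("parameter ", nm, " must be >= 0", call. = FALSE)
  }
  if (!p$head_form %in% c(1, 2)) {
    stop("head_form must be 1 (multiplicative) or 2 (ternary complex)",
         call. = FALSE)
  }
  if (p$r_pgi < 1) stop("r_pgi must be >= 1", call. = FALSE)
  if (p$water_frac <= 0 || p$water_frac > 1) {
    stop("water_frac must be in (0, 1]", call. = FALSE)
  }
  if (p$atp_init > p$a_pool_init) {
    stop("atp_init must not exceed a_pool_init", call. = FALSE)
  }
  structure(p, class = "glycodyn_params")
}

#' @export
print.glycodyn_params <- function(x, ...) {
  cat("<glycodyn_params> (", length(x), " parameters)\n", sep = "")
  df <- data.frame(value = unlist(x))
  print(df)
  invisible(x)
}

#' Read / write a flat key-value parameter file
#'
#' Parameter files are flat YAML maps (one `key: value` per line). Unknown
#' keys are rejected so that typos cannot silently fall back to defaults.
#'
#' @param path file path.
#' @param validate validate as a complete parameter set (default `TRUE`).
#'   With `validate = FALSE` the raw named list is returned.
#' @return A `glycodyn_params` (or named list when `validate = FALSE`).
#' @seealso [cell_parameters()]
#' @export
read_parameter_file <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw))) {
    stop("parameter file must be a flat key: value map", call. = FALSE)
  }
  unknown <- setdiff(names(raw), param_names())
  if (length(unknown)) {
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  raw <- lapply(raw, as.numeric)
  if (validate) validate_cell_parameters(raw) else raw
}

#' @param p a `glycodyn_params` object (or complete named list).
#' @rdname read_parameter_file
#' @export
write_parameter_file <- function(p, path) {
  p <- validate_cell_parameters(p)
  yaml::write_yaml(lapply(unclass(p), function(x) unname(x)), path,
                   precision = 15)
  invisible(path)
}
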