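#' Simulate noisy observable tables from the model
#'
#' Generates synthetic measurement tables by simulating a set of
#' suspension scenarios at known ("true") parameters, sampling the
#' classical observables (FBP, ATP, cumulative glucose uptake,
#' cumulative lactate, O2 consumption rate) at given instants, and
#' adding multiplicative Gaussian noise. Used to validate the parameter
#' estimation machinery by parameter recovery.
#'
#' @param p_true the generating [cell_parameters()].
#' @param scenarios named list of [suspension_scenario()] objects.
#' @param noise relative standard deviation of the multiplicative noise
#'   (0 = exact model output).
#' @param seed RNG seed; recorded in the result's `seed` attribute so
#'   tables are bitwise reproducible.
#' @param times sampling instants, s (default: the classical grid
#'   5–300 s clipped to each scenario's duration).
#' @param n_replicates replicate measurements per instant.
#' @param observables which observables to sample.
#' @return Tibble with `scenario`, `replicate`, `time`, `observable`,
#'   `value`, `true_value`.
#' @export
generate_synthetic_dataset <- function(p_true, scenarios, noise = 0.05,
                                       seed = 1, times = NULL,
                                       n_replicates = 1,
                                       observables = c("fbp", "atp",
                                                       "cum_glc",
                                                       "cum_lac",
                                                       "o2_rate")) {
  stopifnot(noise >= 0, n_replicates >= 1)
  if (is.null(names(scenarios)) || any(names(scenarios) == "")) {
    stop("scenarios must be a named list", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rows <- purrr::imap(scenarios, function(scn, nm) {
    tt <- times %||% c(5, 10, 20, 30, 60, 90, 120, 180, 240, 300)
    tt <- tt[tt <= scn$duration]
    sim <- run_suspension(scn, p_true)
    vals <- purrr::map(observables, function(ob)
      observable_at(sim, ob, tt))
    names(vals) <- observables
    truth <- tidyr::pivot_longer(
      tibble::tibble(time = tt, !!!vals), -"time",
      names_to = "observable", values_to = "true_value")
    truth <- truth[rep(seq_len(nrow(truth)), n_replicates), ]
    truth$replicate <- rep(seq_len(n_replicates),
                           each = nrow(truth) / n_replicates)
    truth$scenario <- nm
    truth$value <- truth$true_value *
      (1 + noise * stats::rnorm(nrow(truth)))
    truth[, c("scenario", "replicate", "time", "observable", "value",
              "true_value")]
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  attr(out, "noise") <- noise
  out
}

observable_at <- function(sim, observable, t) {
  col <- switch(observable,
                fbp = "fbp", atp = "atp", cum_glc = "cum_glc",
                cum_lac = "cum_lac", o2_rate = "j_o2",
                stop("unknown observable: ", observable, call. = FALSE))
  stats::approx(sim$time, sim[[col]], xout = t)$y
}

simulate_observables <- function(p, scenarios, data) {
  out <- numeric(nrow(data))
  for (nm in unique(data$scenario)) {
    sim <- run_suspension(scenarios[[nm]], p)
    for (ob in unique(data$observable[data$scenario == nm])) {
      sel <- data$scenario == nm & data$observable == ob
      out[sel] <- observable_at(sim, ob, data$time[sel])
    }
  }
  out
}

#' Fit model parameters to observable tables
#'
#' Weighted least squares over simulated-versus-measured observables,
#' with weights `1 / scale^2` per observable type (scale = mean absolute
#' measured value), so contents (µM) and rates (µM/s) contribute
#' comparably. Optimization is bounded L-BFGS-B on log-parameters with
#' deterministic multistart.
#'
#' @param data observable table as produced by
#'   [generate_synthetic_dataset()] (columns `scenario`, `time`,
#'   `observable`, `value`).
#' @param scenarios named list of [suspension_scenario()] covering every
#'   scenario in `data`.
#' @param p_init starting [cell_parameters()].
#' @param free character vector of parameter names to fit (empty:
#'   returns `p_init` with the objective of the pure simulation).
#' @param lower,upper named bounds for the free parameters (defaults:
#'   `p_init / 50` and `p_init * 50`).
#' @param n_starts number of multistart runs (start 1 = `p_init`, the
#'   rest log-normally jittered; deterministic given `seed`).
#' @param seed RNG seed for the multistart jitter.
#' @param maxit L-BFGS-B iteration cap per start.
#' @param flat_tol relative objective change below which a parameter
#'   direction is flagged as non-identifiable.
#' @return List of class `glycodyn_fit`: `params` (fitted set),
#'   `objective`, `free`, `starts` (per-start tibble), `flat`
#'   (character vector of non-identifiable parameters, with a warning),
#'   `data`, `scenarios`, `weights`.
#' @export
fit_parameters <- function(data, scenarios, p_init, free,
                           lower = NULL, upper = NULL, n_starts = 8,
                           seed = 1, maxit = 150, flat_tol = 1e-6) {
  stopifnot(is.data.frame(data),
            all(c("scenario", "time", "observable", "value") %in%
                  names(data)))
  missing_scn <- setdiff(unique(data$scenario), names(scenarios))
  if (length(missing_scn)) {
    stop("no scenario definition for: ",
         paste(missing_scn, collapse = ", "), call. = FALSE)
  }
  p_init <- validate_cell_parameters(p_init)
  data <- as.data.frame(data)
  rownames(data) <- NULL
  scales <- tapply(abs(data$value), data$observable, mean)
  scales[scales <= 0] <- 1
  w <- as.numeric(1 / scales[data$observable]^2)
  obj_p <- function(p) {
    pred <- try(simulate_observables(p, scenarios, data), silent = TRUE)
    if (inherits(pred, "try-error")) return(1e12)
    sum(w * (pred - data$value)^2)
  }
  if (length(free) == 0) {
    return(structure(list(params = p_init, objective = obj_p(p_init),
                          free = character(0),
                          starts = tibble::tibble(), flat = character(0),
                          data = data, scenarios = scenarios,
                          weights = w),
                     class = "glycodyn_fit"))
  }
  bad <- setdiff(free, param_names())
  if (length(bad)) stop("unknown free parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  th0 <- log(unlist(p_init[free]))
  lo <- hi <- numeric(length(free))
  names(lo) <- names(hi) <- free
  for (nm in free) {
    lo[nm] <- log(if (!is.null(lower[[nm]])) lower[[nm]] else
      p_init[[nm]] / 50)
    hi[nm] <- log(if (!is.null(upper[[nm]])) upper[[nm]] else
      p_init[[nm]] * 50)
  }
  obj_theta <- function(theta) {
    pl <- as.list(exp(theta))
    names(pl) <- free
    p <- try(do.call(cell_parameters, c(pl, list(base = p_init))),
             silent = TRUE)
    if (inherits(p, "try-error")) return(1e12)
    obj_p(p)
  }
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  starts <- list()
  best <- NULL
  for (i in seq_len(n_starts)) {
    th_start <- if (i == 1) th0 else
      pmin(pmax(th0 + stats::rnorm(length(th0), 0, 0.3), lo), hi)
    fit <- try(stats::optim(th_start, obj_theta, method = "L-BFGS-B",
                            lower = lo, upper = hi,
                            control = list(maxit = maxit)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    starts[[i]] <- tibble::tibble(start = i, objective = fit$value,
                                  convergence = fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed",
                          call. = FALSE)
  pl <- as.list(exp(best$par))
  names(pl) <- free
  p_fit <- do.call(cell_parameters, c(pl, list(base = p_init)))
  # flat-direction (non-identifiability) check, relative to the total
  # weighted sum of squares of the data
  f0 <- best$value
  ss_scale <- sum(w * data$value^2)
  flat <- character(0)
  for (nm in free) {
    th <- best$par
    th[nm] <- th[nm] + log(1.1)
    df <- abs(obj_theta(th) - f0)
    if (df <= flat_tol * max(ss_scale, 1e-12)) flat <- c(flat, nm)
  }
  if (length(flat)) {
    warning("objective is flat in parameter direction(s): ",
            paste(flat, collapse = ", "),
            " (structurally non-identifiable from these data)",
            call. = FALSE)
  }
  structure(list(params = p_fit, objective = f0, free = free,
                 starts = dplyr::bind_rows(starts), flat = flat,
                 data = data, scenarios = scenarios, weights = w),
            class = "glycodyn_fit")
}

#' @export
print.glycodyn_fit <- function(x, ...) {
  cat("<glycodyn_fit> ", length(x$free), " free parameter(s), objective ",
      format(x$objective), "\n", sep = "")
  if (length(x$free)) {
    print(unlist(x$params[x$free]))
  }
  invisible(x)
}

#' Parameter-ensemble uncertainty analysis
#'
#' Builds a parameter ensemble around a fit and propagates it to
#' predictive bands for every observable. Two methods:
#' \describe{
#'   \item{`"laplace"`}{Gaussian approximation: finite-difference
#'     Jacobian of the residuals at the optimum gives a parameter
#'     covariance scaled by the residual variance; the ensemble is
#'     sampled from it. Fast; zero-width for noiseless data.}
#'   \item{`"bootstrap"`}{residual bootstrap: resample relative
#'     residuals, refit for each draw. Slow but assumption-light.}
#' }
#'
#' @param fit a [fit_parameters()] result with at least one free
#'   parameter.
#' @param n_draws ensemble size.
#' @param seed RNG seed.
#' @param method `"laplace"` or `"bootstrap"`.
#' @param band_times time grid for the predictive bands (default: the
#'   data's time points).
#' @param level band coverage level (default 0.95).
#' @return List of class `glycodyn_uq`: `ensemble` (tibble of parameter
#'   draws), `bands` (tibble `scenario`, `observable`, `time`, `lo`,
#'   `fit`, `hi`), `method`, `level`.
#' @export
uncertainty_ensemble <- function(fit, n_draws = 100, seed = 1,
                                 method = c("laplace", "bootstrap"),
                                 band_times = NULL, level = 0.95) {
  stopifnot(inherits(fit, "glycodyn_fit"), n_draws >= 1)
  method <- match.arg(method)
  if (!length(fit$free)) stop("fit has no free parameters",
                              call. = FALSE)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  data <- fit$data
  free <- fit$free
  th_hat <- log(unlist(fit$params[free]))
  pred_hat <- simulate_observables(fit$params, fit$scenarios, data)
  if (n_draws == 1) {
    draws <- matrix(th_hat, nrow = 1,
                    dimnames = list(NULL, free))
  } else if (method == "laplace") {
    # weighted Jacobian of predictions wrt log-parameters
    jac <- matrix(0, nrow(data), length(free))
    h <- 1e-4
    for (j in seq_along(free)) {
      th <- th_hat
      th[j] <- th[j] + h
      pl <- as.list(exp(th)); names(pl) <- free
      p <- do.call(cell_parameters, c(pl, list(base = fit$params)))
      jac[, j] <- (simulate_observables(p, fit$scenarios, data) -
                     pred_hat) / h
    }
    wj <- sqrt(fit$weights) * jac
    dof <- max(1, nrow(data) - length(free))
    s2 <- sum(fit$weights * (data$value - pred_hat)^2) / dof
    cov_th <- tryCatch(s2 * solve(crossprod(wj)),
                       error = function(e) {
                         diag(1e-12, length(free))
                       })
    ch <- chol(cov_th + diag(1e-14, length(free)))
    z <- matrix(stats::rnorm(n_draws * length(free)), n_draws)
    draws <- sweep(z %*% ch, 2, th_hat, "+")
    colnames(draws) <- free
  } else {
    rel_res <- (data$value - pred_hat) / pmax(abs(pred_hat), 1e-12)
    draws <- matrix(NA_real_, n_draws, length(free),
                    dimnames = list(NULL, free))
    for (b in seq_len(n_draws)) {
      d_b <- data
      d_b$value <- pred_hat *
        (1 + sample(rel_res, nrow(data), replace = TRUE))
      fit_b <- fit_parameters(d_b, fit$scenarios, fit$params, free,
                              n_starts = 1, maxit = 60)
      draws[b, ] <- log(unlist(fit_b$params[free]))
    }
  }
  # predictive bands
  tt <- band_times %||% sort(unique(data$time))
  band_rows <- list()
  sims <- apply(draws, 1, function(th) {
    pl <- as.list(exp(th)); names(pl) <- free
    p <- do.call(cell_parameters, c(pl, list(base = fit$params)))
    purrr::imap(fit$scenarios, function(scn, nm) {
      sim <- run_suspension(scn, p)
      obs <- unique(data$observable[data$scenario == nm])
      purrr::map(stats::setNames(obs, obs), function(ob)
        observable_at(sim, ob, tt[tt <= scn$duration]))
    })
  })
  for (nm in names(fit$scenarios)) {
    obs <- unique(data$observable[data$scenario == nm])
    tts <- tt[tt <= fit$scenarios[[nm]]$duration]
    for (ob in obs) {
      mat <- vapply(sims, function(s) s[[nm]][[ob]],
                    numeric(length(tts)))
      mat <- matrix(mat, nrow = length(tts))
      a <- (1 - level) / 2
      band_rows[[length(band_rows) + 1]] <- tibble::tibble(
        scenario = nm, observable = ob, time = tts,
        lo = apply(mat, 1, stats::quantile, probs = a),
        fit = apply(mat, 1, stats::median),
        hi = apply(mat, 1, stats::quantile, probs = 1 - a))
    }
  }
  structure(list(ensemble = tibble::as_tibble(as.data.frame(draws)),
                 bands = dplyr::bind_rows(band_rows), method = method,
                 level = level),
            class = "glycodyn_uq")
}
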