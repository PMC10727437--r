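#' Room-model parameter set
#'
#' The Room thermal performance curve is a four-parameter piecewise Gaussian:
#' peak height `p_max` (per day) at the optimal temperature `t_opt` (degrees
#' C), with separate shape coefficients `a` below and `b` above the optimum.
#' Both branches meet at `p_max` so the curve is continuous, unimodal, and
#' defined at all temperatures.
#'
#' @param p_max Peak growth rate, per day (> 0).
#' @param t_opt Optimal temperature, degrees C (finite).
#' @param a Rise-side shape coefficient, applied below `t_opt` (> 0).
#' @param b Fall-side shape coefficient, applied above `t_opt` (> 0).
#' @return An object of class `room_params`.
#' @export
room_params <- function(p_max, t_opt, a, b) {
  stopifnot(is.finite(p_max), is.finite(t_opt), is.finite(a), is.finite(b))
  if (p_max <= 0) stop("p_max must be > 0", call. = FALSE)
  if (a <= 0) stop("a must be > 0", call. = FALSE)
  if (b <= 0) stop("b must be > 0", call. = FALSE)
  structure(list(p_max = p_max, t_opt = t_opt, a = a, b = b),
            class = "room_params")
}

#' @export
print.room_params <- function(x, ...) {
  cat(sprintf(
    "Room TPC parameters: p_max = %.4g d^-1, t_opt = %.4g degC, a = %.4g, b = %.4g\n",
    x$p_max, x$t_opt, x$a, x$b))
  invisible(x)
}

#' Evaluate the Room thermal performance curve
#'
#' `P(T) = p_max * exp(-a (T - t_opt)^2)` for `T <= t_opt` and
#' `p_max * exp(-b (T - t_opt)^2)` for `T > t_opt`. Strictly positive and
#' continuous at the optimum, where both branches equal `p_max`.
#'
#' @param temperature Temperature(s), degrees C; any finite value.
#' @param params A [room_params()] object.
#' @return Predicted growth rate(s), per day, same length as `temperature`.
#' @examples
#' p <- room_params(0.25, 24.5, 0.0155, 0.00344)
#' room_performance(c(14.5, 24.5, 34.5), p)
#' @export
room_performance <- function(temperature, params) {
  stopifnot(inherits(params, "room_params"))
  d2 <- (temperature - params$t_opt)^2
  shape <- ifelse(temperature <= params$t_opt,
                  exp(-params$a * d2), exp(-params$b * d2))
  params$p_max * shape
}

# shape with unit peak; p_max enters separately so the study-level peak
# multiplier can be applied without re-evaluating the exponentials
room_shape <- function(temperature, params) {
  room_performance(temperature, params) / params$p_max
}

#' Joint negative log-likelihood at fixed study effects
#'
#' Gaussian observation model: record i in study j has
#' `rgr_ij ~ N(p_max * exp(u_j) * shape(T_ij), sigma_resid)`, where `u_j` is
#' the study-level offset on log peak height. The returned value is the sum
#' of the observation negative log densities plus, when `sigma_study > 0`,
#' the `N(0, sigma_study)` negative log density of each offset (the joint
#' NLL of data and effects). With `sigma_study = 0` all offsets must be zero
#' and no offset term is added.
#'
#' @param table A `record_table` (needs `study_id`, `temperature`, `rgr`).
#' @param params A [room_params()] object.
#' @param sigma_resid Residual SD of RGR, per day (> 0).
#' @param sigma_study SD of the study effect on log peak height (>= 0).
#' @param study_effects Named numeric vector of offsets, one per `study_id`
#'   present in `table`.
#' @return The joint negative log-likelihood (scalar).
#' @export
negative_log_likelihood <- function(table, params, sigma_resid, sigma_study,
                                    study_effects) {
  if (!is.finite(sigma_resid) || sigma_resid <= 0) {
    stop("sigma_resid must be > 0", call. = FALSE)
  }
  if (sigma_study < 0) stop("sigma_study must be >= 0", call. = FALSE)
  studies <- unique(table$study_id)
  if (!all(studies %in% names(study_effects))) {
    stop("every study_id needs an offset in `study_effects`", call. = FALSE)
  }
  u <- study_effects[table$study_id]
  mu <- params$p_max * exp(u) * room_shape(table$temperature, params)
  nll <- -sum(stats::dnorm(table$rgr, mu, sigma_resid, log = TRUE))
  if (sigma_study > 0) {
    nll <- nll - sum(stats::dnorm(study_effects[studies], 0, sigma_study,
                                  log = TRUE))
  } else if (any(study_effects[studies] != 0)) {
    stop("sigma_study = 0 requires all study effects to be zero",
         call. = FALSE)
  }
  nll
}

#' Integrated (marginal) negative log-likelihood
#'
#' Marginalizes the study-level offset out of the conditional likelihood by
#' adaptive Gauss-Hermite quadrature: for each study j,
#' `L_j = integral N(u; 0, sigma_study) * prod_i N(rgr_ij; p_max e^u
#' shape(T_ij), sigma_resid) du`. The integrand is first located by a 1-D
#' search for its mode and Laplace scale, then evaluated at `n_nodes`
#' Hermite nodes shifted to the mode and scaled to the local curvature, so
#' the rule stays accurate even when the conditional likelihood is much
#' sharper than the random-effect distribution. Each study's sum is
#' computed in log space with a max shift, so the result is finite for any
#' finite parameters. `sigma_study = 0` degenerates exactly to
#' [negative_log_likelihood()] with all offsets zero.
#'
#' @inheritParams negative_log_likelihood
#' @param n_nodes Number of quadrature nodes (>= 3; odd recommended so the
#'   mode is a node). Default 21.
#' @return `-sum_j log L_j` (scalar).
#' @export
integrated_nll <- function(table, params, sigma_resid, sigma_study,
                           n_nodes = 21) {
  if (!is.finite(sigma_resid) || sigma_resid <= 0) {
    stop("sigma_resid must be > 0", call. = FALSE)
  }
  if (n_nodes < 3) stop("n_nodes must be >= 3", call. = FALSE)
  if (sigma_study == 0) {
    u0 <- stats::setNames(rep(0, length(unique(table$study_id))),
                          unique(table$study_id))
    return(negative_log_likelihood(table, params, sigma_resid, 0, u0))
  }
  gh <- pracma::gaussHermite(n_nodes)
  shape <- room_shape(table$temperature, params)
  split_idx <- split(seq_len(nrow(table)), table$study_id)
  total <- 0
  for (idx in split_idx) {
    y <- table$rgr[idx]
    s <- shape[idx]
    # log integrand: conditional log-likelihood + random-effect log density
    lg <- function(u) {
      sum(stats::dnorm(y, params$p_max * exp(u) * s, sigma_resid,
                       log = TRUE)) +
        stats::dnorm(u, 0, sigma_study, log = TRUE)
    }
    span <- 10 * sigma_study + 5
    opt <- stats::optimize(lg, interval = c(-span, span), maximum = TRUE,
                           tol = 1e-10)
    u0 <- opt$maximum
    d <- 1e-4 * max(1, abs(u0))
    h <- (lg(u0 - d) - 2 * opt$objective + lg(u0 + d)) / d^2
    tau <- if (is.finite(h) && h < 0) 1 / sqrt(-h) else sigma_study
    u_nodes <- u0 + sqrt(2) * tau * gh$x
    lt <- log(sqrt(2) * tau) + log(gh$w) + gh$x^2 +
      vapply(u_nodes, lg, numeric(1))
    m <- max(lt)
    total <- total - (m + log(sum(exp(lt - m))))
  }
  total
}

#' Fitting configuration
#'
#' @param n_quadrature_nodes Gauss-Hermite nodes for the marginal likelihood
#'   (positive odd integer, default 21).
#' @param n_starts Number of multi-start optimizations (default 8).
#' @param seed Integer seed for the deterministic start-point jitter.
#' @param bounds Named list of `c(lower, upper)` box constraints for
#'   `p_max`, `t_opt`, `a`, `b`, `sigma_resid`, `sigma_study`.
#' @param factr `optim` L-BFGS-B convergence tolerance factor.
#' @param maxit Maximum iterations per start.
#' @param use_weights Weight records by inverse reported variance where an SD
#'   is available (default `FALSE`; reserved, not used by the fitter yet).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_quadrature_nodes = 21, n_starts = 8, seed = 1,
                       bounds = list(p_max = c(1e-4, 2), t_opt = c(0, 50),
                                     a = c(1e-6, 1), b = c(1e-6, 1),
                                     sigma_resid = c(1e-5, 5),
                                     sigma_study = c(1e-5, 5)),
                       factr = 1e7, maxit = 500, use_weights = FALSE) {
  stopifnot(n_quadrature_nodes >= 3, n_starts >= 1)
  structure(list(n_quadrature_nodes = n_quadrature_nodes,
                 n_starts = n_starts, seed = seed, bounds = bounds,
                 factr = factr, maxit = maxit, use_weights = use_weights),
            class = "fit_config")
}

# parameter vector <-> transformed optimizer scale
# theta = (log p_max, t_opt, log a, log b, log sigma_resid, log sigma_study)
theta_to_par <- function(theta) {
  list(params = room_params(exp(theta[1]), theta[2], exp(theta[3]),
                            exp(theta[4])),
       sigma_resid = exp(theta[5]), sigma_study = exp(theta[6]))
}

#' Fit the Room model to one species by marginal maximum likelihood
#'
#' Minimizes [integrated_nll()] over `(log p_max, t_opt, log a, log b,
#' log sigma_resid, log sigma_study)` with box-constrained L-BFGS-B from
#' multiple deterministic jittered starts. The optimal temperature start is
#' anchored at the temperature of the largest observed RGR and the peak
#' height start at that RGR value. The best start (lowest NLL, ties broken
#' by start index) wins; the result is reproducible for a fixed
#' `config$seed`.
#'
#' @param table A `record_table` for a single species with at least two
#'   distinct temperatures.
#' @param config A [fit_config()].
#' @return A list of class `tpc_fit`: `params` ([room_params()]),
#'   `variance` (`sigma_resid`, `sigma_study`), `loglik` (maximized
#'   integrated log-likelihood), `converged`, `n_obs`, `n_studies`,
#'   `per_start` diagnostics tibble, and the `config` echo.
#' @export
fit_tpc <- function(table, config = fit_config()) {
  if (nrow(table) == 0) stop("empty record table", call. = FALSE)
  if (length(unique(table$species)) > 1) {
    stop("fit_tpc expects a single species; got: ",
         paste(unique(table$species), collapse = ", "), call. = FALSE)
  }
  if (length(unique(table$temperature)) < 2) {
    stop("need at least two distinct temperature schemes", call. = FALSE)
  }
  b <- config$bounds
  lower <- c(log(b$p_max[1]), b$t_opt[1], log(b$a[1]), log(b$b[1]),
             log(b$sigma_resid[1]), log(b$sigma_study[1]))
  upper <- c(log(b$p_max[2]), b$t_opt[2], log(b$a[2]), log(b$b[2]),
             log(b$sigma_resid[2]), log(b$sigma_study[2]))

  objective <- function(theta) {
    p <- theta_to_par(theta)
    integrated_nll(table, p$params, p$sigma_resid, p$sigma_study,
                   n_nodes = config$n_quadrature_nodes)
  }

  # data-anchored centre of the start cloud
  i_max <- which.max(table$rgr)
  t0 <- min(max(table$temperature[i_max], b$t_opt[1] + 1), b$t_opt[2] - 1)
  p0 <- max(table$rgr[i_max], 1e-3)
  r0 <- max(stats::sd(table$rgr) / 2, 1e-3)
  centre <- c(log(p0), t0, log(0.01), log(0.005), log(r0), log(0.1))

  starts <- with_local_seed(config$seed, {
    lapply(seq_len(config$n_starts), function(k) {
      if (k == 1) return(centre)
      jitter <- c(stats::rnorm(1, 0, 0.2), stats::rnorm(1, 0, 2),
                  stats::rnorm(1, 0, 0.7), stats::rnorm(1, 0, 0.7),
                  stats::rnorm(1, 0, 0.3), stats::rnorm(1, 0, 0.5))
      pmin(pmax(centre + jitter, lower + 1e-8), upper - 1e-8)
    })
  })

  runs <- lapply(seq_along(starts), function(k) {
    fit <- tryCatch(
      stats::optim(starts[[k]], objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = config$factr,
                                  maxit = config$maxit)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(list(start = k, nll = Inf, convergence = NA_integer_,
                  theta = rep(NA_real_, 6)))
    }
    list(start = k, nll = fit$value, convergence = fit$convergence,
         theta = fit$par)
  })

  per_start <- tibble::tibble(
    start = vapply(runs, `[[`, integer(1), "start"),
    nll = vapply(runs, `[[`, numeric(1), "nll"),
    convergence = vapply(runs, `[[`, integer(1), "convergence")
  )
  ok <- which(is.finite(per_start$nll) & per_start$convergence == 0L)
  if (!length(ok)) {
    stop("no optimization start converged; diagnostics:\n",
         paste(utils::capture.output(print(per_start)), collapse = "\n"),
         call. = FALSE)
  }
  best <- ok[order(per_start$nll[ok], per_start$start[ok])][1]
  p <- theta_to_par(runs[[best]]$theta)

  structure(list(
    params = p$params,
    variance = list(sigma_resid = p$sigma_resid,
                    sigma_study = p$sigma_study),
    loglik = -per_start$nll[best],
    converged = TRUE,
    n_obs = nrow(table),
    n_studies = length(unique(table$study_id)),
    species = unique(table$species),
    per_start = per_start,
    config = config
  ), class = "tpc_fit")
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat(sprintf("Room TPC fit (%s): %d records, %d studies\n",
              x$species, x$n_obs, x$n_studies))
  print(x$params)
  cat(sprintf("  sigma_resid = %.4g, sigma_study = %.4g, logLik = %.3f\n",
              x$variance$sigma_resid, x$variance$sigma_study, x$loglik))
  invisible(x)
}

# run expr with a temporary RNG state so callers' streams are untouched
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Serialize / restore a fit as JSON
#'
#' The JSON fit file is the handoff format between the fitting and
#' projection stages: parameter names and values, variance components,
#' log-likelihood, and a config echo. Interval fields are reserved but
#' empty (the fitter reports point estimates only).
#'
#' @param fit A `tpc_fit`.
#' @param path Output / input JSON path.
#' @return `write_fit_json` returns `path` invisibly; `read_fit_json`
#'   returns a list with `params` as a [room_params()] object.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    species = fit$species,
    params = fit$params[c("p_max", "t_opt", "a", "b")],
    variance = fit$variance,
    loglik = fit$loglik,
    converged = fit$converged,
    n_obs = fit$n_obs,
    n_studies = fit$n_studies,
    confidence_intervals = NULL,
    config = list(n_quadrature_nodes = fit$config$n_quadrature_nodes,
                  n_starts = fit$config$n_starts, seed = fit$config$seed)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$params <- room_params(obj$params$p_max, obj$params$t_opt,
                            obj$params$a, obj$params$b)
  obj
}
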