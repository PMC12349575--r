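#' Monte-Carlo one-at-a-time parameter sensitivity
#'
#' Perturbs a single model parameter uniformly within +/-20% of its
#' nominal value, runs the steady-state forward model for each draw with
#' all other parameters at nominal, and summarizes the spread of the
#' simulated sweat cortisol as a coefficient of variation (CV, percent).
#' Because the surface readout is exactly proportional to the
#' free-cortisol fraction `alpha`, the CV for `alpha` converges to the CV
#' of the uniform perturbation itself, `0.2/sqrt(3)` (about 11.55%), as
#' the number of draws grows.
#'
#' @param parameter_name Name of the perturbable [transport_parameters()]
#'   field. Its nominal value in `p` must be non-zero (for the enzyme
#'   turnover rate, which has no literature value, supply a nominal, e.g.
#'   the mid-point of the personalization bounds).
#' @param p Nominal [transport_parameters()].
#' @param d A [discretization()] object.
#' @param n_samples Number of uniform draws (default 100).
#' @param seed RNG seed for reproducibility.
#' @param C_blood Operating-point blood cortisol \[nmol L^-1\]
#'   (default 355, the estimation initialization value).
#' @param u_sweat_n Operating-point normalized sweat velocity (default 1).
#' @param range_fraction Half-width of the uniform perturbation as a
#'   fraction of nominal (default 0.2, i.e. +/-20%).
#' @param method Forward-solver route (see [simulate_steady_state()]).
#' @return An object of class `sensitivity_result`: `parameter_name`,
#'   `n_samples`, `cv_percent`, a `samples` tibble (drawn value, output
#'   in nmol/L, convergence flag), and `seed`.
#' @examples
#' p <- transport_parameters()
#' run_sensitivity("alpha", p, discretization(), n_samples = 20, seed = 1)
#' @export
run_sensitivity <- function(parameter_name, p, d = discretization(),
                            n_samples = 100L, seed = 1L,
                            C_blood = 355, u_sweat_n = 1,
                            range_fraction = 0.2,
                            method = c("direct", "transient")) {
  stopifnot(inherits(p, "transport_parameters"))
  method <- match.arg(method)
  if (!parameter_name %in% names(p)) {
    stop("unknown parameter: ", parameter_name, call. = FALSE)
  }
  nominal <- p[[parameter_name]]
  if (nominal == 0) {
    stop(sprintf(paste0("nominal value of '%s' is zero; supply a non-zero ",
                        "nominal (e.g. via transport_parameters()) before ",
                        "perturbing it"), parameter_name), call. = FALSE)
  }
  set.seed(seed)
  draws <- stats::runif(n_samples, (1 - range_fraction) * nominal,
                        (1 + range_fraction) * nominal)
  out <- numeric(n_samples)
  ok <- logical(n_samples)
  for (i in seq_len(n_samples)) {
    pp <- do.call(update_parameters,
                  c(list(p), stats::setNames(list(draws[i]), parameter_name)))
    res <- simulate_steady_state(C_blood, u_sweat_n, pp, d, method = method)
    out[i] <- sweat_surface_nmol_l(res)
    ok[i] <- res$converged
  }
  if (any(!ok)) {
    warning(sum(!ok), " non-converged simulation(s) excluded")
    if (mean(!ok) > 0.1) {
      stop("more than 10% of sensitivity simulations failed to converge",
           call. = FALSE)
    }
  }
  kept <- out[ok]
  cv <- 100 * stats::sd(kept) / mean(kept)
  structure(list(parameter_name = parameter_name,
                 n_samples = n_samples,
                 cv_percent = cv,
                 samples = tibble::tibble(value = draws,
                                          output_nmol_l = out,
                                          converged = ok),
                 seed = seed),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Sensitivity of sweat cortisol to '%s': CV = %.3g%% (n = %d, seed = %s)\n",
              x$parameter_name, x$cv_percent, x$n_samples, x$seed))
  invisible(x)
}

#' Run the sensitivity analysis over several parameters
#'
#' @param parameters Character vector of parameter names; defaults to all
#'   perturbable physiological parameters with non-zero nominal value.
#' @inheritParams run_sensitivity
#' @return A list of `sensitivity_result` objects, one per parameter.
#' @examples
#' p <- transport_parameters()
#' sw <- sensitivity_sweep(c("alpha", "K_wc"), p, n_samples = 20, seed = 1)
#' rank_parameters(sw)
#' @export
sensitivity_sweep <- function(parameters = NULL, p, d = discretization(),
                              n_samples = 100L, seed = 1L,
                              C_blood = 355, u_sweat_n = 1,
                              method = c("direct", "transient")) {
  method <- match.arg(method)
  if (is.null(parameters)) {
    parameters <- names(p)[vapply(p, function(v) v != 0, logical(1))]
  }
  lapply(stats::setNames(parameters, parameters), function(nm) {
    run_sensitivity(nm, p, d, n_samples = n_samples, seed = seed,
                    C_blood = C_blood, u_sweat_n = u_sweat_n,
                    method = method)
  })
}

#' Rank parameters by output coefficient of variation
#'
#' Orders parameters by descending CV and keeps those whose CV exceeds a
#' threshold; the retained set defines the parameters eligible for
#' personalization in the inner estimation loop.
#'
#' @param results A list of `sensitivity_result` objects.
#' @param threshold_percent CV threshold in percent (default 0.1).
#' @return Character vector of parameter names in descending CV order,
#'   with the CVs (percent) as names attribute via `attr(, "cv_percent")`.
#' @export
rank_parameters <- function(results, threshold_percent = 0.1) {
  if (length(results) == 0L) stop("empty results", call. = FALSE)
  cv <- vapply(results, function(r) r$cv_percent, numeric(1))
  nm <- vapply(results, function(r) r$parameter_name, character(1))
  ord <- order(cv, decreasing = TRUE)
  keep <- cv[ord] > threshold_percent
  out <- nm[ord][keep]
  attr(out, "cv_percent") <- unname(cv[ord][keep])
  out
}
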