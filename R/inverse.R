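#' Settings for the double-loop blood cortisol estimation
#'
#' @param C_blood_init Initialization of the blood cortisol estimate
#'   \[nmol L^-1\]. The default 355 is the pre-surgery cohort average blood
#'   cortisol used to seed the optimization.
#' @param stop_criterion Squared-error stopping threshold on the sweat
#'   concentration fit \[nmol^2 L^-2\].
#' @param max_outer_iter Maximum outer-loop iterations.
#' @param personalized_params Character vector of parameter names eligible
#'   for the inner personalization loop. Default `"alpha"`: the
#'   free-cortisol fraction dominates the model-output sensitivity by an
#'   order of magnitude, and is the parameter most altered by surgery and
#'   dexamethasone.
#' @param param_bounds Named list of `c(low, high)` box constraints for the
#'   personalized parameters. Defaults: `alpha` in \[0.01, 0.30\] (spans
#'   the literature 5% baseline and post-surgical elevations), `S_enzyme`
#'   in \[0, 0.01\] s^-1.
#' @param method Forward-solver route passed to [simulate_steady_state()];
#'   `"direct"` (default) is exact for the linear steady state and fast in
#'   the optimization loops.
#' @return An object of class `estimation_settings`.
#' @examples
#' estimation_settings(personalized_params = c("alpha", "S_enzyme"))
#' @export
estimation_settings <- function(C_blood_init = 355,
                                stop_criterion = 0.01,
                                max_outer_iter = 50L,
                                personalized_params = "alpha",
                                param_bounds = list(alpha = c(0.01, 0.30),
                                                    S_enzyme = c(0, 0.01)),
                                method = c("direct", "transient")) {
  method <- match.arg(method)
  stopifnot(is.numeric(C_blood_init), C_blood_init >= 0,
            is.numeric(stop_criterion), stop_criterion > 0,
            is.numeric(max_outer_iter), max_outer_iter >= 1)
  known <- names(formals(transport_parameters))
  bad <- setdiff(personalized_params, known)
  if (length(bad)) {
    stop("personalized_params not transport parameters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (nm in personalized_params) {
    b <- param_bounds[[nm]]
    if (is.null(b) || length(b) != 2L || !all(is.finite(b)) || b[1L] > b[2L]) {
      stop("param_bounds must give finite ordered bounds for '", nm, "'",
           call. = FALSE)
    }
  }
  structure(list(C_blood_init = C_blood_init,
                 stop_criterion = stop_criterion,
                 max_outer_iter = as.integer(max_outer_iter),
                 personalized_params = personalized_params,
                 param_bounds = param_bounds,
                 method = method),
            class = "estimation_settings")
}

#' Squared sweat-concentration error
#'
#' The scalar objective of the estimation loops:
#' `(C_sweat_meas - C_sweat_model)^2`.
#'
#' @param C_sweat_meas Measured sweat cortisol \[nmol L^-1\].
#' @param C_sweat_model Model-predicted sweat cortisol \[nmol L^-1\].
#' @return Squared error \[nmol^2 L^-2\].
#' @examples
#' sweat_error(10, 7)  # 9
#' @export
sweat_error <- function(C_sweat_meas, C_sweat_model) {
  if (!all(is.finite(C_sweat_meas)) || !all(is.finite(C_sweat_model))) {
    stop("inputs must be finite", call. = FALSE)
  }
  (C_sweat_meas - C_sweat_model)^2
}

#' Construct a single sweat measurement record
#'
#' @param subject_id Opaque subject identifier.
#' @param condition One of `"pre_surgery"`, `"post_no_dexa"`,
#'   `"post_dexa"`.
#' @param C_sweat Sweat cortisol concentration \[nmol L^-1\], >= 0.
#' @param u_sweat_n Normalized sweat velocity (dimensionless, >= 0).
#' @param C_blood_ref Optional reference blood cortisol \[nmol L^-1\]
#'   (present for calibration/validation records; `NA` otherwise).
#' @return A one-row tibble.
#' @examples
#' sweat_measurement("s01", "pre_surgery", 0.74, 1, 355)
#' @export
sweat_measurement <- function(subject_id, condition, C_sweat, u_sweat_n,
                              C_blood_ref = NA_real_) {
  condition <- match.arg(condition, cortisol_conditions())
  stopifnot(is.numeric(C_sweat), C_sweat >= 0,
            is.numeric(u_sweat_n), u_sweat_n >= 0)
  tibble::tibble(subject_id = as.character(subject_id),
                 condition = condition,
                 C_sweat = C_sweat,
                 u_sweat_n = u_sweat_n,
                 C_blood_ref = as.numeric(C_blood_ref))
}

#' Valid clinical condition labels
#'
#' Pre-surgery, post-surgery without dexamethasone, and post-surgery with
#' intra-operative dexamethasone.
#'
#' @return Character vector of condition labels.
#' @export
cortisol_conditions <- function() {
  c("pre_surgery", "post_no_dexa", "post_dexa")
}

forward_sweat <- function(C_blood, u_sweat_n, p, d, method) {
  res <- simulate_steady_state(C_blood, u_sweat_n, p, d, method = method)
  if (!res$converged) {
    stop("forward simulation did not reach steady state", call. = FALSE)
  }
  sweat_surface_nmol_l(res)
}

#' Estimate blood cortisol from a single sweat measurement (outer loop)
#'
#' Inverts the forward transport model for one record: candidate blood
#' cortisol values are iterated from the initialization, each forward
#' simulation producing a predicted sweat cortisol compared against the
#' measurement by the squared error, until the stopping criterion is met.
#' The update is a safeguarded secant step; because the forward map is
#' linear through the origin it converges in very few iterations.
#'
#' @param m A one-row measurement as from [sweat_measurement()] (fields
#'   `C_sweat`, `u_sweat_n`).
#' @param p A [transport_parameters()] object (held fixed; no inner loop).
#' @param s An [estimation_settings()] object.
#' @param d A [discretization()] object.
#' @return An object of class `estimation_result`: `C_blood_hat`
#'   \[nmol L^-1\], `personalized` (named list of the parameter values
#'   used), `error_trace` \[nmol^2 L^-2\] starting at the initialization's
#'   error, `n_iter`, `converged`.
#' @examples
#' p <- transport_parameters()
#' m <- sweat_measurement("s01", "pre_surgery", 0.7, 1)
#' estimate_blood(m, p, estimation_settings(), discretization())
#' @export
estimate_blood <- function(m, p, s = estimation_settings(),
                           d = discretization()) {
  stopifnot(inherits(p, "transport_parameters"),
            inherits(s, "estimation_settings"),
            inherits(d, "discretization"))
  meas <- m$C_sweat[1L]
  u_n <- m$u_sweat_n[1L]
  if (!is.finite(meas) || meas < 0) {
    stop("C_sweat must be a non-negative number", call. = FALSE)
  }
  pers <- as.list(unlist(p)[s$personalized_params])
  if (meas == 0) {
    # the forward map is linear through the origin
    return(new_estimation_result(0, pers, error_trace = 0, n_iter = 0L,
                                 converged = TRUE))
  }
  x0 <- s$C_blood_init
  f0 <- forward_sweat(x0, u_n, p, d, s$method) - meas
  # the trace starts at the initialization's error; the criterion is
  # checked on updated estimates, so at least one update is always taken
  trace <- f0^2
  mod0 <- f0 + meas
  if (mod0 <= 0) {
    warning("forward model output is zero; blood cortisol unidentifiable")
    return(new_estimation_result(x0, pers, trace, 0L, FALSE))
  }
  # proportional first step (exact for a linear map), then secant
  x1 <- max(x0 * meas / mod0, 0)
  converged <- FALSE
  n_iter <- 0L
  best_x <- x0
  best_e <- trace[1L]
  repeat {
    f1 <- forward_sweat(x1, u_n, p, d, s$method) - meas
    trace <- c(trace, f1^2)
    n_iter <- n_iter + 1L
    if (f1^2 < best_e) {
      best_e <- f1^2
      best_x <- x1
    }
    if (f1^2 <= s$stop_criterion) {
      converged <- TRUE
      break
    }
    if (n_iter >= s$max_outer_iter) break
    denom <- f1 - f0
    x2 <- if (denom != 0) x1 - f1 * (x1 - x0) / denom else x1
    if (!is.finite(x2)) x2 <- x1
    if (x2 < 0) {
      warning("negative blood cortisol candidate clipped to 0")
      x2 <- 0
    }
    x0 <- x1; f0 <- f1; x1 <- x2
  }
  new_estimation_result(best_x, pers, trace, n_iter, converged)
}

new_estimation_result <- function(C_blood_hat, personalized, error_trace,
                                  n_iter, converged) {
  structure(list(C_blood_hat = C_blood_hat,
                 personalized = personalized,
                 error_trace = error_trace,
                 n_iter = n_iter,
                 converged = converged),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat("Blood cortisol estimate\n")
  cat(sprintf("  C_blood_hat: %.4g nmol/L\n", x$C_blood_hat))
  if (length(x$personalized)) {
    cat("  personalized:",
        paste(sprintf("%s = %.4g", names(x$personalized),
                      unlist(x$personalized)), collapse = ", "), "\n")
  }
  cat(sprintf("  iterations: %d, final error: %.3g nmol^2/L^2, converged: %s\n",
              x$n_iter, x$error_trace[length(x$error_trace)], x$converged))
  invisible(x)
}

#' Personalize physiological parameters from calibration records (inner loop)
#'
#' For each subject-by-condition group of records carrying a reference
#' blood cortisol value, finds the values of the personalized parameters
#' (within bounds) minimizing the summed squared sweat-concentration error
#' between simulated and measured sweat cortisol at the reference blood
#' concentration. With the default single parameter (`alpha`) the
#' minimization is a bounded one-dimensional least squares; with several
#' parameters a box-constrained quasi-Newton search is used.
#'
#' @param measurements A tibble of measurement records (rows as from
#'   [sweat_measurement()]); every row must carry `C_blood_ref`.
#' @param p Baseline [transport_parameters()].
#' @param s An [estimation_settings()] object.
#' @param d A [discretization()] object.
#' @return A tibble with one row per subject-condition group: identifiers,
#'   one column per personalized parameter (e.g. `alpha`), the residual
#'   sum of squares `sse` \[nmol^2 L^-2\] and `n_records`.
#' @examples
#' p <- transport_parameters()
#' d <- discretization()
#' truth <- update_parameters(p, alpha = 0.1)
#' sw <- sweat_surface_nmol_l(simulate_steady_state(400, 1, truth, d))
#' m <- sweat_measurement("s01", "pre_surgery", sw, 1, 400)
#' personalize_params(m, p, estimation_settings(), d)
#' @export
personalize_params <- function(measurements, p, s = estimation_settings(),
                               d = discretization()) {
  stopifnot(inherits(p, "transport_parameters"),
            inherits(s, "estimation_settings"))
  if (length(s$personalized_params) == 0L) {
    stop("personalized_params is empty; nothing to personalize",
         call. = FALSE)
  }
  if (nrow(measurements) == 0L) {
    stop("no calibration records supplied", call. = FALSE)
  }
  if (any(!is.finite(measurements$C_blood_ref))) {
    stop("all calibration records must carry C_blood_ref", call. = FALSE)
  }
  groups <- split(measurements,
                  interaction(measurements$subject_id,
                              measurements$condition, drop = TRUE))
  rows <- lapply(groups, function(g) {
    fit <- personalize_group(g, p, s, d)
    out <- tibble::tibble(subject_id = g$subject_id[1L],
                          condition = g$condition[1L],
                          n_records = nrow(g), sse = fit$sse)
    for (nm in s$personalized_params) out[[nm]] <- fit$par[[nm]]
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$subject_id, res$condition), ]
}

personalize_group <- function(g, p, s, d) {
  npar <- length(s$personalized_params)
  if (npar > nrow(g)) {
    stop(sprintf(paste0("unidentifiable personalization: %d free ",
                        "parameter(s) but only %d calibration record(s) ",
                        "for subject '%s', condition '%s'"),
                 npar, nrow(g), g$subject_id[1L], g$condition[1L]),
         call. = FALSE)
  }
  objective <- function(theta) {
    pp <- do.call(update_parameters,
                  c(list(p), stats::setNames(as.list(theta),
                                             s$personalized_params)))
    sum(vapply(seq_len(nrow(g)), function(i) {
      pred <- forward_sweat(g$C_blood_ref[i], g$u_sweat_n[i], pp, d, s$method)
      sweat_error(g$C_sweat[i], pred)
    }, numeric(1)))
  }
  lo <- vapply(s$personalized_params, function(nm) s$param_bounds[[nm]][1L],
               numeric(1))
  hi <- vapply(s$personalized_params, function(nm) s$param_bounds[[nm]][2L],
               numeric(1))
  if (npar == 1L) {
    opt <- stats::optimize(function(x) objective(x), lower = lo, upper = hi,
                           tol = 1e-7 * (hi - lo))
    par <- stats::setNames(list(opt$minimum), s$personalized_params)
    sse <- opt$objective
  } else {
    start <- pmin(pmax(unlist(p)[s$personalized_params], lo), hi)
    opt <- stats::optim(start, objective, method = "L-BFGS-B",
                        lower = lo, upper = hi)
    par <- as.list(opt$par)
    sse <- opt$value
  }
  list(par = par, sse = sse)
}

#' Double-loop blood cortisol estimation over a measurement set
#'
#' Interleaves the two optimization loops: the inner loop personalizes the
#' high-sensitivity physiological parameters (default: the free-cortisol
#' fraction `alpha`) on records that carry a reference blood cortisol
#' value, per subject-condition group; the outer loop then inverts the
#' forward model for every record using its group's personalized
#' parameters. The interleave repeats until the personalized parameters
#' stabilize. Groups without any calibration record use the baseline
#' parameters.
#'
#' @param measurements A tibble of measurement records; rows with a finite
#'   `C_blood_ref` are used as calibration records.
#' @param p Baseline [transport_parameters()].
#' @param s An [estimation_settings()] object.
#' @param d A [discretization()] object.
#' @return A tibble with one row per input record: the input fields plus
#'   the group's personalized parameter columns (e.g. `alpha_hat`),
#'   `C_blood_hat` \[nmol L^-1\], `n_iter`, `converged`, and the
#'   `error_trace` list-column.
#' @examples
#' p <- transport_parameters()
#' d <- discretization()
#' sw <- sweat_surface_nmol_l(simulate_steady_state(355, 1, p, d))
#' m <- sweat_measurement("s01", "pre_surgery", sw, 1, 355)
#' double_loop(m, p, estimation_settings(), d)
#' @export
double_loop <- function(measurements, p, s = estimation_settings(),
                        d = discretization()) {
  stopifnot(inherits(p, "transport_parameters"),
            inherits(s, "estimation_settings"))
  measurements <- tibble::as_tibble(measurements)
  if (!all(c("subject_id", "condition", "C_sweat", "u_sweat_n") %in%
           names(measurements))) {
    stop("measurements must have subject_id, condition, C_sweat, u_sweat_n",
         call. = FALSE)
  }
  if (!"C_blood_ref" %in% names(measurements)) {
    measurements$C_blood_ref <- NA_real_
  }
  calib <- measurements[is.finite(measurements$C_blood_ref), , drop = FALSE]
  key <- function(df) paste(df$subject_id, df$condition, sep = "\r")

  pers_tab <- NULL
  prev <- NULL
  max_interleave <- 5L
  for (it in seq_len(max_interleave)) {
    if (nrow(calib) > 0L && length(s$personalized_params) > 0L) {
      pers_tab <- personalize_params(calib, p, s, d)
    }
    cur <- if (is.null(pers_tab)) numeric(0) else
      unlist(pers_tab[s$personalized_params])
    if (!is.null(prev) &&
        (length(cur) == 0L ||
         max(abs(cur - prev) / pmax(abs(prev), 1e-12)) < 1e-9)) break
    if (is.null(pers_tab)) break
    prev <- cur
  }

  pers_key <- if (is.null(pers_tab)) character(0) else key(pers_tab)
  results <- lapply(seq_len(nrow(measurements)), function(i) {
    m <- measurements[i, ]
    idx <- match(key(m), pers_key)
    pp <- p
    if (!is.na(idx)) {
      repl <- as.list(pers_tab[idx, s$personalized_params])
      pp <- do.call(update_parameters, c(list(p), repl))
    }
    est <- estimate_blood(m, pp, s, d)
    row <- m
    for (nm in s$personalized_params) {
      row[[paste0(nm, "_hat")]] <- unname(unlist(pp[nm]))
    }
    row$C_blood_hat <- est$C_blood_hat
    row$n_iter <- est$n_iter
    row$converged <- est$converged
    row$error_trace <- list(est$error_trace)
    row
  })
  out <- do.call(rbind, results)
  tibble::as_tibble(out)
}

#' Read a sweat-measurement CSV file
#'
#' Expected columns: `subject_id, condition, sweat_cortisol_nmol_l,
#' sweat_velocity_norm, blood_cortisol_nmol_l` (the last optional or
#' empty for estimation-only rows); header required; UTF-8.
#'
#' @param path Path to the CSV file.
#' @return A tibble of measurement records with the internal field names
#'   (`C_sweat`, `u_sweat_n`, `C_blood_ref`).
#' @export
read_sweat_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("subject_id", "condition", "sweat_cortisol_nmol_l",
            "sweat_velocity_norm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$condition), cortisol_conditions())
  if (length(bad)) {
    stop("invalid condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$sweat_cortisol_nmol_l < 0, na.rm = TRUE) ||
      any(df$sweat_velocity_norm < 0, na.rm = TRUE)) {
    stop("sweat concentration and velocity must be non-negative",
         call. = FALSE)
  }
  ref <- if ("blood_cortisol_nmol_l" %in% names(df)) {
    as.numeric(df$blood_cortisol_nmol_l)
  } else NA_real_
  tibble::tibble(subject_id = as.character(df$subject_id),
                 condition = df$condition,
                 C_sweat = as.numeric(df$sweat_cortisol_nmol_l),
                 u_sweat_n = as.numeric(df$sweat_velocity_norm),
                 C_blood_ref = ref)
}

#' Write measurement records to the standard CSV layout
#'
#' @param measurements A tibble of measurement records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweat_measurements <- function(measurements, path) {
  df <- data.frame(subject_id = measurements$subject_id,
                   condition = measurements$condition,
                   sweat_cortisol_nmol_l = measurements$C_sweat,
                   sweat_velocity_norm = measurements$u_sweat_n,
                   blood_cortisol_nmol_l = measurements$C_blood_ref)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
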