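#' Specification of a synthetic patient cohort
#'
#' Describes the statistical structure of a perioperative cohort with
#' paired pre- and post-surgery sweat/blood cortisol measurements: each
#' subject contributes one pre-surgery visit and one post-surgery visit,
#' the post arm being dexamethasone-treated for a configurable fraction of
#' subjects. Per-condition free-cortisol fractions and blood cortisol
#' concentrations are drawn from log-normal distributions (positive and
#' right-skewed, as cortisol data typically are).
#'
#' Default medians for the free-cortisol fraction are 4.8% pre-surgery,
#' 11.3% post-surgery without dexamethasone (surgical stress lowers CBG,
#' raising the free fraction), and 5.4% post-surgery with dexamethasone
#' (suppression). The pre-surgery blood cortisol distribution is tied to a
#' 355 nmol/L mean.
#'
#' @param n_subjects Number of subjects (default 44).
#' @param dexa_fraction Fraction of subjects receiving dexamethasone
#'   during surgery (default 34/50).
#' @param alpha_median Named per-condition medians of the free-cortisol
#'   fraction.
#' @param alpha_sdlog Log-scale SD of the free-cortisol fraction draws
#'   (0 fixes alpha at the condition median).
#' @param blood_median Named per-condition medians of blood cortisol
#'   \[nmol L^-1\]. The pre-surgery default equals `355 * exp(-sdlog^2/2)`
#'   so the distribution mean is 355 nmol/L.
#' @param blood_sdlog Log-scale SD of blood cortisol draws.
#' @param velocity_median Median normalized sweat velocity.
#' @param velocity_sdlog Log-scale SD of normalized sweat velocity draws.
#' @param noise_cv Multiplicative measurement-noise CV applied to the
#'   sweat and blood assays (log-normal; 0 yields exactly model-consistent
#'   data).
#' @param seed RNG seed; generation is deterministic under seed.
#' @return An object of class `cohort_spec`.
#' @examples
#' cohort_spec(n_subjects = 8, noise_cv = 0)
#' @export
cohort_spec <- function(n_subjects = 44L,
                        dexa_fraction = 34 / 50,
                        alpha_median = c(pre_surgery = 0.048,
                                         post_no_dexa = 0.113,
                                         post_dexa = 0.054),
                        alpha_sdlog = 0.25,
                        blood_median = c(pre_surgery = 355 * exp(-0.4^2 / 2),
                                         post_no_dexa = 500,
                                         post_dexa = 120),
                        blood_sdlog = 0.4,
                        velocity_median = 1,
                        velocity_sdlog = 0.3,
                        noise_cv = 0.10,
                        seed = 1L) {
  stopifnot(n_subjects >= 1,
            dexa_fraction >= 0, dexa_fraction <= 1,
            all(alpha_median > 0), all(blood_median > 0),
            alpha_sdlog >= 0, blood_sdlog >= 0,
            velocity_median > 0, velocity_sdlog >= 0,
            noise_cv >= 0)
  need <- cortisol_conditions()
  if (!all(need %in% names(alpha_median)) ||
      !all(need %in% names(blood_median))) {
    stop("alpha_median and blood_median must be named for all conditions: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 dexa_fraction = dexa_fraction,
                 alpha_median = alpha_median,
                 alpha_sdlog = alpha_sdlog,
                 blood_median = blood_median,
                 blood_sdlog = blood_sdlog,
                 velocity_median = velocity_median,
                 velocity_sdlog = velocity_sdlog,
                 noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# log-normal draw parameterized by median (scalar or per-draw vector);
# sdlog = 0 degenerates to the median
draw_lognormal <- function(n, median, sdlog) {
  if (sdlog == 0) unname(rep_len(median, n)) else
    stats::rlnorm(n, meanlog = log(rep_len(median, n)), sdlog = sdlog)
}

# multiplicative assay noise: Gaussian on the log scale with the given CV
noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sdlog))
}

#' Generate a synthetic cohort of sweat/blood cortisol measurements
#'
#' For each subject and visit, draws a true free-cortisol fraction and a
#' true blood cortisol concentration from the per-condition distributions,
#' forward-simulates the noise-free sweat cortisol concentration through
#' the transport model, and applies multiplicative measurement noise to
#' both assays. Returns the measurement table alongside a row-aligned
#' ground-truth sidecar, so parameter- and concentration-recovery can be
#' scored exactly.
#'
#' @param spec A [cohort_spec()] object.
#' @param p Baseline [transport_parameters()]; the free-cortisol fraction
#'   is overridden per record by the drawn true value.
#' @param d A [discretization()] object.
#' @param method Forward-solver route (see [simulate_steady_state()]).
#' @return A list of class `synthetic_cohort` with tibbles `measurements`
#'   (fields as [sweat_measurement()]; `C_blood_ref` carries the noisy
#'   measured blood value) and `truth` (row-aligned: true `C_blood`
#'   \[nmol L^-1\], true `alpha`, noise-free `C_sweat_clean`).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 3, seed = 7),
#'                        transport_parameters(), discretization())
#' nrow(coh$measurements)  # 6: paired pre/post visits
#' @export
generate_cohort <- function(spec, p = transport_parameters(),
                            d = discretization(),
                            method = c("direct", "transient")) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(p, "transport_parameters"))
  method <- match.arg(method)
  set.seed(spec$seed)
  n <- spec$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  dexa <- stats::rbinom(n, 1L, spec$dexa_fraction) == 1L
  post_cond <- ifelse(dexa, "post_dexa", "post_no_dexa")
  subject <- rep(ids, each = 2L)
  condition <- as.vector(rbind("pre_surgery", post_cond))
  nrec <- length(condition)

  alpha_true <- draw_lognormal(nrec, spec$alpha_median[condition],
                               spec$alpha_sdlog)
  alpha_true <- pmin(alpha_true, 1)
  blood_true <- draw_lognormal(nrec, spec$blood_median[condition],
                               spec$blood_sdlog)
  u_n <- draw_lognormal(nrec, spec$velocity_median, spec$velocity_sdlog)
  sweat_noise <- noise_factor(nrec, spec$noise_cv)
  blood_noise <- noise_factor(nrec, spec$noise_cv)

  sweat_clean <- numeric(nrec)
  for (i in seq_len(nrec)) {
    pp <- update_parameters(p, alpha = alpha_true[i])
    ok <- FALSE
    for (try in 1:3) {
      res <- simulate_steady_state(blood_true[i], u_n[i], pp, d,
                                   method = method)
      if (res$converged) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("forward simulation failed to converge for record ", i,
           call. = FALSE)
    }
    sweat_clean[i] <- sweat_surface_nmol_l(res)
  }

  measurements <- tibble::tibble(
    subject_id = subject,
    condition = condition,
    C_sweat = sweat_clean * sweat_noise,
    u_sweat_n = u_n,
    C_blood_ref = blood_true * blood_noise
  )
  truth <- tibble::tibble(
    subject_id = subject,
    condition = condition,
    C_blood = blood_true,
    alpha = unname(alpha_true),
    C_sweat_clean = sweat_clean
  )
  structure(list(measurements = measurements, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d records (noise CV %.0f%%, seed %d)\n",
              x$spec$n_subjects, nrow(x$measurements),
              100 * x$spec$noise_cv, x$spec$seed))
  print(utils::head(x$measurements, 4))
  invisible(x)
}
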