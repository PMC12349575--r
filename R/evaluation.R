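#' Agreement statistics between estimated and measured concentrations
#'
#' Computes the method-agreement summary for paired estimated and measured
#' blood cortisol values: root-mean-square error, Pearson correlation with
#' a Fisher-z 95% confidence interval, and Bland-Altman bias with limits
#' of agreement (bias +/- 1.96 SD of the differences). Differences are
#' oriented estimated minus measured.
#'
#' @param estimated Numeric vector of estimated values \[nmol L^-1\].
#' @param measured Numeric vector of measured values \[nmol L^-1\], same
#'   length (>= 3).
#' @return An object of class `agreement_stats`: `n`, `rmse`, `pearson_r`,
#'   `r_ci_low`, `r_ci_high`, `bias`, `loa_low`, `loa_high`.
#' @examples
#' agreement(c(2, 4, 6) + 0.1, c(1, 2, 3))
#' @export
agreement <- function(estimated, measured) {
  if (length(estimated) != length(measured)) {
    stop("estimated and measured must have equal length", call. = FALSE)
  }
  if (length(estimated) < 3L) {
    stop("at least 3 pairs are required", call. = FALSE)
  }
  if (!all(is.finite(estimated)) || !all(is.finite(measured))) {
    stop("inputs must be finite", call. = FALSE)
  }
  n <- length(estimated)
  diffs <- estimated - measured
  rmse <- sqrt(mean(diffs^2))
  bias <- mean(diffs)
  sd_d <- stats::sd(diffs)
  loa <- bias + c(-1, 1) * 1.96 * sd_d
  if (stats::sd(estimated) == 0 || stats::sd(measured) == 0) {
    stop("Pearson correlation undefined: zero variance in input",
         call. = FALSE)
  }
  r <- stats::cor(estimated, measured)
  if (abs(r) >= 1 - 1e-15) {
    ci <- c(r, r)  # Fisher z diverges at |r| = 1
  } else {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    ci <- tanh(z + stats::qnorm(c(0.025, 0.975)) * se)
  }
  structure(list(n = n, rmse = rmse,
                 pearson_r = r, r_ci_low = ci[1L], r_ci_high = ci[2L],
                 bias = bias, loa_low = loa[1L], loa_high = loa[2L]),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("Agreement over %d pairs\n", x$n))
  cat(sprintf("  RMSE: %.4g nmol/L\n", x$rmse))
  cat(sprintf("  Pearson r: %.3f (95%% CI: %.3f-%.3f)\n",
              x$pearson_r, x$r_ci_low, x$r_ci_high))
  cat(sprintf("  Bland-Altman bias: %.4g (LoA: %.4g to %.4g) nmol/L\n",
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
as.data.frame.agreement_stats <- function(x, ...) {
  data.frame(n = x$n, rmse = x$rmse, pearson_r = x$pearson_r,
             r_ci_low = x$r_ci_low, r_ci_high = x$r_ci_high,
             bias = x$bias, loa_low = x$loa_low, loa_high = x$loa_high)
}

#' Per-condition and overall agreement report
#'
#' Applies [agreement()] within each clinical condition and over the full
#' set, mirroring the stratified evaluation of perioperative data:
#' pre-surgery, post-surgery with dexamethasone, and post-surgery without
#' dexamethasone. Conditions with fewer than 3 pairs are reported with
#' empty statistics and a warning.
#'
#' @param results A data frame with columns `condition`, `C_blood_hat`
#'   (estimated) and `C_blood_ref` (measured reference), e.g. the output
#'   of [double_loop()] joined with reference values.
#' @return A tibble with one row per condition present plus an `"overall"`
#'   row: `condition`, `n`, `rmse`, `pearson_r`, `r_ci_low`, `r_ci_high`,
#'   `bias`, `loa_low`, `loa_high`.
#' @export
stratified_report <- function(results) {
  need <- c("condition", "C_blood_hat", "C_blood_ref")
  miss <- setdiff(need, names(results))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(results$C_blood_ref))) {
    stop("every record needs a reference blood value for evaluation",
         call. = FALSE)
  }
  one <- function(df, label) {
    if (nrow(df) < 3L) {
      warning(sprintf("condition '%s' has fewer than 3 pairs; statistics omitted",
                      label))
      return(tibble::tibble(condition = label, n = nrow(df),
                            rmse = NA_real_, pearson_r = NA_real_,
                            r_ci_low = NA_real_, r_ci_high = NA_real_,
                            bias = NA_real_, loa_low = NA_real_,
                            loa_high = NA_real_))
    }
    st <- as.data.frame(agreement(df$C_blood_hat, df$C_blood_ref))
    tibble::as_tibble(cbind(data.frame(condition = label), st))
  }
  conds <- intersect(cortisol_conditions(), unique(results$condition))
  rows <- lapply(conds, function(cn) {
    one(results[results$condition == cn, , drop = FALSE], cn)
  })
  rows <- c(rows, list(one(results, "overall")))
  do.call(rbind, rows)
}
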