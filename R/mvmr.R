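# Multivariable MR estimation and instrument-strength diagnostics.

#' Multivariable IVW estimate for two exposures
#'
#' Weighted no-intercept regression of the outcome associations on the
#' trait and mediator association columns (weights `1/se_out^2`), giving
#' each exposure's direct effect on the outcome conditional on the other.
#' Coefficient SEs carry the same multiplicative residual floor as
#' [mr_ivw()], with the residual scale estimated on `L - K` degrees of
#' freedom.
#'
#' @param h A `harmonised_set` with `beta_med`/`se_med` columns (see
#'   [merge_for_mvmr()]) and at least 3 variants.
#' @param random_effects As in [mr_ivw()].
#' @return A list of class `mvmr_result`: `exposure_ids`, `estimates`,
#'   `ses`, `ci_low`, `ci_high`, `pvals` (each a named length-2 vector,
#'   `exposure` then `mediator`), and `n_variants`.
#' @export
mvmr_ivw <- function(h, random_effects = TRUE) {
  stopifnot(inherits(h, "harmonised_set"), "beta_med" %in% names(h))
  L <- nrow(h)
  K <- 2L
  if (L < K + 1) {
    stop("multivariable IVW needs at least ", K + 1, " variants",
         call. = FALSE)
  }
  x <- cbind(exposure = h$beta_exp, mediator = h$beta_med)
  w <- 1 / h$se_out^2
  if (all(h$beta_med == 0)) {
    # degenerate nested case: the mediator contributes nothing and its
    # coefficient is undefined; the trait coefficient is the univariate
    # IVW estimate
    warning("mediator associations are identically zero; returning the",
            " univariate fit for the trait", call. = FALSE)
    uni <- mr_ivw(h, random_effects = random_effects)
    est <- c(exposure = uni$estimate, mediator = NA_real_)
    ses <- c(exposure = uni$se, mediator = NA_real_)
    return(structure(list(exposure_ids = colnames(x), estimates = est,
                          ses = ses, ci_low = est - Z95 * ses,
                          ci_high = est + Z95 * ses,
                          pvals = 2 * stats::pnorm(-abs(est / ses)),
                          n_variants = L),
                     class = "mvmr_result"))
  }
  if (kappa(x, exact = TRUE) > 1e8) {
    stop("collinear exposure associations (exposure vs mediator)",
         call. = FALSE)
  }
  xtwx <- crossprod(x, w * x)
  a <- solve(xtwx)
  coefs <- drop(a %*% crossprod(x, w * h$beta_out))
  resid <- h$beta_out - drop(x %*% coefs)
  q <- sum(w * resid^2)
  sigma <- if (random_effects) max(1, sqrt(q / (L - K))) else 1
  ses <- sigma * sqrt(diag(a))
  structure(list(exposure_ids = colnames(x),
                 estimates = coefs,
                 ses = ses,
                 ci_low = coefs - Z95 * ses,
                 ci_high = coefs + Z95 * ses,
                 pvals = 2 * stats::pnorm(-abs(coefs / ses)),
                 n_variants = L),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat("Multivariable IVW (", x$n_variants, " variants):\n", sep = "")
  print(data.frame(exposure = x$exposure_ids, estimate = x$estimates,
                   se = x$ses, ci_low = x$ci_low, ci_high = x$ci_high,
                   pval = x$pvals, row.names = NULL))
  invisible(x)
}

#' Conditional F statistic for instrument strength in multivariable MR
#'
#' Measures how strongly the instruments predict one exposure's
#' associations conditional on the other exposure's: the chosen exposure's
#' associations are regressed (no intercept, weights `1/se^2` of the
#' chosen exposure, cross-trait sampling covariance taken as 0) on the
#' other exposure's associations; the weighted residual sum of squares
#' `Q_x` is returned as `Q_x / (L - K + 1)`.
#'
#' @param h A `harmonised_set` with mediator columns.
#' @param exposure Which exposure to assess: `"exposure"` or
#'   `"mediator"`.
#' @return The conditional F statistic (non-negative scalar).
#' @export
conditional_f <- function(h, exposure = c("exposure", "mediator")) {
  exposure <- match.arg(exposure)
  stopifnot(inherits(h, "harmonised_set"), "beta_med" %in% names(h))
  L <- nrow(h)
  K <- 2L
  if (L < K + 1) {
    stop("conditional F needs at least ", K + 1, " variants", call. = FALSE)
  }
  if (exposure == "exposure") {
    y <- h$beta_exp; se <- h$se_exp; z <- h$beta_med
  } else {
    y <- h$beta_med; se <- h$se_med; z <- h$beta_exp
  }
  w <- 1 / se^2
  fit <- stats::lm.wfit(x = cbind(z), y = y, w = w)
  q_x <- sum(w * fit$residuals^2)
  q_x / (L - K + 1)
}

#' Modified Cochran's Q for multivariable MR
#'
#' Heterogeneity of the outcome associations about the fitted
#' multivariable model:
#' `Q_A = sum w_i (beta_out_i - sum_j theta_j beta_j_i)^2`,
#' `w_i = 1/se_out_i^2`, on `L - K` degrees of freedom, compared against
#' the 5% upper chi-squared critical value. Exceeding the critical value
#' indicates the instruments predict the exposures beyond noise (or
#' residual pleiotropy).
#'
#' @param h A `harmonised_set` with mediator columns.
#' @param fitted An `mvmr_result` from [mvmr_ivw()] on the same set.
#' @return A list: `q_a`, `q_a_df`, `q_a_critical_5pct`, `q_a_exceeds`,
#'   `pval`.
#' @export
modified_q <- function(h, fitted) {
  stopifnot(inherits(h, "harmonised_set"), inherits(fitted, "mvmr_result"))
  L <- nrow(h)
  K <- length(fitted$estimates)
  w <- 1 / h$se_out^2
  pred <- fitted$estimates["exposure"] * h$beta_exp +
    fitted$estimates["mediator"] * h$beta_med
  q_a <- sum(w * (h$beta_out - pred)^2)
  df <- L - K
  crit <- stats::qchisq(0.95, df)
  list(q_a = q_a, q_a_df = df, q_a_critical_5pct = crit,
       q_a_exceeds = q_a > crit,
       pval = stats::pchisq(q_a, df, lower.tail = FALSE))
}
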