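# Univariate two-sample MR estimators and diagnostics.

Z95 <- stats::qnorm(0.975)

new_mr_result <- function(method, estimate, se, pval, n_variants,
                          ci_mult = Z95) {
  # keep p-values inside (0, 1] even when the normal tail underflows
  pval <- min(max(pval, .Machine$double.xmin), 1)
  structure(list(method = method,
                 estimate = estimate,
                 se = se,
                 ci_low = estimate - ci_mult * se,
                 ci_high = estimate + ci_mult * se,
                 pval = pval,
                 n_variants = n_variants),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR %s: %.4g (SE %.4g, 95%% CI %.4g to %.4g, p = %.3g, k = %d)\n",
              x$method, x$estimate, x$se, x$ci_low, x$ci_high, x$pval,
              x$n_variants))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, n_variants = x$n_variants,
             estimate = x$estimate, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             stringsAsFactors = FALSE)
}

#' Wald ratio estimate from a single variant
#'
#' The single-variant causal estimate `beta_out / beta_exp` with the
#' first-order standard error `se_out / |beta_exp|`.
#'
#' @param beta_exp,se_exp Variant-exposure association and its SE (the SE
#'   is not used by the first-order formula but kept for interface
#'   symmetry).
#' @param beta_out,se_out Variant-outcome association and its SE.
#' @return An `mr_result`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (beta_exp == 0) {
    stop("Wald ratio undefined for beta_exp = 0", call. = FALSE)
  }
  est <- beta_out / beta_exp
  se <- se_out / abs(beta_exp)
  new_mr_result("wald", est, se, 2 * stats::pnorm(-abs(est / se)), 1L)
}

#' Inverse-variance weighted MR estimate
#'
#' The IVW estimate is the no-intercept weighted regression of outcome on
#' exposure associations with weights `1/se_out^2`. Standard errors use a
#' multiplicative random-effects model: the residual scale
#' `sqrt(Q / (k - 1))` multiplies the fixed-effects SE but is floored at 1,
#' so the SE never undershoots the fixed-effects value. A single variant
#' delegates to [wald_ratio()].
#'
#' @param h A `harmonised_set`.
#' @param random_effects Apply the multiplicative residual scaling
#'   (default `TRUE`; `FALSE` gives pure fixed effects).
#' @return An `mr_result` with method `"ivw"`.
#' @export
mr_ivw <- function(h, random_effects = TRUE) {
  k <- nrow(h)
  if (k == 0) stop("empty harmonised set", call. = FALSE)
  if (k == 1) {
    return(wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out))
  }
  if (all(h$beta_exp == 0)) {
    stop("degenerate instrument: all exposure associations are zero",
         call. = FALSE)
  }
  w <- 1 / h$se_out^2
  bhat <- sum(w * h$beta_exp * h$beta_out) / sum(w * h$beta_exp^2)
  q <- sum(w * (h$beta_out - bhat * h$beta_exp)^2)
  sigma <- if (random_effects) max(1, sqrt(q / (k - 1))) else 1
  se <- sigma * sqrt(1 / sum(w * h$beta_exp^2))
  new_mr_result("ivw", bhat, se, 2 * stats::pnorm(-abs(bhat / se)), k)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure associations with an
#' unconstrained intercept (weights `1/se_out^2`). The intercept estimates
#' average directional pleiotropy; the slope is a pleiotropy-adjusted
#' causal estimate valid under the InSIDE assumption. Both coefficient SEs
#' carry the same multiplicative residual floor as [mr_ivw()]; inference
#' uses the t distribution with `k - 2` degrees of freedom, the small-k
#' case where it matters. Requires the exposure-increasing orientation
#' applied by [harmonise()].
#'
#' @param h A `harmonised_set` with at least 3 variants.
#' @param random_effects As in [mr_ivw()].
#' @return A list with elements `slope` and `intercept` (both `mr_result`)
#'   and `heterogeneity` (list `q`, `df`, `pval`, `i2gx`).
#' @export
mr_egger <- function(h, random_effects = TRUE) {
  k <- nrow(h)
  if (k < 3) stop("MR-Egger needs at least 3 variants", call. = FALSE)
  if (stats::var(h$beta_exp) == 0) {
    stop("rank-deficient design: all exposure associations equal",
         call. = FALSE)
  }
  w <- 1 / h$se_out^2
  x <- cbind(intercept = 1, slope = h$beta_exp)
  xtwx <- crossprod(x, w * x)
  a <- solve(xtwx)
  coefs <- drop(a %*% crossprod(x, w * h$beta_out))
  resid <- h$beta_out - drop(x %*% coefs)
  q <- sum(w * resid^2)
  df <- k - 2L
  sigma <- if (random_effects) max(1, sqrt(q / df)) else 1
  ses <- sigma * sqrt(diag(a))
  tq <- stats::qt(0.975, df)
  pvals <- 2 * stats::pt(-abs(coefs / ses), df)
  i2 <- if (all(is.finite(h$se_exp))) i2gx(h) else NA_real_
  list(slope = new_mr_result("egger-slope", coefs[["slope"]],
                             ses[["slope"]], pvals[["slope"]], k,
                             ci_mult = tq),
       intercept = new_mr_result("egger-intercept", coefs[["intercept"]],
                                 ses[["intercept"]], pvals[["intercept"]],
                                 k, ci_mult = tq),
       heterogeneity = list(q = q, df = df,
                            pval = stats::pchisq(q, df, lower.tail = FALSE),
                            i2gx = i2))
}

#' I-squared statistic for exposure associations
#'
#' Measures regression-dilution bias of the MR-Egger slope from
#' measurement error in the variant-exposure associations (the
#' no-measurement-error assumption): `I2_GX = (Q_GX - (k - 1)) / Q_GX`
#' with `Q_GX` the inverse-variance weighted heterogeneity of `beta_exp`,
#' truncated below at 0. `1 - I2_GX` bounds the relative attenuation of
#' the Egger slope towards the null (see [egger_attenuation()]).
#'
#' @param h A `harmonised_set` with at least 2 variants and exposure SEs.
#' @return The statistic, in `[0, 1)`.
#' @export
i2gx <- function(h) {
  k <- nrow(h)
  if (k < 2) stop("I2_GX needs at least 2 variants", call. = FALSE)
  if (!all(is.finite(h$se_exp))) {
    stop("exposure standard errors are required for I2_GX", call. = FALSE)
  }
  v <- 1 / h$se_exp^2
  mu <- sum(v * h$beta_exp) / sum(v)
  q_gx <- sum(v * (h$beta_exp - mu)^2)
  if (q_gx <= 0) return(0)
  max(0, (q_gx - (k - 1)) / q_gx)
}

# Weighted median of ratio estimates by cumulative-percentile interpolation.
.weighted_median_point <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]
  ww <- w[o] / sum(w[o])
  s <- cumsum(ww)
  p <- s - ww / 2
  if (0.5 <= p[1]) return(th[1])
  if (0.5 >= p[length(p)]) return(th[length(th)])
  stats::approx(p, th, xout = 0.5, ties = "ordered")$y
}

.ratio_filter <- function(h) {
  drop <- h$beta_exp == 0
  if (any(drop)) {
    warning(sum(drop), " variant(s) with beta_exp = 0 excluded from",
            " ratio-based estimation", call. = FALSE)
  }
  as.data.frame(h)[!drop, , drop = FALSE]
}

#' Weighted-median MR estimate
#'
#' The weighted median of the per-variant ratio estimates
#' `theta_i = beta_out_i / beta_exp_i`, with inverse-variance weights
#' `(se_out_i / beta_exp_i)^-2`. Sorted ratios are assigned cumulative
#' percentiles `S_i - w_i/2` and the estimate is interpolated at the 50th
#' percentile; it is consistent when at least half the weight comes from
#' valid instruments. The SE comes from a seeded parametric bootstrap
#' resampling both association vectors from their sampling distributions.
#'
#' @param h A `harmonised_set` with at least 3 usable variants.
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Integer seed for the bootstrap; `NULL` leaves the RNG state
#'   alone.
#' @return An `mr_result` with method `"weighted-median"`.
#' @export
weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  d <- .ratio_filter(h)
  k <- nrow(d)
  if (k < 3) stop("weighted median needs at least 3 usable variants",
                  call. = FALSE)
  theta <- d$beta_out / d$beta_exp
  w <- (d$beta_exp / d$se_out)^2
  est <- .weighted_median_point(theta, w)
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(k, d$beta_exp, d$se_exp)
    by <- stats::rnorm(k, d$beta_out, d$se_out)
    ok <- bx != 0
    .weighted_median_point(by[ok] / bx[ok], (bx[ok] / d$se_out[ok])^2)
  }, 0.0)
  se <- stats::sd(boot)
  new_mr_result("weighted-median", est, se,
                2 * stats::pnorm(-abs(est / se)), k)
}

# Argmax of a Gaussian-kernel-smoothed weighted density on a fixed grid.
.mode_point <- function(theta, w, bw, grid_points = 512) {
  grid <- seq(min(theta) - 3 * bw, max(theta) + 3 * bw,
              length.out = grid_points)
  dens <- as.vector(crossprod(w, stats::dnorm(outer(theta, grid, "-"),
                                              sd = bw)))
  grid[which.max(dens)]
}

#' Mode-based MR estimate (simple or weighted)
#'
#' The mode of the per-variant ratio estimates, located as the argmax of a
#' Gaussian-kernel-smoothed density evaluated on a fixed grid of 512
#' points spanning `[min(theta) - 3h, max(theta) + 3h]`. The bandwidth is
#' `phi` times Silverman's rule-of-thumb on the ratios. Weights are
#' uniform for the simple mode and normalised inverse-variance for the
#' weighted mode; it is consistent when the largest homogeneous cluster of
#' instruments is valid. The SE comes from a seeded parametric bootstrap.
#'
#' @param h A `harmonised_set` with at least 3 usable variants.
#' @param weighted Use inverse-variance weights (`TRUE`) or uniform
#'   (`FALSE`, the simple mode).
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot,seed As in [weighted_median()].
#' @param grid_points Grid resolution (default 512).
#' @return An `mr_result` with method `"weighted-mode"` or
#'   `"simple-mode"`.
#' @export
mode_estimator <- function(h, weighted = FALSE, phi = 1, n_boot = 1000,
                           seed = NULL, grid_points = 512) {
  d <- .ratio_filter(h)
  k <- nrow(d)
  if (k < 3) stop("mode estimator needs at least 3 usable variants",
                  call. = FALSE)
  theta <- d$beta_out / d$beta_exp
  wts <- function(bx, se_out) {
    if (weighted) {
      wv <- (bx / se_out)^2
      wv / sum(wv)
    } else {
      rep(1 / length(bx), length(bx))
    }
  }
  point <- function(th, w) {
    if (length(unique(th)) == 1) return(th[1])
    bw <- phi * stats::bw.nrd0(th)
    if (bw <= 0) return(th[1])
    .mode_point(th, w, bw, grid_points)
  }
  est <- point(theta, wts(d$beta_exp, d$se_out))
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(k, d$beta_exp, d$se_exp)
    by <- stats::rnorm(k, d$beta_out, d$se_out)
    ok <- bx != 0
    point(by[ok] / bx[ok], wts(bx[ok], d$se_out[ok]))
  }, 0.0)
  se <- stats::sd(boot)
  new_mr_result(if (weighted) "weighted-mode" else "simple-mode",
                est, se, 2 * stats::pnorm(-abs(est / se)), k)
}

#' Cochran's Q heterogeneity statistic for ratio estimates
#'
#' `Q = sum w_i (theta_i - estimate)^2` with first-order ratio weights
#' `w_i = (se_out_i / beta_exp_i)^-2`; for the IVW estimate this is
#' algebraically the weighted residual sum of squares of the no-intercept
#' regression. Referred to the upper chi-squared tail on `k - 1` degrees
#' of freedom.
#'
#' @param h A `harmonised_set` with at least 2 variants.
#' @param estimate The causal estimate the per-variant ratios are compared
#'   against (typically the IVW estimate).
#' @return A list with `q`, `df`, `pval`.
#' @export
cochran_q <- function(h, estimate) {
  d <- .ratio_filter(h)
  k <- nrow(d)
  if (k < 2) stop("Cochran's Q needs at least 2 usable variants",
                  call. = FALSE)
  theta <- d$beta_out / d$beta_exp
  w <- (d$beta_exp / d$se_out)^2
  q <- sum(w * (theta - estimate)^2)
  df <- k - 1L
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate omitting each variant in turn, to reveal
#' single variants driving the pooled effect.
#'
#' @param h A `harmonised_set` with at least 3 variants.
#' @param random_effects As in [mr_ivw()].
#' @return A data.frame with one row per omitted variant: `variant_id`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `pval`.
#' @export
leave_one_out <- function(h, random_effects = TRUE) {
  k <- nrow(h)
  if (k < 3) stop("leave-one-out needs at least 3 variants", call. = FALSE)
  d <- as.data.frame(h)
  rows <- lapply(seq_len(k), function(i) {
    r <- mr_ivw(new_harmonised_set(d[-i, , drop = FALSE], k - 1L, 0L, 0L),
                random_effects = random_effects)
    cbind(data.frame(variant_id = d$variant_id[i], stringsAsFactors = FALSE),
          as.data.frame(r)[c("estimate", "se", "ci_low", "ci_high", "pval")])
  })
  do.call(rbind, rows)
}

#' Run the full univariate MR suite for one exposure-outcome pair
#'
#' Pipeline: instrument selection at `p_threshold`, greedy LD clumping,
#' the minimum-instrument-count gate, allele harmonisation, then the IVW
#' estimate plus MR-Egger, weighted-median and mode sensitivity analyses
#' with heterogeneity (`Q`, `I2_GX`) diagnostics. Traits failing the count
#' gate are marked ineligible and produce no estimates.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param config A [study_config()] list (thresholds, LD source, bootstrap
#'   settings, seed).
#' @return A list of class `uvmr_suite`: `eligible` flag, `n_instruments`
#'   post-clumping, `harmonised` set (or `NULL`), and `results`, a tidy
#'   data.frame with one row per method and columns
#'   `exposure_id, outcome_id, method, n_variants, estimate, se, ci_low,
#'   ci_high, pval, q, q_df, q_pval, i2gx`.
#' @export
run_uvmr_suite <- function(exposure, outcome, config = study_config()) {
  inst <- select_instruments(exposure, config$p_threshold)
  inst <- greedy_clump(inst, config$ld, config$r2_threshold,
                       config$window_bp)
  cols <- c("exposure_id", "outcome_id", "method", "n_variants", "estimate",
            "se", "ci_low", "ci_high", "pval", "q", "q_df", "q_pval", "i2gx")
  empty <- stats::setNames(
    data.frame(character(), character(), character(), integer(), numeric(),
               numeric(), numeric(), numeric(), numeric(), numeric(),
               integer(), numeric(), numeric(), stringsAsFactors = FALSE),
    cols)
  out <- list(exposure_id = trait_id(exposure),
              outcome_id = trait_id(outcome),
              eligible = count_rule(inst, config$min_instruments),
              n_instruments = nrow(inst),
              harmonised = NULL,
              results = empty)
  class(out) <- "uvmr_suite"
  if (!out$eligible) return(out)
  h <- harmonise(inst, outcome, config$palindrome_eaf_window)
  out$harmonised <- h
  k <- nrow(h)
  if (k == 0) return(out)

  add_row <- function(r, q = NA_real_, q_df = NA_integer_, q_pval = NA_real_,
                      i2 = NA_real_) {
    cbind(data.frame(exposure_id = out$exposure_id,
                     outcome_id = out$outcome_id,
                     stringsAsFactors = FALSE),
          as.data.frame(r),
          data.frame(q = q, q_df = q_df, q_pval = q_pval, i2gx = i2))
  }
  rows <- list()
  methods <- config$methods
  if ("ivw" %in% methods || k == 1) {
    ivw <- mr_ivw(h, config$random_effects)
    qs <- if (k >= 2) cochran_q(h, ivw$estimate) else
      list(q = NA_real_, df = NA_integer_, pval = NA_real_)
    rows$ivw <- add_row(ivw, qs$q, qs$df, qs$pval)
  }
  if ("egger" %in% methods && k >= 3) {
    eg <- mr_egger(h, config$random_effects)
    rows$egger_slope <- add_row(eg$slope, eg$heterogeneity$q,
                                eg$heterogeneity$df, eg$heterogeneity$pval,
                                eg$heterogeneity$i2gx)
    rows$egger_intercept <- add_row(eg$intercept)
  }
  if ("weighted-median" %in% methods && k >= 3) {
    rows$wm <- add_row(weighted_median(h, config$n_boot, config$seed))
  }
  if ("simple-mode" %in% methods && k >= 3) {
    rows$sm <- add_row(mode_estimator(h, weighted = FALSE, phi = config$phi,
                                      n_boot = config$n_boot,
                                      seed = config$seed))
  }
  if ("weighted-mode" %in% methods && k >= 3) {
    rows$wmode <- add_row(mode_estimator(h, weighted = TRUE,
                                         phi = config$phi,
                                         n_boot = config$n_boot,
                                         seed = config$seed))
  }
  out$results <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

#' @export
print.uvmr_suite <- function(x, ...) {
  cat("Univariate MR suite: ", x$exposure_id, " -> ", x$outcome_id, "\n",
      sep = "")
  if (!x$eligible) {
    cat("ineligible: only ", x$n_instruments,
        " post-clumping instrument(s)\n", sep = "")
  } else {
    print(x$results, ...)
  }
  invisible(x)
}
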