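# Two-step MR mediation: effect decomposition and the Egger attenuation
# bound.

#' Two-step MR mediation decomposition
#'
#' Combines three fitted quantities for one trait-mediator-outcome triple:
#' the total effect (univariate MR of trait on outcome), the direct effect
#' of the trait conditional on the mediator (multivariable MR), and the
#' trait-on-mediator effect (univariate MR). The indirect (mediated)
#' effect is the product of coefficients
#' `indirect = b1 * b2`, where `b1` is the trait-on-mediator estimate and
#' `b2` the mediator-on-outcome direct estimate from the multivariable
#' fit. Its SE uses the sum-of-squares (delta) method with no covariance
#' term, `sqrt(b2^2 se1^2 + b1^2 se2^2)`, appropriate because the two
#' estimates come from separate fits. The proportion mediated is
#' `indirect / total`, reported as computed (values outside \[0, 1\] are
#' flagged, never truncated) and undefined when the total is zero.
#'
#' @param total `mr_result` for the trait-on-outcome total effect.
#' @param mvmr `mvmr_result` for (trait, mediator) on the outcome.
#' @param trait_to_mediator `mr_result` for the trait-on-mediator effect.
#' @param trait_id,mediator_id,outcome_id Labels carried into the result.
#' @param proportion_ci Also compute a delta-method CI for the proportion
#'   mediated (off by default; the point estimate is the primary report).
#' @return A list of class `mediation_result` with elements `total`,
#'   `direct`, `indirect` (each estimate/se/ci_low/ci_high),
#'   `beta_trait_mediator`, `direct_mediator_outcome`,
#'   `proportion_mediated`, and `flags`.
#' @export
decompose <- function(total, mvmr, trait_to_mediator,
                      trait_id = NA_character_, mediator_id = NA_character_,
                      outcome_id = NA_character_, proportion_ci = FALSE) {
  stopifnot(inherits(total, "mr_result"), inherits(mvmr, "mvmr_result"),
            inherits(trait_to_mediator, "mr_result"))
  b1 <- trait_to_mediator$estimate
  se1 <- trait_to_mediator$se
  b2 <- unname(mvmr$estimates["mediator"])
  se2 <- unname(mvmr$ses["mediator"])
  indirect <- b1 * b2
  se_ind <- sqrt(b2^2 * se1^2 + b1^2 * se2^2)
  direct <- unname(mvmr$estimates["exposure"])
  se_dir <- unname(mvmr$ses["exposure"])
  flags <- character(0)
  if (total$estimate == 0) {
    prop <- NA_real_
    flags <- c(flags, "total_zero_proportion_undefined")
  } else {
    prop <- indirect / total$estimate
    if (prop < 0 || prop > 1) flags <- c(flags, "proportion_outside_unit")
  }
  band <- function(est, se) {
    list(estimate = est, se = se,
         ci_low = est - Z95 * se, ci_high = est + Z95 * se)
  }
  out <- list(trait_id = trait_id, mediator_id = mediator_id,
              outcome_id = outcome_id,
              total = band(total$estimate, total$se),
              direct = band(direct, se_dir),
              indirect = band(indirect, se_ind),
              beta_trait_mediator = list(estimate = b1, se = se1),
              direct_mediator_outcome = list(estimate = b2, se = se2),
              proportion_mediated = prop,
              flags = flags)
  if (proportion_ci && !is.na(prop) && total$estimate != 0) {
    # delta method on the ratio, again with no covariance term
    se_prop <- sqrt(se_ind^2 / total$estimate^2 +
                      indirect^2 * total$se^2 / total$estimate^4)
    out$proportion_ci <- c(prop - Z95 * se_prop, prop + Z95 * se_prop)
  }
  class(out) <- "mediation_result"
  out
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Two-step MR mediation: ", x$trait_id, " -> ", x$mediator_id, " -> ",
      x$outcome_id, "\n", sep = "")
  fmt <- function(nm, b) {
    cat(sprintf("  %-9s %.4g (95%% CI %.4g to %.4g)\n", nm, b$estimate,
                b$ci_low, b$ci_high))
  }
  fmt("total", x$total); fmt("direct", x$direct); fmt("indirect", x$indirect)
  cat(sprintf("  proportion mediated: %.3g\n", x$proportion_mediated))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(trait_id = x$trait_id, mediator_id = x$mediator_id,
             outcome_id = x$outcome_id,
             total = x$total$estimate, total_se = x$total$se,
             total_ci_low = x$total$ci_low, total_ci_high = x$total$ci_high,
             direct = x$direct$estimate, direct_se = x$direct$se,
             direct_ci_low = x$direct$ci_low,
             direct_ci_high = x$direct$ci_high,
             indirect = x$indirect$estimate, indirect_se = x$indirect$se,
             indirect_ci_low = x$indirect$ci_low,
             indirect_ci_high = x$indirect$ci_high,
             proportion_mediated = x$proportion_mediated,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Maximum relative attenuation of the MR-Egger slope
#'
#' Measurement error in the variant-exposure associations dilutes the
#' MR-Egger slope towards the null by at most `(1 - I2_GX) * 100` per
#' cent; an `I2_GX` of 0.93 therefore bounds the relative bias at 7%.
#'
#' @param i2gx The I-squared statistic for the exposure associations, in
#'   `[0, 1)` (see [i2gx()]).
#' @return The attenuation bound as a percentage.
#' @export
egger_attenuation <- function(i2gx) {
  stopifnot(is.numeric(i2gx), all(i2gx >= 0), all(i2gx <= 1))
  (1 - i2gx) * 100
}
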