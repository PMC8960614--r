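# Seeded generator of three-sample GWAS summary statistics with a known
# trait -> mediator -> outcome causal system.

#' Simulation configuration
#'
#' Parameters of the structural model used to generate three-sample
#' summary statistics (trait, mediator and outcome GWAS from
#' non-overlapping samples). The trait's instruments carry per-variant
#' effects `gamma`; the mediator inherits `beta_XM * gamma` from the trait
#' plus its own instruments `delta`; the outcome association of every
#' variant is `theta_X * (variant-trait) + theta_M * (variant-mediator)`
#' plus any pleiotropic term, so the implied total trait-on-outcome effect
#' is `theta_X + beta_XM * theta_M`. Observed associations add sampling
#' noise with `se = 1/sqrt(n * 2 f (1 - f))`, independent across the three
#' samples.
#'
#' Default effect sizes (`theta_X = 0.2`, `beta_XM = 0.3`,
#' `theta_M = 0.5`) define the reference mediation system used throughout
#' the package's validation (implied proportion mediated 0.15/0.35); the
#' default sample size of 200,000 per GWAS matches the scale of modern
#' biobank and consortium studies.
#'
#' @param n_snps_trait,n_snps_mediator Instrument counts for the trait and
#'   the mediator's own instruments.
#' @param n_trait,n_mediator_gwas,n_outcome_gwas Effective GWAS sample
#'   sizes.
#' @param theta_X Direct trait-on-outcome effect.
#' @param beta_XM Trait-on-mediator effect.
#' @param theta_M Direct mediator-on-outcome effect.
#' @param reverse_MX Mediator-on-trait effect (nonzero for bidirectional
#'   fixtures).
#' @param pleiotropy_mode `"none"`, `"balanced"` (mean-zero direct
#'   variant-outcome effects) or `"directional"` (mean
#'   `pleiotropy_mean`).
#' @param pleiotropy_sd,pleiotropy_mean Pleiotropic effect distribution,
#'   in outcome-effect units.
#' @param invalid_fraction Fraction of trait instruments given pleiotropic
#'   effects.
#' @param ld_block_size,ld_rho Variants come in consecutive blocks of this
#'   size with pairwise correlation `ld_rho` (block size 1 = independent);
#'   marginal associations and sampling noise both respect the block
#'   correlation.
#' @param eaf_range Range of the uniform effect-allele-frequency draw.
#' @param gamma_range Range of the uniform draw of instrument effect
#'   magnitudes (signs random).
#' @param palindrome_rate Fraction of variants given A/T or C/G allele
#'   pairs.
#' @param strand_flip_rate,allele_swap_rate Rates at which the mediator
#'   and outcome files report variants on the complementary strand or
#'   with swapped alleles, exercising harmonisation.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps_trait = 50, n_snps_mediator = 30,
                       n_trait = 2e5, n_mediator_gwas = 2e5,
                       n_outcome_gwas = 2e5,
                       theta_X = 0.2, beta_XM = 0.3, theta_M = 0.5,
                       reverse_MX = 0,
                       pleiotropy_mode = c("none", "balanced",
                                           "directional"),
                       pleiotropy_sd = 0.02, pleiotropy_mean = 0.05,
                       invalid_fraction = 0,
                       ld_block_size = 1, ld_rho = 0,
                       eaf_range = c(0.05, 0.95),
                       gamma_range = c(0.03, 0.08),
                       palindrome_rate = 0.1, strand_flip_rate = 0.1,
                       allele_swap_rate = 0.2, seed = NULL) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snps_trait >= 0, n_snps_mediator >= 0,
            n_trait > 0, n_mediator_gwas > 0, n_outcome_gwas > 0,
            invalid_fraction >= 0, invalid_fraction <= 1,
            abs(ld_rho) < 1, ld_block_size >= 1)
  structure(as.list(environment()), class = "sim_config")
}

.non_palindromic_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                   "G", "A", "C", "A", "G", "T", "C", "T"),
                                 ncol = 2, byrow = TRUE)

# Draw allele pairs: palindromic (A/T or C/G) with the configured rate.
.draw_alleles <- function(m, palindrome_rate) {
  pal <- stats::runif(m) < palindrome_rate
  ea <- oa <- character(m)
  if (any(pal)) {
    at <- stats::runif(sum(pal)) < 0.5
    ea[pal] <- ifelse(at, "A", "C")
    oa[pal] <- ifelse(at, "T", "G")
  }
  if (any(!pal)) {
    pick <- sample(nrow(.non_palindromic_pairs), sum(!pal), replace = TRUE)
    ea[!pal] <- .non_palindromic_pairs[pick, 1]
    oa[!pal] <- .non_palindromic_pairs[pick, 2]
  }
  data.frame(effect_allele = ea, other_allele = oa,
             stringsAsFactors = FALSE)
}

# Re-express a summary table with swapped alleles and/or on the
# complementary strand, as an independent GWAS might report it.
.obscure_representation <- function(df, strand_flip_rate, allele_swap_rate) {
  m <- nrow(df)
  swap <- stats::runif(m) < allele_swap_rate
  if (any(swap)) {
    ea <- df$effect_allele[swap]
    df$effect_allele[swap] <- df$other_allele[swap]
    df$other_allele[swap] <- ea
    df$beta[swap] <- -df$beta[swap]
    df$eaf[swap] <- 1 - df$eaf[swap]
  }
  flip <- stats::runif(m) < strand_flip_rate
  if (any(flip)) {
    # strand flip relabels the alleles only; beta and eaf still refer to
    # the same physical allele
    df$effect_allele[flip] <- comp_allele(df$effect_allele[flip])
    df$other_allele[flip] <- comp_allele(df$other_allele[flip])
  }
  df
}

# Block-structured LD correlation matrix for m variants.
.block_ld <- function(m, block_size, rho) {
  r <- diag(m)
  if (block_size > 1 && rho != 0) {
    for (start in seq(1, m, by = block_size)) {
      idx <- start:min(start + block_size - 1, m)
      r[idx, idx] <- rho
      diag(r)[idx] <- 1
    }
  }
  r
}

# Correlated sampling noise: per-variant scale se, correlation r.
.ld_noise <- function(se, r_chol) {
  se * drop(t(r_chol) %*% stats::rnorm(length(se)))
}

#' Simulate a three-sample summary-statistics study
#'
#' Generates trait, mediator and outcome GWAS summary statistics under the
#' linear structural model described in [sim_config()], together with the
#' LD matrix used and a ground-truth record for parameter-recovery tests.
#' Allele representations in the mediator and outcome files are randomly
#' swapped or strand-flipped so that harmonisation is exercised
#' end-to-end.
#'
#' @param cfg A [sim_config()].
#' @return A list: `trait`, `mediator`, `outcome` ([sumstats] objects),
#'   `ld` (an [ld_matrix()]), and `truth` (list with the realised per-SNP
#'   effects, the structural parameters, and the implied `total`,
#'   `indirect` and `proportion_mediated`).
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nt <- cfg$n_snps_trait
  nm <- cfg$n_snps_mediator
  m <- nt + nm
  stopifnot(m > 0)

  ids <- sprintf("rs%07d", seq_len(m))
  n_blocks <- ceiling(m / cfg$ld_block_size)
  block <- rep(seq_len(n_blocks), each = cfg$ld_block_size)[seq_len(m)]
  chromosome <- as.character(((block - 1) %% 22) + 1)
  block_on_chr <- stats::ave(block, chromosome, FUN = function(b)
    match(b, unique(b)))
  within_block <- stats::ave(seq_len(m), block, FUN = seq_along)
  position <- as.integer(1e6 + (block_on_chr - 1) * 3e7 +
                           (within_block - 1) * 5000)

  f <- stats::runif(m, cfg$eaf_range[1], cfg$eaf_range[2])
  alleles <- .draw_alleles(m, cfg$palindrome_rate)

  gamma <- numeric(0)
  if (nt > 0) {
    gamma <- sample(c(-1, 1), nt, replace = TRUE) *
      stats::runif(nt, cfg$gamma_range[1], cfg$gamma_range[2])
  }
  delta <- numeric(0)
  if (nm > 0) {
    delta <- sample(c(-1, 1), nm, replace = TRUE) *
      stats::runif(nm, cfg$gamma_range[1], cfg$gamma_range[2])
  }

  alpha <- numeric(m)
  if (nt > 0 && cfg$pleiotropy_mode != "none" && cfg$invalid_fraction > 0) {
    n_invalid <- ceiling(cfg$invalid_fraction * nt)
    invalid <- sample(seq_len(nt), n_invalid)
    mu <- if (cfg$pleiotropy_mode == "directional") cfg$pleiotropy_mean else 0
    alpha[invalid] <- stats::rnorm(n_invalid, mu, cfg$pleiotropy_sd)
  }

  b_x_joint <- c(gamma, cfg$reverse_MX * delta)
  b_m_joint <- c(cfg$beta_XM * gamma, delta)
  # pleiotropic effects are defined per exposure-increasing allele, so
  # they survive harmonisation's orientation step with their sign intact
  sgn <- sign(b_x_joint)
  sgn[sgn == 0] <- 1
  b_y_joint <- cfg$theta_X * b_x_joint + cfg$theta_M * b_m_joint +
    alpha * sgn

  r <- .block_ld(m, cfg$ld_block_size, cfg$ld_rho)
  b_x <- drop(r %*% b_x_joint)
  b_m <- drop(r %*% b_m_joint)
  b_y <- drop(r %*% b_y_joint)

  r_chol <- chol(r)
  se_of <- function(n) 1 / sqrt(n * 2 * f * (1 - f))
  make_set <- function(b_true, n, id, label, type, obscure) {
    se <- se_of(n)
    beta <- b_true + .ld_noise(se, r_chol)
    df <- data.frame(variant_id = ids, chromosome = chromosome,
                     position = position,
                     effect_allele = alleles$effect_allele,
                     other_allele = alleles$other_allele,
                     eaf = f, beta = beta, se = se,
                     pval = pmax(2 * stats::pnorm(-abs(beta / se)),
                                 .Machine$double.xmin),
                     n = n, stringsAsFactors = FALSE)
    if (obscure) {
      df <- .obscure_representation(df, cfg$strand_flip_rate,
                                    cfg$allele_swap_rate)
    }
    sumstats(df, trait_id = id, trait_label = label, trait_type = type)
  }

  trait <- make_set(b_x, cfg$n_trait, "trait", "simulated trait",
                    "continuous", obscure = FALSE)
  mediator <- make_set(b_m, cfg$n_mediator_gwas, "mediator",
                       "simulated mediator", "binary-logistic",
                       obscure = TRUE)
  outcome <- make_set(b_y, cfg$n_outcome_gwas, "outcome",
                      "simulated outcome", "binary-logistic",
                      obscure = TRUE)

  total <- cfg$theta_X + cfg$beta_XM * cfg$theta_M
  truth <- list(gamma = gamma, delta = delta, alpha = alpha,
                theta_X = cfg$theta_X, beta_XM = cfg$beta_XM,
                theta_M = cfg$theta_M, reverse_MX = cfg$reverse_MX,
                total = total,
                indirect = cfg$beta_XM * cfg$theta_M,
                proportion_mediated = cfg$beta_XM * cfg$theta_M / total)

  list(trait = trait, mediator = mediator, outcome = outcome,
       ld = ld_matrix(ids, r), truth = truth)
}

#' Bidirectional trait-mediator fixture
#'
#' Convenience wrapper around [simulate_study()] whose default
#' configuration gives the mediator's own instruments a nonzero effect on
#' the trait (`reverse_MX = 0.3`), so that bidirectional univariate MR
#' finds supportive evidence in both directions.
#'
#' @param cfg A [sim_config()]; the default sets `reverse_MX = 0.3`.
#' @return As [simulate_study()].
#' @export
make_bidirectional_fixture <- function(cfg = sim_config(reverse_MX = 0.3)) {
  simulate_study(cfg)
}

#' Simulate a multi-trait screening study
#'
#' Generates a shared mediator and outcome GWAS plus one trait GWAS per
#' entry of `trait_specs`, with per-trait causal structure, for testing
#' the two-stage screening and decision logic. Every trait has its own
#' instrument SNPs (mutually independent across traits); the mediator
#' file covers all SNPs; each outcome's associations accumulate every
#' trait's direct effect plus the mediated path.
#'
#' @param trait_specs Named list; each element a list with fields
#'   `n_snps`, `beta_XM`, `reverse_MX`, and `theta`, a named numeric
#'   vector of direct effects on each outcome.
#' @param outcome_theta_M Named numeric vector: the mediator's direct
#'   effect on each outcome (names define the outcomes).
#' @param n_snps_mediator Mediator's own instrument count.
#' @param n_gwas Sample size used for every GWAS.
#' @param gamma_range,eaf_range,palindrome_rate,strand_flip_rate,allele_swap_rate
#'   As in [sim_config()].
#' @param seed Integer seed.
#' @return A list: `traits` (named list of [sumstats]), `mediator`,
#'   `outcomes` (named list of [sumstats]), `truth` (per-trait implied
#'   totals and proportions mediated per outcome).
#' @export
simulate_screening_study <- function(trait_specs, outcome_theta_M,
                                     n_snps_mediator = 30, n_gwas = 2e5,
                                     gamma_range = c(0.03, 0.08),
                                     eaf_range = c(0.05, 0.95),
                                     palindrome_rate = 0.1,
                                     strand_flip_rate = 0.1,
                                     allele_swap_rate = 0.2, seed = NULL) {
  stopifnot(is.list(trait_specs), !is.null(names(trait_specs)),
            is.numeric(outcome_theta_M), !is.null(names(outcome_theta_M)))
  if (!is.null(seed)) set.seed(seed)
  outcome_ids <- names(outcome_theta_M)
  n_per_trait <- vapply(trait_specs, function(s) as.integer(s$n_snps), 0L)
  m <- sum(n_per_trait) + n_snps_mediator
  ids <- sprintf("rs%07d", seq_len(m))
  owner <- rep(c(names(trait_specs), ".mediator"),
               c(n_per_trait, n_snps_mediator))
  chromosome <- as.character(((seq_len(m) - 1) %% 22) + 1)
  position <- as.integer(1e6 +
                           (stats::ave(seq_len(m), chromosome,
                                       FUN = seq_along) - 1) * 3e7)
  f <- stats::runif(m, eaf_range[1], eaf_range[2])
  alleles <- .draw_alleles(m, palindrome_rate)
  eff <- sample(c(-1, 1), m, replace = TRUE) *
    stats::runif(m, gamma_range[1], gamma_range[2])

  # true associations, all m variants
  b_med <- numeric(m)
  b_trait <- stats::setNames(
    rep(list(numeric(m)), length(trait_specs)), names(trait_specs))
  med_own <- owner == ".mediator"
  b_med[med_own] <- eff[med_own]
  for (tn in names(trait_specs)) {
    own <- owner == tn
    b_trait[[tn]][own] <- eff[own]
    b_trait[[tn]][med_own] <- trait_specs[[tn]]$reverse_MX * eff[med_own]
    b_med[own] <- b_med[own] + trait_specs[[tn]]$beta_XM * eff[own]
  }
  b_out <- stats::setNames(rep(list(numeric(m)), length(outcome_ids)),
                           outcome_ids)
  for (on in outcome_ids) {
    acc <- outcome_theta_M[[on]] * b_med
    for (tn in names(trait_specs)) {
      acc <- acc + trait_specs[[tn]]$theta[[on]] * b_trait[[tn]]
    }
    b_out[[on]] <- acc
  }

  se <- 1 / sqrt(n_gwas * 2 * f * (1 - f))
  make <- function(idx, b_true, id, type, obscure) {
    beta <- b_true[idx] + stats::rnorm(length(idx)) * se[idx]
    df <- data.frame(variant_id = ids[idx], chromosome = chromosome[idx],
                     position = position[idx],
                     effect_allele = alleles$effect_allele[idx],
                     other_allele = alleles$other_allele[idx],
                     eaf = f[idx], beta = beta, se = se[idx],
                     pval = pmax(2 * stats::pnorm(-abs(beta / se[idx])),
                                 .Machine$double.xmin),
                     n = n_gwas, stringsAsFactors = FALSE)
    if (obscure) {
      df <- .obscure_representation(df, strand_flip_rate, allele_swap_rate)
    }
    sumstats(df, trait_id = id,
             trait_type = if (type) "binary-logistic" else "continuous")
  }

  traits <- stats::setNames(lapply(names(trait_specs), function(tn) {
    idx <- which(owner %in% c(tn, ".mediator"))
    make(idx, b_trait[[tn]], tn, type = FALSE, obscure = FALSE)
  }), names(trait_specs))
  mediator <- make(seq_len(m), b_med, "mediator", type = TRUE,
                   obscure = TRUE)
  outcomes <- stats::setNames(lapply(outcome_ids, function(on) {
    make(seq_len(m), b_out[[on]], on, type = TRUE, obscure = TRUE)
  }), outcome_ids)

  truth <- lapply(names(trait_specs), function(tn) {
    spec <- trait_specs[[tn]]
    tot <- vapply(outcome_ids, function(on)
      spec$theta[[on]] + spec$beta_XM * outcome_theta_M[[on]], 0.0)
    list(trait_id = tn, beta_XM = spec$beta_XM,
         reverse_MX = spec$reverse_MX, total = tot,
         indirect = spec$beta_XM * outcome_theta_M,
         proportion_mediated = ifelse(tot != 0,
                                      spec$beta_XM * outcome_theta_M / tot,
                                      NA_real_))
  })
  names(truth) <- names(trait_specs)

  list(traits = traits, mediator = mediator, outcomes = outcomes,
       truth = truth)
}
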