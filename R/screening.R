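# Stage-1 evidence classification and two-stage study orchestration.

#' Benjamini-Hochberg false-discovery-rate screening
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]) with rejection at
#' adjusted p strictly below `alpha`.
#'
#' @param pvals Numeric vector of p-values in (0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return A list: `adjusted` (BH-adjusted p-values) and `reject` (logical
#'   flags). Empty input gives empty output.
#' @export
bh_fdr <- function(pvals, alpha = 0.05) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  if (length(pvals) == 0) {
    return(list(adjusted = numeric(0), reject = logical(0)))
  }
  stopifnot(all(is.na(pvals) | (pvals > 0 & pvals <= 1)))
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted < alpha)
}

#' Classify the direction of a trait-mediator relationship
#'
#' Maps the pair of supportive-evidence flags from the forward
#' (trait-on-mediator) and reverse (mediator-on-trait) univariate MR
#' analyses to a category. Bidirectional traits are excluded from
#' mediation analysis because neither phenotype can be designated the
#' exposure.
#'
#' @param forward,reverse Logical supportive-evidence flags.
#' @return One of `"cause-only"`, `"consequence-only"`, `"bidirectional"`,
#'   `"neither"`.
#' @export
classify_bidirectional <- function(forward, reverse) {
  stopifnot(is.logical(forward), is.logical(reverse),
            !is.na(forward), !is.na(reverse))
  if (forward && reverse) "bidirectional"
  else if (forward) "cause-only"
  else if (reverse) "consequence-only"
  else "neither"
}

#' Stage-2 eligibility decision for one trait
#'
#' A trait progresses to mediation analysis for an outcome when stage 1
#' found (1) supportive evidence of an effect of the trait on the
#' mediator, (2) limited evidence of an effect of the mediator on the
#' trait, and (3) supportive evidence of an effect of the trait on that
#' outcome.
#'
#' @param evidence An evidence data.frame with columns `trait_id`,
#'   `family`, `supportive` (families `"trait->mediator"`,
#'   `"mediator->trait"` and `"trait-><outcome_id>"`).
#' @param trait_id The trait to decide.
#' @param outcome_ids Character vector of outcome identifiers.
#' @return A one-row data.frame: `trait_id`, `cause_of_mediator`,
#'   `consequence_of_mediator`, `bidirectional`, `category`, and one
#'   logical `stage2_<outcome>` column per outcome.
#' @export
stage2_eligibility <- function(evidence, trait_id, outcome_ids) {
  rows <- evidence[evidence$trait_id == trait_id, ]
  need <- c("trait->mediator", "mediator->trait",
            paste0("trait->", outcome_ids))
  missing_fam <- setdiff(need, rows$family)
  if (length(missing_fam) > 0) {
    stop("incomplete evidence for trait '", trait_id, "': missing ",
         paste(missing_fam, collapse = ", "), call. = FALSE)
  }
  sup <- function(fam) {
    v <- rows$supportive[rows$family == fam][1]
    isTRUE(v)
  }
  fwd <- sup("trait->mediator")
  rev <- sup("mediator->trait")
  cat_ <- classify_bidirectional(fwd, rev)
  out <- data.frame(trait_id = trait_id,
                    cause_of_mediator = fwd,
                    consequence_of_mediator = rev,
                    bidirectional = fwd && rev,
                    category = cat_,
                    stringsAsFactors = FALSE)
  for (o in outcome_ids) {
    out[[paste0("stage2_", o)]] <- fwd && !rev && sup(paste0("trait->", o))
  }
  out
}

#' Study configuration
#'
#' Bundles the thresholds, LD source and reproducibility settings used
#' across the pipeline. Defaults follow standard two-sample MR practice:
#' genome-wide significance 5e-8, clumping at r-squared 0.001 within a
#' 10 Mb window, at least 10 instruments, 5% FDR.
#'
#' @param p_threshold Instrument p-value threshold (strict `<`).
#' @param r2_threshold,window_bp Clumping parameters.
#' @param min_instruments Minimum post-clump instrument count.
#' @param fdr_alpha FDR level for supportive evidence.
#' @param fdr_scope `"family"` applies BH within each analysis family
#'   (trait-on-mediator, mediator-on-trait, trait-on-each-outcome);
#'   `"joint"` corrects across all families at once.
#' @param palindrome_eaf_window Frequency half-width for palindromic
#'   variants (see [harmonise()]).
#' @param n_boot Bootstrap replicates for median/mode SEs.
#' @param phi Mode-estimator bandwidth multiplier.
#' @param seed Integer seed used for every stochastic step.
#' @param random_effects Multiplicative random-effects SEs (see
#'   [mr_ivw()]).
#' @param methods Estimators to run in the univariate suite.
#' @param ld An [ld_matrix()] or `NULL` (all variants independent).
#' @return A list of class `study_config`.
#' @export
study_config <- function(p_threshold = 5e-8, r2_threshold = 0.001,
                         window_bp = 1e7, min_instruments = 10,
                         fdr_alpha = 0.05,
                         fdr_scope = c("family", "joint"),
                         palindrome_eaf_window = 0.08, n_boot = 1000,
                         phi = 1, seed = 1, random_effects = TRUE,
                         methods = c("ivw", "egger", "weighted-median",
                                     "simple-mode", "weighted-mode"),
                         ld = NULL) {
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_bp = window_bp, min_instruments = min_instruments,
                 fdr_alpha = fdr_alpha, fdr_scope = match.arg(fdr_scope),
                 palindrome_eaf_window = palindrome_eaf_window,
                 n_boot = n_boot, phi = phi, seed = seed,
                 random_effects = random_effects, methods = methods,
                 ld = ld),
            class = "study_config")
}

.ivw_row <- function(suite) {
  r <- suite$results[suite$results$method %in% c("ivw", "wald"), ]
  if (nrow(r) == 0) NULL else r[1, ]
}

#' Run the full two-stage mediation study
#'
#' Stage 1 runs bidirectional univariate MR between every trait and the
#' mediator plus univariate MR of every trait on every outcome, applies
#' BH-FDR screening, and classifies each trait (cause-only,
#' consequence-only, bidirectional, neither). Stage 2 runs, for each
#' eligible (trait, outcome) pair, multivariable MR with trait and
#' mediator as joint exposures (instruments: the clumped union of both
#' exposures' genome-wide-significant variants, clumped on the p-values of
#' whichever exposure has the smaller pre-clump instrument set), the
#' conditional F and modified Q diagnostics, and the two-step mediation
#' decomposition.
#'
#' @param traits Named list of [sumstats] objects (candidate exposures).
#' @param mediator A [sumstats] object (e.g. liability to type 2
#'   diabetes).
#' @param outcomes Named list of [sumstats] objects (e.g. coronary and
#'   peripheral artery disease).
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, writes
#'   `stage1_evidence.tsv`, `stage_decisions.tsv`, `mvmr_results.tsv`,
#'   `mediation_results.tsv` and `run_manifest.json` (with per-file MD5
#'   checksums).
#' @return A list of class `mr_study`: `stage1` (evidence data.frame with
#'   raw and FDR-adjusted p-values), `decisions`, `mvmr_results`,
#'   `mediation_results`, `manifest`.
#' @export
run_study <- function(traits, mediator, outcomes, config = study_config(),
                      out_dir = NULL) {
  stopifnot(is.list(traits), length(traits) > 0, !is.null(names(traits)),
            inherits(mediator, "sumstats"), is.list(outcomes),
            !is.null(names(outcomes)))
  warnings_log <- character(0)
  note <- function(...) {
    warnings_log <<- c(warnings_log, paste0(...))
  }

  suites <- list()      # keyed by paste(trait, family)
  evidence <- list()
  for (tn in names(traits)) {
    analyses <- c(list(`trait->mediator` = list(traits[[tn]], mediator),
                       `mediator->trait` = list(mediator, traits[[tn]])),
                  stats::setNames(
                    lapply(names(outcomes),
                           function(o) list(traits[[tn]], outcomes[[o]])),
                    paste0("trait->", names(outcomes))))
    for (fam in names(analyses)) {
      suite <- tryCatch(
        run_uvmr_suite(analyses[[fam]][[1]], analyses[[fam]][[2]], config),
        error = function(e) {
          note("uvmr failed for ", tn, " [", fam, "]: ",
               conditionMessage(e))
          NULL
        })
      suites[[paste(tn, fam)]] <- suite
      ivw <- if (is.null(suite)) NULL else .ivw_row(suite)
      evidence[[paste(tn, fam)]] <- data.frame(
        trait_id = tn, family = fam,
        eligible = !is.null(suite) && suite$eligible,
        n_variants = if (is.null(ivw)) NA_integer_ else ivw$n_variants,
        estimate = if (is.null(ivw)) NA_real_ else ivw$estimate,
        se = if (is.null(ivw)) NA_real_ else ivw$se,
        pval = if (is.null(ivw)) NA_real_ else ivw$pval,
        stringsAsFactors = FALSE)
      if (!is.null(suite) && !suite$eligible) {
        note("trait ", tn, " [", fam, "] ineligible: ",
             suite$n_instruments, " post-clump instrument(s)")
      }
    }
  }
  evidence <- do.call(rbind, c(evidence, list(make.row.names = FALSE)))

  # FDR screening: within each analysis family by default
  evidence$fdr_pval <- NA_real_
  evidence$supportive <- FALSE
  if (config$fdr_scope == "family") {
    for (fam in unique(evidence$family)) {
      i <- which(evidence$family == fam & !is.na(evidence$pval))
      if (length(i) == 0) next
      f <- bh_fdr(evidence$pval[i], config$fdr_alpha)
      evidence$fdr_pval[i] <- f$adjusted
      evidence$supportive[i] <- f$reject
    }
  } else {
    i <- which(!is.na(evidence$pval))
    f <- bh_fdr(evidence$pval[i], config$fdr_alpha)
    evidence$fdr_pval[i] <- f$adjusted
    evidence$supportive[i] <- f$reject
  }

  decisions <- do.call(rbind, lapply(names(traits), function(tn) {
    stage2_eligibility(evidence, tn, names(outcomes))
  }))

  # Stage 2: multivariable MR + mediation for eligible pairs
  mvmr_rows <- list()
  med_rows <- list()
  for (tn in names(traits)) {
    for (on in names(outcomes)) {
      if (!isTRUE(decisions[[paste0("stage2_", on)]][
        decisions$trait_id == tn])) next
      res <- tryCatch(
        .stage2_pair(traits[[tn]], mediator, outcomes[[on]], tn, on,
                     suites, config),
        error = function(e) {
          note("stage 2 failed for ", tn, " -> ", on, ": ",
               conditionMessage(e))
          NULL
        })
      if (!is.null(res)) {
        mvmr_rows[[paste(tn, on)]] <- res$mvmr_row
        med_rows[[paste(tn, on)]] <- res$mediation_row
      }
    }
  }
  empty_bind <- function(rows) {
    if (length(rows) == 0) NULL
    else do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }

  study <- list(stage1 = evidence,
                decisions = decisions,
                mvmr_results = empty_bind(mvmr_rows),
                mediation_results = empty_bind(med_rows),
                manifest = NULL)
  class(study) <- "mr_study"

  manifest <- list(
    package = "mrmediate",
    version = as.character(utils::packageVersion("mrmediate")),
    seed = config$seed,
    config = config[c("p_threshold", "r2_threshold", "window_bp",
                      "min_instruments", "fdr_alpha", "fdr_scope",
                      "palindrome_eaf_window", "n_boot", "phi",
                      "random_effects", "methods")],
    conventions = list(
      clump_window = "one-sided: full window_bp from the index variant",
      conditional_f_denominator = "L - K + 1",
      modified_q_df = "L - K",
      cross_trait_sampling_covariance = 0),
    n_traits = length(traits),
    n_outcomes = length(outcomes),
    n_stage1_rows = nrow(evidence),
    n_mediation_rows = if (is.null(study$mediation_results)) 0L
      else nrow(study$mediation_results),
    warnings = warnings_log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(stage1_evidence = "stage1_evidence.tsv",
               stage_decisions = "stage_decisions.tsv",
               mvmr_results = "mvmr_results.tsv",
               mediation_results = "mediation_results.tsv")
    tables <- list(stage1_evidence = evidence,
                   stage_decisions = decisions,
                   mvmr_results = study$mvmr_results,
                   mediation_results = study$mediation_results)
    paths <- character(0)
    for (nm in names(files)) {
      p <- file.path(out_dir, files[[nm]])
      tab <- tables[[nm]]
      if (is.null(tab)) {
        tab <- data.frame()
      }
      utils::write.table(tab, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths[files[[nm]]] <- p
    }
    manifest$files <- lapply(paths, function(p)
      unname(tools::md5sum(p)))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  study$manifest <- manifest
  study
}

# One stage-2 (trait, outcome) pair: instrument union, clump, three-way
# harmonisation, multivariable fit, diagnostics, mediation decomposition.
.stage2_pair <- function(trait, mediator, outcome, tn, on, suites, config) {
  sig_t <- select_instruments(trait, config$p_threshold)
  sig_m <- select_instruments(mediator, config$p_threshold)
  # clump the union on the p-values of the exposure with the smaller
  # pre-clump instrument set
  chosen <- if (nrow(sig_t) <= nrow(sig_m)) sig_t else sig_m
  other <- if (nrow(sig_t) <= nrow(sig_m)) sig_m else sig_t
  extra <- subset_sumstats(other, !other$variant_id %in% chosen$variant_id)
  # where the chosen exposure also covers the other's variants, use its
  # p-values for those variants too
  chosen_full <- if (nrow(sig_t) <= nrow(sig_m)) trait else mediator
  in_chosen <- extra$variant_id %in% chosen_full$variant_id
  if (any(in_chosen)) {
    repl <- subset_sumstats(chosen_full,
                            match(extra$variant_id[in_chosen],
                                  chosen_full$variant_id))
    extra <- rbind(as.data.frame(repl),
                   as.data.frame(extra)[!in_chosen, , drop = FALSE])
  } else {
    extra <- as.data.frame(extra)
  }
  union_set <- sumstats(rbind(as.data.frame(chosen), extra),
                        trait_id = paste0(trait_id(chosen), "+union"))
  clumped <- greedy_clump(union_set, config$ld, config$r2_threshold,
                          config$window_bp)
  h3 <- merge_for_mvmr(trait, mediator, outcome, clumped$variant_id,
                       config$palindrome_eaf_window)
  fit <- mvmr_ivw(h3, config$random_effects)
  f_t <- conditional_f(h3, "exposure")
  f_m <- conditional_f(h3, "mediator")
  qa <- modified_q(h3, fit)
  total_suite <- suites[[paste(tn, paste0("trait->", on))]]
  fwd_suite <- suites[[paste(tn, "trait->mediator")]]
  total_row <- .ivw_row(total_suite)
  fwd_row <- .ivw_row(fwd_suite)
  as_mr <- function(row, method) {
    new_mr_result(method, row$estimate, row$se, row$pval, row$n_variants)
  }
  med <- decompose(total = as_mr(total_row, "ivw"),
                   mvmr = fit,
                   trait_to_mediator = as_mr(fwd_row, "ivw"),
                   trait_id = tn, mediator_id = trait_id(mediator),
                   outcome_id = on)
  mvmr_row <- data.frame(
    trait_id = tn, mediator_id = trait_id(mediator), outcome_id = on,
    n_variants = fit$n_variants,
    direct_trait = unname(fit$estimates["exposure"]),
    direct_trait_se = unname(fit$ses["exposure"]),
    direct_trait_ci_low = unname(fit$ci_low["exposure"]),
    direct_trait_ci_high = unname(fit$ci_high["exposure"]),
    direct_trait_pval = unname(fit$pvals["exposure"]),
    direct_mediator = unname(fit$estimates["mediator"]),
    direct_mediator_se = unname(fit$ses["mediator"]),
    direct_mediator_ci_low = unname(fit$ci_low["mediator"]),
    direct_mediator_ci_high = unname(fit$ci_high["mediator"]),
    direct_mediator_pval = unname(fit$pvals["mediator"]),
    f_trait = f_t, f_mediator = f_m,
    q_a = qa$q_a, q_a_df = qa$q_a_df,
    q_a_critical_5pct = qa$q_a_critical_5pct,
    q_a_exceeds = qa$q_a_exceeds,
    stringsAsFactors = FALSE)
  list(mvmr_row = mvmr_row, mediation_row = as.data.frame(med))
}

#' @export
print.mr_study <- function(x, ...) {
  cat("Two-stage MR mediation study\n")
  cat("  stage 1: ", nrow(x$stage1), " analyses over ",
      length(unique(x$stage1$trait_id)), " trait(s)\n", sep = "")
  cat("  stage 2: ",
      if (is.null(x$mediation_results)) 0 else nrow(x$mediation_results),
      " mediation result(s)\n", sep = "")
  invisible(x)
}
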