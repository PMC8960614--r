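# Allele harmonisation of summary statistics across GWAS samples.

comp_allele <- function(a) chartr("ACGT", "TGCA", a)

is_palindromic <- function(a1, a2) comp_allele(a1) == a2

# Align one "other" GWAS onto the exposure's allele coding, variant by
# variant. Returns a data.frame keyed by variant_id with aligned beta, se,
# eaf and a status column in {"ok", "palindromic", "incompatible"}.
# No exposure-increasing orientation is applied here; see orient_harmonised().
align_pair <- function(exposure, other, palindrome_eaf_window = 0.08) {
  ids <- intersect(exposure$variant_id, other$variant_id)
  ex <- as.data.frame(exposure)[match(ids, exposure$variant_id), ]
  ot <- as.data.frame(other)[match(ids, other$variant_id), ]

  ea_x <- ex$effect_allele; oa_x <- ex$other_allele
  ea_o <- ot$effect_allele; oa_o <- ot$other_allele

  beta <- ot$beta
  eaf <- ot$eaf
  status <- rep("ok", length(ids))
  w <- palindrome_eaf_window

  direct <- ea_o == ea_x & oa_o == oa_x
  swapped <- ea_o == oa_x & oa_o == ea_x
  s_direct <- comp_allele(ea_o) == ea_x & comp_allele(oa_o) == oa_x
  s_swapped <- comp_allele(ea_o) == oa_x & comp_allele(oa_o) == ea_x
  pal <- is_palindromic(ea_x, oa_x)

  # Non-palindromic variants: label (plus strand-complement) matching is
  # unambiguous.
  np <- !pal
  flip <- np & !direct & (swapped | s_swapped)
  incompatible <- np & !(direct | swapped | s_direct | s_swapped)
  beta[flip] <- -beta[flip]
  eaf[flip] <- 1 - eaf[flip]
  status[incompatible] <- "incompatible"

  # Palindromic variants: labels cannot distinguish an allele swap from a
  # strand flip, so alignment is resolved by effect-allele frequency.
  # Variants with missing eaf, or either frequency within
  # [0.5 - w, 0.5 + w], are dropped.
  if (any(pal)) {
    pal_bad_labels <- pal & !(direct | swapped)
    status[pal_bad_labels] <- "incompatible"
    p <- pal & !pal_bad_labels
    # first align nominally by labels
    pflip <- p & swapped
    beta[pflip] <- -beta[pflip]
    eaf[pflip] <- 1 - eaf[pflip]
    unresolved <- p & (is.na(ex$eaf) | is.na(eaf) |
                         abs(ex$eaf - 0.5) <= w | abs(eaf - 0.5) <= w)
    status[unresolved] <- "palindromic"
    # residual strand flip: frequencies on opposite sides of 0.5
    res <- p & !unresolved & (ex$eaf - 0.5) * (eaf - 0.5) < 0
    beta[res] <- -beta[res]
    eaf[res] <- 1 - eaf[res]
  }

  data.frame(variant_id = ids,
             beta = beta, se = ot$se, eaf = eaf, pval = ot$pval, n = ot$n,
             status = status, stringsAsFactors = FALSE)
}

new_harmonised_set <- function(df, n_matched, n_dropped_palindromic,
                               n_dropped_incompatible) {
  rownames(df) <- NULL
  structure(df,
            n_matched = n_matched,
            n_dropped_palindromic = n_dropped_palindromic,
            n_dropped_incompatible = n_dropped_incompatible,
            class = c("harmonised_set", "data.frame"))
}

# Orient every variant so beta_exp >= 0, flipping allele labels, frequencies
# and all aligned betas together.
orient_harmonised <- function(df) {
  neg <- df$beta_exp < 0
  if (any(neg)) {
    ea <- df$effect_allele[neg]
    df$effect_allele[neg] <- df$other_allele[neg]
    df$other_allele[neg] <- ea
    df$eaf[neg] <- 1 - df$eaf[neg]
    for (col in intersect(c("beta_exp", "beta_out", "beta_med"), names(df))) {
      df[[col]][neg] <- -df[[col]][neg]
    }
  }
  df
}

#' Harmonise exposure and outcome summary statistics
#'
#' Matches variants by identifier, aligns the outcome associations onto the
#' exposure's allele coding (flipping signs for swapped alleles,
#' complementing for strand flips), resolves palindromic (A/T, C/G)
#' variants by effect-allele frequency, and finally orients every variant
#' to the exposure-increasing allele so that `beta_exp >= 0`.
#'
#' Palindromic variants are retained only when both frequencies are present
#' and fall outside `[0.5 - w, 0.5 + w]`; frequencies on opposite sides of
#' 0.5 indicate a strand flip and the outcome effect is flipped
#' accordingly. Unresolvable palindromes and variants with incompatible
#' alleles are dropped and counted in the attributes
#' `n_dropped_palindromic` and `n_dropped_incompatible`
#' (`n_matched = nrow + both drop counts`).
#'
#' @param exposure,outcome [sumstats] objects.
#' @param palindrome_eaf_window Half-width `w` of the ambiguous frequency
#'   interval around 0.5 (default 0.08).
#' @return A `harmonised_set`: a data.frame with columns `variant_id`,
#'   `chromosome`, `position`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`, with drop counts as
#'   attributes.
#' @export
harmonise <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  if (nrow(exposure) == 0 || nrow(outcome) == 0) {
    stop("cannot harmonise empty summary-statistic sets", call. = FALSE)
  }
  al <- align_pair(exposure, outcome, palindrome_eaf_window)
  if (nrow(al) == 0) {
    stop("no overlapping variants between '", trait_id(exposure), "' and '",
         trait_id(outcome), "'", call. = FALSE)
  }
  ex <- as.data.frame(exposure)[match(al$variant_id, exposure$variant_id), ]
  keep <- al$status == "ok"
  df <- data.frame(variant_id = al$variant_id[keep],
                   chromosome = ex$chromosome[keep],
                   position = ex$position[keep],
                   effect_allele = ex$effect_allele[keep],
                   other_allele = ex$other_allele[keep],
                   eaf = ex$eaf[keep],
                   beta_exp = ex$beta[keep],
                   se_exp = ex$se[keep],
                   beta_out = al$beta[keep],
                   se_out = al$se[keep],
                   stringsAsFactors = FALSE)
  df <- orient_harmonised(df)
  new_harmonised_set(df,
                     n_matched = nrow(al),
                     n_dropped_palindromic = sum(al$status == "palindromic"),
                     n_dropped_incompatible = sum(al$status == "incompatible"))
}

#' Three-way harmonisation for multivariable MR
#'
#' Aligns mediator and outcome associations onto the exposure's allele
#' coding at a supplied instrument list, keeping only variants present and
#' alignable in all three sets, oriented to the exposure-increasing allele.
#'
#' @param exposure,mediator,outcome [sumstats] objects.
#' @param instruments Character vector of variant identifiers (typically
#'   the clumped union of both exposures' instruments).
#' @param palindrome_eaf_window As in [harmonise()].
#' @return A `harmonised_set` with additional columns `beta_med`, `se_med`.
#'   Fewer surviving variants than the number of exposures + 1 triggers a
#'   warning (downstream estimation will fail).
#' @export
merge_for_mvmr <- function(exposure, mediator, outcome, instruments,
                           palindrome_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "sumstats"), inherits(mediator, "sumstats"),
            inherits(outcome, "sumstats"), is.character(instruments))
  ex <- subset_sumstats(exposure, exposure$variant_id %in% instruments)
  if (nrow(ex) == 0) stop("no instrument present in the exposure set",
                          call. = FALSE)
  al_med <- align_pair(ex, mediator, palindrome_eaf_window)
  al_out <- align_pair(ex, outcome, palindrome_eaf_window)
  ids <- intersect(al_med$variant_id[al_med$status == "ok"],
                   al_out$variant_id[al_out$status == "ok"])
  both <- intersect(al_med$variant_id, al_out$variant_id)
  sm <- al_med$status[match(both, al_med$variant_id)]
  so <- al_out$status[match(both, al_out$variant_id)]
  n_pal <- sum((sm == "palindromic" | so == "palindromic") & !both %in% ids)
  exm <- as.data.frame(ex)[match(ids, ex$variant_id), ]
  am <- al_med[match(ids, al_med$variant_id), ]
  ao <- al_out[match(ids, al_out$variant_id), ]
  df <- data.frame(variant_id = ids,
                   chromosome = exm$chromosome,
                   position = exm$position,
                   effect_allele = exm$effect_allele,
                   other_allele = exm$other_allele,
                   eaf = exm$eaf,
                   beta_exp = exm$beta,
                   se_exp = exm$se,
                   beta_med = am$beta,
                   se_med = am$se,
                   beta_out = ao$beta,
                   se_out = ao$se,
                   stringsAsFactors = FALSE)
  df <- orient_harmonised(df)
  if (nrow(df) < 3) {
    warning("only ", nrow(df), " variant(s) survive three-way harmonisation;",
            " multivariable estimation needs at least 3", call. = FALSE)
  }
  n_matched <- length(instruments)
  new_harmonised_set(df,
                     n_matched = n_matched,
                     n_dropped_palindromic = n_pal,
                     n_dropped_incompatible = n_matched - nrow(df) - n_pal)
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat("Harmonised set: ", nrow(x), " variant(s) retained (",
      attr(x, "n_dropped_palindromic"), " palindromic, ",
      attr(x, "n_dropped_incompatible"), " incompatible/absent dropped)\n",
      sep = "")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Write a harmonised set and its drop counts
#'
#' Writes the aligned table as TSV plus a JSON sidecar recording the
#' matched/dropped variant counts.
#'
#' @param h A `harmonised_set`.
#' @param path Output TSV path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_harmonised <- function(h, path) {
  utils::write.table(as.data.frame(h), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(n_matched = attr(h, "n_matched"),
         n_retained = nrow(h),
         n_dropped_palindromic = attr(h, "n_dropped_palindromic"),
         n_dropped_incompatible = attr(h, "n_dropped_incompatible")),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
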