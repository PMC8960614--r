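# Fixture builders shared across the test files. Everything is generated
# in code; no stored data.

mk_ss <- function(variant_id, effect_allele, other_allele, beta,
                  se = rep(0.01, length(variant_id)),
                  pval = rep(1e-10, length(variant_id)),
                  eaf = rep(NA_real_, length(variant_id)),
                  chromosome = rep("1", length(variant_id)),
                  position = seq_along(variant_id) * 1000L,
                  n = 1e5, trait_id = "trait") {
  suppressMessages(sumstats(
    data.frame(variant_id = variant_id, chromosome = chromosome,
               position = position, effect_allele = effect_allele,
               other_allele = other_allele, eaf = eaf, beta = beta,
               se = se, pval = pval, n = n, stringsAsFactors = FALSE),
    trait_id = trait_id))
}

mk_h <- function(beta_exp, beta_out,
                 se_out = rep(1, length(beta_exp)),
                 se_exp = rep(0.01, length(beta_exp)),
                 beta_med = NULL, se_med = NULL) {
  k <- length(beta_exp)
  df <- data.frame(variant_id = sprintf("rs%03d", seq_len(k)),
                   chromosome = "1", position = seq_len(k) * 1000L,
                   effect_allele = "A", other_allele = "G",
                   eaf = 0.3, beta_exp = beta_exp, se_exp = se_exp,
                   beta_out = beta_out, se_out = se_out,
                   stringsAsFactors = FALSE)
  if (!is.null(beta_med)) {
    df$beta_med <- beta_med
    df$se_med <- if (is.null(se_med)) rep(0.01, k) else se_med
  }
  structure(df, n_matched = k, n_dropped_palindromic = 0L,
            n_dropped_incompatible = 0L,
            class = c("harmonised_set", "data.frame"))
}

# random harmonised set for property-style loops
rand_h <- function(k, mediator = FALSE) {
  bx <- runif(k, 0, 0.5)
  mk_h(beta_exp = bx,
       beta_out = 0.3 * bx + rnorm(k, 0, 0.05),
       se_out = runif(k, 0.02, 0.4),
       se_exp = runif(k, 0.005, 0.05),
       beta_med = if (mediator) runif(k, -0.5, 0.5) else NULL,
       se_med = if (mediator) runif(k, 0.005, 0.05) else NULL)
}

# independent step-up BH oracle, straight from the definition
bh_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  adjusted <- numeric(m)
  for (i in seq_len(m)) {
    adjusted[o[i]] <- min(vapply(i:m, function(j)
      min(1, m * p[o[j]] / j), 0.0))
  }
  list(adjusted = adjusted, reject = adjusted < alpha)
}

# weighted-median oracle: explicit search for the bracketing pair of
# cumulative percentiles
wm_oracle <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]
  ww <- w[o] / sum(w)
  p <- cumsum(ww) - ww / 2
  n <- length(th)
  if (0.5 <= p[1]) return(th[1])
  if (0.5 >= p[n]) return(th[n])
  for (i in seq_len(n - 1)) {
    if (p[i] <= 0.5 && 0.5 <= p[i + 1]) {
      return(th[i] + (th[i + 1] - th[i]) * (0.5 - p[i]) / (p[i + 1] - p[i]))
    }
  }
  stop("unreachable")
}

# exposure sumstats rebuilt from the harmonised (oriented) columns
subset_oriented <- function(exposure, h) {
  mk_ss(h$variant_id, h$effect_allele, h$other_allele, beta = h$beta_exp,
        se = h$se_exp, eaf = h$eaf, chromosome = h$chromosome,
        position = h$position)
}

# a sumstats object with one variant removed
subset_oriented_drop <- function(s, id) {
  suppressMessages(sumstats(
    as.data.frame(s)[s$variant_id != id, , drop = FALSE],
    trait_id = attr(s, "trait_id")))
}
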