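# FDR screening, bidirectionality classification, study orchestration.

test_that("bh_fdr reproduces the step-up procedure", {
  f <- bh_fdr(c(0.001, 0.02, 0.03, 0.5), alpha = 0.05)
  expect_equal(f$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(f$adjusted, c(0.004, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(rep(1, 5))$reject, rep(FALSE, 5))
  expect_true(bh_fdr(0.04, 0.05)$reject)
  expect_equal(bh_fdr(numeric(0))$adjusted, numeric(0))
})

test_that("bh_fdr matches the brute-force oracle on random lists", {
  set.seed(61)
  for (rep in 1:50) {
    p <- runif(sample(1:10, 1))
    f <- bh_fdr(p, 0.05)
    o <- bh_oracle(p, 0.05)
    expect_equal(f$adjusted, o$adjusted)
    expect_equal(f$reject, o$reject)
  }
})

test_that("bh_fdr rejections are monotone in alpha", {
  set.seed(62)
  for (rep in 1:20) {
    p <- runif(8)
    r1 <- bh_fdr(p, 0.01)$reject
    r2 <- bh_fdr(p, 0.05)$reject
    r3 <- bh_fdr(p, 0.2)$reject
    expect_true(all(r2[r1]))
    expect_true(all(r3[r2]))
    expect_true(all(bh_fdr(p)$adjusted >= p))
  }
})

test_that("classify_bidirectional maps the truth table", {
  expect_equal(classify_bidirectional(TRUE, FALSE), "cause-only")
  expect_equal(classify_bidirectional(FALSE, TRUE), "consequence-only")
  expect_equal(classify_bidirectional(TRUE, TRUE), "bidirectional")
  expect_equal(classify_bidirectional(FALSE, FALSE), "neither")
})

test_that("stage2_eligibility applies the three-condition rule", {
  ev <- data.frame(
    trait_id = rep(c("a", "b", "c"), each = 4),
    family = rep(c("trait->mediator", "mediator->trait", "trait->cad",
                   "trait->pad"), 3),
    supportive = c(TRUE, FALSE, TRUE, FALSE,    # a: cause, CAD only
                   TRUE, TRUE, TRUE, TRUE,      # b: bidirectional
                   TRUE, FALSE, FALSE, FALSE),  # c: cause, no outcome
    stringsAsFactors = FALSE)
  a <- stage2_eligibility(ev, "a", c("cad", "pad"))
  expect_true(a$stage2_cad)
  expect_false(a$stage2_pad)
  expect_equal(a$category, "cause-only")
  b <- stage2_eligibility(ev, "b", c("cad", "pad"))
  expect_false(b$stage2_cad)
  expect_false(b$stage2_pad)
  expect_true(b$bidirectional)
  c_ <- stage2_eligibility(ev, "c", c("cad", "pad"))
  expect_false(c_$stage2_cad || c_$stage2_pad)
  expect_error(stage2_eligibility(ev[-1, ], "a", c("cad", "pad")),
               "incomplete")
})

test_that("a bidirectional trait appears in stage 1 but not stage 2", {
  study_data <- simulate_screening_study(
    trait_specs = list(
      good = list(n_snps = 30, beta_XM = 0.3, reverse_MX = 0,
                  theta = c(out = 0.3)),
      bidir = list(n_snps = 30, beta_XM = 0.3, reverse_MX = 0.3,
                   theta = c(out = 0.3))),
    outcome_theta_M = c(out = 0.5),
    seed = 63)
  res <- run_study(study_data$traits, study_data$mediator,
                   study_data$outcomes,
                   study_config(methods = "ivw", seed = 63))
  expect_setequal(unique(res$stage1$trait_id), c("good", "bidir"))
  d <- res$decisions
  expect_equal(d$category[d$trait_id == "bidir"], "bidirectional")
  expect_true(d$stage2_out[d$trait_id == "good"])
  expect_false(d$stage2_out[d$trait_id == "bidir"])
  expect_equal(res$mediation_results$trait_id, "good")
  # stage-2 flags never true when the forward evidence is not supportive
  fwd <- res$stage1[res$stage1$family == "trait->mediator", ]
  for (tn in d$trait_id) {
    if (!fwd$supportive[fwd$trait_id == tn]) {
      expect_false(d$stage2_out[d$trait_id == tn])
    }
  }
})

test_that("mediation output agrees with the simulated truth", {
  study_data <- simulate_screening_study(
    trait_specs = list(
      tr = list(n_snps = 40, beta_XM = 0.3, reverse_MX = 0,
                theta = c(out = 0.2))),
    outcome_theta_M = c(out = 0.5),
    n_gwas = 1e5, seed = 64)
  res <- run_study(study_data$traits, study_data$mediator,
                   study_data$outcomes,
                   study_config(methods = "ivw", seed = 64))
  m <- res$mediation_results
  expect_equal(nrow(m), 1)
  truth <- study_data$truth$tr
  expect_lt(abs(m$total - truth$total[["out"]]), 0.05)
  expect_lt(abs(m$indirect - truth$indirect[["out"]]), 0.05)
  expect_lt(abs(m$proportion_mediated -
                  truth$proportion_mediated[["out"]]), 0.1)
  mv <- res$mvmr_results
  expect_true(mv$f_trait > 0 && mv$f_mediator > 0)
  expect_equal(mv$q_a_df, mv$n_variants - 2)
})

test_that("rerunning with the same seed writes byte-identical outputs", {
  study_data <- simulate_screening_study(
    trait_specs = list(
      tr = list(n_snps = 25, beta_XM = 0.3, reverse_MX = 0,
                theta = c(out = 0.2))),
    outcome_theta_M = c(out = 0.5),
    seed = 65)
  cfg <- study_config(n_boot = 50, seed = 65)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_study(study_data$traits, study_data$mediator,
                  study_data$outcomes, cfg, out_dir = d1)
  r2 <- run_study(study_data$traits, study_data$mediator,
                  study_data$outcomes, cfg, out_dir = d2)
  for (f in c("stage1_evidence.tsv", "stage_decisions.tsv",
              "mvmr_results.tsv", "mediation_results.tsv")) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  }
  expect_equal(r1$manifest$files, r2$manifest$files)
})

test_that("estimation failures are recorded per trait without aborting", {
  study_data <- simulate_screening_study(
    trait_specs = list(
      ok = list(n_snps = 25, beta_XM = 0.3, reverse_MX = 0,
                theta = c(out = 0.2)),
      weak = list(n_snps = 5, beta_XM = 0.3, reverse_MX = 0,
                  theta = c(out = 0.2))),
    outcome_theta_M = c(out = 0.5),
    seed = 66)
  res <- run_study(study_data$traits, study_data$mediator,
                   study_data$outcomes,
                   study_config(methods = "ivw", seed = 66))
  ev <- res$stage1
  expect_false(any(ev$eligible[ev$trait_id == "weak" &
                                 ev$family == "trait->mediator"]))
  expect_true(any(grepl("ineligible", res$manifest$warnings)))
  expect_false("weak" %in% res$mediation_results$trait_id)
})
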