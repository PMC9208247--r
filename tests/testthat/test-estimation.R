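test_that("quadrature marginal likelihood matches brute-force enumeration", {
  bank <- tiny_bank()
  grid <- theta_grid()
  en <- enumerate_patterns(bank, grid)
  ## feed every pattern once; the fitted engine's E-step marginal must agree
  d <- response_matrix(en$patterns, n_cat = 3L)
  cp <- bsasirt:::collapse_patterns(d)
  plist <- bsasirt:::item_prob_list(
    vapply(bank$items, `[[`, numeric(1), "slope"),
    lapply(bank$items, `[[`, "thresholds"), grid$nodes)
  es <- bsasirt:::estep_patterns(cp$patterns, cp$counts, plist, grid$weights)
  key_fit <- do.call(paste, c(as.data.frame(cp$patterns), sep = ","))
  key_or <- do.call(paste, c(as.data.frame(en$patterns), sep = ","))
  expect_equal(es$marginal[match(key_or, key_fit)], en$marginal,
               tolerance = 1e-10)
  expect_equal(sum(en$marginal), 1, tolerance = 1e-10)
})

test_that("the EM log-likelihood never decreases across cycles", {
  spec <- cohort_spec(group_sizes = c(all = 400), latent_means = c(all = 0),
                      seed = 402)
  fit <- fit_grm(simulate_cohort(spec), control = quick_control(se = FALSE))
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("GRM estimation recovers the generating parameters", {
  spec <- cohort_spec(group_sizes = c(all = 2000), latent_means = c(all = 0),
                      missing_rates = 0, seed = 515)
  d <- simulate_cohort(spec)
  fit <- fit_grm(d, control = grm_control(se = FALSE))
  expect_true(fit$converged)
  a_hat <- vapply(fit$bank$items, `[[`, numeric(1), "slope")
  b_hat <- t(vapply(fit$bank$items, `[[`, numeric(4), "thresholds"))
  expect_lt(mean(abs(a_hat - published_slopes)), 0.35)
  expect_lt(mean(abs(b_hat - published_thresholds)), 0.20)
})

test_that("estimation is invariant to respondent and item order", {
  spec <- cohort_spec(group_sizes = c(all = 300), latent_means = c(all = 0),
                      missing_rates = 0, seed = 88)
  d <- simulate_cohort(spec)
  ctl <- grm_control(se = FALSE)
  fit <- fit_grm(d, control = ctl)
  ## respondent shuffle
  set.seed(1); perm <- sample(nrow(d$responses))
  d2 <- response_matrix(d$responses[perm, ])
  fit2 <- fit_grm(d2, control = ctl)
  expect_equal(param_table(fit)$slope, param_table(fit2)$slope,
               tolerance = 1e-3)
  ## item shuffle (estimates follow the relabeling)
  jp <- c(3, 1, 7, 2, 5, 6, 4)
  d3 <- response_matrix(d$responses[, jp])
  fit3 <- fit_grm(d3, control = ctl)
  expect_equal(param_table(fit3)$slope, param_table(fit)$slope[jp],
               tolerance = 1e-3)
})

test_that("missingness is skipped in the likelihood, barely moving estimates", {
  base <- cohort_spec(group_sizes = c(all = 1500), latent_means = c(all = 0),
                      missing_rates = 0, seed = 77)
  holey <- cohort_spec(group_sizes = c(all = 1500), latent_means = c(all = 0),
                       missing_rates = 0.02, seed = 77)
  ctl <- grm_control(se = FALSE)
  f1 <- fit_grm(simulate_cohort(base), control = ctl)
  f2 <- fit_grm(simulate_cohort(holey), control = ctl)
  delta <- abs(c(param_table(f1)$slope - param_table(f2)$slope,
                 unlist(lapply(1:7, function(j)
                   f1$bank$items[[j]]$thresholds - f2$bank$items[[j]]$thresholds))))
  expect_lt(mean(delta), 0.1)
})

test_that("degenerate items are rejected with the item named", {
  m <- matrix(sample(0:4, 300, TRUE), 100, 3)
  m[, 2] <- 1L
  d <- response_matrix(m, item_labels = c("ok1", "stuck", "ok2"))
  expect_error(suppressWarnings(fit_grm(d)), "stuck")
})

test_that("the equal-slope restriction is nested in the free model", {
  spec <- cohort_spec(group_sizes = c(all = 500), latent_means = c(all = 0),
                      missing_rates = 0, seed = 99)
  d <- simulate_cohort(spec)
  ctl <- quick_control(se = FALSE)
  full <- fit_grm(d, control = ctl)
  rasch <- fit_rasch(d, control = ctl)
  a <- vapply(rasch$bank$items, `[[`, numeric(1), "slope")
  expect_equal(max(a) - min(a), 0)
  expect_lte(rasch$loglik, full$loglik + 1e-6)
  expect_equal(full$n_params - rasch$n_params, 6L)
  fixed <- fit_rasch(d, control = ctl, constraint = "fixed")
  expect_equal(full$n_params - fixed$n_params, 7L)
  cmp <- lr_compare(rasch, full)
  expect_gte(cmp$delta_chi2, 0)
  expect_equal(cmp$df, 6L)
  expect_equal(cmp$delta_chi2, 2 * (full$loglik - rasch$loglik),
               tolerance = 1e-8)
  ## information criteria follow their definitions
  expect_equal(full$aic, -2 * full$loglik + 2 * full$n_params)
  expect_equal(full$bic, -2 * full$loglik + full$n_params * log(full$n_used))
  expect_error(lr_compare(full, rasch), "fewer parameters")
})

test_that("identical fits compare with zero chi-square and p of one", {
  spec <- cohort_spec(group_sizes = c(all = 200), latent_means = c(all = 0),
                      missing_rates = 0, seed = 5)
  d <- simulate_cohort(spec)
  f <- fit_grm(d, control = quick_control(se = FALSE))
  cmp <- lr_compare(f, f)
  expect_equal(cmp$delta_chi2, 0)
  expect_equal(cmp$p, 1)
  ## different data are refused
  spec2 <- cohort_spec(group_sizes = c(all = 201), latent_means = c(all = 0),
                       missing_rates = 0, seed = 5)
  f2 <- fit_grm(simulate_cohort(spec2), control = quick_control(se = FALSE))
  expect_error(lr_compare(f, f2), "same data")
})

test_that("standard errors are finite, positive and shrink with sample size", {
  ctl <- grm_control()
  spec_small <- cohort_spec(group_sizes = c(all = 500),
                            latent_means = c(all = 0), missing_rates = 0,
                            seed = 313)
  spec_big <- cohort_spec(group_sizes = c(all = 2000),
                          latent_means = c(all = 0), missing_rates = 0,
                          seed = 313)
  f_small <- fit_grm(simulate_cohort(spec_small), control = ctl)
  f_big <- fit_grm(simulate_cohort(spec_big), control = ctl)
  for (f in list(f_small, f_big)) {
    expect_true(all(is.finite(f$se_bank$slope)))
    expect_true(all(f$se_bank$slope > 0))
    expect_true(all(is.finite(unlist(f$se_bank$thresholds))))
  }
  ratio <- f_small$se_bank$slope / f_big$se_bank$slope
  expect_true(all(ratio > 1.2))
  expect_equal(mean(ratio), 2, tolerance = 0.5)
  ## published slope standard errors are of the magnitude seen at N ~ 970
  spec_n968 <- cohort_spec(seed = 968)
  f968 <- fit_grm(simulate_cohort(spec_n968), control = ctl)
  expect_gt(f968$se_bank$slope[1], 0.17 / 2)
  expect_lt(f968$se_bank$slope[1], 0.17 * 2)
})

test_that("response files round-trip and the 1-5 recode matches pre-recoded data", {
  spec <- cohort_spec(group_sizes = c(f = 60, m = 40),
                      latent_means = c(f = 0, m = 0), seed = 21)
  d <- simulate_cohort(spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(d, path)
  back <- read_responses(path)
  expect_equal(back$responses, d$responses)
  expect_equal(back$groups, d$groups)
  ## shift codes to 1..5 and read with the recode flag
  shifted <- d$responses + 1L
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(cbind(as.data.frame(shifted), group = d$groups), path2,
                     sep = ",", row.names = FALSE, quote = FALSE)
  back2 <- read_responses(path2, recode_1_5 = TRUE)
  expect_equal(back2$responses, d$responses, ignore_attr = TRUE)
  suppressWarnings(
    expect_error(read_responses(withr::local_tempfile(fileext = ".csv"))))
})
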