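test_that("summed-score likelihoods reduce to category probabilities for one item", {
  bank <- one_item_bank()
  th <- c(-1, 0.3, 2)
  S <- score_likelihoods(bank, th)
  expect_equal(unname(S), unname(category_probs(bank$items[[1]], th)))
})

test_that("the recursion matches brute-force pattern enumeration", {
  bank <- tiny_bank()
  grid <- theta_grid()
  for (th in c(-1.7, 0, 0.9)) {
    S <- score_likelihoods(bank, th)
    ## enumerate all 27 patterns at this theta
    pats <- as.matrix(expand.grid(lapply(bank$items, function(it)
      0:(it$K - 1L))))
    lik <- vapply(seq_len(nrow(pats)), function(i) {
      prod(vapply(seq_along(bank$items), function(j)
        category_probs(bank$items[[j]], th)[pats[i, j] + 1L], numeric(1)))
    }, numeric(1))
    oracle <- vapply(0:max_score(bank), function(s)
      sum(lik[rowSums(pats) == s]), numeric(1))
    expect_equal(unname(S), oracle, tolerance = 1e-12)
    expect_equal(sum(S), 1, tolerance = 1e-12)
  }
  ## extreme theta piles all mass on the top score
  expect_equal(unname(score_likelihoods(bank, 40)),
               c(rep(0, max_score(bank)), 1), tolerance = 1e-10)
})

test_that("recursion/enumeration equivalence holds for random small banks", {
  set.seed(11)
  for (r in 1:20) {
    J <- sample(2:4, 1)
    bank <- item_bank(lapply(seq_len(J), function(j)
      item_params(paste0("i", j), runif(1, 0.4, 2.5),
                  sort(runif(sample(1:3, 1), -2, 2)))))
    th <- rnorm(1)
    S <- score_likelihoods(bank, th)
    pats <- as.matrix(expand.grid(lapply(bank$items, function(it)
      0:(it$K - 1L))))
    lik <- vapply(seq_len(nrow(pats)), function(i)
      prod(vapply(seq_len(J), function(j)
        category_probs(bank$items[[j]], th)[pats[i, j] + 1L], numeric(1))),
      numeric(1))
    oracle <- vapply(0:max_score(bank), function(s)
      sum(lik[rowSums(pats) == s]), numeric(1))
    expect_equal(unname(S), oracle, tolerance = 1e-12)
  }
})

test_that("score tables have increasing EAPs and normalized proportions", {
  tab <- build_score_table(bsas_bank())
  expect_s3_class(tab, "score_table")
  expect_equal(nrow(tab), 29L)
  expect_true(all(diff(tab$eap) > 0))
  expect_true(all(tab$sd > 0))
  expect_equal(sum(tab$modelled_proportion), 1, tolerance = 1e-10)
  expect_true(attr(tab, "monotone_eap"))
  ## equal slopes make the summed score a monotone-likelihood-ratio
  ## statistic, so EAP monotonicity is guaranteed there
  set.seed(23)
  for (r in 1:15) {
    a <- runif(1, 0.4, 2.5)
    bank <- item_bank(lapply(1:4, function(j)
      item_params(paste0("i", j), a, sort(runif(3, -2.5, 2.5)))))
    tb <- build_score_table(bank)
    expect_true(all(diff(tb$eap) > 0))
    expect_equal(sum(tb$modelled_proportion), 1, tolerance = 1e-10)
  }
  ## heterogeneous-slope banks: proportions always normalized, EAP
  ## monotone in the large majority of draws
  mono <- vapply(1:40, function(r) {
    bank <- item_bank(lapply(1:5, function(j)
      item_params(paste0("i", j), runif(1, 0.9, 2.6),
                  sort(runif(4, -2.2, 2.4)))))
    tb <- build_score_table(bank)
    expect_equal(sum(tb$modelled_proportion), 1, tolerance = 1e-10)
    attr(tb, "monotone_eap")
  }, logical(1))
  expect_gte(mean(mono), 0.85)
})

test_that("a symmetric bank yields an antisymmetric EAP column", {
  tab <- build_score_table(symmetric_bank())
  expect_equal(tab$eap, -rev(tab$eap), tolerance = 1e-10)
  expect_equal(tab$modelled_proportion, rev(tab$modelled_proportion),
               tolerance = 1e-10)
})

test_that("cut-offs pick the smallest score reaching each band", {
  tab <- build_score_table(bsas_bank())
  cuts <- derive_cutoffs(tab, bands = c(0, 1, 2))
  for (i in seq_len(nrow(cuts))) {
    s <- cuts$score[i]
    expect_gte(tab$eap[tab$summed_score == s], cuts$band[i])
    if (s > 0)
      expect_lt(tab$eap[tab$summed_score == s - 1], cuts$band[i])
  }
  ## unattainable band is reported, not thrown
  far <- derive_cutoffs(tab, bands = 10)
  expect_true(is.na(far$score))
  expect_false(attr(far, "attainable"))
})

test_that("pattern EAP agrees with the score table on single-pattern scores", {
  bank <- bsas_bank()
  tab <- build_score_table(bank)
  lo <- pattern_eap(bank, rep(0L, 7))
  hi <- pattern_eap(bank, rep(4L, 7))
  expect_equal(lo$eap, tab$eap[1], tolerance = 1e-6)
  expect_equal(lo$sd, tab$sd[1], tolerance = 1e-6)
  expect_equal(hi$eap, tab$eap[29], tolerance = 1e-6)
  ## flat likelihood limit: posterior reverts to the prior
  flat <- item_bank(item_params("f", 1e-8, c(-1, 0, 1, 2)))
  pe <- pattern_eap(flat, 2L)
  expect_equal(pe$eap, 0, tolerance = 1e-6)
  expect_equal(pe$sd, 1, tolerance = 0.01)
  expect_error(pattern_eap(bank, rep(NA_integer_, 7)), "missing")
})

test_that("classification cuts summed scores into bands and compares groups", {
  bank <- bsas_bank()
  cuts <- derive_cutoffs(build_score_table(bank), c(1, 2))
  ## everyone at the top score is high risk
  all_max <- response_matrix(matrix(4L, 20, 7),
                             groups = rep(c("a", "b"), 10))
  cl <- classify(all_max, cuts)
  expect_true(all(cl$respondents$band == "high"))
  ## two identical groups show no high-risk difference
  set.seed(9)
  spec <- cohort_spec(group_sizes = c(a = 300, b = 300),
                      latent_means = c(a = 0, b = 0), missing_rates = 0,
                      seed = 303)
  cl2 <- classify(simulate_cohort(spec), cuts)
  expect_gt(cl2$high_risk_test$p, 0.01)
  ## missing rows are excluded unless pattern_eap policy is chosen
  m <- matrix(2L, 5, 7); m[1, 3] <- NA_integer_
  rm5 <- response_matrix(m)
  cl3 <- classify(rm5, cuts)
  expect_true(is.na(cl3$respondents$band[1]))
  cl4 <- classify(rm5, cuts, policy = "pattern_eap", bank = bank)
  expect_false(is.na(cl4$respondents$band[1]))
})

test_that("the modelled high-risk tail matches the score-table sum", {
  tab <- build_score_table(bsas_bank())
  cut <- derive_cutoffs(tab, 2)$score
  tail_mass <- sum(tab$modelled_proportion[tab$summed_score >= cut])
  ## population mass beyond the +2SD raw cut is a few percent
  expect_gt(tail_mass, 0.001)
  expect_lt(tail_mass, 0.09)
  ## a large simulated cohort realizes the same tail frequency
  spec <- cohort_spec(group_sizes = c(all = 20000), latent_means = c(all = 0),
                      missing_rates = 0, seed = 71)
  d <- simulate_cohort(spec)
  frac <- mean(rowSums(d$responses) >= cut)
  expect_lt(abs(frac - tail_mass), 0.01)
})
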