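test_that("boundary probabilities follow the cumulative logistic", {
  it <- item_params("salience", 1.55, c(-1.32, -0.11, 0.56, 1.83))
  ## high-precision evaluation of the logistic formula
  expect_equal(boundary_prob(it, 1, 0), 1 / (1 + exp(-1.55 * 1.32)),
               tolerance = 1e-12)
  expect_equal(round(boundary_prob(it, 1, 0), 3), 0.886)
  ## logistic symmetry: P* = 0.5 at the threshold
  for (k in 1:4) expect_equal(boundary_prob(it, k, it$thresholds[k]), 0.5)
  expect_equal(boundary_prob(it, 1, -50), 0, tolerance = 1e-12)
  expect_error(boundary_prob(it, 5, 0), "1..4")
  expect_error(boundary_prob(it, 0, 0), "1..4")
})

test_that("category probabilities are differences of boundary curves", {
  it <- item_params("salience", 1.55, c(-1.32, -0.11, 0.56, 1.83))
  p <- category_probs(it, 0)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(unname(p), c(0.114, 0.344, 0.247, 0.240, 0.056),
               tolerance = 3e-3)
  expect_equal(unname(category_probs(it, 50)), c(0, 0, 0, 0, 1),
               tolerance = 1e-10)
  ## oracle: direct differences of boundary probabilities
  th <- 0.37
  ps <- c(1, vapply(1:4, boundary_prob, numeric(1), item = it, theta = th), 0)
  expect_equal(unname(category_probs(it, th)), -diff(ps), tolerance = 1e-12)
})

test_that("category probabilities sum to one across random items and thetas", {
  set.seed(42)
  for (i in 1:200) {
    K <- sample(2:6, 1)
    it <- item_params("r", runif(1, 0.2, 4),
                      sort(rnorm(K - 1, sd = 1.5)) + cumsum(rep(1e-3, K - 1)))
    th <- rnorm(5, sd = 2)
    p <- category_probs(it, th)
    if (is.null(dim(p))) p <- matrix(p, ncol = 1)
    expect_equal(colSums(p), rep(1, length(th)), tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("item information matches the negative second derivative of the expected log-likelihood", {
  ## Fisher information oracle: I(theta) = sum_k P_k (d log P_k / d theta)^2
  ## evaluated by central finite differences on log P_k
  set.seed(7)
  for (i in 1:20) {
    it <- item_params("r", runif(1, 0.5, 3), sort(runif(4, -2, 2.5)))
    th <- rnorm(1)
    h <- 1e-4
    lp_plus <- log(category_probs(it, th + h))
    lp_minus <- log(category_probs(it, th - h))
    dlogp <- (lp_plus - lp_minus) / (2 * h)
    oracle <- sum(category_probs(it, th) * dlogp^2)
    expect_equal(item_information(it, th), oracle, tolerance = 1e-4)
  }
})

test_that("information vanishes with the slope and is never negative", {
  it <- item_params("flat", 1e-6, c(-1, 0, 1))
  expect_lt(max(item_information(it, seq(-3, 3, 0.5))), 1e-10)
  it2 <- item_params("steep", 4, c(0, 0.5, 1))
  expect_true(all(item_information(it2, seq(-4, 4, 0.25)) >= 0))
})

test_that("test information adds the prior and expected SE is its reciprocal root", {
  bank <- bsas_bank()
  th <- c(-2, 0, 1.4)
  item_sum <- rowSums(vapply(bank$items, item_information, numeric(3),
                             theta = th))
  expect_equal(test_information(bank, th), item_sum + 1)
  expect_equal(test_information(bank, th, prior_information = 0), item_sum)
  expect_equal(expected_sem(c(1, 4, 13.03)),
               c(1, 0.5, 1 / sqrt(13.03)))
  expect_equal(round(expected_sem(13.03), 2), 0.28)
  expect_equal(round(expected_sem(14.30), 2), 0.26)
  expect_error(expected_sem(0), "positive")
  expect_error(expected_sem(-2), "positive")
})

test_that("intercept conversion matches -slope * threshold and round-trips", {
  bank <- bsas_bank()
  it1 <- bank$items[[1]]
  expect_equal(round(to_intercepts(it1)[1], 2), 2.05)
  for (it in bank$items) {
    ci <- to_intercepts(it)
    expect_true(all(diff(ci) < 0))
    back <- from_intercepts(it$label, it$slope, ci, component = it$component)
    expect_equal(back$thresholds, it$thresholds, tolerance = 1e-12)
  }
  ## thresholds at zero give intercepts at zero
  expect_equal(to_intercepts(item_params("z", 2, c(-1e-12, 1e-12))),
               c(2e-12, -2e-12))
})

test_that("the test characteristic curve is the summed expected item score", {
  bank <- bsas_bank()
  th <- seq(-2.8, 2.8, by = 0.4)
  tcc <- expected_score_curve(bank, th)
  ## direct-summation oracle
  oracle <- vapply(th, function(t0)
    sum(vapply(bank$items, function(it)
      sum((0:(it$K - 1)) * category_probs(it, t0)), numeric(1))), numeric(1))
  expect_equal(tcc, oracle, tolerance = 1e-12)
  expect_true(all(diff(tcc) > 0))
  expect_lt(expected_score_curve(bank, -12), 1e-4)
  expect_gt(expected_score_curve(bank, 12), 28 - 1e-4)
})

test_that("curve tables stack ICC/IIF/TCC/TIF/SE in long format", {
  bank <- tiny_bank()
  ct <- curve_table(bank, thetas = c(-1, 0, 1))
  expect_named(ct, c("theta", "item", "quantity", "value"))
  expect_setequal(unique(ct$quantity[ct$item == "test"]),
                  c("tcc", "tif", "se"))
  icc <- ct[ct$quantity == "icc_cat0" & ct$item == "t1", ]
  expect_equal(icc$value, category_probs(bank$items[[1]], c(-1, 0, 1))[1, ],
               ignore_attr = TRUE)
  se <- ct[ct$quantity == "se", "value"]
  tif <- ct[ct$quantity == "tif", "value"]
  expect_equal(se, 1 / sqrt(tif))
})
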